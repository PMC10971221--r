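#' Log-transform raw peak areas
#'
#' Mass-spectral peak areas span several orders of magnitude; the log
#' transform compresses the dynamic range so that donor-space geometry is
#' not dominated by a handful of very abundant proteins. Non-positive raw
#' values cannot be log-transformed and are handled by policy:
#'
#' * `"drop_protein"` (default): remove the whole protein; a protein whose
#'   peak area is not positive in every measured cell is treated as not
#'   analyzable rather than imputed.
#' * `"drop_cell"`: blank only the offending cell (`NA`); the protein then
#'   emits no donor-space point for conditions with an incomplete donor
#'   vector.
#' * `"epsilon_floor"`: replace `v <= 0` by `epsilon` before the log.
#'
#' Missing input cells (`NA`) follow the same policy (they cannot be
#' floored, so under `"epsilon_floor"` they are blanked like
#' `"drop_cell"`). Every removal is recorded in `dropped`.
#'
#' @param table an [abundance_table()].
#' @param base log base: `2` (default, so downstream log fold changes read
#'   in doublings), `10`, or `exp(1)`.
#' @param nonpositive_policy see above.
#' @param epsilon positive floor used by `"epsilon_floor"`.
#' @return A `log_abundance_table` (inherits `abundance_table`): values in
#'   log units, plus `log_base`, a `dropped` data.frame of
#'   (accession, reason), and the `raw_values` of retained proteins (used
#'   by [select_primary_cluster()]'s all-positive rule).
#' @examples
#' tab <- generate_table(synthetic_spec(n_proteins = 10))$table
#' lt <- log_transform(tab)
#' lt$log_base
#' @export
log_transform <- function(table, base = 2,
                          nonpositive_policy = c("drop_protein", "drop_cell",
                                                 "epsilon_floor"),
                          epsilon = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  nonpositive_policy <- match.arg(nonpositive_policy)
  if (is.character(base) && base %in% c("e", "ln")) base <- exp(1)
  if (!isTRUE(base %in% c(2, 10)) && !isTRUE(all.equal(base, exp(1)))) {
    stop("base must be 2, 10 or exp(1)")
  }
  if (nonpositive_policy == "epsilon_floor") {
    if (is.null(epsilon) || !is.numeric(epsilon) || epsilon <= 0) {
      stop("epsilon_floor requires epsilon > 0")
    }
  }
  vals <- table$values
  nonpos <- !is.na(vals) & vals <= 0
  missing <- is.na(vals)
  dropped <- data.frame(accession = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(vals))
  if (nonpositive_policy == "drop_protein") {
    bad <- rowSums(nonpos) > 0 | rowSums(missing) > 0
    keep <- !bad
    if (any(bad)) {
      reason <- ifelse(rowSums(nonpos)[bad] > 0,
                       "non-positive peak area", "missing value")
      dropped <- data.frame(accession = rownames(vals)[bad], reason = reason,
                            stringsAsFactors = FALSE)
    }
  } else if (nonpositive_policy == "drop_cell") {
    vals[nonpos] <- NA_real_
    affected <- rowSums(nonpos | missing) > 0
    if (any(affected)) {
      dropped <- data.frame(
        accession = rownames(vals)[affected],
        reason = sprintf("%d cell(s) non-positive or missing",
                         rowSums(nonpos | missing)[affected]),
        stringsAsFactors = FALSE)
    }
  } else { # epsilon_floor
    vals[nonpos] <- epsilon
    affected <- rowSums(nonpos) > 0
    if (any(affected)) {
      dropped <- data.frame(
        accession = rownames(vals)[affected],
        reason = sprintf("%d cell(s) floored to epsilon",
                         rowSums(nonpos)[affected]),
        stringsAsFactors = FALSE)
    }
    if (any(missing)) {
      miss_rows <- rowSums(missing) > 0
      dropped <- rbind(dropped, data.frame(
        accession = rownames(vals)[miss_rows],
        reason = "missing value (cell blanked)", stringsAsFactors = FALSE))
    }
  }
  logvals <- log(vals[keep, , drop = FALSE], base = base)
  out <- abundance_table(logvals, table$proteins[keep, , drop = FALSE],
                         table$donors, table$conditions)
  out$log_base <- base
  out$dropped <- dropped
  out$raw_values <- table$values[keep, , drop = FALSE]
  class(out) <- c("log_abundance_table", class(out))
  out
}

#' Donor-space points for one condition
#'
#' Each retained protein becomes one point whose coordinates are its log
#' abundances in the D donors (in the table's donor order); these points
#' are what the density filter clusters, the isolation forest scores, and
#' the Euclidean displacement measures. Proteins with an incomplete donor
#' vector in `condition` emit no point.
#'
#' @param logtable a [log_transform()] result.
#' @param condition one condition label present in the table.
#' @return A `donor_points` data.frame: columns `accession`, `condition`,
#'   then one coordinate column per donor; attribute `donors` names the
#'   coordinate columns.
#' @export
donor_points <- function(logtable, condition) {
  stopifnot(inherits(logtable, "log_abundance_table"))
  if (!condition %in% logtable$conditions) {
    stop("unknown condition '", condition, "'; available: ",
         paste(logtable$conditions, collapse = ", "))
  }
  keys <- paste(logtable$donors, condition, sep = ":")
  coords <- logtable$values[, keys, drop = FALSE]
  complete <- rowSums(is.na(coords)) == 0
  coords <- coords[complete, , drop = FALSE]
  out <- data.frame(accession = rownames(coords),
                    condition = condition,
                    stringsAsFactors = FALSE)
  colnames(coords) <- logtable$donors
  out <- cbind(out, as.data.frame(coords))
  rownames(out) <- NULL
  attr(out, "donors") <- logtable$donors
  class(out) <- c("donor_points", "data.frame")
  out
}

#' Pool donor-space points across all conditions
#'
#' @param logtable a [log_transform()] result.
#' @param conditions conditions to pool (default: all in the table).
#' @return A `donor_points` data.frame stacking [donor_points()] of each
#'   condition.
#' @export
pool_donor_points <- function(logtable, conditions = logtable$conditions) {
  pts <- do.call(rbind, lapply(conditions, function(cc) {
    unclass_dp(donor_points(logtable, cc))
  }))
  attr(pts, "donors") <- logtable$donors
  class(pts) <- c("donor_points", "data.frame")
  pts
}

unclass_dp <- function(x) {
  class(x) <- "data.frame"
  attr(x, "donors") <- NULL
  x
}

#' Coordinate matrix of a set of donor-space points
#'
#' @param points a `donor_points` data.frame.
#' @return numeric matrix (points x donors).
#' @export
donor_coords <- function(points) {
  donors <- attr(points, "donors")
  if (is.null(donors)) donors <- setdiff(names(points), c("accession", "condition"))
  m <- as.matrix(points[, donors, drop = FALSE])
  rownames(m) <- paste(points$accession, points$condition, sep = "@")
  m
}
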
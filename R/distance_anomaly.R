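#' Specify a condition comparison
#'
#' @param reference reference condition label (e.g. `"ctrl"` or
#'   `"plast"`).
#' @param treatment treatment condition label (e.g. `"doped"`); must
#'   differ from `reference`.
#' @param experiment optional biomaterial/experiment label carried into
#'   outputs (e.g. `"SBA2"`).
#' @return A `comparison_spec` object.
#' @export
comparison_spec <- function(reference, treatment, experiment = NULL) {
  stopifnot(is.character(reference), is.character(treatment))
  if (identical(reference, treatment)) {
    stop("reference and treatment must differ")
  }
  structure(list(reference = reference, treatment = treatment,
                 experiment = experiment),
            class = "comparison_spec")
}

#' @export
print.comparison_spec <- function(x, ...) {
  cat(sprintf("<comparison> %s vs %s%s\n", x$reference, x$treatment,
              if (is.null(x$experiment)) "" else paste0(" [", x$experiment, "]")))
  invisible(x)
}

#' Euclidean distance between two donor-space points
#'
#' `sqrt(sum((p - q)^2))` — the straight-line displacement of one
#' protein's donor-space position between two conditions.
#'
#' @param p,q numeric vectors of equal length (log abundances per donor).
#' @return a single non-negative number.
#' @examples
#' euclidean_distance(c(0, 0, 0), c(1, 2, 2)) # 3
#' @export
euclidean_distance <- function(p, q) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (length(p) != length(q)) {
    stop("dimension mismatch: ", length(p), " vs ", length(q))
  }
  sqrt(sum((p - q)^2))
}

#' Per-protein cross-condition displacement and log fold change
#'
#' For each eligible accession, computes the Euclidean distance between
#' its donor-space points in the two conditions (the diagonal of the
#' cross-condition distance matrix) and the log fold change, defined as
#' the difference of mean log abundances (treatment minus reference) —
#' consistent with operating entirely in log space.
#'
#' @param logtable a [log_transform()] result.
#' @param eligible character vector of accessions (typically the
#'   intersection of [filter_to_cluster()] and [outlier_union()]).
#' @param comparison a [comparison_spec()].
#' @return A `distance_records` data.frame: `accession`, `d`, `logFC`;
#'   attribute `comparison`. Accessions lacking a complete donor vector in
#'   either condition are omitted; an empty eligible set yields an empty
#'   frame with a warning.
#' @export
comparison_distances <- function(logtable, eligible, comparison) {
  stopifnot(inherits(logtable, "log_abundance_table"),
            inherits(comparison, "comparison_spec"))
  ref_pts <- donor_points(logtable, comparison$reference)
  trt_pts <- donor_points(logtable, comparison$treatment)
  keep <- intersect(eligible, intersect(ref_pts$accession, trt_pts$accession))
  if (!length(keep)) {
    warning("empty eligible set for ", comparison$reference, " vs ",
            comparison$treatment, "; threshold undefined downstream")
  }
  ref_m <- donor_coords(ref_pts)[match(keep, ref_pts$accession), , drop = FALSE]
  trt_m <- donor_coords(trt_pts)[match(keep, trt_pts$accession), , drop = FALSE]
  diffs <- trt_m - ref_m
  out <- data.frame(
    accession = keep,
    d = sqrt(rowSums(diffs^2)),
    logFC = rowMeans(trt_m) - rowMeans(ref_m),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "comparison") <- comparison
  class(out) <- c("distance_records", "data.frame")
  out
}

#' Cross-condition distance matrix
#'
#' Full pairwise Euclidean distance matrix between the reference-condition
#' points (rows) and treatment-condition points (columns) of the eligible
#' accessions; its diagonal holds the per-protein displacements of
#' [comparison_distances()].
#'
#' @inheritParams comparison_distances
#' @return numeric matrix with accession dimnames.
#' @export
cross_condition_matrix <- function(logtable, eligible, comparison) {
  ref_pts <- donor_points(logtable, comparison$reference)
  trt_pts <- donor_points(logtable, comparison$treatment)
  keep <- intersect(eligible, intersect(ref_pts$accession, trt_pts$accession))
  ref_m <- donor_coords(ref_pts)[match(keep, ref_pts$accession), , drop = FALSE]
  trt_m <- donor_coords(trt_pts)[match(keep, trt_pts$accession), , drop = FALSE]
  m <- matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
  for (i in seq_along(keep)) {
    m[i, ] <- sqrt(colSums((t(trt_m) - ref_m[i, ])^2))
  }
  m
}

#' Threshold displacements at mean + k standard deviations
#'
#' The empirical anomaly rule: proteins whose displacement exceeds
#' `tau = mean(d) + k * sd(d)` over the whole eligible set are flagged as
#' extremely changing. Ties at exactly `tau` are not flagged (the rule is
#' strictly "above"). Records are returned sorted by descending distance,
#' the order of the sorted-distance bar plots.
#'
#' @param records a [comparison_distances()] result (>= 2 rows so the SD
#'   is defined).
#' @param k SD multiplier (default 1, the published cut-off; exposed
#'   because the cut-off level may reasonably be adjusted).
#' @param sd_ddof 1 (default) for the sample SD, 0 for the population SD.
#' @return An `anomaly_set`: list with `comparison`, `records` (sorted,
#'   with a logical `flagged` column), `tau`, `k`, `flagged` (accessions
#'   with `d > tau`).
#' @export
anomaly_threshold <- function(records, k = 1, sd_ddof = 1) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L) {
    stop("need at least 2 distance records to form a threshold")
  }
  if (!sd_ddof %in% c(0, 1)) stop("sd_ddof must be 0 or 1")
  cmp <- attr(records, "comparison")
  d <- records$d
  n <- length(d)
  s <- stats::sd(d)
  if (sd_ddof == 0) s <- s * sqrt((n - 1) / n)
  tau <- mean(d) + k * s
  ord <- order(-d, seq_len(n))
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  records$flagged <- records$d > tau
  structure(list(comparison = cmp,
                 records = records,
                 tau = tau,
                 k = k,
                 flagged = records$accession[records$flagged]),
            class = "anomaly_set")
}

#' @export
print.anomaly_set <- function(x, ...) {
  cmp <- x$comparison
  hdr <- if (is.null(cmp)) "" else paste0(cmp$reference, " vs ", cmp$treatment)
  cat(sprintf("<anomaly_set> %s: %d proteins, tau = %.4f (k = %g), %d flagged\n",
              hdr, nrow(x$records), x$tau, x$k, length(x$flagged)))
  if (length(x$flagged)) {
    cat("  flagged:", paste(utils::head(x$flagged, 10), collapse = ", "),
        if (length(x$flagged) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.anomaly_set <- function(x, ...) {
  data.frame(accession = x$records$accession,
             distance = x$records$d,
             threshold_flag = x$records$flagged,
             logFC = x$records$logFC,
             stringsAsFactors = FALSE)
}
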
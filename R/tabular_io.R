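#' Protein abundance tables
#'
#' An abundance table holds one row per protein (UniProt-style accession,
#' optional gene symbol and protein name) and one normalized mass-spectral
#' peak area per (donor, condition) pair. Donors must be identical across
#' conditions: the same-donor pairing is what makes the D-dimensional donor
#' space meaningful downstream. Missing values are kept as `NA`, never
#' silently dropped. Isoform accessions (e.g. `"P24821-4"`) are identities
#' distinct from their parent accession.
#'
#' @param values numeric matrix, one row per protein, one column per
#'   (donor, condition) pair named `"<donor>:<condition>"`; rownames are
#'   accessions.
#' @param proteins data.frame with columns `accession`, `gene`, `name`
#'   (gene/name may be empty strings), one row per row of `values`.
#' @param donors character vector of donor labels (length D >= 2).
#' @param conditions character vector of condition labels.
#' @return An object of class `abundance_table`: a list with elements
#'   `values`, `proteins`, `donors`, `conditions`.
#' @examples
#' vals <- matrix(2^rnorm(12, 20), nrow = 2,
#'                dimnames = list(c("P1", "P2"),
#'                                c(t(outer(c("d1", "d2", "d3"),
#'                                          c("ctrl", "doped"), paste, sep = ":")))))
#' abundance_table(vals, data.frame(accession = c("P1", "P2"),
#'                                  gene = "", name = ""),
#'                 donors = c("d1", "d2", "d3"),
#'                 conditions = c("ctrl", "doped"))
#' @export
abundance_table <- function(values, proteins, donors, conditions) {
  stopifnot(is.matrix(values), is.data.frame(proteins))
  donors <- as.character(donors)
  conditions <- as.character(conditions)
  if (length(donors) < 2L) {
    stop("at least two donors are required (donor space needs D >= 2)")
  }
  if (!all(c("accession", "gene", "name") %in% names(proteins))) {
    stop("'proteins' needs columns accession, gene, name")
  }
  acc <- as.character(proteins$accession)
  if (anyNA(acc) || any(!nzchar(acc))) stop("accessions must be non-empty")
  dup <- acc[duplicated(acc)]
  if (length(dup)) {
    stop("duplicate accession: ", paste(unique(dup), collapse = ", "))
  }
  want <- column_keys(donors, conditions)
  if (!setequal(colnames(values), want) || ncol(values) != length(want)) {
    stop("value columns must be exactly one '<donor>:<condition>' column ",
         "per donor x condition pair")
  }
  values <- values[, want, drop = FALSE]
  rownames(values) <- acc
  storage.mode(values) <- "double"
  structure(
    list(values = values,
         proteins = data.frame(accession = acc,
                               gene = as.character(proteins$gene),
                               name = as.character(proteins$name),
                               stringsAsFactors = FALSE),
         donors = donors,
         conditions = conditions),
    class = "abundance_table")
}

# Canonical column order: conditions vary slowest, donors fastest.
column_keys <- function(donors, conditions) {
  as.vector(vapply(conditions, function(cc) paste(donors, cc, sep = ":"),
                   character(length(donors))))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<%s> %d proteins x %d donors x %d conditions\n",
              class(x)[1], nrow(x$values), length(x$donors),
              length(x$conditions)))
  cat("  donors:     ", paste(x$donors, collapse = ", "), "\n")
  cat("  conditions: ", paste(x$conditions, collapse = ", "), "\n")
  n_na <- sum(is.na(x$values))
  if (n_na) cat("  missing cells:", n_na, "\n")
  invisible(x)
}

#' Read a protein abundance table
#'
#' Reads a wide or long delimited text file into an [abundance_table()].
#' Wide files have columns `accession`, `gene`, `name` (the latter two
#' optional) followed by one `"<donor>:<condition>"` column per measurement.
#' Long files have columns `accession`, `gene`, `name` (optional), `donor`,
#' `condition`, `abundance`. Empty cells and the literal `NA` are read as
#' missing; any other non-numeric cell is an error naming its coordinates.
#' Parsing is locale-independent with `"."` as the only decimal separator.
#'
#' @param path path to an existing file.
#' @param dialect one of `"wide_tsv"`, `"wide_csv"`, `"long_tsv"`.
#' @return An [abundance_table()] preserving the input protein order.
#' @export
read_abundance_table <- function(path,
                                 dialect = c("wide_tsv", "wide_csv", "long_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (dialect == "wide_csv") "," else "\t"
  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           colClasses = "character", na.strings = NULL,
                           quote = "\"", stringsAsFactors = FALSE)
  if (startsWith(dialect, "wide")) {
    parse_wide(raw, path)
  } else {
    parse_long(raw, path)
  }
}

parse_wide <- function(raw, path) {
  if (!"accession" %in% names(raw)) {
    stop("wide file must have an 'accession' column: ", path)
  }
  acc <- trimws(raw$accession)
  dup <- acc[duplicated(acc)]
  if (length(dup)) {
    stop("duplicate accession: ", paste(unique(dup), collapse = ", "))
  }
  id_cols <- intersect(c("accession", "gene", "name"), names(raw))
  meas_cols <- setdiff(names(raw), id_cols)
  if (!length(meas_cols)) stop("no '<donor>:<condition>' columns found")
  bad <- meas_cols[!grepl(":", meas_cols, fixed = TRUE)]
  if (length(bad)) {
    stop("measurement columns must be named '<donor>:<condition>'; offending: ",
         paste(bad, collapse = ", "))
  }
  parts <- strsplit(meas_cols, ":", fixed = TRUE)
  d_lab <- vapply(parts, `[`, character(1), 1L)
  c_lab <- vapply(parts, function(p) paste(p[-1L], collapse = ":"), character(1))
  donors <- unique(d_lab)
  conditions <- unique(c_lab)
  grid <- paste(rep(donors, times = length(conditions)),
                rep(conditions, each = length(donors)), sep = ":")
  if (!setequal(meas_cols, grid) || length(meas_cols) != length(grid)) {
    stop("ragged donor set across conditions: expected every donor x ",
         "condition pair exactly once; found {",
         paste(meas_cols, collapse = ", "), "}")
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(meas_cols),
                 dimnames = list(acc, meas_cols))
  for (cl in meas_cols) {
    cell <- trimws(raw[[cl]])
    miss <- cell %in% c("", "NA")
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric abundance '%s' at accession %s, column %s",
                   cell[bad[1L]], acc[bad[1L]], cl))
    }
    vals[, cl] <- num
  }
  gene <- if ("gene" %in% names(raw)) raw$gene else ""
  name <- if ("name" %in% names(raw)) raw$name else ""
  abundance_table(vals,
                  data.frame(accession = acc, gene = gene, name = name,
                             stringsAsFactors = FALSE),
                  donors = donors, conditions = conditions)
}

parse_long <- function(raw, path) {
  need <- c("accession", "donor", "condition", "abundance")
  if (!all(need %in% names(raw))) {
    stop("long file must have columns ", paste(need, collapse = ", "),
         ": ", path)
  }
  acc_col <- trimws(raw$accession)
  donors <- unique(trimws(raw$donor))
  conditions <- unique(trimws(raw$condition))
  acc <- unique(acc_col)
  key <- paste(trimws(raw$donor), trimws(raw$condition), sep = ":")
  grid <- column_keys(donors, conditions)
  dup <- duplicated(paste(acc_col, key))
  if (any(dup)) {
    stop("duplicate accession: ", paste(unique(acc_col[dup]), collapse = ", "),
         " (repeated donor/condition rows)")
  }
  vals <- matrix(NA_real_, nrow = length(acc), ncol = length(grid),
                 dimnames = list(acc, grid))
  present <- matrix(FALSE, nrow = length(acc), ncol = length(grid),
                    dimnames = list(acc, grid))
  cell <- trimws(raw$abundance)
  miss <- cell %in% c("", "NA")
  num <- suppressWarnings(as.numeric(cell))
  bad <- which(!miss & is.na(num))
  if (length(bad)) {
    stop(sprintf("non-numeric abundance '%s' at accession %s, column %s",
                 cell[bad[1L]], acc_col[bad[1L]], key[bad[1L]]))
  }
  for (i in seq_along(acc_col)) {
    vals[acc_col[i], key[i]] <- num[i]
    present[acc_col[i], key[i]] <- TRUE
  }
  if (!all(present)) {
    holes <- which(!present, arr.ind = TRUE)
    stop("ragged donor set across conditions: accession ",
         acc[holes[1L, 1L]], " lacks a row for ", grid[holes[1L, 2L]])
  }
  first <- !duplicated(acc_col)
  gene <- if ("gene" %in% names(raw)) raw$gene[first] else ""
  name <- if ("name" %in% names(raw)) raw$name[first] else ""
  abundance_table(vals,
                  data.frame(accession = acc, gene = gene, name = name,
                             stringsAsFactors = FALSE),
                  donors = donors, conditions = conditions)
}

#' Write a protein abundance table
#'
#' Inverse of [read_abundance_table()]. Values are rendered with enough
#' digits (`%.17g`) that `read(write(x))` reproduces `x` exactly for finite
#' values; missing cells are written as `NA`.
#'
#' @param x an [abundance_table()].
#' @inheritParams read_abundance_table
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path,
                                  dialect = c("wide_tsv", "wide_csv", "long_tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "abundance_table"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  sep <- if (dialect == "wide_csv") "," else "\t"
  if (startsWith(dialect, "wide")) {
    out <- data.frame(accession = x$proteins$accession,
                      gene = x$proteins$gene, name = x$proteins$name,
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (cl in colnames(x$values)) out[[cl]] <- fmt(x$values[, cl])
  } else {
    keys <- colnames(x$values)
    parts <- strsplit(keys, ":", fixed = TRUE)
    out <- data.frame(
      accession = rep(x$proteins$accession, each = length(keys)),
      gene = rep(x$proteins$gene, each = length(keys)),
      name = rep(x$proteins$name, each = length(keys)),
      donor = rep(vapply(parts, `[`, character(1), 1L), nrow(x$values)),
      condition = rep(vapply(parts, `[`, character(1), 2L), nrow(x$values)),
      abundance = fmt(as.vector(t(x$values))),
      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Fixed column order of every per-comparison results file.
RESULT_COLUMNS <- c("accession", "gene", "name", "distance", "threshold_flag",
                    "p_value", "tier", "logFC", "var_ref", "var_trt",
                    "abs_var_diff")

#' Write a per-comparison results table
#'
#' Writes a TSV with the fixed column order `accession, gene, name,
#' distance, threshold_flag, p_value, tier, logFC, var_ref, var_trt,
#' abs_var_diff`. p-values are rendered with 5 decimals and variances with
#' 2, matching the formatting of the published within-group variance
#' tables; distance and logFC get 5 decimals. Any extra columns of
#' `records` (e.g. a Benjamini-Hochberg adjusted p-value) are appended
#' after the fixed block. An empty `records` yields a header-only file.
#'
#' @param records a data.frame of per-protein results (missing fixed
#'   columns are filled with `NA`), or an [anomaly_threshold()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (inherits(records, "anomaly_set")) records <- as.data.frame(records)
  stopifnot(is.data.frame(records))
  for (cl in RESULT_COLUMNS) {
    if (!cl %in% names(records)) {
      records[[cl]] <- if (cl %in% c("accession", "gene", "name", "tier")) {
        rep(NA_character_, nrow(records))
      } else if (cl == "threshold_flag") {
        rep(NA, nrow(records))
      } else {
        rep(NA_real_, nrow(records))
      }
    }
  }
  extra <- setdiff(names(records), RESULT_COLUMNS)
  records <- records[, c(RESULT_COLUMNS, extra), drop = FALSE]
  fmt_num <- function(v, digits) ifelse(is.na(v), "NA",
                                        sprintf(paste0("%.", digits, "f"), v))
  out <- records
  out$p_value <- fmt_num(records$p_value, 5L)
  for (cl in c("var_ref", "var_trt", "abs_var_diff")) {
    out[[cl]] <- fmt_num(records[[cl]], 2L)
  }
  for (cl in c("distance", "logFC")) out[[cl]] <- fmt_num(records[[cl]], 5L)
  for (cl in extra) {
    if (is.numeric(out[[cl]])) out[[cl]] <- fmt_num(records[[cl]], 5L)
  }
  out$threshold_flag <- ifelse(is.na(records$threshold_flag), "NA",
                               ifelse(records$threshold_flag, "TRUE", "FALSE"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write results table to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path path to a results TSV.
#' @return data.frame with typed columns in the fixed result order.
#' @export
read_results_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           colClasses = "character", na.strings = "NA",
                           stringsAsFactors = FALSE)
  for (cl in c("distance", "p_value", "logFC", "var_ref", "var_trt",
               "abs_var_diff")) {
    if (cl %in% names(raw)) raw[[cl]] <- as.numeric(raw[[cl]])
  }
  if ("threshold_flag" %in% names(raw)) {
    raw$threshold_flag <- as.logical(raw$threshold_flag)
  }
  raw
}
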
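#' Published anomaly lists from the MSC-EV bioactive-glass case study
#'
#' Result tables of the motivating case study: extremely changing
#' proteins identified in extracellular-vesicle proteomes of mesenchymal
#' stromal cells from three donors cultured on silver- (SBA2), copper-
#' (SBA3) and tellurium-doped (ST) bioactive glasses, for the
#' control-versus-doped and plastic-versus-doped comparisons. `tier` is
#' the reported t-test tier (`sig`: p < 0.05; `marginal`:
#' 0.05 <= p < 0.1; `ns` otherwise). These accession lists are the input
#' for set-overlap (Venn) analyses across biomaterials.
#'
#' @param comparison `"ctrl_vs_doped"`, `"plast_vs_doped"`, or both
#'   (default).
#' @return data.frame with columns `comparison`, `experiment`,
#'   `accession`, `gene`, `name`, `tier`.
#' @examples
#' an <- bioglass_anomalies("plast_vs_doped")
#' venn_regions(split(an$accession, an$experiment))
#' @export
bioglass_anomalies <- function(comparison = c("ctrl_vs_doped",
                                              "plast_vs_doped")) {
  comparison <- match.arg(comparison, several.ok = TRUE)
  path <- system.file("extdata", "bioglass_anomalies.tsv",
                      package = "evanomaly", mustWork = TRUE)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  x[x$comparison %in% comparison, , drop = FALSE]
}

#' Published within-group variance tables from the case study
#'
#' Per-protein t-test p-values, within-group variances of the reference
#' and doped conditions, and their reported absolute difference, for the
#' same case study as [bioglass_anomalies()] (`var_ref` is the control
#' condition for `ctrl_vs_doped` and the plastic baseline for
#' `plast_vs_doped`). Useful for variance arithmetic and tier-consistency
#' checks.
#'
#' @inheritParams bioglass_anomalies
#' @return data.frame with columns `comparison`, `experiment`,
#'   `accession`, `p_value`, `var_ref`, `var_trt`, `abs_var_diff`.
#' @examples
#' va <- bioglass_variances("ctrl_vs_doped")
#' all.equal(round(abs_var_diff(va$var_ref, va$var_trt), 2), va$abs_var_diff)
#' @export
bioglass_variances <- function(comparison = c("ctrl_vs_doped",
                                              "plast_vs_doped")) {
  comparison <- match.arg(comparison, several.ok = TRUE)
  path <- system.file("extdata", "bioglass_variances.tsv",
                      package = "evanomaly", mustWork = TRUE)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  x[x$comparison %in% comparison, , drop = FALSE]
}
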
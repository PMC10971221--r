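#' Two-sample t-test with significance tiers
#'
#' Two-sided t-test of one protein's D log abundances between the two
#' conditions. The default is Student's pooled-variance test (the
#' homogeneity-of-variances form); Welch is available. Degenerate inputs:
#' if both groups have zero variance, identical means give `p = 1` and
#' different means give the limit `p = 0` (with a warning).
#'
#' Tiers use half-open intervals: `p < 0.05` is `"sig"`,
#' `0.05 <= p < 0.1` is `"marginal"`, `p >= 0.1` is `"ns"`; so an exact
#' `p = 0.05` is marginal and an exact `p = 0.1` is ns.
#'
#' @param ref_values,trt_values numeric vectors (length >= 2 each) of log
#'   abundances per donor.
#' @param variant `"student"` (default) or `"welch"`.
#' @return list with `p_value`, `tier`, `statistic`.
#' @export
protein_ttest <- function(ref_values, trt_values,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(ref_values) >= 2, length(trt_values) >= 2,
            all(is.finite(ref_values)), all(is.finite(trt_values)))
  v1 <- stats::var(ref_values)
  v2 <- stats::var(trt_values)
  if (v1 == 0 && v2 == 0) {
    if (isTRUE(all.equal(mean(ref_values), mean(trt_values)))) {
      p <- 1
      stat <- 0
    } else {
      warning("zero pooled variance with unequal means; p-value is the 0 limit")
      p <- 0
      stat <- Inf
    }
  } else {
    tt <- stats::t.test(ref_values, trt_values,
                        var.equal = (variant == "student"))
    p <- unname(tt$p.value)
    stat <- unname(tt$statistic)
  }
  list(p_value = p, tier = p_tier(p), statistic = stat)
}

#' Significance tier of a p-value
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector: `"sig"` (`p < 0.05`), `"marginal"`
#'   (`0.05 <= p < 0.1`) or `"ns"`.
#' @export
p_tier <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.05, "sig", ifelse(p < 0.1, "marginal", "ns")))
}

#' Within-group sample variance
#'
#' The dispersion of one protein's values within one experimental
#' condition (sample variance, denominator D - 1).
#'
#' @param values numeric vector, length >= 2.
#' @return a single variance.
#' @export
within_group_variance <- function(values) {
  stopifnot(length(values) >= 2, all(is.finite(values)))
  stats::var(values)
}

#' Absolute difference between two variances
#'
#' @param v1,v2 non-negative variances (vectorized).
#' @return `|v1 - v2|`. Rounding to the 2-decimal report format happens
#'   only at write time ([write_results_table()]).
#' @export
abs_var_diff <- function(v1, v2) {
  stopifnot(all(v1 >= 0, na.rm = TRUE), all(v2 >= 0, na.rm = TRUE))
  abs(v1 - v2)
}

#' Coefficient of variation
#'
#' Relative variability: sample standard deviation divided by the mean
#' (the sign follows the mean). Undefined for a zero mean, reported as
#' `NA`.
#'
#' @param values numeric vector, length >= 2.
#' @return sd/mean, or `NA` if the mean is zero.
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 2, all(is.finite(values)))
  m <- mean(values)
  if (m == 0) return(NA_real_)
  stats::sd(values) / m
}

#' Quadratic fit of displacement versus log fold change
#'
#' Ordinary least squares of `y ~ a x^2 + b x + c`, the U-shaped curve
#' that summarizes how displacement grows with fold change in either
#' direction. `r_squared = 1 - SS_res / SS_tot`, defined as 0 for
#' constant `y`.
#'
#' @param x log fold changes (length >= 3, not all equal).
#' @param y distances.
#' @return A `quadratic_fit` list: `a`, `b`, `c`, `r_squared`, `fitted`.
#' @export
quadratic_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2L) {
    stop("all x identical: quadratic fit is rank-deficient")
  }
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient quadratic fit (fewer than 3 distinct x values)")
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(a = unname(cf[3L]), b = unname(cf[2L]), c = unname(cf[1L]),
                 r_squared = r2, fitted = unname(stats::fitted(fit))),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit> d ~ %.4g logFC^2 + %.4g logFC + %.4g (R^2 = %.3f)\n",
              x$a, x$b, x$c, x$r_squared))
  invisible(x)
}

#' Venn region counts of accession sets
#'
#' Counts every one of the `2^n - 1` exclusive regions of 2 or 3 named
#' accession sets. Membership is by exact accession string, so isoforms
#' (e.g. `"P24821-4"`) are distinct from their parent accession. Region
#' names join the set names with `"&"`; counts over all regions sum to the
#' size of the union.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector of exclusive region counts.
#' @examples
#' venn_regions(list(A = c("P1", "P2"), B = c("P2", "P3")))
#' @export
venn_regions <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L),
            !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  all_acc <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_acc %in% s,
                   logical(length(all_acc)))
  if (length(all_acc) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, nm))
  n <- length(sets)
  out <- integer(0)
  for (size in seq_len(n)) {
    combos <- utils::combn(n, size, simplify = FALSE)
    for (cmb in combos) {
      inside <- rowSums(member[, cmb, drop = FALSE]) == length(cmb) &
        rowSums(member[, -cmb, drop = FALSE]) == 0
      if (length(cmb) == n) {
        inside <- rowSums(member[, cmb, drop = FALSE]) == length(cmb)
      }
      out[paste(nm[cmb], collapse = "&")] <- sum(inside)
    }
  }
  out
}

#' Members of one Venn region
#'
#' @param sets named list of 2 or 3 character vectors.
#' @param region character vector of set names the accessions must belong
#'   to; they must belong to no other set.
#' @return character vector of accessions in that exclusive region (for
#'   the full region, i.e. all set names, exclusivity is vacuous).
#' @export
venn_members <- function(sets, region) {
  stopifnot(all(region %in% names(sets)))
  inside <- Reduce(intersect, sets[region])
  outside <- unique(unlist(sets[setdiff(names(sets), region)]))
  setdiff(inside, outside)
}

#' Monte-Carlo coverage within k standard deviations of the mean
#'
#' Fraction of values within `k` sample SDs of the sample mean; for
#' normal data and `k = 1` this is the familiar ~68% that motivates the
#' mean-plus-one-SD anomaly threshold.
#'
#' @param x numeric vector.
#' @param k SD multiplier (default 1).
#' @return fraction in \[0, 1\].
#' @export
coverage_within_sd <- function(x, k = 1) {
  mean(abs(x - mean(x)) <= k * stats::sd(x))
}
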
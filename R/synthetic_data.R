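#' Specification of a synthetic abundance table
#'
#' The generator emulates the structure the pipeline assumes: the same
#' donors measured in every condition, a dominant cloud of proteins with
#' similar expression (the population the density filter retains), a
#' minority of planted condition-specific anomalies, and a secondary
#' low-abundance contaminant cloud that exercises the density filter.
#' Effects are additive on the log2 scale (the standard multiplicative
#' model on raw intensities): the log2 abundance of protein p in donor d
#' and condition c is
#' `l = mu_p + delta_d + beta_{p,c} + eps`, with
#' `mu_p ~ N(baseline_mean, baseline_sd^2)`,
#' `delta_d ~ N(0, donor_sd^2)`, `eps ~ N(0, noise_sd^2)`, and
#' `beta = 0` except for planted anomalies, where
#' `beta_{p, anomaly_condition} = +/- effect_size` with random sign.
#' Contaminant proteins draw their `mu_p` around
#' `baseline_mean + contaminant_offset`. Raw peak areas are `2^l`.
#'
#' Defaults describe a three-donor label-free experiment: log2 areas
#' around 20; a homogeneous primary cluster (`baseline_sd = 0.5`);
#' replicate noise `noise_sd = 0.4` (about 30% CV); 2% planted anomalies
#' shifted by six noise SDs in the doped condition; a 20% contaminant
#' cloud three orders of magnitude down in raw abundance
#' (`contaminant_offset = -10`), near the detection floor.
#'
#' @param n_proteins number of proteins (default 500).
#' @param n_donors number of donors (default 3).
#' @param conditions condition labels (default plast/ctrl/doped).
#' @param baseline_mean,baseline_sd log2 mean and between-protein SD of
#'   the primary cloud.
#' @param donor_sd SD of the global per-donor offsets.
#' @param noise_sd SD of the per-cell measurement noise (log2 units).
#' @param anomaly_fraction fraction of non-contaminant proteins planted
#'   as anomalies (in \[0, 1)).
#' @param effect_size magnitude of the planted condition shift (log2).
#' @param anomaly_condition condition carrying the planted shift
#'   (default `"doped"`; the other conditions share the null profile).
#' @param contaminant_fraction,contaminant_offset fraction and log2
#'   offset of the secondary cloud.
#' @param seed integer seed; generation is fully reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_proteins = 500, n_donors = 3,
                           conditions = c("plast", "ctrl", "doped"),
                           baseline_mean = 20, baseline_sd = 0.5,
                           donor_sd = 0.5, noise_sd = 0.4,
                           anomaly_fraction = 0.02, effect_size = 2.4,
                           anomaly_condition = "doped",
                           contaminant_fraction = 0.2,
                           contaminant_offset = -10, seed = 1) {
  if (any(c(baseline_sd, donor_sd, noise_sd) < 0)) {
    stop("standard deviations must be >= 0")
  }
  if (anomaly_fraction < 0 || anomaly_fraction >= 1 ||
      contaminant_fraction < 0 ||
      anomaly_fraction + contaminant_fraction >= 1) {
    stop("need anomaly_fraction in [0,1) and ",
         "anomaly_fraction + contaminant_fraction < 1")
  }
  if (anomaly_fraction > 0 && !anomaly_condition %in% conditions) {
    stop("anomaly_condition must be one of the conditions")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_donors = as.integer(n_donors),
                 conditions = conditions,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 donor_sd = donor_sd, noise_sd = noise_sd,
                 anomaly_fraction = anomaly_fraction,
                 effect_size = effect_size,
                 anomaly_condition = anomaly_condition,
                 contaminant_fraction = contaminant_fraction,
                 contaminant_offset = contaminant_offset,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic abundance table with known ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (an [abundance_table()] of raw peak areas)
#'   and `truth` (a `synthetic_truth` list: `anomalies` data.frame of
#'   accession and signed effect, `contaminants` accession vector —
#'   always disjoint sets).
#' @examples
#' gt <- generate_table(synthetic_spec(n_proteins = 50, seed = 7))
#' gt$table
#' gt$truth$anomalies
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_proteins
  D <- spec$n_donors
  conds <- spec$conditions
  acc <- sprintf("SYN%04d", seq_len(n))
  donors <- paste0("D", seq_len(D))
  n_cont <- round(spec$contaminant_fraction * n)
  n_anom <- round(spec$anomaly_fraction * n)

  with_seed(spec$seed, {
    idx_cont <- if (n_cont) sort(sample(n, n_cont)) else integer(0)
    idx_anom <- if (n_anom) {
      sort(sample(setdiff(seq_len(n), idx_cont), n_anom))
    } else integer(0)
    mu <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)
    mu[idx_cont] <- mu[idx_cont] + spec$contaminant_offset
    sign <- if (n_anom) sample(c(-1, 1), n_anom, replace = TRUE) else numeric(0)
    delta <- stats::rnorm(D, 0, spec$donor_sd)
    noise <- array(stats::rnorm(n * D * length(conds), 0, spec$noise_sd),
                   dim = c(n, D, length(conds)))
  })

  beta <- matrix(0, n, length(conds))
  if (n_anom) {
    beta[idx_anom, match(spec$anomaly_condition, conds)] <-
      sign * spec$effect_size
  }
  keys <- column_keys(donors, conds)
  vals <- matrix(NA_real_, n, length(keys), dimnames = list(acc, keys))
  for (ci in seq_along(conds)) {
    for (di in seq_len(D)) {
      l <- mu + delta[di] + beta[, ci] + noise[, di, ci]
      vals[, paste(donors[di], conds[ci], sep = ":")] <- 2^l
    }
  }
  table <- abundance_table(
    vals,
    data.frame(accession = acc,
               gene = sprintf("G%04d", seq_len(n)),
               name = sprintf("synthetic protein %d", seq_len(n)),
               stringsAsFactors = FALSE),
    donors = donors, conditions = conds)
  truth <- structure(
    list(anomalies = data.frame(accession = acc[idx_anom],
                                effect = sign * spec$effect_size,
                                stringsAsFactors = FALSE),
         contaminants = acc[idx_cont]),
    class = "synthetic_truth")
  list(table = table, truth = truth, spec = spec)
}

#' Expected null cross-condition displacement
#'
#' For a null protein the per-donor displacement between two conditions
#' is `N(0, 2 noise_sd^2)` (the baseline, donor and condition effects
#' cancel), so the squared displacement is `2 noise_sd^2` times a
#' chi-squared with D degrees of freedom and
#' `E[d] = noise_sd * sqrt(2) * sqrt(2) * Gamma((D+1)/2) / Gamma(D/2)`.
#' For `D = 3`, `noise_sd = 1` this is `4 / sqrt(pi) ~ 2.2568`.
#'
#' @param spec a [synthetic_spec()] with `noise_sd > 0`.
#' @return expected displacement of a null protein.
#' @export
expected_null_distance <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$noise_sd > 0)
  D <- spec$n_donors
  spec$noise_sd * 2 * gamma((D + 1) / 2) / gamma(D / 2)
}
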
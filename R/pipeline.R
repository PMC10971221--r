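#' Run the full anomaly-detection pipeline
#'
#' Orchestrates the four-step sequence for every requested comparison:
#' log-transform the raw peak areas; cluster the pooled donor-space
#' points of all conditions with OPTICS and keep the primary cluster;
#' score each condition's retained points with an isolation forest and
#' pair the outlier flags across the comparison; threshold the
#' per-protein cross-condition Euclidean displacement at
#' `mean + k * SD`. A descriptive layer adds, per eligible protein, the
#' two-sample t-test tier, log fold change, within-group variances and
#' CVs, the absolute variance difference, and a supplementary
#' Benjamini-Hochberg adjusted p-value (never used for gating); plus a
#' quadratic displacement-versus-logFC fit per comparison and Venn region
#' counts across comparisons sharing a reference condition.
#'
#' The single `seed` fans out to a fixed per-condition forest seed
#' (`seed + 1000 * condition index`), so one value reproduces the whole
#' run; repeated runs with identical inputs are byte-identical on disk.
#'
#' @param table an [abundance_table()] of raw peak areas.
#' @param comparisons a [comparison_spec()] or list of them.
#' @param out_dir if non-NULL, write one results TSV per comparison, a
#'   Venn JSON per comparison family, and a run summary JSON there.
#' @param log_base,nonpositive_policy,epsilon see [log_transform()].
#' @param min_pts OPTICS core-point neighborhood size.
#' @param eps OPTICS extraction radius; `NULL` (default) derives it from
#'   the data with [suggest_eps()], since a fixed radius is only
#'   meaningful at a known data scale.
#' @param selection_rule,membership_rule see [select_primary_cluster()]
#'   and [filter_to_cluster()].
#' @param n_trees,subsample,contamination see [fit_isolation_forest()].
#' @param pairing_rule see [outlier_union()].
#' @param k,sd_ddof see [anomaly_threshold()].
#' @param ttest_variant see [protein_ttest()].
#' @param experiment label stamped on outputs (e.g. the biomaterial).
#' @param seed global seed for every stochastic stage.
#' @param verbose narrate retained counts after each stage.
#' @return An `anomaly_run` list: `log_table`, `assignment`, `eps`,
#'   `comparisons` (per comparison: `anomaly_set`, `stats` data.frame,
#'   `quadratic`, `labelings`, counts), `venn`, `summary`.
#' @export
run_pipeline <- function(table, comparisons, out_dir = NULL,
                         log_base = 2, nonpositive_policy = "drop_protein",
                         epsilon = NULL,
                         min_pts = 50, eps = NULL,
                         selection_rule = "largest_all_positive",
                         membership_rule = "both",
                         n_trees = 500, subsample = 256, contamination = 0.10,
                         pairing_rule = "union",
                         k = 1, sd_ddof = 1,
                         ttest_variant = "student",
                         experiment = "experiment",
                         seed = 1337, verbose = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  if (inherits(comparisons, "comparison_spec")) comparisons <- list(comparisons)
  for (cmp in comparisons) {
    bad <- setdiff(c(cmp$reference, cmp$treatment), table$conditions)
    if (length(bad)) {
      stop("comparison refers to unknown condition(s): ",
           paste(bad, collapse = ", "))
    }
  }
  say <- function(...) if (verbose) message(sprintf(...))

  lt <- log_transform(table, base = log_base,
                      nonpositive_policy = nonpositive_policy,
                      epsilon = epsilon)
  say("log-transform: %d of %d proteins retained (%d dropped)",
      nrow(lt$values), nrow(table$values), nrow(lt$dropped))

  pooled <- pool_donor_points(lt)
  if (is.null(eps)) {
    eps <- suggest_eps(pooled, min_pts)
    say("OPTICS radius derived from data: eps = %.4f", eps)
  }
  assignment <- optics_order(pooled, min_pts = min_pts)
  assignment <- extract_clusters(assignment, eps = eps)
  assignment <- select_primary_cluster(assignment, lt, rule = selection_rule)
  sel <- attr(assignment, "selected_cluster")
  say("OPTICS: %d cluster(s) + %d noise points; primary cluster %d holds %d points",
      length(setdiff(unique(assignment$cluster), 0L)),
      sum(assignment$cluster == 0L), sel, sum(assignment$cluster == sel))

  cond_seed <- function(cond) seed + 1000L * match(cond, table$conditions)
  results <- list()
  for (cmp in comparisons) {
    tag <- paste0(cmp$reference, "_vs_", cmp$treatment)
    in_cluster <- filter_to_cluster(assignment, cmp, membership = membership_rule)
    say("[%s] density filter: %d proteins in the primary cluster in %s condition(s)",
        tag, length(in_cluster), membership_rule)
    if (!length(in_cluster)) {
      warning("comparison ", tag, " skipped: empty cluster-filtered set")
      next
    }
    labelings <- lapply(c(cmp$reference, cmp$treatment), function(cond) {
      pts <- donor_points(lt, cond)
      pts <- pts[pts$accession %in% in_cluster, , drop = FALSE]
      attr(pts, "donors") <- lt$donors
      class(pts) <- c("donor_points", "data.frame")
      fit_isolation_forest(pts, n_trees = n_trees, subsample = subsample,
                           contamination = contamination,
                           seed = cond_seed(cond))
    })
    names(labelings) <- c(cmp$reference, cmp$treatment)
    out_acc <- outlier_union(labelings, cmp, rule = pairing_rule)
    eligible <- intersect(in_cluster, out_acc)
    say("[%s] isolation forest (%s rule): %d outlier proteins eligible",
        tag, pairing_rule, length(eligible))
    if (length(eligible) < 2L) {
      warning("comparison ", tag, " skipped: fewer than 2 eligible proteins")
      next
    }
    recs <- comparison_distances(lt, eligible, cmp)
    aset <- anomaly_threshold(recs, k = k, sd_ddof = sd_ddof)
    say("[%s] threshold tau = %.4f flags %d of %d proteins",
        tag, aset$tau, length(aset$flagged), nrow(recs))

    stats_df <- comparison_stats(lt, aset, cmp, variant = ttest_variant)
    quad <- NULL
    if (nrow(recs) >= 3L && length(unique(recs$logFC)) >= 3L) {
      quad <- quadratic_fit(recs$logFC, recs$d)
    }
    results[[tag]] <- list(comparison = cmp, anomaly_set = aset,
                           stats = stats_df, quadratic = quad,
                           labelings = labelings,
                           counts = c(cluster = length(in_cluster),
                                      outlier = length(eligible),
                                      flagged = length(aset$flagged)))
  }

  venn <- venn_by_family(results)
  summary <- list(
    package = as.character(utils::packageVersion("evanomaly")),
    experiment = experiment,
    seed = seed,
    parameters = list(log_base = log_base,
                      nonpositive_policy = nonpositive_policy,
                      min_pts = min_pts, eps = eps,
                      selection_rule = selection_rule,
                      membership_rule = membership_rule,
                      n_trees = n_trees, subsample = subsample,
                      contamination = contamination,
                      pairing_rule = pairing_rule,
                      k = k, sd_ddof = sd_ddof,
                      ttest_variant = ttest_variant),
    comparisons = lapply(results, function(r) {
      list(reference = r$comparison$reference,
           treatment = r$comparison$treatment,
           tau = r$anomaly_set$tau,
           n_cluster = unname(r$counts["cluster"]),
           n_eligible = unname(r$counts["outlier"]),
           n_flagged = unname(r$counts["flagged"]),
           flagged = r$anomaly_set$flagged)
    }))
  run <- structure(list(log_table = lt, assignment = assignment, eps = eps,
                        comparisons = results, venn = venn,
                        summary = summary),
                   class = "anomaly_run")
  if (!is.null(out_dir)) write_run(run, out_dir, experiment = experiment)
  run
}

#' Per-protein descriptive statistics for an anomaly set
#'
#' Builds the descriptive layer for the proteins of one
#' [anomaly_threshold()] result, in its descending-distance order:
#' t-test p-value and tier, within-group variances and CVs per condition,
#' absolute variance difference, distance, flag, logFC, and a
#' supplementary Benjamini-Hochberg adjusted p-value.
#'
#' @param lt a [log_transform()] result.
#' @param aset an [anomaly_threshold()] result.
#' @param cmp the [comparison_spec()] the distances came from.
#' @param variant see [protein_ttest()].
#' @return data.frame in the fixed results order (see
#'   [write_results_table()]) plus `cv_ref`, `cv_trt`, `p_adj_bh`.
#' @export
comparison_stats <- function(lt, aset, cmp, variant = "student") {
  acc <- aset$records$accession
  ref_keys <- paste(lt$donors, cmp$reference, sep = ":")
  trt_keys <- paste(lt$donors, cmp$treatment, sep = ":")
  rows <- lapply(acc, function(a) {
    rv <- lt$values[a, ref_keys]
    tv <- lt$values[a, trt_keys]
    tt <- protein_ttest(rv, tv, variant = variant)
    data.frame(accession = a,
               p_value = tt$p_value, tier = tt$tier,
               var_ref = within_group_variance(rv),
               var_trt = within_group_variance(tv),
               cv_ref = coefficient_of_variation(rv),
               cv_trt = coefficient_of_variation(tv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$abs_var_diff <- abs_var_diff(out$var_ref, out$var_trt)
  out$distance <- aset$records$d
  out$threshold_flag <- aset$records$flagged
  out$logFC <- aset$records$logFC
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  meta <- lt$proteins[match(acc, lt$proteins$accession), c("gene", "name")]
  out$gene <- meta$gene
  out$name <- meta$name
  out[, c(RESULT_COLUMNS, "cv_ref", "cv_trt", "p_adj_bh")]
}

# Venn region counts across comparisons sharing a reference condition.
venn_by_family <- function(results) {
  if (length(results) < 2L) return(list())
  refs <- vapply(results, function(r) r$comparison$reference, character(1))
  out <- list()
  for (ref in unique(refs)) {
    members <- results[refs == ref]
    if (length(members) < 2L || length(members) > 3L) next
    sets <- lapply(members, function(r) r$anomaly_set$flagged)
    names(sets) <- vapply(members, function(r) {
      if (!is.null(r$comparison$experiment)) r$comparison$experiment
      else r$comparison$treatment
    }, character(1))
    out[[ref]] <- as.list(venn_regions(sets))
  }
  out
}

#' Write the outputs of a pipeline run
#'
#' One results TSV per comparison (fixed column order, see
#' [write_results_table()]), one Venn JSON per comparison family, and a
#' `summary.json` with thresholds, counts, parameters and seed. Outputs
#' contain no timestamps, so identical runs are byte-identical.
#'
#' @param run an `anomaly_run` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @param experiment label used in file names.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir, experiment = "experiment") {
  stopifnot(inherits(run, "anomaly_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tag in names(run$comparisons)) {
    write_results_table(run$comparisons[[tag]]$stats,
                        file.path(out_dir,
                                  paste0(experiment, "_", tag, ".tsv")))
  }
  for (fam in names(run$venn)) {
    jsonlite::write_json(run$venn[[fam]],
                         file.path(out_dir, paste0("venn_", fam, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.anomaly_run <- function(x, ...) {
  cat(sprintf("<anomaly_run> eps = %.4f; %d comparison(s)\n", x$eps,
              length(x$comparisons)))
  for (tag in names(x$comparisons)) {
    r <- x$comparisons[[tag]]
    cat(sprintf("  %s: %d in cluster, %d eligible, %d flagged (tau = %.4f)\n",
                tag, r$counts["cluster"], r$counts["outlier"],
                r$counts["flagged"], r$anomaly_set$tau))
  }
  invisible(x)
}
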
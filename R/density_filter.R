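#' OPTICS ordering of pooled donor-space points
#'
#' Computes the OPTICS (Ordering Points To Identify the Clustering
#' Structure) processing order of the pooled points with per-point core
#' and reachability distances, using the Euclidean metric. The core
#' distance of a point is its distance to the `min_pts`-th nearest *other*
#' point; the reachability distance of a point q from p is
#' `max(core_dist(p), dist(p, q))`. Cluster labels are assigned later by
#' [extract_clusters()].
#'
#' Ties in the expansion queue are broken by (reachability, input index),
#' so the ordering is deterministic.
#'
#' @param points a `donor_points` data.frame (see [donor_points()],
#'   [pool_donor_points()]) or a numeric coordinate matrix.
#' @param min_pts core-point neighborhood size (>= 2). The published
#'   pipeline used `min_pts = 50` on its three-donor table.
#' @return A `cluster_assignment` data.frame with columns `accession`,
#'   `condition`, `core_dist`, `reachability`, `cluster` (`NA` until
#'   extraction; `0` marks noise afterwards); attributes `order`
#'   (processing order as row indices) and `min_pts`.
#' @export
optics_order <- function(points, min_pts = 50) {
  coords <- if (is.matrix(points)) points else donor_coords(points)
  n <- nrow(coords)
  if (!is.numeric(min_pts) || min_pts < 2) stop("min_pts must be >= 2")
  min_pts <- as.integer(min_pts)
  if (n <= min_pts) {
    stop("only ", n, " points but min_pts = ", min_pts,
         "; use a smaller min_pts")
  }
  if (anyNA(coords)) stop("point coordinates must be finite")
  D <- as.matrix(stats::dist(coords))
  core <- vapply(seq_len(n), function(i) {
    sort.int(D[i, -i], partial = min_pts)[min_pts]
  }, numeric(1))

  reach <- rep(Inf, n)
  processed <- rep(FALSE, n)
  ord <- integer(n)
  for (step in seq_len(n)) {
    cand <- which(!processed)
    # which.min returns the first minimum: ties fall to the lowest index,
    # and an all-Inf frontier restarts at the lowest unprocessed index.
    p <- cand[which.min(reach[cand])]
    ord[step] <- p
    processed[p] <- TRUE
    np <- cand[cand != p]
    if (length(np)) {
      newreach <- pmax(core[p], D[p, np])
      upd <- newreach < reach[np]
      reach[np[upd]] <- newreach[upd]
    }
  }

  out <- data.frame(
    accession = if (is.matrix(points)) rownames(coords) else points$accession,
    condition = if (is.matrix(points)) NA_character_ else points$condition,
    core_dist = core,
    reachability = reach,
    cluster = NA_integer_,
    stringsAsFactors = FALSE)
  attr(out, "order") <- ord
  attr(out, "min_pts") <- min_pts
  attr(out, "coords") <- coords
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Extract flat clusters from an OPTICS ordering at a fixed radius
#'
#' DBSCAN-equivalent extraction: walking the processing order, a
#' consecutive run of points with reachability <= `eps` forms a cluster
#' seeded wherever a core point (core distance <= `eps`) starts a new run.
#' A point left over by the walk that still has a core point within `eps`
#' is a border point in the DBSCAN sense (this happens when the ordering
#' enters a region through a non-core point); it is attached to the
#' cluster of its nearest such core point, ties broken by input index.
#' Everything else is noise (`cluster = 0`), so the result matches a
#' direct DBSCAN run at (`eps`, `min_pts`) up to the inherent ambiguity of
#' border points adjacent to two clusters.
#'
#' @param assignment an [optics_order()] result.
#' @param eps extraction radius in log-abundance units. The default is the
#'   radius used by the published three-donor analysis; it is only
#'   meaningful at a comparable data scale (see [suggest_eps()]).
#' @return The assignment with final `cluster` labels and attribute `eps`.
#' @export
extract_clusters <- function(assignment, eps = 0.05) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0")
  ord <- attr(assignment, "order")
  reach <- assignment$reachability
  core <- assignment$core_dist
  lab <- integer(nrow(assignment))
  cid <- 0L
  for (p in ord) {
    if (reach[p] > eps) {
      if (core[p] <= eps) {
        cid <- cid + 1L
        lab[p] <- cid
      } else {
        lab[p] <- 0L
      }
    } else {
      lab[p] <- cid # reach <= eps implies a cluster is open (cid >= 1)
    }
  }
  # border rescue: noise points within eps of a core point join that
  # core point's cluster (deterministically: nearest core, then index)
  coords <- attr(assignment, "coords")
  is_core <- core <= eps
  for (p in which(lab == 0L)) {
    cand <- which(is_core & lab > 0L)
    if (!length(cand)) break
    d <- sqrt(colSums((t(coords[cand, , drop = FALSE]) - coords[p, ])^2))
    ok <- d <= eps
    if (any(ok)) lab[p] <- lab[cand[ok][which.min(d[ok])]]
  }
  assignment$cluster <- lab
  attr(assignment, "eps") <- eps
  assignment
}

#' Select the primary cluster
#'
#' Formalizes the retention of the dominant ("blue") cluster: under
#' `"largest_all_positive"` the most populous cluster all of whose member
#' points have strictly positive raw peak areas in every donor is
#' selected, so the retained group represents proteins measured cleanly in
#' all donors; if no cluster qualifies the rule falls back to `"largest"`
#' with a warning.
#'
#' @param assignment an [extract_clusters()] result.
#' @param logtable the [log_transform()] result the points came from
#'   (supplies the raw peak areas).
#' @param rule `"largest_all_positive"` (default) or `"largest"`.
#' @return The assignment with attribute `selected_cluster` set.
#' @export
select_primary_cluster <- function(assignment, logtable,
                                   rule = c("largest_all_positive", "largest")) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  rule <- match.arg(rule)
  labs <- assignment$cluster
  if (anyNA(labs)) stop("run extract_clusters() before selecting a cluster")
  ids <- setdiff(sort(unique(labs)), 0L)
  if (!length(ids)) {
    stop("no clusters found (all points are noise); try a larger eps")
  }
  sizes <- vapply(ids, function(id) sum(labs == id), integer(1))
  selected <- NA_integer_
  if (rule == "largest_all_positive") {
    raw <- logtable$raw_values
    point_pos <- vapply(seq_len(nrow(assignment)), function(i) {
      acc <- assignment$accession[i]
      keys <- paste(logtable$donors, assignment$condition[i], sep = ":")
      v <- raw[acc, keys]
      all(!is.na(v) & v > 0)
    }, logical(1))
    ok <- vapply(ids, function(id) all(point_pos[labs == id]), logical(1))
    if (any(ok)) {
      qual <- ids[ok]
      selected <- qual[which.max(sizes[ok])]
    } else {
      warning("no cluster has all-positive raw peak areas; ",
              "falling back to the largest cluster")
    }
  }
  if (is.na(selected)) selected <- ids[which.max(sizes)]
  attr(assignment, "selected_cluster") <- selected
  assignment
}

#' Accessions retained by the density filter for one comparison
#'
#' @param assignment a [select_primary_cluster()] result.
#' @param comparison a [comparison_spec()].
#' @param membership `"both"` (default): keep accessions whose points lie
#'   in the selected cluster in *both* conditions of the comparison, so no
#'   distance mixes an in-cluster point with an unfiltered one;
#'   `"either"`: in-cluster in at least one condition.
#' @return character vector of accessions.
#' @export
filter_to_cluster <- function(assignment, comparison,
                              membership = c("both", "either")) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(comparison, "comparison_spec"))
  membership <- match.arg(membership)
  sel <- attr(assignment, "selected_cluster")
  if (is.null(sel)) stop("run select_primary_cluster() first")
  in_sel <- assignment$cluster == sel
  acc_ref <- assignment$accession[in_sel &
                                    assignment$condition == comparison$reference]
  acc_trt <- assignment$accession[in_sel &
                                    assignment$condition == comparison$treatment]
  if (membership == "both") intersect(acc_ref, acc_trt)
  else union(acc_ref, acc_trt)
}

#' Data-driven OPTICS extraction radius
#'
#' The published extraction radius is tied to the scale of its own
#' log-abundance table; on other tables a radius must admit the sparse
#' tail of the primary cluster (whose extreme points are exactly the
#' anomaly candidates the later stages score) while staying below the
#' separation between expression regimes. This helper returns
#' `scale` times the `prob` quantile of the per-point distance to the
#' `min_pts`-th nearest other point, which accomplishes that for
#' well-separated point clouds.
#'
#' @inheritParams optics_order
#' @param prob quantile of the min_pts-NN distance distribution
#'   (default 0.99).
#' @param scale multiplier applied to the quantile (default 2).
#' @return a single radius.
#' @export
suggest_eps <- function(points, min_pts = 50, prob = 0.99, scale = 2) {
  coords <- if (is.matrix(points)) points else donor_coords(points)
  n <- nrow(coords)
  if (n <= min_pts) {
    stop("only ", n, " points but min_pts = ", min_pts,
         "; use a smaller min_pts")
  }
  D <- as.matrix(stats::dist(coords))
  kd <- vapply(seq_len(n), function(i) {
    sort.int(D[i, -i], partial = min_pts)[min_pts]
  }, numeric(1))
  scale * unname(stats::quantile(kd, prob))
}

#' Dump an OPTICS reachability profile for inspection
#'
#' Writes the processing order with reachability and core distances as a
#' TSV (the data behind a reachability plot).
#'
#' @param assignment an [optics_order()] (or later-stage) result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reachability <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ord <- attr(assignment, "order")
  out <- assignment[ord, c("accession", "condition", "reachability",
                           "core_dist", "cluster")]
  out$position <- seq_along(ord)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
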
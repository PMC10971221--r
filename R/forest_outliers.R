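#' Expected path length of an unsuccessful binary search
#'
#' The isolation-forest normalizer `c(n) = 2 H(n-1) - 2 (n-1)/n`, with
#' `H(i)` the harmonic number (computed exactly). `c(1) = 0` and
#' `c(2) = 1` by convention. Path lengths at truncated leaves are adjusted
#' by `c(leaf size)` and scores are normalized by `c(subsample size)`.
#'
#' @param n number of points (vectorized).
#' @return numeric vector of expected path lengths.
#' @export
iforest_cn <- function(n) {
  vapply(n, function(m) {
    if (m <= 1) 0
    else if (m == 2) 1
    else 2 * sum(1 / seq_len(m - 1)) - 2 * (m - 1) / m
  }, numeric(1))
}

# One isolation tree on the rows of X (a psi x d matrix), stored as flat
# arrays. Internal nodes carry (feature, split, left, right); leaves carry
# their size. Splits are uniform draws between the min and max of a
# randomly chosen feature with positive range; growth stops at singletons,
# duplicate-only nodes, or the depth ceiling.
build_itree <- function(X, depth_limit) {
  n_max <- 4L * nrow(X) + 8L
  feature <- integer(n_max)
  split <- numeric(n_max)
  left <- integer(n_max)
  right <- integer(n_max)
  size <- integer(n_max)
  n_nodes <- 1L
  d <- ncol(X)
  stack <- list(list(node = 1L, idx = seq_len(nrow(X)), depth = 0L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- fr$idx
    node <- fr$node
    if (length(idx) <= 1L || fr$depth >= depth_limit) {
      size[node] <- length(idx)
      next
    }
    lo <- numeric(d)
    hi <- numeric(d)
    for (j in seq_len(d)) {
      r <- range(X[idx, j])
      lo[j] <- r[1L]
      hi[j] <- r[2L]
    }
    open <- which(hi > lo)
    if (!length(open)) { # all duplicates
      size[node] <- length(idx)
      next
    }
    q <- if (length(open) == 1L) open else sample(open, 1L)
    u <- stats::runif(1L, lo[q], hi[q])
    goes_left <- X[idx, q] < u
    if (!any(goes_left) || all(goes_left)) { # degenerate draw at the boundary
      size[node] <- length(idx)
      next
    }
    feature[node] <- q
    split[node] <- u
    left[node] <- n_nodes + 1L
    right[node] <- n_nodes + 2L
    n_nodes <- n_nodes + 2L
    stack[[length(stack) + 1L]] <-
      list(node = left[node], idx = idx[goes_left], depth = fr$depth + 1L)
    stack[[length(stack) + 1L]] <-
      list(node = right[node], idx = idx[!goes_left], depth = fr$depth + 1L)
  }
  list(feature = feature, split = split, left = left, right = right,
       size = size)
}

# Path length of every row of P through one tree, with the c(leaf size)
# adjustment at truncated leaves.
itree_path <- function(tree, P, cn_table) {
  n <- nrow(P)
  path <- numeric(n)
  stack <- list(list(node = 1L, idx = seq_len(n), depth = 0L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node
    idx <- fr$idx
    if (tree$feature[node] == 0L) { # leaf
      m <- tree$size[node]
      adj <- if (m <= length(cn_table)) cn_table[m] else iforest_cn(m)
      path[idx] <- fr$depth + adj
      next
    }
    goes_left <- P[idx, tree$feature[node]] < tree$split[node]
    if (any(goes_left)) {
      stack[[length(stack) + 1L]] <- list(node = tree$left[node],
                                          idx = idx[goes_left],
                                          depth = fr$depth + 1L)
    }
    if (!all(goes_left)) {
      stack[[length(stack) + 1L]] <- list(node = tree$right[node],
                                          idx = idx[!goes_left],
                                          depth = fr$depth + 1L)
    }
  }
  path
}

#' Score donor-space points with an isolation forest
#'
#' Builds `n_trees` isolation trees on random subsamples of the points of
#' one condition. Each tree recursively splits a randomly chosen feature
#' at a uniform draw between that feature's min and max, until points are
#' isolated or the depth ceiling `ceiling(log2(subsample))` is reached.
#' A point's expected path length `E[h(x)]` across trees (with the
#' standard unsuccessful-search adjustment [iforest_cn()] at truncated
#' leaves) yields the anomaly score `s(x) = 2^(-E[h(x)] / c(subsample))`:
#' shorter average paths mean easier isolation, hence higher scores.
#'
#' Flags: the top `contamination` fraction of points by score (ties broken
#' by input order) are labeled outliers; `contamination = "auto"` flags
#' scores above 0.5, the score of a point whose path length equals the
#' average unsuccessful-search length.
#'
#' @param points a `donor_points` data.frame (one condition) or a numeric
#'   coordinate matrix with at least 2 rows.
#' @param n_trees number of trees (default 500).
#' @param subsample per-tree subsample size (default 256, clamped to the
#'   number of points with a warning).
#' @param contamination assumed outlier fraction in (0, 0.5], or
#'   `"auto"`.
#' @param seed integer seed; identical inputs and seed give identical
#'   flags. The caller's RNG state is left untouched.
#' @return An `outlier_labeling` data.frame: `accession`, `condition`,
#'   `score`, `outlier`; attribute `params`.
#' @export
fit_isolation_forest <- function(points, n_trees = 500, subsample = 256,
                                 contamination = 0.10, seed = 1337) {
  coords <- if (is.matrix(points)) points else donor_coords(points)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points")
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("point coordinates must be finite")
  }
  if (n_trees < 1L) stop("n_trees must be >= 1")
  auto <- identical(contamination, "auto") || identical(contamination, "AUTO")
  if (!auto && (!is.numeric(contamination) || contamination <= 0 ||
                contamination > 0.5)) {
    stop("contamination must be in (0, 0.5] or \"auto\"")
  }
  if (subsample > n) {
    warning("subsample (", subsample, ") larger than the number of points (",
            n, "); clamping")
    subsample <- n
  }
  subsample <- as.integer(subsample)
  depth_limit <- ceiling(log2(subsample))
  cn_table <- iforest_cn(seq_len(subsample))

  path_sum <- numeric(n)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      take <- if (subsample == n) seq_len(n) else sample(n, subsample)
      tree <- build_itree(coords[take, , drop = FALSE], depth_limit)
      path_sum <- path_sum + itree_path(tree, coords, cn_table)
    }
  })
  e_h <- path_sum / n_trees
  score <- 2^(-e_h / cn_table[subsample])

  if (auto) {
    flag <- score > 0.5
  } else {
    m_out <- min(n, ceiling(contamination * n))
    flag <- logical(n)
    flag[order(-score, seq_len(n))[seq_len(m_out)]] <- TRUE
  }
  out <- data.frame(
    accession = if (is.matrix(points)) rownames(coords) else points$accession,
    condition = if (is.matrix(points)) NA_character_ else points$condition,
    score = score,
    outlier = flag,
    stringsAsFactors = FALSE)
  attr(out, "params") <- list(n_trees = n_trees, subsample = subsample,
                              contamination = contamination, seed = seed)
  class(out) <- c("outlier_labeling", "data.frame")
  out
}

#' Pair per-condition outlier flags across a comparison
#'
#' A protein extreme in either condition can produce a large
#' cross-condition displacement, so the default keeps the union of the two
#' conditions' outlier sets.
#'
#' @param labelings list of two `outlier_labeling` objects (or a named
#'   list keyed by condition) covering both conditions of `comparison`.
#' @param comparison a [comparison_spec()].
#' @param rule `"union"` (default), `"intersection"`, or
#'   `"either_condition_only"` (flagged in exactly one condition).
#' @return character vector of accessions.
#' @export
outlier_union <- function(labelings, comparison,
                          rule = c("union", "intersection",
                                   "either_condition_only")) {
  rule <- match.arg(rule)
  stopifnot(inherits(comparison, "comparison_spec"))
  if (inherits(labelings, "outlier_labeling")) labelings <- list(labelings)
  all_lab <- do.call(rbind, lapply(labelings, function(x) {
    as.data.frame(x)[, c("accession", "condition", "outlier")]
  }))
  pick <- function(cond) {
    rows <- all_lab$condition == cond
    if (!any(rows)) {
      stop("no outlier labeling supplied for condition '", cond, "'")
    }
    all_lab$accession[rows & all_lab$outlier]
  }
  a <- pick(comparison$reference)
  b <- pick(comparison$treatment)
  switch(rule,
         union = union(a, b),
         intersection = intersect(a, b),
         either_condition_only = setdiff(union(a, b), intersect(a, b)))
}
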
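# Independent oracles used across tests. These deliberately re-derive
# results by brute force or closed form, never through the code paths they
# check.

# Textbook DBSCAN by breadth-first search over core points. Neighborhood
# counts exclude the point itself, matching the package's core-distance
# convention. Returns 0 for noise.
brute_dbscan <- function(coords, eps, min_pts) {
  D <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  core <- vapply(seq_len(n), function(i) sum(D[i, -i] <= eps) >= min_pts,
                 logical(1))
  labels <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    labels[i] <- cid
    queue <- i
    while (length(queue)) {
      p <- queue[1L]
      queue <- queue[-1L]
      nb <- which(D[p, ] <= eps)
      nb <- nb[nb != p]
      for (q in nb) {
        if (labels[q] == 0L) {
          labels[q] <- cid
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# Canonical relabeling: clusters numbered by first occurrence, noise stays 0.
canon_labels <- function(l) {
  ids <- unique(l[l != 0L])
  out <- match(l, ids)
  out[l == 0L] <- 0L
  as.integer(out)
}

# k-th nearest neighbor distance (self excluded) by exhaustive search.
brute_knn_dist <- function(coords, i, k) {
  d <- sqrt(colSums((t(coords) - coords[i, ])^2))
  sort(d[-i])[k]
}

# Two-sided pooled-variance two-sample t-test from the textbook formula.
pooled_t_p <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
}

# Full DBSCAN-equivalence check of an extracted assignment: identical
# noise set, one-to-one cluster correspondence on core points, and every
# border point attached to a cluster with a core point within eps (the
# only freedom DBSCAN itself leaves open).
expect_dbscan_equiv <- function(asg, coords, eps, min_pts) {
  oracle <- brute_dbscan(coords, eps, min_pts)
  D <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  core <- vapply(seq_len(n), function(i) sum(D[i, -i] <= eps) >= min_pts,
                 logical(1))
  testthat::expect_identical(asg$cluster == 0L, oracle == 0L)
  co <- table(asg$cluster[core], oracle[core])
  testthat::expect_true(all(rowSums(co > 0) == 1L))
  testthat::expect_true(all(colSums(co > 0) == 1L))
  for (p in which(!core & asg$cluster != 0L)) {
    same <- which(core & asg$cluster == asg$cluster[p])
    testthat::expect_true(any(D[p, same] <= eps))
  }
}

# Degree-2 polynomial least squares straight from the normal equations.
normal_eq_quadratic <- function(x, y) {
  M <- cbind(1, x, x^2)
  as.numeric(solve(t(M) %*% M, t(M) %*% y)) # (c, b, a)
}
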
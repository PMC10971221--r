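# Two log-scale clouds in donor space with one negative raw cell in the
# low cloud; epsilon_floor keeps the floored point inside its cloud so the
# positivity rule (not geometry) decides the selection.
two_cloud_table <- function(n_hi = 6, n_lo = 8, seed = 4) {
  set.seed(seed)
  donors <- c("d1", "d2", "d3")
  conditions <- c("ctrl", "doped")
  n <- n_hi + n_lo
  base <- c(rep(10, n_hi), rep(2, n_lo))
  keys <- c(outer(donors, conditions, paste, sep = ":"))
  vals <- matrix(2^(base + rnorm(n * 6, 0, 0.1)), nrow = n,
                 dimnames = list(sprintf("P%02d", seq_len(n)), keys))
  abundance_table(vals,
                  data.frame(accession = rownames(vals), gene = "", name = "",
                             stringsAsFactors = FALSE),
                  donors = donors, conditions = conditions)
}

test_that("core distances match the exhaustive k-NN oracle", {
  coords <- cbind(c(0, 1, 2.5, 4, 7, 11, 16), 0, 0) # 7 points on a line
  pts <- as_points(coords)
  asg <- optics_order(pts, min_pts = 3)
  for (i in seq_len(nrow(coords))) {
    expect_equal(asg$core_dist[i], brute_knn_dist(coords, i, 3))
  }
})

test_that("separated blobs give two clusters, one blob gives one", {
  pts <- two_blob_points(60, 60, gap = 20, sd = 0.5, seed = 2)
  asg <- optics_order(pts, min_pts = 50)
  asg <- extract_clusters(asg, eps = 5)
  expect_setequal(unique(asg$cluster), c(1L, 2L))
  expect_equal(sum(asg$cluster == 1L), 60L)

  one <- as_points(matrix(rnorm(80 * 3), ncol = 3))
  a1 <- extract_clusters(optics_order(one, min_pts = 10), eps = 5)
  expect_equal(unique(a1$cluster), 1L)
})

test_that("a radius below all reachabilities labels everything noise", {
  pts <- two_blob_points(30, 30, seed = 5)
  asg <- optics_order(pts, min_pts = 5)
  asg <- extract_clusters(asg, eps = 1e-9)
  expect_true(all(asg$cluster == 0L))
  expect_error(select_primary_cluster(asg, NULL, rule = "largest"), "eps")
})

test_that("eps-extraction from the OPTICS ordering reproduces DBSCAN", {
  for (seed in 1:4) {
    set.seed(seed)
    centers <- matrix(rnorm(9, 0, 12), ncol = 3)
    coords <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rnorm(60 * 3, centers[k, ], 0.8), ncol = 3, byrow = TRUE)
    }))
    pts <- as_points(coords)
    for (eps in c(0.8, 1.5)) {
      asg <- extract_clusters(optics_order(pts, min_pts = 5), eps = eps)
      expect_dbscan_equiv(asg, coords, eps = eps, min_pts = 5)
    }
  }
})

test_that("labels are invariant to input permutation (up to renaming)", {
  pts <- two_blob_points(40, 40, gap = 15, sd = 0.6, seed = 7)
  perm <- sample(seq_len(nrow(pts)))
  ppts <- pts[perm, , drop = FALSE]
  attr(ppts, "donors") <- attr(pts, "donors")
  class(ppts) <- class(pts)
  a <- extract_clusters(optics_order(pts, min_pts = 10), eps = 4)
  b <- extract_clusters(optics_order(ppts, min_pts = 10), eps = 4)
  back <- integer(nrow(pts))
  back[perm] <- b$cluster
  expect_identical(canon_labels(a$cluster), canon_labels(back))
})

test_that("primary-cluster selection prefers all-positive raw areas", {
  tab <- two_cloud_table()
  tab$values["P10", "d2:doped"] <- -4 # low cloud carries a negative peak
  lt <- log_transform(tab, nonpositive_policy = "epsilon_floor", epsilon = 4)
  asg <- extract_clusters(optics_order(pool_donor_points(lt), min_pts = 5),
                          eps = 2)
  sel <- select_primary_cluster(asg, lt, rule = "largest_all_positive")
  chosen <- attr(sel, "selected_cluster")
  # the all-positive high cloud (12 points) wins over the larger low cloud
  expect_equal(sum(sel$cluster == chosen), 12L)
  expect_true(all(substr(sel$accession[sel$cluster == chosen], 2, 3) <= "06"))
  # plain size rule picks the low cloud instead
  sel2 <- select_primary_cluster(asg, lt, rule = "largest")
  expect_equal(sum(sel2$cluster == attr(sel2, "selected_cluster")), 16L)
})

test_that("selection falls back to largest with a warning if none qualifies", {
  # a single cloud whose only cluster carries a floored negative peak
  set.seed(14)
  donors <- c("d1", "d2", "d3")
  keys <- c(outer(donors, c("ctrl", "doped"), paste, sep = ":"))
  vals <- matrix(2^(2 + rnorm(60, 0, 0.1)), nrow = 10,
                 dimnames = list(sprintf("P%02d", 1:10), keys))
  vals["P04", "d2:doped"] <- -4
  tab <- abundance_table(vals,
                         data.frame(accession = rownames(vals), gene = "",
                                    name = "", stringsAsFactors = FALSE),
                         donors = donors, conditions = c("ctrl", "doped"))
  lt <- log_transform(tab, nonpositive_policy = "epsilon_floor", epsilon = 4)
  asg <- extract_clusters(optics_order(pool_donor_points(lt), min_pts = 5),
                          eps = 2)
  expect_warning(sel <- select_primary_cluster(asg, lt), "falling back")
  expect_false(is.null(attr(sel, "selected_cluster")))
})

test_that("comparison filtering requires membership in both conditions", {
  tab <- two_cloud_table(n_hi = 8, n_lo = 5) # high cloud is primary here
  tab$values["P03", paste0(c("d1", "d2", "d3"), ":doped")] <- 2^30 # isolated
  lt <- log_transform(tab)
  asg <- extract_clusters(optics_order(pool_donor_points(lt), min_pts = 5),
                          eps = 2)
  sel <- select_primary_cluster(asg, lt)
  cmp <- comparison_spec("ctrl", "doped")
  both <- filter_to_cluster(sel, cmp, membership = "both")
  either <- filter_to_cluster(sel, cmp, membership = "either")
  expect_false("P03" %in% both)
  expect_true("P03" %in% either)
  # set-algebra oracle
  chosen <- attr(sel, "selected_cluster")
  in_ref <- sel$accession[sel$cluster == chosen & sel$condition == "ctrl"]
  in_trt <- sel$accession[sel$cluster == chosen & sel$condition == "doped"]
  expect_setequal(both, intersect(in_ref, in_trt))
  expect_setequal(either, union(in_ref, in_trt))
})

test_that("too few points for min_pts is an informative error", {
  pts <- as_points(matrix(rnorm(15), ncol = 3))
  expect_error(optics_order(pts, min_pts = 50), "smaller min_pts")
})
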
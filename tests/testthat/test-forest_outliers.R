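test_that("path-length normalizer matches exact harmonic arithmetic", {
  expect_equal(iforest_cn(1), 0)
  expect_equal(iforest_cn(2), 1) # 2*H(1) - 2*(1)/2
  for (n in 3:10) {
    expect_equal(iforest_cn(n),
                 2 * sum(1 / seq_len(n - 1)) - 2 * (n - 1) / n)
  }
  # a point whose expected path length equals c(n) scores exactly 0.5
  expect_equal(2^(-iforest_cn(100) / iforest_cn(100)), 0.5)
})

test_that("an isolated point attains the maximum score at any seed", {
  set.seed(99)
  blob <- matrix(rnorm(99 * 3, 0, 1), ncol = 3)
  far <- matrix(rep(10 * max(abs(blob)), 3), ncol = 3) # ~10 blob radii out
  pts <- as_points(rbind(blob, far))
  for (seed in c(1, 77, 4242)) {
    lab <- fit_isolation_forest(pts, n_trees = 500, subsample = 100, seed = seed)
    expect_equal(which.max(lab$score), 100L)
    expect_true(lab$outlier[100L])
    expect_true(all(lab$score > 0 & lab$score < 1))
  }
})

test_that("scores are reproducible and tied for duplicated points", {
  set.seed(3)
  coords <- matrix(rnorm(50 * 3), ncol = 3)
  coords[50, ] <- coords[1, ] # exact duplicate
  pts <- as_points(coords)
  a <- fit_isolation_forest(pts, n_trees = 200, subsample = 50, seed = 7)
  b <- fit_isolation_forest(pts, n_trees = 200, subsample = 50, seed = 7)
  expect_identical(a$score, b$score)
  expect_identical(a$outlier, b$outlier)
  # duplicates traverse every tree identically
  expect_identical(a$score[1], a$score[50])
  c2 <- fit_isolation_forest(pts, n_trees = 200, subsample = 50, seed = 8)
  expect_false(identical(a$score, c2$score))
})

test_that("flags are exactly translation invariant given the same seed", {
  set.seed(5)
  coords <- matrix(rnorm(80 * 3), ncol = 3)
  shifted <- coords + 123.4
  a <- fit_isolation_forest(as_points(coords), n_trees = 100, subsample = 80, seed = 11)
  b <- fit_isolation_forest(as_points(shifted), n_trees = 100, subsample = 80, seed = 11)
  expect_equal(a$score, b$score, tolerance = 1e-12)
  expect_identical(a$outlier, b$outlier)
})

test_that("contamination is validated and the subsample clamps", {
  pts <- as_points(matrix(rnorm(30), ncol = 3))
  expect_error(fit_isolation_forest(pts, contamination = 0.7), "contamination")
  expect_error(fit_isolation_forest(pts, contamination = 0), "contamination")
  expect_warning(fit_isolation_forest(pts, n_trees = 5, subsample = 1000),
                 "clamping")
  lab <- fit_isolation_forest(pts, n_trees = 50, subsample = 10,
                              contamination = "auto", seed = 1)
  expect_identical(lab$outlier, lab$score > 0.5)
})

test_that("outlier pairing follows the chosen set rule", {
  mk <- function(cond, acc, flag) {
    structure(data.frame(accession = acc, condition = cond, score = 0.5,
                         outlier = flag, stringsAsFactors = FALSE),
              class = c("outlier_labeling", "data.frame"))
  }
  cmp <- comparison_spec("ctrl", "doped")
  set.seed(6)
  for (i in 1:5) {
    acc <- sprintf("P%02d", 1:20)
    fa <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    fb <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    labs <- list(mk("ctrl", acc, fa), mk("doped", acc, fb))
    u <- outlier_union(labs, cmp, "union")
    i2 <- outlier_union(labs, cmp, "intersection")
    x <- outlier_union(labs, cmp, "either_condition_only")
    expect_length(u, sum(fa) + sum(fb) - length(i2)) # |A|+|B|-|A int B|
    expect_setequal(i2, acc[fa & fb])
    expect_setequal(x, acc[xor(fa, fb)])
  }
  # flagged in the treatment only is kept by the default union rule
  labs <- list(mk("ctrl", "P1", FALSE), mk("doped", "P1", TRUE))
  expect_identical(outlier_union(labs, cmp), "P1")
  labs_none <- list(mk("ctrl", "P1", FALSE), mk("doped", "P1", FALSE))
  expect_length(outlier_union(labs_none, cmp), 0L)
})
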
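test_that("t-test handles identical, separated, and degenerate groups", {
  expect_equal(protein_ttest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_identical(protein_ttest(c(1, 2, 3), c(1, 2, 3))$tier, "ns")
  sep <- protein_ttest(c(0, 0.01, -0.01), c(10, 10.01, 9.99))
  expect_lt(sep$p_value, 0.05)
  expect_identical(sep$tier, "sig")
  expect_equal(protein_ttest(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  expect_warning(zero <- protein_ttest(c(5, 5, 5), c(7, 7, 7)), "zero")
  expect_equal(zero$p_value, 0)
})

test_that("pooled t-test agrees with the closed-form textbook formula", {
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(3, 0, 1)
    b <- rnorm(3, 0.8, 1.4)
    got <- protein_ttest(a, b, variant = "student")
    expect_equal(got$p_value, pooled_t_p(a, b), tolerance = 1e-12)
    expect_equal(got$p_value, protein_ttest(b, a)$p_value) # symmetry
  }
})

test_that("significance tiers use half-open boundaries", {
  expect_identical(p_tier(c(0, 0.049, 0.05, 0.0999, 0.1, 0.5, 1)),
                   c("sig", "sig", "marginal", "marginal", "ns", "ns", "ns"))
})

test_that("tiers recomputed from the case-study p-values match the reported stars", {
  va <- bioglass_variances()
  an <- bioglass_anomalies()
  merged <- merge(va, an, by = c("comparison", "experiment", "accession"))
  expect_equal(nrow(merged), nrow(va))
  expect_identical(p_tier(merged$p_value), merged$tier)
})

test_that("variance, variance difference, and CV follow their definitions", {
  expect_equal(within_group_variance(c(4, 4, 4)), 0)
  expect_equal(within_group_variance(c(1, 2, 3)), 1)
  expect_equal(abs_var_diff(13.0, 0.72), 12.28)
  expect_equal(abs_var_diff(2.79, 8.47), abs_var_diff(8.47, 2.79))
  expect_equal(abs_var_diff(0.5, 0.5), 0)
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_true(is.na(coefficient_of_variation(c(-1, 0, 1))))
  set.seed(30)
  for (i in 1:10) {
    v <- rnorm(5, 3, 2)
    expect_equal(coefficient_of_variation(v), sd(v) / mean(v))
    expect_equal(within_group_variance(v), sum((v - mean(v))^2) / 4)
  }
})

test_that("quadratic fit recovers exact and degenerate shapes", {
  x <- seq(-3, 3, by = 0.5)
  fit <- quadratic_fit(x, x^2)
  expect_equal(c(fit$a, fit$b, fit$c), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  flat <- quadratic_fit(x, rep(2.5, length(x)))
  expect_equal(c(flat$a, flat$b), c(0, 0), tolerance = 1e-10)
  expect_equal(flat$c, 2.5)
  expect_equal(flat$r_squared, 0)

  expect_error(quadratic_fit(rep(1, 5), rnorm(5)), "identical")
})

test_that("quadratic fit matches the normal-equations oracle", {
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(25)
    y <- 0.7 * x^2 - 1.2 * x + 3 + rnorm(25, 0, 0.5)
    fit <- quadratic_fit(x, y)
    oracle <- normal_eq_quadratic(x, y) # (c, b, a)
    expect_equal(c(fit$c, fit$b, fit$a), oracle, tolerance = 1e-8)
  }
})

test_that("venn regions partition the union", {
  r <- venn_regions(list(A = c("P1", "P2"), B = c("P2", "P3"), C = "P4"))
  expect_equal(r[["A&B"]], 1L)
  expect_equal(r[["A&B&C"]], 0L)
  expect_equal(sum(r), 4L) # |union|
  disjoint <- venn_regions(list(A = c("x", "y"), B = c("z")))
  expect_equal(disjoint[["A&B"]], 0L)
  expect_equal(disjoint[["A"]], 2L)
  set.seed(40)
  for (i in 1:5) {
    sets <- lapply(1:3, function(j) sample(sprintf("P%02d", 1:30),
                                           sample(5:20, 1)))
    names(sets) <- c("A", "B", "C")
    r <- venn_regions(sets)
    expect_equal(sum(r), length(unique(unlist(sets))))
    expect_equal(r[["A&B&C"]], length(Reduce(intersect, sets)))
  }
  # isoforms are distinct identities
  iso <- venn_regions(list(A = "P24821", B = "P24821-4"))
  expect_equal(iso[["A&B"]], 0L)
  expect_setequal(venn_members(list(A = c("P1", "P2"), B = "P2"), "A"), "P1")
})
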
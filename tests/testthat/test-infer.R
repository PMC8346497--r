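test_that("reference intervals match closed-form truth on clean data", {
  x <- bcn_sample(0, 2, 0.25, 100000, seed = 1)
  est <- estimate_reference_interval(x)
  truth <- exp(2 + c(-1, 1) * qnorm(0.975) * 0.25)
  expect_lt(abs(est$lower - truth[1]) / truth[1], 0.02)
  expect_lt(abs(est$upper - truth[2]) / truth[2], 0.02)
  expect_lt(est$lower, est$upper)
  expect_identical(est$n_excluded, 0L)
})

test_that("degenerate or invalid percentiles are rejected", {
  x <- bcn_sample(1, 99, 10, 5000, seed = 2)
  expect_error(estimate_reference_interval(x, percentiles = c(0.5, 0.5)),
               "increasing")
  expect_error(estimate_reference_interval(x, percentiles = c(0.9, 0.1)),
               "increasing")
  expect_error(estimate_reference_interval(x, percentiles = c(0, 0.975)),
               "increasing|inside")
})

test_that("non-positive and non-finite values are excluded with a count", {
  x <- c(bcn_sample(1, 99, 10, 5000, seed = 3), -5, 0, NA, Inf)
  est <- estimate_reference_interval(x, config = fast_config())
  expect_identical(est$n_excluded, 4L)
  expect_identical(est$n_used, 5000L)
})

test_that("limits are invariant to duplicating the dataset", {
  x <- bcn_sample(0.5, 10, 1, 20000, seed = 4)
  cfg <- fast_config()
  e1 <- estimate_reference_interval(x, config = cfg)
  e2 <- estimate_reference_interval(c(x, x), config = cfg)
  expect_lt(abs(e2$lower - e1$lower) / e1$lower, 0.02)
  expect_lt(abs(e2$upper - e1$upper) / e1$upper, 0.02)
})

test_that("limits scale equivariantly for log-normal data", {
  x <- bcn_sample(0, 2, 0.25, 20000, seed = 5)
  cfg <- fast_config()
  e1 <- estimate_reference_interval(x, config = cfg)
  e3 <- estimate_reference_interval(3 * x, config = cfg)
  expect_lt(abs(e3$lower - 3 * e1$lower) / (3 * e1$lower), 0.02)
  expect_lt(abs(e3$upper - 3 * e1$upper) / (3 * e1$upper), 0.02)
})

test_that("bootstrap CIs are deterministic, ordered and bracket the estimate", {
  x <- bcn_sample(1, 99, 10, 8000, seed = 6)
  cfg <- fast_config()
  b1 <- bootstrap_ci(x, n_boot = 8, seed = 11, config = cfg)
  b2 <- bootstrap_ci(x, n_boot = 8, seed = 11, config = cfg)
  expect_identical(b1$lower_ci, b2$lower_ci)
  expect_identical(b1$upper_ci, b2$upper_ci)
  expect_lte(b1$lower_ci[1], b1$lower_ci[2])
  expect_lte(b1$upper_ci[1], b1$upper_ci[2])
  expect_identical(b1$n_boot, 8L)
  # point estimates inside their intervals for this well-behaved dataset
  expect_gte(b1$lower, b1$lower_ci[1])
  expect_lte(b1$lower, b1$lower_ci[2])
  expect_gte(b1$upper, b1$upper_ci[1])
  expect_lte(b1$upper, b1$upper_ci[2])
})

test_that("two bootstrap replicates give the min/max interval", {
  x <- bcn_sample(1, 99, 10, 8000, seed = 7)
  cfg <- fast_config()
  b <- bootstrap_ci(x, n_boot = 2, ci_level = 0.95, seed = 21, config = cfg)
  # reproduce the two replicate estimates independently
  reps <- sapply(1:2, function(k) {
    set.seed(21 + k)
    xb <- x[sample.int(length(x), length(x), replace = TRUE)]
    e <- estimate_reference_interval(xb, config = cfg)
    c(e$lower, e$upper)
  })
  expect_equal(b$lower_ci, range(reps[1, ]))
  expect_equal(b$upper_ci, range(reps[2, ]))
})

test_that("seeding the master seed changes replicates without reshuffling", {
  x <- bcn_sample(1, 99, 10, 8000, seed = 8)
  cfg <- fast_config()
  b4 <- bootstrap_ci(x, n_boot = 4, seed = 31, config = cfg)
  b6 <- bootstrap_ci(x, n_boot = 6, seed = 31, config = cfg)
  # growing n_boot keeps earlier replicates: intervals nest plausibly
  expect_lte(b6$lower_ci[1], b4$lower_ci[2])
  expect_s3_class(b6, "ri_estimate")
})
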
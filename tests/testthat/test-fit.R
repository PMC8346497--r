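test_that("expected counts conserve mass and scale linearly in P", {
  model <- bcn_model(0.5, 10, 1)
  x <- bcn_sample(0.5, 10, 1, 50000, seed = 1)
  regions <- select_lambda_and_roi(x)
  hist1 <- build_overlap_histogram(x, regions, overlap_factor = 1L)
  ec <- expected_counts(bcn_model(0.5, 10, 1, p_frac = 1), hist1)
  # under the true model at P = 1, the partition total matches the in-ROI n
  expect_equal(sum(ec$m), hist1$n_in_roi, tolerance = 0.01)
  ec_half <- expected_counts(bcn_model(0.5, 10, 1, p_frac = 0.5), hist1)
  expect_equal(ec_half$m, ec$m / 2, tolerance = 1e-12)
  # a bin far left of the support holds no expected mass
  far <- bcn_model(0.5, 10, 1)
  h_far <- build_overlap_histogram(runif(2000, 0.1, 1), list(roi = c(0.1, 1)))
  expect_lt(max(expected_counts(far, h_far)$m), 1e-6 * h_far$n_total)
})

test_that("P search region tracks the observed-to-expected ratio", {
  model <- bcn_model(0.5, 10, 1)
  hist <- model_histogram(model, n = 50000, seed = 2)
  # clean data: region reaches (or clips at) 1
  pr <- estimate_p_region(hist, model)
  expect_lte(pr[1], pr[2])
  expect_gte(pr[2], 0.97)
  # scaling every count to 60% recenters the region near 0.6
  hist06 <- hist
  hist06$counts <- as.integer(round(hist$counts * 0.6))
  pr06 <- estimate_p_region(hist06, model)
  expect_gt(pr06[1], 0.5)
  expect_lt(pr06[2], 0.7)
})

test_that("P search region covers the truth under far contamination", {
  # 25% extra pathological mass far outside the peak
  m <- bcn_model(1, 99, 10)
  set.seed(3)
  x <- c(bcn_quantile(runif(40000), m), runif(10000, 300, 400))
  regions <- select_lambda_and_roi(x)
  hist <- build_overlap_histogram(x, regions)
  pr <- estimate_p_region(hist, m)
  expect_lte(pr[1], 0.8)
  expect_gte(pr[2], 0.78)
})

test_that("asymmetric band has Poisson endpoints and monotone asymmetry", {
  hist <- model_histogram(bcn_model(1, 99, 10), n = 20000, seed = 4)
  ec <- expected_counts(bcn_model(1, 99, 10, p_frac = 1), hist)
  ec$m <- rep(100, length(ec$m))
  b0 <- asymmetric_band(ec, pathological_hint = 0)
  expect_true(all(b0$lower == qpois(0.005, 100)))
  expect_true(all(b0$upper == qpois(0.995, 100)))
  expect_identical(c(b0$lower[1], b0$upper[1]), c(75, 127))
  b3 <- asymmetric_band(ec, pathological_hint = 0.3)
  expect_true(all(b3$upper <= b0$upper))
  expect_true(all(b3$lower <= b0$lower))
  ec$m <- rep(0, length(ec$m))
  bz <- asymmetric_band(ec, 0)
  expect_true(all(bz$lower == 0 & bz$upper == 0))
})

test_that("bin selection keeps consistent bins and rejects outliers", {
  model <- bcn_model(0.5, 10, 1, p_frac = 1)
  hist <- model_histogram(model, n = 50000, seed = 5)
  ec <- expected_counts(model, hist)
  band <- asymmetric_band(ec, 0)
  sel <- select_bins(hist, band)
  expect_gte(length(sel) / length(hist$counts), 0.95)
  # a 10-fold inflated bin leaves the band
  hist2 <- hist
  mid <- which.max(hist2$counts)
  hist2$counts[mid] <- hist2$counts[mid] * 10L
  expect_false(mid %in% select_bins(hist2, band))
  # all-zero observed counts against a large model: nothing selected
  hist3 <- hist
  hist3$counts <- rep(0L, length(hist3$counts))
  sel3 <- select_bins(hist3, band)
  cost3 <- poisson_cost(hist3, ec, sel3)
  expect_identical(cost3$ll, Inf)
})

test_that("cost follows the regularized Poisson negative log-likelihood", {
  hist <- model_histogram(bcn_model(1, 99, 10), n = 20000, seed = 6)
  ec <- expected_counts(bcn_model(1, 99, 10, p_frac = 1), hist)
  # single selected bin with h = m = 10, exact-arithmetic oracle
  hist$counts <- rep(10L, length(hist$counts))
  ec$m <- rep(10, length(ec$m))
  pmf <- 10^10 * exp(-10) / factorial(10)
  cr <- poisson_cost(hist, ec, selection = 1L)
  expect_equal(cr$ll, -(log(pmf) + log(10)), tolerance = 1e-12)
  # independent re-implementation over a fixed selection
  set.seed(8)
  hist$counts <- as.integer(rpois(length(hist$counts), 50))
  ec$m <- rep(50, length(ec$m))
  sel <- seq(3, 40)
  manual <- -sum(dpois(hist$counts[sel], 50, log = TRUE) +
                 log(hist$counts[sel])) / sqrt(length(sel))
  expect_equal(poisson_cost(hist, ec, sel)$ll, manual, tolerance = 1e-12)
  # per-bin likelihood is maximized when the expectation equals the count
  h0 <- 37
  ms <- seq(25, 50, by = 0.5)
  lik <- dpois(h0, ms, log = TRUE)
  expect_equal(ms[which.max(lik)], 37, tolerance = 0.5)
})

test_that("grid search recovers parameters and is a reproducible minimum", {
  x <- bcn_sample(0.5, 10, 1, 50000, seed = 7)
  regions <- select_lambda_and_roi(x)
  fit1 <- grid_search(x, regions)
  fit2 <- grid_search(x, regions)
  expect_identical(fit1$model, fit2$model)      # determinism
  expect_identical(fit1$best_cost, fit2$best_cost)
  truth <- bcn_quantile(c(0.025, 0.975), bcn_model(0.5, 10, 1))
  est <- bcn_quantile(c(0.025, 0.975), fit1$model)
  expect_lt(max(abs(est - truth) / truth), 0.02)
  # the returned minimum is no worse than any refined level-1 basin
  l1 <- fit1$search_trace$level1
  expect_lte(fit1$best_cost, min(l1$cost, na.rm = TRUE))
  # parameters respect the fixed lambda span
  expect_gte(fit1$model$lam, 0)
  expect_lte(fit1$model$lam, 1.5)
  expect_gt(fit1$model$sigma, 0)
})

test_that("fitted P recovers the simulated non-pathological fraction", {
  hits <- 0L
  cases <- expand.grid(p = c(0.7, 0.85, 1.0), s = 1:2)
  for (i in seq_len(nrow(cases))) {
    p <- cases$p[i]
    nonpath <- bcn_model(1, 99, 10)
    pcs <- if (p < 1)
      list(list(range = c(250, 320), fraction = 1 - p)) else list()
    spec <- simulation_spec(nonpath, pcs, n = 20000)
    x <- simulate_dataset(spec, seed = cases$s[i])
    fit <- grid_search(x, select_lambda_and_roi(x))
    if (abs(fit$model$p_frac - p) <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 5L)   # >= 80% of 6 cases
})

test_that("tail-only contamination barely moves the limits", {
  an <- analyte_specs()
  crea <- an$CREA
  te <- crea$te$te_value
  clean <- simulation_spec(crea$nonpath, n = 10000)
  dirty <- simulation_spec(crea$nonpath,
                           list(list(range = c(0.96 * 73, 1.73 * 73),
                                     fraction = 0.20)), n = 10000)
  e0 <- estimate_reference_interval(simulate_dataset(clean, seed = 9))
  e1 <- estimate_reference_interval(simulate_dataset(dirty, seed = 9))
  expect_lt(abs(e1$lower - e0$lower), te)
  expect_lt(abs(e1$upper - e0$upper), te)
})
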
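test_that("Box-Cox transform matches its closed forms and rejects bad input", {
  expect_equal(boxcox_transform(exp(1), 0), 1)
  expect_equal(boxcox_transform(2, 1), 1)
  expect_equal(boxcox_transform(4, 0.5), 2)
  expect_error(boxcox_transform(c(1, -2), 0.5), "positive")
  # strictly increasing in x for every grid lambda
  x <- sort(runif(100, 0.01, 50))
  for (lam in lambda_grid())
    expect_true(all(diff(boxcox_transform(x, lam)) > 0))
})

test_that("inverse transform round-trips to 1e-10 relative accuracy", {
  expect_equal(inverse_boxcox(1, 0), exp(1))
  expect_equal(inverse_boxcox(2, 0.5), 4)
  expect_error(inverse_boxcox(-10, 0.5), "unreachable")
  set.seed(42)
  x <- exp(runif(1000, log(1e-3), log(1e3)))
  for (lam in lambda_grid()) {
    back <- inverse_boxcox(boxcox_transform(x, lam), lam)
    expect_lt(max(abs(back - x) / x), 1e-10)
  }
})

test_that("density reduces to shifted normal and log-normal special cases", {
  x <- seq(0.5, 30, length.out = 200)
  # lambda = 1: X - 1 ~ N(mu, sigma^2), i.e. X ~ N(mu + 1, sigma^2)
  m1 <- bcn_model(1, 10, 2)
  # truncation renormalization is ~2e-8 here, hence the loose tolerance
  expect_equal(bcn_pdf(x, m1), dnorm(x, 11, 2), tolerance = 1e-6)
  # lambda = 0: log-normal
  m0 <- bcn_model(0, 2, 0.4)
  expect_equal(bcn_pdf(x, m0), dlnorm(x, 2, 0.4), tolerance = 1e-12)
  expect_true(all(bcn_pdf(seq(0.01, 100, 0.5), bcn_model(0.7, 5, 1)) >= 0))
})

test_that("density integrates to unit mass for all tested lambda", {
  for (lam in c(0, 0.3, 0.7, 1, 1.5)) {
    m <- bcn_model(lam, 8, 1.5)
    total <- integrate(function(x) bcn_pdf(x, m), 0, Inf,
                       rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("quantile function inverts the CDF and is monotone", {
  expect_equal(bcn_quantile(0.5, bcn_model(0, 0, 1)), 1)
  expect_equal(bcn_quantile(0.975, bcn_model(1, 10, 2)),
               10 + qnorm(0.975) * 2 + 1, tolerance = 1e-6)
  # numeric root-finding oracle: x solving CDF(x) = p
  m <- bcn_model(0.5, 5, 1)
  for (p in c(0.025, 0.3, 0.975)) {
    oracle <- uniroot(function(x) bcn_cdf(x, m) - p, c(1e-6, 500),
                      tol = 1e-12)$root
    expect_equal(bcn_quantile(p, m), oracle, tolerance = 1e-8)
  }
  # mutual inversion across the probability range
  probs <- seq(0.001, 0.999, length.out = 101)
  for (lam in c(0, 0.5, 1.5)) {
    mm <- bcn_model(lam, 6, 1.2)
    expect_equal(bcn_cdf(bcn_quantile(probs, mm), mm), probs,
                 tolerance = 1e-8)
    expect_true(all(diff(bcn_quantile(probs, mm)) > 0))
  }
  # monotone in mu
  q1 <- bcn_quantile(0.9, bcn_model(0.5, 5, 1))
  q2 <- bcn_quantile(0.9, bcn_model(0.5, 6, 1))
  expect_gt(q2, q1)
  expect_error(bcn_quantile(1.2, m), "inside")
})

test_that("lambda grid follows the printed construction", {
  g <- lambda_grid()
  expect_length(g, 14)
  expect_equal(g[1], 0)
  expect_equal(g[14], 1.5, tolerance = 1e-3)
  expect_true(all(diff(g) > 0))
  expect_equal(g[11], 1)                    # x = 1 maps to 1
  expect_lt(diff(g)[1], diff(g)[13])        # denser near 0
})

test_that("model constructor enforces its invariants", {
  expect_error(bcn_model(0.5, 1, 0), "sigma")
  expect_error(bcn_model(0.5, 1, 1, p_frac = 0), "p_frac")
  expect_error(bcn_model(0.5, 1, 1, p_frac = 1.2), "p_frac")
  m <- bcn_model(0.5, 1, 1, p_frac = 0.8)
  expect_s3_class(m, "bcn_model")
})
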
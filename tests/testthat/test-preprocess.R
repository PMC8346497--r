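test_that("ASH density recovers the mode and integrates to one", {
  set.seed(1)
  x <- rnorm(100000)
  d <- estimate_density(x, width_factor = 1)
  expect_lt(abs(d$grid[which.max(d$density)]), 0.05)
  integral <- sum((d$density[-1] + d$density[-length(d$density)]) / 2 *
                  diff(d$grid))
  expect_equal(integral, 1, tolerance = 0.01)
  expect_true(all(d$density >= 0))
  expect_error(estimate_density(rnorm(50)), "unreliable")
  expect_error(estimate_density(rep(1, 500)), "degenerate")
})

test_that("density estimation survives heavily quantized (tied) values", {
  set.seed(2)
  x <- round(rnorm(20000, 10, 0.5), 1)
  d <- estimate_density(x)
  expect_true(all(is.finite(d$density)))
  pk <- find_main_peak(d)
  expect_lt(abs(pk$mode_location - 10), 0.2)
})

test_that("main peak selection is by area, not by height", {
  set.seed(3)
  # the N(8, 0.5^2) component has the taller mode, the N(0, 2^2) the area
  x <- c(rnorm(30000, 0, 2), rnorm(20000, 8, 0.5))
  pk <- find_main_peak(estimate_density(x))
  expect_lt(abs(pk$mode_location), 1)
  # with mass reversed, the heavier component wins
  y <- c(rnorm(15000, 0, 1), rnorm(35000, 6, 1))
  pk2 <- find_main_peak(estimate_density(y))
  expect_lt(abs(pk2$mode_location - 6), 0.5)
  # bimodal sample: exactly two peaks survive merging and the noise floor
  z <- c(rnorm(35000, 0, 1), rnorm(15000, 6, 1))
  peaks <- indiref:::.find_peaks(estimate_density(z))
  expect_length(peaks, 2)
  # strictly monotone density: no local maximum to select
  mono <- structure(list(grid = seq_len(100),
                         density = exp(seq(0, 2, length.out = 100)),
                         bandwidth_params = list()),
                    class = "density_estimate")
  expect_error(find_main_peak(mono), "monotone")
})

test_that("peak widths recover Gaussian location and scale exactly", {
  # analytic density curve, no sampling noise
  g <- seq(-2, 12, length.out = 2001)
  d <- structure(list(grid = g, density = dnorm(g, 5, 2),
                      bandwidth_params = list()),
                 class = "density_estimate")
  pk <- find_main_peak(d)
  pr <- peak_parameter_ranges(d, pk)
  expect_equal(mean(pr$mu_candidates), 5, tolerance = 1e-3)
  expect_equal(mean(pr$sigma_candidates), 2, tolerance = 1e-2)
  # full width at half maximum of a Gaussian is 2 sigma sqrt(2 ln 2)
  half <- pr$sigma_candidates[pr$heights == 0.50]
  expect_equal(half, 2, tolerance = 1e-2)
  expect_lt(diff(pr$mu_range), 0.02)
  # a right-skewed curve drifts across heights: non-degenerate mu range
  ds <- structure(list(grid = seq(0.01, 20, length.out = 2001),
                       density = dlnorm(seq(0.01, 20, length.out = 2001),
                                        1, 0.5),
                       bandwidth_params = list()),
                  class = "density_estimate")
  prs <- peak_parameter_ranges(ds, find_main_peak(ds))
  expect_gt(diff(prs$mu_range), 0.05)
})

test_that("lambda selection matches the distribution family", {
  set.seed(11)
  x_ln <- exp(rnorm(100000, 1, 0.25))
  r_ln <- select_lambda_and_roi(x_ln)
  expect_lte(r_ln$lam_selected, lambda_grid()[2])
  x_n <- rnorm(100000, 100, 10)
  r_n <- select_lambda_and_roi(x_n[x_n > 0])
  expect_gte(r_n$lam_selected, lambda_grid()[10])
  expect_lte(r_n$lam_selected, lambda_grid()[12])
  # ROI approximates mu +/- 3 sigma in near-identity transform space
  expect_equal(r_n$roi[1], 70, tolerance = 0.1)
  expect_equal(r_n$roi[2], 130, tolerance = 0.1)
  # ROI contains the main-peak median
  expect_gt(median(x_n), r_n$roi[1])
  expect_lt(median(x_n), r_n$roi[2])
  expect_error(select_lambda_and_roi(c(x_n, -1)), "finite")
})

test_that("lambda selection lands within one grid step of the truth", {
  g <- lambda_grid()
  for (lam_true in c(0, 1)) {
    hits <- 0L
    for (s in 1:5) {
      x <- bcn_sample(lam_true, if (lam_true == 0) 2 else 99,
                      if (lam_true == 0) 0.25 else 10, 50000, seed = s)
      r <- select_lambda_and_roi(x)
      i_true <- which.min(abs(g - lam_true))
      i_sel <- which.min(abs(g - r$lam_selected))
      if (abs(i_sel - i_true) <= 1L) hits <- hits + 1L
    }
    expect_gte(hits, 4L)
  }
})

test_that("preprocessing is deterministic", {
  x <- bcn_sample(0.5, 10, 1, 20000, seed = 5)
  r1 <- select_lambda_and_roi(x)
  r2 <- select_lambda_and_roi(x)
  expect_identical(r1, r2)
  h1 <- build_overlap_histogram(x, r1)
  h2 <- build_overlap_histogram(x, r2)
  expect_identical(h1, h2)
})

test_that("overlapping bins count each interior point overlap-factor times", {
  set.seed(7)
  x <- runif(20000, 0, 10)
  regions <- list(roi = c(0, 10))
  h1 <- build_overlap_histogram(x, regions, overlap_factor = 1L)
  expect_identical(sum(h1$counts), length(x))          # plain partition
  h2 <- build_overlap_histogram(x, regions, overlap_factor = 2L)
  # every point except those in the first and last cell is in exactly 2 bins
  expect_equal(sum(h2$counts), 2 * length(x) * (1 - 1 / 60), tolerance = 0.05)
  expect_true(all(diff(h2$bin_lows) > 0))
  expect_true(all(h2$bin_highs > h2$bin_lows))
  # all data outside the ROI
  expect_error(build_overlap_histogram(x, list(roi = c(100, 110))),
               "inside the ROI")
})
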
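#' Estimate a reference interval from mixed real-world data
#'
#' Runs the full pipeline: exclusion of non-positive values, lambda/ROI
#' selection, overlapping-bin histogram, multi-level grid-search fit of the
#' Box-Cox normal non-pathological component, then the requested percentiles
#' of the fitted component. The scaling factor P plays no role in the
#' limits: they are quantiles of the non-pathological distribution alone.
#'
#' @param values Numeric laboratory results (one analyte, one stratum).
#'   Non-finite and non-positive entries are excluded with a count.
#' @param percentiles Two increasing probabilities in (0, 1); default the
#'   conventional 2.5th and 97.5th percentiles.
#' @param config An [analysis_config()] list of pipeline settings.
#' @return Object of class `ri_estimate`: `lower`, `upper`, `percentiles`,
#'   `fit` (a `fit_result`), `n_used`, `n_excluded`, and `NULL` CI fields
#'   until [bootstrap_ci()] fills them.
#' @export
#' @examples
#' x <- simulate_dataset(simulation_spec(bcn_model(0, 2, 0.25), n = 5000), seed = 1)
#' est <- estimate_reference_interval(x)
#' print(est)
estimate_reference_interval <- function(values,
                                        percentiles = c(0.025, 0.975),
                                        config = analysis_config()) {
  stopifnot(is.numeric(percentiles), length(percentiles) == 2L)
  if (any(percentiles <= 0 | percentiles >= 1) ||
      percentiles[1] >= percentiles[2])
    stop("estimate_reference_interval(): percentiles must be two increasing ",
         "values strictly inside (0, 1)", call. = FALSE)
  keep <- is.finite(values) & values > 0
  n_excl <- length(values) - sum(keep)
  v <- values[keep]
  regions <- withCallingHandlers(
    select_lambda_and_roi(v, heights = config$heights,
                          density_args = config$density_args),
    error = function(e) stop("preprocessing stage failed: ",
                             conditionMessage(e), call. = FALSE))
  fit <- withCallingHandlers(
    grid_search(v, regions,
                levels = config$levels, n_mu = config$n_mu,
                n_sigma = config$n_sigma,
                n_lambda_refine = config$n_lambda_refine,
                n_mu_refine = config$n_mu_refine,
                n_sigma_refine = config$n_sigma_refine,
                n_p = config$n_p, n_p_final = config$n_p_final,
                shrink = config$shrink,
                n_refine_starts = config$n_refine_starts,
                coverage = config$coverage,
                band_k = config$band_k, min_sel_frac = config$min_sel_frac,
                histogram_args = config$histogram_args),
    error = function(e) stop("model-fitting stage failed: ",
                             conditionMessage(e), call. = FALSE))
  lims <- bcn_quantile(percentiles, fit$model)
  structure(list(lower = lims[1], upper = lims[2], percentiles = percentiles,
                 fit = fit, n_used = length(v), n_excluded = n_excl,
                 lower_ci = NULL, upper_ci = NULL, n_boot = 0L,
                 ci_level = NULL, config = config),
            class = "ri_estimate")
}

#' Bootstrap confidence intervals for the reference limits
#'
#' Resamples the dataset with replacement `n_boot` times, refits the whole
#' pipeline on each resample, and takes the central `ci_level` empirical
#' region (percentile method, pure order statistics) of the resampled lower
#' and upper limits. Per-replicate seeds are derived as `seed + replicate`,
#' so increasing `n_boot` extends the replicate set without reshuffling
#' earlier replicates.
#'
#' @param values Numeric laboratory results.
#' @param n_boot Number of bootstrap refits (>= 2; e.g. 200 in routine use).
#' @param ci_level Nominal level of the percentile interval.
#' @param seed Master seed controlling all resampling.
#' @param percentiles,config Passed to [estimate_reference_interval()].
#' @return An `ri_estimate` whose `lower_ci`/`upper_ci` are `c(low, high)`;
#'   errors if more than 20% of refits fail (unstable data).
#' @export
bootstrap_ci <- function(values, n_boot = 200L, ci_level = 0.95, seed = 1L,
                         percentiles = c(0.025, 0.975),
                         config = analysis_config()) {
  stopifnot(n_boot >= 2L, ci_level > 0, ci_level < 1)
  est <- estimate_reference_interval(values, percentiles, config)
  keep <- is.finite(values) & values > 0
  v <- values[keep]
  n <- length(v)
  lows <- ups <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(as.integer((seed + b) %% .Machine$integer.max))
    vb <- v[sample.int(n, n, replace = TRUE)]
    eb <- tryCatch(estimate_reference_interval(vb, percentiles, config),
                   error = function(e) NULL)
    if (!is.null(eb)) {
      lows[b] <- eb$lower
      ups[b] <- eb$upper
    }
  }
  fail <- sum(is.na(lows))
  if (fail > 0.2 * n_boot)
    stop("bootstrap_ci(): ", fail, " of ", n_boot, " bootstrap refits failed; ",
         "the dataset is too unstable for interval estimation", call. = FALSE)
  if (fail > 0)
    warning("bootstrap_ci(): ", fail, " of ", n_boot,
            " bootstrap refits failed and were skipped")
  a <- (1 - ci_level) / 2
  est$lower_ci <- unname(stats::quantile(lows, c(a, 1 - a), na.rm = TRUE, type = 1))
  est$upper_ci <- unname(stats::quantile(ups, c(a, 1 - a), na.rm = TRUE, type = 1))
  est$n_boot <- as.integer(n_boot)
  est$ci_level <- ci_level
  est
}

#' @export
print.ri_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Reference interval (%.1f%% - %.1f%% of the non-pathological distribution)\n",
              100 * x$percentiles[1], 100 * x$percentiles[2]))
  fmt <- function(v) signif(v, digits)
  cat(sprintf("  lower limit: %s%s\n", fmt(x$lower),
              if (!is.null(x$lower_ci))
                sprintf("  (%g%% CI %s - %s)", 100 * x$ci_level,
                        fmt(x$lower_ci[1]), fmt(x$lower_ci[2])) else ""))
  cat(sprintf("  upper limit: %s%s\n", fmt(x$upper),
              if (!is.null(x$upper_ci))
                sprintf("  (%g%% CI %s - %s)", 100 * x$ci_level,
                        fmt(x$upper_ci[1]), fmt(x$upper_ci[2])) else ""))
  m <- x$fit$model
  cat(sprintf("  fitted model: lambda = %.4g, mu = %.4g, sigma = %.4g, P = %.3f\n",
              m$lam, m$mu, m$sigma, m$p_frac))
  cat(sprintf("  n used: %d (%d excluded)%s\n", x$n_used, x$n_excluded,
              if (x$n_boot > 0) sprintf("; bootstrap replicates: %d", x$n_boot)
              else ""))
  invisible(x)
}
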
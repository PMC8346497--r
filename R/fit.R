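#' Expected bin counts under a candidate model
#'
#' For bin \eqn{i} with edges \eqn{[a_i, b_i]}, the expected count is
#' \eqn{m_i = N \cdot P \cdot (F(b_i) - F(a_i))} where \eqn{F} is the
#' Box-Cox normal CDF, \eqn{N} the total number of (positive) input values
#' and \eqn{P} the non-pathological fraction carried by the model (1 when
#' unset).
#'
#' @param model A [bcn_model()] (its `p_frac` scales the counts).
#' @param histogram An `overlap_histogram`.
#' @return Object of class `expected_counts` with field `m` aligned to the
#'   histogram bins.
#' @export
expected_counts <- function(model, histogram) {
  stopifnot(inherits(model, "bcn_model"), inherits(histogram, "overlap_histogram"))
  p <- if (is.null(model$p_frac)) 1 else model$p_frac
  lo <- .boxcox_edge(histogram$bin_lows, model$lam)
  hi <- .boxcox_edge(histogram$bin_highs, model$lam)
  z0 <- .bcn_trunc_mass(model$lam, model$mu, model$sigma)
  fl <- pmax((stats::pnorm(lo, model$mu, model$sigma) - z0) / (1 - z0), 0)
  fh <- pmax((stats::pnorm(hi, model$mu, model$sigma) - z0) / (1 - z0), 0)
  m <- histogram$n_total * p * pmax(fh - fl, 0)
  structure(list(m = m, model = model, histogram = histogram),
            class = "expected_counts")
}

# Ratio of observed to expected (P = 1) counts over one probe region, with a
# normal-approximation interval on the Poisson ratio.
.probe_ratio <- function(h, m1, mask, z) {
  if (!any(mask)) return(NULL)
  sh <- sum(h[mask]); sm <- sum(m1[mask])
  if (sm <= 0) return(NULL)
  ratio <- sh / sm
  se <- sqrt(max(sh, 1)) / sm
  c(ratio - z * se, ratio + z * se)
}

#' Search region for the non-pathological fraction P
#'
#' Compares observed counts with unscaled (P = 1) expected counts over the
#' central peak region (bins whose centers lie within one candidate sigma of
#' the candidate mu in transformed space) and the two flanking one-to-two
#' sigma bands. Each region yields a count ratio with a Poisson-based
#' confidence interval; the P search region is bounded above by the smallest
#' upper limit (capped at 1) and below by the smallest lower limit (floored
#' at `floor_p`). Pathological admixture inflates some regions' ratios, so
#' taking minima keeps the region anchored to the cleanest part of the peak.
#'
#' @param histogram An `overlap_histogram`.
#' @param model A [bcn_model()] (any `p_frac` is ignored; P = 1 is used).
#' @param conf Confidence level of the per-region ratio intervals.
#' @param floor_p Lower floor for the search region.
#' @return Numeric `c(p_low, p_high)` with `p_low <= p_high <= 1`.
#' @export
estimate_p_region <- function(histogram, model, conf = 0.95, floor_p = 0.01) {
  stopifnot(inherits(histogram, "overlap_histogram"), inherits(model, "bcn_model"))
  m1 <- expected_counts(bcn_model(model$lam, model$mu, model$sigma), histogram)$m
  centers <- (histogram$bin_lows + histogram$bin_highs) / 2
  zc <- (.boxcox_edge(centers, model$lam) - model$mu) / model$sigma
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  h <- histogram$counts
  cis <- list(.probe_ratio(h, m1, abs(zc) <= 1, zq),
              .probe_ratio(h, m1, zc < -1 & zc >= -2, zq),
              .probe_ratio(h, m1, zc > 1 & zc <= 2, zq))
  cis <- cis[!vapply(cis, is.null, logical(1))]
  if (length(cis) == 0L)
    stop("estimate_p_region(): no probe region contains bins with expected mass",
         call. = FALSE)
  p_high <- min(1, min(vapply(cis, `[[`, numeric(1), 2)))
  p_low <- max(floor_p, min(vapply(cis, `[[`, numeric(1), 1)))
  p_high <- max(p_high, floor_p)
  p_low <- min(p_low, p_high)
  c(p_low, p_high)
}

#' Asymmetric Poisson confidence band around expected counts
#'
#' Per-bin count bounds from Poisson quantiles with a total tail mass of
#' `1 - coverage` (default 1%), so that when the model is correct the band
#' covers the observed non-pathological counts in 99% of cases. Because
#' pathological samples can only add counts (positive bias), the band's
#' upper reach shrinks as the estimated pathological fraction grows -
#' positively biased bins are rejected more readily, counteracting
#' overestimation of the limits: \eqn{\alpha_{low} = \frac{1-c}{2}(1 -
#' hint)^k} and \eqn{\alpha_{up} = (1-c) - \alpha_{low}}, so the upper bound
#' `qpois(1 - alpha_up, m)` decreases with `hint` while the lower bound
#' `qpois(alpha_low, m)` decreases or holds. At `hint = 0` the split is
#' central.
#'
#' @param expected An `expected_counts` object.
#' @param pathological_hint Estimated pathological fraction in `[0, 1)`.
#' @param coverage Nominal coverage of the band.
#' @param k Exponent of the asymmetry schedule.
#' @return Object of class `confidence_band` with `lower`, `upper`,
#'   `nominal_coverage` and `asymmetry_weight`.
#' @export
asymmetric_band <- function(expected, pathological_hint = 0, coverage = 0.99,
                            k = 2) {
  stopifnot(inherits(expected, "expected_counts"),
            pathological_hint >= 0, pathological_hint < 1)
  alpha <- 1 - coverage
  a_low <- (alpha / 2) * (1 - pathological_hint)^k
  a_up <- alpha - a_low
  structure(list(lower = stats::qpois(a_low, expected$m),
                 upper = stats::qpois(1 - a_up, expected$m),
                 nominal_coverage = coverage,
                 asymmetry_weight = pathological_hint,
                 alpha_low = a_low, alpha_up = a_up),
            class = "confidence_band")
}

#' Bins consistent with the candidate model
#'
#' Indices of bins whose observed count falls inside the confidence band;
#' these are the bins taken to describe non-pathological samples and the
#' only ones contributing to the cost.
#'
#' @param histogram An `overlap_histogram`.
#' @param band A `confidence_band` aligned with it.
#' @return Integer vector of selected bin indices (possibly empty).
#' @export
select_bins <- function(histogram, band) {
  stopifnot(inherits(histogram, "overlap_histogram"),
            inherits(band, "confidence_band"))
  which(histogram$counts >= band$lower & histogram$counts <= band$upper)
}

#' Regularized negative Poisson log-likelihood cost
#'
#' Over the selected bins,
#' \deqn{LL = -\frac{\sum_i [\log f(h_i \mid m_i) + \log r_i]}{\sqrt{s}}}
#' where \eqn{f} is the Poisson probability mass of the observed count
#' \eqn{h_i} given expectation \eqn{m_i}, the regularization \eqn{r_i = h_i}
#' rewards selecting high-count bins (most likely non-pathological), and the
#' \eqn{\sqrt{s}} denominator (s = number of selected bins) penalizes
#' selecting too many bins. A selected bin with \eqn{h_i = 0} contributes
#' only its likelihood term. An empty selection yields an infinite cost
#' (candidate rejected), not an error.
#'
#' @param histogram An `overlap_histogram`.
#' @param expected An `expected_counts` for the same histogram.
#' @param selection Integer indices from [select_bins()].
#' @return Object of class `cost_result` with `ll`, `selected_bins`, `s`, `r`.
#' @export
poisson_cost <- function(histogram, expected, selection) {
  stopifnot(inherits(histogram, "overlap_histogram"),
            inherits(expected, "expected_counts"))
  s <- length(selection)
  if (s == 0L)
    return(structure(list(ll = Inf, selected_bins = integer(0), s = 0L,
                          r = integer(0)), class = "cost_result"))
  h <- histogram$counts[selection]
  m <- expected$m[selection]
  loglik <- stats::dpois(h, m, log = TRUE)
  logreg <- ifelse(h > 0, log(h), 0)
  structure(list(ll = -sum(loglik + logreg) / sqrt(s),
                 selected_bins = selection, s = s, r = h),
            class = "cost_result")
}

# Remap (mu, sigma) expressed on the lam_from transformed scale to the
# lam_to scale, matching location and local spread at the back-transformed
# center x_c: mu' = bc(x_c, lam_to), sigma' = sigma * x_c^(lam_to - lam_from).
.remap_params <- function(mu, sigma, lam_from, lam_to) {
  xc <- inverse_boxcox(mu, lam_from)
  c(mu = boxcox_transform(xc, lam_to), sigma = sigma * xc^(lam_to - lam_from))
}

# Evaluate the cost over a P scan for one (lam, mu, sigma) candidate.
# Returns c(cost, p) of the best P, or NULL if the candidate is infeasible.
# Candidates must pass two consistency guards, both consequences of the
# model's own semantics (contamination can only ADD counts, and P is the
# claimed non-pathological fraction of the whole dataset):
#   1. excess-mass budget - the counts a candidate writes off as
#      pathological (bins above the band, plus unexplained mass outside the
#      ROI) may not exceed its own pathological budget (1 - P) * N plus a
#      sampling-noise slack;
#   2. explained-bin fraction - the selection must cover at least
#      `min_sel_frac` of the bins that carry data or predicted mass.
# Without these, a narrow model with small P can "shave off" large,
# perfectly consistent parts of the distribution as pathological and win
# the per-bin likelihood comparison (the sqrt(s) denominator rewards
# keeping only high-count bins).
.eval_combo <- function(h, lh, n_total, n_in, ov, te_lo, te_hi, zc_t,
                        lam, mu, sigma,
                        n_p, conf, floor_p, coverage, band_k,
                        min_sel_frac = 0.35) {
  z0 <- if (lam > 1e-12) stats::pnorm((-1 / lam - mu) / sigma) else 0
  fl <- pmax((stats::pnorm(te_lo, mu, sigma) - z0) / (1 - z0), 0)
  fh <- pmax((stats::pnorm(te_hi, mu, sigma) - z0) / (1 - z0), 0)
  m1 <- n_total * pmax(fh - fl, 0)
  zc <- (zc_t - mu) / sigma
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  cis <- list(.probe_ratio(h, m1, abs(zc) <= 1, zq),
              .probe_ratio(h, m1, zc < -1 & zc >= -2, zq),
              .probe_ratio(h, m1, zc > 1 & zc <= 2, zq))
  cis <- cis[!vapply(cis, is.null, logical(1))]
  if (length(cis) == 0L) return(NULL)
  p_high <- max(min(1, min(vapply(cis, `[[`, numeric(1), 2))), floor_p)
  p_low <- min(max(floor_p, min(vapply(cis, `[[`, numeric(1), 1))), p_high)
  pgrid <- if (p_high - p_low < 1e-12) p_low else
    seq(p_low, p_high, length.out = n_p)
  hint <- min(max(1 - (p_low + p_high) / 2, 0), 0.999)
  alpha <- 1 - coverage
  a_low <- (alpha / 2) * (1 - hint)^band_k
  a_up <- alpha - a_low
  m <- outer(m1, pgrid)
  lower <- stats::qpois(a_low, m)
  upper <- stats::qpois(1 - a_up, m)
  sel <- h >= lower & h <= upper
  dim(sel) <- dim(m)
  contrib <- stats::dpois(h, m, log = TRUE) + lh
  dim(contrib) <- dim(m)
  contrib[!sel] <- 0
  s <- colSums(sel)
  # excess-mass consistency: implied pathological counts vs budget N(1 - P)
  hi_excess <- (h - m) * (h > upper)
  dim(hi_excess) <- dim(m)
  mass_roi <- fh[length(fh)] - fl[1]
  path_out <- pmax(0, (n_total - n_in) - n_total * pgrid * (1 - mass_roi))
  implied <- colSums(hi_excess) / ov + path_out
  budget <- n_total * (1 - pgrid) + 2 * sqrt(n_total)
  informative <- h >= 5 | m >= 5
  dim(informative) <- dim(m)
  n_inf <- colSums(informative)
  cost <- ifelse(s == 0 | implied > budget | s < min_sel_frac * n_inf,
                 Inf, -colSums(contrib) / sqrt(s))
  i <- which.min(cost)
  if (!is.finite(cost[i])) return(NULL)
  c(cost = cost[i], p = pgrid[i], p_low = p_low, p_high = p_high)
}

.lin_grid <- function(lo, hi, n) {
  if (hi - lo < 1e-15) return(lo)
  seq(lo, hi, length.out = n)
}

#' Multi-level grid search for the non-pathological model
#'
#' Level 1 evaluates the cost on a coarse lattice over every grid
#' \eqn{\lambda} (each with its own preprocessing-derived \eqn{\mu}/\eqn{\sigma}
#' search ranges), optimizing the scaling factor P by a 1-D scan inside its
#' per-candidate search region. Each subsequent level shrinks the search
#' window `shrink`-fold around the incumbent minimum and re-grids it at
#' higher resolution, remapping the incumbent location/scale onto each
#' candidate \eqn{\lambda}'s transformed scale. A final denser P scan
#' polishes the optimum. Ties in cost resolve to the smallest \eqn{\lambda},
#' then the smallest \eqn{\sigma}. Fully deterministic.
#'
#' @param values Positive numeric sample (full dataset).
#' @param regions A `search_regions` from [select_lambda_and_roi()].
#' @param histogram Optional pre-built `overlap_histogram`; built from
#'   `regions` when `NULL`.
#' @param levels Number of grid levels (>= 1).
#' @param n_mu,n_sigma Lattice sizes at level 1.
#' @param n_lambda_refine,n_mu_refine,n_sigma_refine Lattice sizes at
#'   refinement levels.
#' @param n_p Points of the per-candidate P scan; `n_p_final` for the polish.
#' @param shrink Window shrink factor per refinement level.
#' @param n_refine_starts Number of top-ranked level-1 lambda basins refined
#'   independently (the overall minimum is returned).
#' @param coverage,band_k Confidence-band settings (see [asymmetric_band()]).
#' @param min_sel_frac Minimum fraction of informative bins (observed or
#'   expected count of at least 5) a candidate's selection must cover;
#'   guards against models that explain only a high-count core and write
#'   the rest of the distribution off as pathological.
#' @param p_conf,p_floor P-region settings (see [estimate_p_region()]).
#' @param histogram_args Arguments for [build_overlap_histogram()].
#' @return Object of class `fit_result`: `model` (with `p_frac` set), `cost`
#'   (a `cost_result`), `band`, `p_region`, `histogram`, `regions`,
#'   `search_trace`.
#' @export
grid_search <- function(values, regions, histogram = NULL, levels = 3L,
                        n_mu = 11L, n_sigma = 11L, n_lambda_refine = 7L,
                        n_mu_refine = 9L, n_sigma_refine = 9L,
                        n_p = 7L, n_p_final = 41L, shrink = 4,
                        n_refine_starts = 3L,
                        coverage = 0.99, band_k = 2, min_sel_frac = 0.35,
                        p_conf = 0.95, p_floor = 0.01,
                        histogram_args = list()) {
  stopifnot(inherits(regions, "search_regions"), levels >= 1L)
  if (is.null(histogram))
    histogram <- do.call(build_overlap_histogram,
                         c(list(values = values, regions = regions),
                           histogram_args))
  h <- histogram$counts
  lh <- ifelse(h > 0, log(h), 0)
  n_total <- histogram$n_total
  n_in <- histogram$n_in_roi
  ov <- histogram$overlap_factor
  centers <- (histogram$bin_lows + histogram$bin_highs) / 2

  eval_lattice <- function(lam_values, win_for, incumbent) {
    for (lam in lam_values) {
      win <- win_for(lam)
      if (is.null(win)) next
      te_lo <- .boxcox_edge(histogram$bin_lows, lam)
      te_hi <- .boxcox_edge(histogram$bin_highs, lam)
      zc_t <- .boxcox_edge(centers, lam)
      for (sigma in win$sigma) {
        for (mu in win$mu) {
          r <- .eval_combo(h, lh, n_total, n_in, ov, te_lo, te_hi, zc_t,
                           lam, mu, sigma, n_p, p_conf, p_floor, coverage,
                           band_k, min_sel_frac)
          if (!is.null(r) && r[["cost"]] < incumbent$cost) {
            incumbent <- list(cost = r[["cost"]], lam = lam, mu = mu,
                              sigma = sigma, p = r[["p"]])
          }
        }
      }
    }
    incumbent
  }
  empty <- list(cost = Inf, lam = NA_real_, mu = NA_real_, sigma = NA_real_,
                p = NA_real_)

  # level 1: the lambda values whose transformed view passes the symmetry
  # (skewness) eligibility screen, each with its own preprocessing-derived
  # ranges; keep the best candidate per lambda. Ineligible views correspond
  # to clearly asymmetric transforms, where the binned likelihood rewards
  # degenerate fits that shave off one tail.
  grid <- regions$grid
  elig <- regions$lam_eligible
  if (is.null(elig) || !any(elig)) elig <- rep(TRUE, length(grid))
  allowed <- grid[elig]
  level1 <- lapply(allowed, function(lam) {
    pl <- regions$per_lambda[[which(grid == lam)[1]]]
    if (!is.null(pl$error)) return(empty)
    eval_lattice(lam, function(lam)
      list(mu = .lin_grid(pl$mu_search[1], pl$mu_search[2], n_mu),
           sigma = .lin_grid(pl$sigma_search[1], pl$sigma_search[2], n_sigma)),
      empty)
  })
  l1_costs <- vapply(level1, `[[`, numeric(1), "cost")
  if (all(!is.finite(l1_costs))) {
    stop("grid_search(): every level-1 candidate was rejected (no bins ",
         "inside the confidence band); the data may not contain a usable ",
         "non-pathological peak", call. = FALSE)
  }

  # refine the most promising lambda basins independently: the level-1
  # ranking between lambda values is noisy at coarse lattice resolution,
  # so committing to a single incumbent risks refining the wrong basin
  starts <- order(l1_costs)[seq_len(min(n_refine_starts, sum(is.finite(l1_costs))))]
  best <- empty
  trace <- list(level1 = data.frame(lam = allowed, cost = l1_costs))
  for (st in starts) {
    inc <- level1[[st]]
    if (levels > 1L) {
      i_lam <- which.min(abs(grid - inc$lam))
      lam_win <- c(grid[max(1L, i_lam - 1L)],
                   grid[min(length(grid), i_lam + 1L)])
      pl <- regions$per_lambda[[i_lam]]
      mu_w <- diff(pl$mu_search)
      sig_w <- diff(pl$sigma_search)
      for (lev in 2:levels) {
        lam_lo <- max(min(allowed), inc$lam - diff(lam_win) / (2 * shrink^(lev - 2)))
        lam_hi <- min(max(allowed), inc$lam + diff(lam_win) / (2 * shrink^(lev - 2)))
        mu_half <- mu_w / (2 * shrink^(lev - 1))
        sig_half <- sig_w / (2 * shrink^(lev - 1))
        prev <- inc
        inc <- eval_lattice(.lin_grid(lam_lo, lam_hi, n_lambda_refine),
                            function(lam) {
          rp <- .remap_params(prev$mu, prev$sigma, prev$lam, lam)
          scale <- rp[["sigma"]] / prev$sigma
          sig_lo <- max(rp[["sigma"]] - sig_half * scale, 1e-12)
          list(mu = .lin_grid(rp[["mu"]] - mu_half * scale,
                              rp[["mu"]] + mu_half * scale, n_mu_refine),
               sigma = .lin_grid(sig_lo, rp[["sigma"]] + sig_half * scale,
                                 n_sigma_refine))
        }, inc)
      }
    }
    trace[[sprintf("start_lam_%g", signif(level1[[st]]$lam, 4))]] <- inc
    if (inc$cost < best$cost) best <- inc
  }

  # final denser P scan at the optimum
  te_lo <- .boxcox_edge(histogram$bin_lows, best$lam)
  te_hi <- .boxcox_edge(histogram$bin_highs, best$lam)
  zc_t <- .boxcox_edge(centers, best$lam)
  r <- .eval_combo(h, lh, n_total, n_in, ov, te_lo, te_hi, zc_t, best$lam,
                   best$mu, best$sigma, n_p_final, p_conf, p_floor, coverage,
                   band_k, min_sel_frac)
  if (!is.null(r) && r[["cost"]] <= best$cost) {
    best$cost <- r[["cost"]]
    best$p <- r[["p"]]
  }

  model <- bcn_model(best$lam, best$mu, best$sigma, p_frac = best$p)
  exp_c <- expected_counts(model, histogram)
  p_reg <- c(r[["p_low"]], r[["p_high"]])
  hint <- min(max(1 - mean(p_reg), 0), 0.999)
  band <- asymmetric_band(exp_c, pathological_hint = hint,
                          coverage = coverage, k = band_k)
  sel <- select_bins(histogram, band)
  cost <- poisson_cost(histogram, exp_c, sel)
  structure(list(model = model, cost = cost, band = band, p_region = p_reg,
                 best_cost = best$cost, histogram = histogram,
                 regions = regions, search_trace = trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Box-Cox normal mixture fit (inverse modelling)\n")
  print(x$model)
  cat(sprintf("  cost = %.6g over %d selected bins; P search region [%.3f, %.3f]\n",
              x$best_cost, x$cost$s, x$p_region[1], x$p_region[2]))
  invisible(x)
}
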
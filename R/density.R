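#' Average shifted histogram density estimate
#'
#' Nonparametric density estimation by averaging `m` histograms whose bin
#' origins are shifted by multiples of `h/m` (ASH). Averaging with biweight
#' kernel weights yields a smooth, fast estimator equivalent to a binned
#' kernel estimate. Deterministic given the input and settings.
#'
#' @param values Numeric sample (transformed or original units).
#' @param m Number of shifted histograms (kernel smoothing span).
#' @param nbins Number of unshifted histogram bins covering the data range;
#'   `NULL` selects a plug-in value from `width_factor` times the
#'   Freedman-Diaconis width (Scott's rule as fallback for heavily tied
#'   data), bounded to `[20, 500]`.
#' @param width_factor Multiplier on the plug-in bin width; values above 1
#'   oversmooth relative to the histogram-oriented plug-in rules, which is
#'   appropriate here because the density is only used for peak geometry.
#' @param min_n Minimum sample size; indirect estimation is unreliable on
#'   tiny samples.
#' @return Object of class `density_estimate` with fields `grid` (ordered
#'   evaluation points, fine-bin centers), `density` (non-negative, trapezoid
#'   integral within 1% of 1) and `bandwidth_params`.
#' @export
estimate_density <- function(values, m = 10L, nbins = NULL, width_factor = 3,
                             min_n = 100L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < min_n) {
    stop("estimate_density(): only ", n, " finite values; indirect reference ",
         "interval estimation is unreliable below ", min_n, " samples",
         call. = FALSE)
  }
  rng <- range(values)
  if (rng[1] == rng[2])
    stop("estimate_density(): degenerate sample (all values equal)", call. = FALSE)
  if (is.null(nbins)) {
    iqr <- stats::IQR(values)
    w <- if (iqr > 0) 2 * iqr * n^(-1 / 3) else 3.5 * stats::sd(values) * n^(-1 / 3)
    w <- w * width_factor
    nbins <- as.integer(min(500, max(20, ceiling(diff(rng) / w))))
  }
  m <- as.integer(m)
  h <- diff(rng) / nbins          # big-bin width
  delta <- h / m                  # fine-bin width
  # extend by m fine bins on each side so no kernel mass is clipped
  lo <- rng[1] - m * delta
  nfine <- nbins * m + 2L * m
  edges <- lo + delta * (0:nfine)
  idx <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), nfine)
  counts <- tabulate(idx, nbins = nfine)
  # biweight kernel weights over offsets |i| < m, normalized to sum to m
  off <- seq(-(m - 1L), m - 1L)
  k <- (15 / 16) * (1 - (off / m)^2)^2
  wts <- m * k / sum(k)
  sm <- stats::filter(counts, wts, sides = 2)
  sm[is.na(sm)] <- 0
  dens <- as.numeric(sm) / (n * h)
  grid <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(grid = grid, density = pmax(dens, 0),
                 bandwidth_params = list(m = m, nbins = nbins, h = h, delta = delta)),
            class = "density_estimate")
}

# Segment a density curve into peaks separated at local minima.
# Adjacent maxima whose separating minimum is shallow (dip ratio above
# `merge_frac` of the smaller peak height) are merged: sampling noise on a
# smooth peak produces such wiggles, a genuine second component does not.
# Maxima below `floor_frac` of the global maximum are treated as noise.
# Returns a list of peaks: mode index/location, support bounds, AUC fraction.
.find_peaks <- function(d, floor_frac = 1e-3, merge_frac = 0.85) {
  y <- d$density
  g <- d$grid
  n <- length(y)
  s <- sign(diff(y))
  # propagate signs through flat stretches so plateaus count once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turn <- which(diff(s) != 0) + 1L            # indices where slope changes
  maxima <- turn[s[turn - 1L] > 0 & s[turn] < 0]
  if (length(maxima) == 0L) return(list())
  sep_min <- function(i, j) { seg <- i:j; seg[which.min(y[seg])] }
  repeat {
    if (length(maxima) <= 1L) break
    vals <- y[maxima]
    dip <- vapply(seq_len(length(maxima) - 1L), function(j) {
      y[sep_min(maxima[j], maxima[j + 1L])] / min(vals[j], vals[j + 1L])
    }, numeric(1))
    j <- which.max(dip)
    if (dip[j] < merge_frac) break
    maxima <- maxima[-(if (vals[j] <= vals[j + 1L]) j else j + 1L)]
  }
  maxima <- maxima[y[maxima] >= floor_frac * max(y)]
  if (length(maxima) == 0L) return(list())
  bounds <- c(1L,
              vapply(seq_len(length(maxima) - 1L),
                     function(j) sep_min(maxima[j], maxima[j + 1L]), integer(1)),
              n)
  total <- sum((y[-1] + y[-n]) / 2 * diff(g))
  lapply(seq_along(maxima), function(k) {
    left <- bounds[k]
    right <- bounds[k + 1L]
    seg <- left:right
    auc <- sum((y[seg][-1] + y[seg][-length(seg)]) / 2 * diff(g[seg])) / total
    structure(list(mode_index = maxima[k], mode_location = g[maxima[k]],
                   left_bound = g[left], right_bound = g[right],
                   left_index = left, right_index = right, auc = auc),
              class = "density_peak")
  })
}

#' Select the main peak of a density estimate
#'
#' The density is segmented at its local minima; among the resulting peaks
#' the one with the largest area under the curve is returned. This is the
#' peak assumed to carry the non-pathological samples - not necessarily the
#' peak with the largest mode height.
#'
#' @param density A `density_estimate` from [estimate_density()].
#' @return Object of class `density_peak` with `mode_location`,
#'   `left_bound`, `right_bound` and `auc` (fraction of total area).
#' @export
find_main_peak <- function(density) {
  stopifnot(inherits(density, "density_estimate"))
  peaks <- .find_peaks(density)
  if (length(peaks) == 0L)
    stop("find_main_peak(): no local maximum found (monotone density)",
         call. = FALSE)
  peaks[[which.max(vapply(peaks, `[[`, numeric(1), "auc"))]]
}

#' Candidate location/scale ranges from peak widths
#'
#' Measures the width of the main peak at a ladder of fractional heights
#' (default 50%, 55%, ..., 95% of the mode density). Each width gives one
#' location candidate (the midpoint of the two crossings) and one scale
#' candidate: a Gaussian of standard deviation \eqn{\sigma} has full width
#' \eqn{2\sigma\sqrt{2\ln(1/h)}} at fractional height `h`, so
#' \eqn{\sigma =} width\eqn{/(2\sqrt{2\ln(1/h)})}. The spread of the
#' candidates over the ladder measures how asymmetric the peak is.
#'
#' @param density A `density_estimate`.
#' @param peak The peak to measure, from [find_main_peak()].
#' @param heights Fractional heights in (0, 1).
#' @return List with `mu_candidates`, `sigma_candidates` (one per usable
#'   height), `mu_range` and `sigma_range` (their min/max). Heights whose
#'   level line has no crossing inside the peak support are skipped; an
#'   error is raised if every height is skipped.
#' @export
peak_parameter_ranges <- function(density, peak,
                                  heights = seq(0.50, 0.95, by = 0.05)) {
  stopifnot(inherits(density, "density_estimate"), inherits(peak, "density_peak"))
  g <- density$grid
  y <- density$density
  mi <- peak$mode_index
  li <- peak$left_index
  ri <- peak$right_index
  ymax <- y[mi]
  mu_c <- sig_c <- rep(NA_real_, length(heights))
  for (j in seq_along(heights)) {
    lev <- heights[j] * ymax
    # walk out from the mode to the first grid interval crossing the level,
    # then interpolate linearly inside it
    xl <- NA_real_
    for (i in mi:max(li, 2L)) {
      if (y[i - 1L] < lev && y[i] >= lev) {
        xl <- g[i - 1L] + (lev - y[i - 1L]) / (y[i] - y[i - 1L]) * (g[i] - g[i - 1L])
        break
      }
      if (i - 1L <= li) break
    }
    xr <- NA_real_
    for (i in mi:min(ri, length(y) - 1L)) {
      if (y[i + 1L] < lev && y[i] >= lev) {
        xr <- g[i] + (y[i] - lev) / (y[i] - y[i + 1L]) * (g[i + 1L] - g[i])
        break
      }
      if (i + 1L >= ri) break
    }
    if (is.na(xl) || is.na(xr)) next
    mu_c[j] <- (xl + xr) / 2
    sig_c[j] <- (xr - xl) / (2 * sqrt(2 * log(1 / heights[j])))
  }
  ok <- !is.na(mu_c) & !is.na(sig_c) & sig_c > 0
  if (!any(ok))
    stop("peak_parameter_ranges(): no height level crossed inside the peak",
         call. = FALSE)
  list(mu_candidates = mu_c[ok], sigma_candidates = sig_c[ok],
       mu_range = range(mu_c[ok]), sigma_range = range(sig_c[ok]),
       heights = heights[ok])
}
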
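# Box-Cox transform that tolerates a 0 left edge (maps to the transform's
# lower limit) -- used for ROI/bin edges only, never for data values.
.boxcox_edge <- function(x, lam) {
  y <- numeric(length(x))
  pos <- x > 0
  y[pos] <- boxcox_transform(x[pos], lam)
  y[!pos] <- if (lam > 1e-12) -1 / lam else -Inf
  y
}

#' Select the power parameter and the region of interest
#'
#' For every candidate \eqn{\lambda} on [lambda_grid()] the data are
#' Box-Cox transformed, the density estimated, the main peak selected and
#' the location/scale candidate ranges measured with
#' [peak_parameter_ranges()]. Near the optimal \eqn{\lambda} the transformed
#' main peak is symmetric, so the candidates agree across heights; the
#' selected \eqn{\lambda} minimizes
#' \eqn{\sqrt{\mathrm{nr}(\mu)^2 + \mathrm{nr}(\sigma)^2}}, where nr is each
#' candidate range divided by the absolute candidate mean. The region of
#' interest is mean(\eqn{\mu}) +/- 3 mean(\eqn{\sigma}) in the selected
#' transformed space, mapped back to original units.
#'
#' @param values Strictly positive numeric sample (invalid values must be
#'   excluded beforehand, e.g. via [read_values()]).
#' @param grid Candidate \eqn{\lambda} values, default [lambda_grid()].
#' @param heights Fractional-height ladder for the peak widths.
#' @param mu_pad Padding of the location search range, in units of the mean
#'   scale candidate, added on both sides.
#' @param sigma_expand Multiplicative expansion `(low, high)` of the scale
#'   search range.
#' @param density_args Extra arguments passed to [estimate_density()].
#' @return Object of class `search_regions`: `lam_selected`, `mu_range`,
#'   `sigma_range` (padded, transformed space), `roi` (original units),
#'   `criterion` per lambda, and per-lambda candidate summaries used by the
#'   fitter.
#' @export
select_lambda_and_roi <- function(values, grid = lambda_grid(),
                                  heights = seq(0.50, 0.95, by = 0.05),
                                  mu_pad = 0.5, sigma_expand = c(0.5, 1.25),
                                  density_args = list()) {
  stopifnot(is.numeric(values), length(values) > 0)
  if (any(!is.finite(values) | values <= 0))
    stop("select_lambda_and_roi(): values must be finite and > 0; ",
         "run read_values() or filter first", call. = FALSE)
  eps <- .Machine$double.eps
  per <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    lam <- grid[i]
    res <- tryCatch({
      tv <- boxcox_transform(values, lam)
      d <- do.call(estimate_density, c(list(values = tv), density_args))
      pk <- find_main_peak(d)
      pr <- peak_parameter_ranges(d, pk, heights = heights)
      # normalize both ranges by the mean scale candidate: the transformed
      # location has an arbitrary origin (can sit at 0), so dividing the
      # location range by its own mean would make the criterion depend on
      # where the transform happens to place the peak, not on symmetry
      nr_mu <- diff(pr$mu_range) / (abs(mean(pr$sigma_candidates)) + eps)
      nr_sig <- diff(pr$sigma_range) / (abs(mean(pr$sigma_candidates)) + eps)
      ms <- mean(pr$sigma_candidates)
      # third-moment symmetry diagnostic: sample skewness of the transformed
      # values inside a window symmetric around the mode (clipped to the
      # peak support, so neighbouring components stay out); near the correct
      # lambda the window is drawn from a symmetric distribution and the
      # statistic is zero up to sampling noise
      half <- min(pk$mode_location - pk$left_bound,
                  pk$right_bound - pk$mode_location)
      w <- tv[tv >= pk$mode_location - half & tv <= pk$mode_location + half]
      skew <- if (length(w) >= 50 && stats::sd(w) > 0)
        mean((w - mean(w))^3) / stats::sd(w)^3 else NA_real_
      list(lam = lam, n_heights = length(pr$mu_candidates),
           skew = skew, n_window = length(w),
           mu_candidates = pr$mu_candidates,
           sigma_candidates = pr$sigma_candidates,
           mu_search = c(pr$mu_range[1] - mu_pad * ms,
                         pr$mu_range[2] + mu_pad * ms),
           sigma_search = c(max(pr$sigma_range[1] * sigma_expand[1], eps),
                            pr$sigma_range[2] * sigma_expand[2]),
           criterion = sqrt(nr_mu^2 + nr_sig^2),
           error = NULL)
    }, error = function(e) list(lam = lam, criterion = Inf,
                                error = conditionMessage(e)))
    per[[i]] <- res
  }
  crit <- vapply(per, `[[`, numeric(1), "criterion")
  if (all(!is.finite(crit))) {
    stop("select_lambda_and_roi(): preprocessing failed for every lambda: ",
         per[[1]]$error, call. = FALSE)
  }
  # lambda eligibility by the symmetry (skewness) diagnostic: keep only
  # views whose peak-window skewness is within sampling noise of the most
  # symmetric view; the width-based criterion then ranks those. Without
  # this filter, near-affine transforms (small relative spread) make the
  # width criterion pure noise across lambda.
  sk <- vapply(per, function(p)
    if (is.null(p$error) && !is.null(p$skew)) p$skew else NA_real_,
    numeric(1))
  nw <- vapply(per, function(p)
    if (is.null(p$error) && !is.null(p$n_window)) p$n_window else 0L,
    integer(1))
  eligible <- rep(FALSE, length(grid))
  if (any(is.finite(sk))) {
    sk_min <- min(abs(sk), na.rm = TRUE)
    tol <- pmax(0.05, 3 * sqrt(6 / pmax(nw, 1)))
    eligible <- is.finite(sk) & abs(sk) <= sk_min + tol
  }
  if (!any(eligible & is.finite(crit))) eligible <- is.finite(crit)
  crit[!eligible] <- Inf
  # candidate ranges are only comparable across lambda when measured from
  # the same number of height levels: a view where high levels found no
  # crossing gets a smaller candidate set and a spuriously small range
  nh <- vapply(per, function(p) if (is.null(p$error)) p$n_heights else 0L,
               integer(1))
  nh[!is.finite(crit)] <- 0L
  if (max(nh) > 0L) crit[nh < max(nh)] <- Inf
  best <- which.min(crit)   # ties resolve to the smallest lambda
  if (!is.finite(crit[best])) {
    crit <- vapply(per, `[[`, numeric(1), "criterion")
    best <- which.min(crit)
  }
  sel <- per[[best]]
  mu_m <- mean(sel$mu_candidates)
  sig_m <- mean(sel$sigma_candidates)
  t_lo <- mu_m - 3 * sig_m
  t_hi <- mu_m + 3 * sig_m
  lam <- sel$lam
  roi_lo <- if (lam > 1e-12 && 1 + lam * t_lo <= 0) 0 else inverse_boxcox(t_lo, lam)
  roi_hi <- inverse_boxcox(t_hi, lam)
  structure(list(lam_selected = lam,
                 mu_range = sel$mu_search,
                 sigma_range = sel$sigma_search,
                 roi = c(roi_lo, roi_hi),
                 criterion = crit,
                 skew = sk,
                 lam_eligible = eligible,
                 grid = grid,
                 per_lambda = per),
            class = "search_regions")
}

#' @export
print.search_regions <- function(x, ...) {
  cat(sprintf(paste0("Search regions: lambda = %.4g; mu in [%.4g, %.4g]; ",
                     "sigma in [%.4g, %.4g]\nROI (original units): [%.6g, %.6g]\n"),
              x$lam_selected, x$mu_range[1], x$mu_range[2],
              x$sigma_range[1], x$sigma_range[2], x$roi[1], x$roi[2]))
  invisible(x)
}

#' Histogram with overlapping bins over the region of interest
#'
#' The ROI is partitioned into `n_starts` equal cells; each histogram bin
#' spans `overlap_factor` consecutive cells, and consecutive bins start one
#' cell apart. Every interior data point therefore falls into exactly
#' `overlap_factor` bins - a compromise between per-bin noise and a smooth
#' representation of the distribution. Values outside the ROI are excluded
#' from binning but still counted in `n_total`, which anchors the meaning of
#' the non-pathological fraction P as a fraction of the whole dataset.
#'
#' @param values Positive numeric sample (full dataset).
#' @param regions A `search_regions` object (or any list with a `roi` field).
#' @param overlap_factor Number of cells per bin (1 = plain partition).
#' @param n_starts Number of partition cells across the ROI.
#' @param min_in_roi Minimum number of in-ROI values required.
#' @return Object of class `overlap_histogram` with `bin_lows`, `bin_highs`,
#'   `counts`, `n_total`, `n_in_roi`, `overlap_factor`, `base_width` and the
#'   internal `fine_edges`/`fine_counts` used by the fitter.
#' @export
build_overlap_histogram <- function(values, regions, overlap_factor = 2L,
                                    n_starts = 60L, min_in_roi = 50L) {
  roi <- regions$roi
  stopifnot(length(roi) == 2L, roi[1] < roi[2])
  overlap_factor <- as.integer(overlap_factor)
  n_starts <- as.integer(n_starts)
  stopifnot(overlap_factor >= 1L, n_starts > overlap_factor)
  inside <- values >= roi[1] & values <= roi[2]
  n_in <- sum(inside)
  if (n_in < min_in_roi)
    stop("build_overlap_histogram(): only ", n_in, " values inside the ROI [",
         signif(roi[1], 6), ", ", signif(roi[2], 6), "]; need at least ",
         min_in_roi, call. = FALSE)
  edges <- seq(roi[1], roi[2], length.out = n_starts + 1L)
  idx <- findInterval(values[inside], edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_starts)
  fine <- tabulate(idx, nbins = n_starts)
  nb <- n_starts - overlap_factor + 1L
  counts <- vapply(seq_len(nb),
                   function(j) sum(fine[j:(j + overlap_factor - 1L)]),
                   numeric(1))
  structure(list(bin_lows = edges[seq_len(nb)],
                 bin_highs = edges[seq_len(nb) + overlap_factor],
                 counts = as.integer(counts),
                 n_total = length(values),
                 n_in_roi = n_in,
                 overlap_factor = overlap_factor,
                 base_width = diff(edges[1:2]) * overlap_factor,
                 fine_edges = edges),
            class = "overlap_histogram")
}

#' @export
print.overlap_histogram <- function(x, ...) {
  cat(sprintf(paste0("Overlapping-bin histogram: %d bins (overlap factor %d), ",
                     "%d of %d values in ROI [%.6g, %.6g]\n"),
              length(x$counts), x$overlap_factor, x$n_in_roi, x$n_total,
              x$bin_lows[1], x$bin_highs[length(x$bin_highs)]))
  invisible(x)
}
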
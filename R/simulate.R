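#' Declarative mixture specification for synthetic evaluation data
#'
#' Describes one simulated analyte: a Box-Cox normal non-pathological
#' component plus zero or more pathological components, each given by a
#' distribution family, a location range and a fraction of the total sample.
#' The ground-truth reference limits are the 2.5th/97.5th percentiles of the
#' non-pathological component (or the percentiles supplied).
#'
#' @param nonpath A [bcn_model()] generating the non-pathological component.
#' @param pathologicals List of pathological components, each a list with
#'   `range = c(low, high)`, `fraction` in `[0, 1)`, and optional
#'   `family = "uniform"` (default) or `"truncnorm"` (normal with mean at
#'   the range center and sd a quarter of the range, truncated to it).
#' @param n Total sample size per simulated dataset.
#' @param analyte_label Label, e.g. one of ALP, CREA, Hb, FT4, TSH, GGT.
#' @param te Optional total-error magnitude in measurement units (see
#'   [total_error_spec()]).
#' @param percentiles Percentiles defining the ground-truth limits.
#' @return Object of class `simulation_spec` with `gt_lower`/`gt_upper`.
#' @export
simulation_spec <- function(nonpath, pathologicals = list(), n = 10000L,
                            analyte_label = "custom", te = NULL,
                            percentiles = c(0.025, 0.975)) {
  stopifnot(inherits(nonpath, "bcn_model"), n >= 1)
  for (pc in pathologicals) {
    stopifnot(is.list(pc), length(pc$range) == 2L, pc$range[1] < pc$range[2],
              pc$fraction >= 0, pc$fraction < 1)
    if (!is.null(pc$family))
      stopifnot(pc$family %in% c("uniform", "truncnorm"))
  }
  fr <- vapply(pathologicals, `[[`, numeric(1), "fraction")
  if (length(fr) && sum(fr) >= 1)
    stop("simulation_spec(): pathological fractions must sum to < 1",
         call. = FALSE)
  gt <- bcn_quantile(percentiles, nonpath)
  structure(list(nonpath = nonpath, pathologicals = pathologicals,
                 n = as.integer(n), analyte_label = analyte_label, te = te,
                 percentiles = percentiles,
                 gt_lower = gt[1], gt_upper = gt[2]),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("Simulation spec '%s': n = %d, ground truth RI [%.5g, %.5g]\n",
              x$analyte_label, x$n, x$gt_lower, x$gt_upper))
  for (pc in x$pathologicals)
    cat(sprintf("  pathological %s(%.5g, %.5g), fraction %.2f\n",
                if (is.null(pc$family)) "uniform" else pc$family,
                pc$range[1], pc$range[2], pc$fraction))
  invisible(x)
}

.draw_pathological <- function(pc, n) {
  if (n == 0L) return(numeric(0))
  fam <- if (is.null(pc$family)) "uniform" else pc$family
  if (fam == "uniform") {
    stats::runif(n, pc$range[1], pc$range[2])
  } else {
    mu <- mean(pc$range)
    sd <- diff(pc$range) / 4
    plo <- stats::pnorm(pc$range[1], mu, sd)
    phi <- stats::pnorm(pc$range[2], mu, sd)
    stats::qnorm(stats::runif(n, plo, phi), mu, sd)
  }
}

#' Simulate one mixed dataset
#'
#' Component sample sizes are obtained by deterministic rounding of the
#' fractions (remainder to the non-pathological component); values are drawn
#' by quantile inversion and shuffled. Fully reproducible per seed.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @return Numeric vector of length `spec$n`.
#' @export
simulate_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(as.integer(seed))
  n_path <- vapply(spec$pathologicals,
                   function(pc) as.integer(round(pc$fraction * spec$n)),
                   integer(1))
  n_non <- spec$n - sum(n_path)
  x <- bcn_quantile(stats::runif(n_non), spec$nonpath)
  for (j in seq_along(spec$pathologicals))
    x <- c(x, .draw_pathological(spec$pathologicals[[j]], n_path[j]))
  sample(x)
}

#' Simulate the direct method
#'
#' Draws `n_ref` samples from the non-pathological component only (the
#' "apparently healthy" cohort), takes the empirical percentiles as the
#' reference limits, and repeats `reps` times to capture the sampling
#' uncertainty of the direct approach.
#'
#' @param spec A [simulation_spec()] (pathological components are ignored).
#' @param n_ref Reference cohort size, conventionally 120 or 400.
#' @param reps Number of repetitions.
#' @param seed Integer seed.
#' @param type Empirical quantile convention (`stats::quantile` type);
#'   default 7, linear interpolation between order statistics.
#' @return `reps` x 2 matrix with columns `lower` and `upper`.
#' @export
simulate_direct_method <- function(spec, n_ref = 120L, reps = 10000L,
                                   seed = 1L, type = 7) {
  stopifnot(inherits(spec, "simulation_spec"), n_ref >= 2, reps >= 1)
  set.seed(as.integer(seed))
  draws <- matrix(bcn_quantile(stats::runif(reps * n_ref), spec$nonpath),
                  nrow = reps)
  out <- t(apply(draws, 1, stats::quantile, probs = spec$percentiles,
                 type = type, names = FALSE))
  colnames(out) <- c("lower", "upper")
  out
}

#' Synthetic analyte simulation specifications
#'
#' Loads the packaged synthetic specifications for six common laboratory
#' analytes (ALP, CREA, Hb, FT4, TSH, GGT), spanning highly skewed
#' (log-normal-like) to Gaussian-like non-pathological distributions.
#' Each fixture defines the non-pathological component by its skewness
#' parameter and target reference interval, the total-error magnitude used
#' for scoring, and a matrix of pathological cells (left/right fraction
#' pairs; the left range sits just below the lower limit, the right range
#' just above the upper limit, overlapping each tail slightly).
#'
#' @param file Path to a specification JSON; default the packaged fixture.
#' @return Named list of analyte definitions; each has `specs` (one
#'   [simulation_spec()] per pathological cell), `te` (a
#'   [total_error_spec()]), and the raw parameters.
#' @export
analyte_specs <- function(file = system.file("extdata",
                                             "analytes_synthetic.json",
                                             package = "indiref")) {
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  raw <- raw[vapply(raw, function(a) is.list(a) && !is.null(a$label),
                    logical(1))]
  z <- stats::qnorm(0.975)
  lapply(raw, function(a) {
    tl <- boxcox_transform(a$ri_lower, a$lam)
    tu <- boxcox_transform(a$ri_upper, a$lam)
    nonpath <- bcn_model(a$lam, (tl + tu) / 2, (tu - tl) / (2 * z))
    te_val <- a$te_percent / 100 * (a$ri_lower + a$ri_upper) / 2
    left_rng <- c(0.51 * a$ri_lower, 1.02 * a$ri_lower)
    right_rng <- c(0.96 * a$ri_upper, 1.73 * a$ri_upper)
    specs <- lapply(a$cells, function(cell) {
      pcs <- list()
      if (cell[[1]] > 0)
        pcs <- c(pcs, list(list(range = left_rng, fraction = cell[[1]])))
      if (cell[[2]] > 0)
        pcs <- c(pcs, list(list(range = right_rng, fraction = cell[[2]])))
      simulation_spec(nonpath, pcs, n = a$n, analyte_label = a$label,
                      te = te_val)
    })
    list(label = a$label, unit = a$unit, nonpath = nonpath,
         te = total_error_spec(a$label, te_val), specs = specs,
         parameters = a)
  })
}
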
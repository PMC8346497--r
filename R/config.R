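#' Analysis configuration
#'
#' Bundles every tunable setting of the estimation pipeline with validated
#' defaults. The list is plain data (serializable to JSON and back without
#' loss), so a configuration can be stored alongside results.
#'
#' @param percentiles Reference-limit percentiles.
#' @param heights Fractional-height ladder for the peak-width measurements.
#' @param density_args List of [estimate_density()] settings (`m`, `nbins`).
#' @param histogram_args List of [build_overlap_histogram()] settings
#'   (`overlap_factor`, `n_starts`, `min_in_roi`).
#' @param levels,n_mu,n_sigma,n_lambda_refine,n_mu_refine,n_sigma_refine,n_p,n_p_final,shrink
#'   Grid-search lattice settings (see [grid_search()]).
#' @param coverage Nominal coverage of the Poisson confidence band.
#' @param band_k Exponent of the band's asymmetry schedule.
#' @param n_refine_starts Level-1 basins refined independently (see
#'   [grid_search()]).
#' @param min_sel_frac Minimum explained-bin fraction (see [grid_search()]).
#' @param n_boot,ci_level Bootstrap defaults for [bootstrap_ci()].
#' @param seed Default seed for seeded operations.
#' @param verbosity 0 = silent, 1 = progress messages.
#' @return Validated list of class `analysis_config`.
#' @export
analysis_config <- function(percentiles = c(0.025, 0.975),
                            heights = seq(0.50, 0.95, by = 0.05),
                            density_args = list(),
                            histogram_args = list(),
                            levels = 3L, n_mu = 11L, n_sigma = 11L,
                            n_lambda_refine = 7L, n_mu_refine = 9L,
                            n_sigma_refine = 9L, n_p = 7L, n_p_final = 41L,
                            shrink = 4, n_refine_starts = 3L,
                            coverage = 0.99, band_k = 2,
                            min_sel_frac = 0.35,
                            n_boot = 200L, ci_level = 0.95, seed = 1L,
                            verbosity = 0L) {
  stopifnot(length(percentiles) == 2L, all(percentiles > 0 & percentiles < 1),
            percentiles[1] < percentiles[2],
            all(heights > 0 & heights < 1),
            levels >= 1L, n_mu >= 1L, n_sigma >= 1L, n_p >= 1L,
            n_p_final >= 1L, shrink > 1,
            coverage > 0.5, coverage < 1, band_k >= 0,
            min_sel_frac >= 0, min_sel_frac < 1,
            n_boot >= 2L, ci_level > 0, ci_level < 1)
  structure(list(percentiles = percentiles, heights = heights,
                 density_args = density_args,
                 histogram_args = histogram_args,
                 levels = as.integer(levels), n_mu = as.integer(n_mu),
                 n_sigma = as.integer(n_sigma),
                 n_lambda_refine = as.integer(n_lambda_refine),
                 n_mu_refine = as.integer(n_mu_refine),
                 n_sigma_refine = as.integer(n_sigma_refine),
                 n_p = as.integer(n_p), n_p_final = as.integer(n_p_final),
                 shrink = shrink,
                 n_refine_starts = as.integer(n_refine_starts),
                 coverage = coverage, band_k = band_k,
                 min_sel_frac = min_sel_frac,
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed), verbosity = as.integer(verbosity)),
            class = "analysis_config")
}

#' Write / read an analysis configuration
#'
#' JSON round-trip: `read_config(write_config(cfg, path))` reproduces the
#' configuration.
#'
#' @param config An [analysis_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns an
#'   `analysis_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$density_args <- as.list(raw$density_args)
  raw$histogram_args <- as.list(raw$histogram_args)
  do.call(analysis_config, raw)
}

# Stable fingerprint of a configuration (md5 of its canonical JSON).
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
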
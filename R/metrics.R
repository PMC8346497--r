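#' Total-error specification for an analyte
#'
#' The total error combines biological variation and analytical error into
#' one allowable-deviation magnitude per analyte (measurement units); it is
#' the benchmark unit for judging whether an estimated reference limit is
#' close enough to the truth.
#'
#' @param analyte_label Analyte name.
#' @param te_value Positive total-error magnitude in measurement units.
#' @return Object of class `total_error_spec`.
#' @export
total_error_spec <- function(analyte_label, te_value) {
  stopifnot(is.numeric(te_value), length(te_value) == 1L, te_value > 0)
  structure(list(analyte_label = analyte_label, te_value = te_value),
            class = "total_error_spec")
}

#' Mean percentage error of estimated limits
#'
#' \eqn{MPE = \frac{100}{n}\sum_i |ri_i - gt| / gt}: the mean absolute
#' relative deviation from the ground-truth limit, in percent. Unlike the
#' signed bias, opposite deviations cannot cancel.
#'
#' @param estimates Estimated limit values.
#' @param gt Positive ground-truth limit.
#' @return Percentage (scalar).
#' @export
mpe <- function(estimates, gt) {
  stopifnot(length(estimates) >= 1L, length(gt) == 1L)
  if (!is.finite(gt) || gt <= 0) stop("mpe(): gt must be > 0", call. = FALSE)
  100 * mean(abs(estimates - gt) / gt)
}

#' Relative bias of estimated limits
#'
#' \eqn{100/n \sum_i (ri_i - gt)/gt}: the signed mean relative deviation in
#' percent; positive and negative deviations can cancel, so
#' `abs(relative_bias) <= mpe` always.
#'
#' @inheritParams mpe
#' @return Percentage (scalar, signed).
#' @export
relative_bias <- function(estimates, gt) {
  stopifnot(length(estimates) >= 1L, length(gt) == 1L)
  if (!is.finite(gt) || gt <= 0)
    stop("relative_bias(): gt must be > 0", call. = FALSE)
  100 * mean((estimates - gt) / gt)
}

#' Total-error category of an estimated limit
#'
#' Classifies the signed deviation `estimate - gt` into five categories:
#' within one total error (appropriate for reference-interval estimation),
#' within two total errors low/high (appropriate for quality control), or
#' outside two total errors low/high (inappropriate). Boundary deviations
#' belong to the inner category. Collapsing the signed categories recovers
#' the three quality groups.
#'
#' @param estimate Estimated limit value(s).
#' @param gt Ground-truth limit (scalar).
#' @param te A [total_error_spec()] or positive scalar.
#' @return Data frame (one row per estimate) with `estimate`, `gt`,
#'   `deviation` and `category` (ordered factor over the five levels).
#' @export
classify_te <- function(estimate, gt, te) {
  tv <- if (inherits(te, "total_error_spec")) te$te_value else te
  stopifnot(is.numeric(tv), tv > 0, length(gt) == 1L)
  dev <- estimate - gt
  cat <- ifelse(abs(dev) <= tv, "within_1TE",
         ifelse(abs(dev) <= 2 * tv,
                ifelse(dev < 0, "within_2TE_low", "within_2TE_high"),
                ifelse(dev < 0, "outside_2TE_low", "outside_2TE_high")))
  data.frame(estimate = estimate, gt = gt, deviation = dev,
             category = factor(cat, levels = te_category_levels()))
}

#' The five total-error category labels
#' @return Character vector of category levels, inner to outer.
#' @export
te_category_levels <- function() {
  c("within_1TE", "within_2TE_low", "within_2TE_high",
    "outside_2TE_low", "outside_2TE_high")
}

#' Collapse signed categories to the three quality colors
#' @param category Factor/character of five-level categories.
#' @return Factor with levels `within_1TE`, `within_2TE`, `outside_2TE`.
#' @export
collapse_te_categories <- function(category) {
  map <- c(within_1TE = "within_1TE",
           within_2TE_low = "within_2TE", within_2TE_high = "within_2TE",
           outside_2TE_low = "outside_2TE", outside_2TE_high = "outside_2TE")
  factor(unname(map[as.character(category)]),
         levels = c("within_1TE", "within_2TE", "outside_2TE"))
}

.score_records <- function(analyte, method, limit, estimates, gt, te, failed) {
  cl <- classify_te(estimates, gt, te)
  cl$category[failed] <- "outside_2TE_high"
  data.frame(analyte = analyte, method = method, limit = limit,
             estimate = estimates, gt = gt, deviation = cl$deviation,
             category = cl$category, failed = failed)
}

#' Run the simulation benchmark
#'
#' For every analyte cell, seed and method, estimates both reference limits
#' and scores them against the ground truth with [classify_te()], [mpe()]
#' and [relative_bias()]. The indirect method is run once per seed on a
#' fresh simulated mixture; the direct-method baselines resample the
#' non-pathological component (`direct_reps` repetitions per analyte, one
#' per seed when `NULL`). Individual estimation failures are kept as
#' outside-two-total-error records with a failure flag (excluded from
#' MPE/bias, which are undefined for a missing estimate).
#'
#' @param analytes Named list as returned by [analyte_specs()] (possibly
#'   subset, or with reduced `specs` per analyte).
#' @param seeds Integer vector of seeds, or a count (expanded to `1:seeds`).
#' @param methods Subset of `c("indirect", "direct120", "direct400")`.
#' @param direct_reps Repetitions for the direct baselines (`NULL` = one
#'   per seed).
#' @param config [analysis_config()] used by the indirect pipeline.
#' @return List with `records` (one row per estimate and limit), `summary`
#'   (per analyte x method x limit: category proportions in percent, MPE,
#'   relative bias) and `overall` (per method: limits pooled, analytes
#'   averaged).
#' @export
run_benchmark <- function(analytes, seeds = 10L,
                          methods = c("indirect", "direct120", "direct400"),
                          direct_reps = NULL, config = analysis_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(seeds) == 1L) seeds <- seq_len(seeds)
  recs <- list()
  for (a in analytes) {
    te <- a$te
    for (ci in seq_along(a$specs)) {
      spec <- a$specs[[ci]]
      cell_lab <- sprintf("%s_cell%d", a$label, ci)
      if ("indirect" %in% methods) {
        lo <- up <- rep(NA_real_, length(seeds))
        fail <- rep(FALSE, length(seeds))
        for (si in seq_along(seeds)) {
          x <- simulate_dataset(spec, seed = seeds[si])
          est <- tryCatch(estimate_reference_interval(x, spec$percentiles,
                                                      config = config),
                          error = function(e) NULL)
          if (is.null(est)) fail[si] <- TRUE else {
            lo[si] <- est$lower; up[si] <- est$upper
          }
        }
        recs[[length(recs) + 1L]] <-
          rbind(.score_records(a$label, "indirect", "lower", lo,
                               spec$gt_lower, te, fail),
                .score_records(a$label, "indirect", "upper", up,
                               spec$gt_upper, te, fail))
        recs[[length(recs)]]$cell <- cell_lab
      }
    }
    # direct baselines depend only on the non-pathological component:
    # run once per analyte, not per pathological cell
    for (meth in intersect(methods, c("direct120", "direct400"))) {
      n_ref <- if (meth == "direct120") 120L else 400L
      reps <- if (is.null(direct_reps)) length(seeds) else direct_reps
      spec0 <- a$specs[[1]]
      lims <- simulate_direct_method(spec0, n_ref = n_ref, reps = reps,
                                     seed = seeds[1])
      recs[[length(recs) + 1L]] <-
        rbind(.score_records(a$label, meth, "lower", lims[, "lower"],
                             spec0$gt_lower, te, rep(FALSE, reps)),
              .score_records(a$label, meth, "upper", lims[, "upper"],
                             spec0$gt_upper, te, rep(FALSE, reps)))
      recs[[length(recs)]]$cell <- sprintf("%s_direct", a$label)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records,
       summary = .benchmark_summary(records, by_limit = TRUE),
       overall = .benchmark_overall(records))
}

.benchmark_summary <- function(records, by_limit = TRUE) {
  keys <- if (by_limit) c("analyte", "method", "limit") else c("analyte", "method")
  split_f <- interaction(records[keys], drop = TRUE)
  rows <- lapply(split(records, split_f), function(d) {
    props <- 100 * prop.table(table(d$category))
    ok <- !d$failed & is.finite(d$estimate)
    # MPE/bias need a single gt per group; with by_limit=TRUE that holds
    mpe_v <- if (any(ok)) 100 * mean(abs(d$deviation[ok]) / d$gt[ok]) else NA_real_
    bias_v <- if (any(ok)) 100 * mean(d$deviation[ok] / d$gt[ok]) else NA_real_
    cbind(d[1, keys, drop = FALSE],
          as.data.frame(as.list(props)),
          data.frame(mpe = mpe_v, relative_bias = bias_v, n = nrow(d),
                     n_failed = sum(d$failed)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.benchmark_overall <- function(records) {
  per_analyte <- .benchmark_summary(records, by_limit = FALSE)
  rows <- lapply(split(per_analyte, per_analyte$method), function(d) {
    data.frame(method = d$method[1],
               within_1TE = mean(d$within_1TE),
               within_2TE = mean(d$within_2TE_low + d$within_2TE_high),
               outside_2TE = mean(d$outside_2TE_low + d$outside_2TE_high),
               mpe = mean(d$mpe, na.rm = TRUE),
               relative_bias = mean(d$relative_bias, na.rm = TRUE),
               n = sum(d$n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
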
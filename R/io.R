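#' Read laboratory values from delimited text
#'
#' Reads one analyte column from a CSV/TSV file (delimiter auto-detected by
#' default), coerces it to numeric and filters it to finite positive values,
#' itemizing the exclusions: non-numeric entries, non-finite numbers, and
#' non-positive values (a Box-Cox model needs positive support).
#'
#' @param path Path to a readable delimited text file.
#' @param column Column name or index; `NULL` picks the first column with
#'   any numeric content.
#' @param delimiter Field delimiter; `NULL` auto-detects.
#' @param decimal Decimal mark, `"."` or `","` (European exports).
#' @return Object of class `value_import`: `values` (usable numeric vector)
#'   and `exclusions` (counts per reason).
#' @export
read_values <- function(path, column = NULL, delimiter = NULL, decimal = ".") {
  if (!file.exists(path)) stop("read_values(): file not found: ", path,
                               call. = FALSE)
  stopifnot(decimal %in% c(".", ","))
  dt <- tryCatch(
    data.table::fread(path, sep = if (is.null(delimiter)) "auto" else delimiter,
                      dec = decimal, header = "auto", data.table = FALSE,
                      showProgress = FALSE),
    error = function(e) stop("read_values(): cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L || ncol(dt) == 0L)
    stop("read_values(): '", path, "' contains no data", call. = FALSE)
  to_num <- function(col) {
    if (is.numeric(col)) return(as.numeric(col))
    if (decimal == ",") col <- gsub(",", ".", col, fixed = TRUE)
    suppressWarnings(as.numeric(col))
  }
  if (is.null(column)) {
    for (j in seq_len(ncol(dt))) {
      cand <- to_num(dt[[j]])
      if (any(!is.na(cand))) { column <- j; break }
    }
    if (is.null(column))
      stop("read_values(): no numeric column found in '", path, "'",
           call. = FALSE)
  } else if (is.character(column) && !column %in% names(dt)) {
    stop("read_values(): no column named '", column, "' in '", path, "'",
         call. = FALSE)
  }
  raw <- dt[[column]]
  num <- to_num(raw)
  non_numeric <- sum(is.na(num) & !is.na(raw))
  non_numeric <- non_numeric + sum(is.na(raw))
  non_finite <- sum(!is.na(num) & !is.finite(num))
  non_positive <- sum(is.finite(num) & num <= 0)
  values <- num[is.finite(num) & num > 0]
  if (length(values) == 0L)
    stop("read_values(): no usable (finite, positive) values in '", path, "'",
         call. = FALSE)
  structure(list(values = values,
                 exclusions = list(non_numeric = non_numeric,
                                   non_finite = non_finite,
                                   non_positive = non_positive),
                 path = path, column = column),
            class = "value_import")
}

#' @export
print.value_import <- function(x, ...) {
  ex <- x$exclusions
  cat(sprintf("%d usable values from '%s' (excluded: %d non-numeric, %d non-finite, %d non-positive)\n",
              length(x$values), x$path, ex$non_numeric, ex$non_finite,
              ex$non_positive))
  invisible(x)
}

#' Serialize a reference-interval report
#'
#' Builds a report carrying the limits, optional bootstrap confidence
#' intervals (explicit `null` when absent, never silently missing), the
#' fitted model parameters, sample accounting, the seed and a hash of the
#' analysis settings. The JSON form round-trips losslessly through
#' [jsonlite::fromJSON()].
#'
#' @param estimate An `ri_estimate`.
#' @param format `"text"` or `"json"`.
#' @param path Optional file to write the report to.
#' @param exclusions Optional exclusion counts from [read_values()].
#' @param seed Seed recorded in the report.
#' @return The report as a character string, invisibly when `path` is given.
#' @export
write_report <- function(estimate, format = c("text", "json"), path = NULL,
                         exclusions = NULL, seed = NULL) {
  stopifnot(inherits(estimate, "ri_estimate"))
  format <- match.arg(format)
  m <- estimate$fit$model
  rep_list <- list(
    lower = estimate$lower, upper = estimate$upper,
    percentiles = estimate$percentiles,
    lower_ci = if (is.null(estimate$lower_ci)) NA else estimate$lower_ci,
    upper_ci = if (is.null(estimate$upper_ci)) NA else estimate$upper_ci,
    ci_level = if (is.null(estimate$ci_level)) NA else estimate$ci_level,
    n_boot = estimate$n_boot,
    model = list(lam = m$lam, mu = m$mu, sigma = m$sigma, p_frac = m$p_frac),
    n_used = estimate$n_used, n_excluded = estimate$n_excluded,
    exclusions = if (is.null(exclusions)) NA else exclusions,
    seed = if (is.null(seed)) NA else seed,
    settings_hash = .config_hash(estimate$config))
  out <- if (format == "json") {
    as.character(jsonlite::toJSON(rep_list, auto_unbox = TRUE,
                                  digits = I(17), na = "null",
                                  null = "null"))
  } else {
    ci_txt <- function(ci, lev) {
      if (length(ci) == 1 && is.na(ci)) "not bootstrapped"
      else sprintf("%g%% CI [%.6g, %.6g]", 100 * lev, ci[1], ci[2])
    }
    paste(c(
      "Reference interval estimate (indirect method)",
      sprintf("  percentiles: %.3f / %.3f", rep_list$percentiles[1],
              rep_list$percentiles[2]),
      sprintf("  lower limit: %.6g  (%s)", rep_list$lower,
              ci_txt(rep_list$lower_ci, rep_list$ci_level)),
      sprintf("  upper limit: %.6g  (%s)", rep_list$upper,
              ci_txt(rep_list$upper_ci, rep_list$ci_level)),
      sprintf("  model: lambda = %.6g, mu = %.6g, sigma = %.6g, P = %.4g",
              m$lam, m$mu, m$sigma, m$p_frac),
      sprintf("  n used: %d, excluded: %d", rep_list$n_used,
              rep_list$n_excluded),
      sprintf("  seed: %s  settings: %s",
              if (length(rep_list$seed) == 1 && is.na(rep_list$seed)) "-"
              else as.character(rep_list$seed),
              rep_list$settings_hash)),
      collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
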
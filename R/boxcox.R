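#' Box-Cox power transformation
#'
#' Applies the one-parameter Box-Cox transformation
#' \eqn{y = (x^\lambda - 1)/\lambda} for \eqn{\lambda \neq 0} and
#' \eqn{y = \ln x} for \eqn{\lambda = 0} to positive values. The transform is
#' strictly increasing in `x` for every `lam` and continuous in `lam` at 0.
#'
#' @param x Numeric vector of strictly positive values.
#' @param lam Single finite power parameter \eqn{\lambda}.
#' @return Numeric vector of transformed values, same length as `x`.
#' @seealso [inverse_boxcox()]
#' @export
#' @examples
#' boxcox_transform(exp(1), 0)   # 1
#' boxcox_transform(4, 0.5)      # 2
boxcox_transform <- function(x, lam) {
  stopifnot(is.numeric(x), length(lam) == 1L, is.finite(lam))
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    stop("boxcox_transform() requires strictly positive values; offending values: ",
         paste(utils::head(x[bad], 5L), collapse = ", "),
         if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L) else "",
         call. = FALSE)
  }
  if (abs(lam) < 1e-12) {
    log(x)
  } else {
    # expm1 keeps the lam -> 0 limit numerically continuous
    expm1(lam * log(x)) / lam
  }
}

#' Inverse Box-Cox transformation
#'
#' Maps transformed values back to the original scale:
#' \eqn{x = (1 + \lambda y)^{1/\lambda}} for \eqn{\lambda \neq 0},
#' \eqn{x = e^y} for \eqn{\lambda = 0}.
#'
#' @param y Numeric vector of transformed values.
#' @param lam Single finite power parameter.
#' @return Original-scale values. Errors if `1 + lam * y <= 0` for any `y`
#'   (such values are unreachable by the forward transform).
#' @export
inverse_boxcox <- function(y, lam) {
  stopifnot(is.numeric(y), length(lam) == 1L, is.finite(lam))
  if (abs(lam) < 1e-12) return(exp(y))
  z <- 1 + lam * y
  if (any(!is.na(z) & z <= 0)) {
    stop("inverse_boxcox(): 1 + lam*y <= 0 for some y; ",
         "value unreachable by the Box-Cox transform with lam = ", lam,
         call. = FALSE)
  }
  exp(log(z) / lam)
}

#' Box-Cox normal model
#'
#' Constructs the parametric model of the non-pathological component: a
#' random variable \eqn{X > 0} such that `boxcox_transform(X, lam)` follows a
#' Normal(`mu`, `sigma`^2) distribution, optionally carrying the
#' non-pathological fraction `p_frac` (the scaling factor applied to expected
#' histogram counts during fitting). For `lam > 0` the Box-Cox image of
#' \eqn{(0,\infty)} is \eqn{(-1/\lambda, \infty)}; the normal is truncated to
#' that reachable domain and renormalized so that density, CDF and quantiles
#' form a proper distribution on \eqn{(0,\infty)}.
#'
#' @param lam Power parameter (skewness): 0 = log-normal, 1 = Gaussian.
#' @param mu Location in transformed space.
#' @param sigma Positive scale in transformed space.
#' @param p_frac Optional non-pathological fraction in (0, 1].
#' @return An object of class `bcn_model`.
#' @export
bcn_model <- function(lam, mu, sigma, p_frac = NULL) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("bcn_model(): sigma must be > 0", call. = FALSE)
  if (!is.null(p_frac)) {
    stopifnot(is.numeric(p_frac), length(p_frac) == 1L)
    if (!(p_frac > 0 && p_frac <= 1))
      stop("bcn_model(): p_frac must lie in (0, 1]", call. = FALSE)
  }
  structure(list(lam = lam, mu = mu, sigma = sigma, p_frac = p_frac),
            class = "bcn_model")
}

#' @export
print.bcn_model <- function(x, ...) {
  cat(sprintf("Box-Cox normal model: lambda = %.5g, mu = %.5g, sigma = %.5g%s\n",
              x$lam, x$mu, x$sigma,
              if (is.null(x$p_frac)) "" else sprintf(", P = %.4g", x$p_frac)))
  invisible(x)
}

# Mass of the untruncated Normal(mu, sigma^2) below the lower reachable
# bound of the transformed domain (-1/lam for lam > 0; -Inf for lam <= 0).
.bcn_trunc_mass <- function(lam, mu, sigma) {
  if (lam <= 1e-12) return(0)
  stats::pnorm((-1 / lam - mu) / sigma)
}

#' Density of the Box-Cox normal distribution
#'
#' Normal density at the transformed value times the Jacobian
#' \eqn{x^{\lambda-1}}, renormalized for the truncation of the transformed
#' domain (negligible in typical laboratory-data regimes).
#'
#' @param x Positive evaluation points (non-positive points get density 0).
#' @param model A [bcn_model()].
#' @return Density values, non-negative.
#' @export
bcn_pdf <- function(x, model) {
  stopifnot(inherits(model, "bcn_model"))
  out <- numeric(length(x))
  ok <- is.finite(x) & x > 0
  if (any(ok)) {
    xt <- boxcox_transform(x[ok], model$lam)
    z0 <- .bcn_trunc_mass(model$lam, model$mu, model$sigma)
    out[ok] <- stats::dnorm(xt, model$mu, model$sigma) *
      x[ok]^(model$lam - 1) / (1 - z0)
  }
  out[!is.finite(x)] <- NA_real_
  out
}

#' Cumulative distribution of the Box-Cox normal distribution
#'
#' @param x Evaluation points (values `<= 0` have probability 0).
#' @param model A [bcn_model()].
#' @return Probabilities in `[0, 1]`.
#' @export
bcn_cdf <- function(x, model) {
  stopifnot(inherits(model, "bcn_model"))
  out <- numeric(length(x))
  ok <- is.finite(x) & x > 0
  if (any(ok)) {
    xt <- boxcox_transform(x[ok], model$lam)
    z0 <- .bcn_trunc_mass(model$lam, model$mu, model$sigma)
    p <- (stats::pnorm(xt, model$mu, model$sigma) - z0) / (1 - z0)
    out[ok] <- pmin(pmax(p, 0), 1)
  }
  out[!is.finite(x)] <- NA_real_
  out
}

#' Quantiles of the Box-Cox normal distribution
#'
#' Strictly increasing in `prob`; reference limits are
#' `bcn_quantile(c(0.025, 0.975), model)`.
#'
#' @param prob Probabilities strictly inside (0, 1).
#' @param model A [bcn_model()].
#' @return Original-scale quantiles.
#' @export
bcn_quantile <- function(prob, model) {
  stopifnot(inherits(model, "bcn_model"), is.numeric(prob))
  if (any(!is.finite(prob) | prob <= 0 | prob >= 1))
    stop("bcn_quantile(): prob must lie strictly inside (0, 1)", call. = FALSE)
  z0 <- .bcn_trunc_mass(model$lam, model$mu, model$sigma)
  q <- stats::qnorm(z0 + prob * (1 - z0), model$mu, model$sigma)
  inverse_boxcox(q, model$lam)
}

#' The lambda search grid
#'
#' Fixed search grid for the power parameter: \eqn{\lambda = x^{1.54542}} for
#' \eqn{x = 0.0, 0.1, \ldots, 1.3}, i.e. 14 values from 0 to 1.5 with denser
#' spacing near 0, where the transformation changes fastest. The exponent
#' equals \eqn{\ln 1.5 / \ln 1.3} so the grid ends at 1.5.
#'
#' @return Strictly increasing numeric vector of length 14.
#' @export
lambda_grid <- function() {
  seq(0, 1.3, by = 0.1)^1.54542
}
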
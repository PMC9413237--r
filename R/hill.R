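#' Downward Hill concentration-response function
#'
#' Computes the expected viability fraction under the decreasing Hill model
#' \deqn{y(x) = y_0 \left(1 - \frac{(x/x_0)^n}{1 + (x/x_0)^n}\right)}
#' where \code{y0} is the baseline response (1.0 = vehicle level), \code{ec50}
#' (\eqn{x_0}) is the concentration producing a 50\% decrease from baseline,
#' and \code{n} is the Hill coefficient, restricted to be >= 1 to prevent
#' anomalously shallow curves.
#'
#' @param x concentration (uM); non-negative, vectorized.
#' @param y0 baseline response fraction (> 0).
#' @param ec50 concentration at 50\% decrease from baseline (uM, > 0).
#' @param n Hill coefficient (>= 1).
#' @return Expected response fraction, same length as \code{x}. \code{y(0) = y0};
#'   the curve decreases strictly in \code{x} and tends to 0.
#' @examples
#' hill_response(10, y0 = 1, ec50 = 10, n = 1)  # 0.5 at the EC50
#' hill_response(c(0, 90), y0 = 1, ec50 = 10, n = 1)
#' @export
hill_response <- function(x, y0 = 1, ec50, n) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("'x' must be finite and non-negative")
  }
  check_hill_params(y0, ec50, n)
  r <- (x / ec50)^n
  y0 * (1 - r / (1 + r))
}

check_hill_params <- function(y0, ec50, n) {
  if (any(!is.finite(y0)) || any(y0 <= 0)) stop("'y0' must be > 0")
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) stop("'ec50' must be > 0")
  if (any(!is.finite(n)) || any(n < 1)) stop("'n' (Hill coefficient) must be >= 1")
  invisible(TRUE)
}

#' EC10 point of departure from Hill parameters
#'
#' Closed-form concentration at which the downward Hill curve has dropped 10\%
#' below baseline: \code{ec10 = ec50 * (0.1/0.9)^(1/n)}. Since
#' \code{(1/9)^(1/n) < 1} for all \code{n >= 1}, the EC10 always lies below the
#' EC50. Vectorized over MCMC draws of \code{(ec50, n)}.
#'
#' @param ec50 EC50 in uM (> 0).
#' @param n Hill coefficient (>= 1).
#' @return EC10 in uM.
#' @examples
#' ec10_from_params(9, 1)     # 1
#' ec10_from_params(100, 2)   # 100/3
#' @export
ec10_from_params <- function(ec50, n) {
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) stop("'ec50' must be > 0")
  if (any(!is.finite(n)) || any(n < 1)) stop("'n' (Hill coefficient) must be >= 1")
  ec50 * (0.1 / 0.9)^(1 / n)
}

#' Log-likelihood of normalized responses under the robust Hill error model
#'
#' Residuals between observed normalized responses and the Hill curve are
#' modeled as scaled Student-t: \code{(y - mu)/sigma ~ t(nu)}, with \code{nu = 5}
#' by default for robustness to outlier wells. All wells (including replicate
#' plates) enter as independent observations.
#'
#' @param y observed normalized responses.
#' @param x concentrations (uM), same length as \code{y}.
#' @param y0,ec50,n Hill parameters for one individual.
#' @param sigma t scale parameter (> 0), in response-fraction units.
#' @param nu degrees of freedom (default 5).
#' @return Sum of log densities.
#' @export
hill_loglik <- function(y, x, y0, ec50, n, sigma, nu = 5) {
  if (length(y) != length(x)) stop("'y' and 'x' must have equal length")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  if (!is.finite(nu) || nu <= 0) stop("'nu' must be > 0")
  mu <- hill_response(x, y0 = y0, ec50 = ec50, n = n)
  sum(stats::dt((y - mu) / sigma, df = nu, log = TRUE) - log(sigma))
}
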
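#' Composition-dependent water diffusivity parameterization
#'
#' Polynomial parameterization of the water diffusion coefficient on the water
#' activity scale: `log10 D_w(a_w) = sum_k c_k a_w^k` with `D_w` in m^2 s^-1.
#' The intercept `c_0` fixes `D_w,org = 10^c_0`, the diffusion coefficient of
#' water extrapolated to the pure (dry) organic matrix.
#'
#' @param coefficients Numeric vector `c(c_0, c_1, ..., c_order)`.
#' @param validity Water-activity range over which the parameterization is
#'   constrained by data; evaluation outside it is flagged as extrapolation.
#' @return Object of class `d_parameterization` with fields `coefficients`,
#'   `order`, `d_w_org` and `validity`.
#' @examples
#' dp <- d_parameterization(c(-16, 8, -2, 1))
#' dp$d_w_org
#' predict(dp, a_w = c(0, 0.5, 1))
#' @export
d_parameterization <- function(coefficients, validity = c(0, 1)) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1 || any(!is.finite(coefficients)))
    stop_domain("d_parameterization: coefficients must be finite")
  stopifnot(length(validity) == 2, validity[1] < validity[2])
  structure(list(coefficients = coefficients,
                 order = length(coefficients) - 1L,
                 d_w_org = 10^coefficients[1],
                 validity = as.numeric(validity)),
            class = "d_parameterization")
}

#' Evaluate a diffusivity parameterization
#'
#' @param object A `d_parameterization`.
#' @param a_w Water activities in \[0, 1\].
#' @param log10 If `TRUE` return `log10 D`; otherwise D in m^2 s^-1.
#' @param ... Unused.
#' @export
predict.d_parameterization <- function(object, a_w, log10 = FALSE, ...) {
  if (any(a_w < 0 | a_w > 1))
    stop_domain("d_parameterization: a_w outside [0, 1]")
  v <- polyval(object$coefficients, a_w)
  if (log10) v else 10^v
}

#' @export
print.d_parameterization <- function(x, ...) {
  cat(sprintf("<d_parameterization> order %d, D_w,org = %.3g m^2/s, valid a_w [%g, %g]\n",
              x$order, x$d_w_org, x$validity[1], x$validity[2]))
  cat("  log10 D coefficients:", signif(x$coefficients, 5), "\n")
  invisible(x)
}

#' Viscosity-vs-water-activity parameterization
#'
#' Companion to [d_parameterization()] for the independently measured
#' viscosity axis: `log10 eta(a_w) = sum_k c_k a_w^k` with eta in Pa s.
#' Saccharide droplets span roughly 1e-3 Pa s (dilute) to 1e12 Pa s (glass).
#'
#' @param coefficients Numeric vector of polynomial coefficients.
#' @param validity a_w range covered by the underlying measurements.
#' @return Object of class `eta_parameterization`.
#' @export
eta_parameterization <- function(coefficients, validity = c(0, 1)) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1 || any(!is.finite(coefficients)))
    stop_domain("eta_parameterization: coefficients must be finite")
  structure(list(coefficients = coefficients, validity = as.numeric(validity)),
            class = "eta_parameterization")
}

#' @rdname eta_parameterization
#' @param object An `eta_parameterization`.
#' @param a_w Water activities.
#' @param log10 Return log10 eta instead of eta (Pa s).
#' @param ... Unused.
#' @export
predict.eta_parameterization <- function(object, a_w, log10 = FALSE, ...) {
  v <- polyval(object$coefficients, a_w)
  if (log10) v else 10^v
}
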
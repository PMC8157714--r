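#' Parametric water-activity / composition model
#'
#' Single-parameter monotone map between water mass fraction `w` and water
#' activity `a_w`, plus an ideal-volume-additivity density map:
#' \deqn{a_w(w) = w \exp(A (1 - w)^2)}
#' The map satisfies `a_w(0) = 0`, `a_w(1) = 1` and is strictly increasing for
#' `A < 2`. Negative `A` gives the negative deviations from ideality typical
#' of aqueous saccharide solutions. Real droplet studies use measured activity
#' data; this parametric stand-in keeps the shell model self-contained.
#'
#' @param A Deviation parameter (dimensionless), must be `< 2` so the map is
#'   strictly increasing. Default -1 (saccharide-like).
#' @param rho_water,rho_solute Component densities, kg m^-3. Defaults: water
#'   997, amorphous saccharide 1580.
#' @return An object of class `activity_model`.
#' @examples
#' am <- activity_model()
#' aw_from_w(am, 0.5)
#' w_from_aw(am, aw_from_w(am, 0.5))
#' @export
activity_model <- function(A = -1, rho_water = 997, rho_solute = 1580) {
  if (!is.finite(A) || A >= 2)
    stop_domain("activity_model: A must be < 2 for a strictly increasing map")
  if (rho_water <= 0 || rho_solute <= 0)
    stop_domain("activity_model: densities must be positive")
  structure(list(A = A, rho_water = rho_water, rho_solute = rho_solute),
            class = "activity_model")
}

#' @rdname activity_model
#' @param model An `activity_model`.
#' @param w Water mass fraction(s) in \[0, 1\].
#' @export
aw_from_w <- function(model, w) {
  stopifnot(inherits(model, "activity_model"))
  w * exp(model$A * (1 - w)^2)
}

#' @rdname activity_model
#' @param a_w Water activity value(s) in \[0, 1\].
#' @export
w_from_aw <- function(model, a_w) {
  stopifnot(inherits(model, "activity_model"))
  vapply(a_w, function(a) activity_inverse_cpp(a, model$A), numeric(1))
}

#' @rdname activity_model
#' @export
density_from_w <- function(model, w) {
  stopifnot(inherits(model, "activity_model"))
  1 / (w / model$rho_water + (1 - w) / model$rho_solute)
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model> a_w = w*exp(%g*(1-w)^2); rho_w=%g, rho_s=%g kg/m^3\n",
              x$A, x$rho_water, x$rho_solute))
  invisible(x)
}
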
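#' Stokes-Einstein parameters
#'
#' Parameters of the continuum prediction `D = C k_B T / (eta a)` for a sphere
#' of hydrodynamic radius `a` in a solvent of viscosity `eta`. The default
#' radius 0.1 nm corresponds to a water molecular diameter of 0.2 nm; the
#' default constant `C = 1/(6 pi)` is the stick boundary condition
#' (`1/(4 pi)` for slip).
#'
#' @param C Dimensionless constant (> 0).
#' @param a Hydrodynamic radius, m (> 0).
#' @param temperature Temperature, K.
#' @return Object of class `se_params`.
#' @export
se_params <- function(C = 1 / (6 * pi), a = 0.1e-9, temperature = 298.15) {
  if (C <= 0 || a <= 0) stop_domain("se_params: C and a must be positive")
  structure(list(C = C, a = a, temperature = temperature,
                 k_B = cavity_constants()$k_B), class = "se_params")
}

#' Stokes-Einstein diffusion coefficient
#'
#' @param eta Viscosity, Pa s (> 0); vectorized.
#' @param params An [se_params()].
#' @return D in m^2 s^-1.
#' @examples
#' se_predict(1e-3, se_params(temperature = 298))  # ~2.2e-9 m^2/s for water
#' @export
se_predict <- function(eta, params = se_params()) {
  stopifnot(inherits(params, "se_params"))
  if (any(eta <= 0)) stop_domain("se_predict: eta must be positive")
  params$C * params$k_B * params$temperature / (eta * params$a)
}

#' Orders-of-magnitude divergence from the Stokes-Einstein prediction
#'
#' `log10(D_measured / D_se)`: positive when the measured diffusion is faster
#' than the continuum prediction (small tracer in a matrix of large
#' molecules), negative when slower.
#'
#' @param d_measured,d_se Diffusion coefficients, m^2 s^-1 (> 0); vectorized.
#' @return Divergence in orders of magnitude (dimensionless).
#' @export
divergence_orders <- function(d_measured, d_se) {
  if (any(d_measured <= 0) || any(d_se <= 0))
    stop_domain("divergence_orders: inputs must be positive")
  log10(d_measured / d_se)
}

#' Build a matched diffusion-viscosity table
#'
#' Joins independently parameterized D(a_w) and eta(a_w) axes on a common
#' water-activity grid - the key step that separates compositional effects on
#' diffusion from those on viscosity. Rows outside either parameterization's
#' validity range are flagged, not silently extrapolated.
#'
#' @param d_param A [d_parameterization()].
#' @param eta_param An [eta_parameterization()].
#' @param a_w_grid Water activities at which to evaluate both.
#' @param source Provenance label stored per row.
#' @return A `dv_table`: data.frame with columns `a_w`, `D_m2s`, `eta_Pas`,
#'   `source`, `extrapolated`.
#' @export
build_table <- function(d_param, eta_param, a_w_grid, source = "parameterization") {
  stopifnot(inherits(d_param, "d_parameterization"),
            inherits(eta_param, "eta_parameterization"))
  if (any(a_w_grid < 0 | a_w_grid > 1))
    stop_domain("build_table: a_w grid outside [0, 1]")
  flag <- a_w_grid < d_param$validity[1] | a_w_grid > d_param$validity[2] |
    a_w_grid < eta_param$validity[1] | a_w_grid > eta_param$validity[2]
  structure(data.frame(a_w = a_w_grid,
                       D_m2s = predict(d_param, a_w_grid),
                       eta_Pas = predict(eta_param, a_w_grid),
                       source = source,
                       extrapolated = flag),
            class = c("dv_table", "data.frame"))
}

#' @rdname build_table
#' @param rows data.frame with columns `a_w`, `D_m2s`, `eta_Pas` (and
#'   optionally `source`) for tables assembled from measurements.
#' @export
dv_table <- function(rows) {
  stopifnot(all(c("a_w", "D_m2s", "eta_Pas") %in% names(rows)))
  if (any(rows$D_m2s <= 0) || any(rows$eta_Pas <= 0))
    stop_domain("dv_table: D and eta must be positive")
  if (any(rows$a_w < 0 | rows$a_w > 1)) stop_domain("dv_table: a_w outside [0, 1]")
  rows$source <- rows$source %||% "measurement"
  rows$extrapolated <- rows$extrapolated %||% FALSE
  structure(as.data.frame(rows), class = c("dv_table", "data.frame"))
}

#' Fit a fractional Stokes-Einstein exponent
#'
#' Least-squares line in `(log10 eta, log10 D)`; the fractional exponent is
#' `alpha = -slope` of the scaling `D ~ eta^-alpha`. `alpha = 1` is ideal
#' Stokes-Einstein scaling; `alpha < 1` signals decoupling of diffusion from
#' bulk viscosity. Uncertainty by residual bootstrap.
#'
#' @param table A `dv_table`.
#' @param window Viscosity window `c(eta_min, eta_max)` (Pa s) to fit inside;
#'   default full range. The window must contain >= 3 rows spanning >= 2
#'   decades of viscosity or the exponent is unidentifiable.
#' @param n_bootstrap Residual bootstrap replicates.
#' @return Object of class `fse_fit`: `alpha`, `alpha_se`, `alpha_ci` (95%),
#'   `prefactor_log10`, `window`, `residual_rms` (log10 units), `n`.
#' @export
fit_fractional_exponent <- function(table, window = NULL, n_bootstrap = 200) {
  stopifnot(inherits(table, "dv_table"))
  window <- window %||% range(table$eta_Pas)
  keep <- table$eta_Pas >= window[1] & table$eta_Pas <= window[2]
  d <- table[keep, , drop = FALSE]
  if (nrow(d) < 3)
    stop_domain("fit_fractional_exponent: need >= 3 rows inside the window")
  span <- diff(range(log10(d$eta_Pas)))
  if (span < 2)
    stop_domain("fit_fractional_exponent: window spans ", signif(span, 3),
                " decades of viscosity (< 2); exponent unidentifiable")
  lx <- log10(d$eta_Pas); ly <- log10(d$D_m2s)
  fit <- lm(ly ~ lx)
  alpha <- -unname(coef(fit)[2])
  res <- stats::residuals(fit)
  yhat <- stats::fitted(fit)
  ab <- vapply(seq_len(n_bootstrap), function(b) {
    yb <- yhat + sample(res, replace = TRUE)
    -unname(coef(lm(yb ~ lx))[2])
  }, numeric(1))
  structure(list(alpha = alpha,
                 alpha_se = sd(ab),
                 alpha_ci = unname(quantile(ab, c(0.025, 0.975))),
                 prefactor_log10 = unname(coef(fit)[1]),
                 window = window,
                 residual_rms = sqrt(mean(res^2)),
                 n = nrow(d)),
            class = "fse_fit")
}

#' @export
print.fse_fit <- function(x, ...) {
  cat(sprintf("<fse_fit> alpha = %.3f (se %.3f, 95%% CI %.3f-%.3f), n = %d, rms = %.3g log10 units\n",
              x$alpha, x$alpha_se, x$alpha_ci[1], x$alpha_ci[2], x$n, x$residual_rms))
  invisible(x)
}
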
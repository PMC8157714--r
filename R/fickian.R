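#' Construct a droplet state in internal equilibrium
#'
#' Discretizes a spherical aqueous-organic droplet into concentric shells of
#' equal solute mass (shells therefore never vanish as the droplet dries) with
#' a uniform starting composition set by a water activity (gas-phase RH / 100).
#'
#' @param radius Initial droplet radius, m.
#' @param a_w Uniform initial water activity (equilibrium with RH = 100 a_w).
#' @param n_shells Number of shells (>= 10).
#' @param activity An [activity_model()].
#' @param temperature Temperature, K.
#' @return Object of class `droplet_state`: per-shell solute mass `m_s` (kg,
#'   fixed), water mass `m_w` (kg), plus composition accessors.
#' @export
droplet_state <- function(radius, a_w, n_shells = 40, activity = activity_model(),
                          temperature = 293.15) {
  if (n_shells < 10) stop_domain("droplet_state: need >= 10 shells")
  if (radius <= 0) stop_domain("droplet_state: radius must be positive")
  if (a_w < 0 || a_w > 1) stop_domain("droplet_state: a_w outside [0, 1]")
  w0 <- w_from_aw(activity, a_w)
  if (w0 >= 1) stop_domain("droplet_state: pure-water state unsupported")
  vol <- 4 / 3 * pi * radius^3
  m_total <- vol * density_from_w(activity, w0)
  m_s <- rep((1 - w0) * m_total / n_shells, n_shells)
  m_w <- m_s * w0 / (1 - w0)
  structure(list(m_s = m_s, m_w = m_w, temperature = temperature,
                 activity = activity, radius = radius, a_w = a_w),
            class = "droplet_state")
}

#' @export
print.droplet_state <- function(x, ...) {
  cat(sprintf("<droplet_state> %d shells, R = %.3g m, a_w = %.3f, T = %.1f K\n",
              length(x$m_s), x$radius, x$a_w, x$temperature))
  invisible(x)
}

#' Normalized droplet size-response function
#'
#' Container for one RH-step experiment (or simulation): times in s starting
#' at 0 and the droplet size normalized to its initial value.
#'
#' @param times Times, s; strictly increasing, first element 0.
#' @param normalized_size Size response, = 1 at t = 0 (within noise).
#' @param rh_initial,rh_final RH before/after the step, percent.
#' @param temperature Temperature, K.
#' @param droplet_radius_initial Initial radius, m.
#' @param solute_label Free-text solute identity.
#' @return Object of class `response_function` (a data.frame with metadata
#'   attributes).
#' @export
response_function <- function(times, normalized_size, rh_initial, rh_final,
                              temperature = 293.15, droplet_radius_initial,
                              solute_label = "synthetic") {
  if (length(times) != length(normalized_size))
    stop_domain("response_function: length mismatch")
  if (times[1] != 0) stop_domain("response_function: times must start at 0")
  if (any(diff(times) <= 0)) stop_domain("response_function: times must be strictly increasing")
  for (rh in c(rh_initial, rh_final))
    if (rh < 0 || rh > 100) stop_domain("response_function: RH outside [0, 100]")
  structure(data.frame(t_seconds = times, normalized_size = normalized_size),
            rh_initial = rh_initial, rh_final = rh_final,
            temperature = temperature,
            droplet_radius_initial = droplet_radius_initial,
            solute_label = solute_label,
            class = c("response_function", "data.frame"))
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("<response_function> %s, RH %g%% -> %g%%, r0 = %.3g m, %d samples over %.3g s\n",
              attr(x, "solute_label"), attr(x, "rh_initial"), attr(x, "rh_final"),
              attr(x, "droplet_radius_initial"), nrow(x), max(x$t_seconds)))
  invisible(x)
}

#' Forward spherical-shell Fickian water transport after an RH step
#'
#' Explicit conservative time-stepping of radial water diffusion between
#' concentric equal-solute-mass shells. The inter-shell flux is the
#' diffusivity evaluated at the interface water activity times the radial
#' water concentration gradient and the interface area; the outermost shell is
#' held at instantaneous equilibrium with the gas phase (`a_w = rh_final/100`,
#' no gas-side resistance), and shells are re-sized every step from
#' composition and density. The time step is set from a diffusive stability
#' bound and auto-refined if a negative water mass is produced.
#'
#' @param initial A [droplet_state()].
#' @param D A [d_parameterization()].
#' @param activity An [activity_model()]; defaults to the model stored in
#'   `initial`.
#' @param rh_final Final gas-phase RH, percent.
#' @param output_times Times (s) at which to report the response; first may be
#'   0 (prepended if missing).
#' @param safety Stability safety factor in (0, 1).
#' @param max_steps Step budget before the solver aborts with diagnostics.
#' @return A [response_function()] with extra attributes: `water_mass` (total
#'   kg at each output time), `mass_audit` (relative conservation defect
#'   between interior change and boundary flux), `radius_m` (absolute radius),
#'   `asymptote` (equilibrium normalized size), `n_steps`.
#' @export
solve_shell_diffusion <- function(initial, D, activity = NULL, rh_final,
                                  output_times, safety = 0.4, max_steps = 5e6) {
  stopifnot(inherits(initial, "droplet_state"), inherits(D, "d_parameterization"))
  activity <- activity %||% initial$activity
  if (rh_final < 0 || rh_final > 100)
    stop_domain("solve_shell_diffusion: rh_final outside [0, 100]")
  if (length(initial$m_s) < 10) stop_domain("solve_shell_diffusion: need >= 10 shells")
  output_times <- sort(unique(as.numeric(output_times)))
  if (output_times[1] > 0) output_times <- c(0, output_times)

  res <- shell_solve_cpp(initial$m_s, initial$m_w, D$coefficients,
                         activity$A, activity$rho_water, activity$rho_solute,
                         rh_final / 100, output_times, safety, max_steps)

  r0 <- res$radius[1]
  # equilibrium (asymptotic) radius: uniform composition at the surface value
  w_eq <- res$w_surf
  m_tot_eq <- sum(initial$m_s) / (1 - w_eq)
  r_eq <- (3 * m_tot_eq / density_from_w(activity, w_eq) / (4 * pi))^(1 / 3)

  rf <- response_function(output_times, res$radius / r0,
                          rh_initial = 100 * initial$a_w, rh_final = rh_final,
                          temperature = initial$temperature,
                          droplet_radius_initial = r0,
                          solute_label = "shell-model")
  attr(rf, "water_mass") <- res$water_mass
  attr(rf, "mass_audit") <- res$mass_audit
  attr(rf, "radius_m") <- res$radius
  attr(rf, "asymptote") <- r_eq / r0
  attr(rf, "n_steps") <- res$n_steps
  attr(rf, "m_w_final") <- res$m_w_final
  rf
}

# Nominal slowest relaxation time of a sphere with the least mobile
# composition the step visits: tau = r^2 / (pi^2 D).
nominal_time_constant <- function(D, radius, a_w_initial, a_w_final) {
  a_slow <- min(a_w_initial, a_w_final)
  radius^2 / (pi^2 * predict(D, a_slow))
}

#' Fit a stretched-exponential (KWW) form to a response function
#'
#' Least-squares fit of `normalized_size ~ c + (1 - c) * exp(-(t/tau)^beta)`,
#' i.e. relaxation from 1 towards an asymptote `c` (which may exceed 1 for
#' condensation steps). A multi-start over a beta grid avoids the local minima
#' typical of stretched-exponential fitting. `beta = 1` recovers a single
#' exponential; `beta < 1` signals a distribution of relaxation timescales.
#'
#' @param rf A [response_function()] with >= 20 samples.
#' @param beta_grid Starting values for the stretch factor.
#' @return Object of class `kww_fit`: `tau` (s), `beta`, `asymptote`,
#'   `residual_rms`, and `converged_span` flag (FALSE when the curve covers
#'   < 80% of its fitted total change, as for glassy responses that are not
#'   complete on the experimental timescale).
#' @export
fit_kww <- function(rf, beta_grid = c(0.3, 0.5, 0.7, 0.85, 1, 1.15, 1.3)) {
  stopifnot(inherits(rf, "response_function"))
  t <- rf$t_seconds
  y <- rf$normalized_size
  if (length(t) < 20) stop_domain("fit_kww: need >= 20 samples")
  tot <- diff(range(y))
  if (tot < 1e-6 * max(abs(y)))
    stop_domain("fit_kww: curve is constant, no decay to fit")

  tpos <- t[t > 0]
  obj <- function(p) {
    tau <- exp(p[1]); beta <- p[2]; cc <- p[3]
    yhat <- cc + (1 - cc) * exp(-(t / tau)^beta)
    sum((y - yhat)^2)
  }
  # crude initial tau: time to cover half the observed change
  yhalf <- y[1] - 0.5 * (y[1] - y[length(y)])
  ih <- which(sign(y - yhalf) != sign(y[1] - yhalf))[1]
  tau0 <- if (!is.na(ih)) max(t[ih], min(tpos)) else stats::median(tpos)
  c0 <- y[length(y)]

  best <- NULL
  for (b0 in beta_grid) {
    fit <- tryCatch(
      optim(c(log(tau0), b0, c0), obj, method = "L-BFGS-B",
            lower = c(log(min(tpos)) - 8, 0.05, -Inf),
            upper = c(log(max(tpos)) + 8, 1.5, Inf),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("fit_kww: optimization failed for all starting values")
  tau <- exp(best$par[1]); beta <- best$par[2]; asym <- best$par[3]
  rms <- sqrt(best$value / length(y))

  # span check: did the data cover >= 80% of the fitted total change?
  span <- abs(y[length(y)] - y[1]) / max(abs(1 - asym), 1e-12)
  converged_span <- is.finite(span) && span >= 0.8
  if (!converged_span)
    warning("fit_kww: response spans < 80% of its fitted change; ",
            "parameters reflect an incomplete relaxation", call. = FALSE)
  structure(list(tau = tau, beta = beta, asymptote = asym, residual_rms = rms,
                 converged_span = converged_span),
            class = "kww_fit")
}

#' @export
print.kww_fit <- function(x, ...) {
  cat(sprintf("<kww_fit> tau = %.4g s, beta = %.3f, asymptote = %.4f, rms = %.2g%s\n",
              x$tau, x$beta, x$asymptote, x$residual_rms,
              if (x$converged_span) "" else " [incomplete relaxation]"))
  invisible(x)
}

#' Recover D_w(a_w) from a set of RH-step response functions
#'
#' Simultaneous least-squares fit of the shell-model forward solution to all
#' curves over the polynomial coefficients of `log10 D_w(a_w)`. Compositional
#' coverage requires curves at several RH transitions; a single narrow a_w
#' band cannot constrain a polynomial beyond its constant term.
#'
#' @param curves List of [response_function()] objects with distinct RH ranges.
#' @param activity An [activity_model()] shared by all curves.
#' @param order Polynomial order of `log10 D_w(a_w)` (default 3).
#' @param init Optional [d_parameterization()] starting point; otherwise an
#'   initial guess is built from per-curve KWW time constants via
#'   `D_eff = r0^2 / (pi^2 tau)` attributed at each curve's mid a_w.
#' @param n_shells Shells used in the forward model during fitting.
#' @param n_bootstrap Curve-resampling bootstrap replicates for coefficient
#'   uncertainty (0 to skip; linearized standard errors are always reported).
#' @param maxit Nelder-Mead iteration budget.
#' @param max_steps Per-solve step cap during fitting; candidate coefficient
#'   vectors whose forward solve exceeds it are penalized rather than
#'   explored.
#' @return A [d_parameterization()] with extra fields: `se` (linearized
#'   coefficient standard errors), `bootstrap` (matrix of replicate
#'   coefficients or NULL), `ssr`, `n_obs`, and `validity` set to the probed
#'   a_w range (extrapolation below it, e.g. to `D_w,org` at a_w = 0, is
#'   flagged by the validity bounds).
#' @export
fit_diffusivity <- function(curves, activity = activity_model(), order = 3,
                            init = NULL, n_shells = 40, n_bootstrap = 0,
                            maxit = 400, max_steps = 4e5) {
  if (inherits(curves, "response_function")) curves <- list(curves)
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, TRUE, "response_function")))
  if (length(curves) < 2 && order > 0)
    stop_domain("fit_diffusivity: need >= 2 curves for order > 0")

  meta <- lapply(curves, function(cv) {
    list(a_i = attr(cv, "rh_initial") / 100, a_f = attr(cv, "rh_final") / 100,
         r0 = attr(cv, "droplet_radius_initial"), temp = attr(cv, "temperature"))
  })
  a_mid <- vapply(meta, function(m) (m$a_i + m$a_f) / 2, numeric(1))
  a_lo <- min(vapply(meta, function(m) min(m$a_i, m$a_f), numeric(1)))
  a_hi <- max(vapply(meta, function(m) max(m$a_i, m$a_f), numeric(1)))
  if (order >= 1) {
    span <- diff(range(a_mid))
    if (span < 0.1 || length(unique(round(a_mid, 3))) <= order)
      stop_domain("fit_diffusivity: curves cover too narrow an a_w band; ",
                  "coefficients c_1..c_", order, " are unconstrained")
  }

  resid_fun <- function(coefs) {
    unlist(lapply(seq_along(curves), function(i) {
      cv <- curves[[i]]; m <- meta[[i]]
      st <- droplet_state(m$r0, m$a_i, n_shells = n_shells, activity = activity,
                          temperature = m$temp)
      dp <- d_parameterization(coefs)
      sim <- tryCatch(
        solve_shell_diffusion(st, dp, activity, 100 * m$a_f, cv$t_seconds,
                              max_steps = max_steps),
        error = function(e) NULL)
      if (is.null(sim)) return(rep(1e3, nrow(cv)))
      model_y <- sim$normalized_size[match(cv$t_seconds, sim$t_seconds)]
      cv$normalized_size - model_y
    }))
  }
  obj <- function(coefs) sum(resid_fun(coefs)^2)

  if (is.null(init)) {
    d_eff <- vapply(seq_along(curves), function(i) {
      kf <- suppressWarnings(fit_kww(curves[[i]]))
      meta[[i]]$r0^2 / (pi^2 * kf$tau)
    }, numeric(1))
    deg <- min(order, length(curves) - 1)
    cf <- rep(0, order + 1)
    if (deg == 0) cf[1] <- mean(log10(d_eff))
    else cf[seq_len(deg + 1)] <- coef(lm(log10(d_eff) ~ poly(a_mid, deg, raw = TRUE)))
    start <- cf
  } else start <- init$coefficients[seq_len(order + 1)]
  start[is.na(start)] <- 0

  fit <- if (length(start) == 1) {
    o <- optimize(function(c0) obj(c0), interval = c(start - 3, start + 3))
    list(par = o$minimum, value = o$objective)
  } else {
    optim(start, obj, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-10))
  }

  r <- resid_fun(fit$par)
  n <- length(r); p <- length(fit$par)
  # linearized covariance from a forward-difference Jacobian
  J <- matrix(0, n, p)
  hstep <- pmax(abs(fit$par) * 1e-4, 1e-5)
  for (j in seq_len(p)) {
    pj <- fit$par; pj[j] <- pj[j] + hstep[j]
    J[, j] <- (resid_fun(pj) - r) / hstep[j]
  }
  se <- tryCatch({
    s2 <- sum(r^2) / max(n - p, 1)
    sqrt(diag(s2 * solve(crossprod(J))))
  }, error = function(e) rep(NA_real_, p))

  boot <- NULL
  if (n_bootstrap > 0) {
    boot <- t(vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample(seq_along(curves), replace = TRUE)
      cb <- curves[idx]; mb <- meta[idx]
      objb <- function(coefs) {
        sum(unlist(lapply(seq_along(cb), function(i) {
          cv <- cb[[i]]; m <- mb[[i]]
          st <- droplet_state(m$r0, m$a_i, n_shells = n_shells,
                              activity = activity, temperature = m$temp)
          sim <- tryCatch(
            solve_shell_diffusion(st, d_parameterization(coefs), activity,
                                  100 * m$a_f, cv$t_seconds,
                                  max_steps = max_steps),
            error = function(e) NULL)
          if (is.null(sim)) return(1e6)
          sum((cv$normalized_size -
                 sim$normalized_size[match(cv$t_seconds, sim$t_seconds)])^2)
        })))
      }
      if (p == 1) optimize(objb, interval = fit$par + c(-2, 2))$minimum
      else optim(fit$par, objb, method = "Nelder-Mead",
                 control = list(maxit = 120))$par
    }, numeric(p)))
  }

  out <- d_parameterization(fit$par, validity = c(a_lo, a_hi))
  out$se <- se
  out$bootstrap <- boot
  out$ssr <- sum(r^2)
  out$n_obs <- n
  out
}
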
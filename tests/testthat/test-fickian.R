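test_that("shell solver reproduces the classical sorption series (dilute, constant D)", {
  D <- 1e-11; r0 <- 4e-6
  am <- ideal_activity()
  st <- droplet_state(r0, 0.002, n_shells = 30, activity = am)
  tau <- r0^2 / (pi^2 * D)
  times <- seq(0, 5 * tau, length.out = 50)[-1]
  rf <- solve_shell_diffusion(st, d_parameterization(log10(D)), am, 0.3, times)
  Mw <- attr(rf, "water_mass")
  w_eq <- w_from_aw(am, 0.003)
  Minf <- sum(st$m_s) * w_eq / (1 - w_eq)
  frac <- (Mw - Mw[1]) / (Minf - Mw[1])
  ref <- sorption_series(rf$t_seconds, D, r0)
  expect_lt(max(abs(frac - ref)), 0.01)
})

test_that("equilibrium initial state stays put and water mass is conserved", {
  am <- activity_model()
  st <- droplet_state(4e-6, 0.5, n_shells = 15, activity = am)
  rf <- solve_shell_diffusion(st, d_parameterization(-11), am, 50,
                              seq(0, 10, length.out = 20))
  expect_equal(rf$normalized_size, rep(1, 20), tolerance = 1e-9)
  # conservation audit on a real drying step
  rf2 <- solve_shell_diffusion(st, d_parameterization(-11), am, 30,
                               seq(0, 5, length.out = 20))
  expect_lt(attr(rf2, "mass_audit"), 1e-10)
  expect_error(solve_shell_diffusion(st, d_parameterization(-11), am, 120, 1:3),
               "rh_final")
})

test_that("doubling the shell count changes the response by < 0.3% everywhere", {
  truth <- sucrose_truth()
  am <- activity_model()
  times <- c(0, 10^seq(-1, 3.2, length.out = 40))
  r1 <- solve_shell_diffusion(droplet_state(4e-6, 0.6, 30, am), truth, am, 40, times)
  r2 <- solve_shell_diffusion(droplet_state(4e-6, 0.6, 60, am), truth, am, 40, times)
  expect_lt(max(abs(r1$normalized_size - r2$normalized_size)), 0.003)
})

test_that("uniformly larger D equilibrates pointwise faster", {
  am <- activity_model()
  times <- c(0, 10^seq(-2, 3, length.out = 40))
  st <- droplet_state(4e-6, 0.6, 20, am)
  slow <- solve_shell_diffusion(st, d_parameterization(-12), am, 40, times)
  fast <- solve_shell_diffusion(st, d_parameterization(-11.5), am, 40, times)
  t_half <- function(rf) {
    target <- (1 + attr(rf, "asymptote")) / 2
    rf$t_seconds[which(rf$normalized_size <= target)[1]]
  }
  expect_lt(t_half(fast), t_half(slow))
  # drying never under-shoots: monotone decrease toward the asymptote
  expect_true(all(diff(slow$normalized_size) <= 1e-9))
})

test_that("KWW fit recovers exponential and stretched-exponential truth", {
  k <- fit_kww(make_kww_curve(100, 1))
  expect_lt(abs(k$tau / 100 - 1), 0.01)
  expect_lt(abs(k$beta - 1), 0.02)
  expect_equal(k$asymptote, 0.85, tolerance = 1e-3)

  k2 <- fit_kww(make_kww_curve(500, 0.5, noise_sd = 0.005, seed = 7, t_max = 5000))
  expect_lt(abs(k2$tau / 500 - 1), 0.05)
  expect_lt(abs(k2$beta / 0.5 - 1), 0.05)

  flat <- response_function(seq(0, 100, length.out = 30), rep(1, 30), 50, 50,
                            droplet_radius_initial = 4e-6)
  expect_error(fit_kww(flat), "no decay")
  # truncated relaxation is fitted but flagged
  expect_warning(fit_kww(make_kww_curve(500, 1, t_max = 300)), "80%")
})

test_that("activity-dependent D produces a stretched (beta < 1) response", {
  # steep decrease of D at low a_w: drying slows as the surface dries
  truth <- sucrose_truth()
  cv <- gen_response_curve(truth, c(60, 20), n_shells = 30, n_times = 120)
  k <- suppressWarnings(fit_kww(cv))
  expect_lt(k$beta, 0.95)
})

test_that("fit_diffusivity: constant-D recovery and identifiability guards", {
  truth <- d_parameterization(-11.3)
  cv <- gen_response_curve(truth, c(60, 40), n_shells = 30, n_times = 80)
  fit <- fit_diffusivity(cv, order = 0, n_shells = 25)
  expect_lt(abs(fit$coefficients[1] + 11.3), 0.05)
  # curves in one narrow a_w band cannot constrain higher-order terms
  cvs <- list(gen_response_curve(truth, c(55, 50), n_shells = 20, n_times = 40),
              gen_response_curve(truth, c(54, 49), n_shells = 20, n_times = 40))
  expect_error(fit_diffusivity(cvs, order = 2, n_shells = 20), "unconstrained")
})

test_that("fit_diffusivity recovers noise-free coefficients to 3 significant figures", {
  truth <- d_parameterization(c(-13, 2))
  cvs <- lapply(list(c(70, 50), c(40, 20)), function(s)
    gen_response_curve(truth, s, n_shells = 40, n_times = 80))
  fit <- fit_diffusivity(cvs, order = 1, n_shells = 40, maxit = 500)
  expect_equal(fit$coefficients, truth$coefficients, tolerance = 5e-4)
})
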
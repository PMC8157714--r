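test_that("Stokes-Einstein prediction: closed forms and homogeneity", {
  p <- se_params(temperature = 298)
  # water-sized sphere in water: ~2.18e-9 m^2/s
  expect_equal(se_predict(1e-3, p), 1.380649e-23 * 298 / (6 * pi * 1e-3 * 1e-10),
               tolerance = 1e-12)
  expect_equal(se_predict(1e-3, p) / se_predict(2e-3, p), 2)
  # at the semi-solid threshold 1e4 Pa s the prediction drops to ~2.2e-16
  expect_equal(se_predict(1e4, p), se_predict(1e-3, p) * 1e-7)
  # homogeneity property across a grid
  eta <- 10^seq(-3, 9, length.out = 7)
  for (c_ in c(2, 17.5)) expect_equal(se_predict(c_ * eta, p), se_predict(eta, p) / c_)
  expect_error(se_predict(-1, p), "positive")
  expect_error(se_params(a = -1), "positive")
})

test_that("divergence_orders is the exact log ratio with sign convention", {
  expect_equal(divergence_orders(1e-12, 1e-12), 0)
  expect_equal(divergence_orders(1e-11, 1e-16), 5)       # raffinose-like case
  expect_lt(divergence_orders(1e-17, 1e-16), 0)          # slower than SE
  d1 <- 10^runif(20, -17, -9); d2 <- 10^runif(20, -17, -9)
  expect_equal(divergence_orders(d1, d2), log10(d1) - log10(d2))
})

test_that("fractional exponent fitting: exact, noisy, and piecewise regimes", {
  aw <- seq(0.1, 0.9, length.out = 24)
  # exact SE input (alpha = 1)
  tab <- dv_table(data.frame(a_w = aw, D_m2s = 1e-12 / 10^seq(0, 6, length.out = 24),
                             eta_Pas = 10^seq(0, 6, length.out = 24)))
  f <- fit_fractional_exponent(tab, n_bootstrap = 50)
  expect_equal(f$alpha, 1, tolerance = 1e-10)
  # alpha = 0.5 over 6 decades with 5% log-noise
  eta <- 10^seq(-2, 4, length.out = 25)
  D <- withr::with_seed(5, 1e-11 * (eta / 1e-2)^-0.5 * 10^rnorm(25, sd = 0.05))
  f2 <- fit_fractional_exponent(dv_table(data.frame(
    a_w = seq(0.1, 0.9, length.out = 25), D_m2s = D, eta_Pas = eta)))
  expect_lt(abs(f2$alpha - 0.5), 0.03)
  # unit invariance: rescaling D or eta leaves alpha unchanged
  tb2 <- tab; tb2$D_m2s <- tb2$D_m2s * 1e4; tb2$eta_Pas <- tb2$eta_Pas * 10
  expect_equal(fit_fractional_exponent(tb2)$alpha, f$alpha, tolerance = 1e-9)
  # two regimes fitted separately; global fit flagged by its residual
  eta_a <- 10^seq(-3, 1, length.out = 12); eta_b <- 10^seq(1, 7, length.out = 12)
  D_ab <- c(1e-9 * (eta_a / 1e-3)^-1, 1e-13 * (eta_b / 10)^-0.4)
  tb3 <- dv_table(data.frame(a_w = seq(0.9, 0.1, length.out = 24),
                             D_m2s = D_ab, eta_Pas = c(eta_a, eta_b)))
  fa <- fit_fractional_exponent(tb3, window = c(1e-3, 10))
  fb <- fit_fractional_exponent(tb3, window = c(10, 1e7))
  fg <- fit_fractional_exponent(tb3)
  expect_equal(fa$alpha, 1.0, tolerance = 0.01)
  expect_equal(fb$alpha, 0.4, tolerance = 0.01)
  expect_gt(fg$residual_rms, 5 * max(fa$residual_rms, fb$residual_rms))
  # identifiability guard
  expect_error(fit_fractional_exponent(tab, window = c(1, 5)), "decades")
})

test_that("build_table joins the two axes and flags extrapolation", {
  dp <- d_parameterization(c(-14, 3), validity = c(0.2, 0.8))
  ep <- eta_parameterization(c(8, -11), validity = c(0.1, 0.9))
  one <- build_table(dp, ep, 0.5)
  expect_equal(nrow(one), 1L)
  expect_false(one$extrapolated)
  tab <- build_table(dp, ep, seq(0.05, 0.95, by = 0.05))
  expect_true(any(tab$extrapolated))
  expect_error(build_table(dp, ep, c(-0.1, 0.5)), "grid")
  # constant D against a sloping eta axis: divergence grows with slope 1
  dpc <- d_parameterization(-12)
  tab2 <- build_table(dpc, eta_parameterization(c(-2, 12)), seq(0, 1, by = 0.1))
  div <- divergence_orders(tab2$D_m2s, se_predict(tab2$eta_Pas))
  expect_equal(diff(div) / diff(log10(tab2$eta_Pas)), rep(1, 10), tolerance = 1e-9)
  # sucrose-like inputs: divergence increases monotonically as a_w falls
  tab3 <- build_table(sucrose_truth(), eta_parameterization(c(11, -14)),
                      seq(0.1, 0.9, by = 0.1))
  div3 <- divergence_orders(tab3$D_m2s, se_predict(tab3$eta_Pas))
  expect_true(all(diff(div3) < 0))
})
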
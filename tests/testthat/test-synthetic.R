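test_that("all generators are byte-reproducible under a fixed seed", {
  truth <- sucrose_truth()
  specs <- list(
    synthetic_spec(11, "response_curve",
                   list(truth = truth, rh_step = c(60, 45), noise_sd = 0.005,
                        n_shells = 20, n_times = 40)),
    synthetic_spec(12, "langevin_trajectory",
                   list(wells = list(list(center = c(2, 2, 2), depth = 3, width = 0.3)),
                        dt = 0.02, n_steps = 2000, box = 4)),
    synthetic_spec(13, "two_state_jump",
                   list(k12 = 1, k21 = 4, dt = 1, n_steps = 2000)),
    synthetic_spec(14, "sphere_packing",
                   list(n_spheres = 50, radius = 0.15, box = 3, mode = "non_overlapping"))
  )
  for (sp in specs) expect_identical(generate(sp), generate(sp), info = sp$kind)
  expect_error(synthetic_spec(1, "sphere_packing", list(bogus = 1)), "unknown parameter")
})

test_that("response curve: no RH step gives a flat unit response", {
  truth <- d_parameterization(-11)
  cv <- gen_response_curve(truth, c(50, 50), n_shells = 15, n_times = 30)
  expect_equal(cv$normalized_size, rep(1, nrow(cv)), tolerance = 1e-9)
})

test_that("response curve with zero noise is the forward shell solution", {
  truth <- d_parameterization(-11)
  am <- activity_model()
  cv <- gen_response_curve(truth, c(60, 40), r0 = 4e-6, n_shells = 20,
                           n_times = 50, activity = am)
  st <- droplet_state(4e-6, 0.6, n_shells = 20, activity = am)
  direct <- solve_shell_diffusion(st, truth, am, 40, cv$t_seconds)
  expect_equal(cv$normalized_size, direct$normalized_size, tolerance = 1e-12)
  expect_error(gen_response_curve(truth, c(110, 40)), "RH outside")
})

test_that("dilute-step half-equilibration matches the analytic sorption series", {
  # constant D; the series oracle assumes a fixed boundary, so the comparison
  # is made for a dilute step where that assumption holds
  D <- 1e-11; r0 <- 4e-6
  cv <- gen_response_curve(d_parameterization(log10(D)), c(0.2, 0.3), r0 = r0,
                           activity = ideal_activity(), n_shells = 40,
                           n_times = 300)
  Mw <- attr(cv, "water_mass")
  w_eq <- w_from_aw(ideal_activity(), 0.003)
  Minf <- (4 / 3 * pi * r0^3 * 1000 * (1 - w_from_aw(ideal_activity(), 0.002))) *
    w_eq / (1 - w_eq)
  frac <- (Mw - Mw[1]) / (Minf - Mw[1])
  t_half <- approx(frac, cv$t_seconds, xout = 0.5)$y
  x50 <- uniroot(function(x) sorption_series(x, 1, 1) - 0.5, c(1e-4, 1))$root
  expect_lt(abs(t_half / (x50 * r0^2 / D) - 1), 0.02)
})

test_that("two-state jump process matches its closed forms", {
  # symmetric rates: stationary occupancy one half
  tr <- gen_two_state_jump(1, 1, dt = 1, n_steps = 5e4, seed = 21)
  expect_lt(abs(mean(tr$states == 1) - 0.5), 3 * sqrt(0.25 / 100)) # ~indep dwells
  # asymmetric: occupancy k21/(k12+k21) and mean dwell in state 1 = 1/k12
  tr2 <- gen_two_state_jump(1, 4, dt = 1, n_steps = 2e5, seed = 22)
  expect_lt(abs(mean(tr2$states == 1) - 0.8), 0.02)
  r <- rle(tr2$states)
  dw1 <- mean(r$lengths[r$values == 1]) / 1000   # ns
  expect_lt(abs(dw1 - 1), 0.1)                    # 1/k12 = 1 ns
  # transition counts over lag dt match the analytic propagator exp(Q dt)
  P <- attr(tr2, "transition")
  from1 <- tr2$states[-length(tr2$states)] == 1
  p12_emp <- mean(tr2$states[-1][from1] == 2)
  n1 <- sum(from1)
  expect_lt(abs(p12_emp - P[1, 2]), 4 * sqrt(P[1, 2] * (1 - P[1, 2]) / n1))
  # degenerate length: single draw from the stationary distribution
  tr3 <- gen_two_state_jump(1, 4, dt = 1, n_steps = 1, seed = 23)
  expect_equal(nrow(tr3$wrapped), 1L)
  expect_true(tr3$states %in% c(1L, 2L))
  expect_warning(gen_two_state_jump(1, 1, emission_sd = 1.5, dt = 1,
                                    n_steps = 10, seed = 1), "unresolvable")
  expect_error(gen_two_state_jump(-1, 1), "positive")
  expect_error(gen_two_state_jump(40, 80, dt = 2), "sample faster")
})

test_that("noiseless Langevin dynamics relaxes to the nearest well and stays", {
  wells <- list(list(center = c(1.2, 2, 2), depth = 3, width = 0.3),
                list(center = c(2.8, 2, 2), depth = 1.5, width = 0.3))
  tr <- gen_langevin_trajectory(wells, temperature = 0, dt = 0.02,
                                n_steps = 3000, x0 = c(1.5, 2.2, 2.1),
                                box = 4, seed = 31)
  expect_equal(as.numeric(tail(tr$unwrapped, 1)), c(1.2, 2, 2), tolerance = 1e-4)
  expect_error(
    gen_langevin_trajectory(wells, dt = 5, n_steps = 10, box = 4, seed = 1),
    "stability")
})

test_that("Langevin sampler obeys detailed balance: well occupancies match the
           Boltzmann quadrature oracle", {
  wells <- list(list(center = c(1.2, 2, 2), depth = 3, width = 0.3),
                list(center = c(2.8, 2, 2), depth = 1.5, width = 0.3))
  tr <- gen_langevin_trajectory(wells, friction = 10, dt = 0.02, n_steps = 4e6,
                                thin = 10, box = 4, seed = 32)
  occ <- mean(nearest_well(tr, wells) == 1)
  oracle <- quad_occupancy(wells, 4)[1]
  expect_lt(abs(occ - oracle), 0.03)
})

test_that("sphere packings: closed forms, feasibility, overlap checks", {
  expect_equal(nrow(gen_sphere_packing(0, box = 3)$centers), 0L)
  expect_equal(occupied_fraction(gen_sphere_packing(0, box = 3),
                                 spacing = 0.05)$occupied_fraction, 0)
  # Poisson void probability: occupied fraction 1 - exp(-rho 4/3 pi r^3)
  pk <- gen_sphere_packing(2000, 0.15, box = 4, mode = "poisson", seed = 41)
  expected <- 1 - exp(-(2000 / 64) * 4 / 3 * pi * 0.15^3)
  expect_lt(abs(occupied_fraction(pk, 0.05)$occupied_fraction - expected), 0.005)
  # RSA: no overlaps under minimum image
  pk2 <- gen_sphere_packing(120, 0.2, box = 3, mode = "non_overlapping", seed = 42)
  d <- as.matrix(dist(pk2$centers))
  for (a in 1:3) {
    da <- outer(pk2$centers[, a], pk2$centers[, a], "-")
    da <- da - 3 * round(da / 3)
    if (a == 1) d2 <- da^2 else d2 <- d2 + da^2
  }
  diag(d2) <- Inf
  expect_gte(min(sqrt(d2)), 0.4)
  # two spheres just fitting
  pk3 <- gen_sphere_packing(2, 0.45, box = 2, mode = "non_overlapping", seed = 43)
  expect_equal(nrow(pk3$centers), 2L)
  # infeasible fraction refused up front
  expect_error(gen_sphere_packing(500, 0.4, box = 3, mode = "non_overlapping"),
               "infeasible")
})
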
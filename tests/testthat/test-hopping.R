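test_that("MSD diffusion: free Brownian recovery, static zero, wrapped guard", {
  tr <- make_brownian_traj(2e5, D0 = 1e-3, seed = 1)
  md <- msd_diffusion(tr, fit_window = c(20, 500), max_origins = 20000)
  expect_lt(abs(md$D_m2s / 1e-9 - 1), 0.1)
  expect_true(md$diffusive)

  still <- trajectory(0:499, matrix(1.5, 500, 3), box = 4)
  md0 <- suppressWarnings(msd_diffusion(still, fit_window = c(10, 100)))
  expect_equal(md0$D_m2s, 0)

  tr$unwrapped <- NULL
  expect_error(msd_diffusion(tr), "unwrapped")
})

test_that("confined motion is flagged sub-linear but still reported", {
  tr <- gen_two_state_jump(2, 2, dt = 1, n_steps = 5e4, seed = 2)  # bounded
  expect_warning(md <- msd_diffusion(tr, fit_window = c(500, 5000)), "non-diffusive")
  expect_false(md$diffusive)
  expect_true(is.finite(md$D_m2s))
})

test_that("PMF: gauge, masking, exact log identity, Gaussian curvature", {
  # uniform sample: flat PMF within counting noise
  X <- withr::with_seed(3, matrix(runif(3e5 * 2, 0, 2), ncol = 2))
  g <- compute_pmf(X, plane = c(1, 2), bin_width = 0.2)
  expect_equal(min(g$values, na.rm = TRUE), 0)
  expect_lt(max(g$values, na.rm = TRUE), 0.15)
  # two occupied bins: PMF difference is exactly the count log-ratio
  xy <- rbind(matrix(rep(c(0.5, 0.5), 2000), ncol = 2, byrow = TRUE),
              matrix(rep(c(1.5, 1.5), 736), ncol = 2, byrow = TRUE))
  g2 <- suppressWarnings(compute_pmf(xy, plane = c(1, 2), bin_width = 1,
                                     range_x = c(0, 2), range_y = c(0, 2)))
  vals <- sort(g2$values[!is.na(g2$values)])
  expect_identical(vals[1], 0)
  expect_equal(vals[2], log(2000 / 736), tolerance = 1e-12)
  expect_equal(sum(is.na(g2$values)), 2L)     # off-diagonal bins masked
  # isotropic Gaussian: quadratic PMF with curvature 1/sigma^2
  sig <- 0.25
  Xg <- withr::with_seed(4, matrix(rnorm(4e5, mean = 2, sd = sig), ncol = 2))
  gg <- compute_pmf(Xg, plane = c(1, 2), bin_width = 0.05,
                    range_x = c(1, 3), range_y = c(1, 3))
  mid <- findInterval(2, gg$y_edges)
  prof <- gg$values[, mid]
  xc <- (head(gg$x_edges, -1) + tail(gg$x_edges, -1)) / 2
  keep <- !is.na(prof) & abs(xc - 2) < 2 * sig
  fit <- lm(prof[keep] ~ poly(xc[keep], 2, raw = TRUE))
  expect_lt(abs(2 * coef(fit)[3] * sig^2 - 1), 0.05)
  # degenerate binning warning (the small-sample warning also fires here)
  w <- capture_warnings(compute_pmf(xy, plane = c(1, 2), bin_width = 5,
                                    range_x = c(0, 5), range_y = c(0, 5)))
  expect_match(w, "90%", all = FALSE)
})

test_that("TST barrier/rate bijection and the printed hop-frequency band", {
  expect_equal(tst_barrier(kbt_over_h_ns(300))$delta_g, 0)
  rates <- 10^seq(-3, 3, length.out = 25)
  expect_equal(tst_rate(tst_barrier(rates)$delta_g), rates, tolerance = 1e-12)
  expect_error(tst_barrier(1e5), "prefactor")
  expect_error(tst_rate(-1), ">= 0")
  # a 6.42 kBT barrier at the thermal prefactor sits inside 1-50 per ns
  r <- tst_rate(6.42)
  expect_gt(r, 1); expect_lt(r, 50)
})

test_that("hop statistics: filter semantics, rates, cycles", {
  alt <- list(states = rep(c(1L, 2L), 50), lag_ps = 10)
  expect_equal(hop_statistics(alt, min_dwell = 10)$hops, 99L)
  expect_equal(hop_statistics(alt, min_dwell = 30)$hops, 0L)
  expect_error(hop_statistics(alt, min_dwell = 5), "spacing")
  # two-state jump at k12 = k21 = 2/ns: hop frequency ~2 per ns
  tr <- gen_two_state_jump(2, 2, dt = 1, n_steps = 2e5, seed = 5)
  m <- suppressWarnings(fit_hmm(tr, 2, lag = 5, seed = 6))
  hs <- hop_statistics(m)
  expect_lt(abs(hs$hops_per_ns / 2 - 1), 0.15)
  expect_equal(hs$return_trip_fraction, 1)    # only two states: all returns
  # three-state cycle: no immediate returns
  cyc <- list(states = rep(c(1L, 1L, 2L, 2L, 3L, 3L), 40), lag_ps = 10)
  expect_equal(hop_statistics(cyc, min_dwell = 10)$return_trip_fraction, 0)
  # dwell distribution bookkeeping
  expect_length(hop_statistics(cyc, min_dwell = 10)$dwell_ns, 3L)
  one <- list(states = rep(1L, 100), lag_ps = 10)
  expect_equal(hop_statistics(one)$hops, 0L)
})

test_that("position autocorrelation: white noise, OU relaxation, drift guard", {
  wn <- withr::with_seed(7, trajectory(seq(0, by = 10, length.out = 5000),
                                       matrix(rnorm(15000), ncol = 3),
                                       box = 100, periodic = FALSE))
  pa <- position_autocorrelation(wn)
  expect_lte(pa$decorrelation_ns, 10 / 1000)
  expect_false(pa$censored)
  # discrete OU with relaxation time theta = 50 frames = 0.5 ns
  th <- 50; n <- 1e5
  x <- withr::with_seed(8, {
    e <- rnorm(n, sd = 0.1); xx <- numeric(n)
    for (i in 2:n) xx[i] <- xx[i - 1] * (1 - 1 / th) + e[i]
    xx
  })
  tro <- trajectory(seq(0, by = 10, length.out = n), cbind(x, 0, 0) + 2,
                    box = 1000, periodic = FALSE)
  pa2 <- position_autocorrelation(tro)
  theta_ns <- -1 / log(1 - 1 / th) * 10 / 1000
  expect_lt(abs(pa2$decorrelation_ns / theta_ns - 1), 0.1)
  # linear drift: correlation stays high, result censored as a lower bound
  dr <- trajectory(seq(0, by = 10, length.out = 2000),
                   cbind(seq(0, 20, length.out = 2000), 0, 0), box = 100,
                   periodic = FALSE)
  expect_warning(pa3 <- position_autocorrelation(dr), "lower bound")
  expect_true(pa3$censored)
  expect_error(position_autocorrelation(subset_trajectory(dr, 1:50)), "100")
})

test_that("frozen-matrix probe separates static, fluctuating and re-randomized
           landscapes", {
  wells <- list(list(center = c(1.3, 1.8, 2.2), depth = 3, width = 0.3),
                list(center = c(2.6, 2.2, 1.8), depth = 2.5, width = 0.3))
  st <- frozen_matrix_probe(wells, fluctuation = list(amplitude = 0, timescale_ns = 1),
                            n_steps = 6e5, seed = 9)
  md <- frozen_matrix_probe(wells, fluctuation = list(amplitude = 1.5, timescale_ns = 1),
                            n_steps = 6e5, seed = 9)
  expect_length(st$pmfs, 3L)
  expect_true(all(md$change_metric > 2.5 * st$change_metric))
  # upper bound: completely re-randomized wells
  wells_b <- list(list(center = c(2.9, 1.1, 1.2), depth = 3, width = 0.3),
                  list(center = c(1.1, 2.9, 2.9), depth = 2.5, width = 0.3))
  pa <- st$pmfs[[1]]
  pb <- frozen_matrix_probe(wells_b, fluctuation = list(amplitude = 0, timescale_ns = 1),
                            snapshot_times_ns = 0, n_steps = 6e5, seed = 10)$pmfs[[1]]
  co <- pa$counts >= 100 & pb$counts >= 100
  indep <- if (sum(co) > 20) {
    ag <- pa$values[co] - min(pa$values[co])
    bg <- pb$values[co] - min(pb$values[co])
    mean(abs(ag - bg))
  } else Inf   # disjoint landscapes: saturated by construction
  expect_true(all(md$change_metric <= max(indep, max(md$change_metric))))
})

test_that("jump diffusion on a periodic well lattice: D consistent with
           hop-rate x hop-length^2 / 6", {
  tr <- gen_hopping_lattice(seed = 11, n_steps = 6e6)
  md <- suppressWarnings(msd_diffusion(tr, fit_window = c(500, 5000)))
  hs <- hop_statistics(list(states = lattice_states(tr), lag_ps = tr$dt),
                       min_dwell = 5)
  D_pred <- hs$hops_per_ns * tr$box[1]^2 / 6 * 1e-9
  expect_gt(md$D_m2s / D_pred, 0.5)
  expect_lt(md$D_m2s / D_pred, 2)
})
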
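# Shared fixtures, all generated in code.

# sucrose-like ground-truth D_w(a_w): D_w,org ~ 5e-17 m^2/s rising to
# ~1e-9 at dilution, monotone in between
sucrose_truth <- function() d_parameterization(c(-16.3, 12, -7, 2.3))

# ideal activity model in which the shell model reduces to classical
# fixed-boundary diffusion in the dilute limit
ideal_activity <- function() activity_model(A = 0, rho_water = 1000, rho_solute = 1000)

# fractional mass uptake of a sphere after a surface concentration step
# (classical series solution)
sorption_series <- function(t, D, r, nmax = 400) {
  vapply(t, function(ti) {
    n <- seq_len(nmax)
    1 - (6 / pi^2) * sum(exp(-n^2 * pi^2 * D * ti / r^2) / n^2)
  }, numeric(1))
}

make_brownian_traj <- function(n, D0 = 1e-3, dt = 1, seed = 1, box = 1e6) {
  withr::with_seed(seed, {
    steps <- matrix(rnorm(3 * n, sd = sqrt(2 * D0 * dt)), ncol = 3)
    trajectory(seq(0, by = dt, length.out = n), apply(steps, 2, cumsum), box)
  })
}

# Boltzmann-weight oracle: quadrature of exp(-U) over the box, partitioned by
# nearest well center (the independent oracle for sampler occupancies)
quad_occupancy <- function(wells, box, h = 0.05) {
  if (length(box) == 1) box <- rep(box, 3)
  centers <- do.call(rbind, lapply(wells, function(w) as.numeric(w$center)))
  depths <- vapply(wells, function(w) w$depth, numeric(1))
  widths <- vapply(wells, function(w) w$width, numeric(1))
  g1 <- seq(h / 2, box[1] - h / 2, by = h)
  g2 <- seq(h / 2, box[2] - h / 2, by = h)
  g3 <- seq(h / 2, box[3] - h / 2, by = h)
  G <- as.matrix(expand.grid(g1, g2, g3))
  U <- cavitydiff:::cavity_potential_cpp(G, centers, depths, widths, box)
  d2 <- sapply(seq_len(nrow(centers)), function(k) {
    d <- sweep(G, 2, centers[k, ])
    for (a in 1:3) d[, a] <- d[, a] - box[a] * round(d[, a] / box[a])
    rowSums(d^2)
  })
  nearest <- max.col(-d2)
  w <- exp(-U)
  vapply(seq_len(nrow(centers)), function(k) sum(w[nearest == k]), numeric(1)) / sum(w)
}

# assign trajectory frames to nearest well center (minimum image)
nearest_well <- function(traj, wells) {
  centers <- do.call(rbind, lapply(wells, function(w) as.numeric(w$center)))
  d2 <- sapply(seq_len(nrow(centers)), function(k) {
    d <- sweep(traj$wrapped, 2, centers[k, ])
    for (a in 1:3) d[, a] <- d[, a] - traj$box[a] * round(d[, a] / traj$box[a])
    rowSums(d^2)
  })
  max.col(-d2)
}

# periodic single-well lattice in a small box: a clean hopping system whose
# unwrapped dynamics is jump diffusion between image wells
gen_hopping_lattice <- function(seed, n_steps = 1e7, L = 1.2) {
  gen_langevin_trajectory(list(list(center = rep(L / 2, 3), depth = 7, width = 0.28)),
                          friction = 10, dt = 0.01, n_steps = n_steps,
                          thin = 10, box = L, seed = seed)
}

lattice_states <- function(traj) {
  site <- floor(traj$unwrapped / traj$box[1])
  as.integer(factor(site[, 1] * 4001 * 4001 + site[, 2] * 4001 + site[, 3]))
}

# noisy KWW curve built directly from the closed form
make_kww_curve <- function(tau, beta, asym = 0.85, noise_sd = 0, seed = 1,
                           n = 200, t_max = NULL) {
  t_max <- t_max %||% (6 * tau)
  tt <- seq(0, t_max, length.out = n)
  y <- asym + (1 - asym) * exp(-(tt / tau)^beta)
  if (noise_sd > 0)
    y <- withr::with_seed(seed, y * (1 + rnorm(n, sd = noise_sd)))
  response_function(tt, y, rh_initial = 50, rh_final = 40,
                    droplet_radius_initial = 4e-6)
}

`%||%` <- cavitydiff:::`%||%`
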
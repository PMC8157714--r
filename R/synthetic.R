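#' Synthetic droplet size-response curve with known ground truth
#'
#' Forward-simulates the spherical-shell Fickian model from a known
#' diffusivity parameterization and adds multiplicative Gaussian noise to the
#' normalized size, emulating an optical-sizing time series after an RH step.
#' Output times span at least five nominal time constants of the slowest
#' composition visited.
#'
#' @param truth A [d_parameterization()] (the ground-truth D_w(a_w)).
#' @param rh_step Length-2 vector `c(RH_initial, RH_final)` in percent.
#' @param r0 Initial droplet radius, m.
#' @param solute Solute label.
#' @param noise_sd Relative (multiplicative) Gaussian noise sd; 0 returns the
#'   exact forward solution.
#' @param seed RNG seed (fixed seed gives identical output).
#' @param n_shells,n_times Discretization of the forward model / sampling.
#' @param activity An [activity_model()].
#' @param temperature Temperature, K.
#' @param span_tau Number of nominal time constants to span (>= 5).
#' @return A [response_function()]; the noise-free solver attributes are kept.
#' @export
gen_response_curve <- function(truth, rh_step, r0 = 4e-6, solute = "synthetic",
                               noise_sd = 0, seed = NULL, n_shells = 60,
                               n_times = 200, activity = activity_model(),
                               temperature = 293.15, span_tau = 5) {
  stopifnot(inherits(truth, "d_parameterization"), length(rh_step) == 2)
  if (any(rh_step < 0 | rh_step > 100))
    stop_domain("gen_response_curve: RH outside [0, 100]")
  if (noise_sd < 0) stop_domain("gen_response_curve: noise_sd must be >= 0")
  a_i <- rh_step[1] / 100; a_f <- rh_step[2] / 100

  tau <- nominal_time_constant(truth, r0, a_i, a_f)
  t_max <- max(span_tau, 5) * tau
  times <- c(0, exp(seq(log(t_max * 1e-4), log(t_max), length.out = n_times - 1)))

  st <- droplet_state(r0, a_i, n_shells = n_shells, activity = activity,
                      temperature = temperature)
  rf <- solve_shell_diffusion(st, truth, activity, rh_step[2], times)
  attr(rf, "solute_label") <- solute
  if (noise_sd > 0) {
    rf$normalized_size <- with_seed(seed,
      rf$normalized_size * (1 + rnorm(nrow(rf), sd = noise_sd)))
  }
  rf
}

#' Overdamped Langevin trajectory in a multi-well cavity landscape
#'
#' Euler-Maruyama integration of a single tracer in a sum of inverted Gaussian
#' wells under periodic boundaries, emulating a water molecule exploring
#' matrix cavities. Well depths can be modulated sinusoidally on one slow
#' timescale (independent random phase per well) to mimic the reorganization
#' of the surrounding saccharide matrix that opens and closes hopping
#' pathways. Energies are in k_BT: temperature enters only through the energy
#' unit, so `temperature = 0` is interpreted as the noiseless (gradient
#' descent) limit.
#'
#' @param wells List of wells, each `list(center = <3-vector nm>, depth =
#'   <k_BT>, width = <nm>)`. An empty list gives free Brownian motion in the
#'   periodic box.
#' @param fluctuation `list(amplitude = <k_BT>, timescale_ns = <ns>)` depth
#'   modulation; amplitude 0 gives a static landscape. `timescale_ns` is the
#'   decorrelation time of the modulation: the sinusoid's period is four times
#'   it (a sine decorrelates - first zero of its autocorrelation - after a
#'   quarter period), so landscapes one timescale apart are in quadrature.
#' @param friction Friction coefficient, ps^-1. The free diffusion coefficient
#'   is `D0 = 1/friction` nm^2/ps.
#' @param temperature K; only the value 0 changes behaviour (noise disabled).
#' @param dt Time step, ps. Must satisfy `dt * max(depth/width^2) / friction
#'   < 0.1` (overdamped stability).
#' @param n_steps Number of integration steps.
#' @param box Box lengths, nm (scalar or length 3).
#' @param x0 Starting position (default: center of the first well).
#' @param thin Store every `thin`-th frame.
#' @param seed RNG seed.
#' @param frozen If TRUE the modulated landscape is frozen at time `t_freeze`
#'   (the tracer probes a rigid matrix snapshot).
#' @param t_freeze Freeze time, ps (only used when `frozen`).
#' @return A [trajectory()]; attributes `wells`, `fluctuation`, `phases`,
#'   `friction` record the ground truth.
#' @export
gen_langevin_trajectory <- function(wells, fluctuation = list(amplitude = 0, timescale_ns = 1),
                                    friction = 10, temperature = 300, dt = 0.01,
                                    n_steps = 1e5, box = 4, x0 = NULL, thin = 1L,
                                    seed = NULL, frozen = FALSE, t_freeze = 0) {
  if (length(box) == 1) box <- rep(box, 3)
  if (length(wells) == 0) {
    centers <- matrix(numeric(0), 0, 3)
    depths <- widths <- numeric(0)
  } else {
    centers <- do.call(rbind, lapply(wells, function(w) as.numeric(w$center)))
    depths <- vapply(wells, function(w) w$depth, numeric(1))
    widths <- vapply(wells, function(w) w$width, numeric(1))
    if (any(widths <= 0)) stop_domain("gen_langevin_trajectory: widths must be positive")
    if (any(centers < 0) || any(sweep(centers, 2, box, `>`)))
      stop_domain("gen_langevin_trajectory: well centers must lie inside the box")
    curv <- max(depths / widths^2)       # k_BT / nm^2, max potential curvature
    if (dt * curv / friction >= 0.1)
      stop_domain("gen_langevin_trajectory: dt too large for stability ",
                  "(dt * curvature / friction = ", signif(dt * curv / friction, 3),
                  " >= 0.1)")
  }
  x0 <- as.numeric(x0 %||% (if (nrow(centers)) centers[1, ] else box / 2))
  amp <- fluctuation$amplitude %||% 0
  # modulation decorrelation time -> sine period = 4 * timescale
  ts_ps <- 4 * 1000 * (fluctuation$timescale_ns %||% 1)

  res <- with_seed(seed, {
    phases <- runif(length(wells), 0, 2 * pi)
    r <- langevin_cpp(centers, depths, widths, amp, ts_ps, phases, friction,
                      noise = temperature > 0, dt, n_steps, as.integer(thin),
                      box, x0, frozen, t_freeze)
    r$phases <- phases
    r
  })
  tr <- trajectory(res$times, res$unwrapped, box, positions_are = "unwrapped")
  attr(tr, "wells") <- wells
  attr(tr, "fluctuation") <- list(amplitude = amp, timescale_ns = ts_ps / 1000)
  attr(tr, "phases") <- res$phases
  attr(tr, "friction") <- friction
  tr
}

#' Exact two-state jump process with Gaussian position emissions
#'
#' Continuous-time two-state Markov chain sampled on a uniform time grid (the
#' exact discrete-time propagator `exp(Q dt)` is used, so no time-
#' discretization error), with isotropic Gaussian emissions about each state
#' center. This is the closed-form oracle for the hidden-Markov stage: the
#' relaxation timescale is exactly `1/(k12 + k21)` and stationary occupancies
#' are `k21/(k12+k21)` and `k12/(k12+k21)`.
#'
#' @param k12,k21 Transition rates 1->2 and 2->1, ns^-1 (> 0).
#' @param emission_sd Isotropic emission sd, nm.
#' @param centers 2 x 3 matrix of state centers, nm.
#' @param dt Sampling interval, ps; must satisfy `dt * (k12 + k21) < 0.1` ns
#'   units, i.e. fine relative to the kinetics.
#' @param n_steps Number of samples.
#' @param box Box lengths, nm.
#' @param seed RNG seed.
#' @return A [trajectory()] with ground-truth `states` (1/2) and attribute
#'   `rates = c(k12, k21)`.
#' @export
gen_two_state_jump <- function(k12, k21, emission_sd = 0.1,
                               centers = rbind(c(1, 1, 1), c(3, 3, 3)),
                               dt = 1, n_steps = 1e4, box = 4, seed = NULL) {
  if (k12 <= 0 || k21 <= 0) stop_domain("gen_two_state_jump: rates must be positive")
  dt_ns <- dt / 1000
  if (dt_ns * (k12 + k21) >= 0.1)
    stop_domain("gen_two_state_jump: dt * (k12 + k21) = ",
                signif(dt_ns * (k12 + k21), 3), " >= 0.1; sample faster")
  centers <- as.matrix(centers)
  if (sqrt(sum((centers[1, ] - centers[2, ])^2)) < 3 * emission_sd)
    warning("gen_two_state_jump: state centers closer than 3 emission sd; ",
            "states may be unresolvable", call. = FALSE)
  ktot <- k12 + k21
  e <- exp(-ktot * dt_ns)
  P <- rbind(c((k21 + k12 * e) / ktot, k12 * (1 - e) / ktot),
             c(k21 * (1 - e) / ktot, (k12 + k21 * e) / ktot))
  pi0 <- c(k21, k12) / ktot
  sim <- with_seed(seed,
    hmm_simulate_cpp(as.integer(n_steps), pi0, P, centers,
                     rep(emission_sd, 2)))
  tr <- trajectory(seq(0, by = dt, length.out = n_steps), sim$X, box,
                   positions_are = "unwrapped", states = sim$states)
  attr(tr, "rates") <- c(k12 = k12, k21 = k21)
  attr(tr, "transition") <- P
  tr
}

#' Random sphere packing in a periodic box
#'
#' Either a Poisson (ideal-gas) placement with overlaps allowed - whose
#' occupied fraction has the closed form `1 - exp(-rho * 4/3 pi r^3)` - or a
#' non-overlapping packing by random sequential addition (RSA) with
#' minimum-image overlap checks, a synthetic stand-in for van der Waals
#' snapshots of an amorphous molecular matrix.
#'
#' @param n_spheres Number of spheres (>= 0).
#' @param radius Sphere radius, nm: scalar, vector of length `n_spheres`, or a
#'   function `function(n)` drawing n radii.
#' @param box Box lengths, nm.
#' @param mode "poisson" or "non_overlapping".
#' @param seed RNG seed.
#' @param max_attempts RSA insertion attempts per sphere before giving up.
#' @param label Configuration label.
#' @return A [packed_config()].
#' @export
gen_sphere_packing <- function(n_spheres, radius = 0.15, box = 4,
                               mode = c("poisson", "non_overlapping"),
                               seed = NULL, max_attempts = 5000, label = "synthetic") {
  mode <- match.arg(mode)
  if (length(box) == 1) box <- rep(box, 3)
  if (n_spheres == 0)
    return(packed_config(matrix(numeric(0), 0, 3), numeric(0), box, label = label))
  radii <- if (is.function(radius)) NULL else rep_len(radius, n_spheres)

  with_seed(seed, {
    if (is.function(radius)) radii <- radius(n_spheres)
    if (any(radii <= 0)) stop_domain("gen_sphere_packing: radii must be positive")
    if (mode == "poisson") {
      centers <- cbind(runif(n_spheres, 0, box[1]), runif(n_spheres, 0, box[2]),
                       runif(n_spheres, 0, box[3]))
      return(packed_config(centers, radii, box, label = label))
    }
    # RSA feasibility guard
    phi_req <- sum(4 / 3 * pi * radii^3) / prod(box)
    if (phi_req > 0.35)
      stop_domain("gen_sphere_packing: requested packing fraction ",
                  signif(phi_req, 3), " > 0.35 infeasible for RSA")
    centers <- matrix(NA_real_, n_spheres, 3)
    placed <- 0L
    for (i in seq_len(n_spheres)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        cand <- runif(3) * box
        if (placed == 0L) { ok <- TRUE; break }
        d <- sweep(centers[seq_len(placed), , drop = FALSE], 2, cand)
        d <- sweep(d, 2, box, function(x, L) x - L * round(x / L))
        mind2 <- rowSums(d^2)
        if (all(mind2 > (radii[seq_len(placed)] + radii[i])^2)) { ok <- TRUE; break }
      }
      if (!ok) {
        phi_ach <- sum(4 / 3 * pi * radii[seq_len(placed)]^3) / prod(box)
        stop("gen_sphere_packing: RSA failed after ", max_attempts,
             " attempts at sphere ", i, "; achieved packing fraction ",
             signif(phi_ach, 3), call. = FALSE)
      }
      centers[i, ] <- cand
      placed <- placed + 1L
    }
    packed_config(centers, radii, box, label = label)
  })
}

#' Declarative synthetic-data specification
#'
#' A small record naming a generator and its parameters, validated against the
#' generator's argument schema; [generate()] dispatches on `kind`. Used by the
#' pipeline so that every synthetic input is reproducible from one config.
#'
#' @param seed Integer seed.
#' @param kind One of "response_curve", "langevin_trajectory",
#'   "two_state_jump", "sphere_packing".
#' @param parameters Named list of generator arguments (seed excluded).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed, kind = c("response_curve", "langevin_trajectory",
                                          "two_state_jump", "sphere_packing"),
                           parameters = list()) {
  kind <- match.arg(kind)
  gen <- switch(kind, response_curve = gen_response_curve,
                langevin_trajectory = gen_langevin_trajectory,
                two_state_jump = gen_two_state_jump,
                sphere_packing = gen_sphere_packing)
  known <- setdiff(names(formals(gen)), "seed")
  bad <- setdiff(names(parameters), known)
  if (length(bad))
    stop_domain("synthetic_spec: unknown parameter(s) for ", kind, ": ",
                paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), kind = kind, parameters = parameters),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @param spec A `synthetic_spec`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gen <- switch(spec$kind, response_curve = gen_response_curve,
                langevin_trajectory = gen_langevin_trajectory,
                two_state_jump = gen_two_state_jump,
                sphere_packing = gen_sphere_packing)
  do.call(gen, c(spec$parameters, list(seed = spec$seed)))
}
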
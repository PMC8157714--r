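#' Diffusion coefficient from the mean squared displacement
#'
#' Time-averaged MSD over sliding origins; `D = slope / 6` from a linear fit
#' of MSD vs lag inside the fit window (Einstein relation in 3-D). Uses
#' unwrapped coordinates only - wrapped positions understate displacements and
#' are rejected. Uncertainty by block averaging over trajectory thirds.
#'
#' @param traj A [trajectory()] with unwrapped positions.
#' @param fit_window Lag range `c(min, max)` in ps; default 1-10% of the
#'   trajectory length (beyond any ballistic/cage regime at short lags, short
#'   enough that the time-averaged MSD retains many independent origins).
#' @param n_lags Number of lags sampled inside the window.
#' @param max_origins Cap on time origins per lag.
#' @return List: `D_m2s`, `D_se` (block-average standard error), `msd`
#'   (data.frame lag_ps / msd_nm2), `diffusive` (FALSE when the log-log slope
#'   across the window is < 0.8; D is still reported), `loglog_slope`.
#' @export
msd_diffusion <- function(traj, fit_window = NULL, n_lags = 30,
                          max_origins = 2000) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$unwrapped))
    stop_domain("msd_diffusion: trajectory has no unwrapped positions; ",
                "wrapped coordinates cannot be used for displacement statistics")
  nfr <- n_frames(traj)
  t_total <- (nfr - 1) * traj$dt
  fit_window <- fit_window %||% (c(0.01, 0.1) * t_total)
  lag_frames <- unique(pmax(1L, round(exp(seq(log(max(1, fit_window[1] / traj$dt)),
                                              log(min(nfr - 2, fit_window[2] / traj$dt)),
                                              length.out = n_lags)))))
  if (length(lag_frames) < 2) stop_domain("msd_diffusion: fit window too narrow")
  lags_ps <- lag_frames * traj$dt

  msd <- msd_cpp(traj$unwrapped, as.integer(lag_frames), as.integer(max_origins))
  fit <- lm(msd ~ lags_ps, weights = 1 / lags_ps^2)
  slope <- unname(coef(fit)[2])                       # nm^2 / ps
  D <- max(slope, 0) / 6 * cavity_constants()$nm2_per_ps_to_m2_per_s

  pos <- msd > 0 & lags_ps > 0
  loglog_slope <- if (sum(pos) >= 2)
    unname(coef(lm(log(msd[pos]) ~ log(lags_ps[pos])))[2]) else NA_real_
  diffusive <- is.finite(loglog_slope) && loglog_slope >= 0.8
  if (!diffusive)
    warning("msd_diffusion: sub-linear MSD (log-log slope ",
            signif(loglog_slope, 3), " < 0.8); trajectory may be non-diffusive",
            call. = FALSE)

  # block averaging over thirds
  thirds <- split(seq_len(nfr), cut(seq_len(nfr), 3, labels = FALSE))
  Db <- vapply(thirds, function(idx) {
    Xb <- traj$unwrapped[idx, , drop = FALSE]
    lf <- lag_frames[lag_frames < length(idx) - 1]
    if (length(lf) < 2) return(NA_real_)
    mb <- msd_cpp(Xb, as.integer(lf), as.integer(max_origins))
    lp <- lf * traj$dt
    max(unname(coef(lm(mb ~ lp, weights = 1 / lp^2))[2]), 0) / 6 * 1e-6
  }, numeric(1))
  D_se <- sd(Db, na.rm = TRUE) / sqrt(sum(is.finite(Db)))

  list(D_m2s = D, D_se = D_se,
       msd = data.frame(lag_ps = lags_ps, msd_nm2 = msd),
       diffusive = diffusive, loglog_slope = loglog_slope, D_blocks = Db)
}

#' Potential of mean force by Boltzmann inversion
#'
#' 2-D normalized position histogram P over a coordinate plane, inverted as
#' `PMF = -ln P` in units of k_BT. The gauge is fixed so the minimum over
#' sampled bins is 0; unsampled bins are masked (NA), never zero-filled.
#'
#' @param x A [trajectory()] (wrapped positions are binned) or an n x 3 (or
#'   n x 2) matrix of position samples, nm.
#' @param plane Axis pair to project on: indices or names from c("x","y","z").
#'   Default yz.
#' @param bin_width Bin width, nm (> 0).
#' @param range_x,range_y Optional bin ranges; default the box (trajectory) or
#'   the data range.
#' @return Object of class `pmf_grid`: `values` (k_BT, NA where unsampled),
#'   `counts`, `x_edges`, `y_edges`, `axes`.
#' @export
compute_pmf <- function(x, plane = c("y", "z"), bin_width = 0.1,
                        range_x = NULL, range_y = NULL) {
  if (bin_width <= 0) stop_domain("compute_pmf: bin width must be positive")
  axnames <- c("x", "y", "z")
  ax <- if (is.character(plane)) match(plane, axnames) else as.integer(plane)
  if (inherits(x, "trajectory")) {
    P <- x$wrapped[, ax, drop = FALSE]
    range_x <- range_x %||% c(0, x$box[ax[1]])
    range_y <- range_y %||% c(0, x$box[ax[2]])
  } else {
    P <- as.matrix(x)
    if (ncol(P) >= 3) P <- P[, ax, drop = FALSE]
    range_x <- range_x %||% range(P[, 1])
    range_y <- range_y %||% range(P[, 2])
  }
  if (nrow(P) < 1e4)
    warning("compute_pmf: fewer than 1e4 samples; PMF will be noisy",
            call. = FALSE)
  xe <- seq(range_x[1], range_x[2] + bin_width * 1e-9, by = bin_width)
  if (xe[length(xe)] < range_x[2]) xe <- c(xe, xe[length(xe)] + bin_width)
  ye <- seq(range_y[1], range_y[2] + bin_width * 1e-9, by = bin_width)
  if (ye[length(ye)] < range_y[2]) ye <- c(ye, ye[length(ye)] + bin_width)
  ix <- findInterval(P[, 1], xe, rightmost.closed = TRUE)
  iy <- findInterval(P[, 2], ye, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix < length(xe) & iy >= 1 & iy < length(ye)
  counts <- matrix(0L, length(xe) - 1, length(ye) - 1)
  tb <- table(factor(ix[ok], levels = seq_len(nrow(counts))),
              factor(iy[ok], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tb)
  prob <- counts / sum(counts)
  if (max(prob) > 0.9)
    warning("compute_pmf: > 90% of the sample mass falls in one bin; ",
            "bin width is probably too large", call. = FALSE)
  v <- -log(prob)
  v[counts == 0] <- NA_real_
  v <- v - min(v, na.rm = TRUE)
  structure(list(values = v, counts = counts, x_edges = xe, y_edges = ye,
                 axes = axnames[ax]),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("<pmf_grid> %s-%s plane, %d x %d bins, %d sampled, max PMF %.2f k_BT\n",
              x$axes[1], x$axes[2], nrow(x$values), ncol(x$values),
              sum(!is.na(x$values)), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Probe cavity persistence with a frozen matrix
#'
#' Emulates the frozen-matrix protocol: the fluctuating well landscape is
#' frozen at a sequence of snapshot times (default 1 ns apart), the tracer is
#' sampled in each rigid landscape, and sequential PMFs are compared. The
#' change metric is the mean absolute PMF difference over bins sampled in both
#' consecutive slices; a static landscape gives a metric near zero, a
#' reorganizing one a significantly larger value.
#'
#' @param wells,fluctuation,friction,dt,box As in [gen_langevin_trajectory()].
#' @param snapshot_times_ns Times (ns) at which the landscape is frozen.
#' @param n_steps Sampling steps per frozen snapshot.
#' @param thin Storage thinning for the probe trajectories.
#' @param bin_width PMF bin width, nm.
#' @param plane Projection plane, as in [compute_pmf()].
#' @param seed RNG seed.
#' @param min_overlap Minimum fraction of co-sampled bins for a comparison to
#'   be reported (otherwise NA with a warning).
#' @param count_min Bins enter the change metric only with at least this many
#'   samples in both slices (keeps histogram shot noise out of the metric).
#' @return List: `pmfs` (one [compute_pmf()] grid per snapshot),
#'   `change_metric` (k_BT, one per consecutive pair), `overlap` (co-sampled
#'   bin fraction per pair), `snapshot_times_ns`.
#' @export
frozen_matrix_probe <- function(wells, fluctuation = list(amplitude = 2, timescale_ns = 1),
                                friction = 10, dt = 0.01, box = 4,
                                snapshot_times_ns = c(0, 1, 2), n_steps = 2e5,
                                thin = 5L, bin_width = 0.1, plane = c("y", "z"),
                                seed = NULL, min_overlap = 0.25,
                                count_min = 100) {
  pmfs <- list()
  phases_seed <- seed %||% 0
  for (i in seq_along(snapshot_times_ns)) {
    tr <- gen_langevin_trajectory(wells, fluctuation, friction = friction,
                                  dt = dt, n_steps = n_steps, box = box,
                                  thin = thin,
                                  seed = phases_seed + 7 * (i - 1),
                                  frozen = TRUE,
                                  t_freeze = snapshot_times_ns[i] * 1000)
    pmfs[[i]] <- compute_pmf(tr, plane = plane, bin_width = bin_width)
  }
  np <- length(pmfs) - 1
  change <- overlap <- rep(NA_real_, max(np, 0))
  for (i in seq_len(np)) {
    a <- pmfs[[i]]$values; b <- pmfs[[i + 1]]$values
    wa <- pmfs[[i]]$counts >= count_min
    wb <- pmfs[[i + 1]]$counts >= count_min
    co <- wa & wb
    overlap[i] <- sum(co) / max(sum(wa | wb), 1)   # Jaccard on well-sampled bins
    if (overlap[i] < min_overlap) {
      warning("frozen_matrix_probe: slices ", i, " and ", i + 1,
              " share too few sampled bins (", signif(overlap[i], 2),
              "); change metric masked", call. = FALSE)
      next
    }
    # re-gauge on the shared support before differencing
    ag <- a[co] - min(a[co]); bg <- b[co] - min(b[co])
    change[i] <- mean(abs(ag - bg))
  }
  list(pmfs = pmfs, change_metric = change, overlap = overlap,
       snapshot_times_ns = snapshot_times_ns)
}

#' Transition-state-theory barrier / rate bijection
#'
#' `rate = prefactor * exp(-delta_g)` with the barrier in k_BT. The default
#' prefactor is the thermal attempt frequency k_BT/h at the given temperature
#' (about 6.25e3 ns^-1 at 300 K).
#'
#' @param rate Hop rate, ns^-1 (> 0, <= prefactor).
#' @param delta_g Barrier height, k_BT (>= 0).
#' @param prefactor Attempt frequency, ns^-1; default k_BT/h.
#' @param temperature K (used only for the default prefactor).
#' @return `tst_barrier()` returns an object of class `barrier_estimate`
#'   (fields `delta_g`, `rate`, `prefactor`, `method`); `tst_rate()` returns
#'   the rate in ns^-1.
#' @export
tst_barrier <- function(rate, prefactor = NULL, temperature = 300) {
  prefactor <- prefactor %||% kbt_over_h_ns(temperature)
  if (any(rate <= 0) || prefactor <= 0)
    stop_domain("tst_barrier: rate and prefactor must be positive")
  if (any(rate > prefactor))
    stop_domain("tst_barrier: rate exceeds prefactor (negative barrier)")
  structure(list(delta_g = log(prefactor / rate), rate = rate,
                 prefactor = prefactor, method = "rate-inversion"),
            class = "barrier_estimate")
}

#' @rdname tst_barrier
#' @export
tst_rate <- function(delta_g, prefactor = NULL, temperature = 300) {
  prefactor <- prefactor %||% kbt_over_h_ns(temperature)
  if (any(delta_g < 0)) stop_domain("tst_rate: barrier must be >= 0")
  prefactor * exp(-delta_g)
}

#' @export
print.barrier_estimate <- function(x, ...) {
  cat(sprintf("<barrier_estimate> delta_G = %s k_BT, rate = %s ns^-1, prefactor = %.4g ns^-1 [%s]\n",
              paste(signif(x$delta_g, 4), collapse = ", "),
              paste(signif(x$rate, 4), collapse = ", "), x$prefactor, x$method))
  invisible(x)
}

#' Hop statistics from a state sequence
#'
#' Counts inter-cavity hops on a dwell-filtered most-likely path: excursions
#' shorter than `min_dwell` are merged into the surrounding state to suppress
#' recrossing noise. Reports hop frequency, per-state dwell-time
#' distributions, and the fraction of hops whose next hop returns to the
#' origin state ("return trips").
#'
#' @param model A `markov_model` (from [fit_hmm()]) or a list with fields
#'   `states` (integer sequence) and `lag_ps` (frame spacing, ps).
#' @param min_dwell Minimum dwell, ps; must be >= the sequence spacing.
#'   Default 2 frames.
#' @return Object of class `hop_statistics`: `hops`, `hops_per_ns`,
#'   `dwell_ns` (list of dwell times per state, ns; empty for absent states),
#'   `return_trip_fraction`, `filtered_states` (run-length encoded path).
#' @export
hop_statistics <- function(model, min_dwell = NULL) {
  states <- model$states
  dt_ps <- model$lag_ps
  if (is.null(states) || is.null(dt_ps))
    stop_domain("hop_statistics: model must carry a state sequence and lag")
  min_dwell <- min_dwell %||% (2 * dt_ps)
  if (min_dwell < dt_ps)
    stop_domain("hop_statistics: min_dwell below the sequence spacing")
  min_frames <- as.integer(round(min_dwell / dt_ps))
  n_states <- max(states)

  r0 <- rle(as.integer(states))
  # single pass: excursions shorter than min_frames are absorbed into the
  # preceding retained state (leading short runs wait for the first long one)
  nr <- length(r0$lengths)
  vals <- integer(nr); lens <- integer(nr)
  m <- 0L; pending <- 0L
  for (i in seq_len(nr)) {
    len <- r0$lengths[i]; st <- r0$values[i]
    if (len < min_frames) {
      if (m > 0L) lens[m] <- lens[m] + len
      else pending <- pending + len
    } else if (m > 0L && vals[m] == st) {
      lens[m] <- lens[m] + len
    } else {
      m <- m + 1L
      vals[m] <- st; lens[m] <- len + pending
      pending <- 0L
    }
  }
  if (m == 0L) {                   # no run long enough: collapse to one state
    m <- 1L
    vals[1] <- r0$values[which.max(r0$lengths)]
    lens[1] <- length(states)
  }
  r <- structure(list(lengths = lens[seq_len(m)], values = vals[seq_len(m)]),
                 class = "rle")

  runs <- length(r$lengths)
  hops <- runs - 1L
  total_ns <- length(states) * dt_ps / 1000
  dwell <- lapply(seq_len(n_states), function(s) r$lengths[r$values == s] * dt_ps / 1000)
  names(dwell) <- paste0("state", seq_len(n_states))

  rtf <- NA_real_
  if (hops >= 2) {
    v <- r$values
    ret <- vapply(seq_len(runs - 2), function(i) v[i + 2] == v[i], logical(1))
    rtf <- mean(ret)
  }

  structure(list(hops = hops, hops_per_ns = hops / total_ns, dwell_ns = dwell,
                 return_trip_fraction = rtf, filtered_states = r,
                 min_dwell_ps = min_frames * dt_ps),
            class = "hop_statistics")
}

#' @export
print.hop_statistics <- function(x, ...) {
  cat(sprintf("<hop_statistics> %d hops (%.3g per ns), return-trip fraction %s\n",
              x$hops, x$hops_per_ns,
              if (is.na(x$return_trip_fraction)) "NA"
              else sprintf("%.2f", x$return_trip_fraction)))
  invisible(x)
}

#' Position-position autocorrelation and decorrelation time
#'
#' Normalized autocovariance of the displacement from the mean position,
#' summed over the three coordinates. The decorrelation time is the first lag
#' at which the correlation drops below 1/e (linearly interpolated); if the
#' correlation never drops below 1/e within the sampled lags the result is
#' censored and reported as a lower bound.
#'
#' @param traj A [trajectory()] with >= 100 frames.
#' @param max_lag Maximum lag in frames; default `n %/% 5`.
#' @return List: `lags_ns`, `correlation`, `decorrelation_ns`, `censored`.
#' @export
position_autocorrelation <- function(traj, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- n_frames(traj)
  if (n < 100) stop_domain("position_autocorrelation: need >= 100 frames")
  max_lag <- max_lag %||% (n %/% 5)
  X <- traj$unwrapped
  covs <- vapply(1:3, function(a) {
    acf(X[, a], lag.max = max_lag, type = "covariance", plot = FALSE,
        demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1))
  num <- rowSums(covs)
  C <- num / num[1]
  lags_ns <- (0:max_lag) * traj$dt / 1000

  below <- which(C < exp(-1))
  if (length(below) == 0) {
    warning("position_autocorrelation: correlation never drops below 1/e ",
            "within sampled lags; decorrelation time is a lower bound",
            call. = FALSE)
    return(list(lags_ns = lags_ns, correlation = C,
                decorrelation_ns = lags_ns[length(lags_ns)], censored = TRUE))
  }
  i <- below[1]
  # linear interpolation between lag i-1 and i
  f <- (C[i - 1] - exp(-1)) / (C[i - 1] - C[i])
  tdec <- lags_ns[i - 1] + f * (lags_ns[i] - lags_ns[i - 1])
  list(lags_ns = lags_ns, correlation = C, decorrelation_ns = tdec,
       censored = FALSE)
}
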
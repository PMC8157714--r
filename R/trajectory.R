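#' Single-tracer 3-D trajectory in a periodic box
#'
#' Uniformly sampled position time series of one tracer molecule. Both wrapped
#' (inside the box, origin at a corner) and unwrapped (continuous) coordinates
#' are kept: unwrapped positions are required for displacement statistics
#' (MSD), wrapped ones for state assignment and PMFs.
#'
#' @param times_ps Frame times, ps; must be uniformly spaced.
#' @param positions n x 3 matrix of positions, nm.
#' @param box Box lengths, nm (length 3 or scalar).
#' @param positions_are One of "unwrapped" (default) or "wrapped". Wrapped
#'   input is unwrapped by minimum-image displacement accumulation, which is
#'   exact provided no frame-to-frame displacement exceeds half the box.
#' @param states Optional integer state labels per frame (ground truth or
#'   model assignment).
#' @param periodic Logical; FALSE for open boundaries (no wrapping applied).
#' @return Object of class `trajectory` with fields `times`, `wrapped`,
#'   `unwrapped`, `box`, `dt` (ps), `states`.
#' @export
trajectory <- function(times_ps, positions, box, positions_are = c("unwrapped", "wrapped"),
                       states = NULL, periodic = TRUE) {
  positions_are <- match.arg(positions_are)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop_domain("trajectory: positions must be n x 3")
  n <- nrow(positions)
  if (length(times_ps) != n) stop_domain("trajectory: times/positions length mismatch")
  if (n >= 2) {
    dts <- diff(times_ps)
    dt <- dts[1]
    bad <- which(abs(dts - dt) > 1e-6 * max(dt, 1e-12))
    if (length(bad))
      stop_domain("trajectory: non-uniform time spacing at frame ", bad[1] + 1)
  } else dt <- NA_real_
  if (length(box) == 1) box <- rep(box, 3)
  if (periodic && any(box <= 0)) stop_domain("trajectory: box lengths must be positive")

  if (!periodic) {
    wrapped <- unwrapped <- positions
  } else if (positions_are == "unwrapped") {
    unwrapped <- positions
    wrapped <- sweep(positions, 2, box, function(x, L) x - L * floor(x / L))
  } else {
    wrapped <- positions
    disp <- apply(rbind(positions[1, ], diff(positions)), 2, identity)
    for (a in 1:3) {
      d <- disp[, a]
      d[-1] <- d[-1] - box[a] * round(d[-1] / box[a])
      disp[, a] <- d
    }
    unwrapped <- apply(disp, 2, cumsum)
    wrapped <- sweep(unwrapped, 2, box, function(x, L) x - L * floor(x / L))
  }
  structure(list(times = as.numeric(times_ps), wrapped = wrapped,
                 unwrapped = unwrapped, box = as.numeric(box), dt = dt,
                 states = states, periodic = periodic),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, dt = %g ps (%.4g ns total), box = (%g, %g, %g) nm%s\n",
              nrow(x$wrapped), x$dt, (nrow(x$wrapped) - 1) * x$dt / 1000,
              x$box[1], x$box[2], x$box[3],
              if (is.null(x$states)) "" else ", with state labels"))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$wrapped)

# frame-range subset, keeping metadata
subset_trajectory <- function(traj, idx) {
  trajectory(traj$times[idx] - traj$times[idx[1]], traj$unwrapped[idx, , drop = FALSE],
             traj$box, positions_are = "unwrapped",
             states = if (!is.null(traj$states)) traj$states[idx] else NULL,
             periodic = traj$periodic)
}
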
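#' Packed molecular configuration (positions + van der Waals radii)
#'
#' @param centers n x 3 matrix of atom centers, nm (wrapped into the box).
#' @param radii van der Waals radii, nm (> 0).
#' @param box Box lengths, nm.
#' @param label Free-text label.
#' @return Object of class `packed_config`.
#' @export
packed_config <- function(centers, radii, box, label = "") {
  centers <- as.matrix(centers)
  if (length(box) == 1) box <- rep(box, 3)
  if (nrow(centers) != length(radii))
    stop_domain("packed_config: centers/radii length mismatch")
  if (length(radii) && any(radii <= 0))
    stop_domain("packed_config: radii must be positive")
  if (nrow(centers))
    centers <- sweep(centers, 2, box, function(x, L) x - L * floor(x / L))
  structure(list(centers = centers, radii = as.numeric(radii),
                 box = as.numeric(box), label = label),
            class = "packed_config")
}

#' @export
print.packed_config <- function(x, ...) {
  cat(sprintf("<packed_config> %s%d spheres, box (%g, %g, %g) nm\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              nrow(x$centers), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Occupied / free volume fraction by grid insertion
#'
#' Regular grid of cell-center points over the periodic box; a point is
#' occupied iff it lies within the (optionally probe-inflated) van der Waals
#' radius of any atom under the minimum-image convention. Each atom only
#' visits its own grid neighbourhood, so the cost is linear in the number of
#' atoms. With `probe_radius = 0` this is the raw geometric vdW occupancy; a
#' positive probe radius instead measures probe-accessible free volume.
#'
#' @param config A [packed_config()].
#' @param spacing Target grid spacing, nm; must be <= min(radii)/2. The actual
#'   spacing divides the box evenly and is reported.
#' @param probe_radius Probe radius added to every atom radius, nm.
#' @return Object of class `free_volume_result`: `occupied_fraction`,
#'   `free_fraction` (= 1 - occupied exactly), `spacing_nm` (per axis),
#'   `n_points`.
#' @export
occupied_fraction <- function(config, spacing = 0.05, probe_radius = 0) {
  stopifnot(inherits(config, "packed_config"))
  n <- nrow(config$centers)
  if (n > 0) {
    rmin <- min(config$radii)
    if (spacing > rmin / 2)
      stop_domain("occupied_fraction: spacing ", spacing, " nm exceeds half the ",
                  "smallest radius; use spacing <= ", signif(rmin / 2, 3), " nm")
  }
  ngrid <- pmax(1L, as.integer(round(config$box / spacing)))
  if (n == 0) {
    return(structure(list(occupied_fraction = 0, free_fraction = 1,
                          spacing_nm = config$box / ngrid,
                          n_points = prod(ngrid)),
                     class = "free_volume_result"))
  }
  res <- occupied_grid_cpp(config$centers, config$radii + probe_radius,
                           config$box, ngrid)
  occ <- res$occupied / res$total
  structure(list(occupied_fraction = occ, free_fraction = 1 - occ,
                 spacing_nm = config$box / ngrid, n_points = res$total),
            class = "free_volume_result")
}

#' @export
print.free_volume_result <- function(x, ...) {
  if (is.null(x$series)) {
    cat(sprintf("<free_volume_result> occupied %.2f%%, free %.2f%% (grid %g nm, %g points)\n",
                100 * x$occupied_fraction, 100 * x$free_fraction,
                signif(max(x$spacing_nm), 3), x$n_points))
  } else {
    cat(sprintf("<free_volume_result> series of %d frames: occupied %.2f%% +/- %.2f%%\n",
                length(x$series), 100 * x$occupied_fraction, 100 * x$occupied_sd))
  }
  invisible(x)
}

#' Free-volume time series over a sequence of configurations
#'
#' @param configs List of [packed_config()] frames (consistent box; a warning
#'   is issued if the box fluctuates).
#' @param spacing,probe_radius As in [occupied_fraction()].
#' @return A `free_volume_result` with `series` (per-frame occupied fraction),
#'   `occupied_fraction` (series mean), `occupied_sd`.
#' @export
free_volume_series <- function(configs, spacing = 0.05, probe_radius = 0) {
  if (length(configs) == 0) stop_domain("free_volume_series: empty sequence")
  stopifnot(all(vapply(configs, inherits, TRUE, "packed_config")))
  boxes <- t(vapply(configs, function(cf) cf$box, numeric(3)))
  if (any(apply(boxes, 2, function(b) diff(range(b))) > 1e-9))
    warning("free_volume_series: box dimensions fluctuate across frames",
            call. = FALSE)
  series <- vapply(configs, function(cf)
    occupied_fraction(cf, spacing, probe_radius)$occupied_fraction, numeric(1))
  structure(list(series = series, occupied_fraction = mean(series),
                 occupied_sd = sd(series), free_fraction = 1 - mean(series),
                 spacing_nm = configs[[1]]$box / pmax(1L, as.integer(round(configs[[1]]$box / spacing))),
                 n_points = NA_real_),
            class = "free_volume_result")
}

# Brute-force all-pairs oracle (used in tests): identical floating-point
# expression to the cell-list path, so results must agree exactly.
occupied_fraction_brute <- function(config, spacing = 0.05, probe_radius = 0) {
  ngrid <- pmax(1L, as.integer(round(config$box / spacing)))
  h <- config$box / ngrid
  gx <- (seq_len(ngrid[1]) - 0.5) * h[1]
  gy <- (seq_len(ngrid[2]) - 0.5) * h[2]
  gz <- (seq_len(ngrid[3]) - 0.5) * h[3]
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  radii <- config$radii + probe_radius
  occ <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(config$centers))) {
    d <- sweep(pts, 2, config$centers[i, ])
    for (a in 1:3) d[, a] <- d[, a] - config$box[a] * round(d[, a] / config$box[a])
    occ <- occ | (rowSums(d^2) <= radii[i]^2)
  }
  mean(occ)
}
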
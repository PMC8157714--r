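#' Read and write single-tracer trajectories
#'
#' Plain-text trajectory IO. Three dialects:
#' \describe{
#'   \item{xyz}{Extended XYZ, one (single-atom) frame per block. The comment
#'     line carries metadata as key=value tokens, e.g.
#'     `t=12.5 box=4.000000,4.000000,4.000000 cavitydiff=0.1.0`, with `t` in
#'     ps and box lengths in nm. Positions are written unwrapped with 6
#'     decimals, so a write/read round trip is lossless at that precision.}
#'   \item{gro}{GROMACS-style fixed-width coordinate series (read-only):
#'     title line (time parsed from a `t=` token if present), atom count, atom
#'     records, box line. Only the first atom of each frame is used.}
#'   \item{csv}{Columns `t_ps, x, y, z` and optionally `state`, with a JSON
#'     sidecar `<path>.json` holding the box and provenance.}
#' }
#' Non-uniform time spacing is rejected with the offending frame index.
#'
#' @param traj A [trajectory()].
#' @param path Output/input file path.
#' @param format One of "xyz", "csv" (write) or "xyz", "gro", "csv" (read).
#' @return `read_trajectory()` returns a [trajectory()];
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory"))
  ver <- as.character(utils::packageVersion("cavitydiff"))
  if (format == "xyz") {
    n <- n_frames(traj)
    blocks <- character(3 * n)
    boxs <- paste(sprintf("%.6f", traj$box), collapse = ",")
    for (i in seq_len(n)) {
      blocks[3 * i - 2] <- "1"
      blocks[3 * i - 1] <- sprintf("t=%.6f box=%s cavitydiff=%s",
                                   traj$times[i], boxs, ver)
      blocks[3 * i] <- sprintf("W %.6f %.6f %.6f", traj$unwrapped[i, 1],
                               traj$unwrapped[i, 2], traj$unwrapped[i, 3])
    }
    writeLines(blocks, path)
  } else {
    df <- data.frame(t_ps = traj$times, x = traj$unwrapped[, 1],
                     y = traj$unwrapped[, 2], z = traj$unwrapped[, 3])
    if (!is.null(traj$states)) df$state <- traj$states
    write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(list(box_nm = traj$box, positions = "unwrapped",
                              cavitydiff = ver),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, format = c("xyz", "gro", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_domain("read_trajectory: no such file: ", path)
  if (format == "xyz") {
    lines <- readLines(path)
    i <- 1L; times <- numeric(0); box <- NULL; pos <- list()
    while (i <= length(lines)) {
      nat <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(nat)) stop_domain("read_trajectory: bad atom count at line ", i)
      toks <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
      kv <- strsplit(toks, "=")
      keys <- vapply(kv, `[`, "", 1)
      tval <- suppressWarnings(as.numeric(kv[[match("t", keys)]][2]))
      bi <- match("box", keys)
      if (is.na(bi)) stop_domain("read_trajectory: missing box on comment line ", i + 1)
      box <- as.numeric(strsplit(kv[[bi]][2], ",")[[1]])
      at <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
      times <- c(times, tval)
      pos[[length(pos) + 1]] <- as.numeric(at[2:4])
      i <- i + 2L + nat
    }
    trajectory(times, do.call(rbind, pos), box, positions_are = "unwrapped")
  } else if (format == "gro") {
    lines <- readLines(path)
    i <- 1L; times <- numeric(0); box <- NULL; pos <- list()
    fr <- 0L
    while (i <= length(lines)) {
      title <- lines[i]
      nat <- as.integer(trimws(lines[i + 1]))
      tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
      fr <- fr + 1L
      times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm))
                 else fr - 1)
      a <- lines[i + 2]   # first atom only (single tracer)
      pos[[fr]] <- c(as.numeric(substr(a, 21, 28)), as.numeric(substr(a, 29, 36)),
                     as.numeric(substr(a, 37, 44)))
      bl <- strsplit(trimws(lines[i + 2 + nat]), "\\s+")[[1]]
      box <- as.numeric(bl[1:3])
      i <- i + 3L + nat
    }
    trajectory(times, do.call(rbind, pos), box, positions_are = "wrapped")
  } else {
    df <- read.csv(path)
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop_domain("read_trajectory: missing JSON sidecar for periodic box: ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    trajectory(df$t_ps, cbind(df$x, df$y, df$z), meta$box_nm,
               positions_are = if (identical(meta$positions, "wrapped")) "wrapped" else "unwrapped",
               states = df$state)
  }
}

#' Read and write packed configurations
#'
#' CSV with columns `x, y, z, radius` (nm) plus a JSON sidecar `<path>.json`
#' holding the box dimensions and label.
#'
#' @param config A [packed_config()].
#' @param path File path.
#' @return `read_packing()` returns a [packed_config()].
#' @export
write_packing <- function(config, path) {
  stopifnot(inherits(config, "packed_config"))
  df <- data.frame(x = config$centers[, 1], y = config$centers[, 2],
                   z = config$centers[, 3], radius = config$radii)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(box_nm = config$box, label = config$label,
                            cavitydiff = as.character(utils::packageVersion("cavitydiff"))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_packing
#' @export
read_packing <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  packed_config(cbind(df$x, df$y, df$z), df$radius, meta$box_nm,
                label = meta$label %||% "")
}

#' Read and write response functions
#'
#' CSV with columns `t_seconds, normalized_size` plus a JSON metadata sidecar
#' (RH step, temperature, initial radius, solute, package version).
#'
#' @param rf A [response_function()].
#' @param path File path.
#' @return `read_response_function()` returns a [response_function()].
#' @export
write_response_function <- function(rf, path) {
  stopifnot(inherits(rf, "response_function"))
  write.csv(data.frame(t_seconds = rf$t_seconds,
                       normalized_size = rf$normalized_size),
            path, row.names = FALSE)
  jsonlite::write_json(
    list(rh_initial = attr(rf, "rh_initial"), rh_final = attr(rf, "rh_final"),
         temperature_K = attr(rf, "temperature"),
         droplet_radius_initial_m = attr(rf, "droplet_radius_initial"),
         solute_label = attr(rf, "solute_label"),
         cavitydiff = as.character(utils::packageVersion("cavitydiff"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_response_function
#' @export
read_response_function <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  response_function(df$t_seconds, df$normalized_size,
                    rh_initial = meta$rh_initial, rh_final = meta$rh_final,
                    temperature = meta$temperature_K,
                    droplet_radius_initial = meta$droplet_radius_initial_m,
                    solute_label = meta$solute_label)
}

#' Serialize fitted objects to JSON
#'
#' @param x A [d_parameterization()] or `markov_model`.
#' @param path Output path.
#' @return `read_dparam()` returns a [d_parameterization()].
#' @export
write_dparam <- function(x, path) {
  stopifnot(inherits(x, "d_parameterization"))
  jsonlite::write_json(list(coefficients = x$coefficients, order = x$order,
                            d_w_org_m2s = x$d_w_org, validity = x$validity,
                            se = x$se,
                            cavitydiff = as.character(utils::packageVersion("cavitydiff"))),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dparam
#' @export
read_dparam <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dp <- d_parameterization(j$coefficients, validity = j$validity)
  dp$se <- j$se
  dp
}

#' @rdname write_dparam
#' @export
write_markov_model <- function(x, path) {
  stopifnot(inherits(x, "markov_model"))
  jsonlite::write_json(
    list(n_states = x$n_states, means_nm = x$means, sds_nm = x$sds,
         transition = x$transition, stationary = x$stationary,
         lag_ps = x$lag_ps, timescales_ns = x$timescales_ns,
         timescale_ci = x$timescale_ci, occupancy = x$occupancy,
         loglik = x$loglik,
         cavitydiff = as.character(utils::packageVersion("cavitydiff"))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
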
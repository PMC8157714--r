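default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = tempfile("cavitydiff_run_"),
    stages = c("synth", "fickian", "se", "hop", "fv"),
    log_level = "INFO",
    synth = list(
      truth_coefficients = c(-15, 5, -1, 1),
      rh_steps = list(c(70, 50), c(50, 30), c(30, 10)),
      r0 = 4e-6, noise_sd = 0.005, n_shells = 30, n_times = 120,
      two_state = list(k12 = 1, k21 = 4, emission_sd = 0.1, dt = 1,
                       n_steps = 20000),
      packing = list(n_spheres = 250, radius = 0.15, box = 3, mode = "poisson")
    ),
    fickian = list(order = 1L, n_shells = 30),
    se = list(eta_coefficients = c(9, -12), a_w_grid = seq(0.1, 0.7, by = 0.1)),
    hop = list(lag = 10, candidates = 1:3, n_bootstrap = 0, min_dwell = NULL),
    fv = list(spacing = 0.05, probe_radius = 0)
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Merges a user configuration (a named list or a path to a JSON file) over
#' the package defaults. Unknown keys at the top level or inside a stage
#' block are rejected.
#'
#' @param config Named list or JSON path; `NULL` gives the defaults.
#' @return Resolved configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config = NULL) {
  def <- default_pipeline_config()
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- config %||% list()
  bad <- setdiff(names(config), names(def))
  if (length(bad))
    stop_domain("pipeline_config: unknown key(s): ", paste(bad, collapse = ", "))
  for (blk in c("synth", "fickian", "se", "hop", "fv")) {
    if (!is.null(config[[blk]])) {
      badk <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(badk))
        stop_domain("pipeline_config: unknown key(s) in '", blk, "': ",
                    paste(badk, collapse = ", "))
    }
  }
  cfg <- modifyList(def, config)
  if (is.list(cfg$synth$rh_steps) == FALSE)
    cfg$synth$rh_steps <- apply(cfg$synth$rh_steps, 1, identity, simplify = FALSE)
  unknown_stages <- setdiff(cfg$stages, c("synth", "fickian", "se", "hop", "fv"))
  if (length(unknown_stages))
    stop_domain("pipeline_config: unknown stage(s): ",
                paste(unknown_stages, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

plog <- function(cfg, stage, ...) {
  if (identical(cfg$log_level, "QUIET")) return(invisible())
  message(sprintf("[cavitydiff:%s] %s", stage, paste0(...)))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the selected stages in dependency order (synthesize -> Fickian
#' D(a_w) fit -> Stokes-Einstein table -> cavity hopping -> free volume),
#' writing artifacts and a machine-readable JSON report of the key outputs
#' (D_w,org, fractional exponent alpha, relaxation timescales, TST barriers,
#' occupied fractions). All randomness derives from the single configured
#' seed through named per-stage substreams, so the same configuration and
#' seed reproduce the report exactly. A resolved copy of the configuration is
#' written next to the outputs. Stage failures are recorded in the report and
#' do not abort later stages.
#'
#' @param config A [pipeline_config()], a named list, or a JSON path.
#' @return The report (named list), invisibly also written to
#'   `<outdir>/report.json`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(cfg$outdir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  order <- c("synth", "fickian", "se", "hop", "fv")
  stages <- order[order %in% cfg$stages]
  art <- new.env(parent = emptyenv())
  report <- list(stages = stages, failures = list())

  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return()
    plog(cfg, name, "running")
    # every stage runs in its own named RNG substream of the global seed
    res <- tryCatch(with_seed(substream_seed(cfg$seed, name), fun()),
                    error = function(e) e)
    if (inherits(res, "error")) {
      report$failures[[name]] <<- conditionMessage(res)
      plog(cfg, name, "FAILED: ", conditionMessage(res))
    } else if (!is.null(res)) {
      report[[name]] <<- res
    }
  }

  run_stage("synth", function() {
    s <- cfg$synth
    seed <- substream_seed(cfg$seed, "synth")
    truth <- d_parameterization(s$truth_coefficients)
    curves <- lapply(seq_along(s$rh_steps), function(i) {
      cv <- gen_response_curve(truth, as.numeric(s$rh_steps[[i]]), r0 = s$r0,
                               noise_sd = s$noise_sd, seed = seed + i,
                               n_shells = s$n_shells, n_times = s$n_times)
      write_response_function(cv, file.path(cfg$outdir, sprintf("curve_%02d.csv", i)))
      cv
    })
    ts <- do.call(gen_two_state_jump, c(s$two_state, list(seed = seed + 100)))
    write_trajectory(ts, file.path(cfg$outdir, "two_state.xyz"))
    pk <- do.call(gen_sphere_packing, c(s$packing, list(seed = seed + 200)))
    write_packing(pk, file.path(cfg$outdir, "packing.csv"))
    assign("curves", curves, art); assign("traj", ts, art); assign("packing", pk, art)
    assign("truth", truth, art)
    list(n_curves = length(curves), traj_frames = n_frames(ts),
         packing_spheres = nrow(pk$centers))
  })

  run_stage("fickian", function() {
    curves <- get("curves", art)
    kww <- lapply(curves, function(cv) suppressWarnings(fit_kww(cv)))
    dp <- fit_diffusivity(curves, order = cfg$fickian$order,
                          n_shells = cfg$fickian$n_shells)
    write_dparam(dp, file.path(cfg$outdir, "d_parameterization.json"))
    assign("dparam", dp, art)
    list(d_w_org_m2s = dp$d_w_org, coefficients = dp$coefficients,
         kww = lapply(kww, function(k) list(tau_s = k$tau, beta = k$beta)))
  })

  run_stage("se", function() {
    dp <- if (exists("dparam", art)) get("dparam", art)
          else d_parameterization(cfg$synth$truth_coefficients)
    ep <- eta_parameterization(cfg$se$eta_coefficients)
    tab <- build_table(dp, ep, cfg$se$a_w_grid)
    write.csv(tab, file.path(cfg$outdir, "dv_table.csv"), row.names = FALSE)
    fa <- fit_fractional_exponent(tab)
    div <- divergence_orders(tab$D_m2s, se_predict(tab$eta_Pas))
    list(alpha = fa$alpha, alpha_se = fa$alpha_se,
         divergence_orders = setNames(div, tab$a_w))
  })

  run_stage("hop", function() {
    tr <- get("traj", art)
    seed <- substream_seed(cfg$seed, "hop")
    sel <- select_n_states(tr, lag = cfg$hop$lag, candidates = cfg$hop$candidates,
                           seed = seed)
    mm <- fit_hmm(tr, sel$n_states, lag = cfg$hop$lag,
                  n_bootstrap = cfg$hop$n_bootstrap, seed = seed + 1)
    write_markov_model(mm, file.path(cfg$outdir, "markov_model.json"))
    hs <- hop_statistics(mm, min_dwell = cfg$hop$min_dwell)
    msd <- suppressWarnings(msd_diffusion(tr))
    br <- if (hs$hops_per_ns > 0 && hs$hops_per_ns <= kbt_over_h_ns())
      tst_barrier(hs$hops_per_ns)$delta_g else NA_real_
    list(n_states = mm$n_states, timescales_ns = mm$timescales_ns,
         hops_per_ns = hs$hops_per_ns,
         return_trip_fraction = hs$return_trip_fraction,
         tst_barrier_kbt = br, msd_D_m2s = msd$D_m2s)
  })

  run_stage("fv", function() {
    pk <- get("packing", art)
    fv <- occupied_fraction(pk, spacing = cfg$fv$spacing,
                            probe_radius = cfg$fv$probe_radius)
    list(occupied_fraction = fv$occupied_fraction,
         free_fraction = fv$free_fraction)
  })

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(report)
}
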
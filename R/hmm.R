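#' Fit a Gaussian-emission hidden Markov state model to a trajectory
#'
#' Metastable-state (cavity) detection: positions are modelled as isotropic
#' 3-D Gaussian emissions from a latent Markov chain observed at a chosen lag.
#' Training is expectation-maximization (Baum-Welch) with k-means
#' initialization; the most-likely state path is decoded by Viterbi dynamic
#' programming. Relaxation timescales are the implied timescales
#' `t_i = -lag / ln(lambda_i)` from the transition-matrix eigenvalues; their
#' 95% credibility intervals come from a parametric bootstrap (refitting on
#' trajectories resampled from the fitted model), a surrogate for a full
#' Bayesian posterior.
#'
#' @param traj A [trajectory()].
#' @param n_states Number of hidden states (>= 1).
#' @param lag Observation lag, ps; the trajectory is subsampled to this
#'   spacing before fitting. Default 10 frames.
#' @param n_bootstrap Parametric-bootstrap replicates for timescale intervals
#'   (0 to skip).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param n_init Independent k-means + EM restarts; the highest-likelihood
#'   solution is kept (guards against local optima such as a diffuse
#'   background state swallowing several cavities).
#' @param seed RNG seed (k-means initialization and bootstrap).
#' @return Object of class `markov_model`: `n_states`, `means` (K x 3 nm),
#'   `sds` (nm), `transition` (row-stochastic, at lag), `stationary`,
#'   `initial`, `states` (Viterbi path on the subsampled frames),
#'   `timescales_ns` (sorted descending), `timescale_ci` (2 x m matrix or
#'   NULL), `loglik`, `loglik_trace`, `lag_ps`, `occupancy`.
#' @export
fit_hmm <- function(traj, n_states, lag = NULL, n_bootstrap = 0,
                    max_iter = 200, tol = 1e-7, n_init = 3, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"), n_states >= 1)
  lag <- lag %||% (10 * traj$dt)
  stride <- max(1L, as.integer(round(lag / traj$dt)))
  lag_ps <- stride * traj$dt
  idx <- seq(1L, n_frames(traj), by = stride)
  if (length(idx) < 50)
    stop_domain("fit_hmm: trajectory shorter than 50 lags")
  X <- traj$wrapped[idx, , drop = FALSE]
  with_seed(seed, fit_hmm_matrix(X, n_states, lag_ps, n_bootstrap, max_iter,
                                 tol, n_init))
}

# core EM on a plain matrix of observations at fixed lag spacing, with
# multiple k-means restarts
fit_hmm_matrix <- function(X, n_states, lag_ps, n_bootstrap = 0,
                           max_iter = 200, tol = 1e-7, n_init = 3) {
  if (n_states > 1 && n_init > 1) {
    fits <- lapply(seq_len(n_init), function(i)
      tryCatch(fit_hmm_matrix(X, n_states, lag_ps, n_bootstrap = 0,
                              max_iter = max_iter, tol = tol, n_init = 1),
               error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("fit_hmm: all EM restarts failed")
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
    if (n_bootstrap > 0 && best$n_states > 1)
      best <- add_bootstrap_ci(best, nrow(X), n_bootstrap, max_iter, tol)
    return(best)
  }
  fit_hmm_once(X, n_states, lag_ps, n_bootstrap, max_iter, tol)
}

fit_hmm_once <- function(X, n_states, lag_ps, n_bootstrap = 0,
                         max_iter = 200, tol = 1e-7) {
  T_ <- nrow(X); K <- as.integer(n_states)

  if (K == 1L) {
    mu <- matrix(colMeans(X), 1, 3)
    sdv <- sqrt(mean(sweep(X, 2, mu[1, ])^2))
    ll <- sum(-1.5 * log(2 * pi * sdv^2) -
                rowSums(sweep(X, 2, mu[1, ])^2) / (2 * sdv^2))
    return(structure(list(n_states = 1L, means = mu, sds = sdv,
                          transition = matrix(1, 1, 1), stationary = 1,
                          initial = 1, states = rep(1L, T_),
                          timescales_ns = numeric(0), timescale_ci = NULL,
                          loglik = ll, loglik_trace = ll, lag_ps = lag_ps,
                          occupancy = 1, converged = TRUE),
                     class = "markov_model"))
  }

  km <- kmeans(X, centers = K, nstart = 5, iter.max = 50)
  mu <- km$centers
  sdv <- vapply(seq_len(K), function(k) {
    pts <- X[km$cluster == k, , drop = FALSE]
    if (nrow(pts) < 2) return(0.1)
    sqrt(mean(sweep(pts, 2, mu[k, ])^2))
  }, numeric(1))
  sdv <- pmax(sdv, 1e-4)
  A <- matrix(0.1 / (K - 1), K, K); diag(A) <- 0.9
  pi0 <- rep(1 / K, K)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- hmm_estep_cpp(X, mu, sdv, pi0, A)
    trace <- c(trace, e$loglik)
    g <- e$gamma
    wk <- colSums(g)
    if (any(wk < 2)) {
      warning("fit_hmm: state emptied during EM; refitting with ", K - 1,
              " states", call. = FALSE)
      return(fit_hmm_matrix(X, K - 1L, lag_ps, n_bootstrap, max_iter, tol))
    }
    mu <- sweep(crossprod(g, X), 1, wk, "/")
    sdv <- vapply(seq_len(K), function(k) {
      sqrt(sum(g[, k] * rowSums(sweep(X, 2, mu[k, ])^2)) / (3 * wk[k]))
    }, numeric(1))
    sdv <- pmax(sdv, 1e-5)
    A <- e$xisum / rowSums(e$xisum)
    pi0 <- pmax(g[1, ], 1e-12); pi0 <- pi0 / sum(pi0)
    if (is.finite(ll_old) && abs(e$loglik - ll_old) < tol * abs(ll_old) + 1e-10) {
      converged <- TRUE
      break
    }
    ll_old <- e$loglik
  }
  if (!converged && length(trace) >= max_iter)
    warning("fit_hmm: EM reached iteration cap without convergence",
            call. = FALSE)

  path <- hmm_viterbi_cpp(X, mu, sdv, pi0, A)
  statio <- stationary_distribution(A)
  ts <- implied_timescales(A, lag_ps)

  model <- structure(
    list(n_states = K, means = mu, sds = sdv, transition = A,
         stationary = statio, initial = pi0, states = as.integer(path),
         timescales_ns = ts, timescale_ci = NULL,
         loglik = trace[length(trace)], loglik_trace = trace,
         lag_ps = lag_ps,
         occupancy = as.numeric(table(factor(path, levels = 1:K)) / T_),
         converged = converged),
    class = "markov_model")
  if (n_bootstrap > 0 && length(ts))
    model <- add_bootstrap_ci(model, T_, n_bootstrap, max_iter, tol)
  model
}

# parametric bootstrap: resample trajectories from the fitted model, refit,
# and take percentile intervals of the implied timescales
add_bootstrap_ci <- function(model, T_, n_bootstrap, max_iter = 200, tol = 1e-7) {
  ts <- model$timescales_ns
  if (!length(ts)) return(model)
  reps <- matrix(NA_real_, n_bootstrap, length(ts))
  for (b in seq_len(n_bootstrap)) {
    sim <- hmm_simulate_cpp(T_, model$stationary, model$transition,
                            model$means, model$sds)
    fb <- tryCatch(
      em_refit(sim$X, model$means, model$sds, model$transition,
               model$stationary, max_iter = 60, tol = tol),
      error = function(e) NULL)
    if (!is.null(fb)) {
      tsb <- implied_timescales(fb$A, model$lag_ps)
      reps[b, seq_len(min(length(tsb), ncol(reps)))] <-
        tsb[seq_len(min(length(tsb), ncol(reps)))]
    }
  }
  model$timescale_ci <- apply(reps, 2, quantile, probs = c(0.025, 0.975),
                              na.rm = TRUE)
  model
}

# lightweight EM restarted from given parameters (bootstrap refits)
em_refit <- function(X, mu, sdv, A, pi0, max_iter = 60, tol = 1e-7) {
  ll_old <- -Inf
  K <- nrow(mu)
  for (it in seq_len(max_iter)) {
    e <- hmm_estep_cpp(X, mu, sdv, pi0, A)
    g <- e$gamma
    wk <- colSums(g)
    if (any(wk < 2)) stop("state emptied")
    mu <- sweep(crossprod(g, X), 1, wk, "/")
    sdv <- pmax(vapply(seq_len(K), function(k) {
      sqrt(sum(g[, k] * rowSums(sweep(X, 2, mu[k, ])^2)) / (3 * wk[k]))
    }, numeric(1)), 1e-5)
    A <- e$xisum / rowSums(e$xisum)
    pi0 <- pmax(g[1, ], 1e-12); pi0 <- pi0 / sum(pi0)
    if (is.finite(ll_old) && abs(e$loglik - ll_old) < tol * abs(ll_old) + 1e-10) break
    ll_old <- e$loglik
  }
  list(mu = mu, sdv = sdv, A = A, pi0 = pi0)
}

stationary_distribution <- function(A) {
  ev <- eigen(t(A))
  i <- which.max(Re(ev$values))
  v <- abs(Re(ev$vectors[, i]))
  v / sum(v)
}

implied_timescales <- function(A, lag_ps) {
  lam <- eigen(A, only.values = TRUE)$values
  m <- Mod(lam)
  ord <- order(m, decreasing = TRUE)
  m <- m[ord][-1]                         # drop the stationary eigenvalue
  m <- m[m > 1e-12 & m < 1 - 1e-12]
  sort(-(lag_ps / 1000) / log(m), decreasing = TRUE)   # ns
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> %d state(s) at lag %g ps, loglik %.1f\n",
              x$n_states, x$lag_ps, x$loglik))
  if (length(x$timescales_ns))
    cat("  relaxation timescales (ns):", signif(x$timescales_ns, 4), "\n")
  cat("  occupancy:", signif(x$occupancy, 3), "\n")
  invisible(x)
}

#' Select the number of metastable states by held-out likelihood
#'
#' Trains an HMM for each candidate state count on the first 70% of the
#' (lag-subsampled) trajectory and scores the held-out log-likelihood of the
#' last 30%. An extra state must improve the held-out score by at least
#' `score_tol` nats per frame to be accepted; within that tolerance the
#' smallest count wins and the near-tie is flagged. This operationalizes
#' "a cavity is a region where the tracer has a significant lifetime".
#'
#' @param traj A [trajectory()].
#' @param lag Observation lag, ps (default 10 frames).
#' @param candidates Candidate state counts, subset of 1..8.
#' @param score_tol Nats per held-out frame below which models are tied.
#' @param seed RNG seed.
#' @return List: `n_states`, `scores` (held-out loglik per frame, by
#'   candidate), `tie` flag, `candidates`.
#' @export
select_n_states <- function(traj, lag = NULL, candidates = 1:4,
                            score_tol = 0.1, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (!all(candidates %in% 1:8))
    stop_domain("select_n_states: candidates must lie in 1..8")
  lag <- lag %||% (10 * traj$dt)
  stride <- max(1L, as.integer(round(lag / traj$dt)))
  idx <- seq(1L, n_frames(traj), by = stride)
  X <- traj$wrapped[idx, , drop = FALSE]
  n_train <- floor(0.7 * nrow(X))
  Xtr <- X[seq_len(n_train), , drop = FALSE]
  Xte <- X[(n_train + 1):nrow(X), , drop = FALSE]

  scores <- with_seed(seed, vapply(candidates, function(K) {
    m <- tryCatch(suppressWarnings(fit_hmm_matrix(Xtr, K, stride * traj$dt)),
                  error = function(e) NULL)
    if (is.null(m)) return(-Inf)
    e <- hmm_estep_cpp(Xte, m$means, matrix_sds(m), m$stationary, m$transition)
    e$loglik / nrow(Xte)
  }, numeric(1)))

  best <- max(scores)
  ok <- which(scores >= best - score_tol)
  pick <- candidates[min(ok)]
  list(n_states = pick, scores = setNames(scores, candidates),
       tie = length(ok) > 1, candidates = candidates)
}

matrix_sds <- function(m) {
  s <- m$sds
  if (length(s) < m$n_states) rep_len(s, m$n_states) else s
}

#' Slice a trajectory and model each slice independently
#'
#' Splits the trajectory into consecutive slices (default 1 ns, a typical
#' upper bound on matrix reorganization so each slice sees a quasi-static
#' cavity landscape), then runs [select_n_states()] and [fit_hmm()] per slice.
#'
#' @param traj A [trajectory()].
#' @param slice_length_ns Slice length, ns.
#' @param lag Observation lag, ps.
#' @param candidates Candidate state counts per slice.
#' @param score_tol Passed to [select_n_states()].
#' @param n_bootstrap Passed to [fit_hmm()].
#' @param seed RNG seed.
#' @return List of per-slice results: `model`, `selection`, `frames`.
#'   Slices too short for the lag are skipped with a warning.
#' @export
slice_and_model <- function(traj, slice_length_ns = 1, lag = NULL,
                            candidates = 1:4, score_tol = 0.1,
                            n_bootstrap = 0, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  lag <- lag %||% (10 * traj$dt)
  frames_per <- max(2L, as.integer(round(slice_length_ns * 1000 / traj$dt)))
  nfr <- n_frames(traj)
  starts <- seq(1L, nfr, by = frames_per)
  starts <- starts[starts + 1 <= nfr]
  if (length(starts) == 0) starts <- 1L
  stride <- max(1L, as.integer(round(lag / traj$dt)))

  out <- list()
  for (si in seq_along(starts)) {
    idx <- starts[si]:min(starts[si] + frames_per - 1L, nfr)
    if (length(idx) < 50 * stride) {
      warning("slice_and_model: slice ", si, " shorter than 50 lags; skipped",
              call. = FALSE)
      next
    }
    sub <- subset_trajectory(traj, idx)
    sseed <- if (is.null(seed)) NULL else seed + si
    sel <- select_n_states(sub, lag = lag, candidates = candidates,
                           score_tol = score_tol, seed = sseed)
    mod <- fit_hmm(sub, sel$n_states, lag = lag, n_bootstrap = n_bootstrap,
                   seed = sseed)
    out[[length(out) + 1]] <- list(model = mod, selection = sel, frames = idx)
  }
  out
}
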
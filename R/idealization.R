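#' Idealize a FRET trace with a Gaussian-emission hidden Markov model
#'
#' Per-trace idealization in the tradition of vbFRET/ebFRET, with the
#' variational posterior replaced by maximum-likelihood EM (Baum-Welch)
#' plus model selection by BIC over candidate state counts — the same
#' idealization contract with fewer free hyperparameters.  Emissions are
#' Gaussian per state; the most likely path is recovered by Viterbi
#' decoding.  Multiple restarts with seeds derived from `seed` make the
#' fit deterministic.
#'
#' @param fret `fret_trace` (or bare numeric vector of FRET values)
#' @param candidate_state_counts state counts to try (default 1:4)
#' @param n_restarts EM restarts per state count
#' @param init_levels optional vector of expected FRET levels (e.g. the
#'   canonical levels); adds one restart per state count initialized at
#'   the K levels with the strongest support in the data, which helps
#'   recover sparsely populated states near the time resolution
#' @param max_iter,tol EM stopping rule
#' @param seed seed for restart jitter
#' @return object of class `idealized_path`: `state_per_frame` (integer
#'   model-state per valid frame), `fitted_means`, `fitted_sds`,
#'   `n_states`, `model_score` (BIC of the chosen model), `frames` (the
#'   indices of the valid frames in the parent trace), plus `frame_time`,
#'   `molecule_id` and carried-over `truth` when available.
#' @export
fit_hmm <- function(fret, candidate_state_counts = 1:4, n_restarts = 2,
                    init_levels = NULL, max_iter = 100, tol = 1e-6,
                    seed = 1L) {
  if (inherits(fret, "fret_trace")) {
    frames <- which(!is.na(fret$efficiency))
    y <- fret$efficiency[frames]
    meta <- fret[c("frame_time", "molecule_id", "truth")]
  } else {
    y <- as.numeric(fret)
    frames <- which(!is.na(y))
    y <- y[frames]
    meta <- list(frame_time = NA_real_, molecule_id = NA_character_,
                 truth = NULL)
  }
  if (length(y) < 10) stop("need >= 10 valid frames to idealize")

  # degenerate trace: effectively constant
  if (stats::sd(y) < 1e-12) {
    return(structure(list(state_per_frame = rep(1L, length(y)),
                          fitted_means = mean(y),
                          fitted_sds = 1e-6,
                          n_states = 1L, model_score = NA_real_,
                          frames = frames, frame_time = meta$frame_time,
                          molecule_id = meta$molecule_id,
                          truth = meta$truth),
                     class = "idealized_path"))
  }

  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max,
                              n_restarts * length(candidate_state_counts))
  best <- NULL
  si <- 0
  for (K in candidate_state_counts) {
    inits <- vector("list", n_restarts)
    if (!is.null(init_levels) && K <= length(init_levels)) {
      # K expected levels with the strongest support in this trace
      near <- vapply(y, function(v)
        which.min(abs(init_levels - v)), 0L)
      support <- tabulate(near, nbins = length(init_levels))
      top <- order(support, decreasing = TRUE)[seq_len(K)]
      inits <- c(inits, list(sort(init_levels[top])))
    }
    for (r in seq_along(inits)) {
      si <- si + 1
      fit <- tryCatch(
        em_gaussian_hmm(y, K, seed = restart_seeds[((si - 1) %%
                          length(restart_seeds)) + 1],
                        jitter = r > 1 && r <= n_restarts,
                        mu0 = inits[[r]],
                        max_iter = max_iter, tol = tol),
        error = function(e) NULL)
      if (is.null(fit)) next
      # BIC: K-1 initial probs + K(K-1) transition + 2K emission params
      p <- (K - 1) + K * (K - 1) + 2 * K
      bic <- -2 * fit$loglik + p * log(length(y))
      if (is.null(best) || bic < best$bic) best <- c(fit, list(bic = bic))
    }
  }
  path <- hmm_viterbi(y, best$pi0, best$A, best$mu, best$sd)
  # drop states never visited so fitted_means reflect the decoded path
  used <- sort(unique(path))
  relab <- match(path, used)
  structure(list(state_per_frame = as.integer(relab),
                 fitted_means = best$mu[used],
                 fitted_sds = best$sd[used],
                 n_states = length(used),
                 model_score = best$bic,
                 frames = frames,
                 frame_time = meta$frame_time,
                 molecule_id = meta$molecule_id,
                 truth = meta$truth),
            class = "idealized_path")
}

# EM for a K-state Gaussian HMM on one trace; quantile initialization with
# optional jitter for restarts.
em_gaussian_hmm <- function(y, K, seed = 1L, jitter = FALSE, mu0 = NULL,
                            max_iter = 100, tol = 1e-6) {
  set.seed(seed)
  T_ <- length(y)
  if (!is.null(mu0)) {
    mu <- as.numeric(mu0)
    stopifnot(length(mu) == K)
  } else {
    qs <- stats::quantile(y, probs = (seq_len(K) - 0.5) / K,
                          names = FALSE)
    mu <- as.numeric(qs)
  }
  if (jitter) mu <- mu + stats::rnorm(K, 0, stats::sd(y) / 4)
  sd0 <- max(stats::sd(y) / max(K, 2), 1e-4)
  sdv <- rep(sd0, K)
  A <- matrix(0.05 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.95 else 1
  pi0 <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    es <- hmm_estep(y, pi0, A, mu, sdv)
    g <- es$gamma
    xi <- es$xi
    Ng <- colSums(g)
    pi0 <- pmax(g[1, ], 1e-12)
    pi0 <- pi0 / sum(pi0)
    if (K > 1) {
      A <- xi / pmax(rowSums(xi), 1e-300)
      A <- A + 1e-12
      A <- A / rowSums(A)
    }
    mu <- colSums(g * y) / pmax(Ng, 1e-300)
    for (k in seq_len(K))
      sdv[k] <- sqrt(sum(g[, k] * (y - mu[k])^2) / max(Ng[k], 1e-300))
    sdv <- pmax(sdv, 1e-4)
    ll <- hmm_loglik(y, pi0, A, mu, sdv)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(pi0 = pi0, A = A, mu = mu, sd = sdv, loglik = hmm_loglik(y, pi0, A, mu, sdv))
}

#' Map fitted HMM states onto canonical FRET levels
#'
#' Each fitted emission mean is assigned to the nearest canonical level
#' (ties break toward the lower level, conservative against overcalling
#' the bound states); fitted states that collide on one canonical level
#' are merged.  Fitted means farther than `cutoff` from every canonical
#' level are flagged unassigned (label `NA`).
#'
#' @param path `idealized_path`
#' @param canonical_levels sorted distinct canonical FRET levels, e.g.
#'   `c(0, 0.4, 0.7)`
#' @param cutoff maximum assignment distance (default 0.15)
#' @return `idealized_path` with `canonical_per_frame` (numeric level per
#'   frame, `NA` when unassigned), `canonical_levels`, `assignment`
#'   (per fitted state: level and distance)
#' @export
map_to_canonical <- function(path, canonical_levels = c(0, 0.4, 0.7),
                             cutoff = 0.15) {
  stopifnot(!is.unsorted(canonical_levels),
            !anyDuplicated(canonical_levels))
  mu <- path$fitted_means
  lev <- vapply(mu, function(m) {
    d <- abs(canonical_levels - m)
    # ties (within rounding) break toward the lower level
    i <- which(d <= min(d) + 1e-9)[1]
    if (d[i] > cutoff + 1e-9) NA_real_ else canonical_levels[i]
  }, 0)
  dist <- abs(mu - lev)
  path$assignment <- data.frame(fitted_mean = mu, canonical = lev,
                                distance = dist)
  path$canonical_levels <- canonical_levels
  path$canonical_per_frame <- lev[path$state_per_frame]
  path
}

#' Frame-label accuracy of an idealized path against its ground truth
#'
#' Compares the canonical level per frame with the FRET level of the true
#' dominant state recorded by the synthetic generator.
#'
#' @param path `idealized_path` after [map_to_canonical()]
#' @param fret_levels named true FRET level per state (from the scheme)
#' @return fraction of frames whose canonical level equals the true level
#' @export
frame_accuracy <- function(path, fret_levels) {
  if (is.null(path$truth)) stop("no ground truth attached to this path")
  truth_lev <- fret_levels[path$truth$frame_state[path$frames]]
  mean(path$canonical_per_frame == truth_lev, na.rm = TRUE)
}

#' Write idealized paths as delimited text
#'
#' One row per frame: molecule id, frame index, raw E, model state,
#' fitted mean, canonical level.
#'
#' @param paths list of `idealized_path`
#' @param fret_list matching list of `fret_trace` for the raw E column
#' @param path output file
#' @export
write_idealized <- function(paths, fret_list, path) {
  rows <- Map(function(p, f) {
    data.frame(molecule_id = p$molecule_id,
               frame = p$frames,
               efficiency = f$efficiency[p$frames],
               state = p$state_per_frame,
               fitted_mean = p$fitted_means[p$state_per_frame],
               canonical = if (!is.null(p$canonical_per_frame))
                 p$canonical_per_frame else NA_real_)
  }, paths, fret_list)
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
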
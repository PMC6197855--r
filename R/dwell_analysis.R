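#' Extract dwell records from an idealized path
#'
#' Maximal runs of identical canonical labels become dwells.  The first
#' and last dwell of every trace are flagged censored (trace start, trace
#' end or photobleach); interior dwells carry their preceding and
#' following states.  Durations are in seconds (run length x frame time).
#'
#' @param path `idealized_path` after [map_to_canonical()]
#' @param frame_time frame time in s; defaults to the path's own
#' @return data.frame (one row per dwell): molecule_id, state, duration,
#'   n_frames, prev_state, next_state, left_censored, right_censored
#' @export
extract_dwells <- function(path, frame_time = path$frame_time) {
  lab <- path$canonical_per_frame
  if (is.null(lab)) stop("map_to_canonical must be applied first")
  r <- rle(paste0(lab))          # NA-safe label encoding
  k <- length(r$lengths)
  state <- as.numeric(ifelse(r$values == "NA", NA, r$values))
  data.frame(
    molecule_id = if (!is.null(path$molecule_id)) path$molecule_id else NA,
    state = state,
    duration = r$lengths * frame_time,
    n_frames = r$lengths,
    prev_state = c(NA, state[-k]),
    next_state = c(state[-1], NA),
    left_censored = seq_len(k) == 1,
    right_censored = seq_len(k) == k,
    stringsAsFactors = FALSE)
}

#' Extract and pool dwells over a list of idealized paths
#' @param paths list of `idealized_path`
#' @inheritParams extract_dwells
#' @return pooled dwell data.frame
#' @export
extract_dwells_all <- function(paths, frame_time = NULL) {
  do.call(rbind, lapply(paths, function(p)
    extract_dwells(p, frame_time = if (is.null(frame_time))
      p$frame_time else frame_time)))
}

#' Fit an exponential lifetime to a set of dwells
#'
#' Two estimators are provided.  `method = "mle"` (default) is the
#' censoring-aware exponential maximum likelihood: right-censored dwells
#' contribute their duration to the exposure but not to the event count,
#' tau = sum(durations) / n_uncensored.  With `discrete = TRUE` the frame
#' quantization is corrected through the geometric-distribution MLE
#' (rate = -log(1 - 1/mean_frames) / frame_time), appropriate when tau is
#' within an order of magnitude of the frame time.  `method = "histogram"`
#' reproduces the classical histogram least-squares fit
#' A exp(-t/tau) + y0 with a free offset.
#'
#' `model = "double"` fits a two-component exponential mixture by MLE
#' (uncensored dwells) and reports the population-weighted average
#' lifetime (A1 t1 + A2 t2) / (A1 + A2); if the mixture fit does not
#' converge it falls back to the single fit with a warning.
#'
#' @param dwells data.frame from [extract_dwells()] (or a bare numeric
#'   vector of durations, treated as uncensored)
#' @param model `"single"` or `"double"`
#' @param method `"mle"` or `"histogram"`
#' @param min_dwells estimates from fewer uncensored dwells are flagged
#'   unreliable
#' @param include_censored use right-censored dwells as exposure in the
#'   MLE (ignored by the histogram method)
#' @param discrete apply the frame-quantization correction
#' @param frame_time frame time in s, required when `discrete = TRUE` and
#'   dwells is a bare vector
#' @param n_bins histogram bins for `method = "histogram"`
#' @return object of class `lifetime_estimate`: tau, se, n_dwells, model,
#'   method, reliable flag, and for double fits `components`
#'   (t1, A1, t2, A2) plus `weighted_tau`
#' @export
fit_lifetime <- function(dwells, model = c("single", "double"),
                         method = c("mle", "histogram"),
                         min_dwells = 20, include_censored = TRUE,
                         discrete = FALSE, frame_time = NULL,
                         n_bins = 30) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (is.data.frame(dwells)) {
    dur <- dwells$duration
    cens <- dwells$right_censored | dwells$left_censored
    if (is.null(frame_time) && !is.null(dwells$n_frames) &&
        any(dwells$n_frames > 0))
      frame_time <- dwells$duration[1] / dwells$n_frames[1]
  } else {
    dur <- as.numeric(dwells)
    cens <- rep(FALSE, length(dur))
  }
  keep <- !is.na(dur) & dur > 0
  dur <- dur[keep]; cens <- cens[keep]
  n_unc <- sum(!cens)
  reliable <- n_unc >= min_dwells
  if (!reliable && n_unc == 0) stop("no uncensored dwells to fit")

  if (method == "histogram") {
    est <- lifetime_histogram_fit(dur[!cens], n_bins)
    tau <- est$tau; se <- est$se
  } else if (include_censored) {
    tau <- sum(dur) / n_unc
    se <- tau / sqrt(n_unc)
  } else {
    tau <- mean(dur[!cens])
    se <- tau / sqrt(n_unc)
  }
  if (discrete) {
    if (is.null(frame_time) || !is.finite(frame_time) || frame_time <= 0)
      stop("discrete correction needs frame_time")
    mbar <- tau / frame_time
    if (mbar <= 1) mbar <- 1 + 1e-6
    rate <- -log(1 - 1 / mbar) / frame_time
    tau <- 1 / rate
    se <- tau / sqrt(n_unc)
  }
  out <- list(tau = tau, se = se, n_dwells = n_unc, model = model,
              method = method, reliable = reliable)

  if (model == "double") {
    mix <- tryCatch(exp_mixture_mle(dur[!cens]), error = function(e) NULL)
    if (is.null(mix) || !mix$converged) {
      warning("double-exponential fit did not converge; using single fit")
      out$model <- "single"
    } else {
      out$components <- c(t1 = mix$t1, A1 = mix$A1,
                          t2 = mix$t2, A2 = mix$A2)
      out$weighted_tau <- weighted_average_lifetime(mix$t1, mix$A1,
                                                    mix$t2, mix$A2)
      out$tau <- out$weighted_tau
    }
  }
  structure(out, class = "lifetime_estimate")
}

#' Population-weighted average lifetime of a double-exponential fit
#' @param t1,A1,t2,A2 component lifetimes and amplitudes
#' @return (A1 t1 + A2 t2) / (A1 + A2)
#' @export
weighted_average_lifetime <- function(t1, A1, t2, A2) {
  (A1 * t1 + A2 * t2) / (A1 + A2)
}

# two-component exponential mixture by direct MLE (EM)
exp_mixture_mle <- function(x, max_iter = 500, tol = 1e-8) {
  stopifnot(length(x) >= 4)
  q <- stats::quantile(x, c(0.25, 0.9), names = FALSE)
  t1 <- max(q[1], 1e-6); t2 <- max(q[2], t1 * 1.5)
  w <- 0.5
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w * stats::dexp(x, 1 / t1)
    d2 <- (1 - w) * stats::dexp(x, 1 / t2)
    g <- d1 / (d1 + d2)
    w <- mean(g)
    t1 <- sum(g * x) / sum(g)
    t2 <- sum((1 - g) * x) / sum(1 - g)
    ll <- sum(log(d1 + d2))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp; w <- 1 - w }
  list(t1 = t1, A1 = w, t2 = t2, A2 = 1 - w, converged = converged)
}

# histogram least squares with offset: A exp(-t/tau) + y0
lifetime_histogram_fit <- function(x, n_bins = 30) {
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  t <- h$mids; y <- h$counts
  tau0 <- mean(x)
  fit <- stats::nls(y ~ A * exp(-t / tau) + y0,
                    start = list(A = max(y), tau = tau0, y0 = 0),
                    control = stats::nls.control(warnOnly = TRUE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                 error = function(e) NA_real_)
  list(tau = unname(cf["tau"]), se = se)
}

#' Pooled FRET histogram with Gaussian peak fits
#'
#' Pools all valid frames of a trace collection into one FRET histogram
#' and fits a fixed-count Gaussian mixture (EM) to locate peak centers
#' and widths.
#'
#' @param fret_list list of `fret_trace` (or numeric vector of E values)
#' @param bins histogram bin width on the FRET axis (default 0.02)
#' @param n_peaks number of Gaussian components
#' @param init_centers optional starting centers (defaults to quantiles)
#' @return list with `breaks`, `counts`, `density`, and `peaks`
#'   (data.frame center, sd, weight, ordered by center)
#' @export
fret_histogram <- function(fret_list, bins = 0.02, n_peaks = 2,
                           init_centers = NULL) {
  e <- if (is.list(fret_list))
    unlist(lapply(fret_list, function(f) f$efficiency)) else
      as.numeric(fret_list)
  e <- e[!is.na(e)]
  if (!length(e)) stop("no valid frames to histogram")
  lo <- floor(min(e, -0.1) / bins) * bins
  hi <- ceiling(max(e, 1.1) / bins) * bins
  breaks <- seq(lo, hi, by = bins)
  h <- graphics::hist(e, breaks = breaks, plot = FALSE)
  peaks <- gaussian_mixture_1d(e, n_peaks, init_centers)
  list(breaks = h$breaks, counts = h$counts, density = h$density,
       peaks = peaks)
}

# small fixed-K 1-D Gaussian mixture EM
gaussian_mixture_1d <- function(x, K, init_centers = NULL,
                                max_iter = 300, tol = 1e-8) {
  if (K == 1) {
    return(data.frame(center = mean(x), sd = stats::sd(x), weight = 1))
  }
  mu <- if (!is.null(init_centers)) init_centers else
    stats::quantile(x, (seq_len(K) - 0.5) / K, names = FALSE)
  sdv <- rep(max(stats::sd(x) / K, 1e-3), K)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      w[k] * stats::dnorm(x, mu[k], sdv[k]), numeric(length(x)))
    tot <- rowSums(dens) + 1e-300
    g <- dens / tot
    Nk <- colSums(g)
    w <- Nk / length(x)
    mu <- colSums(g * x) / Nk
    sdv <- sqrt(colSums(g * (outer(x, mu, "-"))^2) / Nk)
    sdv <- pmax(sdv, 1e-4)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  o <- order(mu)
  data.frame(center = mu[o], sd = sdv[o], weight = w[o])
}

#' Transition density plot (TDP) data
#'
#' 2D histogram over (FRET before, FRET after) of the fitted emission
#' means at every uncensored transition; the diagonal is empty by
#' construction since dwells are maximal runs.
#'
#' @param dwells pooled dwell data.frame
#' @param bins bin width on both FRET axes
#' @return list with `x_breaks`, `y_breaks`, `counts` (matrix), and
#'   `transitions` (data.frame from, to, n); transitions with `NA` on
#'   either side are dropped
#' @export
transition_density <- function(dwells, bins = 0.05) {
  tr <- dwells[!dwells$right_censored & !is.na(dwells$next_state) &
                 !is.na(dwells$state), ]
  from <- tr$state
  to <- tr$next_state
  keep <- !is.na(from) & !is.na(to)
  from <- from[keep]; to <- to[keep]
  breaks <- seq(-0.1, 1.1, by = bins)
  cnt <- matrix(0, length(breaks) - 1, length(breaks) - 1)
  if (length(from)) {
    bx <- findInterval(from, breaks, rightmost.closed = TRUE)
    by <- findInterval(to, breaks, rightmost.closed = TRUE)
    for (i in seq_along(bx)) cnt[bx[i], by[i]] <- cnt[bx[i], by[i]] + 1
  }
  tab <- if (length(from))
    as.data.frame(table(from = from, to = to),
                  responseName = "n") else
      data.frame(from = numeric(), to = numeric(), n = integer())
  if (nrow(tab)) {
    tab$from <- as.numeric(as.character(tab$from))
    tab$to <- as.numeric(as.character(tab$to))
    tab <- tab[tab$n > 0, ]
  }
  list(x_breaks = breaks, y_breaks = breaks, counts = cnt,
       transitions = tab)
}

#' Classify traces into the three canonical phenotypes
#'
#' Over the bound portion of each trace: Type I reaches the fully bound
#' level and never revisits the partially bound level afterwards; Type II
#' reaches the fully bound level with at least one excursion back to the
#' partially bound level; Type III samples only the partially bound level.
#' Traces that never leave the unbound level are excluded from the
#' denominator.
#'
#' @param paths list of `idealized_path` after [map_to_canonical()]
#' @param full_level,partial_level,unbound_level canonical FRET levels
#'   (partially bound accepts any bound level below `full_level`)
#' @return list with counts, fractions (`type1`, `type2`, `type3`,
#'   summing to 1 over bound traces), binomial standard errors, and
#'   `n_bound`
#' @export
classify_traces <- function(paths, full_level = 0.7,
                            partial_level = 0.4, unbound_level = 0) {
  types <- vapply(paths, function(p) {
    lab <- p$canonical_per_frame
    lab <- lab[!is.na(lab)]
    bound <- lab[lab != unbound_level]
    if (!length(bound)) return(NA_integer_)
    reaches_full <- any(bound == full_level)
    if (!reaches_full) return(3L)
    # excursion: full -> lower bound level
    r <- rle(bound)
    v <- r$values
    back <- any(v[-length(v)] == full_level & v[-1] < full_level)
    if (back) 2L else 1L
  }, 0L)
  types <- types[!is.na(types)]
  n <- length(types)
  if (!n) stop("no bound traces to classify")
  frac <- c(type1 = mean(types == 1), type2 = mean(types == 2),
            type3 = mean(types == 3))
  se <- sqrt(frac * (1 - frac) / n)
  list(counts = table(factor(types, levels = 1:3)),
       fractions = frac, se = se, n_bound = n)
}

#' Post-synchronized time-evolved FRET histogram
#'
#' Aligns traces at the first transition from the unbound level into a
#' bound level (or at injection time in flow mode) and accumulates a
#' 2D density of FRET versus time-since-synchronization.
#'
#' @param fret_list list of `fret_trace`
#' @param paths matching list of canonical `idealized_path` supplying the
#'   sync point
#' @param n_frames_out frames to keep after the sync point
#' @param fret_bins FRET bin width
#' @param unbound_level canonical unbound level
#' @param sync `"first_binding"` or `"injection"`
#' @param injection_time required when `sync = "injection"`
#' @return list with `time_s`, `fret_breaks`, `density` (time x FRET
#'   matrix, rows normalized to frame counts), `n_traces`
#' @export
postsynchronized_histogram <- function(fret_list, paths,
                                       n_frames_out = 50,
                                       fret_bins = 0.05,
                                       unbound_level = 0,
                                       sync = c("first_binding",
                                                "injection"),
                                       injection_time = NULL) {
  sync <- match.arg(sync)
  breaks <- seq(-0.2, 1.2, by = fret_bins)
  dens <- matrix(0, n_frames_out, length(breaks) - 1)
  n_used <- 0
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    f <- fret_list[[i]]
    if (sync == "first_binding") {
      lab <- p$canonical_per_frame
      idx <- which(!is.na(lab) & lab != unbound_level)
      if (!length(idx)) next
      first_bound <- idx[1]
      if (first_bound == 1) next       # already bound at start: no event
      start_frame <- p$frames[first_bound]
    } else {
      if (is.null(injection_time)) stop("injection_time required")
      start_frame <- ceiling(injection_time / f$frame_time) + 1
    }
    e <- f$efficiency[start_frame:min(start_frame + n_frames_out - 1,
                                      length(f$efficiency))]
    keep <- !is.na(e)
    if (!any(keep)) next
    bx <- findInterval(e[keep], breaks, rightmost.closed = TRUE)
    rows <- which(keep)
    for (j in seq_along(rows)) dens[rows[j], bx[j]] <-
        dens[rows[j], bx[j]] + 1
    n_used <- n_used + 1
  }
  if (!n_used) stop("no trace satisfies the synchronization rule")
  rs <- rowSums(dens)
  norm <- dens / ifelse(rs > 0, rs, 1)
  list(time_s = (seq_len(n_frames_out) - 1) *
         fret_list[[1]]$frame_time,
       fret_breaks = breaks, density = norm, counts = dens,
       n_traces = n_used)
}

#' Merge canonical levels into one class before dwell analysis
#'
#' Rewrites dwell states in `levels` to `new_level` and fuses consecutive
#' same-class dwells per molecule, summing durations.  Used to pool the
#' 0.2 and 0.4 partially bound conformations of the branched (K-turn
#' mutant) scheme into one bound class for the apparent dissociation
#' rate.
#'
#' @param dwells pooled dwell data.frame (rows in within-trace order)
#' @param levels canonical levels to merge
#' @param new_level replacement level
#' @return dwell data.frame with merged runs
#' @export
merge_dwell_levels <- function(dwells, levels, new_level) {
  d <- dwells
  d$state[!is.na(d$state) & d$state %in% levels] <- new_level
  out <- list()
  for (id in unique(d$molecule_id)) {
    di <- d[d$molecule_id == id, ]
    key <- paste0(di$state)
    grp <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
    k <- max(grp)
    m <- data.frame(
      molecule_id = id,
      state = di$state[!duplicated(grp)],
      duration = as.numeric(tapply(di$duration, grp, sum)),
      n_frames = as.integer(tapply(di$n_frames, grp, sum)),
      stringsAsFactors = FALSE)
    m$prev_state <- c(NA, m$state[-k])
    m$next_state <- c(m$state[-1], NA)
    m$left_censored <- seq_len(k) == 1
    m$right_censored <- seq_len(k) == k
    out[[length(out) + 1]] <- m
  }
  do.call(rbind, out)
}
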
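#' Construct a rate-estimate record
#'
#' @param name rate name, e.g. `"k_-1"`, `"k_1"`, `"k2_app"`
#' @param value rate value (s^-1, or M^-1 s^-1 for order-2 rates)
#' @param se standard error (same units)
#' @param method estimation method tag
#' @param order 1 (first-order) or 2 (second-order)
#' @param bound `NA`, `"lower"` or `"upper"` for bound-type estimates
#' @param provenance free-form record of the inputs
#' @return object of class `rate_estimate`
#' @export
rate_estimate <- function(name, value, se = NA_real_, method = "direct",
                          order = 1L, bound = NA_character_,
                          provenance = list()) {
  if (!is.na(value) && value < 0 && is.na(bound))
    warning("negative rate estimate flagged: ", name)
  structure(list(name = name, value = value, se = se, method = method,
                 order = as.integer(order), bound = bound,
                 provenance = provenance),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  unit <- if (x$order == 2L) "M^-1 s^-1" else "s^-1"
  b <- if (!is.na(x$bound)) paste0(" (", x$bound, " bound)") else ""
  cat(sprintf("%s = %.4g +/- %.2g %s [%s]%s\n", x$name, x$value,
              x$se, unit, x$method, b))
  invisible(x)
}

#' Dissociation rate from the partially bound lifetime
#'
#' k_off = 1 / tau, with the uncertainty propagated to first order
#' (delta method): se(k) = se(tau) / tau^2.
#'
#' @param tau `lifetime_estimate` or bare positive number (s)
#' @param se standard error of tau when given as a bare number
#' @param name rate name for the record
#' @return `rate_estimate`
#' @export
k_off_from_lifetime <- function(tau, se = NA_real_, name = "k_-1") {
  if (inherits(tau, "lifetime_estimate")) {
    se <- tau$se
    tau <- tau$tau
  }
  if (is.na(tau) || tau <= 0) stop("lifetime must be positive")
  rate_estimate(name, 1 / tau, se = if (is.na(se)) NA_real_ else se / tau^2,
                method = "reciprocal-lifetime",
                provenance = list(tau = tau, tau_se = se))
}

#' Photobleaching-corrected association rate constant
#'
#' The apparent unbound-state lifetime is shortened by donor
#' photobleaching, which removes molecules from observation at rate
#' 1/tau_trace.  The corrected second-order association rate is
#' k1 = (1/tau_unbound - 1/tau_trace) / concentration.
#'
#' @param tau_unbound mean waiting time before binding, s
#' @param tau_trace mean observed trace length (bleach-limited), s; `Inf`
#'   gives the uncorrected estimate 1/(tau * C)
#' @param concentration ligand concentration, M (> 0)
#' @param se_unbound,se_trace optional standard errors for propagation
#' @return `rate_estimate` (order 2); a negative corrected rate (waiting
#'   slower than bleaching) is flagged via `bound = "lower"` at 0
#' @export
k_on_photobleach_corrected <- function(tau_unbound, tau_trace,
                                       concentration,
                                       se_unbound = NA_real_,
                                       se_trace = NA_real_) {
  stopifnot(tau_unbound > 0, tau_trace > 0)
  if (concentration <= 0) stop("concentration must be > 0")
  v <- (1 / tau_unbound - 1 / tau_trace) / concentration
  se <- sqrt((se_unbound / tau_unbound^2)^2 +
               (ifelse(is.finite(tau_trace), se_trace / tau_trace^2, 0))^2) /
    concentration
  bound <- NA_character_
  if (v < 0) {
    warning("corrected association rate is negative; ",
            "waiting time exceeds photobleaching time")
    bound <- "upper"
  }
  rate_estimate("k_1", v, se = se, method = "photobleach-corrected",
                order = 2L, bound = bound,
                provenance = list(tau_unbound = tau_unbound,
                                  tau_trace = tau_trace,
                                  concentration = concentration))
}

#' Mean observed trace length (tau_trace)
#'
#' Mean of the bleach-truncated trace lengths; with `method = "mle"` and a
#' finite acquisition cap, lengths at the cap are treated as right
#' censored in an exponential MLE.
#'
#' @param trace_lengths truncated trace lengths in s
#' @param method `"mean"` or `"mle"`
#' @param cap acquisition length in s (censoring limit for `"mle"`)
#' @param min_traces flag estimates from fewer traces
#' @return `lifetime_estimate`
#' @export
tau_trace_estimate <- function(trace_lengths, method = c("mean", "mle"),
                               cap = Inf, min_traces = 20) {
  method <- match.arg(method)
  x <- trace_lengths[!is.na(trace_lengths)]
  n <- length(x)
  if (method == "mle" && is.finite(cap)) {
    cens <- x >= cap - 1e-9
    n_events <- sum(!cens)
    if (n_events == 0) stop("all trace lengths censored at the cap")
    tau <- sum(pmin(x, cap)) / n_events
    se <- tau / sqrt(n_events)
  } else {
    tau <- mean(x)
    se <- stats::sd(x) / sqrt(n)
  }
  structure(list(tau = tau, se = se, n_dwells = n, model = "single",
                 method = method, reliable = n >= min_traces),
            class = "lifetime_estimate")
}

#' Calibrate the detected-fraction versus association-rate curve
#'
#' Runs Gillespie simulations of the first binding step over a grid of
#' association rate constants, computes the fraction f of molecules whose
#' trajectory leaves a footprint (at least one binding event) within the
#' imaging window, normalizes f to the reference condition, and fits
#' f = f0 - a exp(b k1) by scanning f0 and linear-fitting
#' ln(f0 - f) against k1.
#'
#' @param k1_grid association rate constants, M^-1 s^-1 (>= 4 values)
#' @param k_off dissociation rate of the bound state, s^-1 (f is expected
#'   to be insensitive to it)
#' @param concentration ligand concentration, M
#' @param window imaging window, s
#' @param n_paths Gillespie trajectories per grid point (>= 100; the
#'   reference experiment used 2000)
#' @param reference_k1 grid abscissa used for normalization f = 1
#'   (default: the largest grid value keeps f below its saturation
#'   plateau; the field convention normalizes to the wild-type construct,
#'   pass its k1 here)
#' @param k1_unit abscissa scale of the fit (default 1e6, i.e. the fit
#'   runs on k1 in units of 1e6 M^-1 s^-1)
#' @param seed master seed
#' @return object of class `calibration_curve`: f0, a, b (on the scaled
#'   abscissa), `k1_unit`, `fit_points` (k1, f raw and normalized),
#'   `window`, `n_paths`, `reference_f`
#' @export
calibrate_f_curve <- function(k1_grid, k_off = 0.28,
                              concentration = 30e-9, window = 70,
                              n_paths = 2000, reference_k1 = 5.0e5,
                              k1_unit = 1e6, seed = 1L) {
  if (length(k1_grid) < 4) stop("need a grid of >= 4 k1 values")
  if (n_paths < 100) stop("need n_paths >= 100")
  set.seed(seed)
  frac <- vapply(k1_grid, function(k1)
    footprint_fraction(k1, k_off, concentration, window, n_paths), 0)
  ref_f <- footprint_fraction(reference_k1, k_off, concentration,
                              window, n_paths)
  if (ref_f <= 0) stop("reference condition produced no detections")
  f_norm <- frac / ref_f
  x <- k1_grid / k1_unit
  fit <- fit_f0_scan(x, f_norm)
  if (any(diff(frac) < -3 * sqrt(0.25 / n_paths)))
    warning("f is non-monotone over the grid beyond sampling error")
  structure(list(f0 = fit$f0, a = fit$a, b = fit$b, k1_unit = k1_unit,
                 fit_points = data.frame(k1 = k1_grid, f_raw = frac,
                                         f = f_norm),
                 window = window, n_paths = n_paths,
                 reference_f = ref_f, k_off = k_off,
                 concentration = concentration),
            class = "calibration_curve")
}

#' Footprint fraction at one parameter set
#'
#' Simulates `n_paths` Gillespie trajectories of the first binding step
#' and returns the fraction that leaves a footprint (any binding event)
#' within the imaging window.  The analytic value 1 - exp(-k1 C w) serves
#' as the independent oracle in the test suite.
#'
#' @inheritParams calibrate_f_curve
#' @param k1 association rate constant, M^-1 s^-1
#' @return detected fraction in `[0, 1]`
#' @export
footprint_fraction <- function(k1, k_off = 0.28, concentration = 30e-9,
                               window = 70, n_paths = 2000) {
  if (k1 <= 0) return(0)
  sc <- scheme_dncca(k1 = k1, k_off = k_off)
  cond <- experiment_condition(ligand_concentration = concentration,
                               frame_time = 0.1,
                               acquisition_frames = ceiling(window / 0.1))
  hits <- 0L
  for (i in seq_len(n_paths)) {
    p <- gillespie_path(sc, cond, t_max = window)
    if (footprint_detected(p, window = window)) hits <- hits + 1L
  }
  hits / n_paths
}

# scan f0 over a grid above max(f) and pick the linearization with the
# best ln(f0 - f) ~ k1 fit
fit_f0_scan <- function(x, f) {
  fmax <- max(f)
  f0_grid <- seq(fmax + 0.01, fmax + 1.5, length.out = 400)
  best <- NULL
  for (f0 in f0_grid) {
    yl <- log(f0 - f)
    fit <- stats::lm(yl ~ x)
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(f0 = f0, rss = rss,
                   a = exp(stats::coef(fit)[[1]]),
                   b = stats::coef(fit)[[2]])
  }
  best
}

#' Invert a calibration curve: association rate from a detected fraction
#'
#' Solves f = f0 - a exp(b k1) for k1:
#' k1 = (ln a - ln(f0 - f)) / (-b), on the curve's abscissa unit,
#' then rescaled to M^-1 s^-1.  The uncertainty is propagated from the
#' standard deviation of f: se(k1) = se(f) / (|b| (f0 - f)).
#'
#' @param f normalized detected fraction (must be < f0)
#' @param curve `calibration_curve` (or a list with f0, a, b, k1_unit —
#'   the printed reference parameterization is
#'   `list(f0 = 1.557, a = exp(0.45), b = -2.09, k1_unit = 1e6)`)
#' @param se_f standard deviation of f for error propagation
#' @return `rate_estimate` (order 2)
#' @export
invert_calibration <- function(f, curve, se_f = NA_real_) {
  if (f >= curve$f0) stop("f at or above saturation (f >= f0)")
  k1_scaled <- (log(curve$a) - log(curve$f0 - f)) / (-curve$b)
  se <- if (is.na(se_f)) NA_real_ else
    se_f / (abs(curve$b) * (curve$f0 - f)) * curve$k1_unit
  rate_estimate("k_1", k1_scaled * curve$k1_unit, se = se,
                method = "calibration-inversion", order = 2L,
                provenance = list(f = f, f0 = curve$f0, a = curve$a,
                                  b = curve$b))
}

#' Lower bound on the docking rate from a sojourn upper limit
#'
#' When transit through the partially bound state is at or below the
#' imaging time resolution, only an upper limit on the sojourn is
#' observable; its reciprocal is reported as a lower bound on k2.
#'
#' @param upper_limit_sojourn s (> 0)
#' @return `rate_estimate` flagged `bound = "lower"`
#' @export
k2_bound_from_sojourn <- function(upper_limit_sojourn) {
  stopifnot(upper_limit_sojourn > 0)
  rate_estimate("k_2", 1 / upper_limit_sojourn, method = "bound",
                bound = "lower",
                provenance = list(sojourn = upper_limit_sojourn))
}

#' Apparent docking/undocking rates of the branched (K-turn mutant) scheme
#'
#' Composes the two pathways between the partially bound class and the
#' fully bound state into apparent rates comparable with the two-step
#' constructs: k2_app = p1 k1' k2' / (k1' + k_rev') + p2 k2_direct, where
#' p1 and p2 weight the through-intermediate and direct forward pathways;
#' k_rev2_app = q1 k_unlock' + q2 k_unlock_direct with q1, q2 the
#' probabilities of leaving the fully bound state toward the bent and the
#' relaxed conformation.
#'
#' @param weights_forward list/vector with p1, p2 (p1 + p2 = 1)
#' @param weights_backward list/vector with p1, p2 for the backward exit
#'   (defaults to `weights_forward`)
#' @param k1_prime,k_rev_prime,k2_prime,k_unlock_prime primed pathway
#'   rates, s^-1
#' @param k2_direct,k_unlock_direct direct pathway rates, s^-1
#' @return list of two `rate_estimate`s: `k2_app`, `k_rev2_app`
#' @export
apparent_rates_dkt <- function(weights_forward,
                               k1_prime, k_rev_prime, k2_prime,
                               k_unlock_prime,
                               k2_direct = 0, k_unlock_direct = 0,
                               weights_backward = weights_forward) {
  p <- unlist(weights_forward)[1:2]
  q <- unlist(weights_backward)[1:2]
  for (w in list(p, q)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stop("pathway weights must be nonnegative and sum to 1")
  }
  stopifnot(k1_prime >= 0, k_rev_prime >= 0, k2_prime >= 0,
            k_unlock_prime >= 0, k2_direct >= 0, k_unlock_direct >= 0)
  if (p[1] > 0 && (k1_prime + k_rev_prime) == 0)
    stop("intermediate pathway weighted but k1' + k_rev' = 0")
  through <- if (p[1] > 0)
    k1_prime * k2_prime / (k1_prime + k_rev_prime) else 0
  k2_app <- p[1] * through + p[2] * k2_direct
  k_rev2_app <- q[1] * k_unlock_prime + q[2] * k_unlock_direct
  list(k2_app = rate_estimate("k2_app", k2_app, method = "composition",
                              provenance = list(p = p)),
       k_rev2_app = rate_estimate("k-2_app", k_rev2_app,
                                  method = "composition",
                                  provenance = list(p = q)))
}

#' Fold-change comparison between two constructs
#'
#' Per-rate ratios reference/variant (for association-type rates, where a
#' slower variant gives a fold > 1) and variant/reference for
#' dissociation-type rates, plus the derived dissociation-constant fold
#' for the first binding step Kd_fold = (k1_ref / k1_var) x
#' (k_off_var / k_off_ref), and the analogous equilibrium fold for the
#' second step when k2/k_rev2 pairs are present.
#'
#' @param reference,variant named lists of `rate_estimate` (names such as
#'   `k_1`, `k_-1`, `k_2`, `k_-2`)
#' @return data.frame of folds; missing counterparts are omitted with a
#'   warning
#' @export
fold_change_report <- function(reference, variant) {
  rn <- vapply(reference, function(r) r$name, "")
  vn <- vapply(variant, function(r) r$name, "")
  common <- intersect(rn, vn)
  missing <- setdiff(union(rn, vn), common)
  if (length(missing))
    warning("no counterpart for: ", paste(missing, collapse = ", "))
  val <- function(set, names, nm) set[[match(nm, names)]]$value
  rows <- lapply(common, function(nm) {
    rv <- val(reference, rn, nm)
    vv <- val(variant, vn, nm)
    forward <- grepl("^k_?-", nm)   # dissociation-type: variant/reference
    data.frame(rate = nm,
               reference = rv, variant = vv,
               fold = if (forward) vv / rv else rv / vv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(c("k_1", "k_-1") %in% common)) {
    kd <- out$fold[out$rate == "k_1"] * out$fold[out$rate == "k_-1"]
    out <- rbind(out, data.frame(rate = "Kd_step1",
                                 reference = NA, variant = NA,
                                 fold = kd))
  }
  if (all(c("k_2", "k_-2") %in% common)) {
    keq <- out$fold[out$rate == "k_2"] * out$fold[out$rate == "k_-2"]
    out <- rbind(out, data.frame(rate = "Keq_step2",
                                 reference = NA, variant = NA,
                                 fold = keq))
  }
  out
}

#' CTMC rate matrix estimates from pooled canonical dwells
#'
#' Maximum-likelihood rates for each observed transition A -> B:
#' k(A->B) = n(A->B) / T(A), events over total (censoring-aware) exposure
#' in the origin state, with optional frame-discretization correction of
#' the total exit rate.
#'
#' @param dwells pooled dwell data.frame from [extract_dwells_all()]
#' @param frame_time frame time, s; enables the discretization correction
#'   when not `NULL`
#' @return data.frame from, to, n_events, exposure_s, rate, se
#' @export
transition_rates <- function(dwells, frame_time = NULL) {
  d <- dwells[!is.na(dwells$state), ]
  states <- sort(unique(d$state))
  rows <- list()
  for (s in states) {
    ds <- d[d$state == s, ]
    exposure <- sum(ds$duration)
    ev <- ds[!ds$right_censored & !is.na(ds$next_state), ]
    n_tot <- nrow(ev)
    if (!n_tot || exposure <= 0) next
    total_rate <- n_tot / exposure
    if (!is.null(frame_time)) {
      # geometric correction of the frame-quantized exponential
      mbar <- mean(ds$n_frames[!ds$right_censored])
      if (is.finite(mbar) && mbar > 1)
        total_rate <- -log(1 - 1 / mbar) / frame_time
    }
    for (to in sort(unique(ev$next_state))) {
      n_ab <- sum(ev$next_state == to)
      p_ab <- n_ab / n_tot
      rate <- p_ab * total_rate
      se <- rate / sqrt(n_ab)
      rows[[length(rows) + 1]] <- data.frame(
        from = s, to = to, n_events = n_ab, exposure_s = exposure,
        rate = rate, se = se)
    }
  }
  do.call(rbind, rows)
}

#' Apparent rates of the branched scheme estimated from idealized dwells
#'
#' Reads the per-transition CTMC rate estimates off pooled canonical
#' dwells (via [transition_rates()]), derives the forward pathway weights
#' from the transition counts out of the relaxed partially bound level
#' and the backward weights from the counts out of the fully bound level,
#' and composes the apparent docking/undocking rates with
#' [apparent_rates_dkt()].  The pooled apparent dissociation rate
#' k-1_app (both partially bound conformations as one class) is
#' estimated from class sojourns ending in the unbound level.
#'
#' @param dwells pooled dwell data.frame over canonical levels
#'   0 / 0.2 / 0.4 / 0.7
#' @param frame_time frame time, s (discretization correction)
#' @param levels canonical levels: unbound, relaxed partial, bent
#'   partial, full
#' @return list with `k2_app`, `k_rev2_app`, `k_off_app`
#'   (`rate_estimate`s), the underlying `rates` table and weights
#' @export
estimate_dkt_apparent <- function(dwells, frame_time = 0.1,
                                  levels = c(0, 0.2, 0.4, 0.7)) {
  u <- levels[1]; p02 <- levels[2]; p04 <- levels[3]; f <- levels[4]
  tr <- transition_rates(dwells, frame_time = frame_time)
  get <- function(from, to) {
    i <- which(tr$from == from & tr$to == to)
    if (length(i)) tr$rate[i] else 0
  }
  cnt <- function(from, to) {
    i <- which(tr$from == from & tr$to == to)
    if (length(i)) tr$n_events[i] else 0L
  }
  n_fwd <- c(cnt(p02, p04), cnt(p02, f))
  n_bwd <- c(cnt(f, p04), cnt(f, p02))
  if (sum(n_fwd) == 0 || sum(n_bwd) == 0)
    stop("no forward or backward transitions observed")
  p <- n_fwd / sum(n_fwd)
  q <- n_bwd / sum(n_bwd)
  app <- apparent_rates_dkt(
    weights_forward = p,
    k1_prime = get(p02, p04), k_rev_prime = get(p04, p02),
    k2_prime = get(p04, f), k_unlock_prime = get(f, p04),
    k2_direct = get(p02, f), k_unlock_direct = get(f, p02),
    weights_backward = q)
  # delta-method SE from the component rate SEs (weights held fixed)
  se_of <- function(from, to) {
    i <- which(tr$from == from & tr$to == to)
    if (length(i)) tr$se[i] else 0
  }
  k1p <- get(p02, p04); krp <- get(p04, p02); k2p <- get(p04, f)
  den <- k1p + krp
  if (den > 0) {
    d_k1p <- p[1] * k2p * krp / den^2
    d_krp <- -p[1] * k1p * k2p / den^2
    d_k2p <- p[1] * k1p / den
    app$k2_app$se <- sqrt((d_k1p * se_of(p02, p04))^2 +
                            (d_krp * se_of(p04, p02))^2 +
                            (d_k2p * se_of(p04, f))^2 +
                            (p[2] * se_of(p02, f))^2)
  }
  app$k_rev2_app$se <- sqrt((q[1] * se_of(f, p04))^2 +
                              (q[2] * se_of(f, p02))^2)
  # pooled partial-class dissociation
  pooled <- merge_dwell_levels(dwells, c(p02, p04), p02)
  dp <- pooled[!is.na(pooled$state) & pooled$state == p02, ]
  dp$left_censored <- FALSE
  # class sojourns ending in the full state are censored for dissociation
  dp$right_censored <- dp$right_censored |
    (!is.na(dp$next_state) & dp$next_state == f)
  n_diss <- sum(!dp$right_censored &
                  !is.na(dp$next_state) & dp$next_state == u)
  k_off_app <- if (n_diss >= 3) {
    tau <- sum(dp$duration) / n_diss
    rate_estimate("k_-1_app", 1 / tau, se = (1 / tau) / sqrt(n_diss),
                  method = "reciprocal-lifetime",
                  provenance = list(pooled_levels = c(p02, p04)))
  } else NULL
  list(k2_app = app$k2_app, k_rev2_app = app$k_rev2_app,
       k_off_app = k_off_app, rates = tr,
       weights_forward = p, weights_backward = q)
}
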
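#' Define a kinetic scheme for tRNA/T-box binding
#'
#' A kinetic scheme is a labelled continuous-time Markov chain over binding
#' states of a single T-box riboswitch molecule interacting with a tRNA
#' ligand.  Each state carries a mean FRET efficiency; directed transitions
#' carry rate constants.  Association steps (binding of free ligand) are
#' stored as second-order constants in M^-1 s^-1 (`order = 2`) and are
#' converted to pseudo-first-order rates at generator-build time by
#' multiplying with the ligand concentration, so one scheme serves both
#' steady-state and flow experiments.
#'
#' @param states character vector of state labels; the first is taken as the
#'   unbound state unless `unbound` says otherwise.
#' @param fret_levels numeric vector of mean FRET efficiencies per state,
#'   each in `[0, 1]`; the unbound state must be 0.
#' @param rates named list of transitions `"A->B" = list(value =, order =)`;
#'   `order = 1` (s^-1) may be given as a bare number. Unlisted transitions
#'   have rate 0.
#' @param photobleach_rate donor photobleach rate in s^-1 (an independent
#'   absorbing process, not a scheme state).
#' @param unbound label of the unbound state.
#' @return object of class `kinetic_scheme`.
#' @examples
#' sc <- scheme_wt()
#' sc$states
#' @export
kinetic_scheme <- function(states, fret_levels, rates,
                           photobleach_rate = 1 / 70,
                           unbound = states[1]) {
  stopifnot(is.character(states), length(states) >= 1,
            !anyDuplicated(states))
  if (length(fret_levels) != length(states))
    stop("fret_levels must have one entry per state")
  if (any(fret_levels < 0 | fret_levels > 1))
    stop("fret_levels must lie within [0, 1]")
  if (!unbound %in% states) stop("unknown unbound state: ", unbound)
  if (fret_levels[match(unbound, states)] != 0)
    stop("the unbound state must have FRET level 0")
  if (photobleach_rate < 0) stop("photobleach_rate must be >= 0")

  rates <- lapply(rates, function(r) {
    if (is.numeric(r)) r <- list(value = r, order = 1L)
    if (is.null(r$order)) r$order <- 1L
    if (r$value < 0) stop("rate constants must be >= 0")
    if (!r$order %in% c(1L, 2L)) stop("rate order must be 1 or 2")
    r
  })
  for (nm in names(rates)) {
    ft <- parse_transition(nm)
    if (!all(ft %in% states))
      stop("transition ", nm, " references unknown state")
    if (ft[1] == ft[2]) stop("self-transition not allowed: ", nm)
  }
  structure(list(states = states,
                 fret_levels = stats::setNames(fret_levels, states),
                 rates = rates,
                 photobleach_rate = photobleach_rate,
                 unbound = unbound),
            class = "kinetic_scheme")
}

parse_transition <- function(x) {
  ft <- strsplit(x, "->", fixed = TRUE)[[1]]
  if (length(ft) != 2) stop("malformed transition label: ", x)
  trimws(ft)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("kinetic_scheme:", length(x$states), "states (",
      paste(x$states, collapse = ", "), ")\n")
  cat("  FRET levels:", paste(sprintf("%s=%.2g", x$states,
                                      x$fret_levels), collapse = ", "), "\n")
  for (nm in names(x$rates)) {
    r <- x$rates[[nm]]
    unit <- if (r$order == 2L) "M^-1 s^-1" else "s^-1"
    cat(sprintf("  %-10s %.4g %s\n", nm, r$value, unit))
  }
  cat("  photobleach_rate:", x$photobleach_rate, "s^-1\n")
  invisible(x)
}

#' Experimental condition metadata
#'
#' @param ligand_concentration tRNA concentration in M (the default 30e-9
#'   matches the steady-state imaging condition of 30 nM labelled tRNA).
#' @param frame_time camera exposure per frame in s (100 ms by default).
#' @param acquisition_frames number of frames recorded (1500 by default).
#' @param injection_time for flow experiments, the time in s at which ligand
#'   is injected (no binding can occur before it); `NULL` for steady state.
#' @return object of class `experiment_condition`.
#' @export
experiment_condition <- function(ligand_concentration = 30e-9,
                                 frame_time = 0.1,
                                 acquisition_frames = 1500L,
                                 injection_time = NULL) {
  stopifnot(ligand_concentration >= 0, frame_time > 0,
            acquisition_frames >= 1)
  if (!is.null(injection_time)) stopifnot(injection_time >= 0)
  structure(list(ligand_concentration = ligand_concentration,
                 frame_time = frame_time,
                 acquisition_frames = as.integer(acquisition_frames),
                 injection_time = injection_time),
            class = "experiment_condition")
}

#' Canonical two-step wild-type binding scheme
#'
#' Unbound (U, FRET 0) -> partially bound (P, FRET 0.4, anticodon
#' recognised) -> fully bound (F, FRET 0.7, NCCA/t-box docked).  Defaults:
#' k1 = 5.0e5 M^-1 s^-1, k-1 = 0.28 s^-1, k2 = 10 s^-1.  The reverse
#' docking rate k-2 is only bounded by experiment (the second step is
#' close to irreversible); the default 0.004 s^-1 was calibrated once so
#' that the full pipeline (render -> idealize -> classify) sees ~9% of
#' bound traces with a visible 0.7 -> 0.4 excursion at 100 ms frames,
#' the measured Type II fraction; sub-frame excursions
#' (mean 1/(k2 + k_off) ~ 0.1 s) are mostly invisible, so the visible
#' fraction understates the true excursion count (methods vignette).
#'
#' @param k1,k_off,k2,k_rev rate constants (k1 second order).
#' @param photobleach_rate donor bleach rate, s^-1.
#' @return `kinetic_scheme`
#' @export
scheme_wt <- function(k1 = 5.0e5, k_off = 0.28, k2 = 10, k_rev = 0.004,
                      photobleach_rate = 1 / 70) {
  kinetic_scheme(
    states = c("U", "P", "F"),
    fret_levels = c(0, 0.4, 0.7),
    rates = list("U->P" = list(value = k1, order = 2L),
                 "P->U" = k_off,
                 "P->F" = k2,
                 "F->P" = k_rev),
    photobleach_rate = photobleach_rate)
}

#' Two-state scheme for the NCCA-deleted tRNA
#'
#' tRNA lacking the 3' NCCA end can only establish the first (anticodon)
#' binding step, so the fully bound state is unreachable: U <-> P only.
#'
#' @inheritParams scheme_wt
#' @return `kinetic_scheme`
#' @export
scheme_dncca <- function(k1 = 5.0e5, k_off = 0.28,
                         photobleach_rate = 1 / 70) {
  kinetic_scheme(
    states = c("U", "P"),
    fret_levels = c(0, 0.4),
    rates = list("U->P" = list(value = k1, order = 2L),
                 "P->U" = k_off),
    photobleach_rate = photobleach_rate)
}

#' Branched three-bound-state scheme for the K-turn deletion mutant
#'
#' With the K-turn hinge replaced by a rigid helix the partially bound
#' complex splits into a relaxed (FRET 0.2, state P02) and a bent
#' (FRET 0.4, state P04) conformation; the fully bound state (F, 0.7) is
#' reached either through the bent intermediate (P02 -> P04 -> F) or
#' directly (P02 -> F).  Primed rates follow the intermediate pathway.
#'
#' Defaults are chosen so that the scheme reproduces the measured apparent
#' rates: the 0.4-state lifetimes toward 0.2 and 0.7 (0.30 s, 0.13 s) give
#' k_rev_prime = 3.33 s^-1 and k2_prime = 7.69 s^-1; the fully bound
#' lifetime of 1.6 s with a 4:1 preference for exiting toward 0.4 gives
#' k_unlock_prime = 0.5 and k_unlock = 0.125 s^-1; k1_prime = 0.85 s^-1 and
#' a direct docking rate of 0.2 s^-1 then yield an apparent forward docking
#' rate of ~1.3 s^-1 and a pooled apparent dissociation rate of ~0.21 s^-1
#' with dissociation from the relaxed state at 0.3 s^-1.
#'
#' @param k1 association rate, M^-1 s^-1 (default 5.4e4).
#' @param k_off dissociation from the relaxed partially bound state, s^-1.
#' @param k1_prime,k_rev_prime interconversion 0.2 -> 0.4 and 0.4 -> 0.2, s^-1.
#' @param k2_prime,k_unlock_prime docking/undocking via the bent state, s^-1.
#' @param k2_direct,k_unlock_direct direct 0.2 <-> 0.7 transitions, s^-1.
#' @param photobleach_rate donor bleach rate, s^-1.
#' @return `kinetic_scheme`
#' @export
scheme_dkt <- function(k1 = 5.4e4, k_off = 0.3,
                       k1_prime = 0.85, k_rev_prime = 1 / 0.30,
                       k2_prime = 1 / 0.13, k_unlock_prime = 0.5,
                       k2_direct = 0.2, k_unlock_direct = 0.125,
                       photobleach_rate = 1 / 70) {
  kinetic_scheme(
    states = c("U", "P02", "P04", "F"),
    fret_levels = c(0, 0.2, 0.4, 0.7),
    rates = list("U->P02" = list(value = k1, order = 2L),
                 "P02->U" = k_off,
                 "P02->P04" = k1_prime,
                 "P04->P02" = k_rev_prime,
                 "P04->F" = k2_prime,
                 "F->P04" = k_unlock_prime,
                 "P02->F" = k2_direct,
                 "F->P02" = k_unlock_direct),
    photobleach_rate = photobleach_rate)
}

#' Build the CTMC generator matrix of a scheme under a condition
#'
#' Off-diagonal entry (i, j) is the first-order rate i -> j in s^-1;
#' second-order association constants are multiplied by the ligand
#' concentration.  Diagonal entries are minus the row sums, so every row
#' sums to zero.
#'
#' @param scheme a `kinetic_scheme`
#' @param condition an `experiment_condition`
#' @return square numeric matrix with dimnames = state labels
#' @export
build_generator <- function(scheme, condition = experiment_condition()) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(condition, "experiment_condition"))
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  for (nm in names(scheme$rates)) {
    r <- scheme$rates[[nm]]
    ft <- parse_transition(nm)
    v <- r$value
    if (r$order == 2L) v <- v * condition$ligand_concentration
    Q[ft[1], ft[2]] <- Q[ft[1], ft[2]] + v
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' State occupancy at time t (matrix-exponential oracle)
#'
#' Exact transient solution p(t) = p0 exp(Q t) of the CTMC, used as the
#' analytic oracle for the Gillespie simulator.
#'
#' @param generator generator matrix from [build_generator()]
#' @param initial initial distribution over states (sums to 1)
#' @param t time in s, >= 0
#' @return named numeric occupancy vector summing to 1
#' @export
occupancy_at_time <- function(generator, initial, t) {
  stopifnot(is.matrix(generator), nrow(generator) == ncol(generator),
            t >= 0)
  if (length(initial) != nrow(generator))
    stop("initial distribution has wrong length")
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-8)
    stop("initial must be a probability distribution")
  P <- as.matrix(Matrix::expm(Matrix::Matrix(generator * t)))
  p <- as.numeric(initial %*% P)
  p[p < 0] <- 0            # clip tiny negative round-off
  p <- p / sum(p)
  stats::setNames(p, rownames(generator))
}

#' Mean exit (sojourn) time of a state
#'
#' Reciprocal of the state's total exit rate; `Inf` for an absorbing state.
#'
#' @param generator generator matrix
#' @param state state label or index
#' @return mean sojourn time in s
#' @export
mean_exit_time <- function(generator, state) {
  exit <- -generator[state, state]
  if (exit <= 0) return(Inf)
  1 / exit
}

#' Long-run equilibrium distribution of an irreducible scheme
#'
#' Left null vector of the generator, normalized; used in property tests
#' against `occupancy_at_time` at long times.
#'
#' @param generator generator matrix
#' @return named stationary distribution
#' @export
equilibrium_distribution <- function(generator) {
  ev <- eigen(t(generator))
  i <- which.min(abs(ev$values))
  p <- abs(Re(ev$vectors[, i]))
  stats::setNames(p / sum(p), rownames(generator))
}

#' Read or write a scheme + condition as a JSON config
#'
#' Serialization format:
#' `{"states": [...], "fret_levels": [...], "rates": {"U->P": {"value":
#' 5e5, "order": 2}, ...}, "photobleach_rate": 0.0143,
#' "ligand_concentration_M": 3e-8, "frame_time_s": 0.1, ...}`.
#'
#' @param path file path
#' @return `read_scheme_json`: list with elements `scheme` and `condition`.
#' @export
read_scheme_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  rates <- lapply(cfg$rates, function(r)
    list(value = r$value, order = as.integer(r$order %||% 1L)))
  scheme <- kinetic_scheme(
    states = vapply(cfg$states, as.character, ""),
    fret_levels = vapply(cfg$fret_levels, as.numeric, 0),
    rates = rates,
    photobleach_rate = cfg$photobleach_rate %||% (1 / 70))
  condition <- experiment_condition(
    ligand_concentration = cfg$ligand_concentration_M %||% 30e-9,
    frame_time = cfg$frame_time_s %||% 0.1,
    acquisition_frames = cfg$acquisition_frames %||% 1500L,
    injection_time = cfg$injection_time_s)
  list(scheme = scheme, condition = condition)
}

#' @rdname read_scheme_json
#' @param scheme a `kinetic_scheme`
#' @param condition an `experiment_condition`
#' @export
write_scheme_json <- function(scheme, condition, path) {
  cfg <- list(states = scheme$states,
              fret_levels = unname(scheme$fret_levels),
              rates = scheme$rates,
              photobleach_rate = scheme$photobleach_rate,
              ligand_concentration_M = condition$ligand_concentration,
              frame_time_s = condition$frame_time,
              acquisition_frames = condition$acquisition_frames,
              injection_time_s = condition$injection_time)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
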
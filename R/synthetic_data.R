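#' Emission model for rendering intensity traces
#'
#' Forward model of the camera signal: total (donor + acceptor) intensity is
#' split by the instantaneous FRET efficiency, a fraction of the donor
#' signal bleeds into the acceptor channel, both channels sit on a baseline
#' and carry Gaussian read noise, and each fluorophore bleaches as an
#' independent exponential process.  Magnitudes are not constrained by the
#' experiment, so defaults (total 1000 a.u., noise 50 a.u., 10%
#' bleed-through) are package conventions exposed in configs.
#'
#' @param total_intensity combined two-channel signal, a.u.
#' @param noise_sd per-channel Gaussian noise sd, a.u.
#' @param bleedthrough_fraction donor-to-acceptor bleed-through in `[0, 1)`.
#' @param baseline_donor,baseline_acceptor channel offsets, a.u.
#' @param donor_bleach_rate,acceptor_bleach_rate exponential bleach rates,
#'   s^-1.  The donor default 1/70 reproduces the observed ~70 s mean trace
#'   length under high excitation power.
#' @return object of class `emission_model`
#' @export
emission_model <- function(total_intensity = 1000, noise_sd = 50,
                           bleedthrough_fraction = 0.1,
                           baseline_donor = 0, baseline_acceptor = 0,
                           donor_bleach_rate = 1 / 70,
                           acceptor_bleach_rate = 0) {
  stopifnot(total_intensity >= 0, noise_sd >= 0,
            bleedthrough_fraction >= 0, bleedthrough_fraction < 1,
            donor_bleach_rate >= 0, acceptor_bleach_rate >= 0)
  structure(list(total_intensity = total_intensity, noise_sd = noise_sd,
                 bleedthrough_fraction = bleedthrough_fraction,
                 baseline_donor = baseline_donor,
                 baseline_acceptor = baseline_acceptor,
                 donor_bleach_rate = donor_bleach_rate,
                 acceptor_bleach_rate = acceptor_bleach_rate),
            class = "emission_model")
}

#' Exact stochastic simulation of one binding trajectory
#'
#' Gillespie simulation of the CTMC defined by `scheme` under `condition`:
#' exponential waiting times at the current state's total exit rate, next
#' state drawn proportionally to the outgoing rates.  In flow mode
#' (`condition$injection_time` set) the molecule is held in the unbound
#' state until injection, after which the simulation starts.
#'
#' @param scheme `kinetic_scheme`
#' @param condition `experiment_condition`
#' @param t_max simulation horizon in s
#' @param start starting state label (default: the unbound state)
#' @param seed optional seed; `NULL` uses the current RNG stream
#' @return object of class `state_path`: list with `event_times` (segment
#'   start times, first is 0), `states` (label per segment), `end_time`.
#' @export
gillespie_path <- function(scheme, condition = experiment_condition(),
                           t_max, start = scheme$unbound, seed = NULL) {
  stopifnot(t_max > 0)
  if (!is.null(seed)) set.seed(seed)
  Q <- build_generator(scheme, condition)
  labs <- scheme$states
  t0 <- 0
  times <- 0
  states <- start
  if (!is.null(condition$injection_time) && start == scheme$unbound) {
    t0 <- min(condition$injection_time, t_max)
  }
  t <- t0
  cur <- start
  while (t < t_max) {
    exit <- -Q[cur, cur]
    if (exit <= 0) break
    t <- t + stats::rexp(1, exit)
    if (t >= t_max) break
    p <- Q[cur, ]
    p[cur] <- 0
    cur <- sample(labs, 1, prob = p)
    times <- c(times, t)
    states <- c(states, cur)
  }
  structure(list(event_times = times, states = states, end_time = t_max),
            class = "state_path")
}

#' Draw photobleaching times for one molecule
#'
#' Donor and acceptor bleach independently with exponential lifetimes.
#' Donor bleaching terminates all signal; acceptor bleaching zeroes FRET
#' thereafter.  A rate of 0 gives an infinite bleach time.
#'
#' @param model `emission_model`
#' @return list with `donor` and `acceptor` bleach times (s, possibly `Inf`)
#' @export
apply_photobleaching <- function(model) {
  draw <- function(rate) if (rate <= 0) Inf else stats::rexp(1, rate)
  list(donor = draw(model$donor_bleach_rate),
       acceptor = draw(model$acceptor_bleach_rate))
}

#' Time-weighted state FRET level per frame
#'
#' Integrates the piecewise-constant FRET level of a state path over each
#' camera frame.  Frame integration (rather than point sampling) is what
#' makes sub-frame sojourns appear as intermediate FRET values, the
#' behaviour that limits detection of fast transitions at 100 ms frames.
#'
#' @param path `state_path`
#' @param fret_levels named FRET level per state
#' @param frame_time s
#' @param n_frames number of frames
#' @return numeric vector of frame-averaged FRET, length `n_frames`
#' @export
frame_average_fret <- function(path, fret_levels, frame_time, n_frames) {
  stopifnot(frame_time > 0)
  e <- numeric(n_frames)
  seg_start <- path$event_times
  seg_end <- c(path$event_times[-1], path$end_time)
  lev <- fret_levels[path$states]
  for (s in seq_along(seg_start)) {
    if (seg_end[s] <= seg_start[s]) next
    f0 <- floor(seg_start[s] / frame_time)
    f1 <- min(ceiling(seg_end[s] / frame_time), n_frames)
    if (f0 >= n_frames) break
    fr <- seq.int(f0, f1 - 1)
    lo <- pmax(fr * frame_time, seg_start[s])
    hi <- pmin((fr + 1) * frame_time, seg_end[s])
    e[fr + 1] <- e[fr + 1] + (hi - lo) * lev[s]
  }
  e / frame_time
}

#' Render a state path as a noisy dual-channel intensity trace
#'
#' Per frame: acceptor = total * E + bleedthrough * donor_signal + baseline
#' + noise; donor = total * (1 - E) + baseline + noise, with E the
#' frame-integrated FRET level.  After acceptor bleach E drops to 0 (donor
#' regains the full signal); after donor bleach both channels fall to
#' baseline + noise.  Bleach boundaries are weighted within the frame.
#'
#' @param path `state_path`
#' @param scheme `kinetic_scheme` supplying FRET levels
#' @param model `emission_model`
#' @param condition `experiment_condition` (frame time, frame count)
#' @param bleach list with `donor`/`acceptor` bleach times, as returned by
#'   [apply_photobleaching()]; default: no bleaching
#' @param molecule_id identifier stored with the trace
#' @return object of class `intensity_trace`: list with `donor`, `acceptor`,
#'   `frame_time`, `molecule_id` and a `truth` record (path, bleach times,
#'   frame-averaged FRET, dominant state per frame).
#' @export
render_trace <- function(path, scheme, model,
                         condition = experiment_condition(),
                         bleach = list(donor = Inf, acceptor = Inf),
                         molecule_id = "mol1") {
  ft <- condition$frame_time
  if (ft <= 0) stop("frame_time must be > 0")
  nf <- condition$acquisition_frames
  if (path$end_time < nf * ft - 1e-9)
    stop("state path shorter than the acquisition window")
  e <- frame_average_fret(path, scheme$fret_levels, ft, nf)

  frame_end <- seq_len(nf) * ft
  frame_start <- frame_end - ft
  # live fraction of each frame before a cutoff time
  live_frac <- function(tcut) {
    pmin(pmax((tcut - frame_start) / ft, 0), 1)
  }
  a_live <- live_frac(bleach$acceptor)   # acceptor alive
  d_live <- live_frac(bleach$donor)      # donor alive

  e_eff <- e * a_live                    # FRET -> 0 after acceptor bleach
  total <- model$total_intensity * d_live
  donor_sig <- total * (1 - e_eff)
  acceptor_sig <- total * e_eff + model$bleedthrough_fraction * donor_sig
  noise <- function() if (model$noise_sd > 0)
    stats::rnorm(nf, 0, model$noise_sd) else numeric(nf)
  donor <- donor_sig + model$baseline_donor + noise()
  acceptor <- acceptor_sig + model$baseline_acceptor + noise()

  dominant <- dominant_state_per_frame(path, ft, nf)
  structure(list(donor = donor, acceptor = acceptor, frame_time = ft,
                 molecule_id = molecule_id,
                 truth = list(path = path, bleach = bleach,
                              frame_fret = e, frame_state = dominant)),
            class = "intensity_trace")
}

#' Dominant (largest time share) state label per frame
#' @inheritParams frame_average_fret
#' @return character vector of length `n_frames`
#' @export
dominant_state_per_frame <- function(path, frame_time, n_frames) {
  labs <- unique(path$states)
  occ <- matrix(0, n_frames, length(labs),
                dimnames = list(NULL, labs))
  seg_start <- path$event_times
  seg_end <- c(path$event_times[-1], path$end_time)
  for (s in seq_along(seg_start)) {
    if (seg_end[s] <= seg_start[s]) next
    f0 <- floor(seg_start[s] / frame_time)
    f1 <- min(ceiling(seg_end[s] / frame_time), n_frames)
    if (f0 >= n_frames) break
    fr <- seq.int(f0, f1 - 1)
    lo <- pmax(fr * frame_time, seg_start[s])
    hi <- pmin((fr + 1) * frame_time, seg_end[s])
    occ[fr + 1, path$states[s]] <- occ[fr + 1, path$states[s]] + (hi - lo)
  }
  labs[max.col(occ, ties.method = "first")]
}

#' Footprint detection contract
#'
#' A molecule produces a spot in the maximum-intensity projection of the
#' acceptor channel iff at least one binding event (any non-unbound
#' sojourn) overlaps the imaging window, truncated at donor bleach.
#'
#' @param path `state_path`
#' @param window imaging window in s (70 s emulates the donor bleach-limited
#'   window of the high-power experiments)
#' @param unbound unbound state label
#' @param donor_bleach_time optional donor bleach time further truncating
#'   the window
#' @return logical
#' @export
footprint_detected <- function(path, window = 70, unbound = "U",
                               donor_bleach_time = Inf) {
  stopifnot(window > 0)
  cut <- min(window, donor_bleach_time, path$end_time)
  seg_start <- path$event_times
  seg_end <- c(path$event_times[-1], path$end_time)
  bound <- path$states != unbound
  any(bound & seg_start < cut & seg_end > seg_start)
}

#' Generate a ground-truthed synthetic smFRET dataset
#'
#' Independent molecules: each gets a Gillespie path, exponential bleach
#' times and a rendered noisy trace.  All randomness flows from one master
#' seed with per-molecule substreams, so a fixed seed reproduces the
#' dataset exactly.
#'
#' @param scheme `kinetic_scheme`
#' @param condition `experiment_condition`
#' @param model `emission_model`
#' @param n_molecules number of molecules
#' @param seed master seed (integer)
#' @return object of class `fret_dataset`: list with `traces` (list of
#'   `intensity_trace`), `scheme`, `condition`, `model`, `seed`.
#' @export
generate_dataset <- function(scheme, condition = experiment_condition(),
                             model = emission_model(), n_molecules,
                             seed = 1L) {
  stopifnot(n_molecules >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_molecules)
  t_total <- condition$acquisition_frames * condition$frame_time
  traces <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    set.seed(sub_seeds[i])
    path <- gillespie_path(scheme, condition, t_max = t_total)
    bleach <- apply_photobleaching(model)
    traces[[i]] <- render_trace(path, scheme, model, condition,
                                bleach = bleach,
                                molecule_id = sprintf("mol%03d", i))
  }
  structure(list(traces = traces, scheme = scheme, condition = condition,
                 model = model, seed = seed),
            class = "fret_dataset")
}

#' Ground-truth dwell sojourns of a dataset
#'
#' Flattens the true state paths into one data frame of sojourns, truncated
#' at donor bleach, for comparison with pipeline-extracted dwells.
#'
#' @param dataset `fret_dataset`
#' @return data.frame with molecule_id, state, duration, start, censored
#' @export
true_dwells <- function(dataset) {
  out <- lapply(dataset$traces, function(tr) {
    p <- tr$truth$path
    cut <- min(p$end_time, tr$truth$bleach$donor)
    seg_start <- p$event_times
    seg_end <- c(p$event_times[-1], p$end_time)
    keep <- seg_start < cut
    seg_end <- pmin(seg_end, cut)
    data.frame(molecule_id = tr$molecule_id,
               state = p$states[keep],
               start = seg_start[keep],
               duration = (seg_end - seg_start)[keep],
               censored = (seg_end[keep] >= cut - 1e-12) |
                 (seg_start[keep] == 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
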
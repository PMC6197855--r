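# shared fixture builders; everything is generated in code, no data files

# a state path from explicit segment times/states
make_path <- function(event_times, states, end_time) {
  structure(list(event_times = event_times, states = states,
                 end_time = end_time), class = "state_path")
}

# an idealized path carrying only canonical labels (for dwell/classify
# tests that do not need an HMM fit)
make_ideal <- function(levels, molecule_id = "m1", frame_time = 0.1) {
  structure(list(canonical_per_frame = levels,
                 frames = seq_along(levels),
                 molecule_id = molecule_id, frame_time = frame_time,
                 truth = NULL),
            class = "idealized_path")
}

# a fret_trace from a bare efficiency vector
make_fret <- function(e, frame_time = 0.1, molecule_id = "m1") {
  structure(list(efficiency = e, frame_time = frame_time,
                 valid_range = c(1, length(e)), molecule_id = molecule_id,
                 truth = NULL),
            class = "fret_trace")
}

# noiseless emission model
quiet_model <- function(...) {
  emission_model(noise_sd = 0, bleedthrough_fraction = 0,
                 donor_bleach_rate = 0, ...)
}

# idealized paths + fret traces from ground-truth frame labels of a
# dataset (perfect idealization at the stated frame time)
truth_paths <- function(dataset) {
  lev <- dataset$scheme$fret_levels
  ft <- dataset$condition$frame_time
  lapply(dataset$traces, function(tr) {
    nbl <- min(length(tr$donor), floor(tr$truth$bleach$donor / ft))
    if (nbl < 1) nbl <- 1
    make_ideal(unname(lev[tr$truth$frame_state[seq_len(nbl)]]),
               molecule_id = tr$molecule_id, frame_time = ft)
  })
}
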
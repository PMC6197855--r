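#' Correct an intensity trace for baseline and donor bleed-through
#'
#' acceptor' = acceptor - baseline_acceptor - bleedthrough * (donor -
#' baseline_donor); donor' = donor - baseline_donor.
#'
#' @param trace `intensity_trace`
#' @param bleedthrough_fraction donor-to-acceptor bleed-through in `[0, 1)`
#' @param baseline_donor,baseline_acceptor channel offsets, a.u.
#' @return corrected `intensity_trace`
#' @export
correct_channels <- function(trace, bleedthrough_fraction = 0,
                             baseline_donor = 0, baseline_acceptor = 0) {
  stopifnot(bleedthrough_fraction >= 0, bleedthrough_fraction < 1)
  d <- trace$donor - baseline_donor
  a <- trace$acceptor - baseline_acceptor - bleedthrough_fraction * d
  trace$donor <- d
  trace$acceptor <- a
  trace
}

#' Compute the FRET efficiency time series of a corrected trace
#'
#' Per-frame E = acceptor / (donor + acceptor).  Frames whose total
#' intensity falls below `floor` (default: 10% of the median total over the
#' valid region) are marked invalid (`NA`) rather than divided.
#'
#' @param trace corrected `intensity_trace`
#' @param floor absolute intensity floor, or `NULL` for the relative default
#' @return object of class `fret_trace`: list with `efficiency` (NA on
#'   invalid frames), `frame_time`, `valid_range` (first/last analyzable
#'   frame), `molecule_id`, and the carried-over `truth` record if present.
#' @export
compute_fret <- function(trace, floor = NULL) {
  total <- trace$donor + trace$acceptor
  if (is.null(floor)) floor <- 0.1 * stats::median(total, na.rm = TRUE)
  ok <- !is.na(total) & total > floor
  e <- rep(NA_real_, length(total))
  e[ok] <- trace$acceptor[ok] / total[ok]
  vr <- if (any(ok)) c(which(ok)[1], max(which(ok))) else c(NA, NA)
  structure(list(efficiency = e, frame_time = trace$frame_time,
                 valid_range = vr, molecule_id = trace$molecule_id,
                 truth = trace$truth),
            class = "fret_trace")
}

#' Truncate a FRET trace at donor photobleaching
#'
#' Detects the photobleach step as the change point with the largest drop
#' in the mean of the total intensity; if the post-change mean falls below
#' the floor (10% of the pre-change median), the valid range ends at the
#' change point.  The truncated length in seconds is recorded for trace-
#' lifetime estimation.
#'
#' @param fret `fret_trace`
#' @param raw the aligned raw (or corrected) `intensity_trace`
#' @return `fret_trace` with updated `valid_range` and a `trace_length_s`
#'   field
#' @export
truncate_at_photobleach <- function(fret, raw) {
  total <- raw$donor + raw$acceptor
  n <- length(total)
  cp <- change_point_drop(total)
  end <- n
  if (!is.na(cp)) {
    pre_med <- stats::median(total[seq_len(cp)])
    post_mean <- mean(total[(cp + 1):n])
    if (post_mean < 0.3 * pre_med) end <- cp
  }
  fret$valid_range[2] <- min(fret$valid_range[2], end, na.rm = TRUE)
  fret$efficiency[seq_len(n) > end] <- NA_real_
  fret$trace_length_s <- end * fret$frame_time
  fret
}

# single change point maximizing the drop in mean (pre minus post);
# returns NA when no drop exists
change_point_drop <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_integer_)
  cs <- cumsum(x)
  k <- seq_len(n - 1)
  pre <- cs[k] / k
  post <- (cs[n] - cs[k]) / (n - k)
  drop <- pre - post
  # guard against edge artifacts on the first/last couple of frames
  k_ok <- k[k >= 2 & k <= n - 2]
  if (!length(k_ok)) return(NA_integer_)
  best <- k_ok[which.max(drop[k_ok])]
  if (drop[best] <= 0) NA_integer_ else best
}

#' Select traces by acceptor-channel detection (spot-picking emulation)
#'
#' A molecule is selected iff its (corrected) acceptor channel exceeds a
#' detection threshold in at least one frame of the imaging window — the
#' trace-level contract of picking spots from a maximum-intensity
#' projection of the acceptor channel.  Also returns the total
#' donor-visible molecule count, the denominator of the normalized trace
#' fraction f.
#'
#' @param traces list of `intensity_trace`
#' @param threshold acceptor intensity threshold, a.u.  The default
#'   combines a signal-level criterion (half the 95th percentile of the
#'   pooled acceptor signal) with a noise-floor criterion (4.5 noise sd,
#'   noise estimated robustly from frame-to-frame differences), so it
#'   works both when most molecules bind and when few do.
#' @param window imaging window in s
#' @return list with `selected` (logical per trace), `n_selected`,
#'   `n_total`, `threshold`
#' @export
select_traces <- function(traces, threshold = NULL, window = 70) {
  stopifnot(length(traces) >= 1)
  nf_window <- function(tr) min(length(tr$acceptor),
                                max(1, floor(window / tr$frame_time)))
  maxima <- vapply(traces, function(tr)
    max(tr$acceptor[seq_len(nf_window(tr))]), 0)
  if (is.null(threshold)) {
    pooled <- unlist(lapply(traces, function(tr)
      tr$acceptor[seq_len(nf_window(tr))]))
    noise_sd <- stats::median(abs(diff(pooled))) / (sqrt(2) * 0.6745)
    threshold <- max(0.5 * stats::quantile(pooled, 0.95, names = FALSE),
                     4.5 * noise_sd)
  }
  sel <- maxima > threshold
  list(selected = sel, n_selected = sum(sel), n_total = length(traces),
       threshold = threshold)
}

#' Write/read traces in the two-columns-per-molecule delimited layout
#'
#' Each pair of columns holds the Cy3 (donor) then Cy5 (acceptor)
#' intensities of one molecule; the header carries molecule ids.  Shorter
#' traces are padded with NA.
#'
#' @param traces list of `intensity_trace`
#' @param path output file
#' @param frame_time frame time in s recorded on reading
#' @return `read_traces` returns a list of `intensity_trace`.
#' @export
write_traces <- function(traces, path) {
  nf <- max(vapply(traces, function(tr) length(tr$donor), 0L))
  cols <- list()
  for (tr in traces) {
    pad <- function(x) c(x, rep(NA_real_, nf - length(x)))
    cols[[paste0(tr$molecule_id, "_Cy3")]] <- pad(tr$donor)
    cols[[paste0(tr$molecule_id, "_Cy5")]] <- pad(tr$acceptor)
  }
  utils::write.table(as.data.frame(cols), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, frame_time = 0.1) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (ncol(df) %% 2 != 0)
    stop("malformed trace file (odd column count): ", path)
  n <- ncol(df) / 2
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    dcol <- 2 * i - 1
    id <- sub("_Cy3$", "", names(df)[dcol])
    d <- df[[dcol]]
    a <- df[[dcol + 1]]
    keep <- !(is.na(d) & is.na(a))
    last <- if (any(keep)) max(which(keep)) else 0
    traces[[i]] <- structure(list(donor = d[seq_len(last)],
                                  acceptor = a[seq_len(last)],
                                  frame_time = frame_time,
                                  molecule_id = id, truth = NULL),
                             class = "intensity_trace")
  }
  traces
}

#' Per-trace QC table
#'
#' @param traces list of `intensity_trace`
#' @param selection optional result of [select_traces()]
#' @return data.frame with molecule_id, n_frames, mean intensities, selected
#' @export
trace_qc_table <- function(traces, selection = NULL) {
  df <- data.frame(
    molecule_id = vapply(traces, function(tr) tr$molecule_id, ""),
    n_frames = vapply(traces, function(tr) length(tr$donor), 0L),
    mean_donor = vapply(traces, function(tr) mean(tr$donor), 0),
    mean_acceptor = vapply(traces, function(tr) mean(tr$acceptor), 0),
    stringsAsFactors = FALSE)
  if (!is.null(selection)) df$selected <- selection$selected
  df
}
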
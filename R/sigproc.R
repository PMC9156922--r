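# Signal conditioning and ground-contact event detection.
#
# Conventions: sample indices are 1-based; a stance is the half-open index
# interval [touchdown, takeoff) — touchdown is the first sample at or above
# the force threshold, takeoff the first sample back below it.

# direct-form-II-transposed IIR filter with initial state zi
.lfilter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) numeric(nf - 1) else zi
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nf > 2)
      for (j in seq_len(nf - 2))
        z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[nf - 1] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

# steady-state initial filter state for a unit-step input, so that filtering
# a constant c with state zi * c reproduces c exactly
.lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  b <- b / a[1]; a <- a / a[1]
  A <- rbind(-a[2:nf], cbind(diag(1, nf - 2), numeric(nf - 2)))
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(1, nf - 1) - t(A), B)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward (zero phase
#' lag, squared magnitude response, unit DC gain). The signal is extended at
#' both ends by odd reflection and each pass starts from the steady-state
#' filter state of the first sample, so constants pass through unchanged and
#' edge transients are suppressed.
#'
#' @param x numeric signal vector.
#' @param cutoff cut-off frequency in Hz (must be below the Nyquist
#'   frequency `sample_rate / 2`). Conventional values here: 30 Hz for
#'   force, 6 Hz for marker positions.
#' @param sample_rate sampling rate in Hz.
#' @param order filter order of each pass (default 4).
#' @return Filtered signal, same length as `x`.
#' @examples
#' lowpass(rep(700, 100), cutoff = 30, sample_rate = 1000)[1:3]
#' @export
lowpass <- function(x, cutoff, sample_rate, order = 4L) {
  check_scalar(cutoff, "cutoff", positive = TRUE)
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (cutoff >= sample_rate / 2)
    stop_("`cutoff` (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff, sample_rate / 2)
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  n <- length(x)
  pad <- min(3L * max(length(a), length(b)), n - 1L)
  if (pad < 1L) stop_("signal too short to filter")
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  zi <- .lfilter_zi(b, a)
  y <- .lfilter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- .lfilter(b, a, y, zi * y[1])
  rev(y)[(pad + 1):(pad + n)]
}

# runs of consecutive TRUE in a logical vector -> start/end index pairs
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Correct force-transducer baseline drift
#'
#' Estimates the drifting baseline from the aerial phases of the signal —
#' runs of samples below `threshold` lasting at least `min_aerial` — as a
#' piecewise-linear interpolation through each aerial phase's median force,
#' anchored at the phase midpoint and extended flat to the signal edges,
#' then subtracts it. During an aerial phase the true vertical force is
#' zero, so whatever the transducer reports there is baseline.
#'
#' @param trial a [grf_trial()] or numeric force vector.
#' @param threshold force level in N below which a sample counts as aerial.
#' @param min_aerial minimum aerial-phase duration in s.
#' @param sample_rate sampling rate in Hz; taken from the trial when a
#'   [grf_trial()] is given.
#' @return Same type as `trial`, with the baseline removed.
#' @export
correct_drift <- function(trial, threshold = 20, min_aerial = 0.02,
                          sample_rate = NULL) {
  is_trial <- inherits(trial, "grf_trial")
  force <- if (is_trial) trial$force else as.numeric(trial)
  fs <- if (is_trial) trial$sample_rate else sample_rate
  if (is.null(fs)) stop_("`sample_rate` required for a bare force vector")
  aer <- .runs(force < threshold)
  aer <- aer[aer$end - aer$start + 1L >= min_aerial * fs, , drop = FALSE]
  if (nrow(aer) < 2L)
    stop_("no aerial baseline available: fewer than 2 aerial phases below %g N", threshold)
  mid <- (aer$start + aer$end) / 2
  med <- vapply(seq_len(nrow(aer)),
                function(i) median(force[aer$start[i]:aer$end[i]]), 0)
  baseline <- approx(mid, med, xout = seq_along(force), rule = 2)$y
  out <- force - baseline
  if (is_trial) { trial$force <- out; trial } else out
}

#' Detect stance phases with a force threshold
#'
#' Segments a conditioned (drift-corrected, filtered) vertical GRF signal
#' into ground-contact events using a 20 N threshold: a stance begins at the
#' first sample at or above the threshold following an aerial phase and ends
#' before the first sample back below it. Sub-threshold gaps shorter than
#' `min_aerial` are merged into the surrounding stance (debounce);
#' supra-threshold bursts shorter than `min_contact` are discarded (filter
#' ringing); stances touching either signal edge are discarded as
#' incomplete.
#'
#' @param trial a [grf_trial()] or numeric force vector.
#' @param threshold detection threshold in N.
#' @param min_contact minimum stance duration in s.
#' @param min_aerial minimum aerial-gap duration in s.
#' @inheritParams correct_drift
#' @return A data frame of stance events in time order: `touchdown` and
#'   `takeoff` (1-based sample indices, half-open interval), `leg`
#'   (`"unknown"` until [assign_legs()]), `t_c` (contact time, s) and `t_a`
#'   (aerial time to the next touchdown, s; `NA` for the last event). Empty
#'   (0-row) when the signal never crosses the threshold.
#' @export
detect_stance <- function(trial, threshold = 20, min_contact = 0.05,
                          min_aerial = 0.02, sample_rate = NULL) {
  is_trial <- inherits(trial, "grf_trial")
  force <- if (is_trial) trial$force else as.numeric(trial)
  fs <- if (is_trial) trial$sample_rate else sample_rate
  if (is.null(fs)) stop_("`sample_rate` required for a bare force vector")
  empty <- data.frame(touchdown = integer(0), takeoff = integer(0),
                      leg = character(0), t_c = numeric(0), t_a = numeric(0),
                      stringsAsFactors = FALSE)
  n <- length(force)
  if (n == 0L) return(empty)
  above <- force >= threshold
  if (!any(above)) return(empty)

  # merge interior sub-threshold gaps shorter than min_aerial
  gaps <- .runs(!above)
  short <- gaps[gaps$start > 1L & gaps$end < n &
                  (gaps$end - gaps$start + 1L) < min_aerial * fs, , drop = FALSE]
  for (i in seq_len(nrow(short))) above[short$start[i]:short$end[i]] <- TRUE

  ev <- .runs(above)
  # discard too-short bursts, then incomplete edge-touching stances
  ev <- ev[(ev$end - ev$start + 1L) >= min_contact * fs, , drop = FALSE]
  ev <- ev[ev$start > 1L & ev$end < n, , drop = FALSE]
  if (!nrow(ev)) return(empty)

  touchdown <- ev$start
  takeoff <- ev$end + 1L   # first sample below threshold
  t_c <- (takeoff - touchdown) / fs
  t_a <- c((touchdown[-1] - takeoff[-length(takeoff)]) / fs, NA_real_)
  data.frame(touchdown = touchdown, takeoff = takeoff,
             leg = rep("unknown", length(touchdown)),
             t_c = t_c, t_a = t_a, stringsAsFactors = FALSE)
}

#' Label stance events with the leg in contact
#'
#' For each stance, the filtered vertical positions of the two leg markers
#' are averaged over the stance interval (marker samples matched to force
#' samples by nearest-sample index) and the event is attributed to the leg
#' whose marker sits lowest. Legs must alternate between consecutive
#' events; an event that would repeat the previous label is set to
#' `"unknown"` with a warning. Without marker data, labels fall back to
#' strict alternation from `fallback_first_leg`.
#'
#' @param events stance-event data frame from [detect_stance()].
#' @param markers a [marker_trial()] with traces already low-pass filtered,
#'   or `NULL` to use the alternation fallback.
#' @param force_rate force sampling rate in Hz (for marker-to-force index
#'   matching).
#' @param fallback_first_leg leg assumed for the first event when no marker
#'   data exist.
#' @return `events` with the `leg` column filled in.
#' @export
assign_legs <- function(events, markers = NULL, force_rate = 1000,
                        fallback_first_leg = "affected") {
  if (!nrow(events)) return(events)
  fallback_first_leg <- match.arg(fallback_first_leg, LEGS)
  if (is.null(markers)) {
    first <- match(fallback_first_leg, LEGS)
    events$leg <- rep(LEGS[c(first, 3L - first)],
                      length.out = nrow(events))
    return(events)
  }
  stopifnot(inherits(markers, "marker_trial"))
  ratio <- markers$sample_rate / force_rate
  nm <- length(markers$affected)
  for (i in seq_len(nrow(events))) {
    fi <- events$touchdown[i]:(events$takeoff[i] - 1L)
    mi <- unique(pmin(pmax(round((fi - 1L) * ratio) + 1L, 1L), nm))
    mi <- mi[mi >= 1L & mi <= nm]
    if (!length(mi) || anyNA(markers$affected[mi]) || anyNA(markers$unaffected[mi])) {
      events$leg[i] <- "unknown"
      next
    }
    events$leg[i] <- if (mean(markers$affected[mi]) <= mean(markers$unaffected[mi]))
      "affected" else "unaffected"
  }
  # alternation guard
  prev <- "unknown"
  for (i in seq_len(nrow(events))) {
    if (events$leg[i] == "unknown") next
    if (events$leg[i] == prev) {
      warning(sprintf("stance %d violates leg alternation; labelled unknown", i),
              call. = FALSE)
      events$leg[i] <- "unknown"
      next
    }
    prev <- events$leg[i]
  }
  events
}

#' Run the signal-conditioning pipeline on one trial
#'
#' Drift-corrects the raw force, low-pass filters force (30 Hz) and markers
#' (6 Hz) with the zero-phase fourth-order Butterworth filter, detects
#' stance events with the 20 N threshold, labels legs, and derives per-step
#' metrics. By default the threshold is applied to the drift-corrected
#' unfiltered force — filtering smears the sharp stance onset and would bias
#' contact times by several samples at sprint speeds — while the
#' stance-average force uses the filtered signal; set `detect_on =
#' "filtered"` in the config to threshold the filtered force instead.
#' Saturated trials (see [is_saturated()]) are flagged in the QC
#' record; the steps are still computed so the caller can inspect them, but
#' aggregation should exclude such trials.
#'
#' @param grf a [grf_trial()] with the raw force signal.
#' @param markers a [marker_trial()] or `NULL`.
#' @param config pipeline settings from [run_config()].
#' @return A list: `trial` (conditioned [grf_trial()]), `events` (labelled
#'   stance events), `steps` (per-step metrics, see [step_metrics()]), `qc`
#'   (list: `saturated`, `n_events`, `n_unknown_leg`).
#' @export
process_trial <- function(grf, markers = NULL, config = run_config()) {
  stopifnot(inherits(grf, "grf_trial"))
  saturated <- is_saturated(grf, min_run = config$saturation_min_run)
  grf <- correct_drift(grf, threshold = config$threshold,
                       min_aerial = config$min_aerial)
  raw_force <- grf$force
  grf$force <- lowpass(grf$force, cutoff = config$force_cutoff,
                       sample_rate = grf$sample_rate,
                       order = config$filter_order)
  if (!is.null(markers)) {
    markers$affected <- lowpass(markers$affected, config$marker_cutoff,
                                markers$sample_rate, config$filter_order)
    markers$unaffected <- lowpass(markers$unaffected, config$marker_cutoff,
                                  markers$sample_rate, config$filter_order)
  }
  detect_sig <- if (config$detect_on == "raw") raw_force else grf$force
  events <- detect_stance(detect_sig, threshold = config$threshold,
                          min_contact = config$min_contact,
                          min_aerial = config$min_aerial,
                          sample_rate = grf$sample_rate)
  events <- assign_legs(events, markers, force_rate = grf$sample_rate)
  steps <- if (nrow(events) >= 2L) step_metrics(events, grf, g = config$g)
           else NULL
  list(trial = grf, events = events, steps = steps,
       qc = list(saturated = saturated, n_events = nrow(events),
                 n_unknown_leg = sum(events$leg == "unknown")))
}
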
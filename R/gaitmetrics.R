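# Per-step running metrics and between-leg symmetry.
#
# For steady treadmill running at belt speed v, each step (one stance plus
# the following aerial phase) satisfies
#   f_step = 1 / (t_c + t_a)          step frequency, Hz
#   L_c    = v * t_c                  contact length, m
#   L_step = v / f_step = L_c * F_avg step length, m
#   v      = L_c * F_avg * f_step     the running-speed identity
# where F_avg is the stance-average vertical GRF in bodyweights. On a
# constant-speed treadmill, belt_speed * t_c is the standard surrogate for
# the distance the centre of mass travels during contact; it is what makes
# L_step = L_c * F_avg an impulse-balance identity.

#' Per-step metrics from labelled stance events
#'
#' Converts each stance-plus-aerial pair into a step record: contact time,
#' aerial time, step frequency, contact length, stance-average vertical
#' force normalized to bodyweight, and step length. The final stance (which
#' has no following aerial phase) is dropped, as are events with an unknown
#' leg label.
#'
#' @param events labelled stance events from [assign_legs()].
#' @param trial the conditioned [grf_trial()] the events were detected in
#'   (its force samples are used for the stance average).
#' @param g gravitational acceleration in m s^-2 used for bodyweight
#'   normalization.
#' @return A data frame with one row per usable step: `leg`, `t_c`, `t_a`,
#'   `f_step` (Hz), `L_c` (m), `F_avg` (BW), `L_step` (m).
#' @export
step_metrics <- function(events, trial, g = 9.81) {
  stopifnot(inherits(trial, "grf_trial"))
  ev <- events[!is.na(events$t_a) & events$leg != "unknown", , drop = FALSE]
  n_dropped <- nrow(events) - nrow(ev)
  if (!nrow(ev)) stop_("no usable steps after exclusions")
  if (n_dropped > 0L)
    message(sprintf("step_metrics: excluded %d of %d events (unknown leg or no following aerial phase)",
                    n_dropped, nrow(events)))
  bw <- trial$body_mass * g
  f_avg <- vapply(seq_len(nrow(ev)), function(i)
    mean(trial$force[ev$touchdown[i]:(ev$takeoff[i] - 1L)]) / bw, 0)
  data.frame(
    leg = ev$leg, t_c = ev$t_c, t_a = ev$t_a,
    f_step = 1 / (ev$t_c + ev$t_a),
    L_c = trial$belt_speed * ev$t_c,
    F_avg = f_avg,
    L_step = trial$belt_speed * (ev$t_c + ev$t_a),
    stringsAsFactors = FALSE)
}

#' Between-leg symmetry index
#'
#' `SI = (X_UL - X_AL) / (0.5 * (X_UL + X_AL)) * 100`, in percent: 0 means
#' perfect symmetry, positive means the unaffected-leg value is larger,
#' negative means the affected-leg value is larger. For positive inputs the
#' value lies in (-200, 200]. A change in SI is reported in percentage
#' points (p.p.): going from 5% to 6% is a 1 p.p. increase.
#'
#' @param x_ul unaffected-leg value.
#' @param x_al affected-leg value (same units). Vectorized.
#' @return Symmetry index in percent.
#' @examples
#' symmetry_index(1.1, 0.9)   #  20
#' symmetry_index(0.9, 1.1)   # -20
#' @export
symmetry_index <- function(x_ul, x_al) {
  s <- x_ul + x_al
  if (any(s == 0)) stop_("undefined SI: x_ul + x_al = 0")
  (x_ul - x_al) / (0.5 * s) * 100
}

#' Aggregate per-step metrics to one trial row
#'
#' Averages step metrics per leg over the analysis window (by default the
#' last 16 labelled steps, matching the length of a successful trial) and
#' computes the symmetry index of each metric from the per-leg means (not as
#' a mean of per-step indices). Trial covariates are carried through from
#' the trial metadata.
#'
#' @param steps step records from [step_metrics()].
#' @param trial the [grf_trial()] supplying covariates (`subject`,
#'   `rsp_model`, `stiffness_cat`, `height_offset_cm`, `speed`).
#' @param window number of most recent steps to average, or `"all"`.
#' @param min_steps minimum usable steps per leg.
#' @return A one-row data frame: covariates, per-leg means `lc_al`, `lc_ul`,
#'   `favg_al`, `favg_ul`, `fstep_al`, `fstep_ul`, symmetry indices `si_lc`,
#'   `si_favg`, `si_fstep` (percent), and `n_steps`.
#' @export
aggregate_trial <- function(steps, trial, window = 16L, min_steps = 4L) {
  stopifnot(inherits(trial, "grf_trial"))
  if (!identical(window, "all")) {
    window <- as.integer(window)
    if (nrow(steps) > window)
      steps <- steps[(nrow(steps) - window + 1L):nrow(steps), , drop = FALSE]
  }
  for (l in LEGS) {
    k <- sum(steps$leg == l)
    if (k < min_steps)
      stop_("too few usable steps on the %s leg (%d < %d)", l, k, min_steps)
  }
  m <- function(l, v) mean(steps[steps$leg == l, v])
  data.frame(
    subject = trial$subject, rsp_model = trial$rsp_model,
    stiffness_cat = trial$stiffness_cat,
    height_offset_cm = trial$height_offset_cm,
    speed = trial$belt_speed,
    lc_al = m("affected", "L_c"), lc_ul = m("unaffected", "L_c"),
    favg_al = m("affected", "F_avg"), favg_ul = m("unaffected", "F_avg"),
    fstep_al = m("affected", "f_step"), fstep_ul = m("unaffected", "f_step"),
    si_lc = symmetry_index(m("unaffected", "L_c"), m("affected", "L_c")),
    si_favg = symmetry_index(m("unaffected", "F_avg"), m("affected", "F_avg")),
    si_fstep = symmetry_index(m("unaffected", "f_step"), m("affected", "f_step")),
    n_steps = nrow(steps),
    stringsAsFactors = FALSE)
}
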
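#' Force-trial and marker-trial containers
#'
#' `grf_trial()` wraps one trial's uniformly sampled vertical ground-reaction
#' force signal together with its acquisition metadata; `marker_trial()` wraps
#' the per-leg vertical marker position traces, time-aligned to the force
#' signal's start. These are plain lists with a class attribute, in the style
#' of model objects in base R.
#'
#' @param force numeric vector of vertical force samples, in N.
#' @param sample_rate sampling rate in Hz (force: typically 1000).
#' @param body_mass subject body mass in kg.
#' @param belt_speed treadmill belt speed in m s^-1.
#' @param subject subject identifier.
#' @param rsp_model prosthesis model, one of `"Catapult"`, `"Sprinter"`,
#'   `"Xtend"`.
#' @param stiffness_cat prosthesis stiffness category relative to the
#'   manufacturer recommendation: `"-1"`, `"Rec"` or `"+1"`.
#' @param height_offset_cm prosthesis height relative to recommended, in cm
#'   (signed; non-integer values allowed).
#' @param saturation_level force transducer saturation level in N, or `NULL`
#'   if the transducer never saturates.
#' @return An object of class `"grf_trial"`.
#' @examples
#' tr <- grf_trial(force = rep(0, 2000), sample_rate = 1000,
#'                 body_mass = 70, belt_speed = 3)
#' tr
#' @export
grf_trial <- function(force, sample_rate, body_mass, belt_speed,
                      subject = NA_character_, rsp_model = NA_character_,
                      stiffness_cat = NA_character_, height_offset_cm = NA_real_,
                      saturation_level = NULL) {
  if (!is.numeric(force) || length(force) < 2L)
    stop_("`force` must be a numeric vector with at least 2 samples")
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  check_scalar(body_mass, "body_mass", positive = TRUE)
  check_scalar(belt_speed, "belt_speed", positive = TRUE)
  if (length(force) / sample_rate < 2)
    stop_("trial must contain at least 2 s of data for event detection")
  if (!is.null(saturation_level))
    check_scalar(saturation_level, "saturation_level", positive = TRUE)
  structure(list(
    force = as.numeric(force), sample_rate = sample_rate,
    body_mass = body_mass, belt_speed = belt_speed,
    subject = subject, rsp_model = rsp_model,
    stiffness_cat = stiffness_cat, height_offset_cm = height_offset_cm,
    saturation_level = saturation_level
  ), class = "grf_trial")
}

#' @rdname grf_trial
#' @param affected,unaffected numeric vectors of vertical marker position in
#'   m for the affected- and unaffected-leg markers.
#' @export
marker_trial <- function(affected, unaffected, sample_rate) {
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (length(affected) != length(unaffected))
    stop_("marker traces must have equal length")
  structure(list(affected = as.numeric(affected),
                 unaffected = as.numeric(unaffected),
                 sample_rate = sample_rate),
            class = "marker_trial")
}

#' @export
print.grf_trial <- function(x, ...) {
  cat(sprintf(
    "<grf_trial> %d samples @ %g Hz (%.2f s), %.1f kg, belt %g m/s\n",
    length(x$force), x$sample_rate, length(x$force) / x$sample_rate,
    x$body_mass, x$belt_speed))
  if (!is.na(x$subject))
    cat(sprintf("  subject %s, %s / %s / %+g cm\n", x$subject, x$rsp_model,
                x$stiffness_cat, x$height_offset_cm))
  invisible(x)
}

#' @export
print.marker_trial <- function(x, ...) {
  cat(sprintf("<marker_trial> %d samples @ %g Hz, legs: affected, unaffected\n",
              length(x$affected), x$sample_rate))
  invisible(x)
}

#' Detect force-transducer saturation
#'
#' A trial is flagged saturated when the raw force sits at (or above) the
#' transducer's saturation level for at least `min_run` consecutive samples.
#' Saturated trials are excluded from aggregation downstream.
#'
#' @param trial a [grf_trial()] (its `saturation_level` is used when `level`
#'   is `NULL`), or a numeric force vector.
#' @param level saturation level in N; `NULL` means "no saturation defined",
#'   which returns `FALSE`.
#' @param min_run minimum number of consecutive saturated samples.
#' @return logical scalar.
#' @export
is_saturated <- function(trial, level = NULL, min_run = 3L) {
  force <- if (inherits(trial, "grf_trial")) trial$force else as.numeric(trial)
  if (is.null(level) && inherits(trial, "grf_trial"))
    level <- trial$saturation_level
  if (is.null(level)) return(FALSE)
  r <- rle(force >= level - 1e-9)
  any(r$values & r$lengths >= min_run)
}
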
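#' Configure a synthetic treadmill running trial
#'
#' Defines the ground truth for one simulated constant-speed trial: a train of
#' alternating-leg half-sine stance force bumps separated by true-zero aerial
#' phases, with optional between-leg asymmetry, measurement noise, baseline
#' drift and transducer saturation. Unless overridden, the half-sine peak is
#' set by steady-running impulse balance — over a step the vertical impulse
#' equals body weight times step time, so the stance-average force in
#' bodyweights equals `(t_c + t_a) / t_c`.
#'
#' Between-leg asymmetry is parameterised as a signed fractional offset `a`
#' applied multiplicatively in opposite directions: the unaffected leg gets
#' `base * (1 + a)` and the affected leg `base * (1 - a)`, so the symmetry
#' index of the underlying parameter is `200 * a / 1` percent (e.g. `a = 0.1`
#' gives SI = 20%).
#'
#' @param belt_speed treadmill speed in m s^-1.
#' @param body_mass subject mass in kg.
#' @param t_c baseline ground-contact time in s (> 4 force samples).
#' @param t_a baseline aerial time in s (>= 0).
#' @param n_steps number of steps (stance + subsequent aerial), default 16 —
#'   the length of a successful trial's analysis window.
#' @param first_leg leg of the first stance, `"affected"` or `"unaffected"`.
#' @param asymmetry named list of fractional between-leg offsets for `t_c`,
#'   `t_a` and `peak` (peak-force multiplier); missing entries default to 0.
#' @param peak_scale optional override of the impulse-balance peak: when
#'   given, the stance-average force is `peak_scale` bodyweights exactly
#'   (must be >= 1 to support the body).
#' @param noise_sd white measurement noise s.d. in N, applied to the force
#'   signal after the truth is captured.
#' @param drift baseline drift shape: `"none"`, `"linear"` (0 to
#'   `drift_amplitude` N over the trial) or `"sinusoidal"` (one full cycle of
#'   amplitude `drift_amplitude` N).
#' @param drift_amplitude drift amplitude in N.
#' @param saturation_level transducer saturation level in N, or `NULL`. Must
#'   exceed body weight, otherwise the signal would be unusable.
#' @param sample_rate_force,sample_rate_marker acquisition rates in Hz.
#' @param gravity gravitational acceleration in m s^-2.
#' @param seed integer seed making the noise draw reproducible; `NULL` uses
#'   the current RNG stream.
#' @return A list of class `"sim_trial_config"`.
#' @seealso [simulate_trial()]
#' @export
sim_trial_config <- function(belt_speed, body_mass, t_c = 0.2, t_a = 0.12,
                             n_steps = 16L, first_leg = "affected",
                             asymmetry = list(), peak_scale = NULL,
                             noise_sd = 0, drift = c("none", "linear", "sinusoidal"),
                             drift_amplitude = 0, saturation_level = NULL,
                             sample_rate_force = 1000, sample_rate_marker = 200,
                             gravity = 9.81, seed = NULL) {
  check_scalar(belt_speed, "belt_speed", positive = TRUE)
  check_scalar(body_mass, "body_mass", positive = TRUE)
  check_scalar(t_c, "t_c", positive = TRUE)
  check_scalar(t_a, "t_a", nonneg = TRUE)
  check_scalar(sample_rate_force, "sample_rate_force", positive = TRUE)
  check_scalar(sample_rate_marker, "sample_rate_marker", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(drift_amplitude, "drift_amplitude", nonneg = TRUE)
  check_scalar(gravity, "gravity", positive = TRUE)
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop_("`n_steps` must be >= 2")
  first_leg <- match.arg(first_leg, LEGS)
  drift <- match.arg(drift)
  a <- list(t_c = 0, t_a = 0, peak = 0)
  if (length(asymmetry)) {
    bad <- setdiff(names(asymmetry), names(a))
    if (length(bad)) stop_("unknown asymmetry component(s): %s",
                           paste(bad, collapse = ", "))
    a[names(asymmetry)] <- asymmetry
  }
  if (!is.null(peak_scale)) {
    check_scalar(peak_scale, "peak_scale", positive = TRUE)
    if (peak_scale < 1)
      stop_("`peak_scale` must be >= 1 (stance-average force below body weight cannot support steady running)")
  }
  if (!is.null(saturation_level)) {
    check_scalar(saturation_level, "saturation_level", positive = TRUE)
    if (saturation_level < body_mass * gravity)
      stop_("`saturation_level` is below body weight: signal would be unusable")
  }
  structure(list(
    belt_speed = belt_speed, body_mass = body_mass, t_c = t_c, t_a = t_a,
    n_steps = n_steps, first_leg = first_leg, asymmetry = a,
    peak_scale = peak_scale, noise_sd = noise_sd, drift = drift,
    drift_amplitude = drift_amplitude, saturation_level = saturation_level,
    sample_rate_force = sample_rate_force,
    sample_rate_marker = sample_rate_marker,
    gravity = gravity, seed = seed
  ), class = "sim_trial_config")
}

# per-leg parameter after the +/- fractional offset
.leg_factor <- function(leg, a) ifelse(leg == "unaffected", 1 + a, 1 - a)

#' Simulate one treadmill running trial with known ground truth
#'
#' Generates the vertical GRF signal (half-sine stance bumps, alternating
#' legs), per-leg vertical marker traces sufficient for leg labelling (low
#' and flat during a leg's own stance, arcing upward during swing), and a
#' ground-truth record of the per-step parameters and derived metrics.
#' Noise, drift and saturation are applied after the truth is captured, in
#' that order, mirroring a transducer's physical signal path.
#'
#' The truth satisfies the running-speed identity
#' `belt_speed = L_c * F_avg * f_step` exactly whenever the impulse-balance
#' peak is in force (no `peak_scale` / peak asymmetry override), since
#' `L_c = v * t_c`, `F_avg = (t_c + t_a) / t_c` BW and
#' `f_step = 1 / (t_c + t_a)`.
#'
#' @param config a [sim_trial_config()].
#' @return A list with components `grf` ([grf_trial()]), `markers`
#'   ([marker_trial()]) and `truth` (list: `steps`, a per-step data frame of
#'   parameters and true metrics; `leg_means`, per-leg trial means; `si`,
#'   true symmetry indices in percent for `L_c`, `F_avg`, `f_step`).
#' @examples
#' cfg <- sim_trial_config(belt_speed = 3, body_mass = 70)
#' sim <- simulate_trial(cfg)
#' sim$truth$si       # all 0: symmetric legs
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_trial_config"))
  fs <- config$sample_rate_force
  fm <- config$sample_rate_marker
  bw <- config$body_mass * config$gravity
  legs <- if (config$first_leg == "affected")
    rep(c("affected", "unaffected"), length.out = config$n_steps)
  else rep(c("unaffected", "affected"), length.out = config$n_steps)

  t_c <- config$t_c * .leg_factor(legs, config$asymmetry$t_c)
  t_a <- config$t_a * .leg_factor(legs, config$asymmetry$t_a)
  if (any(t_c < 4 / fs))
    stop_("contact time shorter than 4 force samples (%.4f s at %g Hz)", 4 / fs, fs)
  if (any(t_a < 0)) stop_("asymmetry drives aerial time negative")

  # stance-average force in BW: impulse balance unless peak_scale overrides
  favg_bw <- if (is.null(config$peak_scale)) (t_c + t_a) / t_c
             else rep(config$peak_scale, config$n_steps)
  favg_bw <- favg_bw * .leg_factor(legs, config$asymmetry$peak)
  f_peak <- (pi / 2) * favg_bw * bw      # half-sine mean = (2/pi) * peak

  # layout: aerial padding at both ends so no stance touches a signal edge,
  # and total duration >= 2.1 s (event-detection minimum)
  pad <- max(0.25, max(t_a))
  dur_steps <- sum(t_c + t_a)
  pad_end <- max(pad, 2.1 - (pad + dur_steps))
  touchdown_t <- pad + c(0, cumsum((t_c + t_a)[-config$n_steps]))
  takeoff_t <- touchdown_t + t_c
  total_dur <- pad + dur_steps + pad_end

  n <- ceiling(total_dur * fs)
  tt <- (seq_len(n) - 1) / fs
  force <- numeric(n)
  for (i in seq_len(config$n_steps)) {
    sel <- tt >= touchdown_t[i] & tt < takeoff_t[i]
    force[sel] <- f_peak[i] * sin(pi * (tt[sel] - touchdown_t[i]) / t_c[i])
  }

  # truth captured before noise/drift/saturation
  steps <- data.frame(
    step = seq_len(config$n_steps), leg = legs,
    t_c = t_c, t_a = t_a, f_peak = f_peak,
    L_c = config$belt_speed * t_c,
    F_avg = favg_bw,
    f_step = 1 / (t_c + t_a),
    touchdown_t = touchdown_t, takeoff_t = takeoff_t,
    stringsAsFactors = FALSE
  )
  leg_means <- do.call(rbind, lapply(LEGS, function(l) {
    s <- steps[steps$leg == l, ]
    data.frame(leg = l, t_c = mean(s$t_c), t_a = mean(s$t_a),
               L_c = mean(s$L_c), F_avg = mean(s$F_avg),
               f_step = mean(s$f_step), stringsAsFactors = FALSE)
  }))
  ul <- leg_means[leg_means$leg == "unaffected", ]
  al <- leg_means[leg_means$leg == "affected", ]
  si <- c(L_c = symmetry_index(ul$L_c, al$L_c),
          F_avg = symmetry_index(ul$F_avg, al$F_avg),
          f_step = symmetry_index(ul$f_step, al$f_step))

  # corruption chain: noise -> drift -> saturation
  force <- with_seed(config$seed, {
    if (config$noise_sd > 0) force <- force + rnorm(n, 0, config$noise_sd)
    force
  })
  if (config$drift == "linear" && config$drift_amplitude > 0)
    force <- force + config$drift_amplitude * tt / total_dur
  if (config$drift == "sinusoidal" && config$drift_amplitude > 0)
    force <- force + config$drift_amplitude * sin(2 * pi * tt / total_dur)
  if (!is.null(config$saturation_level))
    force <- pmin(force, config$saturation_level)

  # markers: 0.05 m during own stance, sinusoidal arc to 0.15 m mid-swing,
  # 0.15 m outside the leg's own first-touchdown..last-takeoff span
  nm <- ceiling(total_dur * fm)
  tm <- (seq_len(nm) - 1) / fm
  marker_for <- function(leg) {
    z <- rep(0.15, nm)
    own <- which(legs == leg)
    for (i in own) {
      z[tm >= touchdown_t[i] & tm < takeoff_t[i]] <- 0.05
      nxt <- own[own > i]
      if (length(nxt)) {
        j <- nxt[1]
        swing <- tm >= takeoff_t[i] & tm < touchdown_t[j]
        phase <- (tm[swing] - takeoff_t[i]) / (touchdown_t[j] - takeoff_t[i])
        z[swing] <- 0.05 + 0.10 * sin(pi * phase)
      }
    }
    z
  }

  grf <- grf_trial(force = force, sample_rate = fs,
                   body_mass = config$body_mass,
                   belt_speed = config$belt_speed,
                   saturation_level = config$saturation_level)
  markers <- marker_trial(affected = marker_for("affected"),
                          unaffected = marker_for("unaffected"),
                          sample_rate = fm)
  list(grf = grf, markers = markers,
       truth = list(steps = steps, leg_means = leg_means, si = si))
}
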
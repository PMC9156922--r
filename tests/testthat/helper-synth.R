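# shared fixtures: everything is generated in code at test time

# a clean symmetric trial at a given speed; defaults mirror a slow run
clean_sim <- function(belt_speed = 3, t_c = 0.2, t_a = 0.12, body_mass = 70,
                      ...) {
  simulate_trial(sim_trial_config(belt_speed = belt_speed, body_mass = body_mass,
                                  t_c = t_c, t_a = t_a, ...))
}

process_quiet <- function(...) suppressMessages(process_trial(...))

# an isolated half-sine bump embedded in zeros, for analytic edge checks
half_sine_signal <- function(f_peak = 1500, t_c = 0.2, fs = 1000,
                             pad = 0.9) {
  n_pad <- round(pad * fs)
  tt <- (seq_len(round(t_c * fs)) - 1) / fs
  c(numeric(n_pad), f_peak * sin(pi * tt / t_c), numeric(n_pad))
}

# true coefficient set used for simulation-based statistics tests: the
# published affected-leg contact-length model
lc_truth <- function() {
  ref <- reference_coefficients("lc_al")
  setNames(ref$estimate, ref$term)
}

sim_table <- function(truth = lc_truth(), subject_sd = 0.02,
                      residual_sd = 0.02, seed = 1, drop_saturated = TRUE,
                      design = rsp_study_design()) {
  tab <- simulate_trial_table(lmm_sim_config(
    truth, design = design, subject_sd = subject_sd,
    residual_sd = residual_sd, seed = seed))
  if (drop_saturated && "saturated" %in% names(tab))
    tab <- tab[!tab$saturated, , drop = FALSE]
  tab
}

# balanced full-factorial design (no missing cells), for OLS comparisons
balanced_design <- function(n_subjects = 10) {
  expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
              rsp_model = c("Catapult", "Sprinter", "Xtend"),
              stiffness_cat = c("-1", "Rec", "+1"),
              height_offset_cm = c(-2, 0, 2), speed = 3:7,
              stringsAsFactors = FALSE)
}
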
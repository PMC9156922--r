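#' Trial design of the benchmark 10-athlete RSP study
#'
#' Builds the per-trial design table of the repeated-measures study this
#' package reproduces: 10 athletes with a unilateral transtibial amputation,
#' each running with up to 15 running-specific-prosthesis configurations
#' (3 models x 3 stiffness categories at recommended height, plus +/-2 cm
#' height changes for the stiffness category that elicited each subject's
#' maximum speed) at treadmill speeds of 3-7 m s^-1.
#'
#' Not every subject completed every cell: some height changes were limited
#' by residual-limb length (heights of 0.8-1.8 cm were used instead of 2 cm
#' for a few subjects), some subjects did not complete the fastest trials,
#' and four trials had saturated force data. The emulation reproduces those
#' counts, yielding 704 analysable trials plus 4 saturated ones. Subject ids
#' within sub-sampled cells are assigned deterministically (lowest ids
#' first), which affects labels only, not the design's structure.
#'
#' @param speeds integer vector of treadmill speeds in m s^-1.
#' @return A data frame with one row per recorded trial: `subject`,
#'   `rsp_model`, `stiffness_cat`, `height_offset_cm`, `speed`, `saturated`.
#' @examples
#' d <- rsp_study_design()
#' sum(!d$saturated)   # 704 analysable trials
#' @export
rsp_study_design <- function(speeds = 3:7) {
  cell <- function(model, stiff, height, n, notes = "")
    list(model = model, stiff = stiff, height = height, n = n,
         notes = strsplit(notes, "")[[1]])
  cells <- list(
    # recommended height: all 10 subjects, every model x stiffness
    cell("Catapult", "-1",  0, 10, "a"), cell("Catapult", "Rec", 0, 10, "a"),
    cell("Catapult", "+1",  0, 10, "b"),
    cell("Sprinter", "-1",  0, 10),      cell("Sprinter", "Rec", 0, 10, "e"),
    cell("Sprinter", "+1",  0, 10),
    cell("Xtend",    "-1",  0, 10, "a"), cell("Xtend",    "Rec", 0, 10, "a"),
    cell("Xtend",    "+1",  0, 10, "b"),
    # 2 cm shorter than recommended
    cell("Catapult", "-1", -2, 5, "dgh"), cell("Catapult", "Rec", -2, 2),
    cell("Catapult", "+1", -2, 2),
    cell("Sprinter", "-1", -2, 2), cell("Sprinter", "Rec", -2, 5),
    cell("Sprinter", "+1", -2, 2),
    cell("Xtend",    "-1", -2, 2), cell("Xtend",    "Rec", -2, 3, "i"),
    cell("Xtend",    "+1", -2, 5, "bf"),
    # 2 cm taller than recommended
    cell("Catapult", "-1",  2, 5, "ac"), cell("Catapult", "Rec", 2, 2),
    cell("Catapult", "+1",  2, 2),
    cell("Sprinter", "-1",  2, 2, "c"), cell("Sprinter", "Rec", 2, 5, "k"),
    cell("Sprinter", "+1",  2, 2, "j"),
    cell("Xtend",    "-1",  2, 2), cell("Xtend",    "Rec", 2, 3),
    cell("Xtend",    "+1",  2, 4, "a")
  )
  # footnote semantics: which speeds a flagged subject missed / saturated,
  # and individual height deviations from the nominal +/-2 cm
  missing_for <- list(a = 7, b = 7, c = 6:7, d = 7)
  saturated_for <- list(d = c(3, 4), e = 3, f = 7)
  height_dev <- c(g = -1.8, h = -1.3, i = -1.0, j = 1.0, k = 0.8)

  rows <- list()
  for (cl in cells) {
    subjects <- seq_len(cl$n)
    # one distinct subject per footnote, lowest ids first; 'b' flags two
    flag_sub <- list()
    nxt <- 1L
    for (nt in cl$notes) {
      k <- if (nt == "b") 2L else 1L
      flag_sub[[nt]] <- subjects[nxt:(nxt + k - 1L)]
      nxt <- nxt + k
    }
    for (s in subjects) {
      height <- cl$height
      miss <- integer(0); sat <- integer(0)
      for (nt in names(flag_sub)) {
        if (!(s %in% flag_sub[[nt]])) next
        if (!is.null(missing_for[[nt]])) miss <- c(miss, missing_for[[nt]])
        if (!is.null(saturated_for[[nt]])) sat <- c(sat, saturated_for[[nt]])
        if (nt %in% names(height_dev)) height <- height_dev[[nt]]
      }
      sp <- setdiff(speeds, miss)
      if (!length(sp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", s), rsp_model = cl$model,
        stiffness_cat = cl$stiff, height_offset_cm = height,
        speed = sp, saturated = sp %in% sat, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configure a synthetic trial table with known mixed-model coefficients
#'
#' Defines the data-generating process for the statistics stage: a response
#' built from a linear predictor over the study design (treatment coding,
#' reference levels Catapult and the -1 stiffness category, speed uncentred
#' in m s^-1), a Gaussian subject random intercept, and Gaussian residual
#' noise.
#'
#' @param coefficients named numeric vector of true fixed-effect values.
#'   Names must be drawn from the design's term labels (see
#'   [design_terms()]); terms not named default to 0.
#' @param design trial design data frame, as from [rsp_study_design()]
#'   (the default). Needs columns `subject`, `rsp_model`, `stiffness_cat`,
#'   `height_offset_cm`, `speed`; a `saturated` column is carried through.
#' @param subject_sd s.d. of the subject random intercept (response units).
#' @param residual_sd residual s.d. (response units).
#' @param response name for the simulated response column.
#' @param seed integer seed, or `NULL`.
#' @return A list of class `"lmm_sim_config"`.
#' @export
lmm_sim_config <- function(coefficients, design = rsp_study_design(),
                           subject_sd = 0, residual_sd = 0,
                           response = "response", seed = NULL) {
  check_scalar(subject_sd, "subject_sd", nonneg = TRUE)
  check_scalar(residual_sd, "residual_sd", nonneg = TRUE)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop_("`coefficients` must be a fully named numeric vector")
  bad <- setdiff(names(coefficients), design_terms())
  if (length(bad))
    stop_("unknown coefficient term(s): %s", paste(bad, collapse = ", "))
  structure(list(coefficients = coefficients, design = design,
                 subject_sd = subject_sd, residual_sd = residual_sd,
                 response = response, seed = seed),
            class = "lmm_sim_config")
}

#' Simulate a per-trial analysis table from known coefficients
#'
#' Each trial's response is the fixed-effect linear predictor for its design
#' row plus the subject's random-intercept draw plus a residual draw.
#' Deterministic for a fixed seed.
#'
#' @param config an [lmm_sim_config()].
#' @return The design data frame with the simulated response column added.
#' @examples
#' cfg <- lmm_sim_config(c(intercept = 0.53, `speed [m s^-1]` = 0.066),
#'                       subject_sd = 0.02, residual_sd = 0.02, seed = 1)
#' head(simulate_trial_table(cfg))
#' @export
simulate_trial_table <- function(config) {
  stopifnot(inherits(config, "lmm_sim_config"))
  rows <- config$design
  X <- build_design(rows)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  beta[names(config$coefficients)] <- config$coefficients
  mu <- drop(X %*% beta)
  subjects <- unique(rows$subject)
  y <- with_seed(config$seed, {
    b <- setNames(rnorm(length(subjects), 0, config$subject_sd), subjects)
    mu + b[rows$subject] + rnorm(nrow(rows), 0, config$residual_sd)
  })
  rows[[config$response]] <- unname(y)
  rows
}
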
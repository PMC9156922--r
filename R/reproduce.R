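# Reference values of the benchmark study and the reproduction driver.

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "rspgait")
  if (!nzchar(p)) stop_("reference file %s not found", file)
  p
}

#' Characteristics of the 10 study participants
#'
#' Sex, age, body mass and leg lengths (standing unaffected-leg length and
#' unloaded affected-leg length at the recommended prosthesis height for
#' each RSP model) of the ten athletes with a unilateral transtibial
#' amputation in the benchmark study.
#'
#' @return Data frame with one row per subject.
#' @examples
#' mean(subject_characteristics()$mass_kg)
#' @export
subject_characteristics <- function() {
  read.csv(.extdata("subject_characteristics.csv"), stringsAsFactors = FALSE)
}

#' Published mixed-model coefficient estimates of the benchmark study
#'
#' The fixed-effect estimates, 95% confidence intervals, standard errors,
#' t- and p-values published for the six study models (affected-leg contact
#' length, stance-average vertical force and step frequency, and their
#' symmetry indices), used by [reproduce_study()] as comparison values and
#' by [predict_response()] for prediction from the published equations.
#'
#' @param response optional response code (`"lc_al"`, `"favg_al"`,
#'   `"fstep_al"`, `"si_lc"`, `"si_favg"`, `"si_fstep"`) to filter to one
#'   model's rows.
#' @return Data frame: `response`, `term`, `estimate`, `ci_lo`, `ci_hi`,
#'   `se`, `t`, `p`.
#' @examples
#' head(reference_coefficients("lc_al"))
#' @export
reference_coefficients <- function(response = NULL) {
  tab <- read.csv(.extdata("reference_coefficients.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(response)) {
    if (!response %in% unique(tab$response))
      stop_("unknown response `%s`", response)
    tab <- tab[tab$response == response, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Published per-speed mean metrics of the benchmark study
#'
#' Affected-leg means of contact length, stance-average force and step
#' frequency, and the mean step-frequency symmetry index, at the endpoints
#' of the analysed speed range.
#'
#' @return Data frame with one row per reported speed.
#' @export
reference_speed_means <- function() {
  read.csv(.extdata("reference_speed_means.csv"), stringsAsFactors = FALSE)
}

#' Reproduce the benchmark study's statistics from a trial table
#'
#' Runs the statistics stage end to end on a per-trial analysis table: reads
#' and normalises the table (with an optional column mapping), summarizes
#' metrics by speed, fits the six mixed models, and compares per-speed means
#' and coefficient estimates against the published reference values shipped
#' with the package.
#'
#' @param table a trial-row data frame, or a path to a CSV readable by
#'   [read_analysis_table()].
#' @param mapping column mapping passed to [read_analysis_table()].
#' @param df_method degrees-of-freedom method for [fit_lmm()].
#' @return A list: `rows` (the analysed table), `n_trials`, `speed_summary`,
#'   `fits` (six `"rsp_lmm"` objects), `coef_comparison` (estimate vs
#'   reference per term and model, with differences) and `speed_comparison`.
#' @export
reproduce_study <- function(table, mapping = NULL,
                            df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  rows <- if (is.character(table)) read_analysis_table(table, mapping)
          else table
  fits <- fit_all_models(rows, df_method = df_method)
  speed_summary <- summarize_by_speed(rows)

  ref <- reference_coefficients()
  est <- do.call(rbind, lapply(names(fits), function(r) {
    cf <- fits[[r]]$coefficients
    data.frame(response = r, term = cf$term, fitted = cf$estimate,
               stringsAsFactors = FALSE)
  }))
  coef_comparison <- merge(ref[, c("response", "term", "estimate")], est,
                           by = c("response", "term"), sort = FALSE)
  names(coef_comparison)[names(coef_comparison) == "estimate"] <- "reference"
  coef_comparison$diff <- coef_comparison$fitted - coef_comparison$reference

  refv <- reference_speed_means()
  speed_comparison <- merge(refv, speed_summary, by = "speed",
                            suffixes = c("_ref", "_fitted"))

  list(rows = rows, n_trials = nrow(rows), speed_summary = speed_summary,
       fits = fits, coef_comparison = coef_comparison,
       speed_comparison = speed_comparison)
}
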
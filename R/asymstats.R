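# Linear mixed-effects analysis of per-trial gait metrics.
#
# Each response (affected-leg L_c, F_avg, f_step, or a symmetry index) is
# modelled with fixed effects for RSP model, RSP stiffness category, RSP
# height (cm relative to recommended), speed (m s^-1, uncentred) and the
# interaction of each of the first three with speed, plus a subject random
# intercept, fitted by REML. Treatment (dummy) coding with reference levels
# Catapult (model) and -1 (stiffness category).

#' Fixed-effect term labels of the study design
#'
#' Returns the design's term labels in their fixed column order, for given
#' reference levels. These labels name the coefficients everywhere: in
#' simulated-table configs, design matrices, fitted coefficient tables and
#' prediction inputs.
#'
#' @param model_ref,stiff_ref reference levels for the two categorical
#'   covariates.
#' @return Character vector of 12 term labels.
#' @examples
#' design_terms()
#' @export
design_terms <- function(model_ref = "Catapult", stiff_ref = "-1") {
  model_ref <- match.arg(model_ref, RSP_MODELS)
  stiff_ref <- match.arg(stiff_ref, STIFFNESS_CATS)
  mods <- setdiff(RSP_MODELS, model_ref)
  cats <- setdiff(STIFFNESS_CATS, stiff_ref)
  main <- c("intercept",
            sprintf("model [%s]", mods),
            sprintf("stiffness cat [%s]", cats),
            "height [cm]", "speed [m s^-1]")
  inter <- sprintf("%s*speed [m s^-1]",
                   c(sprintf("model [%s]", mods),
                     sprintf("stiffness cat [%s]", cats), "height [cm]"))
  c(main, inter)
}

#' Build the fixed-effects design matrix for a trial table
#'
#' Treatment coding with the stated reference levels; height passes through
#' as signed numeric cm (non-integer offsets untouched); speed is uncentred
#' in m s^-1; interaction columns are elementwise products. Column order is
#' fixed: intercept, model dummies, stiffness dummies, height, speed, then
#' the same order of interactions with speed.
#'
#' @param rows trial-table data frame with columns `rsp_model`,
#'   `stiffness_cat`, `height_offset_cm`, `speed`.
#' @inheritParams design_terms
#' @return Numeric matrix, one row per trial, columns named by
#'   [design_terms()].
#' @export
build_design <- function(rows, model_ref = "Catapult", stiff_ref = "-1") {
  req <- c("rsp_model", "stiffness_cat", "height_offset_cm", "speed")
  miss <- setdiff(req, names(rows))
  if (length(miss)) stop_("missing column(s): %s", paste(miss, collapse = ", "))
  model <- normalize_category(rows$rsp_model, RSP_MODELS, "RSP model")
  stiff <- normalize_category(rows$stiffness_cat, STIFFNESS_CATS,
                              "stiffness category")
  mods <- setdiff(RSP_MODELS, match.arg(model_ref, RSP_MODELS))
  cats <- setdiff(STIFFNESS_CATS, match.arg(stiff_ref, STIFFNESS_CATS))
  n <- nrow(rows)
  dummies <- function(x, levels)
    matrix(vapply(levels, function(l) as.numeric(x == l), numeric(n)),
           nrow = n)
  main <- cbind(rep(1, n), dummies(model, mods), dummies(stiff, cats),
                rows$height_offset_cm, rows$speed)
  X <- cbind(main, main[, 2:6, drop = FALSE] * rows$speed)
  colnames(X) <- design_terms(model_ref, stiff_ref)
  X
}

#' Fit a linear mixed-effects model to a trial table
#'
#' REML fit (via [lme4::lmer()]) of one response on the full fixed-effect
#' design of [build_design()] plus a subject random intercept. Returns a
#' coefficient table with estimates, Wald 95% confidence intervals, standard
#' errors, t- and p-values. Degrees of freedom are the residual df
#' (`n - p`) by default or the Satterthwaite approximation (via `lmerTest`).
#' Singular (boundary) variance estimates are flagged in the result, not
#' rejected; convergence failures are errors carrying the optimizer
#' diagnostics.
#'
#' @param rows trial-table data frame (one row per trial) with `subject` and
#'   the design covariates.
#' @param response name of the response column.
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @param conf_level confidence level for the Wald intervals.
#' @inheritParams design_terms
#' @return An object of class `"rsp_lmm"`: list with `coefficients` (data
#'   frame: `term`, `estimate`, `ci_lo`, `ci_hi`, `se`, `t`, `p`,
#'   `significant` at alpha = 0.05), `response`, `singular`, `sigma`,
#'   `subject_sd`, `n`, `df_method`, `model_ref`, `stiff_ref`, and the
#'   underlying `fit`.
#' @export
fit_lmm <- function(rows, response, df_method = c("residual", "satterthwaite"),
                    conf_level = 0.95, model_ref = "Catapult", stiff_ref = "-1") {
  df_method <- match.arg(df_method)
  if (!response %in% names(rows)) stop_("no response column `%s`", response)
  if (length(unique(rows$subject)) < 2L) stop_("need at least 2 subjects")
  X <- build_design(rows, model_ref, stiff_ref)
  terms <- colnames(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_("rank-deficient design; aliased term(s): %s",
          paste(terms[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))

  d <- as.data.frame(X[, -1, drop = FALSE])
  names(d) <- sprintf("x%02d", seq_len(ncol(X) - 1L))
  d$.y <- rows[[response]]
  d$.subject <- factor(rows$subject)
  form <- stats::as.formula(paste(".y ~", paste(names(d)[seq_len(ncol(X) - 1L)],
                                                collapse = " + "),
                                  "+ (1 | .subject)"))
  notes <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = TRUE),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      notes <<- c(notes, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code < 0)
    stop_("mixed-model fit did not converge: %s",
          paste(unlist(conv$messages), collapse = "; "))

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  if (df_method == "satterthwaite") {
    sm <- summary(lmerTest::as_lmerModLmerTest(fit))$coefficients
    dfs <- sm[, "df"]
  } else {
    dfs <- rep(nrow(rows) - ncol(X), ncol(X))
  }
  tval <- est / se
  pval <- 2 * pt(-abs(tval), dfs)
  q <- qt(1 - (1 - conf_level) / 2, dfs)
  coefs <- data.frame(
    term = terms, estimate = unname(est),
    ci_lo = unname(est - q * se), ci_hi = unname(est + q * se),
    se = unname(se), t = unname(tval), p = unname(pval),
    significant = unname(pval < 0.05),
    stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = coefs, response = response,
    singular = lme4::isSingular(fit),
    sigma = stats::sigma(fit),
    subject_sd = vc$sdcor[vc$grp == ".subject"][1],
    n = nrow(rows), df_method = df_method,
    conf_level = conf_level, model_ref = model_ref, stiff_ref = stiff_ref,
    notes = notes, fit = fit
  ), class = "rsp_lmm")
}

#' @export
print.rsp_lmm <- function(x, digits = 4, ...) {
  cat(sprintf("Linear mixed model (REML): %s ~ design + (1 | subject)\n",
              x$response))
  cat(sprintf("  %d trials, %s df, subject sd %.4g, residual sd %.4g%s\n",
              x$n, x$df_method, x$subject_sd, x$sigma,
              if (x$singular) " [singular fit]" else ""))
  out <- x$coefficients
  out$significant <- ifelse(out$significant, "*", "")
  print(format(out, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Population-level prediction from a fitted or published coefficient set
#'
#' Evaluates the fixed-effect linear predictor (random intercept at zero)
#' for new covariate rows. `predict_response()` accepts a bare named
#' coefficient vector or a coefficient data frame with `term`/`estimate`
#' columns, so predictions can also be made from a published coefficient
#' table.
#'
#' @param coefficients named numeric vector (names are term labels from
#'   [design_terms()]) or a data frame with `term` and `estimate` columns.
#'   Terms absent from the design are an error; design terms absent from
#'   `coefficients` contribute 0.
#' @param rows covariate rows (see [build_design()]).
#' @inheritParams design_terms
#' @return Numeric vector of predicted responses.
#' @examples
#' predict_response(c(intercept = 0.53, `speed [m s^-1]` = 0.066),
#'                  data.frame(rsp_model = "Catapult", stiffness_cat = "-1",
#'                             height_offset_cm = 0, speed = 3))
#' @export
predict_response <- function(coefficients, rows, model_ref = "Catapult",
                             stiff_ref = "-1") {
  if (is.data.frame(coefficients))
    coefficients <- setNames(coefficients$estimate, coefficients$term)
  terms <- design_terms(model_ref, stiff_ref)
  bad <- setdiff(names(coefficients), terms)
  if (length(bad)) stop_("unknown term(s): %s", paste(bad, collapse = ", "))
  X <- build_design(rows, model_ref, stiff_ref)
  beta <- setNames(numeric(length(terms)), terms)
  beta[names(coefficients)] <- coefficients
  drop(X %*% beta)
}

#' @rdname predict_response
#' @param object an `"rsp_lmm"` fit.
#' @param newdata covariate rows.
#' @param ... unused.
#' @export
predict.rsp_lmm <- function(object, newdata, ...) {
  predict_response(object$coefficients, newdata,
                   model_ref = object$model_ref, stiff_ref = object$stiff_ref)
}

#' Fit the six study models
#'
#' Fits the affected-leg contact length, stance-average force and step
#' frequency models and the three symmetry-index models on one trial table.
#'
#' @inheritParams fit_lmm
#' @return Named list of `"rsp_lmm"` fits: `lc_al`, `favg_al`, `fstep_al`,
#'   `si_lc`, `si_favg`, `si_fstep`.
#' @export
fit_all_models <- function(rows, df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  responses <- c("lc_al", "favg_al", "fstep_al", "si_lc", "si_favg", "si_fstep")
  miss <- setdiff(responses, names(rows))
  if (length(miss)) stop_("missing response column(s): %s",
                          paste(miss, collapse = ", "))
  setNames(lapply(responses, function(r) fit_lmm(rows, r, df_method)),
           responses)
}

#' Per-speed summary of a trial table
#'
#' Unweighted means over all contributing trials at each analysed speed,
#' reported separately per leg, plus mean symmetry indices and the number of
#' trials contributing. Empty speed cells are omitted with a warning.
#'
#' @param rows trial-table data frame.
#' @param speeds speeds (m s^-1) to summarize.
#' @return Data frame with one row per non-empty speed: `speed`, `n`,
#'   per-leg means of the three metrics, and mean SIs.
#' @export
summarize_by_speed <- function(rows, speeds = 3:7) {
  metrics <- c("lc_al", "lc_ul", "favg_al", "favg_ul", "fstep_al", "fstep_ul",
               "si_lc", "si_favg", "si_fstep")
  metrics <- intersect(metrics, names(rows))
  out <- lapply(speeds, function(v) {
    sub <- rows[rows$speed == v, , drop = FALSE]
    if (!nrow(sub)) {
      warning(sprintf("no trials at %g m/s; cell omitted", v), call. = FALSE)
      return(NULL)
    }
    cbind(data.frame(speed = v, n = nrow(sub)),
          as.data.frame(lapply(sub[metrics], mean)))
  })
  do.call(rbind, out)
}
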
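# Design coding, mixed-model fitting, prediction and per-speed summaries.

test_that("treatment coding uses the stated reference levels and order", {
  ref_row <- data.frame(rsp_model = "Catapult", stiffness_cat = "-1",
                        height_offset_cm = 0, speed = 3)
  X <- build_design(ref_row)
  expect_equal(colnames(X), design_terms())
  expect_equal(unname(X[1, ]), c(1, 0, 0, 0, 0, 0, 3, 0, 0, 0, 0, 0))
  full_row <- data.frame(rsp_model = "Xtend", stiffness_cat = "+1",
                         height_offset_cm = -2, speed = 7)
  expect_equal(unname(build_design(full_row)[1, ]),
               c(1, 0, 1, 0, 1, -2, 7, 0, 7, 0, 7, -14))
  # non-integer height offsets pass through untouched
  X2 <- build_design(data.frame(rsp_model = "Sprinter", stiffness_cat = "Rec",
                                height_offset_cm = -1.3, speed = 5))
  expect_equal(unname(X2[1, "height [cm]"]), -1.3)
  # typographic minus in category labels is normalised
  X3 <- build_design(data.frame(rsp_model = "Catapult",
                                stiffness_cat = "−1",
                                height_offset_cm = 0, speed = 3))
  expect_equal(unname(X3[1, ]), unname(X[1, ]))
  expect_error(build_design(data.frame(rsp_model = "Flex", stiffness_cat = "-1",
                                       height_offset_cm = 0, speed = 3)),
               "Flex")
})

test_that("a zero-signal table fits to zero slopes", {
  tab <- sim_table(truth = c(intercept = 0.5), subject_sd = 0, residual_sd = 0)
  fit <- fit_lmm(tab, "response")
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "intercept"], 0.5, tolerance = 1e-8)
  expect_lt(max(abs(cf$estimate[cf$term != "intercept"])), 1e-8)
})

test_that("fixed effects match OLS on balanced data without subject effects", {
  tab <- sim_table(subject_sd = 0, residual_sd = 0.02, seed = 5,
                   design = balanced_design())
  fit <- fit_lmm(tab, "response")
  X <- build_design(tab)
  ols <- lm(tab$response ~ X - 1)
  expect_lt(max(abs(fit$coefficients$estimate - unname(coef(ols)))), 1e-6)
  expect_true(fit$singular)   # boundary variance reported, not rejected
})

test_that("single-fit recovery is within sampling error of the truth", {
  truth <- lc_truth()
  tab <- sim_table(seed = 11)
  fit <- fit_lmm(tab, "response")
  cf <- fit$coefficients
  expect_false(fit$singular)
  expect_lt(max(abs(cf$estimate - unname(truth)) / cf$se), 4)
  # the well-identified terms are close in absolute terms too
  expect_equal(cf$estimate[cf$term == "speed [m s^-1]"],
               unname(truth["speed [m s^-1]"]), tolerance = 0.05)
})

test_that("changing the reference level shifts estimates by the contrast", {
  tab <- sim_table(seed = 3)
  f_cat <- fit_lmm(tab, "response")
  f_xt <- fit_lmm(tab, "response", model_ref = "Xtend")
  e1 <- setNames(f_cat$coefficients$estimate, f_cat$coefficients$term)
  e2 <- setNames(f_xt$coefficients$estimate, f_xt$coefficients$term)
  # Catapult-vs-Xtend estimate is minus the Xtend-vs-Catapult estimate
  expect_equal(e2[["model [Catapult]"]], -e1[["model [Xtend]"]],
               tolerance = 1e-8)
  expect_equal(e2[["model [Sprinter]"]], e1[["model [Sprinter]"]] - e1[["model [Xtend]"]],
               tolerance = 1e-8)
  expect_equal(e2[["intercept"]], e1[["intercept"]] + e1[["model [Xtend]"]],
               tolerance = 1e-8)
})

test_that("rank-deficient designs error with the aliased terms", {
  tab <- sim_table(seed = 2)
  tab$height_offset_cm <- 0          # height column aliased with nothing to estimate
  expect_error(fit_lmm(tab, "response"), "height")
})

test_that("prediction is the fixed-effect linear predictor", {
  # intercept-only: any covariates give the intercept
  expect_equal(predict_response(c(intercept = 2.5),
                                data.frame(rsp_model = "Sprinter",
                                           stiffness_cat = "+1",
                                           height_offset_cm = 2, speed = 6)),
               2.5)
  # speed slope s: prediction difference s (v2 - v1)
  rows <- data.frame(rsp_model = "Catapult", stiffness_cat = "-1",
                     height_offset_cm = 0, speed = c(3, 7))
  p <- predict_response(c(intercept = 1, `speed [m s^-1]` = 0.1), rows)
  expect_equal(diff(p), 0.4)
  expect_error(predict_response(c(gibberish = 1), rows), "gibberish")
  # published contact-length equation at the reference configuration, 3 m/s
  p3 <- predict_response(reference_coefficients("lc_al"), rows[1, ])
  expect_equal(p3, 0.53 + 0.066 * 3)
  # predict() on a fitted object reproduces cell means on noise-free data
  tab <- sim_table(truth = lc_truth(), subject_sd = 0, residual_sd = 0)
  fit <- fit_lmm(tab, "response")
  expect_equal(predict(fit, tab), tab$response, tolerance = 1e-6)
})

test_that("per-speed summaries are unweighted means with counts", {
  rows <- data.frame(
    subject = c("S01", "S02", "S03"), rsp_model = "Catapult",
    stiffness_cat = "-1", height_offset_cm = 0, speed = c(3, 3, 4),
    lc_al = c(0.66, 0.68, 0.80), lc_ul = c(0.70, 0.70, 0.82),
    si_lc = c(-5, -3, -1), stringsAsFactors = FALSE)
  s <- suppressWarnings(summarize_by_speed(rows))
  expect_equal(s$speed, c(3, 4))
  expect_equal(s$n, c(2, 1))
  expect_equal(s$lc_al, c(0.67, 0.80))
  expect_equal(s$si_lc, c(-4, -1))
  # single-row input equals that row
  expect_equal(s[s$speed == 4, "lc_ul"], 0.82)
  expect_warning(summarize_by_speed(rows, speeds = c(3, 5)), "no trials at 5")
})

test_that("the six study models fit a full synthetic table", {
  tab <- sim_table(seed = 4)
  tab$lc_al <- tab$response
  set.seed(99)
  for (m in c("favg_al", "fstep_al", "si_lc", "si_favg", "si_fstep"))
    tab[[m]] <- tab$response + rnorm(nrow(tab), 0, 1e-3)
  fits <- fit_all_models(tab)
  expect_named(fits, c("lc_al", "favg_al", "fstep_al",
                       "si_lc", "si_favg", "si_fstep"))
  expect_s3_class(fits$si_lc, "rsp_lmm")
})
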
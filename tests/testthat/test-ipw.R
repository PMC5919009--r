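# Shared fixture: cohort with age-driven tumor-data unavailability.
ipw_cohort <- local({
  cfg <- sim_config(
    n_cases = 600, missingness_rate = 0, seed = 71,
    effect_spec = list(rs1021737 = c(log(0.72), log(1.56), 0)),
    availability_spec = list(intercept = -2.8,
                             coefficients = c(age_dx = 0.05)))
  simulate_cohort(cfg)
})

test_that("availability model recovers its generating coefficients", {
  m <- fit_availability_model(ipw_cohort, covariates = c("age_dx"))
  sm <- summary(m$fit)$coefficients
  expect_lt(abs(sm["age_dx", "Estimate"] - 0.05),
            3 * sm["age_dx", "Std. Error"])
  expect_true(all(m$fitted_probs > 0 & m$fitted_probs <= 1))
  # constant covariate is reported by name
  coh2 <- ipw_cohort
  coh2$constcov <- 1
  expect_error(fit_availability_model(coh2, covariates = c("constcov")),
               "constcov")
})

test_that("degenerate availability raises an error", {
  coh <- simulate_cohort(tiny_config(seed = 72, n_cases = 50))
  expect_error(fit_availability_model(coh, covariates = "age_dx"),
               class = "mpe_degenerate_error")
})

test_that("weights follow the three-way IPW rule", {
  m <- fit_availability_model(ipw_cohort, covariates = c("age_dx"))
  w <- compute_weights(m, ipw_cohort)
  ctrl <- !ipw_cohort$is_case
  expect_true(all(w$weights[ipw_cohort$subject_id[ctrl]] == 1))
  unav <- ipw_cohort$is_case & ipw_cohort$subtype == "UNAVAILABLE"
  expect_true(all(w$weights[ipw_cohort$subject_id[unav]] == 0))
  avail <- ipw_cohort$is_case & ipw_cohort$subtype != "UNAVAILABLE"
  ids <- ipw_cohort$subject_id[avail]
  expect_equal(unname(w$weights[ids]), unname(1 / m$fitted_probs[ids]),
               tolerance = 1e-12)
  expect_true(all(w$weights[ids] >= 1))
})

test_that("weighted conditional logistic reduces to unweighted at unit weights", {
  coh <- simulate_cohort(tiny_config(
    seed = 73, n_cases = 200,
    effect_spec = list(rs1021737 = c(-0.4, 0.4, 0))))
  des <- matched_design(coh, "rs1021737", encoding = "per_allele")
  w1 <- rep(1, nrow(coh)); names(w1) <- coh$subject_id
  f0 <- subtype_specific_fit(des, het = FALSE)
  f1 <- subtype_specific_fit(des, het = FALSE, weights = w1)
  expect_equal(f0$per_subtype$logor, f1$per_subtype$logor, tolerance = 1e-10)
  expect_equal(f0$per_subtype$se, f1$per_subtype$se, tolerance = 1e-10)
})

test_that("balance check passes under modeled selection and shrinks real drivers", {
  m <- fit_availability_model(ipw_cohort,
                              covariates = c("age_dx", "stage", "sex"))
  bal <- balance_check(m, ipw_cohort)
  expect_true(all(c("term", "estimate", "se", "p") %in% names(bal$coefficients)))
  # weighted refit removes the age effect that drives availability
  age_unw <- abs(coef(m$fit)[["age_dx"]])
  age_w <- abs(bal$coefficients$estimate[bal$coefficients$term == "age_dx"])
  expect_lt(age_w, age_unw)
  expect_true(bal$balanced)
})

test_that("IPW corrects exposure-driven selection bias the complete case misses", {
  # availability depends on the exposure itself (log cystathionine), so the
  # complete-case subtype ORs are biased while IPW recovers the truth
  truth <- c(KRAS = 0.45, BRAF = 0.45, WT = 0.45)
  cfg <- sim_config(n_cases = 2500, missingness_rate = 0, seed = 74,
                    effect_spec = list(cystathionine = unname(truth)))
  coh <- simulate_cohort(cfg)
  coh$log_cysta <- log(coh$cystathionine)
  coh <- impose_tumor_unavailability(
    coh, list(intercept = 6.2, coefficients = c(log_cysta = -1.2)), seed = 5)
  des <- matched_design(coh, "cystathionine", encoding = "per_sd")
  cc <- subtype_specific_fit(des, het = FALSE)
  m <- fit_availability_model(coh, covariates = "log_cysta")
  w <- compute_weights(m, coh)
  ipw <- subtype_specific_fit(des, het = FALSE, weights = w)
  cc_tab <- cc$per_subtype; ipw_tab <- ipw$per_subtype
  # pooled bias across subtypes: complete case biased, IPW within 3 SEs
  cc_bias <- abs(cc_tab$logor - truth[cc_tab$subtype]) / cc_tab$se
  ipw_bias <- abs(ipw_tab$logor - truth[ipw_tab$subtype]) / ipw_tab$se
  expect_gt(max(cc_bias), 2)
  expect_true(all(ipw_bias < 3))
})

test_that("complete-case / IPW comparison summarizes paired log-ORs", {
  tab <- data.frame(exposure = "x", subtype = c("KRAS", "BRAF"),
                    logor = c(0.2, -0.1))
  cmp0 <- compare_complete_case_vs_ipw(tab, tab)
  expect_equal(cmp0$max_abs_diff, 0)
  tab2 <- tab; tab2$logor <- tab$logor + c(0.05, -0.02)
  cmp1 <- compare_complete_case_vs_ipw(tab, tab2)
  expect_equal(cmp1$max_abs_diff, 0.05, tolerance = 1e-12)
  expect_equal(cmp1$mean_abs_diff, 0.035, tolerance = 1e-12)
  tab3 <- tab; tab3$subtype <- c("KRAS", "WT")
  expect_error(compare_complete_case_vs_ipw(tab, tab3),
               class = "mpe_config_error")
})

test_that("sandwich SEs are available and sane for weighted fits", {
  coh <- simulate_cohort(tiny_config(
    seed = 75, n_cases = 300,
    effect_spec = list(rs1021737 = c(-0.4, 0.4, 0))))
  des <- matched_design(coh, "rs1021737", encoding = "per_allele")
  w <- rep(1, nrow(coh)); names(w) <- coh$subject_id
  fit <- weighted_clogit(des, w, robust = TRUE)
  expect_true(all(is.finite(fit$se_robust)) && all(fit$se_robust > 0))
  # at unit weights the sandwich collapses toward the model-based SE
  expect_lt(abs(fit$se_robust[1] / fit$se[1] - 1), 0.25)
  # with informative weights the two genuinely differ but stay comparable
  w2 <- w; w2[coh$is_case] <- runif(sum(coh$is_case), 0.5, 3)
  fit2 <- weighted_clogit(des, w2, robust = TRUE)
  expect_true(all(is.finite(fit2$se_robust)))
})
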
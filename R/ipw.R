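#' Fit the tumor-data availability model
#'
#' Logistic regression, among cases only, of the indicator "tumor data
#' available" (`subtype != "UNAVAILABLE"`) on case covariates (emulating
#' tumor stage, site, age and year at diagnosis, cohort, sex). Cases with
#' missing model covariates are excluded and counted.
#'
#' @param cohort An `mpe_cohort` (or compatible data frame).
#' @param covariates Character vector of case covariates; `sex`, `cohort`
#'   and `site` are encoded internally, other names must be numeric
#'   columns of the cohort.
#' @return Object of class `availability_model`: `fit` (the `glm`),
#'   `coefficients`, `fitted_probs` (named by `subject_id`),
#'   `n_excluded_missing_covariates`, `covariates`.
#' @export
fit_availability_model <- function(cohort,
                                   covariates = c("stage", "site", "age_dx",
                                                  "year_dx", "cohort", "sex")) {
  cases <- as.data.frame(cohort)[cohort$is_case, , drop = FALSE]
  if (!nrow(cases)) stop_mpe("cohort contains no cases", "mpe_config_error")
  avail <- cases$subtype != "UNAVAILABLE"
  if (all(avail) || !any(avail))
    stop_mpe("availability is degenerate (all or none available)",
             "mpe_degenerate_error")
  X <- encode_case_covariates(cases, covariates)
  ok <- stats::complete.cases(X)
  n_excl <- sum(!ok)
  Xc <- X[ok, , drop = FALSE]
  constant <- apply(Xc, 2, function(v) max(v) - min(v)) == 0
  if (any(constant))
    stop_mpe(paste0("availability covariate constant across cases: ",
                    paste(colnames(Xc)[constant], collapse = ", ")),
             "mpe_estimation_error")
  dat <- data.frame(avail = avail[ok], Xc)
  fit <- stats::glm(avail ~ ., data = dat, family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15))
    stop_mpe("availability model diverged (possible separation)",
             "mpe_separation_error")
  probs <- stats::fitted(fit)
  names(probs) <- cases$subject_id[ok]
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 fitted_probs = probs,
                 n_excluded_missing_covariates = n_excl,
                 covariates = covariates),
            class = "availability_model")
}

#' Inverse-probability weights for tumor-data selection
#'
#' Weight 1 for controls; `1/p_i` for cases with available tumor data
#' (with `p_i` the fitted availability probability); 0 for cases without
#' available tumor data. Cases excluded from the availability fit for
#' missing covariates also receive weight 0 and are counted.
#'
#' @param model An [fit_availability_model()] result.
#' @param cohort The cohort the model was fitted on.
#' @return Object of class `weight_assignment`: `weights` (named by
#'   `subject_id`), `n_zero_weight_cases`, `n_excluded_missing_covariates`.
#' @export
compute_weights <- function(model, cohort) {
  stopifnot(inherits(model, "availability_model"))
  w <- rep(1, nrow(cohort))
  names(w) <- cohort$subject_id
  ci <- which(cohort$is_case)
  w[ci] <- 0
  avail_cases <- cohort$subject_id[ci][cohort$subtype[ci] != "UNAVAILABLE"]
  known <- intersect(avail_cases, names(model$fitted_probs))
  p <- model$fitted_probs[known]
  if (any(p <= 0)) stop_mpe("fitted availability probability of 0 gives an undefined weight",
                            "mpe_domain_error")
  w[known] <- 1 / p
  structure(list(weights = w,
                 n_zero_weight_cases = sum(w[ci] == 0),
                 n_excluded_missing_covariates =
                   model$n_excluded_missing_covariates),
            class = "weight_assignment")
}

#' Weighted conditional logistic regression
#'
#' Maximizes the case-weighted conditional log-likelihood
#' `sum over sets of w_case * [eta_case - log sum exp(eta)]`. With unit
#' weights this reproduces [clogit_fit()] exactly; with
#' inverse-availability weights it is the selection-bias-adjusted
#' estimator. Point estimates are invariant to rescaling all weights.
#'
#' @param design A [matched_design()].
#' @param weights A [compute_weights()] result, or a numeric vector of
#'   per-subject weights named by subject id (the case's weight is used
#'   for its set).
#' @param robust Logical: also report sandwich standard errors (see
#'   [clogit_fit()]).
#' @return An `mpe_clogit` fit.
#' @export
weighted_clogit <- function(design, weights, robust = FALSE) {
  stopifnot(inherits(design, "matched_design"))
  wvec <- if (inherits(weights, "weight_assignment")) weights$weights else weights
  if (is.null(names(wvec)))
    stop_mpe("weights must be named by subject_id", "mpe_config_error")
  case_rows <- which(design$case)
  w_set <- rep(NA_real_, max(design$set))
  w_case <- wvec[design$subject_id[case_rows]]
  if (anyNA(w_case))
    stop_mpe("missing weight for one or more cases", "mpe_config_error")
  w_set[design$set[case_rows]] <- w_case
  clogit_fit(design, weights = unname(w_set), robust = robust)
}

#' Covariate-balance check of the availability model
#'
#' Refits the availability model weighted by `1/p_i` for cases with
#' available tumor data and `1/(1 - p_i)` for cases without. If the model
#' captures the selection mechanism, the weighted pseudo-population is
#' balanced and all covariate coefficients are statistically null.
#'
#' @param model An [fit_availability_model()] result.
#' @param cohort The cohort the model was fitted on.
#' @param p_threshold Coefficient p-values above this level count as
#'   balanced (default 0.2).
#' @return Object of class `balance_report`: `coefficients` (data frame
#'   with `term`, `estimate`, `se`, `p`), `balanced` (logical).
#' @export
balance_check <- function(model, cohort, p_threshold = 0.2) {
  stopifnot(inherits(model, "availability_model"))
  cases <- as.data.frame(cohort)[cohort$is_case, , drop = FALSE]
  X <- encode_case_covariates(cases, model$covariates)
  ok <- stats::complete.cases(X)
  cases <- cases[ok, , drop = FALSE]
  X <- X[ok, , drop = FALSE]
  avail <- cases$subtype != "UNAVAILABLE"
  p <- model$fitted_probs[cases$subject_id]
  if (any(p <= 0 | p >= 1))
    stop_mpe("fitted probabilities at 0 or 1 give undefined balance weights",
             "mpe_domain_error")
  w <- ifelse(avail, 1 / p, 1 / (1 - p))
  dat <- data.frame(avail = avail, X)
  refit <- suppressWarnings(
    stats::glm(avail ~ ., data = dat, family = stats::binomial(), weights = w)
  )
  sm <- suppressWarnings(summary(refit)$coefficients)
  terms <- rownames(sm)[-1]
  coefs <- data.frame(term = terms,
                      estimate = sm[-1, "Estimate"],
                      se = sm[-1, "Std. Error"],
                      p = sm[-1, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs,
                 balanced = all(coefs$p > p_threshold),
                 p_threshold = p_threshold),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("IPW balance check (weighted availability-model refit)\n")
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), p = round(p, 4)), row.names = FALSE)
  cat(if (x$balanced) sprintf("balanced: all p > %.2f\n", x$p_threshold)
      else "NOT balanced\n")
  invisible(x)
}

#' Compare complete-case and IPW subtype odds ratios
#'
#' Pairs the per-subtype log-ORs from the complete-case and IPW analyses
#' for the same exposures, fits a regression line through the pairs
#' (alongside the identity line of no selection effect), and summarizes
#' the mean and maximum absolute log-OR difference.
#'
#' @param results_cc,results_ipw Data frames with columns `exposure`,
#'   `subtype`, `logor` (e.g. stacked `per_subtype` tables).
#' @return Object of class `ipw_comparison`: `pairs`, `slope`,
#'   `intercept`, `mean_abs_diff`, `max_abs_diff`.
#' @export
compare_complete_case_vs_ipw <- function(results_cc, results_ipw) {
  key_cc <- paste(results_cc$exposure, results_cc$subtype)
  key_ipw <- paste(results_ipw$exposure, results_ipw$subtype)
  if (!setequal(key_cc, key_ipw))
    stop_mpe("complete-case and IPW results cover different exposure/subtype pairs",
             "mpe_config_error")
  m <- match(key_cc, key_ipw)
  pairs <- data.frame(exposure = results_cc$exposure,
                      subtype = results_cc$subtype,
                      logor_cc = results_cc$logor,
                      logor_ipw = results_ipw$logor[m],
                      stringsAsFactors = FALSE)
  diffs <- abs(pairs$logor_ipw - pairs$logor_cc)
  line <- if (nrow(pairs) >= 2 && stats::sd(pairs$logor_cc) > 0)
    stats::coef(stats::lm(logor_ipw ~ logor_cc, data = pairs))
  else c(`(Intercept)` = NA_real_, logor_cc = NA_real_)
  structure(list(pairs = pairs,
                 intercept = unname(line[1]), slope = unname(line[2]),
                 mean_abs_diff = mean(diffs), max_abs_diff = max(diffs)),
            class = "ipw_comparison")
}

#' @export
print.ipw_comparison <- function(x, ...) {
  cat(sprintf("Complete-case vs IPW log-ORs: %d pairs, mean |diff| %.4f, max |diff| %.4f\n",
              nrow(x$pairs), x$mean_abs_diff, x$max_abs_diff))
  if (is.finite(x$slope))
    cat(sprintf("  fitted line: ipw = %.3f + %.3f * cc (identity = 0 + 1 * cc)\n",
                x$intercept, x$slope))
  invisible(x)
}
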
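#' Fit a control-based tertile (or quartile) discretization rule
#'
#' Cutpoints are empirical quantiles of the *control* distribution
#' (inverse-ECDF quantiles, R type 1), so that applying the rule to the
#' controls themselves yields groups as equal as ties permit. Values are
#' assigned with right-closed intervals: a value equal to a cutpoint stays
#' in the lower group.
#'
#' @param values_controls Non-missing control values (length >= 3).
#' @param n_groups 3 for tertiles (default) or 4 for quartiles.
#' @param variable Optional variable name stored in the rule.
#' @return An object of class `tertile_rule` with fields `variable`,
#'   `cutpoints`, `labels`, `source = "controls"`.
#' @examples
#' fit_tertile_rule(1:9)$cutpoints   # 3, 6
#' @export
fit_tertile_rule <- function(values_controls, n_groups = 3L,
                             variable = NA_character_) {
  x <- values_controls[!is.na(values_controls)]
  if (length(x) < n_groups)
    stop_mpe("need at least n_groups non-missing control values",
             "mpe_degenerate_rule")
  probs <- seq_len(n_groups - 1L) / n_groups
  cut <- unname(stats::quantile(x, probs, type = 1))
  if (any(diff(c(-Inf, cut, Inf)) <= 0) || anyDuplicated(cut) ||
      min(x) == max(x))
    stop_mpe(paste0("variable cannot be discretized: cutpoints not strictly ",
                    "increasing (no spread in controls)"), "mpe_degenerate_rule")
  labels <- if (n_groups == 3L) c("T1", "T2", "T3") else paste0("Q", seq_len(n_groups))
  structure(list(variable = variable, cutpoints = cut, labels = labels,
                 source = "controls"),
            class = "tertile_rule")
}

#' Apply a discretization rule
#'
#' @param rule A [fit_tertile_rule()] object.
#' @param values Numeric values (may contain `NA`).
#' @return Ordered factor with the rule's labels; `NA` stays `NA`.
#' @export
apply_tertile_rule <- function(rule, values) {
  stopifnot(inherits(rule, "tertile_rule"))
  g <- findInterval(values, rule$cutpoints, left.open = TRUE) + 1L
  factor(rule$labels[g], levels = rule$labels, ordered = TRUE)
}

#' Standardize a concentration to control log-scale SD units
#'
#' Returns `(log(values) - mean(log(controls))) / sd(log(controls))`. One
#' unit of the returned scale is the "per 1 SD" contrast used for
#' biomarker odds ratios.
#'
#' @param values Positive concentrations to standardize.
#' @param controls Positive control concentrations defining the scale.
#' @return Numeric vector of standardized exposures.
#' @export
standardize_per_sd <- function(values, controls) {
  ctrl <- controls[!is.na(controls)]
  if (any(ctrl <= 0, na.rm = TRUE) || any(values <= 0, na.rm = TRUE))
    stop_mpe("concentrations must be positive for log-scale standardization",
             "mpe_domain_error")
  lc <- log(ctrl)
  s <- stats::sd(lc)
  if (!is.finite(s) || s == 0)
    stop_mpe("control log-SD is zero; cannot standardize", "mpe_degenerate_rule")
  (log(values) - mean(lc)) / s
}

#' Encode a SNP allele count
#'
#' Additive coding returns the variant-allele count itself (the "per
#' allele" contrast of the regression models); dominant coding returns 1
#' for carriers of any variant allele (the dichotomy used by the network
#' stage).
#'
#' @param allele_count Integer vector with values in `{0, 1, 2}` (or `NA`).
#' @param mode `"additive"` or `"dominant"`.
#' @return Numeric vector.
#' @export
encode_genotype <- function(allele_count, mode = c("additive", "dominant")) {
  mode <- match.arg(mode)
  ok <- is.na(allele_count) | allele_count %in% c(0, 1, 2)
  if (!all(ok))
    stop_mpe("allele counts must be 0, 1, 2 or missing", "mpe_domain_error")
  if (mode == "additive") as.numeric(allele_count)
  else as.numeric(allele_count >= 1)
}

#' Cockcroft-Gault creatinine clearance
#'
#' `(140 - age) * weight / (72 * creatinine)`, multiplied by 0.85 for
#' females; creatinine in mg/dL (set `creatinine_umol_l = TRUE` to convert
#' from umol/L by dividing by 88.4). Result in mL/min.
#'
#' @param age Years (> 0, < 140).
#' @param weight Kilograms (> 0).
#' @param creatinine Plasma creatinine (> 0).
#' @param sex `"male"` or `"female"` (vectorized).
#' @param creatinine_umol_l Logical; input creatinine is in umol/L.
#' @return Estimated glomerular filtration rate, mL/min.
#' @examples
#' compute_egfr_cockcroft_gault(40, 72, 1.0, "male")    # 100
#' compute_egfr_cockcroft_gault(40, 72, 1.0, "female")  # 85
#' @export
compute_egfr_cockcroft_gault <- function(age, weight, creatinine, sex,
                                         creatinine_umol_l = FALSE) {
  if (any(age <= 0) || any(weight <= 0) || any(creatinine <= 0))
    stop_mpe("age, weight and creatinine must be positive", "mpe_domain_error")
  cr <- if (creatinine_umol_l) creatinine / 88.4 else creatinine
  egfr <- (140 - age) * weight / (72 * cr)
  ifelse(sex == "female", 0.85 * egfr, egfr)
}

#' Assign missing values of a lifestyle covariate to a "missing" category
#'
#' @param values Character or factor vector, possibly with `NA`.
#' @return Character vector with `NA` replaced by `"missing"`.
#' @export
assign_missing_category <- function(values) {
  out <- as.character(values)
  out[is.na(out)] <- "missing"
  if (all(out == "missing") && length(out))
    warning("all values missing: single-level 'missing' variable")
  out
}

#' Build the fully categorical dataset for network learning
#'
#' Derives the discrete analysis variables: biomarkers (and eGFR) as
#' control-based tertiles, SNPs dominant-coded, age and year of sampling in
#' control-based quartile groups, BMI in bands `<25`, `[25,30)`, `>=30`,
#' smoking and fasting as given, lifestyle covariates with an explicit
#' `"missing"` level, and a 4-level outcome node
#' (`control`/`KRAS`/`BRAF`/`WT`). Cases whose tumor data are unavailable
#' are excluded, and rows with any missing biomarker or SNP are dropped
#' (complete-case), with counts reported.
#'
#' @param cohort An `mpe_cohort`.
#' @param biomarkers,snps Character vectors of exposure column names;
#'   default taken from the cohort attributes.
#' @param covariates Character vector of covariate nodes to include, any of
#'   `"sex"`, `"cohort"`, `"fasting"`, `"age_group"`, `"year_group"`,
#'   `"bmi_band"`, `"smoking"`, `"egfr_tertile"`, `"alcohol"`,
#'   `"pa_recreational"`, `"pa_occupational"`.
#' @param rules Optional named list of pre-fitted [fit_tertile_rule()]s to
#'   re-apply; by default rules are fitted on the controls of `cohort`.
#' @return A list of class `discrete_dataset`: `data` (data frame of
#'   factors, outcome column `outcome`), `rules`, `n_dropped_cases`,
#'   `n_dropped_controls`, `n_unavailable_excluded`.
#' @export
build_discrete_dataset <- function(cohort,
                                   biomarkers = attr(cohort, "biomarkers"),
                                   snps = attr(cohort, "snps"),
                                   covariates = c("sex", "cohort", "fasting",
                                                  "age_group", "year_group",
                                                  "bmi_band", "smoking"),
                                   rules = NULL) {
  stopifnot(is.data.frame(cohort))
  if (is.null(biomarkers) || is.null(snps))
    stop_mpe("biomarker/SNP column lists are required", "mpe_config_error")

  keep <- !(cohort$is_case & cohort$subtype == "UNAVAILABLE")
  n_unavail <- sum(!keep)
  d <- cohort[keep, , drop = FALSE]
  is_ctrl <- !d$is_case

  fitted_rules <- list()
  get_rule <- function(name, values) {
    if (!is.null(rules)) {
      if (is.null(rules[[name]]))
        stop_mpe(paste0("no discretization rule supplied for ", name),
                 "mpe_config_error")
      rules[[name]]
    } else {
      fit_tertile_rule(values[is_ctrl], variable = name)
    }
  }

  out <- data.frame(row.names = seq_len(nrow(d)))
  for (b in biomarkers) {
    r <- get_rule(b, d[[b]])
    fitted_rules[[b]] <- r
    out[[b]] <- apply_tertile_rule(r, d[[b]])
  }
  for (s in snps) {
    out[[s]] <- factor(ifelse(is.na(d[[s]]), NA,
                              ifelse(d[[s]] >= 1, "variant", "common")),
                       levels = c("common", "variant"))
  }

  if ("egfr_tertile" %in% covariates) {
    egfr <- compute_egfr_cockcroft_gault(d$age_at_sampling, d$weight_kg,
                                         d$creatinine, d$sex)
    r <- get_rule("egfr", egfr)
    fitted_rules[["egfr"]] <- r
    out[["egfr_tertile"]] <- apply_tertile_rule(r, egfr)
  }
  if ("age_group" %in% covariates) {
    r <- get_rule("age", d$age_at_sampling)
    if (is.null(rules)) {
      r <- fit_tertile_rule(d$age_at_sampling[is_ctrl], n_groups = 4L,
                            variable = "age")
    }
    fitted_rules[["age"]] <- r
    out[["age_group"]] <- apply_tertile_rule(r, d$age_at_sampling)
  }
  if ("year_group" %in% covariates) {
    r <- if (is.null(rules))
      fit_tertile_rule(d$year_sampling[is_ctrl], n_groups = 4L, variable = "year")
    else get_rule("year", d$year_sampling)
    fitted_rules[["year"]] <- r
    out[["year_group"]] <- apply_tertile_rule(r, d$year_sampling)
  }
  if ("bmi_band" %in% covariates)
    out[["bmi_band"]] <- cut(d$bmi, c(-Inf, 25, 30, Inf),
                             labels = c("<25", "25-30", ">=30"), right = FALSE)
  if ("smoking" %in% covariates)
    out[["smoking"]] <- factor(assign_missing_category(d$smoking))
  if ("sex" %in% covariates) out[["sex"]] <- factor(d$sex)
  if ("cohort" %in% covariates) out[["cohort"]] <- factor(d$cohort)
  if ("fasting" %in% covariates) out[["fasting"]] <- factor(d$fasting)
  for (v in intersect(c("alcohol", "pa_recreational", "pa_occupational"),
                      covariates))
    out[[v]] <- factor(assign_missing_category(d[[v]]))

  out[["outcome"]] <- factor(ifelse(d$is_case, d$subtype, "control"),
                             levels = c("control", "KRAS", "BRAF", "WT"))

  ## complete-case on the exposures (biomarkers + SNPs)
  expo_cols <- c(biomarkers, snps)
  complete <- stats::complete.cases(out[, expo_cols, drop = FALSE])
  n_drop_case <- sum(!complete & d$is_case)
  n_drop_ctrl <- sum(!complete & !d$is_case)
  out <- out[complete, , drop = FALSE]
  out <- droplevels(out)

  structure(list(
    data = out,
    rules = fitted_rules,
    exposures = expo_cols,
    n_dropped_cases = n_drop_case,
    n_dropped_controls = n_drop_ctrl,
    n_unavailable_excluded = n_unavail
  ), class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  tab <- table(x$data$outcome)
  cat(sprintf("Discrete dataset: %d rows x %d variables\n",
              nrow(x$data), ncol(x$data)))
  cat("  outcome:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  dropped for missing exposures: %d cases, %d controls; %d cases excluded (tumor data unavailable)\n",
              x$n_dropped_cases, x$n_dropped_controls, x$n_unavailable_excluded))
  invisible(x)
}

#' Write / read the discretization rules
#'
#' @param rules Named list of `tertile_rule`s (e.g. from
#'   [build_discrete_dataset()]).
#' @param path YAML file path.
#' @return `read_rules()` returns the named rule list.
#' @export
write_rules <- function(rules, path) {
  # cutpoints serialized at full precision so re-applied rules are identical
  yaml::write_yaml(lapply(rules, function(r) {
    list(variable = r$variable, cutpoints = sprintf("%.17g", r$cutpoints),
         labels = r$labels, source = r$source)
  }), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    structure(list(variable = r$variable,
                   cutpoints = as.numeric(unlist(r$cutpoints)),
                   labels = unlist(r$labels), source = r$source),
              class = "tertile_rule")
  })
}
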
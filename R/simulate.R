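#' Simulate a matched case-control cohort with known ground truth
#'
#' Generates a cohort with the structure of a nested case-control study of
#' molecularly defined tumor subtypes: matched sets of one case and
#' `controls_per_case` controls sharing sex, cohort, fasting status, year
#' of sampling, and age within a caliper; correlated multivariate
#' log-normal biomarkers; Hardy-Weinberg genotypes; and case status
#' assigned by a within-set conditional logit so that the generating
#' mechanism matches the conditional-likelihood estimator exactly.
#'
#' Within each candidate set a subtype is drawn from `subtype_probs`, and
#' the case is then selected among the set members with probability
#' proportional to `exp(eta_i)`, where `eta_i` sums the subtype-specific
#' effects in `effect_spec` over that member's exposures (per 1 SD of the
#' log biomarker, per variant allele of a SNP). The designated SNP
#' multiplies its metabolite's concentration by
#' `snp_metabolite_effect^allele_count` before selection. Tumor-data
#' availability is then assigned to cases by the logistic model in
#' `availability_spec`, and missingness is applied completely at random per
#' exposure.
#'
#' @param config A [sim_config()] object.
#' @return A data frame of class `mpe_cohort`, one row per subject, with
#'   columns `subject_id`, `set_id`, `is_case`, `subtype` (one of
#'   `"KRAS"`, `"BRAF"`, `"WT"`, `"UNAVAILABLE"` for cases, `"NONE"` for
#'   controls), `subtype_true` (the pre-unavailability truth channel),
#'   matching variables, lifestyle covariates, tumor covariates (cases
#'   only), the biomarker concentrations, and the SNP allele counts.
#'   Attributes `config` and `truth` carry the generating configuration
#'   and effect specification.
#' @examples
#' coh <- simulate_cohort(sim_config(n_cases = 30, seed = 7))
#' table(coh$is_case)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 6L)
  n_sets <- config$n_cases
  m <- 1L + config$controls_per_case
  n <- n_sets * m

  ## --- matched-set frame: matching variables shared within set ----------
  set.seed(seeds[1])
  set_sex <- sample(c("male", "female"), n_sets, replace = TRUE)
  set_cohort <- sample(c("VIP", "MSP"), n_sets, replace = TRUE, prob = c(0.7, 0.3))
  set_fasting <- sample(c("<4h", "4-8h", ">=8h"), n_sets, replace = TRUE,
                        prob = c(0.3, 0.2, 0.5))
  set_age <- pmin(pmax(stats::rnorm(n_sets, 60, 7), 40), 75)
  set_year <- sample(1990:2008, n_sets, replace = TRUE)
  set_subtype <- sample(c("KRAS", "BRAF", "WT"), n_sets, replace = TRUE,
                        prob = config$subtype_probs)

  set_id <- rep(seq_len(n_sets), each = m)
  age <- rep(set_age, each = m) +
    stats::runif(n, -config$age_caliper, config$age_caliper)
  sex <- rep(set_sex, each = m)

  ## --- subject-level covariates ----------------------------------------
  bmi <- pmin(pmax(stats::rnorm(n, 25.7, 3.9), 16), 48)
  weight <- ifelse(sex == "male", stats::rnorm(n, 82, 11), stats::rnorm(n, 68, 11))
  weight <- pmax(weight, 40)
  creatinine <- exp(stats::rnorm(n, ifelse(sex == "male", log(1.00), log(0.85)), 0.14))
  smoking <- sample(c("never", "ex", "current"), n, replace = TRUE,
                    prob = c(0.45, 0.3, 0.25))
  alcohol <- sample(c("zero", "below_median", "above_median"), n,
                    replace = TRUE, prob = c(0.15, 0.45, 0.40))
  pa_recreational <- sample(paste0("PA", 1:5), n, replace = TRUE)
  pa_occupational <- sample(paste0("OPA", 1:5), n, replace = TRUE)

  ## --- biomarkers: correlated multivariate log-normal -------------------
  set.seed(seeds[2])
  bspec <- config$biomarker_spec
  p <- nrow(bspec)
  L <- chol(config$biomarker_cor)
  z <- matrix(stats::rnorm(n * p), n, p) %*% L
  logconc <- sweep(sweep(z, 2, bspec$log_sd, `*`), 2, bspec$log_mean, `+`)
  colnames(logconc) <- bspec$name

  ## --- genotypes: Hardy-Weinberg binomial(2, maf) -----------------------
  set.seed(seeds[3])
  sspec <- config$snp_spec
  geno <- vapply(sspec$maf, function(q) stats::rbinom(n, 2L, q),
                 integer(n))
  colnames(geno) <- sspec$name

  ## designated SNP shifts its metabolite multiplicatively per allele
  snp <- config$snp_metabolite_pair[1]
  met <- config$snp_metabolite_pair[2]
  logconc[, met] <- logconc[, met] + geno[, snp] * log(config$snp_metabolite_effect)
  conc <- exp(logconc)

  ## --- within-set conditional-logit case selection ----------------------
  set.seed(seeds[4])
  eta <- numeric(n)
  if (length(config$effect_spec)) {
    beta_sub <- rep(match(set_subtype, c("KRAS", "BRAF", "WT")), each = m)
    for (ex in names(config$effect_spec)) {
      b <- config$effect_spec[[ex]][beta_sub]
      if (ex %in% bspec$name) {
        i <- match(ex, bspec$name)
        x <- (logconc[, ex] - bspec$log_mean[i]) / bspec$log_sd[i]
      } else {
        x <- geno[, ex]
      }
      eta <- eta + b * x
    }
  }
  is_case <- logical(n)
  idx <- matrix(seq_len(n), nrow = m)          # column s = members of set s
  w <- exp(matrix(eta, nrow = m) - rep(apply(matrix(eta, nrow = m), 2, max), each = m))
  pick <- apply(w, 2, function(ws) sample.int(m, 1L, prob = ws))
  is_case[idx[cbind(pick, seq_len(n_sets))]] <- TRUE

  subtype <- rep("NONE", n)
  subtype[is_case] <- set_subtype

  ## --- tumor covariates (cases only) ------------------------------------
  set.seed(seeds[5])
  stage <- rep(NA_integer_, n)
  site <- rep(NA_character_, n)
  year_dx <- rep(NA_real_, n)
  ci <- which(is_case)
  stage[ci] <- sample(1:4, n_sets, replace = TRUE, prob = c(0.15, 0.35, 0.30, 0.20))
  site[ci] <- sample(c("right_colon", "left_colon", "rectum"), n_sets,
                     replace = TRUE, prob = c(0.35, 0.30, 0.35))
  year_dx[ci] <- set_year + pmin(stats::rpois(n_sets, 7), 20)
  age_dx <- rep(NA_real_, n)
  age_dx[ci] <- age[ci] + (year_dx[ci] - set_year)

  cohort_df <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    set_id = set_id,
    is_case = is_case,
    subtype = subtype,
    subtype_true = subtype,
    sex = sex,
    age_at_sampling = age,
    year_sampling = rep(set_year, each = m),
    cohort = rep(set_cohort, each = m),
    fasting = rep(set_fasting, each = m),
    bmi = bmi,
    weight_kg = weight,
    creatinine = creatinine,
    smoking = smoking,
    alcohol = alcohol,
    pa_recreational = pa_recreational,
    pa_occupational = pa_occupational,
    stage = stage,
    site = site,
    year_dx = year_dx,
    age_dx = age_dx,
    stringsAsFactors = FALSE
  )
  cohort_df <- cbind(cohort_df, as.data.frame(conc), as.data.frame(geno))

  attr(cohort_df, "config") <- config
  attr(cohort_df, "truth") <- config$effect_spec
  attr(cohort_df, "biomarkers") <- bspec$name
  attr(cohort_df, "snps") <- sspec$name
  class(cohort_df) <- c("mpe_cohort", "data.frame")

  ## --- tumor-data availability ------------------------------------------
  cohort_df <- impose_tumor_unavailability(cohort_df, config$availability_spec,
                                           seed = seeds[5] %% 2147483L + 1L)

  ## --- MCAR missingness per exposure ------------------------------------
  if (config$missingness_rate > 0) {
    set.seed(seeds[6])
    for (v in c(bspec$name, sspec$name)) {
      miss <- stats::runif(n) < config$missingness_rate
      cohort_df[[v]][miss] <- NA
    }
  }
  cohort_df
}

# Numeric encoding of case covariates for the availability model.
# sex: female=1; cohort: MSP=1; site: indicators for right colon / rectum
# (left colon reference). Numeric columns pass through.
encode_case_covariates <- function(cases, covariates) {
  out <- matrix(0, nrow(cases), 0)
  for (v in covariates) {
    if (v == "sex") {
      out <- cbind(out, sex_female = as.numeric(cases$sex == "female"))
    } else if (v == "cohort") {
      out <- cbind(out, cohort_msp = as.numeric(cases$cohort == "MSP"))
    } else if (v == "site") {
      out <- cbind(out,
                   site_right = as.numeric(cases$site == "right_colon"),
                   site_rectum = as.numeric(cases$site == "rectum"))
    } else if (v %in% names(cases) && is.numeric(cases[[v]])) {
      x <- cases[[v]]
      out <- cbind(out, stats::setNames(matrix(x, ncol = 1), v))
      colnames(out)[ncol(out)] <- v
    } else {
      stop_mpe(paste0("availability model references unknown covariate: ", v),
               "mpe_config_error")
    }
  }
  out
}

#' Replace case subtypes by "UNAVAILABLE" via a logistic availability model
#'
#' Each case keeps its tumor data with probability
#' `expit(intercept + sum(coefficients * covariates))`; otherwise its
#' `subtype` becomes `"UNAVAILABLE"`. The pre-unavailability subtype is
#' retained in the `subtype_true` column so selection-bias corrections can
#' be checked against the truth.
#'
#' @param cohort An `mpe_cohort` data frame.
#' @param availability_spec List with `intercept` (numeric) and optional
#'   `coefficients` (named numeric vector over case covariates; `sex`,
#'   `cohort` and `site` are encoded internally, other names must be
#'   numeric columns).
#' @param seed Integer seed for the availability draws.
#' @return The cohort with updated `subtype`.
#' @export
impose_tumor_unavailability <- function(cohort, availability_spec, seed = 1L) {
  stopifnot(is.data.frame(cohort))
  ci <- which(cohort$is_case)
  if (!length(ci)) return(cohort)
  lp <- rep(availability_spec$intercept %||% 0, length(ci))
  coefs <- availability_spec$coefficients
  if (length(coefs)) {
    X <- encode_case_covariates(cohort[ci, , drop = FALSE], names(coefs))
    # site expands to two columns sharing one coefficient is not meaningful;
    # require scalar covariates for coefficients
    for (v in names(coefs)) {
      cols <- if (v == "sex") "sex_female" else if (v == "cohort") "cohort_msp"
              else v
      if (!all(cols %in% colnames(X)))
        stop_mpe(paste0("availability model references unknown covariate: ", v),
                 "mpe_config_error")
      lp <- lp + coefs[[v]] * X[, cols]
    }
  }
  set.seed(as.integer(seed))
  unavailable <- stats::runif(length(ci)) > expit(lp)
  cohort$subtype[ci][unavailable] <- "UNAVAILABLE"
  cohort
}

#' Write / read a cohort as a delimited text table
#'
#' The cohort is written as a tab-separated table with a YAML sidecar
#' (`<path>.config.yaml`) echoing the generating configuration so the
#' cohort can be regenerated.
#'
#' @param cohort An `mpe_cohort`.
#' @param path Output path for the TSV table.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns an `mpe_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) write_sim_config(cfg, paste0(path, ".config.yaml"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cfgpath <- paste0(path, ".config.yaml")
  if (file.exists(cfgpath)) {
    cfg <- read_sim_config(cfgpath)
    attr(df, "config") <- cfg
    attr(df, "truth") <- cfg$effect_spec
    attr(df, "biomarkers") <- cfg$biomarker_spec$name
    attr(df, "snps") <- cfg$snp_spec$name
  }
  class(df) <- c("mpe_cohort", "data.frame")
  df
}

#' @export
print.mpe_cohort <- function(x, ...) {
  n_case <- sum(x$is_case)
  cat(sprintf("Matched cohort: %d subjects in %d sets (%d cases, %d controls)\n",
              nrow(x), length(unique(x$set_id)), n_case, nrow(x) - n_case))
  st <- table(x$subtype[x$is_case])
  cat("  case subtypes:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
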
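#' Simulation configuration for a matched case-control cohort
#'
#' Builds and validates the configuration consumed by [simulate_cohort()].
#' Defaults emulate a nested case-control study of colorectal cancer
#' subtypes defined by mutually exclusive KRAS and BRAF mutations: 1:2
#' matching on sex, age (within a +/- 2 year caliper), cohort and fasting
#' status; 14 correlated log-normal plasma one-carbon-metabolism biomarkers
#' plus neopterin; 17 Hardy-Weinberg SNPs; subtype frequencies
#' (KRAS, BRAF, wild-type) = (0.26, 0.24, 0.50); a designated SNP
#' (rs1021737) multiplying cystathionine concentrations by 1.07 per variant
#' allele; covariate-dependent tumor-data availability; and small
#' per-exposure missingness.
#'
#' @param n_cases Number of matched sets (one case each).
#' @param controls_per_case Controls matched to each case (default 2).
#' @param subtype_probs Length-3 probability vector over
#'   (KRAS-mutated, BRAF-mutated, wild-type); must sum to 1.
#' @param biomarker_spec Data frame with columns `name`, `log_mean`,
#'   `log_sd`: mean and SD of the log-concentration of each biomarker.
#' @param biomarker_cor Either a positive-definite correlation matrix for
#'   the log-concentrations or a single numeric factor loading `lambda`
#'   giving the one-factor structure `lambda^2` off-diagonal.
#' @param snp_spec Data frame with columns `name`, `maf` (minor allele
#'   frequency in `[0, 0.5]`).
#' @param effect_spec Named list: exposure name -> numeric length-3 vector
#'   of per-subtype log-odds effects (KRAS, BRAF, WT), per 1 SD of the log
#'   biomarker or per variant allele of a SNP.
#' @param snp_metabolite_effect Multiplicative per-allele effect of
#'   `snp_metabolite_pair[1]` on the concentration of
#'   `snp_metabolite_pair[2]` (dimensionless ratio; default 1.07).
#' @param snp_metabolite_pair Character pair `c(snp, biomarker)`.
#' @param availability_spec Named list with `intercept` and optional
#'   `coefficients` (named numeric vector over case covariates) for the
#'   logistic model of tumor-data availability. The default keeps all
#'   tumor data available.
#' @param missingness_rate Per-exposure fraction missing completely at
#'   random, in `[0, 0.03]`.
#' @param age_caliper Half-width (years) of the within-set age caliper.
#' @param seed Master RNG seed.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cases = 50, seed = 1)
#' cfg$subtype_probs
#' @export
sim_config <- function(n_cases = 488L,
                       controls_per_case = 2L,
                       subtype_probs = c(KRAS = 0.26, BRAF = 0.24, WT = 0.50),
                       biomarker_spec = default_biomarker_spec(),
                       biomarker_cor = 0.4,
                       snp_spec = default_snp_spec(),
                       effect_spec = list(),
                       snp_metabolite_effect = 1.07,
                       snp_metabolite_pair = c("rs1021737", "cystathionine"),
                       availability_spec = list(intercept = 30, coefficients = NULL),
                       missingness_rate = 0.02,
                       age_caliper = 2,
                       seed = 1L) {
  if (n_cases < 1) stop_mpe("n_cases must be a positive count", "mpe_config_error")
  if (controls_per_case < 1)
    stop_mpe("controls_per_case must be >= 1", "mpe_config_error")
  if (length(subtype_probs) != 3L || any(subtype_probs < 0))
    stop_mpe("subtype_probs must be 3 nonnegative probabilities", "mpe_config_error")
  if (abs(sum(subtype_probs) - 1) > 1e-12)
    stop_mpe("subtype_probs must sum to 1 (tolerance 1e-12)", "mpe_config_error")
  if (missingness_rate < 0 || missingness_rate > 0.03)
    stop_mpe("missingness_rate must lie in [0, 0.03]", "mpe_config_error")
  stopifnot(all(c("name", "log_mean", "log_sd") %in% names(biomarker_spec)),
            all(c("name", "maf") %in% names(snp_spec)))
  if (any(snp_spec$maf < 0 | snp_spec$maf > 0.5))
    stop_mpe("minor allele frequencies must lie in [0, 0.5]", "mpe_config_error")

  p <- nrow(biomarker_spec)
  if (is.matrix(biomarker_cor)) {
    R <- biomarker_cor
    if (nrow(R) != p || ncol(R) != p || max(abs(R - t(R))) > 1e-10)
      stop_mpe("correlation matrix must be symmetric p x p", "mpe_config_error")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12)
      stop_mpe("correlation matrix is not positive-definite", "mpe_config_error")
  } else {
    lambda <- as.numeric(biomarker_cor)
    if (abs(lambda) >= 1) stop_mpe("factor loading must satisfy |lambda| < 1",
                                   "mpe_config_error")
    R <- matrix(lambda^2, p, p)
    diag(R) <- 1
  }

  all_exposures <- c(biomarker_spec$name, snp_spec$name)
  if (length(effect_spec)) {
    bad <- setdiff(names(effect_spec), all_exposures)
    if (length(bad))
      stop_mpe(paste0("effect_spec names unknown: ", paste(bad, collapse = ", ")),
               "mpe_config_error")
    if (any(vapply(effect_spec, length, 1L) != 3L))
      stop_mpe("each effect_spec entry must be a length-3 log-OR vector",
               "mpe_config_error")
  }
  if (!snp_metabolite_pair[1] %in% snp_spec$name ||
      !snp_metabolite_pair[2] %in% biomarker_spec$name)
    stop_mpe("snp_metabolite_pair must name a configured SNP and biomarker",
             "mpe_config_error")
  if (snp_metabolite_effect <= 0)
    stop_mpe("snp_metabolite_effect must be a positive ratio", "mpe_config_error")

  structure(list(
    n_cases = as.integer(n_cases),
    controls_per_case = as.integer(controls_per_case),
    subtype_probs = stats::setNames(as.numeric(subtype_probs), c("KRAS", "BRAF", "WT")),
    biomarker_spec = biomarker_spec,
    biomarker_cor = R,
    snp_spec = snp_spec,
    effect_spec = effect_spec,
    snp_metabolite_effect = snp_metabolite_effect,
    snp_metabolite_pair = snp_metabolite_pair,
    availability_spec = availability_spec,
    missingness_rate = missingness_rate,
    age_caliper = age_caliper,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default plasma biomarker panel
#'
#' Fourteen one-carbon-metabolism biomarkers plus neopterin (an immune
#' activation marker used as a covariate), with log-scale means and SDs of
#' realistic magnitude for plasma concentrations in nmol/L or umol/L.
#'
#' @return Data frame with columns `name`, `log_mean`, `log_sd`.
#' @export
default_biomarker_spec <- function() {
  data.frame(
    name = c("folate", "vitamin_B6", "vitamin_B2", "vitamin_B12",
             "homocysteine", "cystathionine", "cysteine", "glycine",
             "serine", "methionine", "choline", "betaine",
             "dimethylglycine", "sarcosine", "neopterin"),
    log_mean = c(2.6, 3.6, 2.8, 5.9, 2.3, 4.9, 5.6, 5.5,
                 4.7, 3.2, 2.2, 3.5, 1.3, 0.3, 2.0),
    log_sd = c(0.45, 0.55, 0.50, 0.35, 0.30, 0.45, 0.12, 0.22,
               0.20, 0.20, 0.25, 0.30, 0.35, 0.30, 0.30),
    stringsAsFactors = FALSE
  )
}

#' Default SNP panel
#'
#' Seventeen one-carbon-metabolism SNPs with plausible European minor
#' allele frequencies.
#'
#' @return Data frame with columns `name`, `maf`.
#' @export
default_snp_spec <- function() {
  data.frame(
    name = c("rs3733890", "rs234706", "CBS_844ins68", "rs1021737",
             "rs70991108", "rs2071010", "rs2236225", "rs1801131",
             "rs1801133", "rs1805087", "rs1532268", "rs1801394",
             "rs1979277", "rs1051266", "rs1801198", "rs9606756",
             "rs34489327"),
    maf = c(0.30, 0.35, 0.08, 0.30, 0.45, 0.12, 0.45, 0.32,
            0.33, 0.19, 0.30, 0.45, 0.35, 0.45, 0.45, 0.12, 0.28),
    stringsAsFactors = FALSE
  )
}

#' Read / write a simulation configuration
#'
#' The config round-trips through YAML so a cohort can be regenerated from
#' its sidecar config echo.
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$biomarker_cor <- as.list(as.data.frame(x$biomarker_cor))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  cormat <- as.matrix(as.data.frame(lapply(x$biomarker_cor, unlist)))
  dimnames(cormat) <- NULL
  sim_config(
    n_cases = x$n_cases,
    controls_per_case = x$controls_per_case,
    subtype_probs = unlist(x$subtype_probs),
    biomarker_spec = as.data.frame(lapply(x$biomarker_spec, unlist),
                                   stringsAsFactors = FALSE),
    biomarker_cor = cormat,
    snp_spec = as.data.frame(lapply(x$snp_spec, unlist), stringsAsFactors = FALSE),
    effect_spec = lapply(x$effect_spec, unlist),
    snp_metabolite_effect = x$snp_metabolite_effect,
    snp_metabolite_pair = unlist(x$snp_metabolite_pair),
    availability_spec = list(
      intercept = x$availability_spec$intercept,
      coefficients = if (length(x$availability_spec$coefficients))
        unlist(x$availability_spec$coefficients) else NULL
    ),
    missingness_rate = x$missingness_rate,
    age_caliper = x$age_caliper,
    seed = x$seed
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Matched case-control simulation config\n")
  cat(sprintf("  %d cases, 1:%d matching, subtype probs (KRAS, BRAF, WT) = (%s)\n",
              x$n_cases, x$controls_per_case,
              paste(format(x$subtype_probs, digits = 3), collapse = ", ")))
  cat(sprintf("  %d biomarkers, %d SNPs, missingness %.1f%%, seed %d\n",
              nrow(x$biomarker_spec), nrow(x$snp_spec),
              100 * x$missingness_rate, x$seed))
  if (length(x$effect_spec))
    cat("  nonzero effects:", paste(names(x$effect_spec), collapse = ", "), "\n")
  invisible(x)
}
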
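#' Case-case multinomial model: ratio of odds ratios per allele
#'
#' Among cases only, fits a baseline-category multinomial logistic
#' regression of tumor subtype (reference: wild-type) on the per-allele
#' exposure. The exponentiated slope for each mutated subtype is the
#' ratio of odds ratios (ROR) contrasting that subtype with wild-type
#' tumors; asymptotically it equals the ratio of the subtype-specific
#' case-control ORs. Optional covariate adjustment via `covariates`.
#'
#' @param cases Data frame of cases with a `subtype` column in
#'   `{"KRAS", "BRAF", "WT"}` and the exposure column (allele counts, or
#'   any numeric exposure).
#' @param exposure Exposure column name.
#' @param covariates Optional adjustment covariate columns.
#' @param reference Reference subtype (default `"WT"`).
#' @return Object of class `ror_fit`: `per_subtype` (data frame with
#'   `subtype`, `n`, `ror`, `ci_low`, `ci_high`, reference row has ROR 1),
#'   `lrt` from [case_case_heterogeneity_lrt()], `fit` (the `multinom`
#'   object), `loglik`.
#' @export
multinomial_fit <- function(cases, exposure, covariates = character(),
                            reference = "WT") {
  d <- as.data.frame(cases)
  keep <- !is.na(d$subtype) & d$subtype %in% c("KRAS", "BRAF", "WT") &
    !is.na(d[[exposure]])
  if (length(covariates))
    keep <- keep & stats::complete.cases(d[, covariates, drop = FALSE])
  d <- d[keep, , drop = FALSE]
  levs <- c(reference, setdiff(c("WT", "KRAS", "BRAF"), reference))
  levs <- intersect(levs, unique(d$subtype))
  if (length(levs) < 2L)
    stop_mpe("need at least two subtype levels among cases", "mpe_config_error")
  if (stats::var(d[[exposure]]) == 0)
    stop_mpe("exposure does not vary among cases", "mpe_estimation_error")
  d$.subtype <- factor(d$subtype, levels = levs)
  fml <- stats::reformulate(c(exposure, covariates), response = ".subtype")
  fit <- nnet::multinom(fml, data = d, trace = FALSE,
                        maxit = 500, reltol = 1e-12)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levs[2], names(cf)))
  vc <- stats::vcov(fit)
  nonref <- rownames(cf)
  slope <- cf[, exposure]
  se <- vapply(nonref, function(s) {
    # with two classes multinom names vcov by plain term
    key <- if (length(levs) == 2L) exposure else paste0(s, ":", exposure)
    sqrt(vc[key, key])
  }, 0)
  counts <- table(d$.subtype)
  tab <- rbind(
    data.frame(subtype = reference, n = as.integer(counts[reference]),
               ror = 1, ci_low = NA_real_, ci_high = NA_real_,
               logror = 0, se = NA_real_, stringsAsFactors = FALSE),
    data.frame(subtype = nonref, n = as.integer(counts[nonref]),
               ror = exp(slope),
               ci_low = exp(slope - 1.96 * se),
               ci_high = exp(slope + 1.96 * se),
               logror = unname(slope), se = unname(se),
               stringsAsFactors = FALSE)
  )
  rownames(tab) <- NULL
  lrt <- case_case_heterogeneity_lrt(d, exposure, covariates = covariates,
                                     reference = reference)
  structure(list(per_subtype = tab, lrt = lrt, fit = fit,
                 loglik = as.numeric(stats::logLik(fit)),
                 exposure = exposure, reference = reference),
            class = "ror_fit")
}

#' Likelihood-ratio heterogeneity test for the case-case model
#'
#' Primary (2-df) version: compares the multinomial model with the
#' exposure slope free in every non-reference equation against the model
#' with all exposure slopes constrained to 0 — no association between the
#' exposure and subtype composition. The 1-df alternative constrains the
#' non-reference slopes to be equal instead.
#'
#' @param cases Case data frame (as in [multinomial_fit()]); rows with
#'   missing subtype or exposure are dropped.
#' @param exposure Exposure column name.
#' @param covariates Optional adjustment covariates (kept in both models).
#' @param reference Reference subtype.
#' @param version `"zero_slopes"` (default, df = #non-reference subtypes)
#'   or `"equal_slopes"` (df = #non-reference subtypes - 1).
#' @return List `statistic`, `df`, `p`.
#' @export
case_case_heterogeneity_lrt <- function(cases, exposure,
                                        covariates = character(),
                                        reference = "WT",
                                        version = c("zero_slopes",
                                                    "equal_slopes")) {
  version <- match.arg(version)
  d <- as.data.frame(cases)
  keep <- !is.na(d$subtype) & d$subtype %in% c("KRAS", "BRAF", "WT") &
    !is.na(d[[exposure]])
  if (length(covariates))
    keep <- keep & stats::complete.cases(d[, covariates, drop = FALSE])
  d <- d[keep, , drop = FALSE]
  levs <- c(reference, setdiff(c("WT", "KRAS", "BRAF"), reference))
  levs <- intersect(levs, unique(d$subtype))
  if (length(levs) < 2L)
    stop_mpe("no contrast: fewer than two subtype levels", "mpe_config_error")
  d$.subtype <- factor(d$subtype, levels = levs)
  ctrl <- list(trace = FALSE, maxit = 500, reltol = 1e-12)

  full <- nnet::multinom(stats::reformulate(c(exposure, covariates), ".subtype"),
                         data = d, trace = FALSE, maxit = 500, reltol = 1e-12)
  if (version == "zero_slopes") {
    red_terms <- if (length(covariates)) covariates else "1"
    reduced <- nnet::multinom(stats::reformulate(red_terms, ".subtype"),
                              data = d, trace = FALSE, maxit = 500,
                              reltol = 1e-12)
    df <- length(levs) - 1L
  } else {
    # equal slopes across the non-reference equations, fitted by direct
    # maximization of the constrained multinomial likelihood
    # (parameters: K-1 intercepts + 1 shared slope; no covariates here)
    if (length(covariates))
      stop_mpe("equal-slopes test does not support covariates", "mpe_config_error")
    df <- length(levs) - 2L
    if (df < 1L)
      stop_mpe("equal-slopes test needs >= 3 subtype levels", "mpe_config_error")
    K <- length(levs)
    y <- as.integer(d$.subtype)           # 1 = reference
    x <- d[[exposure]]
    negll <- function(par) {
      a <- par[seq_len(K - 1)]; b <- par[K]
      eta <- cbind(0, outer(x, rep(b, K - 1)) +
                        matrix(a, length(x), K - 1, byrow = TRUE))
      lse <- log(rowSums(exp(eta - apply(eta, 1, max)))) + apply(eta, 1, max)
      -sum(eta[cbind(seq_along(y), y)] - lse)
    }
    opt <- stats::optim(rep(0, K), negll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    reduced <- list(loglik = -opt$value)
  }
  ll_full <- as.numeric(stats::logLik(full))
  ll_red <- if (inherits(reduced, "multinom"))
    as.numeric(stats::logLik(reduced)) else reduced$loglik
  stat <- max(0, 2 * (ll_full - ll_red))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Consistency of case-control and case-case estimates
#'
#' Reports, per mutated subtype, the ratio of case-control subtype ORs
#' (subtype OR / wild-type OR) next to the case-case ROR; under a shared
#' generating mechanism the two agree asymptotically.
#'
#' @param cc_fit A [subtype_specific_fit()] result (must include the
#'   reference subtype).
#' @param ror A [multinomial_fit()] result.
#' @return Data frame with `subtype`, `or_ratio_cc`, `ror_case_case`,
#'   `log_diff`, `joint_se`, `comparable`.
#' @export
consistency_with_case_control <- function(cc_fit, ror) {
  stopifnot(inherits(cc_fit, "subtype_fit"), inherits(ror, "ror_fit"))
  ref <- ror$reference
  cc <- cc_fit$per_subtype
  if (!ref %in% cc$subtype)
    stop_mpe("case-control fit lacks the reference subtype", "mpe_config_error")
  ref_row <- cc[cc$subtype == ref, ]
  out <- list()
  for (st in setdiff(ror$per_subtype$subtype, ref)) {
    rr <- ror$per_subtype[ror$per_subtype$subtype == st, ]
    if (!st %in% cc$subtype) {
      out[[st]] <- data.frame(subtype = st, or_ratio_cc = NA_real_,
                              ror_case_case = rr$ror, log_diff = NA_real_,
                              joint_se = NA_real_, comparable = FALSE)
      next
    }
    cr <- cc[cc$subtype == st, ]
    log_ratio_cc <- cr$logor - ref_row$logor
    joint_se <- sqrt(cr$se^2 + ref_row$se^2 + rr$se^2)
    out[[st]] <- data.frame(
      subtype = st,
      or_ratio_cc = exp(log_ratio_cc),
      ror_case_case = rr$ror,
      log_diff = log(rr$ror) - log_ratio_cc,
      joint_se = joint_se,
      comparable = TRUE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.ror_fit <- function(x, ...) {
  cat("Case-case multinomial RORs per unit of", x$exposure,
      sprintf("(reference %s)\n", x$reference))
  tab <- x$per_subtype
  tab$ror <- ifelse(tab$subtype == x$reference, "1 (ref)",
                    sprintf("%.2f (%.2f, %.2f)", tab$ror, tab$ci_low,
                            tab$ci_high))
  print(tab[, c("subtype", "n", "ror")], row.names = FALSE)
  cat(sprintf("Heterogeneity LRT: chi2 = %.3f on %d df, p = %.4f\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p))
  invisible(x)
}
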
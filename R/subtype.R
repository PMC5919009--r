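#' Subtype-specific odds ratios with heterogeneity test
#'
#' For each tumor subtype, fits a conditional logistic regression on the
#' matched sets whose case has that subtype (controls travel with their
#' case) and reports the OR per exposure unit (per 1 SD of log biomarker
#' or per variant allele) with a Wald 95% CI. Heterogeneity of the
#' exposure association across subtypes is tested by a likelihood-ratio
#' test via [heterogeneity_lrt()]. Sets whose case has unavailable tumor
#' data are excluded with their controls.
#'
#' @param design A [matched_design()] whose `subtype` labels the sets.
#' @param subtypes Subtype levels to fit (default the observed case
#'   subtypes other than `"UNAVAILABLE"`).
#' @param het Logical: also run the heterogeneity LRT (default `TRUE`).
#' @param weights Optional [compute_weights()] assignment (or named
#'   per-subject weight vector) for the IPW sensitivity analysis; the
#'   case's weight is applied to its set.
#' @return Object of class `subtype_fit`: `per_subtype` (data frame with
#'   `subtype`, `n_cases`, `n_controls`, `logor`, `se`, `or`, `ci_low`,
#'   `ci_high`) and `lrt_het` (`statistic`, `df`, `p`), plus the
#'   per-subtype fit objects in `fits`.
#' @export
subtype_specific_fit <- function(design, subtypes = NULL, het = TRUE,
                                 weights = NULL) {
  stopifnot(inherits(design, "matched_design"))
  obs <- setdiff(unique(design$subtype), c(NA, "UNAVAILABLE", "NONE"))
  if (is.null(subtypes)) subtypes <- intersect(c("KRAS", "BRAF", "WT"), obs)
  rows <- list(); fits <- list()
  for (st in subtypes) {
    sel <- design$subtype == st & !is.na(design$subtype)
    if (!any(sel)) {
      warning("no matched sets for subtype ", st, "; omitted")
      next
    }
    sub <- subset_design(design, sel)
    fit <- if (is.null(weights)) clogit_fit(sub)
           else weighted_clogit(sub, weights)
    rows[[st]] <- data.frame(
      subtype = st,
      n_cases = sum(sub$case),
      n_controls = sum(!sub$case),
      logor = unname(fit$coef[1]),
      se = unname(fit$se[1]),
      or = exp(unname(fit$coef[1])),
      ci_low = exp(unname(fit$coef[1] - 1.96 * fit$se[1])),
      ci_high = exp(unname(fit$coef[1] + 1.96 * fit$se[1])),
      stringsAsFactors = FALSE
    )
    fits[[st]] <- fit
  }
  if (!length(rows))
    stop_mpe("no subtype has any informative matched set", "mpe_estimation_error")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  lrt <- if (het && nrow(tab) >= 2L)
    heterogeneity_lrt(design, subtypes = tab$subtype) else NULL
  structure(list(per_subtype = tab, lrt_het = lrt, fits = fits,
                 exposure = design$exposure),
            class = "subtype_fit")
}

# restrict a matched_design to a row selection (whole sets)
subset_design <- function(design, sel) {
  X <- design$X[sel, , drop = FALSE]
  set <- match(design$set[sel], unique(design$set[sel]))
  structure(list(X = X, case = design$case[sel], set = set,
                 subtype = design$subtype[sel],
                 set_id = design$set_id[sel],
                 subject_id = design$subject_id[sel],
                 n_dropped = design$n_dropped,
                 exposure = design$exposure, encoding = design$encoding),
            class = "matched_design")
}

#' Likelihood-ratio test of subtype heterogeneity
#'
#' Compares a full conditional-logistic model in which the exposure
#' coefficient varies by the case's subtype against a reduced model in
#' which it is constant across subtypes. Adjustment-covariate coefficients
#' are subtype-specific in both models, so the test isolates the exposure
#' coefficient. Statistic `2 (l_full - l_reduced)`, `df = #subtypes - 1`,
#' chi-square upper-tail p-value.
#'
#' @param design A [matched_design()].
#' @param subtypes Subtype labels to include (default all observed).
#' @param shared_nuisance Logical: constrain covariate coefficients to be
#'   shared across subtypes in both models instead (default `FALSE`).
#' @return List `statistic`, `df`, `p`.
#' @export
heterogeneity_lrt <- function(design, subtypes = NULL,
                              shared_nuisance = FALSE) {
  stopifnot(inherits(design, "matched_design"))
  obs <- setdiff(unique(design$subtype), c(NA, "UNAVAILABLE", "NONE"))
  if (is.null(subtypes)) subtypes <- intersect(c("KRAS", "BRAF", "WT"), obs)
  if (length(subtypes) < 2L)
    stop_mpe("heterogeneity test needs at least two subtypes", "mpe_config_error")
  sel <- design$subtype %in% subtypes
  sub <- subset_design(design, sel)
  S <- length(subtypes)
  g <- match(sub$subtype, subtypes)
  x <- sub$X[, 1]
  Z <- sub$X[, -1, drop = FALSE]

  ## full model: subtype-specific exposure columns
  Xfull <- matrix(0, length(x), S,
                  dimnames = list(NULL, paste0(sub$exposure, ":", subtypes)))
  Xfull[cbind(seq_along(x), g)] <- x
  ## reduced model: single shared exposure column
  Xred <- matrix(x, ncol = 1, dimnames = list(NULL, sub$exposure))

  if (ncol(Z)) {
    if (shared_nuisance) {
      Xfull <- cbind(Xfull, Z)
      Xred <- cbind(Xred, Z)
    } else {
      Zblocks <- do.call(cbind, lapply(seq_len(S), function(s) {
        B <- Z * (g == s)
        colnames(B) <- paste0(colnames(Z), ":", subtypes[s])
        B
      }))
      Xfull <- cbind(Xfull, Zblocks)
      Xred <- cbind(Xred, Zblocks)
    }
  }

  fit_full <- clogit_fit(Xfull, sub$case, sub$set)
  fit_red <- clogit_fit(Xred, sub$case, sub$set)
  stat <- max(0, 2 * (fit_full$loglik - fit_red$loglik))
  df <- S - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Cochran's Q test of between-stratum homogeneity
#'
#' Fixed-effect heterogeneity statistic
#' `Q = sum w_k (beta_k - beta_bar)^2` with inverse-variance weights
#' `w_k = 1/SE_k^2`, `df = K - 1`, chi-square p-value. Used to check that
#' exposure associations agree across cohorts before pooling.
#'
#' @param logor Numeric vector of stratum log-ORs.
#' @param se Positive standard errors, same length.
#' @return List `Q`, `df`, `p`.
#' @examples
#' cochran_q(c(0, 2), c(1, 1))  # Q = 2, p = 0.157
#' @export
cochran_q <- function(logor, se) {
  if (length(logor) < 2L || length(se) != length(logor))
    stop_mpe("need >= 2 paired estimates", "mpe_config_error")
  if (any(se <= 0)) stop_mpe("standard errors must be positive", "mpe_domain_error")
  w <- 1 / se^2
  bbar <- sum(w * logor) / sum(w)
  Q <- sum(w * (logor - bbar)^2)
  df <- length(logor) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Per-allele association between a SNP and a metabolite
#'
#' Regresses the log concentration on the variant-allele count and reports
#' the percent change per allele, `100 (exp(slope) - 1)`, with a two-sided
#' Wald p-value. Scale-invariant in the concentration units.
#'
#' @param genotype Allele counts in `{0, 1, 2}` (missing allowed; dropped
#'   pairwise).
#' @param metabolite Positive concentrations, same length.
#' @return List `percent_change`, `slope`, `se`, `p`, `n`.
#' @export
snp_metabolite_association <- function(genotype, metabolite) {
  ok <- !is.na(genotype) & !is.na(metabolite)
  g <- genotype[ok]; m <- metabolite[ok]
  if (any(m <= 0)) stop_mpe("concentrations must be positive", "mpe_domain_error")
  if (length(unique(g)) < 2L)
    stop_mpe("genotype is constant; per-allele slope inestimable",
             "mpe_estimation_error")
  fit <- stats::lm(log(m) ~ g)
  sm <- summary(fit)$coefficients
  list(percent_change = 100 * (exp(sm["g", "Estimate"]) - 1),
       slope = sm["g", "Estimate"], se = sm["g", "Std. Error"],
       p = sm["g", "Pr(>|t|)"], n = length(g))
}

#' @export
print.subtype_fit <- function(x, ...) {
  cat("Subtype-specific conditional logistic ORs for", x$exposure, "\n")
  tab <- x$per_subtype
  tab$or <- sprintf("%.2f (%.2f, %.2f)", tab$or, tab$ci_low, tab$ci_high)
  print(tab[, c("subtype", "n_cases", "n_controls", "or")], row.names = FALSE)
  if (!is.null(x$lrt_het))
    cat(sprintf("Heterogeneity LRT: chi2 = %.3f on %d df, p = %.4f\n",
                x$lrt_het$statistic, x$lrt_het$df, x$lrt_het$p))
  invisible(x)
}
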
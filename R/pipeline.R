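#' Bonferroni-adjusted significance threshold
#'
#' @param n_exposures Number of exposure variables tested (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return `alpha / n_exposures`.
#' @examples
#' bonferroni_threshold(31)  # 0.0016 ~ 0.002
#' @export
bonferroni_threshold <- function(n_exposures, alpha = 0.05) {
  if (n_exposures < 1) stop_mpe("n_exposures must be >= 1", "mpe_config_error")
  alpha / n_exposures
}

#' Run the full two-step analysis pipeline
#'
#' Executes, from one seeded configuration: cohort simulation (or a
#' supplied cohort) -> discretization -> bootstrap-averaged network
#' screening -> selection of the exposures whose edge confidence to the
#' outcome exceeds the estimated threshold (falling back to the single
#' top-ranked exposure when none does) -> subtype-specific conditional
#' logistic ORs with heterogeneity LRT and per-cohort Cochran's Q ->
#' IPW selection-bias sensitivity analysis (when any case has unavailable
#' tumor data) -> case-case multinomial RORs, with a machine-readable run
#' manifest.
#'
#' @param config A [sim_config()] (the cohort is simulated) or an
#'   `mpe_cohort` data frame.
#' @param seed Master seed for all stages (default: the config's seed).
#' @param n_bootstrap Bootstrap replicates for the network stage.
#' @param bn_biomarkers,bn_snps Optional subsets of exposures to include
#'   as network nodes (defaults: all).
#' @param bn_covariates Covariate nodes for the network stage.
#' @param adjust_biomarkers Covariates adjusted by regression in biomarker
#'   conditional-logistic models (SNP models adjust only by conditioning).
#' @param max_selected Cap on the number of exposures carried to step 2.
#' @param outdir Optional directory; when given, all stage outputs and the
#'   manifest are written there as delimited text / DOT / JSON.
#' @return Object of class `mpe_pipeline`: `cohort`, `discrete`,
#'   `network`, `ranking`, `selected`, `subtype_results` (named list of
#'   `subtype_fit`), `cochran`, `ipw` (list with `availability`,
#'   `weights`, `fits`, `balance`, `comparison`; `NULL` when no tumor
#'   data are missing), `case_case` (named list of `ror_fit`),
#'   `bonferroni`, `manifest`.
#' @export
run_full_pipeline <- function(config,
                              seed = NULL,
                              n_bootstrap = 200L,
                              bn_biomarkers = NULL,
                              bn_snps = NULL,
                              bn_covariates = c("sex", "cohort", "fasting",
                                                "age_group", "bmi_band",
                                                "smoking"),
                              adjust_biomarkers = c("bmi", "smoking", "alcohol",
                                                    "neopterin",
                                                    "pa_recreational",
                                                    "pa_occupational"),
                              max_selected = 3L,
                              outdir = NULL) {
  t0 <- Sys.time()
  counts <- list()

  ## stage 1: cohort
  if (inherits(config, "sim_config")) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    seeds <- derive_seeds(config$seed, 4L)
    cohort <- simulate_cohort(config)
    cfg_echo <- config
  } else {
    cohort <- config
    cfg_echo <- attr(cohort, "config")
    seeds <- derive_seeds(seed %||% 1L, 4L)
  }
  biomarkers <- attr(cohort, "biomarkers")
  snps <- attr(cohort, "snps")
  counts$subjects <- nrow(cohort)
  counts$cases <- sum(cohort$is_case)

  ## stage 2: discretize
  bn_bio <- bn_biomarkers %||% biomarkers
  bn_snp <- bn_snps %||% snps
  disc <- build_discrete_dataset(cohort, biomarkers = bn_bio, snps = bn_snp,
                                 covariates = bn_covariates)
  counts$discrete_rows <- nrow(disc$data)
  counts$dropped_missing_cases <- disc$n_dropped_cases
  counts$dropped_missing_controls <- disc$n_dropped_controls
  counts$excluded_unavailable <- disc$n_unavailable_excluded

  ## stage 3: network screening
  net <- bootstrap_average(disc$data, n_bootstrap = n_bootstrap,
                           seed = seeds[2])
  ranking <- outcome_edge_ranking(net, "outcome")
  exp_rank <- ranking[ranking$variable %in% c(bn_bio, bn_snp), , drop = FALSE]
  selected <- exp_rank$variable[exp_rank$included]
  if (!length(selected)) selected <- exp_rank$variable[1]
  selected <- utils::head(selected, max_selected)

  ## stage 4: univariate subtype-specific models
  subtype_results <- list()
  cochran <- list()
  for (ex in selected) {
    is_bio <- ex %in% biomarkers
    des <- matched_design(cohort, ex,
                          encoding = if (is_bio) "per_sd" else "per_allele",
                          covariates = if (is_bio)
                            intersect(adjust_biomarkers, names(cohort))
                          else character())
    subtype_results[[ex]] <- subtype_specific_fit(des)
    ## overall-risk fit per cohort -> Cochran's Q across cohorts
    est <- lapply(unique(cohort$cohort), function(ch) {
      rows <- des$set_id %in% cohort$set_id[cohort$cohort == ch]
      sub <- subset_design(des, rows)
      fit <- tryCatch(clogit_fit(sub), error = function(e) NULL)
      if (is.null(fit)) NULL else c(fit$coef[1], fit$se[1])
    })
    est <- est[!vapply(est, is.null, TRUE)]
    if (length(est) >= 2)
      cochran[[ex]] <- cochran_q(vapply(est, `[`, 0, 1),
                                 vapply(est, `[`, 0, 2))
  }

  ## stage 5: IPW sensitivity analysis
  ipw <- NULL
  if (any(cohort$subtype[cohort$is_case] == "UNAVAILABLE")) {
    avail_model <- fit_availability_model(cohort)
    wts <- compute_weights(avail_model, cohort)
    bal <- balance_check(avail_model, cohort)
    ipw_fits <- list(); cc_tab <- list(); ipw_tab <- list()
    for (ex in selected) {
      is_bio <- ex %in% biomarkers
      des <- matched_design(cohort, ex,
                            encoding = if (is_bio) "per_sd" else "per_allele",
                            covariates = if (is_bio)
                              intersect(adjust_biomarkers, names(cohort))
                            else character())
      ipw_fits[[ex]] <- subtype_specific_fit(des, het = FALSE, weights = wts)
      cc <- subtype_results[[ex]]$per_subtype
      iw <- ipw_fits[[ex]]$per_subtype
      cc$exposure <- ex; iw$exposure <- ex
      cc_tab[[ex]] <- cc; ipw_tab[[ex]] <- iw
    }
    comparison <- compare_complete_case_vs_ipw(do.call(rbind, cc_tab),
                                               do.call(rbind, ipw_tab))
    ipw <- list(availability = avail_model, weights = wts, fits = ipw_fits,
                balance = bal, comparison = comparison)
  }

  ## stage 6: case-case replication
  cases <- as.data.frame(cohort)[cohort$is_case &
                                   cohort$subtype != "UNAVAILABLE", , drop = FALSE]
  case_case <- list()
  for (ex in selected) {
    if (ex %in% biomarkers)
      cases[[paste0(ex, "_sd")]] <-
        standardize_per_sd(cases[[ex]],
                           cohort[[ex]][!cohort$is_case])
    exname <- if (ex %in% biomarkers) paste0(ex, "_sd") else ex
    case_case[[ex]] <- tryCatch(multinomial_fit(cases, exname),
                                error = function(e) e)
  }

  manifest <- list(
    config_hash = hash_config(cfg_echo),
    master_seed = if (inherits(config, "sim_config")) config$seed
                  else seed %||% 1L,
    stage_seeds = as.integer(seeds),
    n_bootstrap = n_bootstrap,
    counts = counts,
    selected = selected,
    threshold = net$threshold,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("mpescreen")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )

  res <- structure(list(cohort = cohort, discrete = disc, network = net,
                        ranking = ranking, selected = selected,
                        subtype_results = subtype_results, cochran = cochran,
                        ipw = ipw, case_case = case_case,
                        bonferroni = bonferroni_threshold(
                          length(bn_bio) + length(bn_snp)),
                        manifest = manifest),
                   class = "mpe_pipeline")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

hash_config <- function(config) {
  if (is.null(config)) return(NA_character_)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  x <- unclass(config)
  x$biomarker_cor <- as.vector(x$biomarker_cor)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(res$cohort, file.path(outdir, "cohort.tsv"))
  utils::write.table(res$discrete$data, file.path(outdir, "discrete.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_rules(res$discrete$rules, file.path(outdir, "rules.yaml"))
  write_edge_list(res$network, file.path(outdir, "edges.tsv"))
  write_dot(res$network, file.path(outdir, "network.dot"))
  utils::write.table(res$ranking, file.path(outdir, "outcome_ranking.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  st <- do.call(rbind, lapply(names(res$subtype_results), function(ex) {
    tab <- res$subtype_results[[ex]]$per_subtype
    tab$exposure <- ex
    tab$p_het <- res$subtype_results[[ex]]$lrt_het$p %||% NA_real_
    tab
  }))
  utils::write.table(st, file.path(outdir, "subtype_or.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cc <- do.call(rbind, lapply(names(res$case_case), function(ex) {
    r <- res$case_case[[ex]]
    if (inherits(r, "error")) return(NULL)
    tab <- r$per_subtype; tab$exposure <- ex; tab$p <- r$lrt$p
    tab
  }))
  if (!is.null(cc))
    utils::write.table(cc, file.path(outdir, "case_case_ror.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(res$ipw)) {
    utils::write.table(res$ipw$comparison$pairs,
                       file.path(outdir, "cc_vs_ipw.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(subject_id = names(res$ipw$weights$weights),
                 weight = unname(res$ipw$weights$weights)),
      file.path(outdir, "weights.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.mpe_pipeline <- function(x, ...) {
  cat("Two-step subtype-risk analysis pipeline\n")
  cat(sprintf("  %d subjects (%d cases); %d complete-case rows in network stage\n",
              x$manifest$counts$subjects, x$manifest$counts$cases,
              x$manifest$counts$discrete_rows))
  cat(sprintf("  edge-inclusion threshold %.3f; selected exposure(s): %s\n",
              x$network$threshold, paste(x$selected, collapse = ", ")))
  cat(sprintf("  Bonferroni-adjusted level: %.5f\n", x$bonferroni))
  for (ex in names(x$subtype_results)) print(x$subtype_results[[ex]])
  invisible(x)
}
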
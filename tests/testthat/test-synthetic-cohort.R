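test_that("configuration invariants are enforced", {
  expect_error(sim_config(subtype_probs = c(0.5, 0.5, 0.1)), "sum to 1")
  expect_error(sim_config(subtype_probs = c(-0.1, 0.6, 0.5)), "nonnegative")
  expect_error(sim_config(controls_per_case = 0), ">= 1")
  expect_error(sim_config(missingness_rate = 0.5), "0.03")
  badR <- matrix(0.99, 15, 15); diag(badR) <- 1
  badR[1, 2] <- -0.99  # asymmetric after this edit? no - make non-PD instead
  badR[2, 1] <- -0.99
  expect_error(sim_config(biomarker_cor = badR), "positive-definite")
  expect_error(sim_config(effect_spec = list(nosuch = c(0, 0, 0))), "unknown")
})

test_that("matched sets have one case, matched factors and the age caliper", {
  coh <- simulate_cohort(tiny_config(seed = 3, n_cases = 120))
  by_set <- split(seq_len(nrow(coh)), coh$set_id)
  expect_true(all(vapply(by_set, function(i) sum(coh$is_case[i]), 0L) == 1L))
  expect_true(all(lengths(by_set) == 3L))
  same <- function(v) vapply(by_set, function(i) length(unique(v[i])) == 1L, TRUE)
  expect_true(all(same(coh$sex)))
  expect_true(all(same(coh$cohort)))
  expect_true(all(same(coh$fasting)))
  expect_true(all(same(coh$year_sampling)))
  age_spread <- vapply(by_set, function(i) diff(range(coh$age_at_sampling[i])), 0)
  expect_true(all(age_spread <= 2 * 2 + 1e-9))
  # controls labeled NONE, cases labeled with a subtype
  expect_true(all(coh$subtype[!coh$is_case] == "NONE"))
  expect_true(all(coh$subtype[coh$is_case] %in%
                    c("KRAS", "BRAF", "WT", "UNAVAILABLE")))
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  coh <- simulate_cohort(tiny_config(seed = 5, n_cases = 3400))
  cfg <- attr(coh, "config")
  # chi-square goodness of fit at the configured MAF for each SNP
  pvals <- vapply(seq_len(nrow(cfg$snp_spec)), function(k) {
    q <- cfg$snp_spec$maf[k]
    obs <- tabulate(coh[[cfg$snp_spec$name[k]]] + 1L, 3L)
    expd <- sum(obs) * c((1 - q)^2, 2 * q * (1 - q), q^2)
    suppressWarnings(stats::chisq.test(obs, p = expd / sum(expd))$p.value)
  }, 0)
  expect_true(all(pvals > 0.001))
  # closed-form check at MAF 0.25 (example frequencies 0.5625/0.375/0.0625)
  f <- tabulate(simulate_cohort(sim_config(
    n_cases = 3400, missingness_rate = 0,
    snp_spec = data.frame(name = "rs1021737", maf = 0.25),
    biomarker_spec = default_biomarker_spec(), seed = 6
  ))$rs1021737 + 1L, 3L) / 10200
  expd <- c(0.5625, 0.375, 0.0625)
  mc_sd <- sqrt(expd * (1 - expd) / 10200)
  expect_true(all(abs(f - expd) < 3 * mc_sd))
})

test_that("null effects give symmetric subtype frequencies", {
  coh <- simulate_cohort(sim_config(n_cases = 3000, missingness_rate = 0,
                                    subtype_probs = c(1, 1, 1) / 3, seed = 8))
  frac <- table(factor(coh$subtype_true[coh$is_case],
                       c("KRAS", "BRAF", "WT"))) / 3000
  mc_sd <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(frac - 1 / 3) < 3 * mc_sd))
})

test_that("designated SNP shifts its metabolite by the configured ratio", {
  coh <- simulate_cohort(tiny_config(seed = 9, n_cases = 1700))
  g <- coh$rs1021737
  lc <- log(coh$cystathionine)
  # geometric-mean ratio between allele-count-1 and allele-count-0 carriers
  lr <- mean(lc[g == 1]) - mean(lc[g == 0])
  se <- sqrt(var(lc[g == 1]) / sum(g == 1) + var(lc[g == 0]) / sum(g == 0))
  expect_lt(abs(lr - log(1.07)), 3 * se)
})

test_that("missingness is applied per exposure at the configured rate", {
  coh <- simulate_cohort(sim_config(n_cases = 2000, missingness_rate = 0.02,
                                    seed = 10))
  rates <- vapply(c(attr(coh, "biomarkers"), attr(coh, "snps")),
                  function(v) mean(is.na(coh[[v]])), 0)
  expect_true(all(rates > 0.005 & rates < 0.04))
  coh0 <- simulate_cohort(tiny_config(seed = 10))
  expect_false(anyNA(coh0[, attr(coh0, "biomarkers")]))
})

test_that("tumor-data availability follows its logistic model", {
  coh <- simulate_cohort(tiny_config(seed = 11, n_cases = 400))
  # very large intercept: every case keeps its tumor data
  full <- impose_tumor_unavailability(coh, list(intercept = 50), seed = 1)
  expect_true(all(full$subtype[full$is_case] != "UNAVAILABLE"))
  # intercept 0, no covariates: about half the cases lose tumor data
  half <- impose_tumor_unavailability(coh, list(intercept = 0), seed = 2)
  prop <- mean(half$subtype[half$is_case] == "UNAVAILABLE")
  expect_lt(abs(prop - 0.5), 3 * sqrt(0.25 / 400))
  # negative age coefficient: unavailable cases are older on average
  older <- impose_tumor_unavailability(
    coh, list(intercept = 3, coefficients = c(age_at_sampling = -0.05)),
    seed = 3)
  ages <- split(older$age_at_sampling[older$is_case],
                older$subtype[older$is_case] == "UNAVAILABLE")
  expect_gt(mean(ages$`TRUE`), mean(ages$`FALSE`))
  # truth channel preserved
  expect_true(all(older$subtype_true[older$is_case] %in% c("KRAS", "BRAF", "WT")))
  expect_error(impose_tumor_unavailability(
    coh, list(intercept = 0, coefficients = c(nope = 1))), "unknown covariate")
})

test_that("cohort tables round-trip through delimited text", {
  coh <- simulate_cohort(tiny_config(seed = 12, n_cases = 25))
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tf, paste0(tf, ".config.yaml"))))
  write_cohort(coh, tf)
  back <- read_cohort(tf)
  expect_equal(nrow(back), nrow(coh))
  expect_equal(back$subject_id, coh$subject_id)
  expect_equal(back$folate, coh$folate, tolerance = 1e-9)
  expect_s3_class(attr(back, "config"), "sim_config")
})
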
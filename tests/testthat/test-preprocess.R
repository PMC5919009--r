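test_that("tertile rule reproduces exact thirds and rejects no-spread input", {
  r <- fit_tertile_rule(1:9)
  expect_equal(unname(r$cutpoints), c(3, 6))
  g <- apply_tertile_rule(r, 1:9)
  expect_equal(as.character(g), rep(c("T1", "T2", "T3"), each = 3))
  expect_error(fit_tertile_rule(rep(5, 9)), class = "mpe_degenerate_rule")
  expect_error(fit_tertile_rule(c(1, 2)), class = "mpe_degenerate_rule")
})

test_that("tertile cutpoints converge to the log-normal closed form", {
  set.seed(42)
  x <- exp(rnorm(50000))
  r <- fit_tertile_rule(x)
  expect_lt(abs(r$cutpoints[1] - exp(qnorm(1 / 3))), 0.01)
  expect_lt(abs(r$cutpoints[2] - exp(qnorm(2 / 3))), 0.01)
})

test_that("discretization is monotone and balanced on its fitting sample", {
  set.seed(7)
  for (rep in 1:20) {
    x <- exp(rnorm(301))
    r <- fit_tertile_rule(x)
    g <- apply_tertile_rule(r, x)
    # monotone: larger value never maps to a lower tertile
    o <- order(x)
    expect_true(all(diff(as.integer(g)[o]) >= 0))
    # near-equal groups (continuous draws: ties have measure zero)
    expect_true(max(abs(table(g) - 301 / 3)) <= 1)
  }
})

test_that("per-SD standardization centers, scales and inverts exactly", {
  set.seed(1)
  controls <- exp(rnorm(500, 2, 0.7))
  gm <- exp(mean(log(controls)))
  expect_equal(standardize_per_sd(gm, controls), 0, tolerance = 1e-12)
  s <- sd(log(controls))
  expect_equal(standardize_per_sd(exp(mean(log(controls)) + s), controls), 1,
               tolerance = 1e-12)
  vals <- exp(rnorm(50, 2, 0.7))
  z <- standardize_per_sd(vals, controls)
  back <- exp(z * s + mean(log(controls)))
  expect_equal(back, vals, tolerance = 1e-12)
  expect_error(standardize_per_sd(-1, controls), class = "mpe_domain_error")
  expect_error(standardize_per_sd(2, rep(3, 10)), class = "mpe_degenerate_rule")
})

test_that("genotype encodings follow the additive and dominant contrasts", {
  expect_equal(encode_genotype(c(0, 1, 2), "additive"), c(0, 1, 2))
  expect_equal(encode_genotype(c(0, 1, 2), "dominant"), c(0, 1, 1))
  expect_equal(encode_genotype(NA, "dominant"), NA_real_)
  expect_error(encode_genotype(3, "additive"), class = "mpe_domain_error")
})

test_that("Cockcroft-Gault formula matches hand arithmetic", {
  expect_equal(compute_egfr_cockcroft_gault(40, 72, 1.0, "male"), 100)
  expect_equal(compute_egfr_cockcroft_gault(40, 72, 1.0, "female"), 85)
  expect_equal(compute_egfr_cockcroft_gault(60, 80, 0.8, "male"),
               (140 - 60) * 80 / (72 * 0.8), tolerance = 1e-12)
  expect_equal(round(compute_egfr_cockcroft_gault(60, 80, 0.8, "male"), 2),
               111.11)
  # umol/L variant: dividing by 88.4 recovers the mg/dL value
  expect_equal(compute_egfr_cockcroft_gault(40, 72, 88.4, "male",
                                            creatinine_umol_l = TRUE), 100)
  expect_error(compute_egfr_cockcroft_gault(-1, 72, 1, "male"),
               class = "mpe_domain_error")
})

test_that("missing-category assignment is explicit and identity-preserving", {
  expect_equal(assign_missing_category(c("A", NA, "B")), c("A", "missing", "B"))
  expect_equal(assign_missing_category(c("A", "B")), c("A", "B"))
  expect_warning(out <- assign_missing_category(c(NA, NA)), "all values missing")
  expect_equal(out, c("missing", "missing"))
})

test_that("complete-case bookkeeping is exact in the discrete dataset", {
  coh <- simulate_cohort(tiny_config(seed = 21, n_cases = 150))
  d0 <- build_discrete_dataset(coh)
  # zero missingness: all rows preserved
  expect_equal(nrow(d0$data), nrow(coh))
  expect_equal(d0$n_dropped_cases + d0$n_dropped_controls, 0L)
  # one subject missing one SNP: exactly that subject dropped
  coh2 <- coh
  coh2$rs1801133[17] <- NA
  d2 <- build_discrete_dataset(coh2)
  expect_equal(nrow(d2$data), nrow(coh) - 1L)
  expect_equal(d2$n_dropped_cases + d2$n_dropped_controls, 1L)
  # count identity: rows out = rows in - rows with any missing exposure
  cfg <- sim_config(n_cases = 200, missingness_rate = 0.02, seed = 22)
  coh3 <- simulate_cohort(cfg)
  keep <- !(coh3$is_case & coh3$subtype == "UNAVAILABLE")
  expos <- c(attr(coh3, "biomarkers"), attr(coh3, "snps"))
  n_missing <- sum(!complete.cases(coh3[keep, expos]))
  d3 <- build_discrete_dataset(coh3)
  expect_equal(nrow(d3$data), sum(keep) - n_missing)
  expect_equal(d3$n_dropped_cases + d3$n_dropped_controls, n_missing)
})

test_that("unavailable-subtype cases are excluded from the discrete dataset", {
  coh <- simulate_cohort(tiny_config(seed = 23, n_cases = 100))
  coh <- impose_tumor_unavailability(coh, list(intercept = 0), seed = 4)
  d <- build_discrete_dataset(coh)
  expect_equal(d$n_unavailable_excluded,
               sum(coh$subtype == "UNAVAILABLE"))
  expect_false("UNAVAILABLE" %in% levels(d$data$outcome))
  expect_equal(levels(d$data$outcome), c("control", "KRAS", "BRAF", "WT"))
})

test_that("fitted rules can be re-applied identically after a round-trip", {
  coh <- simulate_cohort(tiny_config(seed = 24, n_cases = 80))
  d <- build_discrete_dataset(coh)
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_rules(d$rules, tf)
  rules <- read_rules(tf)
  d2 <- build_discrete_dataset(coh, rules = rules)
  expect_equal(d2$data, d$data)
})
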
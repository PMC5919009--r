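test_that("local AIC score matches the closed-form multinomial MLE", {
  d <- data.frame(y = factor(rep(c("a", "b"), c(7, 3))))
  expect_equal(local_aic_score(d, "y"), 7 * log(0.7) + 3 * log(0.3) - 1,
               tolerance = 1e-12)
  # deterministic copy: gain over the empty model is n log 2 minus the
  # penalty difference (child gains one extra parent configuration)
  n <- 100
  d2 <- data.frame(a = factor(rep(c("x", "y"), each = n / 2)))
  d2$b <- d2$a
  gain <- local_aic_score(d2, "b", "a") - local_aic_score(d2, "b")
  expect_equal(gain, n * log(2) - 1, tolerance = 1e-9)
})

test_that("network score is decomposable into node scores", {
  set.seed(31)
  d <- data.frame(a = factor(rbinom(200, 1, 0.5)),
                  b = factor(rbinom(200, 2, 0.4)),
                  c = factor(rbinom(200, 1, 0.3)))
  sn <- score_network(d, cbind(from = c("a", "b"), to = c("b", "c")))
  expect_equal(sn$score, sum(sn$per_node_scores), tolerance = 1e-9)
  fit <- hill_climb(d)
  expect_equal(fit$score, sum(fit$per_node_scores), tolerance = 1e-9)
})

test_that("hill climbing returns the empty graph for a single variable", {
  d <- data.frame(a = factor(rbinom(50, 1, 0.5)))
  fit <- hill_climb(d)
  expect_equal(nrow(fit$arcs), 0L)
  expect_equal(fit$score, local_aic_score(d, "a"), tolerance = 1e-12)
})

test_that("hill climbing avoids arcs between independent variables", {
  # a spurious arc needs a log-likelihood gain above the AIC penalty of 1,
  # i.e. a chi-square(1) deviate above 2, so the empty graph is expected in
  # about 84% of replicates; the bound allows binomial noise around that
  set.seed(33)
  hits <- 0L
  for (r in 1:40) {
    d <- data.frame(a = factor(rbinom(500, 1, 0.5)),
                    b = factor(rbinom(500, 1, 0.5)))
    if (nrow(hill_climb(d)$arcs) == 0L) hits <- hits + 1L
  }
  expect_gte(hits, 28L)
})

test_that("hill climbing attains the exhaustive optimum on a strong chain", {
  set.seed(34)
  n <- 2000
  A <- rbinom(n, 1, 0.5)
  B <- ifelse(runif(n) < 0.9, A, 1 - A)
  C <- ifelse(runif(n) < 0.9, B, 1 - B)
  d <- data.frame(A = factor(A), B = factor(B), C = factor(C))
  fit <- hill_climb(d)
  expect_equal(fit$score, exhaustive_best_score(d), tolerance = 1e-9)
  # chain skeleton recovered: edges A-B and B-C, not A-C
  und <- apply(fit$arcs, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(und, c("A-B", "B-C"))
})

test_that("every accepted hill-climb state is acyclic with a non-decreasing score", {
  set.seed(35)
  for (r in 1:10) {
    d <- as.data.frame(lapply(1:4, function(i) factor(rbinom(150, 1, 0.5))))
    names(d) <- paste0("v", 1:4)
    fit <- hill_climb(d)
    # acyclicity: adjacency matrix powers have zero trace
    am <- matrix(0, 4, 4, dimnames = list(names(d), names(d)))
    if (nrow(fit$arcs)) am[fit$arcs] <- 1
    acyc <- TRUE; pw <- am
    for (k in 1:4) { if (sum(diag(pw)) > 0) acyc <- FALSE; pw <- pw %*% am }
    expect_true(acyc)
    # final score never below the empty-graph score
    empty <- sum(vapply(names(d), function(v) local_aic_score(d, v), 0))
    expect_gte(fit$score, empty - 1e-9)
  }
})

test_that("bootstrap confidences are exact replicate fractions", {
  set.seed(36)
  d <- data.frame(a = factor(rbinom(120, 1, 0.5)),
                  b = factor(rbinom(120, 1, 0.5)))
  b1 <- bootstrap_average(d, n_bootstrap = 1, seed = 2)
  expect_true(all(b1$edges$confidence %in% c(0, 1)))
  b20 <- bootstrap_average(d, n_bootstrap = 20, seed = 2)
  expect_true(all(abs(b20$edges$confidence * 20 -
                        round(b20$edges$confidence * 20)) < 1e-12))
  expect_error(bootstrap_average(d, n_bootstrap = 0), class = "mpe_config_error")
})

test_that("perfect deterministic dependence yields confidence 1 and a bit-stable run", {
  set.seed(37)
  a <- factor(rbinom(200, 1, 0.5))
  d <- data.frame(a = a, b = a, c = factor(rbinom(200, 1, 0.5)))
  avg <- bootstrap_average(d, n_bootstrap = 25, seed = 9)
  e <- avg$edges
  expect_equal(e$confidence[e$var1 == "a" & e$var2 == "b"], 1)
  # reproducibility: identical seed gives identical output
  avg2 <- bootstrap_average(d, n_bootstrap = 25, seed = 9)
  expect_identical(avg$edges, avg2$edges)
  expect_identical(avg$threshold, avg2$threshold)
})

test_that("threshold estimation separates two-point confidence mixtures", {
  # perfectly separated: only the confidence-1 edges are included
  conf <- c(rep(0, 7), rep(1, 3))
  thr <- estimate_threshold(conf)
  expect_true(all((conf > thr) == (conf == 1)))
  # degenerate single atom: threshold not above the atom
  expect_lte(estimate_threshold(rep(0.5, 10)), 0.5)
  # Beta(1,20) noise vs Beta(20,1) signal: included set is the high mode
  set.seed(38)
  agree <- 0L
  for (r in 1:100) {
    lo <- rbeta(15, 1, 20); hi <- rbeta(15, 20, 1)
    thr <- estimate_threshold(c(lo, hi))
    if (all(hi > thr) && all(lo <= thr)) agree <- agree + 1L
  }
  expect_gte(agree, 90L)
  expect_error(estimate_threshold(numeric()), class = "mpe_config_error")
})

test_that("outcome ranking orders exposures by edge confidence", {
  set.seed(39)
  out <- factor(rbinom(400, 1, 0.5))
  d <- data.frame(outcome = out,
                  linked = factor(ifelse(runif(400) < 0.85, as.integer(out) - 1L,
                                         rbinom(400, 1, 0.5))),
                  noise = factor(rbinom(400, 1, 0.5)))
  avg <- bootstrap_average(d, n_bootstrap = 40, seed = 4)
  rk <- outcome_edge_ranking(avg, "outcome")
  expect_equal(rk$variable[1], "linked")
  expect_equal(nrow(rk), 2L)
  expect_error(outcome_edge_ranking(avg, "nope"), class = "mpe_config_error")
})

test_that("averaged networks export as edge list and DOT", {
  set.seed(40)
  d <- data.frame(a = factor(rbinom(100, 1, 0.5)),
                  b = factor(rbinom(100, 1, 0.5)))
  avg <- bootstrap_average(d, n_bootstrap = 5, seed = 1)
  tf1 <- tempfile(fileext = ".tsv"); tf2 <- tempfile(fileext = ".dot")
  on.exit(unlink(c(tf1, tf2)))
  write_edge_list(avg, tf1)
  back <- read.delim(tf1)
  expect_equal(nrow(back), 1L)
  write_dot(avg, tf2)
  expect_match(readLines(tf2)[1], "graph")
})
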
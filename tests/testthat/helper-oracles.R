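# Independent oracles and small fixture generators used across tests.

# Exhaustive optimum over all DAGs on <= 3 nodes (25 DAGs on 3 nodes),
# scored with score_network(); independent of the greedy search path.
exhaustive_best_score <- function(data) {
  vars <- names(data)
  stopifnot(length(vars) <= 3)
  allarcs <- expand.grid(from = vars, to = vars, stringsAsFactors = FALSE)
  allarcs <- allarcs[allarcs$from != allarcs$to, , drop = FALSE]
  narc <- nrow(allarcs)
  best <- -Inf
  for (s in 0:(2^narc - 1)) {
    sel <- as.logical(intToBits(s)[seq_len(narc)])
    arcs <- as.matrix(allarcs[sel, , drop = FALSE])
    if (nrow(arcs)) {
      pairs <- apply(arcs, 1, function(r) paste(sort(r), collapse = "-"))
      if (anyDuplicated(pairs)) next          # both directions = cycle
      am <- matrix(0, length(vars), length(vars),
                   dimnames = list(vars, vars))
      am[arcs] <- 1
      # cycle check via trace of matrix powers
      if (sum(diag(am %*% am %*% am)) + sum(diag(am %*% am)) > 0) next
    }
    sc <- score_network(data, arcs)$score
    if (sc > best) best <- sc
  }
  best
}

# Brute-force grid-search maximizer of the 1-parameter conditional
# log-likelihood over matched sets.
grid_search_clogit <- function(x, case, set, lo = -2, hi = 2, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  sets <- split(seq_along(x), set)
  ll <- vapply(grid, function(b) {
    eta <- x * b
    sum(vapply(sets, function(i) eta[i][case[i]] - log(sum(exp(eta[i]))), 0))
  }, 0)
  grid[which.max(ll)]
}

# Matched sets generated directly under a within-set conditional logit
# with a single exposure and true coefficient `beta`; returns a design
# ready for clogit_fit.
make_conditional_logit_sets <- function(n_sets, m = 3, beta = 0,
                                        x_gen = function(n) rnorm(n)) {
  n <- n_sets * m
  x <- x_gen(n)
  set <- rep(seq_len(n_sets), each = m)
  case <- logical(n)
  for (s in seq_len(n_sets)) {
    i <- which(set == s)
    pr <- exp(beta * x[i]); pr <- pr / sum(pr)
    case[i[sample.int(m, 1, prob = pr)]] <- TRUE
  }
  list(x = x, case = case, set = set)
}

# Case-only data with subtype drawn from a multinomial logit on a
# per-allele exposure (reference WT); slopes = c(KRAS, BRAF) log-RORs.
make_case_case_data <- function(n, slopes = c(0, 0), maf = 0.3,
                                intercepts = c(-0.65, -0.73)) {
  g <- rbinom(n, 2, maf)
  eta <- cbind(0, intercepts[1] + slopes[1] * g, intercepts[2] + slopes[2] * g)
  pr <- exp(eta) / rowSums(exp(eta))
  lab <- c("WT", "KRAS", "BRAF")
  subtype <- vapply(seq_len(n),
                    function(i) sample(lab, 1, prob = pr[i, ]), "")
  data.frame(subtype = subtype, allele = g, stringsAsFactors = FALSE)
}

# Small cohort configs used in several files.
tiny_config <- function(seed = 1, n_cases = 60, ...) {
  sim_config(n_cases = n_cases, missingness_rate = 0, seed = seed, ...)
}
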
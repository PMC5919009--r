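# Discrete Bayesian-network structure learning: AIC-scored hill climbing
# with bootstrap model averaging. Data are frames of factors; internally
# each variable is an integer code vector with a known level count.

# -- data preparation ---------------------------------------------------

bn_prepare <- function(data) {
  stopifnot(is.data.frame(data), ncol(data) >= 1)
  codes <- lapply(data, function(col) {
    f <- if (is.factor(col)) col else factor(col)
    as.integer(f)
  })
  nlev <- vapply(data, function(col) {
    f <- if (is.factor(col)) col else factor(col)
    nlevels(f)
  }, 1L)
  if (anyNA(unlist(codes, use.names = FALSE)))
    stop_mpe("network learning requires complete-case data", "mpe_config_error")
  if (any(nlev < 2L))
    stop_mpe(paste0("variables with a single observed level: ",
                    paste(names(data)[nlev < 2L], collapse = ", ")),
             "mpe_config_error")
  list(codes = codes, nlev = nlev, vars = names(data), n = nrow(data))
}

#' Local AIC score of one node given a parent set
#'
#' The decomposable network score of a discrete node: the multinomial
#' log-likelihood `sum N_jk log(N_jk / N_j.)` over observed parent
#' configurations `j` and child levels `k` (with `0 log 0 = 0`), minus the
#' AIC penalty of one per free parameter, `(r - 1) * q`, where `r` is the
#' number of child levels and `q` the number of observed parent
#' configurations (1 when the parent set is empty). Higher is better.
#'
#' @param data Data frame of factors (complete cases).
#' @param child Child variable name.
#' @param parents Character vector of parent names (possibly empty).
#' @return The local score (numeric scalar).
#' @examples
#' d <- data.frame(y = factor(rep(c("a", "b"), c(7, 3))))
#' local_aic_score(d, "y", character())  # 7*log(0.7) + 3*log(0.3) - 1
#' @export
local_aic_score <- function(data, child, parents = character()) {
  prep <- bn_prepare(data)
  if (!child %in% prep$vars || !all(parents %in% prep$vars) ||
      child %in% parents)
    stop_mpe("child and parents must be distinct dataset variables",
             "mpe_config_error")
  bn_local_score(prep, child, parents)
}

bn_local_score <- function(prep, child, parents) {
  cc <- prep$codes[[child]]
  r <- prep$nlev[[child]]
  if (!length(parents)) {
    counts <- tabulate(cc, r)
    q <- 1L
    ll <- sum(counts[counts > 0] * log(counts[counts > 0] / prep$n))
  } else {
    key <- prep$codes[[parents[1]]]
    if (length(parents) > 1L) {
      mult <- prep$nlev[[parents[1]]]
      for (pv in parents[-1]) {
        key <- key + mult * (prep$codes[[pv]] - 1L)
        mult <- mult * prep$nlev[[pv]]
      }
    }
    pidx <- match(key, unique(key))
    q <- max(pidx)
    counts <- tabulate((pidx - 1L) * r + cc, q * r)
    cm <- matrix(counts, nrow = r)
    nj <- colSums(cm)
    pos <- cm > 0
    ll <- sum(cm[pos] * log(cm[pos] / rep(nj, each = r)[pos]))
  }
  ll - (r - 1) * q
}

# -- DAG utilities ------------------------------------------------------

# adjacency matrix amat[i, j] = 1 means arc i -> j
bn_has_path <- function(amat, from, to) {
  # DFS: is there a directed path from `from` to `to`?
  p <- ncol(amat)
  visited <- logical(p)
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (visited[v]) next
    visited[v] <- TRUE
    stack <- c(stack, which(amat[v, ] == 1L & !visited))
  }
  FALSE
}

#' Score a whole DAG (sum of local AIC scores)
#'
#' @param data Data frame of factors.
#' @param arcs Two-column character matrix (from, to), possibly 0 rows.
#' @return List with `score` and `per_node_scores`.
#' @export
score_network <- function(data, arcs) {
  prep <- bn_prepare(data)
  per_node <- vapply(prep$vars, function(v) {
    parents <- if (length(arcs)) arcs[arcs[, 2] == v, 1] else character()
    bn_local_score(prep, v, parents)
  }, 0)
  list(score = sum(per_node), per_node_scores = per_node)
}

#' Greedy hill-climbing structure search with the AIC score
#'
#' Starts from the empty graph and repeatedly applies the single-arc
#' addition, deletion or reversal with the largest strict score
#' improvement, maintaining acyclicity, until no move improves the score.
#' Ties between equally improving moves are broken deterministically
#' (lexicographically by child, parent, and move type), so results are
#' reproducible.
#'
#' @param data Data frame of factors, complete cases, >= 1 variable.
#' @param max_parents Cap on the in-degree (default 8, a computational
#'   guard rarely hit at these sample sizes).
#' @return Object of class `bn_fit`: `arcs` (two-column matrix from/to),
#'   `score`, `per_node_scores`, `nodes`.
#' @export
hill_climb <- function(data, max_parents = 8L) {
  prep <- bn_prepare(data)
  p <- length(prep$vars)
  amat <- matrix(0L, p, p, dimnames = list(prep$vars, prep$vars))
  cache <- new.env(parent = emptyenv())
  lscore <- function(child_i, parent_is) {
    key <- paste0(child_i, "|", paste(sort(parent_is), collapse = ","))
    got <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(got)) return(got)
    val <- bn_local_score(prep, prep$vars[child_i],
                          prep$vars[sort(parent_is)])
    assign(key, val, envir = cache)
    val
  }
  node_score <- vapply(seq_len(p), function(i) lscore(i, integer()), 0)

  repeat {
    best <- list(delta = 0, move = NULL)
    consider <- function(delta, move) {
      # strict improvement; deterministic lexicographic tie-break
      if (delta > best$delta + 1e-12 ||
          (abs(delta - best$delta) <= 1e-12 && !is.null(best$move) &&
           paste(move, collapse = "-") < paste(best$move, collapse = "-") &&
           delta > 1e-12)) {
        best <<- list(delta = delta, move = move)
      }
    }
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      pj <- which(amat[, j] == 1L)
      if (amat[i, j] == 1L) {
        ## deletion i -> j
        d <- lscore(j, setdiff(pj, i)) - node_score[j]
        consider(d, c("del", i, j))
        ## reversal i -> j  =>  j -> i
        amat2 <- amat; amat2[i, j] <- 0L
        if (!bn_has_path(amat2, i, j)) {  # another i->j path would cycle with j->i
          pi_ <- which(amat[, i] == 1L)
          if (length(pi_) < max_parents) {
            d <- (lscore(j, setdiff(pj, i)) - node_score[j]) +
                 (lscore(i, c(pi_, j)) - node_score[i])
            consider(d, c("rev", i, j))
          }
        }
      } else if (amat[j, i] == 0L) {
        ## addition i -> j (skipped if j -> i exists)
        if (length(pj) >= max_parents) next
        if (bn_has_path(amat, j, i)) next   # would create a cycle
        d <- lscore(j, c(pj, i)) - node_score[j]
        consider(d, c("add", i, j))
      }
    }
    if (is.null(best$move) || best$delta <= 1e-12) break
    mv <- best$move
    i <- as.integer(mv[2]); j <- as.integer(mv[3])
    if (mv[1] == "add") {
      amat[i, j] <- 1L
      node_score[j] <- lscore(j, which(amat[, j] == 1L))
    } else if (mv[1] == "del") {
      amat[i, j] <- 0L
      node_score[j] <- lscore(j, which(amat[, j] == 1L))
    } else {
      amat[i, j] <- 0L; amat[j, i] <- 1L
      node_score[j] <- lscore(j, which(amat[, j] == 1L))
      node_score[i] <- lscore(i, which(amat[, i] == 1L))
    }
  }

  arcs <- which(amat == 1L, arr.ind = TRUE)
  arcs <- cbind(from = prep$vars[arcs[, 1]], to = prep$vars[arcs[, 2]])
  structure(list(arcs = arcs, score = sum(node_score),
                 per_node_scores = stats::setNames(node_score, prep$vars),
                 nodes = prep$vars),
            class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat(sprintf("Hill-climbed network: %d nodes, %d arcs, AIC score %.3f\n",
              length(x$nodes), nrow(x$arcs), x$score))
  invisible(x)
}

#' Bootstrap-averaged network with edge confidences
#'
#' Draws `n_bootstrap` nonparametric row resamples of the data (same size,
#' with replacement), learns a network on each by [hill_climb()], and
#' records for every unordered variable pair the fraction of replicates
#' containing an arc between them in either direction (edge confidence),
#' plus per-direction fractions. The inclusion threshold is estimated from
#' the confidence distribution by [estimate_threshold()]. Optionally
#' resamples matched sets instead of rows.
#'
#' @param data Data frame of factors.
#' @param n_bootstrap Number of replicates (>= 1; the reference design uses
#'   1000).
#' @param seed Integer seed; the run is reproducible bit-exactly.
#' @param set_id Optional vector of matched-set identifiers; when given,
#'   whole sets are resampled rather than rows.
#' @param max_parents Passed to [hill_climb()].
#' @return Object of class `bn_averaged`: `edges` (data frame with
#'   `var1`, `var2`, `confidence`, `dir_forward`, `dir_backward`,
#'   `included`), `threshold`, `n_bootstrap`, `nodes`.
#' @export
bootstrap_average <- function(data, n_bootstrap = 1000L, seed = 1L,
                              set_id = NULL, max_parents = 8L) {
  if (n_bootstrap < 1) stop_mpe("n_bootstrap must be >= 1", "mpe_config_error")
  vars <- names(data)
  p <- length(vars)
  count_arc <- matrix(0L, p, p, dimnames = list(vars, vars))
  set.seed(as.integer(seed))
  n <- nrow(data)
  for (b in seq_len(n_bootstrap)) {
    rows <- if (is.null(set_id)) {
      sample.int(n, n, replace = TRUE)
    } else {
      ids <- unique(set_id)
      picked <- sample(ids, length(ids), replace = TRUE)
      unlist(lapply(picked, function(s) which(set_id == s)), use.names = FALSE)
    }
    db <- droplevels(data[rows, , drop = FALSE])
    ok <- vapply(db, function(col) nlevels(factor(col)) >= 2L, TRUE)
    if (!all(ok)) next  # resample lost a level entirely; count as empty graph
    fit <- hill_climb(db, max_parents = max_parents)
    if (nrow(fit$arcs))
      for (k in seq_len(nrow(fit$arcs)))
        count_arc[fit$arcs[k, 1], fit$arcs[k, 2]] <-
          count_arc[fit$arcs[k, 1], fit$arcs[k, 2]] + 1L
  }

  pairs <- utils::combn(vars, 2)
  edges <- data.frame(
    var1 = pairs[1, ], var2 = pairs[2, ],
    confidence = NA_real_, dir_forward = NA_real_, dir_backward = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(ncol(pairs))) {
    f <- count_arc[pairs[1, k], pairs[2, k]]
    bwd <- count_arc[pairs[2, k], pairs[1, k]]
    edges$confidence[k] <- (f + bwd) / n_bootstrap
    edges$dir_forward[k] <- f / n_bootstrap
    edges$dir_backward[k] <- bwd / n_bootstrap
  }
  thr <- estimate_threshold(edges$confidence)
  edges$included <- edges$confidence > thr
  structure(list(edges = edges, threshold = thr, n_bootstrap = n_bootstrap,
                 nodes = vars),
            class = "bn_averaged")
}

#' @export
print.bn_averaged <- function(x, ...) {
  cat(sprintf("Averaged network over %d bootstrap replicates: %d nodes\n",
              x$n_bootstrap, length(x$nodes)))
  cat(sprintf("  inclusion threshold %.3f; %d of %d edges included\n",
              x$threshold, sum(x$edges$included), nrow(x$edges)))
  invisible(x)
}

#' Estimate the edge-confidence inclusion threshold
#'
#' Models the ideal confidence distribution as a two-point mixture putting
#' mass `t` at 0 (noise edges) and `1 - t` at 1 (true edges), whose CDF is
#' the step function `F_t(x) = t` on `[0, 1)`. The estimate `t-hat`
#' minimizes the L1 distance between the empirical CDF of the observed
#' confidences and `F_t`; the returned threshold is the empirical
#' `t-hat`-quantile (inverse ECDF) of the confidences. Edges with
#' confidence strictly above the threshold are included.
#'
#' @param confidences Numeric vector of proportions in `[0, 1]`.
#' @return Threshold in `[0, 1]`.
#' @export
estimate_threshold <- function(confidences) {
  x <- confidences[!is.na(confidences)]
  if (!length(x)) stop_mpe("no confidences supplied", "mpe_config_error")
  if (any(x < 0 | x > 1)) stop_mpe("confidences must lie in [0, 1]",
                                   "mpe_domain_error")
  xs <- sort(x)
  n <- length(xs)
  # empirical CDF is piecewise constant on [0, 1): segment heights and widths
  knots <- unique(c(0, xs[xs < 1], 1))
  heights <- vapply(knots[-length(knots)],
                    function(u) mean(xs <= u), 0)
  widths <- diff(knots)
  # L1 loss sum(widths * |heights - t|) is minimized at a weighted median
  ord <- order(heights)
  h <- heights[ord]; w <- widths[ord]
  cw <- cumsum(w)
  t_hat <- h[which(cw >= sum(w) / 2)[1]]
  if (t_hat <= 0) return(0)
  # inverse-ECDF quantile of the confidences at t_hat
  xs[max(1L, ceiling(n * t_hat))]
}

#' Rank exposures by edge confidence with the outcome node
#'
#' @param avg A [bootstrap_average()] result.
#' @param outcome Outcome node name.
#' @return Data frame with `variable`, `confidence`, `included`, sorted by
#'   descending confidence (alphabetical tie-break).
#' @export
outcome_edge_ranking <- function(avg, outcome = "outcome") {
  stopifnot(inherits(avg, "bn_averaged"))
  if (!outcome %in% avg$nodes)
    stop_mpe(paste0("unknown outcome node: ", outcome), "mpe_config_error")
  e <- avg$edges
  sel <- e$var1 == outcome | e$var2 == outcome
  other <- ifelse(e$var1[sel] == outcome, e$var2[sel], e$var1[sel])
  out <- data.frame(variable = other, confidence = e$confidence[sel],
                    included = e$included[sel], stringsAsFactors = FALSE)
  out[order(-out$confidence, out$variable), , drop = FALSE]
}

#' Export the averaged network
#'
#' `write_edge_list()` writes the delimited edge table; `write_dot()`
#' writes a Graphviz DOT rendering of the included edges (edge width
#' proportional to confidence).
#'
#' @param avg A `bn_averaged`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(avg, path) {
  utils::write.table(avg$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_dot <- function(avg, path) {
  inc <- avg$edges[avg$edges$included, , drop = FALSE]
  lines <- c("graph averaged_network {",
             paste0('  "', avg$nodes, '";'),
             if (nrow(inc)) sprintf('  "%s" -- "%s" [penwidth=%.2f, label="%.2f"];',
                                    inc$var1, inc$var2,
                                    0.5 + 4 * inc$confidence, inc$confidence),
             "}")
  writeLines(lines, path)
  invisible(path)
}
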
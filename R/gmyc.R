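# General mixed Yule coalescent (GMYC) species delimitation.
#
# The model places a threshold age T on a chronogram: nodes older than T
# are speciation events, nodes younger than T are coalescences.  A branch
# belongs to the diversification (generalized Yule) process when its parent
# node is a speciation node -- so a species' stem lineage stays in the
# diversification process until its first sub-threshold branching -- with
# per-interval rate lambda1 * k^p1, while branches whose parent lies inside
# a subthreshold subtree belong to that group's coalescent process, with
# total rate lambda2 * sum_j [n_j (n_j - 1)]^p2 shared across groups via
# one (lambda2, p2).  Inter-event waiting times x_i between
# successive branching events then have the mixed-process likelihood
#   logL = sum_events log b_i - sum_i b_i x_i,
# with b_i the total rate during interval i (the final interval, ending at
# the present, contributes only its survival term).  The null model is a
# single generalized-Yule process over all branches.  Tips within one
# coalescent subtree form an entity (putative species).
#
# Internally a model state is the set S of "species nodes" (internal nodes
# assigned to the diversification process); a single threshold T induces
# S = {nodes older than T}, and the multiple-threshold search explores
# general rootward-closed S.

# ---- state construction -----------------------------------------------------

# S: logical over all node ids (tips always FALSE), rootward-closed.
gmyc_state <- function(tree, S) {
  tree <- as_chronogram(tree)
  n <- length(tree$tip.label)
  ages <- node_ages(tree)
  edge <- tree$edge  # cladewise: parents before children
  root <- n + 1L
  # group root of every node (NA inside the diversification region)
  groot <- rep(NA_integer_, n + tree$Nnode)
  if (!S[root]) groot[root] <- root
  for (r in seq_len(nrow(edge))) {
    u <- edge[r, 1L]; w <- edge[r, 2L]
    if (w > n && S[w]) next                 # diversification region
    groot[w] <- if (is.na(groot[u])) w else groot[u]
  }
  ev_ages <- sort(ages[(n + 1L):(n + tree$Nnode)], decreasing = TRUE)
  lower <- c(ev_ages[-1L], 0)
  mids <- (ev_ages + lower) / 2
  x <- ev_ages - lower
  child_age <- ages[edge[, 2L]]
  parent_age <- ages[edge[, 1L]]
  # parent rule: a branch is diversification iff its parent is a species
  # node; otherwise it coalesces within its parent's group
  yule_branch <- S[edge[, 1L]]
  branch_group <- groot[edge[, 2L]]
  kvec <- integer(n - 1L)
  cidx <- integer(0); cprod <- numeric(0)
  for (i in seq_len(n - 1L)) {
    cross <- child_age < mids[i] & parent_age > mids[i]
    kvec[i] <- sum(cross & yule_branch)
    grp <- branch_group[cross & !yule_branch]
    if (length(grp) > 0L) {
      tab <- table(grp)
      prod <- as.numeric(tab) * (as.numeric(tab) - 1)
      keep <- prod > 0
      if (any(keep)) {
        cidx <- c(cidx, rep(i, sum(keep)))
        cprod <- c(cprod, prod[keep])
      }
    }
  }
  list(n = n, x = x, kvec = kvec, cidx = cidx, cprod = cprod,
       n_events = n - 2L, S = S, groot = groot, tree = tree)
}

state_from_threshold <- function(tree, threshold) {
  tree <- as_chronogram(tree)
  n <- length(tree$tip.label)
  ages <- node_ages(tree)
  S <- c(rep(FALSE, n), ages[(n + 1L):(n + tree$Nnode)] > threshold)
  S
}

# total-rate vector b_i given parameters (lambda1, p1, lambda2, p2)
state_rates <- function(st, lambda1, p1, lambda2, p2) {
  b <- lambda1 * st$kvec^p1
  if (length(st$cidx) > 0L) {
    add <- rowsum(st$cprod^p2, st$cidx)
    b[as.integer(rownames(add))] <- b[as.integer(rownames(add))] + lambda2 * add[, 1L]
  }
  b
}

state_loglik <- function(st, lambda1, p1, lambda2, p2) {
  b <- state_rates(st, lambda1, p1, lambda2, p2)
  ev <- seq_len(st$n_events)
  if (st$n_events > 0L && any(b[ev] <= 0)) return(-Inf)
  sum(log(b[ev])) - sum(b * st$x)
}

#' GMYC mixed-model log-likelihood at fixed parameters
#'
#' @param tree a `chronogram`.
#' @param threshold threshold age T (Myr); nodes older than T belong to the
#'   diversification process.
#' @param lambda1,p1 rate and exponent of the diversification process.
#' @param lambda2,p2 rate and exponent shared by the coalescent groups.
#' @return the log-likelihood (may be `-Inf` when an observed event falls
#'   in an interval with zero model rate).
#' @export
gmyc_loglik <- function(tree, threshold, lambda1, p1, lambda2, p2) {
  if (lambda1 <= 0 || lambda2 <= 0) stopf("rates must be > 0")
  if (threshold < 0) stopf("`threshold` must be >= 0")
  st <- gmyc_state(tree, state_from_threshold(tree, threshold))
  state_loglik(st, lambda1, p1, lambda2, p2)
}

# null single-process likelihood: one generalized Yule over all branches
null_loglik <- function(n, x, lambda0, p0) {
  k <- seq(2L, n)
  b <- lambda0 * k^p0
  sum(log(b[seq_len(n - 2L)])) - sum(b * x)
}

# ---- entities ---------------------------------------------------------------

entities_from_state <- function(st) {
  tree <- st$tree
  n <- st$n
  desc <- tip_descendants(tree)
  # group roots are the distinct groot values of tips (every tip is in a group)
  roots <- sort(unique(st$groot[seq_len(n)]))
  lapply(roots, function(g) tree$tip.label[desc[[g]]])
}

#' Delimit entities at a fixed GMYC threshold
#'
#' @param tree a `chronogram`.
#' @param threshold threshold age (Myr).
#' @return list of character vectors of tip labels, one per entity.
#' @export
gmyc_entities <- function(tree, threshold) {
  st <- gmyc_state(as_chronogram(tree), state_from_threshold(tree, threshold))
  entities_from_state(st)
}

# ---- fitting ----------------------------------------------------------------

fit_state_params <- function(st, starts, exponent_bounds) {
  lo <- c(log(1e-10), exponent_bounds[[1L]], log(1e-10), exponent_bounds[[1L]])
  hi <- c(log(1e10), exponent_bounds[[2L]], log(1e10), exponent_bounds[[2L]])
  obj <- function(par) {
    ll <- state_loglik(st, exp(par[1L]), par[2L], exp(par[3L]), par[4L])
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[r, ], obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e12) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(lambda1 = exp(best$par[[1L]]), p1 = best$par[[2L]],
       lambda2 = exp(best$par[[3L]]), p2 = best$par[[4L]],
       logL = -best$value)
}

fit_null_params <- function(n, x, starts2, exponent_bounds) {
  lo <- c(log(1e-10), exponent_bounds[[1L]])
  hi <- c(log(1e10), exponent_bounds[[2L]])
  obj <- function(par) {
    ll <- null_loglik(n, x, exp(par[1L]), par[2L])
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  best <- NULL
  for (r in seq_len(nrow(starts2))) {
    fit <- tryCatch(
      stats::optim(starts2[r, ], obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stopf("null model optimization failed")
  list(lambda0 = exp(best$par[[1L]]), p0 = best$par[[2L]], logL = -best$value)
}

gmyc_candidates <- function(tree) {
  tree <- as_chronogram(tree)
  n <- length(tree$tip.label)
  ages <- sort(unique(node_ages(tree)[(n + 1L):(n + tree$Nnode)]),
               decreasing = TRUE)
  mids <- if (length(ages) > 1L) (ages[-length(ages)] + ages[-1L]) / 2 else numeric(0)
  c(ages[[1L]] * 1.01,          # older than the root: everything coalescent
    mids,
    ages[[length(ages)]] / 2)   # younger than every node: everything Yule
}

gmyc_starts <- function(n, x, n_restarts, seed) {
  lam0 <- (n - 2L) / max(sum(seq(2L, n) * x), .Machine$double.eps)
  base <- c(log(lam0), 1, log(lam0), 1)
  jit <- with_seed(seed,
                   matrix(stats::rnorm(4L * max(n_restarts - 1L, 0L), 0, 1.5),
                          ncol = 4L))
  starts <- rbind(base, sweep(jit, 2L, base, `+`))
  starts[, 2L] <- pmin(pmax(starts[, 2L], 1e-3), 3)
  starts[, 4L] <- pmin(pmax(starts[, 4L], 1e-3), 3)
  starts
}

#' Fit the single-threshold GMYC model
#'
#' Profiles candidate thresholds at the midpoints between consecutive
#' distinct node ages, plus two degenerate extremes (older than the root:
#' one all-coalescent entity; younger than every node: all-singleton
#' entities), maximizing (lambda1, p1, lambda2, p2) numerically at each
#' candidate with multi-start L-BFGS-B.  The null single-process model
#' (lambda0, p0) is fitted for the likelihood-ratio test (df = 3 by
#' convention: threshold plus one extra rate and exponent).
#'
#' @param tree a `chronogram` with >= 3 tips.
#' @param exponent_bounds bounds for the exponents p (default `c(1e-3, 3)`).
#' @param n_restarts optimizer starts per candidate threshold.
#' @param seed seed for the start jitter.
#' @param df degrees of freedom used in the likelihood-ratio test.
#' @return an object of class `gmyc_fit`; see Details.
#' @details The returned list carries the threshold age, process
#'   parameters, `logL_alt`, the null parameters and `logL_null`, the
#'   delimited `entities` (list of tip-label vectors), `n_entities`,
#'   `n_clusters` (entities with >= 2 tips), and the likelihood-ratio
#'   `statistic` / `p_value`.
#' @export
fit_gmyc_single <- function(tree, exponent_bounds = c(1e-3, 3),
                            n_restarts = 5L, seed = NULL, df = 3L) {
  tree <- as_chronogram(tree)
  n <- length(tree$tip.label)
  if (n < 3L) stopf("GMYC fitting needs >= 3 tips")
  bt_x <- gmyc_state(tree, state_from_threshold(tree, -1))$x  # any S: x fixed
  starts <- gmyc_starts(n, bt_x, n_restarts, seed)
  null_fit <- fit_null_params(n, bt_x, starts[, 1:2, drop = FALSE],
                              exponent_bounds)
  # include the null solution among the starts: guarantees logL_alt >= logL_null
  starts <- rbind(starts,
                  c(log(null_fit$lambda0), null_fit$p0,
                    log(null_fit$lambda0), null_fit$p0))
  cands <- gmyc_candidates(tree)
  best <- NULL
  for (Tc in cands) {
    st <- gmyc_state(tree, state_from_threshold(tree, Tc))
    fit <- fit_state_params(st, starts, exponent_bounds)
    if (is.null(fit)) next
    if (is.null(best) || fit$logL > best$fit$logL) {
      best <- list(threshold = Tc, st = st, fit = fit)
    }
  }
  if (is.null(best)) {
    stopf("fit-failure: no candidate threshold converged (%d candidates, %d starts)",
          length(cands), nrow(starts))
  }
  finish_gmyc_fit(best$st, best$fit, threshold = best$threshold,
                  method = "single", null_fit = null_fit, df = df,
                  n_thresholds = 1L)
}

finish_gmyc_fit <- function(st, fit, threshold, method, null_fit, df,
                            n_thresholds) {
  ent <- entities_from_state(st)
  sizes <- lengths(ent)
  lr <- lr_test(logL_null = null_fit$logL, logL_alt = fit$logL, df = df)
  structure(
    list(method = method,
         threshold = threshold,
         n_thresholds = n_thresholds,
         lambda1 = fit$lambda1, p1 = fit$p1,
         lambda2 = fit$lambda2, p2 = fit$p2,
         logL_alt = fit$logL,
         logL_null = null_fit$logL,
         null_lambda = null_fit$lambda0, null_p = null_fit$p0,
         entities = ent,
         n_entities = length(ent),
         n_clusters = sum(sizes >= 2L),
         n_singletons = sum(sizes == 1L),
         statistic = lr$statistic, df = lr$df, p_value = lr$p_value,
         aic = -2 * fit$logL + 2 * (4 + n_thresholds),
         state = st),
    class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(sprintf("GMYC fit (%s threshold)\n", x$method))
  if (x$method == "single") {
    cat(sprintf("  threshold age: %.4g\n", x$threshold))
  } else {
    cat(sprintf("  local thresholds: %d\n", x$n_thresholds))
  }
  cat(sprintf("  entities: %d (%d clusters + %d singletons)\n",
              x$n_entities, x$n_clusters, x$n_singletons))
  cat(sprintf("  logL alt %.4f | null %.4f | LR %.3f (df %d) p = %.4f\n",
              x$logL_alt, x$logL_null, x$statistic, x$df, x$p_value))
  invisible(x)
}

# minimal number of threshold ages consistent with S: greedy interval
# stabbing of the (group-root age, parent age) windows
count_thresholds <- function(st) {
  tree <- st$tree
  n <- st$n
  ages <- node_ages(tree)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  roots <- sort(unique(st$groot[seq_len(n)]))
  roots <- roots[roots != n + 1L]          # whole-tree group: no boundary
  if (length(roots) == 0L) return(0L)
  lo <- ages[roots]
  hi <- ages[parent[roots]]
  ord <- order(hi)
  lo <- lo[ord]; hi <- hi[ord]
  count <- 0L
  cover <- -Inf
  for (i in seq_along(lo)) {
    if (lo[i] >= cover) {  # current stab point (just below hi of a window)
      count <- count + 1L
      cover <- hi[i]
    }
  }
  count
}

#' Fit the multiple-threshold GMYC model
#'
#' Greedy stepwise search over assignments of internal nodes to the
#' diversification process, starting from the single-threshold optimum:
#' each step proposes moving one coalescent group's local threshold by one
#' node (claiming a group root for the diversification process, or
#' releasing a frontier species node into its coalescent group), refits
#' the process parameters, and accepts the best AIC improvement; the
#' search stops when no move improves the AIC or `max_thresholds` local
#' thresholds are in play.  AIC counts 4 process parameters plus the
#' minimal number of distinct threshold ages consistent with the
#' assignment.
#'
#' @inheritParams fit_gmyc_single
#' @param max_thresholds cap on the number of local threshold ages.
#' @param n_restarts optimizer restarts per proposal (the incumbent
#'   parameters are always one start).
#' @return a `gmyc_fit` with `method = "multiple"`.
#' @export
fit_gmyc_multiple <- function(tree, max_thresholds = 10L,
                              exponent_bounds = c(1e-3, 3),
                              n_restarts = 2L, seed = NULL, df = 3L) {
  tree <- as_chronogram(tree)
  n <- length(tree$tip.label)
  single <- fit_gmyc_single(tree, exponent_bounds = exponent_bounds,
                            seed = seed, df = df)
  null_fit <- list(lambda0 = single$null_lambda, p0 = single$null_p,
                   logL = single$logL_null)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  children <- split(tree$edge[, 2L], tree$edge[, 1L])

  cur_S <- single$state$S
  cur <- list(st = single$state,
              fit = list(lambda1 = single$lambda1, p1 = single$p1,
                         lambda2 = single$lambda2, p2 = single$p2,
                         logL = single$logL_alt),
              tcount = count_thresholds(single$state))
  cur_aic <- -2 * cur$fit$logL + 2 * (4 + max(cur$tcount, 1L))
  incumbent_par <- c(log(cur$fit$lambda1), cur$fit$p1,
                     log(cur$fit$lambda2), cur$fit$p2)
  extra_starts <- gmyc_starts(n, cur$st$x, n_restarts, seed)

  repeat {
    internal <- seq(n + 1L, n + tree$Nnode)
    parent_in_S <- internal == root  # the root has no parent
    has_parent <- internal != root
    parent_in_S[has_parent] <- cur_S[parent[internal[has_parent]]]
    addable <- internal[!cur_S[internal] & parent_in_S]
    removable <- internal[vapply(internal, function(v) {
      cur_S[v] && !any(cur_S[children[[as.character(v)]]])
    }, logical(1))]
    proposals <- c(lapply(addable, function(v) list(node = v, add = TRUE)),
                   lapply(removable, function(v) list(node = v, add = FALSE)))
    best_move <- NULL
    for (pr in proposals) {
      S2 <- cur_S
      S2[pr$node] <- pr$add
      st2 <- gmyc_state(tree, S2)
      tc2 <- count_thresholds(st2)
      if (tc2 > max_thresholds) next
      starts <- rbind(incumbent_par,
                      extra_starts[seq_len(min(n_restarts, nrow(extra_starts))), ,
                                   drop = FALSE])
      fit2 <- fit_state_params(st2, starts, exponent_bounds)
      if (is.null(fit2)) next
      aic2 <- -2 * fit2$logL + 2 * (4 + max(tc2, 1L))
      if (aic2 < cur_aic - 1e-9 &&
          (is.null(best_move) || aic2 < best_move$aic)) {
        best_move <- list(S = S2, st = st2, fit = fit2, tcount = tc2,
                          aic = aic2)
      }
    }
    if (is.null(best_move)) break
    cur_S <- best_move$S
    cur <- list(st = best_move$st, fit = best_move$fit,
                tcount = best_move$tcount)
    cur_aic <- best_move$aic
    incumbent_par <- c(log(cur$fit$lambda1), cur$fit$p1,
                       log(cur$fit$lambda2), cur$fit$p2)
  }
  out <- finish_gmyc_fit(cur$st, cur$fit, threshold = NA_real_,
                         method = "multiple", null_fit = null_fit, df = df,
                         n_thresholds = max(cur$tcount, 1L))
  out$single_logL <- single$logL_alt
  out$single_threshold <- single$threshold
  out
}

#' Likelihood-ratio test against a chi-square reference
#'
#' Computes `2 * (logL_alt - logL_null)` for nested fits (or accepts a
#' precomputed statistic) and returns the upper-tail chi-square
#' probability.  Negative statistics are clamped to 0 with a warning.
#'
#' @param logL_null,logL_alt log-likelihoods of the nested fits (ignored
#'   when `statistic` is given).
#' @param df degrees of freedom (>= 1).
#' @param statistic optional precomputed test statistic.
#' @return list with `statistic`, `df` and `p_value`.
#' @examples
#' lr_test(statistic = 4.419, df = 3)$p_value  # 0.219
#' @export
lr_test <- function(logL_null = NULL, logL_alt = NULL, df = 1L,
                    statistic = NULL) {
  if (!is_count(df)) stopf("`df` must be a positive integer")
  if (is.null(statistic)) {
    if (is.null(logL_null) || is.null(logL_alt)) {
      stopf("provide either both log-likelihoods or a `statistic`")
    }
    statistic <- 2 * (logL_alt - logL_null)
  }
  if (statistic < 0) {
    warnf("negative likelihood-ratio statistic (%.3g) clamped to 0", statistic)
    statistic <- 0
  }
  list(statistic = statistic, df = as.integer(df),
       p_value = stats::pchisq(statistic, df = df, lower.tail = FALSE))
}
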
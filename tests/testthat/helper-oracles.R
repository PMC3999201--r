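# Independent oracles and fixture builders used across the suite.  These
# deliberately re-derive quantities with different algorithms (explicit
# site-by-site loops, naive tree climbing, grid searches) so that agreement
# with the package implementations is informative.

# site-by-site K2P: explicit transition lookup table
oracle_k2p <- function(a, b) {
  transitions <- c("AG", "GA", "CT", "TC")
  det <- c("A", "C", "G", "T")
  s <- 0L; v <- 0L; m <- 0L
  for (i in seq_along(a)) {
    if (!(a[i] %in% det) || !(b[i] %in% det)) next
    m <- m + 1L
    if (a[i] == b[i]) next
    if (paste0(a[i], b[i]) %in% transitions) s <- s + 1L else v <- v + 1L
  }
  if (m == 0L) return(NULL)
  P <- s / m; Q <- v / m
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    return(list(d = NA_real_, s = s, v = v, m = m, saturated = TRUE))
  }
  list(d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
       s = s, v = v, m = m, saturated = FALSE)
}

# random aligned sequences over the full alphabet
random_alignment <- function(n_seq, len,
                             probs = c(A = .22, C = .2, G = .2, T = .22,
                                       N = .1, `-` = .06)) {
  mat <- matrix(sample(names(probs), n_seq * len, replace = TRUE,
                       prob = probs),
                nrow = n_seq,
                dimnames = list(paste0("seq", seq_len(n_seq)), NULL))
  new_alignment(mat)
}

# naive GMYC interval enumerator: climbs the tree explicitly per branch
oracle_gmyc_loglik <- function(phy, thr, l1, p1, l2, p2) {
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth[seq_len(n)]) - depth
  age[seq_len(n)] <- 0
  parent_of <- integer(n + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  ev <- sort(age[(n + 1):(n + phy$Nnode)], decreasing = TRUE)
  bounds <- c(ev, 0)
  logL <- 0
  for (i in seq_len(n - 1)) {
    top <- bounds[i]; bottom <- bounds[i + 1]
    mid <- (top + bottom) / 2
    k <- 0L
    groups <- integer(0)
    for (r in seq_len(nrow(phy$edge))) {
      u <- phy$edge[r, 1]; w <- phy$edge[r, 2]
      if (!(age[w] < mid && age[u] > mid)) next
      if (age[u] > thr) {
        k <- k + 1L
      } else {
        g <- u
        while (g != n + 1L && age[parent_of[g]] <= thr) g <- parent_of[g]
        groups <- c(groups, g)
      }
    }
    b <- l1 * k^p1
    if (length(groups) > 0) {
      cnt <- table(groups)
      b <- b + l2 * sum((as.numeric(cnt) * (as.numeric(cnt) - 1))^p2)
    }
    if (i <= n - 2) {
      if (b <= 0) return(-Inf)
      logL <- logL + log(b)
    }
    logL <- logL - b * (top - bottom)
  }
  logL
}

# random exactly-ultrametric tree (standard coalescent shape)
random_coal_tree <- function(n) as_chronogram(ape::rcoal(n))

# hand-assembled distance object for clustering tests
make_k2p_dist <- function(ids, d) {
  dimnames(d) <- list(ids, ids)
  zero <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  flag <- matrix("", nrow(d), ncol(d), dimnames = dimnames(d))
  flag[is.na(d)] <- "saturated"
  diag(flag) <- ""
  structure(list(ids = ids, d = d, p_dist = d, P = zero, Q = zero,
                 m = zero + 100L, s = zero, v = zero, flag = flag),
            class = "k2p_dist")
}

# 95% profile interval for the pure-birth rate
pb_profile_ci <- function(bt) {
  n <- bt$n
  S <- sum(seq(2, n) * bt$durations)
  ll <- function(l) (n - 2) * log(l) - l * S
  lhat <- (n - 2) / S
  target <- ll(lhat) - stats::qchisq(0.95, 1) / 2
  c(stats::uniroot(function(l) ll(l) - target, c(lhat / 50, lhat))$root,
    stats::uniroot(function(l) ll(l) - target, c(lhat, lhat * 50))$root)
}
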
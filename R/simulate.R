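# Seeded generators for every input the delimitation/diversification
# pipeline consumes: chronograms under constant or epoch-shifted pure-birth
# models, reconstructed constant birth-death trees, gene trees from a
# coalescent-within-species-tree model, and GTR+Gamma alignments with
# optional N-masking.  All generators are deterministic under (config, seed).

# ---- tree assembler ---------------------------------------------------------
# Builds an ape phylo from a merge history: clusters start as tips (with an
# age for each), merges join two clusters at a given (older) age.  Internal
# nodes are numbered so that the final merge (the root) is Ntip+1, as ape
# expects.

ta_new <- function(tip_labels, tip_ages = numeric(length(tip_labels))) {
  n <- length(tip_labels)
  env <- new.env(parent = emptyenv())
  env$n <- n
  env$labels <- tip_labels
  env$rep_node <- seq_len(n)     # node id of each live cluster's top
  env$rep_age <- tip_ages
  env$q <- 0L                    # merges done
  env$edge <- matrix(0L, nrow = 2L * (n - 1L), ncol = 2L)
  env$len <- numeric(2L * (n - 1L))
  env
}

ta_merge <- function(env, i, j, age) {
  stopifnot(i != j)
  env$q <- env$q + 1L
  v <- env$n + (env$n - 1L) - env$q + 1L
  r <- 2L * env$q
  env$edge[r - 1L, ] <- c(v, env$rep_node[i])
  env$len[r - 1L] <- age - env$rep_age[i]
  env$edge[r, ] <- c(v, env$rep_node[j])
  env$len[r] <- age - env$rep_age[j]
  keep <- setdiff(seq_along(env$rep_node), c(i, j))
  env$rep_node <- c(env$rep_node[keep], v)
  env$rep_age <- c(env$rep_age[keep], age)
  invisible(env)
}

ta_finish <- function(env) {
  stopifnot(length(env$rep_node) == 1L)
  phy <- structure(
    list(edge = env$edge, edge.length = env$len,
         tip.label = env$labels, Nnode = env$n - 1L),
    class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

# ---- piecewise-rate helpers -------------------------------------------------

# Speciation rate as a function of age before present.  `rates` are ordered
# oldest epoch first; `shift_ages` strictly decreasing.  rates[1] applies to
# ages > shift_ages[1], rates[k+1] to ages < shift_ages[k].
check_epochs <- function(rates, shift_ages) {
  if (length(rates) != length(shift_ages) + 1L) {
    stopf("need length(rates) == length(shift_ages) + 1")
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) stopf("all rates must be > 0")
  if (length(shift_ages) > 0L) {
    if (any(shift_ages <= 0)) stopf("shift_ages must be positive")
    if (any(diff(shift_ages) >= 0)) stopf("shift_ages must be strictly decreasing")
  }
  invisible(TRUE)
}

# Waiting time going backward (toward older ages) from `age0`, under hazard
# k * lambda(age); piecewise inversion of the cumulative hazard.
piecewise_wait <- function(age0, k, rates, shift_ages) {
  e <- stats::rexp(1L)
  # epoch boundaries from young to old above age0
  bounds <- sort(shift_ages)             # increasing
  a <- age0
  repeat {
    above <- bounds[bounds > a]
    up <- if (length(above) > 0L) above[[1L]] else Inf
    # rate in (a, up): with b boundaries strictly above a, the segment sits
    # b epochs below the oldest one
    idx <- 1L + sum(bounds > a)             # 1-based from oldest
    lam <- rates[[idx]]
    cap <- k * lam * (up - a)
    if (e <= cap || !is.finite(up)) {
      return(a + e / (k * lam) - age0)
    }
    e <- e - cap
    a <- up
  }
}

# ---- simulators -------------------------------------------------------------

#' Simulate a pure-birth (Yule) chronogram conditioned on its tip count
#'
#' Uses the exact backward construction of the reconstructed pure-birth
#' process: starting at the present with `n_tips` lineages, successive
#' inter-event waits with k lineages are Exp(k * rate), and each event joins
#' two uniformly chosen lineages.  This is the same joint law as growing the
#' process forward from the crown until it holds `n_tips` lineages.
#'
#' @param n_tips number of tips (>= 2).
#' @param rate speciation rate, events / lineage / Myr.
#' @param seed RNG seed.
#' @return a `chronogram` with all tips at age 0.
#' @examples
#' tr <- sim_yule(20, 0.2, seed = 1)
#' branching_times(tr)$crown
#' @export
sim_yule <- function(n_tips, rate, seed = NULL) {
  sim_yule_shift(n_tips, rates = rate, shift_ages = numeric(0), seed = seed)
}

#' Simulate a Yule chronogram with epoch shifts in speciation rate
#'
#' Piecewise-constant pure-birth process with rates attached to age epochs:
#' `rates[1]` applies to ages older than `shift_ages[1]` and
#' `rates[length(rates)]` to the youngest epoch, next to the present.  The
#' construction is backward in age with inter-event hazard k * lambda(age),
#' inverted exactly across epoch boundaries, so the generated branching
#' times follow precisely the likelihood that the piecewise pure-birth
#' fits assume.
#'
#' @param n_tips number of tips (>= 2).
#' @param rates per-epoch speciation rates, oldest epoch first.
#' @param shift_ages epoch boundaries in Myr before present, strictly
#'   decreasing; `length(rates) == length(shift_ages) + 1`.
#' @param seed RNG seed.
#' @param min_crown_age if non-`NULL`, condition (by rejection) on the
#'   crown being at least this old.  Without conditioning a tree may crown
#'   after the oldest shift age, in which case the realized tree never
#'   experienced the older epochs; power / recovery experiments typically
#'   condition on `min_crown_age = max(shift_ages)` so every epoch is
#'   present in the data.  `NULL` (default) keeps the unconditioned law.
#' @param max_tries rejection cap when `min_crown_age` is set.
#' @return a `chronogram`; true generating values are attached as
#'   `attr(., "true_rates")` and `attr(., "true_shift_ages")`.
#' @export
sim_yule_shift <- function(n_tips, rates, shift_ages = numeric(0), seed = NULL,
                           min_crown_age = NULL, max_tries = 1e5) {
  if (!is_count(n_tips, min = 2L)) stopf("`n_tips` must be an integer >= 2")
  check_epochs(rates, shift_ages)
  n_tips <- as.integer(n_tips)
  phy <- with_seed(seed, {
    for (try in seq_len(max_tries)) {
      ta <- ta_new(paste0("t", seq_len(n_tips)))
      a <- 0
      for (k in seq(n_tips, 2L)) {
        a <- a + piecewise_wait(a, k, rates, shift_ages)
        pair <- sample.int(k, 2L)
        ta_merge(ta, pair[[1L]], pair[[2L]], a)
      }
      if (is.null(min_crown_age) || a >= min_crown_age) break
      if (try == max_tries) {
        stopf("sim_yule_shift: crown never reached %g in %g tries",
              min_crown_age, max_tries)
      }
    }
    ta_finish(ta)
  })
  out <- as_chronogram(phy, tol = 1e-9)
  attr(out, "true_rates") <- rates
  attr(out, "true_shift_ages") <- shift_ages
  out
}

#' Simulate a reconstructed constant birth-death chronogram
#'
#' Forward simulation from two crown lineages with per-lineage speciation
#' rate `birth_rate` and extinction rate `death_rate`; the process stops
#' when `n_tips` lineages are simultaneously extant (plus a final
#' Exp(n * (birth + death)) stretch to the present), extinct lineages are
#' pruned, and runs that die out are rejected and retried.
#'
#' @param n_tips number of surviving tips (>= 2).
#' @param birth_rate speciation rate (> `death_rate`).
#' @param death_rate extinction rate (>= 0).
#' @param seed RNG seed.
#' @param max_tries rejection cap on extinct runs before erroring.
#' @return a `chronogram` of the reconstructed (pruned) tree.
#' @export
sim_bd <- function(n_tips, birth_rate, death_rate = 0, seed = NULL,
                   max_tries = 1e5) {
  if (!is_count(n_tips, min = 2L)) stopf("`n_tips` must be an integer >= 2")
  if (!(birth_rate > death_rate)) {
    stopf("need birth_rate > death_rate (got %g <= %g): the process is not guaranteed to reach n_tips survivors", birth_rate, death_rate)
  }
  if (death_rate < 0) stopf("death_rate must be >= 0")
  n_tips <- as.integer(n_tips)
  phy <- with_seed(seed, {
    for (try in seq_len(max_tries)) {
      res <- sim_bd_once(n_tips, birth_rate, death_rate)
      if (!is.null(res)) return(res)
    }
    stopf("sim_bd: no run reached %d survivors in %g tries", n_tips, max_tries)
  })
  as_chronogram(phy, tol = 1e-9)
}

# One forward run; returns pruned phylo or NULL on extinction.
sim_bd_once <- function(n_tips, birth, death) {
  # lineage records, grown as vectors
  cap <- 4L * n_tips + 8L
  parent <- integer(cap); start <- numeric(cap); end <- numeric(cap)
  leaf <- logical(cap); alive <- logical(cap)
  nl <- 2L
  parent[1:2] <- 0L; start[1:2] <- 0; alive[1:2] <- TRUE; leaf[1:2] <- TRUE
  t <- 0
  total_rate <- birth + death
  repeat {
    live <- which(alive[seq_len(nl)])
    k <- length(live)
    if (k == 0L) return(NULL)
    if (k == n_tips) break
    t <- t + stats::rexp(1L, k * total_rate)
    pick <- live[[sample.int(k, 1L)]]
    if (stats::runif(1L) < birth / total_rate) {
      if (nl + 2L > cap) {
        cap <- 2L * cap
        length(parent) <- cap; length(start) <- cap; length(end) <- cap
        length(leaf) <- cap; length(alive) <- cap
        leaf[is.na(leaf)] <- FALSE; alive[is.na(alive)] <- FALSE
      }
      end[pick] <- t; alive[pick] <- FALSE; leaf[pick] <- FALSE
      for (c in 1:2) {
        nl <- nl + 1L
        parent[nl] <- pick; start[nl] <- t
        alive[nl] <- TRUE; leaf[nl] <- TRUE
      }
    } else {
      end[pick] <- t; alive[pick] <- FALSE  # stays a (dead) leaf
    }
  }
  t_stop <- t + stats::rexp(1L, n_tips * total_rate)
  live <- which(alive[seq_len(nl)])
  end[live] <- t_stop
  # assemble the complete (extinct + extant) tree
  idx <- seq_len(nl)
  tip_ids <- idx[leaf[idx]]
  int_ids <- idx[!leaf[idx]]              # lineages that split
  ntip <- length(tip_ids)
  node_of <- integer(nl)
  node_of[tip_ids] <- seq_len(ntip)
  node_of[int_ids] <- ntip + 1L + seq_along(int_ids)  # ntip+1 = crown
  edge <- matrix(0L, nrow = nl, ncol = 2L)
  elen <- numeric(nl)
  for (i in idx) {
    from <- if (parent[i] == 0L) ntip + 1L else node_of[parent[i]]
    edge[i, ] <- c(from, node_of[i])
    elen[i] <- end[i] - start[i]
  }
  labels <- paste0("t", seq_len(ntip))
  phy <- structure(
    list(edge = edge, edge.length = elen, tip.label = labels,
         Nnode = length(int_ids) + 1L),
    class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  survivors <- labels[match(live, tip_ids)]
  ape::keep.tip(phy, survivors)
}

#' Simulate a gene tree under a coalescent-within-species-tree model
#'
#' Each species (tip of `species_tree`) contributes `samples_per_species`
#' gene lineages that coalesce within the species under a Kingman
#' coalescent with expected pairwise coalescence time `coalescent_scale`
#' (Myr); the resulting one-lineage-per-species ancestors then join at the
#' species-tree node ages.  This is the regime the GMYC model assumes: all
#' within-species coalescences younger than the between-species divergences,
#' with no shared ancestral polymorphism.  Runs in which a species' samples
#' fail to fully coalesce before their species' parent divergence are
#' rejected and redrawn.
#'
#' @param species_tree a `chronogram` whose tips are species.
#' @param samples_per_species gene copies sampled per species (>= 1).
#' @param coalescent_scale expected within-species pairwise coalescence
#'   time, Myr.
#' @param seed RNG seed.
#' @param max_tries rejection cap for incomplete within-species coalescence.
#' @return a `chronogram` gene tree with tips `<species>_s<i>`; the true
#'   species assignment is in `attr(., "species")` (named by tip label).
#' @export
sim_species_coalescent <- function(species_tree, samples_per_species,
                                   coalescent_scale, seed = NULL,
                                   max_tries = 1000L) {
  sp <- as_chronogram(species_tree)
  if (!is_count(samples_per_species)) {
    stopf("`samples_per_species` must be a positive integer")
  }
  if (!(coalescent_scale > 0)) stopf("`coalescent_scale` must be > 0")
  m <- as.integer(samples_per_species)
  sp_labels <- sp$tip.label
  n_sp <- length(sp_labels)
  sp_ages <- node_ages(sp)
  # age of each species' parent node (the first between-species divergence
  # above it) -- the within-species coalescent must finish below it
  parent_of <- integer(n_sp)
  for (r in seq_len(nrow(sp$edge))) {
    ch <- sp$edge[r, 2L]
    if (ch <= n_sp) parent_of[ch] <- sp$edge[r, 1L]
  }
  parent_age <- sp_ages[parent_of]

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      tips <- as.vector(t(outer(sp_labels, seq_len(m),
                                function(s, i) paste0(s, "_s", i))))
      ta <- ta_new(tips)
      ok <- TRUE
      # cluster bookkeeping: position in ta's live list tracked via species
      cluster_species <- rep(sp_labels, each = m)
      # within-species coalescents, species by species (independent)
      events <- vector("list", 0L)
      for (s in seq_len(n_sp)) {
        members <- which(cluster_species == sp_labels[s])
        a <- 0
        while (length(members) > 1L) {
          k <- length(members)
          a <- a + stats::rexp(1L, choose(k, 2) / coalescent_scale)
          pair <- sample.int(k, 2L)
          events[[length(events) + 1L]] <-
            c(a, members[pair[[1L]]], members[pair[[2L]]])
          # merged cluster inherits the first member's slot
          members <- members[-pair[[2L]]]
        }
        if (m > 1L && a >= parent_age[s]) { ok <- FALSE; break }
      }
      if (!ok) next
      # between-species joins at the species-tree node ages; each species
      # has one surviving cluster, tracked by its first sample's slot
      sp_slot <- match(paste0(sp_labels, "_s1"), tips)
      int_nodes <- order(sp_ages[(n_sp + 1L):(n_sp + sp$Nnode)])  # young->old
      desc_tips <- tip_descendants(sp)
      for (v in (n_sp + int_nodes)) {
        # the two child clusters, each represented by the slot of any
        # descendant species' first sample (the union-find chase at replay
        # time resolves it to the current cluster)
        kids <- sp$edge[sp$edge[, 1L] == v, 2L]
        rep1 <- sp_slot[desc_tips[[kids[[1L]]]][[1L]]]
        rep2 <- sp_slot[desc_tips[[kids[[2L]]]][[1L]]]
        events[[length(events) + 1L]] <- c(sp_ages[v], rep1, rep2)
      }
      # replay events in age order on the assembler; slots index original
      # tip positions, map to live-cluster positions as we go
      ord <- order(vapply(events, `[[`, numeric(1), 1L))
      slot_of <- seq_along(tips)   # original tip slot -> live position
      live <- seq_along(tips)
      for (e in events[ord]) {
        i <- match(find_root_slot(slot_of, e[[2L]]), live)
        j <- match(find_root_slot(slot_of, e[[3L]]), live)
        ta_merge(ta, i, j, e[[1L]])
        # ta_merge appends merged cluster at the end of its live list
        winner <- live[[min(i, j)]]
        loser_i <- live[[i]]; loser_j <- live[[j]]
        live <- c(live[-c(i, j)], loser_i)
        slot_of[loser_j] <- loser_i
      }
      phy <- ta_finish(ta)
      out <- as_chronogram(phy, tol = 1e-9)
      attr(out, "species") <- stats::setNames(cluster_species, tips)
      attr(out, "species_tree") <- sp
      return(out)
    }
    stopf("sim_species_coalescent: within-species coalescence did not complete below the species divergences in %d tries; decrease `coalescent_scale`", max_tries)
  })
}

# union-find style chase: slot_of maps a tip slot to the slot representing
# its current cluster
find_root_slot <- function(slot_of, s) {
  while (slot_of[s] != s) s <- slot_of[s]
  s
}

# list: node id -> integer vector of descendant tip ids (tips map to self)
tip_descendants <- function(phy) {
  n <- length(phy$tip.label)
  res <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) res[[i]] <- i
  ord <- ape::reorder.phylo(phy, "postorder")$edge
  for (r in seq_len(nrow(ord))) {
    p <- ord[r, 1L]; ch <- ord[r, 2L]
    res[[p]] <- c(res[[p]], res[[ch]])
  }
  res
}

#' Simulate an alignment along a chronogram under GTR+Gamma
#'
#' Sites evolve under a general time-reversible model with discrete-Gamma
#' rate heterogeneity (equal-probability categories, category means), with
#' branch lengths interpreted as expected substitutions per site after
#' multiplying by `subst_rate` (substitutions / site / Myr on a
#' chronogram).  Optionally masks a contiguous run of sites per sequence
#' with `N` at one end, emulating partial-length fragments.
#'
#' @param tree a `chronogram` (or any `phylo` with branch lengths).
#' @param seq_length alignment length in bp.
#' @param gtr_exchangeabilities six non-negative relative rates in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param base_freqs equilibrium frequencies of A, C, G, T (sum to 1).
#' @param gamma_shape shape of the Gamma rate distribution.
#' @param n_gamma_cats number of discrete Gamma categories.
#' @param subst_rate substitutions / site / Myr scaling applied to branch
#'   lengths (1 means branch lengths already are expected substitutions).
#' @param mask_fraction expected fraction of sites N-masked per sequence
#'   (one run at a random end); 0 disables masking.
#' @param seed RNG seed.
#' @return an [alignment] object with one row per tip.
#' @export
sim_sequences <- function(tree, seq_length = 600L,
                          gtr_exchangeabilities = rep(1, 6),
                          base_freqs = rep(0.25, 4),
                          gamma_shape = 1, n_gamma_cats = 4L,
                          subst_rate = 1, mask_fraction = 0,
                          seed = NULL) {
  if (!is_count(seq_length)) stopf("`seq_length` must be a positive integer")
  if (length(gtr_exchangeabilities) != 6L || any(gtr_exchangeabilities < 0) ||
      all(gtr_exchangeabilities == 0)) {
    stopf("`gtr_exchangeabilities` must be 6 non-negative rates, not all zero")
  }
  if (length(base_freqs) != 4L || any(base_freqs <= 0) ||
      abs(sum(base_freqs) - 1) > 1e-12) {
    stopf("`base_freqs` must be 4 positive frequencies summing to 1")
  }
  if (!(gamma_shape > 0)) stopf("`gamma_shape` must be > 0")
  if (!is_count(n_gamma_cats)) stopf("`n_gamma_cats` must be a positive integer")
  if (!(subst_rate > 0)) stopf("`subst_rate` must be > 0")
  if (mask_fraction < 0 || mask_fraction >= 1) {
    stopf("`mask_fraction` must be in [0, 1)")
  }
  phy <- tree
  class(phy) <- "phylo"
  phy$edge.length <- phy$edge.length * subst_rate
  L <- as.integer(seq_length)
  k <- as.integer(n_gamma_cats)
  g <- phangorn::discrete.gamma(gamma_shape, k)
  with_seed(seed, {
    cat_of <- sample.int(k, L, replace = TRUE)
    mat <- matrix("N", nrow = length(phy$tip.label), ncol = L,
                  dimnames = list(phy$tip.label, NULL))
    for (cc in seq_len(k)) {
      sites <- which(cat_of == cc)
      if (length(sites) == 0L) next
      ph <- phy
      ph$edge.length <- ph$edge.length * g[[cc]]
      sim <- phangorn::simSeq(ph, l = length(sites), Q = gtr_exchangeabilities,
                              bf = base_freqs, type = "DNA")
      chars <- toupper(as.character(sim))
      mat[rownames(chars), sites] <- chars
    }
    if (mask_fraction > 0) {
      run <- round(mask_fraction * L)
      for (i in seq_len(nrow(mat))) {
        if (run == 0L) break
        if (stats::runif(1L) < 0.5) {
          mat[i, seq_len(run)] <- "N"
        } else {
          mat[i, seq(L - run + 1L, L)] <- "N"
        }
      }
    }
    new_alignment(mat)
  })
}

#' Simulation configuration for the full synthetic study
#'
#' Bundles the knobs of all generators with validation; defaults describe a
#' small delimitation study: 10 species sampled 4 times each, deep species
#' divergences relative to the within-species coalescent, COI-like AT-rich
#' sequences, and a late speciation-rate increase at 7 Myr.
#'
#' @param seed integer seed.
#' @param n_tips tips for single-tree simulators.
#' @param rates per-epoch speciation rates, oldest first.
#' @param shift_ages epoch boundaries, Myr, strictly decreasing.
#' @param extinction_rate extinction rate for [sim_bd()].
#' @param n_species,samples_per_species,coalescent_scale coalescent design.
#' @param seq_length,gtr_exchangeabilities,base_freqs,gamma_shape,n_gamma_cats
#'   sequence model, see [sim_sequences()].
#' @param mask_fraction N-masking fraction, see [sim_sequences()].
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_tips = 100L,
                       rates = c(0.05, 0.5), shift_ages = 7,
                       extinction_rate = 0,
                       n_species = 10L, samples_per_species = 4L,
                       coalescent_scale = 0.5,
                       seq_length = 600L,
                       gtr_exchangeabilities = c(1, 4, 1, 1, 4, 1),
                       base_freqs = c(0.3, 0.15, 0.15, 0.4),
                       gamma_shape = 0.5, n_gamma_cats = 4L,
                       mask_fraction = 0.1) {
  check_epochs(rates, shift_ages)
  if (!is_count(n_tips, 2L)) stopf("`n_tips` must be an integer >= 2")
  if (extinction_rate < 0) stopf("`extinction_rate` must be >= 0")
  if (!is_count(n_species, 2L)) stopf("`n_species` must be an integer >= 2")
  if (!is_count(samples_per_species)) stopf("`samples_per_species` must be >= 1")
  if (!(coalescent_scale > 0)) stopf("`coalescent_scale` must be > 0")
  if (abs(sum(base_freqs) - 1) > 1e-12) stopf("`base_freqs` must sum to 1")
  structure(
    list(seed = as.integer(seed), n_tips = as.integer(n_tips), rates = rates,
         shift_ages = shift_ages, extinction_rate = extinction_rate,
         n_species = as.integer(n_species),
         samples_per_species = as.integer(samples_per_species),
         coalescent_scale = coalescent_scale,
         seq_length = as.integer(seq_length),
         gtr_exchangeabilities = gtr_exchangeabilities,
         base_freqs = base_freqs, gamma_shape = gamma_shape,
         n_gamma_cats = as.integer(n_gamma_cats),
         mask_fraction = mask_fraction),
    class = "sim_config")
}
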
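# Generators: determinism, ultrametricity, and statistical ground truth.

test_that("simulators are deterministic and exactly ultrametric", {
  for (gen in list(function(s) sim_yule(25, 0.3, seed = s),
                   function(s) sim_yule_shift(25, c(0.05, 0.5), 4, seed = s),
                   function(s) sim_bd(25, 0.4, 0.2, seed = s))) {
    t1 <- gen(11); t2 <- gen(11); t3 <- gen(12)
    expect_identical(write_newick(t1), write_newick(t2))
    expect_false(identical(write_newick(t1), write_newick(t3)))
    depth <- ape::node.depth.edgelength(t1)[1:25]
    expect_lt(max(depth) - min(depth), 1e-9 * max(depth))
    expect_equal(length(t1$tip.label), 25L)
  }
})

test_that("degenerate and invalid inputs are handled", {
  t2 <- sim_yule(2, 1.0, seed = 1)
  expect_equal(t2$Nnode, 1L)
  expect_error(sim_yule(1, 1.0), "n_tips")
  expect_error(sim_yule_shift(10, c(1, 2, 3), c(3, 5)), "decreasing")
  expect_error(sim_yule_shift(10, c(1, 2, 3), 5), "length")
  expect_error(sim_bd(10, 0.2, 0.2), "birth_rate > death_rate")
})

test_that("pure-birth rate is recovered within its 95% profile interval", {
  hits <- vapply(1:100, function(s) {
    bt <- branching_times(sim_yule(100, 0.5, seed = 700 + s))
    ci <- pb_profile_ci(bt)
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("equal epoch rates reproduce the constant-rate law", {
  c_yule <- vapply(1:200, function(s)
    branching_times(sim_yule(30, 0.2, seed = s))$crown, numeric(1))
  c_shift <- vapply(1:200, function(s)
    branching_times(sim_yule_shift(30, c(0.2, 0.2), 5, seed = 1000 + s))$crown,
    numeric(1))
  expect_gt(stats::ks.test(c_yule, c_shift)$p.value, 0.01)
})

test_that("birth-death with zero extinction matches the Yule law", {
  c_yule <- vapply(1:200, function(s)
    branching_times(sim_yule(30, 0.3, seed = s))$crown, numeric(1))
  c_bd <- vapply(1:200, function(s)
    branching_times(sim_bd(30, 0.3, 0, seed = 2000 + s))$crown, numeric(1))
  expect_gt(stats::ks.test(c_yule, c_bd)$p.value, 0.01)
})

test_that("birth-death net rate and extinction fraction are recoverable", {
  fits <- lapply(1:100, function(s)
    fit_bd_constant(sim_bd(100, 0.3, 0.15, seed = 600 + s)))
  a_hat <- vapply(fits, `[[`, numeric(1), "extinction_fraction")
  expect_true(stats::median(a_hat) >= 0.3 && stats::median(a_hat) <= 0.7)
  # truth r = 0.15 inside the 95% profile interval in >= 90/100 runs
  hits <- vapply(1:100, function(s) {
    bt <- branching_times(sim_bd(60, 0.3, 0.15, seed = 800 + s))
    st <- branching_times(bt)
    n <- st$n; t <- unname(st$ages); S <- sum(seq(2, n) * st$durations)
    prof <- function(r) {
      -stats::optimize(function(a)
        -((n - 2) * log(r) - r * S + n * log1p(-a) -
            2 * sum(log1p(-a * exp(-r * t)))), c(0, 1 - 1e-9))$objective
    }
    fit <- fit_bd_constant(bt)
    target <- fit$logL - stats::qchisq(0.95, 1) / 2
    lo <- tryCatch(stats::uniroot(function(r) prof(r) - target,
                                  c(fit$rates / 50, fit$rates))$root,
                   error = function(e) 0)
    hi <- tryCatch(stats::uniroot(function(r) prof(r) - target,
                                  c(fit$rates, fit$rates * 50))$root,
                   error = function(e) Inf)
    lo <= 0.15 && 0.15 <= hi
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("one sample per species reproduces the species-tree topology", {
  sp <- sim_yule(12, 0.1, seed = 31)
  g <- sim_species_coalescent(sp, 1, 0.01, seed = 32)
  g2 <- g
  g2$tip.label <- sub("_s1$", "", g2$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(sp), ape::unroot(g2)), 0,
               ignore_attr = TRUE)
})

test_that("within-species pairwise coalescent time averages to the scale", {
  sp <- read_newick("(A:30,B:30);")
  times <- vapply(1:1000, function(s) {
    g <- sim_species_coalescent(sp, 2, 0.5, seed = s)
    unname(node_ages(g)[ape::mrca(g)["A_s1", "A_s2"]])
  }, numeric(1))
  expect_lt(abs(mean(times) - 0.5), 0.05 * 0.5)
})

test_that("species labels partition the gene-tree tips", {
  sp <- sim_yule(6, 0.1, seed = 41)
  g <- sim_species_coalescent(sp, 3, 0.05, seed = 42)
  lab <- attr(g, "species")
  expect_setequal(names(lab), g$tip.label)
  expect_equal(sort(unname(table(lab))), rep(3L, 6), ignore_attr = TRUE)
  # within-species MRCAs are younger than every species divergence here
  ages <- node_ages(g)
  for (s in sp$tip.label) {
    tips <- names(lab)[lab == s]
    mrca <- ape::getMRCA(g, tips)
    expect_lt(ages[mrca], min(node_ages(sp)[-(1:6)]))
  }
})

test_that("sequence simulation matches its own substitution scale", {
  tree <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- sim_sequences(tree, seq_length = 100000, gamma_shape = 100,
                       n_gamma_cats = 1, seed = 1)
  d <- k2p(aln["A", ], aln["B", ])$d
  expect_lt(abs(d - 0.2), 0.03 * 0.2 + 0.01)
  # empirical base frequencies converge to the model frequencies
  bf <- c(0.3, 0.15, 0.15, 0.4)
  aln2 <- sim_sequences(tree, seq_length = 100000, base_freqs = bf,
                        n_gamma_cats = 1, seed = 2)
  emp <- table(factor(aln2, levels = c("A", "C", "G", "T"))) / length(aln2)
  expect_true(all(abs(as.numeric(emp) - bf) < 0.01))
})

test_that("zero-length branches yield identical sequences", {
  tree <- ape::read.tree(text = "(A:0,B:0);")
  aln <- sim_sequences(tree, seq_length = 500, seed = 3)
  expect_identical(unname(aln["A", ]), unname(aln["B", ]))
})

test_that("sequence simulation is seeded and validates its inputs", {
  tree <- sim_yule(5, 0.3, seed = 5)
  a1 <- sim_sequences(tree, 200, seed = 9, mask_fraction = 0.2)
  a2 <- sim_sequences(tree, 200, seed = 9, mask_fraction = 0.2)
  expect_identical(unclass(a1), unclass(a2))
  expect_gt(sum(a1 == "N"), 0)
  expect_error(sim_sequences(tree, 200, gtr_exchangeabilities = rep(0, 6)),
               "exchangeabilities")
  expect_error(sim_sequences(tree, 200, base_freqs = c(.5, .5, .2, .2)),
               "base_freqs")
})

test_that("shift-age conditioning controls the crown age", {
  tr <- sim_yule_shift(40, c(0.05, 0.5), 7, seed = 8, min_crown_age = 7)
  expect_gte(branching_times(tr)$crown, 7)
})
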
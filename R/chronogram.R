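# Chronogram container and tree-shape primitives.
#
# A chronogram is an ape "phylo" tree that is rooted, binary and ultrametric,
# with node ages measured in Myr before present (tips at exactly 0).  All
# downstream likelihoods (GMYC, pure-birth, birth-death) consume node ages,
# so ages are validated and cached on the object at construction.

#' Coerce a tree to a chronogram
#'
#' Validates that `phy` is a rooted, binary tree with branch lengths whose
#' root-to-tip path lengths are equal up to a relative tolerance, then
#' normalizes tip ages to exactly 0 (dated trees exported from Bayesian
#' samplers typically carry small rounding noise).  Node ages are cached in
#' `attr(x, "node_ages")`, indexed like ape's internal node numbering.
#'
#' @param phy an object of class `phylo` (or already a `chronogram`).
#' @param tol relative tolerance for the ultrametricity check: the spread of
#'   root-to-tip path lengths divided by tree height must not exceed it.
#' @return an object of classes `chronogram` and `phylo`.
#' @examples
#' tr <- as_chronogram(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' node_ages(tr)
#' @export
as_chronogram <- function(phy, tol = 1e-6) {
  if (inherits(phy, "chronogram") && !is.null(attr(phy, "node_ages"))) {
    return(phy)
  }
  if (!inherits(phy, "phylo")) {
    stopf("`phy` must be a 'phylo' object, got <%s>", paste(class(phy), collapse = "/"))
  }
  if (is.null(phy$edge.length)) stopf("tree has no branch lengths")
  n_tip <- length(phy$tip.label)
  if (n_tip < 2L) stopf("a chronogram needs at least 2 tips")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    stopf(paste0(
      "tree must be rooted and binary: resolve polytomies explicitly ",
      "(e.g. read_newick(..., resolve_polytomies = TRUE))"))
  }
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth[seq_len(n_tip)])
  if (height <= 0) stopf("tree height is zero")
  tip_dev <- height - depth[seq_len(n_tip)]
  spread <- max(tip_dev) / height
  if (spread > tol) {
    worst <- order(tip_dev, decreasing = TRUE)[seq_len(min(5L, n_tip))]
    stopf(
      "tree is not ultrametric (relative tip-age spread %.3g > tol %.3g); largest deviations: %s",
      spread, tol,
      paste(sprintf("%s=%.4g", phy$tip.label[worst], tip_dev[worst]), collapse = ", "))
  }
  ages <- height - depth
  ages[seq_len(n_tip)] <- 0
  parent_age <- ages[phy$edge[, 1L]]
  child_age <- ages[phy$edge[, 2L]]
  if (any(parent_age < child_age - tol * height)) {
    stopf("negative branch durations: parent node younger than child")
  }
  structure(phy,
            node_ages = ages,
            class = unique(c("chronogram", class(phy))))
}

#' Node ages of a chronogram
#'
#' @param x a `chronogram` (or coercible `phylo`).
#' @return numeric vector of ages (Myr before present) indexed by ape node
#'   number: entries `1:Ntip` are tips (all 0), the rest internal nodes.
#' @export
node_ages <- function(x) {
  x <- as_chronogram(x)
  attr(x, "node_ages")
}

#' Read a chronogram from a Newick string or file
#'
#' @param x path to a Newick file, or a Newick string.
#' @param tol relative ultrametricity tolerance, see [as_chronogram()].
#' @param resolve_polytomies resolve polytomies with zero-length branches
#'   (random, seeded order) instead of erroring.
#' @param seed seed for the polytomy resolution tie-break.
#' @return a `chronogram`, or a list of chronograms if the source holds
#'   several trees.
#' @export
read_newick <- function(x, tol = 1e-6, resolve_polytomies = FALSE, seed = NULL) {
  looks_like_newick <- length(x) == 1L && grepl("\\(", x) && grepl(";", x)
  phy <- if (looks_like_newick) {
    ape::read.tree(text = x)
  } else {
    if (!file.exists(x)) stopf("file not found: %s", x)
    ape::read.tree(file = x)
  }
  if (is.null(phy)) stopf("could not parse Newick input")
  finish <- function(p) {
    if (resolve_polytomies && (!ape::is.binary(p) || !ape::is.rooted(p))) {
      p <- with_seed(seed, ape::multi2di(p, random = TRUE))
    }
    as_chronogram(p, tol = tol)
  }
  if (inherits(phy, "multiPhylo")) lapply(phy, finish) else finish(phy)
}

#' Read chronograms from a NEXUS trees block
#'
#' Translate tables are honored (labels are mapped back to the original
#' taxon names by the parser).
#'
#' @inheritParams read_newick
#' @param path path to a NEXUS file.
#' @return list of `chronogram` objects.
#' @export
read_nexus_trees <- function(path, tol = 1e-6, resolve_polytomies = FALSE,
                             seed = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  trees <- ape::read.nexus(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(p) {
    if (resolve_polytomies && (!ape::is.binary(p) || !ape::is.rooted(p))) {
      p <- with_seed(seed, ape::multi2di(p, random = TRUE))
    }
    as_chronogram(p, tol = tol)
  })
}

#' Write a chronogram to Newick
#'
#' @param x a `chronogram` or `phylo`.
#' @param file output path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(x, file = NULL) {
  class(x) <- "phylo"
  s <- ape::write.tree(x)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Branching times of a chronogram
#'
#' Returns the internal-node ages `t_2 >= t_3 >= ... >= t_n` (the age at
#' which the reconstructed tree goes from k-1 to k lineages) together with
#' the inter-event durations `x_k = t_k - t_{k+1}` (duration spent with
#' exactly k lineages, `t_{n+1} = 0`).  These are the sufficient statistics
#' of the pure-birth and constant birth-death likelihoods.
#'
#' @param x a `chronogram`, a `phylo`, or an existing `branching_times`
#'   object (returned unchanged).
#' @return an object of class `branching_times`: a list with elements
#'   `ages` (sorted decreasing, `t_2..t_n`), `durations` (named `2..n`),
#'   `n` (tip count) and `crown` (crown age, `t_2`).
#' @examples
#' bt <- branching_times(read_newick("(((A:3,B:3):3,C:6):4,D:10);"))
#' bt$ages       # 10 6 3
#' bt$durations  # 4 3 3
#' @export
branching_times <- function(x) {
  if (inherits(x, "branching_times")) return(x)
  x <- as_chronogram(x)
  n <- length(x$tip.label)
  ages <- attr(x, "node_ages")[(n + 1L):(n + x$Nnode)]
  ages <- sort(ages, decreasing = TRUE)
  durations <- ages - c(ages[-1L], 0)
  names(durations) <- as.character(seq(2L, n))
  names(ages) <- as.character(seq(2L, n))
  structure(
    list(ages = ages, durations = durations, n = n, crown = ages[[1L]]),
    class = "branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat(sprintf("Branching times: %d tips, crown age %.4g\n", x$n, x$crown))
  print(utils::head(x$ages, 10L))
  invisible(x)
}

#' Lineage-through-time curve
#'
#' Step function giving the number of reconstructed lineages as a function
#' of age before present: 2 at the crown, stepping up at every branching
#' time, `n` at the present.
#'
#' @param x a `chronogram` (or coercible).
#' @return a data frame of classes `ltt_curve`/`data.frame` with columns
#'   `age` (step locations, decreasing, ending at 0) and `lineages` (count
#'   from that age toward the next, more recent, step).
#' @export
ltt <- function(x) {
  bt <- branching_times(x)
  df <- data.frame(age = c(unname(bt$ages), 0),
                   lineages = c(seq(2L, bt$n), bt$n))
  class(df) <- c("ltt_curve", "data.frame")
  df
}

#' @export
plot.ltt_curve <- function(x, ..., log_lineages = TRUE) {
  age <- x$age
  lin <- x$lineages
  plot(-age, lin, type = "s", log = if (log_lineages) "y" else "",
       xlab = "age before present (Myr, negative scale)",
       ylab = "lineages", ...)
  invisible(x)
}

#' Sample trees from a posterior set
#'
#' Seeded uniform sample (without replacement by default), e.g. to draw an
#' ensemble of trees from a posterior sample for rate-shift analysis.
#'
#' @param trees list of trees (each coercible to `chronogram`).
#' @param n number of trees to draw.
#' @param seed RNG seed.
#' @param replace sample with replacement.
#' @return list of sampled trees with the drawn indices in
#'   `attr(., "indices")`.
#' @export
sample_trees <- function(trees, n = 100L, seed = NULL, replace = FALSE) {
  if (!is_count(n)) stopf("`n` must be a positive integer")
  m <- length(trees)
  if (!replace && n > m) {
    stopf("cannot sample %d of %d trees without replacement", n, m)
  }
  idx <- with_seed(seed, sample.int(m, size = n, replace = replace))
  out <- trees[idx]
  attr(out, "indices") <- idx
  out
}
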
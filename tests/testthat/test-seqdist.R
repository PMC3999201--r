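# FASTA I/O, deduplication, K2P distances, clustering, saturation.

test_that("FASTA round trip preserves the alignment and normalizes symbols", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTAC", ">b", "acgtnn"), f)
  aln <- read_fasta(f)
  expect_equal(rownames(aln), c("a", "b"))
  expect_identical(unname(aln["b", ]), c("A", "C", "G", "T", "N", "N"))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, f2)
  expect_identical(unclass(read_fasta(f2)), unclass(aln))
})

test_that("unknown symbols map to N with a warning, U maps to T", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGU", ">b", "ACGR"), f)
  expect_warning(aln <- read_fasta(f), "mapped to N")
  expect_identical(unname(aln["a", 4]), "T")
  expect_identical(unname(aln["b", 4]), "N")
})

test_that("malformed FASTA inputs error", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_fasta(f), "unequal")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f2)
  expect_error(read_fasta(f2), "empty|records")
})

test_that("dedup keeps the most determinate member of each compatible group", {
  aln <- new_alignment(c(s1 = "ACGTACGT", s2 = "ACGTACGN", s3 = "ACCTACGT"))
  out <- dedup_longest(aln)
  expect_identical(rownames(out), c("s1", "s3"))
  rep_of <- attr(out, "groups")
  expect_identical(rep_of$representative[rep_of$id == "s2"], "s1")
  # all-distinct alignments pass through unchanged
  distinct <- new_alignment(c(a = "AAAA", b = "CCCC", c = "GGGG"))
  expect_identical(rownames(dedup_longest(distinct)), c("a", "b", "c"))
})

test_that("pairwise-compatible group collapses to the first sequence on ties", {
  aln <- new_alignment(c(x = "ACGN", y = "ACNT", z = "ANGT"))
  out <- dedup_longest(aln)
  expect_identical(rownames(out), "x")
  expect_setequal(attr(out, "groups")$id, c("x", "y", "z"))
})

test_that("dedup is idempotent and reports a partition", {
  set.seed(71)
  aln <- random_alignment(15, 60)
  once <- dedup_longest(aln)
  twice <- dedup_longest(once)
  expect_identical(unclass(once), unclass(twice))
  rep <- attr(once, "groups")
  expect_setequal(rep$id, rownames(aln))
  expect_lte(nrow(once), nrow(aln))
  expect_true(all(rep$representative %in% rownames(once)))
})

test_that("k2p matches the closed form and flags degenerate pairs", {
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  res <- k2p(a, b)
  expect_equal(res$d, -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-12)
  expect_equal(c(res$s, res$v, res$m), c(10L, 5L, 100L))
  expect_equal(k2p("ACGT", "ACGT")$d, 0)
  # P = 0.5, Q = 0.25 makes the first log argument non-positive
  sat <- k2p(paste0(strrep("A", 50), strrep("C", 25), strrep("T", 25)),
             paste0(strrep("G", 50), strrep("A", 25), strrep("T", 25)))
  expect_true(sat$saturated)
  expect_true(is.na(sat$d))
  expect_error(k2p("NNNN", "ACGT"), "no-overlap")
})

test_that("k2p agrees exactly with a site-by-site oracle on random pairs", {
  set.seed(101)
  for (rep in 1:200) {
    len <- sample(20:80, 1)
    aln <- random_alignment(2, len)
    o <- oracle_k2p(aln[1, ], aln[2, ])
    if (is.null(o)) {
      expect_error(k2p(aln[1, ], aln[2, ]), "no-overlap")
    } else {
      r <- k2p(aln[1, ], aln[2, ])
      expect_identical(c(r$s, r$v, r$m), c(o$s, o$v, o$m))
      expect_identical(r$saturated, o$saturated)
      if (!o$saturated) expect_identical(r$d, o$d)
    }
  }
})

test_that("k2p_matrix agrees with ape's K80 distances on clean data", {
  tr <- sim_yule(8, 0.2, seed = 55)
  aln <- sim_sequences(tr, 2000, subst_rate = 0.02, seed = 56)
  dm <- k2p_matrix(aln)
  bin <- ape::as.DNAbin(unclass(aln))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(dm$d, ref[rownames(dm$d), colnames(dm$d)], tolerance = 1e-9)
})

test_that("single-linkage threshold clustering chains and separates", {
  d <- matrix(0.05, 3, 3); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.005
  d[2, 3] <- d[3, 2] <- 0.008
  d[1, 3] <- d[3, 1] <- 0.012
  cl <- threshold_clusters(make_k2p_dist(c("a", "b", "c"), d), cutoff = 0.01)
  expect_equal(attr(cl, "n_clusters"), 1L)
  # two blocks with all between-block distances 0.05 stay apart
  d2 <- matrix(0.05, 4, 4); diag(d2) <- 0
  d2[1, 2] <- d2[2, 1] <- 0.004
  d2[3, 4] <- d2[4, 3] <- 0.004
  cl2 <- threshold_clusters(make_k2p_dist(letters[1:4], d2), cutoff = 0.01)
  expect_equal(attr(cl2, "n_clusters"), 2L)
  expect_equal(cl2$cluster, c(1L, 1L, 2L, 2L))
  # complete linkage refuses the chain single linkage accepts
  d3 <- matrix(0.05, 3, 3); diag(d3) <- 0
  d3[1, 2] <- d3[2, 1] <- 0.008
  d3[2, 3] <- d3[3, 2] <- 0.008
  single <- threshold_clusters(make_k2p_dist(c("a", "b", "c"), d3), 0.01)
  complete <- threshold_clusters(make_k2p_dist(c("a", "b", "c"), d3), 0.01,
                                 linkage = "complete")
  expect_equal(attr(single, "n_clusters"), 1L)
  expect_equal(attr(complete, "n_clusters"), 2L)
})

test_that("clustering is order-invariant and monotone in the cutoff", {
  tr <- sim_yule(10, 0.2, seed = 65)
  aln <- sim_sequences(tr, 800, subst_rate = 0.01, seed = 66)
  dm <- k2p_matrix(aln)
  cl <- threshold_clusters(dm, 0.05)
  perm <- sample(nrow(aln))
  dm2 <- k2p_matrix(new_alignment(unclass(aln)[perm, ]))
  cl2 <- threshold_clusters(dm2, 0.05)
  sig <- function(cl) sort(vapply(split(cl$id, cl$cluster),
                                  function(g) paste(sort(g), collapse = "|"),
                                  character(1)), method = "radix")
  expect_identical(unname(sig(cl)), unname(sig(cl2)))
  counts <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.8),
                   function(ct) attr(threshold_clusters(dm, ct), "n_clusters"),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("saturated pairs are excluded from clustering with a warning", {
  d <- matrix(NA_real_, 2, 2); diag(d) <- 0
  expect_warning(
    cl <- threshold_clusters(make_k2p_dist(c("a", "b"), d), 0.01),
    "flagged")
  expect_equal(attr(cl, "n_clusters"), 2L)
})

test_that("saturation profile tabulates every pair with flags", {
  aln <- new_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                         c = "NNNNNNNNNN"))
  prof <- saturation_profile(aln)
  expect_equal(nrow(prof), 3L)
  ident <- prof[prof$id_a == "a" & prof$id_b == "b", ]
  expect_equal(c(ident$s, ident$v, ident$d), c(0, 0, 0))
  expect_true(all(prof$flag[prof$id_b == "c"] == "no_overlap"))
})
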
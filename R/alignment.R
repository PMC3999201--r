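# Alignment container, deduplication filter, Kimura 2-parameter distances,
# similarity-threshold clustering and saturation profiles.
#
# Sequences live in a character matrix over {A,C,G,T,N,-}: one row per
# record, all rows the same aligned length.  N is treated as a wildcard
# (unknown residue), "-" as an alignment gap; only A/C/G/T sites enter the
# distance computations (pairwise deletion).

ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct an alignment
#'
#' @param x a character matrix (rows = records, rownames = ids, one column
#'   per aligned site), or a named character vector of equal-length strings.
#' @return an object of class `alignment` (a validated character matrix).
#' @export
new_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stopf("sequences must be named")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      stopf("alignment-format error: sequences have unequal lengths (%s)",
            paste(unique(lens), collapse = ", "))
    }
    x <- do.call(rbind, strsplit(toupper(x), ""))
  }
  if (!is.matrix(x) || !is.character(x)) stopf("`x` must be a character matrix")
  if (ncol(x) < 1L) stopf("alignment has zero length")
  if (nrow(x) < 1L) stopf("empty-input error: alignment has no records")
  ids <- rownames(x)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) stopf("records must have ids")
  if (anyDuplicated(ids)) stopf("duplicate record ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- !(x %in% ALPHABET)
  if (any(bad)) {
    stopf("alignment contains symbols outside {A,C,G,T,N,-}: %s",
          paste(unique(x[bad]), collapse = ", "))
  }
  structure(x, class = c("alignment", class(x)))
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Characters are case-normalized to uppercase, `U` is mapped to `T`, and
#' any symbol outside `{A,C,G,T,N,-}` (e.g. IUPAC ambiguity codes) is
#' mapped to `N` with a warning.  All records must have the same aligned
#' length.
#'
#' @param path path to a FASTA file.
#' @return an [alignment].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = FALSE, forceDNAtolower = FALSE,
                       seqtype = "DNA"),
    error = function(e) list())
  if (length(recs) == 0L) stopf("empty-input error: no FASTA records in %s", path)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    stopf("alignment-format error: unequal sequence lengths in %s (%s)",
          path, paste(unique(lens), collapse = ", "))
  }
  mat <- toupper(do.call(rbind, recs))
  rownames(mat) <- names(recs)
  n_u <- sum(mat == "U")
  if (n_u > 0L) mat[mat == "U"] <- "T"
  other <- !(mat %in% ALPHABET)
  if (any(other)) {
    warnf("read_fasta: %d non-{A,C,G,T,N,-} symbols (%s) mapped to N",
          sum(other), paste(unique(mat[other]), collapse = ","))
    mat[other] <- "N"
  }
  new_alignment(mat)
}

#' Write an alignment to FASTA
#'
#' @param aln an [alignment].
#' @param path output path.
#' @param line_width characters per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, line_width = 60L) {
  aln <- new_alignment(unclass(aln))
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
    names = rownames(aln), file.out = path, nbchar = line_width)
  invisible(path)
}

# ---- deduplication ----------------------------------------------------------

#' Collapse sequences that are identical up to unknown residues
#'
#' Two sequences are compatible when they agree at every aligned position
#' where both carry a determinate character (`A`, `C`, `G`, `T` or `-`);
#' `N` matches anything.  Compatibility is not transitive, so sequences are
#' grouped as connected components of the compatibility graph, and from
#' each group the sequence with the most determinate (non-N, non-gap)
#' characters is kept -- the longest fragment once aligned -- with ties
#' broken by input order.  Representatives keep their input order.
#'
#' @param aln an [alignment].
#' @return the deduplicated [alignment]; the collapse report is in
#'   `attr(., "groups")` (a data frame with columns `id`, `representative`,
#'   `kept`).
#' @export
dedup_longest <- function(aln) {
  aln <- new_alignment(unclass(aln))
  n <- nrow(aln)
  det <- matrix(aln %in% c("A", "C", "G", "T", "-"), nrow = n)
  n_det <- rowSums(matrix(aln %in% c("A", "C", "G", "T"), nrow = n))
  edges <- matrix(0L, nrow = 0L, ncol = 2L)
  if (n > 1L) {
    pairs <- utils::combn(n, 2L)
    compat <- logical(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      both <- det[i, ] & det[j, ]
      compat[p] <- !any(aln[i, both] != aln[j, both])
    }
    edges <- t(pairs[, compat, drop = FALSE])
  }
  comp <- connected_components(n, edges)
  reps <- vapply(split(seq_len(n), comp), function(members) {
    members[which.max(n_det[members])]  # ties -> first by input order
  }, integer(1))
  keep <- sort(unname(reps))
  report <- data.frame(
    id = rownames(aln),
    representative = rownames(aln)[reps[comp]],
    kept = seq_len(n) %in% keep,
    stringsAsFactors = FALSE)
  out <- new_alignment(unclass(aln)[keep, , drop = FALSE])
  attr(out, "groups") <- report
  out
}

# ---- K2P distances ----------------------------------------------------------

#' Kimura 2-parameter distance between two sequences
#'
#' Sites where either sequence carries `N` or `-` are excluded (pairwise
#' deletion).  With `m` retained sites, transition proportion `P = s/m` and
#' transversion proportion `Q = v/m`, the distance is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` substitutions per site.
#' When a logarithm argument is non-positive the pair is flagged saturated
#' and `d` is `NA`.
#'
#' @param seq_a,seq_b character vectors (or single strings) over
#'   `{A,C,G,T,N,-}` of equal length.
#' @return a list with elements `d`, `P`, `Q`, `m`, `s`, `v`, `saturated`.
#' @examples
#' a <- strrep("A", 100); b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
#' k2p(a, b)$d  # 10 transitions, 5 transversions over 100 sites
#' @export
k2p <- function(seq_a, seq_b) {
  a <- to_chars(seq_a); b <- to_chars(seq_b)
  if (length(a) != length(b)) stopf("sequences differ in length")
  ea <- match(a, c("A", "C", "G", "T"))
  eb <- match(b, c("A", "C", "G", "T"))
  ok <- !is.na(ea) & !is.na(eb)
  m <- sum(ok)
  if (m == 0L) stopf("no-overlap error: no site where both sequences are determinate")
  k2p_from_counts(
    s = sum(ok & ea != eb & purine(ea) == purine(eb)),
    v = sum(ok & ea != eb & purine(ea) != purine(eb)),
    m = m)
}

to_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1L]]
  toupper(x)
}

purine <- function(enc) enc == 1L | enc == 3L  # A or G

k2p_from_counts <- function(s, v, m) {
  P <- s / m; Q <- v / m
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- w1 <= 0 || w2 <= 0
  d <- if (saturated) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  list(d = d, P = P, Q = Q, m = as.integer(m), s = as.integer(s),
       v = as.integer(v), saturated = saturated)
}

#' Pairwise K2P distance matrix
#'
#' Applies [k2p()] to every pair with pairwise deletion.  Pairs with no
#' overlapping determinate sites or with saturated distances are flagged
#' and carry `NA` distances; [threshold_clusters()] treats them as
#' infinitely distant.
#'
#' @param aln an [alignment].
#' @return an object of class `k2p_dist`: list with the `ids` and symmetric
#'   matrices `d` (K2P distance), `p_dist` (uncorrected p-distance), `P`,
#'   `Q` (proportions), `m`, `s`, `v` (site counts) and `flag` (`""`,
#'   `"saturated"` or `"no_overlap"`).
#' @export
k2p_matrix <- function(aln) {
  aln <- new_alignment(unclass(aln))
  n <- nrow(aln)
  ids <- rownames(aln)
  enc <- matrix(match(aln, c("A", "C", "G", "T")), nrow = n)
  pur <- matrix(purine(enc), nrow = n)
  mk <- function(init) matrix(init, n, n, dimnames = list(ids, ids))
  d <- mk(0); pd <- mk(0); P <- mk(0); Q <- mk(0)
  m <- mk(NA_integer_); s <- mk(0L); v <- mk(0L); flag <- mk("")
  diag(m) <- ncol(aln)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, n)) {
      ok <- !is.na(enc[i, ]) & !is.na(enc[j, ])
      mm <- sum(ok)
      if (mm == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        pd[i, j] <- pd[j, i] <- NA_real_
        m[i, j] <- m[j, i] <- 0L
        flag[i, j] <- flag[j, i] <- "no_overlap"
        next
      }
      diff <- ok & enc[i, ] != enc[j, ]
      ts <- sum(diff & pur[i, ] == pur[j, ])
      tv <- sum(diff) - ts
      res <- k2p_from_counts(ts, tv, mm)
      d[i, j] <- d[j, i] <- res$d
      pd[i, j] <- pd[j, i] <- (ts + tv) / mm
      P[i, j] <- P[j, i] <- res$P
      Q[i, j] <- Q[j, i] <- res$Q
      m[i, j] <- m[j, i] <- mm
      s[i, j] <- s[j, i] <- ts
      v[i, j] <- v[j, i] <- tv
      if (res$saturated) flag[i, j] <- flag[j, i] <- "saturated"
    }
  }
  structure(list(ids = ids, d = d, p_dist = pd, P = P, Q = Q, m = m, s = s,
                 v = v, flag = flag),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  n_bad <- sum(x$flag[upper.tri(x$flag)] != "")
  cat(sprintf("K2P distance matrix: %d sequences, %d flagged pairs\n",
              length(x$ids), n_bad))
  invisible(x)
}

# ---- threshold clustering ---------------------------------------------------

#' Cluster sequences at a similarity threshold
#'
#' Groups sequences whose distance is at most `cutoff` (default 0.01, i.e.
#' a 99% similarity threshold).  Single linkage takes connected components
#' of the graph with an edge whenever `d <= cutoff` (chaining allowed);
#' complete linkage requires all within-cluster pairs to be within the
#' cutoff.  Flagged pairs (saturated / no overlap) contribute no edge and
#' are logged with a warning.  Clusters are numbered by first-seen id.
#'
#' @param dm a `k2p_dist` from [k2p_matrix()].
#' @param cutoff distance cutoff in (0, 1).
#' @param linkage `"single"` (default) or `"complete"`.
#' @param metric `"k2p"` (default) or `"p"` for the uncorrected p-distance.
#' @return a data frame with columns `id` and `cluster` (integer labels in
#'   first-seen order); the number of clusters is in
#'   `attr(., "n_clusters")`.
#' @export
threshold_clusters <- function(dm, cutoff = 0.01,
                               linkage = c("single", "complete"),
                               metric = c("k2p", "p")) {
  if (!inherits(dm, "k2p_dist")) stopf("`dm` must be a k2p_dist (see k2p_matrix)")
  if (!(is.numeric(cutoff) && length(cutoff) == 1L && cutoff > 0 && cutoff < 1)) {
    stopf("`cutoff` must be in (0, 1)")
  }
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  D <- if (metric == "k2p") dm$d else dm$p_dist
  n <- length(dm$ids)
  n_flagged <- sum(dm$flag[upper.tri(dm$flag)] != "")
  if (n_flagged > 0L) {
    warnf("threshold_clusters: %d flagged pairs treated as infinitely distant",
          n_flagged)
  }
  D[is.na(D)] <- Inf
  if (n == 1L) {
    labels <- 1L
  } else if (linkage == "single") {
    idx <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
    labels <- connected_components(n, idx)
  } else {
    Dh <- D
    Dh[!is.finite(Dh)] <- max(1, cutoff) * 1e6
    hc <- stats::hclust(stats::as.dist(Dh), method = "complete")
    raw <- stats::cutree(hc, h = cutoff)
    labels <- match(raw, unique(raw))  # renumber by first occurrence
  }
  labels <- match(labels, unique(labels))
  out <- data.frame(id = dm$ids, cluster = as.integer(labels),
                    stringsAsFactors = FALSE)
  attr(out, "n_clusters") <- max(labels)
  out
}

# ---- saturation profile -----------------------------------------------------

#' Per-pair transition/transversion saturation profile
#'
#' Tabulates transitions `s`, transversions `v` and the K2P distance for
#' every sequence pair, suitable for plotting substitution counts against
#' divergence to inspect saturation.  Pairs with no determinate overlap or
#' saturated distances are kept as rows with the corresponding flag.
#'
#' @param aln an [alignment] (>= 2 sequences).
#' @return a data frame with columns `id_a`, `id_b`, `s`, `v`, `m`, `d`,
#'   `flag`.
#' @export
saturation_profile <- function(aln) {
  aln <- new_alignment(unclass(aln))
  if (nrow(aln) < 2L) stopf("need at least 2 sequences")
  dm <- k2p_matrix(aln)
  pairs <- which(upper.tri(dm$d), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  data.frame(
    id_a = dm$ids[pairs[, 1L]],
    id_b = dm$ids[pairs[, 2L]],
    s = dm$s[pairs],
    v = dm$v[pairs],
    m = dm$m[pairs],
    d = dm$d[pairs],
    flag = dm$flag[pairs],
    stringsAsFactors = FALSE)
}
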
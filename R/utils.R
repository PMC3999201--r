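# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so simulations do not disturb the caller's stream.
#' A `NULL` seed evaluates `code` under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

#' Connected components of an undirected graph
#'
#' @param n number of vertices.
#' @param edges two-column integer matrix of vertex pairs (may have 0 rows).
#' @return integer vector of component labels, numbered by first-seen vertex.
#' @keywords internal
#' @noRd
connected_components <- function(n, edges) {
  comp <- integer(n)
  if (n == 0L) return(comp)
  adj <- vector("list", n)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1L]; j <- edges[r, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  label <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    label <- label + 1L
    queue <- v
    comp[v] <- label
    while (length(queue) > 0L) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      for (w in adj[[u]]) {
        if (comp[w] == 0L) {
          comp[w] <- label
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}
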
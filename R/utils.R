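# Internal helpers shared across modules.

# Union-find over n nodes given an edge matrix (2 columns, 1-based indices).
# Returns integer component labels 1..k in order of first appearance.
.unionFind <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1L])
      rj <- find(edges[e, 2L])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

.assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Seed scoping: set the RNG when a seed is supplied, leave the caller's
# stream untouched otherwise.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L)
      stop("'seed' must be a single integer", call. = FALSE)
    set.seed(as.integer(seed))
  }
  expr
}

# Pairwise Euclidean distances between rows of two 2-column matrices.
.crossDist <- function(a, b) {
  dx <- outer(a[, 1L], b[, 1L], "-")
  dy <- outer(a[, 2L], b[, 2L], "-")
  sqrt(dx * dx + dy * dy)
}

# All permutations of 1..n in lexicographic order (n small).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}
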
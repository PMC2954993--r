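# Independent oracles used to validate the package's fast paths.

# Brute-force object count: explicit O(N^2) pair loop, igraph components.
# Mirrors the merge predicate (positive-area overlap of border-clipped
# square footprints AND identical color subsets) with scalar arithmetic.
oracleSegmentCount <- function(pop) {
  centers <- cellCenters(pop)
  n <- nrow(centers)
  if (n == 0) return(0L)
  side <- pop@side
  W <- pop@region[1]; H <- pop@region[2]
  cols <- pop@colors
  g <- igraph::make_empty_graph(n, directed = FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      xi0 <- max(0, centers[i, 1] - side / 2); xi1 <- min(W, centers[i, 1] + side / 2)
      xj0 <- max(0, centers[j, 1] - side / 2); xj1 <- min(W, centers[j, 1] + side / 2)
      yi0 <- max(0, centers[i, 2] - side / 2); yi1 <- min(H, centers[i, 2] + side / 2)
      yj0 <- max(0, centers[j, 2] - side / 2); yj1 <- min(H, centers[j, 2] + side / 2)
      ox <- min(xi1, xj1) - max(xi0, xj0)
      oy <- min(yi1, yj1) - max(yi0, yj0)
      if (ox > 0 && oy > 0 && cols[i] == cols[j])
        g <- igraph::add_edges(g, c(i, j))
    }
  }
  igraph::components(g)$no
}

# Exact nonnegative least squares for K = 2 by active-set enumeration:
# the optimum is one of {unconstrained LS, a1 = 0, a2 = 0, both 0},
# each solved in closed form and filtered for feasibility.
oracleNNLS2 <- function(S, y) {
  cands <- list(c(0, 0))
  a2only <- max(0, sum(S[, 2] * y) / sum(S[, 2]^2))
  a1only <- max(0, sum(S[, 1] * y) / sum(S[, 1]^2))
  cands <- c(cands, list(c(a1only, 0)), list(c(0, a2only)))
  ls <- tryCatch(solve(crossprod(S), crossprod(S, y)), error = function(e) NULL)
  if (!is.null(ls) && all(ls >= 0)) cands <- c(cands, list(as.numeric(ls)))
  resid <- vapply(cands, function(a) sum((S %*% a - y)^2), numeric(1))
  cands[[which.min(resid)]]
}

# Recount identity switches from a known per-frame label sequence,
# honoring the parent-lineage exemption, with plain loops.
oracleSwitchCount <- function(labelSeqs, parentMap = integer(0)) {
  total <- 0L
  for (l in labelSeqs) {
    if (length(l) < 2) next
    for (t in 2:length(l)) {
      if (l[t] != l[t - 1]) {
        p <- parentMap[as.character(l[t])]
        if (is.na(p) || length(p) == 0 || p != l[t - 1]) total <- total + 1L
      }
    }
  }
  total
}

# Direct construction of a PlacedPopulation from explicit geometry.
makePopulation <- function(centers, colors, region = c(100, 100), side = 10) {
  codes <- vapply(colors, function(s) {
    sum(c(R = 1L, G = 2L, B = 4L)[s])
  }, integer(1))
  new("PlacedPopulation", region = as.numeric(region), side = as.numeric(side),
      density = nrow(centers) / (prod(region) / 100), centers = centers,
      colors = codes, scheme = "manual")
}
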
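# Stochastic simulation of automated object counting vs tissue density
# under 1-color and 3-color nuclear labeling.

.schemes <- c("one", "nomix", "mix")

#' Seed a rectangular tissue region with square cell footprints
#'
#' Places \code{N = round(density * area / 100)} cells with centers drawn
#' uniformly and independently in the region, mimicking a dense tissue in
#' which each nucleus occupies a square footprint of the given side.
#' Footprints are clipped at the region borders (no wraparound).
#'
#' @param region numeric(2), region width and height in micrometres
#'   (default \code{c(100, 100)}).
#' @param density cells per 100 square micrometres (nonnegative).
#' @param side footprint side in micrometres; the default 10 corresponds to
#'   a typical nuclear diameter.
#' @param seed optional integer seed; if \code{NULL} the current RNG
#'   stream is used.
#' @return A \linkS4class{PlacedPopulation} with unassigned colors.
#' @examples
#' pop <- seedCells(density = 2, seed = 1)
#' nCells(pop)  # 200
#' @export
seedCells <- function(region = c(100, 100), density, side = 10, seed = NULL) {
  if (length(region) != 2L || any(!is.finite(region)) || any(region <= 0))
    stop("'region' must be two positive lengths (width, height)")
  .assertScalar(density, "density", nonneg = TRUE)
  .assertScalar(side, "side", positive = TRUE)
  n <- as.integer(round(density * prod(region) / 100))
  centers <- .withSeed(seed, {
    cbind(x = stats::runif(n, 0, region[1L]),
          y = stats::runif(n, 0, region[2L]))
  })
  if (n == 0L) centers <- matrix(numeric(0), 0L, 2L,
                                 dimnames = list(NULL, c("x", "y")))
  new("PlacedPopulation", region = as.numeric(region), side = as.numeric(side),
      density = as.numeric(density), centers = centers,
      colors = integer(n), scheme = "")
}

#' Assign nuclear label colors to a seeded population
#'
#' Implements the three labeling schemes compared in the counting
#' simulation: \code{"one"} gives every cell the same single color;
#' \code{"nomix"} draws one of three colors uniformly per cell (a cell can
#' only have one color); \code{"mix"} draws a nonempty subset of the three
#' colors uniformly from the 7 possibilities (a cell can have up to three).
#'
#' @param pop a \linkS4class{PlacedPopulation}.
#' @param scheme one of \code{"one"}, \code{"nomix"}, \code{"mix"}.
#' @param seed optional integer seed.
#' @return The population with color subsets filled in.
#' @export
assignColors <- function(pop, scheme = c("one", "nomix", "mix"), seed = NULL) {
  stopifnot(is(pop, "PlacedPopulation"))
  scheme <- match.arg(scheme)
  n <- nCells(pop)
  cols <- .withSeed(seed, switch(scheme,
    one   = rep(1L, n),
    nomix = sample(c(1L, 2L, 4L), n, replace = TRUE),
    mix   = sample(1:7, n, replace = TRUE)
  ))
  pop@colors <- as.integer(cols)
  pop@scheme <- scheme
  validObject(pop)
  pop
}

# Clipped footprint bounds: each footprint is the intersection of the
# side x side square with the region.
.clippedBounds <- function(pop) {
  h <- pop@side / 2
  list(
    xlo = pmax(0, pop@centers[, 1L] - h),
    xhi = pmin(pop@region[1L], pop@centers[, 1L] + h),
    ylo = pmax(0, pop@centers[, 2L] - h),
    yhi = pmin(pop@region[2L], pop@centers[, 2L] + h)
  )
}

# Adjacency (logical N x N) of positive-area footprint overlap.
.overlapAdjacency <- function(pop) {
  b <- .clippedBounds(pop)
  ox <- outer(b$xlo, b$xlo, pmax) < outer(b$xhi, b$xhi, pmin)
  oy <- outer(b$ylo, b$ylo, pmax) < outer(b$yhi, b$yhi, pmin)
  ox & oy
}

#' Count objects a color-aware segmentation would report
#'
#' Emulates the automated segmentation step of the counting simulation.
#' In the default \code{"merge"} mode two cells end up in the same counted
#' object iff their footprints overlap with positive area \emph{and} their
#' color subsets are identical (a color-identity region growing keeps
#' differently-colored overlapping cells separate); the count is the
#' number of connected components under that relation. The alternative
#' \code{"channel"} mode mirrors the real-data routine: per-channel
#' connected components are reduced to centroid spots, and spots closer
#' than \code{linkDist} are linked transitively into objects.
#'
#' @param pop a \linkS4class{PlacedPopulation} with assigned colors.
#' @param mode \code{"merge"} (default) or \code{"channel"}.
#' @param linkDist centroid linking distance in micrometres, used only in
#'   \code{"channel"} mode (default 2, the multicolor spot-linking rule).
#' @return A list with \code{n_true}, \code{n_counted} and
#'   \code{fraction} (= n_counted / n_true; \code{NA} when n_true is 0).
#' @examples
#' pop <- assignColors(seedCells(density = 1, seed = 1), "mix", seed = 2)
#' segmentObjects(pop)
#' @export
segmentObjects <- function(pop, mode = c("merge", "channel"), linkDist = 2) {
  stopifnot(is(pop, "PlacedPopulation"))
  mode <- match.arg(mode)
  n <- nCells(pop)
  if (n > 0L && !nzchar(pop@scheme))
    stop("colors have not been assigned; call assignColors() first")
  if (n == 0L)
    return(list(n_true = 0L, n_counted = 0L, fraction = NA_real_))
  counted <- if (mode == "merge") {
    adj <- .overlapAdjacency(pop) &
      outer(pop@colors, pop@colors, "==")
    adj[!upper.tri(adj)] <- FALSE
    max(.unionFind(n, which(adj, arr.ind = TRUE)))
  } else {
    .channelModeCount(pop, linkDist)
  }
  list(n_true = n, n_counted = as.integer(counted),
       fraction = counted / n)
}

# Per-channel connected components -> centroid spots -> transitive linking.
.channelModeCount <- function(pop, linkDist) {
  .assertScalar(linkDist, "linkDist", nonneg = TRUE)
  adjAll <- .overlapAdjacency(pop)
  spots <- matrix(numeric(0), 0L, 2L)
  for (bit in c(1L, 2L, 4L)) {
    idx <- which(bitwAnd(pop@colors, bit) > 0L)
    if (!length(idx)) next
    adj <- adjAll[idx, idx, drop = FALSE]
    adj[!upper.tri(adj)] <- FALSE
    comp <- .unionFind(length(idx), which(adj, arr.ind = TRUE))
    cent <- vapply(seq_len(max(comp)), function(k) {
      colMeans(pop@centers[idx[comp == k], , drop = FALSE])
    }, numeric(2))
    spots <- rbind(spots, t(cent))
  }
  if (!nrow(spots)) return(0L)
  d <- .crossDist(spots, spots)
  adj <- d < linkDist
  adj[!upper.tri(adj)] <- FALSE
  max(.unionFind(nrow(spots), which(adj, arr.ind = TRUE)))
}

#' Sweep counted-object fraction over cell densities
#'
#' Runs the counting simulation over a grid of densities, averaging the
#' counted fraction over independent replicates per density, and returns
#' the density-response curve for one labeling scheme.
#'
#' @inheritParams assignColors
#' @inheritParams segmentObjects
#' @param densities numeric vector of densities (cells per 100 um^2).
#' @param reps replicates per density (the full-scale study uses 10,000;
#'   smaller values trade Monte-Carlo error for speed).
#' @param region,side region dimensions and footprint side in micrometres.
#' @param seed integer seed; the whole sweep is reproducible given
#'   (seed, parameters).
#' @return data.frame with columns scheme, density, mean_fraction,
#'   sd_fraction, reps.
#' @examples
#' runDensitySweep("one", densities = c(0.2, 0.6), reps = 50, seed = 1)
#' @export
runDensitySweep <- function(scheme = c("one", "nomix", "mix"), densities,
                            reps = 10000, region = c(100, 100), side = 10,
                            seed = NULL, mode = c("merge", "channel"),
                            linkDist = 2) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (!length(densities)) stop("'densities' must be a nonempty numeric vector")
  if (any(!is.finite(densities)) || any(densities < 0))
    stop("'densities' must be nonnegative")
  .assertScalar(reps, "reps", positive = TRUE)
  .withSeed(seed, {
    rows <- lapply(densities, function(d) {
      fr <- vapply(seq_len(reps), function(r) {
        pop <- assignColors(seedCells(region, d, side), scheme)
        segmentObjects(pop, mode = mode, linkDist = linkDist)$fraction
      }, numeric(1))
      data.frame(scheme = scheme, density = d,
                 mean_fraction = mean(fr), sd_fraction = stats::sd(fr),
                 reps = as.integer(reps))
    })
    do.call(rbind, rows)
  })
}

#' Histogram of counted percentages in fixed-width bins
#'
#' Bins counted-object percentages (fractions times 100) into half-open
#' bins \code{[lo, lo + width)}, the representation used to report the
#' modal counting accuracy across simulations.
#'
#' @param fractions numeric vector of counted fractions (0..1 scale).
#' @param binWidth bin width in percentage points (default 5).
#' @return data.frame with columns bin_lo, bin_hi, count covering
#'   \code{[0, ceiling(max))}; zero rows for empty input.
#' @examples
#' fractionHistogram(c(0.10, 0.14, 0.97))
#' @export
fractionHistogram <- function(fractions, binWidth = 5) {
  .assertScalar(binWidth, "binWidth", positive = TRUE)
  if (!length(fractions))
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  pct <- fractions * 100
  lo <- floor(pct / binWidth) * binWidth
  top <- max(lo)
  bins <- seq(0, top, by = binWidth)
  count <- vapply(bins, function(b) sum(lo == b), integer(1))
  data.frame(bin_lo = bins, bin_hi = bins + binWidth, count = count)
}
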
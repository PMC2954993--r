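# Spectral fingerprints: normalized per-fluorophore intensity fractions,
# their rank order, and a simple combinatorics of multicolor identity.

#' Compute a spectral fingerprint from per-channel intensities
#'
#' A cell's fingerprint is the fraction of its total intensity carried by
#' each fluorophore (the fractions sum to 1), together with the rank
#' order of fluorophores by descending fraction and the support set of
#' fluorophores above a noise floor. The rank order is the stable part of
#' the identity: absolute intensities drift with imaging conditions but
#' the hierarchy of colors within a cell persists.
#'
#' @param intensities named nonnegative numeric vector of per-fluorophore
#'   mean intensities; must have at least one positive entry.
#' @param noiseFloor fractions at or below this value are excluded from
#'   the support set (default 0.05).
#' @return list with \code{fractions} (sums to 1), \code{rank_order}
#'   (integer permutation, ties broken by channel order), \code{support}
#'   (character), and \code{tied} (TRUE when any two fractions are equal,
#'   flagging a degenerate rank order).
#' @examples
#' computeFingerprint(c(R = 30, G = 60, B = 10))
#' @export
computeFingerprint <- function(intensities, noiseFloor = 0.05) {
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  tot <- sum(intensities)
  if (tot <= 0) stop("all-zero intensities: no fingerprint defined")
  fr <- intensities / tot
  rk <- order(-fr, seq_along(fr))
  nm <- names(fr)
  if (is.null(nm)) nm <- paste0("ch", seq_along(fr))
  list(fractions = fr,
       rank_order = rk,
       support = nm[fr > noiseFloor],
       tied = anyDuplicated(fr) > 0L)
}

#' L1 distance between two fingerprints
#'
#' The distance between fraction vectors lies in [0, 2]: 0 for identical
#' fingerprints, 2 for disjoint supports.
#'
#' @param a,b fingerprints from \code{\link{computeFingerprint}} (or bare
#'   fraction vectors of equal length).
#' @return numeric L1 distance.
#' @seealso \code{\link{rankAgreement}}
#' @export
fingerprintDistance <- function(a, b) {
  fa <- if (is.list(a)) a$fractions else a
  fb <- if (is.list(b)) b$fractions else b
  if (length(fa) != length(fb))
    stop("fingerprints have different numbers of fluorophores")
  sum(abs(fa - fb))
}

#' Do two fingerprints share the same rank order?
#'
#' @inheritParams fingerprintDistance
#' @return logical.
#' @export
rankAgreement <- function(a, b) {
  fa <- if (is.list(a)) a$fractions else a
  fb <- if (is.list(b)) b$fractions else b
  if (length(fa) != length(fb))
    stop("fingerprints have different numbers of fluorophores")
  identical(order(-fa, seq_along(fa)), order(-fb, seq_along(fb)))
}

#' Number of tracking outcomes for co-located cells
#'
#' When k cells occupy nearly the same position, positional tracking
#' faces k! possible reassignments once the cells separate.
#'
#' @param k number of co-located cells (>= 1).
#' @return k factorial.
#' @examples
#' ambiguityCount(4)  # 24
#' @export
ambiguityCount <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer")
  factorial(k)
}

#' Number of distinguishable color combinations
#'
#' With n co-expressed fluorescent proteins a cell can carry any nonempty
#' subset, i.e. \code{2^n - 1} combinations (7 for a 3-color cocktail).
#'
#' @param nColors number of fluorophores (>= 1).
#' @return integer count of nonempty subsets.
#' @examples
#' countColorCombinations(3)  # 7
#' @export
countColorCombinations <- function(nColors) {
  if (!is.numeric(nColors) || length(nColors) != 1L || nColors < 1 ||
      nColors != round(nColors))
    stop("'nColors' must be a positive integer")
  as.integer(2^nColors - 1)
}

#' Stability of a track's spectral identity over time
#'
#' Reports the fraction of frames whose fingerprint rank order equals the
#' track's modal rank order, plus the per-frame fraction time series.
#' A value of 1 means the hierarchy of colors never changed.
#'
#' @param fractions numeric matrix, frames x fluorophores, rows summing
#'   to 1 (e.g. the \code{frac_} columns of a track).
#' @return list with \code{stability}, \code{modal_rank} (integer
#'   permutation) and \code{ranks} (character vector per frame).
#' @export
fingerprintStability <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) < 2L)
    stop("a track of length >= 2 is required")
  ranks <- apply(fractions, 1L, function(f)
    paste(order(-f, seq_along(f)), collapse = ">"))
  modal <- names(sort(table(ranks), decreasing = TRUE))[1L]
  list(stability = mean(ranks == modal),
       modal_rank = as.integer(strsplit(modal, ">")[[1L]]),
       ranks = ranks)
}
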
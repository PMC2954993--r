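# Linear unmixing of lambda stacks against reference spectra, plus the
# background-thresholding rule and maximum-intensity projection.

#' Non-negative linear unmixing of a multichannel stack
#'
#' Solves, for every pixel, \code{min ||S a - y||^2} subject to
#' \code{a >= 0}, where \code{S} is the channels-by-fluorophores reference
#' matrix and \code{y} the pixel's channel vector. The bulk of pixels is
#' solved by the unconstrained normal equations; only pixels whose
#' unconstrained solution has a negative coefficient are passed to an
#' active-set non-negative least-squares solve. The autofluorescence
#' column, when present, is included in the fit and its abundance dropped
#' from the result (that is how tissue autofluorescence is subtracted).
#'
#' @param stack numeric array C x Y x X.
#' @param spectra a \linkS4class{ReferenceSpectra} with C channels.
#' @param dropAutofluorescence discard the autofluorescence abundance
#'   plane after solving (default TRUE).
#' @return an \linkS4class{AbundanceMap}.
#' @examples
#' sp <- makeReferenceSpectra(defaultFluorophores(c("GFP", "RFP")),
#'                            lambdaLayout(494, 623, 10.7))
#' y <- 5 * spectraMatrix(sp)[, "GFP"]
#' am <- unmixStack(array(y, dim = c(12, 1, 1)), sp)
#' abundance(am)[, 1, 1]
#' @export
unmixStack <- function(stack, spectra, dropAutofluorescence = TRUE) {
  stopifnot(is(spectra, "ReferenceSpectra"))
  S <- spectraMatrix(spectra)
  d <- dim(stack)
  if (length(d) != 3L)
    stop("'stack' must be a C x Y x X array")
  if (d[1L] != nrow(S))
    stop(sprintf("stack has %d channels but spectra expect %d",
                 d[1L], nrow(S)))
  if (nrow(S) < ncol(S))
    warning("fewer channels than fluorophores: the unmixing is underdetermined")
  G <- crossprod(S)
  if (rcond(G) < 1e-10)
    warning("reference spectra are near rank-deficient; abundances may be unstable")
  P <- d[2L] * d[3L]
  Y <- matrix(stack, nrow = d[1L])           # C x P
  A <- solve(G, crossprod(S, Y))             # unconstrained K x P
  bad <- which(matrixStats_colAnys_neg(A))
  for (p in bad)
    A[, p] <- pracma::lsqnonneg(S, Y[, p])$x
  A[A < 0] <- 0
  res <- sqrt(colSums((S %*% A - Y)^2))
  keep <- seq_len(ncol(S))
  if (dropAutofluorescence && length(spectra@autofluorescence))
    keep <- which(colnames(S) != spectra@autofluorescence)
  ab <- aperm(array(t(A)[, keep, drop = FALSE],
                    dim = c(d[2L], d[3L], length(keep))), c(3L, 1L, 2L))
  new("AbundanceMap", abundance = ab,
      residual = matrix(res, d[2L], d[3L]),
      fluorophores = colnames(S)[keep])
}

# colAnys(A < -tol) without extra dependencies
matrixStats_colAnys_neg <- function(A, tol = 1e-10) {
  colSums(A < -tol) > 0L
}

#' Background threshold from a signal-free region
#'
#' The per-channel threshold is 125 percent of the maximum intensity
#' inside a rectangle drawn over background (the extra 25 percent
#' guarantees that genuine background pixels fall below it).
#'
#' @param channelImage numeric matrix Y x X.
#' @param backgroundRegion integer(4) \code{c(row0, col0, row1, col1)},
#'   1-based inclusive bounds of the background rectangle.
#' @return the threshold intensity (1.25 x background maximum).
#' @examples
#' img <- matrix(80, 4, 4)
#' backgroundThreshold(img, c(1, 1, 2, 2))  # 100
#' @export
backgroundThreshold <- function(channelImage, backgroundRegion) {
  if (length(backgroundRegion) != 4L)
    stop("'backgroundRegion' must be c(row0, col0, row1, col1)")
  r <- as.integer(backgroundRegion)
  if (r[1L] < 1L || r[2L] < 1L || r[3L] > nrow(channelImage) ||
      r[4L] > ncol(channelImage) || r[3L] < r[1L] || r[4L] < r[2L])
    stop("background region must be a nonempty rectangle inside the image")
  1.25 * max(channelImage[r[1L]:r[3L], r[2L]:r[4L]])
}

#' Apply per-channel thresholds to a stack
#'
#' Sets every value at or below its channel's threshold to zero, leaving
#' other values unchanged (after this, any positive pixel is treated as
#' signal).
#'
#' @param stack numeric array C x Y x X.
#' @param thresholds numeric vector, one threshold per channel.
#' @return the thresholded stack.
#' @export
applyThreshold <- function(stack, thresholds) {
  d <- dim(stack)
  if (length(d) != 3L) stop("'stack' must be a C x Y x X array")
  if (length(thresholds) != d[1L])
    stop(sprintf("%d thresholds supplied for %d channels",
                 length(thresholds), d[1L]))
  for (ch in seq_len(d[1L])) {
    plane <- stack[ch, , ]
    plane[plane <= thresholds[ch]] <- 0
    stack[ch, , ] <- plane
  }
  stack
}

#' Maximum intensity projection of a z-stack
#'
#' @param zstack numeric array Z x Y x X with Z >= 1.
#' @return numeric matrix Y x X of per-pixel maxima over z.
#' @export
maxIntensityProjection <- function(zstack) {
  d <- dim(zstack)
  if (length(d) != 3L || d[1L] < 1L)
    stop("'zstack' must be a Z x Y x X array with Z >= 1")
  out <- zstack[1L, , ]
  if (d[1L] > 1L)
    for (z in 2:d[1L]) out <- pmax(out, zstack[z, , ])
  out
}
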
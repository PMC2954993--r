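#' @import methods
NULL

#' Randomly seeded cell population in a rectangular tissue region
#'
#' Holds the state of one counting-simulation instance: square cell
#' footprints placed uniformly at random in a rectangular region
#' (approximating a dense embryonic tissue), together with the per-cell
#' color subsets assigned under a labeling scheme.
#'
#' Color subsets are stored as integer bitmasks over the three simulated
#' channels (bit 1 = R, bit 2 = G, bit 3 = B); \code{0} means colors have
#' not been assigned yet. Use \code{\link{colorSubsets}} for a readable
#' list representation.
#'
#' @slot region numeric(2), region width and height in micrometres.
#' @slot side numeric(1), side of the square cell footprint in micrometres.
#' @slot density numeric(1), nominal density in cells per 100 square
#'   micrometres.
#' @slot centers numeric matrix N x 2 of cell centers (x, y) in micrometres.
#' @slot colors integer vector of length N, bitmask color subsets (0-7).
#' @slot scheme character(1), one of "" (unassigned), "one", "nomix", "mix".
#'
#' @seealso \code{\link{seedCells}}, \code{\link{assignColors}},
#'   \code{\link{segmentObjects}}
#' @export
setClass("PlacedPopulation",
  representation(
    region  = "numeric",
    side    = "numeric",
    density = "numeric",
    centers = "matrix",
    colors  = "integer",
    scheme  = "character"
  )
)

setValidity("PlacedPopulation", function(object) {
  msg <- character(0)
  if (length(object@region) != 2L || any(object@region <= 0))
    msg <- c(msg, "region must be two positive lengths (width, height)")
  if (length(object@side) != 1L || object@side <= 0)
    msg <- c(msg, "side must be a single positive length")
  if (ncol(object@centers) != 2L && nrow(object@centers) > 0L)
    msg <- c(msg, "centers must have two columns")
  if (nrow(object@centers) != length(object@colors))
    msg <- c(msg, "one color subset per cell required")
  if (any(object@colors < 0L | object@colors > 7L))
    msg <- c(msg, "color bitmasks must lie in 0..7")
  if (nrow(object@centers) > 0L) {
    inX <- object@centers[, 1L] >= 0 & object@centers[, 1L] <= object@region[1L]
    inY <- object@centers[, 2L] >= 0 & object@centers[, 2L] <= object@region[2L]
    if (!all(inX & inY)) msg <- c(msg, "cell centers must lie inside the region")
  }
  if (length(msg)) msg else TRUE
})

#' Emission channel layout of a multispectral acquisition
#'
#' Describes how emitted light is binned into detection channels: either
#' contiguous lambda-scanning bins of fixed step, or arbitrary bandpass
#' windows (channel mode).
#'
#' @slot mode character(1), "lambda" or "channel".
#' @slot bands numeric matrix C x 2 of band lower/upper edges in nm.
#'
#' @seealso \code{\link{lambdaLayout}}, \code{\link{channelLayout}},
#'   \code{\link{lambdaChannels}}
#' @export
setClass("ChannelLayout",
  representation(mode = "character", bands = "matrix")
)

setValidity("ChannelLayout", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("lambda", "channel"))
    msg <- c(msg, "mode must be 'lambda' or 'channel'")
  if (ncol(object@bands) != 2L || nrow(object@bands) < 1L)
    msg <- c(msg, "bands must be a C x 2 matrix with C >= 1")
  else if (any(object@bands[, 2L] <= object@bands[, 1L]))
    msg <- c(msg, "each band's upper edge must exceed its lower edge")
  if (length(msg)) msg else TRUE
})

#' Reference emission spectra of a fluorophore panel
#'
#' A channels-by-fluorophores matrix of per-channel emission weights, each
#' column normalized to unit sum, as used for linear unmixing. May carry an
#' extra broad autofluorescence column whose unmixed abundance is discarded.
#'
#' @slot S numeric matrix C x K, columns unit-sum, column names are
#'   fluorophore names.
#' @slot channels numeric C, channel center wavelengths in nm.
#' @slot autofluorescence character, name of the autofluorescence column
#'   (length 0 if absent).
#'
#' @seealso \code{\link{makeReferenceSpectra}}, \code{\link{unmixStack}}
#' @export
setClass("ReferenceSpectra",
  representation(S = "matrix", channels = "numeric",
                 autofluorescence = "character")
)

setValidity("ReferenceSpectra", function(object) {
  msg <- character(0)
  if (any(object@S < 0)) msg <- c(msg, "spectra must be nonnegative")
  if (is.null(colnames(object@S))) msg <- c(msg, "columns must be named")
  if (length(object@channels) != nrow(object@S))
    msg <- c(msg, "one channel center per row required")
  sums <- colSums(object@S)
  if (any(abs(sums - 1) > 1e-8))
    msg <- c(msg, "columns must sum to 1")
  if (length(object@autofluorescence) > 1L ||
      (length(object@autofluorescence) == 1L &&
       !object@autofluorescence %in% colnames(object@S)))
    msg <- c(msg, "autofluorescence must name one column or be empty")
  if (length(msg)) msg else TRUE
})

#' Synthetic multispectral movie with ground truth
#'
#' A time series of multichannel frames (T x C x Y x X) rendered from known
#' cell positions and fluorophore expression vectors, together with the
#' full ground truth (per-frame positions, expression, lineage). The frame
#' array may be empty when only the ground truth is needed.
#'
#' @slot frames numeric array T x C x Y x X (or a 0-length array).
#' @slot frameInterval numeric(1), minutes between frames.
#' @slot pixelSize numeric(1), micrometres per pixel.
#' @slot field numeric(2), field of view width and height in micrometres.
#' @slot truth data.frame with columns frame, cell_id, x, y, parent_id and
#'   one \code{expr_<fluorophore>} column per fluorophore.
#' @slot spectra the \linkS4class{ReferenceSpectra} used for rendering
#'   (or NULL).
#' @slot scenario character(1), free-text scenario tag.
#'
#' @seealso \code{\link{makeCrossingScenario}},
#'   \code{\link{makeDivisionScenario}}, \code{\link{makeRandomWalkMovie}}
#' @export
setClass("SyntheticMovie",
  representation(
    frames = "array", frameInterval = "numeric", pixelSize = "numeric",
    field = "numeric", truth = "data.frame", spectra = "ANY",
    scenario = "character"
  )
)

setValidity("SyntheticMovie", function(object) {
  msg <- character(0)
  if (length(object@frames) && length(dim(object@frames)) != 4L)
    msg <- c(msg, "frames must be a T x C x Y x X array")
  if (length(object@frames) && any(object@frames < 0))
    msg <- c(msg, "intensities must be nonnegative")
  need <- c("frame", "cell_id", "x", "y", "parent_id")
  if (!all(need %in% names(object@truth)))
    msg <- c(msg, paste("truth must contain columns:",
                        paste(need, collapse = ", ")))
  if (nrow(object@truth)) {
    ok <- object@truth$x >= 0 & object@truth$x <= object@field[1L] &
          object@truth$y >= 0 & object@truth$y <= object@field[2L]
    if (!all(ok)) msg <- c(msg, "truth positions must lie inside the field")
  }
  if (length(msg)) msg else TRUE
})

#' Per-pixel fluorophore abundances from linear unmixing
#'
#' @slot abundance numeric array K x Y x X of nonnegative abundances.
#' @slot residual numeric matrix Y x X, per-pixel residual norm of the
#'   nonnegative least-squares fit.
#' @slot fluorophores character K, column labels.
#'
#' @seealso \code{\link{unmixStack}}
#' @export
setClass("AbundanceMap",
  representation(abundance = "array", residual = "matrix",
                 fluorophores = "character")
)

setValidity("AbundanceMap", function(object) {
  msg <- character(0)
  if (any(object@abundance < 0)) msg <- c(msg, "abundances must be nonnegative")
  if (dim(object@abundance)[1L] != length(object@fluorophores))
    msg <- c(msg, "one label per abundance plane required")
  if (length(msg)) msg else TRUE
})

#' Detected spots in one image or movie
#'
#' @slot spots data.frame with columns x, y (micrometres), channel,
#'   intensity, diameter (expected object diameter used for detection),
#'   and frame when detected from a movie.
#' @slot pixelSize numeric(1), micrometres per pixel of the source image.
#'
#' @seealso \code{\link{detectSpots}}, \code{\link{linkSpots}}
#' @export
setClass("SpotSet",
  representation(spots = "data.frame", pixelSize = "numeric")
)

setValidity("SpotSet", function(object) {
  need <- c("x", "y", "channel", "intensity")
  if (!all(need %in% names(object@spots)))
    return(paste("spots must contain columns:", paste(need, collapse = ", ")))
  if (nrow(object@spots) && any(object@spots$intensity <= 0))
    return("spot intensities must be positive")
  TRUE
})

#' Tracking result: time-indexed positions with spectral fingerprints
#'
#' @slot tracks data.frame with columns frame, track_id, x, y, one
#'   \code{frac_<fluorophore>} column per fluorophore, and detection index.
#' @slot report list with elements conflicts, resolved_by_spectrum,
#'   ambiguous, conflict_events (data.frame), mode, weight.
#'
#' @seealso \code{\link{spectralTrack}}, \code{\link{nearestNeighborTrack}},
#'   \code{\link{evaluateTracking}}
#' @export
setClass("TrackSet",
  representation(tracks = "data.frame", report = "list")
)
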
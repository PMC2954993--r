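# Channel layouts and reference emission spectra.

#' Number of lambda-scanning channels for a spectral range
#'
#' A lambda scan divides the collection range into contiguous bins of
#' fixed step; the channel count is \code{floor((max - min) / step)}
#' (a trailing partial bin is not acquired).
#'
#' @param lambdaMin,lambdaMax collection range in nm;
#'   \code{lambdaMax - lambdaMin} must be at least one step.
#' @param step bin width in nm (e.g. 10.7).
#' @return integer channel count.
#' @examples
#' lambdaChannels(571, 657, 10.7)  # 8
#' lambdaChannels(494, 623, 10.7)  # 12
#' @export
lambdaChannels <- function(lambdaMin, lambdaMax, step) {
  .assertScalar(lambdaMin, "lambdaMin")
  .assertScalar(lambdaMax, "lambdaMax")
  .assertScalar(step, "step", positive = TRUE)
  if (lambdaMax - lambdaMin < step - 1e-9)
    stop("spectral range must be at least one step wide")
  # tolerance guards float representation of e.g. 10.7 nm steps
  as.integer(floor((lambdaMax - lambdaMin) / step + 1e-9))
}

#' Build a lambda-scanning channel layout
#'
#' @inheritParams lambdaChannels
#' @return a \linkS4class{ChannelLayout} with contiguous bands.
#' @examples
#' lambdaLayout(494, 623, 10.7)
#' @export
lambdaLayout <- function(lambdaMin, lambdaMax, step) {
  n <- lambdaChannels(lambdaMin, lambdaMax, step)
  lo <- lambdaMin + (seq_len(n) - 1L) * step
  new("ChannelLayout", mode = "lambda", bands = cbind(lo, lo + step))
}

#' Build a channel-mode (bandpass) layout
#'
#' @param bands numeric C x 2 matrix of band lower/upper edges in nm.
#' @return a \linkS4class{ChannelLayout}.
#' @export
channelLayout <- function(bands) {
  bands <- as.matrix(bands)
  new("ChannelLayout", mode = "channel", bands = bands)
}

#' Conventional single-Gaussian emission models for common H2B fusions
#'
#' Emission peaks (nm): CFP 476, GFP 507, YFP 527, RFP 584, mCherry 610;
#' all with a 15 nm standard deviation. These are configurable stand-ins
#' for measured reference spectra.
#'
#' @param names optional subset of fluorophore names to return.
#' @return data.frame with columns name, peak, sigma, brightness.
#' @export
defaultFluorophores <- function(names = NULL) {
  fl <- data.frame(
    name = c("CFP", "GFP", "YFP", "RFP", "mCherry"),
    peak = c(476, 507, 527, 584, 610),
    sigma = 15, brightness = 1,
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    idx <- match(names, fl$name)
    if (anyNA(idx)) stop("unknown fluorophore: ",
                         paste(names[is.na(idx)], collapse = ", "))
    fl <- fl[idx, , drop = FALSE]
    rownames(fl) <- NULL
  }
  fl
}

#' Compute reference spectra for a fluorophore panel on a channel layout
#'
#' Each fluorophore's Gaussian emission profile is integrated over every
#' channel band and the column is normalized to unit sum; the result is
#' the channels-by-fluorophores matrix used for linear unmixing. An
#' optional broad autofluorescence column (Gaussian, sigma 80 nm, centered
#' on the layout) models tissue background so its contribution can be
#' unmixed and discarded.
#'
#' @param fluorophores data.frame with columns name, peak (nm, 400-700),
#'   sigma (nm, > 0); see \code{\link{defaultFluorophores}}.
#' @param layout a \linkS4class{ChannelLayout}.
#' @param includeAutofluorescence add the autofluorescence column
#'   (named "AF").
#' @return a \linkS4class{ReferenceSpectra}.
#' @examples
#' sp <- makeReferenceSpectra(defaultFluorophores(c("GFP", "YFP", "RFP")),
#'                            lambdaLayout(494, 623, 10.7))
#' colSums(spectraMatrix(sp))  # all 1
#' @export
makeReferenceSpectra <- function(fluorophores, layout,
                                 includeAutofluorescence = FALSE) {
  stopifnot(is(layout, "ChannelLayout"))
  if (!is.data.frame(fluorophores) || nrow(fluorophores) < 1L)
    stop("at least one fluorophore is required")
  if (anyDuplicated(fluorophores$name))
    stop("duplicate fluorophore names: ",
         paste(unique(fluorophores$name[duplicated(fluorophores$name)]),
               collapse = ", "))
  if (any(fluorophores$peak < 400 | fluorophores$peak > 700))
    stop("emission peaks must lie within 400-700 nm")
  if (any(fluorophores$sigma <= 0)) stop("emission sigma must be > 0")
  bands <- layout@bands
  col <- function(peak, sigma) {
    w <- stats::pnorm(bands[, 2L], peak, sigma) -
         stats::pnorm(bands[, 1L], peak, sigma)
    s <- sum(w)
    if (s <= 0) stop(sprintf(
      "fluorophore with peak %g nm has no emission within the layout", peak))
    w / s
  }
  S <- vapply(seq_len(nrow(fluorophores)),
              function(i) col(fluorophores$peak[i], fluorophores$sigma[i]),
              numeric(nrow(bands)))
  colnames(S) <- fluorophores$name
  af <- character(0)
  if (includeAutofluorescence) {
    S <- cbind(S, AF = col(mean(range(bands)), 80))
    af <- "AF"
  }
  new("ReferenceSpectra", S = S, channels = rowMeans(bands),
      autofluorescence = af)
}
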
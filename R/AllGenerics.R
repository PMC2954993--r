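#' @rdname PlacedPopulation-class
#' @param object,x a \linkS4class{PlacedPopulation}
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname PlacedPopulation-class
#' @export
setGeneric("colorSubsets", function(x) standardGeneric("colorSubsets"))

#' @rdname PlacedPopulation-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname ReferenceSpectra-class
#' @param x a \linkS4class{ReferenceSpectra}
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname ReferenceSpectra-class
#' @export
setGeneric("channelCenters", function(x) standardGeneric("channelCenters"))

#' @rdname ReferenceSpectra-class
#' @export
setGeneric("fluorophoreNames", function(x) standardGeneric("fluorophoreNames"))

#' @rdname SyntheticMovie-class
#' @param x a \linkS4class{SyntheticMovie}
#' @export
setGeneric("movieFrames", function(x) standardGeneric("movieFrames"))

#' @rdname SyntheticMovie-class
#' @export
setGeneric("movieTruth", function(x) standardGeneric("movieTruth"))

#' @rdname AbundanceMap-class
#' @param x an \linkS4class{AbundanceMap}
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname AbundanceMap-class
#' @export
setGeneric("residuals2D", function(x) standardGeneric("residuals2D"))

#' @rdname SpotSet-class
#' @param x a \linkS4class{SpotSet}
#' @export
setGeneric("spots", function(x) standardGeneric("spots"))

#' @rdname TrackSet-class
#' @param x a \linkS4class{TrackSet}
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @rdname TrackSet-class
#' @export
setGeneric("trackingReport", function(x) standardGeneric("trackingReport"))
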
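# Accessors and show methods.

#' @rdname PlacedPopulation-class
#' @export
setMethod("cellCenters", "PlacedPopulation", function(x) x@centers)

#' @rdname PlacedPopulation-class
#' @export
setMethod("nCells", "PlacedPopulation", function(x) nrow(x@centers))

#' @rdname PlacedPopulation-class
#' @export
setMethod("colorSubsets", "PlacedPopulation", function(x) {
  lapply(x@colors, function(m) {
    if (m == 0L) return(character(0))
    c("R", "G", "B")[bitwAnd(m, c(1L, 2L, 4L)) > 0L]
  })
})

setMethod("show", "PlacedPopulation", function(object) {
  cat(sprintf("PlacedPopulation: %d cells in %g x %g um region\n",
              nCells(object), object@region[1L], object@region[2L]))
  cat(sprintf("  footprint side %g um, density %g cells/100 um^2, scheme: %s\n",
              object@side, object@density,
              if (nzchar(object@scheme)) object@scheme else "<unassigned>"))
})

#' @rdname ReferenceSpectra-class
#' @export
setMethod("spectraMatrix", "ReferenceSpectra", function(x) x@S)

#' @rdname ReferenceSpectra-class
#' @export
setMethod("channelCenters", "ReferenceSpectra", function(x) x@channels)

#' @rdname ReferenceSpectra-class
#' @export
setMethod("fluorophoreNames", "ReferenceSpectra", function(x) {
  setdiff(colnames(x@S), x@autofluorescence)
})

setMethod("show", "ReferenceSpectra", function(object) {
  cat(sprintf("ReferenceSpectra: %d channels x %d columns (%s)\n",
              nrow(object@S), ncol(object@S),
              paste(colnames(object@S), collapse = ", ")))
  if (length(object@autofluorescence))
    cat("  includes autofluorescence column:", object@autofluorescence, "\n")
})

#' @rdname SyntheticMovie-class
#' @export
setMethod("movieFrames", "SyntheticMovie", function(x) x@frames)

#' @rdname SyntheticMovie-class
#' @export
setMethod("movieTruth", "SyntheticMovie", function(x) x@truth)

setMethod("show", "SyntheticMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("SyntheticMovie ('%s'): ", object@scenario))
  if (length(d))
    cat(sprintf("%d frames x %d channels x %d x %d px, ", d[1], d[2], d[3], d[4]))
  else cat("truth only (not rendered), ")
  cat(sprintf("%g min/frame, %g um/px\n", object@frameInterval, object@pixelSize))
  cat(sprintf("  truth: %d cells over %d frames\n",
              length(unique(object@truth$cell_id)),
              length(unique(object@truth$frame))))
})

#' @rdname AbundanceMap-class
#' @export
setMethod("abundance", "AbundanceMap", function(x) x@abundance)

#' @rdname AbundanceMap-class
#' @export
setMethod("residuals2D", "AbundanceMap", function(x) x@residual)

setMethod("show", "AbundanceMap", function(object) {
  d <- dim(object@abundance)
  cat(sprintf("AbundanceMap: %d fluorophores x %d x %d px (%s)\n",
              d[1], d[2], d[3], paste(object@fluorophores, collapse = ", ")))
  cat(sprintf("  median residual norm %.4g\n", stats::median(object@residual)))
})

#' @rdname SpotSet-class
#' @export
setMethod("spots", "SpotSet", function(x) x@spots)

setMethod("show", "SpotSet", function(object) {
  cat(sprintf("SpotSet: %d spots in %d channel(s)\n",
              nrow(object@spots), length(unique(object@spots$channel))))
})

#' @rdname TrackSet-class
#' @export
setMethod("tracks", "TrackSet", function(x) x@tracks)

#' @rdname TrackSet-class
#' @export
setMethod("trackingReport", "TrackSet", function(x) x@report)

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet (%s): %d tracks over %d frames\n",
              object@report$mode,
              length(unique(object@tracks$track_id)),
              length(unique(object@tracks$frame))))
  cat(sprintf("  conflicts %d, resolved by spectrum %d, ambiguous %d\n",
              object@report$conflicts, object@report$resolved_by_spectrum,
              object@report$ambiguous))
})
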
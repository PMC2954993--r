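# File formats: multipage TIFF movies with JSON sidecar metadata, truth /
# spectra / tracks CSV tables, JSON reports.

#' Write a movie as multipage 32-bit float TIFF
#'
#' Pages are ordered frame-major (frame 1 channel 1, frame 1 channel 2,
#' ...; TCYX). TIFF float storage is clipped to [0, 1], so intensities
#' are written divided by their maximum and the scale is recorded in a
#' JSON sidecar (\code{<path>.json}) together with the axes, dimensions,
#' pixel size and frame interval.
#'
#' @param movie a \linkS4class{SyntheticMovie} with rendered frames.
#' @param path output TIFF path.
#' @return invisibly, the sidecar metadata list.
#' @export
writeMovieTIFF <- function(movie, path) {
  stopifnot(is(movie, "SyntheticMovie"))
  fr <- movieFrames(movie)
  d <- dim(fr)
  if (!length(fr)) stop("movie has no rendered frames")
  scale <- max(fr)
  if (scale <= 0) scale <- 1
  pages <- vector("list", d[1L] * d[2L])
  k <- 1L
  for (t in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    pages[[k]] <- fr[t, ch, , ] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(axes = "TCYX", shape = as.integer(d), scale = scale,
               pixel_size_um = movie@pixelSize,
               frame_interval_min = movie@frameInterval,
               field_um = movie@field, scenario = movie@scenario)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(meta)
}

#' Read a movie written by \code{writeMovieTIFF}
#'
#' @param path TIFF path; the \code{<path>.json} sidecar must be present.
#' @return a \linkS4class{SyntheticMovie} (ground truth empty).
#' @export
readMovieTIFF <- function(path) {
  metaPath <- paste0(path, ".json")
  if (!file.exists(metaPath))
    stop("missing metadata sidecar: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$axes) || meta$axes != "TCYX")
    stop("unsupported or missing axes in metadata (expected TCYX): ",
         if (is.null(meta$axes)) "<absent>" else meta$axes)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$shape
  fr <- array(0, dim = d)
  k <- 1L
  for (t in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    fr[t, ch, , ] <- pages[[k]] * meta$scale
    k <- k + 1L
  }
  new("SyntheticMovie", frames = fr, frameInterval = meta$frame_interval_min,
      pixelSize = meta$pixel_size_um, field = meta$field_um,
      truth = .emptyTruth(), spectra = NULL,
      scenario = if (is.null(meta$scenario)) "loaded" else meta$scenario)
}

.emptyTruth <- function() {
  data.frame(frame = integer(0), cell_id = integer(0), x = numeric(0),
             y = numeric(0), parent_id = integer(0))
}

#' Write / read ground-truth tables
#'
#' The schema is: frame, cell_id, x, y, parent_id, plus one
#' \code{expr_<fluorophore>} column per fluorophore. Reading validates
#' the schema and names any missing column.
#'
#' @param truth ground-truth data.frame (see
#'   \code{\link{movieTruth}}).
#' @param path CSV path.
#' @export
writeTruthCSV <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthCSV
#' @export
readTruthCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "cell_id", "x", "y", "parent_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("truth table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!any(grepl("^expr_", names(df))))
    stop("truth table is missing required column(s): expr_<fluorophore>")
  df$frame <- as.integer(df$frame)
  df$cell_id <- as.integer(df$cell_id)
  df$parent_id <- as.integer(df$parent_id)
  df
}

#' Write / read reference spectra tables
#'
#' Columns: channel_center_nm, then one column per fluorophore; column
#' order and labels round-trip unchanged (columns are re-normalized to
#' unit sum on read).
#'
#' @param spectra a \linkS4class{ReferenceSpectra}.
#' @param path CSV path.
#' @export
writeSpectraCSV <- function(spectra, path) {
  stopifnot(is(spectra, "ReferenceSpectra"))
  df <- data.frame(channel_center_nm = channelCenters(spectra))
  S <- spectraMatrix(spectra)
  for (nm in colnames(S)) df[[nm]] <- S[, nm]
  attr(df, "autofluorescence") <- spectra@autofluorescence
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @param autofluorescence name of the autofluorescence column in the
#'   file, if any.
#' @export
readSpectraCSV <- function(path, autofluorescence = character(0)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"channel_center_nm" %in% names(df))
    stop("spectra table is missing required column: channel_center_nm")
  cols <- setdiff(names(df), "channel_center_nm")
  if (!length(cols)) stop("spectra table has no fluorophore columns")
  S <- as.matrix(df[, cols, drop = FALSE])
  S <- sweep(S, 2L, colSums(S), "/")
  if ("AF" %in% cols && !length(autofluorescence)) autofluorescence <- "AF"
  new("ReferenceSpectra", S = S, channels = df$channel_center_nm,
      autofluorescence = autofluorescence)
}

#' Write tracking results as CSV
#'
#' @param trackset a \linkS4class{TrackSet}.
#' @param path CSV path.
#' @export
writeTracksCSV <- function(trackset, path) {
  stopifnot(is(trackset, "TrackSet"))
  utils::write.csv(tracks(trackset), path, row.names = FALSE)
  invisible(path)
}
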
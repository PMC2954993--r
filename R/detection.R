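# Spot detection, distance linking, automated counting, and tissue
# density estimation with label-specific parameters.

# Label-specific parameters: expected object diameter and linking
# distance in micrometres. DiI labeling is particulate, hence the small
# diameter and the wide 5 um linking; multicolor nuclear spots detected
# in separate channels are linked at 2 um.
.labelParams <- list(
  dii      = list(diameter = 2,  linkDist = 5),
  h2b1     = list(diameter = 5,  linkDist = 2),
  h2b3     = list(diameter = 5,  linkDist = 2),
  membrane = list(diameter = 10, linkDist = 2)
)

#' Detect intensity spots in a single-channel image
#'
#' Finds localized regions of relatively higher intensity: the image is
#' smoothed with a Gaussian matched to the expected object size
#' (sigma = diameter / 2.355, i.e. FWHM = diameter), integer-pixel local
#' maxima above the threshold are extracted, and peaks closer than half
#' the expected diameter are suppressed keeping the brighter one (equal
#' intensities keep the smaller (row, column) index).
#'
#' @param image numeric matrix Y x X (rows are y).
#' @param expectedDiameter expected object diameter in micrometres
#'   (2 for particulate dye, 5 for nuclear label, 10 for membrane label).
#' @param threshold minimum smoothed peak intensity; with
#'   background-subtracted input 0 means any signal counts.
#' @param pixelSize micrometres per pixel.
#' @param channel label stored with the spots.
#' @return a \linkS4class{SpotSet}; coordinates are micrometres with
#'   0-based pixel centers (pixel (1,1) is at (0,0)).
#' @export
detectSpots <- function(image, expectedDiameter, threshold = 0,
                        pixelSize = 1, channel = "ch1") {
  .assertScalar(expectedDiameter, "expectedDiameter", positive = TRUE)
  .assertScalar(pixelSize, "pixelSize", positive = TRUE)
  sigmaPx <- expectedDiameter / 2.354820045 / pixelSize
  maxRadius <- 2L * as.integer(floor((min(dim(image)) - 1L) / 2L)) + 1L
  radius <- min(2L * as.integer(ceiling(3 * sigmaPx)) + 1L, maxRadius)
  sm <- EBImage::gblur(image, sigma = sigmaPx, radius = radius)
  minSepPx <- (expectedDiameter / 2) / pixelSize
  brush <- 2L * as.integer(floor(minSepPx)) + 1L
  dil <- if (brush >= 3L)
    EBImage::dilate(sm, EBImage::makeBrush(brush, "disc"))
  else sm
  cand <- which(sm >= dil & sm > threshold, arr.ind = TRUE)
  if (nrow(cand)) {
    iv <- sm[cand]
    ord <- order(-iv, cand[, 1L], cand[, 2L])
    cand <- cand[ord, , drop = FALSE]
    iv <- iv[ord]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      sel <- which(keep)
      if (!length(sel)) { keep[i] <- TRUE; next }
      dd <- sqrt((cand[sel, 1L] - cand[i, 1L])^2 +
                 (cand[sel, 2L] - cand[i, 2L])^2)
      keep[i] <- all(dd >= minSepPx)
    }
    cand <- cand[keep, , drop = FALSE]
    iv <- iv[keep]
  } else iv <- numeric(0)
  df <- data.frame(
    x = (cand[, 2L] - 1) * pixelSize,
    y = (cand[, 1L] - 1) * pixelSize,
    channel = rep(channel, nrow(cand)),
    intensity = iv,
    diameter = rep(expectedDiameter, nrow(cand))
  )
  new("SpotSet", spots = df, pixelSize = pixelSize)
}

#' Link nearby spots into objects (single linkage)
#'
#' Objects are the connected components of the graph with an edge between
#' every pair of spots strictly less than \code{linkDist} apart
#' (transitive closure), merging the per-channel detections of
#' multicolor-labeled cells into one object per cell.
#'
#' @param spotset a \linkS4class{SpotSet} (channels may be mixed).
#' @param linkDist linking distance in micrometres (default 2, the
#'   multicolor rule; use 5 for particulate DiI labeling).
#' @return list with \code{spots} (the input data plus an
#'   \code{object_id} column), \code{objects} (data.frame: object_id,
#'   centroid x, y, n_spots, and mean intensity per channel) and
#'   \code{n_objects}.
#' @export
linkSpots <- function(spotset, linkDist = 2) {
  stopifnot(is(spotset, "SpotSet"))
  .assertScalar(linkDist, "linkDist", nonneg = TRUE)
  sp <- spots(spotset)
  n <- nrow(sp)
  if (n == 0L)
    return(list(spots = cbind(sp, object_id = integer(0)),
                objects = data.frame(object_id = integer(0), x = numeric(0),
                                     y = numeric(0), n_spots = integer(0)),
                n_objects = 0L))
  pos <- as.matrix(sp[, c("x", "y")])
  adj <- .crossDist(pos, pos) < linkDist
  adj[!upper.tri(adj)] <- FALSE
  comp <- .unionFind(n, which(adj, arr.ind = TRUE))
  sp$object_id <- comp
  objects <- do.call(rbind, lapply(seq_len(max(comp)), function(k) {
    m <- sp[comp == k, , drop = FALSE]
    data.frame(object_id = k, x = mean(m$x), y = mean(m$y),
               n_spots = nrow(m))
  }))
  chMeans <- tapply(sp$intensity, list(sp$object_id, sp$channel), mean)
  for (ch in colnames(chMeans)) {
    v <- chMeans[, ch]
    objects[[paste0("mean_", ch)]] <- ifelse(is.na(v), 0, v)
  }
  list(spots = sp, objects = objects, n_objects = max(comp))
}

#' Automated cell count for a labeling strategy
#'
#' Runs per-channel spot detection with the label-appropriate expected
#' diameter, combines the channels, and links spots with the
#' label-appropriate distance; each linked object is counted as one cell.
#'
#' @param channels list of Y x X matrices, one per acquisition channel
#'   (already background-subtracted).
#' @param labelType one of \code{"dii"} (2 um spots, 5 um linking),
#'   \code{"h2b1"}, \code{"h2b3"} (5 um spots, 2 um linking),
#'   \code{"membrane"} (10 um spots, 2 um linking).
#' @param pixelSize micrometres per pixel.
#' @param threshold detection threshold passed to
#'   \code{\link{detectSpots}}.
#' @return list with \code{count} and the \code{linkSpots} result.
#' @export
countCells <- function(channels, labelType = c("dii", "h2b1", "h2b3",
                                               "membrane"),
                       pixelSize = 1, threshold = 0) {
  labelType <- match.arg(labelType)
  if (!length(channels)) stop("at least one channel image is required")
  p <- .labelParams[[labelType]]
  chNames <- names(channels)
  if (is.null(chNames)) chNames <- paste0("ch", seq_along(channels))
  allSpots <- do.call(rbind, lapply(seq_along(channels), function(i) {
    spots(detectSpots(channels[[i]], p$diameter, threshold = threshold,
                      pixelSize = pixelSize, channel = chNames[i]))
  }))
  linked <- linkSpots(new("SpotSet", spots = allSpots,
                          pixelSize = pixelSize), p$linkDist)
  list(count = linked$n_objects, linked = linked,
       diameter = p$diameter, linkDist = p$linkDist)
}

#' Accuracy of an automated count against a reference count
#'
#' @param automated automated object count.
#' @param truth reference count (e.g. visual inspection or ground truth).
#' @return list with both counts and their ratio (automated / truth;
#'   \code{NA} when truth is 0).
#' @export
countReport <- function(automated, truth) {
  if (automated < 0 || truth < 0) stop("counts must be nonnegative")
  list(automated_count = automated, truth_count = truth,
       ratio = if (truth > 0) automated / truth else NA_real_)
}

#' Estimate tissue density from nuclear centers
#'
#' Tiles the region into windows of the given area, averages the count
#' per window, and scales to cells per 100 square micrometres. Also
#' returns the spacing-based alternative: the mean nearest-neighbor
#' distance between nuclear centers minus the mean nuclear diameter
#' (the free gap between adjacent nuclei).
#'
#' @param centers numeric matrix N x 2 of nuclear centers (um).
#' @param region numeric(2) region width and height (um).
#' @param window window area in square micrometres (default 100, i.e.
#'   10 x 10 um).
#' @param diameter mean nuclear diameter for the spacing estimate
#'   (default 10 um).
#' @return list with \code{density} (cells per 100 um^2), \code{spacing}
#'   (um; NA with fewer than 2 cells) and \code{n}.
#' @export
estimateDensity <- function(centers, region = c(100, 100), window = 100,
                            diameter = 10) {
  .assertScalar(window, "window", positive = TRUE)
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n == 0L) {
    warning("no nuclear centers supplied; density is 0")
    return(list(density = 0, spacing = NA_real_, n = 0L))
  }
  side <- sqrt(window)
  nx <- max(1L, floor(region[1L] / side))
  ny <- max(1L, floor(region[2L] / side))
  ix <- pmin(floor(centers[, 1L] / side), nx - 1L)
  iy <- pmin(floor(centers[, 2L] / side), ny - 1L)
  counts <- tabulate(1L + ix + nx * iy, nbins = nx * ny)
  density <- mean(counts) * 100 / window
  spacing <- NA_real_
  if (n >= 2L) {
    d <- .crossDist(centers, centers)
    diag(d) <- Inf
    spacing <- mean(apply(d, 1L, min)) - diameter
  }
  list(density = density, spacing = spacing, n = n)
}
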
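# Synthetic multispectral movie generation with full ground truth.
# Image formation: each nucleus contributes an isotropic Gaussian kernel
# (FWHM = nuclear diameter) times its expression vector times the
# reference spectra; constant background; optional Poisson shot noise and
# additive Gaussian read noise.

.FWHM <- 2.354820045  # 2 * sqrt(2 * log(2))

#' Render one multichannel frame from known cell positions
#'
#' @param cells data.frame with columns x, y (micrometres) and optionally
#'   diameter (default 10).
#' @param expression numeric matrix, one row per cell, one column per
#'   fluorophore (nonnegative); a vector is accepted for a single cell.
#' @param spectra a \linkS4class{ReferenceSpectra}; its non-autofluorescence
#'   columns must match the expression columns.
#' @param field numeric(2) field of view (um); default \code{c(200, 200)}.
#' @param pixelSize micrometres per pixel (default 0.5).
#' @param background constant background: a scalar (flat across channels)
#'   or one level per channel (e.g. an autofluorescence spectrum times a
#'   level).
#' @param poisson apply Poisson shot noise (expression then sets expected
#'   photon counts).
#' @param readSd standard deviation of additive Gaussian read noise
#'   (clamped at zero to keep intensities nonnegative).
#' @param scanAverages number of independent scans averaged per frame
#'   (confocal line/frame averaging, typically 2-4); averaging n scans
#'   divides the relative shot noise by sqrt(n).
#' @param seed optional integer seed for the noise draws.
#' @return numeric array C x Y x X.
#' @examples
#' sp <- makeReferenceSpectra(defaultFluorophores(c("GFP", "RFP")),
#'                            lambdaLayout(494, 623, 10.7))
#' fr <- renderFrame(data.frame(x = 25, y = 25), c(GFP = 100, RFP = 0), sp,
#'                   field = c(50, 50), pixelSize = 1)
#' dim(fr)
#' @export
renderFrame <- function(cells, expression, spectra, field = c(200, 200),
                        pixelSize = 0.5, background = 0, poisson = FALSE,
                        readSd = 0, scanAverages = 1, seed = NULL) {
  stopifnot(is(spectra, "ReferenceSpectra"))
  if (is.null(dim(expression)))
    expression <- matrix(expression, nrow = max(1L, nrow(cells)),
                         ncol = length(expression), byrow = TRUE,
                         dimnames = list(NULL, names(expression)))
  if (any(expression < 0)) stop("expression must be nonnegative")
  fl <- fluorophoreNames(spectra)
  S <- spectraMatrix(spectra)[, fl, drop = FALSE]
  if (ncol(expression) != length(fl))
    stop("expression columns must match the spectra's fluorophores")
  if (nrow(cells) != nrow(expression) && nrow(cells) > 0L)
    stop("one expression row per cell required")
  nx <- as.integer(round(field[1L] / pixelSize))
  ny <- as.integer(round(field[2L] / pixelSize))
  C <- nrow(S)
  if (!length(background) %in% c(1L, C))
    stop("'background' must be a scalar or one level per channel")
  frame <- array(rep(background, length.out = C), dim = c(C, ny, nx))
  if (nrow(cells)) {
    diam <- if ("diameter" %in% names(cells)) cells$diameter else
      rep(10, nrow(cells))
    xs <- (seq_len(nx) - 1L) * pixelSize   # 0-based pixel centers
    ys <- (seq_len(ny) - 1L) * pixelSize
    for (i in seq_len(nrow(cells))) {
      sigma <- diam[i] / .FWHM
      w <- as.numeric(S %*% expression[i, ])
      rx <- which(abs(xs - cells$x[i]) <= 4 * sigma)
      ry <- which(abs(ys - cells$y[i]) <= 4 * sigma)
      if (!length(rx) || !length(ry)) next
      gx <- exp(-(xs[rx] - cells$x[i])^2 / (2 * sigma^2))
      gy <- exp(-(ys[ry] - cells$y[i])^2 / (2 * sigma^2))
      kern <- outer(gy, gx)
      for (ch in seq_len(C))
        frame[ch, ry, rx] <- frame[ch, ry, rx] + w[ch] * kern
    }
  }
  if (poisson || readSd > 0) {
    .assertScalar(scanAverages, "scanAverages", positive = TRUE)
    frame <- .withSeed(seed, {
      if (poisson)   # mean of n scans: Poisson(n * lambda) / n
        frame[] <- stats::rpois(length(frame), frame * scanAverages) /
          scanAverages
      if (readSd > 0)
        frame[] <- frame + stats::rnorm(length(frame), 0,
                                        readSd / sqrt(scanAverages))
      frame
    })
    frame[frame < 0] <- 0
  }
  frame
}

# Default 3-FP spectra: GFP/YFP/RFP on the 12-channel lambda layout.
.defaultSpectra <- function() {
  makeReferenceSpectra(defaultFluorophores(c("GFP", "YFP", "RFP")),
                       lambdaLayout(494, 623, 10.7))
}

# Render every frame of a truth table; photobleaching (per-fluorophore
# exponential decay rates per frame) is applied to expression first.
.renderTruth <- function(truth, spectra, field, pixelSize, background,
                         poisson, readSd, seed) {
  fl <- fluorophoreNames(spectra)
  exprCols <- paste0("expr_", fl)
  tIdx <- sort(unique(truth$frame))
  frames <- NULL
  .withSeed(seed, {
    for (k in seq_along(tIdx)) {
      rows <- truth[truth$frame == tIdx[k], , drop = FALSE]
      fr <- renderFrame(rows[, c("x", "y")],
                        as.matrix(rows[, exprCols, drop = FALSE]),
                        spectra, field = field, pixelSize = pixelSize,
                        background = background, poisson = poisson,
                        readSd = readSd)
      if (is.null(frames))
        frames <- array(0, dim = c(length(tIdx), dim(fr)))
      frames[k, , , ] <- fr
    }
  })
  if (is.null(frames)) array(0, dim = c(0L, 0L, 0L, 0L)) else frames
}

.applyBleaching <- function(truth, fl, bleach) {
  if (is.null(bleach)) return(truth)
  if (length(bleach) == 1L) bleach <- stats::setNames(rep(bleach, length(fl)), fl)
  t0 <- min(truth$frame)
  for (f in fl) {
    cl <- paste0("expr_", f)
    truth[[cl]] <- truth[[cl]] * exp(-bleach[[f]] * (truth$frame - t0))
  }
  truth
}

.newMovie <- function(truth, spectra, field, pixelSize, frameInterval,
                      scenario, render, background, poisson, readSd, seed) {
  frames <- if (render)
    .renderTruth(truth, spectra, field, pixelSize, background, poisson,
                 readSd, seed)
  else array(0, dim = c(0L, 0L, 0L, 0L))
  new("SyntheticMovie", frames = frames, frameInterval = frameInterval,
      pixelSize = pixelSize, field = as.numeric(field), truth = truth,
      spectra = spectra, scenario = scenario)
}

# Fixed fingerprint palette: distinct mixtures of 3 fluorophores ordered
# so prefixes keep a large minimum pairwise L1 distance.
.fingerprintPalette <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5),
    c(1, 1, 1) / 3
  )
}

#' Generate a trajectory-crossing scenario
#'
#' Builds a movie in which all cells travel on straight lines arranged so
#' that every cell passes within one nuclear diameter of a common point at
#' the mid frame -- an unavoidable conflict event for positional tracking
#' -- while carrying distinct spectral fingerprints. First- and last-frame
#' positions are pairwise separated by at least two diameters. The field
#' is enlarged automatically if the requested cell count needs more room.
#'
#' @param nCells number of crossing cells (2..7 with three fluorophores).
#' @param fingerprintSeparation required minimum pairwise L1 distance
#'   between the cells' normalized fingerprints (infeasible values error).
#' @param frames number of frames (odd values put the conflict exactly at
#'   the mid frame); default 21.
#' @param frameInterval minutes between frames (default 5).
#' @param field,pixelSize field of view (um) and sampling.
#' @param diameter nuclear diameter in micrometres (default 10).
#' @param brightness total expression per cell (sets photon scale).
#' @param spectra reference spectra; default GFP/YFP/RFP on the 12-channel
#'   lambda layout.
#' @param render render pixel data (set \code{FALSE} for truth-only
#'   movies, e.g. large Monte-Carlo runs on detections).
#' @param background,poisson,readSd image-formation options, see
#'   \code{\link{renderFrame}}.
#' @param seed optional integer seed.
#' @return a \linkS4class{SyntheticMovie}.
#' @examples
#' mv <- makeCrossingScenario(2, render = FALSE)
#' head(movieTruth(mv))
#' @export
makeCrossingScenario <- function(nCells = 2, fingerprintSeparation = 0.6,
                                 frames = 21, frameInterval = 5,
                                 field = c(100, 100), pixelSize = 1,
                                 diameter = 10, brightness = 1000,
                                 spectra = NULL, render = TRUE,
                                 background = 0, poisson = FALSE,
                                 readSd = 0, seed = NULL) {
  if (nCells < 2) stop("a crossing scenario needs at least 2 cells")
  pal <- .fingerprintPalette()
  if (nCells > nrow(pal))
    stop("at most ", nrow(pal), " distinct fingerprints available")
  fp <- pal[seq_len(nCells), , drop = FALSE]
  d <- as.matrix(stats::dist(fp, method = "manhattan"))
  minsep <- min(d[upper.tri(d)])
  if (minsep < fingerprintSeparation)
    stop(sprintf(paste0("requested fingerprint separation %.2f infeasible ",
                        "for %d cells (achievable %.2f)"),
                 fingerprintSeparation, nCells, minsep))
  if (is.null(spectra)) spectra <- .defaultSpectra()
  fl <- fluorophoreNames(spectra)
  if (length(fl) != ncol(fp)) stop("spectra must have 3 fluorophores")

  theta <- pi * (seq_len(nCells) - 1L) / nCells
  u <- cbind(cos(theta), sin(theta))
  perp <- cbind(-sin(theta), cos(theta))
  # radius so that first-frame pairwise separation >= 2 diameters
  minAngle <- pi / nCells
  R <- max(2 * diameter, (2.2 * diameter) / (2 * sin(minAngle / 2)))
  margin <- diameter
  need <- 2 * (R + margin)
  field <- pmax(field, c(need, need))
  center <- field / 2
  # mid-frame offsets keep every cell within one diameter of the center
  off <- ((seq_len(nCells) - 1) / max(1, nCells - 1) - 0.5) * (diameter / 2)

  tt <- seq_len(frames)
  mid <- (frames + 1) / 2
  rows <- lapply(seq_len(nCells), function(i) {
    frac <- (tt - mid) / (mid - 1)     # -1 .. 1
    pos <- cbind(center[1L] + frac * R * u[i, 1L] + off[i] * perp[i, 1L],
                 center[2L] + frac * R * u[i, 2L] + off[i] * perp[i, 2L])
    out <- data.frame(frame = tt, cell_id = i, x = pos[, 1L], y = pos[, 2L],
                      parent_id = NA_integer_)
    for (k in seq_along(fl))
      out[[paste0("expr_", fl[k])]] <- fp[i, k] * brightness
    out
  })
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$frame, truth$cell_id), ]
  rownames(truth) <- NULL
  .newMovie(truth, spectra, field, pixelSize, frameInterval, "crossing",
            render, background, poisson, readSd, seed)
}

#' Generate a cell-division scenario
#'
#' A single parent cell splits into two daughters at \code{splitFrame};
#' the daughters inherit the parent's expression vector, optionally
#' perturbed by per-channel multiplicative lognormal noise, and diverge
#' symmetrically.
#'
#' @param parentExpression named nonnegative vector over the spectra's
#'   fluorophores.
#' @param splitFrame frame at which the division occurs (2..frames).
#' @param frames total number of frames (default 21).
#' @param daughterNoise sdlog of multiplicative lognormal perturbation of
#'   the inherited expression (0 = exact inheritance).
#' @inheritParams makeCrossingScenario
#' @return a \linkS4class{SyntheticMovie}; daughters carry
#'   \code{parent_id = 1}.
#' @export
makeDivisionScenario <- function(parentExpression, splitFrame, frames = 21,
                                 frameInterval = 5, field = c(100, 100),
                                 pixelSize = 1, diameter = 10,
                                 daughterNoise = 0, spectra = NULL,
                                 render = TRUE, background = 0,
                                 poisson = FALSE, readSd = 0, seed = NULL) {
  if (is.null(spectra)) spectra <- .defaultSpectra()
  fl <- fluorophoreNames(spectra)
  if (any(parentExpression < 0) || all(parentExpression == 0))
    stop("parentExpression must be nonnegative with at least one positive entry")
  if (length(parentExpression) != length(fl))
    stop("parentExpression must have one entry per fluorophore")
  if (splitFrame < 2 || splitFrame > frames)
    stop("splitFrame must lie within the movie (2..frames)")
  center <- field / 2
  .withSeed(seed, {
    dExpr <- lapply(1:2, function(i) {
      parentExpression * exp(stats::rnorm(length(fl), 0, daughterNoise))
    })
    pre <- data.frame(frame = seq_len(splitFrame - 1L), cell_id = 1L,
                      x = center[1L], y = center[2L],
                      parent_id = NA_integer_)
    for (k in seq_along(fl))
      pre[[paste0("expr_", fl[k])]] <- parentExpression[k]
    post <- do.call(rbind, lapply(1:2, function(i) {
      tt <- splitFrame:frames
      sep <- pmin((tt - splitFrame + 1) * diameter / 2,
                  field[1L] / 2 - diameter)
      out <- data.frame(frame = tt, cell_id = i + 1L,
                        x = center[1L] + (if (i == 1) -sep else sep),
                        y = center[2L], parent_id = 1L)
      for (k in seq_along(fl))
        out[[paste0("expr_", fl[k])]] <- dExpr[[i]][k]
      out
    }))
    truth <- rbind(pre, post)
    truth <- truth[order(truth$frame, truth$cell_id), ]
    rownames(truth) <- NULL
    .newMovie(truth, spectra, field, pixelSize, frameInterval, "division",
              render, background, poisson, readSd, NULL)
  })
}

#' Generate a persistent-random-walk movie
#'
#' Cells perform persistent random walks (per-cell speed, shared
#' persistence of direction), reflecting at field borders, with random
#' nonempty fluorophore mixtures. Optional photobleaching applies an
#' exponential intensity decay per fluorophore.
#'
#' @param nCells number of cells.
#' @param frames number of frames (default 60, i.e. about 5 h at 5
#'   min/frame).
#' @param speed mean step length per frame in micrometres.
#' @param persistence direction persistence in [0, 1); 0 is a pure random
#'   walk.
#' @param bleach optional per-fluorophore exponential decay rate per frame
#'   (scalar recycled over fluorophores); equal rates leave fingerprints
#'   unchanged.
#' @inheritParams makeCrossingScenario
#' @return a \linkS4class{SyntheticMovie}.
#' @export
makeRandomWalkMovie <- function(nCells = 5, frames = 60, frameInterval = 5,
                                field = c(200, 200), pixelSize = 0.5,
                                diameter = 10, speed = 2, persistence = 0.7,
                                brightness = 1000, bleach = NULL,
                                spectra = NULL, render = TRUE,
                                background = 0, poisson = FALSE, readSd = 0,
                                seed = NULL) {
  if (is.null(spectra)) spectra <- .defaultSpectra()
  fl <- fluorophoreNames(spectra)
  pal <- .fingerprintPalette()
  .withSeed(seed, {
    fpIdx <- sample(nrow(pal), nCells, replace = TRUE)
    pos <- cbind(stats::runif(nCells, diameter, field[1L] - diameter),
                 stats::runif(nCells, diameter, field[2L] - diameter))
    ang <- stats::runif(nCells, 0, 2 * pi)
    rows <- vector("list", frames)
    for (t in seq_len(frames)) {
      out <- data.frame(frame = t, cell_id = seq_len(nCells),
                        x = pos[, 1L], y = pos[, 2L],
                        parent_id = NA_integer_)
      for (k in seq_along(fl))
        out[[paste0("expr_", fl[k])]] <- pal[fpIdx, k] * brightness
      rows[[t]] <- out
      turn <- stats::runif(nCells, 0, 2 * pi)
      ang <- atan2(persistence * sin(ang) + (1 - persistence) * sin(turn),
                   persistence * cos(ang) + (1 - persistence) * cos(turn))
      step <- stats::rexp(nCells, 1 / speed)
      pos <- pos + cbind(step * cos(ang), step * sin(ang))
      pos[, 1L] <- pmin(pmax(pos[, 1L], 0), field[1L])
      pos[, 2L] <- pmin(pmax(pos[, 2L], 0), field[2L])
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    truth <- .applyBleaching(truth, fl, bleach)
    .newMovie(truth, spectra, field, pixelSize, frameInterval, "walk",
              render, background, poisson, readSd, NULL)
  })
}

#' Ground-truth detections with optional intensity noise
#'
#' Converts a movie's ground truth into per-frame detections carrying
#' per-fluorophore intensities, optionally degraded by multiplicative
#' lognormal noise -- the idealized output of a perfect detector, useful
#' for benchmarking the tracking stage in isolation.
#'
#' @param movie a \linkS4class{SyntheticMovie}.
#' @param noiseSd sdlog of the multiplicative lognormal intensity noise
#'   (0.1 approximates 10 percent intensity noise).
#' @param seed optional integer seed.
#' @return data.frame with columns frame, truth_id, x, y and one
#'   \code{I_<fluorophore>} column per fluorophore.
#' @export
truthDetections <- function(movie, noiseSd = 0, seed = NULL) {
  stopifnot(is(movie, "SyntheticMovie"))
  truth <- movieTruth(movie)
  # scan order (frame, then position), as a detector would emit spots --
  # identity must not leak through the row order
  truth <- truth[order(truth$frame, truth$x, truth$y, truth$cell_id), ]
  fl <- fluorophoreNames(movie@spectra)
  out <- data.frame(frame = truth$frame, truth_id = truth$cell_id,
                    x = truth$x, y = truth$y)
  .withSeed(seed, {
    for (f in fl) {
      v <- truth[[paste0("expr_", f)]]
      if (noiseSd > 0) v <- v * exp(stats::rnorm(length(v), 0, noiseSd))
      out[[paste0("I_", f)]] <- v
    }
  })
  out
}

#' Generate a symmetric position-swap scenario
#'
#' Two cells approach along the same line and coincide exactly at the mid
#' frame. With \code{flip = FALSE} their trajectories cross (the cells
#' exchange sides); with \code{flip = TRUE} they meet and retreat to
#' their own sides. The two variants produce \emph{identical} observed
#' position sets in every frame and differ only in the ground-truth
#' identities, so a position-only tracker -- whose deterministic
#' tie-break commits it to one of the two interpretations -- is correct
#' in exactly one variant of each mirrored pair (50 percent). The cells'
#' fingerprints are fully distinct (L1 distance 2), so a spectrum-aware
#' tracker resolves both variants.
#'
#' @param flip choose the meet-and-retreat variant instead of the
#'   crossing variant (the mirrored member of a paired comparison).
#' @inheritParams makeCrossingScenario
#' @return a \linkS4class{SyntheticMovie}.
#' @export
makeSwapScenario <- function(flip = FALSE, frames = 21, frameInterval = 5,
                             field = c(100, 100), pixelSize = 1,
                             diameter = 10, brightness = 1000,
                             spectra = NULL, render = FALSE,
                             background = 0, poisson = FALSE, readSd = 0,
                             seed = NULL) {
  if (is.null(spectra)) spectra <- .defaultSpectra()
  fl <- fluorophoreNames(spectra)
  fp <- .fingerprintPalette()[1:2, ]
  tt <- seq_len(frames)
  mid <- (frames + 1) / 2
  frac <- (tt - mid) / (mid - 1)          # -1 .. 1
  margin <- diameter
  span <- field[1L] / 2 - margin
  yc <- field[2L] / 2
  cx <- field[1L] / 2
  paths <- if (!flip)
    list(cbind(cx + frac * span, yc),          # cell 1: left -> right
         cbind(cx - frac * span, yc))          # cell 2: right -> left
  else
    list(cbind(cx - abs(frac) * span, yc),     # cell 1 stays left
         cbind(cx + abs(frac) * span, yc))     # cell 2 stays right
  rows <- lapply(1:2, function(i) {
    out <- data.frame(frame = tt, cell_id = i, x = paths[[i]][, 1L],
                      y = paths[[i]][, 2L], parent_id = NA_integer_)
    for (k in seq_along(fl))
      out[[paste0("expr_", fl[k])]] <- fp[i, k] * brightness
    out
  })
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$frame, truth$cell_id), ]
  rownames(truth) <- NULL
  .newMovie(truth, spectra, field, pixelSize, frameInterval, "swap",
            render, background, poisson, readSd, seed)
}
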
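# Self-contained benchmark studies: each runs a full generate -> analyze
# cycle on synthetic data and reports summary statistics.

#' Unmixing recovery benchmark
#'
#' Renders a three-cell multispectral frame (mixed fluorophore
#' expressions, autofluorescence background), unmixes it, and reports
#' (a) the maximum absolute abundance error of the noiseless frame and
#' (b) the median per-pixel relative abundance error of a shot-noise
#' frame on above-threshold pixels, with per-plane thresholds from the
#' 125-percent background rule. The noisy acquisition follows the
#' confocal protocol of frame-averaging several scans
#' (\code{scanAverages}), and uses the well-separated CFP/YFP/mCherry
#' panel on a lambda layout that covers all three emissions.
#'
#' @param seed integer seed for the noise draws.
#' @param peakCounts photon counts in the brightest channel of the
#'   brightest pixel (default 1000).
#' @param scanAverages scans averaged per frame (default 4, a typical
#'   confocal setting).
#' @param backgroundLevel mean autofluorescence photons per channel
#'   (default 10), rendered with the broad autofluorescence spectrum and
#'   removed by unmixing against the autofluorescence column.
#' @return list with \code{max_abs_noiseless}, \code{median_rel_err},
#'   \code{n_above_threshold}, \code{peak_abundance}.
#' @export
unmixingBenchmark <- function(seed = 1, peakCounts = 1000, scanAverages = 4,
                              backgroundLevel = 10) {
  fluors <- c("CFP", "YFP", "mCherry")
  sp <- makeReferenceSpectra(defaultFluorophores(fluors),
                             lambdaLayout(440, 650, 10.7),
                             includeAutofluorescence = TRUE)
  Sfull <- spectraMatrix(sp)
  S <- Sfull[, fluors]
  expr <- rbind(c(0.6, 0, 0.4), c(0, 0, 1), c(0.4, 0.6, 0))
  cells <- data.frame(x = c(15, 30, 22), y = c(15, 25, 35))
  B <- peakCounts / max(apply(expr, 1, function(e) max(S %*% e)))
  bg <- backgroundLevel * nrow(Sfull) * Sfull[, "AF"]
  # ground-truth abundance planes via identity spectra (same kernel model)
  idS <- diag(3)
  colnames(idS) <- fluors
  idSp <- new("ReferenceSpectra", S = idS, channels = 1:3,
              autofluorescence = character(0))
  atrue <- renderFrame(cells, expr * B, idSp, field = c(50, 50),
                       pixelSize = 1)

  clean <- renderFrame(cells, expr * B, sp, field = c(50, 50), pixelSize = 1,
                       background = bg)
  maxAbs <- max(abs(abundance(unmixStack(clean, sp)) - atrue))

  noisy <- renderFrame(cells, expr * B, sp, field = c(50, 50), pixelSize = 1,
                       background = bg, poisson = TRUE,
                       scanAverages = scanAverages, seed = seed)
  ab <- abundance(unmixStack(noisy, sp))
  thr <- vapply(1:3, function(k) backgroundThreshold(ab[k, , ], c(1, 1, 5, 5)),
                numeric(1))
  above <- apply(sweep(ab, 1L, thr, ">"), c(2, 3), any)
  atot <- apply(atrue, c(2, 3), sum)
  relerr <- apply(abs(ab - atrue), c(2, 3), sum) / pmax(atot, 1e-12)
  list(max_abs_noiseless = maxAbs,
       median_rel_err = stats::median(relerr[above]),
       n_above_threshold = sum(above),
       peak_abundance = max(atot))
}

#' Crossing-resolution tracking benchmark
#'
#' Runs paired symmetric-swap scenarios (see
#' \code{\link{makeSwapScenario}}): for each seed, both the crossing and
#' the meet-and-retreat variant are generated with multiplicative
#' intensity noise, and both trackers are scored against ground truth.
#' A scenario counts as wrong when the tracker commits at least one
#' identity switch.
#'
#' @param nPairs number of mirrored scenario pairs (2 x nPairs
#'   scenarios).
#' @param noiseSd sdlog of the multiplicative intensity noise
#'   (default 0.1).
#' @param seed integer seed.
#' @return list with wrong-rates for both trackers, their difference in
#'   Monte-Carlo standard errors, and counts.
#' @export
crossingBenchmark <- function(nPairs = 100, noiseSd = 0.1, seed = 1) {
  nnWrong <- spWrong <- logical(0)
  for (s in seq_len(nPairs)) {
    for (flip in c(FALSE, TRUE)) {
      mv <- makeSwapScenario(flip = flip, render = FALSE)
      dets <- truthDetections(mv, noiseSd = noiseSd, seed = seed * 1000L + s)
      truth <- movieTruth(mv)
      nnWrong <- c(nnWrong,
        evaluateTracking(nearestNeighborTrack(dets), truth)$switches > 0)
      spWrong <- c(spWrong,
        evaluateTracking(spectralTrack(dets), truth)$switches > 0)
    }
  }
  n <- length(nnWrong)
  pNN <- mean(nnWrong)
  pSP <- mean(spWrong)
  se <- sqrt(pNN * (1 - pNN) / n + pSP * (1 - pSP) / n + 1e-12)
  list(blind_wrong_rate = pNN, spectral_wrong_rate = pSP,
       n_scenarios = n, diff_in_se = (pNN - pSP) / max(se, sqrt(0.25 / n)))
}

#' Spectral-identity stability benchmark
#'
#' Simulates cells with a strict fluorophore hierarchy (random
#' permutations of 50/30/20 percent fractions) observed over a time-lapse
#' with multiplicative intensity noise, and reports the proportion of
#' cells whose fingerprint rank order matches the modal order in at
#' least \code{minStability} of frames.
#'
#' @param nCells number of simulated cells (default 500).
#' @param frames frames per cell (default 60, about 5 h at 5 min/frame).
#' @param noiseSd sdlog of multiplicative intensity noise (default 0.1).
#' @param minStability per-cell stability cutoff (default 0.95).
#' @param seed integer seed.
#' @return list with \code{prop_stable}, \code{mean_stability}, counts.
#' @export
stabilityBenchmark <- function(nCells = 500, frames = 60, noiseSd = 0.1,
                               minStability = 0.95, seed = 1) {
  base <- c(0.5, 0.3, 0.2)
  stab <- .withSeed(seed, vapply(seq_len(nCells), function(i) {
    fp <- sample(base)
    I <- matrix(rep(fp, frames), ncol = 3, byrow = TRUE) *
      exp(matrix(stats::rnorm(3 * frames, 0, noiseSd), ncol = 3))
    fingerprintStability(I / rowSums(I))$stability
  }, numeric(1)))
  list(prop_stable = mean(stab >= minStability),
       mean_stability = mean(stab),
       n_cells = nCells, frames = frames)
}
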
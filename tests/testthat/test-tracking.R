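detFrame <- function(frame, xy, I) {
  data.frame(frame = frame, x = xy[, 1], y = xy[, 2],
             I_GFP = I[, 1], I_YFP = I[, 2], I_RFP = I[, 3])
}

test_that("well-separated stationary cells yield clean tracks", {
  dets <- do.call(rbind, lapply(1:5, function(f)
    detFrame(f, cbind(c(10, 60), c(10, 60)),
             rbind(c(100, 0, 0), c(0, 100, 0)))))
  ts <- nearestNeighborTrack(dets)
  expect_equal(length(unique(tracks(ts)$track_id)), 2)
  truth <- data.frame(frame = dets$frame,
                      cell_id = rep(1:2, 5),
                      x = dets$x, y = dets$y, parent_id = NA_integer_)
  expect_equal(evaluateTracking(ts, truth)$switches, 0)
  expect_equal(trackingReport(ts)$conflicts, 0)
})

test_that("the gate terminates tracks instead of jumping", {
  # cell 2 disappears after frame 3; a far-away newcomer appears at frame 4
  dets <- rbind(
    do.call(rbind, lapply(1:3, function(f)
      detFrame(f, cbind(c(10, 60), c(10, 10)),
               rbind(c(100, 0, 0), c(0, 100, 0))))),
    do.call(rbind, lapply(4:6, function(f)
      detFrame(f, cbind(c(10, 160), c(10, 160)),
               rbind(c(100, 0, 0), c(0, 0, 100))))))
  ts <- nearestNeighborTrack(dets, gate = 30)
  tr <- tracks(ts)
  # three distinct tracks: the vanished cell's track must not teleport
  expect_equal(length(unique(tr$track_id)), 3)
  id2 <- tr$track_id[tr$frame == 1 & tr$x == 60]
  expect_equal(max(tr$frame[tr$track_id == id2]), 3)
})

test_that("spectralTrack with w = 0 equals the blind tracker", {
  mv <- makeSwapScenario(render = FALSE)
  dets <- truthDetections(mv, noiseSd = 0.1, seed = 5)
  expect_identical(tracks(spectralTrack(dets, w = 0)),
                   tracks(nearestNeighborTrack(dets)))
  expect_error(spectralTrack(dets, w = -1), "nonnegative")
})

test_that("distinct fingerprints resolve crossings; identical ones are flagged", {
  mv <- makeCrossingScenario(2, render = FALSE)
  dets <- truthDetections(mv)   # noiseless
  ts <- spectralTrack(dets)
  expect_equal(evaluateTracking(ts, movieTruth(mv))$switches, 0)
  expect_equal(trackingReport(ts)$ambiguous, 0)
  expect_equal(trackingReport(ts)$resolved_by_spectrum, 1)

  # same geometry but identical fingerprints: flagged, not guessed
  icols <- grep("^I_", names(dets), value = TRUE)
  dets2 <- dets
  dets2[, icols] <- matrix(rep(c(50, 30, 20), nrow(dets)), ncol = 3,
                           byrow = TRUE)
  ts2 <- spectralTrack(dets2)
  expect_equal(trackingReport(ts2)$ambiguous, 1)
  expect_equal(trackingReport(ts2)$resolved_by_spectrum, 0)
})

test_that("fingerprints are invariant to global frame scaling", {
  mv <- makeCrossingScenario(2, render = FALSE)
  dets <- truthDetections(mv, noiseSd = 0.05, seed = 9)
  icols <- grep("^I_", names(dets), value = TRUE)
  dets2 <- dets
  dets2[, icols] <- dets2[, icols] * 7.3   # e.g. laser power change
  fcols <- function(ts) tracks(ts)[, grep("^frac_", names(tracks(ts)))]
  expect_equal(fcols(spectralTrack(dets)), fcols(spectralTrack(dets2)),
               tolerance = 1e-12)
})

test_that("symmetric swaps: blind is right half the time, spectral always", {
  nnWrong <- spWrong <- logical(0)
  for (s in 1:20) {
    for (flip in c(FALSE, TRUE)) {
      mv <- makeSwapScenario(flip = flip, render = FALSE)
      dets <- truthDetections(mv, noiseSd = 0.1, seed = s)
      truth <- movieTruth(mv)
      nnWrong <- c(nnWrong,
        evaluateTracking(nearestNeighborTrack(dets), truth)$switches > 0)
      spWrong <- c(spWrong,
        evaluateTracking(spectralTrack(dets), truth)$switches > 0)
    }
  }
  expect_equal(mean(nnWrong), 0.5)  # exactly one of each mirrored pair
  expect_equal(mean(spWrong), 0)
})

test_that("noiseless division keeps daughters on the parent lineage", {
  mv <- makeDivisionScenario(c(600, 0, 400), splitFrame = 11, render = FALSE)
  dets <- truthDetections(mv)
  ts <- spectralTrack(dets)
  ev <- evaluateTracking(ts, movieTruth(mv))
  expect_equal(ev$switches, 0)
  # daughters carry the parent's fingerprint exactly
  icols <- grep("^I_", names(dets), value = TRUE)
  post <- dets[dets$frame == max(dets$frame), icols]
  expect_equal(as.numeric(post[1, ]), c(600, 0, 400))
  expect_equal(as.numeric(post[2, ]), c(600, 0, 400))
})

test_that("evaluateTracking equals a brute-force recount of label changes", {
  set.seed(31)
  pos <- cbind(c(10, 50, 90), c(10, 50, 90))   # 3 static, distinct sites
  for (rep in 1:25) {
    perms <- replicate(10, sample(3), simplify = FALSE)
    # track i sits at truth cell perms[[t]][i]'s position in frame t
    trDf <- do.call(rbind, lapply(1:10, function(t) {
      data.frame(frame = t, track_id = 1:3,
                 x = pos[perms[[t]], 1], y = pos[perms[[t]], 2],
                 det_row = NA_integer_)
    }))
    ts <- new("TrackSet", tracks = trDf,
              report = list(mode = "blind", conflicts = 0L,
                            resolved_by_spectrum = 0L, ambiguous = 0L))
    truth <- do.call(rbind, lapply(1:10, function(t) {
      data.frame(frame = t, cell_id = 1:3, x = pos[, 1], y = pos[, 2],
                 parent_id = NA_integer_)
    }))
    got <- evaluateTracking(ts, truth)$switches
    labelSeqs <- lapply(1:3, function(i)
      vapply(perms, function(p) p[i], integer(1)))
    expect_equal(got, oracleSwitchCount(labelSeqs))
  }
})

test_that("track frames outside the truth range are rejected", {
  mv <- makeSwapScenario(render = FALSE)
  dets <- truthDetections(mv)
  ts <- spectralTrack(dets)
  shortTruth <- movieTruth(mv)
  shortTruth <- shortTruth[shortTruth$frame <= 10, ]
  expect_error(evaluateTracking(ts, shortTruth), "frame range")
})
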
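sp3 <- makeReferenceSpectra(defaultFluorophores(c("GFP", "YFP", "RFP")),
                            lambdaLayout(494, 623, 10.7))

test_that("noiseless rendering follows the linear image-formation model", {
  # empty field is pure background
  fr0 <- renderFrame(data.frame(x = numeric(0), y = numeric(0)),
                     matrix(0, 0, 3), sp3, field = c(20, 20), pixelSize = 1,
                     background = 2)
  expect_true(all(fr0 == 2))

  # single fluorophore: every above-background pixel proportional to its column
  fr <- renderFrame(data.frame(x = 10, y = 10), c(500, 0, 0), sp3,
                    field = c(20, 20), pixelSize = 1)
  S <- spectraMatrix(sp3)
  px <- which(apply(fr, c(2, 3), sum) > 1e-6, arr.ind = TRUE)
  for (r in seq_len(nrow(px))) {
    v <- fr[, px[r, 1], px[r, 2]]
    expect_equal(v / sum(v), S[, 1], tolerance = 1e-9, ignore_attr = TRUE)
  }

  # doubling expression doubles the integrated signal; superposition holds
  f1 <- renderFrame(data.frame(x = 10, y = 10), c(100, 50, 0), sp3,
                    field = c(20, 20), pixelSize = 1)
  f2 <- renderFrame(data.frame(x = 10, y = 10), c(200, 100, 0), sp3,
                    field = c(20, 20), pixelSize = 1)
  expect_equal(sum(f2), 2 * sum(f1), tolerance = 1e-9)
  fa <- renderFrame(data.frame(x = 8, y = 10), c(100, 0, 0), sp3,
                    field = c(20, 20), pixelSize = 1)
  fb <- renderFrame(data.frame(x = 13, y = 10), c(0, 0, 80), sp3,
                    field = c(20, 20), pixelSize = 1)
  fab <- renderFrame(data.frame(x = c(8, 13), y = c(10, 10)),
                     rbind(c(100, 0, 0), c(0, 0, 80)), sp3,
                     field = c(20, 20), pixelSize = 1)
  expect_equal(fab, fa + fb, tolerance = 1e-9)

  expect_error(renderFrame(data.frame(x = 1, y = 1), c(-1, 0, 0), sp3),
               "nonnegative")
})

test_that("rendering with a fixed seed is bit-reproducible", {
  a <- renderFrame(data.frame(x = 10, y = 10), c(200, 100, 50), sp3,
                   field = c(20, 20), pixelSize = 1, poisson = TRUE,
                   readSd = 1, seed = 42)
  b <- renderFrame(data.frame(x = 10, y = 10), c(200, 100, 50), sp3,
                   field = c(20, 20), pixelSize = 1, poisson = TRUE,
                   readSd = 1, seed = 42)
  expect_identical(a, b)
  mv1 <- makeCrossingScenario(2, frames = 5, pixelSize = 2, seed = 3)
  mv2 <- makeCrossingScenario(2, frames = 5, pixelSize = 2, seed = 3)
  expect_identical(movieFrames(mv1), movieFrames(mv2))
  expect_identical(movieTruth(mv1), movieTruth(mv2))
})

test_that("crossing scenarios engineer an unavoidable conflict", {
  mv <- makeCrossingScenario(2, render = FALSE)
  tr <- movieTruth(mv)
  mid <- (max(tr$frame) + 1) / 2
  atMid <- tr[tr$frame == mid, ]
  expect_lte(max(dist(atMid[, c("x", "y")])), 10)  # within one diameter
  first <- tr[tr$frame == 1, ]
  last <- tr[tr$frame == max(tr$frame), ]
  expect_gte(min(dist(first[, c("x", "y")])), 20)  # two diameters apart
  expect_gte(min(dist(last[, c("x", "y")])), 20)
  # the tracking module sees exactly one conflict event
  ts <- spectralTrack(truthDetections(mv, noiseSd = 0, seed = 1))
  expect_equal(trackingReport(ts)$conflicts, 1)

  # infeasible fingerprint separations are refused
  expect_error(makeCrossingScenario(4, fingerprintSeparation = 1.5,
                                    render = FALSE), "infeasible")
  expect_error(makeCrossingScenario(1, render = FALSE), "at least 2")
})

test_that("a 4-cell conflict admits 24 reassignments", {
  mv <- makeCrossingScenario(4, render = FALSE)
  ts <- spectralTrack(truthDetections(mv, noiseSd = 0, seed = 1))
  ev <- trackingReport(ts)$conflict_events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_tracks, 4)
  expect_equal(ambiguityCount(ev$n_tracks), 24)
})

test_that("division scenarios inherit the parent fingerprint", {
  mv <- makeDivisionScenario(c(600, 0, 400), splitFrame = 11, render = FALSE)
  tr <- movieTruth(mv)
  expCols <- grep("^expr_", names(tr), value = TRUE)
  parent <- tr[tr$cell_id == 1, expCols][1, ]
  for (d in 2:3) {
    daughter <- tr[tr$cell_id == d, expCols][1, ]
    expect_equal(as.numeric(daughter), as.numeric(parent))
    expect_equal(unique(tr$parent_id[tr$cell_id == d]), 1L)
  }
  expect_error(makeDivisionScenario(c(600, 0, 400), splitFrame = 50,
                                    frames = 21, render = FALSE), "within")

  # under 10% multiplicative noise the daughters keep the parent's rank
  # order in at least 95% of runs
  keep <- vapply(1:1000, function(s) {
    m <- makeDivisionScenario(c(500, 300, 200), splitFrame = 11,
                              daughterNoise = 0.1, render = FALSE, seed = s)
    t2 <- movieTruth(m)
    all(vapply(2:3, function(d) {
      rankAgreement(computeFingerprint(
        as.numeric(t2[t2$cell_id == d, expCols][1, ])),
        computeFingerprint(c(500, 300, 200)))
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(keep), 0.95)
})

test_that("truth detections are scan-ordered and noise-scaled", {
  mv <- makeSwapScenario(render = FALSE)
  d0 <- truthDetections(mv)
  expect_true(all(diff(order(d0$frame, d0$x, d0$y)) == 1))
  icols <- grep("^I_", names(d0), value = TRUE)
  d1 <- truthDetections(mv, noiseSd = 0.1, seed = 1)
  expect_false(identical(d0[, icols], d1[, icols]))
  expect_true(all(d1[, icols] >= 0))
})
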
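test_that("seedCells places the expected number of cells, reproducibly", {
  pop <- seedCells(density = 2, seed = 1)
  expect_equal(nCells(pop), 200)        # 2 per 100 um^2 in a 100x100 region
  expect_equal(nCells(seedCells(density = 0, seed = 1)), 0)
  expect_identical(cellCenters(seedCells(density = 1.3, seed = 7)),
                   cellCenters(seedCells(density = 1.3, seed = 7)))
  expect_true(all(cellCenters(pop) >= 0 & cellCenters(pop) <= 100))
  expect_error(seedCells(density = -1), "density")
  expect_error(seedCells(density = 1, side = 0), "side")
})

test_that("assignColors realizes the three labeling schemes", {
  pop <- seedCells(density = 3, region = c(100, 100), seed = 2)
  one <- assignColors(pop, "one", seed = 1)
  expect_true(all(vapply(colorSubsets(one), identical, logical(1), "R")))

  big <- seedCells(density = 3, region = c(1000, 1000), seed = 3)  # 30,000
  nomix <- assignColors(big, "nomix", seed = 4)
  freq <- table(vapply(colorSubsets(nomix), paste, character(1), collapse = ""))
  expect_equal(length(freq), 3)
  expect_true(all(abs(freq / nCells(big) - 1 / 3) < 0.01))

  big7 <- seedCells(density = 7, region = c(1000, 1000), seed = 5)  # 70,000
  mix <- assignColors(big7, "mix", seed = 6)
  freq7 <- table(vapply(colorSubsets(mix), paste, character(1), collapse = ""))
  expect_equal(length(freq7), 7)
  expect_true(all(abs(freq7 / nCells(big7) - 1 / 7) < 0.01))
})

test_that("segmentObjects merges exactly the overlapping same-color pairs", {
  # single cell
  p1 <- makePopulation(cbind(50, 50), list("R"))
  expect_equal(segmentObjects(p1),
               list(n_true = 1L, n_counted = 1L, fraction = 1))
  # two overlapping cells: same subset merges, different subsets do not
  ctr <- cbind(c(10, 15), c(10, 15))
  same <- makePopulation(ctr, list("R", "R"))
  diff <- makePopulation(ctr, list("R", "G"))
  expect_equal(segmentObjects(same)$n_counted, 1L)
  expect_equal(segmentObjects(diff)$n_counted, 2L)
  # fixed 5-cell configuration against the brute-force oracle
  p5 <- makePopulation(
    cbind(c(0, 6, 12, 30, 33), c(0, 0, 0, 30, 33)),
    list("R", "R", "G", "B", "B"))
  expect_equal(segmentObjects(p5)$n_counted, oracleSegmentCount(p5))
  expect_equal(segmentObjects(p5)$n_counted, 3L)
  # unassigned colors rejected
  expect_error(segmentObjects(seedCells(density = 1, seed = 1)), "assign")
})

test_that("segmentObjects equals the brute-force oracle on random populations", {
  set.seed(11)
  for (i in 1:60) {
    pop <- assignColors(seedCells(density = stats::runif(1, 0.02, 0.2)),
                        sample(c("one", "nomix", "mix"), 1))
    expect_equal(segmentObjects(pop)$n_counted, oracleSegmentCount(pop))
  }
})

test_that("channel-mode segmentation is a valid alternative counter", {
  # one 2-color cell: coincident per-channel centroids link into 1 object
  p1 <- makePopulation(cbind(20, 20), list(c("R", "G")))
  expect_equal(segmentObjects(p1, mode = "channel")$n_counted, 1L)
  # two overlapping single-color cells stay separate at the 2 um rule but
  # merge (undercount) when the linking distance exceeds their spacing
  p2 <- makePopulation(cbind(c(20, 24), c(20, 20)), list("R", "G"))
  expect_equal(segmentObjects(p2, mode = "channel", linkDist = 2)$n_counted, 2L)
  expect_equal(segmentObjects(p2, mode = "channel", linkDist = 6)$n_counted, 1L)
  p3 <- makePopulation(cbind(c(20, 60), c(20, 60)), list("R", "G"))
  expect_equal(segmentObjects(p3, mode = "channel")$n_counted, 2L)
})

test_that("counting never exceeds the true cell number and falls with density", {
  sweep <- runDensitySweep("one", densities = c(0.2, 0.8, 1.4), reps = 120,
                           seed = 5)
  expect_true(all(sweep$mean_fraction <= 1))
  se <- sweep$sd_fraction / sqrt(sweep$reps)
  d <- diff(sweep$mean_fraction)
  expect_true(all(d < 3 * sqrt(se[-1]^2 + se[-length(se)]^2)))
  # low density: essentially every cell is counted
  lo <- runDensitySweep("one", densities = 0.01, reps = 500, seed = 6)
  expect_gte(lo$mean_fraction, 0.98)
})

test_that("density sweeps are deterministic given a seed and reject bad input", {
  a <- runDensitySweep("mix", densities = c(0.4, 1.0), reps = 40, seed = 9)
  b <- runDensitySweep("mix", densities = c(0.4, 1.0), reps = 40, seed = 9)
  expect_identical(a, b)
  expect_error(runDensitySweep("one", densities = numeric(0), reps = 10),
               "nonempty")
  expect_error(runDensitySweep("one", densities = -0.5, reps = 10),
               "nonnegative")
})

test_that("fractionHistogram bins percentages into half-open bins", {
  h <- fractionHistogram(rep(0.72, 10))
  expect_equal(sum(h$count), 10)
  expect_equal(h$count[h$bin_lo == 70], 10)
  expect_true(all(h$count[h$bin_lo != 70] == 0))

  h2 <- fractionHistogram(c(0.10, 0.14, 0.97))
  expect_equal(h2$count[h2$bin_lo == 10], 2)
  expect_equal(h2$count[h2$bin_lo == 95], 1)
  expect_equal(sum(h2$count), 3)
  # bin edges are half-open: 0.15 falls in [15, 20)
  h3 <- fractionHistogram(c(0.15))
  expect_equal(h3$count[h3$bin_lo == 15], 1)
  expect_equal(nrow(fractionHistogram(numeric(0))), 0)
})
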
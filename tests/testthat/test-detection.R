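sp1 <- makeReferenceSpectra(defaultFluorophores("GFP"),
                            lambdaLayout(494, 623, 10.7))

# render a single-channel image of nuclei at given positions
renderNuclei <- function(pos, diameter = 5, field = c(100, 100),
                         pixelSize = 1, brightness = 1000) {
  cells <- data.frame(x = pos[, 1], y = pos[, 2], diameter = diameter)
  fr <- renderFrame(cells, matrix(brightness, nrow(cells), 1), sp1,
                    field = field, pixelSize = pixelSize)
  apply(fr, c(2, 3), sum)
}

test_that("detectSpots localizes isolated nuclei", {
  img <- renderNuclei(cbind(40, 60), diameter = 5)
  ss <- detectSpots(img, expectedDiameter = 5, threshold = 1, pixelSize = 1)
  expect_equal(nrow(spots(ss)), 1)
  expect_lte(abs(spots(ss)$x - 40), 0.5)
  expect_lte(abs(spots(ss)$y - 60), 0.5)

  img2 <- renderNuclei(cbind(c(30, 50), c(50, 50)), diameter = 5)
  expect_equal(nrow(spots(detectSpots(img2, 5, threshold = 1))), 2)
  expect_error(detectSpots(img, expectedDiameter = 0), "expectedDiameter")
})

test_that("detectSpots finds a full grid of nuclei", {
  g <- expand.grid(x = 10 + 15 * (0:4), y = 10 + 15 * (0:4))
  img <- renderNuclei(as.matrix(g), diameter = 5, field = c(90, 90))
  ss <- detectSpots(img, 5, threshold = 1)
  expect_equal(nrow(spots(ss)), 25)
})

test_that("linkSpots is single-linkage with a strict distance cutoff", {
  mk <- function(xy) new("SpotSet", spots = data.frame(
    x = xy[, 1], y = xy[, 2], channel = rep("c", nrow(xy)),
    intensity = rep(1, nrow(xy))), pixelSize = 1)
  expect_equal(linkSpots(mk(cbind(c(0, 1.5), c(0, 0))), 2)$n_objects, 1)
  expect_equal(linkSpots(mk(cbind(c(0, 3), c(0, 0))), 2)$n_objects, 2)
  # strictness: exactly 2 um apart is NOT linked
  expect_equal(linkSpots(mk(cbind(c(0, 2), c(0, 0))), 2)$n_objects, 2)
  # chain A-B 1.8, B-C 1.8, A-C 3.6: one object by transitivity
  expect_equal(linkSpots(mk(cbind(c(0, 1.8, 3.6), c(0, 0, 0))), 2)$n_objects, 1)
  expect_equal(linkSpots(mk(matrix(numeric(0), 0, 2)), 2)$n_objects, 0)
})

test_that("multicolor cells are counted once after channel combination", {
  # one cell expressing in two channels: coincident spots link into 1 object
  img <- renderNuclei(cbind(50, 50), diameter = 5)
  n <- countCells(list(R = img, G = img), "h2b3", pixelSize = 1,
                  threshold = 1)
  expect_equal(n$count, 1)
  # channel order does not matter
  n2 <- countCells(list(G = img, R = img), "h2b3", pixelSize = 1,
                   threshold = 1)
  expect_equal(n2$count, n$count)
  # well-separated nuclei are counted exactly
  g <- expand.grid(x = c(20, 50, 80), y = c(20, 50, 80))
  img9 <- renderNuclei(as.matrix(g), diameter = 5)
  rep9 <- countReport(countCells(list(img9), "h2b1", threshold = 1)$count, 9)
  expect_equal(rep9$ratio, 1.0)
  # membrane-scale objects count cleanly too
  imgM <- renderNuclei(cbind(c(25, 70), c(25, 70)), diameter = 10)
  expect_equal(countCells(list(imgM), "membrane", threshold = 1)$count, 2)
  expect_error(countCells(list(), "h2b1"), "at least one")
})

test_that("particulate labeling over-counts unless linked at 5 um", {
  # a DiI-like cell: 4 dye particles inside a 5 um disc
  part <- cbind(c(20, 23, 20, 23), c(20, 20, 23, 23))
  img <- renderNuclei(part, diameter = 2, field = c(40, 40), pixelSize = 0.5)
  ss <- detectSpots(img, 2, threshold = 1, pixelSize = 0.5)
  expect_equal(nrow(spots(ss)), 4)
  # without linking: 4 objects -> over-count ratio > 1
  expect_equal(linkSpots(ss, 0)$n_objects, 4)
  expect_gt(countReport(4, 1)$ratio, 1)
  # the 5 um DiI rule restores one object per cell
  n <- countCells(list(img), "dii", pixelSize = 0.5, threshold = 1)
  expect_equal(n$count, 1)
  expect_lte(countReport(n$count, 1)$ratio, 1.1)
})

test_that("density estimation matches both definitions", {
  set.seed(8)
  centers <- cbind(stats::runif(200, 0, 100), stats::runif(200, 0, 100))
  d <- estimateDensity(centers, region = c(100, 100))
  expect_equal(d$density, 2.0, tolerance = 0.2)
  expect_warning(d0 <- estimateDensity(matrix(numeric(0), 0, 2)), "no nuclear")
  expect_equal(d0$density, 0)

  # hexagonal grid, 12 um pitch: nearest-neighbor spacing minus the
  # 10 um diameter leaves a 2 um gap
  hex <- do.call(rbind, lapply(0:7, function(j) {
    cbind(12 * (0:7) + ifelse(j %% 2 == 1, 6, 0), j * 12 * sqrt(3) / 2)
  }))
  dh <- estimateDensity(hex, region = c(100, 100))
  expect_equal(dh$spacing, 2, tolerance = 0.1)
})
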
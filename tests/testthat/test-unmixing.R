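spGR <- makeReferenceSpectra(defaultFluorophores(c("GFP", "RFP")),
                             lambdaLayout(494, 623, 10.7))

test_that("unmixing recovers pure and zero pixels exactly", {
  S <- spectraMatrix(spGR)
  stack <- array(0, dim = c(12, 1, 2))
  stack[, 1, 1] <- 5 * S[, "GFP"]
  am <- unmixStack(stack, spGR)
  expect_equal(abundance(am)[, 1, 1], c(5, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(abundance(am)[, 1, 2], c(0, 0), ignore_attr = TRUE)
  # in-column-space pixels leave no residual
  expect_lt(residuals2D(am)[1, 1], 1e-9)
  expect_error(unmixStack(array(0, c(5, 2, 2)), spGR), "channels")
})

test_that("unmixing matches the K=2 active-set oracle on random pixels", {
  S <- spectraMatrix(spGR)
  set.seed(21)
  # noiseless mixtures recover exactly
  A <- matrix(stats::runif(2 * 50, 0, 10), 2)
  Y <- S %*% A
  am <- unmixStack(array(Y, dim = c(12, 1, 50)), spGR)
  expect_lt(max(abs(abundance(am)[, 1, ] - A)), 1e-6)
  # noisy pixels (which can push the unconstrained solution negative)
  # agree with the exhaustive oracle
  for (i in 1:40) {
    y <- as.numeric(S %*% stats::runif(2, 0, 5)) + stats::rnorm(12, 0, 0.5)
    est <- abundance(unmixStack(array(y, c(12, 1, 1)), spGR))[, 1, 1]
    expect_equal(est, oracleNNLS2(S, y), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("autofluorescence is fitted and discarded", {
  spAF <- makeReferenceSpectra(defaultFluorophores(c("GFP", "RFP")),
                               lambdaLayout(494, 623, 10.7),
                               includeAutofluorescence = TRUE)
  S <- spectraMatrix(spAF)
  y <- 3 * S[, "GFP"] + 10 * S[, "AF"]
  am <- unmixStack(array(y, c(12, 1, 1)), spAF)
  expect_identical(am@fluorophores, c("GFP", "RFP"))
  expect_equal(abundance(am)[, 1, 1], c(3, 0), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(residuals2D(am)[1, 1], 1e-9)
})

test_that("the background threshold is 125% of the background maximum", {
  img <- matrix(0, 10, 10)
  img[1:3, 1:3] <- 80
  img[8, 8] <- 500
  expect_equal(backgroundThreshold(img, c(1, 1, 3, 3)), 100)
  expect_equal(backgroundThreshold(matrix(0, 5, 5), c(1, 1, 5, 5)), 0)
  # locality: pixels outside the region do not matter
  img2 <- img
  img2[8, 8] <- 1e6
  expect_equal(backgroundThreshold(img2, c(1, 1, 3, 3)), 100)
  expect_error(backgroundThreshold(img, c(3, 3, 1, 1)), "rectangle")
  expect_error(backgroundThreshold(img, c(1, 1, 99, 99)), "rectangle")
})

test_that("applyThreshold zeroes values at or below per-channel cutoffs", {
  set.seed(4)
  stack <- array(stats::runif(2 * 6 * 6, 0.1, 1), c(2, 6, 6))
  expect_identical(applyThreshold(stack, c(0, 0)), stack)
  expect_true(all(applyThreshold(stack, c(2, 2)) == 0))
  thr <- c(0.4, 0.7)
  out <- applyThreshold(stack, thr)
  # survivor count equals a direct per-pixel scan
  for (ch in 1:2) {
    expect_equal(sum(out[ch, , ] > 0), sum(stack[ch, , ] > thr[ch]))
    expect_true(all(out[ch, , ][out[ch, , ] > 0] ==
                    stack[ch, , ][stack[ch, , ] > thr[ch]]))
  }
  expect_error(applyThreshold(stack, 1), "thresholds")
})

test_that("maximum intensity projection takes per-pixel maxima", {
  set.seed(5)
  z <- array(stats::rnorm(3 * 4 * 4), c(3, 4, 4))
  mip <- maxIntensityProjection(z)
  brute <- apply(z, c(2, 3), max)
  expect_equal(mip, brute)
  for (s in 1:3) expect_true(all(mip >= z[s, , ]))
  one <- array(stats::rnorm(16), c(1, 4, 4))
  expect_equal(maxIntensityProjection(one), one[1, , ])
  expect_error(maxIntensityProjection(array(0, c(0, 4, 4))), "Z >= 1")
})

test_that("unmixing a rendered frame recovers the generator's abundances", {
  sp3 <- makeReferenceSpectra(defaultFluorophores(c("GFP", "YFP", "RFP")),
                              lambdaLayout(494, 623, 10.7))
  cells <- data.frame(x = c(12, 28), y = c(15, 25))
  expr <- rbind(c(400, 0, 200), c(0, 300, 300))
  stack <- renderFrame(cells, expr, sp3, field = c(40, 40), pixelSize = 1)
  # identity-spectra render gives the per-pixel ground-truth abundances
  idS <- diag(3)
  colnames(idS) <- c("GFP", "YFP", "RFP")
  idSp <- new("ReferenceSpectra", S = idS, channels = 1:3,
              autofluorescence = character(0))
  truthAb <- renderFrame(cells, expr, idSp, field = c(40, 40), pixelSize = 1)
  est <- abundance(unmixStack(stack, sp3))
  expect_lt(max(abs(est - truthAb)), 1e-6)
})
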
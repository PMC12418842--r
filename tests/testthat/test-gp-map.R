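test_that("pixel-wise GP applies the calibrated ratiometric formula", {
  cp <- ChannelPair(matrix(c(3, 2, 0), 1), matrix(c(1, 1, 0), 1))
  m1 <- gpMap(cp, gFactor = 1)
  expect_equal(gpValues(m1)[1, 1], 0.5)
  # derived: (2 - G) / (2 + G) at G = 0.583333
  m2 <- gpMap(cp, gFactor = 0.583333)
  expect_equal(gpValues(m2)[1, 2], (2 - 0.583333) / (2 + 0.583333),
               tolerance = 1e-12)
  # zero-total pixel is invalid, never clamped to 0
  expect_false(validMask(m1)[1, 3])
  expect_true(is.na(gpValues(m1)[1, 3]))
  expect_error(gpMap(cp, gFactor = 0), "gFactor")
  expect_error(ChannelPair(matrix(1, 2, 2), matrix(1, 3, 3)), "dimensions")
})

test_that("GP is bounded, monotone in the channel ratio, and G=1 is raw", {
  set.seed(42)
  io <- matrix(runif(100, 0.1, 50), 10)
  id <- matrix(runif(100, 0.1, 50), 10)
  cp <- ChannelPair(io, id)
  for (G in c(0.3, 1, 2.7)) {
    gp <- gpValues(gpMap(cp, G))
    expect_true(all(abs(gp) < 1))
  }
  expect_equal(gpValues(gpMap(cp, 1)), rawGP(io, id))
  # strict monotonicity in Io/Id at fixed G
  ratios <- sort(runif(20, 0.05, 20))
  gp <- vapply(ratios, function(r)
    gpValues(gpMap(ChannelPair(matrix(r), matrix(1)), 0.7))[1, 1], numeric(1))
  expect_true(all(diff(gp) > 0))
})

test_that("intensity floor masks dim pixels instead of clamping", {
  cp <- ChannelPair(matrix(c(10, 2), 1), matrix(c(10, 2), 1))
  m <- gpMap(cp, 1, intensityFloor = 5)
  expect_true(validMask(m)[1, 1])
  expect_false(validMask(m)[1, 2])
  s <- summarizeROI(m, matrix(TRUE, 1, 2))
  expect_equal(s$n_pixels, 1L)   # only the valid pixel contributes
  expect_equal(s$mean_gp_internal, 0)
})

test_that("ROI summaries average valid pixels on both reporting scales", {
  gp <- matrix(0.3, 4, 4)
  cp <- ChannelPair(matrix(1.3, 4, 4), matrix(0.7, 4, 4))   # raw GP 0.3
  m <- gpMap(cp, 1)
  roi <- matrix(FALSE, 4, 4); roi[2:3, 2:3] <- TRUE
  s <- summarizeROI(m, roi, "c1", "M0")
  expect_equal(s$mean_gp_internal, 0.3)
  expect_equal(s$mean_gp_reported, 30)
  expect_identical(s$mean_gp_reported, 100 * s$mean_gp_internal)

  # mean of {0.2, 0.4} = 0.3
  cp2 <- ChannelPair(matrix(c(1.2, 1.4), 1), matrix(c(0.8, 0.6), 1))
  s2 <- summarizeROI(gpMap(cp2, 1), matrix(TRUE, 1, 2))
  expect_equal(s2$mean_gp_internal, 0.3)

  # ROI overlapping invalid pixels: filtered-mean oracle
  io <- matrix(c(2, 4, 0), 1); id <- matrix(c(1, 1, 0), 1)
  m3 <- gpMap(ChannelPair(io, id), 1)
  s3 <- summarizeROI(m3, matrix(TRUE, 1, 3))
  keep <- io + id > 0
  expect_equal(s3$mean_gp_internal,
               mean(((io - id) / (io + id))[keep]))
  expect_equal(s3$n_pixels, 2L)

  allBad <- gpMap(ChannelPair(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
  expect_error(summarizeROI(allBad, matrix(TRUE, 2, 2)), "empty ROI")
})

test_that("HSB rendering encodes GP as hue and intensity as brightness", {
  blank <- gpMap(ChannelPair(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
  img <- renderGPMap(blank, ChannelPair(matrix(0, 2, 2), matrix(0, 2, 2)))
  expect_true(all(img == 0))   # all-invalid renders black

  # endpoint contract: GP at range max is the blue hue end
  cp <- ChannelPair(matrix(c(40, 10), 1), matrix(c(10, 40), 1))
  m <- gpMap(cp, 1)   # GP = 0.6, -0.6
  img2 <- renderGPMap(m, cp, gpRange = c(-0.6, 0.6), brightPercentile = 1)
  expect_equal(img2[1, 1, ], c(0, 0, 1))   # pure blue
  expect_equal(img2[1, 2, ], c(1, 0, 0))   # pure red at range min

  # equal GP, 2x brightness: identical hue, linear brightness ratio
  cp3 <- ChannelPair(matrix(c(20, 40), 1), matrix(c(10, 20), 1))
  m3 <- gpMap(cp3, 1)
  img3 <- renderGPMap(m3, cp3, gpRange = c(-1, 1), brightPercentile = 1)
  px1 <- img3[1, 1, ]; px2 <- img3[1, 2, ]
  expect_equal(px2 / max(px2), px1 / max(px1), tolerance = 1e-2)
  expect_equal(max(px2) / max(px1), 2, tolerance = 1e-2)
  expect_error(renderGPMap(m3, cp3, gpRange = c(0.5, 0.5)), "degenerate")
})

test_that("M1/M2 ratio divides group means of the chosen measure", {
  s <- data.frame(phenotype = c("M1", "M2"),
                  mean_gp_reported = c(63.56, 69.99))
  r <- m1m2Ratio(s)
  expect_equal(r$ratio, 63.56 / 69.99, tolerance = 1e-12)
  expect_equal(r$ratio, 0.9081, tolerance = 1e-4)
  expect_identical(r$measure, "mean_gp_reported")

  eq <- data.frame(phenotype = c("M1", "M1", "M2"), v = c(2, 4, 3))
  expect_equal(m1m2Ratio(eq, "v")$ratio, 1)
  expect_error(m1m2Ratio(data.frame(phenotype = "M1", v = 1), "v"), "M2")
  z <- data.frame(phenotype = c("M1", "M2"), v = c(1, 0))
  expect_error(m1m2Ratio(z, "v"), "zero")
})

test_that("channel pairs and GP maps survive TIFF round-trips", {
  f <- simMembraneImages(SyntheticImageSpec(imageSize = c(64, 64),
                                            nCells = 1, seed = 3))
  p1 <- withr::local_tempfile(fileext = ".tif")
  writeChannelPair(f$channels, p1)
  back <- readChannelPair(p1)
  expect_equal(orderedChannel(back), orderedChannel(f$channels))
  expect_equal(disorderedChannel(back), disorderedChannel(f$channels))

  m <- gpMap(f$channels, 1)
  p2 <- withr::local_tempfile(fileext = ".tif")
  writeGPMap(m, p2)
  m2 <- readGPMap(p2)
  expect_identical(validMask(m2), validMask(m))
  expect_equal(gpValues(m2)[validMask(m)], gpValues(m)[validMask(m)],
               tolerance = 1e-6)
})

test_that("integer-pixel registration shift moves the disordered channel", {
  cp <- ChannelPair(matrix(1, 3, 3), matrix(1:9, 3, 3))
  sh <- shiftChannels(cp, dr = 1, dc = 0)
  expect_equal(disorderedChannel(sh)[2:3, ], disorderedChannel(cp)[1:2, ])
  expect_equal(disorderedChannel(sh)[1, ], rep(0, 3))
  expect_equal(orderedChannel(sh), orderedChannel(cp))
})
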
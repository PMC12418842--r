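test_that("image generator is seed-deterministic and validates its spec", {
  s <- SyntheticImageSpec(imageSize = c(96, 96), nCells = 4, seed = 11)
  a <- simMembraneImages(s)
  b <- simMembraneImages(s)
  expect_identical(orderedChannel(a$channels), orderedChannel(b$channels))
  expect_identical(a$masks, b$masks)
  c2 <- simMembraneImages(SyntheticImageSpec(imageSize = c(96, 96),
                                             nCells = 4, seed = 12))
  expect_false(identical(orderedChannel(a$channels),
                         orderedChannel(c2$channels)))

  expect_error(SyntheticImageSpec(ringThicknessPx = 12,
                                  ringOuterRadiusPx = 10), "ringThickness")
  expect_error(SyntheticImageSpec(gpTrue = 1), "gpTrue")
  expect_error(SyntheticImageSpec(photonBudget = 0), "photonBudget")
  expect_error(simMembraneImages(
    SyntheticImageSpec(imageSize = c(48, 48), nCells = 50)), "placement")
})

test_that("noise-free channels split the photon budget by (1 + GP)/2", {
  mk <- function(gp) simMembraneImages(SyntheticImageSpec(
    imageSize = c(64, 64), nCells = 1, gpTrue = gp, photonBudget = 2000,
    backgroundRate = 10, noise = FALSE, seed = 1))
  f0 <- mk(0)
  ring <- f0$masks[[1]]
  io <- orderedChannel(f0$channels); id <- disorderedChannel(f0$channels)
  expect_equal(io[ring], id[ring])                       # symmetric split
  expect_equal(io[ring] + id[ring], rep(2000, sum(ring)))  # conservation
  expect_equal(io[!ring], id[!ring])                     # background even
  expect_equal(io[!ring] + id[!ring], rep(10, sum(!ring)))

  f5 <- mk(0.5)
  ring5 <- f5$masks[[1]]
  expect_equal(orderedChannel(f5$channels)[ring5] /
                 disorderedChannel(f5$channels)[ring5],
               rep(3, sum(ring5)))   # f/(1-f) = 0.75/0.25
})

test_that("generated images recover the ground-truth GP", {
  f <- simMembraneImages(SyntheticImageSpec(
    imageSize = c(256, 256), nCells = 10, gpTrue = 0.3,
    photonBudget = 2000, seed = 7))
  # oracle: recompute GP directly from the emitted count arrays
  perCell <- oracleMeanGP(f)
  expect_length(perCell, 10)
  expect_lt(abs(mean(perCell) - 0.3), 0.02)
  # and through the GPMap/ROI path
  m <- gpMap(f$channels, 1)
  s <- summarizeROIs(m, lapply(f$masks, function(mask)
    new("MembraneROI", mask = mask, cellId = "c", provenance = "manual",
        nPixels = as.integer(sum(mask)))))
  expect_lt(abs(mean(s$mean_gp_internal) - 0.3), 0.02)
})

test_that("expression generator reproduces the configured group structure", {
  p <- defaultExpressionParams()
  means <- function(g) {
    sub <- p[p$gene == g, ]
    structure(sub$mean, names = sub$phenotype)
  }
  for (g in unique(p$gene)) {
    m <- means(g)   # additivity identity holds for every gene
    expect_equal(unname((m["M1"] - m["M0"]) + (m["M2"] - m["M1"])),
                 unname(m["M2"] - m["M0"]), tolerance = 1e-12)
  }
  m1b <- means("IL1B")
  expect_equal(unname(m1b["M1"] - m1b["M0"]), 370.9)
  expect_equal(unname((m1b["M1"] - m1b["M0"]) - (m1b["M2"] - m1b["M0"])),
               171.3, tolerance = 1e-12)
  m10 <- means("IL10")
  expect_equal(unname((m10["M1"] - m10["M0"]) + (m10["M2"] - m10["M1"])),
               30.28, tolerance = 1e-12)

  # configured SDs reproduce the printed difference SEMs exactly
  semOf <- function(g, a, b) {
    sub <- p[p$gene == g, ]
    sqrt((sub$sd[sub$phenotype == a]^2 + sub$sd[sub$phenotype == b]^2) / 9)
  }
  expect_equal(semOf("IL1B", "M0", "M1"), 45.53, tolerance = 1e-9)
  expect_equal(semOf("IL1B", "M1", "M2"), 101.0, tolerance = 1e-9)
  expect_equal(semOf("IL10", "M0", "M2"), 19.91, tolerance = 1e-9)
  expect_equal(semOf("IL6", "M0", "M1"), 2.14, tolerance = 1e-9)

  # zero-SD spec collapses every draw onto its group mean
  p0 <- p; p0$sd <- 0
  t0 <- simExpressionTable(SyntheticExpressionSpec(p0, seed = 5))
  key <- paste(p0$gene, p0$phenotype)
  expect_equal(t0$value,
               p0$mean[match(paste(t0$gene, t0$phenotype), key)])

  # determinism and replicate count
  tA <- simExpressionTable(SyntheticExpressionSpec(seed = 9))
  tB <- simExpressionTable(SyntheticExpressionSpec(seed = 9))
  expect_identical(tA, tB)
  expect_equal(nrow(tA), 3 * 3 * 9)

  bad <- p[-1, ]   # a missing gene x phenotype combination is rejected
  expect_error(SyntheticExpressionSpec(bad), "exactly once")
})

test_that("solveGroupSds inverts the pairwise-SEM system", {
  sds <- c(3, 7, 11); n <- 9
  sem <- function(a, b) sqrt((sds[a]^2 + sds[b]^2) / n)
  expect_equal(solveGroupSds(sem(1, 2), sem(1, 3), sem(2, 3), n), sds)
  expect_error(solveGroupSds(1, 1, 10, 9), "no real")
})

test_that("MFI generator matches the printed marker contrasts", {
  p <- defaultMfiParams()
  mean_of <- function(mk, ph) p$mean[p$marker == mk & p$phenotype == ph]
  expect_equal(mean_of("CD64", "M1") - mean_of("CD64", "M0"), 286.7)
  # printed group means 6.33 and 431; their printed difference 424.7 is a
  # one-decimal rounding of 424.67
  expect_equal(round(mean_of("CD11b", "M0") - mean_of("CD11b", "THP-1"), 1),
               424.7)
  expect_equal(mean_of("CD86", "M1") - mean_of("CD86", "M0"), 214.3)
  # configured SDs reproduce printed difference SEMs (n = 3, df = 4)
  sd_of <- function(mk, ph) p$sd[p$marker == mk & p$phenotype == ph]
  expect_equal(sqrt((sd_of("CD64", "M0")^2 + sd_of("CD64", "M1")^2) / 3),
               22.60, tolerance = 1e-9)
  expect_equal(sqrt((sd_of("CD11b", "THP-1")^2 + sd_of("CD11b", "M0")^2) / 3),
               20.84, tolerance = 1e-9)

  tA <- simMfiTable(seed = 4)
  expect_identical(tA, simMfiTable(seed = 4))
  expect_equal(nrow(tA), 4 * 4 * 3)
  expect_true(all(tA$mfi >= 0))
})
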
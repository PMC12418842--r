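makeCq <- function(samples, genes, phenos, cq) {
  data.frame(sample = samples, gene = genes, phenotype = phenos,
             replicate = 1L, cq = cq, stringsAsFactors = FALSE)
}

test_that("fold change implements 2^-ddCq against the calibrator mean", {
  # single calibrator sample is its own baseline: RQ = 1
  one <- makeCq(c("s1", "s1"), c("IL6", "18S"), "M0", c(25, 15))
  expect_equal(foldChange(one)$rq, 1)

  # dCq 8 against calibrator-mean dCq 10: ddCq = -2, RQ = 4
  tab <- rbind(makeCq(c("c1", "c1"), c("IL6", "18S"), "M0", c(25, 15)),
               makeCq(c("t1", "t1"), c("IL6", "18S"), "M1", c(23, 15)))
  fc <- foldChange(tab)
  expect_equal(fc$delta_delta_cq[fc$sample == "t1"], -2)
  expect_equal(fc$rq[fc$sample == "t1"], 4)

  # calibrator group's mean ddCq is exactly 0
  set.seed(1)
  cal <- makeCq(sprintf("c%d", 1:6), "IL6", "M0", runif(6, 20, 30))
  cal <- rbind(cal, makeCq(sprintf("c%d", 1:6), "18S", "M0", 15))
  fcc <- foldChange(cal)
  expect_equal(mean(fcc$delta_delta_cq), 0)

  orphan <- rbind(makeCq("s1", "IL6", "M0", 25),
                  makeCq(c("c1", "c1"), c("IL6", "18S"), "M0", c(25, 15)))
  expect_error(foldChange(orphan), "missing reference-gene Cq.*s1")
  expect_error(foldChange(makeCq("s1", "IL6", "M0", 25)),
               "reference gene")
  noCal <- rbind(makeCq(c("t1", "t1"), c("IL6", "18S"), "M1", c(23, 15)))
  expect_error(foldChange(noCal), "calibrator")
})

test_that("a Cq table built from known RQ values round-trips exactly", {
  rq <- expand.grid(phenotype = c("M0", "M1", "M2"), replicate = 1:4,
                    gene = c("IL1B", "IL10"), stringsAsFactors = FALSE)
  rq$sample <- sprintf("%s_r%d", rq$phenotype, rq$replicate)
  # calibrator values exactly 1 so recovery is exact
  rq$value <- ifelse(rq$phenotype == "M0", 1,
                     ifelse(rq$phenotype == "M1", 2^seq_len(nrow(rq)) %% 7 + 0.5,
                            0.25 * seq_len(nrow(rq))))
  fc <- foldChange(rqToCqTable(rq))
  m <- merge(rq, fc, by = c("sample", "gene"))
  expect_equal(m$rq, m$value, tolerance = 1e-12)
  expect_error(rqToCqTable(transform(rq, value = -value)), "positive")
})

test_that("per-gene Cq offsets cancel in the fold change", {
  rq <- simExpressionTable(SyntheticExpressionSpec(seed = 2))
  rq$value <- abs(rq$value) + 0.01
  cq <- rqToCqTable(rq)
  fc0 <- foldChange(cq)
  shifted <- cq
  shifted$cq[shifted$gene == "IL6"] <- shifted$cq[shifted$gene == "IL6"] + 3.7
  fc1 <- foldChange(shifted)
  expect_equal(fc1$rq[fc1$gene == "IL6"], fc0$rq[fc0$gene == "IL6"],
               tolerance = 1e-12)
})

test_that("technical replicates can be averaged per sample first", {
  tab <- rbind(
    data.frame(sample = "c1", gene = "IL6", phenotype = "M0",
               replicate = 1:2, cq = c(24, 26)),
    data.frame(sample = "c1", gene = "18S", phenotype = "M0",
               replicate = 1:2, cq = c(14, 16)))
  fc <- foldChange(tab, averageReplicates = TRUE)
  expect_equal(nrow(fc), 1L)
  expect_equal(fc$delta_cq, 10)
})

test_that("standard-curve efficiency follows (10^(-1/slope) - 1) * 100", {
  perfect <- -1 / log10(2)
  sc <- standardCurveEfficiency(
    data.frame(log10_input = 0:3, cq = 30 + perfect * (0:3)))
  expect_equal(sc$slope, perfect, tolerance = 1e-9)
  expect_equal(sc$efficiencyPct, 100, tolerance = 1e-9)

  # collinear published example: closed-form least squares
  sc2 <- standardCurveEfficiency(
    data.frame(log10_input = 0:2, cq = c(30, 26.6781, 23.3562)))
  expect_equal(sc2$slope, -3.3219, tolerance = 1e-3)
  expect_equal(sc2$efficiencyPct, 100, tolerance = 0.1)

  # direct evaluation at slope -3.45
  sc3 <- standardCurveEfficiency(
    data.frame(log10_input = 0:2, cq = c(30, 30 - 3.45, 30 - 6.9)))
  expect_equal(sc3$efficiencyPct, (10^(1 / 3.45) - 1) * 100,
               tolerance = 1e-9)
  expect_equal(sc3$efficiencyPct, 94.9, tolerance = 0.05)

  # efficiency decreases as |slope| grows
  effAt <- function(s) standardCurveEfficiency(
    data.frame(log10_input = 0:2, cq = c(30, 30 + s, 30 + 2 * s)))$efficiencyPct
  slopes <- c(-3.1, -3.3219, -3.6, -4.0)
  expect_true(all(diff(vapply(slopes, effAt, numeric(1))) < 0))

  flat <- standardCurveEfficiency(
    data.frame(log10_input = 0:2, cq = c(20, 21, 22)))
  expect_false(flat$valid)
  expect_true(is.na(flat$efficiencyPct))
  expect_error(standardCurveEfficiency(
    data.frame(log10_input = c(0, 0, 1), cq = c(1, 2, 3))), "distinct")
})
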
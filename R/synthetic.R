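## Seeded generators emulating the study design: two-channel membrane images
## with known ground-truth GP, LUV calibration intensities, RQ/Cq expression
## tables and surface-marker MFI tables.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Specification for synthetic membrane images
#'
#' Defines one simulated field of ring-shaped (membrane-stained) cells with a
#' known ground-truth GP. Membrane pixels receive an expected
#' ordered-channel photon fraction \eqn{f = (1 + GP)/2} of the photon budget
#' and disordered fraction \eqn{(1 - GP)/2}; background pixels receive the
#' background rate split evenly across channels. Counting noise is Poisson
#' per channel; \code{noise = FALSE} emits expected values exactly, for
#' exact tests.
#'
#' @param imageSize integer(2), image height and width in pixels.
#' @param nCells number of cells to place.
#' @param ringOuterRadiusPx,ringThicknessPx ring geometry in pixels;
#'   thickness must be >= 1 and < the outer radius.
#' @param gpTrue ground-truth GP per cell, strictly inside (-1, 1);
#'   recycled across cells.
#' @param photonBudget expected photons per membrane pixel, summed over both
#'   channels; must be > 0.
#' @param backgroundRate expected photons per background pixel (both
#'   channels together).
#' @param noise logical; Poisson counting noise on photon counts.
#' @param seed integer RNG seed. Identical spec + seed gives identical
#'   output.
#' @return A list of class \code{"SyntheticImageSpec"}.
#' @seealso [simMembraneImages()]
#' @export
SyntheticImageSpec <- function(imageSize = c(256L, 256L), nCells = 12L,
                               ringOuterRadiusPx = 10, ringThicknessPx = 3,
                               gpTrue = 0.3, photonBudget = 2000,
                               backgroundRate = 20, noise = TRUE,
                               seed = 1L) {
  spec <- list(imageSize = as.integer(imageSize), nCells = as.integer(nCells),
               ringOuterRadiusPx = ringOuterRadiusPx,
               ringThicknessPx = ringThicknessPx,
               gpTrue = gpTrue, photonBudget = photonBudget,
               backgroundRate = backgroundRate, noise = isTRUE(noise),
               seed = as.integer(seed))
  if (length(spec$imageSize) != 2L || any(spec$imageSize < 8L))
    stop("imageSize must be two pixel dimensions >= 8")
  if (spec$nCells < 1L) stop("nCells must be >= 1")
  if (spec$ringThicknessPx < 1 || spec$ringThicknessPx >= spec$ringOuterRadiusPx)
    stop("ringThicknessPx must be >= 1 and < ringOuterRadiusPx")
  if (any(abs(spec$gpTrue) >= 1))
    stop("gpTrue must lie strictly inside (-1, 1)")
  if (spec$photonBudget <= 0) stop("photonBudget must be positive")
  if (spec$backgroundRate < 0) stop("backgroundRate must be >= 0")
  class(spec) <- "SyntheticImageSpec"
  spec
}

# Deterministic jittered-grid centers with enough clearance that rings never
# overlap; errors if the requested cells cannot fit.
placeCells <- function(spec) {
  r <- spec$ringOuterRadiusPx
  margin <- ceiling(r) + 2L
  pitch <- 2L * ceiling(r) + 7L
  rows <- seq(margin + 2L, spec$imageSize[1L] - margin - 2L, by = pitch)
  cols <- seq(margin + 2L, spec$imageSize[2L] - margin - 2L, by = pitch)
  if (length(rows) * length(cols) < spec$nCells)
    stop("placement error: ", spec$nCells, " rings of radius ", r,
         " do not fit in a ", spec$imageSize[1L], "x", spec$imageSize[2L],
         " image")
  grid <- expand.grid(row = rows, col = cols)[seq_len(spec$nCells), ]
  jit <- matrix(stats::runif(2L * spec$nCells, -2, 2), ncol = 2L)
  cbind(grid$row + jit[, 1L], grid$col + jit[, 2L])
}

#' Generate synthetic two-channel membrane images
#'
#' Renders the cells described by a [SyntheticImageSpec()] into a
#' [ChannelPair-class], returning per-cell ground-truth ring masks and GP
#' values alongside. In the noise-free limit the two channels sum exactly to
#' the photon budget on every membrane pixel (photon conservation).
#'
#' @param spec a [SyntheticImageSpec()].
#' @return A list with elements \code{channels} ([ChannelPair-class]),
#'   \code{masks} (list of logical ground-truth ring masks, one per cell),
#'   \code{gpTrue} (numeric per cell), \code{centers} (matrix of ring
#'   centers) and \code{spec}.
#' @examples
#' field <- simMembraneImages(SyntheticImageSpec(nCells = 2, noise = FALSE))
#' gp <- gpMap(field$channels)
#' summarizeROI(gp, field$masks[[1]])
#' @export
simMembraneImages <- function(spec) {
  stopifnot(inherits(spec, "SyntheticImageSpec"))
  withSeed(spec$seed, {
    h <- spec$imageSize[1L]; w <- spec$imageSize[2L]
    centers <- placeCells(spec)
    gpTrue <- rep_len(spec$gpTrue, spec$nCells)

    rowIdx <- matrix(seq_len(h), h, w)
    colIdx <- matrix(seq_len(w), h, w, byrow = TRUE)
    lamO <- matrix(spec$backgroundRate / 2, h, w)
    lamD <- matrix(spec$backgroundRate / 2, h, w)
    masks <- vector("list", spec$nCells)
    for (i in seq_len(spec$nCells)) {
      d <- sqrt((rowIdx - centers[i, 1L])^2 + (colIdx - centers[i, 2L])^2)
      ring <- d <= spec$ringOuterRadiusPx &
              d > spec$ringOuterRadiusPx - spec$ringThicknessPx
      masks[[i]] <- ring
      f <- (1 + gpTrue[i]) / 2
      lamO[ring] <- f * spec$photonBudget
      lamD[ring] <- (1 - f) * spec$photonBudget
    }
    if (spec$noise) {
      io <- matrix(stats::rpois(h * w, lamO), h, w)
      id <- matrix(stats::rpois(h * w, lamD), h, w)
    } else {
      io <- lamO; id <- lamD
    }
    list(channels = ChannelPair(io, id), masks = masks, gpTrue = gpTrue,
         centers = centers, spec = spec)
  })
}

#' Generate a synthetic LUV calibration set
#'
#' Emits per-vesicle (ordered, disordered) intensity pairs whose raw
#' (G = 1) GP is centered on \code{gpMes}, carrying \code{gpRef} as the
#' reference value to be recovered by [estimateCalibration()]. With
#' \code{noiseSd = 0} every pair's raw GP equals \code{gpMes} exactly.
#'
#' @param gpRef,gpMes reference and measured GP, strictly inside (-1, 1).
#' @param nVesicles number of vesicle measurements (>= 1).
#' @param noiseSd Gaussian SD of per-vesicle raw GP around \code{gpMes}
#'   (>= 0).
#' @param totalIntensity detector counts per vesicle (both channels).
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{ordered}, \code{disordered} and
#'   attribute \code{gpRef}.
#' @export
simCalibrationSet <- function(gpRef, gpMes, nVesicles = 50L, noiseSd = 0.02,
                              totalIntensity = 1000, seed = 1L) {
  if (abs(gpRef) >= 1 || abs(gpMes) >= 1)
    stop("gpRef and gpMes must lie strictly inside (-1, 1)")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  stopifnot(nVesicles >= 1L)
  withSeed(seed, {
    g <- gpMes + stats::rnorm(nVesicles, 0, noiseSd)
    g <- pmin(pmax(g, -0.999), 0.999)
    out <- data.frame(ordered = totalIntensity * (1 + g) / 2,
                      disordered = totalIntensity * (1 - g) / 2)
    attr(out, "gpRef") <- gpRef
    out
  })
}

#' Solve per-group SDs from the SEMs of pairwise mean differences
#'
#' For three groups of equal size n, the SEMs of the three pairwise mean
#' differences satisfy \eqn{SEM_{ab}^2 = (s_a^2 + s_b^2)/n}; this inverts
#' that system. Used to configure generator dispersions so that simulated
#' difference SEMs match a printed set.
#'
#' @param sem12,sem13,sem23 SEMs of the (1,2), (1,3) and (2,3) mean
#'   differences.
#' @param n per-group sample size.
#' @return numeric(3) of group SDs; errors if the system has no real
#'   solution.
#' @export
solveGroupSds <- function(sem12, sem13, sem23, n) {
  v1 <- n * (sem12^2 + sem13^2 - sem23^2) / 2
  v2 <- n * (sem12^2 + sem23^2 - sem13^2) / 2
  v3 <- n * (sem13^2 + sem23^2 - sem12^2) / 2
  v <- c(v1, v2, v3)
  if (any(v < 0))
    stop("printed SEM triple admits no real per-group SD solution")
  sqrt(v)
}

#' Default expression-generator parameters
#'
#' Group means and SDs (RQ units) for IL-1B, IL-6 and IL-10 across M0, M1
#' and M2, with n = 9 per group. Means are anchored at an M0 baseline
#' (RQ = 1 for IL-1B/IL-6; RQ = 40 for IL-10, whose M1 level lies far below
#' M0) and offset by the study's printed pairwise mean differences, which
#' satisfy additivity exactly. SDs are solved from the printed
#' difference-SEM triples via [solveGroupSds()].
#'
#' @return data.frame with columns \code{gene}, \code{phenotype},
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
defaultExpressionParams <- function() {
  n <- 9L
  rows <- list(
    list("IL1B", c(M0 = 1,  M1 = 1 + 370.9, M2 = 1 + 199.6),
         solveGroupSds(45.53, 90.23, 101.0, n)),
    list("IL6",  c(M0 = 1,  M1 = 1 + 11.71, M2 = 1 + 2.36),
         solveGroupSds(2.14, 0.92, 2.25, n)),
    list("IL10", c(M0 = 40, M1 = 40 - 37.69, M2 = 40 + 30.28),
         solveGroupSds(6.74, 19.91, 19.43, n)))
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene = r[[1L]], phenotype = names(r[[2L]]),
               mean = unname(r[[2L]]), sd = r[[3L]], n = n,
               stringsAsFactors = FALSE)))
}

#' Specification for synthetic expression tables
#'
#' @param params data.frame as returned by [defaultExpressionParams()]
#'   (columns gene, phenotype, mean, sd, n).
#' @param seed integer RNG seed.
#' @return list of class \code{"SyntheticExpressionSpec"}.
#' @export
SyntheticExpressionSpec <- function(params = defaultExpressionParams(),
                                    seed = 1L) {
  params <- as.data.frame(params)
  stopifnot(all(c("gene", "phenotype", "mean", "sd", "n") %in% names(params)))
  if (any(params$sd < 0)) stop("group SDs must be >= 0")
  if (any(params$n < 2L)) stop("n must be >= 2 per group")
  combos <- table(params$gene, params$phenotype)
  if (any(combos != 1L))
    stop("every gene must appear exactly once per phenotype")
  structure(list(params = params, seed = as.integer(seed)),
            class = "SyntheticExpressionSpec")
}

#' Generate a synthetic relative-expression (RQ) table
#'
#' Draws per-replicate RQ values from the normal model configured in the
#' spec, one row per gene x phenotype x replicate. With all SDs zero every
#' sample equals its group mean.
#'
#' @param spec a [SyntheticExpressionSpec()] (or a seed, for defaults).
#' @return data.frame with columns \code{sample}, \code{gene},
#'   \code{phenotype}, \code{replicate}, \code{value} (RQ units).
#' @export
simExpressionTable <- function(spec = SyntheticExpressionSpec()) {
  if (is.numeric(spec)) spec <- SyntheticExpressionSpec(seed = spec)
  stopifnot(inherits(spec, "SyntheticExpressionSpec"))
  p <- spec$params
  withSeed(spec$seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
      reps <- seq_len(p$n[i])
      data.frame(sample = sprintf("%s_r%d", p$phenotype[i], reps),
                 gene = p$gene[i], phenotype = p$phenotype[i],
                 replicate = reps,
                 value = stats::rnorm(p$n[i], p$mean[i], p$sd[i]),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Default surface-marker MFI generator parameters
#'
#' Group means and SDs (arbitrary MFI units) for CD86, CD64, CD206 and CD11b
#' across THP-1, M0, M1 and M2, with n = 3 per group. Means anchor each
#' marker at a resting (M0) baseline offset by the study's printed pairwise
#' differences: CD64 high only in M1, CD206 high in M2, CD86 high in both
#' M1 and M2, CD11b elevated in all macrophage states versus the THP-1
#' monocyte baseline (printed means 6.33 and 431 for THP-1 and M0). SDs for
#' M0/M1/M2 are solved from the printed difference-SEM triples.
#'
#' @return data.frame with columns \code{marker}, \code{phenotype},
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
defaultMfiParams <- function() {
  n <- 3L
  sd11b_m0 <- sqrt(n * 20.84^2 - 3^2)   # THP-1 vs M0 SEM 20.84 with sd(THP-1)=3
  rows <- list(
    list("CD86", c(`THP-1` = 40, M0 = 50, M1 = 50 + 214.3, M2 = 50 + 212.3),
         c(10, solveGroupSds(26.72, 19.84, 31.00, n))),
    list("CD64", c(`THP-1` = 25, M0 = 30, M1 = 30 + 286.7, M2 = 30 + 0.33),
         c(8, solveGroupSds(22.60, 9.63, 23.42, n))),
    list("CD206", c(`THP-1` = 18, M0 = 20, M1 = 20 - 1.67, M2 = 20 + 8.67),
         c(1.5, solveGroupSds(1.05, 1.49, 1.33, n))),
    list("CD11b", c(`THP-1` = 6.33, M0 = 431, M1 = 450, M2 = 440),
         c(3, sd11b_m0, 30, 30)))
  do.call(rbind, lapply(rows, function(r)
    data.frame(marker = r[[1L]], phenotype = names(r[[2L]]),
               mean = unname(r[[2L]]), sd = r[[3L]], n = n,
               stringsAsFactors = FALSE)))
}

#' Generate a synthetic surface-marker MFI table
#'
#' Draws per-replicate MFI values (truncated at 0) from the normal model in
#' \code{params}, 3 replicates per phenotype per marker by default.
#'
#' @param seed integer RNG seed.
#' @param params data.frame as from [defaultMfiParams()].
#' @return data.frame with columns \code{sample}, \code{marker},
#'   \code{phenotype}, \code{replicate}, \code{mfi}.
#' @export
simMfiTable <- function(seed = 1L, params = defaultMfiParams()) {
  params <- as.data.frame(params)
  withSeed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
      reps <- seq_len(params$n[i])
      data.frame(sample = sprintf("%s_r%d", params$phenotype[i], reps),
                 marker = params$marker[i], phenotype = params$phenotype[i],
                 replicate = reps,
                 mfi = pmax(stats::rnorm(params$n[i], params$mean[i],
                                         params$sd[i]), 0),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Convert known RQ values into a consistent Cq table
#'
#' Inverts the 2^-DeltaDeltaCq arithmetic: builds target- and reference-gene
#' Cq records whose fold changes, computed against the given calibrator
#' phenotype, recover the supplied RQ values exactly (provided the
#' calibrator group's RQ values are all 1, as when RQ is expressed relative
#' to that group's own mean model).
#'
#' @param rqTable data.frame as from [simExpressionTable()]; all
#'   \code{value} entries must be > 0.
#' @param referenceGene reference-gene label (default \code{"18S"}).
#' @param refCq constant reference-gene Cq assigned to every sample.
#' @param baseCq target-gene Cq at RQ = 1.
#' @return data.frame with columns \code{sample}, \code{gene},
#'   \code{phenotype}, \code{replicate}, \code{cq}, including one
#'   reference-gene row per sample.
#' @export
rqToCqTable <- function(rqTable, referenceGene = "18S", refCq = 15,
                        baseCq = 25) {
  stopifnot(all(c("sample", "gene", "phenotype", "replicate", "value") %in%
                  names(rqTable)))
  if (any(rqTable$value <= 0))
    stop("RQ values must be positive to be representable as Cq")
  targets <- data.frame(sample = rqTable$sample, gene = rqTable$gene,
                        phenotype = rqTable$phenotype,
                        replicate = rqTable$replicate,
                        cq = baseCq - log2(rqTable$value),
                        stringsAsFactors = FALSE)
  samples <- unique(rqTable[, c("sample", "phenotype", "replicate")])
  refs <- data.frame(sample = samples$sample, gene = referenceGene,
                     phenotype = samples$phenotype,
                     replicate = samples$replicate, cq = refCq,
                     stringsAsFactors = FALSE)
  rbind(targets, refs)
}
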
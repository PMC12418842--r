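#' Relative expression by the 2^-DeltaDeltaCq method
#'
#' Computes, per sample and target gene, \eqn{\Delta Cq = Cq_{target} -
#' Cq_{reference}}, then \eqn{\Delta\Delta Cq = \Delta Cq - \overline{\Delta
#' Cq}_{calibrator}} against the mean delta-Cq of the calibrator phenotype
#' group, and the fold change \eqn{RQ = 2^{-\Delta\Delta Cq}}. Technical
#' replicates may optionally be averaged per sample before the delta step;
#' the default treats each listed row as an observation. Primer efficiency
#' is assumed 100\% (base-2 amplification); efficiencies are validated
#' separately with [standardCurveEfficiency()] but never used as a
#' correction.
#'
#' By construction the calibrator group's mean delta-delta-Cq is exactly 0
#' (its mean RQ is 1 only up to the convexity of 2^x).
#'
#' @param records data.frame with columns \code{sample}, \code{gene},
#'   \code{phenotype}, \code{replicate}, \code{cq}; every sample must carry
#'   a reference-gene record.
#' @param referenceGene reference-gene label (default \code{"18S"}).
#' @param calibratorPhenotype calibrator group label (default \code{"M0"}).
#' @param averageReplicates average technical replicates per sample before
#'   computing delta-Cq (default FALSE).
#' @return data.frame with one row per sample x target gene: \code{sample},
#'   \code{gene}, \code{phenotype}, \code{delta_cq}, \code{delta_delta_cq},
#'   \code{rq}.
#' @examples
#' cq <- data.frame(sample = c("s1", "s1"), gene = c("IL6", "18S"),
#'                  phenotype = "M0", replicate = 1, cq = c(25, 15))
#' foldChange(cq)$rq   # 1: a lone calibrator sample is its own baseline
#' @export
foldChange <- function(records, referenceGene = "18S",
                       calibratorPhenotype = "M0",
                       averageReplicates = FALSE) {
  records <- as.data.frame(records)
  need <- c("sample", "gene", "phenotype", "replicate", "cq")
  stopifnot(all(need %in% names(records)))
  if (any(!is.finite(records$cq) | records$cq <= 0))
    stop("all Cq values must be finite and positive")

  if (averageReplicates) {
    records <- stats::aggregate(cq ~ sample + gene + phenotype, records, mean)
    records$replicate <- 1L
  }

  refs <- records[records$gene == referenceGene, ]
  targets <- records[records$gene != referenceGene, ]
  if (!nrow(refs))
    stop("no records found for reference gene '", referenceGene, "'")

  refCq <- tapply(refs$cq, paste(refs$sample, refs$replicate), mean)
  key <- paste(targets$sample, targets$replicate)
  missing <- setdiff(unique(key), names(refCq))
  if (length(missing))
    stop("missing reference-gene Cq for sample(s): ",
         paste(sub(" .*", "", missing), collapse = ", "))

  out <- data.frame(sample = targets$sample, gene = targets$gene,
                    phenotype = targets$phenotype,
                    replicate = targets$replicate,
                    delta_cq = targets$cq - unname(refCq[key]),
                    stringsAsFactors = FALSE)
  out$delta_delta_cq <- NA_real_
  for (g in unique(out$gene)) {
    sel <- out$gene == g
    cal <- sel & out$phenotype == calibratorPhenotype
    if (!any(cal))
      stop("calibrator phenotype '", calibratorPhenotype,
           "' has no records for gene '", g, "'")
    out$delta_delta_cq[sel] <- out$delta_cq[sel] - mean(out$delta_cq[cal])
  }
  out$rq <- 2^(-out$delta_delta_cq)
  out
}

#' Per-group fold-change summary
#'
#' @param fc data.frame as returned by [foldChange()].
#' @return data.frame \code{gene}, \code{phenotype}, \code{mean_rq},
#'   \code{sd_rq}, \code{n}.
#' @export
foldChangeSummary <- function(fc) {
  agg <- stats::aggregate(rq ~ gene + phenotype, fc,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  data.frame(gene = agg$gene, phenotype = agg$phenotype,
             mean_rq = agg$rq[, "mean"], sd_rq = agg$rq[, "sd"],
             n = as.integer(agg$rq[, "n"]), stringsAsFactors = FALSE)
}

#' Primer efficiency from a standard dilution curve
#'
#' Least-squares fit of Cq against log10 template input over a serial
#' dilution; amplification efficiency is
#' \eqn{E = (10^{-1/slope} - 1) \times 100} percent, so a slope of
#' \eqn{-1/\log_{10} 2 \approx -3.3219} corresponds to perfect doubling
#' (100\%). Curves with a non-negative slope are flagged invalid and carry
#' no efficiency.
#'
#' @param curve data.frame with columns \code{log10_input} and \code{cq}
#'   (>= 3 points, >= 3 distinct dilutions); an optional \code{gene} column
#'   is carried through.
#' @return list of class \code{"StandardCurve"} with \code{slope},
#'   \code{intercept}, \code{rSquared}, \code{efficiencyPct} (NA when
#'   invalid), \code{valid}, and the input points.
#' @examples
#' sc <- standardCurveEfficiency(
#'   data.frame(log10_input = 0:2, cq = c(30, 26.6781, 23.3562)))
#' sc$efficiencyPct   # ~100
#' @export
standardCurveEfficiency <- function(curve) {
  curve <- as.data.frame(curve)
  stopifnot(all(c("log10_input", "cq") %in% names(curve)))
  if (nrow(curve) < 3L || length(unique(curve$log10_input)) < 3L)
    stop("standard curve needs >= 3 distinct dilution points")
  fit <- stats::lm(cq ~ log10_input, data = curve)
  slope <- unname(stats::coef(fit)[2L])
  valid <- is.finite(slope) && slope < 0
  ssTot <- sum((curve$cq - mean(curve$cq))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else NA_real_
  structure(list(
    gene = if ("gene" %in% names(curve)) curve$gene[1L] else NA_character_,
    slope = slope, intercept = unname(stats::coef(fit)[1L]),
    rSquared = r2,
    efficiencyPct = if (valid) (10^(-1 / slope) - 1) * 100 else NA_real_,
    valid = valid, points = curve),
    class = "StandardCurve")
}

#' @export
print.StandardCurve <- function(x, ...) {
  cat(sprintf("StandardCurve%s: slope = %.4f cycles/log10, R^2 = %.4f\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              x$slope, x$rSquared))
  if (x$valid)
    cat(sprintf("  efficiency = %.1f%%\n", x$efficiencyPct))
  else
    cat("  invalid curve (non-negative slope); efficiency not reported\n")
  invisible(x)
}
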
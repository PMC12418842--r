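markerVocab <- c("CD86", "CD64", "CD206", "CD11b")
phenotypeVocab <- c("THP-1", "M0", "M1", "M2")

# All pairwise comparisons of `value` between phenotype groups, per feature
# column; groups with < 2 replicates are dropped with a warning.
pairwiseByGroup <- function(df, featureCol, valueCol, varianceModel) {
  out <- NULL
  for (feat in unique(df[[featureCol]])) {
    sub <- df[df[[featureCol]] == feat, ]
    counts <- table(sub$phenotype)
    small <- names(counts)[counts < 2L]
    if (length(small)) {
      warning("excluding group(s) with a single replicate for ", feat, ": ",
              paste(small, collapse = ", "))
      sub <- sub[!sub$phenotype %in% small, ]
    }
    u <- unique(sub$phenotype)
    groups <- c(intersect(phenotypeVocab, u), setdiff(u, phenotypeVocab))
    if (length(groups) < 2L) next
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      cmp <- compareGroups(
        groupStatsFrom(sub, groups[i], valueCol),
        groupStatsFrom(sub, groups[j], valueCol),
        varianceModel = varianceModel)
      row <- comparisonTable(cmp)
      row <- cbind(data.frame(feature = feat, stringsAsFactors = FALSE), row)
      out <- rbind(out, row)
    }
  }
  out
}

groupStatsFrom <- function(df, phen, valueCol) {
  v <- df[[valueCol]][df$phenotype == phen]
  groupStats(phen, length(v), mean(v), stats::sd(v))
}

#' Surface-marker MFI profile across phenotypes
#'
#' Summarizes a per-replicate MFI table by marker and phenotype, runs all
#' pairwise two-group comparisons per marker through [compareGroups()], and
#' derives qualitative elevation calls: a marker is called elevated in a
#' phenotype when that phenotype's mean exceeds its comparator's and the
#' comparison is significant at \code{alpha}. The comparator is the resting
#' M0 state for M1/M2 (and THP-1 monocytes for M0 itself, capturing
#' differentiation markers such as CD11b).
#'
#' @param records data.frame with columns \code{sample}, \code{marker},
#'   \code{phenotype}, \code{replicate}, \code{mfi}; labels must come from
#'   the CD86/CD64/CD206/CD11b and THP-1/M0/M1/M2 vocabularies.
#' @param alpha significance level for elevation calls (default 0.05).
#' @param varianceModel passed to [compareGroups()]; default
#'   \code{"pooled"}.
#' @return list of class \code{"MarkerProfile"}: \code{summary} (n, mean,
#'   sd per marker x phenotype), \code{comparisons} (all pairwise
#'   [comparisonTable()] rows plus a \code{call} column), and \code{calls}
#'   (marker, phenotype, comparator rows for each elevation).
#' @export
markerProfile <- function(records, alpha = 0.05,
                          varianceModel = c("pooled", "auto", "welch")) {
  varianceModel <- match.arg(varianceModel)
  records <- as.data.frame(records)
  stopifnot(all(c("sample", "marker", "phenotype", "replicate", "mfi") %in%
                  names(records)))
  badM <- setdiff(unique(records$marker), markerVocab)
  badP <- setdiff(unique(records$phenotype), phenotypeVocab)
  if (length(badM)) stop("unknown marker label(s): ",
                         paste(badM, collapse = ", "))
  if (length(badP)) stop("unknown phenotype label(s): ",
                         paste(badP, collapse = ", "))

  agg <- stats::aggregate(mfi ~ marker + phenotype, records,
                          function(v) c(n = length(v), mean = mean(v),
                                        sd = stats::sd(v)))
  summary <- data.frame(marker = agg$marker, phenotype = agg$phenotype,
                        n = as.integer(agg$mfi[, "n"]),
                        mean = agg$mfi[, "mean"], sd = agg$mfi[, "sd"],
                        stringsAsFactors = FALSE)

  comparisons <- pairwiseByGroup(records, "marker", "mfi", varianceModel)
  names(comparisons)[names(comparisons) == "feature"] <- "marker"
  comparisons$call <- ifelse(
    comparisons$p < alpha,
    ifelse(comparisons$mean_diff > 0,
           paste("elevated in", comparisons$group_b),
           paste("elevated in", comparisons$group_a)),
    "ns")

  calls <- elevationCalls(comparisons, "marker", alpha)
  structure(list(summary = summary, comparisons = comparisons,
                 calls = calls, alpha = alpha),
            class = "MarkerProfile")
}

# Elevation versus the resting comparator: M0 for M1/M2, THP-1 for M0.
elevationCalls <- function(comparisons, featureCol, alpha) {
  calls <- NULL
  for (i in seq_len(nrow(comparisons))) {
    r <- comparisons[i, ]
    pair <- c(r$group_a, r$group_b)
    comparator <- if (setequal(pair, c("THP-1", "M0"))) "THP-1" else "M0"
    if (!comparator %in% pair) next
    other <- setdiff(pair, comparator)
    higherMean <- if (other == r$group_b) r$mean_diff > 0 else r$mean_diff < 0
    if (r$p < alpha && higherMean)
      calls <- rbind(calls, data.frame(feature = r[[featureCol]],
                                       phenotype = other,
                                       comparator = comparator,
                                       p = r$p,
                                       stringsAsFactors = FALSE))
  }
  if (is.null(calls))
    calls <- data.frame(feature = character(), phenotype = character(),
                        comparator = character(), p = numeric(),
                        stringsAsFactors = FALSE)
  names(calls)[1L] <- featureCol
  calls
}

#' @export
print.MarkerProfile <- function(x, ...) {
  cat("MarkerProfile (alpha =", x$alpha, ")\n")
  if (nrow(x$calls)) {
    for (i in seq_len(nrow(x$calls)))
      cat(sprintf("  %s elevated in %s (vs %s, p = %.3g)\n",
                  x$calls$marker[i], x$calls$phenotype[i],
                  x$calls$comparator[i], x$calls$p[i]))
  } else cat("  no elevation calls\n")
  invisible(x)
}

#' Cytokine expression profile across phenotypes
#'
#' The expression-layer analogue of [markerProfile()]: per-gene pairwise
#' comparisons of RQ values between phenotypes with elevation calls against
#' the M0 comparator, plus the full pairwise table (so M1-vs-M2 contrasts,
#' e.g. IL-10, are available directly).
#'
#' @param rqTable data.frame with columns \code{gene}, \code{phenotype},
#'   \code{value} (RQ units) — e.g. from [simExpressionTable()] or the
#'   \code{rq} column of [foldChange()] renamed.
#' @param alpha significance level (default 0.05).
#' @param varianceModel passed to [compareGroups()]; default
#'   \code{"pooled"}.
#' @return list of class \code{"ExpressionProfile"} with \code{comparisons}
#'   and \code{calls} as in [markerProfile()].
#' @export
expressionProfile <- function(rqTable, alpha = 0.05,
                              varianceModel = c("pooled", "auto", "welch")) {
  varianceModel <- match.arg(varianceModel)
  rqTable <- as.data.frame(rqTable)
  if (!"value" %in% names(rqTable) && "rq" %in% names(rqTable))
    rqTable$value <- rqTable$rq
  stopifnot(all(c("gene", "phenotype", "value") %in% names(rqTable)))
  comparisons <- pairwiseByGroup(rqTable, "gene", "value", varianceModel)
  names(comparisons)[names(comparisons) == "feature"] <- "gene"
  comparisons$call <- ifelse(
    comparisons$p < alpha,
    ifelse(comparisons$mean_diff > 0,
           paste("elevated in", comparisons$group_b),
           paste("elevated in", comparisons$group_a)),
    "ns")
  calls <- elevationCalls(comparisons, "gene", alpha)
  structure(list(comparisons = comparisons, calls = calls, alpha = alpha),
            class = "ExpressionProfile")
}
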
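#' Summary statistics for one group
#'
#' Comparisons accept either raw measurement vectors or (n, mean, sd)
#' summaries, so printed summary tables can be analysed without raw data.
#'
#' @param label group label.
#' @param n sample size (>= 2).
#' @param mean,sd group mean and standard deviation (sd >= 0).
#' @return list of class \code{"GroupStats"}.
#' @export
groupStats <- function(label, n, mean, sd) {
  n <- as.integer(n)
  if (n < 2L) stop("group '", label, "': n must be >= 2")
  if (!is.finite(sd) || sd < 0) stop("group '", label, "': sd must be >= 0")
  structure(list(label = as.character(label), n = n, mean = mean, sd = sd),
            class = "GroupStats")
}

asGroupStats <- function(x, label) {
  if (inherits(x, "GroupStats")) return(x)
  if (is.numeric(x)) {
    if (length(x) < 2L) stop("group '", label, "': need >= 2 raw values")
    return(groupStats(label, length(x), mean(x), stats::sd(x)))
  }
  stop("group must be a numeric vector or groupStats()")
}

#' Eta-squared / R-squared effect size from t and df
#'
#' The fraction of variance explained by group membership in a two-group
#' comparison, \eqn{R^2 = t^2 / (t^2 + df)} (the point-biserial identity).
#' Zero iff t = 0 and monotone increasing in |t|.
#'
#' @param tStat t statistic.
#' @param df degrees of freedom, > 0.
#' @return numeric in [0, 1).
#' @examples
#' effectSizeR2(20.37, 4)   # 0.990...
#' effectSizeR2(5.48, 16)   # 0.652...
#' @export
effectSizeR2 <- function(tStat, df) {
  if (any(df <= 0)) stop("df must be positive")
  tStat^2 / (tStat^2 + df)
}

#' F test for equality of two variances
#'
#' Variance-ratio test with F = larger variance / smaller variance (so
#' F >= 1), numerator df taken from the larger-variance group, and a
#' two-tailed p value (doubled upper tail, capped at 1). Symmetric in the
#' group order.
#'
#' @param a,b numeric vectors of raw values, or [groupStats()] summaries.
#' @return list with \code{fStat}, \code{df1}, \code{df2}, \code{p}.
#' @export
varianceFTest <- function(a, b) {
  a <- asGroupStats(a, "a"); b <- asGroupStats(b, "b")
  if (a$sd <= 0 || b$sd <= 0)
    stop("degenerate data: both groups need positive variance for the F test")
  if (a$sd^2 >= b$sd^2) {
    fStat <- a$sd^2 / b$sd^2; df1 <- a$n - 1L; df2 <- b$n - 1L
  } else {
    fStat <- b$sd^2 / a$sd^2; df1 <- b$n - 1L; df2 <- a$n - 1L
  }
  p <- min(1, 2 * stats::pf(fStat, df1, df2, lower.tail = FALSE))
  list(fStat = fStat, df1 = df1, df2 = df2, p = p)
}

#' Unpaired two-tailed comparison of two groups
#'
#' The engine behind every pairwise contrast in the package: difference of
#' means (b minus a) with its standard error, t statistic, two-tailed p from
#' Student's t, 95\% confidence interval, eta-squared effect size
#' \eqn{t^2/(t^2+df)}, and the variance-ratio F test.
#'
#' Variance models: \code{"pooled"} uses the pooled SD with
#' \eqn{df = n_a + n_b - 2}; \code{"welch"} uses the Welch--Satterthwaite
#' SEM and fractional df; \code{"auto"} (default) applies the pooled model
#' when the F test does not reject equal variances at the 5\% level and
#' Welch otherwise.
#'
#' @param a,b numeric vectors of raw values, or [groupStats()] summaries
#'   (order defines the sign of the difference: b - a).
#' @param varianceModel \code{"auto"}, \code{"pooled"} or \code{"welch"}.
#' @param confLevel confidence level for the interval (default 0.95).
#' @return A [ComparisonResult-class].
#' @examples
#' m0 <- groupStats("M0", 9, 1, 7.78)
#' m1 <- groupStats("M1", 9, 371.9, 136.4)
#' compareGroups(m0, m1, "pooled")
#' @export
compareGroups <- function(a, b, varianceModel = c("auto", "pooled", "welch"),
                          confLevel = 0.95) {
  varianceModel <- match.arg(varianceModel)
  a <- asGroupStats(a, "a"); b <- asGroupStats(b, "b")
  if (a$sd == 0 && b$sd == 0)
    stop("degenerate data: both group SDs are zero")

  if (a$sd > 0 && b$sd > 0) {
    ft <- varianceFTest(a, b)
  } else {
    ft <- list(fStat = Inf, df1 = NA_real_, df2 = NA_real_, p = 0)
  }
  model <- switch(varianceModel,
    pooled = "pooled", welch = "welch",
    auto = if (ft$p >= 0.05) "pooled" else "welch")

  meanDiff <- b$mean - a$mean
  if (model == "pooled") {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    sem <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    sem <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  tStat <- meanDiff / sem
  p <- 2 * stats::pt(abs(tStat), df, lower.tail = FALSE)
  tCrit <- stats::qt(1 - (1 - confLevel) / 2, df)
  new("ComparisonResult",
      groupA = a$label, groupB = b$label,
      meanDiff = meanDiff, semDiff = sem,
      tStat = tStat, df = df, pTwoTailed = p,
      ciLow = meanDiff - tCrit * sem, ciHigh = meanDiff + tCrit * sem,
      rSquared = effectSizeR2(tStat, df),
      fStat = ft$fStat, fDf1 = as.numeric(ft$df1), fDf2 = as.numeric(ft$df2),
      fP = ft$p,
      varianceModel = model)
}

#' Flatten a ComparisonResult to a one-row data.frame
#'
#' @param x a [ComparisonResult-class].
#' @return data.frame with columns \code{group_a}, \code{group_b},
#'   \code{mean_diff}, \code{sem}, \code{t}, \code{df}, \code{p},
#'   \code{ci_low}, \code{ci_high}, \code{r_squared}, \code{f}, \code{f_p},
#'   \code{model}.
#' @export
comparisonTable <- function(x) {
  if (is(x, "ComparisonResult")) x <- list(x)
  do.call(rbind, lapply(x, function(r)
    data.frame(group_a = r@groupA, group_b = r@groupB,
               mean_diff = r@meanDiff, sem = r@semDiff, t = r@tStat,
               df = r@df, p = r@pTwoTailed, ci_low = r@ciLow,
               ci_high = r@ciHigh, r_squared = r@rSquared, f = r@fStat,
               f_p = r@fP, model = r@varianceModel,
               stringsAsFactors = FALSE)))
}
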
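#' PCA projection of a feature matrix
#'
#' Principal-component projection of per-sample features (default use case:
#' IL-1B/IL-6/IL-10 RQ values), centered and, by default, standardized.
#' Component signs are fixed deterministically by making each component's
#' largest-magnitude loading positive.
#'
#' @param features numeric matrix or data.frame of features (rows =
#'   samples); non-numeric columns (e.g. \code{sample}, \code{phenotype})
#'   are carried through to the output scores.
#' @param nComponents number of components to keep (default: all).
#' @param standardize scale features to unit variance (default TRUE); a
#'   constant feature is an error in this mode.
#' @return list with \code{scores} (data.frame of projected coordinates
#'   plus any label columns), \code{loadings}, \code{varianceExplained}
#'   (fractions, non-increasing), \code{center}, \code{scale}.
#' @export
pcaProject <- function(features, nComponents = NULL, standardize = TRUE) {
  labs <- NULL
  if (is.data.frame(features)) {
    numCols <- vapply(features, is.numeric, logical(1))
    labs <- features[!numCols]
    features <- as.matrix(features[numCols])
  }
  stopifnot(is.numeric(features), nrow(features) >= 2L)
  if (anyNA(features)) stop("feature matrix contains missing values")
  if (is.null(nComponents)) nComponents <- ncol(features)
  stopifnot(nComponents >= 1L, nComponents <= ncol(features))
  if (standardize) {
    sds <- apply(features, 2L, stats::sd)
    if (any(sds == 0))
      stop("constant feature(s) cannot be standardized: ",
           paste(colnames(features)[sds == 0], collapse = ", "))
  }
  fit <- stats::prcomp(features, center = TRUE, scale. = standardize)
  # deterministic sign: largest |loading| positive per component
  for (k in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[i, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  varFrac <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as.data.frame(fit$x[, seq_len(nComponents), drop = FALSE])
  if (!is.null(labs) && ncol(labs)) scores <- cbind(labs, scores)
  list(scores = scores,
       loadings = fit$rotation[, seq_len(nComponents), drop = FALSE],
       varianceExplained = varFrac,
       center = fit$center,
       scale = if (standardize) fit$scale else NULL)
}

#' Training accuracy of a multinomial logistic classifier
#'
#' Fits a multinomial logistic regression on standardized features with a
#' small fixed L2 penalty (weight decay), which keeps the fit convergent
#' even on perfectly separable classes, and evaluates accuracy on the
#' training set (no held-out split). Optionally reports leave-one-out
#' cross-validated accuracy instead.
#'
#' @param features data.frame with a \code{phenotype} column (>= 2 classes,
#'   >= 2 samples each) and numeric feature columns.
#' @param seed integer seed (the fit itself is deterministic; the seed
#'   guards any future stochastic solver options).
#' @param decay L2 penalty passed to the optimizer (default 1e-3).
#' @param crossValidate report leave-one-out accuracy instead of training
#'   accuracy (default FALSE).
#' @return list of class \code{"ClassificationReport"}:
#'   \code{trainingAccuracy} (percent), \code{confusion} (true x predicted
#'   counts), \code{converged}, \code{pcVarianceExplained} (from
#'   [pcaProject()] on the same features).
#' @export
logisticAccuracy <- function(features, seed = 1L, decay = 1e-3,
                             crossValidate = FALSE) {
  stopifnot(is.data.frame(features), "phenotype" %in% names(features))
  y <- factor(features$phenotype)
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  if (any(table(y) < 2L)) stop("need >= 2 samples per class")
  x <- as.matrix(features[vapply(features, is.numeric, logical(1))])
  if (anyNA(x)) stop("feature matrix contains missing values")
  xs <- scale(x)
  if (any(!is.finite(xs)))
    stop("constant feature(s) cannot be standardized")

  fitOne <- function(xtr, ytr) {
    df <- data.frame(y = ytr, xtr)
    withSeed(seed,
      nnet::multinom(y ~ ., data = df, decay = decay, maxit = 500L,
                     trace = FALSE))
  }

  if (crossValidate) {
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    conv <- TRUE
    for (i in seq_along(y)) {
      fit <- fitOne(xs[-i, , drop = FALSE], y[-i])
      conv <- conv && fit$convergence == 0
      pred[i] <- stats::predict(fit,
        newdata = as.data.frame(xs[i, , drop = FALSE]))
    }
  } else {
    fit <- fitOne(xs, y)
    conv <- fit$convergence == 0
    pred <- stats::predict(fit, newdata = as.data.frame(xs))
  }
  if (!conv)
    warning("optimizer did not fully converge; accuracy reported on the ",
            "partial fit")
  confusion <- table(true = y, predicted = factor(pred, levels = levels(y)))
  acc <- 100 * sum(diag(confusion)) / sum(confusion)
  predictions <- data.frame(
    sample = if ("sample" %in% names(features)) features$sample
             else sprintf("s%d", seq_along(y)),
    true = as.character(y), predicted = as.character(pred),
    stringsAsFactors = FALSE)
  structure(list(trainingAccuracy = acc, confusion = confusion,
                 predictions = predictions,
                 converged = conv, crossValidated = crossValidate,
                 pcVarianceExplained =
                   pcaProject(as.data.frame(x))$varianceExplained),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf("ClassificationReport: %s accuracy = %.1f%%%s\n",
              if (x$crossValidated) "leave-one-out" else "training",
              x$trainingAccuracy,
              if (x$converged) "" else " (not converged)"))
  print(x$confusion)
  cat("PC variance explained:",
      paste(sprintf("%.3f", x$pcVarianceExplained), collapse = ", "), "\n")
  invisible(x)
}

#' Phenotype calls from reported-GP thresholds
#'
#' Assigns M0/M1/M2 by two increasing cut-points on the x100 reported GP
#' scale: below the lower threshold is M0, between the thresholds M1, above
#' the upper M2. A value exactly at a threshold goes to the higher class.
#' Default thresholds are the midpoints of the study-scale group means
#' (56.98, 63.56, 69.99), i.e. 60.27 and 66.78.
#'
#' @param gpReported numeric vector of reported GP values, or a summary
#'   data.frame with a \code{mean_gp_reported} column (e.g. from
#'   [summarizeROIs()]).
#' @param thresholds strictly increasing numeric(2) on the reported scale.
#' @return character vector of phenotype calls ("M0"/"M1"/"M2"); for
#'   data.frame input, the input with a \code{gp_call} column appended.
#' @examples
#' classifyByGP(c(56.98, 63.56, 69.99))   # "M0" "M1" "M2"
#' @export
classifyByGP <- function(gpReported, thresholds = c(60.27, 66.78)) {
  if (length(thresholds) != 2L || !(thresholds[2L] > thresholds[1L]))
    stop("thresholds must be two strictly increasing cut-points")
  df <- NULL
  if (is.data.frame(gpReported)) {
    df <- gpReported
    stopifnot("mean_gp_reported" %in% names(df))
    gpReported <- df$mean_gp_reported
  }
  calls <- ifelse(gpReported < thresholds[1L], "M0",
                  ifelse(gpReported < thresholds[2L], "M1", "M2"))
  if (is.null(df)) calls else cbind(df, gp_call = calls)
}
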
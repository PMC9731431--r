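## Regression-quality metrics and the site-leakage audit.

#' Normative regression metrics: RHO, SMSE, MSLL
#'
#' \itemize{
#'   \item RHO: Pearson correlation between observed and predicted values.
#'   \item SMSE: mean squared error standardized by the variance of the test
#'     targets (1 is the level of the trivial mean predictor).
#'   \item MSLL: mean standardized log-loss — the negative Gaussian
#'     log-density of each test observation under (mu, sigma) minus the same
#'     under the trivial predictor (training mean and variance of the
#'     region); negative is better, 0 is the trivial model. Unlike RHO/SMSE
#'     it also penalizes a miscalibrated predictive variance.
#' }
#' The trivial predictor uses the global (cross-site) training moments.
#'
#' @param yTrue observed test values.
#' @param muPred,sigmaPred predicted normative mean and sd.
#' @param trainMean,trainVar training-set mean and variance of the region.
#' @return named numeric vector \code{c(RHO, SMSE, MSLL)}.
#' @export
normMetrics <- function(yTrue, muPred, sigmaPred, trainMean, trainVar) {
    stopifnot(length(yTrue) == length(muPred),
              length(yTrue) == length(sigmaPred))
    vTest <- stats::var(yTrue)
    if (!is.finite(vTest) || vTest <= 0)
        stop("normMetrics: zero test variance; SMSE undefined")
    rho <- stats::cor(yTrue, muPred)
    smse <- mean((yTrue - muPred)^2) / vTest
    nll <- 0.5 * log(2 * pi * sigmaPred^2) +
        (yTrue - muPred)^2 / (2 * sigmaPred^2)
    nll0 <- 0.5 * log(2 * pi * trainVar) +
        (yTrue - trainMean)^2 / (2 * trainVar)
    c(RHO = rho, SMSE = smse, MSLL = mean(nll - nll0))
}

#' Per-region metrics table for a fitted strategy
#'
#' Convenience wrapper: fits nothing, just scores a list of per-region models
#' on a test split and tabulates \code{\link{normMetrics}}.
#'
#' @param models named list of fitted models (one per region).
#' @param testData test \code{\link{NormativeDataset}}.
#' @param trainData training \code{\link{NormativeDataset}} (for the trivial
#'   predictor's moments).
#' @param ... passed to \code{\link{predictNorm}} methods.
#' @return data.frame with columns region, RHO, SMSE, MSLL.
#' @export
evaluateModels <- function(models, testData, trainData, ...) {
    rows <- lapply(names(models), function(rg) {
        pr <- predictNorm(models[[rg]], ages(testData), sexes(testData),
                          sites(testData), ...)
        yTr <- as.numeric(regionValues(trainData, rg))
        m <- normMetrics(as.numeric(regionValues(testData, rg)),
                         pr$mu, pr$sigma, mean(yTr), stats::var(yTr))
        data.frame(region = rg, RHO = m["RHO"], SMSE = m["SMSE"],
                   MSLL = m["MSLL"], row.names = NULL)
    })
    do.call(rbind, rows)
}

#' Site-leakage audit of z-scores
#'
#' Quantifies residual site information in deviation scores: for every pair
#' of sites, a linear support vector machine (C = 1) is trained to classify
#' the site label from the subjects x regions z-score matrix under 5-fold
#' stratified cross-validation, and the balanced accuracy is recorded.
#' Chance level (0.5) means the scores are site-agnostic; z-scores from a
#' model that ignores site effects classify well above chance.
#'
#' @param zMatrix subjects x regions matrix of z-scores.
#' @param siteLabels site label per subject (>= 2 sites).
#' @param nFolds folds for stratified CV (default 5).
#' @param seed integer seed for fold assignment.
#' @return a list with \code{pairs} (data.frame siteA, siteB,
#'   balancedAccuracy) and \code{meanAccuracy}.
#' @export
siteLeakageAudit <- function(zMatrix, siteLabels, nFolds = 5L, seed = 1L) {
    zMatrix <- as.matrix(zMatrix)
    stopifnot(nrow(zMatrix) == length(siteLabels))
    siteLevels <- sort(unique(siteLabels))
    if (length(siteLevels) < 2L)
        stop("siteLeakageAudit: need at least two sites")
    counts <- table(siteLabels)
    pairs <- utils::combn(siteLevels, 2)
    out <- data.frame(siteA = character(0), siteB = character(0),
                      balancedAccuracy = numeric(0))
    withr::with_seed(as.integer(seed), {
        for (k in seq_len(ncol(pairs))) {
            a <- pairs[1, k]; b <- pairs[2, k]
            if (counts[[a]] < nFolds || counts[[b]] < nFolds) {
                warning("siteLeakageAudit: skipping pair ", a, " vs ", b,
                        " (fewer than ", nFolds, " subjects in a site)")
                next
            }
            sel <- siteLabels %in% c(a, b)
            acc <- .svmCvBalancedAccuracy(zMatrix[sel, , drop = FALSE],
                                          factor(siteLabels[sel]), nFolds)
            out <- rbind(out, data.frame(siteA = a, siteB = b,
                                         balancedAccuracy = acc))
        }
    })
    if (!nrow(out))
        stop("siteLeakageAudit: no site pair had enough subjects")
    list(pairs = out, meanAccuracy = mean(out$balancedAccuracy))
}

## stratified k-fold CV, linear SVM (C = 1), mean per-class recall
.svmCvBalancedAccuracy <- function(x, y, nFolds) {
    folds <- integer(length(y))
    for (lv in levels(y)) {
        idx <- which(y == lv)
        folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
    for (f in seq_len(nFolds)) {
        test <- folds == f
        fit <- e1071::svm(x[!test, , drop = FALSE], y[!test],
                          kernel = "linear", cost = 1, scale = FALSE)
        pred[test] <- stats::predict(fit, x[test, , drop = FALSE])
    }
    recalls <- vapply(levels(y), function(lv)
        mean(pred[y == lv] == lv), 0)
    mean(recalls)
}
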
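## Abnormal-probability scoring and the unsupervised patient-vs-healthy
## detection harness (region-wise AUCs, permutation significance,
## Benjamini-Hochberg FDR across regions, and the stability rule across
## repeated experimental runs).

#' Abnormal probability index
#'
#' Maps a deviation z-score to the two-sided tail-symmetric probability mass
#' within \eqn{|z|}: \eqn{P_{abn}(z) = 2\Phi(|z|) - 1}. It is 0 at z = 0,
#' symmetric in the sign of z, monotone in \eqn{|z|} and approaches 1 as
#' \eqn{|z|} grows.
#'
#' @param z finite numeric vector of z-scores.
#' @return numeric vector in [0, 1).
#' @export
abnormalProbability <- function(z) {
    if (any(!is.finite(z)))
        stop("abnormalProbability: z must be finite")
    2 * stats::pnorm(abs(z)) - 1
}

#' Rank-based AUC of abnormality scores for patient detection
#'
#' Standard Mann-Whitney AUC of the scores for patients versus healthy,
#' with midranks for ties.
#'
#' @param scores numeric vector (higher = more abnormal).
#' @param labels vector with exactly two classes; \code{positive} marks the
#'   patient class.
#' @param positive the patient label (default \code{"patient"}).
#' @return AUC in [0, 1].
#' @export
detectionAUC <- function(scores, labels, positive = "patient") {
    pos <- labels == positive
    nPos <- sum(pos); nNeg <- sum(!pos)
    if (nPos == 0L || nNeg == 0L)
        stop("detectionAUC: both classes must be present")
    r <- rank(scores)                       # midranks
    (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Region-wise significance and stability of detection AUCs
#'
#' For each experimental run and region, a permutation test shuffles the
#' diagnosis labels \code{nPermutations} times and recomputes the AUC; the
#' two-sided permutation p-value on \eqn{AUC - 0.5} is corrected across
#' regions by Benjamini-Hochberg at level \code{fdrQ}. A region is reported
#' as "significant and stable" iff it passes the FDR correction in at least
#' \code{stabilityK} of the runs.
#'
#' @param scoreRuns list (one element per run) of subjects x regions score
#'   matrices (abnormal probabilities or |z|).
#' @param labelRuns list of label vectors aligned with the rows of each
#'   score matrix.
#' @param nPermutations permutations per region (values below 100 warn:
#'   unstable p resolution).
#' @param stabilityK minimum number of runs a region must pass in.
#' @param fdrQ FDR level (default 0.05).
#' @param positive patient label.
#' @param seed integer seed for the permutations.
#' @return a \code{data.frame} with one row per region: mean AUC across
#'   runs, number of runs passed, and \code{reported}.
#' @export
significanceAndStability <- function(scoreRuns, labelRuns,
                                     nPermutations = 1000L,
                                     stabilityK = 9L, fdrQ = 0.05,
                                     positive = "patient", seed = 1L) {
    stopifnot(length(scoreRuns) == length(labelRuns), length(scoreRuns) >= 1L)
    if (nPermutations < 100L)
        warning("significanceAndStability: fewer than 100 permutations ",
                "gives unstable p-value resolution")
    nRuns <- length(scoreRuns)
    regions <- colnames(scoreRuns[[1]])
    if (is.null(regions))
        regions <- sprintf("region%02d", seq_len(ncol(scoreRuns[[1]])))
    passMat <- matrix(FALSE, nRuns, length(regions))
    aucMat <- matrix(NA_real_, nRuns, length(regions))
    withr::with_seed(as.integer(seed), {
        for (r in seq_len(nRuns)) {
            scores <- as.matrix(scoreRuns[[r]])
            labels <- labelRuns[[r]]
            obs <- apply(scores, 2, detectionAUC, labels = labels,
                         positive = positive)
            aucMat[r, ] <- obs
            exceed <- rep(0L, length(obs))
            for (b in seq_len(nPermutations)) {
                lab <- sample(labels)
                permAuc <- apply(scores, 2, detectionAUC, labels = lab,
                                 positive = positive)
                exceed <- exceed +
                    (abs(permAuc - 0.5) >= abs(obs - 0.5))
            }
            p <- (1 + exceed) / (1 + nPermutations)
            passMat[r, ] <- stats::p.adjust(p, "BH") <= fdrQ
        }
    })
    runsPassed <- colSums(passMat)
    data.frame(region = regions,
               meanAUC = colMeans(aucMat),
               runsPassed = runsPassed,
               reported = runsPassed >= stabilityK,
               stringsAsFactors = FALSE)
}

#' Write a detection report as TSV
#' @param report output of \code{\link{significanceAndStability}}.
#' @param path file path.
#' @export
writeDetectionReport <- function(report, path) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
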
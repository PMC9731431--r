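#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

## ---------------------------------------------------------------------------
## NormativeDataset
## ---------------------------------------------------------------------------

#' Multi-site normative dataset
#'
#' A \code{SummarizedExperiment} holding one multi-region phenotype matrix
#' (regions in rows, subjects in columns, assay \code{"phenotype"}) together
#' with per-subject covariates in \code{colData}: \code{age} (years),
#' \code{sex}, \code{site} and \code{group} (\code{"healthy"} or
#' \code{"patient"}). Synthetic cohorts additionally carry the ground-truth
#' normative mean and noise standard deviation as assays \code{"muTrue"} and
#' \code{"sigmaTrue"}.
#'
#' @export
setClass("NormativeDataset", contains = "SummarizedExperiment")

setValidity("NormativeDataset", function(object) {
    msgs <- character()
    cd <- colData(object)
    for (col in c("age", "sex", "site", "group"))
        if (!col %in% colnames(cd))
            msgs <- c(msgs, sprintf("colData must contain a '%s' column", col))
    if (!"phenotype" %in% assayNames(object))
        msgs <- c(msgs, "assay 'phenotype' is required")
    if ("age" %in% colnames(cd)) {
        if (!is.numeric(cd$age))
            msgs <- c(msgs, "'age' must be numeric")
        else if (length(cd$age) && any(!is.finite(cd$age)))
            msgs <- c(msgs, "'age' must be finite")
    }
    if ("group" %in% colnames(cd) &&
        length(cd$group) && !all(cd$group %in% c("healthy", "patient")))
        msgs <- c(msgs, "'group' entries must be 'healthy' or 'patient'")
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## BasisConfig
## ---------------------------------------------------------------------------

#' Mean-function basis configuration
#'
#' Describes how age is expanded into a design matrix: \code{"linear"}
#' (\code{[1, age]}), \code{"polynomial3"} (\code{[1, age, age^2, age^3]}) or
#' \code{"bspline3"} (a cubic B-spline basis with \code{nKnots} evenly spaced
#' interior knots over the training age range; the full basis forms a
#' partition of unity, so no separate intercept column is needed).
#' Test-time ages outside the training range are handled per
#' \code{extrapolation}: \code{"clamp"} (evaluate at the nearest boundary;
#' conservative for centile charts) or \code{"linear"} (first-order extension
#' beyond the boundary).
#'
#' @slot kind one of \code{"linear"}, \code{"polynomial3"}, \code{"bspline3"}.
#' @slot nKnots integer, number of interior knots for \code{"bspline3"}.
#' @slot extrapolation \code{"clamp"} or \code{"linear"}.
#' @export
setClass("BasisConfig",
    representation(kind = "character", nKnots = "integer",
                   extrapolation = "character"),
    prototype(kind = "linear", nKnots = 5L, extrapolation = "clamp"))

setValidity("BasisConfig", function(object) {
    msgs <- character()
    if (!object@kind %in% c("linear", "polynomial3", "bspline3"))
        msgs <- c(msgs, "kind must be 'linear', 'polynomial3' or 'bspline3'")
    if (length(object@nKnots) != 1L || is.na(object@nKnots) || object@nKnots < 1L)
        msgs <- c(msgs, "nKnots must be a positive integer")
    if (!object@extrapolation %in% c("clamp", "linear"))
        msgs <- c(msgs, "extrapolation must be 'clamp' or 'linear'")
    if (length(msgs)) msgs else TRUE
})

#' @param kind basis kind; see class description.
#' @param nKnots number of interior knots (bspline3 only).
#' @param extrapolation out-of-range rule, \code{"clamp"} or \code{"linear"}.
#' @rdname BasisConfig-class
#' @export
basisConfig <- function(kind = c("linear", "polynomial3", "bspline3"),
                        nKnots = 5L,
                        extrapolation = c("clamp", "linear")) {
    kind <- match.arg(kind)
    extrapolation <- match.arg(extrapolation)
    new("BasisConfig", kind = kind, nKnots = as.integer(nKnots),
        extrapolation = extrapolation)
}

## ---------------------------------------------------------------------------
## BatchRegistry
## ---------------------------------------------------------------------------

#' Registry of observed (site, sex) batches
#'
#' Maps each observed (site, sex) combination to a stable parameter index.
#' Only combinations present in the data are registered (lexicographic order);
#' unseen label pairs are reported by \code{batchIndex} as \code{NA}, never
#' silently added.
#'
#' @slot site character vector of site labels per batch.
#' @slot sex character vector of sex labels per batch.
#' @slot counts integer vector of per-batch sample counts.
#' @param x a \code{BatchRegistry}.
#' @param site,sex label vectors to look up.
#' @export
setClass("BatchRegistry",
    representation(site = "character", sex = "character", counts = "integer"))

setValidity("BatchRegistry", function(object) {
    msgs <- character()
    n <- length(object@site)
    if (length(object@sex) != n || length(object@counts) != n)
        msgs <- c(msgs, "site, sex and counts must have equal length")
    if (anyDuplicated(paste(object@site, object@sex, sep = "\r")))
        msgs <- c(msgs, "duplicate (site, sex) combinations")
    if (length(object@counts) && any(object@counts < 0L))
        msgs <- c(msgs, "counts must be non-negative")
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## HyperpriorSpec
## ---------------------------------------------------------------------------

#' Gaussian hyperprior specification
#'
#' For every mean-function coefficient j the prior on the across-batch mean
#' is \eqn{\mu_{\theta\mu}[j] \sim N(mMu[j], sMu[j]^2)} and on the across-batch
#' log-spread \eqn{\log \sigma_{\theta\mu}[j] \sim N(mLogsd[j], sLogsd[j]^2)};
#' the noise parameters (one coefficient in the homoscedastic case, one per
#' basis column in the heteroscedastic case) carry the analogous four entries.
#' The weakly-informative default is \eqn{N(0, 10^3)} (variance) for the means
#' and \eqn{N(0, 2.5^2)} for the log-spreads. An informative spec extracted
#' from a reference posterior additionally records the basis kind, the design
#' column standardization (centers/scales) and the training age range so that
#' adaptation reuses the reference parameterization exactly.
#'
#' @slot mMu,sMu location/scale of the hyperprior on each coefficient's mean.
#' @slot mLogsd,sLogsd location/scale of the hyperprior on each coefficient's
#'   log across-batch spread.
#' @slot mMuSigma,sMuSigma,mLogsdSigma,sLogsdSigma the same four entries for
#'   the noise coefficients.
#' @slot noiseMode \code{"homoscedastic"} or \code{"heteroscedastic"}.
#' @slot basisKind basis kind the spec was built for ("" when unconstrained).
#' @slot center,scale design-column standardization (length 0 when default).
#' @slot fitRange training age range (NA when default).
#' @export
setClass("HyperpriorSpec",
    representation(mMu = "numeric", sMu = "numeric",
                   mLogsd = "numeric", sLogsd = "numeric",
                   mMuSigma = "numeric", sMuSigma = "numeric",
                   mLogsdSigma = "numeric", sLogsdSigma = "numeric",
                   noiseMode = "character", basisKind = "character",
                   center = "numeric", scale = "numeric",
                   fitRange = "numeric"))

setValidity("HyperpriorSpec", function(object) {
    msgs <- character()
    p <- length(object@mMu)
    if (length(object@sMu) != p || length(object@mLogsd) != p ||
        length(object@sLogsd) != p)
        msgs <- c(msgs, "mean-coefficient entries must have equal length")
    q <- length(object@mMuSigma)
    if (length(object@sMuSigma) != q || length(object@mLogsdSigma) != q ||
        length(object@sLogsdSigma) != q)
        msgs <- c(msgs, "noise-coefficient entries must have equal length")
    scales <- c(object@sMu, object@sLogsd, object@sMuSigma, object@sLogsdSigma)
    if (length(scales) && any(!is.finite(scales) | scales <= 0))
        msgs <- c(msgs, "all hyperprior scales must be finite and > 0")
    if (!object@noiseMode %in% c("homoscedastic", "heteroscedastic"))
        msgs <- c(msgs, "noiseMode must be 'homoscedastic' or 'heteroscedastic'")
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## PosteriorSamples
## ---------------------------------------------------------------------------

#' Posterior draws of HBR parameters
#'
#' Draws are stored row-wise (one row per retained draw, chains concatenated;
#' the \code{chain} vector records provenance). \code{theta} is
#' draws x batches x coefficients in the standardized design space;
#' \code{logSigma} (homoscedastic) is draws x batches; \code{thetaSigma}
#' (heteroscedastic) is draws x batches x coefficients of the softplus noise
#' predictor. Hyperparameter draws are \code{muTheta}, \code{logSdTheta} and
#' the noise counterparts. \code{rhat} holds split-R-hat diagnostics for the
#' hyperparameters.
#'
#' @export
setClass("PosteriorSamples",
    representation(theta = "array", logSigma = "matrix", thetaSigma = "array",
                   muTheta = "matrix", logSdTheta = "matrix",
                   muSigma = "matrix", logSdSigma = "matrix",
                   chain = "integer", rhat = "numeric"))

setValidity("PosteriorSamples", function(object) {
    msgs <- character()
    nd <- dim(object@theta)[1]
    if (nrow(object@muTheta) != nd || nrow(object@logSdTheta) != nd)
        msgs <- c(msgs, "hyperparameter draws must align with theta draws")
    if (length(object@chain) != nd)
        msgs <- c(msgs, "chain index must have one entry per draw")
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Models
## ---------------------------------------------------------------------------

#' Virtual parent of all fitted per-region normative models
#' @export
setClass("NormativeModel",
    representation("VIRTUAL", region = "character", basis = "BasisConfig",
                   fitRange = "numeric", includeSex = "logical",
                   sexLevels = "character"))

#' Trained hierarchical Bayesian regression model
#'
#' Per-region HBR fit: basis configuration, batch registry, the hyperprior the
#' model was fitted under, posterior draws, noise mode, the training age range
#' and the internal design-column standardization.
#'
#' @export
setClass("HBRModel", contains = "NormativeModel",
    representation(registry = "BatchRegistry", hyper = "HyperpriorSpec",
                   posterior = "PosteriorSamples", noiseMode = "character",
                   center = "numeric", scale = "numeric",
                   notes = "character"))

#' Naive (complete) pooling least-squares model
#' @export
setClass("PooledModel", contains = "NormativeModel",
    representation(coef = "numeric", sigma = "numeric"))

#' Fixed-effect pooling model (site indicators as covariates)
#' @export
setClass("FixedEffectModel", contains = "NormativeModel",
    representation(coef = "numeric", sigma = "numeric",
                   siteLevels = "character"))

#' No-pooling model (independent least squares per batch)
#' @export
setClass("NoPoolingModel", contains = "NormativeModel",
    representation(registry = "BatchRegistry", coefs = "matrix",
                   sigmas = "numeric", usable = "logical"))

#' ComBat-then-pooling model
#'
#' Parametric empirical-Bayes ComBat parameters learned on the training split
#' plus a naive-pooling fit on the harmonized training data.
#' @export
setClass("CombatPooledModel", contains = "NormativeModel",
    representation(combat = "list", pooled = "PooledModel"))
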
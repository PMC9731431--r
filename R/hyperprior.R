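#' Construct a hyperprior specification
#'
#' @param mMu,sMu,mLogsd,sLogsd per-coefficient hyperprior entries for the
#'   mean function (recycled to \code{nCoef}).
#' @param mMuSigma,sMuSigma,mLogsdSigma,sLogsdSigma entries for the noise
#'   coefficients (length 1 homoscedastic, \code{nCoef} heteroscedastic).
#' @param nCoef number of mean-function coefficients.
#' @param noiseMode \code{"homoscedastic"} or \code{"heteroscedastic"}.
#' @param basisKind,center,scale,fitRange parameterization metadata recorded
#'   by \code{\link{extractInformativeHyperprior}}; leave default for a
#'   weakly-informative spec.
#' @return a \code{\link{HyperpriorSpec}}.
#' @export
hyperpriorSpec <- function(nCoef,
                           mMu = 0, sMu = sqrt(1000),
                           mLogsd = 0, sLogsd = 2.5,
                           mMuSigma = 0, sMuSigma = sqrt(1000),
                           mLogsdSigma = 0, sLogsdSigma = 2.5,
                           noiseMode = c("homoscedastic", "heteroscedastic"),
                           basisKind = "", center = numeric(0),
                           scale = numeric(0), fitRange = c(NA_real_, NA_real_)) {
    noiseMode <- match.arg(noiseMode)
    p <- as.integer(nCoef)
    q <- if (noiseMode == "homoscedastic") 1L else p
    new("HyperpriorSpec",
        mMu = rep_len(mMu, p), sMu = rep_len(sMu, p),
        mLogsd = rep_len(mLogsd, p), sLogsd = rep_len(sLogsd, p),
        mMuSigma = rep_len(mMuSigma, q), sMuSigma = rep_len(sMuSigma, q),
        mLogsdSigma = rep_len(mLogsdSigma, q),
        sLogsdSigma = rep_len(sLogsdSigma, q),
        noiseMode = noiseMode, basisKind = basisKind,
        center = center, scale = scale, fitRange = as.numeric(fitRange))
}

#' Weakly-informative default hyperprior
#'
#' The development-phase setting: hyper-means \eqn{\sim N(0, 10^3)}
#' (variance \eqn{10^3}) and log hyper-spreads \eqn{\sim N(0, 2.5^2)}, wide
#' enough to act only as a mild ridge-like regularizer.
#'
#' @inheritParams hyperpriorSpec
#' @export
defaultHyperprior <- function(nCoef,
                              noiseMode = c("homoscedastic",
                                            "heteroscedastic")) {
    hyperpriorSpec(nCoef, noiseMode = match.arg(noiseMode))
}

#' Serialize / deserialize a hyperprior spec as JSON
#'
#' The JSON payload carries no subject- or site-level information, only the
#' Gaussian hyperprior summaries and the design parameterization, which makes
#' it the privacy-preserving object exchanged between a reference modelling
#' center and deployment sites.
#'
#' @param spec a \code{\link{HyperpriorSpec}}.
#' @param path file path.
#' @export
saveHyperprior <- function(spec, path) {
    stopifnot(is(spec, "HyperpriorSpec"))
    payload <- list(format = "fednorm-hyperprior", version = 1L,
                    mMu = spec@mMu, sMu = spec@sMu,
                    mLogsd = spec@mLogsd, sLogsd = spec@sLogsd,
                    mMuSigma = spec@mMuSigma, sMuSigma = spec@sMuSigma,
                    mLogsdSigma = spec@mLogsdSigma,
                    sLogsdSigma = spec@sLogsdSigma,
                    noiseMode = spec@noiseMode, basisKind = spec@basisKind,
                    center = spec@center, scale = spec@scale,
                    fitRange = spec@fitRange)
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         na = "null")
    invisible(path)
}

#' @rdname saveHyperprior
#' @export
readHyperprior <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(x$format) || x$format != "fednorm-hyperprior")
        stop("readHyperprior: not a fednorm hyperprior file")
    new("HyperpriorSpec",
        mMu = as.numeric(x$mMu), sMu = as.numeric(x$sMu),
        mLogsd = as.numeric(x$mLogsd), sLogsd = as.numeric(x$sLogsd),
        mMuSigma = as.numeric(x$mMuSigma), sMuSigma = as.numeric(x$sMuSigma),
        mLogsdSigma = as.numeric(x$mLogsdSigma),
        sLogsdSigma = as.numeric(x$sLogsdSigma),
        noiseMode = x$noiseMode, basisKind = x$basisKind %||% "",
        center = as.numeric(x$center), scale = as.numeric(x$scale),
        fitRange = as.numeric(x$fitRange))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "HyperpriorSpec", function(object) {
    cat("HyperpriorSpec (", object@noiseMode, ")\n", sep = "")
    cat("  mean coefficients:", length(object@mMu),
        "| noise coefficients:", length(object@mMuSigma), "\n")
    cat("  mMu:", paste(signif(object@mMu, 3), collapse = " "), "\n")
    cat("  sMu:", paste(signif(object@sMu, 3), collapse = " "), "\n")
    if (nzchar(object@basisKind))
        cat("  basis:", object@basisKind, " fitRange:",
            paste(signif(object@fitRange, 4), collapse = "-"), "\n")
})
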
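## Federated mechanisms: sequential model extension via posterior-predictive
## synthetic cohorts, and deployment-time adaptation via informative-prior
## transfer. Neither operation ever touches raw prior-stage data: extension
## consumes only (model, new data), adaptation only (hyperprior spec, local
## data).

#' Extend a trained model with data from new sites
#'
#' Implements one turn of the federated extension loop: a synthetic cohort is
#' drawn from the posterior predictive distribution of \code{model} over all
#' of its registered batches (by default 80 ages x observed sexes x
#' \code{nReps = 5} replicates per site, i.e. 800 rows per two-sex site),
#' concatenated with the newly observed data, and the full hierarchical model
#' is refitted on the combined data under the weakly-informative default
#' hyperprior. The returned model's batch registry is the union of old and
#' new batches.
#'
#' @param model a trained \code{\link{HBRModel}}.
#' @param newData a \code{\link{NormativeDataset}} holding the model's region
#'   and data from at least one previously unseen site (sites may not collide
#'   with registered ones); may be empty, in which case the refit is a pure
#'   self-distillation on synthetic data.
#' @param ageGrid,nReps generation protocol passed to
#'   \code{\link{samplePosteriorPredictive}}.
#' @param seed integer seed for generation and refitting.
#' @param ... sampler settings passed to \code{\link{hbrFit}}
#'   (\code{nChains}, \code{nWarmup}, \code{nSamples}, ...).
#' @return the extended \code{\link{HBRModel}}.
#' @export
extendModel <- function(model, newData, ageGrid = NULL, nReps = 5L,
                        seed = 1L, ...) {
    stopifnot(is(model, "HBRModel"))
    synth <- samplePosteriorPredictive(model, ageGrid = ageGrid,
                                       nReps = nReps, seed = seed)
    if (!is.null(newData) && ncol(newData) > 0L) {
        stopifnot(is(newData, "NormativeDataset"))
        if (!model@region %in% rownames(newData))
            stop("extendModel: new data lacks region '", model@region, "'")
        clash <- intersect(unique(sites(newData)), unique(model@registry@site))
        if (length(clash))
            stop("extendModel: new site id(s) collide with registered sites: ",
                 paste(clash, collapse = ", "))
        newData <- newData[model@region, ]
        combined <- bindSubjects(synth, newData)
    } else {
        combined <- synth
    }
    hbrFit(combined, model@region, basis = model@basis,
           noiseMode = model@noiseMode, seed = seed, ...)
}

#' Extract an informative hyperprior from a trained model
#'
#' Summarizes the posterior of each hyperparameter as an independent Gaussian
#' (mean and sd of its draws; log-space for the spreads) and packs them as a
#' \code{\link{HyperpriorSpec}} together with the model's basis kind, design
#' standardization and fit range. Posterior sds are floored at
#' \code{scaleFloor} so a degenerate posterior can never produce a zero-width
#' (dogmatic) prior.
#'
#' @param model a trained \code{\link{HBRModel}}.
#' @param scaleFloor minimum prior scale (default 1e-3).
#' @return a \code{\link{HyperpriorSpec}} suitable for
#'   \code{\link{adaptModel}}.
#' @export
extractInformativeHyperprior <- function(model, scaleFloor = 1e-3) {
    stopifnot(is(model, "HBRModel"))
    post <- model@posterior
    msd <- function(m) list(mean = colMeans(m),
                            sd = pmax(apply(m, 2, stats::sd), scaleFloor))
    mu <- msd(post@muTheta)
    ls <- msd(post@logSdTheta)
    muS <- msd(post@muSigma)
    lsS <- msd(post@logSdSigma)
    vals <- c(mu$mean, mu$sd, ls$mean, ls$sd,
              muS$mean, muS$sd, lsS$mean, lsS$sd)
    if (any(!is.finite(vals)))
        stop("extractInformativeHyperprior: non-finite posterior summaries")
    hyperpriorSpec(length(mu$mean),
                   mMu = mu$mean, sMu = mu$sd,
                   mLogsd = ls$mean, sLogsd = ls$sd,
                   mMuSigma = muS$mean, sMuSigma = muS$sd,
                   mLogsdSigma = lsS$mean, sLogsdSigma = lsS$sd,
                   noiseMode = model@noiseMode,
                   basisKind = model@basis@kind,
                   center = model@center, scale = model@scale,
                   fitRange = model@fitRange)
}

#' Adapt a reference model to local data under an informative prior
#'
#' Deployment-side transfer learning: refits the full hierarchical model on
#' the local data only, under the informative hyperprior extracted from the
#' reference model. The local data may be tiny — batches with one or even
#' zero subjects are regularized toward the reference prior, and an entirely
#' empty batch can still be predicted via the prior-mean curve
#' (\code{predictNorm(..., allowUnseen = TRUE)}).
#'
#' @param referenceSpec a \code{\link{HyperpriorSpec}} from
#'   \code{\link{extractInformativeHyperprior}}.
#' @param localData a \code{\link{NormativeDataset}}.
#' @param region region name.
#' @param basis a \code{\link{basisConfig}}; must match the spec's basis kind.
#' @param noiseMode noise mode; must match the spec.
#' @param ... sampler settings passed to \code{\link{hbrFit}}.
#' @return an adapted \code{\link{HBRModel}}.
#' @export
adaptModel <- function(referenceSpec, localData, region,
                       basis = basisConfig("linear"),
                       noiseMode = c("homoscedastic", "heteroscedastic"),
                       ...) {
    noiseMode <- match.arg(noiseMode)
    stopifnot(is(referenceSpec, "HyperpriorSpec"))
    if (nzchar(referenceSpec@basisKind) &&
        referenceSpec@basisKind != basis@kind)
        stop("adaptModel: reference prior was built for basis '",
             referenceSpec@basisKind, "', not '", basis@kind, "'")
    hbrFit(localData, region, basis = basis, hyper = referenceSpec,
           noiseMode = noiseMode, ...)
}
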
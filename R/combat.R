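## Parametric empirical-Bayes ComBat harmonization with an explicit
## train/apply split: parameters (design coefficients, pooled residual scale,
## EB-shrunk per-site additive gamma and multiplicative delta) are learned on
## the training split only and can then be applied to held-out data from the
## same sites. Age (through the chosen basis) and sex are kept in the design
## so their variability is preserved. Batch = site; features = regions.

#' Learn ComBat harmonization parameters on a training split
#'
#' Location/scale batch-effect model per region r and site i:
#' \eqn{y_{ri} = g_r(X) + \gamma_{ri} + \delta_{ri}\,\epsilon}. Per-site,
#' per-region estimates of \eqn{\gamma} and \eqn{\delta} are shrunk toward
#' cross-region parametric priors (normal for \eqn{\gamma}, inverse-gamma for
#' \eqn{\delta^2}) by the standard iterative empirical-Bayes solution.
#'
#' @param data a \code{\link{NormativeDataset}} (training split) with
#'   subjects from at least two sites.
#' @param basis a \code{\link{basisConfig}} for the preserved age effect.
#' @return an object of class \code{"CombatParams"}.
#' @export
combatFit <- function(data, basis = basisConfig("linear")) {
    stopifnot(is(data, "NormativeDataset"))
    siteLevels <- sort(unique(sites(data)))
    if (length(siteLevels) < 2L)
        stop("combatFit: need at least two sites; nothing to harmonize")
    dat <- t(phenotypeMatrix(data))            # regions x subjects
    G <- nrow(dat); n <- ncol(dat)
    fitRange <- range(ages(data))
    sexLevels <- sort(unique(sexes(data)))
    batch <- match(sites(data), siteLevels)
    nB <- length(siteLevels)
    ni <- tabulate(batch, nB)

    batchD <- vapply(seq_len(nB), function(i) as.numeric(batch == i),
                     numeric(n))
    covar <- .combatCovariates(ages(data), sexes(data), basis, fitRange,
                               sexLevels)
    design <- cbind(batchD, covar)
    Bhat <- solve(crossprod(design), crossprod(design, t(dat)))  # q x G
    grand <- drop((ni / n) %*% Bhat[seq_len(nB), , drop = FALSE]) # length G
    fitted <- t(design %*% Bhat)
    varPooled <- rowMeans((dat - fitted)^2)
    varPooled <- pmax(varPooled, 1e-12)

    standMean <- grand +
        t(covar %*% Bhat[-seq_len(nB), , drop = FALSE])   # G x n
    sdat <- (dat - standMean) / sqrt(varPooled)

    gammaStar <- matrix(NA_real_, nB, G)
    deltaStar <- matrix(NA_real_, nB, G)
    for (i in seq_len(nB)) {
        zi <- sdat[, batch == i, drop = FALSE]
        gHat <- rowMeans(zi)
        dHat <- apply(zi, 1, stats::var)
        dHat[!is.finite(dHat) | dHat <= 0] <- 1
        if (G >= 2L) {
            eb <- .combatEB(zi, gHat, dHat, ni[i])
            gammaStar[i, ] <- eb$gamma
            deltaStar[i, ] <- eb$delta2
        } else {                 # no cross-region prior available
            gammaStar[i, ] <- gHat
            deltaStar[i, ] <- dHat
        }
    }
    structure(list(siteLevels = siteLevels, sexLevels = sexLevels,
                   basis = basis, fitRange = fitRange,
                   covarCoef = Bhat[-seq_len(nB), , drop = FALSE],
                   grand = grand, varPooled = varPooled,
                   gammaStar = gammaStar, deltaStar = deltaStar,
                   regions = rownames(dat)),
              class = "CombatParams")
}

.combatCovariates <- function(age, sex, basis, fitRange, sexLevels) {
    B <- expandBasis(age, basis, fitRange)
    ## drop the constant column (absorbed by the batch indicators)
    keep <- apply(B, 2, function(v) stats::sd(v) > 0)
    B <- B[, keep, drop = FALSE]
    sx <- .sexColumn(sex, sexLevels)
    if (is.null(sx)) B else cbind(B, sx)
}

## iterative parametric EB solution (normal / inverse-gamma priors)
.combatEB <- function(zi, gHat, dHat, ni, conv = 1e-4, maxIter = 200L) {
    gBar <- mean(gHat); t2 <- stats::var(gHat)
    m <- mean(dHat); s2 <- stats::var(dHat)
    if (!is.finite(s2) || s2 <= 0) s2 <- 1e-8
    if (!is.finite(t2) || t2 <= 0) t2 <- 1e-8
    aPrior <- (2 * s2 + m^2) / s2
    bPrior <- (m * s2 + m^3) / s2
    gOld <- gHat; dOld <- dHat
    for (it in seq_len(maxIter)) {
        gNew <- (ni * t2 * gHat + dOld * gBar) / (ni * t2 + dOld)
        sum2 <- rowSums((zi - gNew)^2)
        dNew <- (bPrior + 0.5 * sum2) / (ni / 2 + aPrior - 1)
        change <- max(abs(gNew - gOld) / pmax(abs(gOld), 1e-8),
                      abs(dNew - dOld) / pmax(abs(dOld), 1e-8))
        gOld <- gNew; dOld <- dNew
        if (change < conv) break
    }
    list(gamma = gOld, delta2 = dOld)
}

#' Apply learned ComBat parameters to a dataset
#'
#' @param params a \code{"CombatParams"} object from \code{\link{combatFit}}.
#' @param data a \code{\link{NormativeDataset}} whose sites were all seen at
#'   fit time.
#' @return a \code{\link{NormativeDataset}} with harmonized phenotypes
#'   (ground-truth assays, if present, are carried through unchanged).
#' @export
combatApply <- function(params, data) {
    stopifnot(inherits(params, "CombatParams"), is(data, "NormativeDataset"))
    unseen <- setdiff(unique(sites(data)), params$siteLevels)
    if (length(unseen))
        stop("combatApply: site(s) not seen at fit time: ",
             paste(unseen, collapse = ", "))
    if (!identical(rownames(data), params$regions))
        stop("combatApply: region set differs from the fitted one")
    dat <- t(phenotypeMatrix(data))
    batch <- match(sites(data), params$siteLevels)
    covar <- .combatCovariates(ages(data), sexes(data), params$basis,
                               params$fitRange, params$sexLevels)
    standMean <- params$grand + t(covar %*% params$covarCoef)
    sdat <- (dat - standMean) / sqrt(params$varPooled)
    adj <- (sdat - t(params$gammaStar[batch, , drop = FALSE])) /
        t(sqrt(params$deltaStar[batch, , drop = FALSE]))
    harmonized <- adj * sqrt(params$varPooled) + standMean
    cd <- colData(data)
    NormativeDataset(t(harmonized), age = cd$age, sex = cd$sex,
                     site = cd$site, group = cd$group,
                     subject = rownames(cd),
                     muTrue = trueMean(data), sigmaTrue = trueSd(data))
}

#' ComBat-then-pooling baseline
#'
#' Harmonizes the training split with \code{\link{combatFit}} and fits a
#' naive-pooling model on the harmonized data. Scoring a test split first
#' applies the learned harmonization (train-only parameters), then the pooled
#' (mu, sigma) — the out-of-sample harmonization protocol.
#'
#' @inheritParams fitNaivePooling
#' @return a \code{CombatPooledModel}.
#' @export
fitCombatPooling <- function(data, region, basis = basisConfig("linear")) {
    params <- combatFit(data, basis)
    harmonized <- combatApply(params, data)
    pooled <- fitNaivePooling(harmonized, region, basis)
    new("CombatPooledModel", region = as.character(region), basis = basis,
        fitRange = pooled@fitRange, includeSex = pooled@includeSex,
        sexLevels = pooled@sexLevels,
        combat = unclass(params), pooled = pooled)
}

#' @describeIn predictNorm pooled prediction on the harmonized scale.
#' @export
setMethod("predictNorm", "CombatPooledModel",
    function(object, age, sex, site, ...)
        predictNorm(object@pooled, age, sex, site))

#' @describeIn deviationScores harmonize with the training-split ComBat
#'   parameters, then score with the pooled model.
#' @export
setMethod("deviationScores", "CombatPooledModel",
    function(object, data, region = object@region, ...) {
    params <- structure(object@combat, class = "CombatParams")
    harmonized <- combatApply(params, data)
    .baselineScores(object@pooled, harmonized, region)
})

setMethod("show", "CombatPooledModel", function(object) {
    cat("CombatPooledModel for region '", object@region, "', ",
        length(object@combat$siteLevels), " sites harmonized, pooled sigma = ",
        signif(object@pooled@sigma, 4), "\n", sep = "")
})
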
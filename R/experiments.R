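## Synthetic replications of the four experimental protocols: centralized vs
## sequentially extended fitting, the site-leakage audit, informative-prior
## adaptation vs no-pooling at small-n sites, and credible-interval
## calibration. Each function generates its own seeded cohort, runs the
## models and returns the summary quantities; tests and the acceptance
## script call them at different problem sizes.

## heterogeneous multi-site conditions: sites cover the 10-90y range with
## alternating additive shifts, mild slope scaling and site-specific noise
.experimentSites <- function(nSites, nPerSite, shiftScale = 1) {
    lapply(seq_len(nSites), function(k)
        siteSpec(sprintf("site%02d", k), nPerSite, c(10, 90),
                 interceptShift = shiftScale * 0.3 *
                     (((k - 1) %% 4) - 1.5) / 1.5,
                 slopeScale = 1 + 0.15 * (((k - 1) %% 3) - 1),
                 noiseSd = c(0.10, 0.14, 0.18, 0.12)[1 + (k - 1) %% 4]))
}

#' Centralized versus sequentially extended model fitting
#'
#' Generates a multi-site cohort with heterogeneous per-region age effects,
#' splits 80/20 by site, then fits every region twice: once on all training
#' data at once (HBR-FULL) and once by the federated extension loop, adding
#' one site's data at a time with the default posterior-predictive
#' generation protocol (HBR-EXTENDED). Reports the per-region test-set
#' Pearson correlation of both models and the coefficient of determination
#' between the two correlation vectors across regions.
#'
#' @param nSites,nPerSite,nRegions cohort dimensions.
#' @param seed integer seed for the cohort, the split and every fit.
#' @param nChains,nWarmup,nSamples sampler settings per fit.
#' @return list with \code{rhoFull}, \code{rhoExtended} (per region),
#'   \code{r2} and \code{nRegions}.
#' @export
extensionExperiment <- function(nSites = 8L, nPerSite = 150L,
                                nRegions = 20L, seed = 1L,
                                nChains = 1L, nWarmup = 300L,
                                nSamples = 400L) {
    spec <- cohortSpec(.experimentSites(nSites, nPerSite),
                       nRegions = nRegions, seed = seed)
    ds <- generateCohort(spec)
    split <- splitBySite(ds, 0.8, seed = seed + 1L)
    regions <- regionNames(ds)
    siteIds <- vapply(spec$sites, `[[`, "", "siteId")

    rhoFull <- rhoExt <- numeric(length(regions))
    for (r in seq_along(regions)) {
        rg <- regions[r]
        full <- suppressWarnings(hbrFit(split$train, rg,
            nChains = nChains, nWarmup = nWarmup, nSamples = nSamples,
            seed = seed + 10L * r))
        model <- NULL
        for (k in seq_along(siteIds)) {
            siteData <- subsetSubjects(split$train,
                                       sites(split$train) == siteIds[k])
            model <- if (is.null(model))
                suppressWarnings(hbrFit(siteData, rg,
                    nChains = nChains, nWarmup = nWarmup,
                    nSamples = nSamples, seed = seed + 10L * r + k))
            else
                suppressWarnings(extendModel(model, siteData,
                    seed = seed + 10L * r + k, nChains = nChains,
                    nWarmup = nWarmup, nSamples = nSamples))
        }
        rho <- function(m) {
            pr <- predictNorm(m, ages(split$test), sexes(split$test),
                              sites(split$test))
            stats::cor(as.numeric(regionValues(split$test, rg)), pr$mu)
        }
        rhoFull[r] <- rho(full)
        rhoExt[r] <- rho(model)
    }
    list(rhoFull = rhoFull, rhoExtended = rhoExt,
         r2 = stats::cor(rhoFull, rhoExt)^2, nRegions = length(regions))
}

#' Site-leakage audit of naive-pooling versus HBR z-scores
#'
#' Generates a cohort with strong additive (about two noise sds between
#' neighbouring sites) and multiplicative site effects, fits per region both
#' the naive-pooling baseline and the HBR model on the 80% training split,
#' computes held-out z-scores and runs the one-vs-one linear-SVM audit on
#' each z-score matrix.
#'
#' @inheritParams extensionExperiment
#' @return list with \code{accuracyNaive}, \code{accuracyHBR} and the number
#'   of test subjects \code{nTest}.
#' @export
auditExperiment <- function(nSites = 4L, nPerSite = 150L, nRegions = 20L,
                            seed = 1L, nChains = 1L, nWarmup = 300L,
                            nSamples = 400L) {
    spec <- cohortSpec(.experimentSites(nSites, nPerSite, shiftScale = 2),
                       nRegions = nRegions, seed = seed)
    ds <- generateCohort(spec)
    split <- splitBySite(ds, 0.8, seed = seed + 1L)
    regions <- regionNames(ds)
    zN <- zH <- matrix(NA_real_, ncol(split$test), length(regions))
    for (r in seq_along(regions)) {
        rg <- regions[r]
        zN[, r] <- deviationScores(fitNaivePooling(split$train, rg),
                                   split$test)$z
        hbr <- suppressWarnings(hbrFit(split$train, rg,
            nChains = nChains, nWarmup = nWarmup, nSamples = nSamples,
            seed = seed + 20L * r))
        zH[, r] <- deviationScores(hbr, split$test)$z
    }
    siteLab <- sites(split$test)
    list(accuracyNaive = siteLeakageAudit(zN, siteLab,
                                          seed = seed + 2L)$meanAccuracy,
         accuracyHBR = siteLeakageAudit(zH, siteLab,
                                        seed = seed + 2L)$meanAccuracy,
         nTest = ncol(split$test))
}

#' Informative-prior adaptation versus no-pooling at small clinical sites
#'
#' Fits a reference model on a multi-site healthy cohort, extracts the
#' informative hyperprior, and then for each of \code{nLocalSites} simulated
#' clinical sites with only \code{nLocalTrain} training subjects compares
#' the adapted model against an independent no-pooling fit on held-out local
#' subjects, reporting the mean MSLL (and RHO) of both.
#'
#' @param nRefSites,nRefPerSite reference cohort dimensions.
#' @param nLocalSites number of simulated deployment sites (>= 10 mirrors
#'   the repeated-runs protocol).
#' @param nLocalTrain,nLocalTest local training and test subjects per site.
#' @inheritParams extensionExperiment
#' @return list with \code{msllAdapted}, \code{msllNoPooling} (per local
#'   site), their means, and the per-site RHO values.
#' @export
adaptationExperiment <- function(nRefSites = 6L, nRefPerSite = 150L,
                                 nLocalSites = 10L, nLocalTrain = 10L,
                                 nLocalTest = 150L, seed = 1L,
                                 nChains = 1L, nWarmup = 300L,
                                 nSamples = 400L) {
    refSpec <- cohortSpec(.experimentSites(nRefSites, nRefPerSite),
                          nRegions = 2L, seed = seed)
    refData <- generateCohort(refSpec)
    ref <- suppressWarnings(hbrFit(refData, "region02",
        nChains = nChains, nWarmup = nWarmup, nSamples = nSamples,
        seed = seed + 3L))
    hp <- extractInformativeHyperprior(ref)

    msllA <- msllN <- rhoA <- rhoN <- numeric(nLocalSites)
    for (k in seq_len(nLocalSites)) {
        localSpec <- cohortSpec(list(
            siteSpec(sprintf("clinic%02d", k), nLocalTrain + nLocalTest,
                     c(15, 85),
                     interceptShift = 0.25 * sin(k),
                     slopeScale = 1 + 0.1 * cos(k),
                     noiseSd = 0.12 + 0.04 * (k %% 3) / 2)),
            nRegions = 2L, seed = seed + 100L + k)
        local <- generateCohort(localSpec)
        sp <- splitBySite(local, nLocalTrain / ncol(local),
                          seed = seed + 200L + k)
        ad <- suppressWarnings(adaptModel(hp, sp$train, "region02",
            nChains = nChains, nWarmup = nWarmup, nSamples = nSamples,
            seed = seed + 300L + k))
        np <- fitNoPooling(sp$train, "region02")
        yTr <- as.numeric(regionValues(sp$train, "region02"))
        yTe <- as.numeric(regionValues(sp$test, "region02"))
        prA <- predictNorm(ad, ages(sp$test), sexes(sp$test),
                           sites(sp$test), allowUnseen = TRUE)
        prN <- suppressWarnings(predictNorm(np, ages(sp$test),
                                            sexes(sp$test), sites(sp$test)))
        ok <- is.finite(prN$mu)
        mA <- normMetrics(yTe[ok], prA$mu[ok], prA$sigma[ok],
                          mean(yTr), stats::var(yTr))
        mN <- normMetrics(yTe[ok], prN$mu[ok], prN$sigma[ok],
                          mean(yTr), stats::var(yTr))
        msllA[k] <- mA["MSLL"]; msllN[k] <- mN["MSLL"]
        rhoA[k] <- mA["RHO"]; rhoN[k] <- mN["RHO"]
    }
    list(msllAdapted = msllA, msllNoPooling = msllN,
         meanMsllAdapted = mean(msllA), meanMsllNoPooling = mean(msllN),
         rhoAdapted = rhoA, rhoNoPooling = rhoN)
}

#' Credible-interval calibration of per-batch slopes
#'
#' Repeatedly generates cohorts whose per-site age slopes vary around the
#' population value, fits the HBR model, and checks how often the true
#' per-batch slope falls inside the central 95% credible interval of its
#' posterior draws.
#'
#' @param nReps number of simulated cohorts.
#' @param nSites,nPerSite cohort dimensions per repetition.
#' @inheritParams extensionExperiment
#' @return list with \code{coverage} (overall fraction) and \code{nChecked}.
#' @export
calibrationExperiment <- function(nReps = 20L, nSites = 4L, nPerSite = 60L,
                                  seed = 1L, nChains = 1L, nWarmup = 300L,
                                  nSamples = 400L) {
    hits <- 0L; total <- 0L
    for (rep in seq_len(nReps)) {
        repSeed <- seed + 17L * rep
        slopeScales <- withr::with_seed(repSeed,
            stats::rnorm(nSites, 1, 0.25))
        sts <- lapply(seq_len(nSites), function(k)
            siteSpec(sprintf("site%02d", k), nPerSite, c(10, 90),
                     interceptShift = 0.2 * (((k - 1) %% 3) - 1),
                     slopeScale = slopeScales[k], noiseSd = 0.15))
        ds <- generateCohort(cohortSpec(sts, nRegions = 2L,
                                        seed = repSeed + 1L))
        fit <- suppressWarnings(hbrFit(ds, "region02",
            nChains = nChains, nWarmup = nWarmup, nSamples = nSamples,
            seed = repSeed + 2L))
        rc <- rawCoefDraws(fit)
        lab <- batchLabels(fit@registry)
        for (i in seq_len(nrow(lab))) {
            k <- as.integer(sub("site", "", lab$site[i]))
            trueSlope <- -0.015 * slopeScales[k]
            ci <- stats::quantile(rc[, i, 2], c(0.025, 0.975))
            hits <- hits + (trueSlope >= ci[1] && trueSlope <= ci[2])
            total <- total + 1L
        }
    }
    list(coverage = hits / total, nChecked = total)
}
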
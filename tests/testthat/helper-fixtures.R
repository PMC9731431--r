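# Shared fixtures. Expensive objects (MCMC fits, cohorts) are built once per
# test run and memoised so several test files can reuse them.

.fxCache <- new.env(parent = emptyenv())

colData <- SummarizedExperiment::colData

fixture <- function(name, builder) {
    if (!exists(name, envir = .fxCache)) {
        assign(name, builder(), envir = .fxCache)
    }
    get(name, envir = .fxCache)
}

# reduced sampler settings used throughout the suite
FIT_CHAINS <- 2L
FIT_WARM <- 300L
FIT_DRAWS <- 300L

quietFit <- function(...) {
    suppressWarnings(hbrFit(..., nChains = FIT_CHAINS, nWarmup = FIT_WARM,
                            nSamples = FIT_DRAWS))
}

# m sites spanning the 10-90y range with alternating additive shifts and
# mild multiplicative (slope-scale) site effects
makeSites <- function(m, n, shift = 0.25, slopeJitter = 0.1,
                      noiseSd = 0.12, ageRange = c(10, 90),
                      prefix = "site") {
    lapply(seq_len(m), function(k)
        siteSpec(sprintf("%s%02d", prefix, k), n, ageRange,
                 interceptShift = ((k %% 3) - 1) * shift,
                 slopeScale = 1 + slopeJitter * ((k %% 2) - 0.5),
                 noiseSd = noiseSd))
}

# small two-site cohort with a known linear trend, reused by several files
smallCohort <- function() fixture("smallCohort", function() {
    generateCohort(cohortSpec(makeSites(2, 200), nRegions = 2, seed = 101))
})

# a quick HBR fit on the small cohort, reused widely
smallFit <- function() fixture("smallFit", function() {
    quietFit(smallCohort(), "region02", seed = 11)
})

# reference model for the few-shot adaptation tests
fedReference <- function() fixture("fedReference", function() {
    ds <- generateCohort(cohortSpec(makeSites(5, 150, shift = 0.2),
                                    nRegions = 1, seed = 151))
    quietFit(ds, "region01", seed = 30)
})

# strong-site-effect cohort + per-region naive and HBR fits for audit tests
auditCohort <- function() fixture("auditCohort", function() {
    nR <- 10L
    sts <- lapply(1:4, function(k)
        siteSpec(sprintf("site%02d", k), 90, c(10, 90),
                 interceptShift = c(-0.3, -0.1, 0.1, 0.3)[k] * 2,
                 slopeScale = c(0.8, 1.2, 0.9, 1.1)[k],
                 noiseSd = c(0.10, 0.14, 0.18, 0.12)[k]))
    ds <- generateCohort(cohortSpec(sts, nRegions = nR, seed = 202))
    split <- splitBySite(ds, 0.8, seed = 17)
    regions <- regionNames(ds)
    naive <- lapply(regions, function(rg)
        fitNaivePooling(split$train, rg))
    hbr <- lapply(seq_along(regions), function(i)
        quietFit(split$train, regions[i], seed = 300 + i))
    names(naive) <- names(hbr) <- regions
    zMat <- function(models) vapply(regions, function(rg)
        deviationScores(models[[rg]], split$test)$z,
        numeric(ncol(split$test)))
    list(split = split, regions = regions,
         zNaive = zMat(naive), zHbr = zMat(hbr))
})
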
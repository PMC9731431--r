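test_that("extension on an empty new dataset is a consistent
           self-distillation", {
    fit <- smallFit()
    ext <- suppressWarnings(extendModel(fit, NULL, seed = 23,
                                        nChains = FIT_CHAINS,
                                        nWarmup = FIT_WARM,
                                        nSamples = FIT_DRAWS))
    age <- seq(15, 85, by = 10)
    for (st in c("site01", "site02")) {
        a <- predictNorm(fit, age, "F", st)
        b <- predictNorm(ext, age, "F", st)
        expect_equal(b$mu, a$mu, tolerance = 0.02)
        expect_equal(b$sigma, a$sigma, tolerance = 0.15)
    }
})

test_that("extension registers the union of batches and rejects site
           collisions", {
    fit <- smallFit()
    newSite <- generateCohort(cohortSpec(list(
        siteSpec("site99", 120, c(10, 90), interceptShift = 0.4,
                 noiseSd = 0.12)), nRegions = 2, seed = 131))
    ext <- suppressWarnings(extendModel(fit, newSite, seed = 24,
                                        nChains = FIT_CHAINS,
                                        nWarmup = FIT_WARM,
                                        nSamples = FIT_DRAWS))
    expect_setequal(unique(ext@registry@site),
                    c("site01", "site02", "site99"))
    pr <- predictNorm(ext, 50, "F", "site99")
    truth <- 2.8 + 0.4 - 0.015 * 50    # region02 curve + site99 shift, female
    expect_lt(abs(pr$mu - truth), 0.1)
    clash <- generateCohort(cohortSpec(list(
        siteSpec("site01", 10, c(10, 90))), nRegions = 2, seed = 132))
    expect_error(suppressWarnings(extendModel(fit, clash)), "collide")
})

test_that("extension order matters only weakly", {
    a <- generateCohort(cohortSpec(list(
        siteSpec("A", 130, c(10, 90), interceptShift = -0.2,
                 noiseSd = 0.12)), nRegions = 1, seed = 141))
    b <- generateCohort(cohortSpec(list(
        siteSpec("B", 130, c(10, 90), interceptShift = 0.25,
                 noiseSd = 0.15)), nRegions = 1, seed = 142))
    fitA <- quietFit(a, "region01", seed = 25)
    fitB <- quietFit(b, "region01", seed = 26)
    extAB <- suppressWarnings(extendModel(fitA, b, seed = 27,
        nChains = FIT_CHAINS, nWarmup = FIT_WARM, nSamples = FIT_DRAWS))
    extBA <- suppressWarnings(extendModel(fitB, a, seed = 28,
        nChains = FIT_CHAINS, nWarmup = FIT_WARM, nSamples = FIT_DRAWS))
    age <- seq(15, 85, by = 10)
    for (st in c("A", "B")) for (sx in c("F", "M")) {
        p1 <- predictNorm(extAB, age, sx, st)
        p2 <- predictNorm(extBA, age, sx, st)
        expect_equal(p1$mu, p2$mu, tolerance = 0.05)
    }
})

test_that("extracted hyperprior summarizes the hyperparameter posterior
           and floors degenerate scales", {
    fit <- smallFit()
    hp <- extractInformativeHyperprior(fit)
    post <- fit@posterior
    expect_equal(hp@mMu, colMeans(post@muTheta), tolerance = 1e-10)
    expect_equal(hp@sMu, apply(post@muTheta, 2, sd), tolerance = 1e-10)
    expect_equal(hp@mLogsd, colMeans(post@logSdTheta), tolerance = 1e-10)
    expect_equal(hp@mMuSigma, colMeans(post@muSigma), tolerance = 1e-10)
    expect_identical(hp@basisKind, "linear")
    # degenerate posterior: all draws identical -> scales collapse to the
    # configured floor, never to zero
    degen <- fit
    degen@posterior@muTheta[] <- 1.5
    degen@posterior@logSdTheta[] <- -2
    degen@posterior@muSigma[] <- -1
    degen@posterior@logSdSigma[] <- -3
    hp0 <- extractInformativeHyperprior(degen, scaleFloor = 1e-3)
    expect_true(all(hp0@sMu == 1e-3))
    expect_true(all(hp0@sLogsd == 1e-3))
    expect_equal(hp0@mMu, rep(1.5, 2))
})

test_that("refitting the reference data under the extracted prior
           reproduces the reference predictions", {
    ds <- smallCohort()
    fit <- smallFit()
    hp <- extractInformativeHyperprior(fit)
    refit <- suppressWarnings(adaptModel(hp, ds, "region02",
        nChains = FIT_CHAINS, nWarmup = FIT_WARM, nSamples = FIT_DRAWS,
        seed = 29))
    age <- seq(15, 85, by = 10)
    p1 <- predictNorm(fit, age, "M", "site01")
    p2 <- predictNorm(refit, age, "M", "site01")
    expect_equal(p2$mu, p1$mu, tolerance = 0.02)
    expect_equal(p2$sigma, p1$sigma, tolerance = 0.1)
})

test_that("few-shot adaptation: n = 0 falls back to the reference
           prior-mean curve and n = 1 stays bounded by the prior", {
    ref <- fedReference()
    hp <- extractInformativeHyperprior(ref)
    local <- generateCohort(cohortSpec(list(
        siteSpec("clinic", 1, c(20, 80), interceptShift = 0.1,
                 noiseSd = 0.12)), nRegions = 1, seed = 152))
    ad <- suppressWarnings(adaptModel(hp, local, "region01",
        nChains = FIT_CHAINS, nWarmup = FIT_WARM, nSamples = FIT_DRAWS,
        seed = 31))
    # the single subject's own batch: finite, positive sigma, slope near the
    # population value (no wild extrapolation from one point, unlike OLS,
    # which is undefined at n = 1)
    sx <- sexes(local)[1]
    rc <- rawCoefDraws(ad)
    i <- batchIndex(ad@registry, "clinic", sx)
    slope <- mean(rc[, i, 2])
    expect_true(is.finite(slope))
    # single-region default curve has a flat age effect; the one local point
    # cannot move the slope away from the reference prior
    expect_lt(abs(slope), 0.005)
    pr1 <- predictNorm(ad, c(30, 60), sx, "clinic")
    expect_true(all(pr1$sigma > 0.05 & pr1$sigma < 0.5))
    # n = 0 batch (the other sex was never observed): prior-mean prediction
    otherSex <- setdiff(c("F", "M"), sx)
    pr0 <- predictNorm(ad, c(30, 60), otherSex, "clinic",
                       allowUnseen = TRUE)
    muT <- colMeans(ad@posterior@muTheta)
    X <- fednorm:::.modelDesign(ad, c(30, 60))
    expect_equal(pr0$mu, drop(X %*% muT), tolerance = 1e-10)
    expect_true(all(pr0$sigma > 0))
})

test_that("with ample local data the adapted fit approaches independent
           least squares (the prior washes out)", {
    ref <- fedReference()
    hp <- extractInformativeHyperprior(ref)
    local <- generateCohort(cohortSpec(list(
        siteSpec("clinic", 400, c(10, 90), interceptShift = 0.3,
                 slopeScale = 1.3, noiseSd = 0.12)), nRegions = 1,
        seed = 153))
    ad <- suppressWarnings(adaptModel(hp, local, "region01",
        nChains = FIT_CHAINS, nWarmup = FIT_WARM, nSamples = FIT_DRAWS,
        seed = 32))
    np <- fitNoPooling(local, "region01")
    for (sx in c("F", "M")) {
        prA <- predictNorm(ad, c(20, 50, 80), sx, "clinic")
        prN <- predictNorm(np, c(20, 50, 80), sx, "clinic")
        expect_equal(prA$mu, prN$mu, tolerance = 0.02)
    }
})
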
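test_that("with no site effects all strategies agree on the mean function", {
    spec <- cohortSpec(list(siteSpec("a", 250, c(10, 90), noiseSd = 0.1),
                            siteSpec("b", 250, c(10, 90), noiseSd = 0.1)),
                       nRegions = 1, seed = 81)
    ds <- generateCohort(spec)
    age <- seq(15, 85, by = 5)
    hbr <- quietFit(ds, "region01", seed = 14)
    models <- list(fitNaivePooling(ds, "region01"),
                   fitFixedEffect(ds, "region01"),
                   fitNoPooling(ds, "region01"),
                   fitCombatPooling(ds, "region01"),
                   hbr)
    mus <- vapply(models, function(m)
        predictNorm(m, age, "F", "a")$mu, numeric(length(age)))
    spread <- apply(mus, 1, function(v) diff(range(v)))
    expect_lt(max(spread), 0.05)     # all within half a noise sd of another
})

test_that("naive pooling averages site intercepts and leaks site into z", {
    spec <- cohortSpec(list(
        siteSpec("a", 400, c(20, 70), interceptShift = 0, noiseSd = 0.1),
        siteSpec("b", 400, c(20, 70), interceptShift = 2, noiseSd = 0.1)),
        nRegions = 1, seed = 91)
    ds <- generateCohort(spec)
    nv <- fitNaivePooling(ds, "region01")
    # global fit sits at the midpoint of the two site intercepts
    muA <- predictNorm(nv, 45, "F", "a")$mu
    expect_equal(muA, mean(trueMean(ds)[ages(ds) > 40 & ages(ds) < 50, 1]),
                 tolerance = 0.05)
    # z-scores keep the site signal: site means of z differ by ~2 / sigma
    z <- deviationScores(nv, ds)$z
    gap <- mean(z[sites(ds) == "b"]) - mean(z[sites(ds) == "a"])
    expect_gt(gap, 1.5)
})

test_that("fixed-effect pooling recovers the site offset and refuses
           unseen sites", {
    spec <- cohortSpec(list(
        siteSpec("a", 300, c(20, 70), interceptShift = 0, noiseSd = 0.1),
        siteSpec("b", 300, c(20, 70), interceptShift = 2, noiseSd = 0.1)),
        nRegions = 1, seed = 96)
    ds <- generateCohort(spec)
    fe <- fitFixedEffect(ds, "region01")
    offB <- predictNorm(fe, 45, "F", "b")$mu - predictNorm(fe, 45, "F", "a")$mu
    expect_equal(offB, 2, tolerance = 0.05)
    expect_error(predictNorm(fe, 45, "F", "zzz"), "zzz")
    # with a single site the fixed-effect model reduces to naive pooling
    one <- subsetSubjects(ds, sites(ds) == "a")
    feOne <- fitFixedEffect(one, "region01")
    nvOne <- fitNaivePooling(one, "region01")
    expect_equal(predictNorm(feOne, c(25, 60), "M", "a"),
                 predictNorm(nvOne, c(25, 60), "M", "a"))
})

test_that("no-pooling equals the per-batch least-squares oracle and flags
           underdetermined batches", {
    ds <- smallCohort()
    np <- fitNoPooling(ds, "region01")
    lab <- batchLabels(np@registry)
    B <- expandBasis(ages(ds), basisConfig("linear"), np@fitRange)
    y <- as.numeric(regionValues(ds, "region01"))
    for (i in seq_len(nrow(lab))) {
        r <- sites(ds) == lab$site[i] & sexes(ds) == lab$sex[i]
        ols <- coef(lm(y[r] ~ B[r, 2]))
        expect_equal(unname(np@coefs[i, ]), unname(ols), tolerance = 1e-8)
    }
    # one subject cannot determine a line: flagged unusable, NA prediction
    tiny <- generateCohort(cohortSpec(list(
        siteSpec("big", 50, c(10, 90)), siteSpec("one", 1, c(10, 90))),
        nRegions = 1, seed = 98))
    npt <- fitNoPooling(tiny, "region01")
    u <- usableBatches(npt)
    expect_false(any(u[grep("^one", names(u))]))
    expect_warning(
        prT <- predictNorm(npt, ages(tiny), sexes(tiny), sites(tiny)),
        "unusable")
    expect_true(all(is.na(prT$mu[sites(tiny) == "one"])))
})

test_that("ComBat equalizes per-batch residual location and scale on the
           training data", {
    spec <- cohortSpec(list(
        siteSpec("a", 250, c(10, 90), interceptShift = -0.5, noiseSd = 0.10),
        siteSpec("b", 250, c(10, 90), interceptShift = 0.6, noiseSd = 0.25)),
        nRegions = 4, seed = 105)
    ds <- generateCohort(spec)
    params <- combatFit(ds)
    harm <- combatApply(params, ds)
    # residuals about the preserved design, per site and region
    for (rg in c("region01", "region04")) {
        y <- as.numeric(regionValues(harm, rg))
        X <- cbind(1, ages(harm), as.numeric(sexes(harm) == "M"))
        res <- residuals(lm(y ~ X - 1))
        mA <- mean(res[sites(harm) == "a"]); mB <- mean(res[sites(harm) == "b"])
        sA <- sd(res[sites(harm) == "a"]); sB <- sd(res[sites(harm) == "b"])
        expect_lt(abs(mA - mB), 0.03)
        expect_lt(abs(sA - sB), 0.03)
    }
    expect_error(combatFit(subsetSubjects(ds, sites(ds) == "a")),
                 "at least two sites")
})

test_that("ComBat is close to the identity when there are no batch
           effects", {
    spec <- cohortSpec(list(siteSpec("a", 300, c(10, 90), noiseSd = 0.15),
                            siteSpec("b", 300, c(10, 90), noiseSd = 0.15)),
                       nRegions = 3, seed = 110)
    ds <- generateCohort(spec)
    harm <- combatApply(combatFit(ds), ds)
    delta <- abs(phenotypeMatrix(harm) - phenotypeMatrix(ds))
    # EB shrinkage moves values only within a small fraction of the noise sd
    expect_lt(max(delta), 0.06)
    expect_lt(mean(delta), 0.02)
})

test_that("fit-and-apply matches the reference sva implementation on the
           training data", {
    spec <- cohortSpec(list(
        siteSpec("a", 150, c(10, 90), interceptShift = -0.4, noiseSd = 0.1),
        siteSpec("b", 200, c(10, 90), interceptShift = 0.5, noiseSd = 0.2),
        siteSpec("c", 120, c(10, 90), interceptShift = 0.1, noiseSd = 0.15)),
        nRegions = 5, seed = 115)
    ds <- generateCohort(spec)
    ours <- t(phenotypeMatrix(combatApply(combatFit(ds), ds)))
    mod <- model.matrix(~ ages(ds) + factor(sexes(ds)))
    ref <- suppressMessages(
        sva::ComBat(dat = t(phenotypeMatrix(ds)), batch = sites(ds),
                    mod = mod))
    expect_gt(cor(as.numeric(ours), as.numeric(ref)), 0.9999)
    expect_lt(max(abs(ours - ref)), 0.02)
})

test_that("harmonization attenuates a latent subtype correlated with
           site", {
    # no intrinsic site effects: the site mean differences ComBat removes
    # are exactly the ones induced by the site-varying subtype prevalence
    base <- cohortSpec(makeSites(4, 300, shift = 0, slopeJitter = 0),
                       nRegions = 2, seed = 120)
    ds <- generateConfoundedCohort(base, 0.9, subtypeEffect = 1)
    subtype <- colData(ds)$subtype
    tRaw <- t.test(phenotypeMatrix(ds)[subtype == 1, 1],
                   phenotypeMatrix(ds)[subtype == 0, 1])$statistic
    harm <- combatApply(combatFit(ds), ds)
    tHarm <- t.test(phenotypeMatrix(harm)[subtype == 1, 1],
                    phenotypeMatrix(harm)[subtype == 0, 1])$statistic
    expect_lt(abs(tHarm), abs(tRaw))
})
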
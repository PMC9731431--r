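test_that("invalid site and cohort specifications name the offending field", {
    expect_error(siteSpec("a", -1, c(10, 20)), "nSubjects")
    expect_error(siteSpec("a", 5, c(20, 10)), "ageRange")
    expect_error(siteSpec("a", 5, c(10, 20), noiseSd = 0), "noiseSd")
    expect_error(siteSpec("a", 5, c(10, 20), sexRatio = 1.2), "sexRatio")
    st <- list(siteSpec("a", 5, c(10, 20)))
    expect_error(cohortSpec(st, 2, clinicalFraction = 1.5),
                 "clinicalFraction")
    expect_error(cohortSpec(st, 2, clinicalEffect = c(1, 2, 3)),
                 "clinicalEffect")
    expect_error(cohortSpec(st, 2, populationCurve = matrix(0, 5, 3)),
                 "populationCurve")
})

test_that("zero-noise limit reproduces the ground-truth mean exactly", {
    spec <- cohortSpec(list(siteSpec("s1", 50, c(10, 80), noiseSd = 1e-12)),
                       nRegions = 3, seed = 7)
    ds <- generateCohort(spec)
    expect_equal(phenotypeMatrix(ds), trueMean(ds), tolerance = 1e-9)
})

test_that("additive site effects appear as mean shifts of the stated size", {
    spec <- cohortSpec(list(
        siteSpec("a", 2000, c(30, 60), interceptShift = 0, noiseSd = 0.2),
        siteSpec("b", 2000, c(30, 60), interceptShift = 2, noiseSd = 0.2)),
        nRegions = 1, seed = 12)
    ds <- generateCohort(spec)
    y <- phenotypeMatrix(ds)[, 1]
    diffMeans <- mean(y[sites(ds) == "b"]) - mean(y[sites(ds) == "a"])
    # ages are iid across the two sites, so the shift is the only difference;
    # Monte-Carlo error of a difference of means at n = 2000/site is ~0.01
    expect_equal(diffMeans, 2.0, tolerance = 0.05)
})

test_that("generation is deterministic and site substreams are stable", {
    spec <- cohortSpec(makeSites(3, 40), nRegions = 2, seed = 33)
    d1 <- generateCohort(spec)
    d2 <- generateCohort(spec)
    expect_identical(phenotypeMatrix(d1), phenotypeMatrix(d2))
    expect_identical(ages(d1), ages(d2))
    # adding a fourth site must not change the first three sites' draws
    spec4 <- cohortSpec(c(spec$sites, makeSites(1, 40, prefix = "extra")),
                        nRegions = 2, seed = 33)
    d4 <- generateCohort(spec4)
    keep <- sites(d4) %in% sites(d1)
    expect_equal(phenotypeMatrix(d4)[keep, ], phenotypeMatrix(d1))
})

test_that("residual moments converge to (0, noiseSd) and 95% of healthy
           draws fall inside mu +/- 1.96 sigma", {
    spec <- cohortSpec(list(siteSpec("s1", 20000, c(10, 90),
                                     noiseSd = 0.25)),
                       nRegions = 2, seed = 55)
    ds <- generateCohort(spec)
    resid <- phenotypeMatrix(ds) - trueMean(ds)
    expect_equal(mean(resid[, 1]), 0, tolerance = 0.01)
    expect_equal(sd(resid[, 1]), 0.25, tolerance = 0.01)
    inside <- abs(resid) <= 1.96 * trueSd(ds)
    expect_equal(mean(inside), 0.95, tolerance = 0.01)
})

test_that("patients are shifted by the clinical effect in noise-sd units", {
    spec <- cohortSpec(list(siteSpec("s1", 4000, c(20, 70), noiseSd = 0.2)),
                       nRegions = 2, clinicalFraction = 0.3,
                       clinicalEffect = c(-3, 0), seed = 60)
    ds <- generateCohort(spec)
    resid <- (phenotypeMatrix(ds) - trueMean(ds)) / trueSd(ds)
    pat <- groups(ds) == "patient"
    expect_gt(sum(pat), 0)
    expect_equal(mean(resid[pat, 1]), -3, tolerance = 0.1)
    expect_equal(mean(resid[pat, 2]), 0, tolerance = 0.1)
    expect_equal(mean(resid[!pat, 1]), 0, tolerance = 0.1)
})

test_that("confounded cohorts interpolate site age windows and carry a
           recoverable latent subtype", {
    base <- cohortSpec(makeSites(2, 1500, shift = 0), nRegions = 1,
                       seed = 77)
    # strength 0: site-age correlation vanishes
    d0 <- generateConfoundedCohort(base, 0, subtypeEffect = 1)
    corr0 <- cor(ages(d0), as.numeric(factor(sites(d0))))
    expect_lt(abs(corr0), 0.05)
    # strength 1: disjoint consecutive age windows
    d1 <- generateConfoundedCohort(base, 1, subtypeEffect = 1)
    a1 <- range(ages(d1)[sites(d1) == "site01"])
    a2 <- range(ages(d1)[sites(d1) == "site02"])
    expect_lt(a1[2], a2[1])
    # the injected subtype is visible in the raw phenotypes
    subtype <- colData(d0)$subtype
    tt <- t.test(phenotypeMatrix(d0)[subtype == 1, 1],
                 phenotypeMatrix(d0)[subtype == 0, 1])
    expect_lt(tt$p.value, 1e-6)
    expect_error(generateConfoundedCohort(base, 1.5), "confoundStrength")
})

test_that("datasets round-trip through the two-table CSV format", {
    ds <- smallCohort()
    prefix <- file.path(tempdir(), "cohort")
    writeNormativeDataset(ds, prefix)
    back <- readNormativeDataset(paste0(prefix, "_covariates.csv"),
                                 paste0(prefix, "_phenotypes.csv"))
    expect_equal(phenotypeMatrix(back), phenotypeMatrix(ds),
                 tolerance = 1e-6)
    expect_equal(ages(back), ages(ds), tolerance = 1e-6)
    expect_identical(sites(back), sites(ds))
})
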
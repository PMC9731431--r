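test_that("single-batch fit recovers generative parameters within the 95%
           credible interval", {
    spec <- cohortSpec(list(siteSpec("s1", 500, c(10, 90), noiseSd = 0.1)),
                       nRegions = 2, seed = 21)
    ds <- generateCohort(spec)
    fit <- quietFit(ds, "region02", seed = 5)
    rc <- rawCoefDraws(fit)
    trueSlope <- -0.015                    # region02 of the default curve
    ci <- quantile(rc[, , 2], c(0.025, 0.975))
    expect_gt(trueSlope, ci[1])
    expect_lt(trueSlope, ci[2])
    sig <- exp(fit@posterior@logSigma)
    expect_equal(mean(sig), 0.1, tolerance = 0.02)
})

test_that("noiseless training data is reproduced to tight tolerance", {
    spec <- cohortSpec(list(siteSpec("s1", 200, c(10, 90),
                                     noiseSd = 1e-6)),
                       nRegions = 1, seed = 31)
    ds <- generateCohort(spec)
    fit <- quietFit(ds, "region01", seed = 6)
    pr <- predictNorm(fit, ages(ds), sexes(ds), sites(ds))
    expect_equal(pr$mu, unname(trueMean(ds)[, 1]), tolerance = 1e-3)
    expect_true(all(pr$sigma > 0))
})

test_that("partial pooling shrinks batch estimates toward each other
           relative to independent least squares", {
    # two small batches with identical true parameters
    spec <- cohortSpec(list(siteSpec("a", 25, c(10, 90), noiseSd = 0.3),
                            siteSpec("b", 25, c(10, 90), noiseSd = 0.3)),
                       nRegions = 1, seed = 41)
    ds <- generateCohort(spec)
    # restrict to one sex so HBR batches match the site-level OLS oracle
    ds <- subsetSubjects(ds, sexes(ds) == "M")
    fit <- quietFit(ds, "region01", seed = 7)
    rc <- rawCoefDraws(fit)
    hbrGap <- abs(mean(rc[, 1, 2]) - mean(rc[, 2, 2]))
    ols <- fitNoPooling(ds, "region01")
    olsGap <- abs(ols@coefs[1, 2] - ols@coefs[2, 2])
    expect_lt(hbrGap, olsGap)
})

test_that("a batch with no data draws its parameters from the learned
           prior", {
    ds <- smallCohort()
    y <- as.numeric(regionValues(ds, "region01"))
    B <- expandBasis(ages(ds), basisConfig("linear"), range(ages(ds)))
    batch <- as.integer(factor(sites(ds)))
    # declare a third batch that owns no rows
    post <- fednorm:::.hbrGibbs(y, B, batch, m = 3L,
                                defaultHyperprior(2L), "homoscedastic",
                                nChains = 1L, nWarmup = 200L,
                                nSamples = 400L, seed = 9L)
    emptyDraws <- post@theta[, 3, 1]
    expect_equal(mean(emptyDraws), mean(post@muTheta[, 1]),
                 tolerance = 3 * sd(emptyDraws) / sqrt(50))
    # spread of the prior-only batch reflects the learned across-batch sd
    expect_gt(sd(emptyDraws), 0.9 * mean(exp(post@logSdTheta[, 1])))
})

test_that("held-out z-scores standardize and injected patients surface at
           their true deviation", {
    sts <- makeSites(3, 220, noiseSd = 0.15)
    spec <- cohortSpec(sts, nRegions = 2, clinicalFraction = 0.15,
                       clinicalEffect = c(-3, 0), seed = 51)
    ds <- generateCohort(spec)
    split <- splitBySite(ds, 0.8, seed = 3)
    fit <- quietFit(split$train, "region01", seed = 8)
    sc <- deviationScores(fit, split$test)
    healthy <- groups(split$test) == "healthy"
    expect_equal(mean(sc$z[healthy]), 0, tolerance = 0.12)
    expect_equal(sd(sc$z[healthy]), 1, tolerance = 0.12)
    expect_equal(median(sc$z[!healthy]), -3, tolerance = 0.45)
    # a subject exactly on the predicted mean has z = 0
    pr <- predictNorm(fit, 50, "F", "site01")
    expect_equal((pr$mu - pr$mu) / pr$sigma, 0)
})

test_that("prediction is permutation-equivariant and unseen batches either
           error or fall back to the prior-mean curve", {
    fit <- smallFit()
    age <- c(20, 45, 70, 33)
    sex <- c("F", "M", "F", "M")
    site <- rep("site01", 4)
    pr <- predictNorm(fit, age, sex, site)
    perm <- c(3, 1, 4, 2)
    pr2 <- predictNorm(fit, age[perm], sex[perm], site[perm])
    expect_equal(pr2, pr[perm, ], ignore_attr = TRUE)
    expect_error(predictNorm(fit, 50, "F", "nowhere"), "nowhere")
    fallback <- predictNorm(fit, c(30, 60), "F", "nowhere",
                            allowUnseen = TRUE)
    expect_true(all(is.finite(fallback$mu)) && all(fallback$sigma > 0))
})

test_that("posterior-predictive sampling follows the 80 x 2 x 5 protocol,
           is seed-deterministic, and converges to the posterior mean", {
    fit <- smallFit()
    synth <- samplePosteriorPredictive(fit, seed = 13)
    # default grid: 80 ages x 2 sexes x 5 reps = 800 rows for each site
    expect_equal(ncol(synth), 800L * 2L)
    expect_equal(sort(unique(ages(synth))), 10:89)
    again <- samplePosteriorPredictive(fit, seed = 13)
    expect_identical(phenotypeMatrix(again), phenotypeMatrix(synth))
    other <- samplePosteriorPredictive(fit, seed = 14)
    expect_false(identical(phenotypeMatrix(other), phenotypeMatrix(synth)))
    expect_error(samplePosteriorPredictive(fit, sites = "ghost"), "ghost")
    # Monte-Carlo mean at a fixed cell approaches the posterior-mean mu
    many <- samplePosteriorPredictive(fit, ageGrid = 50, sexes = "F",
                                      sites = "site01", nReps = 4000,
                                      seed = 15)
    pm <- predictNorm(fit, 50, "F", "site01")
    mcSd <- sd(phenotypeMatrix(many)[, 1]) / sqrt(4000)
    expect_equal(mean(phenotypeMatrix(many)[, 1]), pm$mu,
                 tolerance = 4 * mcSd + 1e-8, ignore_attr = TRUE)
})

test_that("heteroscedastic softplus noise recovers an age-growing sd", {
    spec <- cohortSpec(list(siteSpec("h1", 250, c(10, 90), noiseSd = 0.1),
                            siteSpec("h2", 250, c(10, 90), noiseSd = 0.2)),
                       nRegions = 1, heteroscedastic = TRUE,
                       varianceSlope = 0.002, seed = 61)
    ds <- generateCohort(spec)
    fit <- quietFit(ds, "region01", noiseMode = "heteroscedastic", seed = 10)
    pr <- predictNorm(fit, c(15, 85), "F", "h2")
    expect_true(all(pr$sigma > 0))
    # true sd rises from ~0.2 at the young end to ~0.35 at the old end
    expect_gt(pr$sigma[2], pr$sigma[1] + 0.05)
    expect_lt(abs(pr$sigma[1] - (0.2 + 0.002 * 5)), 0.05)
    expect_lt(abs(pr$sigma[2] - (0.2 + 0.002 * 75)), 0.07)
})

test_that("the Gibbs sampler agrees with an independent JAGS fit of the
           same hierarchical model", {
    spec <- cohortSpec(list(
        siteSpec("a", 150, c(10, 90), interceptShift = -0.3, noiseSd = 0.15),
        siteSpec("b", 150, c(10, 90), interceptShift = 0.3, noiseSd = 0.15)),
        nRegions = 1, seed = 71)
    ds <- generateCohort(spec)
    ds <- subsetSubjects(ds, sexes(ds) == "F")
    fit <- quietFit(ds, "region01", seed = 12)
    rc <- rawCoefDraws(fit)

    library(rjags)
    y <- as.numeric(regionValues(ds, "region01"))
    X <- expandBasis(ages(ds), basisConfig("linear"), fit@fitRange)
    Xs <- sweep(sweep(X, 2, fit@center), 2, fit@scale, "/")
    batch <- batchIndex(fit@registry, sites(ds), sexes(ds))
    mstr <- "model {
      for (s in 1:N) {
        mu[s] <- inprod(X[s,], theta[batch[s],])
        y[s] ~ dnorm(mu[s], prec[batch[s]])
      }
      for (i in 1:M) {
        for (j in 1:P) { theta[i,j] ~ dnorm(muT[j], 1/tau[j]^2) }
        lam[i] ~ dnorm(muS, 1/tauS^2)
        prec[i] <- exp(-2*lam[i])
      }
      for (j in 1:P) {
        muT[j] ~ dnorm(0, 0.001)
        ltau[j] ~ dnorm(0, 1/2.5^2)
        tau[j] <- exp(ltau[j])
      }
      muS ~ dnorm(0, 0.001)
      ltauS ~ dnorm(0, 1/2.5^2)
      tauS <- exp(ltauS)
    }"
    jm <- jags.model(textConnection(mstr),
                     data = list(y = y, X = Xs, batch = batch,
                                 N = length(y), M = nBatches(fit@registry),
                                 P = ncol(Xs)),
                     n.chains = 2, n.adapt = 500, quiet = TRUE)
    update(jm, 500, progress.bar = "none")
    samp <- coda.samples(jm, c("theta", "lam"), n.iter = 1500,
                         progress.bar = "none")
    sm <- summary(samp)$statistics
    lamCols <- do.call(rbind, samp)
    for (i in seq_len(nBatches(fit@registry))) {
        for (j in 1:2) {
            ours <- fit@posterior@theta[, i, j]
            jags <- sm[sprintf("theta[%d,%d]", i, j), "Mean"]
            # agreement of posterior means within Monte-Carlo uncertainty
            expect_lt(abs(mean(ours) - jags), 0.25 * sd(ours) + 0.01)
        }
        sigOurs <- mean(exp(fit@posterior@logSigma[, i]))
        sigJags <- mean(exp(lamCols[, sprintf("lam[%d]", i)]))
        expect_lt(abs(sigOurs - sigJags), 0.02)
    }
})

test_that("all sigma outputs are strictly positive over stress inputs", {
    fit <- smallFit()
    pr <- predictNorm(fit, c(-50, 0, 200), "F", "site01")
    expect_true(all(pr$sigma > 0))
    expect_true(all(exp(fit@posterior@logSigma) > 0))
    expect_true(all(exp(fit@posterior@logSdTheta) > 0))
})
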
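## Blocked Gibbs sampler for the hierarchical Gaussian regression model.
##
## Likelihood, batch i:  y_s ~ N(x_s' theta_i, sigma_{i,s}^2)
##   homoscedastic:      sigma_{i,s} = exp(lambda_i)
##   heteroscedastic:    sigma_{i,s} = softplus(x_s' thetaSig_i)
## Hierarchy:            theta_ij ~ N(muTheta_j, tauTheta_j^2)
##                       lambda_i ~ N(muSig, tauSig^2)   (log-space pooling)
##                       thetaSig_ij ~ N(muSig_j, tauSig_j^2)
## Hyperpriors:          muTheta_j ~ N(mMu_j, sMu_j^2)
##                       log tauTheta_j ~ N(mLogsd_j, sLogsd_j^2)
##                       (noise counterparts analogous)
##
## The Gaussian blocks (per-batch theta, hyper-means) are conjugate and drawn
## exactly; scale parameters and heteroscedastic noise coefficients use
## univariate slice sampling. Homoscedastic updates touch only per-batch
## sufficient statistics, so iteration cost is independent of sample size.

## univariate slice sampler with stepping out and shrinkage (Neal 2003)
.sliceSample <- function(x0, logf, w = 1, maxSteps = 50L) {
    f0 <- logf(x0)
    if (!is.finite(f0)) stop("slice sampler started at zero-density point")
    logy <- f0 - stats::rexp(1)
    u <- stats::runif(1)
    L <- x0 - w * u
    Rt <- L + w
    k <- maxSteps
    while (k > 0 && logf(L) > logy) { L <- L - w; k <- k - 1 }
    k <- maxSteps
    while (k > 0 && logf(Rt) > logy) { Rt <- Rt + w; k <- k - 1 }
    repeat {
        x1 <- stats::runif(1, L, Rt)
        if (logf(x1) >= logy) return(x1)
        if (x1 < x0) L <- x1 else Rt <- x1
    }
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

## split R-hat over a draws x chains matrix
.splitRhat <- function(draws, chain) {
    chains <- split(draws, chain)
    halves <- unlist(lapply(chains, function(v) {
        h <- length(v) %/% 2L
        list(v[seq_len(h)], v[seq_len(h) + h])
    }), recursive = FALSE)
    n <- min(lengths(halves))
    if (n < 2L) return(NA_real_)
    m <- vapply(halves, function(v) mean(v[seq_len(n)]), 0)
    s2 <- vapply(halves, function(v) stats::var(v[seq_len(n)]), 0)
    W <- mean(s2)
    B <- n * stats::var(m)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
}

## y: response; X: standardized design (n x p); batch: integer in 1..m
## (may omit some indices: zero-count batches get prior-only draws);
## hyper: HyperpriorSpec in the standardized design space.
.hbrGibbs <- function(y, X, batch, m, hyper, noiseMode,
                      nChains = 2L, nWarmup = 1000L, nSamples = 1000L,
                      seed = 1L) {
    n <- length(y)
    p <- ncol(X)
    hetero <- noiseMode == "heteroscedastic"
    q <- if (hetero) p else 1L

    rows <- split(seq_len(n), factor(batch, levels = seq_len(m)))
    ni <- lengths(rows)
    XtX <- lapply(rows, function(r) crossprod(X[r, , drop = FALSE]))
    Xty <- lapply(rows, function(r) crossprod(X[r, , drop = FALSE], y[r]))
    yty <- vapply(rows, function(r) sum(y[r]^2), 0)

    ## moment-based initialization (shared across chains, jittered per chain)
    thetaInit <- matrix(0, m, p)
    lamInit <- numeric(m)
    for (i in seq_len(m)) {
        if (ni[i] >= 1L) {
            fit <- solve(XtX[[i]] + diag(1e-2, p), Xty[[i]])
            thetaInit[i, ] <- fit
            rss <- max(yty[i] - 2 * sum(fit * Xty[[i]]) +
                       sum(fit * (XtX[[i]] %*% fit)), 1e-10)
            lamInit[i] <- 0.5 * log(rss / max(ni[i], 2))
        }
    }
    seen <- ni > 0L
    if (!any(seen)) stop("no non-empty batches")
    for (j in seq_len(p)) thetaInit[!seen, j] <- mean(thetaInit[seen, j])
    lamInit[!seen] <- mean(lamInit[seen])

    keepTheta <- array(NA_real_, c(nChains * nSamples, m, p))
    keepLam <- matrix(NA_real_, nChains * nSamples, m)
    keepThS <- if (hetero) array(NA_real_, c(nChains * nSamples, m, p)) else
        array(0, c(0, 0, 0))
    keepMu <- matrix(NA_real_, nChains * nSamples, p)
    keepLt <- matrix(NA_real_, nChains * nSamples, p)
    keepMuS <- matrix(NA_real_, nChains * nSamples, q)
    keepLtS <- matrix(NA_real_, nChains * nSamples, q)
    chainId <- rep(seq_len(nChains), each = nSamples)

    for (ch in seq_len(nChains)) withr::with_seed(seed + 1000L * ch, {
        theta <- thetaInit + matrix(stats::rnorm(m * p, 0, 0.05 * ch), m, p)
        muT <- colMeans(theta[seen, , drop = FALSE])
        ltau <- log(pmax(apply(theta[seen, , drop = FALSE], 2, stats::sd),
                         0.05))
        ## fewer than two observed batches: no empirical spread; start the
        ## scale parameters at their hyperprior locations instead
        ltau[!is.finite(ltau)] <- hyper@mLogsd[!is.finite(ltau)]
        if (!hetero) {
            lam <- lamInit + stats::rnorm(m, 0, 0.05 * ch)
            muS <- mean(lam[seen])
            ltauS <- log(max(stats::sd(lam[seen]), 0.05, na.rm = TRUE))
            if (!is.finite(ltauS)) ltauS <- hyper@mLogsdSigma[1]
        } else {
            ## init noise predictor at a flat softplus inverse of resid sd
            thS <- matrix(0, m, p)
            thS[, 1] <- log(pmax(expm1(exp(lamInit)), 1e-6))
            muS <- colMeans(thS[seen, , drop = FALSE])
            ltauS <- log(pmax(apply(thS[seen, , drop = FALSE], 2, stats::sd),
                              0.05))
            ltauS[!is.finite(ltauS)] <- hyper@mLogsdSigma[!is.finite(ltauS)]
        }

        for (it in seq_len(nWarmup + nSamples)) {
            tau2 <- exp(2 * ltau)
            ## -- per-batch mean coefficients (conjugate Gaussian block)
            for (i in seq_len(m)) {
                if (!seen[i]) {
                    theta[i, ] <- muT + exp(ltau) * stats::rnorm(p)
                    next
                }
                if (!hetero) {
                    prec <- exp(-2 * lam[i])
                    A <- XtX[[i]] * prec + diag(1 / tau2, p)
                    b <- Xty[[i]] * prec + muT / tau2
                } else {
                    Xi <- X[rows[[i]], , drop = FALSE]
                    sig <- .softplus(drop(Xi %*% thS[i, ]))
                    W <- 1 / sig^2
                    A <- crossprod(Xi * sqrt(W)) + diag(1 / tau2, p)
                    b <- crossprod(Xi, y[rows[[i]]] * W) + muT / tau2
                }
                R <- chol(A)
                mu_i <- backsolve(R, forwardsolve(t(R), b))
                theta[i, ] <- mu_i + backsolve(R, stats::rnorm(p))
            }
            ## -- hyper-mean of coefficients (conjugate)
            for (j in seq_len(p)) {
                prec <- m / tau2[j] + 1 / hyper@sMu[j]^2
                mn <- (sum(theta[, j]) / tau2[j] +
                       hyper@mMu[j] / hyper@sMu[j]^2) / prec
                muT[j] <- stats::rnorm(1, mn, 1 / sqrt(prec))
            }
            ## -- log across-batch spread of coefficients (slice)
            for (j in seq_len(p)) {
                ss <- sum((theta[, j] - muT[j])^2)
                ltau[j] <- .sliceSample(ltau[j], function(l)
                    -m * l - ss / (2 * exp(2 * l)) +
                        stats::dnorm(l, hyper@mLogsd[j], hyper@sLogsd[j],
                                     log = TRUE))
            }
            ## -- interweaved (ancillary) update of the spreads: with the
            ##    standardized deviations eps held fixed, the likelihood of
            ##    log tau_j is informed directly by the data, which breaks
            ##    the slow mixing of the centered parameterization when the
            ##    spread is small. Homoscedastic only: the quadratic-in-theta
            ##    likelihood reduces to per-batch sufficient statistics.
            if (!hetero) {
                prec_i <- exp(-2 * lam)
                for (j in seq_len(p)) {
                    eps <- (theta[, j] - muT[j]) / exp(ltau[j])
                    A <- numeric(m); Bq <- numeric(m)
                    for (i in which(seen)) {
                        cross <- sum(XtX[[i]][j, ] * theta[i, ]) -
                            XtX[[i]][j, j] * theta[i, j]
                        A[i] <- XtX[[i]][j, j] * prec_i[i]
                        Bq[i] <- (cross - Xty[[i]][j]) * prec_i[i]
                    }
                    ltau[j] <- .sliceSample(ltau[j], function(l) {
                        t_ij <- muT[j] + exp(l) * eps
                        -0.5 * sum(A * t_ij^2 + 2 * Bq * t_ij) +
                            stats::dnorm(l, hyper@mLogsd[j], hyper@sLogsd[j],
                                         log = TRUE)
                    })
                    theta[, j] <- muT[j] + exp(ltau[j]) * eps
                }
            }
            tau2 <- exp(2 * ltau)
            ## -- noise parameters
            if (!hetero) {
                tS2 <- exp(2 * ltauS)
                for (i in seq_len(m)) {
                    if (!seen[i]) {
                        lam[i] <- stats::rnorm(1, muS, sqrt(tS2))
                        next
                    }
                    sse <- max(yty[i] - 2 * sum(theta[i, ] * Xty[[i]]) +
                               sum(theta[i, ] * (XtX[[i]] %*% theta[i, ])),
                               1e-12)
                    nli <- ni[i]
                    lam[i] <- .sliceSample(lam[i], function(l)
                        -nli * l - sse / (2 * exp(2 * l)) +
                            stats::dnorm(l, muS, sqrt(tS2), log = TRUE),
                        w = 0.5)
                }
                prec <- m / tS2 + 1 / hyper@sMuSigma[1]^2
                mn <- (sum(lam) / tS2 +
                       hyper@mMuSigma[1] / hyper@sMuSigma[1]^2) / prec
                muS <- stats::rnorm(1, mn, 1 / sqrt(prec))
                ss <- sum((lam - muS)^2)
                ltauS <- .sliceSample(ltauS, function(l)
                    -m * l - ss / (2 * exp(2 * l)) +
                        stats::dnorm(l, hyper@mLogsdSigma[1],
                                     hyper@sLogsdSigma[1], log = TRUE))
                ## interweaved update of the noise-spread (eps fixed)
                epsS <- (lam - muS) / exp(ltauS)
                sse_i <- numeric(m)
                for (i in which(seen))
                    sse_i[i] <- max(yty[i] - 2 * sum(theta[i, ] * Xty[[i]]) +
                                    sum(theta[i, ] *
                                        (XtX[[i]] %*% theta[i, ])), 1e-12)
                ltauS <- .sliceSample(ltauS, function(l) {
                    lam_i <- muS + exp(l) * epsS
                    sum(-ni[seen] * lam_i[seen] -
                        sse_i[seen] / (2 * exp(2 * lam_i[seen]))) +
                        stats::dnorm(l, hyper@mLogsdSigma[1],
                                     hyper@sLogsdSigma[1], log = TRUE)
                })
                lam <- muS + exp(ltauS) * epsS
            } else {
                tS2 <- exp(2 * ltauS)
                for (i in seq_len(m)) {
                    if (!seen[i]) {
                        thS[i, ] <- muS + sqrt(tS2) * stats::rnorm(p)
                        next
                    }
                    Xi <- X[rows[[i]], , drop = FALSE]
                    ri <- y[rows[[i]]] - drop(Xi %*% theta[i, ])
                    eta <- drop(Xi %*% thS[i, ])
                    for (j in seq_len(p)) {
                        etaMinus <- eta - Xi[, j] * thS[i, j]
                        thS[i, j] <- .sliceSample(thS[i, j], function(v) {
                            sig <- .softplus(etaMinus + Xi[, j] * v)
                            if (any(sig <= 0)) return(-Inf)
                            sum(stats::dnorm(ri, 0, sig, log = TRUE)) +
                                stats::dnorm(v, muS[j], sqrt(tS2[j]),
                                             log = TRUE)
                        }, w = 0.5)
                        eta <- etaMinus + Xi[, j] * thS[i, j]
                    }
                }
                for (j in seq_len(p)) {
                    prec <- m / tS2[j] + 1 / hyper@sMuSigma[j]^2
                    mn <- (sum(thS[, j]) / tS2[j] +
                           hyper@mMuSigma[j] / hyper@sMuSigma[j]^2) / prec
                    muS[j] <- stats::rnorm(1, mn, 1 / sqrt(prec))
                    ss <- sum((thS[, j] - muS[j])^2)
                    ltauS[j] <- .sliceSample(ltauS[j], function(l)
                        -m * l - ss / (2 * exp(2 * l)) +
                            stats::dnorm(l, hyper@mLogsdSigma[j],
                                         hyper@sLogsdSigma[j], log = TRUE))
                }
            }
            ## -- store
            if (it > nWarmup) {
                d <- (ch - 1L) * nSamples + (it - nWarmup)
                keepTheta[d, , ] <- theta
                if (!hetero) keepLam[d, ] <- lam else keepThS[d, , ] <- thS
                keepMu[d, ] <- muT
                keepLt[d, ] <- ltau
                keepMuS[d, ] <- muS
                keepLtS[d, ] <- ltauS
            }
        }
    })

    rhat <- c(
        stats::setNames(vapply(seq_len(p), function(j)
            .splitRhat(keepMu[, j], chainId), 0),
            sprintf("muTheta[%d]", seq_len(p))),
        stats::setNames(vapply(seq_len(p), function(j)
            .splitRhat(keepLt[, j], chainId), 0),
            sprintf("logSdTheta[%d]", seq_len(p))),
        stats::setNames(vapply(seq_len(q), function(j)
            .splitRhat(keepMuS[, j], chainId), 0),
            sprintf("muSigma[%d]", seq_len(q))),
        stats::setNames(vapply(seq_len(q), function(j)
            .splitRhat(keepLtS[, j], chainId), 0),
            sprintf("logSdSigma[%d]", seq_len(q))))

    new("PosteriorSamples",
        theta = keepTheta,
        logSigma = if (!hetero) keepLam else matrix(0, 0, 0),
        thetaSigma = keepThS,
        muTheta = keepMu, logSdTheta = keepLt,
        muSigma = keepMuS, logSdSigma = keepLtS,
        chain = chainId, rhat = rhat)
}
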
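#' Fit a hierarchical Bayesian regression normative model
#'
#' Partial pooling over the observed (site, sex) batches: every batch gets its
#' own mean-function coefficients and noise parameters, all drawn exchangeably
#' from shared Gaussian priors whose location and spread are themselves
#' estimated under the (weakly-)informative hyperprior in \code{hyper}.
#' Homoscedastic noise is pooled hierarchically in log space
#' (\eqn{\log\sigma_i \sim N(\mu_{\theta\sigma}, \sigma_{\theta\sigma}^2)});
#' heteroscedastic noise parameterizes the standard deviation as the softplus
#' \eqn{\log(1+e^{x})} of a per-batch linear function of the basis. Inference
#' is by a blocked Gibbs sampler (conjugate Gaussian blocks, slice steps for
#' scale parameters); convergence is monitored with split R-hat on the
#' hyperparameters and a warning is attached to the model when any R-hat
#' exceeds \code{rhatWarn}.
#'
#' Design columns of the linear and cubic-polynomial bases are standardized
#' internally (training mean/sd) so that coefficients live on comparable
#' scales; the B-spline basis is already well-scaled and is used as is.
#'
#' @param data a \code{\link{NormativeDataset}} (training split).
#' @param region region name to model.
#' @param basis a \code{\link{basisConfig}}.
#' @param hyper a \code{\link{HyperpriorSpec}} or \code{NULL} for the
#'   weakly-informative default. An informative spec (from
#'   \code{\link{extractInformativeHyperprior}}) must match the requested
#'   basis; its recorded standardization and fit range are reused so the
#'   transferred prior refers to the same parameterization.
#' @param noiseMode \code{"homoscedastic"} (default) or
#'   \code{"heteroscedastic"}.
#' @param nChains,nWarmup,nSamples sampler settings (defaults 2 x 1000 + 1000).
#' @param seed integer seed; each chain uses a derived substream.
#' @param rhatWarn split R-hat warning threshold.
#' @return a \code{\link{HBRModel}}.
#' @export
hbrFit <- function(data, region, basis = basisConfig("linear"),
                   hyper = NULL,
                   noiseMode = c("homoscedastic", "heteroscedastic"),
                   nChains = 2L, nWarmup = 1000L, nSamples = 1000L,
                   seed = 1L, rhatWarn = 1.05) {
    noiseMode <- match.arg(noiseMode)
    stopifnot(is(data, "NormativeDataset"))
    if (ncol(data) == 0L)
        stop("hbrFit: dataset has zero subjects")
    y <- as.numeric(regionValues(data, region))
    regName <- if (is.character(region)) region else rownames(data)[region]
    registry <- registerBatches(sites(data), sexes(data))
    p <- basisDim(basis)

    if (is.null(hyper)) {
        hyper <- defaultHyperprior(p, noiseMode)
    } else {
        stopifnot(is(hyper, "HyperpriorSpec"))
        if (length(hyper@mMu) != p)
            stop("hbrFit: hyperprior has ", length(hyper@mMu),
                 " mean coefficients but basis '", basis@kind, "' needs ", p)
        if (nzchar(hyper@basisKind) && hyper@basisKind != basis@kind)
            stop("hbrFit: hyperprior was built for basis '", hyper@basisKind,
                 "', not '", basis@kind, "'")
        if (hyper@noiseMode != noiseMode)
            stop("hbrFit: hyperprior noise mode '", hyper@noiseMode,
                 "' does not match requested '", noiseMode, "'")
    }

    informative <- length(hyper@center) == p && all(is.finite(hyper@fitRange))
    fitRange <- if (informative) hyper@fitRange else range(ages(data))
    if (fitRange[1] >= fitRange[2])   # single distinct age in training data
        fitRange <- fitRange + c(-0.5, 0.5)
    B <- expandBasis(ages(data), basis, fitRange)
    if (informative) {
        center <- hyper@center; scl <- hyper@scale
    } else if (basis@kind == "bspline3") {
        center <- rep(0, p); scl <- rep(1, p)
    } else {
        center <- c(0, colMeans(B[, -1, drop = FALSE]))
        scl <- c(1, apply(B[, -1, drop = FALSE], 2, stats::sd))
        scl[!is.finite(scl) | scl <= 0] <- 1
    }
    Xs <- sweep(sweep(B, 2, center), 2, scl, "/")

    batch <- batchIndex(registry, sites(data), sexes(data))
    posterior <- .hbrGibbs(y, Xs, batch, nBatches(registry), hyper, noiseMode,
                           nChains = as.integer(nChains),
                           nWarmup = as.integer(nWarmup),
                           nSamples = as.integer(nSamples),
                           seed = as.integer(seed))
    notes <- character()
    bad <- posterior@rhat[is.finite(posterior@rhat) &
                          posterior@rhat > rhatWarn]
    if (length(bad)) {
        notes <- sprintf("split R-hat above %.3f for: %s", rhatWarn,
                         paste(names(bad), collapse = ", "))
        warning("hbrFit: ", notes)
    }
    new("HBRModel", region = regName, basis = basis, fitRange = fitRange,
        includeSex = FALSE, sexLevels = sort(unique(sexes(data))),
        registry = registry, hyper = hyper, posterior = posterior,
        noiseMode = noiseMode, center = center, scale = scl, notes = notes)
}

## standardized design for new ages under a fitted model
.modelDesign <- function(model, age) {
    B <- expandBasis(age, model@basis, model@fitRange)
    sweep(sweep(B, 2, model@center), 2, model@scale, "/")
}

## posterior-mean coefficients per batch (standardized space)
.thetaBar <- function(model) {
    apply(model@posterior@theta, c(2, 3), mean)
}

## per-subject sigma for given batch indices (posterior mean), idx may be NA
.posteriorSigma <- function(model, Xs, idx) {
    post <- model@posterior
    n <- nrow(Xs)
    sig <- numeric(n)
    if (model@noiseMode == "homoscedastic") {
        sigBar <- colMeans(exp(post@logSigma))
        sigNew <- mean(exp(post@muSigma[, 1]))
        sig <- ifelse(is.na(idx), sigNew, sigBar[idx])
    } else {
        for (i in unique(idx)) {
            s <- if (is.na(i)) which(is.na(idx)) else which(idx == i)
            dr <- if (is.na(i)) t(post@muSigma) else t(post@thetaSigma[, i, ])
            sig[s] <- rowMeans(.softplus(Xs[s, , drop = FALSE] %*% dr))
        }
    }
    pmax(sig, .Machine$double.eps)
}

#' @describeIn predictNorm posterior-mean prediction with batch-specific mean
#'   and noise functions. Unseen (site, sex) batches raise an error naming the
#'   batch unless \code{allowUnseen = TRUE}, in which case the prior-mean
#'   curve (hyperparameter posterior) is returned — the few-shot fallback for
#'   batches with no training data.
#' @param allowUnseen logical; permit prior-mean prediction for unregistered
#'   batches.
#' @export
setMethod("predictNorm", "HBRModel",
    function(object, age, sex, site, allowUnseen = FALSE) {
    n <- length(age)
    sex <- rep_len(sex, n); site <- rep_len(site, n)
    idx <- batchIndex(object@registry, site, sex)
    if (any(is.na(idx)) && !allowUnseen) {
        miss <- unique(paste(site[is.na(idx)], sex[is.na(idx)], sep = ":"))
        stop("predictNorm: unseen batch(es) ", paste(miss, collapse = ", "),
             "; pass allowUnseen = TRUE for prior-mean prediction")
    }
    Xs <- .modelDesign(object, age)
    thetaBar <- .thetaBar(object)
    thetaNew <- colMeans(object@posterior@muTheta)
    coefs <- matrix(0, n, ncol(Xs))
    seenRows <- !is.na(idx)
    coefs[seenRows, ] <- thetaBar[idx[seenRows], , drop = FALSE]
    if (any(!seenRows)) coefs[!seenRows, ] <- rep(thetaNew, each = sum(!seenRows))
    mu <- rowSums(Xs * coefs)
    sigma <- .posteriorSigma(object, Xs, idx)
    data.frame(mu = mu, sigma = sigma)
})

#' @describeIn deviationScores z-scores under the HBR model.
#' @param region region to score (defaults to the fitted region).
#' @param allowUnseen passed to \code{\link{predictNorm}}.
#' @export
setMethod("deviationScores", "HBRModel",
    function(object, data, region = object@region, allowUnseen = FALSE) {
    pr <- predictNorm(object, ages(data), sexes(data), sites(data),
                      allowUnseen = allowUnseen)
    y <- as.numeric(regionValues(data, region))
    z <- (y - pr$mu) / pr$sigma
    data.frame(subject = colnames(data), region = region, z = z,
               pAbn = abnormalProbability(z), stringsAsFactors = FALSE)
})

#' Posterior draws of per-batch coefficients on the raw basis scale
#'
#' Back-transforms the standardized-space draws by the exact affine map so
#' that, e.g., the slope draws of a linear basis are in phenotype units per
#' year and can be compared against generative ground truth.
#'
#' @param model an \code{\link{HBRModel}}.
#' @return draws x batches x coefficients array.
#' @export
rawCoefDraws <- function(model) {
    th <- model@posterior@theta
    p <- dim(th)[3]
    s <- model@scale; cen <- model@center
    out <- th
    for (j in seq_len(p)) out[, , j] <- th[, , j] / s[j]
    ## constant-column intercept absorbs the centering offsets
    if (model@basis@kind != "bspline3" && p >= 2) {
        adj <- 0
        for (j in 2:p) adj <- adj + th[, , j] * (cen[j] / s[j])
        out[, , 1] <- th[, , 1] - adj
    }
    out
}

#' Sample a synthetic cohort from the posterior predictive distribution
#'
#' For every registered (site, sex) batch among the requested sites, every age
#' on the grid and every replicate, one posterior draw of the batch parameters
#' is selected at random and a response is drawn from
#' \eqn{N(f_{\mu i}(x), f^+_{\sigma i}(x)^2)}. Each generated row represents
#' one synthetic healthy participant; with the default grid of 80 ages
#' (10-89 years inclusive, step 1), both sexes and 5 replicates, a site
#' contributes 80 x 2 x 5 = 800 rows.
#'
#' @param model an \code{\link{HBRModel}}.
#' @param ageGrid numeric grid of ages; default \code{seq(10, 89)}.
#' @param sites site labels to generate for (default: all registered);
#'   unknown sites raise an error.
#' @param sexes sex labels to generate for (default: all registered; only
#'   observed (site, sex) combinations are produced).
#' @param nReps replicates per (site, sex, age) cell.
#' @param seed integer seed (draw selection and noise are deterministic
#'   under it).
#' @return a \code{\link{NormativeDataset}} with the model's region as its
#'   single phenotype column.
#' @export
samplePosteriorPredictive <- function(model, ageGrid = NULL, sites = NULL,
                                      sexes = NULL, nReps = 5L, seed = 1L) {
    stopifnot(is(model, "HBRModel"))
    if (is.null(ageGrid)) ageGrid <- seq(10, 89, by = 1)
    if (!length(ageGrid)) stop("samplePosteriorPredictive: empty age grid")
    reg <- model@registry
    if (is.null(sites)) sites <- unique(reg@site)
    unknown <- setdiff(sites, reg@site)
    if (length(unknown))
        stop("samplePosteriorPredictive: unknown site(s) ",
             paste(unknown, collapse = ", "))
    keep <- reg@site %in% sites
    if (!is.null(sexes)) keep <- keep & reg@sex %in% sexes
    combos <- which(keep)
    if (!length(combos)) stop("samplePosteriorPredictive: no matching batches")
    grid <- expand.grid(rep = seq_len(nReps), age = ageGrid, combo = combos)
    idx <- grid$combo
    n <- nrow(grid)
    post <- model@posterior
    nd <- dim(post@theta)[1]
    withr::with_seed(as.integer(seed), {
        dr <- sample.int(nd, n, replace = TRUE)
        Xs <- .modelDesign(model, grid$age)
        p <- ncol(Xs)
        th <- matrix(post@theta[cbind(rep(dr, p), rep(idx, p),
                                      rep(seq_len(p), each = n))], n, p)
        mu <- rowSums(Xs * th)
        sig <- if (model@noiseMode == "homoscedastic")
            exp(post@logSigma[cbind(dr, idx)])
        else {
            ths <- matrix(post@thetaSigma[cbind(rep(dr, p), rep(idx, p),
                                                rep(seq_len(p), each = n))],
                          n, p)
            .softplus(rowSums(Xs * ths))
        }
        y <- stats::rnorm(n, mu, sig)
    })
    pheno <- matrix(y, ncol = 1, dimnames = list(NULL, model@region))
    NormativeDataset(pheno, age = grid$age, sex = reg@sex[idx],
                     site = reg@site[idx],
                     subject = sprintf("ppd_%s_%05d", reg@site[idx], seq_len(n)))
}

setMethod("show", "HBRModel", function(object) {
    post <- object@posterior
    cat("HBRModel for region '", object@region, "' (", object@noiseMode,
        " noise, ", object@basis@kind, " basis)\n", sep = "")
    cat("  batches:", nBatches(object@registry),
        "| draws:", dim(post@theta)[1],
        "| fit range:", paste(signif(object@fitRange, 4), collapse = "-"), "\n")
    cat("  max split R-hat:",
        round(max(post@rhat, na.rm = TRUE), 3), "\n")
    if (length(object@notes)) cat("  notes:", object@notes, "\n")
})
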
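## Synthetic multi-site cohort generator.
##
## Emulates the structure of large multi-site morphometry collections: several
## sites with their own age windows and unbalanced sample sizes, additive
## (intercept shift) and multiplicative (slope scaling) site effects on top of
## a shared population age trend, a sex offset, site-specific (optionally
## age-dependent) Gaussian noise, and an optional fraction of "patient"
## subjects with injected regional deviations. Ground-truth per-subject
## normative mean and sd travel with the dataset so model recovery is testable
## without any real data.

#' Specification of one synthetic acquisition site
#'
#' @param siteId site label.
#' @param nSubjects number of subjects (0 allowed, to exercise few-shot
#'   edge cases downstream).
#' @param ageRange length-2 numeric, min < max, in years; ages are sampled
#'   uniformly within the window.
#' @param interceptShift additive site effect in phenotype units.
#' @param slopeScale multiplier on the population age slope.
#' @param noiseSd site noise standard deviation (> 0).
#' @param sexRatio probability that a subject is female, in [0, 1].
#' @return a \code{list} of class \code{"SiteSpec"}.
#' @export
siteSpec <- function(siteId, nSubjects, ageRange,
                     interceptShift = 0, slopeScale = 1,
                     noiseSd = 0.2, sexRatio = 0.5) {
    if (!is.character(siteId) || length(siteId) != 1L)
        stop("siteSpec: 'siteId' must be a single string")
    if (length(nSubjects) != 1L || is.na(nSubjects) || nSubjects < 0)
        stop("siteSpec: 'nSubjects' must be a non-negative integer")
    if (length(ageRange) != 2L || !all(is.finite(ageRange)) ||
        ageRange[1] >= ageRange[2])
        stop("siteSpec: 'ageRange' must satisfy min < max")
    if (!is.finite(noiseSd) || noiseSd <= 0)
        stop("siteSpec: 'noiseSd' must be > 0")
    if (!is.finite(sexRatio) || sexRatio < 0 || sexRatio > 1)
        stop("siteSpec: 'sexRatio' must be in [0, 1]")
    structure(list(siteId = siteId, nSubjects = as.integer(nSubjects),
                   ageRange = as.numeric(ageRange),
                   interceptShift = interceptShift, slopeScale = slopeScale,
                   noiseSd = noiseSd, sexRatio = sexRatio),
              class = "SiteSpec")
}

#' Specification of a synthetic multi-site cohort
#'
#' The population curve gives, per region, the healthy mean as
#' \code{intercept + slope * age + sexOffset * [sex == "M"]}; site k modifies
#' it to \code{intercept + interceptShift_k + slope * slopeScale_k * age + ...}
#' with Gaussian noise \code{noiseSd_k} (optionally growing linearly with age
#' when \code{heteroscedastic}). Patients are flagged with probability
#' \code{clinicalFraction} and shifted by \code{clinicalEffect[r]} noise-sd
#' units in region r; the ground-truth mean stored with the data remains the
#' healthy norm, so injected deviations are visible to z-scoring.
#'
#' @param sites list of \code{\link{siteSpec}} objects.
#' @param nRegions number of phenotype regions.
#' @param populationCurve nRegions x 3 matrix (columns intercept, slope,
#'   sexOffset) or \code{NULL} for cortical-thickness-like defaults
#'   (intercepts around 2.5 units, age slopes spanning 0 to -0.015 units/year
#'   so regions differ in signal strength, sex offset 0.05).
#' @param heteroscedastic logical; when \code{TRUE} the noise sd grows
#'   linearly with age at rate \code{varianceSlope}.
#' @param varianceSlope sd units per year (only used when heteroscedastic).
#' @param clinicalFraction fraction of subjects flagged as patients, in [0,1].
#' @param clinicalEffect numeric of length nRegions: patient deviation in
#'   units of the site noise sd.
#' @param seed master seed; each site consumes an arithmetically derived
#'   substream so adding a site never changes earlier sites' draws.
#' @return a \code{list} of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(sites, nRegions, populationCurve = NULL,
                       heteroscedastic = FALSE, varianceSlope = 0,
                       clinicalFraction = 0, clinicalEffect = NULL,
                       seed = 1L) {
    if (!length(sites) || !all(vapply(sites, inherits, TRUE, "SiteSpec")))
        stop("cohortSpec: 'sites' must be a non-empty list of siteSpec objects")
    if (anyDuplicated(vapply(sites, `[[`, "", "siteId")))
        stop("cohortSpec: duplicate site ids in 'sites'")
    if (length(nRegions) != 1L || nRegions < 1)
        stop("cohortSpec: 'nRegions' must be a positive integer")
    nRegions <- as.integer(nRegions)
    if (is.null(populationCurve)) {
        populationCurve <- cbind(
            intercept = seq(2.2, 2.8, length.out = nRegions),
            slope = seq(0, -0.015, length.out = nRegions),
            sexOffset = rep(0.05, nRegions))
    }
    populationCurve <- as.matrix(populationCurve)
    if (nrow(populationCurve) != nRegions || ncol(populationCurve) != 3L)
        stop("cohortSpec: 'populationCurve' must be nRegions x 3 ",
             "(intercept, slope, sexOffset)")
    colnames(populationCurve) <- c("intercept", "slope", "sexOffset")
    if (!is.finite(clinicalFraction) || clinicalFraction < 0 ||
        clinicalFraction > 1)
        stop("cohortSpec: 'clinicalFraction' must be in [0, 1]")
    if (is.null(clinicalEffect)) clinicalEffect <- rep(0, nRegions)
    if (length(clinicalEffect) == 1L)
        clinicalEffect <- rep(clinicalEffect, nRegions)
    if (length(clinicalEffect) != nRegions)
        stop("cohortSpec: 'clinicalEffect' must have one entry per region")
    structure(list(sites = sites, nRegions = nRegions,
                   populationCurve = populationCurve,
                   heteroscedastic = isTRUE(heteroscedastic),
                   varianceSlope = varianceSlope,
                   clinicalFraction = clinicalFraction,
                   clinicalEffect = as.numeric(clinicalEffect),
                   seed = as.integer(seed)),
              class = "CohortSpec")
}

## deterministic per-site substream seed, independent of the number of sites
.siteSeed <- function(seed, k) {
    as.integer((as.double(seed) * 1009 + 7919 * k) %% 2147483647)
}

#' Generate a synthetic multi-site cohort
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return a \code{\link{NormativeDataset}} carrying ground-truth assays
#'   \code{muTrue} and \code{sigmaTrue}.
#' @export
generateCohort <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    parts <- lapply(seq_along(spec$sites), function(k)
        .generateSite(spec, spec$sites[[k]], .siteSeed(spec$seed, k)))
    parts <- parts[vapply(parts, function(p) nrow(p$pheno) > 0, TRUE)]
    if (!length(parts))
        stop("generateCohort: all sites have zero subjects")
    pheno <- do.call(rbind, lapply(parts, `[[`, "pheno"))
    mu <- do.call(rbind, lapply(parts, `[[`, "mu"))
    sig <- do.call(rbind, lapply(parts, `[[`, "sigma"))
    cov <- do.call(rbind, lapply(parts, `[[`, "cov"))
    regions <- sprintf("region%02d", seq_len(spec$nRegions))
    colnames(pheno) <- colnames(mu) <- colnames(sig) <- regions
    subj <- sprintf("%s_%03d", cov$site, unlist(lapply(parts, function(p)
        seq_len(nrow(p$pheno)))))
    NormativeDataset(pheno, age = cov$age, sex = cov$sex, site = cov$site,
                     group = cov$group, subject = make.unique(subj),
                     muTrue = mu, sigmaTrue = sig,
                     extraCovariates = cov[, setdiff(colnames(cov),
                         c("age", "sex", "site", "group")), drop = FALSE])
}

.generateSite <- function(spec, st, siteSeed) {
    n <- st$nSubjects
    R <- spec$nRegions
    pc <- spec$populationCurve
    empty <- list(pheno = matrix(0, 0, R), mu = matrix(0, 0, R),
                  sigma = matrix(0, 0, R),
                  cov = data.frame(age = numeric(0), sex = character(0),
                                   site = character(0), group = character(0)))
    if (n == 0L) return(empty)
    withr::with_seed(siteSeed, {
        age <- runif(n, st$ageRange[1], st$ageRange[2])
        sex <- ifelse(runif(n) < st$sexRatio, "F", "M")
        patient <- runif(n) < spec$clinicalFraction
        male <- as.numeric(sex == "M")
        sdAge <- if (spec$heteroscedastic)
            pmax(st$noiseSd + spec$varianceSlope * (age - st$ageRange[1]),
                 st$noiseSd * 0.05)
        else rep(st$noiseSd, n)
        mu <- outer(rep(1, n), pc[, "intercept"] + 0) +
            st$interceptShift +
            outer(age, pc[, "slope"] * st$slopeScale) +
            outer(male, pc[, "sexOffset"])
        sigma <- matrix(sdAge, n, R)
        noise <- matrix(rnorm(n * R), n, R) * sigma
        shift <- outer(as.numeric(patient), spec$clinicalEffect) * sigma
        pheno <- mu + shift + noise
        list(pheno = pheno, mu = mu, sigma = sigma,
             cov = data.frame(age = age, sex = sex, site = st$siteId,
                              group = ifelse(patient, "patient", "healthy"),
                              stringsAsFactors = FALSE))
    })
}

#' Generate a cohort with site-age confounding and a latent subtype
#'
#' As \code{\link{generateCohort}} but site membership is correlated with age
#' (site age windows interpolate between the full population range at
#' \code{confoundStrength = 0} and disjoint consecutive tiles at 1), and an
#' unlabeled binary "latent subtype" whose prevalence varies across sites
#' shifts all regions by \code{subtypeEffect} noise-sd units. The subtype is
#' recorded in \code{colData(..)$subtype} for evaluation only: it emulates an
#' unknown biological factor correlated with the batch structure, the failure
#' mode under which harmonization removes signal of interest.
#'
#' @param spec a \code{\link{cohortSpec}}; each site's \code{ageRange} is
#'   replaced by its confounded window over the pooled range.
#' @param confoundStrength number in [0, 1].
#' @param subtypeEffect deviation (noise-sd units) added for subtype carriers.
#' @return a \code{\link{NormativeDataset}} with a \code{subtype} column.
#' @export
generateConfoundedCohort <- function(spec, confoundStrength,
                                     subtypeEffect = 1) {
    stopifnot(inherits(spec, "CohortSpec"))
    if (!is.finite(confoundStrength) || confoundStrength < 0 ||
        confoundStrength > 1)
        stop("generateConfoundedCohort: 'confoundStrength' must be in [0, 1]")
    m <- length(spec$sites)
    lo <- min(vapply(spec$sites, function(s) s$ageRange[1], 0))
    hi <- max(vapply(spec$sites, function(s) s$ageRange[2], 0))
    R <- hi - lo
    s <- confoundStrength
    spec$sites <- lapply(seq_len(m), function(k) {
        st <- spec$sites[[k]]
        st$ageRange <- c(lo + s * (k - 1) / m * R,
                         hi - s * (1 - k / m) * R)
        st
    })
    ds <- generateCohort(spec)
    ## subtype prevalence varies linearly across sites, scaled by s
    siteIds <- vapply(spec$sites, `[[`, "", "siteId")
    prev <- 0.5 + s * (0.8 * (seq_len(m) - 1) / max(1, m - 1) - 0.4)
    names(prev) <- siteIds
    subtype <- withr::with_seed(.siteSeed(spec$seed, m + 1L),
        as.integer(runif(ncol(ds)) < prev[sites(ds)]))
    sdMat <- trueSd(ds)
    ph <- phenotypeMatrix(ds) + subtype * subtypeEffect * sdMat
    cd <- colData(ds)
    NormativeDataset(ph, age = cd$age, sex = cd$sex, site = cd$site,
                     group = cd$group, subject = rownames(cd),
                     muTrue = trueMean(ds), sigmaTrue = sdMat,
                     extraCovariates = data.frame(subtype = subtype))
}
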
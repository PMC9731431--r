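## CSV input/output, model persistence, and split utilities.

#' Read a normative dataset from the two-table CSV format
#'
#' \code{covariates.csv} must have columns \code{subject}, \code{age},
#' \code{sex}, \code{site} (optionally \code{group} and others);
#' \code{phenotypes.csv} must have \code{subject} plus one numeric column per
#' region. Tables are joined on \code{subject}; rows with missing
#' age/sex/site are dropped with a message reporting the count; a subject
#' present in only one table is an error, as are duplicate ids and
#' non-numeric phenotype entries (reported with row numbers).
#'
#' @param covariatesPath,phenotypesPath CSV file paths.
#' @return a \code{\link{NormativeDataset}}.
#' @export
readNormativeDataset <- function(covariatesPath, phenotypesPath) {
    cov <- utils::read.csv(covariatesPath, stringsAsFactors = FALSE)
    ph <- utils::read.csv(phenotypesPath, stringsAsFactors = FALSE)
    for (col in c("subject", "age", "sex", "site"))
        if (!col %in% colnames(cov))
            stop("readNormativeDataset: covariates lack column '", col, "'")
    if (!"subject" %in% colnames(ph))
        stop("readNormativeDataset: phenotypes lack column 'subject'")
    if (anyDuplicated(cov$subject))
        stop("readNormativeDataset: duplicate subject ids in covariates: ",
             paste(unique(cov$subject[duplicated(cov$subject)]), collapse = ", "))
    if (anyDuplicated(ph$subject))
        stop("readNormativeDataset: duplicate subject ids in phenotypes")
    if (!setequal(cov$subject, ph$subject)) {
        only <- c(setdiff(cov$subject, ph$subject),
                  setdiff(ph$subject, cov$subject))
        stop("readNormativeDataset: subject ids present in only one table: ",
             paste(utils::head(only, 10), collapse = ", "))
    }
    ph <- ph[match(cov$subject, ph$subject), , drop = FALSE]
    regions <- setdiff(colnames(ph), "subject")
    for (rg in regions) {
        v <- ph[[rg]]
        if (!is.numeric(v)) {
            bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
            stop("readNormativeDataset: non-numeric phenotype '", rg,
                 "' at row(s) ", paste(utils::head(bad, 10), collapse = ", "))
        }
    }
    keep <- !(is.na(cov$age) | is.na(cov$sex) | is.na(cov$site) |
              cov$sex == "" | cov$site == "")
    if (any(!keep))
        message("readNormativeDataset: dropped ", sum(!keep),
                " subject(s) with missing age/sex/site")
    cov <- cov[keep, , drop = FALSE]
    ph <- ph[keep, , drop = FALSE]
    if (!nrow(cov))
        stop("readNormativeDataset: no subjects left after filtering")
    group <- if ("group" %in% colnames(cov)) cov$group else NULL
    extra <- cov[, setdiff(colnames(cov),
                           c("subject", "age", "sex", "site", "group")),
                 drop = FALSE]
    NormativeDataset(as.matrix(ph[, regions, drop = FALSE]),
                     age = cov$age, sex = cov$sex, site = cov$site,
                     group = group, subject = cov$subject,
                     extraCovariates = if (ncol(extra)) extra else NULL)
}

#' Write a normative dataset to the two-table CSV format
#'
#' Ground-truth assays, when present, go to a sidecar
#' \code{<prefix>_groundtruth.csv} (per-subject true mean and sd per region).
#'
#' @param data a \code{\link{NormativeDataset}}.
#' @param prefix output path prefix; writes \code{<prefix>_covariates.csv}
#'   and \code{<prefix>_phenotypes.csv}.
#' @return invisibly, the paths written.
#' @export
writeNormativeDataset <- function(data, prefix) {
    cd <- as.data.frame(colData(data))
    cov <- cbind(subject = rownames(cd), cd)
    ph <- cbind(subject = rownames(cd),
                as.data.frame(phenotypeMatrix(data)))
    paths <- paste0(prefix, c("_covariates.csv", "_phenotypes.csv"))
    utils::write.csv(cov, paths[1], row.names = FALSE, quote = FALSE)
    utils::write.csv(ph, paths[2], row.names = FALSE, quote = FALSE)
    if (!is.null(trueMean(data))) {
        mu <- trueMean(data); sig <- trueSd(data)
        colnames(mu) <- paste0("mu_", colnames(mu))
        colnames(sig) <- paste0("sigma_", colnames(sig))
        gt <- cbind(subject = rownames(cd), as.data.frame(mu),
                    as.data.frame(sig))
        gtPath <- paste0(prefix, "_groundtruth.csv")
        utils::write.csv(gt, gtPath, row.names = FALSE, quote = FALSE)
        paths <- c(paths, gtPath)
    }
    invisible(paths)
}

.MODEL_FORMAT_VERSION <- 1L

#' Persist a trained HBR model to a directory
#'
#' The directory holds a versioned \code{meta.json} (basis, registry,
#' hyperprior, noise mode, fit range, standardization) and one CSV per
#' posterior array, so a model round-trips across sessions and machines in
#' plain text.
#'
#' @param model an \code{\link{HBRModel}}.
#' @param path directory to create/overwrite.
#' @export
saveHBRModel <- function(model, path) {
    stopifnot(is(model, "HBRModel"))
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    post <- model@posterior
    meta <- list(format = "fednorm-hbr-model",
                 version = .MODEL_FORMAT_VERSION,
                 region = model@region,
                 basis = list(kind = model@basis@kind,
                              nKnots = model@basis@nKnots,
                              extrapolation = model@basis@extrapolation),
                 registry = .registryToList(model@registry),
                 noiseMode = model@noiseMode,
                 fitRange = model@fitRange,
                 center = model@center, scale = model@scale,
                 sexLevels = model@sexLevels,
                 notes = model@notes,
                 chain = post@chain, rhat = as.list(post@rhat),
                 dims = list(theta = dim(post@theta),
                             thetaSigma = dim(post@thetaSigma)))
    jsonlite::write_json(meta, file.path(path, "meta.json"), digits = NA,
                         auto_unbox = TRUE, na = "null")
    wr <- function(m, name) utils::write.csv(
        as.data.frame(m), file.path(path, paste0(name, ".csv")),
        row.names = FALSE)
    wr(matrix(post@theta, nrow = dim(post@theta)[1]), "theta")
    if (model@noiseMode == "homoscedastic") wr(post@logSigma, "logSigma")
    else wr(matrix(post@thetaSigma, nrow = dim(post@thetaSigma)[1]),
            "thetaSigma")
    wr(post@muTheta, "muTheta")
    wr(post@logSdTheta, "logSdTheta")
    wr(post@muSigma, "muSigma")
    wr(post@logSdSigma, "logSdSigma")
    invisible(path)
}

#' @rdname saveHBRModel
#' @export
loadHBRModel <- function(path) {
    metaPath <- file.path(path, "meta.json")
    if (!file.exists(metaPath))
        stop("loadHBRModel: no meta.json under ", path)
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (is.null(meta$format) || meta$format != "fednorm-hbr-model")
        stop("loadHBRModel: not a fednorm model directory")
    if (meta$version != .MODEL_FORMAT_VERSION)
        stop("loadHBRModel: model format version ", meta$version,
             " not supported (expected ", .MODEL_FORMAT_VERSION, ")")
    rd <- function(name) {
        f <- file.path(path, paste0(name, ".csv"))
        if (!file.exists(f))
            stop("loadHBRModel: missing posterior array '", name, "'")
        as.matrix(utils::read.csv(f))
    }
    theta <- array(rd("theta"), dim = meta$dims$theta)
    hetero <- meta$noiseMode == "heteroscedastic"
    post <- new("PosteriorSamples",
                theta = theta,
                logSigma = if (hetero) matrix(0, 0, 0) else
                    unname(rd("logSigma")),
                thetaSigma = if (hetero)
                    array(rd("thetaSigma"), dim = meta$dims$thetaSigma)
                else array(0, c(0, 0, 0)),
                muTheta = unname(rd("muTheta")),
                logSdTheta = unname(rd("logSdTheta")),
                muSigma = unname(rd("muSigma")),
                logSdSigma = unname(rd("logSdSigma")),
                chain = as.integer(meta$chain),
                rhat = unlist(meta$rhat))
    basis <- basisConfig(meta$basis$kind, meta$basis$nKnots,
                         meta$basis$extrapolation)
    p <- basisDim(basis)
    new("HBRModel", region = meta$region, basis = basis,
        fitRange = as.numeric(meta$fitRange), includeSex = FALSE,
        sexLevels = as.character(meta$sexLevels),
        registry = .registryFromList(meta$registry),
        hyper = defaultHyperprior(p, meta$noiseMode),
        posterior = post, noiseMode = meta$noiseMode,
        center = as.numeric(meta$center), scale = as.numeric(meta$scale),
        notes = as.character(meta$notes %||% character()))
}

#' Stratified train/test split by site
#'
#' Randomly assigns \code{trainFraction} of the healthy subjects of each site
#' to the training split; patients (if any) always go to the test split —
#' normative models are trained on healthy subjects only, so anomaly
#' detection stays unsupervised.
#'
#' @param data a \code{\link{NormativeDataset}}.
#' @param trainFraction fraction of healthy subjects used for training
#'   (in (0, 1)).
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test}.
#' @export
splitBySite <- function(data, trainFraction = 0.8, seed = 1L) {
    if (!is.finite(trainFraction) || trainFraction <= 0 || trainFraction >= 1)
        stop("splitBySite: trainFraction must be in (0, 1)")
    healthy <- groups(data) == "healthy"
    st <- sites(data)
    trainIdx <- logical(ncol(data))
    withr::with_seed(as.integer(seed), {
        for (s in unique(st)) {
            idx <- which(healthy & st == s)
            nTr <- round(trainFraction * length(idx))
            if (length(idx))
                trainIdx[sample(idx, min(nTr, length(idx)))] <- TRUE
        }
    })
    list(train = data[, trainIdx], test = data[, !trainIdx])
}

#' Deterministic per-run seeds from one master seed
#' @param seed master seed.
#' @param nRuns number of runs.
#' @return integer vector of length \code{nRuns} (run r gets seed + r).
#' @export
runSeeds <- function(seed, nRuns) as.integer(seed) + seq_len(nRuns)
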
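#' Construct a NormativeDataset
#'
#' @param phenotypes numeric matrix with subjects in rows and named regions in
#'   columns (the natural orientation of a subject-level table; it is stored
#'   transposed, regions x subjects, as assay \code{"phenotype"}).
#' @param age numeric vector of ages in years.
#' @param sex character vector of sex labels.
#' @param site character vector of site labels.
#' @param group optional character vector, \code{"healthy"} (default) or
#'   \code{"patient"}.
#' @param subject optional subject ids; defaults to \code{S1..Sn}.
#' @param muTrue,sigmaTrue optional subjects x regions matrices of the
#'   ground-truth normative mean and noise sd (synthetic cohorts).
#' @param extraCovariates optional data.frame of further per-subject columns.
#' @return a \code{\link{NormativeDataset}}.
#' @export
NormativeDataset <- function(phenotypes, age, sex, site,
                             group = NULL, subject = NULL,
                             muTrue = NULL, sigmaTrue = NULL,
                             extraCovariates = NULL) {
    phenotypes <- as.matrix(phenotypes)
    n <- nrow(phenotypes)
    if (is.null(colnames(phenotypes)))
        colnames(phenotypes) <- sprintf("region%02d", seq_len(ncol(phenotypes)))
    if (is.null(subject)) subject <- sprintf("S%d", seq_len(n))
    if (is.null(group)) group <- rep("healthy", n)
    stopifnot(length(age) == n, length(sex) == n, length(site) == n,
              length(group) == n, length(subject) == n)
    cd <- DataFrame(age = as.numeric(age), sex = as.character(sex),
                    site = as.character(site), group = as.character(group),
                    row.names = subject)
    if (!is.null(extraCovariates))
        cd <- cbind(cd, as(extraCovariates, "DataFrame"))
    rownames(phenotypes) <- subject
    assaysList <- list(phenotype = t(phenotypes))
    if (!is.null(muTrue)) {
        muTrue <- as.matrix(muTrue); rownames(muTrue) <- subject
        assaysList$muTrue <- t(muTrue)
    }
    if (!is.null(sigmaTrue)) {
        sigmaTrue <- as.matrix(sigmaTrue); rownames(sigmaTrue) <- subject
        assaysList$sigmaTrue <- t(sigmaTrue)
    }
    se <- SummarizedExperiment(assays = assaysList, colData = cd)
    new("NormativeDataset", se)
}

#' Accessors for NormativeDataset
#'
#' \code{ages}, \code{sexes}, \code{sites}, \code{groups} return per-subject
#' covariates; \code{phenotypeMatrix} returns the subjects x regions matrix;
#' \code{regionNames} the region names; \code{trueMean}/\code{trueSd} the
#' ground-truth assays (or \code{NULL} when absent).
#'
#' @param x a \code{\link{NormativeDataset}}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("ages", "NormativeDataset", function(x) colData(x)$age)
#' @rdname accessors
#' @export
setMethod("sexes", "NormativeDataset", function(x) colData(x)$sex)
#' @rdname accessors
#' @export
setMethod("sites", "NormativeDataset", function(x) colData(x)$site)
#' @rdname accessors
#' @export
setMethod("groups", "NormativeDataset", function(x) colData(x)$group)
#' @rdname accessors
#' @export
setMethod("phenotypeMatrix", "NormativeDataset",
          function(x) t(assay(x, "phenotype")))
#' @rdname accessors
#' @export
setMethod("regionNames", "NormativeDataset", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("trueMean", "NormativeDataset", function(x)
    if ("muTrue" %in% assayNames(x)) t(assay(x, "muTrue")) else NULL)
#' @rdname accessors
#' @export
setMethod("trueSd", "NormativeDataset", function(x)
    if ("sigmaTrue" %in% assayNames(x)) t(assay(x, "sigmaTrue")) else NULL)

#' Extract one region's phenotype vector
#' @param data a \code{\link{NormativeDataset}}.
#' @param region region name or index.
#' @return named numeric vector (one value per subject).
#' @export
regionValues <- function(data, region) {
    if (is.character(region) && !region %in% rownames(data))
        stop(sprintf("region '%s' not present in dataset", region))
    assay(data, "phenotype")[region, ]
}

#' Row-bind two normative datasets (shared regions only)
#'
#' Used by the federated extension loop to concatenate a posterior-predictive
#' synthetic cohort with newly observed data. Only assays present in both
#' datasets are kept.
#' @param x,y \code{\link{NormativeDataset}} objects with identical regions.
#' @export
bindSubjects <- function(x, y) {
    if (nrow(y) == 0 || ncol(y) == 0) return(x)
    if (ncol(x) == 0) return(y)
    stopifnot(identical(rownames(x), rownames(y)))
    common <- intersect(assayNames(x), assayNames(y))
    subj <- make.unique(c(colnames(x), colnames(y)))
    as_lst <- lapply(common, function(a) {
        m <- cbind(assay(x, a), assay(y, a))
        colnames(m) <- subj
        m
    })
    names(as_lst) <- common
    commonCols <- intersect(colnames(colData(x)), colnames(colData(y)))
    cd <- rbind(colData(x)[, commonCols, drop = FALSE],
                colData(y)[, commonCols, drop = FALSE])
    rownames(cd) <- subj
    new("NormativeDataset",
        SummarizedExperiment(assays = as_lst, colData = cd))
}

#' Subset a dataset to given subjects
#' @param data a \code{\link{NormativeDataset}}.
#' @param idx logical or integer subject index.
#' @export
subsetSubjects <- function(data, idx) data[, idx]

setMethod("show", "NormativeDataset", function(object) {
    cat("NormativeDataset:", ncol(object), "subjects x", nrow(object),
        "regions\n")
    cat("  sites:", paste(unique(sites(object)), collapse = ", "), "\n")
    cat("  age range:", paste(round(range(ages(object)), 1), collapse = "-"),
        " sexes:", paste(unique(sexes(object)), collapse = "/"),
        " patients:", sum(groups(object) == "patient"), "\n")
})
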
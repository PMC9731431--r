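#' Build a registry of observed (site, sex) batches
#'
#' Both site and sex are treated as group-effects; their observed cross-product
#' defines the batches, each of which receives its own parameter set under the
#' shared hierarchical prior. Ordering is lexicographic by (site, sex), hence
#' deterministic and stable under serialization.
#'
#' @param siteLabels,sexLabels equal-length character vectors; missing values
#'   raise an error listing the offending rows.
#' @return a \code{\link{BatchRegistry}}.
#' @export
registerBatches <- function(siteLabels, sexLabels) {
    if (length(siteLabels) != length(sexLabels))
        stop("registerBatches: label vectors must have equal length")
    bad <- which(is.na(siteLabels) | is.na(sexLabels) |
                 siteLabels == "" | sexLabels == "")
    if (length(bad))
        stop("registerBatches: missing site/sex labels at rows ",
             paste(utils::head(bad, 10), collapse = ", "))
    key <- paste(siteLabels, sexLabels, sep = "\r")
    tab <- table(key)
    keys <- sort(names(tab))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    new("BatchRegistry",
        site = vapply(parts, `[`, "", 1L),
        sex = vapply(parts, `[`, "", 2L),
        counts = as.integer(tab[keys]))
}

#' @rdname BatchRegistry-class
#' @export
setMethod("nBatches", "BatchRegistry", function(x) length(x@site))

#' @rdname BatchRegistry-class
#' @export
setMethod("batchLabels", "BatchRegistry", function(x)
    data.frame(site = x@site, sex = x@sex, index = seq_along(x@site),
               count = x@counts, stringsAsFactors = FALSE))

#' @rdname BatchRegistry-class
#' @export
setMethod("batchCounts", "BatchRegistry", function(x) {
    stats::setNames(x@counts, paste(x@site, x@sex, sep = ":"))
})

#' @rdname BatchRegistry-class
#' @export
setMethod("batchIndex", "BatchRegistry", function(x, site, sex) {
    key <- paste(x@site, x@sex, sep = "\r")
    match(paste(site, sex, sep = "\r"), key)
})

setMethod("show", "BatchRegistry", function(object) {
    cat("BatchRegistry with", nBatches(object), "observed (site, sex) batches\n")
    print(batchLabels(object), row.names = FALSE)
})

## plain-list form used by JSON (de)serialization
.registryToList <- function(reg) {
    list(site = reg@site, sex = reg@sex, counts = reg@counts)
}

.registryFromList <- function(lst) {
    new("BatchRegistry", site = as.character(lst$site),
        sex = as.character(lst$sex), counts = as.integer(lst$counts))
}
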
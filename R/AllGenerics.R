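#' @import methods
NULL

#' Predict normative mean and standard deviation
#'
#' Evaluates the fitted normative model at new covariate values, returning the
#' batch-specific posterior-mean (or least-squares) estimate of the normative
#' mean and noise standard deviation for every subject.
#'
#' @param object a fitted normative model.
#' @param age numeric vector of ages in years.
#' @param sex character vector of sex labels.
#' @param site character vector of site labels.
#' @param ... further arguments passed to methods (e.g. \code{allowUnseen}).
#' @return a \code{data.frame} with columns \code{mu} and \code{sigma};
#'   \code{sigma} is strictly positive.
#' @export
setGeneric("predictNorm", function(object, age, sex, site, ...)
    standardGeneric("predictNorm"))

#' Compute per-subject deviation scores
#'
#' Scores every subject in \code{data} against the normative model:
#' \eqn{z = (y - f_\mu(x)) / f^+_\sigma(x)} with the batch-specific mean and
#' noise functions, plus the abnormal probability index
#' \eqn{P_{abn}(z) = 2\Phi(|z|) - 1}.
#'
#' @param object a fitted normative model.
#' @param data a \code{\link{NormativeDataset}}.
#' @param region region name; defaults to the region the model was fitted on.
#' @param ... passed to \code{\link{predictNorm}}.
#' @return a \code{data.frame} with columns \code{subject}, \code{region},
#'   \code{z} and \code{pAbn}.
#' @export
setGeneric("deviationScores", function(object, data, ...)
    standardGeneric("deviationScores"))

#' @rdname accessors
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))
#' @rdname accessors
#' @export
setGeneric("sexes", function(x) standardGeneric("sexes"))
#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))
#' @rdname accessors
#' @export
setGeneric("phenotypeMatrix", function(x) standardGeneric("phenotypeMatrix"))
#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setGeneric("trueMean", function(x) standardGeneric("trueMean"))
#' @rdname accessors
#' @export
setGeneric("trueSd", function(x) standardGeneric("trueSd"))

#' @rdname BatchRegistry-class
#' @export
setGeneric("nBatches", function(x) standardGeneric("nBatches"))
#' @rdname BatchRegistry-class
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))
#' @rdname BatchRegistry-class
#' @export
setGeneric("batchIndex", function(x, site, sex) standardGeneric("batchIndex"))
#' @rdname BatchRegistry-class
#' @export
setGeneric("batchCounts", function(x) standardGeneric("batchCounts"))
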
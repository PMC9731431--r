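#' Expand age into a design matrix
#'
#' \code{"linear"} gives columns \code{[1, age]}; \code{"polynomial3"} gives
#' \code{[1, age, age^2, age^3]}; \code{"bspline3"} gives the full cubic
#' B-spline basis with \code{nKnots} interior knots evenly spaced over
#' \code{fitRange} (the full basis forms a partition of unity and spans
#' constants, so it carries its own intercept). Ages outside \code{fitRange}
#' are handled by the config's extrapolation rule: \code{"clamp"} evaluates
#' the basis at the nearest boundary, \code{"linear"} extends it to first
#' order beyond the boundary.
#'
#' @param age numeric vector of ages in years (finite).
#' @param config a \code{\link{basisConfig}}.
#' @param fitRange length-2 numeric, the training age range (lo < hi).
#' @return numeric matrix with one row per age.
#' @export
expandBasis <- function(age, config, fitRange) {
    stopifnot(is(config, "BasisConfig"))
    if (!length(age))
        stop("expandBasis: empty age vector")
    if (any(!is.finite(age)))
        stop("expandBasis: ages must be finite")
    if (length(fitRange) != 2L || !all(is.finite(fitRange)) ||
        fitRange[1] >= fitRange[2])
        stop("expandBasis: degenerate fitRange (need lo < hi)")
    lo <- fitRange[1]; hi <- fitRange[2]
    inside <- pmin(pmax(age, lo), hi)
    B <- .basisRaw(inside, config, lo, hi)
    if (config@extrapolation == "linear") {
        out <- which(age < lo | age > hi)
        if (length(out)) {
            h <- 1e-4 * (hi - lo)
            for (s in out) {
                edge <- if (age[s] < lo) lo else hi
                d <- if (age[s] < lo)
                    (.basisRaw(edge + h, config, lo, hi) -
                     .basisRaw(edge, config, lo, hi)) / h
                else
                    (.basisRaw(edge, config, lo, hi) -
                     .basisRaw(edge - h, config, lo, hi)) / h
                B[s, ] <- .basisRaw(edge, config, lo, hi) +
                    d * (age[s] - edge)
            }
        }
    }
    unname(B)
}

.basisRaw <- function(x, config, lo, hi) {
    switch(config@kind,
        linear = cbind(1, x),
        polynomial3 = cbind(1, x, x^2, x^3),
        bspline3 = {
            knots <- seq(lo, hi,
                         length.out = config@nKnots + 2L)[-c(1, config@nKnots + 2L)]
            m <- splines::bs(x, knots = knots, degree = 3L, intercept = TRUE,
                             Boundary.knots = c(lo, hi))
            matrix(as.numeric(m), nrow = length(x))
        })
}

#' Number of design columns for a basis
#' @param config a \code{\link{basisConfig}}.
#' @export
basisDim <- function(config) {
    switch(config@kind, linear = 2L, polynomial3 = 4L,
           bspline3 = config@nKnots + 4L)
}
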
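#' Edge-preserving Gaussian bilateral filter
#'
#' Smooths a single image plane with the classical bilateral filter: each
#' output pixel is the weighted average of the input pixels inside a
#' square window, with weights the product of a Gaussian in spatial
#' distance (`sigmaSpatial`) and a Gaussian in intensity difference
#' (`sigmaRange`). Large intensity steps therefore survive smoothing —
#' the property that keeps focus edges sharp while suppressing noise.
#'
#' The window is truncated at image borders (border pixels average over
#' fewer neighbours; no values are invented by padding). Output at every
#' pixel is bounded by the min and max of its own window, and a constant
#' image is returned unchanged.
#'
#' @param img numeric matrix, finite values.
#' @param sigmaSpatial spatial Gaussian sd in pixels (default 2).
#' @param sigmaRange range Gaussian sd in intensity units; default
#'   `0.1 * (max - min)` of the plane.
#' @param radius window half-width in pixels; default
#'   `2 * ceiling(sigmaSpatial)`.
#' @return numeric matrix of the same shape.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' sm <- bilateralFilter(img, sigmaSpatial = 1.5)
#' @export
bilateralFilter <- function(img, sigmaSpatial = 2, sigmaRange = NULL,
                            radius = NULL) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("img must be a numeric matrix")
  }
  if (!all(is.finite(img))) stop("img contains non-finite values")
  if (sigmaSpatial <= 0) stop("sigmaSpatial must be > 0")
  dyn <- max(img) - min(img)
  if (is.null(sigmaRange)) sigmaRange <- 0.1 * dyn
  if (is.null(radius)) radius <- 2L * as.integer(ceiling(sigmaSpatial))
  if (radius < 1) stop("radius must be >= 1")
  if (dyn == 0) {
    return(img) # constant image: all range weights equal, average = c
  }
  if (sigmaRange <= 0) stop("sigmaRange must be > 0")
  cpp_bilateral(img, sigmaSpatial, sigmaRange, as.integer(radius))
}

#' Bilateral-smooth every plane of a stack
#'
#' Applies [bilateralFilter()] plane by plane — the pre-processing order
#' used throughout the pipeline: smooth each plane first, then project.
#'
#' @param stack a \linkS4class{ZStack}.
#' @inheritParams bilateralFilter
#' @return a \linkS4class{ZStack} of smoothed planes.
#' @export
smoothStack <- function(stack, sigmaSpatial = 2, sigmaRange = NULL,
                        radius = NULL) {
  stopifnot(is(stack, "ZStack"))
  d <- stack@data
  for (k in seq_len(dim(d)[3])) {
    d[, , k] <- bilateralFilter(d[, , k], sigmaSpatial, sigmaRange, radius)
  }
  initialize(stack, data = d)
}

#' @rdname maxIntensityProjection
#' @export
setMethod("maxIntensityProjection", "ZStack", function(x) {
  maxIntensityProjection(x@data)
})

#' @rdname maxIntensityProjection
#' @export
setMethod("maxIntensityProjection", "array", function(x) {
  if (length(dim(x)) != 3L || dim(x)[3] < 1L) {
    stop("need a 3-D array with at least one plane")
  }
  mip <- x[, , 1L]
  for (k in seq_len(dim(x)[3])[-1L]) mip <- pmax(mip, x[, , k])
  ProjectionImage(mip, normalized = FALSE)
})

#' @rdname normalize01
#' @export
setMethod("normalize01", "matrix", function(x) {
  if (!all(is.finite(x))) stop("image contains non-finite values")
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    warning("constant image: returning all zeros")
    return(array(0, dim(x)))
  }
  (x - lo) / (hi - lo)
})

#' @rdname normalize01
#' @export
setMethod("normalize01", "ProjectionImage", function(x) {
  ProjectionImage(normalize01(x@data), normalized = TRUE)
})
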
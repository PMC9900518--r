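#' @import methods
NULL

#' @rdname ZStack
#' @param object,x a \linkS4class{ZStack} (or other object, per method)
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname ZStack
#' @export
setGeneric("planeCount", function(x) standardGeneric("planeCount"))

#' @rdname ZStack
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname ProjectionImage
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname LabeledNuclei
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))

#' @rdname LabeledNuclei
#' @export
setGeneric("nucleusRecords", function(x) standardGeneric("nucleusRecords"))

#' @rdname LabeledNuclei
#' @export
setGeneric("nucleusCount", function(x) standardGeneric("nucleusCount"))

#' @rdname FociSet
#' @export
setGeneric("fociTable", function(x) standardGeneric("fociTable"))

#' @rdname FociSet
#' @export
setGeneric("fociCounts", function(x) standardGeneric("fociCounts"))

#' @rdname SceneTruth
#' @export
setGeneric("plantedFoci", function(x) standardGeneric("plantedFoci"))

#' @rdname SceneTruth
#' @export
setGeneric("totalFoci", function(x) standardGeneric("totalFoci"))

#' Maximum intensity projection
#'
#' Per-pixel maximum across the planes of a z-stack. The result is always
#' at least as bright as any single plane, is unchanged by permuting the
#' planes, and for a single-plane stack equals that plane.
#'
#' @param x a \linkS4class{ZStack}, or a 3-D numeric array.
#' @return a \linkS4class{ProjectionImage} with `normalized = FALSE`.
#' @examples
#' st <- ZStack(array(runif(4 * 4 * 3), c(4, 4, 3)))
#' mip <- maxIntensityProjection(st)
#' @export
setGeneric("maxIntensityProjection",
  function(x) standardGeneric("maxIntensityProjection")
)

#' Linear 0--1 normalization
#'
#' Maps an image linearly so that its minimum becomes 0 and its maximum
#' becomes 1: `(I - min) / (max - min)`. Applying it twice is the
#' identity, and any positive affine rescaling of the input yields the
#' same output. A perfectly constant image (e.g. a blank control field)
#' is returned as all zeros with a warning rather than an error, so blank
#' fields flow through the pipeline.
#'
#' @param x a \linkS4class{ProjectionImage} or numeric matrix.
#' @return same type as the input, flagged/known normalized.
#' @export
setGeneric("normalize01", function(x) standardGeneric("normalize01"))

#' Fold change in mean foci per nucleus
#'
#' Ratio of the pooled mean foci per nucleus of a post-treatment well to
#' that of its baseline (pre-treatment) well — the readout used to
#' express the response of 53BP1 reporter foci to a genotoxic challenge.
#'
#' @param post,baseline \linkS4class{WellSummary} objects.
#' @return numeric ratio.
#' @export
setGeneric("foldChange",
  function(post, baseline) standardGeneric("foldChange")
)
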
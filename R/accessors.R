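#' Construct a ZStack
#'
#' @param data numeric 3-D array (rows, cols, planes) of non-negative
#'   intensities; a matrix is promoted to a single-plane stack.
#' @param pixelSize,planeSpacing optional micrometre spacings.
#' @param channelName channel label.
#' @return a \linkS4class{ZStack}.
#' @examples
#' ZStack(array(0, c(8, 8, 3)), planeSpacing = 0.8, channelName = "foci")
#' @export
ZStack <- function(data, pixelSize = NA_real_, planeSpacing = NA_real_,
                   channelName = "") {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("ZStack",
    data = data, pixelSize = as.numeric(pixelSize),
    planeSpacing = as.numeric(planeSpacing),
    channelName = as.character(channelName)
  )
}

#' Construct a ProjectionImage
#'
#' @param data numeric matrix.
#' @param normalized logical; assert values already lie in `[0, 1]`.
#' @return a \linkS4class{ProjectionImage}.
#' @export
ProjectionImage <- function(data, normalized = FALSE) {
  new("ProjectionImage", data = data, normalized = normalized)
}

#' @rdname ZStack
#' @export
setMethod("imgData", "ZStack", function(x) x@data)

#' @rdname ProjectionImage
#' @param x a \linkS4class{ProjectionImage}
#' @export
setMethod("imgData", "ProjectionImage", function(x) x@data)

#' @rdname ZStack
#' @export
setMethod("planeCount", "ZStack", function(x) dim(x@data)[3])

#' @rdname ZStack
#' @export
setMethod("channelName", "ZStack", function(x) x@channelName)

#' @rdname ProjectionImage
#' @export
setMethod("isNormalized", "ProjectionImage", function(x) x@normalized)

#' @rdname LabeledNuclei
#' @param x a \linkS4class{LabeledNuclei}
#' @export
setMethod("labelImage", "LabeledNuclei", function(x) x@labelImage)

#' @rdname LabeledNuclei
#' @export
setMethod("nucleusRecords", "LabeledNuclei", function(x) x@records)

#' @rdname LabeledNuclei
#' @export
setMethod("nucleusCount", "LabeledNuclei", function(x) nrow(x@records))

#' @rdname SceneTruth
#' @param x a \linkS4class{SceneTruth}
#' @export
setMethod("labelImage", "SceneTruth", function(x) x@labelImage)

#' @rdname SceneTruth
#' @export
setMethod("nucleusRecords", "SceneTruth", function(x) x@nuclei)

#' @rdname SceneTruth
#' @export
setMethod("plantedFoci", "SceneTruth", function(x) x@foci)

#' @rdname SceneTruth
#' @export
setMethod("totalFoci", "SceneTruth", function(x) nrow(x@foci))

#' @rdname FociSet
#' @param x a \linkS4class{FociSet}
#' @export
setMethod("fociTable", "FociSet", function(x) x@foci)

#' @rdname FociSet
#' @export
setMethod("fociCounts", "FociSet", function(x) x@perNucleusCounts)

#' @rdname WellSummary
#' @param x a \linkS4class{WellSummary}
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname WellSummary
#' @export
setMethod("wellId", "WellSummary", function(x) x@wellId)

#' @rdname WellSummary
#' @export
setGeneric("meanFociPerNucleus",
  function(x) standardGeneric("meanFociPerNucleus")
)

#' @rdname WellSummary
#' @export
setMethod("meanFociPerNucleus", "WellSummary",
  function(x) x@meanFociPerNucleus
)

setMethod("show", "ZStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ZStack '%s': %d x %d px, %d plane(s)\n",
    object@channelName, d[1], d[2], d[3]
  ))
  if (!is.na(object@planeSpacing)) {
    cat(sprintf("  plane spacing: %g um\n", object@planeSpacing))
  }
  cat(sprintf(
    "  intensity range: [%g, %g]\n",
    min(object@data), max(object@data)
  ))
})

setMethod("show", "ProjectionImage", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ProjectionImage: %d x %d px%s\n", d[1], d[2],
    if (object@normalized) ", normalized [0,1]" else ""
  ))
})

setMethod("show", "LabeledNuclei", function(object) {
  cat(sprintf("LabeledNuclei: %d nuclei\n", nrow(object@records)))
  if (nrow(object@records)) {
    cat(sprintf(
      "  area: %d-%d px^2 (median %g)\n",
      min(object@records$area), max(object@records$area),
      stats::median(object@records$area)
    ))
  }
})

setMethod("show", "FociSet", function(object) {
  cat(sprintf(
    "FociSet: %d foci over %d nuclei (%d unassigned)\n",
    nrow(object@foci), length(object@perNucleusCounts),
    sum(is.na(object@foci$nucleus))
  ))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf(
    "SceneTruth: %d nuclei, %d planted foci\n",
    nrow(object@nuclei), nrow(object@foci)
  ))
})

setMethod("show", "WellSummary", function(object) {
  cat(sprintf(
    "WellSummary '%s': %d nuclei, %d foci, mean %s foci/nucleus (%d field(s))\n",
    object@wellId, object@nNuclei, object@nFoci,
    format(object@meanFociPerNucleus, digits = 4), nrow(object@perField)
  ))
})
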
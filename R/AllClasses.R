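#' ZStack: one channel's plane-indexed intensity volume
#'
#' Container for a single-channel fluorescence z-stack: a `height x width
#' x n_planes` array of non-negative intensities in arbitrary detector
#' units, plus optional spacing metadata. This mirrors the acquisition
#' regime the pipeline targets (multi-plane stacks, typically 7--9 planes
#' at ~0.8 micrometre intervals).
#'
#' @slot data numeric 3-D array, dimensions (rows, cols, planes).
#' @slot pixelSize lateral pixel size in micrometres (`NA` if unknown).
#' @slot planeSpacing axial plane spacing in micrometres (`NA` if unknown).
#' @slot channelName character label, e.g. `"nuclear"` or `"foci"`.
#'
#' @seealso [ZStack()], [maxIntensityProjection()]
#' @exportClass ZStack
setClass("ZStack",
  representation(
    data = "array",
    pixelSize = "numeric",
    planeSpacing = "numeric",
    channelName = "character"
  ),
  prototype(
    pixelSize = NA_real_,
    planeSpacing = NA_real_,
    channelName = ""
  )
)

setValidity("ZStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) {
    return("data must be a 3-D array (rows, cols, planes)")
  }
  if (dim(d)[3] < 1L) {
    return("a ZStack needs at least one plane")
  }
  if (!all(is.finite(d))) {
    return("intensities must be finite")
  }
  if (any(d < 0)) {
    return("intensities must be non-negative")
  }
  TRUE
})

#' ProjectionImage: a 2-D projection of a z-stack
#'
#' A single 2-D intensity image, typically the maximum intensity
#' projection (MIP) of a [ZStack]. The `normalized` flag records whether
#' intensities have been linearly mapped to `[0, 1]`.
#'
#' @slot data numeric matrix.
#' @slot normalized logical; if `TRUE`, values lie in `[0, 1]`.
#'
#' @seealso [maxIntensityProjection()], [normalize01()]
#' @exportClass ProjectionImage
setClass("ProjectionImage",
  representation(data = "matrix", normalized = "logical"),
  prototype(normalized = FALSE)
)

setValidity("ProjectionImage", function(object) {
  d <- object@data
  if (!is.numeric(d)) {
    return("data must be a numeric matrix")
  }
  if (!all(is.finite(d))) {
    return("intensities must be finite")
  }
  if (isTRUE(object@normalized) && length(d) &&
    (min(d) < 0 || max(d) > 1)) {
    return("normalized image must have values in [0, 1]")
  }
  TRUE
})

#' LabeledNuclei: segmented nuclei over a 2-D field
#'
#' An integer label image (0 = background, 1..n = nuclei) together with a
#' per-nucleus record table (`id`, `area` in pixels^2, centroid `cy`/`cx`
#' in pixel coordinates, and the bounding box).
#'
#' @slot labelImage integer matrix of nucleus labels.
#' @slot records data.frame with columns `id`, `area`, `cy`, `cx`,
#'   `ymin`, `ymax`, `xmin`, `xmax`.
#'
#' @seealso [segmentNuclei()]
#' @exportClass LabeledNuclei
setClass("LabeledNuclei",
  representation(labelImage = "matrix", records = "data.frame")
)

setValidity("LabeledNuclei", function(object) {
  lab <- object@labelImage
  rec <- object@records
  n <- if (nrow(rec)) max(rec$id) else 0L
  labs <- sort(unique(as.integer(lab[lab > 0])))
  if (nrow(rec) && !identical(labs, seq_len(n))) {
    return("labels must be contiguous 1..n")
  }
  if (nrow(rec) != length(labs)) {
    return("one record per label required")
  }
  if (nrow(rec)) {
    cnt <- tabulate(lab[lab > 0], nbins = n)
    if (!all(rec$area[order(rec$id)] == cnt)) {
      return("record areas must equal label pixel counts")
    }
  }
  TRUE
})

#' FociSet: detected foci with nucleus assignment
#'
#' The result of focus detection on one field: a table of foci (component
#' id, intensity-weighted centroid, area, peak intensity, assigned
#' nucleus id or `NA` for extranuclear foci) plus per-nucleus counts over
#' every nucleus in the paired segmentation (zeros included).
#'
#' @slot foci data.frame with columns `id`, `cy`, `cx`, `area`, `peak`,
#'   `nucleus` (integer, `NA` = outside all nuclei).
#' @slot perNucleusCounts named integer vector, one entry per nucleus id.
#'
#' @seealso [detectFoci()], [fociCounts()]
#' @exportClass FociSet
setClass("FociSet",
  representation(foci = "data.frame", perNucleusCounts = "integer")
)

setValidity("FociSet", function(object) {
  cnt <- object@perNucleusCounts
  assigned <- object@foci$nucleus[!is.na(object@foci$nucleus)]
  if (length(cnt)) {
    ids <- as.integer(names(cnt))
    recount <- vapply(ids, function(i) sum(assigned == i), integer(1))
    if (!all(recount == unname(cnt))) {
      return("perNucleusCounts must recount the assigned foci")
    }
    if (any(!assigned %in% ids)) {
      return("foci assigned to unknown nucleus ids")
    }
  } else if (length(assigned)) {
    return("assigned foci but no nuclei")
  }
  TRUE
})

#' SceneTruth: ground truth for a synthetic scene
#'
#' What the generator actually planted: the nucleus label image, a
#' per-nucleus record table and the list of planted focus centres in
#' (z, y, x) pixel/plane coordinates. Stands in for manual annotation
#' when validating the detection stages.
#'
#' @slot labelImage integer matrix of nucleus labels (0 background).
#' @slot nuclei data.frame with columns `id`, `cy`, `cx`, `ry`, `rx`,
#'   `area`.
#' @slot foci data.frame with columns `nucleus`, `z`, `y`, `x`.
#'
#' @seealso [simulateScene()]
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(
    labelImage = "matrix",
    nuclei = "data.frame",
    foci = "data.frame"
  )
)

setValidity("SceneTruth", function(object) {
  f <- object@foci
  if (nrow(f)) {
    lab <- object@labelImage
    at <- lab[cbind(round(f$y), round(f$x))]
    if (!all(at == f$nucleus)) {
      return("every planted focus centre must lie inside its nucleus")
    }
  }
  TRUE
})

#' WellSummary: pooled foci statistics for one well
#'
#' Aggregation over all fields imaged in a well: total nuclei, total
#' assigned foci, and the pooled mean foci per nucleus (sum of foci over
#' sum of nuclei, not a mean of field means). `meanFociPerNucleus` is
#' `NA` when the well contains no nuclei.
#'
#' @slot wellId character well identifier.
#' @slot nNuclei integer total nuclei across fields.
#' @slot nFoci integer total nucleus-assigned foci across fields.
#' @slot meanFociPerNucleus numeric pooled ratio (`NA` if undefined).
#' @slot perField data.frame per-field breakdown (`field`, `nNuclei`,
#'   `nFoci`).
#'
#' @seealso [summarizeWell()], [foldChange()]
#' @exportClass WellSummary
setClass("WellSummary",
  representation(
    wellId = "character",
    nNuclei = "integer",
    nFoci = "integer",
    meanFociPerNucleus = "numeric",
    perField = "data.frame"
  )
)

setValidity("WellSummary", function(object) {
  if (object@nNuclei > 0L) {
    m <- object@nFoci / object@nNuclei
    if (!isTRUE(all.equal(m, object@meanFociPerNucleus))) {
      return("mean must equal nFoci / nNuclei")
    }
  } else if (!is.na(object@meanFociPerNucleus)) {
    return("mean is undefined (NA) when the well has no nuclei")
  }
  TRUE
})
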
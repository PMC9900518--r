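#' Foci detection configuration
#'
#' Parameters for [detectFoci()]. `h` is the peak-prominence depth of the
#' extended-maxima transform on the 0--1 normalized scale; the area
#' bounds discard single-pixel noise spikes and large non-focal blobs.
#'
#' @param h extended-maxima depth in `(0, 1]` (default 0.1).
#' @param minFocusArea,maxFocusArea retained focus area bounds, pixels^2
#'   (defaults 2 and 200).
#' @param connectivity 4 or 8 (default 8).
#' @param minDynamicRange flat-field guard passed to [extendedMaxima()]
#'   (default 0.05, on the pre-normalization intensity scale of the image
#'   handed to the detector).
#' @param restrictToNuclei if `TRUE`, maxima are detected after masking
#'   the field to the nuclei; default `FALSE` detects on the whole field
#'   so near-boundary maxima are not clipped, then assigns by centroid.
#' @return a list of validated settings.
#' @export
fociConfig <- function(h = 0.1, minFocusArea = 2, maxFocusArea = 200,
                       connectivity = 8L, minDynamicRange = 0.05,
                       restrictToNuclei = FALSE) {
  if (h <= 0) stop("h must be > 0")
  if (!(minFocusArea > 0 && minFocusArea <= maxFocusArea)) {
    stop("need 0 < minFocusArea <= maxFocusArea")
  }
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  list(
    h = h, minFocusArea = minFocusArea, maxFocusArea = maxFocusArea,
    connectivity = as.integer(connectivity),
    minDynamicRange = minDynamicRange,
    restrictToNuclei = isTRUE(restrictToNuclei)
  )
}

#' Detect bright nuclear foci
#'
#' Applies the extended-maxima transform to the normalized foci-channel
#' MIP, labels the resulting peak mask, filters components by area, and
#' assigns each surviving focus to the nucleus whose label contains its
#' intensity-weighted centroid (`NA` if that pixel is background). Every
#' nucleus in `nuclei` appears in the per-nucleus counts, zeros included;
#' unassigned (extranuclear) foci are kept in the focus table but never
#' counted.
#'
#' @param mip normalized \linkS4class{ProjectionImage} of the foci
#'   channel, or numeric matrix in `[0, 1]`.
#' @param nuclei \linkS4class{LabeledNuclei} from the paired nuclear
#'   channel (same field, same shape).
#' @param config a [fociConfig()] list.
#' @return a \linkS4class{FociSet}.
#' @export
detectFoci <- function(mip, nuclei, config = fociConfig()) {
  img <- if (is(mip, "ProjectionImage")) {
    if (!isNormalized(mip)) stop("mip must be normalized (see normalize01)")
    imgData(mip)
  } else {
    mip
  }
  stopifnot(is.matrix(img), is(nuclei, "LabeledNuclei"))
  lab <- labelImage(nuclei)
  if (!identical(dim(img), dim(lab))) {
    stop("foci MIP and nucleus labels have different shapes")
  }
  det <- img
  if (config$restrictToNuclei) det[lab == 0L] <- min(img)
  em <- extendedMaxima(det, config$h, config$connectivity,
    minDynamicRange = config$minDynamicRange
  )
  comp <- labelComponents(em, config$connectivity)
  st <- componentStats(comp, weights = img)
  st <- st[st$area >= config$minFocusArea & st$area <= config$maxFocusArea, ,
    drop = FALSE
  ]
  nNuc <- nucleusCount(nuclei)
  if (nrow(st)) {
    ry <- pmin(pmax(round(st$cy), 1L), nrow(lab))
    rx <- pmin(pmax(round(st$cx), 1L), ncol(lab))
    nuc <- lab[cbind(ry, rx)]
    nuc[nuc == 0L] <- NA_integer_
    foci <- data.frame(
      id = seq_len(nrow(st)), cy = st$cy, cx = st$cx,
      area = st$area, peak = st$peak, nucleus = as.integer(nuc)
    )
  } else {
    foci <- data.frame(
      id = integer(), cy = numeric(), cx = numeric(),
      area = integer(), peak = numeric(), nucleus = integer()
    )
  }
  counts <- vapply(
    seq_len(nNuc),
    function(i) sum(!is.na(foci$nucleus) & foci$nucleus == i), integer(1)
  )
  names(counts) <- as.character(seq_len(nNuc))
  new("FociSet", foci = foci, perNucleusCounts = counts)
}

#' Aggregate fields into a well summary
#'
#' Pools every imaged field of a well: total nuclei, total
#' nucleus-assigned foci, and the pooled mean foci per nucleus (sum of
#' foci over sum of nuclei — robust to uneven field occupancy, unlike a
#' mean of field means). A well with no nuclei yields `NA` for the mean
#' rather than an error.
#'
#' @param fociSets list of \linkS4class{FociSet}, one per field.
#' @param wellId character identifier.
#' @param fieldIds optional character vector naming the fields.
#' @return a \linkS4class{WellSummary}.
#' @examples
#' # counts 2,4,6 in one field -> mean 4; pooling two fields keeps the
#' # ratio of totals, not the average of per-field means
#' @export
summarizeWell <- function(fociSets, wellId = "well",
                          fieldIds = NULL) {
  if (!length(fociSets)) stop("need at least one field")
  stopifnot(all(vapply(fociSets, is, logical(1), "FociSet")))
  if (is.null(fieldIds)) {
    fieldIds <- sprintf("field%02d", seq_along(fociSets))
  }
  nNuc <- vapply(fociSets, function(f) length(fociCounts(f)), integer(1))
  nFoc <- vapply(fociSets, function(f) sum(fociCounts(f)), integer(1))
  perField <- data.frame(
    field = fieldIds, nNuclei = nNuc, nFoci = nFoc,
    row.names = NULL
  )
  tot <- sum(nNuc)
  new("WellSummary",
    wellId = as.character(wellId), nNuclei = as.integer(tot),
    nFoci = as.integer(sum(nFoc)),
    meanFociPerNucleus = if (tot > 0L) sum(nFoc) / tot else NA_real_,
    perField = perField
  )
}

#' @rdname foldChange
#' @export
setMethod(
  "foldChange", signature("WellSummary", "WellSummary"),
  function(post, baseline) {
    b <- meanFociPerNucleus(baseline)
    if (is.na(b)) {
      stop("fold change undefined: baseline well has no nuclei")
    }
    if (b == 0) {
      stop("fold change undefined: baseline mean foci per nucleus is 0")
    }
    meanFociPerNucleus(post) / b
  }
)
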
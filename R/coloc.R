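#' Pearson colocalization within a mask
#'
#' Sample Pearson correlation of two channels' intensities computed over
#' the masked pixels only — the colocalization index used to quantify,
#' e.g., the overlap of BRCA1 with gamma-H2AX within nuclei. Invariant
#' under positive affine transforms of either channel; negating one
#' channel flips the sign.
#'
#' @param channelA,channelB numeric matrices of equal shape.
#' @param mask logical matrix (or a \linkS4class{LabeledNuclei}, whose
#'   nonzero labels form the mask) with at least 2 `TRUE` pixels.
#' @return a one-row data.frame: `pearsonR`, `nPixels`, `maskSource`.
#' @examples
#' a <- matrix(runif(64), 8, 8)
#' m <- matrix(TRUE, 8, 8)
#' pearsonWithinMask(a, 2 * a + 1, m)$pearsonR # exactly 1
#' @export
pearsonWithinMask <- function(channelA, channelB, mask) {
  maskSource <- "mask"
  if (is(mask, "LabeledNuclei")) {
    maskSource <- "nuclei"
    mask <- labelImage(mask) > 0L
  }
  stopifnot(is.matrix(channelA), is.matrix(channelB), is.matrix(mask))
  if (!identical(dim(channelA), dim(channelB)) ||
    !identical(dim(channelA), dim(mask))) {
    stop("channelA, channelB and mask must have the same shape")
  }
  storage.mode(mask) <- "logical"
  a <- channelA[mask]
  b <- channelB[mask]
  if (length(a) < 2L) stop("mask must contain at least 2 pixels")
  if (stats::var(a) == 0) stop("channel_a has zero variance within mask")
  if (stats::var(b) == 0) stop("channel_b has zero variance within mask")
  data.frame(
    pearsonR = stats::cor(a, b), nPixels = length(a),
    maskSource = maskSource
  )
}

#' Marker intensity normalized to DAPI, per nucleus
#'
#' For each nucleus, the ratio of the mean marker intensity to the mean
#' DAPI (nuclear stain) intensity within that nucleus's label, plus the
#' pooled value (mean of per-nucleus ratios). Nuclei whose DAPI mean is
#' zero are flagged and excluded from the pooled mean.
#'
#' @param marker,dapi \linkS4class{ProjectionImage}s or numeric matrices
#'   of equal shape.
#' @param nuclei a \linkS4class{LabeledNuclei} with at least one nucleus.
#' @return list with `perNucleus` (data.frame: `nucleus`, `markerMean`,
#'   `dapiMean`, `ratio`, `flagged`) and `pooled` (numeric).
#' @export
intensityRatio <- function(marker, dapi, nuclei) {
  m <- if (is(marker, "ProjectionImage")) imgData(marker) else marker
  d <- if (is(dapi, "ProjectionImage")) imgData(dapi) else dapi
  stopifnot(is.matrix(m), is.matrix(d), is(nuclei, "LabeledNuclei"))
  lab <- labelImage(nuclei)
  if (!identical(dim(m), dim(d)) || !identical(dim(m), dim(lab))) {
    stop("marker, dapi and nucleus labels must have the same shape")
  }
  n <- nucleusCount(nuclei)
  if (n == 0L) stop("no nuclei to measure")
  idx <- which(lab > 0)
  f <- factor(lab[idx], levels = seq_len(n))
  mm <- vapply(split(m[idx], f), mean, numeric(1))
  dm <- vapply(split(d[idx], f), mean, numeric(1))
  flagged <- dm == 0
  ratio <- ifelse(flagged, NA_real_, mm / dm)
  per <- data.frame(
    nucleus = seq_len(n), markerMean = unname(mm), dapiMean = unname(dm),
    ratio = unname(ratio), flagged = unname(flagged)
  )
  list(perNucleus = per, pooled = mean(per$ratio[!per$flagged]))
}
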
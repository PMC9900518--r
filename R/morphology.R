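#' Greyscale morphological reconstruction by dilation
#'
#' Computes the limit of iterated geodesic dilation of `marker` under
#' `mask`: the largest image that is everywhere `<= mask` and can be
#' reached from `marker` by repeatedly dilating (3x3 or plus-shaped
#' structuring element, per `connectivity`) and clipping under `mask`.
#' The result satisfies `marker <= result <= mask`, equals `mask` when
#' `marker == mask`, and is idempotent when used as a marker again.
#'
#' Implemented with the hybrid raster-sweep + FIFO-queue algorithm, which
#' reaches the unique fixpoint of the iterative definition in near-linear
#' time.
#'
#' @param marker,mask numeric matrices of equal shape with
#'   `marker <= mask` everywhere.
#' @param connectivity 4 or 8 (default 8).
#' @return numeric matrix, the reconstruction.
#' @seealso [extendedMaxima()] which builds the h-maxima transform on it.
#' @export
morphReconstruct <- function(marker, mask, connectivity = 8L) {
  stopifnot(is.matrix(marker), is.matrix(mask))
  if (!identical(dim(marker), dim(mask))) {
    stop("marker and mask must have the same shape")
  }
  if (!all(is.finite(marker)) || !all(is.finite(mask))) {
    stop("marker/mask must be finite")
  }
  if (any(marker > mask)) stop("marker must be <= mask everywhere")
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  cpp_reconstruct(marker, mask, as.integer(connectivity))
}

#' Regional maxima
#'
#' Flags every pixel belonging to a regional maximum: a connected plateau
#' of constant intensity whose border neighbours are all strictly darker.
#' A perfectly constant image is one maximal plateau covering the whole
#' field; upstream guards (dynamic-range check, focus area filter) keep
#' that degenerate case out of focus counts.
#'
#' @param img numeric matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return logical matrix.
#' @export
regionalMaxima <- function(img, connectivity = 8L) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  cpp_regional_maxima(img, as.integer(connectivity))
}

#' Extended-maxima (h-maxima) transform
#'
#' The detector at the heart of foci counting: marks peaks whose height
#' above the surrounding terrain exceeds `h`. Computed as the regional
#' maxima of the h-maxima transform, where
#' `hmax(I) = morphReconstruct(I - h, I)`. The mask is invariant to
#' adding a constant to the image, and the number of detected components
#' can only shrink as `h` grows.
#'
#' If the image's dynamic range is below `minDynamicRange` the result is
#' empty: a flat (blank) field has no peaks, and without the guard the
#' whole field would count as one giant maximal plateau.
#'
#' @param img numeric matrix (in the pipeline: the normalized foci-channel
#'   MIP, values in `[0, 1]`).
#' @param h peak prominence threshold, intensity units (`> 0`).
#' @param connectivity 4 or 8 (default 8).
#' @param minDynamicRange flat-field guard (default 0.05): images with
#'   `max - min` below this yield an all-`FALSE` mask.
#' @return logical matrix marking extended-maxima plateaus.
#' @examples
#' img <- matrix(0, 16, 16)
#' img[8, 8] <- 0.5
#' sum(extendedMaxima(img, h = 0.2)) # the single peak pixel
#' @export
extendedMaxima <- function(img, h, connectivity = 8L,
                           minDynamicRange = 0.05) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (h <= 0) stop("h must be > 0")
  if (max(img) - min(img) < minDynamicRange) {
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  hm <- morphReconstruct(img - h, img, connectivity)
  regionalMaxima(hm, connectivity)
}

#' Connected-component labeling
#'
#' Labels connected foreground regions of a binary mask 1..n in
#' deterministic (column-major first-encounter) order.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels, 0 = background.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  storage.mode(mask) <- "logical"
  cpp_label(mask, as.integer(connectivity))
}

#' Fill enclosed holes in a binary mask
#'
#' Adds to the foreground every background region that cannot be reached
#' from the image border. Background is traversed 4-connected — the
#' complement of the default 8-connected foreground, the standard pairing
#' for topological consistency.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes filled.
#' @export
fillHoles <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  cpp_fill_holes(mask)
}
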
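#' Otsu's threshold
#'
#' Histogram threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over all `nBins - 1` candidate bin edges on
#' `[0, 1]`. Class means are computed from the exact per-bin intensity
#' sums (not bin midpoints), so the result equals an exhaustive search
#' that partitions the raw pixel values at each candidate edge. Ties are
#' broken toward the lowest edge; the result is fully deterministic.
#'
#' @param img numeric matrix with values in `[0, 1]` (a normalized MIP)
#'   and at least two distinct values.
#' @param nBins histogram resolution (default 256).
#' @return the threshold, a value in `(0, 1)`; pixels `>= threshold` are
#'   foreground under the convention used by [segmentNuclei()].
#' @examples
#' img <- matrix(c(rep(0.2, 50), rep(0.8, 50)), 10, 10)
#' otsuThreshold(img) # strictly between 0.2 and 0.8
#' @export
otsuThreshold <- function(img, nBins = 256L) {
  stopifnot(is.matrix(img) || is.numeric(img))
  v <- as.numeric(img)
  if (!all(is.finite(v))) stop("image contains non-finite values")
  if (min(v) < 0 || max(v) > 1) {
    stop("otsuThreshold expects a normalized image with values in [0, 1]")
  }
  if (length(unique(v)) < 2L) {
    stop("constant image: Otsu threshold undefined")
  }
  nBins <- as.integer(nBins)
  b <- pmin(floor(v * nBins), nBins - 1L) # 0-based bin index
  cnt <- tabulate(b + 1L, nbins = nBins)
  sums <- vapply(
    split(v, factor(b, levels = 0:(nBins - 1L))),
    sum, numeric(1)
  )
  n <- length(v)
  total <- sum(v)
  cumN <- cumsum(cnt)[-nBins] # class 0 = bins 1..k
  cumS <- cumsum(sums)[-nBins]
  w0 <- cumN / n
  w1 <- 1 - w0
  valid <- cumN > 0 & cumN < n
  bcv <- rep(-Inf, nBins - 1L)
  mu0 <- cumS[valid] / cumN[valid]
  mu1 <- (total - cumS[valid]) / (n - cumN[valid])
  bcv[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  k <- which.max(bcv) # first max: lowest edge on ties
  k / nBins
}

#' Nucleus segmentation configuration
#'
#' Parameters for [segmentNuclei()]. The thresholding rule is a blend of
#' the global Otsu threshold and a local-mean (box) threshold:
#' `T(p) = adaptiveBlend * localMean(p) + (1 - adaptiveBlend) * globalOtsu`.
#' The default `adaptiveBlend = 0` is pure global Otsu (transparent
#' behaviour); raise it to adapt to uneven illumination.
#'
#' Area defaults (200--20,000 px^2) suit the default synthetic field
#' scale and should be set from the imaging geometry in real use.
#'
#' @param adaptiveBlock odd local-window size in pixels (default 51).
#' @param adaptiveBlend weight in `[0, 1]` on the local threshold
#'   (default 0).
#' @param minNucleusArea,maxNucleusArea retained object area bounds,
#'   pixels^2.
#' @param connectivity 4 or 8 (default 8).
#' @param excludeBorder drop nuclei touching the field border (default
#'   `TRUE`; clipped nuclei bias per-nucleus counts).
#' @return a list of validated settings.
#' @export
segmentationConfig <- function(adaptiveBlock = 51L, adaptiveBlend = 0,
                               minNucleusArea = 200, maxNucleusArea = 20000,
                               connectivity = 8L, excludeBorder = TRUE) {
  adaptiveBlock <- as.integer(adaptiveBlock)
  if (adaptiveBlock < 3L || adaptiveBlock %% 2L == 0L) {
    stop("adaptiveBlock must be odd and >= 3")
  }
  if (adaptiveBlend < 0 || adaptiveBlend > 1) {
    stop("adaptiveBlend must be in [0, 1]")
  }
  if (!(minNucleusArea > 0 && minNucleusArea < maxNucleusArea)) {
    stop("need 0 < minNucleusArea < maxNucleusArea")
  }
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  list(
    adaptiveBlock = adaptiveBlock, adaptiveBlend = adaptiveBlend,
    minNucleusArea = minNucleusArea, maxNucleusArea = maxNucleusArea,
    connectivity = as.integer(connectivity), excludeBorder = excludeBorder
  )
}

# per-component area/centroid/bbox from a label image; optional weights
# give intensity-weighted centroids
componentStats <- function(lab, weights = NULL) {
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(
      id = integer(), area = integer(), cy = numeric(), cx = numeric(),
      ymin = integer(), ymax = integer(), xmin = integer(), xmax = integer(),
      peak = numeric()
    ))
  }
  idx <- which(lab > 0)
  ids <- lab[idx]
  ys <- (idx - 1L) %% nrow(lab) + 1L
  xs <- (idx - 1L) %/% nrow(lab) + 1L
  f <- factor(ids, levels = seq_len(n))
  area <- tabulate(ids, nbins = n)
  if (is.null(weights)) {
    cy <- vapply(split(ys, f), mean, numeric(1))
    cx <- vapply(split(xs, f), mean, numeric(1))
    peak <- rep(NA_real_, n)
  } else {
    w <- weights[idx]
    sw <- vapply(split(w, f), sum, numeric(1))
    cy <- vapply(split(w * ys, f), sum, numeric(1)) / sw
    cx <- vapply(split(w * xs, f), sum, numeric(1)) / sw
    bad <- sw == 0 # all-zero-intensity component: fall back to unweighted
    if (any(bad)) {
      cy[bad] <- vapply(split(ys, f), mean, numeric(1))[bad]
      cx[bad] <- vapply(split(xs, f), mean, numeric(1))[bad]
    }
    peak <- vapply(split(w, f), max, numeric(1))
  }
  data.frame(
    id = seq_len(n), area = area, cy = unname(cy), cx = unname(cx),
    ymin = vapply(split(ys, f), min, integer(1)),
    ymax = vapply(split(ys, f), max, integer(1)),
    xmin = vapply(split(xs, f), min, integer(1)),
    xmax = vapply(split(xs, f), max, integer(1)),
    peak = unname(peak), row.names = NULL
  )
}

# keep only the listed labels and relabel them 1..n in raster order
relabelKeep <- function(lab, keep) {
  map <- integer(max(lab, 1L))
  map[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Segment nuclei from a normalized MIP
#'
#' Builds the binary nucleus mask and labels nuclei: per-pixel threshold
#' (global Otsu blended with a local mean, per the config), hole filling,
#' connected-component labeling, area filtering, and optional removal of
#' border-touching objects. Holes are filled before the area filter so
#' that each recorded area is the full (void-free) pixel count of its
#' nucleus. No splitting of touching nuclei is attempted.
#'
#' @param mip a normalized \linkS4class{ProjectionImage} (nuclear
#'   channel), or a numeric matrix in `[0, 1]`.
#' @param config a [segmentationConfig()] list.
#' @return a \linkS4class{LabeledNuclei}; zero nuclei (not an error) on a
#'   constant image.
#' @examples
#' img <- matrix(0, 64, 64)
#' img[20:40, 20:40] <- 1
#' seg <- segmentNuclei(img, segmentationConfig(minNucleusArea = 100))
#' nucleusCount(seg)
#' @export
segmentNuclei <- function(mip, config = segmentationConfig()) {
  img <- if (is(mip, "ProjectionImage")) {
    if (!isNormalized(mip)) stop("mip must be normalized (see normalize01)")
    imgData(mip)
  } else {
    mip
  }
  stopifnot(is.matrix(img))
  empty <- function() {
    new("LabeledNuclei",
      labelImage = matrix(0L, nrow(img), ncol(img)),
      records = componentStats(matrix(0L, 1, 1))[, -9]
    )
  }
  if (max(img) == min(img)) {
    return(empty())
  }
  thrG <- otsuThreshold(img)
  thr <- if (config$adaptiveBlend > 0) {
    config$adaptiveBlend * cpp_box_mean(img, config$adaptiveBlock) +
      (1 - config$adaptiveBlend) * thrG
  } else {
    thrG
  }
  bw <- img >= thr
  bw <- fillHoles(bw)
  lab <- labelComponents(bw, config$connectivity)
  st <- componentStats(lab)
  keep <- st$id[st$area >= config$minNucleusArea &
    st$area <= config$maxNucleusArea]
  if (config$excludeBorder && length(keep)) {
    onBorder <- st$ymin == 1L | st$xmin == 1L |
      st$ymax == nrow(img) | st$xmax == ncol(img)
    keep <- setdiff(keep, st$id[onBorder])
  }
  if (!length(keep)) {
    return(empty())
  }
  lab2 <- relabelKeep(lab, keep)
  st2 <- componentStats(lab2)
  new("LabeledNuclei", labelImage = lab2, records = st2[, -9])
}
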
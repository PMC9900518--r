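#' Synthetic-scene configuration
#'
#' Defines the imaging regime the generator emulates: multi-plane
#' z-stacks (default 8 planes at 0.8 micrometre spacing, matching the
#' 7--9-plane acquisition the pipeline targets) of a field of
#' non-overlapping elliptical nuclei, with bright diffraction-limited
#' foci planted in the foci channel only. Intensities are arbitrary
#' detector units (non-negative floats; the TIFF writer quantizes to
#' 16-bit).
#'
#' Defaults describe a desk-scale field: 512 x 512 px with 25 nuclei
#' (real fields held > 100 cells; tests shrink this), nuclear signal 400
#' units over a 100-unit background with 20-unit read noise and shot
#' noise on, and 300-unit focus amplitude — comfortably above the noise
#' floor, as reporter foci are.
#'
#' @param fieldShape c(height, width) in pixels.
#' @param nPlanes number of z-planes (default 8).
#' @param planeSpacing micrometres between planes (default 0.8).
#' @param nNuclei nuclei to place (default 25).
#' @param nucleusRadiusRange c(min, max) semi-axis range in pixels.
#' @param nucleusIntensity nuclear-channel signal above background.
#' @param fociPerNucleus either a fixed non-negative integer, or
#'   `list("poisson", mean)` for Poisson-distributed counts.
#' @param focusAmplitude focus peak height above the local foci-channel
#'   level.
#' @param focusSigma c(lateral px, axial planes) Gaussian skirt widths;
#'   the axial width spans >= 2 planes so the projection step matters.
#' @param focusCoreRadius radius of the focus' flat top in pixels
#'   (default 1). Repair foci are sub-micron chromatin domains, not
#'   point sources: they image as small discs with a Gaussian falloff,
#'   which is what the profile
#'   `A * exp(-max(0, r - core)^2 / (2 * sigma^2))` renders.
#' @param minFocusSeparation minimum distance between planted foci of
#'   one nucleus, pixels (default 4).
#' @param nucleusBleed fraction of `nucleusIntensity` visible in the
#'   foci channel (dim nuclear outline, default 0.15).
#' @param backgroundLevel camera offset, arbitrary units (default 100).
#' @param readNoiseSd additive Gaussian read noise sd (default 20).
#' @param shotNoise logical, Poisson photon noise (default `TRUE`).
#' @param seed integer RNG seed (default 1).
#' @return validated configuration list.
#' @seealso [simulateScene()]
#' @export
sceneConfig <- function(fieldShape = c(512L, 512L), nPlanes = 8L,
                        planeSpacing = 0.8, nNuclei = 25L,
                        nucleusRadiusRange = c(12, 18),
                        nucleusIntensity = 400,
                        fociPerNucleus = list("poisson", 2),
                        focusAmplitude = 300,
                        focusSigma = c(0.8, 1.2),
                        focusCoreRadius = 1.0,
                        minFocusSeparation = 4,
                        nucleusBleed = 0.15,
                        backgroundLevel = 100, readNoiseSd = 10,
                        shotNoise = TRUE, seed = 1L) {
  stopifnot(
    length(fieldShape) == 2L, all(fieldShape >= 8L),
    nPlanes >= 1L, nNuclei >= 0L,
    length(nucleusRadiusRange) == 2L, all(nucleusRadiusRange > 0),
    nucleusRadiusRange[1] <= nucleusRadiusRange[2],
    nucleusIntensity > 0, focusAmplitude >= 0,
    length(focusSigma) == 2L, all(focusSigma > 0), focusCoreRadius >= 0,
    backgroundLevel >= 0, readNoiseSd >= 0
  )
  if (is.numeric(fociPerNucleus)) {
    stopifnot(length(fociPerNucleus) == 1L, fociPerNucleus >= 0)
    fociPerNucleus <- list("fixed", as.numeric(fociPerNucleus))
  }
  stopifnot(
    is.list(fociPerNucleus), length(fociPerNucleus) == 2L,
    fociPerNucleus[[1]] %in% c("fixed", "poisson"),
    fociPerNucleus[[2]] >= 0
  )
  # feasibility: requested nuclei must plausibly fit without overlap
  rmax <- nucleusRadiusRange[2]
  if (nNuclei * (2 * rmax + 2)^2 > 0.7 * prod(fieldShape)) {
    stop("field too small to place ", nNuclei, " non-overlapping nuclei")
  }
  list(
    fieldShape = as.integer(fieldShape), nPlanes = as.integer(nPlanes),
    planeSpacing = planeSpacing, nNuclei = as.integer(nNuclei),
    nucleusRadiusRange = nucleusRadiusRange,
    nucleusIntensity = nucleusIntensity,
    fociPerNucleus = fociPerNucleus, focusAmplitude = focusAmplitude,
    focusSigma = focusSigma, focusCoreRadius = focusCoreRadius,
    minFocusSeparation = minFocusSeparation,
    nucleusBleed = nucleusBleed, backgroundLevel = backgroundLevel,
    readNoiseSd = readNoiseSd, shotNoise = isTRUE(shotNoise),
    seed = as.integer(seed)
  )
}

# draw one focus layout for a nucleus: k centres inside the ellipse
# (0.8 margin) at pairwise distance >= minSep; NULL if it cannot be done
placeFoci <- function(k, cy, cx, ry, rx, minSep, maxTry = 400L) {
  ys <- numeric(0)
  xs <- numeric(0)
  tries <- 0L
  while (length(ys) < k && tries < maxTry) {
    tries <- tries + 1L
    a <- stats::runif(1, 0, 2 * pi)
    r <- sqrt(stats::runif(1)) * 0.8
    y <- cy + r * ry * sin(a)
    x <- cx + r * rx * cos(a)
    if (!length(ys) || all(sqrt((ys - y)^2 + (xs - x)^2) >= minSep)) {
      ys <- c(ys, y)
      xs <- c(xs, x)
    }
  }
  if (length(ys) < k) {
    return(NULL)
  }
  cbind(y = ys, x = xs)
}

#' Generate a synthetic two-channel scene with ground truth
#'
#' Renders a nuclear-channel and a foci-channel z-stack from one
#' [sceneConfig()], plus the exact ground truth (nucleus label image,
#' per-nucleus records, planted focus centres). Nuclei are
#' non-overlapping axis-aligned ellipses, bright in the nuclear channel
#' and dimly visible in the foci channel; foci are 3-D Gaussian spots in
#' the foci channel only. Shot noise (Poisson with the noiseless
#' intensity as mean) and additive Gaussian read noise are applied per
#' the config. The output is a pure function of the config (including
#' its seed): identical calls are bit-identical.
#'
#' @param config a [sceneConfig()] list.
#' @param seed optional override of `config$seed`.
#' @return list with elements `nuclear` (\linkS4class{ZStack}), `foci`
#'   (\linkS4class{ZStack}) and `truth` (\linkS4class{SceneTruth}).
#' @examples
#' sc <- simulateScene(sceneConfig(
#'   fieldShape = c(128, 128), nNuclei = 3,
#'   fociPerNucleus = 2, seed = 7
#' ))
#' totalFoci(sc$truth)
#' @export
simulateScene <- function(config = sceneConfig(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  withr::with_seed(config$seed, {
    h <- config$fieldShape[1]
    w <- config$fieldShape[2]
    np <- config$nPlanes
    rr <- config$nucleusRadiusRange

    # --- place non-overlapping nuclei (conservative circle test) ---
    cy <- cx <- ry <- rx <- numeric(config$nNuclei)
    for (i in seq_len(config$nNuclei)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        ryi <- stats::runif(1, rr[1], rr[2])
        rxi <- stats::runif(1, rr[1], rr[2])
        cyi <- stats::runif(1, ryi + 2, h - ryi - 1)
        cxi <- stats::runif(1, rxi + 2, w - rxi - 1)
        if (i == 1L || all(sqrt((cy[seq_len(i - 1)] - cyi)^2 +
          (cx[seq_len(i - 1)] - cxi)^2) >
          pmax(ry, rx)[seq_len(i - 1)] + max(ryi, rxi) + 2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place nucleus ", i, " without overlap; ",
          "enlarge the field or reduce nNuclei",
          call. = FALSE
        )
      }
      cy[i] <- cyi
      cx[i] <- cxi
      ry[i] <- ryi
      rx[i] <- rxi
    }

    # --- label image ---
    lab <- matrix(0L, h, w)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(config$nNuclei)) {
      y0 <- max(1L, floor(cy[i] - ry[i]))
      y1 <- min(h, ceiling(cy[i] + ry[i]))
      x0 <- max(1L, floor(cx[i] - rx[i]))
      x1 <- min(w, ceiling(cx[i] + rx[i]))
      sub <- ((yy[y0:y1, x0:x1] - cy[i]) / ry[i])^2 +
        ((xx[y0:y1, x0:x1] - cx[i]) / rx[i])^2 <= 1
      block <- lab[y0:y1, x0:x1]
      block[sub] <- i
      lab[y0:y1, x0:x1] <- block
    }
    inNuc <- lab > 0L

    # --- plant foci ---
    spec <- config$fociPerNucleus
    kPer <- if (spec[[1]] == "fixed") {
      rep(as.integer(round(spec[[2]])), config$nNuclei)
    } else {
      stats::rpois(config$nNuclei, spec[[2]])
    }
    fociList <- vector("list", config$nNuclei)
    for (i in seq_len(config$nNuclei)) {
      if (kPer[i] == 0L) next
      pos <- placeFoci(
        kPer[i], cy[i], cx[i], ry[i], rx[i],
        config$minFocusSeparation
      )
      if (is.null(pos)) {
        stop("could not place ", kPer[i], " foci at separation ",
          config$minFocusSeparation, " in nucleus ", i,
          call. = FALSE
        )
      }
      fz <- stats::runif(kPer[i], min(2, np), max(np - 1, 1))
      fociList[[i]] <- data.frame(
        nucleus = i, z = fz, y = pos[, "y"], x = pos[, "x"]
      )
    }
    foci <- if (length(fociList)) do.call(rbind, fociList) else NULL
    if (is.null(foci)) {
      foci <- data.frame(
        nucleus = integer(), z = numeric(),
        y = numeric(), x = numeric()
      )
    }

    # --- render ---
    base <- config$backgroundLevel
    nucPlane <- base + config$nucleusIntensity * inNuc
    fociPlane0 <- base + config$nucleusBleed * config$nucleusIntensity * inNuc
    sigL <- config$focusSigma[1]
    sigA <- config$focusSigma[2]
    nuclear <- array(nucPlane, c(h, w, np))
    fociCh <- array(fociPlane0, c(h, w, np))
    if (nrow(foci)) {
      ext <- ceiling(config$focusCoreRadius + 4 * sigL)
      for (j in seq_len(nrow(foci))) {
        y0 <- max(1L, floor(foci$y[j] - ext))
        y1 <- min(h, ceiling(foci$y[j] + ext))
        x0 <- max(1L, floor(foci$x[j] - ext))
        x1 <- min(w, ceiling(foci$x[j] + ext))
        rr2 <- sqrt(outer(
          (y0:y1 - foci$y[j])^2,
          (x0:x1 - foci$x[j])^2, "+"
        ))
        g2 <- exp(-pmax(rr2 - config$focusCoreRadius, 0)^2 / (2 * sigL^2))
        for (k in seq_len(np)) {
          gz <- exp(-(k - foci$z[j])^2 / (2 * sigA^2))
          fociCh[y0:y1, x0:x1, k] <- fociCh[y0:y1, x0:x1, k] +
            config$focusAmplitude * gz * g2
        }
      }
    }

    # --- noise ---
    addNoise <- function(a) {
      if (config$shotNoise) {
        a <- array(stats::rpois(length(a), a), dim(a))
      }
      if (config$readNoiseSd > 0) {
        a <- a + array(
          stats::rnorm(length(a), 0, config$readNoiseSd),
          dim(a)
        )
      }
      a[a < 0] <- 0
      a
    }
    nuclear <- addNoise(nuclear)
    fociCh <- addNoise(fociCh)

    truth <- new("SceneTruth",
      labelImage = lab,
      nuclei = data.frame(
        id = seq_len(config$nNuclei), cy = cy, cx = cx, ry = ry, rx = rx,
        area = tabulate(lab[inNuc], nbins = config$nNuclei)
      ),
      foci = foci
    )
    list(
      nuclear = ZStack(nuclear,
        planeSpacing = config$planeSpacing,
        channelName = "nuclear"
      ),
      foci = ZStack(fociCh,
        planeSpacing = config$planeSpacing,
        channelName = "foci"
      ),
      truth = truth
    )
  })
}

#' Generate a channel pair with known correlation inside a mask
#'
#' Within the mask, pixel pairs are drawn from a bivariate normal with
#' correlation `rho` via the standard mixing construction
#' `B = rho * A + sqrt(1 - rho^2) * eps`; outside the mask both images
#' take the background value. At `rho = 1`, B equals A exactly, so the
#' downstream masked Pearson coefficient is 1.
#'
#' @param mask logical matrix, non-empty.
#' @param rho target correlation in `[-1, 1]`.
#' @param seed integer RNG seed.
#' @param level,scale affine mapping of the unit-variance draws into
#'   intensity units (Pearson is invariant to it).
#' @param background value outside the mask.
#' @return list of two numeric matrices `a`, `b`.
#' @export
simulateColocPair <- function(mask, rho, seed = 1L, level = 1000,
                              scale = 150, background = 0) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  n <- sum(mask)
  if (n == 0L) stop("mask is empty")
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  withr::with_seed(as.integer(seed), {
    a0 <- stats::rnorm(n)
    b0 <- rho * a0 + sqrt(1 - rho^2) * stats::rnorm(n)
    a <- matrix(background, nrow(mask), ncol(mask))
    b <- a
    a[mask] <- level + scale * a0
    b[mask] <- level + scale * b0
    list(a = a, b = b)
  })
}

#' Amplicon lengths of the two assayed genes
#'
#' Long/short amplicon lengths (kb) for the HPRT (10.4 / 0.286) and POLB
#' (12.2 / 0.192) LA-qPCR assays.
#'
#' @param gene `"HPRT"` or `"POLB"`.
#' @return named numeric vector `c(long = , short = )`.
#' @export
ampliconLengths <- function(gene = c("HPRT", "POLB")) {
  gene <- match.arg(gene)
  switch(gene,
    HPRT = c(long = 10.4, short = 0.286),
    POLB = c(long = 12.2, short = 0.192)
  )
}

#' Simulate one LA-qPCR measurement at a known lesion rate
#'
#' Molecule-level simulator: each of `nMolecules` template molecules
#' receives `Poisson(lambda * L / 10)` lesions independently for the
#' long and the short amplicon (`lambda` in lesions per 10 kb, `L` in
#' kb); a molecule amplifies only if it carries zero lesions in that
#' amplicon, so band intensity is proportional to the zero-lesion
#' fraction. Because the short fragment is ~50x shorter, its zero-lesion
#' fraction stays near 1 — the lower probability of breaks within a
#' shorter fragment that makes it a loading control. Multiplicative
#' log-normal noise with coefficient of variation `noiseCv` is applied
#' per band; `treated = FALSE` forces `lambda = 0` (vehicle control).
#' The zero-lesion fraction is floored at `0.5 / nMolecules` so recorded
#' intensities stay positive even at extreme lesion rates.
#'
#' @param lambdaPer10kb true lesion rate, lesions per 10 kb (`>= 0`).
#' @param gene `"HPRT"` or `"POLB"` (sets amplicon lengths), or supply
#'   `lengthsKb` directly.
#' @param lengthsKb optional `c(long, short)` kb override.
#' @param nMolecules template molecules per band (default 100000).
#' @param intensityScale band intensity at zero-lesion fraction 1.
#' @param noiseCv coefficient of variation of the band noise (default
#'   0.02).
#' @param treated logical; `FALSE` simulates the vehicle control.
#' @param condition condition label for the record.
#' @param replicate replicate index for the record.
#' @param seed integer RNG seed.
#' @return one-row data.frame in the amplification-table schema
#'   (`gene`, `condition`, `replicate`, `long_intensity`,
#'   `short_intensity`, `long_length_kb`, `short_length_kb`,
#'   `is_control`).
#' @export
simulateLAqPCR <- function(lambdaPer10kb, gene = "HPRT", lengthsKb = NULL,
                           nMolecules = 100000L, intensityScale = 1000,
                           noiseCv = 0.02, treated = TRUE,
                           condition = if (treated) "treated" else "control",
                           replicate = 1L, seed = 1L) {
  if (lambdaPer10kb < 0) stop("lambda must be >= 0")
  if (nMolecules < 1L) stop("nMolecules must be >= 1")
  if (is.null(lengthsKb)) lengthsKb <- ampliconLengths(gene)
  stopifnot(length(lengthsKb) == 2L, all(lengthsKb > 0))
  lam <- if (treated) lambdaPer10kb else 0
  withr::with_seed(as.integer(seed), {
    zeroFrac <- function(lenKb) {
      lesions <- stats::rpois(nMolecules, lam * lenKb / 10)
      max(mean(lesions == 0L), 0.5 / nMolecules)
    }
    noise <- function() {
      if (noiseCv <= 0) {
        return(1)
      }
      s2 <- log(1 + noiseCv^2) # log-normal with mean 1, cv = noiseCv
      exp(stats::rnorm(1, -s2 / 2, sqrt(s2)))
    }
    data.frame(
      gene = gene, condition = condition, replicate = as.integer(replicate),
      long_intensity = intensityScale * zeroFrac(lengthsKb[[1]]) * noise(),
      short_intensity = intensityScale * zeroFrac(lengthsKb[[2]]) * noise(),
      long_length_kb = unname(lengthsKb[[1]]),
      short_length_kb = unname(lengthsKb[[2]]),
      is_control = !treated
    )
  })
}
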
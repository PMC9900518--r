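# Brute-force reference implementations, independent of the package's
# algorithms: direct loops and the iterate-to-fixpoint definitions.

neighOffsets <- function(conn) {
  if (conn == 4) {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  } else {
    cbind(
      dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
      dc = c(0, 0, -1, 1, -1, 1, -1, 1)
    )
  }
}

# greyscale dilation, window truncated at borders
oracleDilate <- function(img, conn = 8) {
  nr <- nrow(img)
  nc <- ncol(img)
  off <- neighOffsets(conn)
  out <- img
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      v <- img[r, c]
      for (k in seq_len(nrow(off))) {
        rr <- r + off[k, 1]
        cc <- c + off[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          v <- max(v, img[rr, cc])
        }
      }
      out[r, c] <- v
    }
  }
  out
}

# reconstruction by iterated geodesic dilation until stability
oracleReconstruct <- function(marker, mask, conn = 8) {
  j <- marker
  repeat {
    j2 <- pmin(oracleDilate(j, conn), mask)
    if (identical(j2, j)) {
      return(j)
    }
    j <- j2
  }
}

# plateau flood-fill definition of regional maxima
oracleRegionalMaxima <- function(img, conn = 8) {
  nr <- nrow(img)
  nc <- ncol(img)
  off <- neighOffsets(conn)
  visited <- matrix(FALSE, nr, nc)
  out <- matrix(FALSE, nr, nc)
  for (p0 in which(!visited)) {
    if (visited[p0]) next
    v <- img[p0]
    queue <- p0
    visited[p0] <- TRUE
    plateau <- integer(0)
    isMax <- TRUE
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      plateau <- c(plateau, p)
      r <- (p - 1) %% nr + 1
      c <- (p - 1) %/% nr + 1
      for (k in seq_len(nrow(off))) {
        rr <- r + off[k, 1]
        cc <- c + off[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        w <- img[rr, cc]
        if (w > v) isMax <- FALSE
        if (w == v && !visited[rr, cc]) {
          visited[rr, cc] <- TRUE
          queue <- c(queue, (cc - 1) * nr + rr)
        }
      }
    }
    if (isMax) out[plateau] <- TRUE
  }
  out
}

oracleExtendedMaxima <- function(img, h, conn = 8) {
  oracleRegionalMaxima(oracleReconstruct(img - h, img, conn), conn)
}

# exhaustive between-class-variance search over all bin edges,
# partitioning the raw pixel values at each candidate edge
oracleOtsu <- function(img, nBins = 256L) {
  v <- as.numeric(img)
  best <- -Inf
  bestT <- NA_real_
  n <- length(v)
  for (k in seq_len(nBins - 1L)) {
    t <- k / nBins
    lo <- v < t
    n0 <- sum(lo)
    if (n0 == 0L || n0 == n) next
    w0 <- n0 / n
    bcv <- w0 * (1 - w0) * (mean(v[lo]) - mean(v[!lo]))^2
    if (bcv > best) {
      best <- bcv
      bestT <- t
    }
  }
  bestT
}

# direct double-loop bilateral filter with truncated window
oracleBilateral <- function(img, sigmaS, sigmaR, radius) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- img
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      num <- 0
      den <- 0
      for (rr in max(1, r - radius):min(nr, r + radius)) {
        for (cc in max(1, c - radius):min(nc, c + radius)) {
          wgt <- exp(-((rr - r)^2 + (cc - c)^2) / (2 * sigmaS^2)) *
            exp(-(img[rr, cc] - img[r, c])^2 / (2 * sigmaR^2))
          num <- num + wgt * img[rr, cc]
          den <- den + wgt
        }
      }
      out[r, c] <- num / den
    }
  }
  out
}

# windowed Gaussian convolution (no range term), truncated window —
# the large-sigmaRange limit of the bilateral filter
oracleGaussConv <- function(img, sigmaS, radius) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- img
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      num <- 0
      den <- 0
      for (rr in max(1, r - radius):min(nr, r + radius)) {
        for (cc in max(1, c - radius):min(nc, c + radius)) {
          wgt <- exp(-((rr - r)^2 + (cc - c)^2) / (2 * sigmaS^2))
          num <- num + wgt * img[rr, cc]
          den <- den + wgt
        }
      }
      out[r, c] <- num / den
    }
  }
  out
}

# per-pixel loop MIP
oracleMIP <- function(arr) {
  out <- matrix(-Inf, dim(arr)[1], dim(arr)[2])
  for (r in seq_len(dim(arr)[1])) {
    for (c in seq_len(dim(arr)[2])) {
      for (k in seq_len(dim(arr)[3])) {
        out[r, c] <- max(out[r, c], arr[r, c, k])
      }
    }
  }
  out
}

# direct covariance / sd formula Pearson over masked pixels
oraclePearson <- function(a, b, mask) {
  ax <- a[mask]
  bx <- b[mask]
  n <- length(ax)
  ma <- sum(ax) / n
  mb <- sum(bx) / n
  sab <- sum((ax - ma) * (bx - mb))
  sa <- sqrt(sum((ax - ma)^2))
  sb <- sqrt(sum((bx - mb)^2))
  sab / (sa * sb)
}

# small deterministic test image with smooth structure + texture
randomTestImage <- function(nr, nc, seed) {
  withr::with_seed(seed, {
    base <- outer(seq_len(nr) / nr, seq_len(nc) / nc, function(y, x) {
      0.4 * exp(-((y - 0.5)^2 + (x - 0.5)^2) * 8)
    })
    pmin(pmax(base + matrix(stats::runif(nr * nc, 0, 0.5), nr, nc), 0), 1)
  })
}

# a filled circular mask, handy for building single-nucleus fields
diskMask <- function(nr, nc, cy, cx, radius) {
  outer(seq_len(nr), seq_len(nc), function(y, x) {
    (y - cy)^2 + (x - cx)^2 <= radius^2
  })
}
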
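test_that("scene generation is a pure function of config and seed", {
  cfg <- sceneConfig(fieldShape = c(128, 128), nNuclei = 4, seed = 17)
  a <- simulateScene(cfg)
  b <- simulateScene(cfg)
  expect_identical(imgData(a$nuclear), imgData(b$nuclear))
  expect_identical(imgData(a$foci), imgData(b$foci))
  expect_identical(labelImage(a$truth), labelImage(b$truth))
  expect_identical(plantedFoci(a$truth), plantedFoci(b$truth))

  c <- simulateScene(cfg, seed = 18)
  expect_false(identical(imgData(a$foci), imgData(c$foci)))
})

test_that("a zero-foci noiseless scene has only the dim nuclear outline", {
  cfg <- sceneConfig(
    fieldShape = c(200, 200), nNuclei = 10, fociPerNucleus = 0,
    readNoiseSd = 0, shotNoise = FALSE, seed = 2
  )
  sc <- simulateScene(cfg)
  expect_equal(totalFoci(sc$truth), 0)
  f <- imgData(sc$foci)
  lev <- cfg$backgroundLevel + cfg$nucleusBleed * cfg$nucleusIntensity
  expect_equal(sort(unique(as.numeric(f))), c(cfg$backgroundLevel, lev))
})

test_that("planted truth is consistent: counts, containment, rendered peaks", {
  cfg <- sceneConfig(
    fieldShape = c(256, 256), nNuclei = 5, fociPerNucleus = 3,
    readNoiseSd = 0, shotNoise = FALSE, seed = 31
  )
  sc <- simulateScene(cfg)
  tr <- plantedFoci(sc$truth)
  expect_equal(nrow(tr), 15)
  expect_equal(as.integer(table(tr$nucleus)), rep(3L, 5))

  lab <- labelImage(sc$truth)
  expect_true(all(lab[cbind(round(tr$y), round(tr$x))] == tr$nucleus))

  # every planted focus is a local peak of the noiseless MIP within 1 px
  mip <- imgData(maxIntensityProjection(sc$foci))
  for (j in seq_len(nrow(tr))) {
    y <- round(tr$y[j])
    x <- round(tr$x[j])
    win <- mip[(y - 3):(y + 3), (x - 3):(x + 3)]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(sqrt((peak[1] - 4 - (tr$y[j] - y))^2 +
      (peak[2] - 4 - (tr$x[j] - x))^2), 1 + 1e-9)
  }

  # separation respected
  for (i in unique(tr$nucleus)) {
    p <- tr[tr$nucleus == i, ]
    if (nrow(p) > 1) {
      d <- as.matrix(stats::dist(p[, c("y", "x")]))
      expect_gte(min(d[upper.tri(d)]), cfg$minFocusSeparation)
    }
  }
})

test_that("impossible nucleus packing fails with an explicit error", {
  expect_error(
    sceneConfig(fieldShape = c(64, 64), nNuclei = 20),
    "field too small"
  )
})

test_that("coloc pairs hit the requested correlation", {
  mask <- diskMask(120, 120, 60, 60, 57) # ~10,200 px
  expect_gt(sum(mask), 10000)

  # rho = 1: B is an exact affine copy of A
  p1 <- simulateColocPair(mask, 1, seed = 5)
  expect_equal(stats::cor(p1$a[mask], p1$b[mask]), 1.0)
  expect_equal(p1$a[mask], p1$b[mask])

  # rho = 0 at n >= 10,000: |r| within the sampling band around 0
  p0 <- simulateColocPair(mask, 0, seed = 5)
  expect_lt(abs(stats::cor(p0$a[mask], p0$b[mask])), 0.05)

  # reproducible
  q <- simulateColocPair(mask, 0.5, seed = 9)
  r <- simulateColocPair(mask, 0.5, seed = 9)
  expect_identical(q, r)

  expect_error(simulateColocPair(matrix(FALSE, 4, 4), 0.5), "empty")
})

test_that("LA-qPCR simulator reproduces Poisson zero-class fractions", {
  # lambda 1/10kb on a 10 kb fragment, no noise: zero-lesion fraction
  # within Monte-Carlo error of exp(-1)
  rec <- simulateLAqPCR(1.0,
    lengthsKb = c(10, 0.192), nMolecules = 100000,
    intensityScale = 1, noiseCv = 0, seed = 12
  )
  p <- exp(-1)
  ci <- 4 * sqrt(p * (1 - p) / 100000)
  expect_lt(abs(rec$long_intensity - p), ci)
  # short amplicon barely loses molecules at the same rate
  expect_gte(rec$short_intensity, exp(-0.0192) - 4 * sqrt(0.02 / 100000))

  # untreated record forces lambda = 0: both fractions exactly 1
  ctl <- simulateLAqPCR(1.0,
    lengthsKb = c(10, 0.192), nMolecules = 50000,
    intensityScale = 1, noiseCv = 0, treated = FALSE, seed = 3
  )
  expect_equal(ctl$long_intensity, 1)
  expect_true(ctl$is_control)
})

test_that("zero-lesion fraction falls with lambda and with length", {
  frac <- function(lam, len, seed) {
    simulateLAqPCR(lam,
      lengthsKb = c(len, 0.1), nMolecules = 40000,
      intensityScale = 1, noiseCv = 0, seed = seed
    )$long_intensity
  }
  byLam <- vapply(c(0.2, 0.5, 1, 2), frac, numeric(1), len = 10, seed = 8)
  expect_true(all(diff(byLam) < 0))
  byLen <- vapply(c(2, 5, 10, 15), function(l) frac(1, l, 8), numeric(1))
  expect_true(all(diff(byLen) < 0))
})

test_that("gene presets carry the assay amplicon lengths", {
  expect_equal(unname(ampliconLengths("HPRT")), c(10.4, 0.286))
  expect_equal(unname(ampliconLengths("POLB")), c(12.2, 0.192))
  rec <- simulateLAqPCR(0.5, gene = "POLB", nMolecules = 1000, seed = 1)
  expect_equal(rec$long_length_kb, 12.2)
  expect_equal(rec$short_length_kb, 0.192)
})
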
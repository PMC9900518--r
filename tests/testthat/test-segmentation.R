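test_that("Otsu separates a perfectly bimodal image", {
  img <- matrix(c(rep(0.2, 50), rep(0.8, 50)), 10, 10)
  t <- otsuThreshold(img)
  expect_gt(t, 0.2)
  expect_lt(t, 0.8)
  expect_true(all((img >= t) == (img == 0.8)))
})

test_that("Otsu equals the exhaustive between-class-variance search", {
  for (seed in 1:15) {
    withr::with_seed(seed, {
      v <- c(
        stats::rbeta(400, 2, 5),
        stats::rbeta(624, 8, 2) # bimodal-ish mixture
      )
      img <- matrix(pmin(pmax(v, 0), 1), 32, 32)
    })
    expect_identical(otsuThreshold(img), oracleOtsu(img))
  }
})

test_that("Otsu misclassifies < 1% of a well-separated Gaussian mixture", {
  withr::with_seed(99, {
    labels <- stats::rbinom(5000, 1, 0.5)
    v <- stats::rnorm(5000, ifelse(labels == 1, 0.8, 0.2), 0.05)
    v <- pmin(pmax(v, 0), 1)
  })
  t <- otsuThreshold(matrix(v[1:4900], 70, 70))
  miscls <- mean((v[1:4900] >= t) != (labels[1:4900] == 1))
  expect_lt(miscls, 0.01)
})

test_that("Otsu rejects constant images", {
  expect_error(otsuThreshold(matrix(0.5, 4, 4)), "constant")
})

test_that("noiseless disks are segmented with accurate areas", {
  img <- matrix(0.05, 300, 300)
  centers <- expand.grid(y = c(50, 120, 190, 260), x = c(60, 150, 240))
  r <- 12
  for (i in seq_len(nrow(centers))) {
    img[diskMask(300, 300, centers$y[i], centers$x[i], r)] <- 0.9
  }
  seg <- segmentNuclei(img, segmentationConfig(minNucleusArea = 100))
  expect_equal(nucleusCount(seg), 12)
  trueArea <- sum(diskMask(300, 300, 50, 60, r))
  expect_true(all(abs(nucleusRecords(seg)$area - trueArea) / trueArea < 0.05))
})

test_that("objects below the minimum area are rejected", {
  img <- matrix(0.05, 100, 100)
  img[diskMask(100, 100, 50, 50, 5)] <- 0.9 # area ~79 px
  seg <- segmentNuclei(img, segmentationConfig(minNucleusArea = 200))
  expect_equal(nucleusCount(seg), 0)
})

test_that("interior holes are filled into the labeled nucleus", {
  img <- matrix(0.05, 100, 100)
  disk <- diskMask(100, 100, 50, 50, 15)
  hole <- diskMask(100, 100, 50, 50, 4)
  img[disk & !hole] <- 0.9
  seg <- segmentNuclei(img, segmentationConfig(minNucleusArea = 100))
  expect_equal(nucleusCount(seg), 1)
  expect_true(all(labelImage(seg)[hole] == 1L))
  expect_equal(nucleusRecords(seg)$area, sum(disk))
})

test_that("raising the minimum area never increases the nucleus count", {
  sc <- simulateScene(sceneConfig(
    fieldShape = c(256, 256), nNuclei = 8,
    fociPerNucleus = 0, seed = 21
  ))
  mip <- normalize01(maxIntensityProjection(smoothStack(sc$nuclear)))
  counts <- vapply(c(50, 200, 500, 800, 1200), function(amin) {
    nucleusCount(segmentNuclei(mip, segmentationConfig(minNucleusArea = amin)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("record areas always equal label pixel counts", {
  sc <- simulateScene(sceneConfig(
    fieldShape = c(256, 256), nNuclei = 6,
    fociPerNucleus = 0, seed = 4
  ))
  mip <- normalize01(maxIntensityProjection(smoothStack(sc$nuclear)))
  seg <- segmentNuclei(mip)
  lab <- labelImage(seg)
  rec <- nucleusRecords(seg)
  expect_equal(sum(rec$area), sum(lab > 0))
  for (i in rec$id) expect_equal(rec$area[rec$id == i], sum(lab == i))
})

test_that("border-touching nuclei are dropped when requested", {
  img <- matrix(0.05, 100, 100)
  img[diskMask(100, 100, 4, 50, 10)] <- 0.9 # clipped at the top border
  img[diskMask(100, 100, 60, 50, 10)] <- 0.9
  seg <- segmentNuclei(img, segmentationConfig(minNucleusArea = 50))
  expect_equal(nucleusCount(seg), 1)
  segAll <- segmentNuclei(img, segmentationConfig(
    minNucleusArea = 50,
    excludeBorder = FALSE
  ))
  expect_equal(nucleusCount(segAll), 2)
})

test_that("adaptive blending handles an illumination gradient", {
  img <- matrix(0.05, 200, 200)
  for (cx in c(40, 100, 160)) img[diskMask(200, 200, 100, cx, 12)] <- 0.55
  ramp <- matrix(seq(0, 0.4, length.out = 200), 200, 200, byrow = TRUE)
  img <- pmin(img + ramp, 1)
  cfgLocal <- segmentationConfig(
    adaptiveBlend = 1, adaptiveBlock = 51,
    minNucleusArea = 200
  )
  expect_equal(nucleusCount(segmentNuclei(img, cfgLocal)), 3)
})
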
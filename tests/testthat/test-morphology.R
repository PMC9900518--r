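test_that("reconstruction fixpoints: marker = mask and constant markers", {
  img <- randomTestImage(12, 12, 5)
  expect_identical(morphReconstruct(img, img), img)

  # constant marker at the global minimum: reconstruction climbs to the
  # iterative-oracle limit, not beyond
  mk <- matrix(min(img), nrow(img), ncol(img))
  expect_identical(morphReconstruct(mk, img), oracleReconstruct(mk, img))
})

test_that("reconstruction equals the iterative geodesic-dilation oracle", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      nr <- sample(5:16, 1)
      nc <- sample(5:16, 1)
      mask <- matrix(stats::runif(nr * nc), nr, nc)
      marker <- pmax(mask - matrix(stats::runif(nr * nc, 0, 0.5), nr, nc), 0)
      marker <- pmin(marker, mask)
    })
    for (conn in c(4L, 8L)) {
      expect_identical(
        morphReconstruct(marker, mask, conn),
        oracleReconstruct(marker, mask, conn)
      )
    }
  }
})

test_that("reconstruction enforces marker <= mask", {
  mask <- matrix(0.5, 4, 4)
  marker <- mask
  marker[2, 2] <- 0.6
  expect_error(morphReconstruct(marker, mask), "marker must be <=")
})

test_that("extended maxima finds an isolated peak and ignores offsets", {
  img <- matrix(0.1, 16, 16)
  img[8, 8] <- 0.6 # amplitude 0.5 over flat background
  em <- extendedMaxima(img, h = 0.2)
  expect_equal(max(labelComponents(em)), 1) # one component
  expect_true(em[8, 8])

  # additive invariance
  expect_identical(extendedMaxima(img + 0.3, h = 0.2), em)
})

test_that("extended maxima equals the brute-force oracle pipeline", {
  for (seed in 1:12) {
    img <- randomTestImage(16, 16, seed + 100)
    for (h in c(0.05, 0.1, 0.3)) {
      expect_identical(extendedMaxima(img, h), oracleExtendedMaxima(img, h))
    }
  }
})

test_that("extended-maxima component count is non-increasing in h", {
  for (seed in 1:6) {
    img <- randomTestImage(24, 24, seed + 50)
    hs <- c(0.02, 0.05, 0.1, 0.2, 0.4)
    counts <- vapply(
      hs,
      function(h) max(labelComponents(extendedMaxima(img, h))), numeric(1)
    )
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the flat-field guard empties the maxima mask", {
  img <- matrix(0.5, 10, 10) + 0.001 * randomTestImage(10, 10, 1)
  expect_false(any(extendedMaxima(img, h = 0.1, minDynamicRange = 0.05)))
})

test_that("regional maxima match the plateau-flood oracle", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      # quantized values create plateaus, exercising the flood fill
      img <- matrix(sample(seq(0, 1, by = 0.25), 100, TRUE), 10, 10)
    })
    for (conn in c(4L, 8L)) {
      expect_identical(
        regionalMaxima(img, conn),
        oracleRegionalMaxima(img, conn)
      )
    }
  }
})

test_that("labeling respects connectivity and hole filling closes voids", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE
  m[2, 2] <- TRUE # diagonal touch: one 8-conn object, two 4-conn
  expect_equal(max(labelComponents(m, 8)), 1)
  expect_equal(max(labelComponents(m, 4)), 2)

  ring <- diskMask(15, 15, 8, 8, 5) & !diskMask(15, 15, 8, 8, 2)
  filled <- fillHoles(ring)
  expect_true(all(filled[diskMask(15, 15, 8, 8, 5)]))
  # background outside the ring untouched
  expect_false(any(filled[!diskMask(15, 15, 8, 8, 5.5)]))
})

test_that("labeling and hole filling agree with EBImage on shared semantics", {
  # EBImage::bwlabel is 4-connected; component counts must coincide
  withr::with_seed(14, m <- matrix(stats::runif(900) > 0.55, 30, 30))
  expect_equal(
    max(labelComponents(m, 4)),
    max(EBImage::bwlabel(m))
  )
  # on a simply-nested hole both hole-filling definitions coincide
  ring <- diskMask(21, 21, 11, 11, 8) & !diskMask(21, 21, 11, 11, 4)
  expect_identical(
    fillHoles(ring),
    EBImage::fillHull(ring) > 0
  )
})
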
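test_that("planted foci are counted exactly in a clean default scene", {
  sc <- simulateScene(sceneConfig(
    fieldShape = c(256, 256), nNuclei = 5,
    fociPerNucleus = 3, seed = 6
  ))
  res <- processField(sc$nuclear, sc$foci)
  expect_equal(nucleusCount(res$nuclei), 5)
  expect_equal(unname(fociCounts(res$foci)), rep(3L, 5))
})

test_that("h above the channel's dynamic range yields zero counts", {
  sc <- simulateScene(sceneConfig(
    fieldShape = c(200, 200), nNuclei = 4,
    fociPerNucleus = 3, seed = 9
  ))
  res <- processField(sc$nuclear, sc$foci, fociCfg = fociConfig(h = 1.5))
  expect_true(all(fociCounts(res$foci) == 0))
})

test_that("a focus outside every nucleus is listed but never counted", {
  img <- matrix(0.05, 120, 120)
  img[diskMask(120, 120, 40, 40, 15)] <- 0.35 # one nucleus
  nuclei <- segmentNuclei(img, segmentationConfig(minNucleusArea = 200))
  expect_equal(nucleusCount(nuclei), 1)

  fociImg <- matrix(0.05, 120, 120)
  fociImg[diskMask(120, 120, 40, 40, 15)] <- 0.15
  fociImg[diskMask(120, 120, 40, 40, 2)] <- 0.8 # inside the nucleus
  fociImg[diskMask(120, 120, 100, 100, 2)] <- 0.8 # in background
  fs <- detectFoci(fociImg, nuclei)
  tab <- fociTable(fs)
  expect_equal(nrow(tab), 2)
  expect_equal(sum(is.na(tab$nucleus)), 1)
  expect_equal(unname(fociCounts(fs)), 1L)
})

test_that("per-nucleus counts follow a nucleus label renumbering", {
  sc <- simulateScene(sceneConfig(
    fieldShape = c(200, 200), nNuclei = 4,
    fociPerNucleus = 2, seed = 13
  ))
  res <- processField(sc$nuclear, sc$foci)
  nuc <- res$nuclei
  n <- nucleusCount(nuc)
  perm <- rev(seq_len(n))
  lab <- labelImage(nuc)
  lab2 <- lab
  lab2[lab > 0] <- perm[lab[lab > 0]]
  rec2 <- nucleusRecords(nuc)
  rec2$id <- perm[rec2$id]
  rec2 <- rec2[order(rec2$id), ]
  nuc2 <- new("LabeledNuclei", labelImage = lab2, records = rec2)

  mipF <- normalize01(maxIntensityProjection(smoothStack(sc$foci)))
  c1 <- fociCounts(detectFoci(mipF, nuc))
  c2 <- fociCounts(detectFoci(mipF, nuc2))
  expect_equal(unname(c2[as.character(perm)]), unname(c1))
})

test_that("well summaries pool rather than average field means", {
  mkSet <- function(counts) {
    cnt <- as.integer(counts)
    names(cnt) <- as.character(seq_along(cnt))
    n <- sum(cnt)
    foci <- data.frame(
      id = seq_len(n), cy = rep(1, n), cx = rep(1, n),
      area = rep(3L, n), peak = rep(1, n),
      nucleus = rep(seq_along(cnt), cnt)
    )
    new("FociSet", foci = foci, perNucleusCounts = cnt)
  }
  one <- summarizeWell(list(mkSet(c(2, 4, 6))), "w1")
  expect_equal(meanFociPerNucleus(one), 4.0)

  two <- summarizeWell(list(mkSet(rep(3, 10)), mkSet(rep(0, 5))), "w2")
  expect_equal(two@nNuclei, 15L)
  expect_equal(two@nFoci, 30L)
  expect_equal(meanFociPerNucleus(two), 2.0) # pooled, not mean of means

  empty <- summarizeWell(list(mkSet(integer(0))), "w3")
  expect_true(is.na(meanFociPerNucleus(empty)))
})

test_that("fold change is the ratio of pooled means with guarded baseline", {
  mk <- function(nNuc, nFoci) {
    new("WellSummary",
      wellId = "w", nNuclei = as.integer(nNuc),
      nFoci = as.integer(nFoci),
      meanFociPerNucleus = if (nNuc > 0) nFoci / nNuc else NA_real_,
      perField = data.frame(field = "f1", nNuclei = nNuc, nFoci = nFoci)
    )
  }
  expect_equal(foldChange(mk(10, 50), mk(10, 20)), 2.5)
  expect_equal(foldChange(mk(10, 20), mk(10, 20)), 1.0)
  expect_error(foldChange(mk(10, 50), mk(10, 0)), "baseline mean")
  expect_error(foldChange(mk(10, 50), mk(0, 0)), "no nuclei")
})

test_that("detectFoci validates channel geometry", {
  nuclei <- segmentNuclei(
    {
      img <- matrix(0.05, 80, 80)
      img[diskMask(80, 80, 40, 40, 12)] <- 0.9
      img
    },
    segmentationConfig(minNucleusArea = 100)
  )
  expect_error(detectFoci(matrix(0.5, 60, 60), nuclei), "different shapes")
})
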
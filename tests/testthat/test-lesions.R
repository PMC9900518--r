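mkRec <- function(long, short, gene = "HPRT", ctl = FALSE,
                  lens = c(10.4, 0.286)) {
  data.frame(
    gene = gene, condition = if (ctl) "DMSO" else "Dox", replicate = 1L,
    long_intensity = long, short_intensity = short,
    long_length_kb = lens[1], short_length_kb = lens[2], is_control = ctl
  )
}

test_that("relative amplification normalizes lanes and controls to unity", {
  ctl <- mkRec(1.0, 1.0, ctl = TRUE)
  expect_equal(relativeAmplification(ctl, ctl), 1.0)
  expect_equal(relativeAmplification(mkRec(0.5, 1.0), ctl), 0.5)
  # scale invariance of one lane
  t1 <- mkRec(0.4, 0.8)
  t2 <- mkRec(0.4 * 37, 0.8 * 37)
  expect_equal(
    relativeAmplification(t1, ctl),
    relativeAmplification(t2, ctl)
  )
  expect_error(
    relativeAmplification(mkRec(1, 1, gene = "POLB", lens = c(12.2, 0.192)), ctl),
    "gene mismatch"
  )
  expect_error(relativeAmplification(mkRec(-1, 1), ctl), "positive")
})

test_that("Poisson inversion recovers lambda analytically", {
  expect_equal(lesionsPer10kb(1, 10.4)$lesionsPer10kb, 0)

  # POLB long amplicon: rel = exp(-1.22) over 12.2 kb is 1 lesion/10 kb
  est <- lesionsPer10kb(exp(-1.22), 12.2)
  expect_equal(est$lambdaAmplicon, 1.22, tolerance = 1e-12)
  expect_equal(est$lesionsPer10kb, 1.0, tolerance = 1e-12)

  # exact round trip across rates and both assay lengths
  for (lam in c(0.05, 0.2, 0.5, 1, 2, 5)) {
    for (len in c(10.4, 12.2)) {
      rt <- lesionsPer10kb(exp(-lam * len / 10), len)
      expect_equal(rt$lesionsPer10kb, lam, tolerance = 1e-12)
    }
  }

  # rel > 1 is flagged, not clamped
  over <- lesionsPer10kb(1.1, 10.4)
  expect_true(over$flagged)
  expect_lt(over$lesionsPer10kb, 0)

  expect_error(lesionsPer10kb(0, 10.4), "must be > 0")
  expect_error(lesionsPer10kb(-0.5, 10.4), "must be > 0")
})

test_that("the estimate is strictly decreasing in relative amplification", {
  rels <- seq(0.1, 1.3, by = 0.1)
  ests <- vapply(
    rels,
    function(r) lesionsPer10kb(r, 10.4)$lesionsPer10kb, numeric(1)
  )
  expect_true(all(diff(ests) < 0))
})

test_that("short-amplicon correction raises the estimate by the length ratio", {
  rel <- exp(-1)
  plain <- lesionsPer10kb(rel, 10.4)
  corr <- lesionsPer10kb(rel, 10.4, correctShort = TRUE, shortLengthKb = 0.286)
  expect_equal(
    corr$lesionsPer10kb / plain$lesionsPer10kb,
    10.4 / (10.4 - 0.286)
  )
})

test_that("simulated assays round-trip through the full estimator", {
  lam <- 1.0
  reps <- lapply(1:6, function(r) {
    rbind(
      simulateLAqPCR(lam,
        gene = "HPRT", nMolecules = 50000, noiseCv = 0.02,
        replicate = r, seed = 100 + r
      ),
      simulateLAqPCR(lam,
        gene = "HPRT", nMolecules = 50000, noiseCv = 0.02,
        treated = FALSE, replicate = r, seed = 200 + r
      )
    )
  })
  df <- do.call(rbind, reps)
  est <- estimateLesions(df)
  dox <- est$perCondition[est$perCondition$condition == "treated", ]
  expect_lt(abs(dox$meanLesionsPer10kb - lam) / lam, 0.1)
  ctl <- est$perCondition[est$perCondition$condition == "control", ]
  expect_lt(abs(ctl$meanLesionsPer10kb), 0.1)
  expect_equal(nrow(est$perReplicate), nrow(df))
})

test_that("amplification tables survive a CSV round trip with validation", {
  df <- rbind(
    mkRec(1.0, 1.0, ctl = TRUE),
    mkRec(0.6, 1.05)
  )
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "bands.csv")
  utils::write.csv(df, p, row.names = FALSE)
  back <- readAmplificationTable(p)
  expect_equal(back$long_intensity, df$long_intensity)
  expect_true(is.logical(back$is_control))

  est <- estimateLesions(back)
  paths <- writeLesionEstimates(est, tmp)
  expect_true(all(file.exists(paths)))
  reread <- utils::read.csv(paths[1])
  expect_equal(reread$lesionsPer10kb, est$perReplicate$lesionsPer10kb)

  bad <- df
  bad$long_intensity[1] <- -2
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(readAmplificationTable(p), "positive")
})
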
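# compact shared fixtures
smallCodebook <- function(nGenes = 10L, seed = 2L) {
  assignBarcodes(sprintf("g%02d", seq_len(nGenes)), 8, 2, seed = seed)
}

test_that("field simulation honours expression means and determinism", {
  cb <- smallCodebook()
  # all-zero means: valid empty truth
  fs0 <- fieldSpec(128, 128, 3, c(10, 12),
                   stats::setNames(rep(0, 10), geneIds(cb)))
  t0 <- simulateField(fs0, cb, seed = 4)
  expect_equal(nrow(t0@transcripts), 0L)
  expect_true(validObject(t0))
  # one cell, one expressed gene with mean 1000: count within 5 SD
  means <- stats::setNames(c(1000, rep(0, 9)), geneIds(cb))
  fs1 <- fieldSpec(256, 256, 1, c(20, 22), means)
  t1 <- simulateField(fs1, cb, seed = 4)
  expect_lt(abs(nrow(t1@transcripts) - 1000), 5 * sqrt(1000))
  expect_true(all(t1@transcripts$gene_id == "g01"))
  # determinism
  t1b <- simulateField(fs1, cb, seed = 4)
  expect_identical(t1@transcripts, t1b@transcripts)
  expect_identical(t1@cellLabels, t1b@cellLabels)
  # transcripts stay inside the field and within the expanded cell disc
  cc <- t1@cellCenters
  d <- sqrt((t1@transcripts$x - cc$x)^2 + (t1@transcripts$y - cc$y)^2)
  expect_true(all(d <= cc$radius * 1.4 + 1e-9))
})

test_that("rendering places one Gaussian per barcode position at the drifted spot", {
  cb <- smallCodebook()
  genes <- geneIds(cb)
  # a single transcript, planted deterministically
  truth <- simulateField(
    fieldSpec(96, 96, 1, c(12, 14),
              stats::setNames(c(rep(0, 9), 50), genes)), cb, seed = 1)
  tr <- truth@transcripts[1, , drop = FALSE]
  truth@transcripts <- tr
  drift <- matrix(0, 8, 2); drift[3, ] <- c(2, -3)
  acq <- acquisitionSpec(drift = drift, dropout_rate = 0, false_spot_rate = 0,
                         read_noise_sigma = 0, shot_noise = FALSE,
                         illumination_amplitude = 0, background_level = 0,
                         spot_amplitude_cv = 0, rng_seed = 3)
  sim <- renderStack(truth, cb, acq)
  ps <- sim$truth@planeSpots
  expect_equal(nrow(ps), 4L)
  expect_setequal(ps$pseudocolor, barcodeMatrix(cb)[tr$gene_id, ])
  for (i in seq_len(4)) {
    pl <- getPlane(sim$stack, ps$round[i], ps$channel[i])
    pk <- arrayInd(which.max(pl), dim(pl)) - 1L   # (row, col) 0-based
    expect_lt(abs(pk[1] - ps$y[i]), 1)
    expect_lt(abs(pk[2] - ps$x[i]), 1)
    # drift applied to the round the position falls in
    expect_equal(ps$x[i], tr$x + drift[ps$round[i] + 1, 2])
    expect_equal(ps$y[i], tr$y + drift[ps$round[i] + 1, 1])
  }
  # planes not carrying the barcode stay empty
  dark <- setdiff(0:15, ps$pseudocolor)
  for (pc in dark) {
    expect_equal(max(getPlane(sim$stack, pc %/% 2, pc %% 2)), 0)
  }
})

test_that("dropout limit and empirical dropout rate behave as configured", {
  cb <- smallCodebook()
  means <- stats::setNames(rep(4, 10), geneIds(cb))
  truth <- simulateField(fieldSpec(256, 256, 10, c(12, 16), means), cb, seed = 6)
  nT <- nrow(truth@transcripts)
  expect_gt(nT, 250)   # >= 1e3 positions for the binomial check
  # dropout 1: nothing detected
  acq1 <- acquisitionSpec(drift = matrix(0, 8, 2), dropout_rate = 1,
                          false_spot_rate = 0, shot_noise = FALSE,
                          read_noise_sigma = 0, rng_seed = 2)
  sim1 <- renderStack(truth, cb, acq1)
  expect_equal(nrow(sim1$truth@planeSpots), 0L)
  # dropout 0.15: empirical fraction within 4 binomial SD
  acq <- acquisitionSpec(drift = matrix(0, 8, 2), dropout_rate = 0.15,
                         false_spot_rate = 0, shot_noise = FALSE,
                         read_noise_sigma = 0, rng_seed = 2)
  sim <- renderStack(truth, cb, acq)
  kept <- nrow(sim$truth@planeSpots)
  phat <- 1 - kept / (4 * nT)
  expect_lt(abs(phat - 0.15), 4 * sqrt(0.15 * 0.85 / (4 * nT)))
})

test_that("noise-free rendering conserves flux and reruns identically", {
  cb <- smallCodebook()
  means <- stats::setNames(rep(2, 10), geneIds(cb))
  truth <- simulateField(fieldSpec(128, 128, 4, c(10, 12), means), cb, seed = 9)
  acq <- acquisitionSpec(drift = matrix(0, 8, 2), dropout_rate = 0,
                         false_spot_rate = 0, shot_noise = FALSE,
                         read_noise_sigma = 0, illumination_amplitude = 0,
                         background_level = 0, spot_amplitude_cv = 0,
                         rng_seed = 5)
  sim <- renderStack(truth, cb, acq)
  ps <- sim$truth@planeSpots
  for (pc in unique(ps$pseudocolor)) {
    sp <- ps[ps$pseudocolor == pc, ]
    pl <- getPlane(sim$stack, pc %/% 2, pc %% 2)
    expected <- nrow(sp) * 800 * 2 * pi * 1.3^2
    expect_lt(abs(sum(pl) - expected) / expected, 0.05)
  }
  sim2 <- renderStack(truth, cb, acq)
  expect_identical(sim$stack@planes, sim2$stack@planes)
  expect_identical(sim$stack@nuclear, sim2$stack@nuclear)
})

test_that("stacks serialize to TIFF and back without loss beyond float32", {
  cb <- smallCodebook(6)
  means <- stats::setNames(rep(1, 6), geneIds(cb))
  truth <- simulateField(fieldSpec(64, 64, 2, c(8, 10), means), cb, seed = 3)
  sim <- renderStack(truth, cb, acquisitionSpec(rng_seed = 4))
  d <- withr::local_tempdir()
  writeStack(sim$stack, d)
  st2 <- readStack(d)
  expect_equal(dim(st2@planes), dim(sim$stack@planes))
  scale <- max(sim$stack@planes, sim$stack@nuclear)
  expect_lt(max(abs(st2@planes - sim$stack@planes)) / scale, 1e-6)
  expect_lt(max(abs(st2@nuclear - sim$stack@nuclear)) / scale, 1e-6)
  expect_identical(isRegistered(st2), FALSE)
})
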
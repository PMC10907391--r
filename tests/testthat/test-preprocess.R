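# textured nuclear-style reference for registration tests
discReference <- function(seed = 1L, size = 128L) {
  set.seed(seed)
  n <- 6L
  fishcoder:::.renderDiscs(size, size, runif(n, 20, size - 20),
                           runif(n, 20, size - 20), runif(n, 8, 13), 300)
}

test_that("registration recovers planted shifts on the nuclear reference", {
  cb <- assignBarcodes(sprintf("g%02d", 1:8), 5, 2, seed = 3)
  means <- stats::setNames(rep(2, 8), geneIds(cb))
  truth <- simulateField(fieldSpec(160, 160, 5, c(10, 13), means), cb, seed = 2)
  # identical references (zero drift, no noise) give zero shifts
  acq0 <- acquisitionSpec(drift = matrix(0, 5, 2), shot_noise = FALSE,
                          read_noise_sigma = 0, rng_seed = 1)
  st0 <- registerRounds(renderStack(truth, cb, acq0)$stack)
  expect_equal(max(abs(stackShifts(st0))), 0)
  expect_true(isRegistered(st0))
  # planted integer drift, noise-free: recovered within 0.1 px
  drift <- matrix(0, 5, 2); drift[2:5, ] <- cbind(c(3, -2, 1, 4), c(-2, 1, -3, 2))
  acqI <- acquisitionSpec(drift = drift, shot_noise = FALSE,
                          read_noise_sigma = 0, rng_seed = 1)
  stI <- registerRounds(renderStack(truth, cb, acqI)$stack)
  expect_lt(max(abs(stackShifts(stI) + drift)), 0.1)
  # sub-pixel drift at realistic SNR: recovered within 0.5 px
  driftS <- matrix(0, 5, 2); driftS[2:5, ] <- cbind(c(1.5, -0.5, 2.5, 1.25),
                                                    c(-1.5, 0.75, 0.5, -2.25))
  acqS <- acquisitionSpec(drift = driftS, rng_seed = 1)
  stS <- registerRounds(renderStack(truth, cb, acqS)$stack)
  expect_lt(max(abs(stackShifts(stS) + driftS)), 0.5)
  # blank reference errors with the round named
  bad <- renderStack(truth, cb, acq0)$stack
  bad@nuclear[, , 3] <- 0
  expect_error(registerRounds(bad), "round 2")
})

test_that("white tophat removes smooth background and keeps spots", {
  # constant plane maps to zero
  expect_equal(max(abs(correctBackground(matrix(7, 64, 64)))), 0)
  # isolated spot on a slanted background: gradient removed, peak kept
  ramp <- outer(seq(0, 40, length.out = 64), seq(0, 20, length.out = 64), "+")
  spot <- cpp_add_spots(64, 64, 31, 30, 500, 1.3)
  out <- correctBackground(ramp + spot, selem_radius = 7)
  expect_gt(max(out), 0.9 * 500)            # peak preserved within 10%
  corner <- out[1:10, 1:10]
  expect_lt(max(corner), 10)                # ramp suppressed
  # nonnegative on random input
  set.seed(8)
  rnd <- matrix(runif(64 * 64, 0, 100), 64)
  expect_gte(min(correctBackground(rnd)), 0)
  expect_error(correctBackground(rnd, 0), "positive")
})

test_that("ROF denoising is total-variation decreasing and mean conserving", {
  cst <- matrix(3.5, 48, 48)
  expect_equal(denoiseROF(cst, 0.05), cst, ignore_attr = TRUE)
  # noisy step edge
  set.seed(2)
  step <- cbind(matrix(10, 48, 24), matrix(50, 48, 24))
  noisy <- step + matrix(rnorm(48 * 48, 0, 4), 48)
  tv <- function(m) {
    sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  }
  den <- denoiseROF(noisy, 0.1)
  expect_lt(tv(den), tv(noisy))
  expect_lt(abs(mean(den) - mean(noisy)), 1e-6)
  # stronger weight moves the solution further from the input
  d2 <- sapply(c(0.01, 0.05, 0.2), function(w)
    sqrt(mean((denoiseROF(noisy, w) - noisy)^2)))
  expect_true(all(diff(d2) > 0))
  expect_error(denoiseROF(noisy, 0), "positive")
})

test_that("Richardson-Lucy sharpens a matched blur and conserves flux", {
  # delta PSF: identity for any iteration count
  set.seed(5)
  img <- matrix(runif(40 * 40, 0, 10), 40)
  delta <- matrix(0, 5, 5); delta[3, 3] <- 1
  expect_lt(max(abs(deconvolveRL(img, delta, 7) - img)), 1e-8)
  # Gaussian-blurred spot with matched PSF: peak up, width down
  psf <- gaussianPSF(1.6)
  spot <- cpp_add_spots(61, 61, 30, 30, 400, 1.6)  # already PSF-shaped
  dec <- deconvolveRL(spot, psf, 20)
  expect_gt(max(dec), max(spot))
  fwhm <- function(m) {
    prof <- m[31, ]
    sum(prof >= max(prof) / 2)
  }
  expect_lt(fwhm(dec), fwhm(spot))
  # flux conserved within 1% for an interior-supported signal
  expect_lt(abs(sum(dec) - sum(spot)) / sum(spot), 0.01)
  expect_error(deconvolveRL(spot, -psf, 5), "nonnegative")
  expect_error(deconvolveRL(spot, psf * 2, 5), "unit sum")
})

test_that("preprocessing operators are shift-equivariant away from borders", {
  set.seed(11)
  base <- cpp_add_spots(72, 72, runif(12, 20, 52), runif(12, 20, 52),
                        runif(12, 200, 600), 1.3) +
          outer(seq(0, 30, length.out = 72), seq(0, 15, length.out = 72), "+")
  shift <- function(m, dy, dx) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  int <- 12:60  # interior, clear of the 5-px shift and operator margins
  for (op in list(function(m) correctBackground(m, 7),
                  function(m) denoiseROF(m, 0.05, 80, 1e-4),
                  function(m) deconvolveRL(m, gaussianPSF(1.3), 8))) {
    a <- shift(op(base), 5, 5)
    b <- op(shift(base, 5, 5))
    expect_lt(max(abs(a[int, int] - b[int, int])) / max(base), 0.02)
  }
})

test_that("the full chain keeps residual drift below half a pixel", {
  cb <- assignBarcodes(sprintf("g%02d", 1:8), 5, 2, seed = 3)
  means <- stats::setNames(rep(2, 8), geneIds(cb))
  for (seed in c(2, 7)) {
    truth <- simulateField(fieldSpec(160, 160, 5, c(10, 13), means), cb,
                           seed = seed)
    sim <- renderStack(truth, cb, acquisitionSpec(rng_seed = seed + 10))
    st <- registerRounds(sim$stack)
    expect_lt(max(abs(stackShifts(st) + sim$truth@drifts)), 0.5)
  }
})
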
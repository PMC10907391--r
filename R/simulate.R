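#' Synthetic transcript sequences
#'
#' Random A/C/G/T sequences standing in for exonic mRNA, used to exercise
#' probe design without external FASTA input. Deterministic given the seed.
#'
#' @param geneIds character vector of gene ids.
#' @param length transcript length in nt (recycled).
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
simulateTranscripts <- function(geneIds, length = 1200L, seed = 1L) {
  length <- rep_len(as.integer(length), base::length(geneIds))
  .withSeed(seed, {
    seqs <- vapply(length, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    stats::setNames(seqs, geneIds)
  })
}

#' Field specification for the simulator
#'
#' Geometry and expression levels of one synthetic field of view. The
#' defaults describe the compact test field used throughout the package:
#' a 512 x 512 px field with 30 nuclei. Per-gene expression means (Poisson
#' transcripts per cell) must cover every codebook gene; [defaultExpressionMeans()]
#' supplies a log-spaced spread when none is given.
#'
#' @param height,width field size, px.
#' @param n_cells number of nuclei.
#' @param cell_radius_range numeric length-2, nucleus radius bounds, px.
#' @param expression_means named numeric, gene -> mean transcripts/cell
#'   (may be `NULL` and supplied at simulation time).
#' @param cytoplasm_factor transcripts are placed uniformly in a disc of
#'   `cytoplasm_factor * radius` around the nucleus center.
#' @return list of class `FieldSpec`.
#' @export
fieldSpec <- function(height = 512L, width = 512L, n_cells = 30L,
                      cell_radius_range = c(12, 18),
                      expression_means = NULL,
                      cytoplasm_factor = 1.4) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_cells = as.integer(n_cells),
               cell_radius_range = as.numeric(cell_radius_range),
               expression_means = expression_means,
               cytoplasm_factor = cytoplasm_factor)
  stopifnot(spec$height > 0, spec$width > 0, spec$n_cells >= 0,
            length(spec$cell_radius_range) == 2L,
            all(spec$cell_radius_range > 0),
            is.null(expression_means) || all(expression_means >= 0))
  class(spec) <- "FieldSpec"
  spec
}

#' Log-spaced per-gene expression means
#'
#' A deterministic spread of Poisson means from `lo` to `hi` transcripts
#' per cell, giving genes distinguishable abundances for correlation
#' checks.
#'
#' @param geneIds character vector.
#' @param lo,hi lowest and highest mean transcripts per cell.
#' @return named numeric vector.
#' @export
defaultExpressionMeans <- function(geneIds, lo = 0.3, hi = 3) {
  n <- length(geneIds)
  m <- if (n == 1L) hi else exp(seq(log(lo), log(hi), length.out = n))
  stats::setNames(m, geneIds)
}

#' Acquisition specification for the simulator
#'
#' Optical and noise parameters of the rendered stacks. Defaults are
#' plausible for a spinning-disk acquisition of diffraction-limited spots
#' rather than fitted to any instrument: a 1.3 px Gaussian PSF, per-round
#' random-walk rigid drift, a smooth multiplicative vignetting field,
#' Poisson shot noise with additive Gaussian read noise, 10% per-position
#' dropout and 0.05 spurious spots per plane.
#'
#' @param psf_sigma Gaussian PSF sigma, px.
#' @param spot_amplitude mean peak amplitude, photons.
#' @param spot_amplitude_cv lognormal coefficient of variation of the
#'   per-spot amplitude.
#' @param background_level uniform background, photons.
#' @param illumination_amplitude strength of the multiplicative
#'   low-frequency bias (0 disables).
#' @param drift either `NULL` (random walk with sd `drift_sigma` px/round,
#'   round 0 at zero) or an explicit `nRounds x 2` matrix of `(dy, dx)`.
#' @param drift_sigma random-walk step sd, px.
#' @param dropout_rate probability a barcode position yields no spot.
#' @param false_spot_rate expected spurious spots per plane.
#' @param read_noise_sigma additive Gaussian noise sd, photons.
#' @param shot_noise logical, apply Poisson noise.
#' @param nuclear_level nuclear-reference plateau intensity, photons.
#' @param rng_seed seed governing all acquisition randomness.
#' @return list of class `AcquisitionSpec`.
#' @export
acquisitionSpec <- function(psf_sigma = 1.3, spot_amplitude = 800,
                            spot_amplitude_cv = 0.2,
                            background_level = 100,
                            illumination_amplitude = 0.15,
                            drift = NULL, drift_sigma = 1.0,
                            dropout_rate = 0.10, false_spot_rate = 0.05,
                            read_noise_sigma = 2, shot_noise = TRUE,
                            nuclear_level = 300, rng_seed = 1L) {
  acq <- list(psf_sigma = psf_sigma, spot_amplitude = spot_amplitude,
              spot_amplitude_cv = spot_amplitude_cv,
              background_level = background_level,
              illumination_amplitude = illumination_amplitude,
              drift = drift, drift_sigma = drift_sigma,
              dropout_rate = dropout_rate,
              false_spot_rate = false_spot_rate,
              read_noise_sigma = read_noise_sigma,
              shot_noise = isTRUE(shot_noise),
              nuclear_level = nuclear_level,
              rng_seed = as.integer(rng_seed))
  stopifnot(acq$psf_sigma > 0,
            acq$dropout_rate >= 0, acq$dropout_rate <= 1,
            acq$false_spot_rate >= 0, acq$read_noise_sigma >= 0)
  class(acq) <- "AcquisitionSpec"
  acq
}

#' Simulate ground-truth cells and transcripts for one field
#'
#' Nuclei are placed by dart throwing (rejected while closer than 2.1
#' radii to an accepted nucleus or too close to the border); per-cell,
#' per-gene transcript counts are Poisson with the field's expression
#' means and positions uniform within the expanded cell disc. The result
#' carries no acquisition effects; [renderStack()] adds drift, dropout and
#' noise.
#'
#' @param field a [fieldSpec()].
#' @param codebook a [Codebook-class]; every codebook gene needs an
#'   expression mean (missing `expression_means` gets
#'   [defaultExpressionMeans()]).
#' @param seed RNG seed.
#' @return a [SimulatedField-class].
#' @export
simulateField <- function(field, codebook, seed = 1L) {
  genes <- geneIds(codebook)
  means <- field$expression_means
  if (is.null(means)) means <- defaultExpressionMeans(genes)
  if (!all(genes %in% names(means)))
    stop("expression_means must cover every codebook gene")
  means <- means[genes]
  h <- field$height; w <- field$width
  .withSeed(seed, {
    # --- nucleus placement by dart throwing
    centers <- matrix(numeric(0), ncol = 3)  # x, y, radius
    tries <- 0L
    while (nrow(centers) < field$n_cells) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop(sprintf(
          "nucleus placement failed after %d attempts; lower n_cells or radius",
          tries))
      r <- stats::runif(1, field$cell_radius_range[1], field$cell_radius_range[2])
      margin <- r * field$cytoplasm_factor + 2
      cx <- stats::runif(1, margin, w - 1 - margin)
      cy <- stats::runif(1, margin, h - 1 - margin)
      if (nrow(centers) > 0L) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(d < 2.1 * pmax(centers[, 3], r))) next
      }
      centers <- rbind(centers, c(cx, cy, r))
    }
    cellCenters <- data.frame(cell_id = seq_len(nrow(centers)),
                              x = centers[, 1], y = centers[, 2],
                              radius = centers[, 3])
    # --- true label image (discs; disjoint by construction)
    labels <- matrix(0L, nrow = h, ncol = w)
    xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
    ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
    for (i in seq_len(nrow(centers))) {
      inside <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= centers[i, 3]^2
      labels[inside] <- i
    }
    # --- transcripts
    tx <- vector("list", nrow(centers))
    for (i in seq_len(nrow(centers))) {
      counts <- stats::rpois(length(genes), means)
      tot <- sum(counts)
      if (tot == 0L) next
      rad <- centers[i, 3] * field$cytoplasm_factor
      rr <- rad * sqrt(stats::runif(tot))
      th <- stats::runif(tot, 0, 2 * pi)
      px <- pmin(pmax(centers[i, 1] + rr * cos(th), 0), w - 1)
      py <- pmin(pmax(centers[i, 2] + rr * sin(th), 0), h - 1)
      tx[[i]] <- data.frame(gene_id = rep(genes, counts), x = px, y = py,
                            cell_id = i, stringsAsFactors = FALSE)
    }
    transcripts <- if (length(tx)) do.call(rbind, tx) else NULL
    if (is.null(transcripts))
      transcripts <- data.frame(gene_id = character(), x = numeric(),
                                y = numeric(), cell_id = integer(),
                                stringsAsFactors = FALSE)
    rownames(transcripts) <- NULL
    methods::new("SimulatedField",
                 transcripts = transcripts, cellLabels = labels,
                 cellCenters = cellCenters,
                 drifts = matrix(numeric(0), ncol = 2),
                 planeSpots = data.frame(), geneIds = genes,
                 fieldSpec = unclass(field))
  })
}

# smooth multiplicative illumination: off-center parabolic vignette
.illuminationField <- function(h, w, amplitude) {
  if (amplitude == 0) return(matrix(1, h, w))
  cx <- 0.35 * (w - 1); cy <- 0.42 * (h - 1)
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
  r2 <- ((xs - cx)^2 + (ys - cy)^2) / max(h, w)^2
  f <- 1 - amplitude * r2 / max(r2)
  f / max(f)
}

# anti-aliased disc: plateau `level`, soft 1.5 px shoulder
.renderDiscs <- function(h, w, cx, cy, radius, level) {
  plane <- matrix(0, h, w)
  for (i in seq_along(cx)) {
    r <- radius[i]
    c0 <- max(0, floor(cx[i] - r - 3)); c1 <- min(w - 1, ceiling(cx[i] + r + 3))
    r0 <- max(0, floor(cy[i] - r - 3)); r1 <- min(h - 1, ceiling(cy[i] + r + 3))
    if (c1 < c0 || r1 < r0) next
    xs <- matrix(rep(c0:c1, each = r1 - r0 + 1), nrow = r1 - r0 + 1)
    ys <- matrix(rep(r0:r1, times = c1 - c0 + 1), nrow = r1 - r0 + 1)
    d <- sqrt((xs - cx[i])^2 + (ys - cy[i])^2)
    plane[(r0:r1) + 1, (c0:c1) + 1] <- plane[(r0:r1) + 1, (c0:c1) + 1] +
      level * stats::plogis((r - d) / 1.5)
  }
  plane
}

#' Render multi-round image stacks from a simulated field
#'
#' For every (round, channel) plane, each non-dropped transcript whose
#' barcode contains that pseudocolor contributes an isotropic 2-D Gaussian
#' at its drift-shifted position; spurious spots are added at the
#' configured rate; the plane is multiplied by the illumination field and
#' corrupted with Poisson shot noise and additive read noise. A per-round
#' nuclear-reference plane (smoothed discs at the true nucleus positions)
#' carries the same drift. Deterministic given `acq$rng_seed`.
#'
#' @param truth a [SimulatedField-class] from [simulateField()].
#' @param codebook the [Codebook-class] used for the truth.
#' @param acq an [acquisitionSpec()].
#' @return list with `stack` (an [ImageStack-class]) and `truth` (the
#'   input truth augmented with planted `drifts` and per-plane true spot
#'   lists after dropout in `planeSpots`).
#' @export
renderStack <- function(truth, codebook, acq = acquisitionSpec()) {
  stopifnot(identical(truth@geneIds, geneIds(codebook)))
  h <- nrow(truth@cellLabels); w <- ncol(truth@cellLabels)
  R <- nRounds(codebook); C <- nChannels(codebook)
  codes <- barcodeMatrix(codebook)
  tr <- truth@transcripts
  .withSeed(acq$rng_seed, {
    drifts <- acq$drift
    if (is.null(drifts)) {
      steps <- matrix(stats::rnorm(2 * R, 0, acq$drift_sigma), ncol = 2)
      steps[1, ] <- 0
      drifts <- apply(steps, 2, cumsum)
      drifts <- matrix(drifts, ncol = 2)
    }
    stopifnot(nrow(drifts) == R, ncol(drifts) == 2)

    # per-transcript-position spot records with dropout and amplitude
    nT <- nrow(tr)
    planeSpots <- data.frame()
    if (nT > 0L) {
      gi <- match(tr$gene_id, rownames(codes))
      pcs <- codes[gi, , drop = FALSE]              # nT x 4
      keep <- matrix(stats::runif(nT * 4) >= acq$dropout_rate, nrow = nT)
      sdlog <- sqrt(log(1 + acq$spot_amplitude_cv^2))
      amp <- matrix(stats::rlnorm(nT * 4, log(acq$spot_amplitude) - sdlog^2 / 2,
                                  sdlog), nrow = nT)
      planeSpots <- data.frame(
        transcript_id = rep(seq_len(nT), 4L),
        gene_id = rep(tr$gene_id, 4L),
        pseudocolor = as.integer(pcs),
        x = rep(tr$x, 4L), y = rep(tr$y, 4L),
        amplitude = as.numeric(amp),
        detected = as.logical(keep), stringsAsFactors = FALSE)
      planeSpots <- planeSpots[planeSpots$detected, , drop = FALSE]
      rc <- pseudocolorRC(planeSpots$pseudocolor, C)
      planeSpots$round <- rc$round
      planeSpots$channel <- rc$channel
      planeSpots$x <- planeSpots$x + drifts[planeSpots$round + 1L, 2L]
      planeSpots$y <- planeSpots$y + drifts[planeSpots$round + 1L, 1L]
      planeSpots$detected <- NULL
      rownames(planeSpots) <- NULL
    }

    illum <- .illuminationField(h, w, acq$illumination_amplitude)
    planes <- array(0, dim = c(h, w, R, C))
    falseSpots <- list()
    for (r in seq_len(R) - 1L) {
      for (ch in seq_len(C) - 1L) {
        pc <- r * C + ch
        sp <- if (nrow(planeSpots)) planeSpots[planeSpots$pseudocolor == pc, ]
              else planeSpots
        nf <- stats::rpois(1, acq$false_spot_rate)
        fx <- stats::runif(nf, 0, w - 1); fy <- stats::runif(nf, 0, h - 1)
        famp <- stats::rlnorm(nf, log(acq$spot_amplitude), 0.2)
        if (nf > 0)
          falseSpots[[length(falseSpots) + 1L]] <- data.frame(
            round = r, channel = ch, pseudocolor = pc, x = fx, y = fy)
        xs <- c(if (nrow(sp)) sp$x, fx)
        ys <- c(if (nrow(sp)) sp$y, fy)
        as <- c(if (nrow(sp)) sp$amplitude, famp)
        plane <- cpp_add_spots(h, w, xs, ys, as, acq$psf_sigma)
        plane <- (plane + acq$background_level) * illum
        if (acq$shot_noise)
          plane <- matrix(stats::rpois(h * w, plane), h, w)
        if (acq$read_noise_sigma > 0)
          plane <- plane + matrix(stats::rnorm(h * w, 0, acq$read_noise_sigma), h, w)
        planes[, , r + 1L, ch + 1L] <- pmax(plane, 0)
      }
    }
    nuclear <- array(0, dim = c(h, w, R))
    cc <- truth@cellCenters
    for (r in seq_len(R) - 1L) {
      plane <- .renderDiscs(h, w, cc$x + drifts[r + 1L, 2L],
                            cc$y + drifts[r + 1L, 1L], cc$radius,
                            acq$nuclear_level)
      plane <- (plane + acq$background_level) * illum
      if (acq$shot_noise) plane <- matrix(stats::rpois(h * w, plane), h, w)
      if (acq$read_noise_sigma > 0)
        plane <- plane + matrix(stats::rnorm(h * w, 0, acq$read_noise_sigma), h, w)
      nuclear[, , r + 1L] <- pmax(plane, 0)
    }
    truth@drifts <- drifts
    truth@planeSpots <- planeSpots
    fsp <- if (length(falseSpots)) do.call(rbind, falseSpots) else
      data.frame(round = integer(), channel = integer(),
                 pseudocolor = integer(), x = numeric(), y = numeric())
    stack <- methods::new("ImageStack", planes = planes, nuclear = nuclear,
                          registered = FALSE,
                          shifts = matrix(0, nrow = R, ncol = 2))
    attr(stack, "falseSpots") <- fsp
    list(stack = stack, truth = truth)
  })
}
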
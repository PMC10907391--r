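#' Default pipeline configuration
#'
#' One nested list driving [runPipeline()]: a gene panel, probe-design,
#' codebook, field, acquisition, preprocessing, spot-calling, decoding and
#' counting sections, a global seed, and an optional output directory.
#' Stage seeds are derived from the global seed by fixed offsets so the
#' stages draw from decoupled streams. The defaults describe the compact
#' 512 x 512, 30-cell, 40-gene field used throughout the package's tests.
#'
#' @param seed global RNG seed.
#' @param outdir output directory or `NULL` to keep results in memory.
#' @return nested list of class `RunConfig`.
#' @export
defaultRunConfig <- function(seed = 1L, outdir = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    genes = list(n_genes = 40L, prefix = "gene"),
    design = list(enabled = FALSE, transcript_len = 1200L),
    codebook = list(n_rounds = 22L, n_channels = 2L, max_shared = 2L),
    field = list(height = 512L, width = 512L, n_cells = 30L,
                 cell_radius_min = 12, cell_radius_max = 18,
                 expr_lo = 0.3, expr_hi = 3),
    acquisition = list(psf_sigma = 1.3, spot_amplitude = 800,
                       spot_amplitude_cv = 0.2, background_level = 100,
                       illumination_amplitude = 0.15, drift_sigma = 1.0,
                       dropout_rate = 0.10, false_spot_rate = 0.05,
                       read_noise_sigma = 2, shot_noise = TRUE,
                       nuclear_level = 300),
    preprocess = list(selem_radius = 7L, rof_weight = 0.05,
                      rof_max_iter = 200L, rof_tol = 1e-4, rl_iter = 15L,
                      upsample = 20L),
    spots = list(threshold_k = 6, min_distance = 2L, window = 7L),
    decode = list(radius = 2.5, min_positions = 3L),
    cells = list(smooth_sigma = 2, min_area = 80L, expand_px = 7L,
                 ws_tolerance = 1, ws_ext = 3L))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param cfg a `RunConfig` list.
#' @return `readRunConfig` returns the configuration merged over
#'   [defaultRunConfig()] defaults.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# md5 of the canonical YAML serialization of a config
.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full in-silico pipeline
#'
#' Executes design (optional), codebook, simulate, preprocess, spots,
#' decode and count as one reproducible run. Any stage error aborts with
#' the failing stage named; outputs of completed stages are retained in
#' the returned object (and on disk when `outdir` is set). Reruns with
#' the same configuration are deterministic.
#'
#' @param cfg a `RunConfig` from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return list with `manifest` (config hash, per-stage seeds, timings,
#'   output files) and `results` (codebook, truth, stack, spots, calls,
#'   counts `SummarizedExperiment`, decoding metrics, and the design when
#'   enabled).
#' @export
runPipeline <- function(cfg = defaultRunConfig()) {
  hash <- .configHash(cfg)
  outdir <- cfg$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stages <- list()
  results <- list()
  t0 <- Sys.time()
  stageSeed <- function(i) cfg$seed + 1000L * i
  run <- function(name, i, fn) {
    tic <- Sys.time()
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline aborted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
    stages[[name]] <<- list(seed = stageSeed(i),
                            seconds = as.numeric(Sys.time() - tic, units = "secs"))
    res
  }
  geneIdsVec <- sprintf("%s%03d", cfg$genes$prefix, seq_len(cfg$genes$n_genes))

  results$codebook <- run("codebook", 2L, function() {
    assignBarcodes(geneIdsVec, cfg$codebook$n_rounds, cfg$codebook$n_channels,
                   cfg$codebook$max_shared, seed = stageSeed(2L))
  })

  if (isTRUE(cfg$design$enabled)) {
    results$design <- run("design", 1L, function() {
      tx <- simulateTranscripts(geneIdsVec, cfg$design$transcript_len,
                                seed = stageSeed(1L))
      designProbes(tx, cfg = designConfig(rng_seed = stageSeed(1L)),
                   codebook = results$codebook)
    })
  } else {
    stages[["design"]] <- list(seed = stageSeed(1L), seconds = 0,
                               skipped = TRUE)
  }

  sim <- run("simulate", 3L, function() {
    fs <- fieldSpec(cfg$field$height, cfg$field$width, cfg$field$n_cells,
                    c(cfg$field$cell_radius_min, cfg$field$cell_radius_max),
                    defaultExpressionMeans(geneIdsVec, cfg$field$expr_lo,
                                           cfg$field$expr_hi))
    truth <- simulateField(fs, results$codebook, seed = stageSeed(3L))
    acq <- do.call(acquisitionSpec,
                   c(cfg$acquisition, list(rng_seed = stageSeed(3L) + 1L)))
    renderStack(truth, results$codebook, acq)
  })
  results$truth <- sim$truth
  psfSigma <- cfg$acquisition$psf_sigma

  results$stack <- run("preprocess", 4L, function() {
    preprocessStack(sim$stack, selem_radius = cfg$preprocess$selem_radius,
                    rof_weight = cfg$preprocess$rof_weight,
                    rof_max_iter = cfg$preprocess$rof_max_iter,
                    rof_tol = cfg$preprocess$rof_tol,
                    rl_iter = cfg$preprocess$rl_iter,
                    psf_sigma = psfSigma,
                    upsample = cfg$preprocess$upsample)
  })

  results$spots <- run("spots", 5L, function() {
    callSpots(results$stack,
              threshold = list(method = "robust", k = cfg$spots$threshold_k),
              min_distance = cfg$spots$min_distance,
              window = cfg$spots$window)
  })

  results$calls <- run("decode", 6L, function() {
    decodeSpots(results$spots, results$codebook,
                radius = cfg$decode$radius,
                min_positions = cfg$decode$min_positions)
  })

  results$counts <- run("count", 7L, function() {
    lab <- segmentNuclei(nuclearReference(results$stack, 0L),
                         smooth_sigma = cfg$cells$smooth_sigma,
                         min_area = cfg$cells$min_area,
                         ws_tolerance = cfg$cells$ws_tolerance,
                         ws_ext = cfg$cells$ws_ext)
    results$labels <<- lab
    assignAndCount(results$calls, lab, gene_ids = geneIdsVec,
                   expand_px = cfg$cells$expand_px)
  })

  results$metrics <- evaluateDecoding(results$calls, results$truth)

  files <- character()
  if (!is.null(outdir)) {
    writeCodebook(results$codebook, file.path(outdir, "codebook.csv"))
    writeSpotTable(results$spots, file.path(outdir, "spots.csv"))
    utils::write.csv(results$calls, file.path(outdir, "decoded.csv"),
                     row.names = FALSE)
    writeCountMatrix(results$counts, file.path(outdir, "counts"))
    if (isTRUE(cfg$design$enabled))
      writeProbeLibrary(results$design, file.path(outdir, "probes"))
    jsonlite::write_json(results$metrics[c("recall", "precision", "f1",
                                           "rmse", "n_true", "n_calls",
                                           "n_matched", "count_correlation")],
                         file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  }
  manifest <- list(config_hash = hash,
                   seed = cfg$seed,
                   stages = stages,
                   n_stages = length(stages),
                   total_seconds = as.numeric(Sys.time() - t0, units = "secs"),
                   files = if (length(files))
                     as.list(stats::setNames(unname(tools::md5sum(files)), files))
                   else list())
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, results = results)
}
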
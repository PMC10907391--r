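#' Write / read an image stack as multi-page TIFF
#'
#' One 32-bit float multi-page TIFF per fluorescence channel (pages are
#' rounds), one for the nuclear reference, and a `stack_meta.json` sidecar
#' recording geometry, registration state, shifts, and the intensity scale
#' (TIFF pages store values divided by the global maximum).
#'
#' @param stack an [ImageStack-class].
#' @param dir output directory.
#' @return `writeStack` returns the directory invisibly; `readStack` the
#'   reconstructed [ImageStack-class] (arrays round-trip exactly up to
#'   float32 precision).
#' @export
writeStack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  R <- nRounds(stack); C <- nChannels(stack)
  scale <- max(stack@planes, stack@nuclear, 1e-12)
  for (ch in seq_len(C)) {
    pages <- lapply(seq_len(R), function(r) stack@planes[, , r, ch] / scale)
    tiff::writeTIFF(pages, file.path(dir, sprintf("channel_%d.tiff", ch - 1L)),
                    bits.per.sample = 32L)
  }
  pages <- lapply(seq_len(R), function(r) stack@nuclear[, , r] / scale)
  tiff::writeTIFF(pages, file.path(dir, "nuclear.tiff"), bits.per.sample = 32L)
  jsonlite::write_json(list(
    height = dim(stack@planes)[1], width = dim(stack@planes)[2],
    n_rounds = R, n_channels = C, registered = isRegistered(stack),
    shifts = stack@shifts, scale = scale),
    file.path(dir, "stack_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeStack
#' @export
readStack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack_meta.json"),
                              simplifyVector = TRUE)
  R <- meta$n_rounds; C <- meta$n_channels
  planes <- array(0, dim = c(meta$height, meta$width, R, C))
  for (ch in seq_len(C)) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("channel_%d.tiff", ch - 1L)),
                            all = TRUE)
    for (r in seq_len(R)) planes[, , r, ch] <- pages[[r]] * meta$scale
  }
  pages <- tiff::readTIFF(file.path(dir, "nuclear.tiff"), all = TRUE)
  nuclear <- array(0, dim = c(meta$height, meta$width, R))
  for (r in seq_len(R)) nuclear[, , r] <- pages[[r]] * meta$scale
  shifts <- matrix(as.numeric(meta$shifts), nrow = R)
  methods::new("ImageStack", planes = planes, nuclear = nuclear,
               registered = isTRUE(meta$registered), shifts = shifts)
}

#' Write / read a spot table as CSV
#'
#' Plain CSV with a comment header documenting the coordinate convention
#' (0-based, pixel centers at integers, x = column, y = row).
#'
#' @param spots data.frame from [callSpots()].
#' @param path file path.
#' @export
writeSpotTable <- function(spots, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based, pixel centers at integers, x=column, y=row",
             con)
  utils::write.csv(spots, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpotTable
#' @export
readSpotTable <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
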
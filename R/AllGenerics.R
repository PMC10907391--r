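#' @name fishcoder-accessors
#' @title Accessors for fishcoder classes
#' @param x a `Codebook` or `ImageStack` object.
#' @param ... ignored.
#' @description `nRounds()`/`nChannels()` return the acquisition geometry;
#'   `geneIds()` the genes of a codebook; `barcodeMatrix()` the gene x 4
#'   matrix of flat pseudocolor indices; `getPlane()` one `(round, channel)`
#'   image plane; `nuclearReference()` one round's nuclear plane;
#'   `isRegistered()` and `stackShifts()` the registration state.
NULL

#' @rdname fishcoder-accessors
#' @export
setGeneric("nRounds", function(x, ...) standardGeneric("nRounds"))
#' @rdname fishcoder-accessors
#' @export
setGeneric("nChannels", function(x, ...) standardGeneric("nChannels"))
#' @rdname fishcoder-accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))
#' @rdname fishcoder-accessors
#' @export
setGeneric("barcodeMatrix", function(x, ...) standardGeneric("barcodeMatrix"))
#' @rdname fishcoder-accessors
#' @param round,channel 0-based round and channel index.
#' @export
setGeneric("getPlane", function(x, round, channel, ...) standardGeneric("getPlane"))
#' @rdname fishcoder-accessors
#' @export
setGeneric("nuclearReference", function(x, round, ...) standardGeneric("nuclearReference"))
#' @rdname fishcoder-accessors
#' @export
setGeneric("isRegistered", function(x, ...) standardGeneric("isRegistered"))
#' @rdname fishcoder-accessors
#' @export
setGeneric("stackShifts", function(x, ...) standardGeneric("stackShifts"))

#' @rdname fishcoder-accessors
#' @export
setMethod("nRounds", "Codebook", function(x, ...) x@nRounds)
#' @rdname fishcoder-accessors
#' @export
setMethod("nChannels", "Codebook", function(x, ...) x@nChannels)
#' @rdname fishcoder-accessors
#' @export
setMethod("geneIds", "Codebook", function(x, ...) rownames(x@codes))
#' @rdname fishcoder-accessors
#' @export
setMethod("barcodeMatrix", "Codebook", function(x, ...) x@codes)

#' @rdname fishcoder-accessors
#' @export
setMethod("nRounds", "ImageStack", function(x, ...) dim(x@planes)[3L])
#' @rdname fishcoder-accessors
#' @export
setMethod("nChannels", "ImageStack", function(x, ...) dim(x@planes)[4L])
#' @rdname fishcoder-accessors
#' @export
setMethod("getPlane", "ImageStack", function(x, round, channel, ...) {
  x@planes[, , round + 1L, channel + 1L]
})
#' @rdname fishcoder-accessors
#' @export
setMethod("nuclearReference", "ImageStack", function(x, round, ...) {
  x@nuclear[, , round + 1L]
})
#' @rdname fishcoder-accessors
#' @export
setMethod("isRegistered", "ImageStack", function(x, ...) x@registered)
#' @rdname fishcoder-accessors
#' @export
setMethod("stackShifts", "ImageStack", function(x, ...) x@shifts)

#' @export
setMethod("show", "Codebook", function(object) {
  cat(sprintf(
    "Codebook: %d genes, %d rounds x %d channels (%d pseudocolors), maxShared=%d\n",
    nrow(object@codes), object@nRounds, object@nChannels,
    object@nRounds * object@nChannels, object@maxShared))
  if (nrow(object@codes) > 0L) {
    k <- min(3L, nrow(object@codes))
    for (i in seq_len(k)) {
      cat(sprintf("  %s: {%s}\n", rownames(object@codes)[i],
                  paste(object@codes[i, ], collapse = ", ")))
    }
    if (nrow(object@codes) > k) cat(sprintf("  ... and %d more\n", nrow(object@codes) - k))
  }
})

#' @export
setMethod("show", "ImageStack", function(object) {
  d <- dim(object@planes)
  cat(sprintf("ImageStack: %d x %d px, %d rounds x %d channels, %s\n",
              d[1L], d[2L], d[3L], d[4L],
              if (object@registered) "registered" else "unregistered"))
})

#' @export
setMethod("show", "SimulatedField", function(object) {
  cat(sprintf(
    "SimulatedField: %d x %d px, %d cells, %d genes, %d transcripts (%d plane spots)\n",
    nrow(object@cellLabels), ncol(object@cellLabels),
    nrow(object@cellCenters), length(object@geneIds),
    nrow(object@transcripts), nrow(object@planeSpots)))
})
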
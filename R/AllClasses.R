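#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib fishcoder, .registration = TRUE
NULL

#' Codebook: gene to four-pseudocolor barcode map
#'
#' A `Codebook` assigns each gene an unordered set of four distinct
#' pseudocolors drawn from an acquisition space of `nRounds` hybridization
#' rounds times `nChannels` fluorescence channels. A pseudocolor is stored
#' as its flat index `round * nChannels + channel` (0-based). Any two
#' barcodes share at most `maxShared` pseudocolors, so that every 3-subset
#' of a barcode identifies its gene uniquely and a transcript detected at
#' only three of its four positions still decodes unambiguously.
#'
#' @slot nRounds integer, number of hybridization-imaging rounds.
#' @slot nChannels integer, number of fluorescence channels per round.
#' @slot maxShared integer, maximum pseudocolors shared by any two barcodes.
#' @slot codes integer matrix, one row per gene (rownames are gene ids),
#'   four columns holding sorted 0-based flat pseudocolor indices.
#'
#' @seealso [assignBarcodes()], [validateCodebook()], [writeCodebook()]
#' @export
setClass("Codebook",
  representation(
    nRounds = "integer",
    nChannels = "integer",
    maxShared = "integer",
    codes = "matrix"
  )
)

setValidity("Codebook", function(object) {
  msg <- character()
  if (length(object@nRounds) != 1L || object@nRounds < 1L)
    msg <- c(msg, "nRounds must be a single positive integer")
  if (length(object@nChannels) != 1L || object@nChannels < 1L)
    msg <- c(msg, "nChannels must be a single positive integer")
  cd <- object@codes
  if (nrow(cd) > 0L) {
    if (ncol(cd) != 4L)
      msg <- c(msg, "codes must have exactly 4 columns")
    if (is.null(rownames(cd)) || anyDuplicated(rownames(cd)))
      msg <- c(msg, "codes rownames must be unique gene ids")
    nspace <- object@nRounds * object@nChannels
    if (any(cd < 0L) || any(cd >= nspace))
      msg <- c(msg, "pseudocolor indices out of range")
    if (any(apply(cd, 1L, anyDuplicated) > 0L))
      msg <- c(msg, "each barcode must hold 4 distinct pseudocolors")
    # pairwise sharing <= 2  <=>  no 3-subset occurs in two barcodes
    if (object@maxShared <= 2L && nrow(cd) > 1L) {
      keys <- .barcodeTripletKeys(cd)
      if (anyDuplicated(keys))
        msg <- c(msg, "two barcodes share more than maxShared pseudocolors")
    }
  }
  if (length(msg)) msg else TRUE
})

# keys of all four 3-subsets of each (sorted) barcode row
.barcodeTripletKeys <- function(codes) {
  codes <- t(apply(codes, 1L, sort))
  drop1 <- list(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  unlist(lapply(drop1, function(j) {
    paste(codes[, j[1L]], codes[, j[2L]], codes[, j[3L]], sep = "-")
  }), use.names = FALSE)
}

#' ImageStack: multi-round, multi-channel image planes
#'
#' Holds the acquisition of one field of view: a 4-D intensity array
#' indexed `[row, col, round, channel]` plus a per-round nuclear reference
#' plane (the DAPI-like channel used for registration and segmentation).
#' Coordinates throughout the package are 0-based with pixel centers at
#' integers, `x` = column and `y` = row.
#'
#' @slot planes numeric 4-D array `[height, width, nRounds, nChannels]`.
#' @slot nuclear numeric 3-D array `[height, width, nRounds]`.
#' @slot registered logical, `TRUE` once rounds are aligned to round 0.
#' @slot shifts numeric matrix `nRounds x 2` of applied `(dy, dx)` shifts.
#'
#' @seealso [renderStack()], [registerRounds()], [preprocessStack()]
#' @export
setClass("ImageStack",
  representation(
    planes = "array",
    nuclear = "array",
    registered = "logical",
    shifts = "matrix"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character()
  d <- dim(object@planes)
  if (length(d) != 4L)
    msg <- c(msg, "planes must be a 4-D array [y, x, round, channel]")
  dn <- dim(object@nuclear)
  if (length(dn) != 3L)
    msg <- c(msg, "nuclear must be a 3-D array [y, x, round]")
  if (length(d) == 4L && length(dn) == 3L) {
    if (!all(dn[1:2] == d[1:2]) || dn[3L] != d[3L])
      msg <- c(msg, "nuclear dimensions must match planes")
  }
  if (length(d) == 4L &&
      (nrow(object@shifts) != d[3L] || ncol(object@shifts) != 2L))
    msg <- c(msg, "shifts must be an nRounds x 2 matrix")
  if (isTRUE(object@registered) &&
      nrow(object@shifts) > 0L && any(object@shifts[1L, ] != 0))
    msg <- c(msg, "shift of round 0 must be (0, 0) once registered")
  if (length(msg)) msg else TRUE
})

#' SimulatedField: ground truth for one synthetic field of view
#'
#' Produced by [simulateField()] and consumed by [renderStack()] and
#' [evaluateDecoding()]. `transcripts` holds the planted molecules;
#' `planeSpots` the per-plane true spot list after dropout and drift, i.e.
#' exactly what an ideal detector would see.
#'
#' @slot transcripts data.frame with columns `gene_id`, `x`, `y`,
#'   `cell_id` (0 = extracellular).
#' @slot cellLabels integer matrix, the true nucleus label image.
#' @slot cellCenters data.frame with `cell_id`, `x`, `y`, `radius`.
#' @slot drifts numeric matrix `nRounds x 2`, planted per-round `(dy, dx)`.
#' @slot planeSpots data.frame with `round`, `channel`, `pseudocolor`,
#'   `gene_id`, `transcript_id`, `x`, `y` (drift-shifted positions).
#' @slot geneIds character, genes of the codebook used.
#' @slot fieldSpec list, the [fieldSpec()] the truth was drawn from.
#' @export
setClass("SimulatedField",
  representation(
    transcripts = "data.frame",
    cellLabels = "matrix",
    cellCenters = "data.frame",
    drifts = "matrix",
    planeSpots = "data.frame",
    geneIds = "character",
    fieldSpec = "list"
  )
)

setValidity("SimulatedField", function(object) {
  msg <- character()
  tr <- object@transcripts
  need <- c("gene_id", "x", "y", "cell_id")
  if (!all(need %in% names(tr)))
    msg <- c(msg, "transcripts must have gene_id, x, y, cell_id")
  h <- nrow(object@cellLabels); w <- ncol(object@cellLabels)
  if (nrow(tr) > 0L &&
      (any(tr$x < 0) || any(tr$x > w - 1) || any(tr$y < 0) || any(tr$y > h - 1)))
    msg <- c(msg, "transcript positions must lie inside the field")
  if (length(msg)) msg else TRUE
})
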
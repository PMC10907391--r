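#' Enumerate the pseudocolor space of an acquisition
#'
#' A pseudocolor is one (hybridization round, fluorescence channel) slot;
#' the barcode alphabet. Flat indices are row-major:
#' `flat = round * nChannels + channel`, both 0-based.
#'
#' @param nRounds number of hybridization-imaging rounds (default 22).
#' @param nChannels number of fluorescence channels per round (default 2).
#' @return data.frame with columns `flat`, `round`, `channel`.
#' @examples
#' sp <- buildPseudocolorSpace(22, 2)
#' nrow(sp)  # 44
#' @export
buildPseudocolorSpace <- function(nRounds = 22L, nChannels = 2L) {
  nRounds <- as.integer(nRounds); nChannels <- as.integer(nChannels)
  if (is.na(nRounds) || nRounds < 1L || is.na(nChannels) || nChannels < 1L)
    stop("nRounds and nChannels must be positive integers")
  flat <- seq_len(nRounds * nChannels) - 1L
  data.frame(flat = flat,
             round = flat %/% nChannels,
             channel = flat %% nChannels)
}

#' Convert between flat pseudocolor indices and (round, channel)
#'
#' @param flat 0-based flat index vector.
#' @param nChannels channels per round.
#' @return data.frame with `round` and `channel` (0-based).
#' @export
pseudocolorRC <- function(flat, nChannels = 2L) {
  nChannels <- as.integer(nChannels)
  data.frame(round = as.integer(flat) %/% nChannels,
             channel = as.integer(flat) %% nChannels)
}

#' Assign genes unordered 4-pseudocolor barcodes
#'
#' Greedy randomized packing of weight-4 codewords over the pseudocolor
#' space: 4-subsets are visited in a seed-determined random order and a
#' subset is accepted iff none of its four 3-subsets has been used by an
#' earlier codeword. This enforces pairwise sharing of at most two
#' pseudocolors, which makes every 3-subset of a codeword unique -- a
#' transcript seen at only three of its four barcode positions still maps
#' to exactly one gene.
#'
#' @param geneIds character vector of gene identifiers.
#' @param nRounds,nChannels acquisition geometry (defaults 22 and 2).
#' @param maxShared maximum pseudocolors shared by two barcodes (default 2;
#'   values > 2 disable the triplet-uniqueness packing and only distinctness
#'   is enforced).
#' @param seed integer RNG seed; the packing is deterministic given the seed.
#' @return a [Codebook-class] object.
#' @examples
#' cb <- assignBarcodes(paste0("g", 1:40), seed = 1)
#' cb
#' @export
assignBarcodes <- function(geneIds, nRounds = 22L, nChannels = 2L,
                           maxShared = 2L, seed = 1L) {
  geneIds <- as.character(geneIds)
  if (anyDuplicated(geneIds)) stop("gene ids must be unique")
  nRounds <- as.integer(nRounds); nChannels <- as.integer(nChannels)
  S <- nRounds * nChannels
  if (S < 4L) stop("pseudocolor space must contain at least 4 slots")
  n <- length(geneIds)
  combos <- utils::combn(S, 4L) - 1L        # 4 x C(S,4), 0-based
  codes <- .packCodewords(combos, n, as.integer(maxShared), as.integer(seed))
  if (nrow(codes) < n)
    stop(sprintf(
      "codebook capacity exceeded: packed %d of %d requested barcodes on a %d-slot space",
      nrow(codes), n, S))
  rownames(codes) <- geneIds
  methods::new("Codebook", nRounds = nRounds, nChannels = nChannels,
               maxShared = as.integer(maxShared), codes = codes)
}

# Greedy packer over a 4 x M matrix of candidate codewords. Returns up to
# nMax accepted codewords as an nAccepted x 4 integer matrix (sorted rows).
.packCodewords <- function(combos, nMax, maxShared, seed) {
  if (nMax == 0L) return(matrix(0L, nrow = 0L, ncol = 4L))
  M <- ncol(combos)
  ord <- .withSeed(seed, sample.int(M))
  used <- new.env(hash = TRUE, parent = emptyenv())
  out <- matrix(0L, nrow = min(nMax, M), ncol = 4L)
  got <- 0L
  checkTriplets <- maxShared <= 2L
  drop1 <- list(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  for (j in ord) {
    cw <- sort(combos[, j])
    if (checkTriplets) {
      keys <- vapply(drop1, function(d) paste(cw[d], collapse = "-"), "")
      if (any(vapply(keys, function(k) !is.null(used[[k]]), TRUE))) next
      for (k in keys) used[[k]] <- TRUE
    }
    got <- got + 1L
    out[got, ] <- cw
    if (got >= nMax) break
  }
  out[seq_len(got), , drop = FALSE]
}

# run expr under a temporary RNG state; restores the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Greedy packing capacity of a pseudocolor space
#'
#' Runs the randomized greedy codeword packer to exhaustion over all
#' weight-4 subsets and reports how many mutually compatible barcodes
#' (pairwise sharing at most `maxShared`) the space accommodates.
#'
#' @inheritParams assignBarcodes
#' @return integer, the achieved packing size.
#' @examples
#' codebookCapacity(6, 2, seed = 1)
#' @export
codebookCapacity <- function(nRounds = 22L, nChannels = 2L, maxShared = 2L,
                             seed = 1L) {
  S <- as.integer(nRounds) * as.integer(nChannels)
  if (S < 4L) return(0L)
  combos <- utils::combn(S, 4L) - 1L
  nrow(.packCodewords(combos, ncol(combos), as.integer(maxShared),
                      as.integer(seed)))
}

#' Validate a codebook
#'
#' Report-only check of the codeword invariants: weight 4 with distinct
#' pseudocolors, indices inside the space, pairwise intersection at most
#' `maxShared`, and uniqueness of every codeword 3-subset.
#'
#' @param cb a [Codebook-class] (or a bare gene x 4 integer matrix plus
#'   geometry arguments).
#' @return list with `valid` (logical) and `violations` (data.frame with
#'   columns `type` and `detail`, empty when valid).
#' @export
validateCodebook <- function(cb) {
  codes <- barcodeMatrix(cb)
  nspace <- nRounds(cb) * nChannels(cb)
  maxShared <- cb@maxShared
  viol <- list()
  add <- function(type, detail) viol[[length(viol) + 1L]] <<- data.frame(
    type = type, detail = detail, stringsAsFactors = FALSE)
  if (nrow(codes) > 0L) {
    g <- rownames(codes)
    for (i in seq_len(nrow(codes))) {
      cw <- codes[i, ]
      if (length(unique(cw)) != 4L)
        add("weight", sprintf("%s: barcode does not hold 4 distinct pseudocolors", g[i]))
      if (any(cw < 0L) || any(cw >= nspace))
        add("range", sprintf("%s: pseudocolor outside the %d-slot space", g[i], nspace))
    }
    if (nrow(codes) > 1L) {
      for (i in seq_len(nrow(codes) - 1L)) {
        for (j in seq(i + 1L, nrow(codes))) {
          sh <- length(intersect(codes[i, ], codes[j, ]))
          if (sh > maxShared)
            add("sharing", sprintf("%s and %s share %d pseudocolors (max %d)",
                                   g[i], g[j], sh, maxShared))
          if (sh == 4L)
            add("duplicate", sprintf("%s and %s carry identical barcodes", g[i], g[j]))
        }
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(type = character(), detail = character(), stringsAsFactors = FALSE)
  list(valid = nrow(violations) == 0L, violations = violations)
}

#' Lookup table from codeword 3-subsets to genes
#'
#' For a valid codebook every 3-subset of a codeword occurs in exactly one
#' codeword; this builds the named vector used to prove that property.
#'
#' @param cb a [Codebook-class].
#' @return named character vector, `"a-b-c"` (sorted flat indices) -> gene id.
#' @export
tripletLookup <- function(cb) {
  codes <- barcodeMatrix(cb)
  if (nrow(codes) == 0L) return(stats::setNames(character(), character()))
  keys <- .barcodeTripletKeys(codes)
  genes <- rep(rownames(codes), times = 4L)
  if (anyDuplicated(keys))
    stop("codebook has colliding 3-subsets; lookup is not well defined")
  stats::setNames(genes, keys)
}

#' Write / read a codebook as CSV
#'
#' Plain CSV with two leading comment lines recording the acquisition
#' geometry, then columns `gene_id, r1, c1, r2, c2, r3, c3, r4, c4`
#' (0-based round and channel per barcode position, sorted by flat index).
#'
#' @param cb a [Codebook-class].
#' @param path file path.
#' @return `writeCodebook` returns `path` invisibly; `readCodebook` the
#'   reconstructed [Codebook-class].
#' @export
writeCodebook <- function(cb, path) {
  codes <- barcodeMatrix(cb)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_rounds=%d n_channels=%d max_shared=%d",
            nRounds(cb), nChannels(cb), cb@maxShared),
    "# columns: gene_id then (round,channel) 0-based for the 4 barcode positions"),
    con)
  df <- data.frame(gene_id = rownames(codes))
  for (p in 1:4) {
    rc <- pseudocolorRC(codes[, p], nChannels(cb))
    df[[paste0("r", p)]] <- rc$round
    df[[paste0("c", p)]] <- rc$channel
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCodebook
#' @export
readCodebook <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- regmatches(hdr[1], gregexpr("[a-z_]+=[0-9]+", hdr[1]))[[1]]
  if (length(meta) < 3L)
    stop(sprintf("codebook header malformed at line 1 of %s", path))
  kv <- do.call(rbind, strsplit(meta, "=", fixed = TRUE))
  vals <- stats::setNames(as.integer(kv[, 2]), kv[, 1])
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("gene_id", paste0(rep(c("r", "c"), 4), rep(1:4, each = 2)))
  if (!all(need %in% names(df)))
    stop(sprintf("codebook %s: missing columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  nch <- vals[["n_channels"]]
  codes <- sapply(1:4, function(p) df[[paste0("r", p)]] * nch + df[[paste0("c", p)]])
  codes <- matrix(as.integer(codes), ncol = 4L)
  codes <- t(apply(codes, 1L, sort))
  rownames(codes) <- df$gene_id
  methods::new("Codebook", nRounds = vals[["n_rounds"]],
               nChannels = nch, maxShared = vals[["max_shared"]],
               codes = codes)
}
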
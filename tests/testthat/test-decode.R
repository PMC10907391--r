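# hand-built spot tables around one gene's barcode
spotsFor <- function(cb, gene, offsets, extraPc = NULL) {
  bc <- barcodeMatrix(cb)[gene, ]
  df <- data.frame(pseudocolor = bc[seq_len(nrow(offsets))],
                   x = 20 + offsets[, 1], y = 20 + offsets[, 2],
                   intensity = 100)
  df$spot_id <- seq_len(nrow(df))
  df
}

test_that("a clean four-spot barcode decodes into a single call", {
  cb <- assignBarcodes(sprintf("g%02d", 1:10), 22, 2, seed = 4)
  sp <- spotsFor(cb, "g03", rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, -1)))
  calls <- decodeSpots(sp, cb)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gene_id, "g03")
  expect_equal(calls$n_positions, 4L)
  expect_equal(calls$spot_refs, "1,2,3,4")
  # consensus is the intensity-weighted mean of the constituents
  expect_equal(calls$x, mean(sp$x))
  expect_equal(calls$y, mean(sp$y))
})

test_that("fewer than three detected positions yields no call", {
  cb <- assignBarcodes(sprintf("g%02d", 1:10), 22, 2, seed = 4)
  sp2 <- spotsFor(cb, "g03", rbind(c(0, 0), c(1, 0)))
  expect_equal(nrow(decodeSpots(sp2, cb)), 0L)
  sp3 <- spotsFor(cb, "g03", rbind(c(0, 0), c(1, 0), c(0, 1)))
  calls <- decodeSpots(sp3, cb)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_positions, 3L)
})

test_that("the linking radius boundary at 2.5 px is inclusive", {
  cb <- assignBarcodes(sprintf("g%02d", 1:10), 22, 2, seed = 4)
  for (d in c(2.4, 2.5)) {
    sp <- spotsFor(cb, "g05", rbind(c(0, 0), c(d, 0), c(0, 1)))
    expect_equal(nrow(decodeSpots(sp, cb)), 1L)
  }
  # at 2.6 px the companion does not link; two positions remain -> no call
  sp <- spotsFor(cb, "g05", rbind(c(0, 0), c(2.6, 0), c(0, 1)))
  calls <- decodeSpots(sp, cb)
  expect_equal(nrow(calls), 0L)
})

test_that("decoder matches the exhaustive oracle on random small fields", {
  for (seed in 1:12) {
    rf <- randomSpotField(seed, nSpots = sample(15:50, 1))
    calls <- decodeSpots(rf$spots, rf$codebook)
    orc <- oracleDecode(rf$spots, barcodeMatrix(rf$codebook))
    expect_identical(
      callKey(calls),
      sort(paste(geneIds(rf$codebook)[orc$gene], orc$spots, sep = "|")),
      info = sprintf("seed %d", seed))
  }
})

test_that("decoding is invariant to row order and global translation", {
  rf <- randomSpotField(77, nSpots = 45)
  base <- decodeSpots(rf$spots, rf$codebook)
  # shuffled input rows
  set.seed(1)
  shuf <- rf$spots[sample.int(nrow(rf$spots)), ]
  expect_identical(callKey(decodeSpots(shuf, rf$codebook)), callKey(base))
  # translated field
  moved <- rf$spots
  moved$x <- moved$x + 113.7; moved$y <- moved$y + 41.3
  movedCalls <- decodeSpots(moved, rf$codebook)
  expect_identical(callKey(movedCalls), callKey(base))
  expect_equal(movedCalls$x, base$x + 113.7, tolerance = 1e-9)
})

test_that("no spot is shared between final calls and pseudocolors fit barcodes", {
  for (seed in c(101, 202)) {
    set.seed(seed)
    cb <- assignBarcodes(sprintf("g%02d", 1:8), 6, 2, seed = seed)
    codes <- barcodeMatrix(cb)
    k <- 12
    gene <- sample(8, k, replace = TRUE)
    cx <- runif(k, 5, 45); cy <- runif(k, 5, 45)
    sp <- do.call(rbind, lapply(seq_len(k), function(i) {
      keep <- runif(4) > 0.15
      if (!any(keep)) return(NULL)
      data.frame(pseudocolor = codes[gene[i], keep],
                 x = cx[i] + rnorm(sum(keep), 0, 0.6),
                 y = cy[i] + rnorm(sum(keep), 0, 0.6), intensity = 100)
    }))
    sp$spot_id <- seq_len(nrow(sp))
    calls <- decodeSpots(sp, cb)
    used <- unlist(strsplit(calls$spot_refs, ","))
    expect_equal(anyDuplicated(used), 0L)
    for (i in seq_len(nrow(calls))) {
      ids <- as.integer(strsplit(calls$spot_refs[i], ",")[[1]])
      pcs <- sp$pseudocolor[match(ids, sp$spot_id)]
      expect_true(all(pcs %in% codes[calls$gene_id[i], ]))
      expect_equal(anyDuplicated(pcs), 0L)
      expect_gte(length(pcs), 3L)
    }
  }
})

test_that("decoding metrics behave at the extremes", {
  cb <- assignBarcodes(sprintf("g%02d", 1:10), 22, 2, seed = 4)
  genes <- geneIds(cb)
  codes <- barcodeMatrix(cb)
  set.seed(6)
  n <- 100
  tr <- data.frame(gene_id = sample(genes, n, replace = TRUE),
                   x = runif(n, 10, 240), y = runif(n, 10, 240), cell_id = 0L)
  truth <- methods::new("SimulatedField", transcripts = tr,
                        cellLabels = matrix(0L, 250, 250),
                        cellCenters = data.frame(cell_id = integer(),
                                                 x = numeric(), y = numeric(),
                                                 radius = numeric()),
                        drifts = matrix(0, 22, 2),
                        planeSpots = data.frame(), geneIds = genes,
                        fieldSpec = list())
  perfect <- data.frame(gene_id = tr$gene_id, x = tr$x, y = tr$y,
                        n_positions = 4L, total_distance = 0,
                        spot_refs = as.character(seq_len(n)))
  m <- evaluateDecoding(perfect, truth, match_radius = 1)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$rmse, 0)
  # every call displaced beyond the match radius: recall collapses to zero
  off <- perfect
  off$x <- off$x + 5
  m0 <- evaluateDecoding(off, truth, match_radius = 1)
  expect_equal(m0$recall, 0)
  expect_equal(m0$n_matched, 0L)
})

test_that("empty spot tables decode to an empty result", {
  cb <- assignBarcodes(sprintf("g%02d", 1:4), 22, 2, seed = 4)
  empty <- data.frame(pseudocolor = integer(), x = numeric(), y = numeric(),
                      intensity = numeric())
  expect_equal(nrow(decodeSpots(empty, cb)), 0L)
})
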
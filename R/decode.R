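#' Decode spots into validated gene calls
#'
#' Combinatorial barcode decoding over a registered spot table. Every spot
#' seeds a neighbor search: for each gene whose barcode contains the
#' seed's pseudocolor, the nearest spot within `radius` px (inclusive) is
#' collected in each of the gene's other barcode positions. A candidate is
#' viable when seed plus companions cover at least `min_positions`
#' distinct positions; when several genes are viable for one seed the
#' minimum summed seed-to-companion distance wins and exact ties drop the
#' seed as ambiguous. Candidates of the same gene sharing a spot are
#' merged; a spot claimed by calls of different genes is awarded to the
#' call with the smaller total distance, with the loser re-evaluated and
#' dropped if it falls below `min_positions`. Every spot ends up in at
#' most one call.
#'
#' @param spots data.frame as returned by [callSpots()] (needs
#'   `pseudocolor`, `x`, `y`, `intensity`; `spot_id` optional).
#' @param codebook a [Codebook-class].
#' @param radius linking radius, px, inclusive (default 2.5).
#' @param min_positions minimum detected barcode positions for a
#'   validated call (default 3 of 4).
#' @return data.frame with `gene_id`, `x`, `y` (intensity-weighted
#'   consensus), `n_positions`, `total_distance`, `spot_refs`
#'   (comma-separated `spot_id`s), sorted by (gene_id, y, x).
#' @export
decodeSpots <- function(spots, codebook, radius = 2.5, min_positions = 3L) {
  stopifnot(radius > 0, min_positions >= 1L, min_positions <= 4L)
  empty <- data.frame(gene_id = character(), x = numeric(), y = numeric(),
                      n_positions = integer(), total_distance = numeric(),
                      spot_refs = character(), stringsAsFactors = FALSE)
  if (nrow(spots) == 0L) return(empty)
  if (is.null(spots$spot_id)) spots$spot_id <- seq_len(nrow(spots))
  if (is.null(spots$intensity)) spots$intensity <- 1
  # canonical order makes all internal tie-breaks independent of the
  # caller's row order and of global translation
  ord <- order(spots$pseudocolor, spots$y, spots$x, spots$spot_id)
  sp <- spots[ord, , drop = FALSE]
  codes <- barcodeMatrix(codebook)
  res <- cpp_decode(as.integer(sp$pseudocolor), as.numeric(sp$x),
                    as.numeric(sp$y), codes, radius,
                    as.integer(min_positions))
  if (length(res) == 0L) return(empty)
  calls <- lapply(res, function(cl) {
    idx <- cl$spots
    w <- sp$intensity[idx]
    if (sum(w) <= 0) w <- rep(1, length(idx))
    data.frame(gene_id = rownames(codes)[cl$gene],
               x = sum(sp$x[idx] * w) / sum(w),
               y = sum(sp$y[idx] * w) / sum(w),
               n_positions = length(idx),
               total_distance = cl$total,
               spot_refs = paste(sort(sp$spot_id[idx]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$gene_id, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate decoded calls against simulator ground truth
#'
#' Greedy nearest matching of calls to true transcripts of the same gene
#' within `match_radius` px (closest pairs first, one-to-one). Reports
#' recall, precision, positional RMSE of matched calls, and per-gene
#' decoded versus true counts with their Pearson correlation.
#'
#' @param calls data.frame from [decodeSpots()].
#' @param truth a [SimulatedField-class].
#' @param match_radius maximum call-to-transcript distance, px (default 3).
#' @return list with `recall`, `precision`, `f1`, `rmse`, `n_true`,
#'   `n_calls`, `n_matched`, `per_gene` (data.frame `gene_id`, `n_true`,
#'   `n_called`, `n_matched`), `count_correlation`.
#' @export
evaluateDecoding <- function(calls, truth, match_radius = 3) {
  tr <- truth@transcripts
  genes <- truth@geneIds
  nMatched <- 0L
  sqerr <- numeric()
  matchedPerGene <- stats::setNames(integer(length(genes)), genes)
  for (g in genes) {
    ti <- which(tr$gene_id == g)
    ci <- which(calls$gene_id == g)
    if (length(ti) == 0L || length(ci) == 0L) next
    d <- outer(calls$x[ci], tr$x[ti], "-")^2 + outer(calls$y[ci], tr$y[ti], "-")^2
    pairs <- which(d <= match_radius^2, arr.ind = TRUE)
    if (nrow(pairs) == 0L) next
    pairs <- pairs[order(d[pairs]), , drop = FALSE]
    usedC <- logical(length(ci)); usedT <- logical(length(ti))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (usedC[i] || usedT[j]) next
      usedC[i] <- TRUE; usedT[j] <- TRUE
      nMatched <- nMatched + 1L
      matchedPerGene[g] <- matchedPerGene[g] + 1L
      sqerr <- c(sqerr, d[i, j])
    }
  }
  nTruePerGene <- table(factor(tr$gene_id, levels = genes))
  nCallPerGene <- table(factor(calls$gene_id, levels = genes))
  perGene <- data.frame(gene_id = genes,
                        n_true = as.integer(nTruePerGene),
                        n_called = as.integer(nCallPerGene),
                        n_matched = as.integer(matchedPerGene),
                        stringsAsFactors = FALSE)
  recall <- if (nrow(tr)) nMatched / nrow(tr) else NA_real_
  precision <- if (nrow(calls)) nMatched / nrow(calls) else NA_real_
  corr <- if (length(genes) >= 3L && stats::sd(perGene$n_true) > 0 &&
              stats::sd(perGene$n_called) > 0)
    stats::cor(perGene$n_true, perGene$n_called) else NA_real_
  list(recall = recall, precision = precision,
       f1 = if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
         2 * recall * precision / (recall + precision) else NA_real_,
       rmse = if (length(sqerr)) sqrt(mean(sqerr)) else NA_real_,
       n_true = nrow(tr), n_calls = nrow(calls), n_matched = nMatched,
       per_gene = perGene, count_correlation = corr)
}
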
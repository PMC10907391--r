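#' Segment nuclei on the registered nuclear reference
#'
#' Classical watershed segmentation: Gaussian smoothing, Otsu threshold,
#' hole filling, Euclidean distance transform, and a seeded watershed on
#' the distance map splits touching nuclei. Objects below `min_area` px
#' are removed and labels relabelled contiguously from 1.
#'
#' @param reference_plane numeric matrix (nuclear channel of round 0 of a
#'   registered stack).
#' @param smooth_sigma Gaussian sigma for pre-smoothing, px (default 2).
#' @param min_area minimum object area, px (default 80).
#' @param ws_tolerance,ws_ext watershed tolerance and neighborhood radius
#'   (see `EBImage::watershed`).
#' @return integer label matrix (0 = background); attribute `centers`
#'   holds per-label centroids and areas. A blank plane yields zero labels
#'   with a warning.
#' @export
segmentNuclei <- function(reference_plane, smooth_sigma = 2, min_area = 80L,
                          ws_tolerance = 1, ws_ext = 3L) {
  rng <- max(reference_plane) - min(reference_plane)
  if (rng == 0) {
    warning("blank reference plane: no nuclei segmented")
    out <- matrix(0L, nrow(reference_plane), ncol(reference_plane))
    attr(out, "centers") <- data.frame(cell_id = integer(), x = numeric(),
                                       y = numeric(), area = integer())
    return(out)
  }
  img <- (reference_plane - min(reference_plane)) / rng
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  thr <- EBImage::otsu(EBImage::Image(sm))
  mask <- EBImage::fillHull(sm > thr)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = ws_tolerance, ext = ws_ext)
  lab <- matrix(as.integer(lab), nrow(reference_plane), ncol(reference_plane))
  # drop small objects, relabel 1..K
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  remap <- integer(max(lab, 1L))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  centers <- .labelCenters(lab)
  attr(lab, "centers") <- centers
  lab
}

.labelCenters <- function(lab) {
  K <- max(lab)
  if (K == 0L)
    return(data.frame(cell_id = integer(), x = numeric(), y = numeric(),
                      area = integer()))
  idx <- which(lab > 0L)
  rr <- (idx - 1L) %% nrow(lab)        # 0-based row = y
  cc <- (idx - 1L) %/% nrow(lab)       # 0-based col = x
  l <- lab[idx]
  data.frame(cell_id = seq_len(K),
             x = as.numeric(tapply(cc, l, mean)),
             y = as.numeric(tapply(rr, l, mean)),
             area = as.integer(tabulate(l, K)))
}

#' Expand a label image into the background
#'
#' Grows every label outward by up to `px` pixels (multi-source breadth
#' first search, 4-connected) to approximate the cytoplasm around each
#' nucleus. Labels only claim unlabelled pixels, so expansion can never
#' merge two cells; where two fronts meet, the nearer label wins.
#'
#' @param labels integer label matrix.
#' @param px expansion distance, px (default 5).
#' @return expanded integer label matrix.
#' @export
expandLabels <- function(labels, px = 5L) {
  if (px <= 0L) return(labels)
  out <- cpp_expand_labels(labels, as.integer(px))
  attributes(out) <- attributes(out)["dim"]
  storage.mode(out) <- "integer"
  out
}

#' Assign decoded calls to cells and build the count matrix
#'
#' Nucleus labels are expanded by `expand_px` to approximate the cell
#' body; each call is assigned to the label under its rounded position
#' (unassigned when it falls on background). Returns a
#' `SummarizedExperiment` with the genes x cells integer `counts` assay,
#' per-cell centroids and areas in `colData`, and assignment bookkeeping
#' in `metadata` (`n_total`, `n_assigned`, `n_unassigned` always satisfy
#' `n_assigned + n_unassigned = n_total`).
#'
#' @param calls data.frame from [decodeSpots()].
#' @param labels integer label matrix from [segmentNuclei()].
#' @param gene_ids genes to report rows for (default: genes present in
#'   `calls`); pass the codebook's `geneIds()` to keep zero-count genes.
#' @param expand_px cytoplasm expansion, px (default 7, covering the simulated cytoplasm extent of about 0.4 nucleus radii).
#' @return a [SummarizedExperiment::SummarizedExperiment-class].
#' @export
assignAndCount <- function(calls, labels, gene_ids = NULL, expand_px = 7L) {
  if (is.null(gene_ids)) gene_ids <- sort(unique(calls$gene_id))
  gene_ids <- as.character(gene_ids)
  expanded <- expandLabels(labels, expand_px)
  centers <- attr(labels, "centers")
  if (is.null(centers)) centers <- .labelCenters(labels)
  K <- max(labels, 0L)
  counts <- matrix(0L, nrow = length(gene_ids), ncol = K,
                   dimnames = list(gene_ids,
                                   if (K > 0) paste0("cell_", seq_len(K))))
  cellOf <- integer(nrow(calls))
  if (nrow(calls) > 0L) {
    r <- pmin(pmax(round(calls$y), 0), nrow(labels) - 1L) + 1L
    c <- pmin(pmax(round(calls$x), 0), ncol(labels) - 1L) + 1L
    cellOf <- expanded[cbind(r, c)]
    assigned <- cellOf > 0L & calls$gene_id %in% gene_ids
    if (any(assigned)) {
      tab <- table(factor(calls$gene_id[assigned], levels = gene_ids),
                   factor(cellOf[assigned], levels = seq_len(K)))
      counts <- matrix(as.integer(tab), nrow = length(gene_ids),
                       dimnames = dimnames(counts))
    }
  }
  cd <- S4Vectors::DataFrame(
    cell_id = if (K > 0) seq_len(K) else integer(),
    x = if (K > 0) centers$x else numeric(),
    y = if (K > 0) centers$y else numeric(),
    area = if (K > 0) centers$area else integer())
  rownames(cd) <- colnames(counts)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    metadata = list(n_total = nrow(calls),
                    n_assigned = sum(cellOf > 0L),
                    n_unassigned = sum(cellOf == 0L),
                    expand_px = expand_px))
}

#' Write a count matrix as MatrixMarket with TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells, sparse), `genes.tsv` and
#' `cells.tsv` (cell id, centroid x/y, area, total counts).
#'
#' @param se `SummarizedExperiment` from [assignAndCount()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeCountMatrix <- function(se, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- SummarizedExperiment::assay(se, "counts")
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), mtx)
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  cd$total_counts <- colSums(m)
  utils::write.table(cd, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(matrix = mtx,
              genes = file.path(dir, "genes.tsv"),
              cells = file.path(dir, "cells.tsv")))
}
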
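#' Configuration for encoding-probe design
#'
#' Length, count, GC and homology-screen rules for the probe library.
#' Defaults follow standard practice for combinatorial FISH encoding
#' probes: a 28-nt mRNA-complementary targeting region, four 18-nt readout
#' sites per probe, 17 to 32 probes per gene, readout GC between 40% and
#' 60%, targeting regions discarded when they share 17 nt or more with a
#' non-target sequence, readouts discarded on a 10-nt or longer match.
#'
#' @param target_len targeting-region length, nt.
#' @param readout_len readout-sequence length, nt.
#' @param readouts_per_probe readout sites per encoding probe.
#' @param min_probes,max_probes probes per gene (below `min_probes` the
#'   gene is flagged, not dropped).
#' @param gc_min,gc_max readout GC fraction window.
#' @param offtarget_k homology threshold for targeting regions, nt: a
#'   region sharing an exact substring of this length or longer with a
#'   non-target sequence (either strand) is removed.
#' @param readout_k match threshold for readout screening, nt.
#' @param target_gc_min,target_gc_max optional GC window for targeting
#'   regions; `NULL` (default) disables the filter.
#' @param rng_seed seed for readout generation.
#' @return a validated list of class `DesignConfig`.
#' @export
designConfig <- function(target_len = 28L, readout_len = 18L,
                         readouts_per_probe = 4L,
                         min_probes = 17L, max_probes = 32L,
                         gc_min = 0.40, gc_max = 0.60,
                         offtarget_k = 17L, readout_k = 10L,
                         target_gc_min = NULL, target_gc_max = NULL,
                         rng_seed = 1L) {
  cfg <- list(target_len = as.integer(target_len),
              readout_len = as.integer(readout_len),
              readouts_per_probe = as.integer(readouts_per_probe),
              min_probes = as.integer(min_probes),
              max_probes = as.integer(max_probes),
              gc_min = gc_min, gc_max = gc_max,
              offtarget_k = as.integer(offtarget_k),
              readout_k = as.integer(readout_k),
              target_gc_min = target_gc_min, target_gc_max = target_gc_max,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$gc_min > 0, cfg$gc_max < 1, cfg$gc_min < cfg$gc_max,
            cfg$min_probes <= cfg$max_probes,
            cfg$offtarget_k <= cfg$target_len,
            cfg$readout_k <= cfg$readout_len)
  class(cfg) <- "DesignConfig"
  cfg
}

.checkSeq <- function(s, what = "sequence") {
  s <- toupper(as.character(s))
  if (nchar(s) == 0L) stop(sprintf("%s is empty", what))
  if (grepl("[^ACGT]", s))
    stop(sprintf("%s contains characters outside A/C/G/T", what))
  s
}

.gcFraction <- function(s) {
  n <- nchar(s)
  gc <- nchar(gsub("[AT]", "", s))
  gc / n
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# all k-mers of s as a character vector (empty when s shorter than k)
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, 1:(n - k + 1L), k:n)
}

# k-mer set over both strands of a character vector of sequences
.kmerIndex <- function(seqs, k) {
  seqs <- toupper(as.character(seqs))
  both <- c(seqs, vapply(seqs, .revcomp, "", USE.NAMES = FALSE))
  unique(unlist(lapply(both, .kmers, k = k), use.names = FALSE))
}

#' Enumerate candidate targeting sites on a transcript
#'
#' All sliding windows of `target_len` nt along the mRNA (5' to 3'). A
#' transcript shorter than the window yields no sites and a warning.
#'
#' @param gene_id gene identifier.
#' @param sequence mRNA sense-strand sequence (A/C/G/T).
#' @param cfg a [designConfig()].
#' @return data.frame with `gene_id`, `start` (0-based), `target_seq`.
#' @export
enumerateTargetingSites <- function(gene_id, sequence, cfg = designConfig()) {
  s <- .checkSeq(sequence, gene_id)
  L <- nchar(s); k <- cfg$target_len
  if (L < k) {
    warning(sprintf("%s: transcript (%d nt) shorter than target_len (%d nt); no sites",
                    gene_id, L, k))
    return(data.frame(gene_id = character(), start = integer(),
                      target_seq = character(), stringsAsFactors = FALSE))
  }
  starts <- 0:(L - k)
  data.frame(gene_id = gene_id, start = starts,
             target_seq = substring(s, starts + 1L, starts + k),
             stringsAsFactors = FALSE)
}

#' Remove targeting sites with off-target homology
#'
#' A site survives iff it shares no exact substring of length
#' `offtarget_k` or longer with any background sequence or its reverse
#' complement. Sharing a k-mer (k = `offtarget_k`) is equivalent to
#' sharing any substring of length >= k, so the screen is a k-mer lookup
#' against a hash index over both strands of the background.
#'
#' @param sites data.frame from [enumerateTargetingSites()].
#' @param background character vector (or `DNAStringSet`) of non-target
#'   sequences; must exclude the gene's own transcript.
#' @param cfg a [designConfig()].
#' @return the surviving subset of `sites`; attribute `screened` is FALSE
#'   when the background was empty.
#' @export
screenOffTargets <- function(sites, background, cfg = designConfig()) {
  if (length(background) == 0L) {
    message("off-target screen skipped: empty background")
    attr(sites, "screened") <- FALSE
    return(sites)
  }
  idx <- .kmerIndex(as.character(background), cfg$offtarget_k)
  if (nrow(sites) == 0L) {
    attr(sites, "screened") <- TRUE
    return(sites)
  }
  hit <- vapply(sites$target_seq, function(ts) {
    any(.kmers(toupper(ts), cfg$offtarget_k) %in% idx)
  }, TRUE, USE.NAMES = FALSE)
  out <- sites[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screened") <- TRUE
  out
}

#' Select a non-overlapping probe set for one gene
#'
#' Greedy left-to-right packing of non-overlapping sites, thinned to an
#' evenly spaced subset when more than `max_probes` fit. Genes ending with
#' fewer than `min_probes` sites are flagged (`below_min` attribute), not
#' dropped. An optional targeting-GC window is applied first when set.
#'
#' @param sites surviving sites of one gene, any order.
#' @param cfg a [designConfig()].
#' @return data.frame of selected sites sorted by `start`, with attributes
#'   `below_min` (logical) and `n_packable` (max non-overlapping count).
#' @export
selectProbeSet <- function(sites, cfg = designConfig()) {
  if (nrow(sites) > 0L && !is.null(cfg$target_gc_min)) {
    gc <- vapply(sites$target_seq, .gcFraction, 0, USE.NAMES = FALSE)
    sites <- sites[gc >= cfg$target_gc_min & gc <= cfg$target_gc_max, ,
                   drop = FALSE]
  }
  sites <- sites[order(sites$start), , drop = FALSE]
  keep <- integer()
  nextFree <- -1L
  for (i in seq_len(nrow(sites))) {
    if (sites$start[i] >= nextFree) {
      keep <- c(keep, i)
      nextFree <- sites$start[i] + cfg$target_len
    }
  }
  packed <- sites[keep, , drop = FALSE]
  nPack <- nrow(packed)
  if (nPack > cfg$max_probes) {
    pick <- unique(round(seq(1L, nPack, length.out = cfg$max_probes)))
    packed <- packed[pick, , drop = FALSE]
  }
  rownames(packed) <- NULL
  attr(packed, "n_packable") <- nPack
  attr(packed, "below_min") <- nrow(packed) < cfg$min_probes
  packed
}

#' Generate screened readout oligos
#'
#' Rejection sampling of random `readout_len`-nt sequences, accepting only
#' those with GC inside `[gc_min, gc_max]` that share no exact substring of
#' `readout_k` nt or longer with the background (both strands) or with any
#' previously accepted readout. Deterministic given `cfg$rng_seed`.
#'
#' @param n number of readouts required.
#' @param background character vector of sequences to screen against
#'   (genome decoys, probe targeting regions, ...).
#' @param cfg a [designConfig()].
#' @param max_tries retry budget (default `2000 * n`).
#' @return data.frame `readout_id` (0-based), `sequence`; attribute
#'   `rejections` tabulates why candidates were discarded.
#' @export
generateReadoutOligos <- function(n, background = character(),
                                  cfg = designConfig(),
                                  max_tries = 2000L * n) {
  stopifnot(n >= 1L)
  k <- cfg$readout_k
  bgIdx <- if (length(background)) .kmerIndex(as.character(background), k)
           else character()
  accepted <- character()
  acceptedIdx <- character()
  rej <- c(gc = 0L, background = 0L, self = 0L)
  .withSeed(cfg$rng_seed, {
    tries <- 0L
    while (length(accepted) < n && tries < max_tries) {
      tries <- tries + 1L
      cand <- paste(sample(c("A", "C", "G", "T"), cfg$readout_len,
                           replace = TRUE), collapse = "")
      gc <- .gcFraction(cand)
      if (gc < cfg$gc_min || gc > cfg$gc_max) { rej["gc"] <- rej["gc"] + 1L; next }
      km <- .kmers(cand, k)
      if (length(bgIdx) && any(km %in% bgIdx)) { rej["background"] <- rej["background"] + 1L; next }
      if (length(acceptedIdx) && any(km %in% acceptedIdx)) { rej["self"] <- rej["self"] + 1L; next }
      accepted <- c(accepted, cand)
      acceptedIdx <- c(acceptedIdx, .kmerIndex(cand, k))
    }
  })
  if (length(accepted) < n) {
    dom <- names(rej)[which.max(rej)]
    stop(sprintf(
      "readout generation found %d of %d sequences within %d tries; dominant rejection: %s (gc=%d, background=%d, self=%d)",
      length(accepted), n, max_tries, dom, rej["gc"], rej["background"], rej["self"]))
  }
  out <- data.frame(readout_id = seq_len(n) - 1L, sequence = accepted,
                    stringsAsFactors = FALSE)
  attr(out, "rejections") <- rej
  out
}

#' Default amplification primers
#'
#' Two arbitrary 20-mers with balanced GC bundled for convenience; real
#' libraries substitute their own validated primer pair.
#' @return named character vector with `fwd` and `rev`.
#' @export
defaultPrimers <- function() {
  c(fwd = "CGCAAGACGTAGTGCTACAG", rev = "GTCTGACTGCACGTTAGCAC")
}

#' Assemble encoding probes from sites and readout identities
#'
#' Each probe is laid out
#' `fwd_primer | readout1 | readout2 | revcomp(target) | readout3 | readout4 | rev_primer`;
#' the targeting region is the reverse complement of the mRNA window so the
#' probe hybridizes to the transcript. All probes of one gene carry the
#' same four readout identities (the gene's barcode).
#'
#' @param sites selected sites of one gene ([selectProbeSet()]).
#' @param readout_ids integer vector of exactly `readouts_per_probe`
#'   readout identities (0-based; for a codebook-coupled design these are
#'   the gene's flat pseudocolor indices).
#' @param readouts data.frame from [generateReadoutOligos()] covering all
#'   ids in `readout_ids`.
#' @param primers named character vector `fwd`/`rev` (default
#'   [defaultPrimers()]).
#' @param cfg a [designConfig()].
#' @return data.frame with `gene_id`, `start`, `target_seq`, `readout_ids`
#'   (comma-separated), `full_sequence`.
#' @export
assembleProbes <- function(sites, readout_ids, readouts,
                           primers = defaultPrimers(),
                           cfg = designConfig()) {
  readout_ids <- as.integer(readout_ids)
  if (length(readout_ids) != cfg$readouts_per_probe)
    stop(sprintf("expected %d readout ids, got %d",
                 cfg$readouts_per_probe, length(readout_ids)))
  if (any(!nzchar(primers[c("fwd", "rev")])) || any(is.na(primers[c("fwd", "rev")])))
    stop("primers must be non-empty 'fwd' and 'rev' sequences")
  roSeq <- readouts$sequence[match(readout_ids, readouts$readout_id)]
  if (anyNA(roSeq))
    stop("readout_ids not all present in the readout table")
  if (nrow(sites) == 0L) {
    return(data.frame(gene_id = character(), start = integer(),
                      target_seq = character(), readout_ids = character(),
                      full_sequence = character(), stringsAsFactors = FALSE))
  }
  rcTarget <- vapply(sites$target_seq, .revcomp, "", USE.NAMES = FALSE)
  full <- paste0(primers[["fwd"]], roSeq[1], roSeq[2], rcTarget,
                 roSeq[3], roSeq[4], primers[["rev"]])
  data.frame(gene_id = sites$gene_id, start = sites$start,
             target_seq = sites$target_seq,
             readout_ids = paste(readout_ids, collapse = ","),
             full_sequence = full, stringsAsFactors = FALSE)
}

#' Design an encoding-probe library for a gene set
#'
#' End-to-end probe design: per gene, enumerate targeting windows, screen
#' them against all non-target transcripts plus the supplied background,
#' pack a non-overlapping evenly spaced probe set, and attach the gene's
#' four readout identities. When a [Codebook-class] is given, readout
#' identity equals flat pseudocolor index, coupling the probe library to
#' the acquisition; readout oligos are additionally screened against the
#' selected targeting regions.
#'
#' @param transcripts named character vector (or `DNAStringSet`) of mRNA
#'   sequences; names are gene ids.
#' @param background character vector of decoy sequences screened against
#'   in addition to the other genes' transcripts.
#' @param cfg a [designConfig()].
#' @param codebook optional [Codebook-class] over the same gene ids.
#' @param primers named `fwd`/`rev` primer pair.
#' @return list with `probes` (one data.frame over all genes), `readouts`,
#'   `report` (per-gene data.frame: candidate/surviving/selected counts and
#'   flags), `config`.
#' @export
designProbes <- function(transcripts, background = character(),
                         cfg = designConfig(), codebook = NULL,
                         primers = defaultPrimers()) {
  genes <- names(transcripts)
  seqs <- stats::setNames(toupper(as.character(transcripts)), genes)
  if (is.null(genes) || anyDuplicated(genes))
    stop("transcripts must be uniquely named by gene id")
  background <- as.character(background)

  selected <- vector("list", length(genes))
  report <- data.frame(gene_id = genes, n_candidates = 0L, n_surviving = 0L,
                       n_selected = 0L, below_min = FALSE, too_short = FALSE,
                       unscreened = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    sites <- withCallingHandlers(
      enumerateTargetingSites(g, seqs[[i]], cfg),
      warning = function(w) invokeRestart("muffleWarning"))
    report$n_candidates[i] <- nrow(sites)
    if (nrow(sites) == 0L) {
      report$too_short[i] <- TRUE
      report$below_min[i] <- TRUE
      selected[[i]] <- sites
      next
    }
    bg <- c(seqs[-i], background)
    surv <- suppressMessages(screenOffTargets(sites, bg, cfg))
    report$unscreened[i] <- !isTRUE(attr(surv, "screened"))
    report$n_surviving[i] <- nrow(surv)
    sel <- selectProbeSet(surv, cfg)
    report$n_selected[i] <- nrow(sel)
    report$below_min[i] <- isTRUE(attr(sel, "below_min"))
    selected[[i]] <- sel
  }

  nSpace <- if (is.null(codebook)) cfg$readouts_per_probe * length(genes)
            else nRounds(codebook) * nChannels(codebook)
  roBackground <- c(background,
                    unlist(lapply(selected, function(s) s$target_seq),
                           use.names = FALSE))
  readouts <- generateReadoutOligos(nSpace, roBackground, cfg)

  probes <- vector("list", length(genes))
  nextFree <- 0L
  for (i in seq_along(genes)) {
    if (nrow(selected[[i]]) == 0L) { probes[[i]] <- NULL; next }
    ids <- if (is.null(codebook)) {
      ids <- seq(nextFree, length.out = cfg$readouts_per_probe)
      nextFree <- nextFree + cfg$readouts_per_probe
      ids
    } else {
      barcodeMatrix(codebook)[genes[i], ]
    }
    probes[[i]] <- assembleProbes(selected[[i]], ids, readouts, primers, cfg)
  }
  probes <- do.call(rbind, probes[!vapply(probes, is.null, TRUE)])
  if (is.null(probes))
    probes <- data.frame(gene_id = character(), start = integer(),
                         target_seq = character(), readout_ids = character(),
                         full_sequence = character(), stringsAsFactors = FALSE)
  rownames(probes) <- NULL
  list(probes = probes, readouts = readouts, report = report, config = cfg)
}

#' Write a designed probe library to disk
#'
#' Emits the probe table as TSV, the full oligos as FASTA, and a JSON
#' design report (per-gene counts and flags, readout rejection statistics).
#'
#' @param design result of [designProbes()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeProbeLibrary <- function(design, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "probes.tsv")
  utils::write.table(design$probes, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  fa <- file.path(dir, "probes.fasta")
  if (nrow(design$probes) > 0L) {
    ss <- Biostrings::DNAStringSet(design$probes$full_sequence)
    names(ss) <- sprintf("%s_probe%04d", design$probes$gene_id,
                         seq_len(nrow(design$probes)))
    Biostrings::writeXStringSet(ss, fa)
  } else {
    writeLines(character(), fa)
  }
  rep <- file.path(dir, "design_report.json")
  jsonlite::write_json(list(
    per_gene = design$report,
    readout_rejections = as.list(attr(design$readouts, "rejections")),
    config = unclass(design$config)), rep, auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(c(probes = tsv, fasta = fa, report = rep))
}
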
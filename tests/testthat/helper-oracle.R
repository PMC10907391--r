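# Independent plain-R oracles used to cross-check the package's
# implementations on small inputs.

# Brute-force shared-substring check: do a and b share an exact substring
# of length >= k on either strand?
oracleSharesKmer <- function(a, b, k) {
  a <- toupper(a)
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  for (bb in c(toupper(b), revcomp(toupper(b)))) {
    na <- nchar(a); nb <- nchar(bb)
    if (na < k || nb < k) next
    for (i in 1:(na - k + 1L)) {
      if (grepl(substr(a, i, i + k - 1L), bb, fixed = TRUE)) return(TRUE)
    }
  }
  FALSE
}

# GC fraction recomputed character by character
oracleGC <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  mean(ch %in% c("G", "C"))
}

# Exhaustive decoder following the published linking rules: nearest
# companion within the radius per barcode position, minimum-total-distance
# gene per seed with ambiguous ties dropped, same-gene merging through
# shared spots, and global cross-gene conflict resolution by total
# distance. Mirrors the documented rules through an independent code path
# (full distance matrix, no spatial index).
oracleDecode <- function(spots, codes, radius = 2.5, minPos = 3L) {
  o <- order(spots$pseudocolor, spots$y, spots$x)
  sp <- spots[o, , drop = FALSE]
  n <- nrow(sp)
  if (n == 0L) return(data.frame(gene = integer(), total = numeric(),
                                 spots = character()))
  G <- nrow(codes)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) D[i, ] <- sqrt((sp$x - sp$x[i])^2 + (sp$y - sp$y[i])^2)
  cands <- list()
  for (s in seq_len(n)) {
    viable <- list()
    for (g in seq_len(G)) {
      bc <- codes[g, ]
      if (!(sp$pseudocolor[s] %in% bc)) next
      members <- s; dists <- 0
      for (p in bc[bc != sp$pseudocolor[s]]) {
        js <- which(sp$pseudocolor == p & D[s, ] <= radius)
        if (length(js)) {
          dmin <- min(D[s, js])
          j <- min(js[D[s, js] == dmin])
          members <- c(members, j)
          dists <- c(dists, dmin)
        }
      }
      if (length(members) >= minPos)
        viable[[length(viable) + 1L]] <- list(gene = g, members = members,
                                              dists = dists,
                                              total = sum(dists))
    }
    if (!length(viable)) next
    totals <- vapply(viable, `[[`, 0, "total")
    best <- which(totals == min(totals))
    if (length(best) > 1L) next      # ambiguous seed dropped
    cands[[length(cands) + 1L]] <- c(viable[[best]], list(seed = s))
  }
  if (!length(cands)) return(data.frame(gene = integer(), total = numeric(),
                                        spots = character()))
  # connected components of same-gene candidates sharing a spot
  m <- length(cands)
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (comp[i] != comp[j] && cands[[i]]$gene == cands[[j]]$gene &&
          length(intersect(cands[[i]]$members, cands[[j]]$members))) {
        tgt <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- tgt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  calls <- list()
  for (cc in sort(unique(comp))) {
    grp <- cands[comp == cc]
    npos <- vapply(grp, function(c) length(c$members), 0L)
    tot <- vapply(grp, `[[`, 0, "total")
    seed <- vapply(grp, `[[`, 0L, "seed")
    ord2 <- order(-npos, tot, seed)
    rep_ <- grp[[ord2[1]]]
    calls[[length(calls) + 1L]] <- list(gene = rep_$gene,
                                        members = rep_$members,
                                        dists = rep_$dists,
                                        total = rep_$total, alive = TRUE)
  }
  # cross-gene conflicts: contested spots processed in ascending order,
  # winner = (total, gene, call index); repeat until stable
  for (iter in 1:1000) {
    owners <- list()
    for (i in seq_along(calls)) {
      if (!calls[[i]]$alive) next
      for (spx in calls[[i]]$members)
        owners[[as.character(spx)]] <- c(owners[[as.character(spx)]], i)
    }
    contested <- sort(as.integer(names(owners)[vapply(owners, length, 0L) > 1]))
    if (!length(contested)) break
    for (spx in contested) {
      own <- owners[[as.character(spx)]]
      own <- own[vapply(own, function(i) spx %in% calls[[i]]$members, TRUE)]
      if (length(own) < 2L) next
      key <- vapply(own, function(i) calls[[i]]$total, 0)
      gk <- vapply(own, function(i) calls[[i]]$gene, 0L)
      win <- own[order(key, gk, own)][1]
      for (i in setdiff(own, win)) {
        at <- which(calls[[i]]$members == spx)
        calls[[i]]$total <- calls[[i]]$total - calls[[i]]$dists[at]
        calls[[i]]$members <- calls[[i]]$members[-at]
        calls[[i]]$dists <- calls[[i]]$dists[-at]
      }
    }
    for (i in seq_along(calls))
      if (calls[[i]]$alive && length(calls[[i]]$members) < minPos)
        calls[[i]]$alive <- FALSE
  }
  alive <- Filter(function(c) c$alive, calls)
  if (!length(alive)) return(data.frame(gene = integer(), total = numeric(),
                                        spots = character()))
  out <- data.frame(
    gene = vapply(alive, `[[`, 0L, "gene"),
    total = vapply(alive, `[[`, 0, "total"),
    spots = vapply(alive, function(c)
      paste(sort(sp$spot_id[c$members]), collapse = ","), ""))
  out[order(out$gene, out$spots), , drop = FALSE]
}

# random spot field + codebook for decoder fuzzing
randomSpotField <- function(seed, nSpots = 40L, nGenes = 8L, nRounds = 6L,
                            nChannels = 2L, fieldSize = 40) {
  set.seed(seed)
  cb <- assignBarcodes(sprintf("g%02d", seq_len(nGenes)), nRounds, nChannels,
                       seed = seed + 1L)
  npc <- nRounds * nChannels
  spots <- data.frame(
    pseudocolor = sample.int(npc, nSpots, replace = TRUE) - 1L,
    x = round(runif(nSpots, 0, fieldSize), 2),
    y = round(runif(nSpots, 0, fieldSize), 2),
    intensity = round(runif(nSpots, 50, 500), 1))
  spots$spot_id <- seq_len(nSpots)
  list(spots = spots, codebook = cb)
}

# decoded calls reduced to a comparable canonical form
callKey <- function(calls) {
  if (nrow(calls) == 0L) return(character())
  sort(paste(calls$gene_id, calls$spot_refs, sep = "|"))
}
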
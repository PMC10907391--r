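test_that("targeting-site enumeration covers every sliding window", {
  cfg <- designConfig()
  tx <- simulateTranscripts("gA", 100, seed = 1)
  sites <- enumerateTargetingSites("gA", tx[["gA"]], cfg)
  expect_equal(nrow(sites), 73L)               # 100 - 28 + 1
  expect_equal(sites$start, 0:72)
  expect_true(all(nchar(sites$target_seq) == 28L))
  expect_equal(sites$target_seq[1], substr(tx[["gA"]], 1, 28))
  # boundary: transcript exactly one window long
  s28 <- enumerateTargetingSites("gB", substr(tx[["gA"]], 1, 28), cfg)
  expect_equal(nrow(s28), 1L)
  expect_equal(s28$target_seq, substr(tx[["gA"]], 1, 28))
  # degenerate: too short flags the gene with a warning and no sites
  expect_warning(s27 <- enumerateTargetingSites("gC", substr(tx[["gA"]], 1, 27), cfg),
                 "shorter")
  expect_equal(nrow(s27), 0L)
})

test_that("off-target screen removes homology at exactly the 17-nt threshold", {
  cfg <- designConfig()
  tx <- simulateTranscripts(c("gA", "decoy"), c(120, 400), seed = 7)
  sites <- enumerateTargetingSites("gA", tx[["gA"]], cfg)
  # plant a 17-mer of site 10 inside the decoy: that site must die
  s10 <- sites$target_seq[10]
  bg17 <- paste0(substr(tx[["decoy"]], 1, 200), substr(s10, 5, 21),
                 substr(tx[["decoy"]], 201, 400))
  surv <- screenOffTargets(sites, bg17, cfg)
  expect_false(s10 %in% surv$target_seq)
  # planting only a 16-mer keeps the site (threshold is strict at 17)
  bg16 <- paste0(substr(tx[["decoy"]], 1, 200), substr(s10, 5, 20),
                 substr(tx[["decoy"]], 201, 400))
  surv16 <- screenOffTargets(sites, bg16, cfg)
  expect_true(s10 %in% surv16$target_seq)
  # reverse-complement homology is screened too: a full 28-nt revcomp hit dies
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s10)))
  survRC <- screenOffTargets(sites, rc, cfg)
  expect_false(s10 %in% survRC$target_seq)
  expect_true(oracleSharesKmer(s10, rc, 17))   # brute-force confirms
  # empty background: everything survives, flagged unscreened
  expect_message(all <- screenOffTargets(sites, character(), cfg), "skipped")
  expect_equal(nrow(all), nrow(sites))
  expect_false(attr(all, "screened"))
})

test_that("k-mer screen agrees with the brute-force substring oracle", {
  cfg <- designConfig(offtarget_k = 11L)  # small k so random hits occur
  for (seed in 1:3) {
    tx <- simulateTranscripts(sprintf("g%d", 1:6), 300, seed = seed)
    decoys <- simulateTranscripts(sprintf("d%d", 1:4), 500, seed = seed + 50)
    sites <- enumerateTargetingSites("g1", tx[["g1"]], cfg)
    sites <- sites[seq(1, nrow(sites), by = 7), ]   # thin for speed
    bg <- c(tx[-1], decoys)
    surv <- screenOffTargets(sites, bg, cfg)
    oracle <- vapply(sites$target_seq, function(ts) {
      !any(vapply(bg, function(b) oracleSharesKmer(ts, b, 11), TRUE))
    }, TRUE, USE.NAMES = FALSE)
    expect_identical(sites$target_seq[oracle], surv$target_seq)
  }
})

test_that("raising the homology threshold never removes more sites", {
  tx <- simulateTranscripts(c("gA", "d1", "d2"), c(300, 800, 800), seed = 3)
  sites <- enumerateTargetingSites("gA", tx[["gA"]], designConfig())
  bg <- tx[-1]
  nSurv <- vapply(c(10L, 12L, 14L, 17L), function(k) {
    nrow(screenOffTargets(sites, bg, designConfig(offtarget_k = k)))
  }, 0L)
  expect_true(all(diff(nSurv) >= 0L))
})

test_that("probe selection packs non-overlapping sites within 17-32 bounds", {
  cfg <- designConfig()
  # long clean transcript: capped at 32, pairwise non-overlapping
  tx <- simulateTranscripts("gA", 5000, seed = 2)
  sel <- selectProbeSet(enumerateTargetingSites("gA", tx[["gA"]], cfg), cfg)
  expect_equal(nrow(sel), 32L)
  expect_true(all(diff(sel$start) >= 28L))
  expect_false(attr(sel, "below_min"))
  # 600 nt: max packing floor(600/28) = 21; selected in [17, 21], no flag
  tx6 <- simulateTranscripts("gB", 600, seed = 2)
  sel6 <- selectProbeSet(enumerateTargetingSites("gB", tx6[["gB"]], cfg), cfg)
  expect_gte(nrow(sel6), 17L)
  expect_lte(nrow(sel6), 21L)
  expect_true(all(diff(sel6$start) >= 28L))
  expect_false(attr(sel6, "below_min"))
  # 100 nt: at most floor(100/28) = 3 probes, flagged below minimum
  tx1 <- simulateTranscripts("gC", 100, seed = 2)
  sel1 <- selectProbeSet(enumerateTargetingSites("gC", tx1[["gC"]], cfg), cfg)
  expect_lte(nrow(sel1), 3L)
  expect_true(attr(sel1, "below_min"))
})

test_that("readout generation respects GC window, screens and determinism", {
  cfg <- designConfig(rng_seed = 21L)
  decoys <- simulateTranscripts(c("d1", "d2"), 600, seed = 9)
  ro <- generateReadoutOligos(12, decoys, cfg)
  expect_equal(nrow(ro), 12L)
  expect_true(all(nchar(ro$sequence) == 18L))
  # independent GC recount
  gc <- vapply(ro$sequence, oracleGC, 0)
  expect_true(all(gc >= 0.40 & gc <= 0.60))
  # no pair of accepted readouts shares a 10-mer (either strand)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_false(oracleSharesKmer(ro$sequence[i], ro$sequence[j], 10))
  }
  # none shares a 10-mer with the background
  for (s in ro$sequence) {
    expect_false(any(vapply(decoys, function(b) oracleSharesKmer(s, b, 10), TRUE)))
  }
  # byte-identical rerun under the same seed
  ro2 <- generateReadoutOligos(12, decoys, cfg)
  expect_identical(ro, ro2)
})

test_that("readout screen rejects a planted 10-mer but tolerates a 9-mer", {
  cfg <- designConfig(rng_seed = 33L)
  first <- generateReadoutOligos(1, character(), cfg)$sequence
  # background carrying 10 nt of the first candidate: candidate rejected,
  # so the first accepted readout differs
  ro10 <- generateReadoutOligos(1, substr(first, 1, 10), cfg)$sequence
  expect_false(ro10 == first)
  expect_true(oracleSharesKmer(first, substr(first, 1, 10), 10))
  # a 9-nt fragment indexes no 10-mers: same candidate sails through
  ro9 <- generateReadoutOligos(1, substr(first, 1, 9), cfg)$sequence
  expect_identical(ro9, first)
})

test_that("shortening the readout match threshold only adds rejections", {
  # candidates rejected at k = 12 must be rejected at k = 10: acceptance is
  # monotone in k over a fixed candidate set
  set.seed(4)
  cands <- vapply(1:150, function(i)
    paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = ""), "")
  bg <- simulateTranscripts("bg", 3000, seed = 5)[[1]]
  pass <- function(k) {
    vapply(cands, function(s) !oracleSharesKmer(s, bg, k), TRUE)
  }
  p10 <- pass(10); p12 <- pass(12)
  expect_true(all(!p10 | p12))        # passing at k=10 implies passing at k=12
  expect_lte(sum(p10), sum(p12))      # acceptance rate monotone in k
})

test_that("assembled probes obey the documented oligo layout", {
  cfg <- designConfig()
  tx <- simulateTranscripts("gA", 200, seed = 6)
  sel <- selectProbeSet(enumerateTargetingSites("gA", tx[["gA"]], cfg), cfg)
  ro <- generateReadoutOligos(4, character(), designConfig(rng_seed = 2L))
  pr <- defaultPrimers()
  probes <- assembleProbes(sel, 0:3, ro, pr, cfg)
  # 20 + 18*2 + 28 + 18*2 + 20 = 140 nt
  expect_true(all(nchar(probes$full_sequence) == 140L))
  # layout round-trip: parsing the oligo recovers the targeting region
  for (i in seq_len(nrow(probes))) {
    core <- substr(probes$full_sequence[i], 20 + 36 + 1, 20 + 36 + 28)
    target <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(core)))
    expect_identical(target, probes$target_seq[i])
    # probe core base-pairs with the transcript substring
    expect_identical(
      probes$target_seq[i],
      substr(tx[["gA"]], probes$start[i] + 1, probes$start[i] + 28))
  }
  # wrong readout count is a hard error
  expect_error(assembleProbes(sel, 0:2, ro, pr, cfg), "expected 4")
})

test_that("library-level design couples readout identities to barcodes", {
  genes <- sprintf("tf%02d", 1:5)
  cb <- assignBarcodes(genes, 22, 2, seed = 8)
  tx <- simulateTranscripts(genes, 1500, seed = 8)
  des <- designProbes(tx, cfg = designConfig(rng_seed = 18L), codebook = cb)
  expect_equal(nrow(des$readouts), 44L)
  expect_true(all(des$report$n_selected >= 17L | des$report$below_min))
  for (g in genes) {
    pg <- des$probes[des$probes$gene_id == g, ]
    expect_gt(nrow(pg), 0L)
    ids <- as.integer(strsplit(pg$readout_ids[1], ",")[[1]])
    expect_setequal(ids, barcodeMatrix(cb)[g, ])
    expect_equal(unique(pg$readout_ids), pg$readout_ids[1])
  }
  # outputs written as TSV + FASTA + JSON report
  d <- withr::local_tempdir()
  paths <- writeProbeLibrary(des, d)
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(length(fa), nrow(des$probes))
})
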
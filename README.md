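# fishcoder

An in-silico toolkit for **combinatorial sequential FISH** (seqFISH-style
image-based spatial transcriptomics), written as a Bioconductor-style R
package. It covers the complete loop of such an experiment, entirely on
synthetic data with known ground truth:

1. **Probe design** — encoding probes with a 28-nt mRNA-complementary
   targeting region, four 18-nt readout sites and two primers; 17–32
   non-overlapping probes per gene; targeting regions removed on ≥ 17 nt
   of exact homology to any non-target sequence (either strand); readout
   oligos rejection-sampled at 40–60% GC and excluded on any ≥ 10 nt
   match.
2. **Codebook** — each gene gets an unordered set of 4 pseudocolors out
   of the 22 rounds × 2 channels = 44-slot acquisition space, packed so
   any two barcodes share at most 2 pseudocolors; every 3-subset of a
   barcode then identifies its gene uniquely, which is what makes
   3-of-4 decoding collision-free.
3. **Simulation** — nuclei, Poisson expression, Gaussian PSF spots,
   per-round rigid drift, multiplicative illumination bias, Poisson +
   read noise, per-position dropout and spurious spots, plus a per-round
   nuclear reference channel.
4. **Recovery** — DAPI-based round registration (phase cross-correlation
   with sub-pixel refinement), white tophat, ROF total-variation
   denoising, Richardson–Lucy deconvolution, local-maxima spot calling
   with radial-center sub-pixel refinement, barcode decoding by
   nearest-neighbour search within a 2.5-px radius with minimum-distance
   ambiguity resolution and ≥ 3-of-4-position validation, watershed
   nucleus segmentation, and transcript-to-cell counting into a
   `SummarizedExperiment` (MatrixMarket on disk).

The decoder is the core statistic: seeding from every spot, a candidate
gene is viable if seed plus nearest in-radius companions cover at least
3 of its 4 barcode positions; competing genes are resolved by minimum
total distance, exact ties are dropped as ambiguous, same-gene candidates
sharing spots merge, and cross-gene spot conflicts are resolved globally
by the same minimum-distance rule. The implementation (C++) is held equal
to an exhaustive brute-force oracle in the test suite.

## Worked example

```r
library(fishcoder)

# 1. barcodes for a 12-gene panel on the 22-round x 2-channel acquisition
cb <- assignBarcodes(sprintf("TF%02d", 1:12), nRounds = 22, nChannels = 2, seed = 42)
cb
#> Codebook: 12 genes, 22 rounds x 2 channels (44 pseudocolors), maxShared=2
#>   TF01: {5, 28, 31, 41}
#>   TF02: {5, 7, 16, 23}
#>   TF03: {11, 31, 37, 43}
#>   ... and 9 more

# 2. simulate a small field and render the image stacks
field <- fieldSpec(256, 256, n_cells = 8,
                   expression_means = defaultExpressionMeans(geneIds(cb), 1, 6))
truth <- simulateField(field, cb, seed = 42)
sim   <- renderStack(truth, cb, acquisitionSpec(rng_seed = 42))
sim$truth
#> SimulatedField: 256 x 256 px, 8 cells, 12 genes, 263 transcripts (929 plane spots)

# 3. recover: register, filter, deconvolve, call spots, decode, count
stack <- preprocessStack(sim$stack)
spots <- callSpots(stack)
calls <- decodeSpots(spots, cb)
head(calls[, 1:5], 3)
#>   gene_id        x         y n_positions total_distance
#> 1    TF01 200.8894  86.24817           3     0.06577991
#> 2    TF01 219.8746 103.02338           3     0.13819088
#> 3    TF01 152.8239 113.12013           4     0.19251828

labels <- segmentNuclei(nuclearReference(stack, 0))
counts <- assignAndCount(calls, labels, gene_ids = geneIds(cb))
counts
#> class: SummarizedExperiment
#> dim: 12 8
#> metadata(4): n_total n_assigned n_unassigned expand_px
#> assays(1): counts
#> rownames(12): TF01 TF02 ... TF11 TF12
#> colnames(8): cell_1 cell_2 ... cell_7 cell_8
#> colData names(4): cell_id x y area

# 4. compare with the planted ground truth
metrics <- evaluateDecoding(calls, sim$truth)
round(unlist(metrics[c("recall", "precision", "count_correlation", "rmse")]), 3)
#>            recall         precision count_correlation              rmse
#>             0.856             0.827             0.986             0.289
```

263 of the planted transcripts, 929 surviving barcode positions after
10% dropout: the chain re-finds 86% of molecules with sub-third-pixel
localization, and per-gene totals correlate with truth at 0.99. (This
12-gene panel is deliberately dense; the default 40-gene profile decodes
at recall 0.87 / precision 0.92.) `runPipeline(defaultRunConfig())` runs
the same chain as one reproducible unit with a manifest, and
`inst/scripts/fishcoder.R` exposes `run` / `codebook` / `design` /
`simulate` subcommands for shell use. Methodological details — every
model, default and open design decision — are in
`vignettes/fishcoder-methods.Rmd`.

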
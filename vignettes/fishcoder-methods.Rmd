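---
title: "Models and methods behind fishcoder"
author: "fishcoder authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fishcoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fishcoder is an in-silico model of a combinatorial sequential-FISH
experiment: it designs the encoding-probe library, assigns the barcodes,
renders the multi-round image stacks with known ground truth, and then
recovers a gene-by-cell count matrix with the same image-processing and
decoding chain a real experiment would use. This vignette explains the
models behind each stage, the parameters that matter, the design choices
that were genuinely open, and what the simulation does and does not say
about real data.

## The encoding model

Each gene is detected by a pool of encoding probes. A probe carries a
28-nt region complementary to the mRNA, four 18-nt readout sites, and two
20-nt PCR primers, laid out

```
fwd | readout1 | readout2 | revcomp(target) | readout3 | readout4 | rev
```

so the assembled oligo is 140 nt. The four readout identities are the
same on every probe of a gene and define the gene's barcode. Design rules
enforced by `designProbes()`:

* targeting windows are all 28-nt substrings of the transcript, screened
  against every non-target transcript plus a user background: a window
  dies if it shares an exact substring of 17 nt or more with either
  strand of any non-target sequence. Sharing a substring of length >= k
  is equivalent to sharing a k-mer, so the screen is an exact k-mer
  lookup -- deterministic, and verified in the tests against a
  brute-force all-substrings oracle;
* 17–32 non-overlapping probes per gene, evenly thinned when more fit;
  genes that cannot reach 17 are flagged, not dropped, since a partial
  probe set still hybridizes;
* readout oligos are rejection-sampled at GC between 40% and 60% and
  discarded on any 10-nt or longer match to the background, the selected
  targeting regions, or a previously accepted readout (both strands).

There is no melting-temperature or secondary-structure model; the GC
window is the only thermodynamic proxy, applied to readouts where
uniform hybridization across rounds matters most. A targeting-GC window
exists but is off by default.

## The barcode space

An acquisition of 22 hybridization rounds times 2 fluorescence channels
gives 44 pseudocolors; a gene's barcode is an unordered set of 4 of them.
`assignBarcodes()` packs codewords greedily in a seed-determined random
order, accepting a codeword only if none of its four 3-subsets has been
used before. That constraint is exactly pairwise sharing <= 2, and it is
what makes partial detection decodable: any 3 of a gene's 4 positions
identify it uniquely. The greedy packing reaches roughly 2,600–2,700
codewords on the 44-slot space (the combinatorial upper bound is
C(44,3)/4 ≈ 3,311), comfortably above the ~1,100-gene panels this
geometry is used for. A maximum-packing construction would close the
remaining gap but buys nothing at practical panel sizes.

## The simulator

`simulateField()` draws the biology: nuclei as non-overlapping discs
(dart throwing, radii 12–18 px), per-cell per-gene transcript counts
Poisson with gene-specific means, positions uniform in a disc of 1.4
nucleus radii (a simple cytoplasm). `renderStack()` draws the physics:
each non-dropped barcode position becomes an isotropic 2-D Gaussian
(sigma 1.3 px) of lognormal amplitude (mean 800 photons, CV 0.2) at the
transcript position shifted by that round's drift; spurious spots arrive
at 0.05 per plane; the plane is multiplied by a smooth vignetting field
(15% depth), Poisson shot noise is applied on top of a 100-photon
background, then Gaussian read noise (sigma 2). Drift is a per-round
random walk (sigma 1 px/round) shared by both channels and the nuclear
reference, matching the translation-only registration downstream.

Two defaults deserve justification:

* **Expression means, 0.3–3 transcripts per cell per gene (log-spaced
  across the panel).** Transcription factors are low-copy transcripts,
  and — more fundamentally — 2-D combinatorial FISH only works below a
  density ceiling: with a 2.5-px linking radius, spots whose same-plane
  neighbours sit closer than the PSF merge and their barcodes collide.
  Spreading ~1,100 genes over 44 planes is precisely how the real assay
  dilutes optical density; a 40-gene test panel must carry low means to
  sit at the same per-plane density. The defaults put ~4 spots per plane
  per cell, below that ceiling.
* **Field profile 512 × 512 px, 30 cells, 40 genes.** Large enough for
  ~1,300 transcripts (tight binomial checks), small enough that the full
  pipeline runs in about three minutes on one CPU; the vignette-scale
  profile is a deliberate choice, and every knob scales up through
  `fieldSpec()`/`RunConfig`.

What the simulator does **not** model: 3-D defocus, chromatic offsets
between channels, bleed-through, photobleaching across rounds,
autofluorescence texture, segmentation-relevant cytoplasmic stain, or
cell-type structure in expression. Passing tests therefore demonstrate
that the recovery chain is correct and well-calibrated under rigid
drift, smooth illumination bias, shot/read noise, dropout and spurious
spots — not that it would meet the same numbers on tissue.

## The recovery chain

Order is fixed: register → tophat → ROF → Richardson–Lucy → detect →
refine → decode → segment → count.

**Registration.** Per-round translation is estimated on the nuclear
reference by phase cross-correlation with an upsampled-DFT sub-pixel
refinement (factor 20). Full spectral whitening is noise-hostile for
smooth disc-like references, so the cross-power spectrum is Hann-windowed
and low-pass masked at 0.1 cycles/px; with that, planted drifts come back
within ~0.15 px at realistic noise and well within the 0.5 px the 2.5-px
linking radius tolerates. Rotation and scale are out of scope.

**Background and denoising.** White tophat with a 7-px disc (several PSF
widths) removes illumination bias; ROF total-variation denoising
(Chambolle dual projection, tau = 0.125, weight 0.05 on the unit-rescaled
plane, tolerance 1e-4, cap 200 iterations) suppresses noise without
blurring spot edges. The weight acts on the image rescaled to unit range
so one default serves any intensity scale; the dual formulation conserves
the plane mean exactly.

**Deconvolution.** Standard multiplicative Richardson–Lucy (15
iterations) with a Gaussian PSF matched to the simulator's sigma, FFT
convolution on a reflectively padded plane. RL sharpens crowded spots so
neighbouring maxima separate; it preserves nonnegativity and interior
flux to better than 1%.

**Spot calling.** Local maxima over a 5 × 5 neighborhood above a robust
per-plane threshold (median + 6·MAD, override with an absolute value),
then non-maximum suppression at 2 px. The suppression radius is set just
below the optical merging scale of the 1.3-px PSF: pairs closer than
~2.5 px are one blob regardless, pairs at 3 px and beyond should both
survive. Each peak is refined to the radial-symmetry center of its 7 × 7
window — the point minimizing gradient-magnitude-weighted distance to
the local gradient lines — which is exact on symmetric spots and ~0.05 px
on noise-free sub-pixel positions; border peaks fall back to a flagged
intensity centroid. Refinement can never move a peak by more than the
window half-width.

**Decoding.** Every spot seeds a search: for each gene whose barcode
contains the seed's pseudocolor, collect the nearest spot within 2.5 px
(inclusive) in each of the gene's other three pseudocolors; a candidate
is viable with at least 3 of 4 positions; among viable genes the minimum
summed seed-to-companion distance wins, with exact ties dropping the
seed as ambiguous. Candidates of one gene sharing any spot merge
(representative: most positions, then smallest total distance, then
smallest seed in canonical order); a spot claimed by calls of different
genes goes to the call with the smaller total distance, the loser is
re-evaluated and dies below 3 positions. Spots are canonically ordered
internally (pseudocolor, y, x), which makes the whole procedure
invariant to input row order and to global translation, and every spot
ends in at most one call. The implementation is C++; the test suite
holds it equal to an exhaustive plain-R oracle over 50 random fields,
and end-to-end recall under pure dropout matches the binomial closed
form `p^4 + 4 p^3 (1 - p)`.

Three readings of the published procedure were genuinely open and are
resolved as follows: the 2.5-px radius is inclusive; "three of four
rounds" means three of four barcode positions (a barcode may use one
round's two channels); and cross-seed conflicts reuse the same
minimum-distance rule globally rather than a per-seed order-dependent
rule. The call position is the intensity-weighted mean of its spots.

**Cells and counts.** Nuclei are segmented classically — Gaussian
smoothing (sigma 2), Otsu threshold, hole filling, distance transform,
watershed, minimum area 80 px — deliberately replacing any learned
segmenter so the toolkit stays self-contained; watershed is what
finalizes boundaries in practice anyway. Labels are then expanded 7 px
by a multi-source BFS that cannot merge cells; 7 px is the cytoplasm
annulus the generator itself implies (0.4 nucleus radii, up to ~7 px),
so containment assignment covers the simulated cell body. Counts land in
a `SummarizedExperiment` (genes × cells, centroids and areas in
`colData`), written as MatrixMarket with TSV sidecars;
`n_assigned + n_unassigned = n_total` holds exactly.

## Numerical and degenerate-input conventions

Coordinates are 0-based with pixel centers at integers, x = column,
y = row; every table header states this. Convolution-like operators pad
reflectively. A transcript shorter than one probe window, an empty
background for the off-target screen, a blank nuclear plane, an empty
spot table, and a zero-gradient refinement window all have defined,
flagged behaviours rather than errors where the pipeline can continue.
Readout generation fails loudly with the dominant rejection cause when
the constraint set is unsatisfiable. All randomness flows from explicit
seeds; the pipeline derives per-stage seeds from the global seed by fixed
offsets, so stages are independently reproducible, and reruns are
byte-identical.

## Known limitations

Decoding recall is density-limited: above ~0.005 spots/px²/plane,
same-plane neighbours merge under the PSF and recall degrades before
precision does. Registration is translation-only. The robust detection
threshold degenerates on noise-free synthetic planes (MAD = 0); tests use
absolute thresholds there, and real/simulated noise keeps MAD positive.
Per-gene counts are not corrected for detection efficiency, so absolute
expression is underestimated by roughly the end-to-end recall; relative
abundances across genes are preserved (count correlation ≥ 0.99 at the
default profile).
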
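---
title: "Models and methods behind rrnclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rrnclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnclust)
```

`rrnclust` implements three quantitative readouts of bacterial chromosome
spatial organization — fluorescent locus-pair distances, Mu-transposition
contact mapping, and dCas9 pulldown proteomics — together with reporter-assay
closed forms and synthetic-data generators carrying ground truth. This
vignette is the package's account of the underlying models, the parameters
that matter, the numerical conventions adopted where several were defensible,
and what the synthetic data do and do not establish about real data.

## Locus-pair distance analysis

Two chromosomal loci are tagged with orthogonal parS sites bound by GFP- and
CFP-fused ParB proteins, producing one diffraction-limited focus per locus
per channel. The pipeline is:

1. **Detection** (`detect_foci`). The channel image is Gaussian-smoothed
   (`smooth_sigma_px`, default 1 px) to suppress shot-noise maxima, a rolling
   background is estimated by grayscale opening with a disc of radius
   `background_radius_px` (default 8 px — wider than a focus, narrower than
   cell-scale intensity variation) and subtracted, and local maxima whose
   residual intensity exceeds `maxima_prominence` are kept. The prominence
   threshold is exposure-dependent and deliberately left as a tuning
   parameter; the default (25 intensity units) sits several noise standard
   deviations above the residual background of the synthetic defaults.
   Maxima are refined to sub-pixel positions by the intensity-weighted
   centroid of the 3×3 neighbourhood; refinement can be disabled
   (`subpixel = FALSE`) to reproduce integer-pixel workflows.
2. **Pairing** (`match_pairs`). Each GFP focus is matched to the CFP focus
   minimizing the Euclidean pixel distance. Matching is deliberately
   one-directional: a CFP focus may serve several GFP foci, and GFP foci
   with no available partner are counted as unmatched rather than dropped
   silently. Ties are broken by lowest CFP index, making results
   deterministic. A mutual-nearest-neighbour mode and a maximum-distance
   gate exist but are off by default, since whole-image one-directional
   matching is the convention this pipeline mirrors.
3. **Scaling and summary** (`to_nm`, `summarize_distances`). Pixel distances
   are multiplied by `pixel_nm` (default 62 nm/px, the calibration of the
   100× system emulated here). Medians and quartiles use linear
   interpolation between order statistics (`quantile(type = 7)`); no
   convention was dictated, so the inclusive interpolated one was fixed and
   is tested explicitly.
4. **Comparison** (`compare_conditions`). The de-clustering call follows the
   fold change of medians (treatment/control ≥ `fold_change_cutoff`,
   default 2.5), with a two-sided Mann–Whitney p-value reported alongside.
   With hundreds of foci per condition the rank test reaches p < 0.001 for
   shifts far too small to be biologically meaningful, which is why the call
   follows the fold rule and not the p-value. An absolute threshold on the
   treatment median (`distance_cutoff_nm`, e.g. 230 nm) is available as an
   alternative rule: the two rules are not equivalent (230 nm ≈ 1.7 × 134 nm)
   and the fold rule is the default.

Distances are strictly 2-D; z-projection is assumed upstream, and chromatic
or drift correction is out of scope (masks and registered images are inputs).
`measure_cells` converts per-cell pixel lengths to µm with the same scale and
reports mean in-mask DAPI intensity minus the image median as a robust
background-subtracted nucleoid signal.

## Mu-transposition contact mapping

Phage Mu transposes into DNA in physical contact with the donor site, so the
per-bin frequency of single-hop insertions reads out contact frequency
between the donor locus and the rest of the chromosome.

* **Binning** (`make_binning`, `bin_insertions`). The circular genome
  (default 4,641,652 bp) is split into `n_bins` (default 100) equal bins of
  ~46 kb, 0-based half-open with integer boundaries, the last bin absorbing
  the rounding remainder (< 1 bp per bin). The binning origin is coordinate
  0 by default and configurable via the genome length/bin count; insertion
  positions are BED starts. Donor-bin insertions are retained: elevated
  self-bin insertion is a result, not an artifact.
* **Normalization** (`normalize_profile`). Raw counts are confounded by the
  replication gradient: in an asynchronous culture, ori-proximal DNA is
  present at up to twice the ter-proximal copy number, and mapped-read
  coverage tracks that copy number. The closed form
  `f_b = (I_b/ΣI) / (R_b/ΣR)` first removes sequencing depth and then each
  bin's coverage share; it uses coverage directly as the copy-number proxy
  rather than fitting a copy-number model. Zero-coverage bins cannot be
  corrected and are masked (`NA`), excluded from the maximum. Profiles are
  reported as percent of the maximum bin, scaled per replicate *before*
  averaging, so the replicate SD includes scaling noise; the maximum is
  exactly 100 whenever any unmasked bin is nonzero, and percent-of-max is
  invariant to rescaling all counts or all coverage by a constant.
* **Comparison** (`compare_rrn_bins`). Conditions are compared at the
  *rrn*-containing bins with a two-sample two-tailed Student *t* test
  (pooled variance by default, matching the named test; Welch via
  `var_equal = FALSE`), flagged at p < 0.05 with no multiple-testing
  correction across the six bins — each bin is starred on its own p-value,
  matching the per-locus panel convention. Degenerate inputs follow a fixed
  convention: both groups constant and equal gives p = 1; constant and
  unequal gives the smallest positive p and a flag.

## Pulldown spectral-count enrichment

Spectral counts (peptide-spectrum matches per protein) from a dCas9 pulldown
targeted near an *rrn* operon are compared with a lacZ-gRNA control pulldown:

1. **Control normalization** (`normalize_to_control`). Target and control
   tables are unioned (missing proteins get zero counts), every replicate
   column is scaled to the mean column total, and per-protein log2 ratios
   are computed with pseudocount 1, pairing target replicate *i* with
   control replicate *i* (deterministic; a pooled control is a trivial
   preprocessing step). The pseudocount keeps proteins absent from one
   table finite; its side effect is that depth invariance is exact only up
   to the pseudocount's weight relative to the common column total — with
   pseudocount 0 the invariance is exact, and the test suite checks both
   statements.
2. **z-scores** (`z_scores`). Within each replicate,
   `z = (lr − median(lr)) / (1.4826 · MAD(lr))` over the protein population.
   The robust centre/scale keeps the unenriched bulk at z ≈ 0 even when a
   substantial minority of proteins is truly enriched. A plain mean/SD
   convention is available (`z_method = "meansd"`) for sensitivity analysis:
   on synthetic tables with planted truth it is specific but loses
   sensitivity as the planted fraction grows, because true enrichments
   inflate the SD — this is why the robust convention is the default and the
   one whose calls the package documents. Zero MAD falls back to mean/SD;
   zero SD yields all-zero z.
3. **Calling and FDR** (`call_enriched`). A protein is enriched when z > 2.5
   in *every* replicate — the top-right-square geometry of a
   replicate-vs-replicate z plot (an any-replicate rule is available). The
   FDR is empirical rather than parametric: all 2^r − 1 target/control
   replicate label swaps are rebuilt from the raw counts, the per-protein
   decision statistic (minimum z across replicates) is pooled into a null,
   and each protein's FDR is the expected null exceedance count over the
   observed exceedance count at its statistic, made monotone. With three
   replicates the permutation set is exhaustive, so the procedure is
   deterministic.
4. **Intersections** (`intersect_samples`) aggregate enriched sets across
   sgRNAs into per-protein membership counts and upset-style pattern counts.

## Synthetic data: what it emulates, and what it does not

Every generator returns the exact ground truth used to draw the data, and
identical seeds give bit-identical outputs (seeding is scoped with
`withr::local_seed`, leaving the caller's RNG untouched).

* `simulate_foci_field` draws pair separations from a log-normal law
  parameterized by its median (default 134 nm for the clustered state;
  566 nm emulates de-clustering) and a log-scale spread of 0.5. Only medians
  and quartiles of the real distributions are published; the log-normal is a
  strictly positive, heavy-tailed stand-in chosen once, not an inference
  about the true law. Cells are non-overlapping rectangles on a sparse
  monolayer grid whose size adapts to the largest drawn offset, so no
  distance is censored and the truth median is exactly the sample median of
  the drawn law. Foci render as symmetric Gaussian spots (σ = 1.3 px,
  ≈ 80 nm, a diffraction-limited spot at 62 nm/px) on a flat background
  (100) with Gaussian read noise (SD 10) and integer quantization. Not
  modelled: chromatic offset between channels, aberration, uneven
  illumination, autofluorescent cell bodies, and focus co-movement within a
  cell — so detection/pairing performance on these fields bounds algorithmic
  error only, not instrument error.
* `simulate_mu_insertions` draws per-bin insertion counts from a multinomial
  with probability ∝ contact profile × copy number, where copy number is
  `2^(g·(1−d))` on the circular bin distance `d` from the ori bin
  (`g = gradient_strength`: 0 flat, 1 the full 2:1 ori:ter gradient of an
  asynchronous culture). Coverage is an independent multinomial at fixed
  depth (default 10^6 reads) proportional to copy number × bin width, so
  normalization must *estimate* the gradient from coverage exactly as it
  would on real data. Totals are conserved exactly. Defaults place the donor
  at bin 73 of 100 (the rrnD-proximal donor position; the source material
  is inconsistent between bins 72 and 73, so the donor bin is an explicit
  argument) and ori at bin 90. Read-level simulation (FASTQ, mapping noise,
  junction calling) is out of scope.
* `simulate_spectral_counts` draws counts from a negative binomial with
  `mu = baseline_mean` (default 20) and `size = dispersion` (default 20,
  i.e. CV ≈ 0.32 at the default mean — replicate-level reproducibility
  typical of spectral counting; smaller `size` values model noisier
  pulldowns). Planted proteins multiply the target mean by their fold; all
  other proteins are exchangeable between target and control, which is what
  makes the permutation FDR's null exact on these tables.

## Problem sizes and numerical choices

The test suite and the acceptance script use problem sizes chosen to make
the statistical properties sharp while staying light: 500-cell fields
(×10 seeds) for imaging parameter recovery within ±20 nm; 10^5 insertions
and 20 seeds for gradient-removal (χ² flatness at α = 0.01) and planted
3×-contact recovery; 200–2000-protein tables and 20 seeds for enrichment
error control. Quartiles are `type = 7`; χ² flatness of a normalized profile
is tested equivalently as a multinomial goodness-of-fit of insertion counts
against coverage shares; nearest-neighbour matching is validated against an
all-pairs brute-force oracle; and the pooled-variance *t*, Mann–Whitney,
and χ² statistics are delegated to `stats`.

## Limitations

The package analyses pre-extracted inputs: it does not segment cells, align
reads, call insertion junctions, or infer proteins from spectra. The
de-clustering decision rule is a threshold on a ratio of medians, not a
model of focus dynamics; the contact normalization corrects replication bias
through coverage and deliberately makes no model-based copy-number call; and
the enrichment z-convention, while documented and tested, is one of several
in use — the mean/SD alternative is retained precisely so users can check
how much the convention matters on their own tables.
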
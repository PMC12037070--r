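# rrnclust

Quantitative pipelines for studying spatial clustering of ribosomal RNA
(*rrn*) operons on the *Escherichia coli* chromosome. Six of the seven *rrn*
operons, spread over half the 4.6 Mb genome, co-localize into a nucleolus-like
cluster; `rrnclust` implements the three independent measurements used to
probe what holds that cluster together and what disrupts it:

1. **Two-channel locus-pair distance analysis** — loci tagged with orthogonal
   parS/ParB fluorescent reporters (GFP and CFP) are detected as
   diffraction-limited foci, each GFP focus is paired with its closest CFP
   focus, and the Euclidean pixel distance is scaled to nanometres
   (1 pixel = 62 nm). Conditions are compared by the fold change of median
   distance, with a two-sided Mann–Whitney test reported alongside; a
   condition is called *de-clustered* when the median distance rises by at
   least 2.5-fold over the control.
2. **Mu-transposition contact mapping** — phage Mu inserts into DNA it
   physically touches, so per-bin insertion frequency proxies chromosomal
   contact frequency. The genome is partitioned into 100 equal bins (~46 kb),
   insertion counts per bin *b* are corrected for sequencing depth and for
   the replication gradient of asynchronous cultures using each bin's share
   of total mapped reads:
   `f_b = (I_b / ΣI) / (R_b / ΣR)`,
   then expressed as percent of the maximum bin (the 100 % bin). Replicates
   are averaged (mean ± sample SD) and conditions compared at *rrn*-containing
   bins with a two-tailed Student *t* test.
3. **dCas9 pulldown spectral-count enrichment** — proteins recovered with
   dCas9 targeted upstream of an *rrn* operon are scored against a lacZ-gRNA
   control pulldown: replicate columns are depth-scaled, per-protein
   log2 ratios (pseudocount 1) are standardized per replicate by robust
   z-score (median/MAD over the protein population), and a protein is called
   enriched when z > 2.5 in every replicate, with an empirical FDR from
   target/control label permutations. Calls are intersected across sgRNAs
   (upset-style co-occurrence).

Closed-form reporter utilities (Miller units, CFU survival fractions) and
synthetic-data generators with ground truth for every stage round out the
package, so the full analysis chain is testable without any external data.

## Worked example

Simulate a clustered (134 nm) and a de-clustered (566 nm) field, run the
image pipeline and compare:

```r
library(rrnclust)

ctl <- simulate_foci_field(500, median_nm = 134, render = TRUE, seed = 41)
trt <- simulate_foci_field(500, median_nm = 566, render = TRUE, seed = 42)
cmp <- compare_conditions(foci_pipeline(ctl)$pairs,
                          foci_pipeline(trt)$pairs)
cmp
#> Pair-distance comparison: control vs treatment
#>   medians: 135.1 nm -> 560.9 nm (fold change 4.15)
#>   Mann-Whitney U = 243626.0, p = 9.11e-149
#>   de-clustering call: YES
```

The fold change of 4.15 exceeds the 2.5-fold rule, so the treatment is
called de-clustered; `tidy(cmp)` and `glance(cmp)` return the result as
tibbles, and `plot_pair_distances()` draws the violin panel.

Contact mapping on simulated Mu insertions:

```r
bn  <- make_binning()                       # 4,641,652 bp / 100 bins
sim <- simulate_mu_insertions(1e5, bn, local_contact_weight = 20, seed = 1)
summ <- aggregate_replicates(
  profile_replicates(sim$insertions, sim$coverage, bn))
summ[which.max(summ$mean_pct), ]
#> # A tibble: 1 x 4
#>     bin mean_pct sd_pct n_replicates
#>   <int>    <dbl>  <dbl>        <int>
#> 1    73      100      0            3
```

The donor bin (73) is the modal bin, as expected when local contacts
dominate; `plot_contact_profile(summ, start_bin = 73)` and
`plot_contact_heatmap()` reproduce the usual bar and heat-map panels.

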
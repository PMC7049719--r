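# insertionfate

Analysis pipeline for studies that scatter a strong reporter promoter
across a circular bacterial chromosome by transposon mutagenesis and
follow its early fate: where insertions land, how the landing site sets
expression level and cell-to-cell noise, and how expression diverges
along microcolony lineages. It is written for microbial genomicists and
quantitative biologists working with insertion-site sequencing
(TraDIS-like site tables), flow-cytometry clone panels, and single-cell
lineage tracking.

## What it computes

**Gene dosage.** In steady exponential growth (doubling time τ,
replication period C, division period D), a locus at relative replichore
position *m* (0 at *oriC*, 1 at *ter*) has population-average copy number

    d(m) = 2^((C(1−m) + D)/τ)

The package provides the closed form, an explicit age-structured
fork-level simulator as a consistency oracle, expected dosage profiles,
and a log–log fit of observed insertion density against predicted dosage
(the exponent α in density ∝ d(m)^α).

**Circular coverage.** Sliding-window insertion density on the circle
(3 kb windows by default), with an origin left–right asymmetry
diagnostic.

**Enrichment.** Co-occurrence of insertion sites with gene lists
(silencer-protein targets, essential genes, ribosomal operons, ...)
scored against a shuffle null that redraws sites from the empirical 3 kb
sliding density of the insertions themselves — Z-scores net of the
origin-proximal trend — plus a flank-coverage variant (fraction of a
10 kb window around each site covered by the list).

**AT bias.** One-tailed Kolmogorov–Smirnov comparison (exact brute-force
ECDF statistic, asymptotic p = exp(−2D²·n_A·n_B/(n_A+n_B))) of AT content
in windows around insertions versus uniformly sampled background windows.

**Expression noise.** Clone-level mean/sd/CV², a robust fit of the
extrinsic scaling law sd = c·mean (slope fixed at 1 in log space, median
and MAD), steep-noise outlier classification, copy-number normalization,
and growth-rate trend labels.

**Lineage divergence.** The time average of |E₁(t) − E₂(t)| between the
two lineages emanating from each division of a microcolony tree, with a
rank-sum contrast between clone groups.

**Synthetic world.** A generator producing all of the above inputs with
the study's statistical structure — dosage- and AT-biased insertion
landscapes on an annotated circular genome, extrinsic plus
telegraph-switching expression, four-round fluorescence sorting,
microcolony lineages — so every stage is testable without downloads.

## Worked example

```r
library(insertionfate)

cfg <- synth_config()                      # the emulated study conditions
ag  <- make_genome(cfg, seed = 1)          # 500 kb annotated circular genome
ins <- sample_insertions(ag, cfg, seed = 1)  # 3000 insertion sites

# dosage exponent: observed density vs Cooper-Helmstetter prediction
obs  <- sliding_coverage(ins, ag$genome, window_bp = 3000, step_bp = 3000)
pred <- dosage_profile(ag$genome, cfg$dosage, centers = obs$centers)
fit_dosage_exponent(obs, pred)
#> <exponent_fit> alpha = 2.981 +/- 0.182 (164 bins, 3 dropped)

# enrichment against the self-density shuffle null
bg <- sliding_coverage(ins, ag$genome)     # 3 kb background
enrichment_z(ins, ag$intervals$hns_targets, ag$genome, bg,
             n_shuffles = 5000, seed = 1)
#> <enrichment_result> 'hns_targets': observed 1037, null 689.5 +/- 23.15, Z = 15.01, p_emp = 0.0002 (5000 shuffles)
enrichment_z(ins, ag$intervals$essential, ag$genome, bg,
             n_shuffles = 5000, seed = 2)
#> <enrichment_result> 'essential': observed 27, null 193 +/- 13.29, Z = -12.49, p_emp = 1 (5000 shuffles)

# AT content around insertions vs genomic background
insertion_at_bias_test(ins, ag$sequence, ag$genome, seed = 1)
#> <ks_result> D = 0.2390, p = 3.78e-75 (3000 insertion vs 3000 background windows of 1000 bp)
```

Reading the output: the fitted α ≈ 3 says the insertion landscape is
about three times steeper (in log space) than gene dosage alone — dosage
is real but insufficient. The AT-island list is strongly enriched
(Z = +15) even though the null already preserves the large-scale density,
essential genes are strongly depleted (Z = −12.5; the enrichment-tail
empirical p is near 1 for a depleted list, the signed Z carries the
direction), and insertion-flanking windows are markedly AT-richer than
background (D = 0.24).

The numbered scripts under `analysis/` run the full story — simulate,
coverage + dosage fit, enrichment across parental and sorted
populations, AT bias, noise classification, lineage divergence — each a
thin driver over the package that prints what it finds and writes tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_coverage_dosage.R
# ... through 06_lineage.R
```

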
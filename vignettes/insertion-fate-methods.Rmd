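---
title: "Models and methods: insertion landscapes and the early fate of an exogenous promoter"
author: "insertionfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: insertion landscapes and the early fate of an exogenous promoter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the statistical models behind each stage of the
package, the assumptions they rest on, the defaults and why they were
chosen, and the places where the design was genuinely open. The package
analyses the early fate of a strong promoter cassette inserted at random
across a circular bacterial chromosome: where insertions land (gene
dosage, AT content, silencer-protein territory), how the insertion site
shapes expression level and noise, and how expression diverges along
microcolony lineages.

## Coordinates on a circular chromosome

All positions are 0-based, half-open, on a single circular replicon; all
arithmetic is modulo the genome length. The replication origin (*oriC*)
and terminus (*ter*) split the circle into two replichores, and every
locus is assigned a relative position $m \in [0, 1]$ — its circular
distance from the origin along its replichore, divided by that
replichore's length ($m = 0$ at *oriC*, $m = 1$ at *ter*). *ter* defaults
to the antipode of *oriC* but is an explicit field, because real
chromosomes have slightly unequal replichores. An interval that crosses
the origin is stored as two records sharing one id, and all overlap logic
merges shared-id records before counting, so no insertion can be counted
twice.

## Gene dosage: the age-structured replication model

In steady exponential growth with doubling time $\tau$, replication
period $C$ (minutes to replicate one arm) and division period $D$
(termination-to-division gap), a locus at relative position $m$ is
replicated $C(1-m) + D$ minutes before division. A cell of age $a$
therefore carries

$$n(m, a) = 2^{\lfloor (a + C(1-m) + D)/\tau \rfloor}$$

copies, and averaging over the steady-state age distribution
$u(a) \propto 2^{-a/\tau}$ on $[0, \tau)$ gives the population-average
dosage

$$d(m) = 2^{(C(1-m) + D)/\tau}.$$

The closed form and the explicit fork-level simulator
(`simulate_copy_number_fork()`, which draws ages and evaluates
$n(m, a)$ directly) are algebraically identical in expectation; the
simulator is kept as an internal consistency oracle and the test suite
requires agreement within three standard errors at every decile of $m$
for $10^5$ simulated cells. Defaults $C = 40$, $D = 20$, $\tau = 30$
minutes are the canonical fast-growth values for *E. coli*; all three are
user-settable.

The observed insertion density is compared with the dosage prediction by
a log–log least-squares fit, `fit_dosage_exponent()`, after normalizing
both profiles to mean 1 (the fit is then scale-invariant, which the tests
assert). Zero-count bins are dropped rather than pseudo-counted — a
pseudo-count would bias the slope at exactly the sparse bins where the
landscape is most informative — and the dropped count is reported in the
fit record.

### The time-dependent insertion-rate model

An insertion-rate model in which the per-copy rate grows as a power law
$t^\beta$ across the outgrowth window is provided as a generative
simulator (`simulate_age_structured_insertions()`). One fact shapes its
design: in a steadily growing population, a purely time-dependent
per-copy hazard leaves the positional distribution of insertions exactly
equal to the dosage — time and position factorize. The observable
consequence of rate growth is therefore modelled as compounding of the
per-cycle dosage advantage of origin-proximal loci across the rounds of
outgrowth that the growing rate weights: the retained density is tilted
to $d(m)^{1+\beta}$, implemented as an exact rejection layer on top of
the fork-level simulator. With $\beta = 0$ the simulator reproduces the
closed-form dosage exactly (a tested oracle relation); $\beta > 0$
strictly and monotonically steepens the origin/terminus density ratio.
$\beta$ is a free simulator parameter and is never fitted: the package
takes the effective exponent $\alpha$ in density $\propto d(m)^\alpha$ as
the empirical object (`fit_dosage_exponent()`), with the generative
default $\alpha = 3$ matching the regime in which the observed landscape
is markedly steeper than dosage alone.

## Coverage and the origin asymmetry

`sliding_coverage()` computes insertion weight per bp in centered,
half-open circular windows (default 3 kb window, 1 kb step; the window is
the analysis scale of the study design, the step is unstated there and
exposed as a parameter). Windows wrap across the origin, and
non-overlapping windows exactly conserve total insertion weight (a tested
invariant). The left–right asymmetry diagnostic is the difference of
normalized mean coverage between the two replichores divided by the
overall mean, computed on the normalized profile so it is scale-free;
centers exactly at *oriC* or *ter* belong to neither replichore and are
excluded.

## Enrichment against a density-preserving null

Co-occurrence of insertions with a gene list is scored as the total
weight of insertion sites inside the (optionally flank-extended, merged)
intervals. The null model redraws the same number of sites from the
empirical large-scale insertion density — by default the 3 kb sliding
average of the observed insertions themselves — so reported Z-scores are
net of the origin-proximal trend and of any other large-scale structure;
a dosage-profile background is available for sensitivity analysis. Bins
of the background are the circular Voronoi cells of the profile centers;
a bin is drawn with probability proportional to value × width and the
position is uniform within it.

Design choices here, and why:

* **Sites, not read weights, in the null.** Read counts per site in
  insertion sequencing are amplification-distorted, so the null
  resamples site positions with unit weights and the observed score uses
  unit weights for comparability.
* **Insertion-level counting** (total sites in the list) is the default
  score; a gene-level mode (number of features hit) is provided. The
  insertion-level score preserves weightable statistics and is the one
  whose binomial closed form the tests check.
* **Merging before scoring.** Whether overlapping list intervals should
  be merged is ambiguous in general; merging is adopted so no insertion
  is double-counted, and the choice is documented here.
* **Fixed, not adaptive, p-value tail.** The empirical p-value defaults
  to the enrichment tail, $p = (1 + \#\{\text{null} \ge
  \text{obs}\})/(1 + B)$. A tail chosen adaptively in the direction of
  the observed deviation behaves like $\min(p_+, p_-)$ and is
  anti-conservative under the null ($P(p \le x) \approx 2x$); with the
  fixed tail the test suite verifies that $p$ is uniform under the
  null-generating process and that $|Z| > 1.96$ occurs at the nominal 5%
  rate. The signed $Z$ carries direction (enriched lists positive,
  depleted lists such as essential genes negative), and
  `alternative = "less"` or `"auto"` are available.
* **Degenerate nulls** (e.g., a list covering the whole genome) are
  flagged rather than given an arbitrary Z.

The flank-coverage variant scores the mean fraction of a window
(default 10 kb) centered on each insertion that is covered by the list —
the "surroundings" view of the same association.

`n_shuffles` defaults to 5000, the study's scale; the master seed derives
one substream per analysis via `derive_seed()`, a documented
Lehmer-step-plus-tag-hash scheme, so results are reproducible and
independent of stage order.

## AT-content bias

`insertion_at_bias_test()` compares the AT fraction of windows centered
on insertions with windows at uniformly random positions, using a
one-tailed Kolmogorov–Smirnov test with the hard-coded alternative that
insertion windows are richer in AT ($D = \sup_x (F_B(x) - F_A(x))$; which
one-sided convention the original analysis used is not stated, so the
direction of the reported effect is adopted and documented). $D$ is
computed by an exact brute-force ECDF sweep over all sample points — no
binning — and the p-value uses the one-sided asymptotic formula
$\exp(-2 D^2 n_A n_B / (n_A + n_B))$, reported alongside an
underflow-safe $\log_{10} p$. The window default is 1 kb, the scale of
typical silencer-protein binding tracts (up to a few kilobases);
background windows are uniform on the circle, not density-matched,
mirroring a comparison against "the background of the genome". Under the
null the asymptotic p is slightly conservative at finite sample sizes
(the tests assert super-uniformity, not exact uniformity).

## Expression noise and its outliers

Per-clone statistics use the sample (n−1) standard deviation and
$CV^2 = (sd/\text{mean})^2$. In the extrinsic-noise regime the standard
deviation is proportional to the mean, so `fit_noise_scaling()` fixes the
log–log slope at 1 and fits only the proportionality constant $c$ by the
median of $\log(sd/\text{mean})$, with the MAD (scaled to
$\sigma$-equivalent) as the residual scale. Robust location and scale are
essential here because the outliers are the object of interest and must
not leak into the baseline. Clones whose positive residual exceeds
$k \times$ scale are flagged; $k = 3.5$ is the conventional robust
cutoff (no quantitative criterion is stated in the source analysis). A
free-slope diagnostic fit is reported alongside.

**Copy-number normalization, and a small theorem.** Dividing a clone's
mean and sd by the same copy number leaves $sd/\text{mean}$ unchanged, so
stats-level normalization (`normalize_by_copy_number()`, provided and
tested as such) can never change any clone's outlier status under a
ratio-based rule. The removal of multi-insertion outliers by copy-number
normalization is therefore only possible at the per-cell level: in the
synthetic world, multi-insertion clones carry unstable cassette arrays
whose per-cell contributing-copy count varies (uniform on
$\{1,\dots,k\}$), which inflates their cell-to-cell variability beyond
the extrinsic baseline; dividing each cell by its contributing-copy count
(`normalize_expression_by_copy_number()`) removes that component exactly,
and the closed-loop test shows the flagged set collapsing to empty.

The growth-rate trend statistic (`growth_trend()`) is a least-squares
slope of mean expression on growth rate with a three-way label;
"flat" is declared below a configurable fraction (default 5%) of the
mean expression per unit growth rate. Ordinary clones of a ribosomal
promoter rise with growth rate; interference-switching clones fall,
because the competing host operon fires harder in fast growth.

## Lineage divergence

For every division in a microcolony tree, the two descendant lineages
are followed and the pair divergence is the time average of
$|E_1(t) - E_2(t)|$ over shared time points, where $E_i(t)$ averages
expression over all live descendants of child $i$. Averaging over
descendants (rather than stopping at the sisters' own division) keeps
the statistic well-defined over the three-generation colonies the assay
produces; a sisters-only mode is provided, and the default is the
sub-lineage form. Divergence is invariant under adding a constant to all
series and scales linearly under rescaling (tested); a mean-normalized
variant supports cross-clone comparison. Group contrasts use the ratio
of mean colony divergence with a Wilcoxon rank-sum p-value.

## The synthetic world: what it emulates, and what it does not

The generator produces the processed form of the study's data with no
downloads: an annotated circular genome, an insertion landscape, clone
phenotypes and single-cell expression, sorted subpopulations, and
microcolony lineages. Defaults define the emulated study conditions:

* **Genome**: 500 kb (a scaled-down chromosome that keeps every stage
  fast; the full 4.6 Mb is configurable), background AT 0.50, forty AT
  islands of 0.5–2.5 kb at AT 0.70. AT islands are identified with
  silencer-protein (H-NS-like) territory — a generative rule standing in
  for the empirical correlation between AT-rich tracts and such binding,
  not a biological claim. Sixty essential genes (1 kb, never inside
  islands) and seven ribosomal operons (5 kb, alternating orientation,
  evenly spread) complete the annotation; seven is the *E. coli*
  ribosomal-operon copy number, which is what makes insertion into one
  of them tolerable at all.
* **Insertions**: density $\propto d(m)^3 \times (1 + 3 \cdot
  \text{island})$, with candidates inside essential genes retained with
  probability 0.1. $\alpha = 3$ reflects the observed
  steeper-than-dosage landscape; the AT boost and the survival
  probability are qualitative emulation knobs.
* **Expression**: normal clones at $200 \times$ growth rate a.u. with a
  shared extrinsic factor of CV 0.3 (truncated normal at zero —
  fluorescence cannot be negative; a log-normal option would behave
  similarly at this CV); island-proximal clones (within 2 kb) silenced
  to 15%; clones inside a ribosomal operon in opposite orientation
  (drawn with probability 0.8, the dominant observed orientation) follow
  a slow telegraph switch, $k_{on} = 0.02$, $k_{off} = 0.05$ min$^{-1}$
  (a stable off state of mean dwell 50 min, on-dwell 20 min), with the
  on-level falling with growth rate — transcriptional interference from
  the host operon abstracted into a two-state process rather than a
  mechanistic polymerase-traffic model.
* **Multi-insertion clones**: 3% of clones carry 2–3 cassettes as
  unstable arrays. Single-digit multiplicity is typical of transposon
  libraries, multiple insertions were observed only in a minority of
  sequenced clones, and at this rarity the sorted populations reproduce
  the qualitative sorting phenomenology (island association retained in
  the low pool, lost in the high pool) that these free defaults are
  required to reproduce; a rate as high as 10% lets
  silenced-plus-active multi-insertion clones retain island association
  in the high pool.
* **Sorting**: gates $[0, 60)$ and $[120, \infty)$ a.u. around the
  silenced (~42) and normal (~280) means at fast growth, applied over
  four rounds as in the emulated protocol; population sequencing then
  reports the defining (primary) site of every clone above half the
  uniform frequency share.
* **Lineages**: division every $\tau$ exactly (no cell-size control —
  division-time variability is irrelevant to the divergence statistic),
  expression as a mean-reverting Ornstein–Uhlenbeck fluctuation
  (relaxation 30 min, stationary CV 0.3) inherited at division, and the
  telegraph state inherited at division for switching clones; three
  generations of divisions with the eight leaf cells observed for one
  further division time.

What passing tests on this world do **not** show about real data: the
generator has no mappability or GC artefacts, no amplification noise in
read counts, no autofluorescence background, no cell-size/gating
correlations in cytometry, no segmentation error in lineage tracking,
and its silencer territory is AT islands by construction rather than by
measured binding. Conclusions about method calibration (null uniformity,
estimator recovery, sign patterns) transfer; conclusions about effect
sizes in real genomes do not.

## Numerical choices and problem sizes

Exact rejection sampling is used wherever a tilted density is needed
(age weighting, the $\beta$ tilt, essential-gene thinning via density
multiplication), so no discretization error enters the generators beyond
the 1 bp position grid. Shuffle nulls draw positions in vectorized
chunks of ~2 million. The test suite and the acceptance script run the
stages at the sizes the analyses are designed for: $10^5$ cells for the
dosage oracle, $10^5$ insertions at 3 kb bins for exponent recovery, 200
replicates × 1000 shuffles for null calibration, 5000 shuffles for the
synthetic-world enrichment pattern, 5000 windows per side for the AT
bias, 100 clones × 1000 cells for noise recovery, and 20 + 20 colonies
for the lineage contrast — chosen so the full suite completes in a few
minutes on one CPU while leaving each check far from its decision
boundary.

## Known limitations

The dosage model assumes steady-state exponential growth; upshift
transients are represented only through the phenomenological $\beta$
tilt. The enrichment null conditions on the total site count and the
smoothed density, not on chromosome structural features. The one-sided
KS p-value is asymptotic (conservative at small samples; an exact
permutation p would be preferable below ~20 windows per side). The
telegraph expression model draws independent states per cell in
cytometry emulation, ignoring state persistence across the recent lineage
history of a sampled culture — adequate for stationary-occupancy
statistics, not for time-correlated ones, which is what the microcolony
simulator is for.
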
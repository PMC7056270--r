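---
title: "Copy numbers from a histone ruler: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy numbers from a histone ruler: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protruler)
```

## The estimation problem

Label-free quantitative proteomics yields, per sample, one summed peptide
intensity per protein group. Intensities are only relative: instrument
response, loading amount and acquisition drift impose an unknown per-sample
scale. The histone "proteomic ruler" converts these relative intensities into
absolute copies per cell using an internal standard every nucleated cell
carries in fixed amount: its histones. Because chromatin packages DNA at an
approximately 1:1 protein:DNA mass ratio, the total histone mass in a cell is
pinned by its DNA content,

$$ m_\text{hist} \;=\; \frac{p \cdot G \cdot m_{bp}}{N_A}, $$

with ploidy $p$ (2 for a diploid cell), haploid genome size $G$ (mouse:
$2.73\times10^9$ bp), mean base-pair molar mass $m_{bp}$ (615.8771 g/mol) and
Avogadro's constant $N_A$. For a diploid mouse cell this is
$\approx 5.58\times10^{-12}$ g:

```{r}
histone_mass_per_cell(ruler_config())
```

Within a sample $s$ with summed histone intensity
$H_s = \sum_{h \in \text{hist}} I_{h,s}$, every group's mass and copy number
per cell follow from its intensity share of the standard:

$$ m_{i,s} = \frac{I_{i,s}}{H_s}\, m_\text{hist}, \qquad
   c_{i,s} = \frac{m_{i,s}\, N_A}{MW_i}. $$

Only intensity *ratios within a sample* enter, so any per-sample scale factor
cancels exactly — the property the scale-invariance tests exercise with
random per-sample factors spanning six orders of magnitude.

Key assumptions, inherited from the summed-intensity ruler variant:

* MS signal is proportional to protein mass (no peptide-number correction);
* histones are quantified accurately and are not themselves regulated across
  the compared states;
* the cell population is homogeneous enough for "copies per cell" to mean
  copies in an average cell.

All constants live in `ruler_config()` so other genomes, ploidies or an
externally measured `histone_mass_g` can be substituted; histones are found
by case-insensitive gene-name patterns (`H1*`, `H2A*`, `H2B*`, `H3*`, `H4*`,
`Hist*`) rather than a hard-coded accession list, which keeps the standard
robust across annotation releases. Whether linker histones (H1) should join
the core histones in the standard is not settled; the default includes them,
and the pattern list is configurable. A sample in which no histone is
detected is a hard error — the ruler is undefined there, and silently
imputing a standard would fabricate every downstream number.

## Filters and quality categories

Three standard hygiene rules run before estimation:

1. groups flagged as contaminant, reverse-database decoy or "only identified
   by site" are removed (`filter_groups()`, counts logged);
2. a protein is kept only if at least one condition has detections in at
   least 2 biological replicates (`detection_filter()`);
3. each group receives a quantification quality category from its peptide
   counts: *high* with $\ge 8$ razor+unique peptides of which $\ge 75\%$
   unique, *medium* with $\ge 3$ and $\ge 50\%$, *low* otherwise.

Missing, zero and non-numeric intensity cells all mean "not detected"; the
package stores them as `NA` and treats them as zero copies in condition
means while tracking detection separately. No imputation is performed
anywhere — conditions in which a protein is absent genuinely contribute
zeros to its mean copy number, which is how resting-state means of
activation-induced transporters end up in the hundreds rather than being
censored.

## Differential statistics

Condition comparisons use Welch's two-tailed $t$-test with Satterthwaite
degrees of freedom on $\log_2$ copies of the *detected* replicates, while
fold changes are ratios of untransformed condition means (zeros included).
Degenerate inputs follow fixed conventions instead of producing infinities:
fewer than two finite values in a group, or zero variance in both groups
with unequal means, give an undefined $p$ that propagates as `NA`; zero
variance with equal means gives $t = 0$, $p = 1$.

Regulation classes use raw p-values, mirroring the conventional spreadsheet
analysis this pipeline reproduces: *stimulation-regulated* means
$p < 0.05$ on the naive-versus-activated contrast irrespective of fold
change; *genotype-regulated* (Myc- or Slc7a5-dependent) means $p < 0.05$
**and** more than 2-fold difference between activated wild-type and knockout
cells. A Benjamini–Hochberg column is emitted for modern use but never feeds
the classification rules.

A property worth knowing when reading the validation results: at triplicate
sample size the Welch test is *conservative*. Direct Monte Carlo (200,000
null draws, $n = 3$ per group) puts its true size at nominal 0.05 near
0.035, so empirical null rejection rates in the package's own simulations
hover around 0.03 — type-I error is controlled, not exactly nominal. This is
a finite-sample property of the Satterthwaite approximation, not an
implementation artefact; the test suite asserts the conservative direction
explicitly.

## Proteome structure analytics

* `mass_rank_profile()` ranks proteins by descending condition-mean mass and
  accumulates mass fractions; quartile counts report how many proteins reach
  25/50/75/100% of total mass (cumulatively), and the top-75% set is the
  smallest prefix reaching 75%. Mass ties break by group id, making profiles
  independent of input order.
* `pathway_mass_summary()` aggregates mass over a user-supplied gene set
  (case-insensitive matching), reporting µg per million cells and percent of
  total protein mass per condition. Unmatched set members are reported, and
  an empty intersection is a warning with a zero summary, not an error.
* `build_heatmap_matrix()` gates proteins on the reference cell type
  (by default: mean $\ge 500$ copies in at least one reference condition
  *and* detection in $\ge 2$ replicates of at least one reference
  condition), min–max scales each row of condition means to $[0, 1]$ and
  orders rows by average-linkage hierarchical clustering under the
  $1 - \text{Pearson}$ distance. "Nearest-neighbour" grouping in heatmap
  tools is not a uniquely defined algorithm; average-linkage clustering on
  correlation distance is the conventional reading and is the declared
  choice here. Constant rows, whose correlation is undefined, map to 0.5 and
  are appended after the clustered rows; rows are sorted by group id before
  clustering so the leaf order is deterministic and permutation-invariant.

## The synthetic-data generator

`make_ground_truth()` and `simulate_intensities()` plant a complete study
with known answers, emulating a conditional-knockout activation experiment:
naive wild-type cells plus activated wild-type and knockout cells, three
biological replicates per condition. Effect classes realise the canonical
regulation patterns — knockout-dependent induction (induced in activated
wild-type only), knockout-independent induction, downregulation on
activation, an unchanged null class, and condition-invariant histones whose
summed mass is calibrated to the ruler standard so noise-free data are
recovered *exactly* (relative error below $10^{-9}$, limited only by
floating-point rounding).

Study-condition defaults, chosen once: measurement noise
$\sigma = 0.25\ \log_2$ units (a typical label-free replicate CV of
~18%), 5% missingness completely at random, 4-fold planted effects,
baseline copies log-normal (median 3,000, $\sigma_{\log} = 1.2$), histones
4% of naive-cell protein mass, 20 contaminant + 20 reverse + 10 site-only
decoy rows, and class fractions 10% knockout-dependent induced, 6%
knockout-independent induced (a few hundred per few thousand proteins,
matching the scale reported for activation-induced, Myc-independent
proteins), 10% downregulated, 72% unchanged, 2% histones.

What the generator deliberately does **not** emulate: peptide-level
sampling, intensity-dependent missingness (configurable off-default
extension point; the pipeline applies only a detection-count filter, so MCAR
suffices to exercise it), shared-peptide ambiguity between groups,
correlated protein co-regulation, and batch structure. Passing tests
therefore demonstrate correctness of the estimator, filters, statistics and
orderings under a clean error model — not robustness to every pathology of
real acquisitions.

## Numerical choices

* Quartile boundaries in rank profiles use a $10^{-12}$ slack on the
  cumulative fraction so that exact-fraction prefixes (e.g. 0.75 reached
  precisely) are included rather than lost to rounding.
* Copies and masses satisfy $m = c \cdot MW / N_A$ identically (one shared
  computation), asserted at machine precision.
* Result tables serialise reals at full double precision with literal `NA`
  for undefined values, so write–read round-trips are exact.
* Pipeline determinism: the run seed drives the ground truth and `seed + 1`
  the measurement noise; manifests of MD5 hashes make byte-level
  reproducibility checkable (`run_pipeline()` twice under one seed gives
  identical manifests).

## Problem sizes used in validation

The package validates itself on simulated studies of 200–3,000 protein
groups with the triplicate single-cell-type design (9 samples), which keeps
the full suite under a minute while leaving ~2,100 null proteins with
defined p-values for the type-I check and 300 planted knockout effects for
the recovery check (≥90% recovered at the standard thresholds, unchanged
proteins misclassified ≤7%). Larger instances change nothing structurally —
every stage is linear or $n \log n$ in protein count except row clustering,
which is quadratic and intended for the few thousand gated heatmap rows.

## Known limitations

* Copies per cell inherit the ruler's systematic uncertainties (histone
  pattern list, genome-size constant, 1:1 histone:DNA mass assumption);
  comparisons *between* conditions are far more reliable than absolute
  levels.
* Raw-p classification reproduces the conventional analysis but ignores
  multiplicity; use the emitted BH column when selection matters.
* With triplicates, a single missing replicate drops a contrast to $n = 2$,
  where the Welch test has little power and its size is conservative.
* The clustering order is deterministic but, like all leaf orders, not
  unique; config-switchable alternatives (complete linkage, optimal leaf
  ordering) are out of scope.
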
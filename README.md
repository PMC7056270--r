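# protruler

Absolute protein copy numbers per cell from label-free proteomics intensity
tables, using the histone **proteomic ruler**, plus the downstream analytics
of a knockout activation study: differential testing on log2 copies,
regulation classes, cumulative mass-rank profiles, gene-set mass fractions
and clustered heatmap matrices.

The package is written for quantitative proteomics of primary immune cells —
the motivating setting is T cell receptor activation of wild-type versus
conditional-knockout (e.g. Myc- or Slc7a5-deficient) CD4⁺/CD8⁺ T cells in
biological triplicate — but every stage is generic over a sample design of
`genotype × cell type × stimulation × replicate`.

## The estimator

Label-free intensities are relative; each sample carries an unknown scale.
The ruler anchors them to an internal standard fixed by DNA content: total
histone mass per cell is taken equal to the genomic DNA mass,

```
m_hist = ploidy × genome_size_bp × bp_molar_mass / N_A   ≈ 5.58 pg (diploid mouse)
```

and within each sample `s`, a group's mass and copies follow from its
intensity share of the summed histone intensity `H_s`:

```
mass_i,s   = I_i,s / H_s × m_hist
copies_i,s = mass_i,s × N_A / MW_i
```

Per-sample scale factors cancel in the ratio. Around the estimator the
package implements the standard hygiene rules: removal of
contaminant/reverse/site-only rows, a ≥2-replicates-in-some-condition
detection filter, and peptide-count quality categories (high: ≥8 razor+unique
peptides, ≥75% unique; medium: ≥3 and ≥50%; low otherwise). Differential
calls use Welch's two-tailed t-test on log2 copies of detected replicates;
fold changes are ratios of untransformed condition means; regulation classes
follow the conventional thresholds (stimulation-regulated: p < 0.05;
genotype-regulated: p < 0.05 and >2-fold).

A synthetic-data generator plants known copy numbers, effect classes,
calibrated histones and decoy rows, so the whole pipeline validates against
ground truth (noise-free data are recovered to < 1e-9 relative error).

## Worked example

```r
library(protruler)

ds   <- simulate_dataset(n_proteins = 1000, cell_types = "CD8", seed = 42)
kept <- detection_filter(filter_groups(ds$groups), ds$design)
rec  <- estimate_copy_numbers(kept, ds$design)

total_protein_content(rec)
#>   condition       total_protein_ug_per_million
#> 1 CD8.Myc_cKO.TCR                         156.
#> 2 CD8.WT.TCR                              194.
#> 3 CD8.WT.naive                            142.
```

Activated wild-type cells carry ~1.4× the protein mass of naive cells, and
the knockout loses most of that gain — the planted biology, recovered from
intensities the ruler had to denominate itself.

```r
res <- classify_regulation(
  differential_test(rec, "CD8.WT.TCR", "CD8.Myc_cKO.TCR"),
  rule = "genotype")
sum(res$regulated)
#> [1] 94
head(dplyr::arrange(res[res$regulated, ], p_value), 3)[, c(1,2,5,6,7,10)]
#>   group_id gene_name    mean_a   mean_b fold_change   p_value
#> 1 P00062   Gene00062  4643728. 1010338.       0.218 0.0000345
#> 2 P00008   Gene00008   499920.  104847.       0.210 0.0000427
#> 3 P00061   Gene00061 17626480. 4136980.       0.235 0.0000773
```

94 of 1000 groups are genotype-regulated (the generator plants 100
knockout-dependent proteins at 4-fold; a few fall to missing replicates or
threshold noise). Mass structure:

```r
mass_rank_profile(rec, "CD8.WT.TCR")$quartile_counts
#>  q25  q50  q75 q100
#>   18   76  230 1000
```

18 proteins carry a quarter of activated-cell protein mass and 230 carry
three quarters. `build_heatmap_matrix(rec, ds$design, reference_celltype =
"CD8")` yields the min–max scaled, correlation-clustered matrix behind the
relative-abundance heatmaps.

The same flow runs from a YAML configuration:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "protruler"))
```

writing copy-number, differential, volcano, rank-profile, pathway and
heatmap tables plus an MD5 manifest (byte-identical across runs with one
seed). A thin CLI with `simulate | quantify | differential | structure |
run` subcommands lives at `inst/scripts/protruler.R`.

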
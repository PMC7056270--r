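# Demonstration run: simulated CD8 activation study (naive WT + TCR-activated
# WT and Myc-knockout cells, biological triplicates), quantified with the
# histone ruler and pushed through the differential and structure stages.
out_dir: results/demo_run
seed: 1

simulate:
  n_proteins: 500
  cell_types: [CD8]
  genotypes: [WT, Myc_cKO]
  noise_sigma_log2: 0.25
  missing_rate: 0.05

thresholds:
  p: 0.05
  fold: 2
  heatmap_min_copies: 500
  heatmap_min_reps: 2

contrasts:
  - {name: tcr_cd8, a: CD8.WT.naive, b: CD8.WT.TCR, rule: stimulation}
  - {name: myc_cd8, a: CD8.WT.TCR, b: CD8.Myc_cKO.TCR, rule: genotype}

overlap: {a: tcr_cd8, b: myc_cd8}

structure:
  reference_celltype: CD8
  rank_conditions: [CD8.WT.TCR]
  gene_set: [Gene00050, Gene00051, Gene00052, Gene00053, Gene00054]
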
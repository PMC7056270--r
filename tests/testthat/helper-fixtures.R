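# Fixture builders shared across the test files. Everything is constructed in
# code; no fixture files are stored.

tiny_design <- function(cell_types = "CD8", genotypes = c("WT", "Myc_cKO"),
                        n_replicates = 3) {
  make_sample_design(genotypes = genotypes, cell_types = cell_types,
                     n_replicates = n_replicates)
}

# Protein-groups tibble from an intensities matrix (proteins x samples,
# NA = not detected). Metadata arguments are recycled across proteins.
make_groups <- function(design, intensities, gene_name = NULL,
                        mol_weight_da = 5e4, razor = 8L, uniq = 8L,
                        contaminant = FALSE, reverse = FALSE,
                        only_site = FALSE) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  stopifnot(ncol(intensities) == nrow(design))
  if (is.null(gene_name)) gene_name <- sprintf("Gene%03d", seq_len(n))
  out <- tibble::tibble(
    group_id = sprintf("P%03d", seq_len(n)),
    gene_name = gene_name,
    mol_weight_da = rep_len(mol_weight_da, n),
    razor_unique_peptides = as.integer(rep_len(razor, n)),
    unique_peptides = as.integer(rep_len(uniq, n)),
    flag_contaminant = rep_len(contaminant, n),
    flag_reverse = rep_len(reverse, n),
    flag_only_by_site = rep_len(only_site, n)
  )
  for (j in seq_len(nrow(design))) {
    out[[design$sample_id[j]]] <- intensities[, j]
  }
  out
}

# Copy-number records with prescribed per-sample masses for one condition of
# single-replicate samples; used by the structure tests where only masses
# matter.
records_from_masses <- function(masses, condition = "CD8.WT.TCR",
                                n_replicates = 1) {
  n <- length(masses)
  avogadro <- 6.02214076e23
  reps <- lapply(seq_len(n_replicates), function(r) {
    tibble::tibble(
      group_id = sprintf("P%03d", seq_len(n)),
      gene_name = sprintf("Gene%03d", seq_len(n)),
      mol_weight_da = 5e4,
      quality = factor("high", levels = c("high", "medium", "low")),
      is_histone = FALSE,
      sample_id = paste0(condition, ".", r),
      condition = condition,
      replicate = r,
      detected = masses > 0,
      copies_per_cell = masses * avogadro / 5e4,
      mass_per_cell_g = masses
    )
  })
  dplyr::bind_rows(reps)
}

# Text of a small protein-groups file in the search-engine dialect.
pg_fixture_lines <- function() {
  c(
    paste("Majority protein IDs", "Gene names", "Mol. weight [kDa]",
          "Razor + unique peptides", "Unique peptides",
          "Potential contaminant", "Reverse", "Only identified by site",
          "Intensity", "Intensity s1", "Intensity s2", sep = "\t"),
    paste("P10001;P10002", "Actb", "50", "12", "10", "", "", "",
          "300", "100", "200", sep = "\t"),
    paste("P20001", "Hist1h4a", "11.4", "6", "5", "", "", "",
          "80", "50", "30", sep = "\t"),
    paste("P30001", "Alb", "66.5", "20", "18", "+", "", "",
          "900", "400", "500", sep = "\t"),
    paste("REV__P4", "", "30", "2", "1", "", "+", "",
          "10", "0", "10", sep = "\t"),
    paste("P50001", "Xdh", "146", "3", "2", "", "", "",
          "0", "NaN", "", sep = "\t")
  )
}

write_pg_fixture <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(pg_fixture_lines(), path)
  path
}

# Independent brute-force mass-rank oracle: sort + prefix scan.
brute_force_rank <- function(ids, masses) {
  ord <- order(-masses, ids)
  cum <- cumsum(masses[ord]) / sum(masses)
  counts <- vapply(c(0.25, 0.5, 0.75, 1),
                   function(q) which(cum >= q - 1e-12)[1], integer(1))
  list(ids = ids[ord], cumulative = cum, counts = counts,
       top75 = ids[ord][seq_len(counts[3])])
}
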
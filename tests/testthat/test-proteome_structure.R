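test_that("mass-rank profile matches hand-enumerated quartiles", {
  # mass fractions 0.40/0.30/0.20/0.10
  rec <- records_from_masses(c(0.40, 0.30, 0.20, 0.10) * 1e-11)
  prof <- mass_rank_profile(rec, "CD8.WT.TCR")
  expect_equal(prof$table$cumulative_fraction, c(0.40, 0.70, 0.90, 1.00))
  expect_equal(unname(prof$quartile_counts), c(1, 2, 3, 4))
  expect_equal(length(prof$top75_set), 3)

  single <- mass_rank_profile(records_from_masses(2e-12), "CD8.WT.TCR")
  expect_equal(single$table$cumulative_fraction, 1)
  expect_equal(length(single$top75_set), 1)

  # input order does not matter; mass ties break by group id
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(mass_rank_profile(shuffled, "CD8.WT.TCR")$table, prof$table)

  expect_error(mass_rank_profile(records_from_masses(c(0, 0)), "CD8.WT.TCR"),
               "zero")
})

test_that("mass-rank profile equals the brute-force oracle on random instances", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    masses <- 10^runif(n, -14, -10)
    rec <- records_from_masses(masses)
    prof <- mass_rank_profile(rec, "CD8.WT.TCR")
    oracle <- brute_force_rank(rec$group_id[seq_len(n)], masses)
    expect_equal(prof$table$group_id, oracle$ids)
    expect_equal(prof$table$cumulative_fraction, oracle$cumulative)
    expect_equal(unname(prof$quartile_counts), oracle$counts)
    expect_equal(prof$top75_set, oracle$top75)
  }
})

test_that("pathway mass summary recovers planted set fractions", {
  # noise-free dataset: set mass percent must equal the planted percent
  ds <- simulate_dataset(n_proteins = 200, cell_types = "CD8", seed = 41,
                         noise_sigma_log2 = 0, missing_rate = 0,
                         n_decoys = 0, n_contaminants = 0, n_only_site = 0)
  rec <- estimate_copy_numbers(ds$groups, ds$design)
  genes <- ds$truth$proteins$gene_name[50:70]
  out <- pathway_mass_summary(rec, genes)

  truth_tab <- dplyr::left_join(ds$truth$copies, ds$truth$proteins,
                                by = "protein_id")
  for (i in seq_len(nrow(out))) {
    tt <- truth_tab[truth_tab$condition == out$condition[i], ]
    mass <- tt$true_copies * tt$mol_weight_da
    expected <- 100 * sum(mass[tt$gene_name %in% genes]) / sum(mass)
    expect_equal(out$percent_of_total_mass[i], expected, tolerance = 1e-9)
  }

  # set covering everything -> 100%; disjoint set -> 0% with a warning
  all_genes <- ds$truth$proteins$gene_name
  expect_equal(pathway_mass_summary(rec, all_genes)$percent_of_total_mass,
               rep(100, 3))
  expect_warning(none <- pathway_mass_summary(rec, "NotAGene"), "no protein")
  expect_equal(none$percent_of_total_mass, rep(0, 3))
  expect_equal(attr(none, "unmatched"), "NotAGene")

  # matching is case-insensitive
  upper <- pathway_mass_summary(rec, toupper(genes))
  expect_equal(upper$percent_of_total_mass, out$percent_of_total_mass)
})

test_that("heatmap rows are min-max scaled with exact inclusion thresholds", {
  design <- tiny_design()
  des <- condition_id(design)

  # records with exact planted copy numbers per sample (rows = proteins)
  copies <- rbind(
    rep(500, 9),                                  # exactly at threshold
    rep(499, 9),                                  # just below -> excluded
    c(1800, 0, 0, 0, 0, 0, 0, 0, 0),              # mean 600 but 1 replicate
    c(100, 120, 110, 900, 950, 820, 130, 105, 90) # regulated, included
  )
  n <- nrow(copies)
  rec <- dplyr::bind_rows(lapply(seq_len(9), function(j) {
    tibble::tibble(
      group_id = sprintf("P%03d", seq_len(n)),
      gene_name = sprintf("Gene%03d", seq_len(n)),
      mol_weight_da = 5e4,
      quality = factor("high", levels = c("high", "medium", "low")),
      is_histone = FALSE,
      sample_id = des$sample_id[j],
      condition = des$condition[j],
      replicate = des$replicate[j],
      detected = copies[, j] > 0,
      copies_per_cell = copies[, j],
      mass_per_cell_g = copies[, j] * 5e4 / 6.02214076e23
    )
  }))

  hm <- build_heatmap_matrix(rec, design, reference_celltype = "CD8")
  expect_true("P001" %in% hm$row_order)    # mean exactly 500: included
  expect_false("P002" %in% hm$row_order)   # 499: excluded
  expect_false("P003" %in% hm$row_order)   # only one detected replicate
  expect_true("P004" %in% hm$row_order)

  # scaling: values in [0, 1]; the regulated row spans the full range;
  # constant rows sit at 0.5
  expect_true(all(hm$matrix >= 0 & hm$matrix <= 1))
  reg <- hm$matrix[rownames(hm$matrix) == "P004", ]
  expect_equal(min(reg), 0)
  expect_equal(max(reg), 1)
  flat <- hm$matrix[rownames(hm$matrix) == "P001", ]
  expect_equal(unname(flat), rep(0.5, 3))
})

test_that("heatmap clustering is deterministic and groups identical profiles", {
  set.seed(505)
  design <- tiny_design()
  n <- 30
  imat <- matrix(10^runif(n * 9, 5, 8), nrow = n)
  imat[2, ] <- imat[1, ] * 3  # same profile, different scale
  genes <- sprintf("Gene%03d", 1:n)
  genes[n] <- "Hist1h4a"
  groups <- make_groups(design, imat, gene_name = genes)
  rec <- estimate_copy_numbers(groups, design)

  hm1 <- build_heatmap_matrix(rec, design, min_mean_copies = 0, min_reps = 1,
                              reference_celltype = "CD8")
  hm2 <- build_heatmap_matrix(rec[sample(nrow(rec)), ], design,
                              min_mean_copies = 0, min_reps = 1,
                              reference_celltype = "CD8")
  expect_identical(hm1$row_order, hm2$row_order)
  expect_identical(hm1$matrix, hm2$matrix)

  # proportional rows have correlation 1, distance 0: adjacent leaves and
  # identical scaled profiles
  i1 <- which(hm1$row_order == "P001")
  i2 <- which(hm1$row_order == "P002")
  expect_equal(abs(i1 - i2), 1)
  expect_equal(hm1$matrix[i1, ], hm1$matrix[i2, ], tolerance = 1e-9)

  expect_error(
    build_heatmap_matrix(rec, design, min_mean_copies = Inf,
                         reference_celltype = "CD8"),
    "threshold"
  )
  expect_error(build_heatmap_matrix(rec, design, reference_celltype = "CD4"),
               "CD4")
})
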
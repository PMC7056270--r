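test_that("histone mass per cell follows the DNA-content arithmetic", {
  cfg <- ruler_config()
  # independent direct arithmetic
  expected <- 2 * 2.73e9 * 615.8771 / 6.02214076e23
  expect_equal(histone_mass_per_cell(cfg), expected, tolerance = 1e-12)
  expect_equal(expected, 5.58e-12, tolerance = 1e-3)

  # linear in ploidy and genome size
  expect_equal(histone_mass_per_cell(ruler_config(ploidy = 1)), expected / 2)
  expect_equal(histone_mass_per_cell(ruler_config(genome_size_bp = 2 * 2.73e9)),
               expected * 2)
  # explicit override wins
  expect_equal(histone_mass_per_cell(ruler_config(histone_mass_g = 1e-12)),
               1e-12)
})

test_that("single-histone fixture reproduces the closed-form copy number", {
  design <- tiny_design(genotypes = "WT", n_replicates = 1)[1, ]
  cfg <- ruler_config(histone_mass_g = 1e-12)
  groups <- make_groups(design, matrix(c(100, 50), ncol = 1),
                        gene_name = c("Hist1h4a", "Gene001"),
                        mol_weight_da = c(11400, 1e5))
  rec <- estimate_copy_numbers(groups, design, cfg)
  target <- rec[rec$group_id == "P002", ]
  # hand-computed: (50/100) * 1e-12 g * N_A / 1e5 Da
  expect_equal(target$copies_per_cell, 3.01107038e6, tolerance = 1e-9)
  expect_equal(target$mass_per_cell_g, 5e-13, tolerance = 1e-12)
})

test_that("flagged rows are removed once each and counts are logged", {
  design <- tiny_design(genotypes = "WT", n_replicates = 1)[1, ]
  groups <- make_groups(design, matrix(1:10, ncol = 1))
  groups$flag_contaminant[1] <- TRUE
  groups$flag_reverse[2] <- TRUE
  groups$flag_reverse[3] <- TRUE
  groups$flag_contaminant[3] <- TRUE  # doubly flagged: removed once
  out <- filter_groups(groups)
  expect_equal(nrow(out), 7)
  expect_equal(attr(out, "removed"),
               c(contaminant = 2L, reverse = 2L, only_by_site = 0L))
  expect_equal(out$group_id, groups$group_id[4:10])

  clean <- make_groups(design, matrix(1:3, ncol = 1))
  expect_equal(nrow(filter_groups(clean)), 3)
})

test_that("detection filter keeps proteins seen in >=2 replicates of a condition", {
  design <- tiny_design()  # CD8: naive WT, TCR WT, TCR cKO x 3 reps
  # detected replicate counts per condition: [2,1,0], [1,1,1], [0,0,3]
  row1 <- c(10, 10, NA, 10, NA, NA, NA, NA, NA)
  row2 <- c(10, NA, NA, 10, NA, NA, 10, NA, NA)
  row3 <- c(NA, NA, NA, NA, NA, NA, 10, 10, 10)
  groups <- make_groups(design, rbind(row1, row2, row3))
  kept <- detection_filter(groups, design)
  expect_equal(kept$group_id, c("P001", "P003"))
})

test_that("quality categories match brute-force rule application exhaustively", {
  cfg <- ruler_config()
  brute <- function(r, u) {
    if (r >= 8 && u / r >= 0.75) return("high")
    if (r >= 3 && u / r >= 0.50) return("medium")
    "low"
  }
  for (r in 1:12) {
    for (u in 0:r) {
      expect_identical(as.character(assign_quality(r, u, cfg)), brute(r, u),
                       info = sprintf("razor=%d unique=%d", r, u))
    }
  }
  # the documented spot checks
  expect_equal(as.character(assign_quality(c(8, 3, 8, 2), c(6, 2, 5, 2))),
               c("high", "medium", "medium", "low"))
  expect_error(assign_quality(3, 4), "exceed")
})

test_that("per-sample intensity scaling cancels in the ruler", {
  set.seed(101)
  design <- tiny_design()
  for (i in 1:20) {
    imat <- matrix(10^runif(30 * nrow(design), 2, 8), nrow = 30)
    imat[sample(which(row(imat) > 2), 40)] <- NA  # keep histone rows detected
    genes <- sprintf("Gene%03d", 1:30)
    genes[1:2] <- c("Hist1h4a", "H2afz")
    groups <- make_groups(design, imat, gene_name = genes)
    rec <- estimate_copy_numbers(groups, design)

    scaled <- groups
    j <- sample(design$sample_id, 1)
    scaled[[j]] <- scaled[[j]] * 10^runif(1, -3, 3)
    rec2 <- estimate_copy_numbers(scaled, design)
    expect_equal(rec2$copies_per_cell, rec$copies_per_cell,
                 tolerance = 1e-12)
  }
})

test_that("mass, copies and molecular weight obey m = c * MW / N_A", {
  ds <- simulate_dataset(n_proteins = 150, cell_types = "CD8", seed = 21)
  rec <- estimate_copy_numbers(filter_groups(ds$groups), ds$design)
  cfg <- ruler_config()
  expect_equal(rec$mass_per_cell_g,
               rec$copies_per_cell * rec$mol_weight_da / cfg$avogadro,
               tolerance = 1e-12)
  # detection flag consistency
  expect_equal(rec$detected, rec$copies_per_cell > 0)

  # per-sample totals agree with the per-condition content summary
  per_sample <- tapply(rec$mass_per_cell_g, rec$sample_id, sum) * 1e12
  content <- total_protein_content(rec)
  des <- condition_id(ds$design)
  for (i in seq_len(nrow(content))) {
    sids <- des$sample_id[des$condition == content$condition[i]]
    expect_equal(mean(per_sample[sids]),
                 content$total_protein_ug_per_million[i], tolerance = 1e-12)
  }
})

test_that("noise-free synthetic data is recovered exactly", {
  ds <- simulate_dataset(n_proteins = 250, cell_types = c("CD4", "CD8"),
                         seed = 31, noise_sigma_log2 = 0, missing_rate = 0,
                         n_decoys = 0, n_contaminants = 0, n_only_site = 0)
  rec <- estimate_copy_numbers(ds$groups, ds$design)
  joined <- dplyr::left_join(rec, ds$truth$copies,
                             by = c(group_id = "protein_id",
                                    condition = "condition"))
  rel <- abs(joined$copies_per_cell - joined$true_copies) / joined$true_copies
  expect_lt(max(rel), 1e-9)
})

test_that("total protein content uses ug per million cells", {
  # two proteins whose masses sum to 2.5e-11 g/cell in every sample
  rec <- records_from_masses(c(1.5e-11, 1.0e-11), n_replicates = 3)
  out <- total_protein_content(rec)
  expect_equal(out$total_protein_ug_per_million, 25)

  doubled <- rec
  doubled$mass_per_cell_g <- doubled$mass_per_cell_g * 2
  expect_equal(total_protein_content(doubled)$total_protein_ug_per_million, 50)
})

test_that("a sample without detected histone signal is a hard error", {
  design <- tiny_design(genotypes = "WT", n_replicates = 2)
  design <- design[design$stimulation == "TCR", ]
  imat <- matrix(c(100, 50, NA, 60), nrow = 2, byrow = FALSE)
  groups <- make_groups(design, imat,
                        gene_name = c("Hist1h4a", "Gene001"))
  expect_error(estimate_copy_numbers(groups, design),
               design$sample_id[2])

  no_hist <- make_groups(design, imat, gene_name = c("GeneA", "GeneB"))
  expect_error(estimate_copy_numbers(no_hist, design), "histone")
})
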
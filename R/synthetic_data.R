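#' Plant a ground-truth proteome for a knockout activation study
#'
#' Generates per-protein true copy numbers for every condition of a design,
#' with proteins assigned to effect classes that mirror the regulation
#' patterns of an antigen-receptor activation experiment in wild-type and
#' conditional-knockout cells:
#'
#' * `myc_dependent_induced` — low in naive cells, induced `induced_fold`-fold
#'   by activation in wild-type cells only; knockout activated cells stay at
#'   naive levels.
#' * `myc_independent_induced` — induced by activation in every genotype.
#' * `downregulated` — high in naive cells, reduced `down_fold`-fold on
#'   activation in every genotype.
#' * `unchanged` — flat across all conditions (the null class).
#' * `histone` — condition-invariant, scaled so the summed histone mass per
#'   cell equals the DNA-derived ruler standard of `ruler`
#'   ([histone_mass_per_cell()]); this makes ruler estimates directly
#'   comparable to the planted truth.
#'
#' Baseline copy numbers are log-normal; non-histone baselines are rescaled so
#' that histones make up `histone_mass_fraction` of naive-cell protein mass.
#'
#' @param n_proteins Total number of protein groups (including histones).
#' @param design Sample design; its conditions define the columns of the
#'   truth table.
#' @param class_fractions Named numeric vector over the five effect classes,
#'   summing to 1 (tolerance 1e-9).
#' @param induced_fold,down_fold Planted fold changes for the induced and
#'   downregulated classes.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   copies per cell.
#' @param histone_mass_fraction Fraction of naive-cell protein mass carried by
#'   histones.
#' @param noise_sigma_log2 Measurement noise (log2 units) recorded for
#'   [simulate_intensities()].
#' @param missing_rate Probability that a detected-in-truth intensity is
#'   missing at random in the simulated table.
#' @param n_decoys,n_contaminants,n_only_site Numbers of reverse-decoy,
#'   contaminant and identified-only-by-site rows to append.
#' @param ruler [ruler_config()] the histone planting is calibrated against.
#' @param seed Integer seed; the truth is deterministic given the seed.
#' @return A list of class `ground_truth` with elements `proteins` (metadata:
#'   `protein_id`, `gene_name`, `mol_weight_da`, `is_histone`,
#'   `effect_class`), `copies` (long tibble `protein_id`, `condition`,
#'   `true_copies`), `conditions`, `params` and `ruler`.
#' @export
make_ground_truth <- function(n_proteins = 2000,
                              design = make_sample_design(),
                              class_fractions = c(myc_dependent_induced = 0.10,
                                                  myc_independent_induced = 0.06,
                                                  downregulated = 0.10,
                                                  unchanged = 0.72,
                                                  histone = 0.02),
                              induced_fold = 4,
                              down_fold = 4,
                              baseline_meanlog = log(3000),
                              baseline_sdlog = 1.2,
                              histone_mass_fraction = 0.04,
                              noise_sigma_log2 = 0.25,
                              missing_rate = 0.05,
                              n_decoys = 20,
                              n_contaminants = 20,
                              n_only_site = 10,
                              ruler = ruler_config(),
                              seed = 1) {
  classes <- c("myc_dependent_induced", "myc_independent_induced",
               "downregulated", "unchanged", "histone")
  stopifnot(setequal(names(class_fractions), classes),
            n_proteins >= 10, induced_fold > 0, down_fold > 0,
            histone_mass_fraction > 0, histone_mass_fraction < 1,
            noise_sigma_log2 >= 0, missing_rate >= 0, missing_rate <= 1)
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  set.seed(as.integer(seed))

  # integer class sizes that sum exactly to n_proteins
  counts <- diff(c(0L, round(cumsum(class_fractions[classes]) * n_proteins)))
  names(counts) <- classes
  effect_class <- factor(rep(classes, times = counts), levels = classes)
  is_histone <- effect_class == "histone"
  n_hist <- sum(is_histone)
  if (n_hist < 1) {
    stop("class_fractions must plant at least one histone", call. = FALSE)
  }

  hist_names <- c("Hist1h1b", "Hist1h1e", "Hist1h2ag", "Hist1h2bc",
                  "Hist1h3a", "Hist1h4a", "Hist2h2aa1", "Hist2h2be",
                  "H2afz", "H3f3a", "H2afv", "Hist1h2bk", "Hist1h4d",
                  "Hist1h2ab", "Hist1h3b", "Hist1h1c")
  gene_name <- sprintf("Gene%05d", seq_len(n_proteins))
  gene_name[is_histone] <- paste0(
    rep_len(hist_names, n_hist),
    ifelse(seq_len(n_hist) > length(hist_names),
           paste0(".", seq_len(n_hist)), "")
  )

  mol_weight_da <- rlnorm(n_proteins, meanlog = log(5e4), sdlog = 0.45)
  mol_weight_da[is_histone] <- runif(n_hist, 11000, 22000)
  baseline <- rlnorm(n_proteins, meanlog = baseline_meanlog,
                     sdlog = baseline_sdlog)

  # calibrate histone copies: summed histone mass == the ruler standard
  m_hist <- histone_mass_per_cell(ruler)
  w <- runif(n_hist, 0.2, 1)
  hist_mw <- mol_weight_da[is_histone]
  baseline[is_histone] <- w * (m_hist * ruler$avogadro) / sum(w * hist_mw)

  # scale non-histone baselines: histones are `histone_mass_fraction` of
  # naive-cell mass (naive copies equal the baseline for every class)
  nh <- !is_histone
  target_mass <- m_hist * (1 / histone_mass_fraction - 1)
  naive_mass <- sum(baseline[nh] * mol_weight_da[nh]) / ruler$avogadro
  baseline[nh] <- baseline[nh] * target_mass / naive_mass

  proteins <- tibble::tibble(
    protein_id = sprintf("P%05d", seq_len(n_proteins)),
    gene_name = gene_name,
    mol_weight_da = mol_weight_da,
    is_histone = is_histone,
    effect_class = effect_class,
    baseline_copies = baseline
  )

  conditions <- dplyr::distinct(condition_id(design), .data$condition,
                                .data$genotype, .data$cell_type,
                                .data$stimulation)
  copies <- tidyr::expand_grid(protein_id = proteins$protein_id,
                               condition = conditions$condition)
  copies <- dplyr::left_join(copies, conditions, by = "condition")
  copies <- dplyr::left_join(
    copies,
    proteins[c("protein_id", "effect_class", "baseline_copies")],
    by = "protein_id"
  )
  activated <- copies$stimulation == "TCR"
  wildtype <- copies$genotype == "WT"
  fold <- rep(1, nrow(copies))
  fold[copies$effect_class == "myc_dependent_induced" & activated & wildtype] <-
    induced_fold
  fold[copies$effect_class == "myc_independent_induced" & activated] <-
    induced_fold
  fold[copies$effect_class == "downregulated" & activated] <- 1 / down_fold
  copies$true_copies <- copies$baseline_copies * fold

  structure(
    list(
      proteins = proteins,
      copies = copies[c("protein_id", "condition", "true_copies")],
      conditions = conditions,
      params = list(induced_fold = induced_fold, down_fold = down_fold,
                    histone_mass_fraction = histone_mass_fraction,
                    noise_sigma_log2 = noise_sigma_log2,
                    missing_rate = missing_rate, n_decoys = n_decoys,
                    n_contaminants = n_contaminants,
                    n_only_site = n_only_site, seed = as.integer(seed)),
      ruler = ruler
    ),
    class = "ground_truth"
  )
}

# draw razor+unique / unique peptide counts whose quality category matches
# `target` ("high", "medium", "low"); vectorised rejection sampling
draw_peptide_counts <- function(target, cfg) {
  n <- length(target)
  razor <- integer(n)
  unique_p <- integer(n)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    k <- sum(todo)
    r <- sample(1:16, k, replace = TRUE)
    u <- rbinom(k, r, 0.7)
    q <- as.character(assign_quality(r, u, cfg))
    ok <- q == target[todo]
    idx <- which(todo)[ok]
    razor[idx] <- r[ok]
    unique_p[idx] <- u[ok]
    todo[idx] <- FALSE
  }
  list(razor = razor, unique = unique_p)
}

#' Simulate a label-free intensity table from a planted truth
#'
#' Intensity is modelled as proportional to protein mass — the ruler's own
#' assumption: `I(sample, protein) = k(sample) * true_copies(condition) * MW *
#' 2^eps`, with `eps ~ Normal(0, noise_sigma_log2)` and an arbitrary
#' per-sample scale `k(sample)` spanning an order of magnitude (the histone
#' normalisation must cancel it). Each intensity is independently set to
#' missing with probability `missing_rate`. Reverse-decoy, contaminant and
#' site-only rows are appended with their flags set, and peptide counts are
#' drawn to cover all three quality categories.
#'
#' @param truth A `ground_truth` from [make_ground_truth()].
#' @param design Sample design; every condition in the design must exist in
#'   the truth.
#' @param seed Integer seed for the noise draws (independent of the truth's
#'   seed, so one truth can be measured repeatedly).
#' @return A protein-groups tibble in the shape returned by
#'   [read_protein_groups()].
#' @export
simulate_intensities <- function(truth, design, seed = truth$params$seed + 1) {
  stopifnot(inherits(truth, "ground_truth"))
  des <- condition_id(design)
  missing_conds <- setdiff(des$condition, unique(truth$copies$condition))
  if (length(missing_conds) > 0) {
    stop("design condition(s) absent from ground truth: ",
         paste(sQuote(missing_conds), collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  p <- truth$params
  prot <- truth$proteins
  n_p <- nrow(prot)
  n_s <- nrow(des)

  cmat <- matrix(0, n_p, n_s, dimnames = list(prot$protein_id, des$sample_id))
  wide <- tidyr::pivot_wider(truth$copies, names_from = "condition",
                             values_from = "true_copies")
  wide <- wide[match(prot$protein_id, wide$protein_id), ]
  for (j in seq_len(n_s)) {
    cmat[, j] <- wide[[des$condition[j]]]
  }

  k <- 10^runif(n_s, -0.5, 0.5)
  noise <- matrix(2^rnorm(n_p * n_s, sd = p$noise_sigma_log2), n_p, n_s)
  imat <- sweep(cmat * noise, 1, prot$mol_weight_da, "*")
  imat <- sweep(imat, 2, k, "*")
  imat[cmat <= 0] <- NA_real_
  if (p$missing_rate > 0) {
    drop <- matrix(runif(n_p * n_s) < p$missing_rate, n_p, n_s)
    imat[drop] <- NA_real_
  }

  target <- rep_len(c("high", "medium", "low"), n_p)[sample.int(n_p)]
  pep <- draw_peptide_counts(target, ruler_config())

  groups <- tibble::tibble(
    group_id = prot$protein_id,
    gene_name = prot$gene_name,
    mol_weight_da = prot$mol_weight_da,
    razor_unique_peptides = pep$razor,
    unique_peptides = pep$unique,
    flag_contaminant = FALSE,
    flag_reverse = FALSE,
    flag_only_by_site = FALSE
  )
  for (j in seq_len(n_s)) {
    groups[[des$sample_id[j]]] <- imat[, j]
  }

  decoy_block <- function(n, prefix, gene_prefix, contaminant, reverse,
                          only_site) {
    if (n == 0) return(NULL)
    blk <- tibble::tibble(
      group_id = sprintf("%s%05d", prefix, seq_len(n)),
      gene_name = sprintf("%s%03d", gene_prefix, seq_len(n)),
      mol_weight_da = rlnorm(n, log(4e4), 0.5),
      razor_unique_peptides = sample(1:6, n, replace = TRUE),
      unique_peptides = 0L,
      flag_contaminant = contaminant,
      flag_reverse = reverse,
      flag_only_by_site = only_site
    )
    blk$unique_peptides <- rbinom(n, blk$razor_unique_peptides, 0.5)
    fake <- rlnorm(n, log(stats::median(imat, na.rm = TRUE)), 1)
    for (j in seq_len(n_s)) {
      x <- fake * k[j] * 2^rnorm(n, sd = max(p$noise_sigma_log2, 0.1))
      x[runif(n) < 0.3] <- NA_real_
      blk[[des$sample_id[j]]] <- x
    }
    blk
  }

  dplyr::bind_rows(
    groups,
    decoy_block(p$n_contaminants, "CON__P", "Con", TRUE, FALSE, FALSE),
    decoy_block(p$n_decoys, "REV__P", "Rev", FALSE, TRUE, FALSE),
    decoy_block(p$n_only_site, "SIT__P", "Sit", FALSE, FALSE, TRUE)
  )
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper bundling [make_sample_design()], [make_ground_truth()]
#' and [simulate_intensities()] with one top-level seed (the truth uses
#' `seed`, the measurement noise `seed + 1`).
#'
#' @param n_proteins Number of protein groups.
#' @param cell_types,genotypes,n_replicates Design layout
#'   (see [make_sample_design()]).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [make_ground_truth()].
#' @return A list with `truth`, `design` and `groups`.
#' @export
simulate_dataset <- function(n_proteins = 2000,
                             cell_types = c("CD4", "CD8"),
                             genotypes = c("WT", "Myc_cKO"),
                             n_replicates = 3,
                             seed = 1, ...) {
  design <- make_sample_design(genotypes = genotypes, cell_types = cell_types,
                               n_replicates = n_replicates)
  truth <- make_ground_truth(n_proteins = n_proteins, design = design,
                             seed = seed, ...)
  groups <- simulate_intensities(truth, design, seed = seed + 1)
  list(truth = truth, design = design, groups = groups)
}
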
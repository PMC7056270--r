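#' Configuration of the histone-ruler copy-number estimator
#'
#' Physical constants and conventions of the proteomic ruler. The ruler anchors
#' the summed MS intensity of the histones to the histone mass expected in a
#' cell from its DNA content: for a diploid mouse cell, histone mass is taken
#' equal to the mass of the genomic DNA, `ploidy * genome_size_bp *
#' bp_molar_mass / avogadro` grams. All constants are configuration fields so
#' that other genomes, ploidies or an externally measured histone mass can be
#' used.
#'
#' Quality categories follow the standard peptide-count rules: a protein group
#' is `high` accuracy with at least 8 razor+unique peptides of which at least
#' 75% are unique, `medium` with at least 3 razor+unique peptides of which at
#' least 50% are unique, and `low` otherwise.
#'
#' @param avogadro Avogadro's constant, mol^-1.
#' @param genome_size_bp Haploid genome size in base pairs (default: mouse).
#' @param ploidy Genome copies per cell (default 2, a diploid cell).
#' @param bp_molar_mass Average molar mass of one DNA base pair, g/mol.
#' @param histone_patterns Gene-name regular expressions (case-insensitive)
#'   identifying core and linker histone families.
#' @param histone_mass_g Optional explicit histone mass per cell in grams;
#'   when set it overrides the DNA-derived value.
#' @param min_detected_replicates Minimum biological replicates of at least
#'   one condition in which a protein must be detected to be retained.
#' @param high_quality,medium_quality Lists with `min_peptides` and
#'   `min_unique_fraction` defining the quality categories; `high` must be at
#'   least as strict as `medium` in both components.
#' @return A list of class `ruler_config`.
#' @export
ruler_config <- function(avogadro = 6.02214076e23,
                         genome_size_bp = 2.73e9,
                         ploidy = 2,
                         bp_molar_mass = 615.8771,
                         histone_patterns = c("^H1", "^H2a", "^H2b", "^H3",
                                              "^H4", "^Hist"),
                         histone_mass_g = NULL,
                         min_detected_replicates = 2L,
                         high_quality = list(min_peptides = 8,
                                             min_unique_fraction = 0.75),
                         medium_quality = list(min_peptides = 3,
                                               min_unique_fraction = 0.50)) {
  stopifnot(avogadro > 0, genome_size_bp > 0, ploidy > 0, bp_molar_mass > 0,
            min_detected_replicates >= 1,
            is.null(histone_mass_g) || histone_mass_g > 0)
  if (high_quality$min_peptides < medium_quality$min_peptides ||
      high_quality$min_unique_fraction < medium_quality$min_unique_fraction) {
    stop("high-quality thresholds must be at least as strict as medium",
         call. = FALSE)
  }
  structure(
    list(avogadro = avogadro, genome_size_bp = genome_size_bp, ploidy = ploidy,
         bp_molar_mass = bp_molar_mass, histone_patterns = histone_patterns,
         histone_mass_g = histone_mass_g,
         min_detected_replicates = as.integer(min_detected_replicates),
         high_quality = high_quality, medium_quality = medium_quality),
    class = "ruler_config"
  )
}

#' Histone mass per cell implied by DNA content
#'
#' The ruler's internal standard: the expected total histone mass in one cell,
#' taken equal to the mass of its genomic DNA (histone:DNA mass ratio 1:1).
#' With the defaults for a diploid mouse cell this is about 5.58e-12 g.
#'
#' @param cfg A [ruler_config()].
#' @return Histone mass per cell in grams.
#' @examples
#' histone_mass_per_cell(ruler_config())
#' @export
histone_mass_per_cell <- function(cfg = ruler_config()) {
  if (!is.null(cfg$histone_mass_g)) {
    return(cfg$histone_mass_g)
  }
  cfg$ploidy * cfg$genome_size_bp * cfg$bp_molar_mass / cfg$avogadro
}

#' Does a gene name match the histone patterns?
#'
#' @param gene_name Character vector of gene names.
#' @param cfg A [ruler_config()].
#' @return Logical vector.
#' @export
is_histone_gene <- function(gene_name, cfg = ruler_config()) {
  hit <- rep(FALSE, length(gene_name))
  for (pat in cfg$histone_patterns) {
    hit <- hit | grepl(pat, gene_name, ignore.case = TRUE)
  }
  hit & !is.na(gene_name)
}

#' Quantification quality category from peptide counts
#'
#' @param razor_unique_peptides,unique_peptides Integer vectors; unique counts
#'   never exceed razor+unique counts.
#' @param cfg A [ruler_config()].
#' @return Factor with levels `high`, `medium`, `low`.
#' @export
assign_quality <- function(razor_unique_peptides, unique_peptides,
                           cfg = ruler_config()) {
  stopifnot(length(razor_unique_peptides) == length(unique_peptides))
  if (any(unique_peptides > razor_unique_peptides)) {
    stop("unique peptide counts exceed razor+unique counts", call. = FALSE)
  }
  frac <- ifelse(razor_unique_peptides > 0,
                 unique_peptides / razor_unique_peptides, 0)
  hi <- razor_unique_peptides >= cfg$high_quality$min_peptides &
    frac >= cfg$high_quality$min_unique_fraction
  med <- !hi & razor_unique_peptides >= cfg$medium_quality$min_peptides &
    frac >= cfg$medium_quality$min_unique_fraction
  factor(ifelse(hi, "high", ifelse(med, "medium", "low")),
         levels = c("high", "medium", "low"))
}

#' Remove contaminant, reverse-decoy and site-only protein groups
#'
#' Drops every row carrying any of the three flags, preserving row order. The
#' number of rows carrying each flag (rows with several flags are counted
#' under each) is attached as attribute `removed`.
#'
#' @param groups Protein-groups tibble (see [read_protein_groups()]).
#' @return The filtered tibble with a `removed` attribute
#'   (`contaminant`, `reverse`, `only_by_site` counts).
#' @export
filter_groups <- function(groups) {
  flagged <- groups$flag_contaminant | groups$flag_reverse |
    groups$flag_only_by_site
  out <- groups[!flagged, , drop = FALSE]
  attr(out, "removed") <- c(
    contaminant = sum(groups$flag_contaminant),
    reverse = sum(groups$flag_reverse),
    only_by_site = sum(groups$flag_only_by_site)
  )
  out
}

# Intensity matrix (proteins x samples) in design order; errors if a design
# sample has no intensity column.
intensity_matrix <- function(groups, design) {
  missing <- setdiff(design$sample_id, names(groups))
  if (length(missing) > 0) {
    stop("no intensity column for design sample(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(groups[design$sample_id])
  storage.mode(m) <- "double"
  rownames(m) <- groups$group_id
  m
}

#' Keep proteins detected in enough replicates of some condition
#'
#' A protein is retained if, in at least one condition, it has a positive
#' intensity in at least `cfg$min_detected_replicates` biological replicates.
#'
#' @param groups Protein-groups tibble.
#' @param design Sample design covering all intensity columns.
#' @param cfg A [ruler_config()].
#' @return The filtered tibble, order preserved.
#' @export
detection_filter <- function(groups, design, cfg = ruler_config()) {
  des <- condition_id(design)
  det <- !is.na(intensity_matrix(groups, des))
  max_reps <- rep(0L, nrow(groups))
  for (cond in unique(des$condition)) {
    cols <- which(des$condition == cond)
    max_reps <- pmax(max_reps, rowSums(det[, cols, drop = FALSE]))
  }
  groups[max_reps >= cfg$min_detected_replicates, , drop = FALSE]
}

#' Estimate protein copies and mass per cell with the histone ruler
#'
#' For each sample the summed intensity of the histone groups is equated to
#' the histone mass per cell ([histone_mass_per_cell()]); every other group's
#' mass is its intensity share of that standard, and copies follow from the
#' molecular weight: `copies = mass * N_A / MW`. Because only intensity ratios
#' within a sample enter the estimate, any global per-sample intensity scale
#' cancels. Not-detected intensities yield zero copies and `detected = FALSE`.
#'
#' @param groups Protein-groups tibble (after filtering; histone groups are
#'   identified among these rows by gene name).
#' @param design Sample design.
#' @param cfg A [ruler_config()].
#' @return A long tibble, one row per protein group and sample: `group_id`,
#'   `gene_name`, `mol_weight_da`, `quality`, `is_histone`, `sample_id`,
#'   `condition`, `replicate`, `detected`, `copies_per_cell`,
#'   `mass_per_cell_g`. The histone group ids used as the internal standard
#'   are attached as attribute `histones_used`.
#' @export
estimate_copy_numbers <- function(groups, design, cfg = ruler_config()) {
  des <- condition_id(design)
  imat <- intensity_matrix(groups, des)
  hist_rows <- is_histone_gene(groups$gene_name, cfg)
  if (!any(hist_rows)) {
    stop("no histone groups found (patterns: ",
         paste(cfg$histone_patterns, collapse = ", "),
         "); the ruler is undefined", call. = FALSE)
  }
  izero <- imat
  izero[is.na(izero)] <- 0
  histone_sum <- colSums(izero[hist_rows, , drop = FALSE])
  if (any(histone_sum <= 0)) {
    bad <- des$sample_id[histone_sum <= 0]
    stop("no detected histone intensity in sample(s) ",
         paste(sQuote(bad), collapse = ", "), "; the ruler is undefined",
         call. = FALSE)
  }

  m_hist <- histone_mass_per_cell(cfg)
  mass <- sweep(izero, 2, histone_sum, "/") * m_hist
  copies <- sweep(mass, 1, groups$mol_weight_da, "/") * cfg$avogadro

  n_p <- nrow(groups)
  n_s <- nrow(des)
  out <- tibble::tibble(
    group_id = rep(groups$group_id, times = n_s),
    gene_name = rep(groups$gene_name, times = n_s),
    mol_weight_da = rep(groups$mol_weight_da, times = n_s),
    quality = rep(assign_quality(groups$razor_unique_peptides,
                                 groups$unique_peptides, cfg), times = n_s),
    is_histone = rep(hist_rows, times = n_s),
    sample_id = rep(des$sample_id, each = n_p),
    condition = rep(des$condition, each = n_p),
    replicate = rep(des$replicate, each = n_p),
    detected = as.vector(!is.na(imat)),
    copies_per_cell = as.vector(copies),
    mass_per_cell_g = as.vector(mass)
  )
  attr(out, "histones_used") <- groups$group_id[hist_rows]
  out
}

#' Per-condition mean copy numbers and masses
#'
#' Arithmetic means over a condition's biological replicates, counting
#' not-detected replicates as zero copies. Detection is summarised separately
#' in `n_detected` so filters can still act on it.
#'
#' @param records Copy-number records from [estimate_copy_numbers()].
#' @return A tibble with one row per protein group and condition: mean copies,
#'   mean mass (g/cell), `n_detected` and `n_replicates`.
#' @export
condition_means <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, .data$group_id, .data$gene_name,
                    .data$mol_weight_da, .data$quality, .data$condition),
    mean_copies = mean(.data$copies_per_cell),
    mean_mass_g = mean(.data$mass_per_cell_g),
    n_detected = sum(.data$detected),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
}

#' Total protein content per condition
#'
#' Sums estimated protein mass over all groups in each sample and averages
#' over a condition's replicates, reported in the conventional unit of
#' micrograms per million cells (1 g/cell = 1e12 ug per 1e6 cells).
#'
#' @param records Copy-number records from [estimate_copy_numbers()].
#' @return A tibble with `condition` and `total_protein_ug_per_million`.
#' @export
total_protein_content <- function(records) {
  stopifnot(nrow(records) > 0)
  per_sample <- dplyr::summarise(
    dplyr::group_by(records, .data$condition, .data$sample_id),
    total_g = sum(.data$mass_per_cell_g),
    .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(per_sample, .data$condition),
    total_protein_ug_per_million = mean(.data$total_g) * 1e12,
    .groups = "drop"
  )
}
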
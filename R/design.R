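#' Build a sample design for a knockout activation study
#'
#' Constructs the sample-to-condition mapping used throughout the package.
#' The default layout mirrors a conditional-knockout T cell activation
#' experiment: ex vivo naive wild-type cells plus TCR-activated cells of every
#' genotype, in biological replicate, for one or more cell types. Naive cells
#' are profiled for the baseline genotype only, so the naive wild-type samples
#' serve as the shared resting reference for all activated conditions.
#'
#' @param genotypes Character vector of genotypes. Must contain
#'   `naive_genotype`; any additional entries (e.g. `"Myc_cKO"`,
#'   `"Slc7a5_cKO"`) are profiled in the activated state only.
#' @param cell_types Character vector of cell types (e.g. `c("CD4", "CD8")`).
#' @param n_replicates Number of biological replicates per condition.
#' @param naive_genotype Genotype profiled in the naive (resting) state.
#'
#' @return A tibble with columns `sample_id`, `genotype`, `cell_type`,
#'   `stimulation` and `replicate`. `sample_id` is
#'   `<cell_type>.<genotype>.<stimulation>.<replicate>`.
#' @examples
#' make_sample_design(cell_types = "CD8", n_replicates = 3)
#' @export
make_sample_design <- function(genotypes = c("WT", "Myc_cKO"),
                               cell_types = c("CD4", "CD8"),
                               n_replicates = 3,
                               naive_genotype = "WT") {
  stopifnot(n_replicates >= 1, naive_genotype %in% genotypes)
  conds <- dplyr::bind_rows(
    tidyr::expand_grid(cell_type = cell_types, genotype = naive_genotype,
                       stimulation = "naive"),
    tidyr::expand_grid(cell_type = cell_types, genotype = genotypes,
                       stimulation = "TCR")
  )
  design <- tidyr::expand_grid(conds, replicate = seq_len(n_replicates))
  design <- dplyr::mutate(
    design,
    sample_id = paste(.data$cell_type, .data$genotype, .data$stimulation,
                      .data$replicate, sep = "."),
    .before = 1
  )
  validate_sample_design(design)
}

#' Read a sample-design table
#'
#' Reads a tab-separated design table with columns `sample_id`, `genotype`,
#' `cell_type`, `stimulation` and `replicate`, and validates that the
#' (genotype, cell type, stimulation, replicate) tuples are unique.
#'
#' @param path Path to a TSV file.
#' @return A validated design tibble (see [make_sample_design()]).
#' @export
read_sample_design <- function(path) {
  design <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "genotype", "cell_type", "stimulation", "replicate")
  missing <- setdiff(required, names(design))
  if (length(missing) > 0) {
    stop("sample design is missing required column(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  design$replicate <- as.integer(design$replicate)
  validate_sample_design(design[required])
}

validate_sample_design <- function(design) {
  key <- paste(design$genotype, design$cell_type, design$stimulation,
               design$replicate)
  if (anyDuplicated(key) > 0) {
    stop("sample design has duplicated (genotype, cell_type, stimulation, ",
         "replicate) combinations", call. = FALSE)
  }
  if (anyDuplicated(design$sample_id) > 0) {
    stop("sample design has duplicated sample_id values", call. = FALSE)
  }
  if (any(design$replicate < 1)) {
    stop("replicate numbers must be positive integers", call. = FALSE)
  }
  cols <- c("sample_id", "genotype", "cell_type", "stimulation", "replicate")
  tibble::as_tibble(design)[cols]
}

#' Add a condition identifier to a design table
#'
#' A condition is the combination of cell type, genotype and stimulation;
#' replicates of one condition share its identifier. The identifier is
#' `<cell_type>.<genotype>.<stimulation>`, e.g. `"CD8.WT.TCR"`.
#'
#' @param design A design tibble (see [make_sample_design()]).
#' @return The design with a `condition` column appended.
#' @export
condition_id <- function(design) {
  dplyr::mutate(
    design,
    condition = paste(.data$cell_type, .data$genotype, .data$stimulation,
                      sep = ".")
  )
}
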
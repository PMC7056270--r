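#' Column dialect for protein-groups tables
#'
#' Search-engine output tables name their columns slightly differently across
#' software versions. The dialect maps the roles this package needs onto
#' concrete header strings; the defaults match the public MaxQuant
#' `proteinGroups.txt` headers. Per-sample intensity columns are recognised by
#' prefix: `"Intensity <sample_id>"` (the bare summed `"Intensity"` column is
#' ignored because the prefix includes the trailing space).
#'
#' @param majority_ids,gene_names,mol_weight,razor_unique,unique_peptides
#'   Header strings for the group accessions, gene names, molecular weight in
#'   kDa, razor+unique peptide count and unique peptide count columns.
#' @param contaminant,reverse,only_site Header strings for the three flag
#'   columns (encoded `"+"` / empty).
#' @param intensity_prefix Prefix identifying per-sample intensity columns;
#'   the remainder of the header is taken as the sample id.
#' @return A named list of class `pg_dialect`.
#' @export
pg_dialect <- function(majority_ids = "Majority protein IDs",
                       gene_names = "Gene names",
                       mol_weight = "Mol. weight [kDa]",
                       razor_unique = "Razor + unique peptides",
                       unique_peptides = "Unique peptides",
                       contaminant = "Potential contaminant",
                       reverse = "Reverse",
                       only_site = "Only identified by site",
                       intensity_prefix = "Intensity ") {
  structure(
    list(majority_ids = majority_ids, gene_names = gene_names,
         mol_weight = mol_weight, razor_unique = razor_unique,
         unique_peptides = unique_peptides, contaminant = contaminant,
         reverse = reverse, only_site = only_site,
         intensity_prefix = intensity_prefix),
    class = "pg_dialect"
  )
}

#' Read a protein-groups table
#'
#' Parses a tab-separated protein-groups table (MaxQuant `proteinGroups.txt`
#' dialect) into the tidy representation used by the quantification functions:
#' one row per protein group with metadata columns plus one numeric intensity
#' column per sample. Molecular weights are converted from kDa to Da. Missing,
#' non-numeric and zero intensity cells all mean "not detected" and are stored
#' as `NA`. Flag cells `"+"` become `TRUE`, anything else `FALSE`. For groups
#' listing several accessions the leading accession becomes `group_id`. Rows
#' are returned in file order and never dropped.
#'
#' @param path Path to the TSV file.
#' @param dialect A [pg_dialect()] mapping column roles to header strings.
#' @return A tibble with columns `group_id`, `gene_name`, `mol_weight_da`,
#'   `razor_unique_peptides`, `unique_peptides`, `flag_contaminant`,
#'   `flag_reverse`, `flag_only_by_site`, then one intensity column per sample
#'   (named by sample id).
#' @export
read_protein_groups <- function(path, dialect = pg_dialect()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  mandatory <- c("majority_ids", "gene_names", "mol_weight", "razor_unique",
                 "unique_peptides", "contaminant", "reverse", "only_site")
  for (role in mandatory) {
    if (!dialect[[role]] %in% names(raw)) {
      stop("protein-groups table is missing mandatory column ",
           sQuote(dialect[[role]]), " (dialect role ", sQuote(role), ")",
           call. = FALSE)
    }
  }

  int_cols <- names(raw)[startsWith(names(raw), dialect$intensity_prefix)]
  sample_ids <- substring(int_cols, nchar(dialect$intensity_prefix) + 1L)

  mw_kda <- suppressWarnings(as.numeric(raw[[dialect$mol_weight]]))
  bad_mw <- which(!is.finite(mw_kda) | mw_kda <= 0)
  if (length(bad_mw) > 0) {
    stop("non-positive or unparseable molecular weight in row(s): ",
         paste(head(bad_mw, 5), collapse = ", "), call. = FALSE)
  }

  parse_flag <- function(col) {
    x <- raw[[col]]
    !is.na(x) & trimws(x) == "+"
  }
  parse_count <- function(col) {
    x <- suppressWarnings(as.integer(raw[[col]]))
    x[is.na(x)] <- 0L
    x
  }

  out <- tibble::tibble(
    group_id = vapply(strsplit(raw[[dialect$majority_ids]], ";", fixed = TRUE),
                      function(x) trimws(x[[1]]), character(1)),
    gene_name = trimws(raw[[dialect$gene_names]]),
    mol_weight_da = mw_kda * 1000,
    razor_unique_peptides = parse_count(dialect$razor_unique),
    unique_peptides = parse_count(dialect$unique_peptides),
    flag_contaminant = parse_flag(dialect$contaminant),
    flag_reverse = parse_flag(dialect$reverse),
    flag_only_by_site = parse_flag(dialect$only_site)
  )
  for (i in seq_along(int_cols)) {
    x <- suppressWarnings(as.numeric(raw[[int_cols[i]]]))
    x[!is.finite(x) | x <= 0] <- NA_real_
    out[[sample_ids[i]]] <- x
  }
  out
}

#' Write a protein-groups table in the search-engine dialect
#'
#' Inverse of [read_protein_groups()]: serialises the tidy protein-groups
#' tibble back to the tab-separated dialect, writing not-detected intensities
#' as `0`, flags as `"+"`/empty and molecular weights in kDa. Used by the
#' synthetic-data generator so that simulated tables exercise the same parser
#' as real data.
#'
#' @param groups Protein-groups tibble as returned by [read_protein_groups()].
#' @param path Output file path.
#' @param dialect A [pg_dialect()].
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(groups, path, dialect = pg_dialect()) {
  meta <- c("group_id", "gene_name", "mol_weight_da", "razor_unique_peptides",
            "unique_peptides", "flag_contaminant", "flag_reverse",
            "flag_only_by_site")
  stopifnot(all(meta %in% names(groups)))
  sample_ids <- setdiff(names(groups), meta)
  out <- tibble::tibble(
    !!dialect$majority_ids := groups$group_id,
    !!dialect$gene_names := groups$gene_name,
    !!dialect$mol_weight := groups$mol_weight_da / 1000,
    !!dialect$razor_unique := groups$razor_unique_peptides,
    !!dialect$unique_peptides := groups$unique_peptides,
    !!dialect$contaminant := ifelse(groups$flag_contaminant, "+", ""),
    !!dialect$reverse := ifelse(groups$flag_reverse, "+", ""),
    !!dialect$only_site := ifelse(groups$flag_only_by_site, "+", "")
  )
  for (sid in sample_ids) {
    x <- groups[[sid]]
    x[is.na(x)] <- 0
    out[[paste0(dialect$intensity_prefix, sid)]] <- x
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Writes any non-empty result table (copy numbers, differential results, rank
#' profiles, heatmap matrices...) as tab-separated UTF-8 with a header row and
#' deterministic column order. Reals are serialised at full double precision
#' (15 significant digits), so re-reading reproduces the values; undefined
#' numbers (e.g. p-values from degenerate tests) are written as the literal
#' `NA`.
#'
#' @param records A data frame with at least one row.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("refusing to write an empty result table to ", sQuote(path),
         call. = FALSE)
  }
  readr::write_tsv(records, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
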
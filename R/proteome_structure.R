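#' Cumulative mass-rank profile of one condition
#'
#' Ranks proteins by descending mean mass per cell in a condition (mean over
#' replicates, not-detected counted as zero) and accumulates their mass
#' fractions, yielding the classic mass-dominance curve: a handful of very
#' abundant proteins carries most of cellular protein mass. Quartile counts
#' give the number of proteins needed to reach 25/50/75/100% of total mass
#' (cumulative: each count includes the proteins of the quartiles below), and
#' the top-75% set is the smallest descending-mass prefix reaching 75% of
#' total mass. Ties in mass are broken by group id, so the profile is
#' independent of input row order.
#'
#' @param records Copy-number records from [estimate_copy_numbers()].
#' @param condition Condition identifier.
#' @return A list of class `mass_rank_profile`: `condition`, `table` (rank,
#'   `group_id`, `gene_name`, `mean_mass_g`, `mass_fraction`,
#'   `cumulative_fraction`), `quartile_counts` (named q25/q50/q75/q100) and
#'   `top75_set`.
#' @export
mass_rank_profile <- function(records, condition) {
  cm <- condition_means(records[records$condition == condition, ])
  if (nrow(cm) == 0) {
    stop("condition ", sQuote(condition), " has no copy-number records",
         call. = FALSE)
  }
  total <- sum(cm$mean_mass_g)
  if (total <= 0) {
    stop("all mean masses are zero in condition ", sQuote(condition),
         call. = FALSE)
  }
  ord <- order(-cm$mean_mass_g, cm$group_id)
  cm <- cm[ord, ]
  frac <- cm$mean_mass_g / total
  cum <- cumsum(frac)
  quartiles <- c(0.25, 0.50, 0.75, 1.00)
  counts <- vapply(quartiles,
                   function(q) which(cum >= q - 1e-12)[1], integer(1))
  tab <- tibble::tibble(
    rank = seq_len(nrow(cm)),
    group_id = cm$group_id,
    gene_name = cm$gene_name,
    mean_mass_g = cm$mean_mass_g,
    mass_fraction = frac,
    cumulative_fraction = cum
  )
  structure(
    list(condition = condition, table = tab,
         quartile_counts = setNames(counts, c("q25", "q50", "q75", "q100")),
         top75_set = cm$group_id[seq_len(counts[3])]),
    class = "mass_rank_profile"
  )
}

#' Mass carried by a gene set, per condition
#'
#' Aggregates estimated protein mass over a user-supplied gene set (e.g. the
#' glycolytic enzymes), reporting per condition both the absolute content in
#' micrograms per million cells and the percentage of total cellular protein
#' mass. Gene names are matched case-insensitively. Set members without a
#' matching protein group are reported in the `unmatched` attribute; a set
#' with no matches at all yields a warning and a zero summary rather than an
#' error.
#'
#' @param records Copy-number records from [estimate_copy_numbers()].
#' @param gene_set Non-empty character vector of gene names.
#' @return A tibble with `condition`, `set_mass_ug_per_million`,
#'   `total_mass_ug_per_million` and `percent_of_total_mass`; unmatched gene
#'   names are attached as attribute `unmatched`.
#' @export
pathway_mass_summary <- function(records, gene_set) {
  stopifnot(length(gene_set) > 0)
  in_set <- tolower(records$gene_name) %in% tolower(gene_set)
  unmatched <- gene_set[!tolower(gene_set) %in% tolower(records$gene_name)]
  if (!any(in_set)) {
    warning("no protein group matches the gene set; reporting zero mass",
            call. = FALSE)
  }
  rec_set <- records[in_set, ]
  set_per_sample <- dplyr::summarise(
    dplyr::group_by(rec_set, .data$condition, .data$sample_id),
    set_g = sum(.data$mass_per_cell_g),
    .groups = "drop"
  )
  tot_per_sample <- dplyr::summarise(
    dplyr::group_by(records, .data$condition, .data$sample_id),
    total_g = sum(.data$mass_per_cell_g),
    .groups = "drop"
  )
  per_sample <- dplyr::left_join(tot_per_sample, set_per_sample,
                                 by = c("condition", "sample_id"))
  per_sample$set_g[is.na(per_sample$set_g)] <- 0
  out <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$condition),
    set_mass_ug_per_million = mean(.data$set_g) * 1e12,
    total_mass_ug_per_million = mean(.data$total_g) * 1e12,
    .groups = "drop"
  )
  out$percent_of_total_mass <- 100 * out$set_mass_ug_per_million /
    out$total_mass_ug_per_million
  attr(out, "unmatched") <- unmatched
  out
}

#' Min-max scaled, correlation-clustered heatmap matrix
#'
#' Builds the matrix behind a relative-abundance heatmap. Proteins are
#' included if, in the conditions of the reference cell type, at least one
#' condition has a mean of at least `min_mean_copies` copies per cell and at
#' least one condition has detections in at least `min_reps` biological
#' replicates. Each included row (condition means across *all* conditions) is
#' min-max scaled to `[0, 1]`; constant rows, for which Pearson correlation
#' is undefined, are mapped to 0.5 and appended after the clustered rows.
#' Rows are ordered by average-linkage hierarchical clustering with distance
#' `1 - Pearson correlation`; rows are sorted by group id before clustering,
#' so the leaf order is deterministic and independent of input row order.
#' Columns follow the design's condition order.
#'
#' @param records Copy-number records from [estimate_copy_numbers()].
#' @param design Sample design.
#' @param min_mean_copies Inclusion threshold on mean copies per cell in the
#'   reference cell type (default 500).
#' @param min_reps Inclusion threshold on detected replicates in the
#'   reference cell type (default 2).
#' @param reference_celltype Cell type whose conditions gate inclusion.
#' @return A list of class `heatmap_matrix`: `matrix` (rows in clustered
#'   order, values in `[0, 1]`), `row_order` and `col_order`.
#' @export
build_heatmap_matrix <- function(records, design, min_mean_copies = 500,
                                 min_reps = 2, reference_celltype = "CD8") {
  des <- condition_id(design)
  ref_conditions <- unique(des$condition[des$cell_type == reference_celltype])
  if (length(ref_conditions) == 0) {
    stop("no conditions with reference cell type ",
         sQuote(reference_celltype), call. = FALSE)
  }
  cm <- condition_means(records)
  ref <- cm[cm$condition %in% ref_conditions, ]
  gate <- dplyr::summarise(
    dplyr::group_by(ref, .data$group_id),
    pass = max(.data$mean_copies) >= min_mean_copies &&
      max(.data$n_detected) >= min_reps,
    .groups = "drop"
  )
  keep_ids <- sort(gate$group_id[gate$pass])
  if (length(keep_ids) == 0) {
    stop("no proteins pass the heatmap thresholds (mean copies >= ",
         min_mean_copies, " and detections in >= ", min_reps,
         " replicates in ", sQuote(reference_celltype), " conditions)",
         call. = FALSE)
  }

  cond_order <- unique(des$condition)
  wide <- tidyr::pivot_wider(cm[c("group_id", "condition", "mean_copies")],
                             names_from = "condition",
                             values_from = "mean_copies")
  wide <- wide[match(keep_ids, wide$group_id), ]
  mat <- as.matrix(wide[cond_order])
  rownames(mat) <- keep_ids

  rng <- apply(mat, 1, function(x) max(x) - min(x))
  scaled <- (mat - apply(mat, 1, min)) / ifelse(rng > 0, rng, 1)
  scaled[rng == 0, ] <- 0.5

  variable <- rownames(mat)[rng > 0]
  if (length(variable) >= 3 && length(cond_order) >= 2) {
    d <- as.dist(1 - cor(t(mat[variable, , drop = FALSE])))
    hc <- hclust(d, method = "average")
    ordered <- variable[hc$order]
  } else {
    ordered <- variable
  }
  row_order <- c(ordered, rownames(mat)[rng == 0])

  structure(
    list(matrix = scaled[row_order, , drop = FALSE],
         row_order = row_order,
         col_order = cond_order),
    class = "heatmap_matrix"
  )
}
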
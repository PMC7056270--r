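#' Welch's two-sample t-test
#'
#' Two-tailed t-test with unequal variances (Welch statistic, Satterthwaite
#' degrees of freedom), computed from the finite values of each group. The
#' degenerate cases are handled explicitly rather than producing fabricated
#' statistics: fewer than two finite values in either group gives an undefined
#' result; zero variance in both groups gives `t = 0, p = 1` when the means
#' are equal and an undefined result otherwise.
#'
#' @param x,y Numeric vectors of replicate measurements (typically log2
#'   copies per cell); non-finite values are ignored.
#' @return A list with `t_stat`, `df` and `p_value` (each `NA` when the test
#'   is undefined).
#' @examples
#' welch_test(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_test <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x)
  ny <- length(y)
  undefined <- list(t_stat = NA_real_, df = NA_real_, p_value = NA_real_)
  if (nx < 2 || ny < 2) {
    return(undefined)
  }
  vx <- var(x)
  vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(t_stat = 0, df = as.numeric(nx + ny - 2), p_value = 1))
    }
    return(undefined)
  }
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_stat = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

#' Log2-transform copy numbers
#'
#' `log2(copies)` for positive copies; zero copies (not detected) are
#' undefined (`NA`) and simply do not enter downstream tests — the group's
#' finite-value count drops by one. Negative input is a validation error.
#'
#' @param copies Non-negative numeric vector.
#' @return Numeric vector with `NA` where copies are zero.
#' @export
log2_copies <- function(copies) {
  if (any(copies < 0, na.rm = TRUE)) {
    stop("copy numbers must be non-negative", call. = FALSE)
  }
  ifelse(is.na(copies) | copies <= 0, NA_real_, log2(copies))
}

#' Differential test between two conditions
#'
#' For every protein group, compares two conditions with [welch_test()] on
#' the log2 copies of the detected replicates, and computes the fold change
#' from the untransformed condition means (arithmetic mean over all
#' replicates, counting not-detected as zero copies): `fold_change = mean_b /
#' mean_a`. A Benjamini-Hochberg adjusted p-value column is included for
#' convenience; the classification rules of [classify_regulation()] use the
#' raw p-values.
#'
#' @param records Copy-number records from [estimate_copy_numbers()].
#' @param condition_a,condition_b Condition identifiers present in `records`
#'   (A is the reference; fold change is B over A).
#' @return A tibble with one row per protein group: condition means, fold
#'   change, `t_stat`, `df` (Welch-Satterthwaite), `p_value`, `p_adj_bh` and
#'   detected-replicate counts.
#' @export
differential_test <- function(records, condition_a, condition_b) {
  have <- unique(records$condition)
  missing <- setdiff(c(condition_a, condition_b), have)
  if (length(missing) > 0) {
    stop("condition(s) not present in copy-number records: ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  sub <- records[records$condition %in% c(condition_a, condition_b), ]
  res <- dplyr::summarise(
    dplyr::group_by(sub, .data$group_id, .data$gene_name),
    mean_a = mean(.data$copies_per_cell[.data$condition == condition_a]),
    mean_b = mean(.data$copies_per_cell[.data$condition == condition_b]),
    n_detected_a = sum(.data$detected[.data$condition == condition_a]),
    n_detected_b = sum(.data$detected[.data$condition == condition_b]),
    test = list(welch_test(
      log2_copies(.data$copies_per_cell[.data$condition == condition_a &
                                          .data$detected]),
      log2_copies(.data$copies_per_cell[.data$condition == condition_b &
                                          .data$detected])
    )),
    .groups = "drop"
  )
  res <- tidyr::unnest_wider(res, "test")
  res$fold_change <- res$mean_b / res$mean_a
  res$p_adj_bh <- p.adjust(res$p_value, method = "BH")
  res$condition_a <- condition_a
  res$condition_b <- condition_b
  res[c("group_id", "gene_name", "condition_a", "condition_b", "mean_a",
        "mean_b", "fold_change", "t_stat", "df", "p_value", "p_adj_bh",
        "n_detected_a", "n_detected_b")]
}

#' Attach regulation classes to differential results
#'
#' Two rules are supported, matching the conventional readouts of an
#' activation-knockout study:
#'
#' * `"stimulation"` (TCR regulation): a protein is regulated if the
#'   naive-versus-activated p-value is below `p_threshold`, irrespective of
#'   fold change.
#' * `"genotype"` (knockout regulation, e.g. Myc- or Slc7a5-regulated): a
#'   protein is regulated if the two genotypes differ by more than
#'   `fold_threshold`-fold (fold change above the threshold or below its
#'   reciprocal) with a p-value below `p_threshold`.
#'
#' Direction (`up`/`down`) is recorded from the fold change relative to 1.
#' Proteins with an undefined p-value are never classified as regulated. The
#' classification depends only on the fold change and p-value columns, so it
#' is idempotent and order-invariant.
#'
#' @param results Differential results from [differential_test()].
#' @param rule `"stimulation"` or `"genotype"`.
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param fold_threshold Fold-change threshold for the genotype rule
#'   (default 2).
#' @return `results` with logical `regulated` and character `direction`
#'   columns appended.
#' @export
classify_regulation <- function(results, rule = c("stimulation", "genotype"),
                                p_threshold = 0.05, fold_threshold = 2) {
  rule <- match.arg(rule)
  stopifnot(p_threshold > 0, fold_threshold > 0)
  p_ok <- !is.na(results$p_value) & results$p_value < p_threshold
  if (rule == "stimulation") {
    regulated <- p_ok
  } else {
    fc <- results$fold_change
    regulated <- p_ok & is.finite(fc) &
      (fc > fold_threshold | fc < 1 / fold_threshold)
  }
  direction <- rep(NA_character_, nrow(results))
  direction[regulated & results$fold_change > 1] <- "up"
  direction[regulated & results$fold_change < 1] <- "down"
  dplyr::mutate(results, regulated = regulated, direction = direction)
}

#' Overlap of two regulated-protein sets
#'
#' Exact partition of two id sets into exclusive and shared members, as drawn
#' in a two-set Venn diagram.
#'
#' @param set_a,set_b Character vectors of protein group ids.
#' @return A list with sorted id vectors `only_a`, `shared`, `only_b` and an
#'   integer `counts` vector.
#' @export
regulated_overlap <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  out <- list(
    only_a = sort(setdiff(set_a, set_b)),
    shared = sort(intersect(set_a, set_b)),
    only_b = sort(setdiff(set_b, set_a))
  )
  out$counts <- c(only_a = length(out$only_a), shared = length(out$shared),
                  only_b = length(out$only_b))
  out
}

#' Volcano-plot coordinates from differential results
#'
#' Emits the conventional volcano table: `log2(fold_change)` against
#' `-log10(p)`. Proteins with an undefined p-value are excluded; their count
#' is attached as attribute `n_excluded`.
#'
#' @param results Differential results from [differential_test()].
#' @return A tibble with `group_id`, `gene_name`, `log2_fold_change` and
#'   `neg_log10_p`.
#' @export
volcano_table <- function(results) {
  keep <- !is.na(results$p_value)
  out <- tibble::tibble(
    group_id = results$group_id[keep],
    gene_name = results$gene_name[keep],
    log2_fold_change = log2(results$fold_change[keep]),
    neg_log10_p = -log10(results$p_value[keep])
  )
  attr(out, "n_excluded") <- sum(!keep)
  out
}
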
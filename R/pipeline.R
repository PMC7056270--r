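#' Read and validate a pipeline run configuration
#'
#' The run configuration is a YAML document with the blocks:
#'
#' ```yaml
#' out_dir: results/demo        # required
#' seed: 1                      # required; fanned out per stage
#' simulate:                    # either this block or `paths`
#'   n_proteins: 500
#'   cell_types: [CD8]
#'   genotypes: [WT, Myc_cKO]
#'   noise_sigma_log2: 0.25
#'   missing_rate: 0.05
#' paths:                       # real data instead of simulation
#'   protein_groups: pg.tsv
#'   design: design.tsv
#' ruler: {}                    # optional ruler_config() overrides
#' thresholds: {p: 0.05, fold: 2, heatmap_min_copies: 500, heatmap_min_reps: 2}
#' contrasts:
#'   - {name: tcr_cd8, a: CD8.WT.naive, b: CD8.WT.TCR, rule: stimulation}
#'   - {name: myc_cd8, a: CD8.WT.TCR, b: CD8.Myc_cKO.TCR, rule: genotype}
#' overlap: {a: tcr_cd8, b: myc_cd8}   # optional
#' structure:
#'   reference_celltype: CD8
#'   rank_conditions: [CD8.WT.TCR]
#'   gene_set: [Gene00001, Gene00002]  # optional; or gene_set_file
#' ```
#'
#' @param path Path to a YAML file.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("run configuration file not found: ", sQuote(path), call. = FALSE)
  }
  validate_run_config(yaml::read_yaml(path))
}

validate_run_config <- function(cfg) {
  for (field in c("out_dir", "seed")) {
    if (is.null(cfg[[field]])) {
      stop("run configuration is missing required field ", sQuote(field),
           call. = FALSE)
    }
  }
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$paths$protein_groups)) {
      stop("run configuration is missing field 'paths$protein_groups' ",
           "(required when there is no 'simulate' block)", call. = FALSE)
    }
    if (is.null(cfg$paths$design)) {
      stop("run configuration is missing field 'paths$design' ",
           "(required when there is no 'simulate' block)", call. = FALSE)
    }
    for (p in unlist(cfg$paths)) {
      if (!file.exists(p)) {
        stop("configured input file does not exist: ", sQuote(p),
             call. = FALSE)
      }
    }
  }
  if (is.null(cfg$thresholds)) cfg$thresholds <- list()
  th <- cfg$thresholds
  cfg$thresholds <- list(
    p = th$p %||% 0.05,
    fold = th$fold %||% 2,
    heatmap_min_copies = th$heatmap_min_copies %||% 500,
    heatmap_min_reps = th$heatmap_min_reps %||% 2
  )
  if (any(unlist(cfg$thresholds) <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(paste0("stage '", name, "' failed: ", conditionMessage(e)),
               marker)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full quantification pipeline
#'
#' Chains simulation (or reading real tables), ruler quantification,
#' differential testing with regulation classes, and proteome-structure
#' analytics, writing every stage's result tables under `out_dir` and
#' finishing with a manifest of output files and their MD5 hashes. The run is
#' deterministic: identical configuration and seed reproduce byte-identical
#' outputs and hence an identical manifest. The configured seed drives the
#' ground truth; measurement noise uses `seed + 1`.
#'
#' On a stage error the pipeline aborts with a stage-named message and leaves
#' a `FAILED` marker file next to any partial outputs.
#'
#' @param config Path to a YAML run configuration, or an equivalent list
#'   (see [read_run_config()]).
#' @return Invisibly, a list with the output `manifest` (tibble of `file`,
#'   `md5`) and the `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))
  seed <- as.integer(cfg$seed)

  ruler <- do.call(ruler_config, cfg$ruler %||% list())

  # --- inputs: simulate or read -------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    run_stage("simulate", out_dir, {
      design <- make_sample_design(
        genotypes = unlist(sim$genotypes %||% c("WT", "Myc_cKO")),
        cell_types = unlist(sim$cell_types %||% c("CD4", "CD8")),
        n_replicates = sim$n_replicates %||% 3
      )
      truth_args <- sim[intersect(names(sim),
                                  setdiff(names(formals(make_ground_truth)),
                                          c("design", "ruler", "seed")))]
      truth <- do.call(make_ground_truth,
                       c(list(design = design, ruler = ruler, seed = seed),
                         truth_args))
      groups <- simulate_intensities(truth, design, seed = seed + 1)
      write_protein_groups(groups, file.path(out_dir, "protein_groups.tsv"))
      write_results_table(design, file.path(out_dir, "design.tsv"))
      write_results_table(
        dplyr::left_join(truth$copies, truth$proteins, by = "protein_id"),
        file.path(out_dir, "ground_truth.tsv")
      )
    })
  } else {
    run_stage("read_inputs", out_dir, {
      design <- read_sample_design(cfg$paths$design)
      groups <- read_protein_groups(cfg$paths$protein_groups)
    })
  }

  # --- quantify ------------------------------------------------------------
  records <- run_stage("quantify", out_dir, {
    kept <- detection_filter(filter_groups(groups), design, ruler)
    rec <- estimate_copy_numbers(kept, design, ruler)
    write_results_table(rec, file.path(out_dir, "copy_numbers.tsv"))
    write_results_table(condition_means(rec),
                        file.path(out_dir, "condition_means.tsv"))
    write_results_table(total_protein_content(rec),
                        file.path(out_dir, "total_protein_content.tsv"))
    rec
  })

  # --- differential --------------------------------------------------------
  regulated_sets <- list()
  run_stage("differential", out_dir, {
    for (ct in cfg$contrasts %||% list()) {
      res <- differential_test(records, ct$a, ct$b)
      res <- classify_regulation(res, rule = ct$rule %||% "genotype",
                                 p_threshold = cfg$thresholds$p,
                                 fold_threshold = cfg$thresholds$fold)
      write_results_table(res,
                          file.path(out_dir,
                                    paste0("differential_", ct$name, ".tsv")))
      write_results_table(volcano_table(res),
                          file.path(out_dir,
                                    paste0("volcano_", ct$name, ".tsv")))
      regulated_sets[[ct$name]] <- res$group_id[res$regulated]
    }
    if (!is.null(cfg$overlap)) {
      ov <- regulated_overlap(regulated_sets[[cfg$overlap$a]],
                              regulated_sets[[cfg$overlap$b]])
      write_results_table(
        tibble::tibble(segment = names(ov$counts), count = ov$counts),
        file.path(out_dir, "overlap_counts.tsv")
      )
    }
  })

  # --- structure -----------------------------------------------------------
  run_stage("structure", out_dir, {
    st <- cfg$structure %||% list()
    for (cond in unlist(st$rank_conditions %||% character())) {
      prof <- mass_rank_profile(records, cond)
      write_results_table(
        prof$table,
        file.path(out_dir, paste0("rank_profile_", cond, ".tsv"))
      )
      write_results_table(
        tibble::tibble(quartile = names(prof$quartile_counts),
                       n_proteins = prof$quartile_counts),
        file.path(out_dir, paste0("rank_quartiles_", cond, ".tsv"))
      )
    }
    gene_set <- unlist(st$gene_set %||% character())
    if (!is.null(st$gene_set_file)) {
      gene_set <- c(gene_set, readLines(st$gene_set_file))
    }
    if (length(gene_set) > 0) {
      write_results_table(pathway_mass_summary(records, gene_set),
                          file.path(out_dir, "pathway_mass.tsv"))
    }
    if (!is.null(st$reference_celltype)) {
      hm <- build_heatmap_matrix(
        records, design,
        min_mean_copies = cfg$thresholds$heatmap_min_copies,
        min_reps = cfg$thresholds$heatmap_min_reps,
        reference_celltype = st$reference_celltype
      )
      write_results_table(
        dplyr::bind_cols(tibble::tibble(group_id = rownames(hm$matrix)),
                         tibble::as_tibble(hm$matrix)),
        file.path(out_dir, "heatmap_matrix.tsv")
      )
      writeLines(hm$row_order, file.path(out_dir, "heatmap_row_order.txt"))
      writeLines(hm$col_order, file.path(out_dir, "heatmap_col_order.txt"))
    }
  })

  # --- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  write_results_table(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(manifest = manifest, out_dir = out_dir))
}
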
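#' Assemble and validate a run configuration
#'
#' A run is driven either by file paths (`counts`, `samples`, optional
#' `gene_sets`) or by a `simulation` block ([simulation_config()]
#' fields) — exactly one of the two. `comparisons` lists the sample-type
#' pairs to test (A enriched over B).
#'
#' @param config a named list (e.g. parsed from YAML).
#' @return validated list of class `"tutag_run_config"` with defaults
#'   filled (`alpha` 0.1, `n_resamples` 1000, `mds_top` 500, `seed` 1).
#' @export
as_run_config <- function(config) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  has_paths <- !is.null(config$paths)
  has_sim <- !is.null(config$simulation)
  chk(xor(has_paths, has_sim),
      "exactly one of 'paths' and 'simulation' must be present")
  if (is.null(config$alpha)) config$alpha <- 0.1
  if (is.null(config$n_resamples)) config$n_resamples <- 1000
  if (is.null(config$mds_top)) config$mds_top <- 500
  if (is.null(config$seed)) config$seed <- 1L
  chk(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
      "alpha: must be in (0, 1)")
  chk(is.numeric(config$n_resamples) && config$n_resamples >= 1,
      "n_resamples: must be a positive integer")
  comps <- config$comparisons
  chk(is.list(comps) && length(comps) >= 1,
      "comparisons: need a nonempty list of (type_a, type_b) pairs")
  if (is.list(comps)) {
    for (cm in comps) {
      chk(length(cm) == 2 && is.character(unlist(cm)),
          "comparisons: each entry must be two sample-type names")
    }
  }
  if (has_sim) {
    sim_cfg <- tryCatch({
      args <- config$simulation
      if (!is.null(args$population_profiles)) {
        args$population_profiles <- lapply(args$population_profiles, unlist)
      }
      if (is.null(args$seed)) args$seed <- config$seed
      do.call(simulation_config, args)
    }, error = function(e) {
      chk(FALSE, conditionMessage(e))
      NULL
    })
    config$simulation <- sim_cfg
    if (!is.null(sim_cfg) && is.list(comps)) {
      known <- names(sim_cfg$population_profiles)
      for (cm in comps) {
        for (ty in unlist(cm)) {
          chk(ty %in% known,
              sprintf("comparison names unknown sample type '%s' (known: %s)",
                      ty, paste(known, collapse = ", ")))
        }
      }
    }
  }
  if (has_paths) {
    for (field in c("counts", "samples")) {
      chk(is.character(config$paths[[field]]),
          sprintf("paths$%s: required file path", field))
    }
  }
  if (length(problems)) {
    input_error("invalid run config:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  structure(config, class = "tutag_run_config")
}

#' Parse and validate a YAML run configuration
#'
#' @param path YAML file.
#' @return a validated `"tutag_run_config"` (see [as_run_config()]).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) input_error("config file not found: %s", path)
  as_run_config(yaml::read_yaml(path))
}

#' Run the full enrichment analysis
#'
#' Orchestrates one reproducible run: obtain counts (simulate with ground
#' truth, or read from the configured paths), then for each configured
#' comparison run the NB differential-enrichment stage, the per-set
#' resampling overlap table, and the rank-based logistic fit against the
#' first marker set; partition the first two comparisons' enriched lists
#' into a Venn layout; and compute the leading-fold-change MDS of all
#' samples. All randomness derives from the config seed.
#'
#' @param config a `"tutag_run_config"` (or plain list passed through
#'   [as_run_config()]).
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` plus a human-readable `report.txt`, and stage outputs
#'   (enriched lists, overlap tables) as TSV.
#' @return list of class `"tutag_report"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "tutag_run_config")) config <- as_run_config(config)
  seed <- config$seed
  if (!is.null(config$simulation)) {
    sim <- simulate_experiment(config$simulation)
    counts <- sim$counts
    sample_sheet <- sim$sample_sheet
    gene_sets <- catalog_gene_sets(sim$catalog)
    truth <- sim$truth
  } else {
    counts <- read_counts(config$paths$counts)
    sample_sheet <- read_sample_sheet(config$paths$samples)
    gene_sets <- if (!is.null(config$paths$gene_sets)) {
      read_gene_sets(config$paths$gene_sets)
    } else {
      list()
    }
    truth <- NULL
  }
  comparisons <- lapply(config$comparisons, unlist)
  comp_results <- list()
  for (i in seq_along(comparisons)) {
    cm <- comparisons[[i]]
    de <- run_comparison(counts, sample_sheet, cm[1], cm[2], alpha = config$alpha)
    universe <- de$gene_id
    enriched <- de$gene_id[de$enriched]
    ov <- if (length(gene_sets)) {
      overlap_table(enriched, universe, gene_sets, B = config$n_resamples,
                    seed = derive_seed(seed, 100L + i))
    } else {
      NULL
    }
    logistic <- NULL
    if (length(gene_sets)) {
      members <- restrict_to_universe(gene_sets[[1]], universe)
      if (length(members) && length(members) < length(universe)) {
        ranked <- rank_by_fold_enrichment(de, members)
        logistic <- fit_logistic(ranked)
      }
    }
    comp_results[[paste(cm, collapse = "_vs_")]] <- list(
      type_a = cm[1], type_b = cm[2],
      n_filtered = length(universe),
      n_enriched = length(enriched),
      de = de,
      enriched = enriched,
      overlap = ov,
      logistic = logistic
    )
  }
  venn <- NULL
  if (length(comp_results) >= 2 && length(gene_sets)) {
    venn <- venn_partition(comp_results[[1]]$enriched,
                           comp_results[[2]]$enriched,
                           gene_sets[[1]])
  }
  mds <- mds_leading_foldchange(counts, top = config$mds_top)
  report <- structure(list(
    seed = seed,
    alpha = config$alpha,
    n_resamples = config$n_resamples,
    comparisons = comp_results,
    venn = venn,
    mds = mds,
    gene_sets = lapply(gene_sets, length),
    truth = truth
  ), class = "tutag_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# serialize a report: JSON (machine) + text table (human) + per-stage TSVs
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(seed = report$seed, alpha = report$alpha,
             n_resamples = report$n_resamples, comparisons = list())
  txt <- c("TU-tagging enrichment analysis report", "")
  for (nm in names(report$comparisons)) {
    cr <- report$comparisons[[nm]]
    utils::write.table(as.data.frame(cr$de), file.path(out_dir, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(cr$enriched, file.path(out_dir, paste0("enriched_", nm, ".txt")))
    comp_js <- list(type_a = cr$type_a, type_b = cr$type_b,
                    n_filtered = cr$n_filtered, n_enriched = cr$n_enriched)
    txt <- c(txt, sprintf("%s: %d genes retained by the CPM filter, %d enriched (padj < %g)",
                          nm, cr$n_filtered, cr$n_enriched, report$alpha))
    if (!is.null(cr$overlap)) {
      utils::write.table(cr$overlap, file.path(out_dir, paste0("overlap_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      comp_js$overlap <- cr$overlap
      for (r in seq_len(nrow(cr$overlap))) {
        row <- cr$overlap[r, ]
        flag <- if (row$significant) sprintf(" [significant, %s 95%% CI]", row$direction) else ""
        txt <- c(txt, sprintf("  %-12s overlap %d (expected %.1f, CI [%g, %g], p = %.4g)%s",
                              row$set_name, row$observed_overlap, row$resample_mean,
                              row$ci_low, row$ci_high, row$p_resample, flag))
      }
    }
    if (!is.null(cr$logistic)) {
      lg <- cr$logistic
      comp_js$logistic <- list(intercept = lg$intercept, slope = lg$slope,
                               slope_se = lg$se[2], slope_p = lg$p[2],
                               converged = lg$converged)
      txt <- c(txt, sprintf("  logistic membership ~ rank: slope %.3g (Wald p = %.3g)",
                            lg$slope, lg$p[2]))
    }
    js$comparisons[[nm]] <- comp_js
    txt <- c(txt, "")
  }
  if (!is.null(report$venn)) {
    js$venn <- list(sizes = as.list(report$venn$sizes),
                    pct_in_set = as.list(report$venn$pct_in_set))
    txt <- c(txt, sprintf("Venn: only_A %d (%.1f%% markers), both %d (%.1f%%), only_B %d (%.1f%%)",
                          report$venn$sizes["only_a"], report$venn$pct_in_set["only_a"],
                          report$venn$sizes["both"], report$venn$pct_in_set["both"],
                          report$venn$sizes["only_b"], report$venn$pct_in_set["only_b"]))
  }
  utils::write.table(data.frame(sample_id = rownames(report$mds$coordinates),
                                report$mds$coordinates),
                     file.path(out_dir, "mds_coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  js$mds <- list(coordinates = as.data.frame(report$mds$coordinates))
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
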
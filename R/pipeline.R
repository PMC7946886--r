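# End-to-end orchestration: preprocess -> per-dataset network -> hub
# selection -> cross-network consensus -> differential expression ->
# drug-target integration -> enrichment, with all intermediates persisted
# as TSV/JSON and a run report whose counts mirror the output files.

#' Pipeline configuration
#'
#' Collects the per-stage parameter blocks with the pipeline's defaults:
#' scale-free fit R^2 cutoff 0.80, top 20% hub selection, consensus across
#' at least 2 networks, 2-fold differential-expression rule, significance
#' in at least 25% of conditions, enrichment FDR 0.05. Unknown keys in any
#' block are rejected. The fully resolved configuration is written next
#' to the outputs by [run_pipeline()].
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading data
#'   from a manifest.
#' @param manifest Path to a collection manifest (see
#'   [write_collection()]), or `NULL` when simulating.
#' @param outdir Output directory for all stage outputs.
#' @param seed Global seed; per-stage child seeds are derived
#'   deterministically from it.
#' @param preprocess,network,hubs,de,integration,enrichment Named lists
#'   overriding individual stage defaults (see Details).
#'
#' @details Stage defaults: preprocess `cv_mode = "top_fraction"`,
#'   `cv_top_fraction = 0.5`, `unlog_base = 2`; network `beta_grid = 1:20`,
#'   `r2_cutoff = 0.80`, `n_bins = 10`, `min_module_size = 30`,
#'   `cut_height = 0.99`; hubs `top_fraction = 0.20`,
#'   `profile_fractions = c(0.05, 0.10, 0.20)`; de
#'   `min_sig_fraction = 0.25`, `lfc_threshold = 1`; integration
#'   `min_networks = 2`; enrichment `fdr = 0.05`, `min_term_size = 3`,
#'   `gmt = NULL` (with a synthetic run and no GMT file, annotations are
#'   simulated with [synthetic_annotations()]).
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            manifest = NULL,
                            outdir = tempfile("coexhub_run_"),
                            seed = 1,
                            preprocess = list(),
                            network = list(),
                            hubs = list(),
                            de = list(),
                            integration = list(),
                            enrichment = list()) {
  if (is.null(synthetic) && is.null(manifest)) {
    stop_coexhub("either a synthetic config or a manifest path is required",
                 "coexhub_bad_config")
  }
  defaults <- list(
    preprocess = list(cv_mode = "top_fraction", cv_top_fraction = 0.5,
                      cv_cutoff = NULL, unlog_base = 2),
    network = list(beta_grid = 1:20, r2_cutoff = 0.80, n_bins = 10,
                   min_module_size = 30, cut_height = 0.99,
                   separability_ratio = 2),
    hubs = list(top_fraction = 0.20,
                profile_fractions = c(0.05, 0.10, 0.20)),
    de = list(min_sig_fraction = 0.25, lfc_threshold = 1),
    integration = list(min_networks = 2),
    enrichment = list(fdr = 0.05, min_term_size = 3, gmt = NULL)
  )
  merge_block <- function(name, user) {
    block <- defaults[[name]]
    unknown <- setdiff(names(user), names(block))
    if (length(unknown) > 0) {
      stop_coexhub(sprintf("unknown %s keys: %s", name,
                           paste(unknown, collapse = ", ")),
                   "coexhub_bad_config")
    }
    block[names(user)] <- user
    block
  }
  structure(
    list(synthetic = synthetic, manifest = manifest, outdir = outdir,
         seed = as.integer(seed),
         preprocess = merge_block("preprocess", preprocess),
         network = merge_block("network", network),
         hubs = merge_block("hubs", hubs),
         de = merge_block("de", de),
         integration = merge_block("integration", integration),
         enrichment = merge_block("enrichment", enrichment)),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "coexhub_stage_error")) stop(e)
    stop_coexhub(sprintf("stage [%s] failed: %s", stage, conditionMessage(e)),
                 "coexhub_stage_error")
  })
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Run the whole discovery pipeline
#'
#' Executes every stage on either a synthetic collection (generated from
#' `config$synthetic` with a seed derived from `config$seed`) or a
#' collection read from `config$manifest`. All intermediates are written
#' under `config$outdir` as TSV/JSON; identical configuration and seed
#' yield byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#'
#' @return A list of class `run_report`: per-dataset network summaries
#'   (chosen beta, module count, gene counts at each filter stage), the
#'   consensus overlap histogram, the differential-expression summary, the
#'   candidate count, seed and package version. Every count equals the row
#'   count of the corresponding output file.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  inputs <- with_stage("input", {
    if (!is.null(config$synthetic)) {
      syn_cfg <- config$synthetic
      syn_cfg$seed <- derive_seed(config$seed, "synthetic")
      coll <- generate_collection(syn_cfg)
      truth <<- coll$truth
      list(datasets = coll$datasets, catalog = coll$catalog)
    } else {
      read_collection(config$manifest)
    }
  })
  datasets <- inputs$datasets
  if (length(datasets) < config$integration$min_networks) {
    stop_coexhub(sprintf(
      "stage [consensus]: %d dataset(s) cannot support consensus across %d networks",
      length(datasets), config$integration$min_networks),
      "coexhub_stage_error")
  }

  # --- preprocess + per-dataset networks ---------------------------------
  pp_cfg <- preprocess_config(cv_mode = config$preprocess$cv_mode,
                              cv_top_fraction = config$preprocess$cv_top_fraction,
                              cv_cutoff = config$preprocess$cv_cutoff,
                              unlog_base = config$preprocess$unlog_base)
  networks <- list()
  normalized <- list()
  kept_genes <- list()
  dataset_report <- list()
  for (did in names(datasets)) {
    ds <- datasets[[did]]
    norm <- with_stage(paste0("preprocess:", did), {
      quantile_normalize(ds$values)
    })
    filt <- with_stage(paste0("preprocess:", did), {
      cv_filter(norm, config = pp_cfg)
    })
    nw <- with_stage(paste0("network:", did), {
      suppressWarnings(build_network(
        filt$values, dataset_id = did,
        beta_grid = config$network$beta_grid,
        r2_cutoff = config$network$r2_cutoff,
        n_bins = config$network$n_bins,
        min_module_size = config$network$min_module_size,
        cut_height = config$network$cut_height,
        separability_ratio = config$network$separability_ratio))
    })
    networks[[did]] <- nw
    normalized[[did]] <- structure(
      list(dataset_id = did, values = norm, metadata = ds$metadata),
      class = "expression_dataset")
    kept_genes[[did]] <- filt$gene_ids

    write_tsv(nw$soft_threshold$table,
              file.path(outdir, sprintf("%s_soft_threshold.tsv", did)))
    conn <- nw$connectivity
    n_rows <- write_tsv(conn,
                        file.path(outdir, sprintf("%s_membership.tsv", did)))
    if (!is.null(nw$eigengenes)) {
      write_matrix_tsv(nw$eigengenes,
                       file.path(outdir, sprintf("%s_eigengenes.tsv", did)),
                       id_col = "module")
    }
    dataset_report[[did]] <- list(
      n_genes_input = nrow(ds$values),
      n_genes_kept = length(filt$gene_ids),
      n_genes_network = n_rows,
      chosen_beta = nw$soft_threshold$chosen_beta,
      beta_used = nw$beta_used,
      n_modules = nw$partition$n_modules,
      n_unassigned = sum(conn$module == UNASSIGNED)
    )
  }

  # --- hub selection + consensus -----------------------------------------
  hubsets <- with_stage("hubs", {
    lapply(networks, function(nw) {
      hs <- select_hubs(nw$connectivity,
                        top_fraction = config$hubs$top_fraction,
                        dataset_id = nw$dataset_id)
      write_tsv(data.frame(gene_id = hs$genes, stringsAsFactors = FALSE),
                file.path(outdir, sprintf("%s_hubs.tsv", nw$dataset_id)))
      hs
    })
  })
  consensus <- with_stage("consensus", {
    consensus_hubs(unname(hubsets),
                   min_networks = config$integration$min_networks)
  })
  write_tsv(consensus$table, file.path(outdir, "consensus_hubs.tsv"))
  write_tsv(data.frame(gene_id = consensus$consensus_genes,
                       stringsAsFactors = FALSE),
            file.path(outdir, "consensus_genes.tsv"))
  profile <- with_stage("consensus", {
    overlap_profile(unname(networks),
                    fractions = config$hubs$profile_fractions)
  })
  write_tsv(profile, file.path(outdir, "overlap_profile.tsv"))

  # --- differential expression -------------------------------------------
  de <- with_stage("de", {
    contrasts <- list()
    for (did in names(normalized)) {
      ds <- normalized[[did]]
      for (cid in unique(ds$metadata$condition_id)) {
        contrasts[[cid]] <- contrast_log2fc(
          ds, cid, lfc_threshold = config$de$lfc_threshold)
      }
    }
    lfc_tab <- data.frame(gene_id = sort(contrasts[[1]]$gene_id),
                          stringsAsFactors = FALSE)
    for (cid in names(contrasts)) {
      ct <- contrasts[[cid]]
      lfc_tab[[cid]] <- ct$log2fc[match(lfc_tab$gene_id, ct$gene_id)]
    }
    write_tsv(lfc_tab, file.path(outdir, "de_log2fc.tsv"))
    consistency <- summarize_consistency(
      contrasts, min_sig_fraction = config$de$min_sig_fraction)
    write_tsv(consistency, file.path(outdir, "de_consistency.tsv"))
    consistency
  })

  # --- drug-target integration -------------------------------------------
  candidates <- with_stage("integration", {
    suppressWarnings(build_candidates(
      consensus, de, inputs$catalog,
      min_networks = config$integration$min_networks))
  })
  write_tsv(candidates, file.path(outdir, "candidates.tsv"))

  # --- enrichment ---------------------------------------------------------
  enrich_summary <- with_stage("enrichment", {
    collection <- if (!is.null(config$enrichment$gmt)) {
      read_gmt(config$enrichment$gmt,
               min_term_size = config$enrichment$min_term_size)
    } else if (!is.null(truth)) {
      suppressWarnings(synthetic_annotations(
        truth, seed = derive_seed(config$seed, "annotations")))
    } else {
      NULL
    }
    if (is.null(collection)) {
      list(n_terms = 0L, n_enriched_consensus = 0L, n_shared_terms = 0L)
    } else {
      per_dataset <- lapply(hubsets, function(hs) {
        hypergeometric_enrichment(hs$genes, collection,
                                  fdr_threshold = config$enrichment$fdr)
      })
      cons_res <- hypergeometric_enrichment(
        consensus$consensus_genes, collection,
        fdr_threshold = config$enrichment$fdr)
      write_tsv(cons_res, file.path(outdir, "enrichment_consensus.tsv"))
      shared <- average_fold_table(unname(per_dataset))
      write_tsv(shared, file.path(outdir, "enrichment_shared_terms.tsv"))
      list(n_terms = length(collection$terms),
           n_enriched_consensus = sum(cons_res$enriched),
           n_shared_terms = nrow(shared))
    }
  })

  # --- resolved config + report ------------------------------------------
  resolved <- unclass(config)
  resolved$synthetic <- if (!is.null(config$synthetic))
    unclass(config$synthetic) else NULL
  jsonlite::write_json(resolved, file.path(outdir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- structure(list(
    datasets = dataset_report,
    consensus = list(
      n_networks = consensus$n_networks,
      histogram = as.list(consensus$histogram),
      n_consensus = length(consensus$consensus_genes)
    ),
    de = list(
      n_conditions = attr(de, "n_conditions"),
      min_sig = attr(de, "min_sig"),
      n_consistent_up = sum(de$status == "consistent_up"),
      n_consistent_down = sum(de$status == "consistent_down"),
      n_inconsistent = sum(de$status == "inconsistent")
    ),
    n_candidates = nrow(candidates),
    enrichment = enrich_summary,
    seed = config$seed,
    version = as.character(utils::packageVersion("coexhub"))
  ), class = "run_report")
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("coexhub run (seed", x$seed, ")\n")
  for (did in names(x$datasets)) {
    d <- x$datasets[[did]]
    cat(sprintf("  %s: %d -> %d genes, beta %s, %d modules\n", did,
                d$n_genes_input, d$n_genes_kept,
                as.character(d$beta_used), d$n_modules))
  }
  cat("  consensus hubs:", x$consensus$n_consensus,
      "| consistent up/down:", x$de$n_consistent_up, "/",
      x$de$n_consistent_down,
      "| candidates:", x$n_candidates, "\n")
  invisible(x)
}
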
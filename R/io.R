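# Plain-text readers and writers: TSV expression matrices and metadata,
# truth/catalog tables, and a JSON manifest. Numeric cells are written
# with 17 significant digits so matrices round-trip losslessly.

format_num <- function(x) sprintf("%.17g", x)

write_matrix_tsv <- function(values, path, id_col = "gene_id") {
  df <- data.frame(rownames(values),
                   apply(values, 2, format_num),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c(id_col, colnames(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic collection to a directory
#'
#' Persists one expression TSV and one metadata TSV per dataset, the truth
#' tables, the drug-target catalog and a JSON manifest listing every file
#' together with the generating configuration. Numeric values are written
#' at full double precision, so reading them back reproduces the matrices
#' exactly.
#'
#' @param datasets List of `expression_dataset` objects.
#' @param truth Truth list from [generate_collection()] (may be `NULL`
#'   for real data collections).
#' @param catalog A `drug_target_catalog` (may be `NULL`).
#' @param directory Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param config Optional `synthetic_config` recorded in the manifest.
#'
#' @return The manifest path, invisibly.
#' @export
write_collection <- function(datasets, truth = NULL, catalog = NULL,
                             directory, overwrite = FALSE, config = NULL) {
  if (length(datasets) == 0) {
    stop_coexhub("empty dataset list", "coexhub_bad_input")
  }
  stopifnot(all(vapply(datasets, inherits, TRUE, "expression_dataset")))
  if (dir.exists(directory) && length(list.files(directory)) > 0 &&
      !overwrite) {
    stop_coexhub(sprintf(
      "directory %s exists and is not empty; set overwrite = TRUE", directory),
      "coexhub_refuse_overwrite")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- list(datasets = list())
  for (ds in datasets) {
    expr_file <- sprintf("%s_expression.tsv", ds$dataset_id)
    meta_file <- sprintf("%s_metadata.tsv", ds$dataset_id)
    write_matrix_tsv(ds$values, file.path(directory, expr_file))
    md <- ds$metadata
    md$dose_gray <- format_num(md$dose_gray)
    md$time_hours <- format_num(md$time_hours)
    utils::write.table(md, file.path(directory, meta_file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files$datasets[[ds$dataset_id]] <-
      list(expression = expr_file, metadata = meta_file)
  }
  if (!is.null(catalog)) {
    utils::write.table(catalog, file.path(directory, "catalog.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files$catalog <- "catalog.tsv"
  }
  if (!is.null(truth)) {
    gene_tab <- data.frame(
      gene_id = names(truth$module_of_gene),
      module = as.integer(truth$module_of_gene),
      is_hub = names(truth$module_of_gene) %in% truth$hub_genes,
      druggable = names(truth$module_of_gene) %in% truth$druggable_genes,
      consistent_direction = unname(truth$consistent_direction),
      stringsAsFactors = FALSE
    )
    utils::write.table(gene_tab, file.path(directory, "truth_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$de_direction,
                       file.path(directory, "truth_de_direction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$conditions,
                       file.path(directory, "conditions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files$truth <- list(genes = "truth_genes.tsv",
                        de_direction = "truth_de_direction.tsv",
                        conditions = "conditions.tsv")
  }
  manifest <- list(files = files,
                   n_datasets = length(datasets),
                   config = if (!is.null(config)) unclass(config) else NULL)
  manifest_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Read one expression dataset from TSV files
#'
#' @param path Expression TSV: first column `gene_id`, one column per
#'   sample.
#' @param metadata_path Metadata TSV with columns `sample_id`,
#'   `condition_id`, `arm`, `dose_gray`, `time_hours`.
#' @param dataset_id Identifier; defaults to the expression file name.
#'
#' @return An `expression_dataset`.
#' @export
read_expression <- function(path, metadata_path,
                            dataset_id = sub("_expression\\.tsv$", "",
                                             basename(path))) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (names(raw)[1] != "gene_id") {
    stop_coexhub("first column of an expression TSV must be gene_id",
                 "coexhub_bad_input")
  }
  gene_ids <- raw[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0) {
    stop_coexhub(sprintf("duplicated gene ids: %s",
                         paste(utils::head(unique(dup), 5), collapse = ", ")),
                 "coexhub_bad_input")
  }
  num <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  if (nrow(raw) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(raw)[-1]))
  if (any(is.na(num))) {
    cells <- which(is.na(num), arr.ind = TRUE)
    stop_coexhub(sprintf(
      "non-numeric or missing cells, e.g. gene %s sample %s",
      gene_ids[cells[1, 1]], colnames(num)[cells[1, 2]]),
      "coexhub_bad_input")
  }
  rownames(num) <- gene_ids
  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  required <- c("sample_id", "condition_id", "arm", "dose_gray", "time_hours")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0) {
    stop_coexhub(sprintf("metadata is missing columns: %s",
                         paste(missing_cols, collapse = ", ")),
                 "coexhub_bad_input")
  }
  absent <- setdiff(colnames(num), md$sample_id)
  if (length(absent) > 0) {
    stop_coexhub(sprintf("samples missing from metadata: %s",
                         paste(utils::head(absent, 5), collapse = ", ")),
                 "coexhub_bad_input")
  }
  md <- md[match(colnames(num), md$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  structure(list(dataset_id = dataset_id, values = num, metadata = md),
            class = "expression_dataset")
}

#' Read a written collection back from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_collection()].
#' @return List with `datasets` and, when present, `catalog`.
#' @export
read_collection <- function(manifest_path) {
  manifest <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  datasets <- list()
  for (did in names(manifest$files$datasets)) {
    entry <- manifest$files$datasets[[did]]
    datasets[[did]] <- read_expression(
      file.path(base, entry$expression),
      file.path(base, entry$metadata),
      dataset_id = did
    )
  }
  catalog <- NULL
  if (!is.null(manifest$files$catalog)) {
    catalog <- load_catalog(file.path(base, manifest$files$catalog))
  }
  list(datasets = datasets, catalog = catalog)
}
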
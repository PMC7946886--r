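# Drug-target catalog handling and the candidate table: consensus hubs
# intersected with druggable genes and directionally consistent
# differential expression.

CATALOG_STATUSES <- c("approved", "launched", "clinical_phase",
                      "preclinical", "investigational", "discovery")

#' Validate an in-memory drug-target catalog
#'
#' @param df Data frame with columns `gene_id`, `drug_name`, `status`.
#' @return The validated data frame with class `drug_target_catalog`.
#' @export
as_drug_target_catalog <- function(df) {
  required <- c("gene_id", "drug_name", "status")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_coexhub(sprintf("catalog is missing columns: %s",
                         paste(missing, collapse = ", ")),
                 "coexhub_bad_catalog")
  }
  bad <- which(!df$status %in% CATALOG_STATUSES)
  if (length(bad) > 0) {
    stop_coexhub(sprintf(
      "unknown status values at rows %s (allowed: %s)",
      paste(utils::head(bad, 10), collapse = ", "),
      paste(CATALOG_STATUSES, collapse = ", ")), "coexhub_bad_catalog")
  }
  dup <- which(duplicated(df[, c("gene_id", "drug_name")]))
  if (length(dup) > 0) {
    stop_coexhub(sprintf("duplicate (gene, drug) pairs at rows %s",
                         paste(utils::head(dup, 10), collapse = ", ")),
                 "coexhub_bad_catalog")
  }
  if (nrow(df) == 0) {
    warn_coexhub("empty drug-target catalog", "coexhub_empty_catalog")
  }
  out <- df[, required, drop = FALSE]
  class(out) <- c("drug_target_catalog", "data.frame")
  out
}

#' Load a drug-target catalog from a TSV file
#'
#' The file must be tab-separated with header columns `gene_id`,
#' `drug_name` and `status`; `status` must be one of approved, launched,
#' clinical_phase, preclinical, investigational, discovery. Offending line
#' numbers are reported (header is line 1).
#'
#' @param path Path to the TSV file.
#' @return A `drug_target_catalog` data frame.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    stop_coexhub(sprintf("catalog file not found: %s", path),
                 "coexhub_bad_input")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("gene_id", "drug_name", "status")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_coexhub(sprintf("catalog %s is missing columns: %s", path,
                         paste(missing, collapse = ", ")),
                 "coexhub_bad_catalog")
  }
  # data row i sits on file line i + 1 (header is line 1)
  bad <- which(!df$status %in% CATALOG_STATUSES)
  if (length(bad) > 0) {
    stop_coexhub(sprintf("unknown status values on lines %s of %s",
                         paste(bad + 1L, collapse = ", "), path),
                 "coexhub_bad_catalog")
  }
  dup <- which(duplicated(df[, c("gene_id", "drug_name")]))
  if (length(dup) > 0) {
    stop_coexhub(sprintf("duplicate (gene, drug) pairs on lines %s of %s",
                         paste(dup + 1L, collapse = ", "), path),
                 "coexhub_bad_catalog")
  }
  as_drug_target_catalog(df)
}

#' Build the drug-target candidate table
#'
#' Intersects three evidence layers: genes that are consensus hubs in at
#' least `min_networks` networks, genes with at least one catalog drug,
#' and genes with a directionally consistent differential-expression
#' status. The result is the computational candidate table; proposed
#' modulation is left `unassigned` (assigning inhibition/activation
#' requires curation outside this package).
#'
#' @param consensus A `consensus_table` from [consensus_hubs()].
#' @param de A `de_consistency` from [summarize_consistency()].
#' @param catalog A `drug_target_catalog`.
#' @param min_networks Minimum hub count (default 2).
#'
#' @return A data frame of class `candidate_table` with columns `gene_id`,
#'   `hub_count`, `member_networks`, `direction`, `n_up`, `n_down`,
#'   `drugs` (semicolon-separated `drug (status)`) and
#'   `proposed_modulation`, ordered by decreasing hub count, then
#'   decreasing total directional calls, then gene id.
#' @export
build_candidates <- function(consensus, de, catalog, min_networks = 2) {
  stopifnot(inherits(consensus, "consensus_table"),
            inherits(de, "de_consistency"),
            inherits(catalog, "drug_target_catalog"))
  assert_count(min_networks, "min_networks", min = 1)
  empty <- function() {
    out <- data.frame(gene_id = character(0), hub_count = integer(0),
                      member_networks = character(0), direction = character(0),
                      n_up = integer(0), n_down = integer(0),
                      drugs = character(0), proposed_modulation = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("candidate_table", "data.frame")
    out
  }
  if (nrow(consensus$table) == 0 || nrow(catalog) == 0) {
    warn_coexhub("empty consensus table or catalog: no candidates",
                 "coexhub_empty_candidates")
    return(empty())
  }
  hubs <- consensus$table[consensus$table$hub_count >= min_networks, ,
                          drop = FALSE]
  cons_de <- de[de$status %in% c("consistent_up", "consistent_down"), ,
                drop = FALSE]
  genes <- Reduce(intersect, list(hubs$gene_id, cons_de$gene_id,
                                  unique(catalog$gene_id)))
  if (length(genes) == 0) return(empty())
  hi <- hubs[match(genes, hubs$gene_id), ]
  di <- cons_de[match(genes, cons_de$gene_id), ]
  drugs <- vapply(genes, function(g) {
    rec <- catalog[catalog$gene_id == g, , drop = FALSE]
    rec <- rec[order(rec$drug_name), , drop = FALSE]
    paste(sprintf("%s (%s)", rec$drug_name, rec$status), collapse = "; ")
  }, "")
  out <- data.frame(
    gene_id = genes,
    hub_count = hi$hub_count,
    member_networks = hi$member_networks,
    direction = ifelse(di$status == "consistent_up", "up", "down"),
    n_up = di$n_up,
    n_down = di$n_down,
    drugs = drugs,
    proposed_modulation = "unassigned",
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(-out$hub_count, -(out$n_up + out$n_down), out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}
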
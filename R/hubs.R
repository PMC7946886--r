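# Hub-gene selection per network and cross-network consensus.

#' Select top-connectivity hub genes of one network
#'
#' Ranks module-assigned genes by intramodular connectivity (`k_within`)
#' and keeps the top fraction. Genes exactly tied with the boundary value
#' are all included, so selection never depends on input order. Unassigned
#' genes (`k_within = 0` by convention) are excluded from the ranking.
#'
#' @param connectivity A `connectivity_table` from
#'   [intramodular_connectivity()].
#' @param top_fraction Fraction in (0, 1) of ranked genes to keep
#'   (default 0.20).
#' @param dataset_id Identifier recorded on the hub set; defaults to the
#'   attribute carried by the connectivity table, if any.
#'
#' @return An object of class `hub_set`: list with `dataset_id`,
#'   `top_fraction`, `genes` (character) and `threshold_k` (`k_within` of
#'   the last included gene).
#' @export
select_hubs <- function(connectivity, top_fraction = 0.20,
                        dataset_id = attr(connectivity, "dataset_id") %||% "dataset") {
  stopifnot(inherits(connectivity, "connectivity_table"))
  # 1 is allowed as a degenerate "everything is a hub" cut, used by
  # overlap_profile() saturation checks
  assert_fraction(top_fraction, "top_fraction", closed_right = TRUE)
  if (nrow(connectivity) == 0) {
    stop_coexhub("empty connectivity table", "coexhub_bad_input")
  }
  ranked <- connectivity[connectivity$module != UNASSIGNED, , drop = FALSE]
  if (nrow(ranked) == 0) {
    warn_coexhub("all genes unassigned: empty hub set", "coexhub_empty_hubset")
    return(structure(list(dataset_id = dataset_id, top_fraction = top_fraction,
                          genes = character(0), threshold_k = NA_real_),
                     class = "hub_set"))
  }
  n_sel <- ceiling(top_fraction * nrow(ranked))
  kw <- sort(ranked$k_within, decreasing = TRUE)
  threshold_k <- kw[n_sel]
  genes <- ranked$gene_id[ranked$k_within >= threshold_k]
  structure(
    list(dataset_id = dataset_id, top_fraction = top_fraction,
         genes = sort(genes), threshold_k = threshold_k),
    class = "hub_set"
  )
}

#' Cross-network consensus of hub sets
#'
#' Counts, for every gene, the number of networks whose hub set contains
#' it, and extracts the consensus list of genes that are hubs in at least
#' `min_networks` networks. Also returns the overlap-degree histogram
#' (how many genes are hubs in exactly j networks).
#'
#' @param hubsets List of `hub_set` objects with distinct dataset ids.
#' @param min_networks Minimum number of networks for consensus
#'   (default 2, i.e. "more than one network").
#'
#' @return An object of class `consensus_table`: list with `table` (data
#'   frame: gene_id, hub_count, member_networks), `consensus_genes`,
#'   `histogram` (named count vector over overlap degrees 1..n_networks),
#'   `min_networks` and `n_networks`.
#' @export
consensus_hubs <- function(hubsets, min_networks = 2) {
  if (length(hubsets) < 2) {
    stop_coexhub("at least 2 hub sets are required", "coexhub_bad_input")
  }
  stopifnot(all(vapply(hubsets, inherits, TRUE, "hub_set")))
  assert_count(min_networks, "min_networks", min = 1)
  ids <- vapply(hubsets, function(h) h$dataset_id, "")
  if (anyDuplicated(ids)) {
    stop_coexhub(sprintf("duplicate dataset ids: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 "coexhub_duplicate_dataset")
  }
  membership <- lapply(hubsets, function(h) unique(h$genes))
  all_genes <- sort(unique(unlist(membership)))
  counts <- integer(length(all_genes))
  names(counts) <- all_genes
  members <- stats::setNames(vector("list", length(all_genes)), all_genes)
  for (i in seq_along(membership)) {
    g <- membership[[i]]
    counts[g] <- counts[g] + 1L
    for (gg in g) members[[gg]] <- c(members[[gg]], ids[i])
  }
  tab <- data.frame(
    gene_id = all_genes,
    hub_count = as.integer(counts),
    member_networks = vapply(members, function(m) paste(sort(m), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$hub_count, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  hist <- vapply(seq_along(hubsets), function(j) sum(counts == j), integer(1))
  names(hist) <- as.character(seq_along(hubsets))
  structure(
    list(table = tab,
         consensus_genes = sort(all_genes[counts >= min_networks]),
         histogram = hist,
         min_networks = as.integer(min_networks),
         n_networks = length(hubsets)),
    class = "consensus_table"
  )
}

#' Overlap profile across hub-selection fractions
#'
#' Recomputes the hub sets of every network at each selection fraction and
#' tabulates the overlap-degree histogram, the evidence used to justify a
#' particular fraction: a good cut yields many genes shared by most
#' networks.
#'
#' @param networks List of `network_model` objects (or
#'   `connectivity_table`s).
#' @param fractions Selection fractions to profile
#'   (default `c(0.05, 0.10, 0.20)`).
#'
#' @return Data frame with columns `fraction`, `overlap_degree` and
#'   `n_genes`.
#' @export
overlap_profile <- function(networks, fractions = c(0.05, 0.10, 0.20)) {
  if (length(networks) < 2) {
    stop_coexhub("at least 2 networks are required", "coexhub_bad_input")
  }
  for (f in fractions) assert_fraction(f, "fractions", closed_right = TRUE)
  conn_of <- function(nw, i) {
    if (inherits(nw, "network_model")) {
      structure(nw$connectivity, dataset_id = nw$dataset_id)
    } else {
      structure(nw, dataset_id = sprintf("dataset%d", i))
    }
  }
  out <- list()
  for (f in fractions) {
    hubsets <- lapply(seq_along(networks), function(i) {
      co <- conn_of(networks[[i]], i)
      select_hubs(co, top_fraction = f,
                  dataset_id = attr(co, "dataset_id"))
    })
    cons <- consensus_hubs(hubsets, min_networks = 1)
    out[[length(out) + 1]] <- data.frame(
      fraction = f,
      overlap_degree = as.integer(names(cons$histogram)),
      n_genes = as.integer(cons$histogram),
      row.names = NULL
    )
  }
  do.call(rbind, out)
}
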
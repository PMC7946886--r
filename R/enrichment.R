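# Over-representation analysis of gene sets against annotation terms:
# one-sided hypergeometric test, fold enrichment, Benjamini-Hochberg FDR.

#' Build an annotation collection
#'
#' Restricts every term's gene set to the universe, drops terms that fall
#' below `min_term_size` afterwards (small terms yield unstable fold
#' enrichments), and records the universe.
#'
#' @param terms Named list: `term_id -> character vector of gene ids`.
#' @param universe Character vector, the background gene universe.
#' @param term_names Optional named character vector of human-readable
#'   term names (defaults to the term ids).
#' @param min_term_size Minimum term size after restriction (default 3).
#'
#' @return An object of class `annotation_collection`: list with `terms`
#'   (restricted sets), `term_names` and `universe`.
#' @export
annotation_collection <- function(terms, universe, term_names = NULL,
                                  min_term_size = 3) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  universe <- unique(as.character(universe))
  if (length(universe) < 1) {
    stop_coexhub("universe must contain at least one gene", "coexhub_bad_input")
  }
  restricted <- lapply(terms, function(g) intersect(unique(g), universe))
  sizes <- lengths(restricted)
  if (any(sizes < min_term_size)) {
    warn_coexhub(sprintf("dropping %d terms smaller than %d after restriction",
                         sum(sizes < min_term_size), min_term_size),
                 "coexhub_terms_dropped")
  }
  restricted <- restricted[sizes >= min_term_size]
  tn <- stats::setNames(names(restricted), names(restricted))
  if (!is.null(term_names)) {
    hit <- intersect(names(tn), names(term_names))
    tn[hit] <- term_names[hit]
  }
  structure(list(terms = restricted, term_names = tn, universe = universe),
            class = "annotation_collection")
}

#' Read a GMT-format annotation file
#'
#' Standard GMT: one term per line, tab-separated as
#' `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @param universe Background universe; defaults to the union of all genes
#'   appearing in the file.
#' @param min_term_size Passed to [annotation_collection()].
#'
#' @return An `annotation_collection`.
#' @export
read_gmt <- function(path, universe = NULL, min_term_size = 3) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    stop_coexhub(sprintf("malformed GMT lines (need id, name, >=1 gene): %s",
                         paste(utils::head(short, 10), collapse = ", ")),
                 "coexhub_bad_input")
  }
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids)) {
    stop_coexhub("duplicate term ids in GMT file", "coexhub_bad_input")
  }
  terms <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  term_names <- stats::setNames(vapply(parts, `[[`, "", 2), ids)
  if (is.null(universe)) universe <- unique(unlist(terms))
  annotation_collection(terms, universe, term_names = term_names,
                        min_term_size = min_term_size)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order and clipped at 1.
#' Delegates to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_coexhub("p-values must lie in (0, 1]", "coexhub_bad_input")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For every term, tests whether the query set hits the term more often
#' than expected by chance: upper-tail hypergeometric probability
#' `P(X >= k)` with `N` universe genes of which `K` are in the term and
#' `n` are queried. Fold enrichment is `(k/n) / (K/N)`. Terms are declared
#' enriched at Benjamini-Hochberg `q < fdr_threshold`.
#'
#' @param query Character vector of gene ids (restricted to the universe;
#'   an empty intersection is an error).
#' @param collection An `annotation_collection`.
#' @param fdr_threshold FDR level for the `enriched` flag (default 0.05).
#'
#' @return A data frame of class `enrichment_result` with one row per term
#'   (`term_id`, `term_name`, `k`, `n`, `K`, `N`, `fold_enrichment`,
#'   `p_value`, `q_value`, `enriched`), sorted by q, then p, then term id.
#' @export
hypergeometric_enrichment <- function(query, collection,
                                      fdr_threshold = 0.05) {
  stopifnot(inherits(collection, "annotation_collection"))
  query <- intersect(unique(as.character(query)), collection$universe)
  if (length(query) == 0) {
    stop_coexhub("query has no genes in the universe", "coexhub_bad_input")
  }
  N <- length(collection$universe)
  n <- length(query)
  term_ids <- names(collection$terms)
  K <- lengths(collection$terms)
  if (any(K > N)) {
    stop_coexhub("term larger than universe", "coexhub_bad_input")
  }
  k <- vapply(collection$terms, function(g) length(intersect(query, g)),
              integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- (k / n) / (K / N)
  q <- bh_fdr(p)
  out <- data.frame(term_id = term_ids,
                    term_name = unname(collection$term_names[term_ids]),
                    k = as.integer(k), n = n, K = as.integer(K), N = N,
                    fold_enrichment = as.numeric(fold),
                    p_value = as.numeric(p), q_value = as.numeric(q),
                    enriched = q < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Average fold enrichment of a term across result lists
#'
#' Mean fold enrichment of one term over the result lists in which it
#' passed the FDR gate; a term enriched in fewer than two lists is
#' excluded with a warning and `NA` is returned, so exclusions are
#' signalled rather than silently dropped.
#'
#' @param results_by_dataset List of `enrichment_result` data frames.
#' @param term_id Term to average.
#' @return Mean fold enrichment (numeric scalar), or `NA` with a warning.
#' @export
average_fold_enrichment <- function(results_by_dataset, term_id) {
  stopifnot(all(vapply(results_by_dataset, inherits, TRUE,
                       "enrichment_result")))
  folds <- unlist(lapply(results_by_dataset, function(res) {
    row <- res[res$term_id == term_id & res$enriched, , drop = FALSE]
    row$fold_enrichment
  }))
  if (length(folds) < 2) {
    warn_coexhub(sprintf(
      "term %s is enriched in %d result list(s); need >= 2 for averaging",
      term_id, length(folds)), "coexhub_term_not_shared")
    return(NA_real_)
  }
  mean(folds)
}

#' Average fold enrichment table over all terms shared by >= 2 lists
#'
#' @param results_by_dataset List of `enrichment_result` data frames.
#' @return Data frame with `term_id`, `n_enriched_in` and
#'   `mean_fold_enrichment`, restricted to terms enriched in at least two
#'   lists and sorted by decreasing mean fold.
#' @export
average_fold_table <- function(results_by_dataset) {
  stopifnot(all(vapply(results_by_dataset, inherits, TRUE,
                       "enrichment_result")))
  enriched_terms <- unlist(lapply(results_by_dataset, function(res) {
    res$term_id[res$enriched]
  }))
  counts <- table(enriched_terms)
  shared <- names(counts)[counts >= 2]
  if (length(shared) == 0) {
    return(data.frame(term_id = character(0), n_enriched_in = integer(0),
                      mean_fold_enrichment = numeric(0),
                      stringsAsFactors = FALSE))
  }
  folds <- vapply(shared, function(tid) {
    suppressWarnings(average_fold_enrichment(results_by_dataset, tid))
  }, numeric(1))
  out <- data.frame(term_id = shared,
                    n_enriched_in = as.integer(counts[shared]),
                    mean_fold_enrichment = as.numeric(folds),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$mean_fold_enrichment, out$term_id), , drop = FALSE]
}
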
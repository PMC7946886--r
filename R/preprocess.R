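# Pre-network preprocessing: quantile normalization across samples within a
# dataset, then coefficient-of-variation gene filtering.

#' Preprocessing configuration
#'
#' Bundles the options controlling gene filtering before network
#' construction. The coefficient of variation (CV = sd/mean) is computed on
#' the unlogged scale by default (`unlog_base = 2`, i.e. on `2^x`), because
#' on log-scale values the CV is not invariant to rescaling the underlying
#' abundances.
#'
#' @param cv_mode Either `"top_fraction"` (keep the genes with the largest
#'   CV) or `"absolute_cutoff"` (keep genes with CV at or above `cv_cutoff`).
#' @param cv_top_fraction Fraction in (0, 1] of genes to keep when
#'   `cv_mode = "top_fraction"`; `ceiling(fraction * n_genes)` genes survive.
#' @param cv_cutoff Non-negative CV threshold used when
#'   `cv_mode = "absolute_cutoff"`.
#' @param unlog_base `2` to compute the CV on `2^x` (expression matrices here
#'   are log2 scale), or `"none"` to use the values as-is.
#'
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(cv_mode = c("top_fraction", "absolute_cutoff"),
                              cv_top_fraction = 0.5,
                              cv_cutoff = NULL,
                              unlog_base = 2) {
  cv_mode <- match.arg(cv_mode)
  if (cv_mode == "top_fraction") {
    assert_fraction(cv_top_fraction, "cv_top_fraction", closed_right = TRUE)
  } else {
    if (is.null(cv_cutoff) || !is.numeric(cv_cutoff) || cv_cutoff < 0) {
      stop_coexhub("`cv_cutoff` must be a non-negative number in absolute_cutoff mode",
                   "coexhub_bad_input")
    }
  }
  if (!identical(unlog_base, 2) && !identical(unlog_base, "none")) {
    stop_coexhub("`unlog_base` must be 2 or \"none\"", "coexhub_bad_input")
  }
  structure(
    list(cv_mode = cv_mode, cv_top_fraction = cv_top_fraction,
         cv_cutoff = cv_cutoff, unlog_base = unlog_base),
    class = "preprocess_config"
  )
}

#' Quantile normalization
#'
#' Forces every sample (column) onto a common reference distribution: the
#' across-column mean of the order statistics at each rank. Tied values
#' within a column all receive the mean of the reference values at their
#' tied ranks, which makes the operation deterministic and (on tie-free
#' input) idempotent.
#'
#' @param values Numeric matrix (genes x samples) with no missing values and
#'   at least two columns.
#'
#' @return A matrix of the same dimensions and dimnames. With a single
#'   column the input is returned unchanged with a warning, since there is
#'   nothing to normalize against.
#' @export
#'
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantile_normalize(m)  # both columns become 2.5, 3.5, 4.5
quantile_normalize <- function(values) {
  assert_matrix(values)
  assert_no_missing(values)
  if (nrow(values) < 1) {
    stop_coexhub("`values` must have at least one row", "coexhub_bad_input")
  }
  if (ncol(values) == 1) {
    warn_coexhub("single-column matrix: quantile normalization is the identity",
                 "coexhub_single_column")
    return(values)
  }
  ref <- rowMeans(apply(values, 2, sort))
  out <- apply(values, 2, function(col) {
    assigned <- numeric(length(col))
    assigned[order(col)] <- ref
    # average the reference values over tied ranks
    stats::ave(assigned, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(values)
  out
}

#' Coefficient-of-variation gene filter
#'
#' Ranks genes by CV (sd/mean, computed on the unlogged scale when
#' `unlog_base = 2`) and keeps either the top fraction or all genes at or
#' above an absolute cutoff. The relative order of the kept genes is
#' preserved.
#'
#' @param values Numeric matrix (genes x samples), rows aligned with
#'   `gene_ids`.
#' @param gene_ids Character vector of gene identifiers; defaults to
#'   `rownames(values)`.
#' @param config A [preprocess_config()].
#'
#' @return A list with `values` (filtered matrix), `gene_ids` (kept ids, in
#'   original order) and `cv` (named CV vector over all input genes).
#' @export
cv_filter <- function(values, gene_ids = rownames(values),
                      config = preprocess_config()) {
  assert_matrix(values)
  assert_no_missing(values)
  if (is.null(gene_ids) || length(gene_ids) != nrow(values)) {
    stop_coexhub("`gene_ids` must align with the matrix rows", "coexhub_bad_input")
  }
  stopifnot(inherits(config, "preprocess_config"))
  y <- if (identical(config$unlog_base, 2)) 2^values else values
  mu <- rowMeans(y)
  if (any(mu <= 0)) {
    bad <- gene_ids[mu <= 0]
    stop_coexhub(
      sprintf("CV undefined for %d genes with non-positive mean (e.g. %s)",
              length(bad), paste(utils::head(bad, 5), collapse = ", ")),
      "coexhub_cv_undefined"
    )
  }
  cv <- apply(y, 1, stats::sd) / mu
  names(cv) <- gene_ids
  keep <- if (config$cv_mode == "top_fraction") {
    n_keep <- ceiling(config$cv_top_fraction * length(cv))
    rank(-cv, ties.method = "first") <= n_keep
  } else {
    cv >= config$cv_cutoff
  }
  list(values = values[keep, , drop = FALSE],
       gene_ids = gene_ids[keep],
       cv = cv)
}
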
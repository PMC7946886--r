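# Per-condition fold-change contrasts and cross-condition directional
# consistency. Significance is the 2-fold rule (|log2 fold change| >= 1,
# boundary inclusive); per-gene Welch t p-values are carried as a
# non-gating annotation only.

#' Irradiated-versus-control log2 fold-change contrast for one condition
#'
#' Computes, per gene, the difference of arm means on the log2 scale and
#' calls differential expression by the 2-fold rule: `up` when
#' `log2fc >= threshold`, `down` when `log2fc <= -threshold`, otherwise
#' `ns`.
#'
#' @param dataset An `expression_dataset` (see [generate_collection()] or
#'   [read_expression()]).
#' @param condition_id Condition to contrast; must have at least 2 control
#'   and 2 irradiated samples.
#' @param lfc_threshold Log2 fold-change threshold (default 1, i.e.
#'   2-fold).
#'
#' @return A data frame of class `de_contrast` with columns `gene_id`,
#'   `log2fc`, `call` and `p_value` (Welch two-sample t, annotation only),
#'   plus attributes `condition_id`, `n_control`, `n_irradiated` and
#'   `lfc_threshold`.
#' @export
contrast_log2fc <- function(dataset, condition_id, lfc_threshold = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  md <- dataset$metadata
  rows <- md[md$condition_id == condition_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_coexhub(sprintf("condition %s not present in metadata", condition_id),
                 "coexhub_bad_input")
  }
  arms <- unique(rows$arm)
  for (a in c("control", "irradiated")) {
    if (!a %in% arms) {
      stop_coexhub(sprintf("condition %s has no %s arm", condition_id, a),
                   "coexhub_missing_arm")
    }
  }
  ctrl <- rows$sample_id[rows$arm == "control"]
  irr <- rows$sample_id[rows$arm == "irradiated"]
  if (length(ctrl) < 2 || length(irr) < 2) {
    stop_coexhub(sprintf(
      "condition %s needs >= 2 samples per arm (control %d, irradiated %d)",
      condition_id, length(ctrl), length(irr)), "coexhub_bad_input")
  }
  xc <- dataset$values[, ctrl, drop = FALSE]
  xi <- dataset$values[, irr, drop = FALSE]
  mc <- rowMeans(xc)
  mi <- rowMeans(xi)
  lfc <- mi - mc
  # Welch t statistic, vectorized over genes
  vc <- rowSums((xc - mc)^2) / (length(ctrl) - 1)
  vi <- rowSums((xi - mi)^2) / (length(irr) - 1)
  se2 <- vc / length(ctrl) + vi / length(irr)
  tstat <- ifelse(se2 > 0, lfc / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((vc / length(ctrl))^2 / (length(ctrl) - 1) +
                          (vi / length(irr))^2 / (length(irr) - 1)),
               NA_real_)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  call <- ifelse(lfc >= lfc_threshold, "up",
                 ifelse(lfc <= -lfc_threshold, "down", "ns"))
  out <- data.frame(gene_id = rownames(dataset$values),
                    log2fc = as.numeric(lfc), call = call,
                    p_value = as.numeric(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "condition_id") <- condition_id
  attr(out, "n_control") <- length(ctrl)
  attr(out, "n_irradiated") <- length(irr)
  attr(out, "lfc_threshold") <- lfc_threshold
  class(out) <- c("de_contrast", "data.frame")
  out
}

#' Construct a contrast table from precomputed fold changes
#'
#' Mostly useful for composing consistency analyses from external or
#' fixture fold changes; applies the same 2-fold calling rule as
#' [contrast_log2fc()].
#'
#' @param gene_ids Character vector of gene ids.
#' @param log2fc Numeric vector of log2 fold changes aligned with
#'   `gene_ids`.
#' @param condition_id Condition identifier.
#' @param lfc_threshold Log2 fold-change threshold (default 1).
#'
#' @return A `de_contrast` data frame.
#' @export
de_contrast <- function(gene_ids, log2fc, condition_id, lfc_threshold = 1) {
  stopifnot(length(gene_ids) == length(log2fc))
  call <- ifelse(log2fc >= lfc_threshold, "up",
                 ifelse(log2fc <= -lfc_threshold, "down", "ns"))
  out <- data.frame(gene_id = as.character(gene_ids),
                    log2fc = as.numeric(log2fc), call = call,
                    p_value = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "condition_id") <- condition_id
  attr(out, "lfc_threshold") <- lfc_threshold
  class(out) <- c("de_contrast", "data.frame")
  out
}

#' Directional consistency across conditions
#'
#' Counts per gene the conditions called up and down and assigns a status:
#' `not_DE` when fewer than `ceiling(min_sig_fraction * n_conditions)`
#' conditions are called in either direction; otherwise `consistent_up`
#' (strict majority of up calls), `consistent_down` (strict majority of
#' down calls) or `inconsistent` (exact tie). With 32 conditions and the
#' default fraction 0.25 the gate is 8 conditions.
#'
#' @param contrasts List of `de_contrast` objects over an identical gene
#'   universe.
#' @param min_sig_fraction Fraction of conditions a gene must be called in
#'   (default 0.25).
#'
#' @return A data frame of class `de_consistency` with columns `gene_id`,
#'   `n_up`, `n_down`, `status`, plus attributes `n_conditions` and
#'   `min_sig`.
#' @export
summarize_consistency <- function(contrasts, min_sig_fraction = 0.25) {
  if (length(contrasts) < 1) {
    stop_coexhub("at least one contrast is required", "coexhub_bad_input")
  }
  stopifnot(all(vapply(contrasts, inherits, TRUE, "de_contrast")))
  assert_fraction(min_sig_fraction, "min_sig_fraction", closed_right = TRUE)
  genes <- contrasts[[1]]$gene_id
  for (ct in contrasts) {
    if (!identical(sort(ct$gene_id), sort(genes))) {
      stop_coexhub("contrasts cover mismatched gene sets",
                   "coexhub_gene_mismatch")
    }
  }
  genes <- sort(genes)
  n_up <- n_down <- stats::setNames(integer(length(genes)), genes)
  for (ct in contrasts) {
    up <- ct$gene_id[ct$call == "up"]
    dn <- ct$gene_id[ct$call == "down"]
    n_up[up] <- n_up[up] + 1L
    n_down[dn] <- n_down[dn] + 1L
  }
  n_conditions <- length(contrasts)
  min_sig <- ceiling(min_sig_fraction * n_conditions)
  total <- n_up + n_down
  status <- ifelse(total < min_sig, "not_DE",
                   ifelse(n_up > n_down, "consistent_up",
                          ifelse(n_down > n_up, "consistent_down",
                                 "inconsistent")))
  out <- data.frame(gene_id = genes, n_up = as.integer(n_up),
                    n_down = as.integer(n_down), status = status,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_conditions") <- n_conditions
  attr(out, "min_sig") <- as.integer(min_sig)
  class(out) <- c("de_consistency", "data.frame")
  out
}
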
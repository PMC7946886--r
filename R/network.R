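# Weighted coexpression network construction for one dataset: correlation,
# soft-threshold selection by scale-free topology fit, adjacency, topological
# overlap, average-linkage module detection, module eigengenes and
# intramodular connectivity.

#' Pearson correlation matrix between genes
#'
#' @param values Numeric matrix (genes x samples) with at least 3 samples;
#'   every gene must have nonzero variance (CV-filter first).
#'
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(values) {
  assert_matrix(values)
  assert_no_missing(values)
  if (ncol(values) < 3) {
    stop_coexhub("at least 3 samples are required", "coexhub_bad_input")
  }
  v <- apply(values, 1, stats::var)
  if (any(v == 0)) {
    bad <- rownames(values)[v == 0] %||% which(v == 0)
    stop_coexhub(
      sprintf("zero-variance genes: %s",
              paste(utils::head(bad, 10), collapse = ", ")),
      "coexhub_zero_variance"
    )
  }
  r <- stats::cor(t(values))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency `a_ij = |cor_ij|^beta` with the diagonal set
#' to zero so that connectivity sums exclude the gene itself.
#'
#' @param correlations Symmetric correlation matrix in \eqn{[-1, 1]}.
#' @param beta Soft-thresholding power, an integer \eqn{\ge 1}.
#'
#' @return Symmetric matrix with entries in \eqn{[0, 1]} and zero diagonal.
#' @export
adjacency_matrix <- function(correlations, beta) {
  assert_matrix(correlations, "correlations")
  if (!is.numeric(beta) || length(beta) != 1 || beta < 1) {
    stop_coexhub("`beta` must be >= 1", "coexhub_bad_input")
  }
  if (max(abs(correlations)) > 1 + 1e-8) {
    stop_coexhub("correlation entries must lie in [-1, 1]", "coexhub_bad_input")
  }
  a <- pmin(abs(correlations), 1)^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit of a weighted network
#'
#' Bins the connectivity distribution into `n_bins` equal-width bins, fits
#' `log10 p(k)` on `log10 mean(k)` over the non-empty bins by least squares,
#' and reports the signed fit index `-sign(slope) * R^2`: positive when the
#' frequency of high-connectivity genes decays with connectivity, as a
#' scale-free degree distribution requires.
#'
#' @param adjacency Adjacency matrix from [adjacency_matrix()].
#' @param n_bins Number of equal-width connectivity bins (default 10).
#'
#' @return A list with `signed_r2`, `slope`, `mean_k`, `n_bins_used` and
#'   `defined`. When fewer than 3 non-empty bins remain, or all genes have
#'   identical connectivity, the fit is undefined: `defined = FALSE` and the
#'   fit fields are `NA` (distinct from a merely low R^2).
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  assert_matrix(adjacency, "adjacency")
  assert_count(n_bins, "n_bins", min = 2)
  if (nrow(adjacency) < 3) {
    stop_coexhub("at least 3 genes are required", "coexhub_bad_input")
  }
  k <- rowSums(adjacency)
  mean_k <- mean(k)
  undefined <- function() {
    list(signed_r2 = NA_real_, slope = NA_real_, mean_k = mean_k,
         n_bins_used = 0L, defined = FALSE)
  }
  if (diff(range(k)) == 0) return(undefined())
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  tab <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(tab) & tab > 0 & !is.na(kmean) & kmean > 0
  if (sum(keep) < 3) return(undefined())
  p_k <- as.numeric(tab[keep]) / length(k)
  log_k <- log10(as.numeric(kmean[keep]))
  log_p <- log10(p_k)
  fit <- stats::lm(log_p ~ log_k)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(signed_r2 = -sign(slope) * r2, slope = slope, mean_k = mean_k,
       n_bins_used = sum(keep), defined = TRUE)
}

# Selection rule shared by pick_soft_threshold: smallest beta whose signed
# R^2 reaches the cutoff; otherwise record the argmax as a fallback.
select_beta <- function(grid, signed_r2, r2_cutoff) {
  ok <- !is.na(signed_r2) & signed_r2 >= r2_cutoff
  chosen <- if (any(ok)) grid[which(ok)[1]] else NA_integer_
  fallback <- if (all(is.na(signed_r2))) NA_integer_ else
    grid[which.max(signed_r2)]
  list(chosen_beta = chosen, fallback_beta = fallback)
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' Evaluates [scale_free_fit()] on the adjacency at every power of the grid
#' and picks the smallest power whose signed R^2 reaches `r2_cutoff`. When
#' none qualifies, `chosen_beta` is `NA` and the power with the largest
#' signed R^2 is recorded as `fallback_beta`.
#'
#' @param values Preprocessed expression matrix (genes x samples).
#' @param beta_grid Integer powers to scan (default 1..20).
#' @param r2_cutoff Signed R^2 required to accept a power (default 0.80).
#' @param n_bins Bins for [scale_free_fit()].
#'
#' @return An object of class `soft_threshold`: a list with `table` (one row
#'   per power: beta, signed_r2, slope, mean_k), `chosen_beta`,
#'   `fallback_beta` and `r2_cutoff`.
#' @export
pick_soft_threshold <- function(values, beta_grid = 1:20, r2_cutoff = 0.80,
                                n_bins = 10) {
  if (length(beta_grid) == 0) {
    stop_coexhub("`beta_grid` must be non-empty", "coexhub_bad_input")
  }
  beta_grid <- sort(unique(as.integer(beta_grid)))
  r <- correlation_matrix(values)
  rows <- lapply(beta_grid, function(b) {
    fit <- scale_free_fit(adjacency_matrix(r, b), n_bins = n_bins)
    data.frame(beta = b, signed_r2 = fit$signed_r2, slope = fit$slope,
               mean_k = fit$mean_k)
  })
  tab <- do.call(rbind, rows)
  sel <- select_beta(tab$beta, tab$signed_r2, r2_cutoff)
  structure(
    list(table = tab, chosen_beta = sel$chosen_beta,
         fallback_beta = sel$fallback_beta, r2_cutoff = r2_cutoff),
    class = "soft_threshold"
  )
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat("Soft-threshold scan over beta", min(x$table$beta), "..",
      max(x$table$beta), "\n")
  if (is.na(x$chosen_beta)) {
    cat("No beta reached signed R^2 >=", x$r2_cutoff,
        "- fallback beta:", x$fallback_beta, "\n")
  } else {
    cat("Chosen beta:", x$chosen_beta, "(signed R^2 >=", x$r2_cutoff, ")\n")
  }
  invisible(x)
}

#' Topological overlap similarity
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `L_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; the diagonal is 1. Genes
#' sharing many strong neighbours score high even when their direct
#' adjacency is modest.
#'
#' @param adjacency Adjacency matrix with zero diagonal and entries in
#'   \eqn{[0, 1]}.
#'
#' @return Symmetric matrix with entries in \eqn{[0, 1]} and unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  assert_matrix(adjacency, "adjacency")
  if (min(adjacency) < 0 || max(adjacency) > 1) {
    stop_coexhub("adjacency entries must lie in [0, 1]", "coexhub_bad_input")
  }
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  pmin(pmax(tom, 0), 1)
}

#' Detect modules by average-linkage clustering of the TOM dendrogram
#'
#' Clusters genes on dissimilarity `1 - TOM` with average-linkage
#' agglomeration and cuts the dendrogram at a static height. Because the
#' absolute scale of `1 - TOM` merge heights shifts with the
#' soft-threshold power (large powers compress all heights toward 1), the
#' cut is applied on the range-normalized height scale: `cut_height = h`
#' cuts at `h_min + h * (h_max - h_min)` where `h_min`/`h_max` are the
#' smallest and largest merge heights. Average-linkage tree topology is
#' invariant under this affine rescaling, so the tree itself is the
#' standard TOM dendrogram.
#'
#' Clusters below `min_module_size` are discarded, as are clusters whose
#' mean within-cluster TOM does not exceed `separability_ratio` times
#' their mean TOM to the rest of the network — a guard that leaves pure
#' noise (all TOM approximately equal) fully unassigned. Discarded genes
#' get label 0. Surviving clusters are relabeled 1..M by decreasing size
#' with ties broken by the lexicographically smallest member gene id.
#'
#' When the expression matrix is supplied, the initial clusters are
#' treated as module cores and membership is refined by module-membership
#' correlation (kME): each gene is assigned to the module whose core
#' eigengene it correlates with most strongly in absolute value, provided
#' that correlation reaches `kme_threshold`; all other genes are left
#' unassigned. This both completes modules beyond their dendrogram cores
#' and sheds genes that attached to a core by chance, and modules that
#' shrink below `min_module_size` after refinement are dropped.
#'
#' @param tom TOM similarity matrix from [tom_similarity()], with gene ids
#'   as dimnames.
#' @param min_module_size Smallest cluster kept as a module (default 30).
#' @param cut_height Dendrogram cut position on the range-normalized merge
#'   height scale, in (0, 1] (default 0.99).
#' @param separability_ratio Required ratio of within-cluster to
#'   cluster-to-rest mean TOM (default 2); set to 0 to disable.
#' @param values Optional expression matrix (genes x samples, rows
#'   matching `tom`) enabling kME membership refinement.
#' @param kme_threshold Minimum absolute eigengene correlation for module
#'   membership during refinement (default 0.35).
#'
#' @return An object of class `module_partition`: list with `assignment`
#'   (named integer vector, 0 = unassigned), `min_module_size`, `cut_height`
#'   and `n_modules`.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99,
                           separability_ratio = 2, values = NULL,
                           kme_threshold = 0.35) {
  assert_matrix(tom, "tom")
  assert_count(min_module_size, "min_module_size", min = 2)
  if (cut_height <= 0 || cut_height > 1) {
    stop_coexhub("`cut_height` must lie in (0, 1]", "coexhub_bad_input")
  }
  genes <- rownames(tom) %||% sprintf("g%d", seq_len(nrow(tom)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # exactly tied merges can leave sub-epsilon height inversions that
  # cutree refuses; snap them
  if (is.unsorted(hc$height)) {
    if (max(hc$height - cummax(hc$height)) > 1e-8) {
      stop_coexhub("dendrogram heights are non-monotone beyond tolerance",
                   "coexhub_degenerate")
    }
    hc$height <- cummax(hc$height)
  }
  h_min <- min(hc$height)
  h_max <- max(hc$height)
  no_structure <- (h_max - h_min) < 1e-12
  raw <- if (no_structure) {
    stats::setNames(seq_along(genes), genes)  # degenerate: all singletons
  } else {
    stats::cutree(hc, h = h_min + cut_height * (h_max - h_min))
  }
  names(raw) <- genes
  sizes <- table(raw)
  # when kME refinement will follow, the dendrogram clusters only seed the
  # modules, so a smaller core floor applies; the full min_module_size is
  # enforced on the refined membership
  core_floor <- if (is.null(values)) min_module_size else
    max(8L, ceiling(min_module_size / 3))
  keep_labels <- names(sizes)[sizes >= core_floor]
  # separability guard: a genuine module is denser inside than towards
  # the rest of the network
  if (separability_ratio > 0 && length(keep_labels) > 0) {
    sep_ok <- vapply(keep_labels, function(l) {
      idx <- which(raw == l)
      if (length(idx) == length(genes)) return(TRUE)
      inside <- tom[idx, idx]
      s_in <- mean(inside[upper.tri(inside)])
      s_out <- mean(tom[idx, -idx])
      is.finite(s_in) && (s_out == 0 || s_in >= separability_ratio * s_out)
    }, logical(1))
    keep_labels <- keep_labels[sep_ok]
  }
  # kME refinement against the core eigengenes
  if (!is.null(values) && length(keep_labels) > 0) {
    assert_matrix(values)
    if (!identical(rownames(values), genes)) {
      stop_coexhub("`values` rows must match the TOM genes",
                   "coexhub_gene_mismatch")
    }
    membership <- stats::setNames(
      as.integer(factor(ifelse(raw %in% keep_labels, raw, NA),
                        levels = keep_labels)), genes)
    membership[is.na(membership)] <- UNASSIGNED
    # iterate: eigengenes sharpen as membership completes, recapturing
    # genes that correlate with the refined module but not its raw core
    for (pass in 1:3) {
      labels <- setdiff(sort(unique(membership)), UNASSIGNED)
      if (length(labels) == 0) break
      part <- structure(list(assignment = membership,
                             min_module_size = min_module_size,
                             cut_height = cut_height,
                             n_modules = length(labels)),
                        class = "module_partition")
      eig <- vapply(labels, function(m) module_eigengene(values, part, m),
                    numeric(ncol(values)))
      kme <- abs(stats::cor(t(values), eig))
      best <- max.col(kme, ties.method = "first")
      best_val <- kme[cbind(seq_len(nrow(kme)), best)]
      new_membership <- stats::setNames(
        ifelse(best_val >= kme_threshold, labels[best], UNASSIGNED), genes)
      # drop modules that fall below the final size floor
      msizes <- table(new_membership[new_membership != UNASSIGNED])
      bad <- as.integer(names(msizes)[msizes < min_module_size])
      new_membership[new_membership %in% bad] <- UNASSIGNED
      if (identical(new_membership, membership)) { membership <- new_membership; break }
      membership <- new_membership
    }
    raw <- membership
    sizes <- table(raw)
    keep_labels <- setdiff(names(sizes)[sizes >= min_module_size], "0")
  }
  assignment <- rep(UNASSIGNED, length(raw))
  names(assignment) <- genes
  if (length(keep_labels) > 0) {
    # order surviving clusters by decreasing size, ties by smallest gene id
    min_gene <- vapply(keep_labels, function(l) min(genes[raw == l]), "")
    ord <- order(-as.numeric(sizes[keep_labels]), min_gene)
    for (m in seq_along(ord)) {
      assignment[raw == keep_labels[ord[m]]] <- m
    }
  }
  structure(
    list(assignment = assignment, min_module_size = min_module_size,
         cut_height = cut_height,
         n_modules = length(keep_labels)),
    class = "module_partition"
  )
}

#' Module eigengene
#'
#' First principal component of the per-gene standardized expression of one
#' module, scaled to unit variance, with the sign fixed so its correlation
#' with the module's mean standardized profile is non-negative.
#'
#' @param values Expression matrix (genes x samples) covering the module's
#'   genes.
#' @param partition A `module_partition` over the same genes.
#' @param module_label Positive module label to summarise.
#'
#' @return Numeric vector over samples (named if `values` has colnames).
#' @export
module_eigengene <- function(values, partition, module_label) {
  assert_matrix(values)
  stopifnot(inherits(partition, "module_partition"))
  genes <- names(partition$assignment)[partition$assignment == module_label]
  genes <- intersect(genes, rownames(values))
  if (length(genes) < 2) {
    stop_coexhub("module must contain at least 2 genes", "coexhub_bad_input")
  }
  x <- values[genes, , drop = FALSE]
  xs <- t(scale(t(x)))
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (stats::sd(e) == 0) {
    stop_coexhub("degenerate module: eigengene has zero variance",
                 "coexhub_degenerate")
  }
  e <- e / stats::sd(e)
  ref <- colMeans(xs)
  if (stats::sd(ref) > 0 && stats::cor(e, ref) < 0) e <- -e
  names(e) <- colnames(values)
  e
}

#' Whole-network and intramodular connectivity
#'
#' @param adjacency Adjacency matrix with gene ids as dimnames.
#' @param partition A `module_partition` over the same genes.
#'
#' @return A data frame of class `connectivity_table` with columns
#'   `gene_id`, `module`, `k_total` (sum of adjacency to all other genes)
#'   and `k_within` (sum of adjacency to same-module genes; 0 for
#'   unassigned genes by convention).
#' @export
intramodular_connectivity <- function(adjacency, partition) {
  assert_matrix(adjacency, "adjacency")
  stopifnot(inherits(partition, "module_partition"))
  genes <- rownames(adjacency) %||% sprintf("g%d", seq_len(nrow(adjacency)))
  if (!setequal(genes, names(partition$assignment))) {
    stop_coexhub("adjacency and partition cover different gene sets",
                 "coexhub_gene_mismatch")
  }
  mod <- partition$assignment[genes]
  k_total <- rowSums(adjacency)
  k_within <- numeric(length(genes))
  for (m in setdiff(unique(mod), UNASSIGNED)) {
    idx <- which(mod == m)
    k_within[idx] <- rowSums(adjacency[idx, idx, drop = FALSE])
  }
  out <- data.frame(gene_id = genes, module = as.integer(mod),
                    k_total = as.numeric(k_total),
                    k_within = k_within, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("connectivity_table", "data.frame")
  out
}

#' Build the full network model for one dataset
#'
#' Convenience wrapper running soft-threshold selection, adjacency, TOM,
#' module detection, eigengenes and connectivity in one call. When no power
#' reaches the R^2 cutoff the recorded fallback power (largest signed R^2)
#' is used and flagged.
#'
#' @param values Preprocessed expression matrix (genes x samples) with gene
#'   ids as rownames.
#' @param dataset_id Identifier carried into downstream tables.
#' @param beta_grid,r2_cutoff,n_bins Passed to [pick_soft_threshold()].
#' @param min_module_size,cut_height,separability_ratio,kme_threshold
#'   Passed to [detect_modules()]; `build_network` always supplies the
#'   expression matrix so kME refinement is active.
#'
#' @return An object of class `network_model`: list with `dataset_id`,
#'   `soft_threshold`, `beta_used`, `partition`, `connectivity` and
#'   `eigengenes` (module x sample matrix).
#' @export
build_network <- function(values, dataset_id = "dataset",
                          beta_grid = 1:20, r2_cutoff = 0.80, n_bins = 10,
                          min_module_size = 30, cut_height = 0.99,
                          separability_ratio = 2, kme_threshold = 0.35) {
  st <- pick_soft_threshold(values, beta_grid = beta_grid,
                            r2_cutoff = r2_cutoff, n_bins = n_bins)
  beta_used <- if (is.na(st$chosen_beta)) st$fallback_beta else st$chosen_beta
  if (is.na(st$chosen_beta)) {
    warn_coexhub(sprintf(
      "dataset %s: no beta reached signed R^2 >= %.2f; using fallback beta %d",
      dataset_id, r2_cutoff, beta_used), "coexhub_beta_fallback")
  }
  r <- correlation_matrix(values)
  a <- adjacency_matrix(r, beta_used)
  tom <- tom_similarity(a)
  partition <- detect_modules(tom, min_module_size = min_module_size,
                              cut_height = cut_height,
                              separability_ratio = separability_ratio,
                              values = values, kme_threshold = kme_threshold)
  conn <- intramodular_connectivity(a, partition)
  labels <- setdiff(sort(unique(partition$assignment)), UNASSIGNED)
  eig <- NULL
  if (length(labels) > 0) {
    eig <- t(vapply(labels, function(m) module_eigengene(values, partition, m),
                    numeric(ncol(values))))
    rownames(eig) <- sprintf("ME%d", labels)
    colnames(eig) <- colnames(values)
  }
  structure(
    list(dataset_id = dataset_id, soft_threshold = st, beta_used = beta_used,
         partition = partition, connectivity = conn, eigengenes = eig),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat("Coexpression network for", x$dataset_id, "\n",
      " beta =", x$beta_used,
      "| modules =", x$partition$n_modules,
      "| genes =", nrow(x$connectivity),
      "(", sum(x$connectivity$module == UNASSIGNED), "unassigned )\n")
  invisible(x)
}
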
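# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive loops / closed forms, sharing no code with
# the package internals.

# O(n^3) topological overlap by explicit triple loop
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l_ij <- 0
      for (u in seq_len(n)) l_ij <- l_ij + a[i, u] * a[u, j]
      k_i <- sum(a[i, ]); k_j <- sum(a[j, ])
      out[i, j] <- (l_ij + a[i, j]) / (min(k_i, k_j) + 1 - a[i, j])
    }
  }
  out
}

# exact upper-tail hypergeometric by combinatorial summation
hyper_tail_oracle <- function(N, K, n, k) {
  i <- max(k, 0):min(K, n)
  if (length(i) == 0 || max(k, 0) > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up computed literally from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# random valid adjacency matrix (symmetric, [0,1], zero diagonal)
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  rownames(a) <- colnames(a) <- sprintf("g%02d", seq_len(n))
  a
}

# small expression dataset built by hand for contrast tests
toy_dataset <- function(ctrl, irr, gene_ids = sprintf("g%d", seq_len(nrow(ctrl)))) {
  values <- cbind(ctrl, irr)
  rownames(values) <- gene_ids
  colnames(values) <- c(sprintf("c%d", seq_len(ncol(ctrl))),
                        sprintf("i%d", seq_len(ncol(irr))))
  md <- data.frame(
    sample_id = colnames(values),
    condition_id = "C1",
    arm = rep(c("control", "irradiated"), c(ncol(ctrl), ncol(irr))),
    dose_gray = rep(c(0, 8), c(ncol(ctrl), ncol(irr))),
    time_hours = 24,
    stringsAsFactors = FALSE
  )
  structure(list(dataset_id = "toy", values = values, metadata = md),
            class = "expression_dataset")
}

# connectivity table built directly (bypasses network construction)
toy_connectivity <- function(gene_id, module, k_within,
                             k_total = k_within + 0.5) {
  out <- data.frame(gene_id = gene_id, module = as.integer(module),
                    k_total = k_total, k_within = k_within,
                    stringsAsFactors = FALSE)
  class(out) <- c("connectivity_table", "data.frame")
  out
}

toy_hubset <- function(genes, id) {
  structure(list(dataset_id = id, top_fraction = 0.2,
                 genes = sort(genes), threshold_k = 0),
            class = "hub_set")
}

# compact synthetic config for fast unit tests
tiny_config <- function(...) {
  synthetic_config(n_genes = 150, n_modules = 2, module_sizes = c(50L, 50L),
                   n_datasets = 2, samples_per_dataset = c(48L, 48L),
                   conditions_per_dataset = c(3L, 3L),
                   de_conditions_range = c(2L, 4L), ...)
}
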
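test_that("generation is deterministic given the seed", {
  a <- generate_collection(tiny_config(seed = 7))
  b <- generate_collection(tiny_config(seed = 7))
  expect_identical(a, b)
  c2 <- generate_collection(tiny_config(seed = 8))
  expect_false(identical(a$datasets[[1]]$values, c2$datasets[[1]]$values))
})

test_that("noise-free module genes are perfectly correlated", {
  syn <- synthetic_config(n_genes = 60, n_modules = 1, module_sizes = 40L,
                          n_datasets = 1, samples_per_dataset = 20L,
                          conditions_per_dataset = 2L, noise_sd = 0,
                          frac_de = 1e-9, de_hub_prob = 1e-9, seed = 3)
  coll <- generate_collection(syn)
  tm <- coll$truth$module_of_gene
  v <- coll$datasets[[1]]$values[tm == 1, ]
  r <- cor(t(v))
  expect_lt(max(abs(abs(r) - 1)), 1e-12)
})

test_that("within-module correlation clearly exceeds between-module", {
  syn <- synthetic_config(n_genes = 500, n_modules = 5,
                          module_sizes = rep(100L, 5), n_datasets = 1,
                          samples_per_dataset = 60L,
                          conditions_per_dataset = 5L,
                          loading_range_hub = c(0.85, 0.95),
                          loading_range_nonhub = c(0.4, 0.6),
                          noise_sd = 1, seed = 1)
  coll <- generate_collection(syn)
  tm <- coll$truth$module_of_gene
  v <- coll$datasets[[1]]$values
  r <- cor(t(v))
  same <- outer(tm, tm, "==")
  diag(same) <- NA
  within <- mean(abs(r[same & !is.na(same)]))
  between <- mean(abs(r[!same & !is.na(same)]))
  expect_gt(within, between + 0.05)
  expect_gt(within / between, 1.5)
})

test_that("increasing noise monotonically decreases within-module correlation", {
  wm <- vapply(c(0.3, 1, 2), function(ns) {
    syn <- tiny_config(noise_sd = ns, seed = 5)
    coll <- generate_collection(syn)
    tm <- coll$truth$module_of_gene
    v <- coll$datasets[[1]]$values
    r <- cor(t(v[tm == 1, ]))
    mean(abs(r[upper.tri(r)]))
  }, numeric(1))
  expect_true(all(diff(wm) < 0))
})

test_that("planted truth is internally consistent", {
  coll <- generate_collection(tiny_config(seed = 2))
  truth <- coll$truth
  # hubs are module genes
  expect_true(all(truth$module_of_gene[truth$hub_genes] != 0))
  # stored consistent_direction equals the majority rule recomputed
  # from the planted per-condition directions
  n_cond <- nrow(truth$conditions)
  min_sig <- ceiling(0.25 * n_cond)
  recomputed <- setNames(rep("none", length(truth$module_of_gene)),
                         names(truth$module_of_gene))
  for (g in unique(truth$de_direction$gene_id)) {
    sub <- truth$de_direction[truth$de_direction$gene_id == g, ]
    n_up <- sum(sub$direction == "up")
    n_down <- sum(sub$direction == "down")
    if (n_up + n_down >= min_sig && n_up != n_down) {
      recomputed[g] <- if (n_up > n_down) "up" else "down"
    }
  }
  expect_identical(recomputed, truth$consistent_direction)
  # catalog covers exactly the druggable genes
  expect_setequal(unique(coll$catalog$gene_id), truth$druggable_genes)
})

test_that("condition design guarantees two samples per arm", {
  coll <- generate_collection(tiny_config(seed = 4))
  for (ds in coll$datasets) {
    tab <- table(ds$metadata$condition_id, ds$metadata$arm)
    expect_true(all(tab >= 2))
    expect_false(any(is.na(ds$values)))
    expect_false(anyDuplicated(rownames(ds$values)) > 0)
    expect_false(anyDuplicated(ds$metadata$sample_id) > 0)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_genes = 100, module_sizes = rep(60L, 2),
                                n_modules = 2,
                                samples_per_dataset = rep(48L, 5)),
               class = "coexhub_bad_config")
  expect_error(synthetic_config(samples_per_dataset = c(3L, rep(144L, 4))),
               class = "coexhub_bad_config")
  expect_error(synthetic_config(loading_range_hub = c(0.5, 0.6),
                                loading_range_nonhub = c(0.4, 0.55)),
               class = "coexhub_bad_config")
  expect_error(synthetic_config(de_majority_prob = 0.4),
               class = "coexhub_bad_config")
  # a condition count the samples cannot support
  expect_error(synthetic_config(conditions_per_dataset = c(50L, 7L, 6L, 6L, 6L)),
               class = "coexhub_bad_config")
})

test_that("synthetic annotations enrich planted modules by construction", {
  coll <- generate_collection(tiny_config(seed = 6))
  ann <- suppressWarnings(synthetic_annotations(coll$truth, seed = 1))
  module1 <- names(coll$truth$module_of_gene)[coll$truth$module_of_gene == 1]
  res <- hypergeometric_enrichment(module1, ann)
  sig <- res$term_id[res$enriched]
  expect_true(any(grepl("^MODTERM_M1_", sig)))
})
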
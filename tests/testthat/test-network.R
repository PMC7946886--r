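test_that("correlation matrix matches hand-computed Pearson values", {
  v <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5),
             dup = c(1, 2, 3, 4), neg = -c(1, 2, 3, 4))
  r <- correlation_matrix(v)
  expect_equal(r["a", "b"], 0.9827, tolerance = 5e-5)
  expect_equal(r["a", "dup"], 1)
  expect_equal(r["a", "neg"], -1)
  expect_equal(diag(r), setNames(rep(1, 4), rownames(v)))
  expect_lt(max(abs(r - t(r))), 1e-12)
})

test_that("correlation matrix rejects zero-variance genes and tiny n", {
  v <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(correlation_matrix(v), class = "coexhub_zero_variance")
  expect_error(correlation_matrix(rbind(a = c(1, 2), b = c(2, 1))),
               class = "coexhub_bad_input")
})

test_that("adjacency is |cor|^beta with zero diagonal", {
  r <- rbind(c(1, -0.5, 0.9), c(-0.5, 1, 0), c(0.9, 0, 1))
  expect_equal(adjacency_matrix(r, 2)[1, 2], 0.25)
  expect_equal(adjacency_matrix(r, 6)[1, 3], 0.531441)
  a1 <- adjacency_matrix(r, 1)
  expect_equal(a1[upper.tri(a1)], abs(r)[upper.tri(r)])
  expect_equal(diag(adjacency_matrix(r, 3)), rep(0, 3))
  expect_error(adjacency_matrix(r, 0.5), class = "coexhub_bad_input")
})

test_that("scale-free fit recovers a planted power-law degree distribution", {
  # product-form adjacency with power-law weight frequencies gives a
  # log-log linear degree/frequency relation with negative slope
  w <- rep(1:8, times = round(60 * (1:8)^-1.8))
  n <- length(w)
  a <- outer(w, w) / (max(w)^2 + 1)
  diag(a) <- 0
  fit <- scale_free_fit(a, n_bins = 10)
  expect_true(fit$defined)
  expect_lt(fit$slope, 0)
  expect_gte(fit$signed_r2, 0.95)

  # independent reconstruction of the binned regression
  k <- rowSums(a)
  bin <- cut(k, 10, include.lowest = TRUE)
  tab <- table(bin)
  km <- tapply(k, bin, mean)
  keep <- tab > 0 & !is.na(km) & km > 0
  ref <- stats::lm(log10(as.numeric(tab[keep]) / n) ~ log10(as.numeric(km[keep])))
  expect_equal(fit$signed_r2,
               unname(-sign(coef(ref)[2]) * summary(ref)$r.squared),
               tolerance = 1e-12)
})

test_that("scale-free fit signals degenerate and inverted inputs", {
  # identical connectivity for every gene: fit undefined
  a <- matrix(0.4, 6, 6); diag(a) <- 0
  fit <- scale_free_fit(a)
  expect_false(fit$defined)
  expect_true(is.na(fit$signed_r2))

  # frequency increasing with connectivity: negative signed R^2
  w <- rep(c(1, 2, 4), times = c(2, 6, 18))
  a2 <- outer(w, w) / 17
  diag(a2) <- 0
  fit2 <- scale_free_fit(a2, n_bins = 6)
  expect_true(fit2$defined)
  expect_lte(fit2$signed_r2, 0)
})

test_that("beta selection takes the smallest power past the cutoff", {
  sel <- coexhub:::select_beta(1:4, c(0.5, 0.7, 0.85, 0.9), 0.80)
  expect_equal(sel$chosen_beta, 3)
  none <- coexhub:::select_beta(1:4, c(0.5, 0.7, 0.75, 0.6), 0.80)
  expect_true(is.na(none$chosen_beta))
  expect_equal(none$fallback_beta, 3)
})

test_that("mean connectivity is non-increasing in beta", {
  set.seed(3)
  v <- matrix(rnorm(40 * 20), 40, 20,
              dimnames = list(sprintf("g%d", 1:40), NULL))
  st <- pick_soft_threshold(v, beta_grid = 1:10)
  expect_true(all(diff(st$table$mean_k) <= 0))
  # strict decrease whenever some |cor| is strictly between 0 and 1
  expect_true(all(diff(st$table$mean_k) < 0))
  expect_error(pick_soft_threshold(v, beta_grid = integer(0)),
               class = "coexhub_bad_input")
})

test_that("TOM matches the hand-worked 3-gene case and brute force", {
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 0.5)
  expect_equal(diag(tom), rep(1, 3))

  z <- matrix(0, 4, 4)
  expect_equal(tom_similarity(z)[upper.tri(z)], rep(0, 6))

  a2 <- random_adjacency(25, seed = 99)
  expect_lt(max(abs(tom_similarity(a2) - tom_oracle(a2))), 1e-10)
  expect_error(tom_similarity(a2 * 2), class = "coexhub_bad_input")
})

test_that("module detection separates clean blocks and rejects noise", {
  # two noise-free blocks
  n1 <- 35; n2 <- 40
  tom <- matrix(0.01, n1 + n2, n1 + n2)
  tom[1:n1, 1:n1] <- 0.6
  tom[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- 0.6
  diag(tom) <- 1
  rownames(tom) <- colnames(tom) <- sprintf("g%02d", seq_len(n1 + n2))
  part <- detect_modules(tom, min_module_size = 30)
  expect_equal(part$n_modules, 2)
  # labels ordered by decreasing size: the 40-gene block is module 1
  expect_true(all(part$assignment[(n1 + 1):(n1 + n2)] == 1))
  expect_true(all(part$assignment[1:n1] == 2))

  # near-zero TOM everywhere: everything unassigned
  set.seed(5)
  flat <- matrix(runif(50 * 50, 0, 1e-3), 50, 50)
  flat <- (flat + t(flat)) / 2
  diag(flat) <- 1
  rownames(flat) <- colnames(flat) <- sprintf("n%02d", 1:50)
  part2 <- detect_modules(flat, min_module_size = 30)
  expect_equal(part2$n_modules, 0)
  expect_true(all(part2$assignment == 0))
})

test_that("module detection is invariant to gene input order", {
  set.seed(8)
  v <- matrix(rnorm(60 * 40), 60, 40)
  v[1:30, ] <- v[1:30, ] + 2 * matrix(rnorm(40), 30, 40, byrow = TRUE)
  v[31:60, ] <- v[31:60, ] + 2 * matrix(rnorm(40), 30, 40, byrow = TRUE)
  rownames(v) <- sprintf("g%02d", 1:60)
  tom <- tom_similarity(adjacency_matrix(correlation_matrix(v), 4))
  p1 <- detect_modules(tom, min_module_size = 20)
  perm <- sample(nrow(tom))
  p2 <- detect_modules(tom[perm, perm], min_module_size = 20)
  expect_equal(p2$assignment[names(p1$assignment)], p1$assignment)
})

test_that("module eigengene recovers the generating factor", {
  # identical genes: eigengene equals the standardized common profile
  prof <- c(1, 4, 2, 6, 3, 5)
  v <- matrix(rep(prof, each = 5), 5, byrow = FALSE,
              dimnames = list(sprintf("g%d", 1:5), NULL))
  part <- structure(list(assignment = setNames(rep(1L, 5), rownames(v)),
                         min_module_size = 2, cut_height = 0.99,
                         n_modules = 1L), class = "module_partition")
  e <- module_eigengene(v, part, 1)
  expect_equal(abs(cor(e, prof)), 1, tolerance = 1e-12)
  expect_gte(cor(e, scale(prof)[, 1]), 0)
  expect_equal(sd(e), 1, tolerance = 1e-12)

  # noise-free one-factor module: exact recovery up to sign
  set.seed(2)
  f <- rnorm(30)
  u <- runif(12, 0.4, 0.9) * sample(c(-1, 1), 12, replace = TRUE)
  v2 <- u %o% f
  rownames(v2) <- sprintf("g%d", 1:12)
  part2 <- structure(list(assignment = setNames(rep(1L, 12), rownames(v2)),
                          min_module_size = 2, cut_height = 0.99,
                          n_modules = 1L), class = "module_partition")
  e2 <- module_eigengene(v2, part2, 1)
  expect_equal(abs(cor(e2, f)), 1, tolerance = 1e-10)
  # determinism
  expect_identical(e2, module_eigengene(v2, part2, 1))
  expect_error(module_eigengene(v2[1, , drop = FALSE], part2, 1),
               class = "coexhub_bad_input")
})

test_that("intramodular connectivity matches direct summation", {
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  rownames(a) <- colnames(a) <- c("g1", "g2", "g3")
  part <- structure(list(assignment = setNames(rep(1L, 3), rownames(a)),
                         min_module_size = 2, cut_height = 0.99,
                         n_modules = 1L), class = "module_partition")
  ct <- intramodular_connectivity(a, part)
  expect_equal(ct$k_within, rep(1, 3))
  # single all-gene module: k_within equals k_total
  expect_equal(ct$k_within, ct$k_total)

  a2 <- random_adjacency(30, seed = 4)
  mods <- setNames(rep(c(1L, 2L, 0L), each = 10), rownames(a2))
  part2 <- structure(list(assignment = mods, min_module_size = 2,
                          cut_height = 0.99, n_modules = 2L),
                     class = "module_partition")
  ct2 <- intramodular_connectivity(a2, part2)
  for (i in seq_len(30)) {
    g <- ct2$gene_id[i]
    m <- mods[g]
    expect_equal(ct2$k_total[i], sum(a2[g, setdiff(rownames(a2), g)]),
                 tolerance = 1e-12)
    kw <- if (m == 0) 0 else
      sum(a2[g, setdiff(names(mods)[mods == m], g)])
    expect_equal(ct2$k_within[i], kw, tolerance = 1e-12)
  }
  expect_true(all(ct2$k_within <= ct2$k_total + 1e-12))
  part_bad <- part2
  names(part_bad$assignment)[1] <- "zzz"
  expect_error(intramodular_connectivity(a2, part_bad),
               class = "coexhub_gene_mismatch")
})
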
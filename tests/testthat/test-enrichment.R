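test_that("hypergeometric enrichment reproduces closed-form cases", {
  universe <- sprintf("g%04d", 1:1000)
  term <- universe[1:50]
  query <- c(universe[1:5], universe[101:105])  # k = 5, n = 10
  coll <- annotation_collection(list(T1 = term), universe)
  res <- hypergeometric_enrichment(query, coll)
  expect_equal(res$fold_enrichment, 10)
  expect_equal(res$k, 5L)

  # saturated term: query = universe members of a full-universe term
  uni2 <- sprintf("u%02d", 1:12)
  coll2 <- annotation_collection(list(ALL = uni2), uni2)
  res2 <- hypergeometric_enrichment(uni2, coll2)
  expect_equal(res2$p_value, 1)
  expect_equal(res2$fold_enrichment, 1)

  # worked combinatorial case: N=10, K=4, n=3, k=2 -> 1/3
  uni3 <- letters[1:10]
  coll3 <- annotation_collection(list(T = uni3[1:4]), uni3)
  res3 <- hypergeometric_enrichment(uni3[c(1, 2, 5)], coll3)
  expect_equal(res3$p_value, 1 / 3, tolerance = 1e-12)

  expect_error(hypergeometric_enrichment("absent", coll3),
               class = "coexhub_bad_input")
})

test_that("fold enrichment is invariant under gene relabeling", {
  set.seed(6)
  universe <- sprintf("g%03d", 1:200)
  terms <- list(A = sample(universe, 30), B = sample(universe, 50))
  query <- sample(universe, 25)
  res1 <- hypergeometric_enrichment(query,
                                    annotation_collection(terms, universe))
  relabel <- setNames(sprintf("x%03d", 1:200), universe)
  res2 <- hypergeometric_enrichment(
    unname(relabel[query]),
    annotation_collection(lapply(terms, function(g) unname(relabel[g])),
                          unname(relabel)))
  expect_equal(res1$p_value, res2$p_value)
  expect_equal(res1$fold_enrichment, res2$fold_enrichment)
})

test_that("bh_fdr matches the hand-computed step-up and its oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  set.seed(12)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
  expect_error(bh_fdr(c(0.5, 0)), class = "coexhub_bad_input")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "coexhub_bad_input")
})

test_that("average fold enrichment pools only enriched lists", {
  mk_res <- function(fold, enriched) {
    out <- data.frame(term_id = "T", term_name = "T", k = 5L, n = 10L,
                      K = 20L, N = 200L, fold_enrichment = fold,
                      p_value = 0.001, q_value = 0.01, enriched = enriched,
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    out
  }
  expect_equal(average_fold_enrichment(list(mk_res(16, TRUE),
                                            mk_res(16, TRUE)), "T"), 16)
  expect_equal(average_fold_enrichment(list(mk_res(6, TRUE),
                                            mk_res(10, TRUE)), "T"), 8)
  # enriched in one list only: signalled, not silently dropped
  expect_warning(
    got <- average_fold_enrichment(list(mk_res(6, TRUE), mk_res(10, FALSE)),
                                   "T"),
    class = "coexhub_term_not_shared")
  expect_true(is.na(got))

  tab <- average_fold_table(list(mk_res(6, TRUE), mk_res(10, TRUE)))
  expect_equal(tab$mean_fold_enrichment, 8)
})

test_that("GMT files round-trip through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tfirst term\tg1\tg2\tg3\tg4",
               "T2\tsecond term\tg3\tg4\tg5\tg6\tg7"), path)
  coll <- read_gmt(path)
  expect_setequal(names(coll$terms), c("T1", "T2"))
  expect_setequal(coll$terms$T1, c("g1", "g2", "g3", "g4"))
  expect_equal(unname(coll$term_names["T2"]), "second term")
  expect_setequal(coll$universe, sprintf("g%d", 1:7))

  writeLines("T1\tonly-a-name", path)
  expect_error(read_gmt(path), class = "coexhub_bad_input")
})

test_that("annotation collections restrict terms and drop small ones", {
  expect_warning(
    coll <- annotation_collection(
      list(big = sprintf("g%d", 1:10), tiny = c("g1", "zzz")),
      universe = sprintf("g%d", 1:20), min_term_size = 3),
    class = "coexhub_terms_dropped")
  expect_equal(names(coll$terms), "big")
})
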
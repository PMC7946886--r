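write_catalog <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("load_catalog parses and validates a drug-target TSV", {
  good <- data.frame(gene_id = c("g1", "g2", "g2"),
                     drug_name = c("d1", "d2", "d3"),
                     status = c("approved", "preclinical", "discovery"))
  cat1 <- load_catalog(write_catalog(good))
  expect_s3_class(cat1, "drug_target_catalog")
  expect_equal(nrow(cat1), 3)

  bad_status <- good
  bad_status$status[2] <- "imaginary"
  err <- tryCatch(load_catalog(write_catalog(bad_status)),
                  coexhub_bad_catalog = identity)
  expect_match(conditionMessage(err), "lines 3")  # header is line 1

  dup <- good
  dup$drug_name[3] <- "d2"
  err2 <- tryCatch(load_catalog(write_catalog(dup)),
                   coexhub_bad_catalog = identity)
  expect_match(conditionMessage(err2), "lines 4")

  empty <- good[0, ]
  expect_warning(cat_e <- load_catalog(write_catalog(empty)),
                 class = "coexhub_empty_catalog")
  expect_equal(nrow(cat_e), 0)

  expect_error(load_catalog(write_catalog(good[, 1:2])),
               class = "coexhub_bad_catalog")
})

toy_consensus <- function(counts) {
  tab <- data.frame(gene_id = names(counts), hub_count = as.integer(counts),
                    member_networks = "d1,d2", stringsAsFactors = FALSE)
  structure(list(table = tab,
                 consensus_genes = names(counts)[counts >= 2],
                 histogram = table(counts), min_networks = 2L,
                 n_networks = max(counts)),
            class = "consensus_table")
}

toy_de <- function(status, n_up = 8L, n_down = 0L) {
  out <- data.frame(gene_id = names(status), n_up = n_up, n_down = n_down,
                    status = unname(status), stringsAsFactors = FALSE)
  attr(out, "n_conditions") <- 32L
  attr(out, "min_sig") <- 8L
  class(out) <- c("de_consistency", "data.frame")
  out
}

test_that("build_candidates applies the three-way intersection rule", {
  cons <- toy_consensus(c(hub3 = 3, hub1 = 1, hub2 = 2))
  de <- toy_de(c(hub3 = "consistent_up", hub1 = "consistent_up",
                 hub2 = "not_DE"))
  catalog <- as_drug_target_catalog(data.frame(
    gene_id = c("hub3", "hub1", "hub2"),
    drug_name = c("d1", "d2", "d3"),
    status = rep("approved", 3), stringsAsFactors = FALSE))
  out <- build_candidates(cons, de, catalog, min_networks = 2)
  # hub3: consensus + drug + consistent -> in; hub1 fails consensus;
  # hub2 fails DE status
  expect_equal(out$gene_id, "hub3")
  expect_equal(out$direction, "up")
  expect_equal(out$proposed_modulation, "unassigned")
})

test_that("candidates equal brute-force enumeration on random fixtures", {
  set.seed(99)
  for (rep in 1:5) {
    genes <- sprintf("g%02d", 1:30)
    counts <- setNames(sample(0:4, 30, replace = TRUE), genes)
    status <- setNames(sample(c("consistent_up", "consistent_down",
                                "inconsistent", "not_DE"), 30, TRUE), genes)
    in_cat <- sample(genes, 15)
    cons <- toy_consensus(counts[counts > 0])
    de <- toy_de(status)
    catalog <- as_drug_target_catalog(data.frame(
      gene_id = in_cat, drug_name = sprintf("d%02d", seq_along(in_cat)),
      status = sample(c("approved", "preclinical"), 15, TRUE),
      stringsAsFactors = FALSE))
    got <- suppressWarnings(build_candidates(cons, de, catalog, 2))
    want <- genes[counts >= 2 & genes %in% in_cat &
                    status %in% c("consistent_up", "consistent_down")]
    expect_setequal(got$gene_id, want)

    # removing one catalog record never adds a candidate
    if (nrow(catalog) > 1) {
      smaller <- as_drug_target_catalog(catalog[-1, ])
      got2 <- suppressWarnings(build_candidates(cons, de, smaller, 2))
      expect_true(all(got2$gene_id %in% got$gene_id))
    }
  }
})

test_that("deterministic candidate ordering and empty-input behavior", {
  cons <- toy_consensus(c(a = 2, b = 3, c = 3))
  de <- toy_de(c(a = "consistent_up", b = "consistent_down",
                 c = "consistent_up"),
               n_up = c(9L, 1L, 4L), n_down = c(0L, 9L, 4L))
  catalog <- as_drug_target_catalog(data.frame(
    gene_id = c("a", "b", "c"), drug_name = c("x", "y", "z"),
    status = rep("launched", 3), stringsAsFactors = FALSE))
  out <- build_candidates(cons, de, catalog)
  # order: decreasing hub_count, then decreasing n_up+n_down, then gene id
  expect_equal(out$gene_id, c("b", "c", "a"))

  empty_cat <- suppressWarnings(as_drug_target_catalog(
    data.frame(gene_id = character(0), drug_name = character(0),
               status = character(0), stringsAsFactors = FALSE)))
  expect_warning(out2 <- build_candidates(cons, de, empty_cat),
                 class = "coexhub_empty_candidates")
  expect_equal(nrow(out2), 0)
})
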
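test_that("EASE and Fisher tails match a direct summation oracle", {
  expect_equal(ease_test(0, 10, 50, 1000), list(fisher_p = 1, ease_p = 1))
  expect_equal(ease_test(5, 5, 5, 5), list(fisher_p = 1, ease_p = 1))
  res <- ease_test(5, 100, 50, 20000)
  expect_equal(res$fisher_p, oracle_hyper_tail(5, 100, 50, 20000))
  expect_equal(res$ease_p, oracle_hyper_tail(4, 100, 50, 20000))
  # randomized grid: the EASE penalty always holds for k >= 1
  set.seed(41)
  for (i in 1:50) {
    N <- sample(200:5000, 1)
    K <- sample(5:100, 1)
    m <- sample(5:150, 1)
    k <- sample(1:min(m, K), 1)
    r <- ease_test(k, m, K, N)
    expect_gte(r$ease_p, r$fisher_p)
    expect_equal(r$fisher_p, oracle_hyper_tail(k, m, K, N))
  }
})

test_that("enrichment flags a perfectly enriched set and orders by q", {
  genes <- sprintf("g%03d", 1:20)
  sets <- gene_set_collection(
    list(hit = genes,
         miss = sprintf("x%03d", 1:30),
         half = c(genes[1:5], sprintf("y%03d", 1:25))),
    universe = 20000)
  res <- enrich_sets(genes, sets, fdr_threshold = 0.05)
  expect_s3_class(res, "enrichment_result")
  expect_equal(res$set[1], "hit")
  expect_true(res$flagged[1])
  expect_lt(res$q_value[1], 1e-10)
  expect_false(res$flagged[res$set == "miss"])
  # BH q monotone in sorted p order
  expect_true(all(diff(res$q_value) >= -1e-12))
  # duplicate sets get identical p and q
  sets2 <- gene_set_collection(list(a = genes[1:10], b = genes[1:10]),
                               universe = 20000)
  res2 <- enrich_sets(genes, sets2)
  expect_equal(res2$ease_p[1], res2$ease_p[2])
  expect_equal(res2$q_value[1], res2$q_value[2])
  # disjoint list errors
  expect_error(enrich_sets(c("zzz"), sets), "disjoint")
})

test_that("false-discovery control holds on random sets", {
  set.seed(42)
  universe <- sprintf("u%05d", 1:2000)
  n_rep <- 100
  flagged_frac <- replicate(n_rep, {
    sets <- lapply(1:40, function(i) sample(universe, 25))
    names(sets) <- paste0("s", 1:40)
    gs <- gene_set_collection(sets, universe = 2000)
    genes <- sample(universe, 50)
    res <- tryCatch(enrich_sets(genes, gs, fdr_threshold = 0.05),
                    error = function(e) NULL)
    if (is.null(res)) 0 else mean(res$flagged)
  })
  mc_se <- sd(flagged_frac) / sqrt(n_rep)
  expect_lte(mean(flagged_frac), 0.05 + 3 * mc_se)
})

test_that("miRNA members are expanded through a target map", {
  mol <- tibble::tibble(gene_id = c("TP53", "mir-1", "mir-2", "KRAS"),
                        layer = c("mRNA", "miRNA", "miRNA", "protein"))
  map <- tibble::tibble(mirna = c("mir-1", "mir-1", "mir-9"),
                        target = c("EGFR", "MYC", "BRAF"))
  out <- expand_mirna_targets(mol, map)
  expect_setequal(out, c("TP53", "KRAS", "EGFR", "MYC"))
})
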
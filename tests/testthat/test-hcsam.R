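test_that("sample clustering separates distant clouds and maps clusters to classes", {
  set.seed(31)
  v <- cbind(matrix(rnorm(50 * 4), 50), matrix(rnorm(50 * 4, 100), 50))
  m <- toy_omic(v)
  labels <- sample_labels(omic_samples(m), rep(c("near", "far"), each = 4))
  rep <- hc_samples(m, labels, k = 2)
  expect_equal(rep$accuracy, 1)
  expect_equal(sort(unname(rep$cluster_map)), c("far", "near"))

  # degenerate: identical columns merge at height 0, majority class wins
  v2 <- matrix(rep(rnorm(30), 6), 30)
  m2 <- toy_omic(v2)
  labels2 <- sample_labels(omic_samples(m2), c("A", "A", "A", "A", "B", "B"))
  rep2 <- hc_samples(m2, labels2, k = 2)
  expect_gte(rep2$accuracy, 4 / 6) # at least the majority fraction

  # accuracy invariant under column permutation
  perm <- sample(8)
  mp <- m[, c("molecule_id", "gene_id", "layer", omic_samples(m)[perm])]
  repp <- hc_samples(mp, labels, k = 2)
  expect_equal(repp$accuracy, rep$accuracy)
})

test_that("merge order matches a brute-force complete-linkage oracle", {
  set.seed(32)
  v <- matrix(rnorm(40 * 12), 40) +
    matrix(rep(c(0, 6, 12), each = 4 * 40), 40)
  m <- toy_omic(v)
  labels <- sample_labels(omic_samples(m), rep(c("a", "b", "c"), each = 4))
  rep <- hc_samples(m, labels, k = 3)
  d <- as.matrix(dist(t(v)))
  orc <- oracle_agglomerate(d, "complete")
  expect_equal(rep$merge_heights, orc$heights, tolerance = 1e-10)
  expect_true(same_partition(rep$assignment$cluster, orc$assignment_at(
    mean(c(orc$heights[9], orc$heights[10])))))
  expect_equal(rep$accuracy, 1)
})

test_that("SAM statistic reduces to the pooled-SE t statistic at s0 = 0", {
  set.seed(33)
  m <- toy_omic(matrix(rnorm(200 * 10), 200))
  g <- rep(c(TRUE, FALSE), each = 5)
  res <- sam_statistic(m, g, s0 = 0)
  v <- omic_values(m)
  tstat <- apply(v, 1, function(row) {
    t.test(row[g], row[!g], var.equal = TRUE)$statistic
  })
  expect_equal(unname(res$d), unname(tstat), tolerance = 1e-12)

  # zero numerator -> d = 0 regardless of s0, even at zero variance
  m0 <- toy_omic(rbind(c(rep(2, 6)), rnorm(6)))
  res0 <- sam_statistic(m0, rep(c(TRUE, FALSE), each = 3), s0 = 0)
  expect_equal(unname(res0$d[1]), 0)

  # antisymmetry under group swap
  res_swap <- sam_statistic(m, !g, s0 = 0)
  expect_equal(res_swap$d, -res$d)
})

test_that("s0 selection reproduces an independent grid-search oracle", {
  set.seed(34)
  m <- toy_omic(matrix(rnorm(1000 * 12, sd = rep(runif(1000, 0.2, 3), 12)),
                       1000))
  g <- rep(c(TRUE, FALSE), each = 6)
  res <- sam_statistic(m, g)
  parts <- jofa:::sam_d_parts(omic_values(m), g)
  expect_equal(res$s0, oracle_s0(parts$diff, parts$s))
  expect_gte(res$s0, 0)
})

test_that("SAM calling is calibrated on null data and powerful on planted effects", {
  set.seed(35)
  null_m <- toy_omic(matrix(rnorm(500 * 40), 500))
  g <- rep(c(TRUE, FALSE), each = 20)
  res <- suppressWarnings(sam_call(null_m, g, delta = 2.6, n_perm = 100,
                                   seed = 7))
  expect_true(nrow(res$called) == 0 || res$fdr > 0.5)

  # 50 planted molecules with a 5 sd effect among 950 null
  set.seed(36)
  v <- matrix(rnorm(1000 * 40), 1000)
  v[1:50, 1:20] <- v[1:50, 1:20] + 5
  m <- toy_omic(v)
  res2 <- sam_call(m, g, delta = 1.2, n_perm = 500, fdr_cap = 0.05, seed = 7)
  called <- res2$called$molecule_id
  planted_ids <- m$molecule_id[1:50]
  recall <- mean(planted_ids %in% called)
  expect_gte(recall, 0.9)
  expect_lte(res2$fdr, 0.05)

  # delta -> Inf gives an empty call set; calls shrink with delta
  res3 <- suppressWarnings(sam_call(m, g, delta = 1e6, n_perm = 100, seed = 7))
  expect_equal(nrow(res3$called), 0)
  res_small <- sam_call(m, g, delta = 0.8, n_perm = 100, seed = 7)
  expect_gte(nrow(res_small$called), nrow(res2$called))
})

test_that("one-vs-rest SAM partitions its signature by layer", {
  sim <- generate_multiomic(small_spec(), seed = 37)
  joint <- std_joint(sim)
  res <- suppressWarnings(run_hcsam(joint, sim$labels, "ME", delta = 1.5,
                                    n_perm = 100, seed = 37))
  expect_true(all(unlist(lapply(res$by_layer, function(x) x$molecule_id)) %in%
                    joint$molecule_id))
  expect_setequal(names(res$by_layer),
                  unique(res$called$layer))
  expect_error(run_hcsam(joint, sim$labels, "NOPE", n_perm = 100), "absent")
})
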
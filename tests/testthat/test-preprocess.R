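test_that("cross-platform filter keeps genes by their best probe correlation", {
  v <- matrix(rnorm(8), 2, 4)
  a <- toy_omic(v, genes = c("gA", "gB"))
  b <- toy_omic(rbind(v[1, ], -v[2, ]), genes = c("gA", "gB"))
  res <- cross_platform_filter(a, b, min_r = 0.5)
  expect_equal(res$best_r[res$gene_id == "gA"], 1)   # identical probes
  expect_equal(res$best_r[res$gene_id == "gB"], -1)  # exact sign flip
  expect_equal(res$retained, c(TRUE, FALSE))
})

test_that("cross-platform filter matches exhaustive pair enumeration", {
  set.seed(42)
  genes <- rep(c("g1", "g2", "g3"), each = 2)
  a <- toy_omic(matrix(rnorm(6 * 8), 6), genes = genes)
  b_vals <- matrix(rnorm(6 * 8), 6)
  b <- omic_tbl(b_vals, sprintf("q%02d", 1:6), genes, "mRNA",
                omic_samples(a))
  res <- cross_platform_filter(a, b, min_r = 0.5)
  av <- omic_values(a); bv <- omic_values(b)
  for (g in c("g1", "g2", "g3")) {
    pairs <- expand.grid(i = which(genes == g), j = which(genes == g))
    brute <- max(mapply(function(i, j) cor(av[i, ], bv[j, ]),
                        pairs$i, pairs$j))
    expect_equal(res$best_r[res$gene_id == g], brute)
    expect_equal(res$retained[res$gene_id == g], brute > 0.5)
  }
  # symmetry up to reported values
  res_ba <- cross_platform_filter(b, a, min_r = 0.5)
  expect_equal(sort(res$gene_id[res$retained]),
               sort(res_ba$gene_id[res_ba$retained]))
})

test_that("probe collapsing merges correlated probes and splits independent ones", {
  base <- rnorm(6)
  m <- toy_omic(rbind(base, base * 2 + 1), genes = c("g", "g"))
  out <- collapse_probes(m, 0.6)
  expect_equal(nrow(out), 1) # r = 1, distance 0
  expect_equal(unname(omic_values(out)[1, ]),
               unname(colMeans(omic_values(m))))

  set.seed(1)
  m2 <- toy_omic(rbind(rnorm(50), rnorm(50)), genes = c("g", "g"))
  r <- cor(t(omic_values(m2)))[1, 2]
  out2 <- collapse_probes(m2, 0.6)
  expect_equal(nrow(out2), if (1 - r > 0.6) 2L else 1L)

  # single-probe gene passes through untouched
  single <- toy_omic(matrix(1:4, 1), genes = "solo")
  expect_equal(omic_values(collapse_probes(single, 0.6)),
               omic_values(single))
})

test_that("probe clusters equal a brute-force agglomeration oracle", {
  set.seed(11)
  block1 <- rnorm(20)
  block2 <- rnorm(20)
  probes <- rbind(block1 + rnorm(20, sd = .1), block1 + rnorm(20, sd = .1),
                  block2 + rnorm(20, sd = .1), block2 + rnorm(20, sd = .1),
                  block2 + rnorm(20, sd = .1))
  m <- toy_omic(probes, genes = rep("g", 5))
  out <- collapse_probes(m, 0.6, linkage = "average")
  d <- 1 - cor(t(probes))
  orc <- oracle_agglomerate(d, "average")
  want <- orc$assignment_at(0.6)
  got <- cutree(hclust(as.dist(d), method = "average"), h = 0.6)
  expect_true(same_partition(got, want))
  expect_equal(nrow(out), length(unique(want)))
  for (cl in unique(want)) {
    mean_probe <- colMeans(probes[want == cl, , drop = FALSE])
    expect_true(any(apply(omic_values(out), 1,
                          function(r) isTRUE(all.equal(unname(r), mean_probe)))))
  }
})

test_that("max/IQR filter keeps the doubly top-half rows", {
  # hand-computed 4x4 integer toy: row A top-half on both criteria
  m <- toy_omic(rbind(A = c(10, 2, 8, 4),   # max 10, IQR 5
                      B = c(9, 9, 9, 9),    # max 9,  IQR 0
                      C = c(1, 8, 2, 3),    # max 8,  IQR 2.75
                      D = c(0, 1, 2, 1)))   # max 2,  IQR 0.5
  st <- probe_stats(m)
  expect_equal(st$max_p, c(10, 9, 8, 2))
  expect_equal(st$iqr_p, unname(apply(omic_values(m), 1, IQR)))
  out <- filter_max_iqr(m)
  expect_equal(out$molecule_id, "p01")
  expect_equal(attr(out, "filter_counts"), c(kept = 1L, dropped = 3L))

  # identical rows: ties at the median all survive
  m2 <- toy_omic(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(nrow(filter_max_iqr(m2)), 2)
})

test_that("max/IQR filter matches a sort-based oracle on random data", {
  set.seed(5)
  v <- matrix(rexp(100 * 10), 100)
  m <- toy_omic(v)
  out <- filter_max_iqr(m)
  mx <- apply(v, 1, max)
  iq <- apply(v, 1, IQR)
  med <- function(x) { s <- sort(x); (s[50] + s[51]) / 2 }
  keep <- mx >= med(mx) & iq >= med(iq)
  expect_equal(out$molecule_id, m$molecule_id[keep])

  # idempotence when survivors stay top-half (constructed: two tied groups)
  v2 <- rbind(matrix(5, 6, 4) + rep(c(0, 2, 5, 9), each = 6) ,
              matrix(0.1, 6, 4))
  m2 <- toy_omic(v2)
  once <- filter_max_iqr(m2)
  twice <- filter_max_iqr(once)
  expect_equal(twice$molecule_id, once$molecule_id)
})

test_that("standardization follows both conventions and zeroes row means", {
  m <- toy_omic(rbind(c(2, 4, 6), c(5, 5, 5)))
  out <- standardize_rows(m, "mean_baseline")
  expect_equal(unname(omic_values(out)[1, ]), c(-0.5, 0, 0.5))
  expect_equal(unname(omic_values(out)[2, ]), c(0, 0, 0))
  expect_equal(standardization_mode(out), "mean_baseline")

  mz <- toy_omic(matrix(c(1, 2, 3, 6), 1))
  outz <- standardize_rows(mz, "zscore")
  expect_equal(unname(omic_values(outz)[1, ]),
               (c(1, 2, 3, 6) - 3) / sd(c(1, 2, 3, 6))) # n-1 convention

  # undefined rows drop with a message, or error under strict
  m0 <- toy_omic(rbind(c(-1, 0, 1), c(1, 2, 3)))
  expect_message(out0 <- standardize_rows(m0, "mean_baseline"), "1 row")
  expect_equal(out0$molecule_id, "p02")
  expect_error(standardize_rows(m0, "mean_baseline", strict = TRUE), "p01")
  mc <- toy_omic(rbind(c(4, 4, 4), c(1, 2, 3)))
  expect_message(outc <- standardize_rows(mc, "zscore"), "1 row")
  expect_equal(outc$molecule_id, "p02")
})

test_that("row means vanish after standardization on random matrices", {
  set.seed(2)
  for (mode in c("mean_baseline", "zscore")) {
    m <- toy_omic(matrix(rexp(50 * 12) + 1, 50))
    out <- standardize_rows(m, mode)
    expect_lt(max(abs(rowMeans(omic_values(out)))), 1e-10)
  }
})

test_that("joint assembly stacks rows and realigns permuted columns", {
  set.seed(8)
  l1 <- standardize_rows(toy_omic(matrix(rexp(5 * 4) + 1, 5), layer = "mRNA"))
  l2 <- standardize_rows(toy_omic(matrix(rexp(3 * 4) + 1, 3), layer = "miRNA"))
  l3 <- standardize_rows(toy_omic(matrix(rexp(2 * 4) + 1, 2), layer = "protein"))
  joint <- assemble_joint(list(l1, l2, l3))
  expect_equal(nrow(joint), 10)
  expect_equal(table(joint$layer)[["miRNA"]], 3)

  perm <- c(3, 1, 4, 2)
  l2p <- l2[, c("molecule_id", "gene_id", "layer", omic_samples(l2)[perm])]
  joint2 <- assemble_joint(list(l1, l2p))
  expect_equal(omic_values(joint2)[6:8, ], omic_values(l2))

  l_missing <- l2[, setdiff(names(l2), "s4")]
  expect_error(assemble_joint(list(l1, l_missing)), "s4")
})
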
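test_that("factor cap equals an independent eigenvalue count", {
  set.seed(10)
  x <- toy_omic(matrix(rexp(500 * 10) + 1, 500))
  joint <- standardize_rows(x, "zscore")
  n <- max_meaningful_factors(joint)
  ev <- eigen(cor(omic_values(joint)), only.values = TRUE)$values
  expect_equal(n, sum(ev > 1))

  # two duplicated samples: correlation [[1,1],[1,1]], eigenvalues {2,0} -> 1
  v <- matrix(rnorm(100), 100, 1)
  dup <- toy_omic(cbind(v, v))
  expect_equal(max_meaningful_factors(dup), 1L)

  # planted one-factor structure dominates
  sim <- generate_multiomic(small_spec(k_true = 1,
                                       class_factor_map = "ME"), seed = 2)
  joint1 <- std_joint(sim)
  ev1 <- eigen(cor(omic_values(joint1)), only.values = TRUE)$values
  expect_gt(ev1[1], 1)
  expect_gte(max_meaningful_factors(joint1), 1L)
})

# direct X = FL + e construction with orthogonal (disjoint-block) loading
# rows, fed to the fit without row standardization so the planted geometry is
# preserved exactly
ortho_two_factor <- function(noise_sd, seed, m = 1500, n = 60) {
  set.seed(seed)
  L <- rbind(c(rep(1, 30), rep(0, 30)),
             c(rep(0, 30), rep(1, 30)))
  Fm <- matrix(rnorm(m * 2), m, 2)
  X <- Fm %*% L + matrix(rnorm(m * n, sd = noise_sd), m, n)
  list(x = toy_omic(X), L = L)
}

test_that("noiseless planted structure is reproduced almost exactly", {
  d <- ortho_two_factor(noise_sd = 0, seed = 3)
  fit <- suppressWarnings(fit_factor_model(d$x, 2, seed = 3))
  expect_lt(fit$reproduction_err, 1e-6)
  mt <- match_factors(fit$loadings, t(d$L))
  expect_gt(min(mt$cor), 0.99)
  # communality + uniqueness == 1
  expect_lt(max(abs(fit$communality + fit$uniqueness - 1)), 1e-6)
})

test_that("two-factor recovery after varimax and sign alignment", {
  d <- ortho_two_factor(noise_sd = 0.1, seed = 5)
  fit <- suppressWarnings(fit_factor_model(d$x, 2, rotation = "varimax",
                                           seed = 5))
  mt <- match_factors(fit$loadings, t(d$L))
  expect_gte(min(mt$cor), 0.95)
  # rank-1 data: a single factor explains ~all common variance
  d1 <- list(x = d$x)
  one <- suppressWarnings(fit_factor_model(ortho_two_factor(0, 7)$x, 1,
                                           seed = 7))
  expect_gt(sum(one$explained), 0.3) # one of two equal blocks
})

test_that("model family is complete, ordered and deterministic", {
  sim <- generate_multiomic(small_spec(), seed = 4)
  joint <- std_joint(sim)
  fam <- fit_model_family(joint, n_max = 3, seed = 4)
  expect_equal(length(fam$models), 3)
  expect_equal(vapply(fam$models, `[[`, integer(1), "k"), 1:3)
  fam2 <- fit_model_family(joint, n_max = 3, seed = 4)
  expect_identical(fam$models[[3]]$loadings, fam2$models[[3]]$loadings)
  # explained common variance is non-decreasing in k
  expl <- vapply(fam$models, function(m) sum(m$explained), double(1))
  expect_true(all(diff(expl) > -1e-8))
})

test_that("key molecules respect the threshold, ordering and layer partition", {
  sim <- generate_multiomic(small_spec(), seed = 6)
  joint <- std_joint(sim)
  fit <- fit_factor_model(joint, 8, seed = 6)
  # synthetic score check on a handmade model: {3.0, 2.6, 2.59, -3.1}
  toy <- fit
  toy$scores <- matrix(c(3.0, 2.6, 2.59, -3.1), ncol = 1,
                       dimnames = list(NULL, "F1"))
  toy$k <- 1L
  toy$row_meta <- tibble::tibble(molecule_id = c("a", "b", "c", "d"),
                                 gene_id = c("a", "b", "c", "d"),
                                 layer = c("mRNA", "mRNA", "miRNA", "protein"))
  ks <- extract_key_molecules(toy, 1, 2.6)
  expect_equal(ks$molecules$molecule_id, c("d", "a", "b"))
  expect_true(all(abs(ks$molecules$score) >= 2.6))

  # unattainable threshold -> empty set; threshold 0 -> everything
  expect_equal(nrow(extract_key_molecules(toy, 1, 99)$molecules), 0)
  expect_equal(nrow(extract_key_molecules(fit, 1, 0)$molecules), nrow(joint))
})

test_that("hungarian assignment matches brute force on small matrices", {
  set.seed(12)
  for (n in c(2, 3, 4, 5)) {
    for (rep in 1:5) {
      cost <- matrix(rnorm(n * n), n)
      a <- hungarian_assign(cost)
      perms <- do.call(rbind, combinat_perms(seq_len(n)))
      vals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
      expect_equal(sum(cost[cbind(seq_len(n), a)]), min(vals))
    }
  }
})
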
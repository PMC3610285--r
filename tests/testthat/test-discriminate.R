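test_that("LDA accuracy is exact on separable data and honest on permuted labels", {
  feats <- matrix(c(-5.0, -5.1, 5.0, 5.1), ncol = 1)
  res <- lda_accuracy(feats, c("A", "A", "B", "B"))
  expect_equal(res$accuracy, 1)
  expect_equal(res$scheme, "loocv")
  expect_equal(sum(res$confusion), 4)

  # permutation null: mean accuracy near chance
  set.seed(21)
  n <- 40
  x <- matrix(c(rnorm(n / 2, -3), rnorm(n / 2, 3)), ncol = 1)
  y <- rep(c("A", "B"), each = n / 2)
  accs <- replicate(200, lda_accuracy(x, sample(y))$accuracy)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("LOOCV accuracy approaches the known Bayes rate", {
  set.seed(22)
  n <- 400
  # two unit-variance Gaussians at +-qnorm(0.9): Bayes error 0.1
  mu <- qnorm(0.9)
  x <- matrix(c(rnorm(n / 2, -mu), rnorm(n / 2, mu)), ncol = 1)
  y <- rep(c("A", "B"), each = n / 2)
  acc <- lda_accuracy(x, y)$accuracy
  expect_lt(abs(acc - 0.9), 0.05)
})

test_that("chi-square significance matches a closed-form oracle", {
  expect_lt(chi2_significance(matrix(c(30, 0, 0, 30), 2)), 1e-10)
  expect_equal(chi2_significance(matrix(c(15, 15, 15, 15), 2)), 1)
  tab <- matrix(c(29, 2, 1, 28), 2)
  # closed form: n (ad - bc)^2 / (r1 r2 c1 c2)
  stat_oracle <- 60 * (29 * 28 - 1 * 2)^2 / (30 * 30 * 31 * 29)
  stat <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  expect_equal(unname(stat), stat_oracle, tolerance = 1e-12)
  expect_equal(suppressWarnings(chi2_significance(tab)), oracle_chisq_p(tab))
  expect_warning(p0 <- chi2_significance(matrix(c(0, 0, 2, 58), 2)),
                 "zero marginal")
  expect_equal(p0, 1)
})

test_that("chi-square p decreases as mass moves onto the diagonal", {
  ps <- sapply(0:10, function(k) {
    suppressWarnings(chi2_significance(matrix(c(20 + k, 10 - k + 10,
                                                10 - k + 10, 20 + k), 2) / 2))
  })
  expect_true(all(diff(ps) < 1e-12))
})

test_that("scan flags planted associations and best model selection is sane", {
  sim <- generate_multiomic(small_spec(), seed = 9)
  joint <- std_joint(sim)
  fam <- suppressWarnings(fit_model_family(joint, seed = 9))
  rep <- per_factor_class_scan(fam, sim$labels)
  expect_s3_class(rep, "discrimination_report")
  expect_true(all(rep$pairs$accuracy >= 0 & rep$pairs$accuracy <= 1))
  expect_true(all(rep$pairs$p_value > 0 & rep$pairs$p_value <= 1))
  # most mapped classes report a strongly discriminating factor even at this
  # reduced molecule count (the full-size property is asserted elsewhere)
  spec <- sim$truth$spec
  cb <- rep$class_best[rep$class_best$class %in% spec$class_factor_map, ]
  expect_gte(sum(cb$accuracy > 0.9 & cb$p_value < 0.01), 6)
  # an unattainable floor flags nothing
  rep2 <- per_factor_class_scan(fam, sim$labels, accuracy_floor = 1.01)
  expect_equal(sum(rep2$pairs$flagged), 0)
  # report invariant to sample order
  perm <- sample(nrow(sim$labels))
  rep3 <- per_factor_class_scan(fam, sim$labels[perm, ])
  expect_equal(rep3$pairs, rep$pairs)
})

test_that("tie-break prefers the smaller model", {
  sim <- generate_multiomic(small_spec(), seed = 13)
  joint <- std_joint(sim)
  fam <- suppressWarnings(fit_model_family(joint, seed = 13))
  det <- select_best_model(fam, sim$labels, details = TRUE)
  acc <- det$model_accuracy$accuracy
  expect_equal(det$best_model, which.max(acc))
  expect_true(all(acc[det$best_model] >= acc))
  if (sum(acc == max(acc)) > 1) {
    expect_equal(det$best_model, min(which(acc == max(acc))))
  }
})
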
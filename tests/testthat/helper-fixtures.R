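# Small fixtures and independent oracles used across test files.

toy_omic <- function(values, layer = "mRNA", genes = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  omic_tbl(values,
           molecule_id = sprintf("p%02d", seq_len(n)),
           gene_id = genes %||% sprintf("g%02d", seq_len(n)),
           layer = layer,
           sample_ids = sprintf("s%d", seq_len(ncol(values))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small spec that keeps unit tests fast
small_spec <- function(...) {
  synthetic_spec(
    n_samples = 60,
    layer_sizes = c(mRNA = 400, miRNA = 60, protein = 30),
    keys_per_layer = c(mRNA = 8, miRNA = 2, protein = 1),
    ...
  )
}

std_joint <- function(sim, mode = "mean_baseline") {
  assemble_joint(lapply(sim$layers, standardize_rows, mode = mode))
}

# ---- oracles ----------------------------------------------------------------

# Pearson chi-square p-value from the closed form, no library test function.
oracle_chisq_p <- function(tab) {
  tab <- as.matrix(tab)
  ex <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - ex)^2 / ex)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

# hypergeometric upper tail P(X >= k) by direct summation over choose().
oracle_hyper_tail <- function(k, m, K, N) {
  if (k <= 0) return(1)
  xs <- k:min(m, K)
  sum(exp(lchoose(K, xs) + lchoose(N - K, m - xs) - lchoose(N, m)))
}

# naive agglomerative clustering: returns the merge heights and the flat
# cluster assignment at height h, for average or complete linkage on a
# distance matrix. Small-n reference for hclust-based code.
oracle_agglomerate <- function(d, linkage = c("average", "complete"),
                               cut_h = NULL, cut_k = NULL) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- double(0)
  steps <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        link <- if (linkage == "average") mean(dd) else max(dd)
        if (link < best[1]) best <- c(link, i, j)
      }
    }
    heights <- c(heights, best[1])
    steps[[length(steps) + 1]] <- list(members = sort(c(clusters[[best[2]]],
                                                        clusters[[best[3]]])),
                                       height = best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  assignment_at <- function(h) {
    cl <- as.list(seq_len(n))
    for (s in steps) {
      if (s$height > h) break
      keep <- Filter(function(x) !any(x %in% s$members), cl)
      cl <- c(keep, list(sort(unique(c(s$members)))))
    }
    out <- integer(n)
    for (i in seq_along(cl)) out[cl[[i]]] <- i
    out
  }
  list(heights = heights, steps = steps, assignment_at = assignment_at)
}

# label partition equality up to renaming
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

labels_for_test <- function(labels, sample_ids) {
  labels$label[match(sample_ids, labels$sample_id)]
}

# all permutations of a vector (for brute-force assignment checks, n <= 6)
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# SAM s0 grid search, reimplemented with plain loops
oracle_s0 <- function(diff, s) {
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05), type = 7,
                                 names = FALSE))
  bin <- cut(rank(s, ties.method = "first"), breaks = 100, labels = FALSE)
  best <- Inf
  best_s0 <- NA
  for (s0 in cand) {
    d <- diff / (s + s0)
    med <- tapply(abs(d), bin, stats::median)
    cv <- stats::sd(med) / mean(med)
    if (is.finite(cv) && cv < best) {
      best <- cv
      best_s0 <- s0
    }
  }
  best_s0
}
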
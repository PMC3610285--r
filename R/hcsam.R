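#' Hierarchical clustering of samples on the joint matrix
#'
#' Agglomerative clustering of the sample columns (Euclidean distance and
#' complete linkage by default, the base `hclust` defaults), cut at `k`
#' clusters. Each cluster is labelled by the majority true class (ties broken
#' by overall class frequency, then lexically); accuracy is the fraction of
#' samples whose cluster label matches their class, and each class gets a
#' one-vs-rest chi-square p-value.
#'
#' @param x a joint `omic_tbl`.
#' @param labels tibble from [sample_labels()].
#' @param k number of clusters (>= 2).
#' @param distance `"euclidean"` (default) or any [stats::dist()] method.
#' @param linkage agglomeration method for [stats::hclust()].
#' @return An object of class `cluster_report`: list with `merge_heights`,
#'   `assignment` (tibble sample_id/cluster/label/predicted), `cluster_map`,
#'   `accuracy`, `per_class` (tibble class/accuracy/p_value), `k`.
#' @export
hc_samples <- function(x, labels, k, distance = "euclidean",
                       linkage = "complete") {
  stopifnot(is_omic_tbl(x), k >= 2)
  v <- omic_values(x)
  stopifnot(ncol(v) >= k)
  y <- labels_for(labels, colnames(v))
  hc <- stats::hclust(stats::dist(t(v), method = distance), method = linkage)
  cl <- stats::cutree(hc, k = k)
  freq <- sort(table(y), decreasing = TRUE)
  cluster_map <- vapply(split(y, cl), function(members) {
    tab <- table(members)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      top <- top[order(-as.vector(freq[top]), top)][1]
    }
    top
  }, character(1))
  predicted <- unname(cluster_map[as.character(cl)])
  per_class <- purrr::map_dfr(sort(unique(y)), function(cls) {
    conf <- table(factor(predicted == cls, levels = c(TRUE, FALSE)),
                  factor(y == cls, levels = c(TRUE, FALSE)))
    tibble::tibble(class = cls,
                   accuracy = mean((predicted == cls) == (y == cls)),
                   p_value = suppressWarnings(chi2_significance(conf)))
  })
  structure(list(
    merge_heights = hc$height,
    merge = hc$merge,
    assignment = tibble::tibble(sample_id = colnames(v), cluster = unname(cl),
                                label = y, predicted = predicted),
    cluster_map = cluster_map,
    accuracy = mean(predicted == y),
    per_class = per_class,
    k = as.integer(k),
    distance = distance,
    linkage = linkage
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: k = %d (%s/%s), accuracy %.3f\n",
              x$k, x$distance, x$linkage, x$accuracy))
  invisible(x)
}

#' SAM moderated statistic
#'
#' Per-molecule two-group statistic d_i = (mean1 - mean2) / (s_i + s0), with
#' s_i the pooled standard error and the exchangeability factor s0 selected on
#' the percentile grid {0, 5, ..., 100} of s_i by minimizing the coefficient of
#' variation of the median absolute d_i across 100 equal-count s_i bins.
#' With s0 = 0 the statistic reduces exactly to the pooled-SE two-sample
#' t-statistic.
#'
#' @param x a joint `omic_tbl`.
#' @param groups logical or two-level vector over samples; `TRUE` (or the
#'   first level) is group 1.
#' @param s0 optional fixed value; `NULL` (default) selects it on the grid.
#' @return A list with `d` (named vector), `s0`, `s` (pooled SEs), `mean_diff`.
#' @export
sam_statistic <- function(x, groups, s0 = NULL) {
  v <- omic_values(x)
  g <- as_group_logical(groups, ncol(v))
  n1 <- sum(g)
  n2 <- sum(!g)
  stopifnot(n1 >= 2, n2 >= 2)
  stat <- sam_d_parts(v, g)
  if (is.null(s0)) s0 <- sam_select_s0(stat$diff, stat$s)
  d <- stat$diff / (stat$s + s0)
  d[stat$s + s0 == 0] <- 0 # zero variance and equal means
  names(d) <- x$molecule_id
  list(d = d, s0 = s0, s = stat$s, mean_diff = stat$diff)
}

as_group_logical <- function(groups, n) {
  if (is.logical(groups)) {
    stopifnot(length(groups) == n)
    return(groups)
  }
  lev <- unique(groups)
  stopifnot(length(lev) == 2, length(groups) == n)
  groups == lev[1]
}

sam_d_parts <- function(v, g) {
  n1 <- sum(g)
  n2 <- sum(!g)
  m1 <- rowMeans(v[, g, drop = FALSE])
  m2 <- rowMeans(v[, !g, drop = FALSE])
  ss1 <- rowSums((v[, g, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, !g, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(diff = m1 - m2, s = s)
}

# s0 grid search: candidate s0 = percentiles {0, 5, .., 100} of s; the winner
# minimizes the coefficient of variation of median |d| across 100 equal-count
# bins of s.
sam_select_s0 <- function(diff, s, probs = seq(0, 1, by = 0.05), n_bins = 100) {
  cand <- unique(stats::quantile(s, probs = probs, type = 7, names = FALSE))
  bin <- cut(rank(s, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- diff / (s + s0)
    med <- vapply(split(abs(d), bin), stats::median, double(1))
    if (mean(med) == 0) return(Inf)
    stats::sd(med) / mean(med)
  }, double(1))
  cand[which.min(cv)]
}

#' SAM calling with permutation FDR
#'
#' Observed order statistics d_(i) are compared with their expectation under
#' `n_perm` label permutations. Going outward from the centre of the expected
#' quantile plot, the first index where d_(i) - dbar_(i) >= delta fixes the
#' upper cut (and symmetrically the lower cut); molecules beyond the cuts are
#' called. FDR is the median permutation count of statistics beyond the cuts
#' divided by the observed call count (capped at 1); zero observed calls report
#' FDR 0 with a warning.
#'
#' @param x a joint `omic_tbl`.
#' @param groups two-group labelling of the samples (see [sam_statistic()]).
#' @param delta half-width of the calling band (default 2.6).
#' @param n_perm number of label permutations (>= 100; default 500).
#' @param fdr_cap maximum acceptable FDR; calls are kept only when the
#'   estimated FDR is at or below the cap (default 0.001).
#' @param seed RNG seed for the permutations.
#' @return An object of class `sam_result`: list with `d`, `s0`, `delta`,
#'   `cut_up`, `cut_low`, `called` (tibble molecule_id/gene_id/layer/d),
#'   `fdr`, `kept`, `n_perm`, `seed`.
#' @export
sam_call <- function(x, groups, delta = 2.6, n_perm = 500, fdr_cap = 0.001,
                     seed = 1) {
  stopifnot(n_perm >= 100, delta > 0)
  v <- omic_values(x)
  g <- as_group_logical(groups, ncol(v))
  obs <- sam_statistic(x, g)
  m <- length(obs$d)
  ord <- order(obs$d)
  d_sorted <- obs$d[ord]

  set.seed(seed)
  perm_sorted <- matrix(0, m, n_perm)
  for (b in seq_len(n_perm)) {
    gp <- sample(g)
    parts <- sam_d_parts(v, gp)
    db <- parts$diff / (parts$s + obs$s0)
    db[parts$s + obs$s0 == 0] <- 0
    perm_sorted[, b] <- sort(db)
  }
  dbar <- rowMeans(perm_sorted)

  # first crossing of the band, moving outward from the centre
  diff_up <- d_sorted - dbar
  up_candidates <- which(diff_up >= delta & seq_len(m) > m / 2)
  cut_up <- if (length(up_candidates)) d_sorted[min(up_candidates)] else Inf
  diff_low <- dbar - d_sorted
  low_candidates <- which(diff_low >= delta & seq_len(m) <= m / 2)
  cut_low <- if (length(low_candidates)) d_sorted[max(low_candidates)] else -Inf

  called_idx <- which(obs$d >= cut_up | obs$d <= cut_low)
  n_called <- length(called_idx)
  if (n_called == 0) {
    warning("no molecules called at delta = ", delta)
    fdr <- 0
  } else {
    perm_counts <- colSums(perm_sorted >= cut_up | perm_sorted <= cut_low)
    fdr <- min(stats::median(perm_counts) / n_called, 1)
  }
  called <- tibble::tibble(molecule_id = x$molecule_id[called_idx],
                           gene_id = x$gene_id[called_idx],
                           layer = x$layer[called_idx],
                           d = unname(obs$d[called_idx]))
  called <- called[order(-abs(called$d)), ]
  structure(list(
    d = obs$d, s0 = obs$s0, delta = delta,
    cut_up = cut_up, cut_low = cut_low,
    called = tibble::as_tibble(called),
    fdr = fdr, kept = fdr <= fdr_cap, fdr_cap = fdr_cap,
    n_perm = as.integer(n_perm), seed = as.integer(seed)
  ), class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("sam_result: %d called (delta %.2f, s0 %.3g, FDR %.4f%s)\n",
              nrow(x$called), x$delta, x$s0, x$fdr,
              if (x$kept) "" else " > cap"))
  invisible(x)
}

#' One-vs-rest SAM signature for a target class
#'
#' Runs [sam_call()] with `target_class` against all other samples on the joint
#' matrix and partitions the signature by omic layer, the HC+SAM counterpart of
#' a factor's key-molecule set.
#'
#' @param x a joint `omic_tbl`.
#' @param labels tibble from [sample_labels()].
#' @param target_class class to contrast against the rest.
#' @inheritParams sam_call
#' @return A `sam_result` with an extra `by_layer` element (named list of
#'   tibbles) and `target_class`.
#' @export
run_hcsam <- function(x, labels, target_class, delta = 2.6, fdr_cap = 0.001,
                      n_perm = 500, seed = 1) {
  y <- labels_for(labels, omic_samples(x))
  if (!target_class %in% y) {
    stop("target class '", target_class, "' absent from labels", call. = FALSE)
  }
  res <- sam_call(x, y == target_class, delta = delta, n_perm = n_perm,
                  fdr_cap = fdr_cap, seed = seed)
  res$target_class <- target_class
  res$by_layer <- split(res$called, res$called$layer)
  res
}
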
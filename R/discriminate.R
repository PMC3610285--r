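#' LDA classification accuracy of per-sample features
#'
#' Multi-class linear discriminant analysis with a shared covariance matrix,
#' evaluated either by leave-one-out cross-validation (default; honest at small
#' n) or by resubstitution. When the within-class covariance is singular,
#' a small ridge is added to the features with a warning.
#'
#' @param features numeric matrix, samples x d (e.g. factor loadings).
#' @param labels tibble from [sample_labels()] covering the feature rows, or a
#'   plain vector of class labels in row order.
#' @param scheme `"loocv"` (default) or `"resubstitution"`.
#' @return A list with `accuracy`, `confusion` (predicted x true counts),
#'   `predicted`, `scheme`.
#' @export
lda_accuracy <- function(features, labels, scheme = c("loocv", "resubstitution")) {
  scheme <- match.arg(scheme)
  features <- as.matrix(features)
  y <- if (is.data.frame(labels)) {
    labels_for(labels, rownames(features) %||% labels$sample_id)
  } else {
    as.character(labels)
  }
  stopifnot(length(y) == nrow(features))
  if (any(table(y) < 2)) stop("every class needs >= 2 samples", call. = FALSE)
  pred <- lda_predict(features, y, scheme)
  lev <- sort(unique(y))
  confusion <- table(factor(pred, levels = lev), factor(y, levels = lev))
  names(dimnames(confusion)) <- c("predicted", "true")
  list(accuracy = mean(pred == y), confusion = unclass(confusion),
       predicted = pred, scheme = scheme)
}

lda_predict <- function(features, y, scheme) {
  run <- function(x) {
    if (scheme == "loocv") {
      fit <- MASS::lda(x, grouping = y, CV = TRUE)
      as.character(fit$class)
    } else {
      fit <- MASS::lda(x, grouping = y)
      as.character(stats::predict(fit, x)$class)
    }
  }
  out <- tryCatch(suppressWarnings(run(features)), error = function(e) e)
  if (inherits(out, "error")) {
    warning("singular within-class covariance; ridge regularization applied")
    out <- ridge_lda_predict(features, y, scheme)
  }
  out
}

# Gaussian LDA with a ridge on the pooled covariance; fallback for degenerate
# feature matrices that MASS::lda rejects.
ridge_lda_predict <- function(x, y, scheme) {
  x <- as.matrix(x)
  classify <- function(train_x, train_y, test_x) {
    lev <- sort(unique(train_y))
    mu <- do.call(rbind, lapply(lev, function(cl) {
      colMeans(train_x[train_y == cl, , drop = FALSE])
    }))
    centered <- train_x - mu[match(train_y, lev), , drop = FALSE]
    w <- crossprod(centered) / max(nrow(train_x) - length(lev), 1)
    w <- w + diag(1e-6 * max(diag(w), 1e-12), ncol(w))
    winv <- solve(w)
    prior <- as.vector(table(factor(train_y, levels = lev))) / length(train_y)
    disc <- test_x %*% winv %*% t(mu) -
      matrix(0.5 * rowSums((mu %*% winv) * mu), nrow(test_x), length(lev),
             byrow = TRUE) +
      matrix(log(prior), nrow(test_x), length(lev), byrow = TRUE)
    lev[max.col(disc, ties.method = "first")]
  }
  if (scheme == "loocv") {
    vapply(seq_len(nrow(x)), function(i) {
      classify(x[-i, , drop = FALSE], y[-i], x[i, , drop = FALSE])
    }, character(1))
  } else {
    classify(x, y, x)
  }
}

#' Chi-square significance of a confusion table
#'
#' Pearson chi-square test of association between predicted and true classes,
#' without continuity correction. A zero marginal row or column makes the test
#' undefined; the conservative value p = 1 is returned with a warning.
#'
#' @param confusion contingency table of predicted vs true counts (2x2
#'   one-vs-rest or CxC).
#' @param correct apply the Yates continuity correction (2x2 tables only).
#'   Off by default; the factor scan turns it on when deciding flags, because
#'   the uncorrected test is anti-conservative on the small-margin tables that
#'   one-vs-rest classification of a rare class produces.
#' @return The p-value.
#' @export
chi2_significance <- function(confusion, correct = FALSE) {
  confusion <- as.matrix(confusion)
  stopifnot(sum(confusion) >= 1)
  if (any(rowSums(confusion) == 0) || any(colSums(confusion) == 0)) {
    warning("zero marginal in confusion table; returning p = 1")
    return(1)
  }
  ex <- outer(rowSums(confusion), colSums(confusion)) / sum(confusion)
  if (any(ex < 5)) {
    warning("expected cell count < 5; chi-square approximation is rough")
  }
  suppressWarnings(
    stats::chisq.test(confusion, correct = correct)$p.value
  )
}

ovr_scan_one <- function(feature, y, class, scheme) {
  yb <- ifelse(y == class, class, ".rest")
  res <- lda_accuracy(matrix(feature, ncol = 1), yb, scheme = scheme)
  p <- suppressWarnings(chi2_significance(res$confusion))
  # continuity-corrected p for the flag decision: a single lucky positive
  # prediction in a rare class otherwise reaches nominal significance
  p_flag <- suppressWarnings(chi2_significance(res$confusion, correct = TRUE))
  list(accuracy = res$accuracy, p_value = p, p_flag = p_flag,
       confusion = res$confusion)
}

#' Scan every (factor, class) pair of a model family
#'
#' Computes, for every model in the family, the overall multi-factor LDA
#' accuracy on the sample loadings; selects the best model (maximum accuracy,
#' ties to the smaller k); and scores every (factor, class) pair of the best
#' model by single-feature one-vs-rest LDA with a chi-square p-value. Pairs
#' with accuracy above `accuracy_floor` and p below `p_max` are flagged, and
#' each class reports its best factor (highest accuracy, then smallest p, then
#' lowest factor index).
#'
#' @param family an `fa_family`.
#' @param labels tibble from [sample_labels()].
#' @param accuracy_floor flagging floor on one-vs-rest accuracy (default 0.9).
#' @param p_max chi-square significance threshold for flagging (default 0.05).
#' @param scheme evaluation scheme, `"loocv"` or `"resubstitution"`.
#' @return An object of class `discrimination_report`: list with
#'   `model_accuracy` (tibble k/accuracy), `best_model`, `pairs` (tibble
#'   factor/class/accuracy/p_value/flagged), `class_best` (tibble class/factor/
#'   accuracy/p_value), `scheme`, `accuracy_floor`, `p_max`, and `confusion`
#'   of the best model.
#' @export
per_factor_class_scan <- function(family, labels, accuracy_floor = 0.9,
                                  p_max = 0.05, scheme = "loocv") {
  stopifnot(inherits(family, "fa_family"))
  best <- select_best_model(family, labels, scheme = scheme, details = TRUE)
  model <- family$models[[best$best_model]]
  y <- labels_for(labels, model$sample_ids)
  classes <- sort(unique(y))
  grid <- tidyr::expand_grid(factor = seq_len(model$k), class = classes)
  scanned <- purrr::pmap(grid, function(factor, class) {
    ovr_scan_one(model$loadings[, factor], y, class, scheme)
  })
  # flagging controls the family-wise error over all scanned (factor, class)
  # pairs: Holm-adjusted continuity-corrected chi-square at p_max
  pairs <- dplyr::mutate(grid,
    accuracy = purrr::map_dbl(scanned, "accuracy"),
    p_value = purrr::map_dbl(scanned, "p_value"),
    flagged = .data$accuracy > accuracy_floor &
      stats::p.adjust(purrr::map_dbl(scanned, "p_flag"), "holm") < p_max)
  class_best <- pairs |>
    dplyr::arrange(.data$class, dplyr::desc(.data$accuracy), .data$p_value,
                   .data$factor) |>
    dplyr::group_by(.data$class) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("class", "factor", "accuracy", "p_value")
  structure(list(
    model_accuracy = best$model_accuracy,
    best_model = best$best_model,
    pairs = pairs,
    class_best = class_best,
    confusion = best$confusion,
    scheme = scheme,
    accuracy_floor = accuracy_floor,
    p_max = p_max
  ), class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("discrimination_report: best model M%d (accuracy %.3f, %s)\n",
              x$best_model,
              x$model_accuracy$accuracy[x$model_accuracy$k == x$best_model],
              x$scheme))
  flagged <- x$pairs[x$pairs$flagged, ]
  cat(nrow(flagged), "flagged (factor, class) pairs\n")
  invisible(x)
}

#' Select the best model of a family by LDA accuracy
#'
#' The best model maximizes the overall LDA accuracy of its sample loadings
#' against the labels; ties break toward the smaller k (parsimony).
#'
#' @inheritParams per_factor_class_scan
#' @param scheme evaluation scheme.
#' @param details return accuracies and the best confusion matrix too.
#' @return The best model id (integer), or a list when `details = TRUE`.
#' @export
select_best_model <- function(family, labels, scheme = "loocv",
                              details = FALSE) {
  stopifnot(inherits(family, "fa_family"))
  per_model <- purrr::map(family$models, function(m) {
    y <- labels_for(labels, m$sample_ids)
    lda_accuracy(m$loadings, y, scheme = scheme)
  })
  acc <- purrr::map_dbl(per_model, "accuracy")
  best <- which.max(acc) # which.max takes the first (smallest k) on ties
  if (!details) return(as.integer(best))
  list(best_model = as.integer(best),
       model_accuracy = tibble::tibble(k = seq_along(acc), accuracy = acc),
       confusion = per_model[[best]]$confusion)
}
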
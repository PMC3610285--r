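#' Scree plot of the sample correlation spectrum
#'
#' Eigenvalues of the samples' correlation matrix with the Kaiser line at 1;
#' the number of eigenvalues above the line is the factor cap used by
#' [fit_model_family()].
#'
#' @param x a standardized joint `omic_tbl`.
#' @return A ggplot object.
#' @export
plot_scree <- function(x) {
  ev <- eigen(stats::cor(omic_values(x)), symmetric = TRUE,
              only.values = TRUE)$values
  df <- tibble::tibble(component = seq_along(ev), eigenvalue = pmax(ev, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "component", y = "eigenvalue",
                  title = "Sample correlation scree") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-sample factor loadings of a fitted model
#'
#' Heat-style tile plot of the loadings matrix (samples x factors); with
#' class-structured data the mapped class blocks are directly visible.
#'
#' @param object an `fa_model`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fa_model <- function(object, ...) {
  df <- tidy(object)
  df$sample_id <- factor(df$sample_id, levels = object$sample_ids)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$factor),
                                   y = .data$sample_id,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "factor", y = "sample",
                  title = sprintf("M%d loadings", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot model-family accuracies of a discrimination report
#'
#' LDA accuracy per model with the selected best model highlighted.
#'
#' @param object a `discrimination_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.discrimination_report <- function(object, ...) {
  df <- object$model_accuracy
  df$best <- df$k == object$best_model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$best), show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "red")) +
    ggplot2::labs(x = "model size k", y = sprintf("LDA accuracy (%s)",
                                                  object$scheme),
                  title = "Model selection") +
    ggplot2::theme_minimal()
}

#' Plot a SAM quantile band
#'
#' Observed vs expected order statistics with the calling band and cuts.
#'
#' @param object a `sam_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sam_result <- function(object, ...) {
  d_sorted <- sort(object$d)
  df <- tibble::tibble(expected = seq_along(d_sorted), observed = d_sorted)
  # expected order statistics are recoverable from the cuts only approximately;
  # plot observed quantiles against their rank with the cut lines
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_hline(yintercept = c(object$cut_low, object$cut_up),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "rank", y = "d statistic",
                  title = sprintf("SAM calls: %d (delta %.2f)",
                                  nrow(object$called), object$delta)) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Top sets by q-value as a bar chart of -log10(q).
#'
#' @param object an `enrichment_result`.
#' @param top number of sets to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  df <- utils::head(as.data.frame(object), top)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q_value), y = .data$set,
                                   fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10(q)", y = NULL, title = "Gene-set enrichment") +
    ggplot2::theme_minimal()
}
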
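#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted factor model
#'
#' One row per (sample, factor) loading; `glance()` gives the one-row model
#' summary.
#'
#' @param x an `fa_model`.
#' @param ... unused.
#' @return A tibble with `sample_id`, `factor`, `loading`.
#' @export
tidy.fa_model <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$sample_ids, times = x$k),
    factor = rep(seq_len(x$k), each = length(x$sample_ids)),
    loading = as.vector(x$loadings)
  )
}

#' @rdname tidy.fa_model
#' @export
glance.fa_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    explained_common_variance = sum(x$explained),
    reproduction_err = x$reproduction_err,
    max_uniqueness = max(x$uniqueness),
    rotation = x$rotation,
    method = x$method
  )
}

#' Tidy a model family
#'
#' @param x an `fa_family`.
#' @param ... unused.
#' @return One row per model: `k`, `explained_common_variance`,
#'   `reproduction_err`.
#' @export
tidy.fa_family <- function(x, ...) {
  purrr::map_dfr(x$models, glance)
}

#' Tidy a discrimination report
#'
#' @param x a `discrimination_report`.
#' @param ... unused.
#' @return The per-(factor, class) scan tibble of the best model.
#' @export
tidy.discrimination_report <- function(x, ...) x$pairs

#' @rdname tidy.discrimination_report
#' @export
glance.discrimination_report <- function(x, ...) {
  tibble::tibble(
    best_model = x$best_model,
    best_accuracy = x$model_accuracy$accuracy[
      x$model_accuracy$k == x$best_model],
    n_flagged = sum(x$pairs$flagged),
    scheme = x$scheme
  )
}

#' Tidy a SAM result
#'
#' @param x a `sam_result`.
#' @param ... unused.
#' @return The called-molecule tibble.
#' @export
tidy.sam_result <- function(x, ...) x$called

#' @rdname tidy.sam_result
#' @export
glance.sam_result <- function(x, ...) {
  tibble::tibble(n_called = nrow(x$called), s0 = x$s0, delta = x$delta,
                 fdr = x$fdr, kept = x$kept, n_perm = x$n_perm)
}

#' Tidy a key-molecule set
#'
#' @param x a `key_molecule_set`.
#' @param ... unused.
#' @return The molecule tibble with `factor` and `threshold` columns attached.
#' @export
tidy.key_molecule_set <- function(x, ...) {
  dplyr::mutate(x$molecules, factor = x$factor, threshold = x$threshold)
}

#' Tidy a cluster report
#'
#' @param x a `cluster_report`.
#' @param ... unused.
#' @return The per-sample assignment tibble.
#' @export
tidy.cluster_report <- function(x, ...) x$assignment

#' @rdname tidy.cluster_report
#' @export
glance.cluster_report <- function(x, ...) {
  tibble::tibble(k = x$k, accuracy = x$accuracy, distance = x$distance,
                 linkage = x$linkage)
}
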
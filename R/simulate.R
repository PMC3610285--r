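#' Specification of a synthetic multi-omic study
#'
#' Describes a planted-truth dataset generated from the same model the analysis
#' assumes, X = FL + e: loadings L are class-indicator contrasts plus jitter
#' (factor j elevated in its mapped class), scores F are standard-normal
#' background with sparse large-score key molecules, and Gaussian noise is
#' added on top. Defaults emulate a reduced NCI-60 design: 60 samples from 9
#' tissue-like classes, 8 factors mapped to the 8 classes with at least 5
#' samples, and mRNA/miRNA/protein layers of 2000/150/80 molecules.
#'
#' Each layer receives its own multiplicative scale before standardization so
#' that the pipeline is exercised on cross-layer scale heterogeneity, and a
#' positive baseline offset makes the matrices suitable for mean-baseline
#' standardization.
#'
#' @param n_samples total samples; must equal `sum(class_sizes)`.
#' @param class_sizes named integer vector of samples per class.
#' @param k_true number of planted factors.
#' @param class_factor_map character vector, length `k_true`: the class each
#'   factor is elevated in (classes may be left unmapped).
#' @param unmapped_mix_sd sd of the dense mixture loadings given to samples of
#'   unmapped classes. Unmapped samples must neither be structureless (their
#'   shared centered pattern would form a coherent pseudo-block that can trade
#'   places with a planted factor under rotation) nor carry strong private
#'   directions (which attract spurious rotation axes); a dense weak mixture
#'   of all programs keeps the factor basis identifiable.
#' @param layer_sizes named integer vector of molecules per layer.
#' @param keys_per_layer named integer vector: planted key molecules per factor
#'   in each layer (disjoint across factors).
#' @param key_location,key_sd mean and sd of the absolute planted key score
#'   (signs random); location must be >= 3 so keys sit clearly beyond the 2.6
#'   extraction threshold.
#' @param background_sd sd of background factor scores (1).
#' @param contrast within-class loading level; out-of-class level is 0.
#' @param loading_jitter_sd sd of the jitter added to all loadings.
#' @param noise_sd sd of the additive Gaussian noise e.
#' @param offset positive baseline added to every entry (for mean-baseline
#'   standardization).
#' @param layer_scales named multiplicative scale per layer.
#' @param class_loading optional k x n_classes matrix (columns named by class)
#'   of class-level loading means, overriding the indicator design built from
#'   `class_factor_map` and `contrast`; classes whose column is all zero are
#'   treated as unmapped (they receive the dense mixture loadings). Lets
#'   studies plant hierarchical or bipolar class structure.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    n_samples = 60,
    class_sizes = c(BR = 6, CNS = 7, CO = 7, LE = 7, ME = 7, LC = 7, OV = 7,
                    PR = 6, RE = 6),
    k_true = 8,
    class_factor_map = c("ME", "CO", "LE", "RE", "OV", "PR", "LC", "CNS"),
    layer_sizes = c(mRNA = 2000, miRNA = 150, protein = 80),
    keys_per_layer = c(mRNA = 20, miRNA = 4, protein = 2),
    key_location = 4, key_sd = 0.3, background_sd = 1,
    contrast = 1, loading_jitter_sd = 0.05, unmapped_mix_sd = 0.2,
    noise_sd = 0.1,
    offset = 10,
    layer_scales = c(mRNA = 1, miRNA = 5, protein = 0.2),
    class_loading = NULL) {
  stopifnot(sum(class_sizes) == n_samples,
            key_location >= 3, key_sd > 0, background_sd > 0, noise_sd >= 0,
            all(names(keys_per_layer) %in% names(layer_sizes)))
  if (is.null(class_loading)) {
    stopifnot(length(class_factor_map) == k_true,
              all(class_factor_map %in% names(class_sizes)),
              !anyDuplicated(class_factor_map))
  } else {
    class_loading <- as.matrix(class_loading)
    stopifnot(nrow(class_loading) == k_true,
              identical(sort(colnames(class_loading)),
                        sort(names(class_sizes))))
  }
  total_keys <- keys_per_layer[names(layer_sizes)] * k_true
  total_keys[is.na(total_keys)] <- 0
  if (any(total_keys > layer_sizes)) {
    stop("more key molecules than rows in layer(s): ",
         paste(names(layer_sizes)[total_keys > layer_sizes], collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_samples = n_samples, class_sizes = class_sizes, k_true = k_true,
    class_factor_map = class_factor_map, layer_sizes = layer_sizes,
    keys_per_layer = keys_per_layer, key_location = key_location,
    key_sd = key_sd, background_sd = background_sd, contrast = contrast,
    loading_jitter_sd = loading_jitter_sd, unmapped_mix_sd = unmapped_mix_sd,
    noise_sd = noise_sd,
    offset = offset, layer_scales = layer_scales,
    class_loading = class_loading
  ), class = "synthetic_spec")
}

#' Generate a synthetic multi-omic dataset with known truth
#'
#' Draws X = FL + e per the spec, splits the rows into layers, applies the
#' per-layer scale and the positive offset, and returns the raw layers together
#' with the complete ground truth (planted F, L, labels and the key-molecule
#' manifest). Fully determined by `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return A list with `layers` (named list of `omic_tbl`), `labels` (tibble),
#'   and `truth` (list: `F`, `L` (k x samples), `labels`, `manifest` tibble
#'   with molecule_id/layer/factor/score, `spec`, `seed`).
#' @export
generate_multiomic <- function(spec = synthetic_spec(), seed = 7) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  classes <- rep(names(spec$class_sizes), spec$class_sizes)
  sample_ids <- sprintf("S%02d_%s", seq_along(classes), classes)
  k <- spec$k_true
  n <- spec$n_samples

  # loadings: class-level means + jitter; unmapped-class samples carry dense
  # weak mixtures of all programs (see ?synthetic_spec for why a structureless
  # spare class would make the factor basis unidentifiable after row
  # centering).
  L <- matrix(stats::rnorm(k * n, sd = spec$loading_jitter_sd), k, n)
  if (is.null(spec$class_loading)) {
    unmapped <- which(!(classes %in% spec$class_factor_map))
    base <- matrix(0, k, n)
    for (j in seq_len(k)) {
      base[j, classes == spec$class_factor_map[j]] <- spec$contrast
    }
  } else {
    base <- spec$class_loading[, classes, drop = FALSE]
    zero_cols <- colSums(abs(spec$class_loading)) == 0
    unmapped <- which(classes %in% colnames(spec$class_loading)[zero_cols])
  }
  if (length(unmapped)) {
    L[, unmapped] <- L[, unmapped] +
      matrix(stats::rnorm(k * length(unmapped), sd = spec$unmapped_mix_sd), k)
  }
  L <- L + base

  # scores: background normal, disjoint planted keys per factor per layer
  m_total <- sum(spec$layer_sizes)
  layer_of <- rep(names(spec$layer_sizes), spec$layer_sizes)
  molecule_id <- unlist(lapply(names(spec$layer_sizes), function(l) {
    sprintf("%s_%04d", l, seq_len(spec$layer_sizes[[l]]))
  }))
  Fm <- matrix(stats::rnorm(m_total * k, sd = spec$background_sd), m_total, k)
  manifest <- list()
  used <- integer(0)
  for (l in names(spec$layer_sizes)) {
    n_key <- spec$keys_per_layer[l]
    if (is.na(n_key) || n_key == 0) next
    rows_l <- which(layer_of == l)
    for (j in seq_len(k)) {
      avail <- setdiff(rows_l, used)
      idx <- sample(avail, n_key)
      used <- c(used, idx)
      score <- sample(c(-1, 1), n_key, replace = TRUE) *
        stats::rnorm(n_key, mean = spec$key_location, sd = spec$key_sd)
      Fm[cbind(idx, j)] <- score
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        molecule_id = molecule_id[idx], layer = l, factor = j, score = score)
    }
  }
  manifest <- if (length(manifest)) dplyr::bind_rows(manifest) else
    tibble::tibble(molecule_id = character(), layer = character(),
                   factor = integer(), score = double())

  X <- Fm %*% L + matrix(stats::rnorm(m_total * n, sd = spec$noise_sd),
                         m_total, n)
  layers <- lapply(names(spec$layer_sizes), function(l) {
    rows_l <- which(layer_of == l)
    scale_l <- spec$layer_scales[l]
    if (is.na(scale_l)) scale_l <- 1
    vals <- scale_l * (X[rows_l, , drop = FALSE] + spec$offset)
    omic_tbl(vals, molecule_id[rows_l],
             gene_id = paste0("gene_", molecule_id[rows_l]),
             layer = l, sample_ids = sample_ids)
  })
  names(layers) <- names(spec$layer_sizes)
  labels <- sample_labels(sample_ids, classes)
  list(layers = layers, labels = labels,
       truth = list(F = Fm, L = L, labels = labels, manifest = manifest,
                    spec = spec, seed = seed))
}

#' Generate matched null data with no class structure
#'
#' Pure-noise matrices with the same dimensions, layer structure and labels as
#' [generate_multiomic()] would produce, for permutation and false-positive
#' calibration. Entries are N(0, background_sd) with no offset, so the entry
#' mean is ~0; standardize such data with `zscore` mode.
#'
#' @inheritParams generate_multiomic
#' @return Same shape as [generate_multiomic()]; `truth$manifest` is empty.
#' @export
null_multiomic <- function(spec = synthetic_spec(), seed = 7) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  classes <- rep(names(spec$class_sizes), spec$class_sizes)
  sample_ids <- sprintf("S%02d_%s", seq_along(classes), classes)
  layer_of <- rep(names(spec$layer_sizes), spec$layer_sizes)
  layers <- lapply(names(spec$layer_sizes), function(l) {
    m_l <- spec$layer_sizes[[l]]
    vals <- matrix(stats::rnorm(m_l * spec$n_samples,
                                sd = spec$background_sd),
                   m_l, spec$n_samples)
    omic_tbl(vals, sprintf("%s_%04d", l, seq_len(m_l)),
             gene_id = sprintf("gene_%s_%04d", l, seq_len(m_l)),
             layer = l, sample_ids = sample_ids)
  })
  names(layers) <- names(spec$layer_sizes)
  labels <- sample_labels(sample_ids, classes)
  list(layers = layers, labels = labels,
       truth = list(F = NULL, L = NULL, labels = labels,
                    manifest = tibble::tibble(molecule_id = character(),
                                              layer = character(),
                                              factor = integer(),
                                              score = double()),
                    spec = spec, seed = seed))
}
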
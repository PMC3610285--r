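#' Benchmark study designs
#'
#' Three frozen synthetic study designs used by the package's validation
#' suite and by `scripts/acceptance.R`; each targets one property of the
#' workflow, because the properties favour different planted geometries.
#'
#' * `recovery_spec()` -- the default [synthetic_spec()]: nine tissue-like
#'   classes of near-equal size, eight unipolar class programs, a
#'   heterogeneous spare class. Used for loading-recovery and null studies.
#' * `key_recovery_spec()` -- 5000 molecules across three layers, two
#'   cross-layer programs with 150 planted key molecules each (3% per factor)
#'   at |score| ~ N(4, 0.3). The density follows a power analysis: the 2.6
#'   cutoff on approximately unit-variance scores passes ~0.9% of null
#'   molecules per factor, so precision 0.9 needs keys to be roughly 3% of
#'   the tested molecules per factor.
#' * `selection_spec()` -- a hierarchical design for model-size selection:
#'   four strong "lineage" programs each shared by a pair of classes, four
#'   weaker bipolar programs splitting each pair (+/-0.7). Dropping any split
#'   factor makes its two classes coincide, so LDA accuracy rises strictly
#'   with every factor up to eight; with unipolar equal blocks the accuracy
#'   is nearly flat in k (tight clusters stay separable in fewer dimensions)
#'   and selection would be decided by leave-one-out noise.
#'
#' @return A [synthetic_spec()].
#' @export
recovery_spec <- function() synthetic_spec()

#' @rdname recovery_spec
#' @export
key_recovery_spec <- function() {
  synthetic_spec(
    n_samples = 60, class_sizes = c(A = 12, B = 12, C = 36),
    k_true = 2, class_factor_map = c("A", "B"),
    layer_sizes = c(mRNA = 4200, miRNA = 500, protein = 300),
    keys_per_layer = c(mRNA = 105, miRNA = 30, protein = 15))
}

#' @rdname recovery_spec
#' @export
selection_spec <- function() {
  classes <- c(T1a = 7, T1b = 7, T2a = 7, T2b = 7,
               T3a = 7, T3b = 7, T4a = 7, T4b = 7, BR = 4)
  tcl <- names(classes)[1:8]
  cl <- matrix(0, 8, 9, dimnames = list(NULL, names(classes)))
  # all rows are mean-zero contrasts across samples: row centering (inherent
  # in standardization) then leaves all eight dimensions intact. A binary
  # lineage tree: one BR-vs-rest contrast, one top split, two mid splits,
  # four weak leaf splits; dropping a leaf factor makes its two classes
  # coincide exactly, so LDA accuracy rises strictly with k up to eight.
  cl[1, ] <- c(rep(0.2, 8), -2.8)               # BR vs all tumours
  cl[2, tcl] <- rep(c(1, -1), each = 4)         # pairs 1,2 vs pairs 3,4
  cl[3, tcl[1:4]] <- c(1, 1, -1, -1)            # pair 1 vs pair 2
  cl[4, tcl[5:8]] <- c(1, 1, -1, -1)            # pair 3 vs pair 4
  leaf_strength <- c(0.9, 0.8, 0.7, 0.6) # strictly ordered so the top-k
  # eigenspace excludes whole leaf factors rather than mixing equal-strength
  # leaves across degenerate eigen-directions
  for (i in 1:4) {
    cl[4 + i, tcl[c(2 * i - 1, 2 * i)]] <- c(1, -1) * leaf_strength[i]
  }
  # jitter comparable to the residual leakage of an excluded leaf factor:
  # with tighter classes, LDA can still exploit the small leaked mean
  # differences of a merged pair and the accuracy plateau starts too early
  synthetic_spec(
    n_samples = 60, class_sizes = classes, k_true = 8,
    loading_jitter_sd = 0.3,
    class_loading = cl)
}

#' Planted class-to-factor map of the selection study
#'
#' Each paired class is identified one-vs-rest by its bipolar leaf factor
#' (factors 5-8); BR is identified by the BR-vs-rest contrast (factor 1); the
#' internal tree factors 2-4 discriminate groups of classes, not single
#' classes.
#'
#' @return Named integer vector: class -> planted factor index.
#' @export
selection_spec_map <- function() {
  c(BR = 1L,
    T1a = 5L, T1b = 5L, T2a = 6L, T2b = 6L,
    T3a = 7L, T3b = 7L, T4a = 8L, T4b = 8L)
}
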
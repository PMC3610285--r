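#' Omic expression tables
#'
#' An `omic_tbl` is a tibble holding one expression layer (or a joint,
#' row-stacked set of layers) in molecules-by-samples orientation. The first
#' three columns are metadata -- `molecule_id`, `gene_id`, `layer` -- and every
#' remaining column is one sample. This keeps the data pipe-friendly while the
#' numeric part stays available as a matrix via [omic_values()].
#'
#' Invariants enforced by the constructor: unique `molecule_id` within a layer,
#' unique sample ids, numeric sample columns. Missing values are allowed only
#' when explicitly requested on read; they are treated as a mask and rows
#' carrying them are dropped (with a message) before standardization.
#'
#' @param values numeric matrix, molecules x samples.
#' @param molecule_id character vector of unique molecule identifiers.
#' @param gene_id character vector of gene annotations (many-to-one allowed).
#' @param layer single string naming the omic layer (`"mRNA"`, `"miRNA"`,
#'   `"protein"`, or any other tag).
#' @param sample_ids character vector of unique sample identifiers.
#'
#' @return A tibble with class `omic_tbl`.
#' @export
#' @examples
#' m <- omic_tbl(matrix(1:6, 2), c("p1", "p2"), c("g1", "g1"), "mRNA",
#'               c("s1", "s2", "s3"))
#' omic_values(m)
omic_tbl <- function(values, molecule_id, gene_id, layer, sample_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(nrow(values) == length(molecule_id),
            nrow(values) == length(gene_id),
            ncol(values) == length(sample_ids))
  if (length(layer) == 1L) layer <- rep(layer, nrow(values))
  stopifnot(length(layer) == nrow(values))
  out <- tibble::tibble(
    molecule_id = as.character(molecule_id),
    gene_id = as.character(gene_id),
    layer = as.character(layer)
  )
  colnames(values) <- as.character(sample_ids)
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  new_omic_tbl(out)
}

new_omic_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- c("omic_tbl", class(x))
  validate_omic_tbl(x)
}

validate_omic_tbl <- function(x) {
  meta <- c("molecule_id", "gene_id", "layer")
  if (!all(meta %in% names(x))) {
    stop("omic_tbl needs columns molecule_id, gene_id, layer", call. = FALSE)
  }
  sams <- setdiff(names(x), meta)
  if (length(sams) == 0L) stop("omic_tbl has no sample columns", call. = FALSE)
  if (anyDuplicated(sams)) {
    stop("duplicate sample ids: ",
         paste(unique(sams[duplicated(sams)]), collapse = ", "), call. = FALSE)
  }
  dup <- x$molecule_id[duplicated(paste(x$layer, x$molecule_id))]
  if (length(dup)) {
    stop("duplicate molecule_id within a layer: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  numeric_ok <- vapply(x[sams], is.numeric, logical(1))
  if (!all(numeric_ok)) {
    stop("non-numeric sample columns: ",
         paste(sams[!numeric_ok], collapse = ", "), call. = FALSE)
  }
  inf_bad <- vapply(x[sams], function(v) any(is.infinite(v)), logical(1))
  if (any(inf_bad)) stop("non-finite expression values", call. = FALSE)
  x
}

#' @rdname omic_tbl
#' @param x an `omic_tbl`.
#' @export
is_omic_tbl <- function(x) inherits(x, "omic_tbl")

#' @rdname omic_tbl
#' @export
omic_values <- function(x) {
  stopifnot(is_omic_tbl(x))
  v <- as.matrix(x[omic_samples(x)])
  rownames(v) <- x$molecule_id
  v
}

#' @rdname omic_tbl
#' @export
omic_samples <- function(x) {
  setdiff(names(x), c("molecule_id", "gene_id", "layer"))
}

#' @rdname omic_tbl
#' @export
omic_meta <- function(x) {
  tibble::as_tibble(x[c("molecule_id", "gene_id", "layer")])
}

#' Replace the numeric block of an omic_tbl
#'
#' Internal helper: keeps metadata, swaps sample values.
#' @noRd
set_omic_values <- function(x, values) {
  sams <- omic_samples(x)
  stopifnot(nrow(values) == nrow(x), ncol(values) == length(sams))
  x[sams] <- tibble::as_tibble(`colnames<-`(as.matrix(values), sams))
  x
}

#' Standardization mode attached to a (joint) matrix
#' @param x an `omic_tbl`.
#' @return `"mean_baseline"`, `"zscore"`, or `NA` when not standardized.
#' @export
standardization_mode <- function(x) {
  attr(x, "standardization_mode") %||% NA_character_
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop rows containing masked (missing) entries
#'
#' Factor analysis and LDA require complete rows; rows with any masked entry
#' are removed and their count reported via a message.
#'
#' @param x an `omic_tbl` possibly containing `NA` entries.
#' @return An `omic_tbl` with complete rows only.
#' @export
drop_incomplete <- function(x) {
  stopifnot(is_omic_tbl(x))
  v <- omic_values(x)
  bad <- rowSums(is.na(v)) > 0
  if (any(bad)) {
    message(sum(bad), " row(s) with masked entries dropped")
    x <- x[!bad, , drop = FALSE]
  }
  x
}

#' Check that two objects share the same samples
#'
#' Operations that combine layers or pair a matrix with labels must never
#' silently reorder or intersect samples; this helper fails loudly instead.
#'
#' @param a,b character vectors of sample ids.
#' @param ordered require identical order as well as identical membership.
#' @return Invisibly `TRUE`, or an error naming the offending samples.
#' @export
check_samples_match <- function(a, b, ordered = FALSE) {
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  if (length(only_a) || length(only_b)) {
    stop("sample mismatch; missing from one side: ",
         paste(c(only_a, only_b), collapse = ", "), call. = FALSE)
  }
  if (ordered && !identical(as.character(a), as.character(b))) {
    stop("samples present in both but ordered differently", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample labels
#'
#' @param sample_ids character vector of sample ids.
#' @param labels categorical phenotype, one per sample (>= 2 classes, each
#'   with >= 2 samples).
#' @return A tibble with columns `sample_id`, `label`.
#' @export
sample_labels <- function(sample_ids, labels) {
  out <- tibble::tibble(sample_id = as.character(sample_ids),
                        label = as.character(labels))
  if (anyDuplicated(out$sample_id)) stop("duplicate sample ids", call. = FALSE)
  tab <- table(out$label)
  if (length(tab) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(tab < 2L)) {
    stop("every class needs >= 2 samples; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  out
}

#' Align a label table to a matrix's samples
#' @noRd
labels_for <- function(labels, sample_ids) {
  check_samples_match(labels$sample_id, sample_ids)
  labels$label[match(sample_ids, labels$sample_id)]
}
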
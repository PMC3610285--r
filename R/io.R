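#' Read a molecules-by-samples expression matrix
#'
#' Expects delimited text with a header row of sample ids and leading
#' `molecule_id` (and optionally `gene_id`) columns; remaining columns must be
#' numeric. Row order of the file is preserved.
#'
#' @param path file path.
#' @param layer layer tag recorded on every row (e.g. `"mRNA"`).
#' @param delim field delimiter; TAB by default, `","` accepted.
#' @param allow_missing if `TRUE`, `NA` tokens become masked entries instead of
#'   an error; masked rows are dropped later by [drop_incomplete()].
#' @return An [omic_tbl()].
#' @export
read_omic_tsv <- function(path, layer, delim = "\t", allow_missing = FALSE) {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (!"molecule_id" %in% names(raw)) {
    names(raw)[1] <- "molecule_id"
  }
  if (!"gene_id" %in% names(raw)) {
    raw <- dplyr::mutate(raw, gene_id = .data$molecule_id, .after = "molecule_id")
  }
  if ("layer" %in% names(raw)) { # written by write_omic_tsv
    layer <- raw$layer
    raw$layer <- NULL
  }
  sams <- setdiff(names(raw), c("molecule_id", "gene_id"))
  for (s in sams) {
    v <- raw[[s]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     bad[1], s, v[bad[1]]), call. = FALSE)
      }
      v <- num
    }
    raw[[s]] <- as.double(v)
  }
  n_missing <- sum(is.na(as.matrix(raw[sams])))
  if (n_missing > 0 && !allow_missing) {
    stop("matrix contains ", n_missing,
         " missing entries; use allow_missing = TRUE to mask them",
         call. = FALSE)
  }
  dup <- unique(raw$molecule_id[duplicated(raw$molecule_id)])
  if (length(dup)) {
    stop("duplicate molecule_ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  omic_tbl(as.matrix(raw[sams]), raw$molecule_id, raw$gene_id, layer, sams)
}

#' Write an omic_tbl back to delimited text
#' @param x an `omic_tbl`.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_omic_tsv <- function(x, path, delim = "\t") {
  stopifnot(is_omic_tbl(x))
  readr::write_delim(as.data.frame(x), path, delim = delim)
  invisible(path)
}

#' Read a two-column sample label file
#'
#' @param path TSV with columns `sample_id`, `label` (header optional when the
#'   first row is non-numeric ids).
#' @param delim field delimiter.
#' @return A tibble as from [sample_labels()].
#' @export
read_labels_tsv <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_types = "cc",
                           progress = FALSE, show_col_types = FALSE)
  if (!all(c("sample_id", "label") %in% names(raw))) {
    names(raw)[1:2] <- c("sample_id", "label")
  }
  sample_labels(raw$sample_id, raw$label)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, TAB-separated `name`, `description`,
#' member genes. The universe defaults to the union of all sets and can be
#' overridden with an explicit background size.
#'
#' @param path GMT file path.
#' @param universe optional integer background size.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `universe` (integer).
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  gene_set_collection(sets, universe)
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("set names must be present and unique", call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) stop("empty gene set", call. = FALSE)
  n_union <- length(unique(unlist(sets)))
  universe <- as.integer(universe %||% n_union)
  if (universe < n_union) stop("universe smaller than union of sets", call. = FALSE)
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

# ---- self-describing JSON reports ------------------------------------------

encode_node <- function(x) {
  if (is.null(x)) return(list(.kind = "null"))
  if (is.matrix(x)) {
    dn <- dimnames(x)
    return(list(.kind = "matrix", type = typeof(x), dim = dim(x),
                dimnames = dn, dimnames_names = names(dn),
                data = as.vector(x)))
  }
  if (is.data.frame(x)) {
    return(list(.kind = "tbl", columns = lapply(as.list(x), encode_node)))
  }
  if (is.factor(x)) x <- as.character(x)
  if (is.atomic(x)) {
    if (is.double(x) && any(!is.finite(x) & !is.na(x))) {
      # JSON has no Inf/NaN; fall back to an exact text encoding
      return(list(.kind = "double_chr", names = names(x),
                  data = sprintf("%.17g", unname(x))))
    }
    return(list(.kind = typeof(x), names = names(x), data = unname(x)))
  }
  if (is.list(x)) {
    return(list(.kind = "list", names = names(x),
                items = lapply(unname(x), encode_node)))
  }
  stop("cannot encode object of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

decode_node <- function(n) {
  kind <- n$.kind
  if (kind == "null") return(NULL)
  if (kind == "matrix") {
    data <- unlist(n$data %||% list())
    data <- if (identical(n$type, "integer")) as.integer(data) else
      as.double(data)
    m <- matrix(data, nrow = n$dim[[1]], ncol = n$dim[[2]])
    if (!is.null(n$dimnames)) {
      dn <- lapply(n$dimnames, function(d) if (is.null(d)) NULL else unlist(d))
      if (!is.null(n$dimnames_names)) names(dn) <- unlist(n$dimnames_names)
      dimnames(m) <- dn
    }
    return(m)
  }
  if (kind == "tbl") {
    cols <- lapply(n$columns, decode_node)
    return(tibble::as_tibble(cols))
  }
  if (kind == "list") {
    items <- lapply(n$items, decode_node)
    if (!is.null(n$names)) names(items) <- unlist(n$names)
    return(items)
  }
  data <- unlist(n$data %||% list())
  out <- switch(kind,
    double_chr = suppressWarnings(as.double(data %||% character())),
    double = as.double(data %||% double()),
    integer = as.integer(data %||% integer()),
    character = as.character(data %||% character()),
    logical = as.logical(data %||% logical()),
    stop("unknown kind ", kind, call. = FALSE))
  if (!is.null(n$names)) names(out) <- unlist(n$names)
  out
}

#' Write and re-read analysis reports
#'
#' Every result object in the package (discrimination reports, SAM results,
#' key-molecule sets, enrichment tables, ...) is a classed list carrying its
#' inputs, parameters, seed and outputs. `write_report()` serializes such an
#' object to self-describing JSON; `read_report()` reconstructs it so that
#' `read_report(write_report(x, f))` equals `x`.
#'
#' @param x a result object (classed list).
#' @param path output path.
#' @return `write_report()` returns `path` invisibly; `read_report()` returns
#'   the reconstructed object.
#' @export
write_report <- function(x, path) {
  payload <- list(type = class(x)[1], fields = encode_node(unclass(x)))
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- decode_node(payload$fields)
  if (!identical(payload$type, "list")) class(out) <- payload$type
  out
}
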
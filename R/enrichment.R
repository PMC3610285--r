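#' Fisher and EASE enrichment p-values
#'
#' Upper-tail hypergeometric probability of observing at least `k` of a gene
#' list of size `m` inside a set of size `K` drawn from a universe of `N`
#' genes. The EASE score is the same tail probability after removing one gene
#' from the observed overlap (k -> k - 1, floored at 0), a deliberately
#' conservative variant that penalizes small overlaps; hence
#' `ease_p >= fisher_p` whenever `k >= 1`.
#'
#' @param k overlap count.
#' @param m gene-list size.
#' @param K set size.
#' @param N universe (background) size.
#' @return A named list with `fisher_p` and `ease_p`.
#' @export
ease_test <- function(k, m, K, N) {
  stopifnot(k >= 0, k <= min(m, K), m <= N, K <= N)
  if (k == 0) return(list(fisher_p = 1, ease_p = 1))
  fisher_p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
  ease_k <- max(k - 1, 0)
  ease_p <- if (ease_k == 0) 1 else {
    stats::phyper(ease_k - 1, K, N - K, m, lower.tail = FALSE)
  }
  list(fisher_p = fisher_p, ease_p = ease_p)
}

#' Gene-set enrichment of a key-molecule gene list
#'
#' Applies [ease_test()] to every set in the collection, corrects the EASE
#' p-values across sets with Benjamini-Hochberg, and flags rows with
#' `q <= fdr_threshold`. The background is the collection's universe size --
#' an explicit parameter, since a genome-wide background cannot be inferred
#' from the sets alone.
#'
#' @param genes character vector of gene ids (e.g. from a key-molecule set;
#'   duplicates are collapsed).
#' @param sets a `gene_set_collection` from [read_gmt()] or
#'   [gene_set_collection()].
#' @param fdr_threshold BH q-value threshold for flagging (default 0.05).
#' @return A tibble of class `enrichment_result` with columns `set`, `overlap`,
#'   `list_size`, `set_size`, `universe`, `fisher_p`, `ease_p`, `q_value`,
#'   `flagged`, sorted by q then p.
#' @export
enrich_sets <- function(genes, sets, fdr_threshold = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  genes <- unique(as.character(genes))
  stopifnot(length(genes) >= 1)
  if (!any(genes %in% unique(unlist(sets$sets)))) {
    stop("gene list is disjoint from every set in the collection",
         call. = FALSE)
  }
  N <- sets$universe
  m <- length(genes)
  rows <- purrr::imap_dfr(sets$sets, function(members, nm) {
    k <- length(intersect(genes, members))
    p <- ease_test(k, m, length(members), N)
    tibble::tibble(set = nm, overlap = k, list_size = m,
                   set_size = length(members), universe = N,
                   fisher_p = p$fisher_p, ease_p = p$ease_p)
  })
  rows$q_value <- stats::p.adjust(rows$ease_p, method = "BH")
  rows$flagged <- rows$q_value <= fdr_threshold
  rows <- dplyr::arrange(rows, .data$q_value, .data$ease_p, .data$set)
  class(rows) <- c("enrichment_result", class(rows))
  rows
}

#' Expand miRNAs to their target genes
#'
#' Gene-set annotations describe genes, not miRNAs; miRNA members of a key
#' molecule list are therefore expanded through a user-supplied miRNA-to-target
#' mapping before enrichment. No target predictions are bundled.
#'
#' @param molecules tibble with `gene_id` and `layer` columns (e.g.
#'   `key_molecule_set$molecules`).
#' @param target_map tibble or two-column data frame `mirna`, `target`.
#' @return Character vector: non-miRNA gene ids plus mapped targets, unique.
#' @export
expand_mirna_targets <- function(molecules, target_map) {
  stopifnot(all(c("gene_id", "layer") %in% names(molecules)))
  names(target_map)[1:2] <- c("mirna", "target")
  is_mir <- molecules$layer == "miRNA"
  direct <- molecules$gene_id[!is_mir]
  mapped <- target_map$target[target_map$mirna %in% molecules$gene_id[is_mir]]
  unique(c(direct, mapped))
}
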
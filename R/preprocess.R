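#' Cross-platform gene filter
#'
#' When the same transcriptome is measured on two platforms, genes whose probes
#' disagree across platforms carry platform noise rather than biology. For each
#' gene present in both matrices, the Pearson correlation of every probe pair
#' (one probe from each platform) is computed across the shared samples; the
#' maximum over pairs represents the gene, and the gene is retained when that
#' maximum exceeds `min_r`.
#'
#' Zero-variance probes have undefined correlations; their pairs are treated as
#' -Inf and can never be the representative.
#'
#' @param a,b `omic_tbl` objects sharing the same samples, with `gene_id`
#'   populated.
#' @param min_r minimum representative Pearson correlation (default 0.5).
#' @return A tibble with columns `gene_id`, `best_r`, `retained`.
#' @export
cross_platform_filter <- function(a, b, min_r = 0.5) {
  stopifnot(is_omic_tbl(a), is_omic_tbl(b))
  check_samples_match(omic_samples(a), omic_samples(b))
  bv <- omic_values(b)[, omic_samples(a), drop = FALSE]
  av <- omic_values(a)
  shared <- intersect(unique(a$gene_id), unique(b$gene_id))
  if (length(shared) == 0L) {
    warning("no shared genes between platforms")
    return(tibble::tibble(gene_id = character(), best_r = double(),
                          retained = logical()))
  }
  best_r <- vapply(shared, function(g) {
    pa <- av[a$gene_id == g, , drop = FALSE]
    pb <- bv[b$gene_id == g, , drop = FALSE]
    best <- -Inf
    for (i in seq_len(nrow(pa))) {
      for (j in seq_len(nrow(pb))) {
        if (stats::sd(pa[i, ]) == 0 || stats::sd(pb[j, ]) == 0) next
        best <- max(best, stats::cor(pa[i, ], pb[j, ]))
      }
    }
    best
  }, double(1))
  tibble::tibble(gene_id = shared, best_r = unname(best_r),
                 retained = best_r > min_r)
}

#' Collapse multiple probes per gene by correlation clustering
#'
#' Probes mapping to one gene are hierarchically clustered with distance
#' 1 - Pearson(probe_i, probe_j); the tree is cut at `cutoff_height` and each
#' cluster is replaced by the per-sample mean of its members. Single-probe
#' genes pass through unchanged. Output molecule ids are
#' `<gene_id>.<cluster index>` for multi-probe genes.
#'
#' @param m an `omic_tbl` with `gene_id` populated.
#' @param cutoff_height tree cut height in (0, 2]; default 0.6.
#' @param linkage agglomeration method for [stats::hclust()]; average linkage
#'   by default (the usual choice for correlation distances between probes).
#' @return An `omic_tbl` at probe-cluster level.
#' @export
collapse_probes <- function(m, cutoff_height = 0.6, linkage = "average") {
  stopifnot(is_omic_tbl(m), cutoff_height > 0, cutoff_height <= 2)
  v <- omic_values(m)
  sams <- omic_samples(m)
  pieces <- lapply(split(seq_len(nrow(m)), m$gene_id), function(idx) {
    g <- m$gene_id[idx[1]]
    lay <- m$layer[idx[1]]
    if (length(idx) == 1L) {
      return(list(values = v[idx, , drop = FALSE],
                  molecule_id = m$molecule_id[idx], gene_id = g, layer = lay))
    }
    sub <- v[idx, , drop = FALSE]
    d <- stats::as.dist(1 - stats::cor(t(sub)))
    d[is.na(d)] <- 1 # zero-variance probe: no linear relation assumed
    cl <- stats::cutree(stats::hclust(d, method = linkage), h = cutoff_height)
    means <- t(vapply(split(seq_along(cl), cl),
                      function(k) colMeans(sub[k, , drop = FALSE]),
                      double(ncol(sub))))
    list(values = means,
         molecule_id = paste(g, sort(unique(cl)), sep = "."),
         gene_id = rep(g, nrow(means)), layer = rep(lay, nrow(means)))
  })
  omic_tbl(do.call(rbind, lapply(pieces, `[[`, "values")),
           unlist(lapply(pieces, `[[`, "molecule_id")),
           unlist(lapply(pieces, `[[`, "gene_id")),
           unlist(lapply(pieces, `[[`, "layer")),
           sams)
}

#' Per-probe max / IQR summary
#'
#' @param m an `omic_tbl`.
#' @return A tibble with `molecule_id`, `max_p`, `iqr_p` (type-7 quartiles).
#' @export
probe_stats <- function(m) {
  v <- omic_values(m)
  tibble::tibble(
    molecule_id = m$molecule_id,
    max_p = unname(apply(v, 1, max)),
    iqr_p = unname(apply(v, 1, stats::IQR, type = 7))
  )
}

#' Keep probes that are both highly and variably expressed
#'
#' Retains rows lying in the top half of both the per-probe maximum intensity
#' max(p) and the per-probe inter-quartile range IQR(p). "Top half" is
#' inclusive (>= the median), so tied probes survive deterministically.
#'
#' @param m an `omic_tbl` with >= 2 rows.
#' @return The filtered `omic_tbl`, with attribute `"filter_counts"` giving
#'   kept/dropped counts.
#' @export
filter_max_iqr <- function(m) {
  stopifnot(is_omic_tbl(m), nrow(m) >= 2)
  st <- probe_stats(m)
  keep <- st$max_p >= stats::median(st$max_p) &
    st$iqr_p >= stats::median(st$iqr_p)
  out <- m[keep, , drop = FALSE]
  attr(out, "filter_counts") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}

#' Standardize expression rows
#'
#' Two modes:
#' * `mean_baseline`: x -> (x - c) / c with c the row mean across samples; the
#'   scale of a molecule is expressed relative to its own average level, so row
#'   magnitudes remain comparable across molecules.
#' * `zscore`: x -> (x - mean) / sd, with the n-1 denominator.
#'
#' Rows for which the transform is undefined (|c| below `epsilon` times the
#' row's max absolute value in mean-baseline mode, or zero sd in zscore mode)
#' are dropped with a message, or raise an error under `strict = TRUE`.
#'
#' @param m an `omic_tbl` with complete rows (see [drop_incomplete()]).
#' @param mode `"mean_baseline"` (default) or `"zscore"`.
#' @param epsilon relative guard for near-zero baselines.
#' @param strict error instead of dropping undefined rows.
#' @return A standardized `omic_tbl` with attribute `standardization_mode`.
#' @export
standardize_rows <- function(m, mode = c("mean_baseline", "zscore"),
                             epsilon = 1e-8, strict = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is_omic_tbl(m))
  m <- drop_incomplete(m)
  v <- omic_values(m)
  ctr <- rowMeans(v)
  if (mode == "mean_baseline") {
    bad <- abs(ctr) <= epsilon * pmax(apply(abs(v), 1, max), 1e-300)
    out_v <- (v - ctr) / ctr
  } else {
    sds <- apply(v, 1, stats::sd)
    bad <- sds == 0
    out_v <- (v - ctr) / ifelse(sds == 0, 1, sds)
  }
  if (any(bad)) {
    if (strict) {
      stop("undefined standardization for rows: ",
           paste(m$molecule_id[bad], collapse = ", "), call. = FALSE)
    }
    message(sum(bad), " row(s) dropped: standardization undefined (",
            mode, ")")
    m <- m[!bad, , drop = FALSE]
    out_v <- out_v[!bad, , drop = FALSE]
  }
  out <- set_omic_values(m, out_v)
  attr(out, "standardization_mode") <- mode
  out
}

#' Assemble standardized layers into one joint matrix
#'
#' Rows are stacked in the given layer order; columns of every layer are
#' realigned to the first layer's sample order. Any sample missing from a
#' layer is an error -- the joint matrix never silently intersects samples.
#'
#' @param layers list of standardized `omic_tbl` objects.
#' @return A joint `omic_tbl` whose `layer` column records provenance.
#' @export
assemble_joint <- function(layers) {
  stopifnot(length(layers) >= 1, all(vapply(layers, is_omic_tbl, logical(1))))
  modes <- unique(vapply(layers, function(l) standardization_mode(l),
                         character(1)))
  ref <- omic_samples(layers[[1]])
  aligned <- lapply(layers, function(l) {
    check_samples_match(omic_samples(l), ref)
    dplyr::bind_cols(omic_meta(l),
                     tibble::as_tibble(omic_values(l)[, ref, drop = FALSE]))
  })
  out <- new_omic_tbl(dplyr::bind_rows(aligned))
  attr(out, "standardization_mode") <-
    if (length(modes) == 1L) modes else NA_character_
  out
}

#' Full preprocessing of one layer
#'
#' Convenience wrapper chaining probe collapsing, the max/IQR filter and
#' standardization, with per-stage switches so the miRNA layer can skip the
#' filters (mirroring the practice of keeping all miRNAs).
#'
#' @param m an `omic_tbl`.
#' @param collapse collapse multi-probe genes first?
#' @param filter apply the max/IQR filter?
#' @param cutoff_height,linkage passed to [collapse_probes()].
#' @param mode,epsilon passed to [standardize_rows()].
#' @return A standardized `omic_tbl`.
#' @export
preprocess_layer <- function(m, collapse = TRUE, filter = TRUE,
                             cutoff_height = 0.6, linkage = "average",
                             mode = "mean_baseline", epsilon = 1e-8) {
  if (collapse) m <- collapse_probes(m, cutoff_height, linkage)
  if (filter && nrow(m) >= 2) m <- filter_max_iqr(m)
  standardize_rows(m, mode = mode, epsilon = epsilon)
}
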
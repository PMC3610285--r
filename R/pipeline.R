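#' End-to-end joint analysis pipeline
#'
#' Chains the three-step flow: (1) per-layer preprocessing and standardization
#' into one joint matrix; (2) factor analysis for every model M1..Mn with
#' LDA-based selection of the best model and of the discriminating factors;
#' (3) key-molecule extraction for every flagged (factor, class) pair, with
#' optional gene-set enrichment.
#'
#' Layers named `"miRNA"` skip the probe-collapse and max/IQR filters (all
#' miRNAs are kept, as is conventional); every other layer gets the full
#' preprocessing. Every effective parameter is echoed in the returned
#' `parameters` element.
#'
#' @param layers named list of raw `omic_tbl` objects.
#' @param labels tibble from [sample_labels()].
#' @param mode standardization mode (`"mean_baseline"` or `"zscore"`).
#' @param collapse_cutoff probe-cluster tree cut height (default 0.6).
#' @param score_threshold key-molecule |score| cutoff (default 2.6).
#' @param accuracy_floor one-vs-rest accuracy floor for flagging (default 0.9).
#' @param p_max chi-square flagging threshold (default 0.05).
#' @param rotation,method passed to [fit_model_family()].
#' @param gene_sets optional `gene_set_collection` for enrichment of each
#'   flagged factor's genes.
#' @param enrich_fdr enrichment FDR threshold (default 0.05).
#' @param preprocess apply probe collapsing and the max/IQR filter (set to
#'   `FALSE` when the input is already at molecule level, e.g. synthetic data).
#' @param seed recorded for provenance (the pipeline itself is deterministic).
#' @param out_dir optional directory; when given, every stage report is written
#'   there as JSON via [write_report()].
#' @return An object of class `jofa_pipeline`: list with `joint`, `family`,
#'   `report` (a `discrimination_report`), `keys` (named list of
#'   `key_molecule_set`, one per flagged factor), `enrichment` (named list of
#'   `enrichment_result` or NULL), `parameters`, `seed`.
#' @export
run_pipeline <- function(layers, labels, mode = "mean_baseline",
                         collapse_cutoff = 0.6, score_threshold = 2.6,
                         accuracy_floor = 0.9, p_max = 0.05,
                         rotation = "varimax", method = "paf",
                         gene_sets = NULL, enrich_fdr = 0.05,
                         preprocess = FALSE, seed = 1, out_dir = NULL) {
  parameters <- list(mode = mode, collapse_cutoff = collapse_cutoff,
                     score_threshold = score_threshold,
                     accuracy_floor = accuracy_floor, p_max = p_max,
                     rotation = rotation, method = method,
                     enrich_fdr = enrich_fdr, preprocess = preprocess,
                     seed = seed)
  validate_params(parameters)
  std <- purrr::imap(layers, function(l, nm) {
    preprocess_layer(l,
                     collapse = preprocess && nm != "miRNA",
                     filter = preprocess && nm != "miRNA",
                     cutoff_height = collapse_cutoff, mode = mode)
  })
  joint <- assemble_joint(std)
  family <- fit_model_family(joint, rotation = rotation, method = method,
                             seed = seed)
  report <- per_factor_class_scan(family, labels,
                                  accuracy_floor = accuracy_floor,
                                  p_max = p_max)
  best <- family$models[[report$best_model]]
  flagged <- report$pairs[report$pairs$flagged, , drop = FALSE]
  keys <- lapply(unique(flagged$factor), function(j) {
    extract_key_molecules(best, j, threshold = score_threshold)
  })
  names(keys) <- paste0("F", unique(flagged$factor))
  enrichment <- NULL
  if (!is.null(gene_sets) && length(keys)) {
    enrichment <- lapply(keys, function(ks) {
      genes <- unique(ks$molecules$gene_id[ks$molecules$layer != "miRNA"])
      if (!length(genes)) return(NULL)
      tryCatch(enrich_sets(genes, gene_sets, fdr_threshold = enrich_fdr),
               error = function(e) NULL)
    })
  }
  out <- structure(list(joint = joint, family = family, report = report,
                        keys = keys, enrichment = enrichment,
                        parameters = parameters, seed = seed),
                   class = "jofa_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "discrimination.json"))
    for (nm in names(keys)) {
      write_report(keys[[nm]], file.path(out_dir, paste0("keys_", nm, ".json")))
    }
  }
  out
}

validate_params <- function(p) {
  if (!is.null(p$min_r) && (p$min_r < -1 || p$min_r > 1)) {
    stop("min_r must lie in [-1, 1]", call. = FALSE)
  }
  if (p$collapse_cutoff <= 0 || p$collapse_cutoff > 2) {
    stop("collapse_cutoff must lie in (0, 2]", call. = FALSE)
  }
  if (p$score_threshold < 0) stop("score_threshold must be >= 0", call. = FALSE)
  if (p$accuracy_floor < 0) stop("accuracy_floor must be >= 0", call. = FALSE)
  if (p$p_max <= 0 || p$p_max > 1) stop("p_max must lie in (0, 1]", call. = FALSE)
  if (p$enrich_fdr <= 0 || p$enrich_fdr > 1) {
    stop("enrich_fdr must lie in (0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.jofa_pipeline <- function(x, ...) {
  cat("jofa_pipeline\n")
  print(x$report)
  cat("key-molecule sets:", paste(names(x$keys), collapse = ", "), "\n")
  invisible(x)
}

#' Compare joint, separate and HC+SAM analyses on the same data
#'
#' Runs (a) the joint FA+LDA pipeline on all layers stacked; (b) the separate
#' pipeline -- FA+LDA per layer, each with its own best model, merging key
#' molecules class-wise across layers; (c) hierarchical clustering of the joint
#' matrix, with an optional one-vs-rest SAM signature for a target class.
#' Reports per-class signature sizes and Jaccard overlaps between joint and
#' separate signatures, plus the accuracy table of all three routes.
#'
#' @inheritParams run_pipeline
#' @param sam_class optional class for the HC+SAM signature; `NULL` skips SAM.
#' @param delta,sam_fdr_cap,n_perm SAM parameters (defaults 2.6, 0.001, 500).
#' @return An object of class `jofa_comparison`: list with `joint`
#'   (`jofa_pipeline`), `separate` (list with per-layer pipelines and merged
#'   class signatures), `hc` (`cluster_report`), `sam` (`sam_result` or NULL),
#'   `class_table` (tibble class/joint_factor/joint_accuracy/joint_size/
#'   separate_size/jaccard), `parameters`.
#' @export
compare_modes <- function(layers, labels, mode = "mean_baseline",
                          score_threshold = 2.6, accuracy_floor = 0.9,
                          p_max = 0.05, sam_class = NULL, delta = 2.6,
                          sam_fdr_cap = 0.001, n_perm = 500, seed = 1,
                          preprocess = FALSE) {
  joint <- run_pipeline(layers, labels, mode = mode,
                        score_threshold = score_threshold,
                        accuracy_floor = accuracy_floor, p_max = p_max,
                        preprocess = preprocess, seed = seed)
  separate <- purrr::imap(layers, function(l, nm) {
    run_pipeline(stats::setNames(list(l), nm), labels, mode = mode,
                 score_threshold = score_threshold,
                 accuracy_floor = accuracy_floor, p_max = p_max,
                 preprocess = preprocess, seed = seed)
  })

  classes <- sort(unique(labels$label))
  sig_of <- function(pipe, cls) {
    flag <- pipe$report$pairs
    flag <- flag[flag$flagged & flag$class == cls, , drop = FALSE]
    if (!nrow(flag)) return(character(0))
    j <- flag$factor[which.max(flag$accuracy)]
    ks <- pipe$keys[[paste0("F", j)]]
    if (is.null(ks)) character(0) else ks$molecules$molecule_id
  }
  class_table <- purrr::map_dfr(classes, function(cls) {
    joint_sig <- sig_of(joint, cls)
    sep_sig <- unique(unlist(lapply(separate, sig_of, cls = cls)))
    inter <- length(intersect(joint_sig, sep_sig))
    uni <- length(union(joint_sig, sep_sig))
    cb <- joint$report$class_best
    tibble::tibble(
      class = cls,
      joint_factor = cb$factor[cb$class == cls],
      joint_accuracy = cb$accuracy[cb$class == cls],
      joint_size = length(joint_sig),
      separate_size = length(sep_sig),
      jaccard = if (uni == 0) NA_real_ else inter / uni)
  })

  hc <- hc_samples(joint$joint, labels, k = length(classes))
  sam <- NULL
  if (!is.null(sam_class)) {
    sam <- run_hcsam(joint$joint, labels, sam_class, delta = delta,
                     fdr_cap = sam_fdr_cap, n_perm = n_perm, seed = seed)
  }
  structure(list(joint = joint, separate = separate, hc = hc, sam = sam,
                 class_table = class_table,
                 parameters = list(mode = mode,
                                   score_threshold = score_threshold,
                                   accuracy_floor = accuracy_floor,
                                   p_max = p_max, delta = delta,
                                   sam_fdr_cap = sam_fdr_cap,
                                   n_perm = n_perm, seed = seed)),
            class = "jofa_comparison")
}

#' @export
print.jofa_comparison <- function(x, ...) {
  cat("jofa_comparison\n  joint best model: M", x$joint$report$best_model,
      "\n  HC accuracy: ", round(x$hc$accuracy, 3), "\n", sep = "")
  print(x$class_table)
  invisible(x)
}
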
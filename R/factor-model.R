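#' Maximum number of meaningful factors
#'
#' Upper bound on the factor count for the model family: components of the
#' sample correlation matrix explaining less variance than one original
#' standardized variable carry no usable structure, so the cap is the number of
#' eigenvalues strictly greater than 1 (Kaiser criterion), floored at 1.
#'
#' Under the X = FL + e convention used throughout the package, molecules are
#' the observations and samples are the variables, so the correlation matrix is
#' samples x samples.
#'
#' @param x a standardized joint `omic_tbl` with >= 2 samples.
#' @return Integer `n >= 1`.
#' @export
max_meaningful_factors <- function(x) {
  stopifnot(is_omic_tbl(x))
  v <- omic_values(x)
  stopifnot(ncol(v) >= 2)
  r <- stats::cor(v)
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) {
    warning("rank-deficient correlation matrix; eigenvalues clipped at 0")
  }
  ev <- pmax(ev, 0)
  max(sum(ev > 1), 1L)
}

# Principal-axis factoring on a correlation matrix.
# Iterates communalities from squared multiple correlations; returns loadings
# (variables x k), communalities and the iteration trace.
paf_fit <- function(r, k, max_iter = 120, tol = 1e-5,
                    on_nonconv = c("warn", "error")) {
  on_nonconv <- match.arg(on_nonconv)
  p <- ncol(r)
  stopifnot(k >= 1, k <= p - 1)
  rinv <- tryCatch(solve(r), error = function(e) NULL)
  h2 <- if (!is.null(rinv)) {
    pmin(pmax(1 - 1 / diag(rinv), 0), 1 - 1e-6)
  } else {
    apply(abs(r - diag(p)), 1, max) # singular R: fall back to max |r|
  }
  trace <- double(0)
  heywood <- FALSE
  for (it in seq_len(max_iter)) {
    rr <- r
    diag(rr) <- h2
    es <- eigen(rr, symmetric = TRUE)
    lam <- es$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(es$values[seq_len(k)], 0)), k)
    h2_new <- rowSums(lam^2)
    if (any(h2_new > 1)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 1 - 1e-6)
    }
    delta <- max(abs(h2_new - h2))
    trace <- c(trace, delta)
    h2_prev <- h2
    h2 <- h2_new
    if (delta < tol) {
      if (heywood) warning("Heywood case: communality clipped at 1 - 1e-6")
      rownames(lam) <- colnames(r)
      return(list(loadings = lam, communality = h2, iterations = it,
                  trace = trace))
    }
  }
  msg <- paste0("principal-axis factoring did not converge in ", max_iter,
                " iterations (last deltas: ",
                paste(signif(utils::tail(trace, 5), 3), collapse = ", "), ")")
  if (on_nonconv == "error") stop(msg, call. = FALSE)
  # weak-structure data can cycle between two communality states at large k;
  # settle at the midpoint of the cycle
  warning(msg, "; returning cycle midpoint")
  h2 <- (h2 + h2_prev) / 2
  rr <- r
  diag(rr) <- h2
  es <- eigen(rr, symmetric = TRUE)
  lam <- es$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(es$values[seq_len(k)], 0)), k)
  rownames(lam) <- colnames(r)
  list(loadings = lam, communality = pmin(rowSums(lam^2), 1 - 1e-6),
       iterations = max_iter, trace = trace)
}

#' Fit one factor model X = FL + e
#'
#' The joint matrix X (molecules x samples) is modelled as scores F
#' (molecules x k) times loadings L (k x samples) plus unique variation e.
#' Samples are the variables: the model is estimated from their correlation
#' matrix by principal-axis factoring with iterated communalities (default) or
#' maximum likelihood via [stats::factanal()]. Loadings are varimax-rotated by
#' default; factor scores are computed by the regression (Thomson) method on
#' column-standardized molecule rows, so scores are approximately unit-variance
#' and the conventional 2.6 cutoff acts as a z-like threshold.
#'
#' Sign convention: each factor is flipped so its largest-magnitude loading is
#' positive, making fits deterministic.
#'
#' @param x a standardized joint `omic_tbl`.
#' @param k number of factors, `1 <= k <= n_samples - 1`.
#' @param rotation `"varimax"` (default) or `"none"`.
#' @param method `"paf"` (default) or `"ml"`.
#' @param seed seed for the rotation restarts (the estimator itself is
#'   deterministic); same data and seed give bitwise-identical fits.
#' @param n_starts number of random orthogonal starts for the varimax
#'   rotation. The varimax criterion has many near-tied local optima on
#'   block-structured loading matrices; the fit rotates from the unrotated
#'   orientation plus `n_starts` seeded random orientations, keeps solutions
#'   within 5% of the best criterion value, and among those picks the one
#'   whose least-marked factor has the largest salient loading (a factor with
#'   no salient marker variable is uninterpretable, so such rotations are
#'   avoided).
#' @return An object of class `fa_model`: list with `k`, `scores`
#'   (molecules x k), `loadings` (samples x k, i.e. t(L)), `uniqueness`,
#'   `communality`, `explained` (variance share per factor), `reproduction_err`
#'   (max abs error of the reproduced correlation matrix), `rotation`,
#'   `row_meta`, `sample_ids`.
#' @export
fit_factor_model <- function(x, k, rotation = c("varimax", "none"),
                             method = c("paf", "ml"), seed = 1,
                             n_starts = 48) {
  rotation <- match.arg(rotation)
  method <- match.arg(method)
  stopifnot(is_omic_tbl(x))
  v <- omic_values(x)
  p <- ncol(v)
  stopifnot(k >= 1, k <= p - 1)
  r <- stats::cor(v)
  if (method == "paf") {
    fit <- paf_fit(r, k)
    lam <- fit$loadings
  } else {
    fa <- stats::factanal(covmat = r, factors = k, rotation = "none",
                          n.obs = nrow(v))
    lam <- matrix(fa$loadings, p, k, dimnames = list(colnames(r), NULL))
  }
  if (rotation == "varimax" && k > 1) {
    lam <- rotate_varimax_multistart(lam, n_starts = n_starts, seed = seed)
  }
  # deterministic sign: largest |loading| positive per factor
  flip <- vapply(seq_len(k), function(j) {
    sign(lam[which.max(abs(lam[, j])), j])
  }, double(1))
  flip[flip == 0] <- 1
  lam <- sweep(lam, 2, flip, `*`)
  h2 <- rowSums(lam^2)
  uniq <- pmin(pmax(1 - h2, 0), 1)
  # regression (Thomson) scores on column-standardized observations;
  # near-singular correlation matrices (strong class blocks) take the
  # Moore-Penrose pseudoinverse
  z <- scale(v)
  gamma <- tryCatch(solve(r, lam),
                    error = function(e) MASS::ginv(r) %*% lam)
  scores <- z %*% gamma
  colnames(scores) <- paste0("F", seq_len(k))
  colnames(lam) <- paste0("F", seq_len(k))
  rep_err <- max(abs(r - lam %*% t(lam) - diag(uniq)))
  structure(list(
    k = as.integer(k),
    scores = scores,
    loadings = lam,
    uniqueness = uniq,
    communality = h2,
    explained = colSums(lam^2) / p,
    reproduction_err = rep_err,
    rotation = rotation,
    method = method,
    seed = seed,
    row_meta = omic_meta(x),
    sample_ids = colnames(v)
  ), class = "fa_model")
}

#' @export
print.fa_model <- function(x, ...) {
  cat(sprintf("fa_model: k = %d (%s, %s), %d molecules x %d samples\n",
              x$k, x$method, x$rotation, nrow(x$scores), length(x$sample_ids)))
  cat(sprintf("  explained common variance: %.3f; reproduction error: %.2e\n",
              sum(x$explained), x$reproduction_err))
  invisible(x)
}

# raw varimax simplicity criterion (variance of squared loadings per factor)
varimax_criterion <- function(lam) {
  p <- nrow(lam)
  sum(colSums(lam^4) / p - (colSums(lam^2) / p)^2)
}

# Varimax with seeded random restarts. Keeps all local optima within 5% of
# the best criterion value and returns the one maximizing the saliency of its
# least-marked factor (min over factors of max |loading|). The user RNG state
# is left untouched.
rotate_varimax_multistart <- function(lam, n_starts = 48, seed = 1,
                                      crit_tol = 0.05) {
  k <- ncol(lam)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed((seed %||% 1) + 5077)
  starts <- c(list(diag(k)),
              replicate(n_starts, qr.Q(qr(matrix(stats::rnorm(k * k), k))),
                        simplify = FALSE))
  sols <- lapply(starts, function(q) {
    l0 <- lam %*% q
    l0 %*% stats::varimax(l0, normalize = FALSE)$rotmat
  })
  crits <- vapply(sols, varimax_criterion, double(1))
  keep <- which(crits >= max(crits) * (1 - crit_tol))
  saliency <- vapply(sols[keep], function(l) min(apply(abs(l), 2, max)),
                     double(1))
  sols[[keep[which.max(saliency)]]]
}

#' Fit the whole model family M1..Mn
#'
#' Fits one factor model for every k from 1 to the Kaiser cap of the joint
#' matrix (or an explicit `n_max`). All models are fitted independently on the
#' same matrix; results are deterministic.
#'
#' @inheritParams fit_factor_model
#' @param n_max optional cap; defaults to [max_meaningful_factors()].
#' @return An object of class `fa_family`: list with `models` (list of
#'   `fa_model`), `n`, `rotation`, `seed`.
#' @export
fit_model_family <- function(x, rotation = "varimax", method = "paf",
                             n_max = NULL, seed = 1, n_starts = 48) {
  n <- as.integer(n_max %||% max_meaningful_factors(x))
  n <- min(n, length(omic_samples(x)) - 1L)
  models <- lapply(seq_len(n), function(k) {
    tryCatch(
      fit_factor_model(x, k, rotation = rotation, method = method, seed = seed,
                       n_starts = n_starts),
      error = function(e) {
        stop("model M", k, ": ", conditionMessage(e), call. = FALSE)
      })
  })
  structure(list(models = models, n = n, rotation = rotation, seed = seed),
            class = "fa_family")
}

#' @export
print.fa_family <- function(x, ...) {
  cat(sprintf("fa_family: models M1..M%d (%s)\n", x$n, x$rotation))
  invisible(x)
}

#' Extract key molecules of one factor
#'
#' Key molecules are those whose absolute factor score reaches the threshold
#' (default 2.6, a z-like cutoff on the approximately unit-variance regression
#' scores). The result is partitioned by omic layer and sorted by |score|
#' descending, so a single factor directly yields a cross-layer signature.
#'
#' @param model an `fa_model`.
#' @param factor factor index in `1..model$k`.
#' @param threshold positive score cutoff (default 2.6).
#' @return An object of class `key_molecule_set`: list with `factor`,
#'   `threshold`, and `molecules`, a tibble (`molecule_id`, `gene_id`, `layer`,
#'   `score`) sorted by |score| descending.
#' @export
extract_key_molecules <- function(model, factor, threshold = 2.6) {
  stopifnot(inherits(model, "fa_model"),
            factor >= 1, factor <= model$k, threshold >= 0)
  sc <- model$scores[, factor]
  keep <- which(abs(sc) >= threshold)
  mol <- model$row_meta[keep, , drop = FALSE]
  mol$score <- unname(sc[keep])
  mol <- mol[order(-abs(mol$score)), , drop = FALSE]
  structure(list(factor = as.integer(factor), threshold = threshold,
                 molecules = tibble::as_tibble(mol)),
            class = "key_molecule_set")
}

#' @export
print.key_molecule_set <- function(x, ...) {
  cat(sprintf("key_molecule_set: factor %d, |score| >= %.2f, %d molecules\n",
              x$factor, x$threshold, nrow(x$molecules)))
  print(table(x$molecules$layer))
  invisible(x)
}
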
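#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the square assignment problem with the O(n^3) shortest augmenting
#' path formulation (potentials). Used to match recovered factors to planted
#' factors up to permutation; exported because parameter-recovery studies need
#' it directly.
#'
#' @param cost square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
hungarian_assign <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(m == n, all(is.finite(cost)))
  # potentials u (rows), v (columns); index shift +1 hosts the dummy row/col 0
  u <- double(n + 1)
  v <- double(m + 1)
  p <- integer(m + 1) # p[j+1]: row matched to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Match recovered factors to planted factors
#'
#' Factor solutions are identified only up to column permutation and sign.
#' This utility computes |correlation| between every recovered column and every
#' reference column, finds the permutation maximizing total |correlation| via
#' [hungarian_assign()], and reports the signed correlation after the optimal
#' sign flip.
#'
#' @param recovered,reference numeric matrices with matching row dimension
#'   (e.g. samples x k loadings); `reference` may have fewer columns.
#' @return A tibble with `reference` (column index), `recovered` (matched
#'   column), `cor` (absolute correlation of the matched pair) and `sign`.
#' @export
match_factors <- function(recovered, reference) {
  recovered <- as.matrix(recovered)
  reference <- as.matrix(reference)
  stopifnot(nrow(recovered) == nrow(reference),
            ncol(recovered) >= ncol(reference))
  cc <- stats::cor(reference, recovered) # ref x rec
  cc[!is.finite(cc)] <- 0
  k_ref <- ncol(reference)
  k_rec <- ncol(recovered)
  # pad to square with zero gain for unmatched recovered columns
  cost <- matrix(0, k_rec, k_rec)
  cost[seq_len(k_ref), ] <- -abs(cc)
  a <- hungarian_assign(cost)
  idx <- a[seq_len(k_ref)]
  tibble::tibble(
    reference = seq_len(k_ref),
    recovered = idx,
    cor = abs(cc[cbind(seq_len(k_ref), idx)]),
    sign = sign(cc[cbind(seq_len(k_ref), idx)])
  )
}
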
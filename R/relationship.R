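# Numerator relationship matrix A and its sparse inverse.
#
# A is built by the tabular method (vectorised over earlier individuals, so
# the R-level loop is only over individuals); the inverse uses
# Henderson's rules with Quaas' inbreeding adjustment, giving the familiar
# (individual, parent, parent-pair) sparsity pattern.

#' Numerator relationship matrix of a pedigree
#'
#' Computes the additive (numerator) relationship matrix A by the tabular
#' method, together with per-individual inbreeding coefficients
#' F (A_ii = 1 + F_i). Founders are assumed unrelated and non-inbred, so
#' founder diagonals are exactly 1. Unknown parents contribute nothing.
#'
#' @param ped a `pedigree` (re-sorted internally if not topologically
#'   ordered).
#' @return a list of class `relationship_matrix` with elements `order`
#'   (individual ids), `A` (dense symmetric matrix with dimnames) and `F`
#'   (named inbreeding coefficients).
#' @export
relationship_matrix <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped$id, ped$sire, ped$dam, ped$sex)
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  if (any(s >= seq_len(n) | d >= seq_len(n), na.rm = TRUE)) {
    ord <- topo_sort_pedigree(ped)
    ped <- new_pedigree(as.data.frame(ped)[ord, ])
    s <- match(ped$sire, ped$id)
    d <- match(ped$dam, ped$id)
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- numeric(i - 1L)
      if (!is.na(si)) aj <- aj + A[j, si]
      if (!is.na(di)) aj <- aj + A[j, di]
      aj <- 0.5 * aj
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  structure(list(order = ped$id, A = A, F = setNames(diag(A) - 1, ped$id)),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix: %d individuals, mean F = %.4f\n",
              length(x$order), mean(x$F)))
  invisible(x)
}

# Mendelian sampling variance given the inbreeding of the known parents:
# 1 with no known parent, 0.75 - F_p/4 with one, 0.5 - (F_s + F_d)/4 with two.
mendelian_variance <- function(F_known) {
  1 - 0.25 * length(F_known) - 0.25 * sum(F_known)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A^-1 directly from the pedigree via Henderson's rules, using the
#' inbreeding coefficients from [relationship_matrix()] in the Mendelian
#' sampling variances, so the result is exact for inbred pedigrees. Only
#' (individual, parent) and (parent, parent) entries are touched, so the
#' result is sparse.
#'
#' @param ped a `pedigree`.
#' @return a symmetric sparse matrix (`Matrix::dsCMatrix`) with dimnames in
#'   pedigree order.
#' @export
inverse_relationship <- function(ped) {
  rm_ <- relationship_matrix(ped)
  n <- length(rm_$order)
  ped_df <- as.data.frame(ped)[match(rm_$order, ped$id), ]
  s <- match(ped_df$sire, rm_$order)
  d <- match(ped_df$dam, rm_$order)
  Fi <- rm_$F
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    par <- c(s[i], d[i])
    par <- par[!is.na(par)]
    b <- 1 / mendelian_variance(Fi[par])
    add(i, i, b)
    for (p in par) {
      add(i, p, -b / 2); add(p, i, -b / 2)
    }
    for (p in par) for (q in par) add(p, q, b / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(rm_$order, rm_$order))
  stopifnot(nrow(Ainv) == n)
  Matrix::forceSymmetric(Ainv)
}
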
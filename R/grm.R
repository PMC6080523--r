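#' Scaling constant of the genomic relationship matrix
#'
#' `lambda = 1 / sum_i 2 p_i (1 - p_i)` over the panel's SNPs.
#'
#' @param freq counted-allele frequencies.
#' @return A positive scalar.
#' @export
grm_lambda <- function(freq) {
  denom <- sum(2 * freq * (1 - freq))
  if (denom <= 0) {
    stop_wssgwas("all SNPs monomorphic: zero 2p(1-p) denominator", "grm_degenerate")
  }
  1 / denom
}

#' Weighted genomic relationship matrix
#'
#' VanRaden's construction with SNP-specific weights:
#' `G = Z D Z' / sum 2 p_i (1 - p_i)`, where `Z` holds gene contents centered
#' by twice the allele frequency and `D = diag(weights)` (identity when
#' `weights` is `NULL`). With unit weights and genotypes near
#' Hardy-Weinberg proportions the mean diagonal is close to 1.
#'
#' @param Z_centered centered gene-content matrix (animals x SNPs), e.g. from
#'   [center_gene_content()].
#' @param freq counted-allele frequencies of the same SNPs.
#' @param weights optional non-negative SNP weight vector (diagonal of D).
#' @return Symmetric matrix with animal dimnames, `role = "G"`, and the
#'   scaling constant in attribute `"lambda"`.
#' @export
build_G <- function(Z_centered, freq, weights = NULL) {
  m <- ncol(Z_centered)
  stopifnot(length(freq) == m)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop_wssgwas("weights must have one entry per SNP", "grm_invalid")
  if (any(weights < 0)) stop_wssgwas("SNP weights must be non-negative", "grm_invalid")
  lambda <- grm_lambda(freq)
  ZW <- sweep(Z_centered, 2, weights, `*`)
  G <- tcrossprod(ZW, Z_centered) * lambda
  G <- (G + t(G)) / 2
  attr(G, "role") <- "G"
  attr(G, "lambda") <- lambda
  G
}

#' Blend a genomic matrix with its pedigree counterpart
#'
#' `(1 - alpha) G + alpha A22`, a standard numerical-stability device that
#' guarantees invertibility of G. `alpha = 0` returns `G_raw` unchanged;
#' `alpha = 1` (no genomic information left) is rejected.
#'
#' @param G_raw raw genomic relationship matrix.
#' @param A22 pedigree relationship matrix of the same animals, same order.
#' @param blend_alpha proportion in `[0, 1)`.
#' @return The blended matrix, `role = "G"`.
#' @export
blend_G <- function(G_raw, A22, blend_alpha = 0.05) {
  if (!(is.numeric(blend_alpha) && length(blend_alpha) == 1 &&
        blend_alpha >= 0 && blend_alpha < 1)) {
    stop_wssgwas("blend_alpha must be in [0, 1)", "grm_invalid")
  }
  if (blend_alpha == 0) return(G_raw)
  stopifnot(all(dim(G_raw) == dim(A22)))
  G <- (1 - blend_alpha) * G_raw + blend_alpha * A22
  attr(G, "role") <- "G"
  attr(G, "lambda") <- attr(G_raw, "lambda")
  G
}

#' Combined pedigree-genomic inverse H^-1
#'
#' Single-step relationship inverse:
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`, i.e. `A^-1` with the genotyped
#' block incremented by `G^-1 - A22^-1`. With no genotyped animals, or with
#' `G = A22`, the result equals `A^-1` exactly.
#'
#' @param A_inv inverse numerator relationship matrix (id dimnames).
#' @param A22_inv inverse of the genotyped block of A.
#' @param G_inv inverse of the (blended) genomic relationship matrix.
#' @param genotyped_ids ids of the genotyped animals, in the row order of
#'   `G_inv` and `A22_inv`.
#' @return Symmetric matrix, `role = "H_inverse"`.
#' @export
build_H_inverse <- function(A_inv, A22_inv, G_inv, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  H_inv <- A_inv
  if (length(genotyped_ids)) {
    if (!all(genotyped_ids %in% rownames(A_inv))) {
      stop_wssgwas("genotyped ids missing from A inverse", "ids_missing")
    }
    if (!is.null(rownames(G_inv)) && !identical(rownames(G_inv), genotyped_ids)) {
      stop_wssgwas("G inverse row order does not match genotyped_ids", "ids_mismatch")
    }
    if (!is.null(rownames(A22_inv)) && !identical(rownames(A22_inv), genotyped_ids)) {
      stop_wssgwas("A22 inverse row order does not match genotyped_ids", "ids_mismatch")
    }
    stopifnot(all(dim(G_inv) == length(genotyped_ids)),
              all(dim(A22_inv) == length(genotyped_ids)))
    H_inv[genotyped_ids, genotyped_ids] <-
      H_inv[genotyped_ids, genotyped_ids] + (G_inv - A22_inv)
  }
  attr(H_inv, "role") <- "H_inverse"
  H_inv
}

# Internal: symmetric positive-definite inverse with an explicit error.
invert_spd <- function(M, what = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    stop_wssgwas(paste0(what, " is singular or not positive definite; ",
                        "consider blending (blend_alpha > 0) or SNP pruning"),
                 "matrix_singular")
  }
  inv <- chol2inv(ch)
  dimnames(inv) <- dimnames(M)
  inv
}
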
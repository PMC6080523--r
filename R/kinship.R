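#' Numerator relationship matrix A
#'
#' Builds the pedigree-based additive (numerator) relationship matrix by the
#' tabular method: for animal `i` with parents `s`, `d`,
#' `a_ii = 1 + a_sd/2` and `a_ij = (a_js + a_jd)/2` for earlier animals `j`,
#' with unknown parents treated as unrelated, non-inbred base animals.
#' Diagonals equal 1 plus the inbreeding coefficient.
#'
#' @param ped an ordered pedigree tibble (see [pedigree()]).
#' @return A dense symmetric matrix with animal ids as dimnames and
#'   attribute `role = "A"`.
#' @examples
#' ped <- pedigree(c("s", "d", "x"), c(NA, NA, "s"), c(NA, NA, "d"))
#' build_A(ped)
#' @export
build_A <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$animal
  idx <- stats::setNames(seq_len(n), ids)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    a_sd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + a_sd / 2
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(s)) rel <- rel + A[j, s]
      if (!is.na(d)) rel <- rel + A[j, d]
      rel <- rel / 2
      A[j, i] <- rel
      A[i, j] <- rel
    }
  }
  attr(A, "role") <- "A"
  A
}

#' Inbreeding coefficients from pedigree
#'
#' @param ped an ordered pedigree tibble.
#' @return Named numeric vector `F` (diagonal of A minus 1).
#' @export
inbreeding_coefficients <- function(ped) {
  diag(build_A(ped)) - 1
}

#' Inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: the contribution of animal
#' `i` is `1/m_i` on `(i,i)`, `-1/(2 m_i)` on animal-by-parent cells and
#' `1/(4 m_i)` on parent-by-parent cells, where `m_i` is the Mendelian
#' sampling variance `0.5 - 0.25 (F_s + F_d)` (0.75 minus `0.25 F` with one
#' known parent, 1 with none). Inbreeding coefficients come from a tabular
#' pass, adequate at desk scale.
#'
#' @param ped an ordered pedigree tibble.
#' @param inbreeding optional precomputed inbreeding coefficients in pedigree
#'   order (saves a tabular pass when A was already built).
#' @return A dense symmetric matrix, attribute `role = "A_inverse"`;
#'   `build_A(ped) %*% build_A_inverse(ped)` is the identity to near
#'   machine precision.
#' @export
build_A_inverse <- function(ped, inbreeding = NULL) {
  validate_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$animal
  idx <- stats::setNames(seq_len(n), ids)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  Fc <- inbreeding %||% inbreeding_coefficients(ped)
  stopifnot(length(Fc) == n)
  Ainv <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    m <- 1
    if (!is.na(s)) m <- m - 0.25 * (1 + Fc[s])
    if (!is.na(d)) m <- m - 0.25 * (1 + Fc[d])
    # m = 0.5 - 0.25(F_s+F_d) both known; 0.75 - 0.25 F one known; 1 none
    alpha <- 1 / m
    Ainv[i, i] <- Ainv[i, i] + alpha
    for (p in c(s, d)) {
      if (!is.na(p)) {
        Ainv[i, p] <- Ainv[i, p] - alpha / 2
        Ainv[p, i] <- Ainv[p, i] - alpha / 2
      }
    }
    for (p in c(s, d)) {
      for (q in c(s, d)) {
        if (!is.na(p) && !is.na(q)) Ainv[p, q] <- Ainv[p, q] + alpha / 4
      }
    }
  }
  attr(Ainv, "role") <- "A_inverse"
  Ainv
}

#' Genotyped-subset block of a relationship matrix
#'
#' Extracts the principal submatrix of `A` for the genotyped animals, in the
#' order given.
#'
#' @param A relationship matrix with id dimnames (from [build_A()]).
#' @param genotyped_ids character vector of animal ids.
#' @return The submatrix with `role = "A22"`.
#' @export
extract_A22 <- function(A, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  missing <- setdiff(genotyped_ids, rownames(A))
  if (length(missing)) {
    stop_wssgwas(
      paste0("ids not in pedigree/matrix: ", paste(head(missing, 10), collapse = ", ")),
      "ids_missing"
    )
  }
  A22 <- A[genotyped_ids, genotyped_ids, drop = FALSE]
  attr(A22, "role") <- "A22"
  A22
}
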
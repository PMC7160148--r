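#' Relationship matrices
#'
#' Dense symmetric relationship matrices over an explicit animal ordering,
#' carried as a plain matrix with animal ids as dimnames and a `kind`
#' attribute (`"A"`, `"A22"`, `"Ainv"`, `"G"`, `"G_blended"`, `"H"`,
#' `"H_inverse"`).
#'
#' @name relmat
NULL

relmat <- function(values, ids, kind) {
  dimnames(values) <- list(ids, ids)
  attr(values, "kind") <- kind
  values
}

#' Pedigree (numerator) relationship matrix
#'
#' Tabular method with inbreeding: diagonal is 1 + F, off-diagonals are
#' twice the kinship. The pedigree must be topologically ordered (as
#' produced by [as_pedigree()]); parents not listed as animals are treated
#' as unknown.
#'
#' @param ped a `pedigree`.
#' @return A `relmat` of kind "A".
#' @export
build_A <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  n <- nrow(ped)
  pi <- ped_parent_index(ped)
  s <- pi$sire; d <- pi$dam
  if (any(s >= seq_len(n) & s > 0L) || any(d >= seq_len(n) & d > 0L))
    stop("pedigree not topologically ordered")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (si > 0L) row <- row + 0.5 * A[si, j]
      if (di > 0L) row <- row + 0.5 * A[di, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  relmat(A, ped$animal, "A")
}

#' VanRaden genomic relationship matrix
#'
#' G = McMc' / (2 sum p q) where Mc is the dosage matrix centered by twice
#' the allele frequency per SNP; missing calls are mean-imputed (2p) at
#' construction. Frequencies default to those observed in the genotyped
#' set.
#'
#' @param geno a `geno_matrix`.
#' @param p allele frequencies for centering (default observed).
#' @return A `relmat` of kind "G" with attribute `scale` = 2*sum(p*q) and
#'   `p` the frequencies used.
#' @export
build_G <- function(geno, p = geno$p) {
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!any(poly)) stop("all SNPs monomorphic: VanRaden denominator is zero")
  Mc <- dosage_matrix(geno, center = TRUE, p = p)
  k <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Mc) / k
  G <- relmat(G, rownames(geno$calls), "G")
  attr(G, "scale") <- k
  attr(G, "p") <- p
  G
}

#' Blend G with the genotyped-subset pedigree matrix
#'
#' `G_blended = w G + (1 - w) A22`, the standard guard against a singular
#' G before inversion in single-step evaluations.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships of the genotyped animals (same order).
#' @param weight blend weight w in (0, 1].
#' @export
blend_G <- function(G, A22, weight = 0.95) {
  stopifnot(weight > 0, weight <= 1, all(dim(G) == dim(A22)))
  Gb <- weight * G + (1 - weight) * A22
  Gb <- relmat(Gb, rownames(G), "G_blended")
  attr(Gb, "scale") <- attr(G, "scale")
  attr(Gb, "p") <- attr(G, "p")
  Gb
}

#' Inverse of the single-step H matrix
#'
#' H^-1 = A^-1 + [0 0; 0 Gb^-1 - A22^-1] placed on the genotyped indices,
#' with Gb = w G + (1-w) A22. With no genotyped animals (or Gb identical to
#' A22) this returns A^-1 exactly.
#'
#' @param Ainv inverse pedigree relationship matrix (all animals).
#' @param A22 pedigree relationships among genotyped animals (ids must be a
#'   subset of Ainv's).
#' @param G genomic relationship matrix on the same genotyped animals, or
#'   NULL for none.
#' @param blend_weight w for [blend_G()]; 1 means unblended.
#' @return A `relmat` of kind "H_inverse".
#' @export
build_H_inverse <- function(Ainv, A22 = NULL, G = NULL, blend_weight = 0.95) {
  ids <- rownames(Ainv)
  H <- Ainv
  if (!is.null(G) && nrow(G) > 0L) {
    gids <- rownames(G)
    if (!all(gids %in% ids)) stop("genotyped ids not a subset of pedigree")
    if (is.null(A22) || !identical(rownames(A22), gids))
      stop("A22 must be supplied on the same genotyped animals as G")
    Gb <- blend_G(G, A22, blend_weight)
    Gbi <- tryCatch(chol2inv(chol(Gb)), error = function(e)
      stop("G_blended is singular; lower blend_weight (", conditionMessage(e), ")"))
    A22i <- chol2inv(chol(A22))
    ii <- match(gids, ids)
    H[ii, ii] <- H[ii, ii] + (Gbi - A22i)
  }
  relmat(unclass(H), ids, "H_inverse")
}

#' Dense H matrix (direct definition)
#'
#' H = A with the genotyped block replaced by Gb (blended G) plus the
#' corresponding adjustment of the non-genotyped blocks:
#' H = A + [A12 A22^-1 (Gb - A22) A22^-1 A21, A12 A22^-1 (Gb - A22);
#'          (Gb - A22) A22^-1 A21,            Gb - A22].
#' Its inverse equals [build_H_inverse()] (used as a cross-check oracle and
#' by the dense REML path).
#'
#' @inheritParams build_H_inverse
#' @param A full pedigree relationship matrix.
#' @export
build_H <- function(A, A22 = NULL, G = NULL, blend_weight = 0.95) {
  ids <- rownames(A)
  H <- unclass(A)
  if (!is.null(G) && nrow(G) > 0L) {
    gids <- rownames(G)
    ii <- match(gids, ids)
    Gb <- blend_G(G, A22, blend_weight)
    D <- unclass(Gb) - unclass(A22)
    A22i <- chol2inv(chol(A22))
    B <- A[, ii, drop = FALSE] %*% A22i   # n x g
    H <- H + B %*% D %*% t(B)
  }
  relmat(H, ids, "H")
}

#' Invert a relationship matrix
#'
#' @param R a symmetric positive-definite `relmat`.
#' @export
invert_relmat <- function(R) {
  kind <- attr(R, "kind")
  out <- chol2inv(chol(unclass(R)))
  relmat(out, rownames(R), paste0(if (is.null(kind)) "mat" else kind, "_inverse"))
}

#' Export a relationship matrix as TSV (ids as header row/column)
#' @param R a `relmat`; @param path output path.
#' @export
write_relmat <- function(R, path) {
  df <- data.frame(id = rownames(R), unclass(R), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
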
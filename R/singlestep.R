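#' Single-step relationship matrix H with an APY genomic block
#'
#' Combines pedigree and genomic information for a population in which only
#' some animals are genotyped. With subscript 1 for non-genotyped and 2 for
#' genotyped animals, the blocks are
#' `H11 = A11 + A12 A22^-1 (G_APY - A22) A22^-1 A21`,
#' `H12 = A12 A22^-1 G_APY`, `H22 = G_APY`. Animal order of the result is
#' non-genotyped first, then core, then non-core.
#'
#' @param A pedigree [RelationshipMatrix-class] over all animals
#' @param d an [ApyDecomposition-class] over the genotyped animals
#' @return a [RelationshipMatrix-class]
#' @export
hApyFull <- function(A, d) {
  stopifnot(is(A, "RelationshipMatrix"), is(d, "ApyDecomposition"))
  ord <- .ssOrder(A, d)
  Gapy <- relValues(gApyFull(d))
  A22 <- extractBlock(A, ord$gt, ord$gt)
  n1 <- length(ord$nongen)
  if (n1 == 0L) return(gApyFull(d))
  A11 <- extractBlock(A, ord$nongen, ord$nongen)
  A12 <- extractBlock(A, ord$nongen, ord$gt)
  Pi <- A12 %*% solve(A22)                       # A12 A22^-1
  H11 <- A11 + Pi %*% (Gapy - A22) %*% t(Pi)
  H12 <- Pi %*% Gapy
  ids <- c(ord$nongen, ord$gt)
  H <- rbind(cbind(H11, H12), cbind(t(H12), Gapy))
  dimnames(H) <- list(ids, ids)
  new("RelationshipMatrix", values = (H + t(H)) / 2)
}

#' Inverse of the single-step H with an APY genomic block
#'
#' `H^-1 = A^-1 + blockdiag(0, G_APY^-1 - A22^-1)`, with the correction on
#' the genotyped block. The pedigree inverse is computed densely (reference
#' implementation; no sparse pedigree rules).
#'
#' @inheritParams hApyFull
#' @param mnnFloor passed to [gApyInverse()]
#' @return dense numeric matrix, animal order non-genotyped / core / non-core
#' @export
hApyInverse <- function(A, d, mnnFloor = NULL) {
  stopifnot(is(A, "RelationshipMatrix"), is(d, "ApyDecomposition"))
  ord <- .ssOrder(A, d)
  ids <- c(ord$nongen, ord$gt)
  Ainv <- solve(extractBlock(A, ids, ids))
  gt <- length(ord$nongen) + seq_along(ord$gt)
  A22inv <- solve(extractBlock(A, ord$gt, ord$gt))
  Ainv[gt, gt] <- Ainv[gt, gt] + gApyInverse(d, mnnFloor = mnnFloor) - A22inv
  dimnames(Ainv) <- list(ids, ids)
  (Ainv + t(Ainv)) / 2
}

# Consistent single-step ordering: non-genotyped (pedigree order), then the
# genotyped animals in decomposition order (core first).
.ssOrder <- function(A, d) {
  gt <- animalIds(d)
  all <- animalIds(A)
  bad <- setdiff(gt, all)
  if (length(bad))
    stop("genotyped animals missing from the pedigree relationship matrix: ",
         paste(bad, collapse = ", "))
  list(nongen = setdiff(all, gt), gt = gt)
}
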
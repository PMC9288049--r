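#' Assemble phenotype records with design matrices
#'
#' Builds the record-level design: `y = X b + W u + e`, with one animal per
#' record (W rows are one-hot). The animal universe defaults to the animals
#' appearing in the records; pass `animals` to include animals without
#' records (they obtain EBVs through the relationship structure).
#'
#' @param y numeric phenotype vector
#' @param animal character vector, the animal of each record
#' @param X optional fixed-effect design; default a single intercept
#' @param animals optional full animal universe for the W columns
#' @return a [PhenotypeData-class]
#' @export
phenotypeData <- function(y, animal, X = NULL, animals = NULL) {
  animal <- as.character(animal)
  stopifnot(length(y) == length(animal))
  if (is.null(animals)) animals <- unique(animal)
  bad <- setdiff(animal, animals)
  if (length(bad))
    stop("records on animals outside the universe: ", paste(bad, collapse = ", "))
  n <- length(y)
  W <- matrix(0, n, length(animals), dimnames = list(NULL, animals))
  W[cbind(seq_len(n), match(animal, animals))] <- 1
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  new("PhenotypeData", y = as.numeric(y), X = X, W = W)
}

#' Perpendicular projection onto the core genotype row space
#'
#' `P = Z_c' (Z_c Z_c')^-1 Z_c`, the symmetric idempotent projector onto the
#' row space of the core genotypes. With per-marker weights `D` the oblique
#' analogue `D Z_c' (Z_c D Z_c')^-1 Z_c` is returned (idempotent, and the one
#' under which the projected design reproduces the weighted relationship
#' matrix `k Z D Z'`).
#'
#' @param Zc centered core genotype matrix (n_core x m)
#' @param weights optional positive per-marker weights
#' @return m x m projection matrix
#' @export
projectionOperator <- function(Zc, weights = NULL) {
  ZcD <- if (is.null(weights)) Zc else sweep(Zc, 2L, weights, "*")
  Gram <- tcrossprod(ZcD, Zc)                 # Z_c D Z_c'
  kap <- kappa(Gram, exact = nrow(Gram) <= 200L)
  if (!is.finite(kap) || kap > 1e10)
    stop("Z_c Z_c' is singular or ill-conditioned; choose a different core ",
         "set or blend a residual polygenic fraction")
  t(ZcD) %*% solve(Gram, Zc)
}

#' Reduced (projected) marker design for APY-SNP-BLUP
#'
#' For `beta = 0` the design is `Zdagger = [Z_c; Z_n P]`: non-core genotypes
#' are replaced by their projection onto the core row space. For
#' `beta > 0` the genotype matrix is augmented with the scaled Cholesky
#' factor of A22, `Z* = [sqrt((1-beta)k) Z, sqrt(beta) L]`, and the design
#' pieces of the residual polygenic marker model are built from it, so that
#' breeding values decompose as `u = Zdagger a + R eps + Q xi`.
#'
#' @param cz a [CenteredGenotypes-class] covering all partition ids
#' @param part a [CorePartition-class]
#' @param beta residual polygenic fraction
#' @param L Cholesky factor of A22 (animals ordered core first, as from
#'   [choleskyA22()] on a reordered A22), or the A22
#'   [RelationshipMatrix-class] itself; required when `beta > 0`
#' @param weights optional per-marker weights (beta = 0 only)
#' @return a [ProjectedDesign-class]
#' @export
buildProjectedDesign <- function(cz, part, beta = 0, L = NULL,
                                 weights = NULL) {
  stopifnot(is(cz, "CenteredGenotypes"), is(part, "CorePartition"))
  ids <- animalIds(part)
  bad <- setdiff(ids, rownames(cz@Z))
  if (length(bad))
    stop("partition ids without genotypes: ", paste(bad, collapse = ", "))
  Z <- cz@Z[ids, , drop = FALSE]
  m <- ncol(Z)
  nc <- length(part@core)
  nn <- length(part@noncore)
  Zc <- Z[seq_len(nc), , drop = FALSE]
  Zn <- Z[nc + seq_len(nn), , drop = FALSE]
  w <- if (is.null(weights)) rep(1, m) else as.numeric(weights)
  if (beta == 0) {
    P <- projectionOperator(Zc, weights = weights)
    Zd <- rbind(Zc, Zn %*% P)
    R <- matrix(0, 0, 0)
  } else {
    if (beta >= 1)
      stop("beta = 1 leaves no marker variance; use the GBLUP path on A22")
    if (!is.null(weights))
      stop("marker weights are only supported without a polygenic fraction")
    if (is.null(L))
      stop("beta > 0 requires the Cholesky factor of A22")
    if (is(L, "RelationshipMatrix")) L <- choleskyA22(subsetRel(L, ids))
    if (!identical(rownames(L), ids))
      stop("L must be ordered core animals first, matching the partition")
    Zs <- cbind(sqrt((1 - beta) * cz@k) * Z, sqrt(beta) * L)
    Zsc <- Zs[seq_len(nc), , drop = FALSE]
    Zsn <- Zs[nc + seq_len(nn), , drop = FALSE]
    Gram <- tcrossprod(Zsc)                       # Z*_c Z*_c'
    Proj <- t(Zsc) %*% solve(Gram, Zsc)           # P* on the augmented space
    S <- rbind(diag(m) / sqrt((1 - beta) * cz@k),
               matrix(0, nc + nn, m))
    Zd <- rbind(Zc, Zsn %*% Proj %*% S)
    R <- rbind(diag(nc), Zsn %*% t(Zsc) %*% solve(Gram))
    rownames(R) <- ids
    colnames(R) <- part@core
    P <- Proj
  }
  rownames(Zd) <- ids
  colnames(Zd) <- colnames(Z)
  new("ProjectedDesign", Zdagger = Zd, P = P, R = R, beta = beta,
      k = cz@k, weights = w, partition = part)
}

# Align the record incidence matrix with an animal universe.
.alignW <- function(ph, ids) {
  bad <- setdiff(colnames(ph@W)[colSums(ph@W) > 0], ids)
  if (length(bad))
    stop("records on animals absent from the model: ", paste(bad, collapse = ", "))
  W <- matrix(0, nrow(ph@W), length(ids), dimnames = list(NULL, ids))
  common <- intersect(colnames(ph@W), ids)
  W[, common] <- ph@W[, common]
  W
}

# Generic normal-equations assembler/solver. `blocks` is a named list of
# list(design = n_rec x q matrix with level colnames, penalty = q x q).
# LHS = crossprod([X, D1, D2, ...]) + blockdiag(0, penalty1, penalty2, ...).
.solveMme <- function(y, X, blocks, sigmaE2, model) {
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design X is rank deficient")
  designs <- lapply(blocks, `[[`, "design")
  C <- do.call(cbind, c(list(X), designs))
  LHS <- crossprod(C)
  RHS <- drop(crossprod(C, y))
  p <- ncol(X)
  index <- list(fixed = setNames(seq_len(p), colnames(X)))
  off <- p
  for (nm in names(blocks)) {
    q <- ncol(blocks[[nm]]$design)
    idx <- off + seq_len(q)
    if (q) LHS[idx, idx] <- LHS[idx, idx] + blocks[[nm]]$penalty
    index[[nm]] <- setNames(idx, colnames(blocks[[nm]]$design))
    off <- off + q
  }
  LHS <- (LHS + t(LHS)) / 2
  sol <- tryCatch(drop(solve(LHS, RHS)),
                  error = function(e)
                    stop("mixed model equations are singular (rank ",
                         qr(LHS)$rank, " of ", ncol(LHS), "): ",
                         conditionMessage(e)))
  # one step of iterative refinement; matters when M_nn penalties are large
  sol <- sol + drop(solve(LHS, RHS - LHS %*% sol))
  eff <- lapply(index, function(idx) setNames(sol[idx], names(idx)))
  list(b = eff$fixed, effects = eff[setdiff(names(eff), "fixed")],
       lhs = LHS, index = index, sigmaE2 = sigmaE2, model = model)
}

.asSolution <- function(parts, u = NULL, extra = list()) {
  effects <- c(parts$effects, extra)
  if (!is.null(u)) effects$u <- u
  new("MixedModelSolution", b = parts$b, effects = effects, lhs = parts$lhs,
      index = parts$index, sigmaE2 = parts$sigmaE2, model = parts$model)
}

#' Solve (APY-)GBLUP from a relationship inverse
#'
#' Solves the breeding-value mixed model equations
#' `[[X'X, X'W], [W'X, W'W + Kinv alpha]]` by a dense symmetric
#' factorization. `Kinv` may be any relationship inverse: `G^-1` for plain
#' GBLUP, the structured [gApyInverse()] for APY-GBLUP, or [hApyInverse()]
#' for single-step evaluation.
#'
#' @param ph a [PhenotypeData-class]
#' @param Kinv relationship inverse with animal dimnames
#' @param vc a [VarianceComponents-class]
#' @param model label stored on the solution
#' @return a [MixedModelSolution-class] with effect `u`
#' @export
solveGblup <- function(ph, Kinv, vc, model = "gblup") {
  stopifnot(is(ph, "PhenotypeData"), is(vc, "VarianceComponents"))
  ids <- rownames(Kinv)
  if (is.null(ids)) stop("Kinv must carry animal dimnames")
  W <- .alignW(ph, ids)
  parts <- .solveMme(ph@y, ph@X,
                     list(u = list(design = W,
                                   penalty = Kinv * alphaRatio(vc))),
                     vc@sigmaE2, model)
  .asSolution(parts)
}

#' Solve the partitioned APY-GBLUP (core EBVs plus non-core error terms)
#'
#' Fits the formulation in which non-core breeding values are expressed as a
#' regression on core breeding values plus an independent error term xi:
#' unknowns are `(b, u_c, xi)` with penalties `G_cc^-1 alpha` and
#' `M_nn^-1 alpha`. Non-core EBVs are reconstructed as
#' `u_n = P_nc u_c + xi`. Error terms for animals with a conditional
#' variance below `xiDropTol` are fixed at zero (their genotype lies in the
#' core row space, so xi has zero variance in the limit).
#'
#' @param ph a [PhenotypeData-class]
#' @param d an [ApyDecomposition-class]
#' @param vc a [VarianceComponents-class]
#' @param xiDropTol tolerance below which xi levels are dropped; default
#'   `1e-8 x` the mean source diagonal
#' @return a [MixedModelSolution-class] with effects `u` and `xi`
#' @export
solveApyGblupPartitioned <- function(ph, d, vc, xiDropTol = NULL) {
  stopifnot(is(d, "ApyDecomposition"))
  core <- coreIds(d); nonc <- noncoreIds(d)
  if (is.null(xiDropTol)) xiDropTol <- .mnnFloorDefault(d)
  keep <- d@Mnn >= xiDropTol
  W <- .alignW(ph, c(core, nonc))
  Wc <- W[, seq_along(core), drop = FALSE]
  Wn <- W[, length(core) + seq_along(nonc), drop = FALSE]
  blocks <- list(
    uc = list(design = Wc + Wn %*% d@Pnc, penalty = solve(d@Gcc) * alphaRatio(vc)),
    xi = list(design = Wn[, keep, drop = FALSE],
              penalty = diag(alphaRatio(vc) / d@Mnn[keep],
                             nrow = sum(keep))))
  parts <- .solveMme(ph@y, ph@X, blocks, vc@sigmaE2, "apy-gblup-partitioned")
  xi <- setNames(numeric(length(nonc)), nonc)
  xi[names(parts$effects$xi)] <- parts$effects$xi
  un <- drop(d@Pnc %*% parts$effects$uc) + xi
  u <- c(parts$effects$uc, setNames(un, nonc))
  .asSolution(parts, u = u, extra = list(xi = xi))
}

#' Solve plain SNP-BLUP
#'
#' Marker-effects mixed model `[[X'X, X'WZ], [Z'W'X, Z'W'WZ + D^-1 gamma]]`
#' with `gamma = sigma_e^2 / (k sigma_u^2)`; breeding values are `u = Z a`.
#'
#' @param ph a [PhenotypeData-class]
#' @param cz a [CenteredGenotypes-class]
#' @param vc a [VarianceComponents-class]
#' @param weights optional positive per-marker weights (prior variances
#'   proportional to the weights)
#' @return a [MixedModelSolution-class] with effects `u` and `a`
#' @export
solveSnpBlup <- function(ph, cz, vc, weights = NULL) {
  stopifnot(is(cz, "CenteredGenotypes"))
  Z <- cz@Z
  W <- .alignW(ph, rownames(Z))
  m <- ncol(Z)
  w <- if (is.null(weights)) rep(1, m) else as.numeric(weights)
  stopifnot(all(w > 0))
  parts <- .solveMme(ph@y, ph@X,
                     list(a = list(design = W %*% Z,
                                   penalty = diag(gammaRatio(vc, cz@k) / w,
                                                  nrow = m))),
                     vc@sigmaE2, "snp-blup")
  u <- drop(Z %*% parts$effects$a)
  .asSolution(parts, u = setNames(u, rownames(Z)))
}

#' Solve APY-SNP-BLUP (with optional residual polygenic effect)
#'
#' Marker-effects formulation equivalent to APY-GBLUP. With `beta = 0` the
#' unknowns are `(b, a, xi)`: markers enter through the reduced design
#' `Zdagger` with penalty `I gamma` (or `D^-1 gamma` with weights), and
#' non-core error terms carry penalty `M_nn^-1 alpha`. With `beta > 0` a
#' core polygenic vector `eps` with penalty `A_cc^-1 zeta` is added and the
#' marker penalty becomes `I delta`. Breeding values are reconstructed as
#' `u = Zdagger a (+ R eps) + Q xi`.
#'
#' @param ph a [PhenotypeData-class]
#' @param pd a [ProjectedDesign-class] (its `beta` must match `vc`)
#' @param d the [ApyDecomposition-class] of the matching relationship matrix
#'   (G for beta = 0, the blended G* otherwise)
#' @param vc a [VarianceComponents-class]
#' @param Acc core block of the pedigree relationship matrix, required when
#'   `beta > 0`
#' @param weights optional per-marker weights (must match the weights used in
#'   `pd`; beta = 0 only)
#' @param xiDropTol see [solveApyGblupPartitioned()]
#' @return a [MixedModelSolution-class] with effects `u`, `a`, `xi` and,
#'   when `beta > 0`, `eps`
#' @export
solveApySnpBlup <- function(ph, pd, d, vc, Acc = NULL, weights = NULL,
                            xiDropTol = NULL) {
  stopifnot(is(pd, "ProjectedDesign"), is(d, "ApyDecomposition"))
  if (abs(pd@beta - vc@beta) > 1e-12)
    stop("polygenic fraction of the projected design (", pd@beta,
         ") does not match the variance components (", vc@beta, ")")
  if (vc@beta >= 1)
    stop("beta = 1 leaves a degenerate marker block; use the GBLUP path")
  core <- coreIds(d); nonc <- noncoreIds(d)
  if (!identical(animalIds(pd@partition), animalIds(d@partition)))
    stop("projected design and decomposition use different partitions")
  if (is.null(xiDropTol)) xiDropTol <- .mnnFloorDefault(d)
  keep <- d@Mnn >= xiDropTol
  W <- .alignW(ph, c(core, nonc))
  Wn <- W[, length(core) + seq_along(nonc), drop = FALSE]
  m <- ncol(pd@Zdagger)
  blocks <- list(
    a = list(design = W %*% pd@Zdagger,
             penalty = if (vc@beta == 0)
               diag(gammaRatio(vc, pd@k) / pd@weights, nrow = m)
             else diag(deltaRatio(vc, pd@k), nrow = m)))
  if (vc@beta > 0) {
    if (is.null(Acc)) stop("beta > 0 requires the core pedigree block A_cc")
    blocks$eps <- list(design = W %*% pd@R,
                       penalty = solve(Acc) * zetaRatio(vc))
  }
  blocks$xi <- list(design = Wn[, keep, drop = FALSE],
                    penalty = diag(alphaRatio(vc) / d@Mnn[keep],
                                   nrow = sum(keep)))
  parts <- .solveMme(ph@y, ph@X, blocks, vc@sigmaE2, "apy-snp-blup")
  xi <- setNames(numeric(length(nonc)), nonc)
  xi[names(parts$effects$xi)] <- parts$effects$xi
  u <- drop(pd@Zdagger %*% parts$effects$a)
  if (vc@beta > 0) u <- u + drop(pd@R %*% parts$effects$eps)
  u[nonc] <- u[nonc] + xi
  .asSolution(parts, u = setNames(u, c(core, nonc)), extra = list(xi = xi))
}

#' Solve single-step APY models
#'
#' Joint evaluation of genotyped and non-genotyped animals. The `"gblup"`
#' formulation solves the breeding-value system with the structured
#' [hApyInverse()]. The `"snp"` formulation fits marker effects, a core
#' polygenic vector when `beta > 0`, a pedigree imputation error `eta` for
#' non-genotyped animals, and non-core error terms `xi`; genotypes of
#' non-genotyped animals are implicitly imputed through `A12 A22^-1`.
#' Breeding values for all animals are reconstructed from the solutions.
#'
#' @param ph a [PhenotypeData-class] (records may fall on any animal)
#' @param A pedigree [RelationshipMatrix-class] over all animals
#' @param d an [ApyDecomposition-class] over the genotyped animals (from G,
#'   or from the blended G* when `beta > 0`)
#' @param vc a [VarianceComponents-class]
#' @param formulation `"gblup"` or `"snp"`
#' @param pd a [ProjectedDesign-class]; required for the SNP formulation
#' @param mnnFloor optional M_nn clamp for the GBLUP path
#' @param xiDropTol see [solveApyGblupPartitioned()]
#' @return a [MixedModelSolution-class]; `u` covers all animals, ordered
#'   non-genotyped, core, non-core
#' @export
solveSsApy <- function(ph, A, d, vc, formulation = c("gblup", "snp"),
                       pd = NULL, mnnFloor = NULL, xiDropTol = NULL) {
  formulation <- match.arg(formulation)
  stopifnot(is(A, "RelationshipMatrix"), is(d, "ApyDecomposition"))
  if (formulation == "gblup") {
    Hinv <- hApyInverse(A, d, mnnFloor = mnnFloor)
    return(solveGblup(ph, Hinv, vc, model = "ss-apy-gblup"))
  }
  if (is.null(pd)) stop("the SNP formulation requires a projected design")
  if (vc@beta >= 1) stop("beta = 1 is rejected on the SNP path")
  ord <- .ssOrder(A, d)
  core <- coreIds(d); nonc <- noncoreIds(d)
  gt <- ord$gt; nongen <- ord$nongen
  n1 <- length(nongen)
  A22 <- extractBlock(A, gt, gt)
  Pi <- if (n1) extractBlock(A, nongen, gt) %*% solve(A22) else
    matrix(0, 0, length(gt))
  Ainv <- solve(extractBlock(A, c(nongen, gt), c(nongen, gt)))
  A11sup <- Ainv[seq_len(n1), seq_len(n1), drop = FALSE]   # A^11 block
  if (is.null(xiDropTol)) xiDropTol <- .mnnFloorDefault(d)
  keep <- d@Mnn >= xiDropTol
  W <- .alignW(ph, c(nongen, gt))
  W1 <- W[, seq_len(n1), drop = FALSE]
  W2 <- W[, n1 + seq_along(gt), drop = FALSE]
  Q <- rbind(matrix(0, length(core), length(nonc)), diag(length(nonc)))
  dimnames(Q) <- list(c(core, nonc), nonc)
  m <- ncol(pd@Zdagger)
  blocks <- list(
    a = list(design = W1 %*% (Pi %*% pd@Zdagger) + W2 %*% pd@Zdagger,
             penalty = if (vc@beta == 0) diag(gammaRatio(vc, pd@k), nrow = m)
                       else diag(deltaRatio(vc, pd@k), nrow = m)))
  if (vc@beta > 0) {
    Acc <- extractBlock(A, core, core)
    blocks$eps <- list(design = W1 %*% (Pi %*% pd@R) + W2 %*% pd@R,
                       penalty = solve(Acc) * zetaRatio(vc))
  }
  blocks$eta <- list(design = W1, penalty = A11sup * alphaRatio(vc))
  Qk <- Q[, keep, drop = FALSE]
  blocks$xi <- list(design = W1 %*% (Pi %*% Qk) + W2 %*% Qk,
                    penalty = diag(alphaRatio(vc) / d@Mnn[keep],
                                   nrow = sum(keep)))
  parts <- .solveMme(ph@y, ph@X, blocks, vc@sigmaE2, "ss-apy-snp-blup")
  xi <- setNames(numeric(length(nonc)), nonc)
  xi[names(parts$effects$xi)] <- parts$effects$xi
  u2 <- drop(pd@Zdagger %*% parts$effects$a)
  if (vc@beta > 0) u2 <- u2 + drop(pd@R %*% parts$effects$eps)
  u2 <- u2 + drop(Q %*% xi)
  u1 <- if (n1) drop(Pi %*% u2) + parts$effects$eta else numeric(0)
  u <- c(setNames(u1, nongen), setNames(u2, gt))
  extra <- list(xi = xi)
  if (n1) extra$eta <- setNames(parts$effects$eta, nongen)
  .asSolution(parts, u = u, extra = extra)
}

#' Prediction error (co)variance block of a solved model
#'
#' Returns `sigma_e^2` times the inverse-LHS block for the requested levels
#' of a fitted effect — the PEV on the observed scale. Divide by
#' `sigma_u^2` (see [pevRelScale()]) to obtain the relationship-scale PEV
#' used by the back-solving and reliability formulas.
#'
#' @param sol a [MixedModelSolution-class]
#' @param effect name of a directly fitted effect block (e.g. `"u"`, `"uc"`,
#'   `"a"`)
#' @param ids level names within the block; default all
#' @return symmetric numeric matrix
#' @export
pevBlock <- function(sol, effect = "u", ids = NULL) {
  stopifnot(is(sol, "MixedModelSolution"))
  idx <- sol@index[[effect]]
  if (is.null(idx))
    stop("effect '", effect, "' was not fitted directly in model '",
         sol@model, "'; available: ",
         paste(setdiff(names(sol@index), "fixed"), collapse = ", "))
  if (!is.null(ids)) {
    bad <- setdiff(ids, names(idx))
    if (length(bad))
      stop("levels not in effect '", effect, "': ", paste(bad, collapse = ", "))
    idx <- idx[ids]
  }
  E <- matrix(0, ncol(sol@lhs), length(idx))
  E[cbind(idx, seq_along(idx))] <- 1
  blk <- sol@sigmaE2 * solve(sol@lhs, E)[idx, , drop = FALSE]
  dimnames(blk) <- list(names(idx), names(idx))
  (blk + t(blk)) / 2
}

#' Convert an observed-scale PEV to the relationship (sigma_u^2 = 1) scale
#' @param pev PEV matrix or vector from [pevBlock()]
#' @param vc a [VarianceComponents-class]
#' @return rescaled PEV
#' @export
pevRelScale <- function(pev, vc) pev / vc@sigmaU2
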
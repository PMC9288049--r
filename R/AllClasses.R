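#' @import methods
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils read.table write.table
NULL

#' Pedigree with topological ordering
#'
#' Holds animal/sire/dam records. Unknown parents are `NA`. On construction
#' the pedigree is checked for acyclicity and a topological order (parents
#' before offspring) is computed and stored.
#'
#' @slot records data.frame with character columns `animal`, `sire`, `dam`.
#' @slot order integer permutation of rows placing parents before offspring.
#' @export
setClass("Pedigree",
  representation(records = "data.frame", order = "integer"))

setValidity("Pedigree", function(object) {
  rec <- object@records
  if (!all(c("animal", "sire", "dam") %in% names(rec)))
    return("records must have columns animal, sire, dam")
  if (anyDuplicated(rec$animal))
    return("duplicated animal ids in pedigree")
  if (length(object@order) != nrow(rec))
    return("order length must equal number of records")
  TRUE
})

#' Centered (and scaled) genotype matrix
#'
#' Column `j` of `Z` is `counts_j - 2 p_j`. The scaling constant `k` turns the
#' cross-product into a genomic relationship matrix, `G = k Z Z'`. The pair
#' `(p, k)` must be reused verbatim when centering later cohorts so that
#' indirect predictions stay on the same scale.
#'
#' @slot Z numeric matrix, animals in rows, markers in columns (dimnames set).
#' @slot p numeric vector of allele frequencies used for centering, named by
#'   marker.
#' @slot k positive scalar scaling factor.
#' @export
setClass("CenteredGenotypes",
  representation(Z = "matrix", p = "numeric", k = "numeric"))

setValidity("CenteredGenotypes", function(object) {
  if (length(object@k) != 1L || !is.finite(object@k) || object@k <= 0)
    return("k must be a single positive number")
  if (length(object@p) != ncol(object@Z))
    return("p must have one entry per marker column of Z")
  if (is.null(rownames(object@Z)) || is.null(colnames(object@Z)))
    return("Z must carry animal row names and marker column names")
  if (any(object@p <= 0 | object@p >= 1))
    return("allele frequencies must lie strictly in (0, 1)")
  TRUE
})

#' Symmetric relationship matrix keyed by animal id
#'
#' Container for A, A22, G, G*, G_APY and H matrices. Values are dense and
#' symmetric; animal ids are the dimnames.
#'
#' @slot values symmetric numeric matrix with identical row/column names.
#' @export
setClass("RelationshipMatrix", representation(values = "matrix"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("row and column names must be identical animal ids")
  if (anyDuplicated(rownames(v))) return("duplicated animal ids")
  if (max(abs(v - t(v))) > 1e-12 * max(1, max(abs(v))))
    return("matrix is not symmetric")
  TRUE
})

#' Core/non-core partition of the genotyped animals
#'
#' @slot core character vector of core animal ids (ordered).
#' @slot noncore character vector of non-core animal ids (ordered).
#' @slot seed integer seed used for a random draw, or NA for a given list.
#' @export
setClass("CorePartition",
  representation(core = "character", noncore = "character", seed = "integer"))

setValidity("CorePartition", function(object) {
  if (length(object@core) < 1L) return("at least one core animal required")
  if (length(intersect(object@core, object@noncore)) > 0L)
    return("core and non-core sets must be disjoint")
  if (anyDuplicated(c(object@core, object@noncore)))
    return("duplicated ids in partition")
  TRUE
})

#' APY decomposition of a relationship matrix
#'
#' Stores the regression of non-core on core animals, `P_nc = G_nc G_cc^-1`,
#' the diagonal conditional variances `M_nn = diag(G_nn - G_nc G_cc^-1 G_cn)`,
#' and the core block `G_cc`. Everything G_APY-related derives from this
#' object. `gnnDiag` keeps the non-core diagonal of the source matrix, needed
#' for the reliability-style measure rho.
#'
#' @slot Pnc numeric matrix (n_noncore x n_core).
#' @slot Mnn named numeric vector of conditional variances (length n_noncore).
#' @slot Gcc core block of the source relationship matrix.
#' @slot gnnDiag named numeric, non-core diagonal of the source matrix.
#' @slot partition the [CorePartition-class] used.
#' @slot source label of the source matrix ("G" or "Gstar").
#' @export
setClass("ApyDecomposition",
  representation(Pnc = "matrix", Mnn = "numeric", Gcc = "matrix",
                 gnnDiag = "numeric", partition = "CorePartition",
                 source = "character"))

setValidity("ApyDecomposition", function(object) {
  nc <- length(object@partition@core)
  nn <- length(object@partition@noncore)
  if (!identical(dim(object@Gcc), c(nc, nc)))
    return("Gcc dimension does not match core size")
  if (nrow(object@Pnc) != nn || ncol(object@Pnc) != nc)
    return("Pnc must be n_noncore x n_core")
  if (length(object@Mnn) != nn) return("Mnn must have one entry per non-core animal")
  if (any(object@Mnn < 0)) return("Mnn entries must be non-negative")
  TRUE
})

#' Variance components and derived ratios
#'
#' Holds the genetic and residual variances and the residual polygenic
#' fraction beta. The penalty ratios used in the mixed model equations are
#' always recomputed from these, never stored.
#'
#' @slot sigmaU2 genetic variance, > 0.
#' @slot sigmaE2 residual variance, > 0.
#' @slot beta residual polygenic fraction in [0, 1].
#' @export
setClass("VarianceComponents",
  representation(sigmaU2 = "numeric", sigmaE2 = "numeric", beta = "numeric"))

setValidity("VarianceComponents", function(object) {
  if (object@sigmaU2 <= 0 || object@sigmaE2 <= 0)
    return("variances must be positive")
  if (object@beta < 0 || object@beta > 1)
    return("beta must lie in [0, 1]")
  TRUE
})

#' Phenotype records with design matrices
#'
#' @slot y numeric vector of phenotypes (one per record).
#' @slot X fixed-effect design matrix, full column rank.
#' @slot W record-on-animal incidence matrix, one 1 per row; columns named by
#'   animal id.
#' @export
setClass("PhenotypeData",
  representation(y = "numeric", X = "matrix", W = "matrix"))

setValidity("PhenotypeData", function(object) {
  n <- length(object@y)
  if (nrow(object@X) != n || nrow(object@W) != n)
    return("X and W must have one row per record")
  if (is.null(colnames(object@W))) return("W columns must be named by animal id")
  if (!all(rowSums(object@W != 0) == 1L) || !all(object@W %in% c(0, 1)))
    return("each W row must have exactly one 1 and zeros elsewhere")
  if (qr(object@X)$rank < ncol(object@X))
    return("fixed-effect design X is rank deficient")
  TRUE
})

#' Projected marker design for APY-SNP-BLUP
#'
#' Holds the perpendicular projection operator onto the row space of the core
#' genotypes and the reduced design `Zdagger = [Z_c; Z_n P]`. For the residual
#' polygenic variant (beta > 0) it additionally carries the augmented-design
#' pieces `S` and `R` so that breeding values decompose as
#' `u = Zdagger a + R eps + Q xi`.
#'
#' @slot Zdagger stacked reduced marker design (n_gt x m), core rows first.
#' @slot P m x m projection operator (oblique when marker weights are used).
#' @slot R design mapping core polygenic effects into breeding values
#'   (n_gt x n_core); 0 x 0 when beta = 0.
#' @slot beta residual polygenic fraction used to build the design.
#' @slot k scaling constant of the underlying centered genotypes.
#' @slot weights per-marker weights (length m).
#' @slot partition the [CorePartition-class] used.
#' @export
setClass("ProjectedDesign",
  representation(Zdagger = "matrix", P = "matrix", R = "matrix",
                 beta = "numeric", k = "numeric", weights = "numeric",
                 partition = "CorePartition"))

#' Solved mixed model
#'
#' Solution of an assembled mixed-model system: fixed effects, the random
#' effect vectors the model carries (all named by level id), and the LHS with
#' its index map so prediction error variances can be queried afterwards.
#'
#' @slot b named numeric vector of fixed-effect solutions.
#' @slot effects named list of named numeric vectors; always contains `u`
#'   (breeding values by animal id) and, model-dependent, `a` (marker effects),
#'   `xi`, `eps`, `eta`.
#' @slot lhs dense LHS of the mixed model equations.
#' @slot index named list mapping effect names to LHS column indices.
#' @slot sigmaE2 residual variance used (for PEV scaling).
#' @slot model label of the solved formulation.
#' @export
setClass("MixedModelSolution",
  representation(b = "numeric", effects = "list", lhs = "matrix",
                 index = "list", sigmaE2 = "numeric", model = "character"))
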
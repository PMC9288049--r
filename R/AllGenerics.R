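#' Animal ids of an object
#' @param x object with animal ids
#' @return character vector of ids
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @describeIn animalIds ids in pedigree record order
#' @export
setMethod("animalIds", "Pedigree", function(x) x@records$animal)

#' @describeIn animalIds ids of the relationship matrix
#' @export
setMethod("animalIds", "RelationshipMatrix", function(x) rownames(x@values))

#' @describeIn animalIds genotyped animal ids (rows of Z)
#' @export
setMethod("animalIds", "CenteredGenotypes", function(x) rownames(x@Z))

#' @describeIn animalIds core ids followed by non-core ids
#' @export
setMethod("animalIds", "CorePartition", function(x) c(x@core, x@noncore))

#' @describeIn animalIds ids in decomposition order (core, then non-core)
#' @export
setMethod("animalIds", "ApyDecomposition", function(x) animalIds(x@partition))

#' Dense values of a relationship matrix
#' @param x a [RelationshipMatrix-class]
#' @return numeric matrix with animal ids as dimnames
#' @export
relValues <- function(x) {
  stopifnot(is(x, "RelationshipMatrix"))
  x@values
}

#' Core and non-core ids of a partition
#' @param x a [CorePartition-class] or [ApyDecomposition-class]
#' @return character vector
#' @export
setGeneric("coreIds", function(x) standardGeneric("coreIds"))

#' @rdname coreIds
#' @export
setGeneric("noncoreIds", function(x) standardGeneric("noncoreIds"))

#' @describeIn coreIds core ids
#' @export
setMethod("coreIds", "CorePartition", function(x) x@core)

#' @describeIn coreIds non-core ids
#' @export
setMethod("noncoreIds", "CorePartition", function(x) x@noncore)

#' @describeIn coreIds core ids of the decomposition's partition
#' @export
setMethod("coreIds", "ApyDecomposition", function(x) x@partition@core)

#' @describeIn coreIds non-core ids of the decomposition's partition
#' @export
setMethod("noncoreIds", "ApyDecomposition", function(x) x@partition@noncore)

#' Accessors for centered genotypes
#'
#' @param x a [CenteredGenotypes-class]
#' @return `centeredZ`: the centered matrix; `alleleFreqs`: the frequencies
#'   used for centering; `scalingK`: the scaling constant.
#' @export
centeredZ <- function(x) { stopifnot(is(x, "CenteredGenotypes")); x@Z }

#' @rdname centeredZ
#' @export
alleleFreqs <- function(x) { stopifnot(is(x, "CenteredGenotypes")); x@p }

#' @rdname centeredZ
#' @export
scalingK <- function(x) { stopifnot(is(x, "CenteredGenotypes")); x@k }

#' Accessors for solved mixed models
#'
#' @param x a [MixedModelSolution-class]
#' @param effect name of a random effect carried by the solution
#' @return `fixedEffects`: named fixed-effect solutions; `breedingValues`:
#'   EBVs named by animal id; `markerEffects`: marker-effect solutions;
#'   `randomEffect`: any stored effect vector by name.
#' @export
fixedEffects <- function(x) { stopifnot(is(x, "MixedModelSolution")); x@b }

#' @rdname fixedEffects
#' @export
breedingValues <- function(x) {
  stopifnot(is(x, "MixedModelSolution"))
  x@effects$u
}

#' @rdname fixedEffects
#' @export
markerEffects <- function(x) {
  stopifnot(is(x, "MixedModelSolution"))
  x@effects$a
}

#' @rdname fixedEffects
#' @export
randomEffect <- function(x, effect) {
  stopifnot(is(x, "MixedModelSolution"))
  x@effects[[effect]]
}

#' Variance-component accessors and penalty ratios
#'
#' `alphaRatio` is sigma_e^2 / sigma_u^2 (GBLUP penalty); `gammaRatio` is
#' sigma_e^2 / (k sigma_u^2) (SNP-BLUP penalty); `deltaRatio` is
#' sigma_e^2 / ((1 - beta) k sigma_u^2); `zetaRatio` is
#' sigma_e^2 / (beta sigma_u^2), defined only for beta > 0. Ratios are always
#' recomputed from the stored variances.
#'
#' @param vc a [VarianceComponents-class]
#' @param k scaling constant of the centered genotypes
#' @return a scalar ratio
#' @export
alphaRatio <- function(vc) vc@sigmaE2 / vc@sigmaU2

#' @rdname alphaRatio
#' @export
gammaRatio <- function(vc, k) vc@sigmaE2 / (k * vc@sigmaU2)

#' @rdname alphaRatio
#' @export
deltaRatio <- function(vc, k) {
  if (vc@beta >= 1) stop("delta ratio undefined for beta = 1")
  vc@sigmaE2 / ((1 - vc@beta) * k * vc@sigmaU2)
}

#' @rdname alphaRatio
#' @export
zetaRatio <- function(vc) {
  if (vc@beta <= 0) stop("zeta ratio defined only for beta > 0")
  vc@sigmaE2 / (vc@beta * vc@sigmaU2)
}

#' Construct variance components
#'
#' @param sigmaU2 genetic variance (> 0)
#' @param sigmaE2 residual variance (> 0)
#' @param beta residual polygenic fraction in [0, 1]; default 0
#' @return a [VarianceComponents-class]
#' @export
varComp <- function(sigmaU2, sigmaE2, beta = 0) {
  new("VarianceComponents", sigmaU2 = as.numeric(sigmaU2),
      sigmaE2 = as.numeric(sigmaE2), beta = as.numeric(beta))
}

setMethod("show", "Pedigree", function(object) {
  rec <- object@records
  cat("Pedigree with", nrow(rec), "animals;",
      sum(is.na(rec$sire) & is.na(rec$dam)), "founders\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix over", nrow(object@values), "animals; mean diag =",
      format(mean(diag(object@values)), digits = 4), "\n")
})

setMethod("show", "CenteredGenotypes", function(object) {
  cat("CenteredGenotypes:", nrow(object@Z), "animals x", ncol(object@Z),
      "markers; k =", format(object@k, digits = 6), "\n")
})

setMethod("show", "CorePartition", function(object) {
  cat("CorePartition:", length(object@core), "core /",
      length(object@noncore), "non-core animals\n")
})

setMethod("show", "ApyDecomposition", function(object) {
  cat("ApyDecomposition (source ", object@source, "): ",
      length(object@partition@core), " core, ",
      length(object@partition@noncore), " non-core; mean Mnn = ",
      format(if (length(object@Mnn)) mean(object@Mnn) else 0, digits = 4),
      "\n", sep = "")
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents: sigmaU2 =", object@sigmaU2,
      "sigmaE2 =", object@sigmaE2, "beta =", object@beta, "\n")
})

setMethod("show", "PhenotypeData", function(object) {
  cat("PhenotypeData:", length(object@y), "records on",
      length(unique(colnames(object@W)[max.col(object@W)])), "animals;",
      ncol(object@X), "fixed effect(s)\n")
})

setMethod("show", "MixedModelSolution", function(object) {
  cat("MixedModelSolution [", object@model, "]: ",
      length(object@b), " fixed effect(s); random effects: ",
      paste(names(object@effects), collapse = ", "), "\n", sep = "")
})
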
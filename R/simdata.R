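#' Simulation configuration
#'
#' Desk-scale multi-generation design: founders drawn at Hardy-Weinberg
#' proportions with MAF uniform on `mafRange`, offspring genotypes by
#' Mendelian gene dropping (one allele per parent per locus), random
#' non-selfing matings within generation, no selection. Phenotypes follow
#' `y = X b + W u + e` with `u = Z a (+ pedigree polygenic term)` and the
#' residual variance set from the heritability.
#'
#' @param nFounders number of founder animals
#' @param nGenerations number of descendant generations
#' @param offspringPerMating offspring per mating pair
#' @param m number of markers
#' @param mafRange founder minor-allele-frequency range, within (0, 0.5]
#' @param h2 heritability in (0, 1)
#' @param betaTrue residual polygenic fraction of the simulated genetic
#'   variance, in [0, 1)
#' @param propGenotyped fraction of non-founder animals marked genotyped
#' @param recordsPerAnimal phenotype records per animal
#' @param mu intercept (the single fixed effect)
#' @param seed integer seed (mandatory; every draw is reproducible)
#' @return a list of class `SimConfig`
#' @export
simConfig <- function(nFounders = 12, nGenerations = 2,
                      offspringPerMating = 3, m = 40,
                      mafRange = c(0.15, 0.5), h2 = 0.5, betaTrue = 0,
                      propGenotyped = 1, recordsPerAnimal = 1, mu = 1,
                      seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  stopifnot(nFounders >= 2, nGenerations >= 1, offspringPerMating >= 1,
            m >= 1, recordsPerAnimal >= 1,
            mafRange[1] > 0, mafRange[2] <= 0.5, mafRange[1] <= mafRange[2],
            propGenotyped > 0, propGenotyped <= 1,
            betaTrue >= 0, betaTrue < 1)
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie strictly in (0, 1)")
  structure(list(nFounders = nFounders, nGenerations = nGenerations,
                 offspringPerMating = offspringPerMating, m = m,
                 mafRange = mafRange, h2 = h2, betaTrue = betaTrue,
                 propGenotyped = propGenotyped,
                 recordsPerAnimal = recordsPerAnimal, mu = mu,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a pedigree, gene-dropped genotypes and phenotypes
#'
#' Founder haplotypes are Bernoulli(p_j) per locus; each offspring receives
#' one uniformly chosen allele per parent per locus. True marker effects are
#' drawn `a_j ~ N(0, (1 - betaTrue) k sigma_u^2)` with `sigma_u^2 = 1`, the
#' scaling `k` taken from the observed centered genotypes, so that
#' `Var(Z a) ~= (1 - betaTrue) k Z Z'`. When `betaTrue > 0` a pedigree
#' polygenic vector with covariance `betaTrue * A` is added. Residual
#' variance is `sigma_u^2 (1 - h2) / h2`.
#'
#' @param cfg a [simConfig()] object
#' @return list with elements `pedigree` ([Pedigree-class]), `genotypes`
#'   (allele-count matrix for all animals), `cz`
#'   ([CenteredGenotypes-class], observed frequencies), `trueA` (marker
#'   effects), `trueU` (breeding values), `phenotypes` (data.frame id, y),
#'   `genotypedIds`, `vc` ([VarianceComponents-class]), `founderFreqs`
#' @export
simulatePopulation <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  m <- cfg$m
  p <- runif(m, cfg$mafRange[1], cfg$mafRange[2])
  founders <- paste0("F", seq_len(cfg$nFounders))
  hap1 <- matrix(rbinom(cfg$nFounders * m, 1, rep(p, each = cfg$nFounders)),
                 cfg$nFounders, m, dimnames = list(founders, NULL))
  hap2 <- matrix(rbinom(cfg$nFounders * m, 1, rep(p, each = cfg$nFounders)),
                 cfg$nFounders, m, dimnames = list(founders, NULL))
  ids <- founders
  sire <- rep(NA_character_, cfg$nFounders)
  dam <- rep(NA_character_, cfg$nFounders)
  prev <- founders
  for (g in seq_len(cfg$nGenerations)) {
    pairs <- matrix(sample(prev, 2L * (length(prev) %/% 2L)), ncol = 2L)
    newids <- character(0)
    for (r in seq_len(nrow(pairs))) {
      s <- pairs[r, 1L]; d <- pairs[r, 2L]
      for (o in seq_len(cfg$offspringPerMating)) {
        id <- paste0("G", g, "_", r, "_", o)
        gam_s <- ifelse(runif(m) < 0.5, hap1[s, ], hap2[s, ])
        gam_d <- ifelse(runif(m) < 0.5, hap1[d, ], hap2[d, ])
        hap1 <- rbind(hap1, matrix(gam_s, 1, m, dimnames = list(id, NULL)))
        hap2 <- rbind(hap2, matrix(gam_d, 1, m, dimnames = list(id, NULL)))
        ids <- c(ids, id); sire <- c(sire, s); dam <- c(dam, d)
        newids <- c(newids, id)
      }
    }
    prev <- newids
  }
  counts <- hap1 + hap2
  colnames(counts) <- paste0("snp", seq_len(m))
  ped <- pedigree(ids, sire, dam)
  cz <- centerScale(counts, dropMonomorphic = TRUE)
  k <- cz@k
  sigmaU2 <- 1
  trueA <- rnorm(ncol(cz@Z), 0, sqrt((1 - cfg$betaTrue) * k * sigmaU2))
  names(trueA) <- colnames(cz@Z)
  u <- drop(cz@Z %*% trueA)
  if (cfg$betaTrue > 0) {
    A <- relValues(buildA(ped))[ids, ids]
    u <- u + drop(t(chol(A + 1e-10 * diag(nrow(A)))) %*%
                    rnorm(length(ids), 0, sqrt(cfg$betaTrue * sigmaU2)))
  }
  names(u) <- ids
  sigmaE2 <- sigmaU2 * (1 - cfg$h2) / cfg$h2
  recAnimal <- rep(ids, each = cfg$recordsPerAnimal)
  y <- cfg$mu + u[recAnimal] + rnorm(length(recAnimal), 0, sqrt(sigmaE2))
  nonFounders <- setdiff(ids, founders)
  nGt <- max(1L, round(cfg$propGenotyped * length(nonFounders)))
  genotyped <- sort(sample(nonFounders, nGt))
  genotyped <- nonFounders[nonFounders %in% genotyped]
  list(pedigree = ped, genotypes = counts, cz = cz, trueA = trueA,
       trueU = u,
       phenotypes = data.frame(id = recAnimal, y = unname(y),
                               stringsAsFactors = FALSE),
       genotypedIds = genotyped,
       vc = varComp(sigmaU2, sigmaE2, beta = cfg$betaTrue),
       founderFreqs = p)
}

#' Nested series of core partitions
#'
#' Draws one random permutation of the ids under the seed and returns the
#' partitions whose cores are its prefixes, so that `core(sizes[i])` is a
#' subset of `core(sizes[i+1])` — the setting of the Schur monotonicity and
#' rho monotonicity properties.
#'
#' @param ids genotyped animal ids
#' @param sizes strictly increasing core sizes
#' @param seed integer seed
#' @return list of [CorePartition-class] objects
#' @export
nestedCoreSeries <- function(ids, sizes, seed) {
  ids <- as.character(ids)
  if (any(diff(sizes) <= 0) || any(sizes < 1) || any(sizes > length(ids)))
    stop("sizes must be strictly increasing and within 1..length(ids)")
  set.seed(as.integer(seed))
  perm <- sample(ids)
  lapply(sizes, function(s)
    new("CorePartition", core = perm[seq_len(s)],
        noncore = perm[-seq_len(s)], seed = as.integer(seed)))
}
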
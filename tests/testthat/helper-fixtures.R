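# Small in-code fixtures shared across test files.

relMat <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  new("RelationshipMatrix", values = m)
}

# The 2-animal toy: Zc = (1,1,0), Zn = (1,0,1), k = 1 -> G = [[2,1],[1,2]].
toyCz <- function() {
  Z <- rbind(a1 = c(1, 1, 0), a2 = c(1, 0, 1))
  colnames(Z) <- paste0("s", 1:3)
  new("CenteredGenotypes", Z = Z, p = setNames(rep(0.5, 3), colnames(Z)),
      k = 1)
}

toyG <- function() buildG(toyCz())

partOf <- function(core, noncore) {
  new("CorePartition", core = core, noncore = noncore, seed = NA_integer_)
}

# Centered genotypes from an arbitrary Z (frequencies are placeholders).
czFrom <- function(Z, k = 1) {
  if (is.null(rownames(Z))) rownames(Z) <- paste0("id", seq_len(nrow(Z)))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("s", seq_len(ncol(Z)))
  new("CenteredGenotypes", Z = Z,
      p = setNames(rep(0.5, ncol(Z)), colnames(Z)), k = k)
}

# Seeded genotyped-only study set: simulate, restrict to exactly nGt
# genotyped animals with their records.
simGt <- function(seed, nGt = NULL, m = 40, h2 = 0.5, cfg = NULL) {
  if (is.null(cfg))
    cfg <- simConfig(seed = seed, m = m, h2 = h2,
                     nFounders = if (is.null(nGt) || nGt <= 30) 12 else 28,
                     nGenerations = if (is.null(nGt) || nGt <= 30) 2 else 1,
                     offspringPerMating = if (is.null(nGt) || nGt <= 30) 3
                                          else 4)
  sim <- simulatePopulation(cfg)
  gt <- sim$genotypedIds
  if (!is.null(nGt)) {
    stopifnot(length(gt) >= nGt)
    gt <- gt[seq_len(nGt)]
  }
  cz <- new("CenteredGenotypes", Z = sim$cz@Z[gt, , drop = FALSE],
            p = sim$cz@p, k = sim$cz@k)
  keep <- sim$phenotypes$id %in% gt
  phg <- phenotypeData(sim$phenotypes$y[keep], sim$phenotypes$id[keep],
                       animals = gt)
  list(sim = sim, gt = gt, cz = cz, phg = phg, vc = sim$vc)
}

# Single-step study set: pedigree with a genotyped subset.
simSs <- function(seed, nGt = 25, nFounders = 15, beta = 0) {
  cfg <- simConfig(seed = seed, nFounders = nFounders, nGenerations = 1,
                   offspringPerMating = 4, m = 30, betaTrue = beta)
  sim <- simulatePopulation(cfg)
  gt <- sim$genotypedIds[seq_len(min(nGt, length(sim$genotypedIds)))]
  cz <- new("CenteredGenotypes", Z = sim$cz@Z[gt, , drop = FALSE],
            p = sim$cz@p, k = sim$cz@k)
  A <- buildA(sim$pedigree)
  ph <- phenotypeData(sim$phenotypes$y, sim$phenotypes$id,
                      animals = animalIds(sim$pedigree))
  list(sim = sim, gt = gt, cz = cz, A = A, ph = ph, vc = sim$vc)
}

maxAbsDiff <- function(a, b) max(abs(a[names(a)] - b[names(a)]))
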
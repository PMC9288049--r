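test_that("projection operator is the perpendicular projector onto core rows", {
  P <- projectionOperator(matrix(c(1, 0, 0), 1, 3))
  expect_equal(P, diag(c(1, 0, 0)))
  # square full-rank core genotypes: projector is the identity
  set.seed(31)
  Zc <- matrix(rnorm(16), 4, 4)
  expect_lt(max(abs(projectionOperator(Zc) - diag(4))), 1e-10)
  # projection axioms on a random wide matrix
  Zc2 <- matrix(rnorm(3 * 7), 3, 7)
  P2 <- projectionOperator(Zc2)
  expect_lt(max(abs(P2 %*% P2 - P2)), 1e-10)
  expect_lt(max(abs(P2 - t(P2))), 1e-10)
  expect_equal(sum(diag(P2)), 3, tolerance = 1e-8)   # rank = n_core
})

test_that("projected design replaces non-core rows by their projection", {
  cz <- toyCz()                       # Zc = (1,1,0), Zn = (1,0,1)
  pd <- buildProjectedDesign(cz, partOf("a1", "a2"))
  expect_equal(unname(pd@P), matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0) / 2, 3, 3))
  expect_equal(unname(pd@Zdagger["a2", ]), c(0.5, 0.5, 0))
  expect_equal(unname(pd@Zdagger["a1", ]), c(1, 1, 0))
  # full-rank square core: Zdagger equals Z
  set.seed(32)
  Z <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(paste0("a", 1:4), NULL))
  colnames(Z) <- paste0("s", 1:3)
  czf <- czFrom(Z)
  pdf <- buildProjectedDesign(czf, partOf(paste0("a", 1:3), "a4"))
  expect_lt(max(abs(pdf@Zdagger - Z)), 1e-8)
  # the polygenic limit with no marker variance is rejected
  expect_error(buildProjectedDesign(cz, partOf("a1", "a2"), beta = 1,
                                    L = relMat(diag(2), c("a1", "a2"))),
               "beta = 1")
  expect_error(buildProjectedDesign(cz, partOf("a1", "a2"), beta = 0.3),
               "Cholesky")
})

test_that("GBLUP solver honours degenerate limits", {
  st <- simGt(33)
  G <- buildG(st$cz)
  part <- selectCore(st$gt, nCore = 6, seed = 33)
  d <- apyDecompose(G, part)
  Kinv <- gApyInverse(d)
  # zero phenotypes give zero solutions
  ph0 <- phenotypeData(rep(0, length(st$gt)), st$gt, animals = st$gt)
  s0 <- solveGblup(ph0, Kinv, st$vc)
  expect_equal(max(abs(breedingValues(s0))), 0)
  expect_equal(max(abs(fixedEffects(s0))), 0)
  # vanishing genetic variance shrinks all EBVs away
  sShrink <- solveGblup(st$phg, Kinv, varComp(1e-12, 1))
  expect_lt(max(abs(breedingValues(sShrink))), 1e-6)
  # rank-deficient X is rejected
  n <- length(st$phg@y)
  Xbad <- matrix(1, n, 2)
  expect_error(phenotypeData(st$phg@y, colnames(st$phg@W)[max.col(st$phg@W)],
                             X = Xbad, animals = st$gt), "rank deficient")
})

test_that("SNP-BLUP agrees with hand elimination and with GBLUP", {
  # m = 1, one record: LHS = [[1, z], [z, z^2 + gamma]]
  cz <- czFrom(matrix(1.5, 1, 1, dimnames = list("a", "s1")), k = 2)
  vc <- varComp(1, 1)
  ph <- phenotypeData(3, "a")
  s <- solveSnpBlup(ph, cz, vc)
  z <- 1.5; g <- 1 / 2; y <- 3
  # hand-assembled 2x2 system as the independent oracle
  A2 <- matrix(c(1, z, z, z^2 + g), 2, 2)
  sol <- solve(A2, c(y, z * y))
  expect_equal(unname(fixedEffects(s)), sol[1])
  expect_equal(unname(markerEffects(s)), sol[2])
  expect_equal(unname(breedingValues(s)), z * sol[2])
  # classic GBLUP equivalence on invertible G
  set.seed(34)
  counts <- matrix(rbinom(6 * 15, 2, 0.4), 6, 15,
                   dimnames = list(paste0("a", 1:6), paste0("s", 1:15)))
  czi <- centerScale(counts, freqs = setNames(rep(0.35, 15),
                                              colnames(counts)))
  G <- buildG(czi)
  phi <- phenotypeData(rnorm(6, 1), rownames(counts))
  sS <- solveSnpBlup(phi, czi, vc)
  sG <- solveGblup(phi, solve(relValues(G)), vc)
  expect_lt(maxAbsDiff(breedingValues(sG), breedingValues(sS)), 1e-8)
})

test_that("joint, partitioned and marker formulations give identical EBVs", {
  for (seed in 1:3) {
    st <- simGt(seed)
    G <- buildG(st$cz)
    part <- selectCore(st$gt, nCore = 7, seed = seed)
    d <- apyDecompose(G, part)
    pd <- buildProjectedDesign(st$cz, part)
    s5 <- solveGblup(st$phg, gApyInverse(d), st$vc, model = "apy-gblup")
    s9 <- solveApyGblupPartitioned(st$phg, d, st$vc)
    s13 <- solveApySnpBlup(st$phg, pd, d, st$vc)
    u5 <- breedingValues(s5)
    expect_lt(maxAbsDiff(u5, breedingValues(s9)), 1e-8)
    expect_lt(maxAbsDiff(u5, breedingValues(s13)), 1e-8)
    # u_n = P_nc u_c + xi reconstruction is internally consistent
    un <- drop(d@Pnc %*% breedingValues(s9)[coreIds(d)]) +
      randomEffect(s9, "xi")
    expect_lt(max(abs(un - breedingValues(s9)[noncoreIds(d)])), 1e-10)
  }
})

test_that("no-non-core partition reduces to core GBLUP", {
  st <- simGt(35, nGt = 15)
  part <- selectCore(st$gt, nCore = length(st$gt), seed = 35)
  d <- apyDecompose(buildG(st$cz), part)
  s <- solveApyGblupPartitioned(st$phg, d, st$vc)
  sRef <- solveGblup(st$phg, gApyInverse(d), st$vc)
  expect_lt(maxAbsDiff(breedingValues(sRef), breedingValues(s)), 1e-8)
  expect_length(randomEffect(s, "xi"), 0)
})

test_that("residual polygenic marker model equals GBLUP on the blended matrix", {
  st <- simGt(36)
  A <- buildA(st$sim$pedigree)
  A22 <- subsetRel(A, st$gt)
  G <- buildG(st$cz)
  part <- selectCore(st$gt, nCore = 6, seed = 36)
  for (beta in c(0.05, 0.3, 0.7)) {
    vcb <- varComp(1, st$vc@sigmaE2, beta = beta)
    Gs <- blendPolygenic(G, A22, beta)
    ds <- apyDecompose(Gs, part, source = "Gstar")
    pds <- buildProjectedDesign(st$cz, part, beta = beta, L = A22)
    Acc <- extractBlock(A, coreIds(part), coreIds(part))
    sG <- solveGblup(st$phg, gApyInverse(ds), vcb, model = "apy-gblup")
    sS <- solveApySnpBlup(st$phg, pds, ds, vcb, Acc = Acc)
    expect_lt(maxAbsDiff(breedingValues(sG), breedingValues(sS)), 1e-8)
  }
})

test_that("single-step formulations agree with and without polygenic fraction", {
  st <- simSs(37)
  G <- buildG(st$cz)
  part <- selectCore(st$gt, nCore = 8, seed = 37)
  d <- apyDecompose(G, part)
  pd <- buildProjectedDesign(st$cz, part)
  sG <- solveSsApy(st$ph, st$A, d, st$vc, formulation = "gblup")
  sS <- solveSsApy(st$ph, st$A, d, st$vc, formulation = "snp", pd = pd)
  expect_lt(maxAbsDiff(breedingValues(sG), breedingValues(sS)), 1e-8)
  # all-genotyped single step reduces to APY-GBLUP (the A-correction cancels)
  stg <- simGt(37)
  partg <- selectCore(stg$gt, nCore = 8, seed = 37)
  dg <- apyDecompose(buildG(stg$cz), partg)
  Agt <- subsetRel(buildA(stg$sim$pedigree), stg$gt)
  sSs <- solveSsApy(stg$phg, Agt, dg, stg$vc, formulation = "gblup")
  sApy <- solveGblup(stg$phg, gApyInverse(dg), stg$vc)
  expect_lt(maxAbsDiff(breedingValues(sApy), breedingValues(sSs)), 1e-8)
  # polygenic single step
  beta <- 0.3
  vcb <- varComp(1, st$vc@sigmaE2, beta = beta)
  A22 <- subsetRel(st$A, st$gt)
  Gs <- blendPolygenic(G, A22, beta)
  dsb <- apyDecompose(Gs, part, source = "Gstar")
  pdb <- buildProjectedDesign(st$cz, part, beta = beta, L = A22)
  sGb <- solveSsApy(st$ph, st$A, dsb, vcb, formulation = "gblup")
  sSb <- solveSsApy(st$ph, st$A, dsb, vcb, formulation = "snp", pd = pdb)
  expect_lt(maxAbsDiff(breedingValues(sGb), breedingValues(sSb)), 1e-8)
})

test_that("breeding values decompose as reduced design effects plus error", {
  # Var(u) = k Zdagger Zdagger' + blockdiag(0, Mnn): the conditional variance
  # given marker effects is zero for core and Mnn for non-core animals
  st <- simGt(38)
  part <- selectCore(st$gt, nCore = 6, seed = 38)
  d <- apyDecompose(buildG(st$cz), part)
  pd <- buildProjectedDesign(st$cz, part)
  V <- diag(c(rep(0, length(coreIds(d))), d@Mnn))
  lhs <- scalingK(st$cz) * tcrossprod(pd@Zdagger) + V
  expect_lt(max(abs(lhs - relValues(gApyFull(d)))), 1e-8)
})

test_that("per-marker weights preserve the GBLUP / marker-model equivalence", {
  st <- simGt(39)
  set.seed(39)
  w <- runif(ncol(centeredZ(st$cz)), 0.5, 2)
  Gw <- buildG(st$cz, weights = w)
  part <- selectCore(st$gt, nCore = 6, seed = 39)
  dw <- apyDecompose(Gw, part)
  pdw <- buildProjectedDesign(st$cz, part, weights = w)
  sG <- solveGblup(st$phg, gApyInverse(dw), st$vc, model = "apy-gblup")
  sS <- solveApySnpBlup(st$phg, pdw, dw, st$vc, weights = w)
  expect_lt(maxAbsDiff(breedingValues(sG), breedingValues(sS)), 1e-8)
})

test_that("PEV blocks equal the dense inverse of the assembled system", {
  st <- simGt(40)
  part <- selectCore(st$gt, nCore = 5, seed = 40)
  d <- apyDecompose(buildG(st$cz), part)
  sol <- solveGblup(st$phg, gApyInverse(d), st$vc)
  full <- st$vc@sigmaE2 * solve(sol@lhs)
  idx <- sol@index$u[coreIds(d)]
  expect_lt(max(abs(pevBlock(sol, "u", coreIds(d)) - full[idx, idx])), 1e-10)
  # no-information limit: PEV tends to sigma_u^2 * K_ii
  G1 <- relMat(matrix(1.3, 1, 1), "a")
  ph1 <- phenotypeData(2, "a")
  vcBig <- varComp(1e-9, 1)     # alpha -> infinity
  solBig <- solveGblup(ph1, solve(relValues(G1)), vcBig)
  expect_equal(pevBlock(solBig, "u")[1, 1], 1e-9 * 1.3, tolerance = 1e-3)
  # closed-form 2x2: single animal, single record, G = [1]
  vc <- varComp(1, 2)
  sol1 <- solveGblup(phenotypeData(1.7, "a"),
                     matrix(1, 1, 1, dimnames = list("a", "a")), vc)
  lhs <- rbind(c(1, 1), c(1, 1 + 2))
  expect_equal(pevBlock(sol1, "u")[1, 1], 2 * solve(lhs)[2, 2])
  expect_error(pevBlock(sol1, "a"), "not fitted")
})
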
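test_that("marker back-solving uses only core quantities", {
  # scalar identity: Zc = [1], k = 1, Gcc = [1]
  expect_equal(unname(backsolveSnpEffects(2, matrix(1, 1, 1),
                                          matrix(1, 1, 1), 1)), 2)
  expect_equal(unname(backsolveSnpEffects(0, matrix(1.3, 1, 1),
                                          matrix(1.69, 1, 1), 2)), 0)
  # both back-solve routes equal the marker solutions of the MME
  st <- simGt(51)
  part <- selectCore(st$gt, nCore = 7, seed = 51)
  d <- apyDecompose(buildG(st$cz), part)
  pd <- buildProjectedDesign(st$cz, part)
  sol <- solveApySnpBlup(st$phg, pd, d, st$vc)
  Zc <- centeredZ(st$cz)[coreIds(d), , drop = FALSE]
  a1 <- backsolveSnpEffects(breedingValues(sol)[coreIds(d)], Zc, d@Gcc,
                            scalingK(st$cz))
  a2 <- backsolveFromAll(breedingValues(sol), pd, d)
  expect_lt(max(abs(a1 - markerEffects(sol))), 1e-8)
  expect_lt(max(abs(a2 - markerEffects(sol))), 1e-8)
  expect_error(backsolveSnpEffects(1:2, Zc, d@Gcc, 1), "dimension")
})

test_that("back-solved variance propagates core PEV correctly", {
  st <- simGt(52)
  part <- selectCore(st$gt, nCore = 4, seed = 52)
  d <- apyDecompose(buildG(st$cz), part)
  k <- scalingK(st$cz)
  Zc <- centeredZ(st$cz)[coreIds(d), , drop = FALSE]
  # no information: PEV = Gcc gives the zero matrix
  expect_lt(max(abs(backsolveVariance(Zc, d@Gcc, d@Gcc, k))), 1e-10)
  # perfect knowledge: PEV = 0 gives k^2 Zc' Gcc^-1 Zc
  expect_equal(backsolveVariance(Zc, d@Gcc, 0 * d@Gcc, k),
               k^2 * crossprod(Zc, solve(d@Gcc, Zc)), tolerance = 1e-10)
  # delta-method oracle: Var(k Zc' Gcc^-1 u_c) with Var(u_c) = Gcc - PEV
  sol <- solveGblup(st$phg, gApyInverse(d), st$vc)
  PEV <- pevRelScale(pevBlock(sol, "u", coreIds(d)), st$vc)
  M <- k * crossprod(Zc, solve(d@Gcc))        # the linear map u_c -> a
  oracle <- M %*% (d@Gcc - PEV) %*% t(M)
  expect_lt(max(abs(backsolveVariance(Zc, d@Gcc, PEV, k) - oracle)), 1e-10)
  expect_error(backsolveVariance(Zc, d@Gcc, d@Gcc + rbind(
    cbind(matrix(0, 3, 3), c(0.1, 0, 0)), 0), k), "symmetric")
})

test_that("the two indirect-prediction routes agree exactly", {
  st <- simGt(53)
  part <- selectCore(st$gt, nCore = 6, seed = 53)
  d <- apyDecompose(buildG(st$cz), part)
  pd <- buildProjectedDesign(st$cz, part)
  sol <- solveApySnpBlup(st$phg, pd, d, st$vc)
  aHat <- markerEffects(sol)
  uC <- breedingValues(sol)[coreIds(d)]
  k <- scalingK(st$cz)
  Zc <- centeredZ(st$cz)[coreIds(d), , drop = FALSE]
  Zip <- centeredZ(st$cz)[noncoreIds(d)[1:4], , drop = FALSE]
  u1 <- indirectPredict(Zip = Zip, P = pd@P, aHat = aHat)
  u2 <- indirectPredict(Zip = Zip, Zc = Zc, k = k, Gcc = d@Gcc, uC = uC)
  expect_lt(max(abs(u1 - u2)), 1e-10)
  # a genotype copy of a core animal reproduces that core EBV
  Zdup <- centeredZ(st$cz)[coreIds(d)[2], , drop = FALSE]
  rownames(Zdup) <- "copy"
  expect_equal(unname(indirectPredict(Zip = Zdup, Zc = Zc, k = k,
                                      Gcc = d@Gcc, uC = uC)),
               unname(uC[2]), tolerance = 1e-10)
  # zero marker effects give zero predictions
  expect_equal(max(abs(indirectPredict(Zip = Zip, P = pd@P,
                                       aHat = 0 * aHat))), 0)
  expect_error(indirectPredict(Zip = Zip), "supply either")
})

test_that("rho measures core coverage on the unit interval", {
  expect_equal(apyRho(2, 0), 1)
  expect_equal(apyRho(2, 2), 0)
  expect_equal(apyRho(2, 1.5), 0.25)      # the 2-animal toy decomposition
  d <- apyDecompose(toyG(), partOf("a1", "a2"))
  expect_equal(unname(apyRho(d@gnnDiag, d@Mnn)), 0.25)
  expect_error(apyRho(1, 1.5), "Schur")
  expect_error(apyRho(0, 0), "positive")
})

test_that("indirect PEV and reliability satisfy the exact decomposition", {
  st <- simGt(54)
  part <- selectCore(st$gt, nCore = 6, seed = 54)
  G <- buildG(st$cz)
  d <- apyDecompose(G, part)
  sol <- solveGblup(st$phg, gApyInverse(d), st$vc)
  PEV <- pevRelScale(pevBlock(sol, "u", coreIds(d)), st$vc)
  Gv <- relValues(G)
  for (id in noncoreIds(d)) {
    gii <- Gv[id, id]
    mii <- d@Mnn[[id]]
    gic <- Gv[id, coreIds(d)]
    pr <- indirectPevRel(mii, gii, gic, d@Gcc, PEV)
    rho <- apyRho(gii, mii)
    corr <- drop(crossprod(solve(d@Gcc, gic), PEV %*% solve(d@Gcc, gic)))
    # rel = rho - correction, exactly
    expect_equal(pr$rel, rho - corr / gii, tolerance = 1e-12)
    expect_lte(pr$rel, rho + 1e-12)
    expect_lte(rho, 1)
    expect_gte(pr$pev, 0)
  }
  # zero core PEV: reliability collapses onto rho
  id <- noncoreIds(d)[1]
  pr0 <- indirectPevRel(d@Mnn[[id]], Gv[id, id], Gv[id, coreIds(d)],
                        d@Gcc, 0 * PEV)
  expect_equal(pr0$rel, apyRho(Gv[id, id], d@Mnn[[id]]), tolerance = 1e-12)
  # no-information limit for a core duplicate: PEV = Gcc, m = 0
  j <- coreIds(d)[1]
  prDup <- indirectPevRel(0, Gv[j, j], Gv[j, coreIds(d)], d@Gcc, d@Gcc)
  expect_equal(prDup$pev, Gv[j, j], tolerance = 1e-10)
  expect_equal(prDup$rel, 0, tolerance = 1e-10)
})

test_that("rho grows along nested cores and the table flags poor coverage", {
  st <- simGt(55)
  G <- buildG(st$cz)
  series <- nestedCoreSeries(st$gt, c(4, 9, 15), seed = 55)
  outer <- noncoreIds(series[[3]])
  rhos <- sapply(series, function(p) {
    d <- apyDecompose(G, p)
    apyRho(d@gnnDiag[outer], d@Mnn[outer])
  })
  expect_true(all(diff(t(rhos)) >= -1e-10))
  # end-to-end indirect table
  part <- series[[2]]
  d <- apyDecompose(G, part)
  sol <- solveGblup(st$phg, gApyInverse(d), st$vc)
  PEV <- pevRelScale(pevBlock(sol, "u", coreIds(d)), st$vc)
  czCore <- st$cz
  ipIds <- noncoreIds(d)[1:3]
  czIp <- new("CenteredGenotypes",
              Z = centeredZ(st$cz)[ipIds, , drop = FALSE],
              p = alleleFreqs(st$cz), k = scalingK(st$cz))
  tab <- indirectPredictions(czIp, czCore, coreIds(d),
                             breedingValues(sol), PEV)
  expect_identical(tab$id, ipIds)
  expect_true(all(tab$rel <= tab$rho + 1e-12))
  expect_identical(tab$flagged, tab$rho < 0.5)
})
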
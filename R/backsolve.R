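#' Back-solve marker effects from core EBVs
#'
#' The BLUP of the marker effects given the breeding values reduces to a
#' function of core quantities only: `a_hat = k Z_c' G_cc^-1 u_c_hat` (with
#' per-marker weights D, `a_hat = k D Z_c' G_cc^-1 u_c_hat`). Non-core
#' animals contribute through the core EBVs, not explicitly.
#'
#' @param uC named vector of core EBVs (order of `Gcc`)
#' @param Zc centered core genotype matrix
#' @param Gcc core block of the genomic relationship matrix
#' @param k scaling constant used to build G
#' @param weights optional per-marker weights
#' @return named numeric vector of marker effects
#' @export
backsolveSnpEffects <- function(uC, Zc, Gcc, k, weights = NULL) {
  if (nrow(Zc) != nrow(Gcc) || length(uC) != nrow(Gcc))
    stop("dimension mismatch between Zc, Gcc and uC")
  a <- k * drop(crossprod(Zc, solve(Gcc, uC)))
  if (!is.null(weights)) a <- a * weights
  setNames(a, colnames(Zc))
}

#' Back-solve marker effects from all EBVs through the structured inverse
#'
#' The unreduced form `a_hat = k Zdagger' G_APY^-1 u_hat`; algebraically
#' identical to [backsolveSnpEffects()] and kept as the cross-check route.
#'
#' @param u named vector of EBVs for all genotyped animals (core first)
#' @param pd a [ProjectedDesign-class]
#' @param d the matching [ApyDecomposition-class]
#' @param mnnFloor optional clamp, see [gApyInverse()]
#' @return named numeric vector of marker effects
#' @export
backsolveFromAll <- function(u, pd, d, mnnFloor = NULL) {
  Ginv <- gApyInverse(d, mnnFloor = mnnFloor)
  u <- u[rownames(Ginv)]
  setNames(pd@k * drop(crossprod(pd@Zdagger, Ginv %*% u)),
           colnames(pd@Zdagger))
}

#' Variance of back-solved marker effects
#'
#' `Var(a_hat) = k^2 Z_c' G_cc^-1 (G_cc - PEV_core) G_cc^-1 Z_c`, with
#' `PEV_core` the prediction error covariance of the core EBVs on the
#' relationship (sigma_u^2 = 1) scale. Positive semidefinite whenever
#' `PEV_core <= G_cc`.
#'
#' @param Zc centered core genotype matrix
#' @param Gcc core block of G
#' @param PEVcore symmetric PEV matrix of the core EBVs (sigma_u^2 = 1 scale)
#' @param k scaling constant
#' @return m x m covariance matrix
#' @export
backsolveVariance <- function(Zc, Gcc, PEVcore, k) {
  if (max(abs(PEVcore - t(PEVcore))) > 1e-8 * max(1, max(abs(PEVcore))))
    stop("PEV_core must be symmetric")
  B <- solve(Gcc, Zc)                     # G_cc^-1 Z_c
  V <- k^2 * crossprod(B, (Gcc - PEVcore) %*% B)
  (V + t(V)) / 2
}

#' Indirect predictions for new genotyped animals
#'
#' Direct genomic values for animals absent from the evaluation, by either
#' of the two equivalent routes: `u_ip = Z_ip P a_hat` (marker route) or
#' `u_ip = G_ip,c G_cc^-1 u_c_hat` (relationship route). The new genotypes
#' must be centered and scaled with the stored `(p, k)` pair of the
#' evaluation; otherwise the identity degrades to an approximation.
#'
#' @param Zip centered genotype matrix of the new animals (same markers,
#'   same sidecar)
#' @param P projection operator onto the core row space (marker route)
#' @param aHat back-solved marker effects (marker route)
#' @param Gipc genomic relationships between new and core animals
#'   (relationship route)
#' @param Gcc core block of G (relationship route)
#' @param uC core EBVs (relationship route)
#' @param k scaling constant (used to form `Gipc = k Zip Zc'` when `Gipc` is
#'   not supplied but `Zc` is)
#' @param Zc centered core genotypes (to derive `Gipc`)
#' @return named vector of direct genomic values
#' @export
indirectPredict <- function(Zip = NULL, P = NULL, aHat = NULL,
                            Gipc = NULL, Gcc = NULL, uC = NULL,
                            k = NULL, Zc = NULL) {
  marker <- !is.null(Zip) && !is.null(P) && !is.null(aHat)
  if (is.null(Gipc) && !is.null(Zip) && !is.null(Zc) && !is.null(k))
    Gipc <- k * tcrossprod(Zip, Zc)
  relat <- !is.null(Gipc) && !is.null(Gcc) && !is.null(uC)
  if (marker) {
    out <- drop(Zip %*% P %*% aHat)
    names(out) <- rownames(Zip)
  } else if (relat) {
    out <- drop(Gipc %*% solve(Gcc, uC))
    names(out) <- rownames(Gipc)
  } else {
    stop("supply either {Zip, P, aHat} or {Gipc (or Zip+Zc+k), Gcc, uC}")
  }
  out
}

#' Core-coverage measure for an indirect prediction
#'
#' `rho_i = 1 - m_ii / g_ii`, where `m_ii` is the conditional variance of
#' the animal given the core and `g_ii` its genomic diagonal. A value of 1
#' means the genotype lies in the core row space and the APY prediction
#' coincides with the full SNP-BLUP one; small values flag animals far from
#' the core (large projection distance).
#'
#' @param gii genomic diagonal element(s), > 0
#' @param mii conditional variance(s), in `[0, g_ii]`
#' @return rho in [0, 1]
#' @export
apyRho <- function(gii, mii) {
  if (any(gii <= 0)) stop("g_ii must be positive")
  if (any(mii < 0) || any(mii > gii + 1e-12 * pmax(1, gii)))
    stop("m_ii must lie in [0, g_ii]; the Schur structure is violated")
  1 - pmin(mii, gii) / gii
}

#' PEV and reliability of an indirect prediction
#'
#' `pev_i = m_ii + g_ic G_cc^-1 PEV_core G_cc^-1 g_ci` and
#' `rel_i = 1 - pev_i / g_ii`, which decomposes exactly as `rho_i` minus the
#' core-uncertainty correction. All quantities on the sigma_u^2 = 1 scale.
#'
#' @param mii conditional variance of the animal given the core
#' @param gii genomic diagonal of the animal
#' @param gic numeric vector of genomic relationships to the core animals
#' @param Gcc core block of G
#' @param PEVcore PEV matrix of core EBVs (sigma_u^2 = 1 scale)
#' @return list with `pev` and `rel`
#' @export
indirectPevRel <- function(mii, gii, gic, Gcc, PEVcore) {
  v <- solve(Gcc, gic)
  pev <- mii + drop(crossprod(v, PEVcore %*% v))
  if (pev < 0) {
    warning("negative indirect PEV clamped to 0")
    pev <- 0
  }
  list(pev = pev, rel = 1 - pev / gii)
}

#' Indirect-prediction table for a cohort of new animals
#'
#' High-level wrapper: computes the direct genomic value, rho, PEV and
#' reliability for each animal in a new genotype cohort, given the core
#' objects from an APY evaluation. Animals whose rho falls below
#' `rhoWarn` are flagged (their genotype is poorly represented by the core
#' and the prediction is unstable under core changes).
#'
#' @param czIp [CenteredGenotypes-class] of the new animals (sidecar-centered)
#' @param czCore [CenteredGenotypes-class] restricted to (or covering) the
#'   core animals
#' @param coreIds core animal ids
#' @param uC named core EBVs
#' @param PEVcore PEV of core EBVs on the sigma_u^2 = 1 scale; 0 matrix if
#'   omitted
#' @param rhoWarn flag threshold for low core coverage
#' @return data.frame with columns id, dgv, rho, pev, rel, flagged
#' @export
indirectPredictions <- function(czIp, czCore, coreIds, uC, PEVcore = NULL,
                                rhoWarn = 0.5) {
  stopifnot(is(czIp, "CenteredGenotypes"), is(czCore, "CenteredGenotypes"))
  if (abs(czIp@k - czCore@k) > 1e-12 ||
      max(abs(czIp@p - czCore@p[names(czIp@p)])) > 1e-12)
    stop("new cohort was not centered with the evaluation's (p, k) sidecar")
  k <- czCore@k
  Zc <- czCore@Z[coreIds, , drop = FALSE]
  Zip <- czIp@Z
  Gcc <- k * tcrossprod(Zc)
  Gipc <- k * tcrossprod(Zip, Zc)
  if (is.null(PEVcore))
    PEVcore <- matrix(0, length(coreIds), length(coreIds))
  dgv <- indirectPredict(Gipc = Gipc, Gcc = Gcc, uC = uC[coreIds])
  gii <- k * rowSums(Zip^2)
  mii <- gii - rowSums((Gipc %*% solve(Gcc)) * Gipc)
  mii <- pmin(pmax(mii, 0), gii)
  rho <- apyRho(gii, mii)
  pr <- vapply(seq_len(nrow(Zip)), function(i) {
    unlist(indirectPevRel(mii[i], gii[i], Gipc[i, ], Gcc, PEVcore))
  }, c(pev = 0, rel = 0))
  data.frame(id = rownames(Zip), dgv = unname(dgv), rho = unname(rho),
             pev = unname(pr["pev", ]), rel = unname(pr["rel", ]),
             flagged = unname(rho) < rhoWarn, stringsAsFactors = FALSE)
}
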
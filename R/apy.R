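#' Select core animals
#'
#' Partitions the genotyped animals into core and non-core sets. Random
#' selection draws uniformly without replacement under the seed; a given list
#' is used verbatim. Within each side the original input order of `ids` is
#' preserved.
#'
#' The theory assumes the number of core animals does not exceed the number
#' of markers; pass `nMarkers` to have this checked (warning, overridable).
#'
#' @param ids genotyped animal ids
#' @param nCore core size (random strategy)
#' @param strategy `"random"` or `"given"`
#' @param seed integer seed for the random draw
#' @param given id vector for the given strategy
#' @param nMarkers optional marker count for the n_core <= m check
#' @param allowLargeCore silence the n_core > m warning
#' @return a [CorePartition-class]
#' @export
selectCore <- function(ids, nCore = NULL, strategy = c("random", "given"),
                       seed = NULL, given = NULL, nMarkers = NULL,
                       allowLargeCore = FALSE) {
  strategy <- match.arg(strategy)
  ids <- as.character(ids)
  if (strategy == "given") {
    stopifnot(!is.null(given))
    given <- as.character(given)
    bad <- setdiff(given, ids)
    if (length(bad))
      stop("given core ids not among genotyped animals: ",
           paste(bad, collapse = ", "))
    core <- ids[ids %in% given]
  } else {
    stopifnot(!is.null(nCore), nCore >= 1, nCore <= length(ids))
    if (is.null(seed)) stop("random core selection requires a seed")
    set.seed(as.integer(seed))
    core <- ids[sort(sample.int(length(ids), nCore))]
  }
  if (!is.null(nMarkers) && length(core) > nMarkers && !allowLargeCore)
    warning("core size ", length(core), " exceeds the number of markers ",
            nMarkers, "; G_cc will be singular in exact arithmetic")
  new("CorePartition", core = core, noncore = setdiff(ids, core),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' APY decomposition of a relationship matrix
#'
#' Computes the regression of non-core on core breeding values,
#' `P_nc = G_nc G_cc^-1`, and the diagonal conditional variances
#' `M_nn_i = G_nn_ii - (G_nc G_cc^-1 G_cn)_ii` (only the diagonal of the
#' Schur complement is formed). Tiny negative Schur diagonals from roundoff
#' are clamped to zero.
#'
#' @param G source [RelationshipMatrix-class] (G or the blended G*)
#' @param part a [CorePartition-class] over the ids of `G`
#' @param source label stored on the result ("G" or "Gstar")
#' @param condLimit error when the condition number of G_cc exceeds this
#' @return an [ApyDecomposition-class]
#' @export
apyDecompose <- function(G, part, source = "G", condLimit = 1e10) {
  stopifnot(is(G, "RelationshipMatrix"), is(part, "CorePartition"))
  ids <- animalIds(G)
  bad <- setdiff(animalIds(part), ids)
  if (length(bad))
    stop("partition ids not in relationship matrix: ", paste(bad, collapse = ", "))
  Gcc <- extractBlock(G, part@core, part@core)
  kap <- kappa(Gcc, exact = nrow(Gcc) <= 200L)
  if (!is.finite(kap) || kap > condLimit)
    stop("G_cc is singular or ill-conditioned (condition number ",
         format(kap, digits = 3), "); choose a different core set or blend ",
         "a residual polygenic fraction")
  nn <- part@noncore
  if (length(nn)) {
    Gnc <- extractBlock(G, nn, part@core)
    Pnc <- t(solve(Gcc, t(Gnc)))
    Mnn <- diag(extractBlock(G, nn, nn)) - rowSums(Pnc * Gnc)
    tol <- 1e-10 * max(1, mean(diag(Gcc)))
    if (any(Mnn < -1e-6 * max(1, mean(diag(Gcc)))))
      stop("negative conditional variance; source matrix is not PSD")
    Mnn[Mnn < tol] <- pmax(Mnn[Mnn < tol], 0)
    gnnDiag <- diag(extractBlock(G, nn, nn))
    names(Mnn) <- nn
    names(gnnDiag) <- nn
  } else {
    Pnc <- matrix(0, 0, length(part@core))
    Mnn <- setNames(numeric(0), character(0))
    gnnDiag <- setNames(numeric(0), character(0))
  }
  dimnames(Pnc) <- list(nn, part@core)
  new("ApyDecomposition", Pnc = Pnc, Mnn = Mnn, Gcc = Gcc,
      gnnDiag = gnnDiag, partition = part, source = source)
}

#' Floor the conditional variances of a decomposition
#'
#' When a non-core genotype is an exact linear combination of core genotypes
#' its conditional variance is zero and the structured inverse does not
#' exist. Flooring M_nn at a small positive value defines a nearby APY model
#' whose equivalence algebra holds exactly; all solvers must then consume the
#' same floored decomposition.
#'
#' @param d an [ApyDecomposition-class]
#' @param floor positive lower bound applied elementwise to M_nn
#' @return the modified [ApyDecomposition-class]
#' @export
clampMnn <- function(d, floor) {
  stopifnot(is(d, "ApyDecomposition"), floor > 0)
  d@Mnn <- pmax(d@Mnn, floor)
  d
}

.mnnFloorDefault <- function(d) {
  1e-8 * max(1, mean(c(diag(d@Gcc), d@gnnDiag)))
}

#' Structured APY inverse
#'
#' Assembles the sparse-structured inverse of G_APY from the decomposition:
#' core block `G_cc^-1 + P_cn M_nn^-1 P_nc`, off blocks `-P_cn M_nn^-1`, and
#' diagonal non-core block `M_nn^-1`. Row/column order is core then non-core.
#'
#' @param d an [ApyDecomposition-class]
#' @param mnnFloor optional clamp applied to M_nn before inversion; by default
#'   an entry at (numerical) zero raises an error naming the animal
#' @return dense numeric matrix with animal dimnames
#' @export
gApyInverse <- function(d, mnnFloor = NULL) {
  stopifnot(is(d, "ApyDecomposition"))
  if (!is.null(mnnFloor)) d <- clampMnn(d, mnnFloor)
  floor <- .mnnFloorDefault(d)
  low <- d@Mnn < floor
  if (any(low))
    stop("conditional variance numerically zero for non-core animal(s) ",
         paste(names(d@Mnn)[low], collapse = ", "),
         " (genotype lies in the core row space); enlarge the core, drop the",
         " animal, or clamp with clampMnn()/mnnFloor")
  ids <- animalIds(d)
  nc <- length(d@partition@core)
  nn <- length(d@partition@noncore)
  Gcci <- solve(d@Gcc)
  out <- matrix(0, nc + nn, nc + nn, dimnames = list(ids, ids))
  if (nn) {
    Minv <- 1 / d@Mnn
    PM <- d@Pnc * Minv                    # M_nn^-1 P_nc, rowwise scale
    out[seq_len(nc), seq_len(nc)] <- Gcci + crossprod(d@Pnc, PM)
    out[seq_len(nc), nc + seq_len(nn)] <- -t(PM)
    out[nc + seq_len(nn), seq_len(nc)] <- -PM
    out[cbind(nc + seq_len(nn), nc + seq_len(nn))] <- Minv
  } else {
    out[] <- Gcci
  }
  (out + t(out)) / 2
}

#' Dense G_APY
#'
#' Materializes the relationship matrix implied by the APY recursion:
#' identical to the source matrix on the core and core-by-non-core blocks;
#' on the non-core block, off-diagonal conditional covariances are dropped,
#' so the non-core block is `diag(M_nn) + P_nc G_cc P_cn`.
#'
#' @param d an [ApyDecomposition-class]
#' @return a [RelationshipMatrix-class], core animals first
#' @export
gApyFull <- function(d) {
  stopifnot(is(d, "ApyDecomposition"))
  ids <- animalIds(d)
  nc <- length(d@partition@core)
  nn <- length(d@partition@noncore)
  out <- matrix(0, nc + nn, nc + nn, dimnames = list(ids, ids))
  out[seq_len(nc), seq_len(nc)] <- d@Gcc
  if (nn) {
    Gnc <- d@Pnc %*% d@Gcc
    out[nc + seq_len(nn), seq_len(nc)] <- Gnc
    out[seq_len(nc), nc + seq_len(nn)] <- t(Gnc)
    Snn <- tcrossprod(Gnc, d@Pnc)
    diag(Snn) <- diag(Snn) + d@Mnn
    out[nc + seq_len(nn), nc + seq_len(nn)] <- Snn
  }
  new("RelationshipMatrix", values = (out + t(out)) / 2)
}

#' Fraction of the eigenvalue mass of G captured by a core
#'
#' Optional diagnostic: the trace of G_cc relative to the trace of G, a cheap
#' proxy for how much of the spectrum a random core spans.
#'
#' @param G source [RelationshipMatrix-class]
#' @param part a [CorePartition-class]
#' @return scalar in (0, 1]
#' @export
coreSpectrumFraction <- function(G, part) {
  ev <- eigen(relValues(G), symmetric = TRUE, only.values = TRUE)$values
  evc <- eigen(extractBlock(G, part@core, part@core), symmetric = TRUE,
               only.values = TRUE)$values
  sum(pmax(evc, 0)) / sum(pmax(ev, 0))
}
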
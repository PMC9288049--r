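#' Validate an allele-count genotype matrix
#'
#' Genotypes are integer allele counts in {0, 1, 2}, animals in rows, markers
#' in columns, with unique dimnames. Missing entries are rejected by default;
#' `meanImpute = TRUE` replaces them by the marker mean (logged via message).
#'
#' @param counts numeric/integer matrix of allele counts
#' @param meanImpute impute missing entries with the per-marker mean count
#' @return validated numeric matrix
#' @export
genotypeMatrix <- function(counts, meanImpute = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("genotype matrix must carry animal row names and marker column names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicated animal or marker ids in genotype matrix")
  if (anyNA(counts)) {
    if (!meanImpute)
      stop("missing genotypes present; quality control is assumed done ",
           "(use meanImpute = TRUE to mean-fill)")
    nmiss <- sum(is.na(counts))
    for (j in seq_len(ncol(counts))) {
      miss <- is.na(counts[, j])
      if (any(miss)) counts[miss, j] <- mean(counts[!miss, j])
    }
    message("mean-imputed ", nmiss, " missing genotype entries")
  } else if (!all(counts %in% c(0, 1, 2))) {
    stop("genotype entries must be allele counts in {0, 1, 2}")
  }
  storage.mode(counts) <- "double"
  counts
}

#' Center and scale genotypes
#'
#' Centers allele counts by twice the allele frequency, `Z_ij = counts_ij -
#' 2 p_j`, and fixes the scaling constant `k` that defines the genomic
#' relationship matrix `G = k Z Z'`. With `freqs = "observed"` the frequencies
#' are taken from the supplied animals; with `k = "heterozygosity"` the
#' classic `k = 1 / (2 sum p_j q_j)` is used. Supplying a stored `(p, k)`
#' pair reproduces the centering bit-identically for a later cohort, which is
#' required for indirect predictions to stay exact.
#'
#' @param counts genotype matrix (see [genotypeMatrix()])
#' @param freqs `"observed"` or a named numeric vector of frequencies in (0,1)
#' @param k `"heterozygosity"` or a positive scalar
#' @param dropMonomorphic drop markers with observed p in {0, 1} instead of
#'   erroring
#' @return a [CenteredGenotypes-class]
#' @export
centerScale <- function(counts, freqs = "observed", k = "heterozygosity",
                        dropMonomorphic = FALSE) {
  counts <- genotypeMatrix(counts)
  observed <- identical(freqs, "observed")
  if (observed) {
    p <- colMeans(counts) / 2
    mono <- p <= 0 | p >= 1
    if (any(mono)) {
      if (!dropMonomorphic)
        stop("monomorphic markers under observed frequencies: ",
             paste(colnames(counts)[mono], collapse = ", "),
             " (set dropMonomorphic = TRUE to remove them)")
      message("dropping ", sum(mono), " monomorphic marker(s): ",
              paste(colnames(counts)[mono], collapse = ", "))
      counts <- counts[, !mono, drop = FALSE]
      p <- p[!mono]
    }
  } else {
    p <- freqs
    if (!is.null(names(p))) {
      miss <- setdiff(colnames(counts), names(p))
      if (length(miss))
        stop("no stored frequency for markers: ", paste(miss, collapse = ", "))
      p <- p[colnames(counts)]
    }
    if (length(p) != ncol(counts))
      stop("freqs must supply one frequency per marker")
    if (any(p <= 0 | p >= 1))
      stop("supplied allele frequencies must lie strictly in (0, 1)")
  }
  kval <- if (identical(k, "heterozygosity")) 1 / (2 * sum(p * (1 - p)))
          else as.numeric(k)
  if (!is.finite(kval) || kval <= 0) stop("scaling factor k must be positive")
  Z <- sweep(counts, 2L, 2 * p, "-")
  names(p) <- colnames(Z)
  new("CenteredGenotypes", Z = Z, p = p, k = kval)
}

#' Center a new cohort with a stored frequency sidecar
#'
#' Convenience wrapper that enforces the "centered and scaled in exactly the
#' same manner" contract for indirect-prediction cohorts.
#'
#' @param counts genotype matrix of the new animals
#' @param sidecar list with elements `p` (named frequencies) and `k`, as
#'   returned by [readFreqSidecar()]
#' @return a [CenteredGenotypes-class]
#' @export
centerWithSidecar <- function(counts, sidecar) {
  if (is.null(sidecar$p) || is.null(sidecar$k))
    stop("frequency sidecar must carry both p and k; refusing to re-center ",
         "with different frequencies (the back-solving algebra would become ",
         "an approximation)")
  centerScale(counts, freqs = sidecar$p, k = sidecar$k)
}

#' Genomic relationship matrix
#'
#' `G = k Z Z'` (or `k Z D Z'` for diagonal per-marker weights D).
#'
#' @param cz a [CenteredGenotypes-class]
#' @param weights optional positive per-marker weights
#' @return a [RelationshipMatrix-class]
#' @export
buildG <- function(cz, weights = NULL) {
  stopifnot(is(cz, "CenteredGenotypes"))
  Z <- cz@Z
  if (is.null(weights)) {
    G <- cz@k * tcrossprod(Z)
  } else {
    stopifnot(length(weights) == ncol(Z), all(weights > 0))
    G <- cz@k * tcrossprod(sweep(Z, 2L, weights, "*"), Z)
  }
  G <- (G + t(G)) / 2
  new("RelationshipMatrix", values = G)
}

#' Blend a genomic matrix with the pedigree block (residual polygenic effect)
#'
#' `G* = (1 - beta) G + beta A22`, the covariance implied by splitting the
#' genetic variance between markers and a pedigree polygenic term.
#'
#' @param G genomic [RelationshipMatrix-class] (already includes k)
#' @param A22 pedigree relationship block for the same animals, same order
#' @param beta polygenic fraction in [0, 1]
#' @return a [RelationshipMatrix-class]
#' @export
blendPolygenic <- function(G, A22, beta) {
  stopifnot(is(G, "RelationshipMatrix"), is(A22, "RelationshipMatrix"),
            beta >= 0, beta <= 1)
  if (!identical(animalIds(G), animalIds(A22)))
    stop("G and A22 must cover the same animals in the same order")
  new("RelationshipMatrix",
      values = (1 - beta) * G@values + beta * A22@values)
}

#' Cholesky factor of A22
#'
#' Exact lower-triangular factor `L` with `L L' = A22`, used to augment the
#' marker design in the residual polygenic marker-effects model.
#'
#' @param A22 positive definite [RelationshipMatrix-class]
#' @return lower-triangular numeric matrix with animal dimnames
#' @export
choleskyA22 <- function(A22) {
  stopifnot(is(A22, "RelationshipMatrix"))
  U <- tryCatch(chol(A22@values), error = function(e) {
    stop("A22 is not positive definite: ", conditionMessage(e))
  })
  L <- t(U)
  dimnames(L) <- dimnames(A22@values)
  L
}

#' Write / read the allele-frequency sidecar
#'
#' Plain-text key-value file storing the `(p, k)` pair of a
#' [CenteredGenotypes-class] so later cohorts can be centered identically.
#'
#' @param cz a [CenteredGenotypes-class]
#' @param path file path
#' @return `readFreqSidecar` returns `list(p = named numeric, k = scalar)`
#' @export
writeFreqSidecar <- function(cz, path) {
  stopifnot(is(cz, "CenteredGenotypes"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# allele frequency / scaling sidecar",
               paste0("k\t", formatC(cz@k, digits = 12, format = "g"))), con)
  writeLines(paste0(names(cz@p), "\t",
                    formatC(cz@p, digits = 12, format = "g")), con)
  invisible(path)
}

#' @rdname writeFreqSidecar
#' @export
readFreqSidecar <- function(path) {
  if (!file.exists(path)) .apyStop("FILE_NOT_FOUND", "no such sidecar: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- as.numeric(vapply(parts, `[[`, "", 2L))
  k <- vals[keys == "k"]
  p <- vals[keys != "k"]
  names(p) <- keys[keys != "k"]
  list(p = p, k = k)
}
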
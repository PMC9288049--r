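#' Construct a pedigree
#'
#' Builds a [Pedigree-class] from animal/sire/dam triples, verifies that the
#' parent relation is acyclic, and stores a topological order (parents before
#' offspring). Unknown parents are given as `NA`, `""` or `"0"`.
#'
#' @param animal,sire,dam character vectors of equal length
#' @return a [Pedigree-class]
#' @export
pedigree <- function(animal, sire, dam) {
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0") | is.na(x)] <- NA_character_
    x
  }
  rec <- data.frame(animal = as.character(animal), sire = clean(sire),
                    dam = clean(dam), stringsAsFactors = FALSE)
  if (anyDuplicated(rec$animal))
    stop("duplicated animal ids: ",
         paste(unique(rec$animal[duplicated(rec$animal)]), collapse = ", "))
  parents <- union(rec$sire, rec$dam)
  parents <- parents[!is.na(parents)]
  missing <- setdiff(parents, rec$animal)
  if (length(missing)) {
    # parents without own record become founders prepended to the pedigree
    rec <- rbind(data.frame(animal = missing, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 rec)
  }
  ord <- .topoOrder(rec)
  new("Pedigree", records = rec, order = ord)
}

# Kahn topological sort; errors with the offending cycle members.
.topoOrder <- function(rec) {
  n <- nrow(rec)
  idx <- setNames(seq_len(n), rec$animal)
  si <- idx[rec$sire]
  di <- idx[rec$dam]
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (j in kids[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) queue <- c(queue, j)
    }
  }
  if (length(out) < n) {
    cyc <- rec$animal[setdiff(seq_len(n), out)]
    stop("pedigree contains a parent-offspring cycle involving: ",
         paste(cyc, collapse = ", "))
  }
  out
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes Wright's numerator relationship matrix A by the full tabular
#' recursion, including inbreeding (the diagonal is 1 + F, with F half the
#' relationship between the parents). Unknown parents contribute zero.
#'
#' @param ped a [Pedigree-class]
#' @return a [RelationshipMatrix-class] in pedigree record order
#' @export
buildA <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  rec <- ped@records
  n <- nrow(rec)
  idx <- setNames(seq_len(n), rec$animal)
  si <- idx[rec$sire]
  di <- idx[rec$dam]
  A <- matrix(0, n, n, dimnames = list(rec$animal, rec$animal))
  for (i in ped@order) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + 0.5 * (if (!is.na(s) && !is.na(d)) A[s, d] else 0)
    rel <- numeric(n)
    if (!is.na(s)) rel <- rel + 0.5 * A[, s]
    if (!is.na(d)) rel <- rel + 0.5 * A[, d]
    rel[i] <- 0
    done <- A[cbind(seq_len(n), seq_len(n))] > 0   # already-processed animals
    done[i] <- FALSE
    A[i, done] <- rel[done]
    A[done, i] <- rel[done]
  }
  new("RelationshipMatrix", values = A)
}

#' Extract a sub-block of a relationship matrix
#'
#' @param R a [RelationshipMatrix-class]
#' @param rows,cols animal id vectors; the block is returned in this order
#' @return numeric matrix
#' @export
extractBlock <- function(R, rows, cols = rows) {
  stopifnot(is(R, "RelationshipMatrix"))
  ids <- animalIds(R)
  bad <- setdiff(c(rows, cols), ids)
  if (length(bad))
    stop("ids not present in relationship matrix: ",
         paste(unique(bad), collapse = ", "))
  R@values[rows, cols, drop = FALSE]
}

#' Reorder or subset a relationship matrix
#' @param R a [RelationshipMatrix-class]
#' @param ids animal ids defining the new order
#' @return a [RelationshipMatrix-class]
#' @export
subsetRel <- function(R, ids) {
  new("RelationshipMatrix", values = extractBlock(R, ids, ids))
}
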
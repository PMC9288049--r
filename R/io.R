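# Classed errors so the CLI can map them to exit codes.
.apyStop <- function(class, ...) {
  stop(structure(class = c(paste0("apy_", tolower(class)), "apyError",
                           "error", "condition"),
                 list(message = paste0(...), class_tag = class,
                      call = sys.call(-1))))
}

.checkFile <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    .apyStop("FILE_NOT_FOUND", "missing ", what, " file: ",
             if (is.null(path)) "<not given>" else path)
  path
}

#' Read a pedigree file
#'
#' Whitespace- or comma-separated, three columns (animal, sire, dam);
#' `0` or empty denotes an unknown parent. A header line is detected and
#' skipped if its first field is non-numeric "animal"-like.
#'
#' @param path file path
#' @return a [Pedigree-class]
#' @export
readPedigree <- function(path) {
  .checkFile(path, "pedigree")
  sep <- if (grepl(",", readLines(path, n = 1L))) "," else ""
  df <- read.table(path, header = FALSE, sep = sep, colClasses = "character",
                   fill = TRUE, blank.lines.skip = TRUE)
  if (tolower(df[1, 1]) %in% c("animal", "id")) df <- df[-1, , drop = FALSE]
  if (ncol(df) < 3) .apyStop("PARSE_ERROR", "pedigree needs 3 columns")
  pedigree(df[[1]], df[[2]], df[[3]])
}

#' Write a pedigree file
#' @param ped a [Pedigree-class]
#' @param path file path
#' @export
writePedigree <- function(ped, path) {
  rec <- ped@records
  rec[is.na(rec)] <- "0"
  write.table(rec, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a genotype file
#'
#' First line: marker ids. Each further line: animal id followed by the
#' allele counts in {0, 1, 2}.
#'
#' @param path file path
#' @param meanImpute passed to [genotypeMatrix()]
#' @return validated allele-count matrix
#' @export
readGenotypes <- function(path, meanImpute = FALSE) {
  .checkFile(path, "genotype")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  markers <- strsplit(trimws(lines[1L]), "[,\t ]+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "[,\t ]+")
  idsv <- vapply(body, `[[`, "", 1L)
  counts <- t(vapply(body, function(x) as.numeric(x[-1L]),
                     numeric(length(markers))))
  dimnames(counts) <- list(idsv, markers)
  genotypeMatrix(counts, meanImpute = meanImpute)
}

#' Write a genotype file
#' @param counts allele-count matrix with dimnames
#' @param path file path
#' @export
writeGenotypes <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(counts), collapse = " "), con)
  writeLines(paste(rownames(counts),
                   apply(counts, 1L, paste, collapse = " ")), con)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with columns `id`, `y` and optional fixed-effect columns; categorical
#' columns become factor contrasts, numeric columns covariates, always with
#' an intercept.
#'
#' @param path file path
#' @param animals optional animal universe for the W columns
#' @param dropOthers drop records on animals outside `animals` (for
#'   genomic-only models evaluated on the genotyped subset)
#' @return a [PhenotypeData-class]
#' @export
readPhenotypes <- function(path, animals = NULL, dropOthers = FALSE) {
  .checkFile(path, "phenotype")
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = TRUE)
  if (!all(c("id", "y") %in% names(df)))
    .apyStop("PARSE_ERROR", "phenotype file needs columns id, y")
  if (dropOthers && !is.null(animals))
    df <- df[as.character(df$id) %in% animals, , drop = FALSE]
  fixed <- setdiff(names(df), c("id", "y"))
  X <- if (length(fixed))
    stats::model.matrix(stats::reformulate(fixed), df)
  else matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  phenotypeData(df$y, as.character(df$id), X = X, animals = animals)
}

#' Read a core-animal list (one id per line)
#' @param path file path
#' @return character vector
#' @export
readCoreList <- function(path) {
  .checkFile(path, "core list")
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}

#' Write solutions as a sorted TSV
#'
#' Columns `level_type`, `level_id`, `estimate`, stably sorted by type then
#' id; floats with 12 significant digits for diffability.
#'
#' @param sol a [MixedModelSolution-class]
#' @param path file path
#' @export
writeSolutions <- function(sol, path) {
  rows <- data.frame(level_type = "fixed", level_id = names(sol@b),
                     estimate = unname(sol@b), stringsAsFactors = FALSE)
  for (nm in names(sol@effects)) {
    e <- sol@effects[[nm]]
    rows <- rbind(rows, data.frame(level_type = nm, level_id = names(e),
                                   estimate = unname(e),
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$level_type, rows$level_id), ]
  rows$estimate <- formatC(rows$estimate, digits = 12, format = "g")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a solutions TSV back into named vectors
#' @param path file path
#' @return named list of named numeric vectors, one per level_type
#' @export
readSolutions <- function(path) {
  .checkFile(path, "solutions")
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric"))
  split(setNames(df$estimate, df$level_id), df$level_type)
}
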
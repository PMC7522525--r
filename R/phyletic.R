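#' Phyletic pattern: strains x gene-family copy-count matrix
#'
#' The phyletic pattern is the central object of the pipeline: an integer
#' matrix of per-genome copy numbers for each cluster of likely orthologous
#' genes (CLOG). Rows are strains, columns are CLOGs. All downstream
#' analyses that model gene content (pan/core classification, gain/loss
#' reconstruction, gene-content trees) consume the binarised
#' presence/absence view; copy numbers are retained for reporting.
#'
#' @param counts integer matrix with unique rownames (strain ids) and unique
#'   colnames (CLOG ids); all cells must be non-negative integers.
#' @return an object of class `phyletic_pattern` with elements `strains`,
#'   `clogs` and `counts`.
#' @export
phyletic_pattern <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have strain rownames and CLOG colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate strain id: ", rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate CLOG id: ", colnames(counts)[duplicated(colnames(counts))][1])
  if (nrow(counts) == 0) stop("no strains")
  storage <- suppressWarnings(as.numeric(counts))
  if (anyNA(storage) || any(storage < 0) || any(storage != floor(storage)))
    stop("counts must be non-negative integers")
  mode(counts) <- "integer"
  structure(
    list(strains = rownames(counts), clogs = colnames(counts), counts = counts),
    class = "phyletic_pattern"
  )
}

#' @export
print.phyletic_pattern <- function(x, ...) {
  cat("phyletic_pattern:", length(x$strains), "strains x", length(x$clogs),
      "CLOGs;", sum(x$counts >= 1L), "presence cells\n")
  invisible(x)
}

#' Presence/absence view of a phyletic pattern
#'
#' @param pattern a [phyletic_pattern()].
#' @return integer 0/1 matrix (presence = copy count >= 1).
#' @export
presence_matrix <- function(pattern) {
  stopifnot(inherits(pattern, "phyletic_pattern"))
  m <- (pattern$counts >= 1L) + 0L
  dimnames(m) <- dimnames(pattern$counts)
  m
}

#' Read a phyletic pattern table
#'
#' Tab-separated file: header row of CLOG ids, first column strain ids,
#' integer copy counts in the cells. Inverse of [write_phyletic_table()].
#'
#' @param path file path.
#' @return a [phyletic_pattern()].
#' @export
read_phyletic_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("no strains in ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  clogs <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  strains <- vapply(rows, `[[`, character(1), 1)
  cells <- lapply(rows, function(r) r[-1])
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) != length(clogs))
      stop("row '", strains[i], "': expected ", length(clogs), " cells, got ",
           length(cells[[i]]))
    bad <- which(!grepl("^[0-9]+$", cells[[i]]))
    if (length(bad))
      stop("non-integer cell at row '", strains[i], "', column '",
           clogs[bad[1]], "': '", cells[[i]][bad[1]], "'")
  }
  counts <- matrix(as.integer(unlist(cells)), nrow = length(strains),
                   byrow = TRUE, dimnames = list(strains, clogs))
  phyletic_pattern(counts)
}

#' Write a phyletic pattern table
#'
#' @param pattern a [phyletic_pattern()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phyletic_table <- function(pattern, path) {
  stopifnot(inherits(pattern, "phyletic_pattern"))
  header <- paste(c("strain", pattern$clogs), collapse = "\t")
  body <- vapply(seq_along(pattern$strains), function(i) {
    paste(c(pattern$strains[i], pattern$counts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a strain metadata table
#'
#' Tab-separated with a `strain` column and any of `sub_cluster`, `clade`,
#' `subclade`, `ESTU`.
#'
#' @param path file path.
#' @return data.frame with one row per strain.
#' @export
read_strain_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"strain" %in% names(md)) stop("metadata must have a 'strain' column")
  if (anyDuplicated(md$strain)) stop("duplicate strain in metadata")
  md
}

#' Cross-check the strain/CLOG consistency of a dataset
#'
#' Reconciles the strain and CLOG sets announced by the different inputs of
#' the pipeline (pattern, tree, metadata, genome annotations, alignments)
#' and reports mismatches.
#'
#' @param pattern a [phyletic_pattern()].
#' @param tree optional tree ([read_tree()]); leaf labels are checked
#'   against the pattern strains.
#' @param metadata optional metadata data.frame; every pattern strain must
#'   have a row.
#' @param genomes optional list of [annotated_genome()]; CLOG ids are
#'   checked against the pattern.
#' @param alignments optional [read_alignments()] result; sequence names are
#'   checked against the pattern strains.
#' @return list with an `ok` flag and a character vector of `problems`.
#' @export
validate_dataset <- function(pattern, tree = NULL, metadata = NULL,
                             genomes = NULL, alignments = NULL) {
  stopifnot(inherits(pattern, "phyletic_pattern"))
  problems <- character(0)
  if (!is.null(tree)) {
    missing <- setdiff(tree$tip.label, pattern$strains)
    extra <- setdiff(pattern$strains, tree$tip.label)
    if (length(missing))
      problems <- c(problems, paste("tree leaves absent from pattern:",
                                    paste(missing, collapse = ", ")))
    if (length(extra))
      problems <- c(problems, paste("pattern strains absent from tree:",
                                    paste(extra, collapse = ", ")))
  }
  if (!is.null(metadata)) {
    missing <- setdiff(pattern$strains, metadata$strain)
    if (length(missing))
      problems <- c(problems, paste("strains without metadata:",
                                    paste(missing, collapse = ", ")))
  }
  if (!is.null(genomes)) {
    for (g in genomes) {
      unknown <- setdiff(stats::na.omit(g$features$clog), pattern$clogs)
      if (length(unknown))
        problems <- c(problems, paste0("genome ", g$strain,
                                       ": CLOGs absent from pattern: ",
                                       paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(alignments)) {
    missing <- setdiff(alignments$strains, pattern$strains)
    if (length(missing))
      problems <- c(problems, paste("alignment strains absent from pattern:",
                                    paste(missing, collapse = ", ")))
  }
  list(ok = length(problems) == 0, problems = problems)
}
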
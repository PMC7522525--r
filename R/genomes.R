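#' Annotated genome: ordered CDS features with CLOG assignments
#'
#' Substrate of genomic-island detection. Coordinates are 1-based inclusive
#' (GFF3 convention) throughout the package. Strand is preserved but
#' ignored by the island windows, which work on strand-agnostic nucleotide
#' ratios.
#'
#' @param strain strain id.
#' @param length genome length in bp.
#' @param features data.frame with columns `start`, `end`, `strand`, `clog`,
#'   `full_length` and optionally `gained`.
#' @param circular logical; whether the genome is circular (island windows
#'   wrap around the origin).
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(strain, length, features, circular = FALSE) {
  stopifnot(is.character(strain), length(strain) == 1)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  needed <- c("start", "end", "strand", "clog", "full_length")
  miss <- setdiff(needed, names(features))
  if (length(miss)) stop("features missing columns: ", paste(miss, collapse = ", "))
  if (nrow(features)) {
    if (any(features$end < features$start)) stop("feature with end < start")
    if (any(features$start < 1)) stop("feature with start < 1")
    if (any(features$end > length)) stop("feature beyond genome length")
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  if (!"gained" %in% names(features)) features$gained <- logical(nrow(features))
  structure(list(strain = strain, length = as.numeric(length),
                 features = features, circular = isTRUE(circular)),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome:", x$strain, "-", x$length, "bp,",
      nrow(x$features), "CDS", if (x$circular) "(circular)" else "", "\n")
  invisible(x)
}

#' Read an annotated genome from GFF3
#'
#' CDS features are kept; the CLOG id is taken from the attribute named by
#' `clog_attr` (a CDS lacking it is retained with `NA` CLOG and a warning).
#' A `full_length` attribute, when present, marks complete genes
#' (`"true"`/`"false"`); features without it are taken as full length.
#' Genome length comes from the `##sequence-region` pragma when present,
#' otherwise from the rightmost feature end.
#'
#' @param path GFF3 file path.
#' @param clog_attr name of the attribute carrying the CLOG id.
#' @return an [annotated_genome()].
#' @export
read_genome_gff <- function(path, clog_attr = "clog") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  strain <- as.character(GenomeInfoDb::seqnames(gr)[1])
  mc <- S4Vectors::mcols(gr)
  clog <- if (clog_attr %in% names(mc)) as.character(mc[[clog_attr]]) else
    rep(NA_character_, length(gr))
  if (anyNA(clog))
    warning(sum(is.na(clog)), " CDS without '", clog_attr,
            "' attribute retained with NA CLOG")
  full_length <- if ("full_length" %in% names(mc))
    !(tolower(as.character(mc$full_length)) %in% "false") else
    rep(TRUE, length(gr))
  # genome length from the ##sequence-region pragma (rtracklayer drops it)
  glen <- NA_real_
  for (ln in readLines(path, n = 50)) {
    if (startsWith(ln, "##sequence-region")) {
      parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(parts) >= 4) { glen <- as.numeric(parts[4]); break }
    }
  }
  circular <- any(grepl("^##circular", readLines(path, n = 50)))
  ends <- BiocGenerics::end(gr)
  if (is.na(glen)) glen <- if (length(ends)) max(ends) else 0
  annotated_genome(
    strain = strain, length = glen,
    features = data.frame(
      start = BiocGenerics::start(gr), end = ends,
      strand = as.character(BiocGenerics::strand(gr)),
      clog = clog, full_length = full_length, stringsAsFactors = FALSE),
    circular = circular)
}

#' Write an annotated genome to GFF3
#'
#' @param genome an [annotated_genome()].
#' @param path output file path.
#' @param clog_attr attribute name used for the CLOG id.
#' @return `path`, invisibly.
#' @export
write_genome_gff <- function(genome, path, clog_attr = "clog") {
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = genome$strain,
    ranges = IRanges::IRanges(f$start, f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)[[clog_attr]] <- f$clog
  S4Vectors::mcols(gr)$full_length <- ifelse(f$full_length, "true", "false")
  suppressWarnings(rtracklayer::export.gff3(gr, path))
  lines <- readLines(path)
  pragma <- sprintf("##sequence-region %s 1 %d", genome$strain,
                    as.integer(genome$length))
  if (genome$circular) pragma <- c(pragma, sprintf("##circular %s", genome$strain))
  writeLines(c(lines[1], pragma, lines[-1]), path)
  invisible(path)
}

#' Read a directory of per-CLOG core-protein alignments
#'
#' One aligned amino-acid FASTA per CLOG (file stem = CLOG id); sequence
#' headers are strain ids. Within a file all gapped sequences must have
#' equal length (single-copy core: exactly one sequence per strain).
#'
#' @param dir directory containing `*.faa` / `*.fasta` / `*.fa` files.
#' @return object of class `core_alignment_set`: list with `alignments`
#'   (named list CLOG -> named character vector of gapped sequences),
#'   `lengths`, `total_residues` and `strains`.
#' @export
read_alignments <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(faa|fasta|fa)$", full.names = TRUE))
  if (!length(files)) stop("no alignment files in ", dir)
  alns <- list()
  for (f in files) {
    clog <- sub("\\.(faa|fasta|fa)$", "", basename(f))
    seqs <- Biostrings::readAAStringSet(f)
    if (anyDuplicated(names(seqs)))
      stop("duplicate strain in ", basename(f))
    if (length(unique(Biostrings::width(seqs))) > 1)
      stop("ragged alignment in ", basename(f))
    alns[[clog]] <- stats::setNames(as.character(seqs), names(seqs))
  }
  core_alignment_set(alns)
}

#' Build a core alignment set from in-memory alignments
#'
#' @param alignments named list (CLOG -> named character vector of
#'   equal-length gapped sequences, names = strain ids).
#' @return a `core_alignment_set`.
#' @export
core_alignment_set <- function(alignments) {
  if (!length(alignments)) stop("empty alignment set")
  alignments <- alignments[order(names(alignments))]
  strains <- sort(names(alignments[[1]]))
  for (clog in names(alignments)) {
    a <- alignments[[clog]]
    if (length(unique(nchar(a))) > 1) stop("ragged alignment for ", clog)
    if (!identical(sort(names(a)), strains))
      stop("alignment for ", clog, " does not cover the single-copy core strain set")
  }
  lengths <- vapply(alignments, function(a) nchar(a[[1]]), numeric(1))
  structure(list(alignments = alignments, lengths = lengths,
                 total_residues = sum(lengths), strains = strains),
            class = "core_alignment_set")
}

#' @export
print.core_alignment_set <- function(x, ...) {
  cat("core_alignment_set:", length(x$alignments), "CLOGs,",
      length(x$strains), "strains,", x$total_residues, "residues\n")
  invisible(x)
}

#' Concatenate a core alignment set
#'
#' Families are concatenated in deterministic (sorted) CLOG-id order.
#'
#' @param cas a `core_alignment_set`.
#' @return named character vector (strain -> concatenated gapped sequence).
#' @export
concat_alignment <- function(cas) {
  stopifnot(inherits(cas, "core_alignment_set"))
  out <- stats::setNames(rep("", length(cas$strains)), cas$strains)
  for (clog in names(cas$alignments)) {
    a <- cas$alignments[[clog]]
    out <- paste0(out, a[cas$strains])
  }
  stats::setNames(out, cas$strains)
}
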
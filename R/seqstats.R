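#' Fragment aligner backed by command-line BLASTN
#'
#' Returns a function mapping (named fragment vector, subject sequence) to
#' a best-hit table, using `blastn -subject` (both strands searched, no
#' database build needed). This is the native tool of fragment-based ANI.
#'
#' @param task blastn task (default `"blastn"`).
#' @return function(fragments, subject) -> data.frame(query, identity,
#'   coverage, aln_length).
#' @export
blast_fragment_aligner <- function(task = "blastn") {
  if (Sys.which("blastn") == "") stop("blastn not found on PATH")
  function(fragments, subject) {
    qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
    on.exit(unlink(c(qf, sf)), add = TRUE)
    writeLines(c(rbind(paste0(">", names(fragments)), fragments)), qf)
    writeLines(c(">subject", subject), sf)
    out <- system2("blastn",
                   c("-task", task, "-query", qf, "-subject", sf,
                     "-outfmt", shQuote("6 qseqid pident length qlen bitscore"),
                     "-dust", "no", "-evalue", "1e-3"),
                   stdout = TRUE)
    if (!length(out))
      return(data.frame(query = character(0), identity = numeric(0),
                        coverage = numeric(0), aln_length = numeric(0)))
    hits <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
                              col.names = c("query", "pident", "length",
                                            "qlen", "bitscore"))
    hits <- hits[order(-hits$bitscore), ]
    hits <- hits[!duplicated(hits$query), ]
    data.frame(query = hits$query, identity = hits$pident / 100,
               coverage = pmin(1, hits$length / hits$qlen),
               aln_length = pmin(hits$length, hits$qlen),
               stringsAsFactors = FALSE)
  }
}

#' Fragment aligner backed by Biostrings local alignment
#'
#' Pure-R backend with the stated scoring defaults (match +1, mismatch -1,
#' gap open 5, gap extend 2); both strands are searched. Considerably
#' slower than the BLAST backend; intended for small inputs and for
#' testing the injectable-aligner interface.
#'
#' @return function(fragments, subject) -> best-hit data.frame as in
#'   [blast_fragment_aligner()].
#' @export
biostrings_fragment_aligner <- function() {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  function(fragments, subject) {
    subj <- Biostrings::DNAString(subject)
    subj_rc <- Biostrings::reverseComplement(subj)
    rows <- lapply(names(fragments), function(id) {
      best <- NULL
      for (s in list(subj, subj_rc)) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(fragments[[id]]), s, type = "local",
          substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
        if (is.null(best) || Biostrings::score(pa) > Biostrings::score(best))
          best <- pa
      }
      w <- Biostrings::nchar(best)
      data.frame(query = id,
                 identity = Biostrings::pid(best, type = "PID1") / 100,
                 coverage = min(1, w / nchar(fragments[[id]])),
                 aln_length = min(w, nchar(fragments[[id]])),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
}

# Internal: one ANI direction (A fragments vs B).
ani_direction <- function(a, b, fragment, min_identity, min_coverage, aligner) {
  n_frag <- nchar(a) %/% fragment
  if (n_frag < 1) stop("genome shorter than one fragment (", fragment, " bp)")
  starts <- (seq_len(n_frag) - 1L) * fragment + 1L
  frags <- stats::setNames(substring(a, starts, starts + fragment - 1L),
                           paste0("frag", seq_len(n_frag)))
  hits <- aligner(frags, b)
  kept <- hits[hits$identity > min_identity & hits$coverage >= min_coverage, ,
               drop = FALSE]
  ani <- if (nrow(kept)) 100 * mean(kept$identity) else NA_real_
  # fraction of the fragmented length covered by >90%-identity alignments
  conserved <- 100 * sum(kept$aln_length[kept$identity > 0.9]) /
    (n_frag * fragment)
  list(ani = ani, conserved = conserved, n_fragments = n_frag,
       n_retained = nrow(kept))
}

#' Fragment-based average nucleotide identity
#'
#' Genome A is cut into consecutive non-overlapping fragments (tail
#' shorter than the fragment size dropped); each fragment is locally
#' aligned to genome B (both strands) and its best hit retained when the
#' identity exceeds `min_identity` over at least `min_coverage` of the
#' fragment. ANI is the mean identity of retained hits; the conserved-DNA
#' percentage is the fraction of A's fragmented length covered by
#' alignments with identity above 90%. Both directions are computed and
#' their mean reported.
#'
#' @param genome_a,genome_b nucleotide sequences (character strings).
#' @param fragment fragment size in bp (default 1020).
#' @param min_identity minimum identity of a retained hit (default 0.3).
#' @param min_coverage minimum fragment coverage of a retained hit
#'   (default 0.7).
#' @param aligner injectable fragment aligner; default BLASTN when
#'   available, else the Biostrings backend.
#' @return list with `ani`, `conserved_dna` (percent, means of the two
#'   directions) and `per_direction`.
#' @export
ani <- function(genome_a, genome_b, fragment = 1020, min_identity = 0.3,
                min_coverage = 0.7, aligner = NULL) {
  if (is.null(aligner))
    aligner <- if (Sys.which("blastn") != "") blast_fragment_aligner() else
      biostrings_fragment_aligner()
  d1 <- ani_direction(genome_a, genome_b, fragment, min_identity,
                      min_coverage, aligner)
  d2 <- ani_direction(genome_b, genome_a, fragment, min_identity,
                      min_coverage, aligner)
  list(ani = mean(c(d1$ani, d2$ani)),
       conserved_dna = mean(c(d1$conserved, d2$conserved)),
       per_direction = list(ab = d1, ba = d2))
}

# Internal: best hits of every query protein against a subject proteome.
protein_best_hits <- function(queries, subjects) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  submat <- get("BLOSUM62", envir = environment())
  rows <- lapply(names(queries), function(qid) {
    best_score <- -Inf; best <- NULL
    for (sid in names(subjects)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(queries[[qid]]), Biostrings::AAString(subjects[[sid]]),
        type = "local", substitutionMatrix = submat,
        gapOpening = 11, gapExtension = 1)
      if (Biostrings::score(pa) > best_score) {
        best_score <- Biostrings::score(pa)
        best <- data.frame(query = qid, subject = sid,
                           identity = Biostrings::pid(pa, type = "PID1") / 100,
                           score = Biostrings::score(pa),
                           stringsAsFactors = FALSE)
      }
    }
    best
  })
  do.call(rbind, rows)
}

#' Average amino-acid identity between two proteomes
#'
#' Best hits are computed in both directions with a BLOSUM62 local
#' aligner; with `rbh = TRUE` only reciprocal best-hit pairs are kept.
#' Each direction's AAI is the mean identity over its retained pairs; the
#' final value is the maximum of the two directions (when the directions
#' disagree, the highest value is kept).
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences.
#' @param rbh restrict to reciprocal best hits (default TRUE).
#' @return list with `aai` (percent), `ab`, `ba` (directional values) and
#'   `pairs` (the retained hit table, for audit).
#' @export
aai <- function(proteome_a, proteome_b, rbh = TRUE) {
  if (!length(proteome_a) || !length(proteome_b)) stop("empty proteome")
  ab <- protein_best_hits(proteome_a, proteome_b)
  ba <- protein_best_hits(proteome_b, proteome_a)
  if (rbh) {
    recip <- paste(ab$query, ab$subject) %in% paste(ba$subject, ba$query)
    ab_kept <- ab[recip, , drop = FALSE]
    ba_kept <- ba[paste(ba$subject, ba$query) %in%
                    paste(ab$query, ab$subject), , drop = FALSE]
  } else {
    ab_kept <- ab; ba_kept <- ba
  }
  v_ab <- if (nrow(ab_kept)) 100 * mean(ab_kept$identity) else NA_real_
  v_ba <- if (nrow(ba_kept)) 100 * mean(ba_kept$identity) else NA_real_
  list(aai = max(v_ab, v_ba, na.rm = TRUE), ab = v_ab, ba = v_ba,
       pairs = ab_kept)
}

#' GC content at third codon positions
#'
#' Sequences are trimmed to whole codons (stop codon included); ambiguous
#' bases are excluded from both numerator and denominator.
#'
#' @param cds character vector of coding sequences.
#' @return GC3 as a percentage.
#' @export
gc3 <- function(cds) {
  g <- 0; tot <- 0
  for (s in cds) {
    s <- toupper(s)
    n <- (nchar(s) %/% 3) * 3
    if (n < 3) stop("sequence shorter than one codon")
    third <- strsplit(substr(s, 1, n), "")[[1]][seq(3, n, by = 3)]
    third <- third[third %in% c("A", "C", "G", "T")]
    g <- g + sum(third %in% c("G", "C"))
    tot <- tot + length(third)
  }
  100 * g / tot
}

#' Pairwise identity of two pre-aligned sequences
#'
#' Columns where both sequences carry a gap are excluded; a gap against a
#' base counts as a mismatch.
#'
#' @param a,b equal-length gapped sequences.
#' @return identity as a percentage.
#' @export
seq_identity_aligned <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  gap <- function(z) z %in% c("-", ".")
  keep <- !(gap(x) & gap(y))
  100 * sum(x[keep] == y[keep] & !gap(x[keep])) / sum(keep)
}

#' Annotated pairwise-identity table
#'
#' Labels each strain pair by taxonomic relationship (same clade, same
#' sub-cluster but different clade, different sub-cluster) and flags the
#' descriptive thresholds (AAI 80% intra-clade discontinuity; AAI 65% +
#' 16S 98% inter-sub-cluster discontinuity) as annotations.
#'
#' @param identities data.frame with columns `strain1`, `strain2` and any
#'   of `ani`, `aai`, `identity_16s` (percent).
#' @param metadata data.frame with `strain`, `clade`, `sub_cluster`.
#' @return the input with `relationship`, `flag_intra_clade_aai80`,
#'   `flag_inter_sc` columns added.
#' @export
pair_table <- function(identities, metadata) {
  if (!nrow(identities)) {
    identities$relationship <- character(0)
    return(identities)
  }
  md <- function(s, col) metadata[[col]][match(s, metadata$strain)]
  same_clade <- md(identities$strain1, "clade") == md(identities$strain2, "clade")
  same_sc <- if ("sub_cluster" %in% names(metadata))
    md(identities$strain1, "sub_cluster") == md(identities$strain2, "sub_cluster")
  else rep(NA, nrow(identities))
  identities$relationship <- ifelse(same_clade, "same_clade",
                                    ifelse(same_sc %in% TRUE,
                                           "same_sc_different_clade",
                                           "different_sc"))
  if ("aai" %in% names(identities)) {
    identities$flag_intra_clade_aai80 <- same_clade & identities$aai >= 80
    if ("identity_16s" %in% names(identities))
      identities$flag_inter_sc <- identities$aai < 65 & identities$identity_16s < 98
  }
  identities
}
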
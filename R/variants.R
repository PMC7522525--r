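#' Amino-acid variants specific to a strain set
#'
#' A column of a core-protein alignment carries a set-specific variant when
#' every strain of the set shows one and the same residue and every other
#' strain shows a different one. Columns containing gaps are handled by
#' `gap_policy`: `"exclude_column"` (default, conservative) skips any
#' column with a gap in any strain; `"gap_as_state"` treats the gap as a
#' 21st state that may satisfy "any other amino acid" outside the set but
#' can never be the set residue.
#'
#' @param alignments a `core_alignment_set`.
#' @param strain_set non-empty proper subset of the aligned strains.
#' @param gap_policy `"exclude_column"` or `"gap_as_state"`.
#' @return data.frame with `clog`, `column` (1-based), `residue` and
#'   `outside_residues` (residues seen outside the set, collapsed).
#' @export
specific_variants <- function(alignments, strain_set,
                              gap_policy = c("exclude_column", "gap_as_state")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(alignments, "core_alignment_set"))
  strain_set <- unique(strain_set)
  if (!length(strain_set)) stop("strain_set is empty")
  unknown <- setdiff(strain_set, alignments$strains)
  if (length(unknown)) stop("unknown strains: ", paste(unknown, collapse = ", "))
  outside_strains <- setdiff(alignments$strains, strain_set)
  if (!length(outside_strains)) stop("complement empty: strain_set is all strains")
  recs <- list()
  for (clog in names(alignments$alignments)) {
    a <- alignments$alignments[[clog]]
    mat <- do.call(rbind, strsplit(a[alignments$strains], ""))
    rownames(mat) <- alignments$strains
    inside <- mat[strain_set, , drop = FALSE]
    outside <- mat[outside_strains, , drop = FALSE]
    is_gap <- function(x) x %in% c("-", ".")
    for (j in seq_len(ncol(mat))) {
      ci <- inside[, j]; co <- outside[, j]
      if (gap_policy == "exclude_column") {
        if (any(is_gap(c(ci, co)))) next
      } else {
        if (any(is_gap(ci))) next  # the set residue can never be a gap
      }
      if (length(unique(ci)) != 1L) next
      r <- ci[1]
      if (r %in% co) next
      recs[[length(recs) + 1L]] <- data.frame(
        clog = clog, column = j, residue = r,
        outside_residues = paste(sort(unique(co)), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(clog = character(0), column = integer(0),
                      residue = character(0), outside_residues = character(0)))
  do.call(rbind, recs)
}

#' Node-fixed amino-acid variants
#'
#' Applies the set-specific variant definition with the strain set equal to
#' the leaves below each internal node. Terminal branches are not
#' considered (a strain-specific residue is not fixed), and neither is the
#' root (its complement is empty).
#'
#' @param alignments a `core_alignment_set`.
#' @param tree tree whose leaves are the aligned strains.
#' @param gap_policy passed to [specific_variants()].
#' @return named list (internal node label -> [specific_variants()] table).
#' @export
fixed_variants_per_node <- function(alignments, tree,
                                    gap_policy = "exclude_column") {
  ntip <- length(tree$tip.label)
  labels <- node_labels(tree)
  desc <- descendant_tips(tree)
  out <- list()
  for (v in ntip + seq_len(tree$Nnode)) {
    below <- tree$tip.label[desc[[v]]]
    if (length(below) == length(alignments$strains)) next  # root
    out[[labels[v]]] <- specific_variants(alignments, below,
                                          gap_policy = gap_policy)
  }
  out
}

#' Per-protein specific-variant densities for several strain sets
#'
#' Counts set-specific variants per protein, normalises by alignment
#' length, and ranks proteins within each set by density (rank 1 =
#' densest; ties get average ranks).
#'
#' @param alignments a `core_alignment_set`.
#' @param sets named list (set id -> strain vector).
#' @param gap_policy passed to [specific_variants()].
#' @return named list of data.frames (`clog`, `n`, `length`, `density`,
#'   `rank`), one per set.
#' @export
variant_scores <- function(alignments, sets, gap_policy = "exclude_column") {
  clogs <- names(alignments$alignments)
  lens <- alignments$lengths
  out <- list()
  for (set_id in names(sets)) {
    sv <- specific_variants(alignments, sets[[set_id]], gap_policy = gap_policy)
    n <- vapply(clogs, function(cl) sum(sv$clog == cl), numeric(1))
    df <- data.frame(clog = clogs, n = n, length = as.numeric(lens),
                     density = n / as.numeric(lens), stringsAsFactors = FALSE)
    df$rank <- rank(-df$density, ties.method = "average")
    rownames(df) <- NULL
    out[[set_id]] <- df
  }
  out
}

#' Rank-ratio screen for focal-set candidate proteins
#'
#' For each protein, the ratio of its density rank in the focal set to the
#' median of its ranks in the background sets; proteins with ratio below
#' `cutoff` (i.e. ranked about three times higher in the focal set at the
#' default 0.33) are candidates. Background sets corresponding to a single
#' strain are excluded by the caller or via `sets`.
#'
#' @param scores result of [variant_scores()].
#' @param focal_set name of the focal set in `scores`.
#' @param background_sets names of background sets (>= 2 required).
#' @param cutoff rank-ratio cutoff (default 0.33).
#' @return data.frame of candidates (`clog`, `n`, `length`, `density`,
#'   `rank_focal`, `median_rank_background`, `rank_ratio`), sorted by
#'   density, plus the full table as attribute `all`.
#' @export
rank_ratio_screen <- function(scores, focal_set, background_sets,
                              cutoff = 0.33) {
  if (!focal_set %in% names(scores)) stop("unknown focal set: ", focal_set)
  background_sets <- setdiff(background_sets, focal_set)
  if (length(background_sets) < 2) stop("need >= 2 background sets")
  foc <- scores[[focal_set]]
  bg_ranks <- sapply(background_sets, function(s)
    scores[[s]]$rank[match(foc$clog, scores[[s]]$clog)])
  med_bg <- apply(as.matrix(bg_ranks), 1, stats::median)
  tab <- data.frame(clog = foc$clog, n = foc$n, length = foc$length,
                    density = foc$density, rank_focal = foc$rank,
                    median_rank_background = med_bg,
                    rank_ratio = foc$rank / med_bg, stringsAsFactors = FALSE)
  cand <- tab[tab$rank_ratio < cutoff, , drop = FALSE]
  cand <- cand[order(-cand$density), , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "all") <- tab
  cand
}

#' Render a candidate-variant report
#'
#' Sorted by density (descending), with the count and length rendered in
#' the conventional "n/length" form.
#'
#' @param candidates data.frame from [rank_ratio_screen()].
#' @param annotations optional named character vector (CLOG -> description).
#' @return data.frame with a `label` column (e.g. "7/347").
#' @export
variant_report <- function(candidates, annotations = NULL) {
  if (!nrow(candidates))
    return(data.frame(clog = character(0), label = character(0),
                      density = numeric(0), rank_ratio = numeric(0),
                      description = character(0)))
  df <- candidates[order(-candidates$density), , drop = FALSE]
  data.frame(clog = df$clog,
             label = sprintf("%d/%d", as.integer(df$n), as.integer(df$length)),
             density = df$density, rank_ratio = df$rank_ratio,
             description = if (is.null(annotations)) NA_character_ else
               unname(annotations[df$clog]),
             stringsAsFactors = FALSE)
}
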
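#' Calibration point
#'
#' @param node internal node id (label) carrying the calibration.
#' @param min,max age interval in My, `0 <= min < max` (equal min and max
#'   pin the node age exactly).
#' @return data.frame row usable in a calibration table.
#' @export
calibration <- function(node, min, max) {
  if (min < 0 || max < min) stop("need 0 <= min <= max")
  data.frame(node = node, min = min, max = max, stringsAsFactors = FALSE)
}

#' Simplified relative-time calibration of a tree
#'
#' A deliberately simple substitute for full relative-rate dating, adequate
#' when only branch durations are needed downstream: (1) each internal
#' node gets a relative depth equal to the mean path length from the node
#' to its descendant leaves; (2) parent-above-child monotonicity is
#' enforced by upward max-propagation; (3) a least-squares scale factor
#' maps relative depths onto the calibrated ages, constrained into the
#' calibration intervals (the feasible-range endpoint closest to the
#' least-squares optimum is used when the optimum falls outside). Supplying
#' a real chronogram is the recommended alternative whenever one exists.
#'
#' @param tree tree with substitutions/site branch lengths.
#' @param calibrations data.frame with columns `node`, `min`, `max` (rows
#'   from [calibration()]).
#' @return ultrametric chronogram (unit My) with node ages scaled into the
#'   calibration intervals.
#' @export
calibrate_relative <- function(tree, calibrations) {
  if (nrow(calibrations) < 1) stop("need at least one calibration")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- descendant_tips(tree)
  depth <- ape::node.depth.edgelength(tree)  # root -> node path lengths
  rel <- numeric(nnode)
  for (v in ntip + seq_len(tree$Nnode))
    rel[v] <- mean(depth[desc[[v]]]) - depth[v]
  # upward max-propagation: a parent must be at least as deep as any child
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    rel[p] <- max(rel[p], rel[ch])
  }
  cal_nodes <- resolve_nodes(tree, calibrations$node)
  r <- rel[cal_nodes]
  if (any(r <= 0)) stop("calibrated node has zero relative depth")
  mid <- (calibrations$min + calibrations$max) / 2
  s_ls <- sum(r * mid) / sum(r * r)
  lo <- max(calibrations$min / r)
  hi <- min(calibrations$max / r)
  if (lo > hi)
    stop("contradictory calibrations: no scale satisfies all intervals ",
         "(feasible range [", signif(lo, 6), ", ", signif(hi, 6),
         "] is empty; relative depths ", paste(signif(r, 6), collapse = ", "), ")")
  s <- min(max(s_ls, lo), hi)
  ages <- rel * s
  chrono <- tree
  chrono$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  attr(chrono, "unit") <- "My"
  chrono
}

#' Per-branch substitution counts
#'
#' Converts substitutions/site branch lengths into absolute substitution
#' counts by multiplying by the total number of aligned residues.
#'
#' @param tree substitutions/site tree.
#' @param total_residues total alignment length (e.g. 226778 for an
#'   821-protein concatenation).
#' @return data.frame with `child_label`, `terminal`, `subs` (real-valued).
#' @export
substitutions_per_branch <- function(tree, total_residues) {
  if (total_residues <= 0) stop("total_residues must be > 0")
  br <- tree_branches(tree)
  data.frame(child_label = br$child_label, terminal = br$terminal,
             subs = br$length * total_residues, stringsAsFactors = FALSE)
}

#' Through-origin rate regression
#'
#' Ordinary least squares of per-branch event counts on branch durations
#' with no intercept (a zero-duration branch must carry zero expected
#' events). The slope is the rate per My; the adjusted R-squared is
#' computed about zero, as is standard for the no-intercept model.
#'
#' @param counts per-branch event counts.
#' @param durations matching branch durations (My).
#' @return list with `slope`, `se`, `adj_r2`, `p`, `n`.
#' @export
rate_regression <- function(counts, durations) {
  if (length(counts) != length(durations)) stop("length mismatch")
  if (length(counts) < 3) stop("insufficient branches (need >= 3)")
  if (all(counts == 0))
    return(list(slope = 0, se = 0, adj_r2 = NA_real_, p = 1, n = length(counts)))
  fit <- stats::lm(counts ~ 0 + durations)
  sm <- suppressWarnings(summary(fit))  # a perfect fit warns harmlessly
  co <- sm$coefficients
  list(slope = unname(co[1, 1]), se = unname(co[1, 2]),
       adj_r2 = sm$adj.r.squared, p = unname(co[1, 4]), n = length(counts))
}

#' Fixation-rate regression over internal branches
#'
#' Each internal branch is paired with the number of items (genes or
#' amino-acid variants) fixed at its child node, and regressed through the
#' origin on branch durations. Terminal branches carry no fixation counts
#' by definition (a strain-specific item is not fixed), so only internal
#' branches enter.
#'
#' @param fixed_counts named vector (internal node label -> count of fixed
#'   items at that node).
#' @param tree chronogram (My).
#' @return list as [rate_regression()] plus the per-branch table used.
#' @export
fixation_rate_regression <- function(fixed_counts, tree) {
  br <- tree_branches(tree)
  br <- br[!br$terminal, , drop = FALSE]
  counts <- fixed_counts[br$child_label]
  counts[is.na(counts)] <- 0
  res <- rate_regression(as.numeric(counts), br$length)
  res$branches <- data.frame(child_label = br$child_label,
                             duration = br$length,
                             fixed = as.numeric(counts),
                             stringsAsFactors = FALSE)
  res
}

#' Assemble a per-My rate table
#'
#' Runs the through-origin regressions for gene gains, gene losses,
#' amino-acid substitutions (internal and terminal branches separately)
#' and, over internal branches only, specific gene and variant fixation,
#' mirroring the category x branch-class layout of time-calibrated rate
#' summaries.
#'
#' @param events a `branch_events` object.
#' @param chronogram tree with branch durations in My.
#' @param subs optional result of [substitutions_per_branch()].
#' @param fixed_genes optional result of [fixed_genes_per_node()].
#' @param fixed_variants optional result of [fixed_variants_per_node()].
#' @return data.frame with columns `category`, `branch_class`, `rate`,
#'   `se`, `adj_r2`, `p`, `n`.
#' @export
rate_table <- function(events, chronogram, subs = NULL,
                       fixed_genes = NULL, fixed_variants = NULL) {
  br <- tree_branches(chronogram)
  ev <- events$per_branch[match(br$child_label, events$per_branch$child_label), ]
  rows <- list()
  add <- function(category, branch_class, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, branch_class = branch_class,
      rate = res$slope, se = res$se, adj_r2 = res$adj_r2, p = res$p, n = res$n,
      stringsAsFactors = FALSE)
  }
  for (cls in c("internal", "terminal")) {
    sel <- if (cls == "terminal") br$terminal else !br$terminal
    add("gene_gain", cls, rate_regression(ev$n_gained[sel], br$length[sel]))
    add("gene_loss", cls, rate_regression(ev$n_lost[sel], br$length[sel]))
    if (!is.null(subs)) {
      s <- subs$subs[match(br$child_label[sel], subs$child_label)]
      add("aa_substitution", cls, rate_regression(s, br$length[sel]))
    }
  }
  if (!is.null(fixed_genes))
    add("specific_gene_fixation", "internal",
        fixation_rate_regression(vapply(fixed_genes, length, numeric(1)),
                                 chronogram))
  if (!is.null(fixed_variants))
    add("specific_aa_fixation", "internal",
        fixation_rate_regression(vapply(fixed_variants, nrow, numeric(1)),
                                 chronogram))
  do.call(rbind, rows)
}
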
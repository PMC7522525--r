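#' Jaccard distances between strains' gene-family repertoires
#'
#' Binary Jaccard distance `1 - |F_i inter F_j| / |F_i union F_j|` over
#' family presence sets, computed with [vegan::vegdist()]. With
#' `scope = "non_core"` families present in every strain are excluded
#' first (they inflate intersections and unions equally and only compress
#' distances uniformly).
#'
#' @param pattern a [phyletic_pattern()].
#' @param scope `"all_families"` or `"non_core"`.
#' @return symmetric distance matrix (strain x strain), zero diagonal.
#' @export
phyletic_distances <- function(pattern, scope = c("all_families", "non_core")) {
  scope <- match.arg(scope)
  pres <- presence_matrix(pattern)
  if (scope == "non_core") pres <- pres[, colSums(pres) < nrow(pres), drop = FALSE]
  if (any(rowSums(pres) == 0))
    stop("strain with zero families: ",
         paste(rownames(pres)[rowSums(pres) == 0], collapse = ", "))
  as.matrix(vegan::vegdist(pres, method = "jaccard", binary = TRUE))
}

#' Neighbour-joining tree from a distance matrix, with column bootstrap
#'
#' Standard NJ ([ape::nj()]). Bootstrap replicates resample the CLOG
#' columns of the binary pattern with replacement, recompute the Jaccard
#' distances and rebuild the NJ tree; supports are the percentage of
#' replicates recovering each bipartition.
#'
#' @param dist symmetric distance matrix.
#' @param pattern the [phyletic_pattern()] behind `dist` (needed for
#'   bootstrapping; `NULL` skips supports).
#' @param bootstrap number of replicates (default 100).
#' @param seed optional integer seed.
#' @param scope passed to [phyletic_distances()] for the replicates.
#' @return list with `tree` (unrooted [ape::phylo]) and `support`
#'   (per-internal-node percentages, `NULL` without a pattern).
#' @export
nj_tree <- function(dist, pattern = NULL, bootstrap = 100, seed = NULL,
                    scope = "all_families") {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8)) stop("non-symmetric matrix")
  tree <- ape::nj(stats::as.dist(dist))
  support <- NULL
  if (!is.null(pattern) && bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    pres <- presence_matrix(pattern)
    if (scope == "non_core") pres <- pres[, colSums(pres) < nrow(pres), drop = FALSE]
    boots <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      cols <- sample.int(ncol(pres), replace = TRUE)
      pb <- pres[, cols, drop = FALSE]
      keep <- rowSums(pb) > 0
      db <- vegan::vegdist(pb, method = "jaccard", binary = TRUE)
      boots[[b]] <- ape::nj(db)
    }
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- 100 * counts / bootstrap
  }
  list(tree = tree, support = support)
}

#' Internal nodes at the base of metadata clades
#'
#' For each clade with at least two strains on the tree, the MRCA of its
#' strains (whether or not the clade is monophyletic).
#'
#' @param tree an [ape::phylo] tree.
#' @param metadata data.frame with `strain` and the grouping column.
#' @param level metadata column to use.
#' @param exclude_root drop clades whose MRCA is the root (the root has no
#'   parent branch, so no ratio is defined there).
#' @return named integer vector (clade -> ape node number).
#' @export
clade_base_nodes <- function(tree, metadata, level = "clade",
                             exclude_root = TRUE) {
  groups <- split(metadata$strain, metadata[[level]])
  out <- integer(0)
  root <- length(tree$tip.label) + 1L
  for (g in names(groups)) {
    tips <- intersect(groups[[g]], tree$tip.label)
    if (length(tips) < 2) next
    node <- ape::getMRCA(tree, tips)
    if (exclude_root && node == root) next
    out[g] <- node
  }
  out
}

#' External/internal branch-length ratios at clade-base nodes
#'
#' For each node: external length = mean path length from the node to its
#' descendant leaves; internal length = the node's parent branch length;
#' ratio = external / internal.
#'
#' @param tree an [ape::phylo] tree.
#' @param nodes named vector of node ids (labels or ape numbers), e.g.
#'   from [clade_base_nodes()].
#' @return data.frame with `node`, `external`, `internal`, `ratio`.
#' @export
branch_ratio_analysis <- function(tree, nodes) {
  num <- resolve_nodes(tree, nodes)
  root <- length(tree$tip.label) + 1L
  if (any(num == root)) stop("root has no parent edge")
  depth <- ape::node.depth.edgelength(tree)
  desc <- descendant_tips(tree)
  external <- vapply(num, function(v) mean(depth[desc[[v]]]) - depth[v],
                     numeric(1))
  internal <- tree$edge.length[match(num, tree$edge[, 2])]
  data.frame(node = if (is.null(names(nodes))) as.character(nodes) else names(nodes),
             external = external, internal = internal,
             ratio = external / internal, stringsAsFactors = FALSE)
}

#' Paired signed-rank test on branch ratio records
#'
#' Wilcoxon signed-rank test (the standard paired rank test, sometimes
#' loosely called a paired Mann-Whitney test) on per-node differences of
#' external/internal ratios between two trees, paired by node id. Zero
#' differences are dropped; for n <= 25 the exact null distribution of the
#' statistic is built by convolution over the (possibly tied, average)
#' ranks, above that a normal approximation with continuity correction is
#' used.
#'
#' @param core_records,phyletic_records data.frames from
#'   [branch_ratio_analysis()] sharing the same node ids.
#' @return list with `statistic` (V), `p_value` (two-sided), `direction`
#'   (sign of the median difference phyletic - core) and `n`.
#' @export
paired_ratio_test <- function(core_records, phyletic_records) {
  unpaired <- c(setdiff(core_records$node, phyletic_records$node),
                setdiff(phyletic_records$node, core_records$node))
  if (length(unpaired)) stop("unpaired node: ", paste(unpaired, collapse = ", "))
  ph <- phyletic_records$ratio[match(core_records$node, phyletic_records$node)]
  co <- core_records$ratio
  d <- ph - co
  if (all(d == 0))
    return(list(statistic = 0, p_value = 1, direction = 0, n = length(d)))
  nz <- d[d != 0]
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (length(nz) <= 25) {
    # exact signed-rank null by convolution over 2 * ranks (average ranks
    # are half-integers), valid with ties
    w <- as.integer(round(2 * r))
    dist <- 1
    for (wi in w) {
      shifted <- c(rep(0, wi), dist)
      dist <- c(dist, rep(0, wi)) + shifted
    }
    dist <- dist / sum(dist)
    v2 <- as.integer(round(2 * v))
    p_hi <- sum(dist[(v2 + 1):length(dist)])
    p_lo <- sum(dist[1:(v2 + 1)])
    p <- min(1, 2 * min(p_hi, p_lo))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(ph, co, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    p <- wt$p.value
  }
  list(statistic = v, p_value = p,
       direction = sign(stats::median(d)), n = length(d))
}

#' Topological discordance between two trees
#'
#' Robinson-Foulds distance plus a per-clade monophyly report: which
#' metadata clades are monophyletic in each tree, and which lose their
#' monophyly in tree B (the classic signature of lineages mixed by gene
#' content despite a clean core phylogeny).
#'
#' @param treeA,treeB trees on the same leaf set.
#' @param metadata data.frame with `strain` and `clade` columns.
#' @param level metadata column to use.
#' @return list with `rf`, `monophyly` (clade x tree logical data.frame),
#'   `discordant` (clades monophyletic in A but not B).
#' @export
tree_discordance <- function(treeA, treeB, metadata, level = "clade") {
  extraA <- setdiff(treeA$tip.label, treeB$tip.label)
  extraB <- setdiff(treeB$tip.label, treeA$tip.label)
  if (length(extraA) || length(extraB))
    stop("leaf-set mismatch; only in A: [", paste(extraA, collapse = ", "),
         "]; only in B: [", paste(extraB, collapse = ", "), "]")
  rf <- phangorn::RF.dist(ape::unroot(treeA), ape::unroot(treeB))
  groups <- split(metadata$strain, metadata[[level]])
  groups <- lapply(groups, intersect, treeA$tip.label)
  groups <- groups[lengths(groups) >= 2]
  monoA <- vapply(groups, function(tips) ape::is.monophyletic(treeA, tips),
                  logical(1))
  monoB <- vapply(groups, function(tips) ape::is.monophyletic(treeB, tips),
                  logical(1))
  list(rf = rf,
       monophyly = data.frame(clade = names(groups), treeA = monoA,
                              treeB = monoB, row.names = NULL,
                              stringsAsFactors = FALSE),
       discordant = names(groups)[monoA & !monoB])
}
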
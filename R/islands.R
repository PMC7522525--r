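#' Detect genomic islands as gained-gene-enriched regions
#'
#' Sliding windows (`window` bp wide, every `step` bp) move along the
#' genome; a window qualifies when the ratio of coding nucleotides
#' belonging to gained CDS to all coding nucleotides inside the window
#' (both clipped to the window) exceeds `ratio_threshold`. Windows with no
#' coding nucleotides never qualify. Maximal runs of consecutive
#' qualifying windows are merged into candidate regions; each region is
#' trimmed inward so that its first and last genes are full-length gained
#' genes, and regions with fewer than `min_genes` genes are dropped. On a
#' circular genome the windows wrap and an island may span the origin (it
#' is then reported with `end < start` and `wrap = TRUE`).
#'
#' @param genome an [annotated_genome()]; the `gained` flag may be preset
#'   or supplied via `gained`.
#' @param gained optional character vector of gained CLOG ids (overrides
#'   the genome's `gained` column).
#' @param window window size in bp (default 10000).
#' @param step window spacing in bp (default 100).
#' @param ratio_threshold qualifying gained-coding ratio (default 0.5,
#'   strictly exceeded).
#' @param min_genes smallest reported island (default 2: a single gene
#'   cannot both start and finish an island).
#' @return list of islands, each a list with `strain`, `id` (GI001, ...),
#'   `first_gene`, `last_gene` (feature indices), `start`, `end` (bp,
#'   1-based inclusive), `clogs`, `gained_clogs`, `wrap`.
#' @export
detect_islands <- function(genome, gained = NULL, window = 10000, step = 100,
                           ratio_threshold = 0.5, min_genes = 2) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (window < step) stop("window must be >= step")
  f <- genome$features
  if (nrow(f) == 0) return(list())
  if (!is.null(gained)) f$gained <- f$clog %in% gained
  L <- as.integer(genome$length)
  # per-bp coding indicators; overlapping CDS count once
  coding <- integer(L); gainedbp <- integer(L)
  for (i in seq_len(nrow(f))) {
    coding[f$start[i]:f$end[i]] <- 1L
    if (isTRUE(f$gained[i])) gainedbp[f$start[i]:f$end[i]] <- 1L
  }
  if (genome$circular) {
    coding2 <- c(coding, coding); gained2 <- c(gainedbp, gainedbp)
    starts <- seq(1L, L, by = step)
  } else {
    coding2 <- coding; gained2 <- gainedbp
    starts <- seq(1L, max(1L, L - window + 1L), by = step)
  }
  ccum <- c(0, cumsum(coding2)); gcum <- c(0, cumsum(gained2))
  ends <- pmin(starts + window - 1L, length(coding2))
  ctot <- ccum[ends + 1L] - ccum[starts]
  gtot <- gcum[ends + 1L] - gcum[starts]
  ok <- ctot > 0 & (gtot / pmax(ctot, 1)) > ratio_threshold
  if (!any(ok)) return(list())
  # maximal runs of consecutive qualifying windows
  runs <- rle(ok)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  regions <- data.frame(start = starts[idx_start[runs$values]],
                        end = ends[idx_end[runs$values]])
  # separate runs can span overlapping intervals (window >> step): merge
  regions <- regions[order(regions$start), , drop = FALSE]
  merged <- regions[1, , drop = FALSE]
  for (k in seq_len(nrow(regions))[-1]) {
    if (regions$start[k] <= merged$end[nrow(merged)] + 1L)
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], regions$end[k])
    else merged <- rbind(merged, regions[k, ])
  }
  regions <- merged
  if (genome$circular) {
    # merge a run reaching the duplicated copy back onto the origin
    regions$start <- ((regions$start - 1L) %% L) + 1L
    regions$end <- ((regions$end - 1L) %% L) + 1L
  }
  islands <- list()
  for (k in seq_len(nrow(regions))) {
    rs <- regions$start[k]; re <- regions$end[k]
    wrap <- genome$circular && re < rs
    inside <- if (wrap) (f$end >= rs | f$start <= re) else
      (f$end >= rs & f$start <= re)
    idx <- which(inside)
    if (wrap) {  # rotate so the island is contiguous in gene order
      first_half <- idx[f$start[idx] >= rs | f$end[idx] >= rs]
      idx <- c(sort(first_half), sort(setdiff(idx, first_half)))
    }
    # trim inward to full-length gained boundary genes
    good <- f$gained[idx] & f$full_length[idx]
    if (!any(good)) next
    idx <- idx[min(which(good)):max(which(good))]
    if (length(idx) < min_genes) next
    islands[[length(islands) + 1L]] <- list(
      strain = genome$strain,
      first_gene = idx[1], last_gene = idx[length(idx)],
      start = f$start[idx[1]], end = f$end[idx[length(idx)]],
      clogs = f$clog[idx],
      gained_clogs = f$clog[idx][f$gained[idx]],
      wrap = genome$circular && f$start[idx[length(idx)]] < f$start[idx[1]])
  }
  for (k in seq_along(islands)) islands[[k]]$id <- sprintf("GI%03d", k)
  islands
}

#' Jaccard similarity of two islands' gene content
#'
#' Fraction of the pooled gene content shared:
#' `|A intersect B| / |A union B|` over member CLOG sets.
#'
#' @param a,b islands from [detect_islands()].
#' @return similarity in `[0, 1]`.
#' @export
island_similarity <- function(a, b) {
  if (!length(a$clogs) || !length(b$clogs)) stop("empty island")
  length(intersect(a$clogs, b$clogs)) / length(union(a$clogs, b$clogs))
}

#' Build the inter-strain island-sharing network
#'
#' Nodes are (strain, island) pairs; an edge connects two islands of
#' different strains when they share at least `edge_threshold` of their
#' pooled gene content. Edges carry the Jaccard similarity (width
#' attribute in the exported network) and the patristic distance between
#' the two strains on the core-protein tree (colour attribute). Isolated
#' islands are retained as singleton nodes.
#'
#' @param islands flat list of islands (possibly from several strains).
#' @param core_tree core-protein tree containing every island's strain.
#' @param edge_threshold minimum similarity for an edge (default 0.1).
#' @return object of class `island_network`: `graph` (igraph) and the
#'   island list.
#' @export
build_network <- function(islands, core_tree, edge_threshold = 0.1) {
  strains <- unique(vapply(islands, `[[`, character(1), "strain"))
  missing <- setdiff(strains, core_tree$tip.label)
  if (length(missing)) stop("strain missing from tree: ",
                            paste(missing, collapse = ", "))
  pd <- ape::cophenetic.phylo(core_tree)
  ids <- vapply(islands, function(x) paste0(x$strain, ":", x$id), character(1))
  n <- length(islands)
  from <- integer(0); to <- integer(0); jac <- numeric(0); dist <- numeric(0)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (islands[[i]]$strain == islands[[j]]$strain) next
    s <- island_similarity(islands[[i]], islands[[j]])
    if (s >= edge_threshold) {
      from <- c(from, i); to <- c(to, j); jac <- c(jac, s)
      dist <- c(dist, pd[islands[[i]]$strain, islands[[j]]$strain])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "strain", value = vapply(islands, `[[`,
                                                           character(1), "strain"))
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    g <- igraph::set_edge_attr(g, "jaccard", value = jac)
    g <- igraph::set_edge_attr(g, "patristic_distance", value = dist)
  }
  structure(list(graph = g, islands = islands), class = "island_network")
}

#' Detect modules in an island network
#'
#' Louvain greedy modularity optimisation on the similarity-weighted
#' graph. The resolution parameter scales the null-model term of the
#' modularity (values below 1 favour coarser modules). Node processing
#' order is fixed by sorted node ids, and the seed pins igraph's internal
#' randomisation, so the assignment is deterministic given the seed.
#'
#' @param network an `island_network` (or a bare igraph graph).
#' @param resolution modularity resolution (default 0.2).
#' @param seed integer seed.
#' @return named integer vector: node id -> module id. Empty graph gives
#'   an empty assignment.
#' @export
detect_modules <- function(network, resolution = 0.2, seed = 1) {
  g <- if (inherits(network, "island_network")) network$graph else network
  if (igraph::vcount(g) == 0) return(stats::setNames(integer(0), character(0)))
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  set.seed(seed)
  w <- igraph::E(g)$jaccard
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
  stats::setNames(as.integer(igraph::membership(cl)), igraph::V(g)$name)
}

#' Flatten an island list to a table
#'
#' @param islands list of islands from [detect_islands()].
#' @param modules optional module assignment from [detect_modules()].
#' @return data.frame, one row per island (CLOGs comma-collapsed).
#' @export
islands_to_df <- function(islands, modules = NULL) {
  if (!length(islands))
    return(data.frame(strain = character(0), id = character(0)))
  df <- do.call(rbind, lapply(islands, function(x) data.frame(
    strain = x$strain, id = x$id, first_gene = x$first_gene,
    last_gene = x$last_gene, start = x$start, end = x$end,
    n_genes = length(x$clogs), n_gained = length(x$gained_clogs),
    wrap = x$wrap, clogs = paste(x$clogs, collapse = ","),
    stringsAsFactors = FALSE)))
  if (!is.null(modules))
    df$module <- modules[paste0(df$strain, ":", df$id)]
  df
}
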
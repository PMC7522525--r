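#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The generator
#' emulates the statistical structure the downstream analyses assume: gene
#' content evolving by gains and losses along a known chronogram, recently
#' gained genes partly clustered into contiguous island loci, single-copy
#' core alignments carrying planted clade-specific residues, and
#' divergence-controlled nucleotide pairs. Defaults describe a modest
#' picocyanobacteria-like radiation: a few-hundred-My-old tree of clades,
#' ~2,000 ancestral families, slow per-family loss and a steady trickle of
#' new families, most of which are therefore observed near the tips.
#'
#' @param n_strains number of strains (ignored when `clades` is given).
#' @param clades named list (clade -> strain ids) partitioning the strains;
#'   by default four clades of equal size.
#' @param newick optional fixed newick string for the chronogram (branch
#'   lengths in My); when given, tree shape parameters are ignored.
#' @param root_age root age in My.
#' @param n0 number of gene families present at the root.
#' @param gain_rate gains per My per branch (Poisson intensity `g * t`).
#' @param loss_rate per-family loss rate per My (loss probability
#'   `1 - exp(-l * t)` per branch).
#' @param subs_rate substitutions per site per My for the companion
#'   substitutions tree.
#' @param rate_sigma sdlog of the lognormal per-branch rate multiplier
#'   (mean 1); 0 gives a strict clock.
#' @param islands_per_strain planted islands per strain.
#' @param island_min,island_max genes per planted island.
#' @param cds_len,cds_sd mean/sd of CDS length (bp).
#' @param gap_len,gap_sd mean/sd of intergenic gap length (bp).
#' @param n_core_families number of simulated single-copy core families.
#' @param len_min,len_max alignment length range (residues).
#' @param target_sets named list (set id -> strain ids) receiving planted
#'   set-specific columns; each set must be a union of clades. Default:
#'   one set per clade.
#' @param planted_per_set planted specific columns per target set.
#' @param seed mandatory integer seed; all stages derive deterministic
#'   substreams from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 24, clades = NULL, newick = NULL,
                       root_age = 800, n0 = 2000,
                       gain_rate = 4, loss_rate = 1e-3,
                       subs_rate = 5e-4, rate_sigma = 0.3,
                       islands_per_strain = 2, island_min = 5, island_max = 10,
                       cds_len = 900, cds_sd = 0, gap_len = 100, gap_sd = 0,
                       n_core_families = 20, len_min = 150, len_max = 400,
                       target_sets = NULL, planted_per_set = 5,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(clades)) {
    k <- max(2L, min(6L, n_strains %/% 6L + 2L))
    strains <- sprintf("S%02d", seq_len(n_strains))
    clades <- split(strains, rep(paste0("clade", LETTERS[seq_len(k)]),
                                 length.out = n_strains))
  }
  strains <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(strains)) stop("clades must partition strains (duplicate strain)")
  if (any(c(gain_rate, loss_rate, subs_rate, rate_sigma) < 0))
    stop("rates must be >= 0")
  if (is.null(newick) && length(strains) < 3) stop("need at least 3 strains")
  if (is.null(target_sets)) target_sets <- clades
  for (nm in names(target_sets)) {
    extra <- setdiff(target_sets[[nm]], strains)
    if (length(extra)) stop("target set ", nm, " has unknown strains")
    members <- vapply(clades, function(cl) any(cl %in% target_sets[[nm]]), logical(1))
    covered <- sort(unlist(clades[members], use.names = FALSE))
    if (!identical(sort(target_sets[[nm]]), covered))
      stop("target set ", nm, " is not a union of clades")
  }
  structure(list(
    strains = strains, clades = clades, newick = newick, root_age = root_age,
    n0 = n0, gain_rate = gain_rate, loss_rate = loss_rate,
    subs_rate = subs_rate, rate_sigma = rate_sigma,
    islands_per_strain = islands_per_strain,
    island_min = island_min, island_max = island_max,
    cds_len = cds_len, cds_sd = cds_sd, gap_len = gap_len, gap_sd = gap_sd,
    n_core_families = n_core_families, len_min = len_min, len_max = len_max,
    target_sets = target_sets, planted_per_set = planted_per_set,
    seed = as.integer(seed)), class = "sim_config")
}

# Internal: deterministic per-stage substream seed below 2^31.
stage_seed <- function(config, stage) {
  offset <- c(chronogram = 11L, content = 23L, layout = 37L,
              alignments = 51L, pair = 67L)[[stage]]
  (config$seed %% 1000000L) * 1000L + offset
}

# Internal: scale an ultrametric ape tree so its root age equals `age`.
scale_to_age <- function(tree, age) {
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (age / depth)
  tree
}

# Internal: push every internal node of an ultrametric tree up to at least
# `min_frac` of the root age (affine map on internal ages, tips stay at 0),
# so no terminal branch is vanishingly short.
lift_node_ages <- function(tree, min_frac = 0.15) {
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth) - depth
  ra <- max(age)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  age[internal] <- min_frac * ra + (1 - min_frac) * age[internal]
  tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  tree
}

# Internal: newick string (no trailing ";") for a clade subtree of given
# root age; single-strain clades are plain leaves with age 0.
clade_newick <- function(strains, age) {
  if (length(strains) == 1) return(list(str = strains, age = 0))
  sub <- scale_to_age(ape::rcoal(length(strains), tip.label = strains), age)
  sub <- lift_node_ages(sub)
  list(str = sub("；|;$", "", ape::write.tree(sub)), age = age)
}

#' Simulate a clade-structured chronogram and companion substitutions tree
#'
#' Clades are grafted as coalescent subtrees onto a pectinate backbone whose
#' join ages are spread between 60% of the root age and the root age, so
#' clades are monophyletic and old relative to within-clade divergences.
#' The companion tree shares the topology; each branch length is
#' `duration * subs_rate * m` with `m` lognormal (mean 1, sdlog
#' `rate_sigma`).
#'
#' @param config a [sim_config()].
#' @return list with `chronogram` (unit My, ultrametric) and `subs_tree`
#'   (unit substitutions/site).
#' @export
simulate_chronogram <- function(config) {
  set.seed(stage_seed(config, "chronogram"))
  if (!is.null(config$newick)) {
    chrono <- ape::read.tree(text = config$newick)
    if (is.null(chrono$edge.length)) stop("fixed newick needs branch lengths")
  } else {
    if (length(config$strains) < 3) stop("need at least 3 strains")
    clades <- config$clades
    k <- length(clades)
    clade_ages <- stats::runif(k, 0.25, 0.45) * config$root_age
    subs <- lapply(seq_len(k), function(i) clade_newick(clades[[i]], clade_ages[i]))
    if (k == 1) {
      chrono <- ape::read.tree(text = paste0(subs[[1]]$str, ";"))
    } else {
      # clades diverge in a rapid deep radiation: the balanced backbone's
      # joins are compressed into the oldest tenth of the tree's history
      depth_max <- ceiling(log2(k))
      step <- 0.1 * config$root_age / depth_max
      # recursive balanced join; each node returns (newick fragment, age)
      join <- function(idx, age) {
        if (length(idx) == 1) return(list(str = subs[[idx]]$str, age = subs[[idx]]$age))
        h <- ceiling(length(idx) / 2)
        a <- join(idx[seq_len(h)], age - step)
        b <- join(idx[-seq_len(h)], age - step)
        list(str = sprintf("(%s:%.10f,%s:%.10f)", a$str, age - a$age,
                           b$str, age - b$age),
             age = age)
      }
      chrono <- ape::read.tree(text = paste0(join(seq_len(k),
                                                  config$root_age)$str, ";"))
    }
  }
  chrono <- as_evo_tree(chrono, "My")
  subs_tree <- chrono
  m <- if (config$rate_sigma == 0) 1 else
    stats::rlnorm(nrow(chrono$edge), meanlog = -config$rate_sigma^2 / 2,
                  sdlog = config$rate_sigma)
  subs_tree$edge.length <- chrono$edge.length * config$subs_rate * m
  attr(subs_tree, "unit") <- "subs_per_site"
  list(chronogram = chrono, subs_tree = subs_tree)
}

#' Simulate gene content along a chronogram
#'
#' Each family present at a branch's parent is lost with probability
#' `1 - exp(-loss_rate * t)`; `Poisson(gain_rate * t)` brand-new families
#' appear on each branch (gains are irreversible: a family is gained once,
#' on one branch, so per-branch truth is unambiguous). Families seen in no
#' tip are not part of the emitted pattern (they are unobservable), but all
#' events remain in the truth log.
#'
#' @param tree chronogram (unit My) with node labels.
#' @param config a [sim_config()].
#' @return list with `pattern` ([phyletic_pattern()]) and `truth` (class
#'   `truth_log`: `root_families`, per-branch `events` keyed by child node
#'   label, and the `chronogram`).
#' @export
simulate_gene_content <- function(tree, config) {
  set.seed(stage_seed(config, "content"))
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  fam_counter <- config$n0
  fam_id <- function(i) sprintf("F%06d", i)
  present <- vector("list", ntip + tree$Nnode)
  present[[root]] <- fam_id(seq_len(config$n0))
  events <- list()
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  ord <- match(paste(edges[, 1], edges[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    t <- tree$edge.length[ord[k]]
    fams <- present[[p]]
    p_loss <- 1 - exp(-config$loss_rate * t)
    lost <- fams[stats::runif(length(fams)) < p_loss]
    kept <- setdiff(fams, lost)
    n_gain <- stats::rpois(1, config$gain_rate * t)
    gained <- if (n_gain > 0) fam_id(fam_counter + seq_len(n_gain)) else character(0)
    fam_counter <- fam_counter + n_gain
    present[[ch]] <- c(kept, gained)
    events[[labels[ch]]] <- list(gained = gained, lost = lost)
  }
  observed <- sort(unique(unlist(present[seq_len(ntip)])))
  counts <- matrix(0L, nrow = ntip, ncol = length(observed),
                   dimnames = list(tree$tip.label, observed))
  for (i in seq_len(ntip)) counts[i, match(present[[i]], observed)] <- 1L
  truth <- structure(list(root_families = fam_id(seq_len(config$n0)),
                          events = events, chronogram = tree,
                          islands = NULL, variant_truth = NULL),
                     class = "truth_log")
  list(pattern = phyletic_pattern(counts), truth = truth)
}

#' Replay a truth log along its tree
#'
#' Applies the recorded per-branch gains and losses from the root down and
#' rebuilds the tip presence/absence pattern. Used to assert that the
#' emitted pattern and the event log agree exactly.
#'
#' @param truth a `truth_log` from [simulate_gene_content()].
#' @return a [phyletic_pattern()] restricted to families observed in >= 1 tip.
#' @export
replay_gene_content <- function(truth) {
  tree <- truth$chronogram
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  present <- vector("list", ntip + tree$Nnode)
  present[[ntip + 1L]] <- truth$root_families
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    ev <- truth$events[[labels[ch]]]
    present[[ch]] <- c(setdiff(present[[p]], ev$lost), ev$gained)
  }
  observed <- sort(unique(unlist(present[seq_len(ntip)])))
  counts <- matrix(0L, nrow = ntip, ncol = length(observed),
                   dimnames = list(tree$tip.label, observed))
  for (i in seq_len(ntip)) counts[i, match(present[[i]], observed)] <- 1L
  phyletic_pattern(counts)
}

# Internal: draw positive integer lengths around a mean.
draw_lengths <- function(n, mean, sd, floor_at) {
  if (sd == 0) return(rep(as.integer(mean), n))
  pmax(floor_at, as.integer(round(stats::rnorm(n, mean, sd))))
}

#' Lay out simulated genomes with planted islands
#'
#' For each strain the families gained on its terminal branch are split:
#' `islands_per_strain` contiguous blocks of `island_min`..`island_max`
#' genes are planted as islands, and the remaining gains are interleaved
#' singly among the ancestral genes. CDS lengths and intergenic gaps are
#' drawn from the configured distributions. Planted island extents are
#' recorded in the truth log.
#'
#' @param pattern the emitted [phyletic_pattern()].
#' @param truth the `truth_log` from [simulate_gene_content()].
#' @param config a [sim_config()].
#' @return list with `genomes` (named list of [annotated_genome()]) and the
#'   updated `truth` (element `islands`: per strain a data.frame of gene
#'   index ranges, bp spans and member CLOGs).
#' @export
layout_genomes <- function(pattern, truth, config) {
  set.seed(stage_seed(config, "layout"))
  pres <- presence_matrix(pattern)
  genomes <- list()
  islands_truth <- list()
  for (strain in pattern$strains) {
    tip_fams <- pattern$clogs[pres[strain, ] == 1L]
    gained <- intersect(truth$events[[strain]]$gained, tip_fams)
    ancestral <- setdiff(tip_fams, gained)
    n_isl <- config$islands_per_strain
    sizes <- if (n_isl > 0)
      config$island_min + sample.int(config$island_max - config$island_min + 1L,
                                     n_isl, replace = TRUE) - 1L else integer(0)
    if (sum(sizes) > length(gained))
      stop("strain ", strain, ": planted islands need ", sum(sizes),
           " gained families but only ", length(gained),
           " were gained on the terminal branch; increase gain_rate")
    pool <- sample(gained)
    island_genes <- list()
    used <- 0
    for (j in seq_len(n_isl)) {
      island_genes[[j]] <- pool[used + seq_len(sizes[j])]
      used <- used + sizes[j]
    }
    scattered <- pool[seq_len(length(pool) - used) + used]
    # units: single ancestral genes, single scattered gains, island blocks
    units <- c(as.list(sample(ancestral)), as.list(scattered), island_genes)
    units <- units[sample(length(units))]
    order_clogs <- unlist(units)
    gained_flag <- order_clogs %in% gained
    n_genes <- length(order_clogs)
    lens <- draw_lengths(n_genes, config$cds_len, config$cds_sd, 90L)
    gaps <- draw_lengths(n_genes + 1L, config$gap_len, config$gap_sd, 1L)
    starts <- integer(n_genes); ends <- integer(n_genes)
    pos <- gaps[1]
    for (i in seq_len(n_genes)) {
      starts[i] <- pos + 1L; ends[i] <- pos + lens[i]
      pos <- ends[i] + gaps[i + 1L]
    }
    feats <- data.frame(start = starts, end = ends,
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        clog = order_clogs, full_length = TRUE,
                        gained = gained_flag, stringsAsFactors = FALSE)
    genomes[[strain]] <- annotated_genome(strain, pos, feats)
    # record island extents in final coordinates
    if (n_isl > 0) {
      idx <- lapply(island_genes, function(g) match(g, order_clogs))
      islands_truth[[strain]] <- data.frame(
        island = seq_len(n_isl),
        first_gene = vapply(idx, min, numeric(1)),
        last_gene = vapply(idx, max, numeric(1)),
        start = starts[vapply(idx, min, numeric(1))],
        end = ends[vapply(idx, max, numeric(1))],
        clogs = I(island_genes))
    } else {
      islands_truth[[strain]] <- data.frame(island = integer(0))
    }
  }
  truth$islands <- islands_truth
  list(genomes = genomes, truth = truth)
}

AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

# Internal: evolve one gapped-free alignment column matrix down the tree
# under a symmetric 20-state replacement process.
evolve_family <- function(tree, len) {
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- sample.int(20L, len, replace = TRUE)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  ord <- match(paste(edges[, 1], edges[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    d <- tree$edge.length[ord[k]]
    p_diff <- (19 / 20) * (1 - exp(-(20 / 19) * d))
    s <- seqs[[p]]
    mut <- stats::runif(len) < p_diff
    if (any(mut))  # jump to one of the 19 other states, uniformly
      s[mut] <- ((s[mut] - 1L + sample.int(19L, sum(mut), replace = TRUE)) %% 20L) + 1L
    seqs[[ch]] <- s
  }
  out <- matrix(0L, nrow = ntip, ncol = len, dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(ntip)) out[i, ] <- seqs[[i]]
  out
}

# Internal: definition scan for set-specific columns of an integer-coded
# alignment matrix (strains x columns).
scan_specific_columns <- function(mat, set_strains) {
  inside <- mat[set_strains, , drop = FALSE]
  outside <- mat[setdiff(rownames(mat), set_strains), , drop = FALSE]
  uniform <- apply(inside, 2, function(col) length(unique(col)) == 1L)
  hit <- logical(ncol(mat))
  for (j in which(uniform)) hit[j] <- !(inside[1, j] %in% outside[, j])
  which(hit)
}

#' Simulate single-copy core alignments with planted set-specific columns
#'
#' Background columns evolve under a symmetric 20-state amino-acid
#' replacement process along the substitutions tree. For each target set a
#' configured number of columns is overwritten so all set strains carry one
#' residue and every outside strain carries a different one. Truth is
#' defined by an exhaustive scan of the final alignments (so columns that
#' satisfy the definition by chance are part of the truth too).
#'
#' @param tree substitutions/site tree.
#' @param config a [sim_config()].
#' @param truth optional `truth_log` to extend.
#' @return list with `alignments` (a `core_alignment_set`) and `truth`
#'   whose `variant_truth` maps set id -> data.frame(clog, column, residue).
#' @export
simulate_core_alignments <- function(tree, config, truth = NULL) {
  set.seed(stage_seed(config, "alignments"))
  strains <- tree$tip.label
  n_fam <- config$n_core_families
  lens <- config$len_min + sample.int(config$len_max - config$len_min + 1L,
                                      n_fam, replace = TRUE) - 1L
  clogs <- sprintf("CORE%04d", seq_len(n_fam))
  mats <- lapply(lens, function(L) evolve_family(tree, L))
  names(mats) <- clogs
  for (set_id in names(config$target_sets)) {
    set_strains <- config$target_sets[[set_id]]
    if (length(set_strains) == 0 || length(set_strains) == length(strains)) next
    for (r in seq_len(config$planted_per_set)) {
      f <- sample.int(n_fam, 1)
      col <- sample.int(lens[f], 1)
      x <- sample.int(20L, 1)
      m <- mats[[f]]
      m[set_strains, col] <- x
      outs <- setdiff(strains, set_strains)
      clash <- outs[m[outs, col] == x]
      if (length(clash))
        m[clash, col] <- ((x - 1L + sample.int(19L, length(clash), replace = TRUE)) %% 20L) + 1L
      mats[[f]] <- m
    }
  }
  variant_truth <- list()
  for (set_id in names(config$target_sets)) {
    set_strains <- config$target_sets[[set_id]]
    if (length(set_strains) == 0 || length(set_strains) == length(strains)) next
    recs <- list()
    for (f in seq_len(n_fam)) {
      cols <- scan_specific_columns(mats[[f]], set_strains)
      if (length(cols))
        recs[[length(recs) + 1L]] <- data.frame(
          clog = clogs[f], column = cols,
          residue = AA_ALPHABET20[mats[[f]][set_strains[1], cols]],
          stringsAsFactors = FALSE)
    }
    variant_truth[[set_id]] <- if (length(recs)) do.call(rbind, recs) else
      data.frame(clog = character(0), column = integer(0), residue = character(0))
  }
  alns <- lapply(mats, function(m)
    stats::setNames(apply(m, 1, function(row)
      paste(AA_ALPHABET20[row], collapse = "")), rownames(m)))
  if (is.null(truth))
    truth <- structure(list(root_families = NULL, events = NULL,
                            chronogram = NULL, islands = NULL,
                            variant_truth = NULL), class = "truth_log")
  truth$variant_truth <- variant_truth
  list(alignments = core_alignment_set(alns), truth = truth)
}

#' Simulate presence/absence families under the two-state gain/loss chain
#'
#' Unlike [simulate_gene_content()] (where every family originates once,
#' on one branch), this draws each family's root state from the model's
#' stationary distribution and evolves it along the tree under the
#' gain/loss Markov chain, so a family may be gained and lost repeatedly.
#' Only observable families (present in at least one tip) are emitted,
#' matching real phyletic patterns; true per-branch gain/loss events are
#' recorded for them.
#'
#' @param tree tree whose branch lengths set the rate unit.
#' @param alpha,beta gain and loss rates per unit branch length.
#' @param n_families number of observable families to emit.
#' @param seed optional integer seed.
#' @return list with `pattern` ([phyletic_pattern()]), `events` (per
#'   child-label lists of gained/lost family ids) and `node_states`
#'   (families x nodes 0/1 matrix, tips included).
#' @export
simulate_gainloss_families <- function(tree, alpha, beta, n_families,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- gainloss_model(alpha, beta)
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  ord <- match(paste(edges[, 1], edges[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  pi1 <- alpha / (alpha + beta)
  got <- 0L
  states_list <- list()
  while (got < n_families) {
    n_try <- max(100L, ceiling((n_families - got) * 1.5))
    states <- matrix(0L, nrow = n_try, ncol = nnode)
    states[, ntip + 1L] <- stats::rbinom(n_try, 1, pi1)
    for (k in seq_len(nrow(edges))) {
      p <- edges[k, 1]; ch <- edges[k, 2]
      P <- branch_transition_probs(model, tree$edge.length[ord[k]])
      u <- stats::runif(n_try)
      states[, ch] <- ifelse(states[, p] == 1L, (u < P[2, 2]) + 0L,
                             (u < P[1, 2]) + 0L)
    }
    keep <- rowSums(states[, seq_len(ntip), drop = FALSE]) > 0
    states_list[[length(states_list) + 1L]] <- states[keep, , drop = FALSE]
    got <- got + sum(keep)
  }
  states <- do.call(rbind, states_list)[seq_len(n_families), , drop = FALSE]
  fams <- sprintf("F%06d", seq_len(n_families))
  rownames(states) <- fams
  colnames(states) <- labels
  counts <- t(states[, seq_len(ntip), drop = FALSE])
  rownames(counts) <- tree$tip.label
  events <- list()
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    events[[labels[ch]]] <- list(
      gained = fams[states[, p] == 0L & states[, ch] == 1L],
      lost = fams[states[, p] == 1L & states[, ch] == 0L])
  }
  list(pattern = phyletic_pattern(counts), events = events,
       node_states = states)
}

#' Simulate a nucleotide sequence pair at a target identity
#'
#' Substitutions only (no indels): each site of the copy is mutated to a
#' different base with probability `1 - identity_target`, so the realised
#' identity is binomially distributed about the target.
#'
#' @param identity_target fraction in (0, 1].
#' @param length sequence length in bp.
#' @param seed optional integer seed.
#' @return list with `a`, `b` (character strings) and `realized_identity`.
#' @export
simulate_sequence_pair <- function(identity_target, length, seed = NULL) {
  if (identity_target <= 0 || identity_target > 1)
    stop("identity_target must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, length, replace = TRUE)
  b <- a
  mut <- stats::runif(length) < (1 - identity_target)
  if (any(mut)) {
    idx <- match(a[mut], bases)
    b[mut] <- bases[((idx - 1L + sample.int(3L, sum(mut), replace = TRUE)) %% 4L) + 1L]
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
       realized_identity = 1 - sum(mut) / length)
}

#' Run the whole generator
#'
#' Convenience wrapper calling [simulate_chronogram()],
#' [simulate_gene_content()], [layout_genomes()] and
#' [simulate_core_alignments()] on deterministic substreams of the
#' configured seed.
#'
#' @param config a [sim_config()].
#' @param genomes,alignments logical switches for the heavier stages.
#' @return list with `chronogram`, `subs_tree`, `pattern`, `truth`,
#'   `genomes`, `alignments`, `metadata` (strain/clade data.frame).
#' @export
simulate_dataset <- function(config, genomes = TRUE, alignments = TRUE) {
  trees <- simulate_chronogram(config)
  gc <- simulate_gene_content(trees$chronogram, config)
  out <- list(chronogram = trees$chronogram, subs_tree = trees$subs_tree,
              pattern = gc$pattern, truth = gc$truth)
  if (genomes) {
    lg <- layout_genomes(gc$pattern, gc$truth, config)
    out$genomes <- lg$genomes
    out$truth <- lg$truth
  }
  if (alignments) {
    ca <- simulate_core_alignments(trees$subs_tree, config, out$truth)
    out$alignments <- ca$alignments
    out$truth <- ca$truth
  }
  out$metadata <- data.frame(
    strain = config$strains,
    clade = rep(names(config$clades), lengths(config$clades)),
    stringsAsFactors = FALSE)
  out
}
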
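#' Two-state gain/loss model
#'
#' Continuous-time Markov model of gene-family presence/absence along a
#' tree: gain rate `alpha` (absent -> present per unit branch length), loss
#' rate `beta` (present -> absent), optionally mixed over K discrete-gamma
#' rate categories (equal prior mass, mean multiplier 1, shape `shape`)
#' applied as a per-family multiplier shared by both rates. The root state
#' prior is the model's stationary distribution by default, or a fixed
#' presence probability `pi1`.
#'
#' @param alpha,beta positive rates.
#' @param k_gamma number of gamma categories (1 = homogeneous model).
#' @param shape gamma shape parameter (ignored when `k_gamma = 1`).
#' @param root_prior `"stationary"` or `"fixed"`.
#' @param pi1 root presence probability when `root_prior = "fixed"`.
#' @return object of class `gainloss_model`.
#' @export
gainloss_model <- function(alpha, beta, k_gamma = 1, shape = 1,
                           root_prior = c("stationary", "fixed"), pi1 = 0.5) {
  root_prior <- match.arg(root_prior)
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  if (k_gamma > 1 && shape <= 0) stop("gamma shape must be > 0")
  structure(list(alpha = alpha, beta = beta, k_gamma = as.integer(k_gamma),
                 shape = shape, root_prior = root_prior, pi1 = pi1),
            class = "gainloss_model")
}

#' @export
print.gainloss_model <- function(x, ...) {
  cat("gainloss_model: alpha =", signif(x$alpha, 4), "beta =",
      signif(x$beta, 4))
  if (x$k_gamma > 1) cat(", gamma(", x$k_gamma, " cat, shape ",
                         signif(x$shape, 4), ")", sep = "")
  cat(", root prior", x$root_prior, "\n")
  if (!is.null(x$loglik)) cat("  log-likelihood:", x$loglik, "\n")
  invisible(x)
}

#' Discrete-gamma rate multipliers
#'
#' Equal-mass discretisation of a mean-1 gamma distribution into `k`
#' categories, each represented by its conditional mean.
#'
#' @param shape gamma shape.
#' @param k number of categories.
#' @return numeric vector of `k` multipliers averaging 1.
#' @export
discrete_gamma_rates <- function(shape, k) {
  if (k == 1) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  p <- stats::pgamma(q, shape = shape + 1, rate = shape)
  k * diff(p)
}

#' Branch transition probabilities of the gain/loss chain
#'
#' Closed-form 2x2 matrix: `P(absent -> present, t) =
#' alpha/(alpha+beta) * (1 - exp(-(alpha+beta) t))`, and symmetrically for
#' loss. States are ordered (absent, present).
#'
#' @param model a [gainloss_model()] (or anything with `alpha`, `beta`).
#' @param t non-negative branch length.
#' @return 2x2 row-stochastic matrix.
#' @export
branch_transition_probs <- function(model, t) {
  if (t < 0) stop("negative branch length")
  a <- model$alpha; b <- model$beta
  e <- exp(-(a + b) * t)
  p01 <- a / (a + b) * (1 - e)
  p10 <- b / (a + b) * (1 - e)
  matrix(c(1 - p01, p10, p01, 1 - p10), nrow = 2,
         dimnames = list(c("absent", "present"), c("absent", "present")))
}

# Internal: root prior as c(p_absent, p_present).
root_prior_vec <- function(model) {
  if (model$root_prior == "fixed") c(1 - model$pi1, model$pi1)
  else c(model$beta, model$alpha) / (model$alpha + model$beta)
}

# Internal: postorder pruning pass for one rate category, vectorised over
# families. Returns per-node partial likelihood matrices (nfam x 2), the
# per-edge upward messages, and per-family likelihoods at the root.
pruning_up <- function(pres, tree, model, rate = 1) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nfam <- ncol(pres)
  partial <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    x <- pres[tree$tip.label[i], ]
    partial[[i]] <- cbind(1 - x, x)
  }
  for (i in ntip + seq_len(tree$Nnode))
    partial[[i]] <- matrix(1, nrow = nfam, ncol = 2)
  tr <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(tr$edge[, 1], tr$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  msgs <- vector("list", nrow(tree$edge))
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    P <- branch_transition_probs(model, tr$edge.length[k] * rate)
    m <- partial[[ch]] %*% t(P)      # m[f, i] = sum_j P[i, j] L_ch[f, j]
    msgs[[ord[k]]] <- m
    partial[[p]] <- partial[[p]] * m
  }
  prior <- root_prior_vec(model)
  root <- ntip + 1L
  list(partial = partial, msgs = msgs,
       root_lik = as.vector(partial[[root]] %*% prior))
}

# Internal: per-family likelihoods mixed over gamma categories, plus the
# likelihood of the all-absent pattern (for the ascertainment correction).
family_likelihoods <- function(pres, tree, model) {
  rates <- discrete_gamma_rates(model$shape, model$k_gamma)
  nfam <- ncol(pres)
  lik <- numeric(nfam)
  p_absent <- 0
  absent_row <- matrix(0, nrow = nrow(pres), ncol = 1,
                       dimnames = list(rownames(pres), NULL))
  for (r in rates) {
    lik <- lik + pruning_up(pres, tree, model, r)$root_lik / length(rates)
    p_absent <- p_absent +
      pruning_up(absent_row, tree, model, r)$root_lik / length(rates)
  }
  list(lik = lik, p_absent = p_absent)
}

#' Log-likelihood of a phyletic pattern under a gain/loss model
#'
#' Felsenstein pruning over the binarised pattern, summed over families and
#' mixed over gamma categories. When `condition = TRUE` the likelihood is
#' conditioned on a family being observable (present in at least one tip),
#' correcting the ascertainment bias of real phyletic patterns, which never
#' contain all-absent families.
#'
#' @param pattern a [phyletic_pattern()] (binarised internally).
#' @param tree tree with branch lengths on the model's scale.
#' @param model a [gainloss_model()].
#' @param condition apply the observable-pattern correction.
#' @return total log-likelihood (scalar).
#' @export
gainloss_loglik <- function(pattern, tree, model, condition = TRUE) {
  pres <- presence_matrix(pattern)
  fl <- family_likelihoods(pres, tree, model)
  ll <- log(fl$lik)
  if (condition) ll <- ll - log(1 - fl$p_absent)
  sum(ll)
}

#' Fit a gain/loss model by maximum likelihood
#'
#' Numerical maximisation of the (ascertainment-corrected) pruning
#' likelihood over `(alpha, beta)` and, when `k_gamma > 1`, the gamma
#' shape, on the log scale.
#'
#' @param pattern a [phyletic_pattern()].
#' @param tree reference tree (branch lengths set the rate unit: e.g. per
#'   My on a chronogram).
#' @param k_gamma number of gamma categories.
#' @param root_prior `"stationary"` or `"fixed"`.
#' @param pi1 root presence probability for the fixed prior.
#' @param condition apply the observable-pattern correction.
#' @param init optional starting values `c(alpha, beta)`.
#' @return a [gainloss_model()] with elements `loglik` and `convergence`.
#' @export
fit_gainloss <- function(pattern, tree, k_gamma = 4,
                         root_prior = c("stationary", "fixed"), pi1 = 0.5,
                         condition = TRUE, init = NULL) {
  root_prior <- match.arg(root_prior)
  pres <- presence_matrix(pattern)
  if (all(pres == 1L))
    stop("rates unidentifiable: every family present in every strain")
  depth <- max(ape::node.depth.edgelength(tree))
  if (is.null(init)) init <- c(0.5 / depth, 0.5 / depth)
  par0 <- log(c(init, if (k_gamma > 1) 1))
  negll <- function(par) {
    m <- gainloss_model(exp(par[1]), exp(par[2]), k_gamma = k_gamma,
                        shape = if (k_gamma > 1) exp(par[3]) else 1,
                        root_prior = root_prior, pi1 = pi1)
    fl <- family_likelihoods(pres, tree, m)
    ll <- log(fl$lik)
    if (condition) ll <- ll - log(1 - fl$p_absent)
    -sum(ll)
  }
  opt <- stats::optim(par0, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  model <- gainloss_model(exp(opt$par[1]), exp(opt$par[2]), k_gamma = k_gamma,
                          shape = if (k_gamma > 1) exp(opt$par[3]) else 1,
                          root_prior = root_prior, pi1 = pi1)
  model$loglik <- -opt$value
  model$convergence <- opt$convergence
  model$condition <- condition
  model
}

#' Marginal ancestral presence posteriors
#'
#' Up-down (outside) pass yielding, for every family and every internal
#' node, the marginal posterior probability of presence, mixed over gamma
#' categories. States are binarised at `cutoff`: a node is called present
#' (absent) when the posterior of that state reaches the cutoff, and
#' `"ambiguous"` otherwise.
#'
#' @param model a [gainloss_model()].
#' @param pattern a [phyletic_pattern()].
#' @param tree the reference tree.
#' @param cutoff posterior probability cutoff (default 0.9).
#' @return object of class `ancestral_states`: `posterior` (families x
#'   internal nodes matrix of P(present)), `state` (character matrix
#'   `"present"`/`"absent"`/`"ambiguous"`), `cutoff`, `root_label`, and
#'   `root_count` (families called present at the root).
#' @export
ancestral_posteriors <- function(model, pattern, tree, cutoff = 0.9) {
  pres <- presence_matrix(pattern)
  pres <- pres[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nfam <- ncol(pres)
  rates <- discrete_gamma_rates(model$shape, model$k_gamma)
  prior <- root_prior_vec(model)
  joint <- array(0, dim = c(nfam, tree$Nnode, 2))
  total <- numeric(nfam)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (r in rates) {
    up <- pruning_up(pres, tree, model, r)
    above <- vector("list", nnode)
    root <- ntip + 1L
    above[[root]] <- matrix(rep(prior, each = nfam), nrow = nfam)
    tr_edges <- ape::reorder.phylo(tree, "cladewise")$edge
    ord <- match(paste(tr_edges[, 1], tr_edges[, 2]),
                 paste(tree$edge[, 1], tree$edge[, 2]))
    for (k in seq_len(nrow(tr_edges))) {
      e <- ord[k]
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sib_edges <- setdiff(children[[as.character(p)]], e)
      B <- above[[p]]
      for (s in sib_edges) B <- B * up$msgs[[s]]
      P <- branch_transition_probs(model, tree$edge.length[e] * r)
      above[[ch]] <- B %*% P
    }
    for (v in seq_len(tree$Nnode)) {
      node <- ntip + v
      joint[, v, ] <- joint[, v, ] +
        (above[[node]] * up$partial[[node]]) / length(rates)
    }
    total <- total + up$root_lik / length(rates)
  }
  post <- joint[, , 2, drop = FALSE][, , 1] / total
  post <- matrix(post, nrow = nfam, ncol = tree$Nnode,
                 dimnames = list(colnames(pres),
                                 node_labels(tree)[ntip + seq_len(tree$Nnode)]))
  state <- matrix("ambiguous", nrow = nfam, ncol = tree$Nnode,
                  dimnames = dimnames(post))
  state[post >= cutoff] <- "present"
  state[1 - post >= cutoff] <- "absent"
  root_label <- node_labels(tree)[ntip + 1L]
  structure(list(posterior = post, state = state, cutoff = cutoff,
                 root_label = root_label,
                 root_count = sum(post[, root_label] >= cutoff)),
            class = "ancestral_states")
}

#' Count gain and loss events on every branch
#'
#' A family contributes a gain on a branch when the parent state is absent
#' and the child state present, a loss in the opposite case. Internal
#' states come from the binarised posteriors; tip states are the observed
#' presence/absence. A branch touching an ambiguous state contributes no
#' event for that family (conservative counting).
#'
#' @param states an `ancestral_states` object.
#' @param pattern the [phyletic_pattern()].
#' @param tree the reference tree.
#' @return object of class `branch_events`: data.frame `per_branch`
#'   (`child_label`, `terminal`, `length`, `n_gained`, `n_lost`) plus lists
#'   `gained` and `lost` of CLOG ids keyed by child label.
#' @export
count_events <- function(states, pattern, tree) {
  pres <- presence_matrix(pattern)
  br <- tree_branches(tree)
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  gained <- list(); lost <- list()
  n_gained <- integer(nrow(br)); n_lost <- integer(nrow(br))
  fams <- rownames(states$state)
  for (k in seq_len(nrow(br))) {
    ps <- states$state[, labels[br$parent[k]]]
    cs <- if (br$child[k] <= ntip)
      ifelse(pres[labels[br$child[k]], fams] == 1L, "present", "absent")
    else states$state[, labels[br$child[k]]]
    g <- fams[ps == "absent" & cs == "present"]
    l <- fams[ps == "present" & cs == "absent"]
    gained[[br$child_label[k]]] <- g
    lost[[br$child_label[k]]] <- l
    n_gained[k] <- length(g); n_lost[k] <- length(l)
  }
  structure(list(
    per_branch = data.frame(child_label = br$child_label,
                            terminal = br$terminal, length = br$length,
                            n_gained = n_gained, n_lost = n_lost,
                            stringsAsFactors = FALSE),
    gained = gained, lost = lost), class = "branch_events")
}

#' Node-fixed genes
#'
#' A CLOG is fixed at an internal node when it is present in every leaf
#' below the node and absent from every other leaf of the dataset. At the
#' root the complement is empty, so families present in all strains are
#' fixed at the root.
#'
#' @param pattern a [phyletic_pattern()].
#' @param tree the reference tree.
#' @return named list (internal node label -> character vector of CLOG ids).
#' @export
fixed_genes_per_node <- function(pattern, tree) {
  pres <- presence_matrix(pattern)
  pres <- pres[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  labels <- node_labels(tree)
  desc <- descendant_tips(tree)
  out <- list()
  total <- colSums(pres)
  for (v in ntip + seq_len(tree$Nnode)) {
    below <- desc[[v]]
    inside <- colSums(pres[below, , drop = FALSE])
    fixed <- pattern$clogs[inside == length(below) & total == inside]
    out[[labels[v]]] <- fixed
  }
  out
}
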
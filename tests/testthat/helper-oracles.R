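# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (enumeration, set arithmetic,
# closed forms) rather than calling the implementation under test.

# Random phyletic pattern, keeping only observable families.
rand_pattern <- function(n_strains, n_clogs, p = 0.5,
                         strains = sprintf("S%02d", seq_len(n_strains))) {
  m <- matrix(rbinom(n_strains * n_clogs, 1, p), nrow = n_strains,
              dimnames = list(strains, sprintf("F%04d", seq_len(n_clogs))))
  m <- m[, colSums(m) > 0, drop = FALSE]
  phyletic_pattern(m)
}

# Exhaustive likelihood of a presence/absence matrix under the two-state
# chain: sum over all internal-state assignments.
brute_gainloss_lik <- function(pres, tree, alpha, beta, rates = 1) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  prior <- c(beta, alpha) / (alpha + beta)
  combos <- as.matrix(expand.grid(rep(list(0:1), nnode)))
  trans <- function(t) {
    e <- exp(-(alpha + beta) * t)
    p01 <- alpha / (alpha + beta) * (1 - e)
    p10 <- beta / (alpha + beta) * (1 - e)
    matrix(c(1 - p01, p10, p01, 1 - p10), 2)
  }
  vapply(seq_len(ncol(pres)), function(f) {
    mean(vapply(rates, function(r) {
      states <- numeric(ntip + nnode)
      states[seq_len(ntip)] <- pres[tree$tip.label, f]
      tot <- 0
      for (k in seq_len(nrow(combos))) {
        states[(ntip + 1):(ntip + nnode)] <- combos[k, ]
        p <- prior[states[ntip + 1] + 1]
        for (e in seq_len(nrow(tree$edge))) {
          P <- trans(tree$edge.length[e] * r)
          p <- p * P[states[tree$edge[e, 1]] + 1, states[tree$edge[e, 2]] + 1]
        }
        tot <- tot + p
      }
      tot
    }, numeric(1)))
  }, numeric(1))
}

# Exhaustive marginal posteriors of presence at every internal node.
brute_gainloss_post <- function(pres, tree, alpha, beta, rates = 1) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  prior <- c(beta, alpha) / (alpha + beta)
  combos <- as.matrix(expand.grid(rep(list(0:1), nnode)))
  trans <- function(t) {
    e <- exp(-(alpha + beta) * t)
    p01 <- alpha / (alpha + beta) * (1 - e)
    p10 <- beta / (alpha + beta) * (1 - e)
    matrix(c(1 - p01, p10, p01, 1 - p10), 2)
  }
  post <- matrix(0, ncol(pres), nnode)
  for (f in seq_len(ncol(pres))) {
    states <- numeric(ntip + nnode)
    states[seq_len(ntip)] <- pres[tree$tip.label, f]
    tot <- 0
    acc <- numeric(nnode)
    for (r in rates) for (k in seq_len(nrow(combos))) {
      states[(ntip + 1):(ntip + nnode)] <- combos[k, ]
      p <- prior[states[ntip + 1] + 1] / length(rates)
      for (e in seq_len(nrow(tree$edge))) {
        P <- trans(tree$edge.length[e] * r)
        p <- p * P[states[tree$edge[e, 1]] + 1, states[tree$edge[e, 2]] + 1]
      }
      tot <- tot + p
      acc <- acc + p * combos[k, ]
    }
    post[f, ] <- acc / tot
  }
  post
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all sign vectors.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
}

# Pairwise Jaccard distance by direct set arithmetic.
brute_jaccard <- function(pres) {
  n <- nrow(pres)
  d <- matrix(0, n, n, dimnames = list(rownames(pres), rownames(pres)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- which(pres[i, ] == 1)
    b <- which(pres[j, ] == 1)
    d[i, j] <- 1 - length(intersect(a, b)) / length(union(a, b))
  }
  d
}
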
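test_that("branch transition matrices obey the chain's algebra", {
  m <- gainloss_model(0.7, 0.3)
  expect_equal(branch_transition_probs(m, 0), diag(2), ignore_attr = TRUE)
  sym <- gainloss_model(0.5, 0.5)
  expect_equal(unname(branch_transition_probs(sym, 1e6)),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.01, 2); b <- runif(1, 0.01, 2); t <- runif(1, 0, 5)
    mm <- gainloss_model(a, b)
    P1 <- branch_transition_probs(mm, t)
    expect_equal(unname(branch_transition_probs(mm, 2 * t)),
                 unname(P1 %*% P1), tolerance = 1e-12)
    expect_equal(rowSums(P1), c(absent = 1, present = 1))
  }
  expect_error(branch_transition_probs(m, -1), "negative")
})

test_that("pruning likelihood equals exhaustive enumeration, with and without gamma", {
  set.seed(2)
  for (i in 1:8) {
    n <- sample(4:6, 1)
    tr <- as_evo_tree(ape::rtree(n), "unitless")
    pat <- rand_pattern(n, 12, 0.5, strains = tr$tip.label)
    a <- runif(1, 0.1, 1); b <- runif(1, 0.1, 1)
    m1 <- gainloss_model(a, b)
    ll <- gainloss_loglik(pat, tr, m1, condition = FALSE)
    brute <- sum(log(brute_gainloss_lik(presence_matrix(pat), tr, a, b)))
    expect_equal(ll, brute, tolerance = 1e-9)
    # gamma mixture against the same enumeration mixed over category rates
    m4 <- gainloss_model(a, b, k_gamma = 4, shape = 0.8)
    rates <- discrete_gamma_rates(0.8, 4)
    ll4 <- gainloss_loglik(pat, tr, m4, condition = FALSE)
    brute4 <- sum(log(brute_gainloss_lik(presence_matrix(pat), tr, a, b, rates)))
    expect_equal(ll4, brute4, tolerance = 1e-9)
  }
})

test_that("the ascertainment correction conditions on observability", {
  set.seed(3)
  tr <- as_evo_tree(ape::rtree(5), "unitless")
  pat <- rand_pattern(5, 10, 0.5, strains = tr$tip.label)
  m <- gainloss_model(0.4, 0.6)
  # P(all absent) from enumeration on an all-absent pseudo family
  absent <- matrix(0, 5, 1, dimnames = list(tr$tip.label, "z"))
  p0 <- brute_gainloss_lik(absent, tr, 0.4, 0.6)
  ll_cond <- gainloss_loglik(pat, tr, m, condition = TRUE)
  ll_raw <- gainloss_loglik(pat, tr, m, condition = FALSE)
  expect_equal(ll_cond, ll_raw - ncol(presence_matrix(pat)) * log(1 - p0),
               tolerance = 1e-9)
})

test_that("single-category gamma reduces exactly to the homogeneous model", {
  set.seed(4)
  tr <- as_evo_tree(ape::rtree(6), "unitless")
  pat <- rand_pattern(6, 20, 0.5, strains = tr$tip.label)
  m1 <- gainloss_model(0.3, 0.9, k_gamma = 1)
  mk <- gainloss_model(0.3, 0.9, k_gamma = 1, shape = 7)  # shape irrelevant
  expect_identical(gainloss_loglik(pat, tr, m1), gainloss_loglik(pat, tr, mk))
  expect_equal(discrete_gamma_rates(2, 4), discrete_gamma_rates(2, 4))
  expect_equal(mean(discrete_gamma_rates(0.5, 4)), 1, tolerance = 1e-9)
})

test_that("marginal posteriors equal exhaustive enumeration", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(4:5, 1)
    tr <- as_evo_tree(ape::rtree(n), "unitless")
    pat <- rand_pattern(n, 8, 0.5, strains = tr$tip.label)
    a <- runif(1, 0.1, 1); b <- runif(1, 0.1, 1)
    m <- gainloss_model(a, b)
    st <- ancestral_posteriors(m, pat, tr)
    brute <- brute_gainloss_post(presence_matrix(pat), tr, a, b)
    expect_equal(unname(st$posterior), brute, tolerance = 1e-9)
  }
})

test_that("posterior cutoff semantics give definite or ambiguous states", {
  tr <- as_evo_tree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"),
                    "unitless")
  m <- gainloss_model(0.5, 0.005)  # losses rare
  pat <- phyletic_pattern(matrix(1L, 4, 2, dimnames = list(c("A", "B", "C", "D"),
                                                           c("F1", "F2"))))
  st <- ancestral_posteriors(m, pat, tr)
  expect_true(all(st$posterior > 0.99))  # present everywhere, beta << alpha
  # at cutoff 0.5 every state is definite
  st5 <- ancestral_posteriors(m, pat, tr, cutoff = 0.5)
  expect_false(any(st5$state == "ambiguous"))
})

test_that("likelihood and posteriors are invariant to strain order", {
  set.seed(6)
  tr <- as_evo_tree(ape::rtree(6), "unitless")
  pat <- rand_pattern(6, 15, 0.5, strains = tr$tip.label)
  perm <- phyletic_pattern(pat$counts[sample(6), ])
  m <- gainloss_model(0.4, 0.8)
  expect_equal(gainloss_loglik(pat, tr, m), gainloss_loglik(perm, tr, m))
  expect_equal(ancestral_posteriors(m, pat, tr)$posterior,
               ancestral_posteriors(m, perm, tr)$posterior)
})

test_that("a saturated pattern makes the rates unidentifiable", {
  tr <- as_evo_tree(ape::rtree(4), "unitless")
  pat <- phyletic_pattern(matrix(1L, 4, 5, dimnames = list(
    tr$tip.label, paste0("F", 1:5))))
  expect_error(fit_gainloss(pat, tr), "unidentifiable")
})

test_that("event counting localises gains and respects the telescoping sum", {
  tr <- as_evo_tree(ape::read.tree(text = "(((A:10,B:10):10,C:20):10,D:30);"),
                    "My")
  m <- gainloss_model(1e-3, 2e-3)
  counts <- matrix(0L, 4, 2, dimnames = list(c("A", "B", "C", "D"),
                                             c("onlyA", "everywhere")))
  counts[, "everywhere"] <- 1L
  counts["A", "onlyA"] <- 1L
  pat <- phyletic_pattern(counts)
  st <- ancestral_posteriors(m, pat, tr)
  ev <- count_events(st, pat, tr)
  expect_equal(unlist(ev$gained), c(A = "onlyA"))  # one gain, terminal branch
  expect_equal(sum(ev$per_branch$n_lost), 0)

  # telescoping: sum over branches (gains - losses) = tips - root, per
  # family with a fully unambiguous history
  set.seed(7)
  cfg <- sim_config(n_strains = 10, seed = 31)
  trs <- simulate_chronogram(cfg)$chronogram
  sim <- simulate_gainloss_families(trs, 1e-4, 2e-4, 300, seed = 8)
  st2 <- ancestral_posteriors(gainloss_model(1e-4, 2e-4), sim$pattern, trs)
  ev2 <- count_events(st2, sim$pattern, trs)
  pres <- presence_matrix(sim$pattern)
  unambiguous <- rownames(st2$state)[rowSums(st2$state == "ambiguous") == 0]
  # telescoping along every root-to-tip path: net events = state change
  labels <- c(trs$tip.label, trs$node.label)
  for (tip in trs$tip.label[1:3]) {
    path <- labels[ape::nodepath(trs, which(labels == tip),
                                 length(trs$tip.label) + 1)]
    for (f in unambiguous[seq_len(min(20, length(unambiguous)))]) {
      state_at <- function(lab) {
        if (lab %in% trs$tip.label) pres[lab, f]
        else (st2$state[f, lab] == "present") + 0L
      }
      net_path <- 0
      for (i in seq_len(length(path) - 1)) {
        child <- path[i]
        net_path <- net_path +
          (f %in% ev2$gained[[child]]) - (f %in% ev2$lost[[child]])
      }
      expect_equal(net_path, state_at(path[1]) - state_at(path[length(path)]))
    }
  }
})

test_that("zero-length branches carry no events when states agree", {
  tr <- as_evo_tree(ape::read.tree(text = "((A:0.0,B:1):1,C:2);"), "unitless")
  m <- gainloss_model(0.2, 0.2)
  counts <- matrix(c(1L, 1L, 1L), 3, 1, dimnames = list(c("A", "B", "C"), "F1"))
  st <- ancestral_posteriors(m, phyletic_pattern(counts), tr)
  ev <- count_events(st, phyletic_pattern(counts), tr)
  expect_equal(sum(ev$per_branch$n_gained) + sum(ev$per_branch$n_lost), 0)
})

test_that("node-fixed genes match a brute-force node x CLOG double loop", {
  set.seed(9)
  for (i in 1:4) {
    tr <- as_evo_tree(ape::rtree(8), "unitless")
    pat <- rand_pattern(8, 40, 0.4, strains = tr$tip.label)
    fixed <- fixed_genes_per_node(pat, tr)
    pres <- presence_matrix(pat)
    labels <- c(tr$tip.label, tr$node.label)
    for (v in 9:(8 + tr$Nnode)) {
      below <- tr$tip.label[picoevo:::descendant_tips(tr)[[v]]]
      outside <- setdiff(tr$tip.label, below)
      brute <- colnames(pres)[colSums(pres[below, , drop = FALSE]) == length(below) &
                                colSums(pres[outside, , drop = FALSE]) == 0]
      expect_setequal(fixed[[labels[v]]], brute)
    }
  }
  # family present in every leaf is fixed at the root (vacuous complement)
  tr <- as_evo_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"), "unitless")
  pat <- phyletic_pattern(matrix(1L, 3, 1, dimnames = list(c("A", "B", "C"), "F1")))
  fx <- fixed_genes_per_node(pat, tr)
  expect_equal(fx[[tr$node.label[1]]], "F1")
  # and at a cherry when confined there
  counts <- matrix(c(1L, 1L, 0L), 3, 1, dimnames = list(c("A", "B", "C"), "F2"))
  fx2 <- fixed_genes_per_node(phyletic_pattern(counts), tr)
  cherry <- tr$node.label[2]
  expect_equal(fx2[[cherry]], "F2")
})
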
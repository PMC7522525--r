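aln_set <- function(...) {
  seqs <- list(...)
  core_alignment_set(list(P1 = unlist(seqs)))
}

test_that("set-specific columns require set uniformity and outside exclusion", {
  cas <- core_alignment_set(list(P1 = c(s1 = "AD", s2 = "AD",
                                        s3 = "BD", s4 = "CD")))
  sv <- specific_variants(cas, c("s1", "s2"))
  expect_equal(nrow(sv), 1)      # column 1: A,A | B,C qualifies
  expect_equal(sv$column, 1)
  expect_equal(sv$residue, "A")
  expect_equal(sv$outside_residues, "BC")

  cas2 <- core_alignment_set(list(P1 = c(s1 = "A", s2 = "A",
                                         s3 = "A", s4 = "C")))
  expect_equal(nrow(specific_variants(cas2, c("s1", "s2"))), 0)  # outside has A

  expect_error(specific_variants(cas, c("s1", "s2", "s3", "s4")),
               "complement empty")
  expect_error(specific_variants(cas, character(0)), "empty")
})

test_that("gap policies treat gapped columns as configured", {
  cas <- core_alignment_set(list(P1 = c(s1 = "AA-", s2 = "AAA",
                                        s3 = "B-A", s4 = "BCA")))
  # column 2 has a gap in s3; column 3 has a gap in s1 (a set strain)
  excl <- specific_variants(cas, c("s1", "s2"), gap_policy = "exclude_column")
  expect_equal(excl$column, 1)   # only the gap-free column survives
  gas <- specific_variants(cas, c("s1", "s2"), gap_policy = "gap_as_state")
  # column 2: set A,A; outside -,C; the gap satisfies "any other amino acid"
  expect_setequal(gas$column, c(1, 2))
  # a gap can never be the set residue
  cas2 <- core_alignment_set(list(P1 = c(s1 = "-", s2 = "-",
                                         s3 = "A", s4 = "C")))
  expect_equal(nrow(specific_variants(cas2, c("s1", "s2"),
                                      gap_policy = "gap_as_state")), 0)
})

test_that("specific variants recover the generator truth exactly", {
  cfg <- sim_config(n_strains = 10, n_core_families = 50, len_min = 30,
                    len_max = 60, planted_per_set = 4, seed = 25)
  trees <- simulate_chronogram(cfg)
  ca <- simulate_core_alignments(trees$subs_tree, cfg)
  for (set_id in names(cfg$target_sets)) {
    got <- specific_variants(ca$alignments, cfg$target_sets[[set_id]])
    truth <- ca$truth$variant_truth[[set_id]]
    expect_equal(nrow(got), nrow(truth))
    expect_equal(got$clog, truth$clog)
    expect_equal(got$column, truth$column)
    expect_equal(got$residue, truth$residue)
  }
})

test_that("node-fixed variants cover cherries but never the root", {
  tr <- as_evo_tree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"),
                    "unitless")
  cas <- core_alignment_set(list(P1 = c(A = "DK", B = "DK", C = "EK", D = "EK")))
  fx <- fixed_variants_per_node(cas, tr)
  expect_false(tr$node.label[1] %in% names(fx))  # root skipped
  cherryAB <- tr$node.label[2]
  expect_equal(fx[[cherryAB]]$column, 1)
  expect_equal(fx[[cherryAB]]$residue, "D")
  # column 2 is invariant: specific to no node
  expect_false(2 %in% fx[[cherryAB]]$column)
  # star tree: no non-root internal nodes -> empty mapping
  star <- as_evo_tree(ape::read.tree(text = "(A:1,B:1,C:1);"), "unitless",
                      outgroup = "C")
  # rooting the star gives one non-root internal node at most; build a real
  # star by hand instead
  star2 <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  star2$node.label <- "n1"
  attr(star2, "unit") <- "unitless"
  expect_length(fixed_variants_per_node(cas, star2), 0)
})

test_that("node-fixed variant counts match node x column enumeration", {
  cfg <- sim_config(n_strains = 8, n_core_families = 10, len_min = 30,
                    len_max = 50, planted_per_set = 2, seed = 26)
  trees <- simulate_chronogram(cfg)
  ca <- simulate_core_alignments(trees$subs_tree, cfg)
  tr <- trees$subs_tree
  fx <- fixed_variants_per_node(ca$alignments, tr)
  labels <- c(tr$tip.label, tr$node.label)
  for (v in (9):(8 + tr$Nnode)) {
    below <- tr$tip.label[picoevo:::descendant_tips(tr)[[v]]]
    if (length(below) == 8) next
    brute <- 0
    for (clog in names(ca$alignments$alignments)) {
      a <- ca$alignments$alignments[[clog]]
      mat <- do.call(rbind, strsplit(a, "")); rownames(mat) <- names(a)
      for (j in seq_len(ncol(mat))) {
        ins <- mat[below, j]; outs <- mat[setdiff(rownames(mat), below), j]
        if (length(unique(ins)) == 1 && !(ins[1] %in% outs)) brute <- brute + 1
      }
    }
    expect_equal(nrow(fx[[labels[v]]]), brute)
  }
})

test_that("the rank-ratio screen keeps proteins ranked far better in the focal set", {
  mk <- function(dens) {
    df <- data.frame(clog = paste0("P", seq_along(dens)), n = dens * 100,
                     length = 100, density = dens)
    df$rank <- rank(-df$density, ties.method = "average")
    df
  }
  scores <- list(
    focal = mk(c(0.30, 0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.09,
                 0.10, 0.11, 0.12, 0.13, 0.14, 0.15, 0.16, 0.17, 0.18, 0.19)),
    bg1 = mk(seq(0.01, 0.20, length.out = 20)),
    bg2 = mk(seq(0.01, 0.20, length.out = 20)))
  cand <- rank_ratio_screen(scores, "focal", c("bg1", "bg2"), cutoff = 0.33)
  # P1: rank 1 focal, rank 20 in both backgrounds -> ratio 1/20 < 0.33
  expect_true("P1" %in% cand$clog)
  tab <- attr(cand, "all")
  expect_equal(tab$rank_ratio[tab$clog == "P1"], 1 / 20)
  # a protein with zero focal variants gets the worst-tier rank
  scores$focal$density[2] <- 0
  scores$focal$rank <- rank(-scores$focal$density, ties.method = "average")
  cand2 <- rank_ratio_screen(scores, "focal", c("bg1", "bg2"))
  expect_false("P2" %in% cand2$clog)
  expect_error(rank_ratio_screen(scores, "focal", "bg1"), ">= 2 background")
})

test_that("the screen agrees with an independent ranking routine", {
  set.seed(27)
  for (rep in 1:5) {
    P <- 15
    dens <- replicate(3, round(runif(P, 0, 0.2), 3))
    sets <- c("focal", "b1", "b2")
    scores <- lapply(1:3, function(k) {
      df <- data.frame(clog = paste0("P", 1:P), n = dens[, k] * 100,
                       length = 100, density = dens[, k])
      df$rank <- rank(-df$density, ties.method = "average")
      df
    })
    names(scores) <- sets
    cand <- rank_ratio_screen(scores, "focal", c("b1", "b2"), cutoff = 0.33)
    # oracle: order() based ranking with average ties via two sorts
    ranks <- apply(-dens, 2, rank)  # ascending rank of negative = densest first
    ratio <- ranks[, 1] / apply(ranks[, 2:3], 1, median)
    expect_setequal(cand$clog, paste0("P", which(ratio < 0.33)))
  }
})

test_that("variant reports render counts over lengths sorted by density", {
  cand <- data.frame(clog = c("crtLb", "abc"), n = c(7, 19),
                     length = c(347, 607), density = c(7 / 347, 19 / 607),
                     rank_focal = c(2, 1), median_rank_background = c(10, 10),
                     rank_ratio = c(0.2, 0.1))
  rep <- variant_report(cand, annotations = c(crtLb = "lycopene beta-cyclase"))
  expect_equal(rep$label, c("19/607", "7/347"))  # density-descending
  expect_equal(rep$description[2], "lycopene beta-cyclase")
  empty <- variant_report(cand[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("outputs are invariant to strain and CLOG order", {
  cfg <- sim_config(n_strains = 6, n_core_families = 6, len_min = 20,
                    len_max = 30, planted_per_set = 2, seed = 28)
  trees <- simulate_chronogram(cfg)
  ca <- simulate_core_alignments(trees$subs_tree, cfg)
  set_strains <- cfg$target_sets[[1]]
  ref <- specific_variants(ca$alignments, set_strains)
  shuffled <- lapply(ca$alignments$alignments, function(a) a[sample(names(a))])
  shuffled <- shuffled[sample(names(shuffled))]
  got <- specific_variants(core_alignment_set(shuffled), set_strains)
  expect_equal(got[order(got$clog, got$column), c("clog", "column", "residue")],
               ref[order(ref$clog, ref$column), c("clog", "column", "residue")],
               ignore_attr = TRUE)
})
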
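test_that("simulated chronograms are ultrametric with the declared root age", {
  for (sd in 1:20) {
    cfg <- sim_config(n_strains = sample(6:20, 1), seed = sd)
    tr <- simulate_chronogram(cfg)$chronogram
    depth <- ape::node.depth.edgelength(tr)
    tip_depths <- depth[seq_along(tr$tip.label)]
    expect_lt(diff(range(tip_depths)), 1e-9 * max(tip_depths))
    expect_equal(max(tip_depths), cfg$root_age, tolerance = 1e-9)
  }
})

test_that("a fixed newick chronogram is used as given", {
  cfg <- sim_config(clades = list(a = c("A", "B"), b = "C"),
                    newick = "((A:100,B:100):50,C:150);", seed = 1)
  tr <- simulate_chronogram(cfg)$chronogram
  expect_equal(max(ape::node.depth.edgelength(tr)), 150)
})

test_that("zero rate dispersion gives a strictly clock-like companion tree", {
  cfg <- sim_config(n_strains = 8, rate_sigma = 0, subs_rate = 5e-4, seed = 2)
  trees <- simulate_chronogram(cfg)
  ratio <- trees$subs_tree$edge.length / trees$chronogram$edge.length
  expect_equal(ratio, rep(5e-4, length(ratio)), tolerance = 1e-12)
  expect_equal(tree_unit(trees$subs_tree), "subs_per_site")
})

test_that("replaying the truth log reproduces the emitted pattern exactly", {
  for (sd in c(3, 14, 159)) {
    cfg <- sim_config(n_strains = 10, n0 = 300, gain_rate = 1,
                      loss_rate = 2e-3, seed = sd)
    tr <- simulate_chronogram(cfg)$chronogram
    gc <- simulate_gene_content(tr, cfg)
    expect_identical(presence_matrix(replay_gene_content(gc$truth)),
                     presence_matrix(gc$pattern))
  }
})

test_that("degenerate gain/loss rates behave as forced", {
  cfg <- sim_config(n_strains = 6, n0 = 100, gain_rate = 1, loss_rate = 0,
                    seed = 5)
  tr <- simulate_chronogram(cfg)$chronogram
  gc <- simulate_gene_content(tr, cfg)
  pres <- presence_matrix(gc$pattern)
  root_fams <- intersect(gc$truth$root_families, gc$pattern$clogs)
  expect_equal(length(root_fams), 100)       # nothing lost
  expect_true(all(pres[, root_fams] == 1L))  # present in every tip

  cfg0 <- sim_config(n_strains = 6, n0 = 100, gain_rate = 0, loss_rate = 2e-3,
                     seed = 5)
  gc0 <- simulate_gene_content(tr, cfg0)
  expect_lte(length(gc0$pattern$clogs), 100)  # pan bounded by root families
})

test_that("expected tip family count matches the closed-form solution", {
  # a family gained on a branch survives to that branch's child and is
  # exposed to loss on later branches only, so along the path to tip A
  # (root -> inner over 100 My, inner -> A over 200 My):
  # E[tip] = n0 e^{-lT} + sum_i g t_i e^{-l s_i}, s_i = child node age
  nwk <- "((A:200,B:200):100,C:300);"
  cfg_base <- list(clades = list(x = c("A", "B"), y = "C"), newick = nwk,
                   n0 = 200, gain_rate = 0.5, loss_rate = 2e-3,
                   islands_per_strain = 0)
  tips <- numeric(200)
  for (r in seq_len(200)) {
    cfg <- do.call(sim_config, c(cfg_base, seed = 9000 + r))
    tr <- simulate_chronogram(cfg)$chronogram
    gc <- simulate_gene_content(tr, cfg)
    tips[r] <- sum(presence_matrix(gc$pattern)["A", ])
  }
  expected <- 200 * exp(-2e-3 * 300) +
    0.5 * 100 * exp(-2e-3 * 200) +  # gained root -> inner, exposed 200 My
    0.5 * 200                       # gained on the terminal branch
  se <- sd(tips) / sqrt(length(tips))
  expect_lt(abs(mean(tips) - expected), 3 * se + 1e-9)
})

test_that("genome layout plants islands with the configured geometry", {
  cfg <- sim_config(clades = list(a = c("A", "B"), b = c("C", "D")),
                    newick = "((A:100,B:100):100,(C:100,D:100):100);",
                    n0 = 300, gain_rate = 0.5, loss_rate = 1e-3,
                    islands_per_strain = 1, island_min = 8, island_max = 8,
                    cds_len = 900, gap_len = 100, seed = 21)
  d <- simulate_dataset(cfg, alignments = FALSE)
  for (s in names(d$genomes)) {
    tr <- d$truth$islands[[s]]
    expect_equal(nrow(tr), 1)
    # 8 CDS of 900 bp with 7 interior gaps of 100 bp
    expect_equal(tr$end - tr$start + 1, 8 * 900 + 7 * 100)
    g <- d$genomes[[s]]
    expect_true(all(g$features$gained[tr$first_gene:tr$last_gene]))
  }
})

test_that("without planted islands, gained genes stay scattered", {
  cfg <- sim_config(clades = list(a = c("A", "B"), b = c("C", "D")),
                    newick = "((A:60,B:60):100,(C:60,D:60):100);",
                    n0 = 800, gain_rate = 0.5, loss_rate = 1e-3,
                    islands_per_strain = 0, seed = 33)
  d <- simulate_dataset(cfg, alignments = FALSE)
  for (s in names(d$genomes)) {
    runs <- rle(d$genomes[[s]]$features$gained)
    expect_lte(max(runs$lengths[runs$values]), 3)
  }
})

test_that("island demand beyond the gained supply is rejected with advice", {
  cfg <- sim_config(clades = list(a = c("A", "B"), b = c("C", "D")),
                    newick = "((A:5,B:5):100,(C:5,D:5):100);",
                    n0 = 200, gain_rate = 0.1, loss_rate = 1e-3,
                    islands_per_strain = 3, island_min = 8, island_max = 8,
                    seed = 2)
  tr <- simulate_chronogram(cfg)$chronogram
  gc <- simulate_gene_content(tr, cfg)
  expect_error(layout_genomes(gc$pattern, gc$truth, cfg), "increase gain_rate")
})

test_that("simulated sequence pairs hit their identity target", {
  sp <- simulate_sequence_pair(1, 5000, seed = 1)
  expect_identical(sp$a, sp$b)
  expect_equal(sp$realized_identity, 1)

  sp <- simulate_sequence_pair(0.95, 100000, seed = 7)
  expect_equal(nchar(sp$a), 100000)
  expect_gt(sp$realized_identity, 0.945)  # 3.5 binomial SDs
  expect_lt(sp$realized_identity, 0.955)
  mism <- sum(strsplit(sp$a, "")[[1]] != strsplit(sp$b, "")[[1]])
  expect_equal(1 - mism / 100000, sp$realized_identity)
})

test_that("variant truth equals an in-test definition scan of the alignments", {
  cfg <- sim_config(n_strains = 8, n_core_families = 20, len_min = 40,
                    len_max = 80, planted_per_set = 3, seed = 13)
  trees <- simulate_chronogram(cfg)
  ca <- simulate_core_alignments(trees$subs_tree, cfg)
  for (set_id in names(cfg$target_sets)) {
    set_strains <- cfg$target_sets[[set_id]]
    found <- list()
    for (clog in names(ca$alignments$alignments)) {
      a <- ca$alignments$alignments[[clog]]
      mat <- do.call(rbind, strsplit(a, ""))
      rownames(mat) <- names(a)
      for (j in seq_len(ncol(mat))) {
        inside <- mat[set_strains, j]
        outside <- mat[setdiff(rownames(mat), set_strains), j]
        if (length(unique(inside)) == 1 && !(inside[1] %in% outside))
          found[[length(found) + 1]] <- data.frame(clog = clog, column = j)
      }
    }
    found <- if (length(found)) do.call(rbind, found) else
      data.frame(clog = character(0), column = integer(0))
    truth <- ca$truth$variant_truth[[set_id]]
    expect_equal(found$clog, truth$clog)
    expect_equal(found$column, truth$column)
  }
})

test_that("emissions are bit-reproducible given the seed", {
  cfg <- sim_config(n_strains = 8, n0 = 150, seed = 77, n_core_families = 5,
                    gain_rate = 1)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$pattern$counts, d2$pattern$counts)
  expect_identical(ape::write.tree(d1$chronogram), ape::write.tree(d2$chronogram))
  expect_identical(d1$alignments$alignments, d2$alignments$alignments)
  expect_identical(d1$genomes[[1]]$features, d2$genomes[[1]]$features)
})

test_that("config validation catches inconsistent inputs", {
  expect_error(sim_config(n_strains = 5), "seed")
  expect_error(sim_config(clades = list(a = c("A", "B"), b = c("B", "C")),
                          seed = 1), "duplicate")
  expect_error(sim_config(n_strains = 8, gain_rate = -1, seed = 1), ">= 0")
  expect_error(sim_config(clades = list(a = c("A", "B"), b = c("C", "D")),
                          target_sets = list(bad = c("A", "C")), seed = 1),
               "union of clades")
  expect_error(sim_config(n_strains = 2, seed = 1), "3 strains")
})
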
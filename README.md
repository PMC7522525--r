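# picoevo

Comparative genomics of long-term gene-content evolution in closely related
bacterial genomes, modelled on the kind of analysis done for marine
picocyanobacteria (*Prochlorococcus* and *Synechococcus*): tens of complete
genomes clustered into gene families, a time-calibrated core-protein
phylogeny, and the question of how much of diversification happens by gene
gain and loss versus by amino-acid substitution.

The package is organised around the **phyletic pattern** — the strains ×
gene-family (CLOG, *cluster of likely orthologous genes*) copy-count matrix
— and provides:

* **Pan/core genome analysis** — core/accessory/unique classification at any
  taxonomic level (a CLOG is core in a group when present in ≥90% of its
  strains), rarefaction curves over random genome orders, and the
  Tettelin-style exponential fit `core(n) = κ·e^(−n/τ) + Ω` whose asymptote
  Ω estimates the persistent core size.
* **Ancestral gene content** — a two-state continuous-time Markov model of
  presence/absence with gain rate α and loss rate β,
  `P(0→1, t) = α/(α+β)·(1 − e^(−(α+β)t))`, optional discrete-gamma rate
  variation across families, likelihood by Felsenstein pruning conditioned
  on family observability, marginal ancestral posteriors by an up–down
  pass, binarised at a 90% posterior cutoff, and per-branch gain/loss event
  counts.
* **Time calibration and rates** — a simplified relative-depth dating
  procedure with interval calibrations (or a user-supplied chronogram), and
  through-origin regressions of per-branch event counts on branch durations
  giving rates per million years (My), with SE, adjusted R² and p-values,
  for gene gain, gene loss, amino-acid substitutions and node-fixed
  gene/variant fixation.
* **Genomic islands** — sliding-window detection (10 kb windows every
  100 bp; a window qualifies when >50% of its coding nucleotides belong to
  recently gained CDS), islands delimited by full-length gained genes, an
  island-sharing network with Jaccard-similarity edges (≥10% of pooled gene
  content) coloured by patristic distance, and Louvain modularity modules.
* **Tree-space comparison** — Jaccard distances between gene repertoires,
  neighbour-joining trees with column bootstrap, external/internal
  branch-length ratios at clade-base nodes, an exact paired Wilcoxon
  signed-rank test between trees, and Robinson–Foulds/monophyly discordance
  reports.
* **Clade-specific variants** — alignment columns where all strains of a
  set share one residue and every other strain carries a different one,
  node-fixed variants, per-protein variant densities, and the rank-ratio
  screen (focal rank / median background rank < 0.33) for candidate
  adaptive proteins.
* **Sequence statistics** — fragment-based ANI (1020-bp fragments, 30%
  identity / 70% coverage retention, conserved-DNA fraction at >90%
  identity), reciprocal-best-hit AAI with max-of-directions symmetrisation,
  GC3, and annotated pairwise-identity tables.
* **A synthetic-data generator** — clade-structured chronograms, gene
  content evolving by gains/losses, genomes with planted island loci,
  core alignments with planted set-specific residues, and
  divergence-controlled sequence pairs — all with machine-readable ground
  truth, so every downstream stage can be tested against known answers.

## Worked example

Simulate gene content under the gain/loss chain on a known chronogram, fit
the model, reconstruct ancestral states and convert branch events into
per-My rates:

```r
library(picoevo)

cfg    <- sim_config(n_strains = 16, seed = 42)
chrono <- simulate_chronogram(cfg)$chronogram
sim    <- simulate_gainloss_families(chrono, alpha = 1e-4, beta = 2e-4,
                                     n_families = 2000, seed = 43)

model  <- fit_gainloss(sim$pattern, chrono, k_gamma = 1)
model
#> gainloss_model: alpha = 9.843e-05 beta = 0.0002009, root prior stationary
#>   log-likelihood: -9182.242

states <- ancestral_posteriors(model, sim$pattern, chrono, cutoff = 0.9)
states$root_count
#> [1] 1032

events <- count_events(states, sim$pattern, chrono)
rate_table(events, chrono)
#>    category branch_class  rate      se adj_r2        p  n
#> 1 gene_gain     internal 0.152 0.01071  0.935 2.72e-09 14
#> 2 gene_loss     internal 0.148 0.00729  0.967 3.29e-11 14
#> 3 gene_gain     terminal 0.189 0.00905  0.965 1.66e-12 16
#> 4 gene_loss     terminal 0.162 0.00696  0.971 3.39e-13 16
```

The fitted rates recover the simulation's α = 1e-4 and β = 2e-4 to within a
few percent, and the per-branch inferred gain counts correlate with the
recorded true events at r = 0.95. The rate table reads like a
time-calibrated rate summary: e.g. 0.19 genes gained per My on terminal
branches of this 16-strain, 800-My-deep radiation.

Island detection and the sharing network follow the same pattern — see
`?detect_islands`, `?build_network`, `?detect_modules` — and the methods
vignette (`vignettes/picoevo-methods.Rmd`) walks through every analysis
with its assumptions and parameter choices.

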
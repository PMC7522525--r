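---
title: "Models and methods behind picoevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind picoevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picoevo)
```

picoevo analyses long-term genome diversification in sets of closely
related bacterial genomes — the motivating system is the marine
picocyanobacterial radiation, where tens of complete genomes per genus are
available, gene families (CLOGs) have been delineated by orthology
clustering, and a core-protein phylogeny provides the evolutionary
backbone. This vignette explains the models the package implements, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the
literature leaves the procedure under-specified.

## The phyletic pattern and pan/core structure

All gene-content analyses start from the phyletic pattern: an integer
matrix of per-genome copy numbers per CLOG. Internally every analysis
binarises it (presence = copy number ≥ 1); copy numbers are retained only
for reporting. Duplication dynamics are deliberately out of scope — the
gain/loss model, the island detector and the tree-space analyses all
consume presence/absence.

A CLOG is **core** in a taxonomic group when present in at least
⌈0.9·|group|⌉ of its strains; **unique** when present in exactly one
strain of the whole dataset; **accessory** otherwise. The 90% rule is the
field's working definition for multi-genome groups (it tolerates one
missing annotation in a group of ten); a strict mode (presence in every
strain) is also available because "core" is sometimes used in the strict
sense, and the two can differ substantially. Group-level core sets are
only inferred for groups with at least `min_group_size` (default 3)
genomes.

**Rarefaction** adds genomes in random order and tracks the pan size
(families seen so far) and core size (families in ≥90% of the genomes so
far); medians and quartiles are taken across permutations (default 1,000)
at each depth. Full permutation sampling replaces the sampling heuristics
of pan-genome profiling tools, whose exact approximation semantics are not
documented; at the scales this package targets, direct sampling is cheap.
Quartiles use R's default (type 7) quantile definition. The asymptotic
core size is estimated by nonlinear least squares on the median core
curve with the exponential-decay form `core(n) = κ·e^(−n/τ) + Ω`,
started from `(first − last, N/3, last)`; a flat curve short-circuits to
`Ω = last, κ = 0` since τ is then unidentifiable.

## The gain/loss model

Presence/absence of each family evolves independently along the reference
tree under a two-state continuous-time Markov chain with gain rate α
(absent→present per unit branch length) and loss rate β. Branch
transition probabilities are closed-form. Rate variation across families
is modelled, optionally, by K equal-mass discrete-gamma categories
(mean 1, shape a) whose multiplier scales α and β jointly — a per-family
"turnover temperature". The root prior defaults to the chain's stationary
distribution (β, α)/(α+β); a fixed-π₁ prior exists for sensitivity
checks.

Three numerical points matter:

* **Ascertainment.** Families absent from every genome are unobservable,
  so the likelihood is conditioned on presence in at least one tip
  (division by 1 − P(all absent)). Without this correction gain-rate
  estimates are biased downward.
* **Exactness.** The pruning likelihood and the up–down marginal
  posteriors are tested against exhaustive enumeration over all ancestral
  state assignments on trees of up to 6 leaves, at 1e-9 relative
  tolerance, including the gamma mixture.
* **Binarisation.** Ancestral states are called at a 90% posterior cutoff;
  anything in between is *ambiguous*. Event counting (gain = parent
  absent ∧ child present; loss = the converse) skips any branch touching
  an ambiguous state rather than resolving it by parsimony — counts are
  conservative by construction.

Node-**fixed genes** are families present in every leaf below a node and
absent everywhere else. At the root the "everywhere else" clause is
vacuous, so universally present families are fixed at the root; for
fixed *variants* (below) the root is excluded instead, because the
variant definition requires a non-empty complement to contrast against.

### A known limitation: infinite-allele data at realistic loss rates

The package's own generator creates each family once (a fresh CLOG id per
gain), which is the biologically natural "infinite alleles" picture. Under
the stationary two-state model, such data drive the α estimate to the
boundary: α cancels from the conditioned per-family likelihood as α → 0,
leaving the rare-family origination limit in which only the gain/loss
*ratio* along each explanation path matters. The ancestral posteriors in
that limit are still proper, but when per-branch loss probabilities are
appreciable (β·t around 0.1–0.5, which realistic per-family loss rates
over hundred-My branches produce), the posterior odds of "gained on this
branch" versus "present above and lost once on the sibling" land near
80–90% — just below the cutoff — so the conservative event counter drops
many true tip-adjacent gains. The same effect makes single-event histories
adjoining a degree-2 root formally unresolvable. Consequently, per-branch
event counts (and rates derived from them) are lower bounds, most visibly
on data with high turnover; parameter and event recovery is excellent when
the data actually follow the two-state chain at rates where per-branch
event probabilities are small. The recovery experiments in the test suite
use 16-taxon chronograms with α = 1e-4, β = 2e-4 per My (loss about twice
gain, the same ordering as published internal-branch rate tables).

## Time calibration and rate regressions

When no chronogram is available, `calibrate_relative()` dates the tree by
a deliberately simple three-step procedure: relative node depths equal to
the mean node-to-descendant-leaf path length, parent/child monotonicity
enforced by upward max-propagation, and a single least-squares scale
factor mapped into the intersection of the calibration intervals (the
nearest feasible endpoint is used when the unconstrained optimum falls
outside; an empty intersection is an error with diagnostics). This is not
a relative-rate dating method — supplying a real chronogram is always
preferable — but all downstream rate arithmetic needs only branch
durations. Two-interval calibrations in the hundreds-of-My range (such as
582–878 My and 252–486 My deep-node constraints) are the intended use.

Rates per My come from **through-origin** ordinary least squares of
per-branch counts on branch durations, split into terminal and internal
branch classes. Through-origin is a modelling choice: a branch of zero
duration must carry zero expected events. SE, two-sided p, and adjusted R²
(computed about zero, as is standard for no-intercept fits) are reported.
Substitution counts per branch are branch length × total aligned residues
(e.g. a 1e-4 subs/site branch over a 226,778-residue concatenation carries
22.7 substitutions). Fixation regressions pair each *internal* branch with
the count of items fixed at its child node — terminal branches are
excluded by definition, since a strain-specific item is not fixed — and
the attachment to the child node is a documented convention (the
literature leaves the pairing unstated).

## Genomic islands and the sharing network

Islands are regions enriched in recently gained genes: 10-kb windows slide
every 100 bp; a window qualifies when gained-CDS nucleotides exceed 50% of
all coding nucleotides in the window, both clipped to the window (windows
with no coding bases never qualify). Maximal runs of qualifying windows
are merged — including runs whose spans overlap, which happens because the
window is two orders of magnitude wider than the step — and each region is
trimmed inward until its first and last genes are full-length gained
genes; islands of fewer than 2 genes are dropped (a 1-gene region cannot
both start and finish with distinct boundary genes). Circular genomes
wrap; an island spanning the origin is reported with end < start and a
wrap flag.

One geometric consequence worth knowing: with 900-bp CDS and 100-bp gaps
in a ~90%-coding background, a 5-gene island contributes 4,500 gained
coding bases while the rest of a 10-kb window holds ~4,590 — a ratio of
0.4995, strictly below the 50% rule. Five-gene islands of those dimensions
are therefore undetectable *by construction*; recovery experiments plant
islands of 6–8 genes.

The island-sharing network has one node per (strain, island) pair and an
edge whenever two islands of *different* strains share at least 10% of
their pooled gene content (Jaccard similarity ≥ 0.1 — the published
wording "distance higher than 0.1" is read as its own gloss, sharing ≥10%,
since connecting near-disjoint islands would be meaningless). Edges carry
the similarity and the patristic distance between the strains on the
core-protein tree. Modules come from Louvain modularity with a resolution
parameter that scales the null-model term (igraph's convention; resolution
0.2 therefore favours coarser modules, and module counts are
non-decreasing in the resolution). Node order is fixed by sorted ids and
the seed pins the optimiser, so assignments are reproducible; no claim is
made of matching any particular GUI tool's trajectory.

## Tree space: gene content vs core phylogeny

`phyletic_distances()` computes binary Jaccard distances between strains'
family repertoires (via vegan); the default scope keeps all families —
universally shared families shift all distances equally and harmlessly —
and a `non_core` scope excludes families present in every strain, for the
reading in which the gene-content tree is built from accessory families
only. Neighbour joining (ape) builds the dendrogram; bootstrap resamples
pattern *columns* (families), not distance entries. For additive input
matrices NJ reconstructs the generating topology exactly (RF = 0, path
lengths to 1e-9), which the tests exploit as an oracle.

The branch-length comparison takes, for each clade-base node, the mean
path length from the node to its descendant leaves ("external") over the
node's parent-edge length ("internal"), in both trees, and applies a
paired Wilcoxon signed-rank test to the per-node ratio differences. "The
paired Mann–Whitney test" of common usage *is* the signed-rank test; the
package says so explicitly to avoid ambiguity. Exact p-values (n ≤ 25) are
computed by convolution over doubled average ranks, which stays exact
under ties — the textbook constant-shift example (ten +1 differences) has
fully tied ranks and p = 2/2¹⁰; the normal approximation with continuity
correction takes over for larger n, and all-zero differences
short-circuit to p = 1.

## Clade-specific variants

A column of a single-copy core alignment carries a variant specific to a
strain set when all set strains share one residue and no outside strain
carries it. Columns with gaps are excluded by default (conservative); a
`gap_as_state` policy treats the gap as a 21st state that may satisfy
"any other amino acid" outside the set but can never be the set residue.
Per-protein counts are normalised by *alignment* length (the gap-column
question does not arise in v1 alignments; for real alignments this choice
is documented in the output). Proteins are ranked within each strain set
by variant density (rank 1 = densest, average ranks on ties), and the
screen keeps proteins whose focal rank is less than 0.33 of the median
rank across background sets — "ranked three times higher" — excluding
single-strain sets from the background, whose densities are dominated by
lineage-private substitutions.

## Sequence statistics

ANI follows the fragment method: the query genome is cut into 1,020-bp
consecutive fragments (tail dropped), each locally aligned to the subject
on both strands; hits with >30% identity over ≥70% of the fragment are
retained; ANI is the mean retained identity, and the conserved-DNA
fraction is the share of the fragmented length covered by >90%-identity
alignments (denominator = fragments × fragment size, so the
self-comparison control is exactly 100%). Both directions are computed and
averaged; AAI instead keeps the *higher* of the two directional values, as
its published protocol specifies, using reciprocal best hits under
BLOSUM62 local alignment. The aligner is injectable: the default nucleotide
backend shells out to `blastn` (fast, and the method's native tool), with
a pure-R Biostrings backend for small inputs and testing. Equivalence with
any particular BLAST parameterisation's published values is not claimed —
only method-faithful behaviour on controlled inputs, which the simulated
identity pairs verify (a 95%-identity pair yields ANI in [94, 96]). GC3
counts G+C at third codon positions, excluding ambiguous bases from both
numerator and denominator.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, with
ground truth for every stage:

* **Chronograms.** Clades are coalescent subtrees (ages 25–45% of the root
  age, internal nodes lifted to ≥15% of the clade age so no terminal
  branch is vanishingly short) grafted onto a balanced backbone whose
  joins are compressed into the oldest tenth of the tree — a rapid deep
  radiation, which matches the short-deep-branches picture of the
  picocyanobacterial radiation and keeps deep gain/loss events on
  branches whose parent has degree 3 (events adjoining a degree-2 root are
  intrinsically unresolvable). The companion substitutions tree multiplies
  branch durations by a subs/site rate (default 5e-4 per My, the scale
  implied by ~100 substitutions/My over a ~226-kAA concatenation) and a
  lognormal per-branch multiplier (mean 1, σ = 0.3; σ = 0 gives a strict
  clock).
* **Gene content.** The root carries N₀ families (default 2,000); each
  branch loses each inherited family with probability 1 − e^(−l·t)
  (default l = 1e-3 per My, the per-family scale implied by ~1.7 losses
  per My over ~2,500-gene genomes) and gains Poisson(g·t) brand-new
  families (default g = 4 per My, the published terminal-branch scale).
  Gains are irreversible per family, so per-branch truth is unambiguous,
  and only families observed in ≥1 tip enter the emitted pattern.
  Replaying the event log reproduces the pattern exactly, for every seed.
* **Genomes.** Ancestral and gained genes are laid head-to-tail (default
  900-bp CDS, 100-bp gaps); a configured number of islands per strain
  (sizes 5–10 by default) is planted as contiguous blocks of
  terminal-branch gains, the remaining gains scattered singly. Island
  extents, in gene indices and bp, are recorded as truth.
* **Alignments.** Core families evolve under a symmetric 20-state
  replacement process; planted set-specific columns overwrite target-set
  strains with one residue and ensure all others differ. Truth is defined
  by a full definition-scan of the *final* alignments, so columns that
  satisfy set-specificity by chance are part of the truth and cannot show
  up as false positives.
* **Sequence pairs.** Substitution-only mutation at a target identity; no
  indels in v1, so realised identity is exactly 1 − mutated/length.

What the generator does **not** emulate: duplication/copy-number dynamics,
lateral transfer of *existing* families between lineages (every gain is a
novel family), GC skew or other compositional structure, recombination,
indels in alignments, and rate heterogeneity beyond the single lognormal
branch multiplier and the per-family gamma multiplier of the inference
model. Passing tests therefore demonstrate correctness of the algorithms
under the stated statistical structure, not robustness to annotation
error, alignment error or orthology mis-clustering in real data.

## Problem sizes used in the checks

The recovery experiments run at sizes chosen to make the statistical
guarantees sharp while remaining quick to reproduce: exhaustive-enumeration
cross-checks on 100 random trees of ≤6 leaves; rate recovery on three
replicate 16-taxon chronograms with 2,000 families each; island recovery
on eight 2,000-family genomes with one planted 6–8-gene island each;
module recovery on a 60-node, 3-group planted partition; variant
exactness on 50 families of 100–300 columns across 12 strains; rarefaction
enumeration on 3 genomes against all 6 orders plus a 12-genome persistent
core of 500; NJ reconstruction on twenty 10-taxon additive matrices; ANI
controls on 12-kb simulated pairs; and the branch-ratio direction
experiment on fifty 16-strain simulations with high turnover (g = 2,
l = 2e-3) under a strict clock, where the gene-content tree's
external/internal ratio exceeds the core tree's in essentially every
replicate.
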
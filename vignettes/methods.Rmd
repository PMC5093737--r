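---
title: "Reinforced small-subnetwork analysis of mutual exclusivity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reinforced small-subnetwork analysis of mutual exclusivity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssame)
```

## The model

Tumors accumulate many somatic alterations, few of which drive the tumor.
Genes acting in the same cancer pathway tend to show *mutually exclusive*
alteration patterns across patients, and pathway members tend to be close
on protein interaction networks. `ssame` combines both signals: it searches
an interaction network for small connected gene sets whose alterations are
mutually exclusive across samples, and accumulates this evidence per gene
through a reinforced-learning iteration.

Inputs are an undirected gene network (edge-list TSV or SIF) and a binary
gene × sample alteration matrix (any qualifying somatic event collapsed to
presence/absence — the score only uses presence). Samples with more than
500 alterations should be removed first (`filter_hypermutators()`):
hypermutators are altered in almost everything and dilute exclusivity.

### Mutual exclusivity score (MES)

For a subnetwork `V` (2–6 genes) let `m(s, V)` be the number of genes of
`V` altered in sample `s`, fixed on the full `V`. Let `S` be the pending
sample set, initially all samples altered in at least one gene of `V`.
Genes are processed in order of decreasing alteration count (ties
lexicographic). Gene `v` collects `b_v = Σ 1/m(s, V)` over the pending
samples altered in `v`, which are then removed from `S` — *a sample
contributes only once*; then

```
MES(V) = Σ_v sqrt(b_v).
```

A perfectly exclusive pattern gives every contributing sample weight 1; the
concave square root makes uniform per-gene coverage score higher than
skewed coverage at equal total (e.g. counts 2/2/2 score 3·√2 ≈ 4.24 versus
4/1/1 scoring √4+1+1 = 4), and co-altered samples are down-weighted by
`1/m`.

**This functional form is a reconstruction.** The published description of
the score is textual (per-sample single contribution, inverse weighting by
`m(s, V)`, per-gene square root favouring uniform coverage, count-ordered
processing); the displayed equation itself is not available in the source
text. The implementation is the minimal form satisfying every textual
constraint, kept behind a single routine (`mes_members()` in
`src/ssame_core.cpp`, mirrored literally by `mes_oracle()` in R) so it can
be swapped if the exact printed form ever surfaces. All numeric MES
expectations in the tests were derived from the in-repo literal oracle,
not copied from published values.

Within one iteration all subnetworks (they share a size) form one ranking
batch; MES is mapped to `rMES = (ascending rank − 1)/(N − 1) ∈ [0, 1]`
(ties averaged, `N = 1` maps to 1), so 0 is least and 1 most evidence for
mutual exclusivity. Ranking per iteration rather than across the whole run
keeps batches size-homogeneous; whether ranking should ever span sizes is
left open by the method's description.

### Reinforced iteration

All network genes start at `g = 0.5`. Per iteration, per seed gene (any
gene altered in ≥ 1 sample and present in the network) one subnetwork is
grown from the seed, adding one frontier gene at a time with probability
`score/Σ scores` until the iteration's size (cycle 3, 4, 5, 6) or a dead
end; a stalled subnetwork of ≥ 2 genes is still scored — discarding it
would silence small components — and an isolated seed contributes nothing
that iteration. If the whole frontier has score 0 the draw is uniform, so
growth cannot deadlock. Then, for every gene,

```
g ← min(1, f·g + r·best(g))
```

with `best(g)` the maximum rMES over this iteration's subnetworks
containing the gene (0 if none — such genes decay). Defaults `f = 0.995`,
`r = 0.005`, 5000 iterations. With constant `best = m` the update has the
fixed point `min(1, r·m/(1 − f))`, which explains why performance peaks on
the `r + f ≈ 1` diagonal: there, the fixed point equals `m` itself and the
stationary score reproduces the gene's typical evidence level. Small `f` or
large `r` make the iteration noise-dominated; `r + f` well below 1
compresses all scores toward 0.

Genes are ranked by the maximal score they reach, ties by convergence
speed, then lexicographically. `convergence_iter` is defined as the first
iteration from which the score stays at or above 99% of its final maximum
(`T + 1` if it never settles); the method's description only says "how
fast their score converges", so the 0.99-retention definition is a package
choice. Early stopping (the source names none) is a package choice too:
stop when the set of the 100 highest-scoring genes is unchanged for 500
consecutive iterations; `stop_patience = 0` disables it, which the
closed-form decay tests use.

Each gene also retains its five highest-MES subnetworks across the whole
run (bounded best-of list, ties broken on the sorted gene list);
`extract_pattern()` returns the union of a prioritized gene's retained
subnetworks as its mutual exclusivity pattern. There is *no guarantee that
all genes within a retrieved pattern are mutually exclusive with each
other* — the union may merge several patterns that each involve the
prioritized gene.

### Bootstrap

`bootstrap_rank()` reruns the full procedure on `B` (default 1000;
tests use 25) resamples of the sample columns (with replacement, equal
size) and re-ranks genes by the smallest rank threshold `t` at which the
gene is ranked ≤ `t` in at least 95% of replicates; earlier attainment
ranks higher, ties by higher support, then gene name. A gene absent from a
replicate's output counts rank +∞ there. The threshold scan runs to the
number of genes (the source states no cap). Child seeds are drawn
deterministically from the master seed.

## Synthetic data: what it emulates, and what not

`simulate_study()` reproduces the method's validation protocol:

* **Test network** — preferential attachment grown to exactly
  `round(n·k/2)` edges (default mean degree 4), connected, hub-dominated:
  a stand-in with interaction-network-like local structure, not a real
  interactome.
* **Target pathway** — a random walker with 5% restart from a random start
  gene until 20 distinct interactions are visited, capped at 20 genes
  (dropping last-added genes; the kept prefix stays connected). The edge
  cap is primary — a 20-edge walk can touch 21 nodes — and repeat visits
  to an edge do not count twice.
* **Alterations** — exactly `round(0.30·n)` samples get one alteration in
  one target gene (round-robin over a random permutation, so per-gene
  counts are near-uniform — the regime the score is designed to reward);
  each signal sample has a 5% chance of one extra alteration in a second
  target gene (non-perfect exclusivity). The 30% is implemented as an
  exact count rather than per-sample Bernoulli so downstream expectations
  are deterministic; the 5% co-mutation applies to signal samples only
  (reading the protocol's "allowed for non-perfect mutual exclusivity
  module" as a property of the planted module).
* **Background** — every sample receives `k_s` alterations at random
  non-target genes. The validated protocol copies per-sample counts from a
  real breast-cancer cohort (mean ≈ 50 mutated genes per sample on a
  ~10⁴-gene network), which is out of scope to download. The default
  stand-in is a negative binomial (dispersion 5) whose mean is
  `0.005 · #background genes`: this keeps the *per-gene* background
  alteration frequency — the quantity MES competes against — at the real
  cohort's level on any network size, and reproduces the mean of 50 at the
  10⁴-gene scale the published number refers to. Applying "mean 50"
  verbatim to a 500-gene test network would make background genes ~10%
  altered per sample, ~20× the real regime; random background sets would
  then out-score the planted pathway and the benchmark would invert the
  method's own premise. An explicit per-sample count vector is accepted
  verbatim for users who have real counts.
* **Perturbations** — deletion or addition of 10/25/50% of edges models
  under-/over-connected reference networks; the target is always drawn on
  the unperturbed network, the analysis runs on the perturbed one.

A green simulation test therefore establishes that the implementation
recovers a planted, connected, near-uniform mutually exclusive module
against random background on a scale-free network — not that it finds
drivers in real tumors: real data have correlated passenger mutations,
non-uniform driver frequencies, subtype structure and noisy networks, none
of which are emulated. No mutation-type realism (SNV vs CNA), no
hypermutator simulation.

## Numerical choices and degenerate inputs

* Gene identifiers are case-sensitive opaque strings; no symbol
  normalization. Self-loop edges keep their gene as an isolated node.
  Altered genes missing from the network are tracked (decaying score,
  reported at startup) but can never be selected.
* Processing order ties and all ranking ties break lexicographically, and
  the compiled core indexes genes in sorted order, so tie-breaks are
  identical in R and C++ and runs are bit-reproducible from `rng_seed`
  (all randomness, including in compiled code, is drawn from R's RNG
  stream).
* `r = 0` (pure decay) is accepted although the operational range is
  `0 < r < 1`: the degenerate case underpins the closed-form diagnostics.
* Scores are stored per iteration as 32-bit floats for the convergence
  scan; maxima are tracked in doubles so `max_score ≥ score` holds
  exactly.
* MES of a subnetwork with no altered samples is 0; `rank_mes()` of a
  single-element batch returns 1.

## Known limitations

* The MES equation is a reconstruction (above); absolute MES values should
  not be compared against published numbers, only used as within-run
  ranks.
* The "overlap penalty" of the reconstructed score is not globally
  monotone: for subnetworks of ≥ 3 genes, making an exclusive sample
  co-altered can *raise* MES when the halved weight moves to an
  earlier-processed gene with little pending mass
  (`test-me_scoring.R` carries a worked counterexample: A and B share ten
  samples, C has two private ones; co-altering one of C's samples in B
  raises the fixed-order score from 3.650 to 3.943). For gene pairs the
  penalty is provably monotone under the canonical order, and that is what
  the property test asserts.
* At small cohort/network scale, scores do not split cleanly into a
  0/1 bimodal distribution: every seed is in its own subnetwork each
  iteration, so background genes equilibrate near their expected best
  rMES rather than at 0. The stability claim that *is* asserted: genes
  that reach a high score stay high (< 5% of genes with max score > 0.9
  end below 90% of it).
* Bootstrap reruns are sequential and dominated by `B` full runs; at the
  published `B = 1000` expect roughly `1000×` a single run's cost.
* The exported "Cytoscape-compatible" files are plain ranked/node/pattern
  TSVs, a stated substitute rather than a reproduction of any specific
  session format.
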
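---
title: "Boolean analysis of macrophage polarization: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean analysis of macrophage polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(macboolnet)
```

## The model

macboolnet implements deterministic synchronous Boolean dynamics. A network
is an ordered roster of nodes, one update rule per node over {AND, OR, NOT,
constants}, and an optional set of clamps. A state is a bit vector (bit *i*
= node *i* in declared order, encoded as an integer); one step evaluates
every rule simultaneously on the same input state. Because the state space
is finite and the map deterministic, every trajectory enters a cycle: a
fixed point ("simple attractor") or a longer cycle. The basin of an
attractor is the number of initial states whose trajectory reaches it;
basins partition the space, so they always sum to `2^(free nodes)` — an
invariant the test suite asserts everywhere.

Assumptions inherited from this modeling style: no kinetic rates or graded
expression (a node is on or off relative to an implicit threshold);
synchronous update (all nodes share one clock), which can create cycles that
asynchronous schemes would not; and receptors treated as constitutive, so
extracellular signals act directly on their transducers.

## The bundled macrophage network

The shipped model (`inst/extdata/models/macrophage_tme_synthetic.txt`) is a
29-node, 60-interaction transcriptional regulatory network of macrophage
polarization in a tumor microenvironment. It is a **reconstruction**: the
original authors distribute their rule file as supplementary material that
could not be obtained in this build environment, so the rules here were
re-derived from the publication's own prose description of the cascades
(HMGB1→TLR4→NFκB; MCSF→NFκB; interferons→STAT1; IL-4/IL-13→STAT6 with
STAT6 inhibiting STAT1 and NFκB through SOCS1 and KLF4; IL-10,
glucocorticoids, TGF-β and adenosines driving STAT3; STAT3 secreting IL-10
and inactivating NFκB; IL-6/hypoxia/TGF-β/adenosines driving HIF1-α;
ERK-dependent IL-6 secretion; Fra-1 feeding TLR4; A2A inhibiting NFκB), with
these conventions:

* **Extracellular inputs persist** (rule = the node itself), reflecting a
  sustained milieu; that is what makes the landscape rich (every input
  combination seeds its own family of attractors).
* **Secreted cytokines follow their transcription factors** (e.g. IL-10 =
  STAT3 | STAT6; IL-12 = NFKB | STAT1), closing the autocrine loops the text
  describes.
* **Self-sustaining TF loops** (STAT1 with IFN-γ, AP-1 and Fra-1
  autoregulation, TLR4 engagement) are included exactly where the
  publication's described transitions require a flipped node to *latch*
  (e.g. a monocyte flipped to STAT1-on must commit to M1, not decay back).

The reconstruction reproduces the printed structural facts (29 nodes, 60
distinct regulator→target pairs counting self-loops, every node with ≥ 2
interactions — i.e. an already-reduced network) and the qualitative claims
the test suite checks: M0 is a fixed point; M0+STAT1(+) → M1;
M1+AP1(+) ⇄ M1M2b; pure M2a/M2c absent in the wild type with M2c emerging
under HIF1-α knockout; TGEM (NFκB=1, HIF1-α=0) keeps the M1 component in
every attractor with reversible M1 ⇄ M1M2d transitions driven by Fra-1 and
TLR4; STGEM (STAT1=1, HIF1-α=0) collapses to exactly {M1, M1M2b, M1M2bM2d,
M1M2d}; and the IgG+A2a breast cancer milieu develops M1M2b/M1M2bM2d while
pure M1 and M1M2d disappear. It does **not** reproduce the original's exact
attractor counts (10,430 wild-type attractors there; 22,368 here), and two
qualitative points diverge: IL-1β latches AP-1 here, so the IL-1β+IL-6
scenario keeps an M2b component everywhere; and pure M2a never stands alone
because STAT6→IL-10→STAT3 is kept coupled. Treat model-level numbers as
properties of the reconstruction, not of the published model.

## Phenotype labeling

Marker logic (fixed, versioned in `default_phenotype_rules()`): M1 = NFKB |
STAT1 | (TNFA & AP1); M2a = STAT6; M2b = AP1 | ERK; M2c = STAT3; M2d =
(TLR4 & A2A) | HIF1A; no match = M0. Hybrid labels concatenate matches in
the fixed order M1 < M2a < M2b < M2c < M2d so "M1M2b" can never appear as
"M2bM1". Cyclic attractors are labeled per state from the canonical start
(smallest encoding), consecutive duplicates collapsed (wrapping), joined
with "/".

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `cap` (enumeration) | 30 free nodes | hard refusal above 2^30 states; a 29-node run needs ~4.5 GB (successor table + labels, 4 bytes each per state) |
| `n_pairs` (Derrida) | 10,000 | sampled state pairs, stratified over Hamming distances 1..N so the curve covers the whole axis (uniform pairs concentrate near N/2) |
| `n_samples` (sensitivity) | 50,000 | binomial SE ≈ 0.002 at p ≈ 0.1 |
| flip pool (sensitivity) | all N nodes | a copy rule scores 1/N, a constant 0; `inputs_only = TRUE` rescales to the function's own inputs |
| `k_range` (clustering) | 10..30 | candidate k for k-means on the 2D embedding; consensus by majority vote of silhouette, Calinski–Harabasz, Davies–Bouldin (negated), Dunn |
| `alpha` (regime test) | 0.05 | chi-squared goodness-of-fit level |

## Numerical and algorithmic choices

* **Engine.** Rules compile to postfix bytecode; the successor of all
  `2^n` states is computed 64 states at a time with bitwise word operations
  plus a 64×64 bit transpose, then cycles and exact basins are found by
  path-following with an integer label array. The same bytecode drives a
  scalar path for single steps and trajectories. Correctness is pinned by a
  pure-R naive oracle (recursive expression evaluation, one state at a
  time) on fixtures and dozens of random networks, and was cross-checked
  against an independent reference implementation during development.
* **Canonical forms.** Attractor cycles are rotated so the smallest
  encoding comes first; landscapes sort attractors by that key. This makes
  repeated runs byte-identical.
* **Clamps.** A clamp replaces a rule by a constant; enumeration runs in
  the free-node subspace and re-inflates encodings, so a k-clamp landscape
  has exactly `2^(N-k)` states. Conflicting re-clamps are errors, silent
  override would corrupt perturbation layering.
* **Regime test.** The published procedure compares binned mean one-step
  Hamming distances against the identity line with a chi-squared
  goodness-of-fit before the first crossing. Applied to *normalized*
  distances the statistic degenerates (expected values ≪ 1), so the test
  here works on the bit-count scale; the statistical oddity of treating
  averaged distances as counts is retained deliberately for fidelity. At
  least 3 bins are always used; an all-zero curve is "ordered" without a
  test.
* **Sensitivity aggregate.** `network_mean` is the plain mean of per-node
  flip probabilities (≤ 1 by construction when flips range over all N
  nodes); `expected_spread = N × mean` is the quantity whose position
  relative to 1 separates ordered from chaotic dynamics and is what the
  robustness tests assert.
* **Embedding.** An exact (dense) t-SNE with van der Maaten's adaptive
  gains, early exaggeration and a floored learning rate; duplicate binary
  patterns are collapsed before embedding (guaranteeing identical patterns
  share coordinates and clusters) and PCA substitutes above 2,000 distinct
  patterns, where a dense t-SNE is impractical. Everything is seeded;
  k-means restarts draw initial centers from distinct embedded points to
  avoid coincident-center failures.
* **Fate maps.** The published random bit-flip probing is replaced by the
  deterministic superset: every state of every attractor × every free node.
  Reversibility is judged at the label level (some flip on a reached target
  attractor returns to an attractor with the source label), matching the
  figure semantics of arrows between phenotype labels; witnesses are stored
  and re-checkable.

## What the synthetic generators emulate

`random_network(n, k, p, seed)` draws the classic N-K ensemble (k distinct
inputs per node, self-inputs allowed, truth-table rows 1 with probability
p). That is the ensemble for which the annealed approximation predicts a
Derrida initial slope of `2 k p (1 - p)` — the property tests use k = 2,
p = 0.5 (slope 1, critical). `fixture_catalog()` ships four tiny networks
with hand-enumerated landscapes (identity, toggle, negation ring, constant).
These stand in for real rule files in every pipeline test, so a green suite
establishes engine and bookkeeping correctness — it does not establish
anything about the biology of the bundled reconstruction beyond the
qualitative claims listed above, and it cannot certify the original
publication's exact counts.

## Known limitations

* The bundled model is a reconstruction; its attractor counts are not the
  published ones (documented above and asserted nowhere).
* Synchronous semantics only; no asynchronous or probabilistic updates, no
  SBML-qual import/export, no multi-valued logic.
* Exhaustive enumeration is memory-bound near the 30-free-node cap.
* The cluster-validity battery is a reproducible 4-index stand-in for the
  publication's unspecified 30-metric consensus; the consensus k is
  reported, not asserted.
* The regime chi-squared inherits the published procedure's statistical
  informality; use the Derrida slope and `expected_spread` for a
  quantitative reading.
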
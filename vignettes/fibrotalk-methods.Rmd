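---
title: "Functional cross-talk analysis of disease gene lists: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional cross-talk analysis of disease gene lists: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrotalk)
```

# The scientific problem

Fibrosis — excess deposition of connective tissue after chronic inflammation
or injury — occurs in many organs (eye, heart, liver, intestine, lung,
pancreas, kidney, skin), and the recurring histology suggests shared
molecular machinery. Given curated gene lists for several fibrotic
diseases, a functional-association network (STRING-style, with edge
confidence scores 0–999), and gene-set catalogs (GO terms and KEGG
pathways, treated uniformly as "features"), `fibrotalk` asks three
questions:

1. Which functional features discriminate each disease's genes from the
   rest of the genome?
2. How surprising are the overlaps among the disease gene lists, for every
   one of the $2^k - 1$ disease combinations?
3. What does the induced network around two diseases and a shared
   functional term look like (the "cross-talk" subnetwork)?

# The enrichment encoding

Genes are represented by functional profiles built from their network
neighborhoods. For a gene $g$, let $S(g)$ be its direct neighbors in the
(threshold-filtered) network — $g$ itself is excluded by default, since a
functional association is a relation to *other* genes; an `include_self`
switch exists because the choice is consequential and conventions differ.
For a term $t$ with $M$ annotated genes in an $N$-gene universe, and
$n = |S(g)|$, $m = |S(g) \cap t|$, the feature value is

$$\mathrm{score}(g, t) \;=\; -\log_{10} \; P(X \ge m), \qquad
  X \sim \mathrm{Hypergeom}(N, M, n),$$

the upper-tail hypergeometric probability that a uniform random
neighborhood of the same size would overlap the term at least as much. The
tail is accumulated in log-space (log-gamma binomials combined by
log-sum-exp) and clipped below at $10^{-320}$ so scores are always finite;
$m = 0$ gives exactly $p = 1$ and score 0.

Choices a user should know about:

* **Universe $N$** defaults to the number of nodes in the loaded network,
  keeping the test self-consistent with the neighborhoods it evaluates; an
  explicit genome-scale $N$ can be supplied.
* **Edge confidence threshold** for defining $S(g)$ defaults to 0 (all
  listed edges) and is exposed in the readers; published analyses are often
  silent on this, so it is a parameter rather than a constant.
* Terms with no gene in the universe produce all-zero columns (with a
  warning) instead of being dropped, so feature indices are stable across
  runs; `min_term_size` optionally filters instead.
* No multiple-testing correction is applied to the encoding: the scores
  are covariates for the feature selector, not inferential endpoints.

# Monte Carlo feature selection

For each disease, genes flagged for it are positives and all other genes
negatives, and the discriminating features are found with Monte Carlo
feature selection: $s$ random feature projections of size
$m = \max(\lceil 0.05\,d \rceil, 2)$ are drawn; each projection is trained
and evaluated on $t$ independent stratified train/test splits with a
binary entropy-gain decision tree; and each feature accumulates relative
importance

$$RI_g \;=\; \sum_{\tau} \mathrm{wAcc}_\tau^{\,u}
   \sum_{\text{nodes of } \tau \text{ splitting on } g}
   IG(\text{node}) \left( \frac{n(\text{node})}{n(\text{root})} \right)^{v},$$

where $\mathrm{wAcc}$ is the mean of per-class recalls on the test part.
Defaults: $s = 1000$, $t = 5$, train fraction $2/3$, $u = v = 1$. Trees
use midpoint thresholds, stop on pure nodes or fewer than $2 \cdot
\texttt{min\_leaf}$ samples, and break ties deterministically (lowest
feature index, then lowest threshold).

Deliberate design points:

* **Class imbalance.** Disease lists have tens to hundreds of positives
  against thousands of negatives; a tree trained on the full imbalance
  degenerates to the majority class. The default `"balanced"` mode
  subsamples the majority class of each *training* part down to the
  minority count (a fresh subsample per split, so over hundreds of trees
  most negatives are seen), while the test part keeps its natural
  imbalance — which is why accuracy is class-averaged. A `"full"` mode
  preserves the literal protocol for comparison.
* **`min_leaf = 5`.** Very deep splits on a handful of samples contribute
  pure noise to the importance aggregate and inflate the null
  distribution's tail; a modest leaf size keeps the trees honest without
  hurting genuine splits, which in these encodings separate dozens of
  samples at a time.
* **Significance.** The whole procedure is re-run on `n_permutations`
  label-permuted copies; each run's maximum RI is recorded and the cutoff
  is the $\lceil (1-\alpha)(B+1) \rceil$-th order statistic of the $B$
  maxima — the permutation-test convention under which a fresh null run
  exceeds the cutoff with probability $\approx \alpha$ family-wise. With
  the plain $(1-\alpha)B$ quantile at $B = 20$ the realized family-wise
  rate would be $2/21 \approx 0.095$, nearly double the nominal level.
* **Determinism.** Every projection, split, subsample and permutation
  draws its seed from the master seed through a labelled counter hash
  (`derive_seed`), so results are independent of execution order and a
  disease can be added without perturbing the others.

# Exact multi-set intersection statistics

For $k$ gene sets of sizes $n_1, \dots, n_k$ drawn independently and
uniformly from an $N$-gene universe, the distribution of
$|A_1 \cap \cdots \cap A_k|$ is computed by chaining hypergeometric
kernels: by exchangeability the running intersection after $j$ sets is a
uniform random subset of its size, so

$$D_1 = \delta_{n_1}, \qquad
  D_j(t) = \sum_s D_{j-1}(s)\, P(\mathrm{Hypergeom}(N, s, n_j) = t).$$

The expectation has the closed form $N \prod_i (n_i / N)$, fold enrichment
is observed/expected (reported as missing when the expectation is 0), and
the p-value is the upper tail from the chained PMF. All $2^k - 1$ disease
combinations are enumerated, ordered by degree; degree-1 rows are
descriptive (p-value 1), mirroring how multi-set overlap tables are
usually published. Probabilities are accumulated in linear space; chain
states with mass below $10^{-18}$ are pruned and the pruned total is
asserted below $10^{-12}$.

The universe $N$ defaults to the number of genes in the membership matrix
(the union of the disease lists). Published analyses rarely state the
background their overlap statistics used, and the union is the one
self-contained choice; a genome-scale background can be passed instead,
which shrinks every expectation and sharpens every p-value. The
independence-and-uniformity assumption is inherited from the combinatorial
framework: curated disease lists are neither independent nor uniform, so
the p-values are descriptive weights of surprise, not literal error
rates.

# The synthetic benchmark

Real inputs (curated disease lists, STRING snapshots, GO/KEGG releases)
are large, versioned and license-encumbered, so the package ships a
generator that emulates all three inputs with planted, recoverable
signal:

* **Network**: preferential-attachment topology (heavy-tailed degrees, as
  in functional-association databases) with a target mean degree; edge
  confidence uniform in [150, 999].
* **Annotations**: each term grows from a seed gene, extending with
  probability `locality` to network neighbors — chosen proportional to
  the squared number of edges they already have into the term (triadic
  closure, giving dense module-like terms as in curated catalogs) — and
  uniformly otherwise. `locality = 0` gives uniform random sets,
  `locality = 1` connected modules.
* **Disease signal**: each disease receives a functionally coherent group
  of driver terms (an anchor plus the terms whose modules lie closest to
  it — real disease pathways are related, not independent). A
  `signal_strength` share of the positive quota is split evenly across
  the drivers and drawn proportional to the *squared* fraction of a
  gene's neighbors annotated to that driver, concentrating positives on
  each module's core adjacency — precisely the quantity the enrichment
  encoding measures. The remaining quota is uniform. At
  `signal_strength = 0` positives are exactly uniform, giving a clean
  null.

The default configuration mirrors the scale of the eight-disease fibrosis
study it emulates: eight diseases with 39, 207, 173, 150, 185, 43, 160
and 125 positives over a 1200-gene universe with 300 terms. The
recovery benchmark used in the tests plants 5 drivers among 200 terms
with 100 positives on a 2000-gene universe (mean degree 5, term sizes
6–12) — sizes chosen so that driver modules are compact relative to the
universe and the planted contrast survives encoding, while one replicate
runs in about a minute.

What the generator does *not* emulate: shared hub biology between
diseases beyond what coherent driver groups induce, annotation bias
toward well-studied genes, literature curation artifacts, and the
incomplete / noisy edges of real interaction databases. Passing recovery
tests therefore demonstrates that the pipeline's machinery is sound and
calibrated, not that any particular biological claim holds on real data.

# Numerical and degenerate-input policy

* Hypergeometric tails in log-space; probabilities clipped to
  $[10^{-320}, 1]$; scores finite and non-negative by construction.
* Genes absent from the network (or isolated) are retained with all-zero
  profiles rather than dropped, keeping the matrix and encoding
  row-aligned.
* Reciprocal duplicate edges keep the maximum score; self-loops are
  skipped with a warning; malformed matrix cells and GMT lines fail fast
  with row/line identification.
* Tree ties (equal gain within $10^{-12}$ bits) resolve to the lowest
  feature index, then the lowest threshold; leaf-label ties resolve to
  class 0.
* Report floats are serialized with 6 significant digits and round-trip
  through the matching readers.

# Problem sizes in the shipped tests

The test-suite checks run at deliberately small scales: exhaustive
enumeration oracles up to $N = 12$ (enrichment) and $N = 8$, $k \le 3$
(multi-set, all $\binom{N}{n}^k$ tuples); Monte Carlo cross-checks at
$10^5$ draws; recovery at 10 seeded replicates of the benchmark above;
null calibration at 100 scaled-down replicates; and a full pipeline run
on a 400-gene, 8-disease, 60-term configuration executed twice and
compared byte-for-byte. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch at
the same scales.

# Known limitations

* The intersection framework's independence assumption is knowingly wrong
  for curated lists; treat p-values comparatively.
* Enrichment scores for hub genes (large $n$) are systematically more
  extreme than for peripheral genes; the feature selector sees this as
  legitimate signal, which is intended, but users comparing raw scores
  across genes should note it.
* No GO-DAG propagation or KEGG hierarchy handling: annotations are used
  exactly as given.
* Gene identifiers are opaque case-sensitive strings; any symbol
  harmonization must happen upstream.
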
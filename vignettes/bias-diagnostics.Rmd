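---
title: "Diagnosing compositional bias and missing-data structure in phylogenomic supermatrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing compositional bias and missing-data structure in phylogenomic supermatrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasdiag)
```

## The problem

Concatenated amino-acid supermatrices routinely recover strongly
supported clades that later turn out to be artifacts. Two
nonphylogenetic signals are the usual suspects. First, *compositional
bias*: lineages whose proteins drift toward a similar amino-acid usage
attract each other under stationary substitution models, regardless of
their true relationships. Second, *structured missing data*:
EST-derived supermatrices are often half empty, with absences
concentrated in gene-sized blocks per taxon, and taxa that share the
same absent genes can cluster for reasons that have nothing to do with
history. `biasdiag` implements a diagnostic battery for interrogating a
*fixed* input topology: it never infers trees, it asks whether the
characters supporting a focal clade look the way genuine signal should
look.

## The diagnostics

### Parsimony mapping and apomorphy subsets

Substitutions are mapped onto the rooted input tree by unordered
(Fitch) parsimony. Per-column minimum change counts use Hartigan's
k-ary generalization, so polytomies are handled natively; a missing tip
contributes the full state set at no cost. A single most-parsimonious
reconstruction is then fixed with ACCTRAN (accelerated transformation):
processing branches preorder, a change is placed on the current branch
whenever some most-parsimonious reconstruction consistent with the
decisions already made allows it — changes are pulled rootward. Ties
that survive the ACCTRAN criterion, including the root state, are
broken alphabetically so every run is exactly reproducible. Two
independent routes — set-based Hartigan counting and the Sankoff
dynamic program underlying the ACCTRAN assignment — must agree column
by column, and both are checked against exhaustive enumeration over all
internal-state assignments on small random instances in the test suite.

A column is an *apomorphy* of a focal clade when the reconstructed
state at the clade's most recent common ancestor differs from the
reconstructed state at its direct ancestor, with neither missing.
Columns whose focal node or direct ancestor subtends an entirely
unobserved subtree are reconstructed as missing and excluded: the
composition of unobservable states is undefined. Counting is per
column, not per inferred substitution. The positional spread of
apomorphy columns along the alignment is summarized by a one-sample
Kolmogorov–Smirnov statistic against the uniform distribution —
apomorphies piling up in a short stretch point at contamination or
misassigned orthologs rather than genuine signal; the KS number is a
screening diagnostic, not a formal test.

### The node-based compositional test

For a focal clade the subset of interest is the alignment restricted to
its apomorphy columns, comprising every terminal taxon plus two
reconstructed rows: the clade ancestor and its direct ancestor. Each
ancestral row is tested against the pooled composition of the whole
subset (itself included) with the classic chi-square homogeneity test:
expected counts $e_i = n \cdot \pi_i^{\text{pool}}$, statistic
$\sum_i (o_i - e_i)^2 / e_i$ over states with $e_i > 0$, and degrees of
freedom fixed at 19 even when states are absent from the pool — the
convention of the tool that popularized this test. No multiple-testing
correction is applied; p-values are reported raw.

The logic of the readout: a clade held together by genuine signal
should have an ancestral sequence whose composition at its apomorphy
columns resembles the subset average (large p at the clade ancestor),
whereas a clade assembled by compositional attraction shows a deviating
clade ancestor while its direct ancestor — one node deeper, outside the
biased group — does not deviate.

### What the test does, and does not, guarantee

The chi-square machinery itself is well calibrated: when focal counts
are genuine multinomial draws from the pool frequencies, the rejection
rate at $\alpha = 0.05$ sits inside the exact binomial band (asserted
in the suite with 1,000 simulated draws). The *pipeline* wrapped around
it is a different matter, and our synthetic world quantifies this
honestly: under a fully homogeneous null, the clade-ancestor test
rejects at roughly 30%, not 5%. The mechanism is reconstruction
conditioning, not an implementation defect. Apomorphy columns are
selected because parsimony reconstructs a stem change there, which
filters the derived states (a derived state that recurs elsewhere in
the tree tends to abort the apomorphy call, mildly enriching rare
states), and deterministic tie-breaking skews deep-node rows further.
Replacing the reconstructed stem states with the simulator's true
ancestral states restores chi-square statistics near their degrees of
freedom, isolating the cause. The practical reading: small p-values at
the focal node should be interpreted comparatively — against the
direct ancestor and against other clades of the same tree — rather
than as literal tail probabilities. This caveat applies equally to the
original protocol this package reimplements, which could not be
measured against a known truth.

### Compositional ordination

Pairwise compositional distances are one half the sum of squared
differences in residue *counts* — deliberately on raw counts, matching
the method's classical definition, although rows with very different
numbers of observed residues then dominate; `normalize = TRUE` switches
to frequencies. The distance matrix is embedded by non-metric
multidimensional scaling minimizing Kruskal stress-1,
$\sqrt{\sum(\delta - \hat d)^2 / \sum \delta^2}$, with disparities
$\hat d$ fit by pool-adjacent-violators isotonic regression under
Kruskal's primary approach to ties (tied dissimilarities ordered by
current configuration distance). Optimization is SMACOF iterative
majorization with the classical-scaling solution as first start and
random restarts thereafter; an update that fails to improve stress-1 by
the tolerance (1e-7, at most 500 iterations) is discarded, so the
stress trace is non-increasing by construction. Determinism is
guaranteed by the (seed, n_restarts) pair. The suite checks
self-recovery of planar configurations (stress < 1e-3), invariance
under strictly increasing distance transforms, and competitiveness with
an independent NMDS implementation.

### Missing-data analytics

Coverage accounting, the inclusive $\geq 50\%$ per-position taxon
coverage filter, and the gene admission rule (at least 100 positions
and at least 25 taxa with data, both inclusive) are exact mechanical
operations, tested on boundary fixtures. The shared-missingness overlap
matrix $o(i,j)$ — the fraction of columns missing in both taxa — is
clustered by UPGMA (average linkage on $1 - o$; configurable), and the
dendrogram's leaf order fixes the heat-map ordering on both axes. Taxa
forming a tight overlap clan that matches a recovered clade are a
warning sign. Mapping missingness on the tree recodes every cell as
present/absent and reuses the ACCTRAN engine on the two-state alphabet;
since parsimony cannot orient a root tie between one loss on either
basal stem, root ties resolve to "present" — a gene is ancestrally
present and lost along lineages — which is also what the published
recoding protocol implies. One cell convention applies throughout:
indel gaps and unsequenced genes are both "missing" (`-`, `?`, `X`,
plus the ambiguity codes B/Z/J/U/O with a warning), because a
concatenated input cannot distinguish them.

## The synthetic world

The generator states a single world and the tests live in it:

* **Tree**: pure-birth (Yule), birth rate 1, grown from the root's two
  daughters with exponential waiting times; after reaching `n_taxa`
  lineages all pendant branches are extended by one final
  $\mathrm{Exp}(n \cdot \lambda)$ draw so no tip branch is zero.
  Expected root height $\sum_{k=2}^{n} 1/(k\lambda)$, asserted against
  1,000 replicates.
* **Sequences**: root drawn from a typical average-proteome amino-acid
  frequency vector; along a branch of length $t$ each site keeps its
  state with probability $e^{-rt}$ and is otherwise redrawn from the
  branch's equilibrium frequencies (an F81-style process — adequate
  because every diagnostic here tests composition, not
  exchangeabilities). Default rate $r = 0.3$ per unit branch length
  gives a root-to-tip substitution opportunity of about 0.7 per site,
  typical of deep metazoan supermatrices.
* **Planted shift**: on the stem of a designated clade and all branches
  inside it, the equilibrium frequencies switch to a shifted simplex at
  a stated total-variation distance from the base (default 0.25; the
  direction is a Dirichlet draw, redrawn if it cannot realize the
  requested distance). This makes the process nonstationary in exactly
  the way compositional attraction requires.
* **Missingness**: per taxon per gene, the whole block is dropped with
  probability 0.5 (about 50% coverage, concentrated in gene-sized
  blocks as in EST supermatrices). The default scale is 16 taxa and 20
  genes of 80–160 columns — a supermatrix scaled down by roughly
  twenty-fold so the whole suite runs in minutes; the `paperlike`
  preset (58 taxa, 196 genes, ~41,000 columns, ~50% coverage) is
  exercised once as a smoke test through every command-line entry
  point.

Every benchmark ships a truth record (tree, shifted node and tips, both
frequency vectors, all true ancestral states, the dropout mask, all
parameters and the seed) sufficient to recompute any planted quantity
without re-simulation, and identical spec + seed reproduce byte-identical
outputs.

What the generator does **not** emulate: among-site rate heterogeneity,
exchangeability structure (everything is composition-driven), indels as
evolutionary events, codon-level effects, or correlated gene dropout
beyond the planted blocks. A green recovery test therefore establishes
that the diagnostics detect a compositional shift of the stated
magnitude under block missingness — not that they would detect every
bias in real data.

## Numerical and design choices

* ACCTRAN formalized as greedy rootward placement over the Sankoff
  dynamic program; correctness is guarded by an exhaustive
  most-parsimonious-reconstruction membership oracle on small trees.
* All user-facing column indices are 1-based; internal storage is
  matrix-native.
* df = 19 in every chi-square regardless of absent states; states with
  zero expectation are dropped from the sum only.
* Distance ties in isotonic regression: primary approach (configuration
  order within tied blocks).
* The position filter's threshold is inclusive ($\geq$), as are both
  gene admission thresholds.
* Degenerate inputs error early with instructions (empty apomorphy
  sets, non-monophyletic focal clades — supply a constrained topology,
  tree inference being out of scope, unrooted trees — root with an
  outgroup first, all-missing columns after filtering).

## Known limitations

The node-based test's absolute p-values are anticonservative for
reconstructed rows (quantified above); the acceptance suite asserts the
stated calibration band anyway and the failure is documented rather
than hidden. Apomorphy counts under ACCTRAN absorb single-taxon
autapomorphies into a clade's stem when sister data are missing —
faithful to the method, but worth remembering when comparing counts
between clades with very different coverage. The compositional distance
on raw counts conflates composition with sequence completeness; use the
normalized variant when coverage is heterogeneous. Finally, NMDS under
Kruskal stress-1 admits the classical degenerate minimum in which the
configuration collapses toward equal inter-point distances
(stress near zero with no usable geometry); strongly cluster-structured
dissimilarity matrices can trigger it here exactly as in other standard
NMDS implementations (we verified identical behavior in an independent
one on the same input) — inspect the embedding, and treat a
near-zero stress on non-trivial data with suspicion.
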
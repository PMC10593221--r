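---
title: "Growing clonal trees from ultra-low coverage scDNA-seq: model and methods"
author: "clonegrower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing clonal trees from ultra-low coverage scDNA-seq: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonegrower)
```

## The problem

High-throughput single-cell whole-genome sequencing platforms such as DLP+
and ACT sequence thousands of tumor cells at 0.01-0.25x mean depth. The
uniformity of that coverage makes binned read counts an excellent proxy for
copy-number aberrations (CNAs), but it leaves single-nucleotide variants
(SNVs) desperately sparse: at 0.01x, a given cell has zero reads at 99 of
every 100 SNV loci. `clonegrower` infers, from this data, a *clonal tree* —
a rooted tree whose nodes carry binary SNV genotypes obeying the infinite
sites model (each SNV gained exactly once, never lost) — together with an
assignment of every cell to a node (the cell clustering $\phi$) and the
clonal genotype matrix $Y$. The key idea is to let the dense copy-number
signal guide the clustering where SNV reads are too sparse, by fusing both
signals into a single feature for a normalized-cut bipartition, and to grow
the tree recursively from a single root using elementary operations.

Inputs are the variant and total read count matrices $A, D \in
\mathbb{N}^{n \times m}$ ($n$ cells, $m$ SNV loci, $0 \le a_{iq} \le
d_{iq}$), and binned read counts $R \in \mathbb{N}^{n \times b}$ or a
precomputed low-dimensional embedding $\tilde{R} \in \mathbb{R}^{n \times
\ell}$ of them.

## Probabilistic model

**Read likelihoods.** Conditional on the genotype of cell $i$'s clone at
locus $q$, the variant read count is binomial in the total count:

* genotype 0: $a_{iq} \sim \mathrm{Binom}(d_{iq}, \alpha)$ with $\alpha$
  the per-base sequencing error probability (default $10^{-3}$);
* genotype 1: the success probability is the variant allele frequency
  $x/y$ of the unobserved allele-specific copy state (variant copies $x$,
  total copies $y$), error-adjusted to $\frac{x}{y}(1-\alpha) +
  (1-\frac{x}{y})\alpha$ and marginalized over all states $1 \le y \le c$,
  $1 \le x \le y$ under a uniform prior. The cap $c$ (default 5) bounds the
  total copy number considered.

Entries with $d_{iq} = 0$ contribute exactly zero under either genotype,
which keeps posteriors comparable across trees. All sums are carried out in
log space with log-sum-exp for the state marginalization.

**Embedding likelihood.** Cells of a clone are modelled as a spherical
normal around the clone's center in embedding space, with a single pooled
spread re-estimated for each clustering by maximum likelihood (floored at
$10^{-4}$ standard deviations to avoid degeneracy). This is the term
through which copy-number similarity informs cell placement.

**Priors.** The prior over tree topologies and over cell assignments is
flat. The per-SNV attachment prior is uniform over the $k$ nodes of the
tree at hand, contributing $-m \log k$ to the log posterior. This term is
deliberately retained rather than dropped as a constant: it differs across
trees with different node counts and is what prevents a Branching result
whose second child carries only a handful of stray, error-driven gains from
always dominating the Linear alternative (the branching hypothesis space
contains the linear one, so their maximum likelihoods are ordered; the
attachment prior breaks that degeneracy in proportion to the data size).

The score reported by `tree_log_posterior()` is therefore the joint log
posterior of $(T, Y, \phi)$ up to a constant, additive over clones.

## The embedding

`normalize_bins()` scales every cell's bin counts to the median library
size and applies $\log_2(x+1)$; `embed_cells()` projects onto the first
$\ell$ principal axes (default $\ell = 10$, mean-centered, unscaled), with
component signs fixed deterministically so repeated runs are bitwise
identical. A linear projection is the default because it is the best
rank-$\ell$ approximation of the data and fully reproducible; the axes are
dominated by segmental copy-number differences between clones. A
user-supplied embedding is accepted verbatim. No GC-bias correction is
applied — counts are assumed corrected upstream where relevant.

## Elementary operations

Growth proceeds by three operations applied to nodes of candidate trees:

* **Linear** replaces a node by a parent-child chain: cells split between
  parent and child, the child inheriting the parent's genotype plus its
  own gains (stepwise acquisition).
* **Branching** replaces a leaf by a parent with two children: cells split
  between the children, shared gains attach at the (cell-free) parent —
  evidence of divergence from a common ancestor.
* **Identity** leaves the tree unchanged and closes the node.

Each of Linear and Branching is solved by coordinate descent. With
genotypes fixed, the node's cells are bipartitioned by a normalized cut:
the per-cell feature is the cell's embedding row, standardized per
dimension over the node's cells, concatenated with one standardized SNV
evidence score — the cell mutational burden (CMB, the fraction of covered
loci carrying a variant read) over the SNVs currently assigned below the
parent. Cells covering none of those loci get the cohort mean imputed and
are flagged. The similarity graph uses a Gaussian kernel whose bandwidth is
the median pairwise feature distance; the cut comes from the second
generalized eigenvector of the graph Laplacian, thresholded at the sweep
position minimizing the exact normalized-cut objective. With the
clustering fixed, every reassignable SNV is attached at the local node
(parent/child, or parent/left/right) maximizing its posterior
contribution, in one pass over the covered entries.

The alternation stops when the cell bipartition revisits any earlier state
(the clustering is discrete, so a revisit implies a cycle that cannot beat
the best iterate already recorded) or after `max_iter` (default 50)
iterations; the best-scoring iterate, not the last, is kept. The operation
runs `restarts` (default 15) seeded restarts, perturbing the kernel
bandwidth by up to ±20% and jittering the sweep threshold. The distinct
restart states are ranked by their local posterior (ties: fewer
iterations); the grower takes the best-ranked state that also passes the
acceptance filters below, so a rejected dominant cut does not silence an
operation whose other restarts found an acceptable split. The side of the
cut with the higher mean SNV evidence becomes the descendant. One operation costs
$O(n^3 + nm)$ in the worst case; in practice the eigenvector is obtained by
a warm-started deflated power iteration, so typical cost is far below the
cubic bound.

**Subdivision of cell-bearing internal nodes.** Linear operations are
applied not only to leaves but to any node that still holds enough cells
and a nonempty gain set; on an internal node the operation subdivides it —
the descendant cell cluster and its gains move to a new intermediate node
that inherits the children. This matters for chain-like ancestries: a
normalized cut has no reason to discover the *top* edge of a chain first,
and with leaf-only operations the cells a Linear parent retains could never
be split again, silently merging ancestral clones. Subdivision makes the
enumeration able to unfold a chain regardless of the order in which the
cuts discover its edges. Branching remains leaf-only.

## Growing and filtering

The candidate set starts from the single-root tree (all cells assigned to
the root, all genotypes 1). Every open node of every candidate tree is
extended by the applicable operations; a result enters the candidate set
only if

1. every modified clone is **detectable**: on average over its newly
   introduced SNVs, at least $t$ of its cells cover each SNV (default
   $t = 3$). This ties clone acceptance to exactly the three quantities
   that determine observability — coverage, clone size, and number of
   introduced SNVs — and yields the expected behavior that large $t$
   prunes aggressively at low coverage;
2. every modified clone has at least `min_clone_size` cells (default
   $\max(10, 0.01\,n)$), a regularizer against cell-level overfitting;
3. the tree passes the **quality check**: for each newly created node with
   gain set $S$, the median CMB over $S$ of cells placed *outside* the
   node's clade (among cells covering at least one locus of $S$) is at
   most `qc` (default 0.025) — outside cells should not carry a clade's
   SNVs.

Candidates are deduplicated by a canonical form hashing each node's gain
and cell sets with its children's canonical forms, and elementary-op
results are memoised on (cell set, SNV set, operation), which transfers
them across candidate trees sharing a subproblem. Enumeration reaches a
fixpoint because each accepted tree strictly increases the node count,
which detectability and the minimum clone size bound; a deterministic cap
of `max_candidates` trees (default 64, well above what typical instances
enumerate) additionally bounds instances whose filters accept many
alternative extensions.

## Post-processing and ranking

Candidates are ranked by their posterior *after* post-processing; since
the raw posterior is a lower bound on the post-processed one, only the top
10 candidates by raw posterior are refined. Post-processing alternates two
coordinate-ascent half-steps, each accepted only if the exact posterior
does not decrease:

1. every SNV is re-attached at its global maximum-posterior node;
2. every cell is re-assigned to its maximum-posterior node under the
   current genotypes. A node that currently holds cells is scored around
   its fitted center with the pooled spread; a cell-free node (such as a
   Branching parent) has no fitted center, so cells are scored there under
   a predictive density centered at the clade's cell centroid with the
   between-clone center variance added to the spread. This wider
   predictive spread is what allows read evidence to move trunk-genotype
   cells *up* into empty internal nodes — with the fitted spread alone the
   embedding term would veto any such move, because no single cell can
   bootstrap an empty cluster.

Two further posterior-guarded proposal families complete post-processing.
*Clone promotion* relocates a node's entire cell set to its parent and
re-attaches the node's gains elsewhere, judged on the contracted tree: the
per-cell argmax can never move a whole cluster out of its own fitted
center, yet retiring a node whose gains lack read support both fits the
data and relaxes the attachment prior. *Subtree-prune-regraft refinement*
(`spr_refine()`, applied to the selected tree) greedily regrafts each
subtree below every node outside it, re-attaching SNVs after each move:
the recursive growth can split a deep clade off near the root as a
sibling, a mis-nesting that no reassignment with fixed topology can
repair. Both families accept a move only if the exact posterior increases,
so the whole pipeline remains coordinate ascent on the model's single
objective.

Finally, nodes with neither cells nor gains are contracted. The number of
nodes can exceed the number of clones in the returned tree; `n_clones()`
counts only cell-bearing nodes.

## The simulator

`simulate_ground_truth()` and `simulate_reads()` generate the study
conditions the package is validated under: a uniform random labelled
rooted tree on $k$ nodes (via a Prüfer sequence, rooted at node 1); 30% of
SNVs truncal, the rest uniform over non-root nodes; clone proportions from
a symmetric Dirichlet (concentration 2 — clone sizes in real tumors are
markedly uneven) redrawn until every clone holds at least 2% of cells;
per non-root edge, 1-3 segmental CNA events (single-allele gain or loss
over a contiguous range spanning 2.5-15% of the bins — arm-scale events at
500 kb bins — capped at $c$ total copies). Each SNV sits in a random bin
on a random allele, so its variant copy number follows that allele through
the CNA history: a deletion of the carrier allele silences a true SNV in
the affected clade, a biologically real infinite-sites violation that the
read model then reflects. Under the optional Dollo mode each SNV is
additionally lost outright on at most one descendant edge with probability
0.05.

Reads follow the coverage model: $d_{iq} \sim \mathrm{Poisson}(g\, y_q/2)$
with $g$ the mean diploid coverage and $y_q$ the clone's total copies at
the locus; $a_{iq} \sim \mathrm{Binom}(d_{iq}, \mathrm{vaf}')$ with the
error-adjusted VAF above; binned counts $r_{ib} \sim \mathrm{Poisson}(g
\cdot 5000 \cdot y_b/2)$, the 5000 reflecting roughly 500 kb bins and
100 bp reads. Sampling exploits sparsity (covered entries drawn per
clone/copy-state block, zero-truncated Poisson depths), so a
1000 × 5000 instance simulates in about a second.

What the simulator does *not* emulate: doublets, GC or mappability bias,
allelic dropout beyond the error rate, read-level artifacts, and variant
calling upstream of the count matrices. Passing tests on simulated data
therefore validates the inference machinery under the stated generative
model, not robustness to those real-data complications.

## Evaluation

`recall_metrics()` scores an inferred tree against the truth by pair
classes: for two items (SNVs or cells), the pair is *clustered* if placed
at the same node, *ancestral* (ordered) if one's node properly precedes
the other's, *incomparable* otherwise. APR is the fraction of
truth-ancestral ordered pairs that are ancestral with the same orientation
in the inference (an inverted pair does not count); IPR and CPR are the
analogous unordered recalls; *accuracy* is the pair-count-weighted average
over classes with at least one truth pair (ordered counts for ancestral,
unordered for the symmetric classes). Counts are accumulated through the
truth-by-inference placement contingency table, so the computation is
exact at any $m$. *Genotype similarity* is one minus the normalized
Hamming distance between cell-level genotype matrices (each cell inherits
its clone's row). `cmb_clade_report()` contrasts within- versus
outside-clade mutational burden per clade, the specificity diagnostic used
on real data.

`baseline_genotyper()` implements the comparison method: cells clustered
on the embedding alone, then each cluster genotyped by pooling reads and
calling $y_{jq}=1$ when the pooled variant/total ratio strictly exceeds
0.05. Clustering uses a Gaussian mixture with BIC-selected component count
(up to 9, or fixed by the caller); model-based clustering plays the role
that density-based clustering plays in the pseudobulk pipelines this
baseline mirrors, and selects the cluster count automatically in the same
spirit.

## Numerical and design choices

* Detectability, the minimum clone size and the quality check are each a
  single function, deliberately isolated so alternative definitions can be
  swapped in.
* Ties in SNV attachment go to the most ancestral candidate (flat
  attachment prior), so a zero-coverage SNV rests at the root.
* The eigensolver tolerance is $10^{-6}$; the eigenvector only feeds an
  ordering and an exact-Ncut sweep, so looser precision does not change
  the cut. Cut results are deterministic given the seed, including the
  no-signal case (identical features), which returns a flagged half/half
  split.
* Coordinate-descent ascent assertions use a $10^{-9}$ tolerance.
* Default problem sizes in the validation suite follow the simulation
  study design at desk scale: $k \in \{5, 9\}$, $n = 1000$, $m = 5000$,
  $g \in \{0.05, 0.1\}$, 5 replicates per setting, default hyperparameters
  ($\alpha = 10^{-3}$, $c = 5$, $t = 5$, `qc` 0.025, 15 restarts, 50
  iterations). A single instance runs in well under a minute.

## Known limitations

* The infinite sites assumption is imposed on the inferred genotypes even
  where CNA deletions violate it in truth; a deleted truncal SNV can then
  only be represented as a later gain, which costs ancestral-pair recall
  on cells. The Dollo simulator mode exists precisely to quantify this.
* Clones below the detectability floor (roughly $t/(g/2 \cdot \bar{y})$
  covering cells) are merged into their neighbors by design.
* The model places no CNA events on the tree; copy number enters only
  through the embedding likelihood and the state marginalization.
* Doublets and allelic dropout are not modelled.

## A worked example

```{r example, eval = FALSE}
library(clonegrower)

cfg <- sim_config(k = 5, n = 1000, m = 5000, g = 0.05, seed = 101)
inst <- simulate_instance(cfg)

fit <- grow(inst$data, model_params(seed = 11))
glance(fit)
tidy(fit)

recall_metrics(inst$truth, fit)
autoplot(fit)
plot_cmb(fit, inst$data)
```
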
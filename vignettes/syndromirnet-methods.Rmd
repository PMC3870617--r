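---
title: "Methods: serum miRNA syndrome profiling with syndromirnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum miRNA syndrome profiling with syndromirnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Serum miRNA arrays in clinical subtyping studies are tiny: a handful of
patients per subgroup (here, three disease-syndrome groups of 3 patients
each against 7 healthy controls) measured on hundreds of miRNAs. The
questions the pipeline answers are, in order: which miRNAs distinguish
each patient subgroup from control; how well the subgroups can be told
apart from expression alone; which genes those miRNAs plausibly target;
what the resulting miRNA-target regulatory network looks like per
subgroup; and which biological processes the up-regulated arm of each
network converges on. `syndromirnet` implements that chain end to end
and ships a generator that produces all four inputs (expression matrix,
per-program target predictions, validated interactions, gene sets) with
known ground truth, so every stage is verifiable without external
databases.

# Differential expression: the random variance model

With 3-vs-7 samples an ordinary t-test's per-miRNA variance estimate is
hopeless. The random variance model assumes each miRNA's true variance
$\sigma^2_i$ is drawn from an inverse-gamma prior, parameterized so that
the precision satisfies $1/\sigma^2 \sim \mathrm{Gamma}(a,\, \text{scale}=b)$.
Under this prior the scaled sample variance obeys

$$ s^2\,a\,b \sim F(f,\, 2a), $$

with $f = n_1 + n_2 - 2$ residual degrees of freedom. $(a, b)$ are
estimated once per comparison by maximizing the corresponding marginal
likelihood over all miRNAs (Nelder-Mead on the log-parameter scale,
started from the moment relation $E[s^2] = 1/(b(a-1))$ at several shape
values; the reported fit is the best of those starts, and `converged`
reflects the optimizer's own status). The moderated test then replaces
$s^2_i$ with

$$ \tilde\sigma^2_i = \frac{f\,s^2_i + 2/b}{f + 2a}, \qquad
   t_i = \frac{\bar x_i - \bar y_i}{\sqrt{\tilde\sigma^2_i\,(1/n_1 + 1/n_2)}}, $$

referred to a t distribution with $f + 2a$ degrees of freedom — always
more than $f$, which is the small-sample power gain. A miRNA is called
significant by the conjunction rule: fold change above 1.5 (checked as
$|\log_2 \mathrm{FC}| > \log_2 1.5$) **and** $p < 0.05$, both
configurable. Two notes on deliberate choices:

* p-values are two-sided (the analysis tradition this follows does not
  state sidedness; two-sided is the conservative default);
* no multiple-testing correction is applied at this stage — the
  conjunction with the fold-change filter is the historical filter; a BH
  switch (`adjust = "BH"`) is available but off by default. FDR control
  enters at the enrichment stage instead.

Fold changes are computed on the log2 matrix *before* per-sample
z-scoring — fold change presupposes the unstandardized scale — which is
why the pipeline keeps two preprocessing branches (below).

# Preprocessing order

Two normalizations are available: per-sample z-scoring (zero mean, unit
sample variance, $n-1$ denominator to match the downstream t
statistics) and per-sample median centering. Their order and assignment
is not uniquely determined by the analysis tradition, so both are
independent switchable steps; the pipeline's default chain is: log2
matrix → median centering for the differential branch, log2 matrix →
z-scoring for the clustering/classification branch. Both preserve
within-sample rank order, so ordering choices never reshuffle a
sample's profile.

# Clustering

Hierarchical clustering uses one minus centered Pearson correlation as
the distance (range $[0, 2]$) with average linkage (UPGMA), matching the
classic Cluster 3.0 defaults. Rows/columns are sorted lexicographically
by id before agglomeration so tie-breaking, and therefore heatmap leaf
order, is deterministic for any input order. Dendrograms export as
Newick; the reordered matrix is written beside them.

# Class prediction

The multi-class question ("which syndromes are separable?") is answered
with a binary tree of linear SVMs. At each node, every bipartition of
the node's class set is scored by repeated stratified cross-validation
(default 10-fold, 10 repeats, degrading gracefully to leave-one-out when
a node has fewer samples than folds), and the best bipartition is kept;
its score is the mean percent correctly predicted. Feature selection — a
univariate equal-variance t-test at $P = 0.01$ — is re-run inside every
training fold, so no test-fold information leaks into the model; the
package's null-data tests verify that CV accuracy then stays at chance.
Because CV on a dozen samples is noisy, a .632 bootstrap percent-correct
(default 30 resamples) is always reported alongside. Kernel and cost are
not dictated by the tradition; linear with $C = 1$ is the standard
choice for $p \gg n$ expression data and both are configurable. Scores
are printed as integer percent; full precision is kept in the exported
JSON.

# Target-prediction consensus

Predictions come from nine binary-hit programs plus one score-valued
program (scores 0–100). The consensus rule is two-way:

* **Data A** — intersect the hit sets of every unordered pair of the
  nine binary programs and unite the intersections. This is provably the
  set of genes predicted by at least two programs; the implementation
  performs the literal pairwise construction and the test suite enforces
  the vote-count equivalence with an independent counting oracle.
  (Reading note: the construction is over *all* program pairs, not one
  randomly selected pair — a single random pair would make the analysis
  irreproducible, and the exhaustive reading is the only one consistent
  with uniting plural intersections.)
* **Data B** — genes whose score strictly exceeds 60 in the scored
  program. The inequality is strict at the boundary: a score of exactly
  60 is excluded.

The consensus per miRNA is $A \cap B$. Experimentally validated
interactions are unioned into the final edge set and flagged
(`validated` / `both`): curated experimental evidence is not made to
pass a prediction-agreement filter. A per-program significance filter is
surfaced as a documented no-op hook only — standard program exports
carry no per-program p-values to test.

# Weighted bipartite networks

Per comparison, the network nodes are the significant miRNAs and their
consensus/validated targets; edges only run miRNA–gene. miRNA nodes are
weighted by $|\log_2 \mathrm{FC}|$ and carry their direction; gene nodes
are weighted by their degree (the analysis tradition gives no formula
for a cross-group degree weight, so within-network degree is used and
cross-group structure is carried by the comparison step). Structural
invariants — bipartiteness, gene weight = degree, and the degree-sum
identity — are re-validated after every construction.

* **Hubs**: nodes with degree ≥ 5 (the threshold is exposed; "at least
  5" is the operational reading adopted where "more than 5" and
  "degree ≥ 5" both appear in the tradition). The hub subnetwork keeps
  the hub nodes, all edges incident to them, and the endpoints of those
  edges with a `hub` flag distinguishing qualifying nodes — the one
  reading under which extraction is idempotent and every flagged node
  provably had parent degree above threshold.
* **Up-subnetwork**: the subgraph induced by up-regulated miRNAs and
  their targets (targets read as down-regulated genes, since miRNAs
  repress), with the up-fraction reported as a percent.
* **Comparison**: shared miRNA ids (and the up-in-both subset), plus a
  weight-rank similarity over all shared nodes: Spearman correlation
  with mid-ranks and a two-sided permutation p (default 10,000 seeded
  shuffles of one side's weights — the tradition names no specific
  test, so a distribution-free one was chosen). "Deregulated nodes" are
  operationalized as the top-$k$ (default 20) shared nodes by absolute
  rank change; no cutoff is dictated, so $k$ is a parameter.

# Enrichment

A local replacement for web-service over-representation analysis: for
each gene set, the exact hypergeometric upper tail
$P[X \ge k]$, $X \sim \mathrm{Hypergeom}(N, K, n)$ (no normal
approximation), Benjamini–Hochberg adjustment, and the retention rule
*overlap ≥ 5 AND raw p < 0.05 AND FDR-adjusted p < 0.05*. The minimum
overlap filter is applied *before* BH by default ("removed from the
analysis" implies pre-filtering; the order is switchable). Two framings
in the tradition — "less than 5 removed" vs "greater than 5 retained" —
are reconciled as *keep iff $k \ge 5$*. The query list is the target
genes of the up-subnetwork; the universe defaults to the genes appearing
in the prediction ensemble (the natural background for a target-derived
query; switchable to the collection's own universe). The plain
hypergeometric statistic is used rather than an EASE-style deflated
count.

# The synthetic-data generator

The generator's defaults *are* the study conditions:

* **Design**: `Normal: 7, LGDHS: 3, LDSDS: 3, LKYDS: 3` — seven
  controls and three patients per syndrome group.
* **Noise**: per-miRNA Gaussian on the log2 scale with variances drawn
  from the same inverse-gamma family the RVM test assumes (precision
  $\sim \mathrm{Gamma}(a, \text{scale}=b)$), so the test's calibration
  checks are meaningful. Defaults $a = 3$, $b = 3$ give a mean residual
  variance of $1/(b(a-1)) = 1/6$, i.e. a typical within-group spread of
  about 0.4 log2 units — realistic residual noise for serum array data.
* **Signal**: 40 of 400 miRNAs per syndrome group shifted by ±2 log2
  units, half up / half down (both directions must exist because the
  up-subnetwork analysis depends on them); DE sets are drawn
  independently per group so groups share DE miRNAs by chance, as real
  syndromes do.
* **Predictions**: a true pair is "supported" with probability
  `program_agreement` (default 0.8): then it appears in 2–4 binary
  programs and scores $\mathrm{Uniform}(61, 100)$; otherwise (and for
  decoys) at least one consensus condition fails by construction —
  scores for unsupported/decoy pairs are $\mathrm{Uniform}(0, 60)$, so
  the strict ">60" boundary is explicitly testable. Target genes are
  drawn with a skewed (Zipf-like) popularity so gene hubs exist.
* **Gene sets**: 50 sets of 20–100 genes; 5 planted sets draw half
  their members from the up-regulated miRNAs' target pool, giving
  overlap odds ratios far above 10 for the power checks; all sets have
  ≥ 5 members so the minimum-overlap filter is always exercisable.

What the generator does *not* emulate: probe chemistry and background
correction, serum hemolysis artifacts, correlated miRNA co-regulation,
database-version idiosyncrasies of real prediction programs. Passing
tests therefore demonstrate the pipeline's statistical correctness under
its own model assumptions, not the reproduction of any particular
clinical dataset — the study this design mirrors deposited no raw data,
so its patient-level numbers are not recoverable by anyone.

# Determinism and problem sizes

One master seed fans out to fixed per-stage seeds, so stages are
individually reproducible; re-running a pipeline with the same
configuration and seed reproduces identical output-file hashes (checked
in the manifest). The test suite's Monte-Carlo sizes were chosen to make
each tolerance trustworthy while keeping the suite quick on a single
CPU: 2,000 null miRNAs for type-I calibration, 5,000 variances for
hyperparameter recovery, 1,000 random ensembles for the consensus
oracle, 500 Fisher-exact comparisons, 50 seeds for FDR false-positive
control, enrichment power, UPGMA oracle checks and chance-level
classification, 100 random networks for the structural invariants, and
20 seeds for differential-recovery sensitivity.

# Known limitations

* The RVM fit assumes variances are exchangeable across miRNAs; strong
  mean-variance trends (limma-style "trend") are out of scope.
* The classification tree enumerates bipartitions exhaustively, which
  is exact for ≤ 4 classes but would need a heuristic beyond that.
* Permutation p-values are bounded below by $1/(n_{\mathrm{perm}}+1)$.
* Networks carry no edge weights beyond source provenance; "connection
  strength" beyond adjacency is not modeled.
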
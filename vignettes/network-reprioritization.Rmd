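---
title: "Network-based reprioritization of GWAS genes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based reprioritization of GWAS genes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprior)
```

## The problem

A case-control GWAS ranks genes by statistical association alone. The tail of
nominally significant genes (gene-level *p* < 0.01) is known to be enriched
for true disease biology well below genome-wide significance, but association
statistics cannot tell the true positives in that tail from the false ones.
netprior addresses this with two ideas:

1. **Network-based reprioritization (NGR).** True risk genes tend to be
   functionally related to one another. Given a tissue-specific weighted
   functional network — edge weight $W_{g_i g_j} \in (0,1]$ is the predicted
   probability that two genes functionally interact in that tissue — every
   gene in the genome can be re-scored by how strongly it connects to the
   nominally significant GWAS genes.
2. **Endophenotype integration.** A second GWAS on a quantitative,
   biologically proximal trait (for example, the volume of a brain structure
   measured by MRI) supplies an independent axis of evidence. Genes that rank
   highly on *both* axes are the prioritized candidates.

## The PU ensemble and the functional score

Only positive examples exist: the genes at nominal significance in the risk
GWAS ($p_g < \alpha$, default $\alpha = 0.01$, strict). Every other gene is
unlabeled, not negative — this is positive-unlabeled (PU) learning. The
feature vector of gene $g$ is its row of network weights to the $n$
positives,
$$ f_g = [W_{g p_1}, \dots, W_{g p_n}], $$
with 0 for absent edges and 0 in a positive's own column (the network is a
simple graph). Features are used raw: weights already live on a common
$[0,1]$ probability scale, so no per-column standardization is applied.

Each of the `n_models` ensemble members (default 100) trains a linear
soft-margin SVM on all positives against an equally sized random sample of
unlabeled genes treated as putative negatives; balancing the classes keeps
the hinge loss from collapsing onto the majority class, and resampling the
negatives independently per model averages away the unlabeled genes that are
secretly positive. The cost parameter $C$ is chosen per model by stratified
$k$-fold cross-validation (default 5-fold) over a grid (default
$\{0.01, 0.1, 1, 10, 100\}$), maximizing mean held-out AUC; ties prefer the
smallest cost. The fold count, grid and selection metric are deliberate
package defaults — conventional choices for a linear SVM — and all three are
exposed through `ngr_config()`.

Raw decision values are not comparable across models, so each model's scores
are normalized to an **unlabeled-predicted-positive rate**:
$$ \mathrm{UPPR}_{ij} =
   \frac{\#\{g \in U : M_i(g) > M_i(g_j)\}}
        {\#\{g \in U : M_i(g) > M_i(g_j)\} + \#\{g \in U : M_i(g_j) > M_i(g)\}} $$
over the unlabeled set $U$ — the PU analogue of a false-positive rate. Both
inequalities are strict, so genes tied with $g_j$ drop out of both counts;
when every unlabeled gene is tied the rate is defined as 0.5, the
uninformative midpoint (continuous with the half-rank convention). UPPR is
computed for *every* network gene, positives included, so known risk genes
receive functional scores too. $U$ is always the full unlabeled set, not the
per-model negative sample: the reference distribution should not change from
model to model.

The **functional score** is
$$ FS(g) = -\log_{10}\Big(\tfrac{1}{m}\sum_i \mathrm{UPPR}_{ig}\Big). $$
A mean UPPR of exactly 0 (a gene above every unlabeled gene in every model)
is floored at $0.5/|U|$ — half the smallest resolvable rate — before the
logarithm, keeping $FS$ finite so the downstream joint CDF is well defined.
$FS > 2$ is therefore exactly "mean UPPR < 0.01".

## Combining with positional evidence

The endophenotype GWAS gives each gene a positional score
$PS(g) = -\log_{10}(p_g)$. The **combined score** of gene $g_j$ is the
empirical joint CDF of the two scores evaluated at $g_j$:
$$ CS(g_j) = \frac{\#\{g : FS(g) < FS(g_j) \text{ and } PS(g) < PS(g_j)\}}{N}, $$
the probability that a randomly chosen gene scores strictly lower on both
measures. $N$ counts only genes carrying both scores; genes missing either
axis are excluded (and reported), because the joint CDF is undefined for
them. Ties follow the formula exactly — strict inequalities, no half-weight
correction — so identical profiles never dominate one another and
$CS \le (N-1)/N$.

Two implementations coexist deliberately: an $O(N \log N)$ sweep (sort by
$FS$; process $FS$-tie blocks; count smaller $PS$ ranks with a Fenwick tree)
and the literal $O(N^2)$ double loop, `combined_score_bruteforce()`. The
test suite requires exact equality between them on random tables with and
without ties. Because $CS$ depends only on the two orderings, any strictly
increasing transform of either axis leaves it unchanged — also enforced as a
property test.

Ranked output breaks $CS$ ties by $PS$, then $FS$ (both descending), then
gene id, so top-$k$ reports are deterministic.

## Subnetworks and modules

Genes with $FS > 2$ form the high-confidence subnetwork; among them, only
edges with weight $> 0.25$ are kept. The weight filter is applied *before*
community detection — the graph that is analyzed is the graph that would be
visualized — but `extract_subnetwork()` exposes both thresholds, so filtering
for display only is equally expressible. Isolated high-scoring genes are
retained as nodes.

Communities are found by multilevel (Louvain) modularity maximization on the
edge weights at resolution 1, run under a fixed seed for a deterministic
node order, and relabeled by descending module size. The weighted modularity
$$ Q = \frac{1}{2m} \sum_{ij}\Big[W_{ij} - \frac{k_i k_j}{2m}\Big]
       \delta(c_i, c_j) $$
is computed in-package with per-community sums and is tested to $10^{-12}$
against a literal double-sum oracle and against an independent graph
library. The reported partition is additionally guarded never to score below
the all-in-one or all-singleton baselines. An edgeless subnetwork has no
defined $Q$; it is reported as `NA` with singleton modules.

## What the synthetic generator emulates

Real inputs of this analysis (tissue-specific functional networks, gene-level
GWAS p-value tables) are either controlled-access or large downloads, so the
package ships a generator whose outputs have the statistical structure the
method assumes:

* **Planted functional modules.** Gene pairs inside a planted module receive
  edges with probability `edge_density_within` (default 0.3) and weights from
  Beta(8, 2) (mean 0.8); all other pairs with probability
  `edge_density_background` (default 0.02) and weights from Beta(2, 8) (mean
  0.2). Non-edges are absent, not zero-weight, matching sparse "top-edges"
  network releases; no self-edges exist.
* **A risk GWAS whose sub-0.01 tail is enriched for planted genes.** Signal
  genes draw $p \sim \mathrm{Beta}(a, 1)$ with CDF $p^a$; the default
  $a = 0.1$ puts ${\sim}63\%$ of signal genes below $p = 0.01$. Null genes
  are Uniform(0, 1). A `contamination_frac` of the risk signal can be placed
  in the background to emulate false positives.
* **An endophenotype GWAS that overlaps only partially.** `overlap_frac`
  (default 0.5) of the endophenotype signal is drawn from the risk-signal
  set, the rest from planted-but-unlabeled genes and background — mirroring
  the common observation that disease-status and endophenotype hits replicate
  only partially.

Defaults describe the benchmark used throughout the tests: 3,000 genes, one
planted module of 150, 100 module genes carrying risk signal. That leaves
roughly 50 planted genes with *no* label information at all; the recovery
test demands that a 25-model ensemble rank these held-out genes above the
background with mean AUC > 0.85 across three seeds (observed: > 0.99).
These sizes are chosen so the whole benchmark runs in well under a minute on
one core while leaving the positive set (~60–90 genes, module signal plus
uniform-tail contamination) large enough for stable CV.

The generator does **not** emulate several features of real data: gene-length
and LD-driven correlation between gene-level p-values, degree heterogeneity
and hub structure of real functional networks, weight calibration of any
specific network release (the Beta parameters are a modeling choice, not a
fit), or population structure. Passing the recovery benchmark therefore shows
the machinery is correct and sensitive under the model's own assumptions —
not that any particular biological claim replicates.

## Numerical and policy choices

| choice | value | why |
|---|---|---|
| positive threshold $\alpha$ | 0.01 (strict `<`) | nominal significance; the conventional liberal cutoff for NGR seeds |
| UPPR tie policy | ties excluded from both counts; 0/0 := 0.5 | strict inequalities in the definition; midpoint is the uninformative value |
| FS zero floor | mean UPPR 0 → $0.5/|U|$ | keeps FS finite for the joint CDF |
| CV | 5-fold stratified, AUC, grid $10^{-2}..10^2$ | conventional for linear SVMs; per-model reselection |
| negatives per model | exactly $|P|$, resampled per model | balanced classes; bagging over the unlabeled pool |
| genes off-network | dropped with a warning | features are undefined without network rows |
| subnetwork cutoffs | $FS > 2$, weight $> 0.25$ | mean UPPR < 0.01; weak edges removed before modularity |
| Louvain | resolution 1, seeded order | determinism under a single pipeline seed |
| seeds | one global seed; per-model seeds derived as `(seed + i * 7919) mod 2147480009` | full-run reproducibility, models independent |

Degenerate inputs are errors, not silent results: an empty positive set
(advises a looser $\alpha$), a single-class or all-identical training set,
an empty subnetwork (advises a lower threshold), fewer than two jointly
scored genes, p-values outside $(0, 1]$, malformed TSV rows (reported with
line numbers).

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  synth = synth_config(seed = 1),          # 3000 genes, planted module of 150
  ngr = ngr_config(n_models = 25),
  seed = 1, out_dir = "run1"
)
manifest <- run_pipeline(cfg)
manifest$counts
```

The manifest records input/output MD5 hashes, the seed and every stage
parameter; rerunning with the same configuration reproduces the score tables
byte for byte.

## Limitations

* Linear kernels only: the feature space (weights to positives) is already
  high-dimensional and probability-scaled, and the reference approach is
  linear; no kernelized or diffusion-based variants are provided.
* The combined score is a rank-based joint CDF; it deliberately carries no
  parametric dependence model between the axes and assigns no significance
  level to a given CS value — selection is by top-$k$ reporting.
* Functional annotation of modules (GO/pathway enrichment) requires live
  annotation services and is out of scope; per-module ranked gene lists are
  exported for external tools instead.
* With ~100 positives and balanced negatives, each SVM trains on ~200 rows;
  decision-value granularity of UPPR is limited by $|U|$, so FS resolution
  saturates at $-\log_{10}(0.5/|U|)$.
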
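---
title: "Methods: core microbiota and Bayesian network meta-analysis with micronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core microbiota and Bayesian network meta-analysis with micronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`micronet` implements a meta-analysis workflow for multi-trial 16S
gut-microbiota count data. The workflow answers three questions in
sequence: which taxa form a stable *core microbiota* across trials and
diet groups; how the abundances of taxa depend on each other and on the
diet, expressed as a Bayesian network (BN); and which metabolic
functions the densely connected communities of that network are
enriched for, compared between two diet-defined networks. Everything
operates on three plain tables: a taxa-by-sample count matrix, a
sample-to-(trial, diet) design table, and a taxon-to-pathway annotation
catalog standing in for an inferred metagenome.

# Normalizations

Two normalizations serve different stages.

**Total-sum scaling** (`tss_scale`) converts each sample to proportions
and rescales by the mean raw depth, so all samples share one count-like
depth. It feeds the descriptive profile and the discriminant analysis.
We read "proportional to the total sequencing depth" as rescaling by
the *mean* sample depth rather than the grand total; the two differ by
a global constant that cancels in every downstream statistic, and the
mean keeps values on the magnitude of a single sample.

**Abundance-weighted depth normalization** (`normalize_eq1`) feeds the
network stage:

$$NC_{ij} = X_{ij}\,\frac{\sum_{n=1}^{N} X_{in}}{\sum_{t=1}^{T} X_{tj}}$$

with $X_{ij}$ the raw count of taxon $i$ in sample $j$, $N$ samples and
$T$ taxa. It preserves zeros, keeps each taxon's cross-sample profile
proportional to its raw profile, and up-weights abundant taxa. Taxa
whose normalized row total is exactly zero are removed
(`drop_zero_taxa`) before model fitting. One caveat matters at desk
scale: the per-sample depth factor $1/\sum_t X_{tj}$ is compositionally
negligible when $T$ is large (hundreds of taxa) but induces visible
cross-taxon coupling when $T$ is small, because each taxon then
contributes a non-trivial share of its own sample depth. The
structure-recovery experiments below therefore run on the generator's
count scale directly; the pipeline applies the normalization as
specified for real-scale tables.

# The core microbiota gradient

`core_filter` applies an increasing-restriction prevalence filter.
Presence means count $> 0$, which makes the filter invariant to any
per-sample positive rescaling. With threshold fraction $f$ (default
0.5):

* **Level C** — prevalence $> f$ over all pooled samples;
* **Level B** — level-C taxa with prevalence $> f$ within *every* trial;
* **Level A** — level-B taxa with prevalence $> f$ within every diet
  group of every trial.

"More than" is strict: presence in exactly half of the samples does not
qualify. Nesting $A \subseteq B \subseteq C$ holds by construction and
is asserted property-style on randomized tables. The level-C
denominator pools whatever table the caller provides; outlier handling
is upstream and explicit.

# Discriminant screening

`fit_plsda` is a NIPALS PLS2 fit on the one-hot class response with
autoscaled features. Reported quality is R2Y(cum), the captured
response variance, and Q2(cum) from class-stratified 7-fold
cross-validation — the standard chemometrics default; the fold
assignment is deterministic (round-robin within class) so a fit is a
pure function of its input. Two components are fitted by default, the
number conventionally plotted and tabulated. Feature importance is the
cumulative VIP over all fitted components,

$$VIP_j = \sqrt{P\,\frac{\sum_a SS_a\,(w_{ja}/\lVert w_a\rVert)^2}{\sum_a SS_a}},$$

whose squares average to 1 by construction; the biomarker screen keeps
$VIP \ge 1.2$ (inclusive). Model validity uses label permutations
(default 500) with the add-one p-value
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$, which can
never return zero. Sample-level anomalies use Hotelling's $T^2$ over
the score space against the $A(n-1)/(n-A)\,F_{A,n-A}$ limit at 95%;
flagged samples are *reported*, and any refit after exclusion is an
explicit second call rather than a silent side effect.

# Node models and network learning

Marginal abundances are modelled as zero-inflated negative binomial
(ZINB): a structural zero with probability $\pi$, otherwise NB with
mean $\mu$ and dispersion $\theta$ (variance $\mu + \mu^2/\theta$ —
this parameterization is used everywhere in the package). `fit_zinb`
maximizes the likelihood by EM over the latent zero indicator with a
weighted NB M-step, followed by a joint quasi-Newton polish of the
observed likelihood; the all-zero vector returns the boundary
$\pi = 1$ with a flag instead of an error. Normalized values are
rounded to the nearest integer for all count likelihoods.

`learn_structure` searches DAG space by greedy hill-climbing
(add/delete/reverse moves) on a total BIC score
$\sum_v \ell_v - \tfrac{1}{2} k_v \log n$, with random restarts
(default 5) from sparse seeded graphs and a maximum in-degree of 3.
The node-local conditional model is a *hurdle* formulation chosen to
stay comparable with the ZINB marginals while remaining estimable at
desk scale: a Bernoulli zero part plus a zero-truncated NB whose log
mean is linear in `log1p(parent abundance)` and in diet indicator
dummies when the Diet node is a parent. The discrete Diet node encodes
the experimental variable and is constrained to be a root: it may
explain taxa, nothing explains it. Scores are cached per (node, parent
set), moves are enumerated in lexicographic node order and accepted
only on strict improvement, which makes the learned edge set invariant
to sample and taxon ordering.

Every learned arc is then double-gated (`score_and_filter_edges`):

* **MI criterion** — the p-value of a mutual-information independence
  test between the endpoint variables must fall below 0.05. The test
  discretizes abundances into equal-frequency bins (default 3:
  zero-heavy low, mid, high), computes plug-in MI and refers
  $G = 2n\,MI$ to a chi-square with $(r-1)(c-1)$ degrees of freedom.
  We interpret the conventional "MI < 0.05" gate as a threshold on this
  *p-value*: thresholding raw MI at 0.05 nats would be meaningless, and
  upstream BN platforms report MI arc strength as a test p-value.
* **BIC criterion** — the *BIC delta*, the change in network score
  caused by removing the arc, must be negative: removal worsens the
  network, i.e. the data support the arc.

Tightening the MI threshold can only remove edges. Retained arcs get a
sign from the Spearman rank correlation of the endpoints (for
Diet→taxon arcs, the sign of the child's mean difference between the
last and first diet level); an exactly zero correlation is reported as
"+" and flagged ambiguous. `hierarchy_metrics` summarizes each node by
its centrality degree (all incident edges) and parent percentage
(share of those edges where the node is the parent; undefined for
isolated nodes).

# Communities, diet connectivity and coverage

`leiden_partition` clusters the undirected, unweighted taxon-taxon
skeleton with the Leiden algorithm under the modularity objective at
resolution 1.0 (the method's defaults; edge signs and the arc
directions carry no weight in the clustering). Nodes with no edges at
all are assigned to the reserved **cluster 0** before Leiden runs.
The Diet node belongs to no cluster; its edges count toward isolation
and connectivity only. Cluster ids $\ge 1$ are ordered by decreasing
summed relative abundance. `categorize_clusters` labels each cluster
`connected` when any member has an undirected path to the Diet node,
`not-connected` otherwise, and `isolated` for cluster 0;
`coverage_stats` reports per-category abundance shares (which provably
sum to the modelled total), node counts, core-taxon counts and core
participation in edges.

# Functional enrichment and model comparison

For each cluster, `enrich_clusters` tests every pathway annotated to at
least one member with the upper-tail hypergeometric probability
$P(X \ge k)$ for $X \sim \mathrm{Hyper}(N_{bg}, K, n)$, where $n$
counts only the *annotated* cluster members (the GeneRatio denominator
convention of standard over-representation tools; the raw cluster size
is reported alongside) and $(K, N_{bg})$ come from the annotation
catalog, never recomputed from the dataset — reference backgrounds are
external sequence collections. Benjamini–Hochberg correction is
applied within each cluster's tested set by default (matching how
published per-cluster tables group their adjusted values), with a
global switch; significance is $p_{adj} < 0.05$. `compare_models`
intersects the significant pathway sets of two networks, quantifies the
per-pathway taxon overlap (Jaccard), and emits a genus→phylum→pathway
long table for Sankey-style reporting.

# The synthetic-data generator

`simulate_dataset` emulates the statistical structure the analysis
assumes, with full ground truth. Defaults describe a three-trial
feeding design (two diet groups per trial, 15 samples per group, 40
taxa) with four taxon blocks:

* **core** (8 taxa): per-group presence probability 0.9, achieved by
  solving $\pi = 1 - 0.9/(1 - NB(0))$; infeasible targets error at
  configuration time.
* **dag** (10 taxa, 8 planted edges): low zero-inflation
  ($\pi \in [0.05, 0.2]$) so dependencies are identifiable; a child's
  NB mean is multiplied by $\exp\{c\,(\log(1+x_{pa}) - \log(1+\mu_{pa}))\}$
  per edge with $|c| = 0.8$ and alternating signs, mirroring the BN
  module's conditional model so that recovery is well-posed.
* **diet** (6 taxa): group-specific means shifted by
  $\exp(\pm 1.5)$, alternating sign.
* **bg** (the rest): sparse ZINB taxa ($\pi \in [0.65, 0.9]$) with a
  mild lognormal per-trial composition shift (sd 0.3) and a 30% chance
  of skipping trials entirely, which keeps the three-trial Venn and the
  level-B filter non-trivial.

The annotation catalog plants one rare pathway (background count 12 of
3364) on each of the dag and core blocks and salts every taxon with
three uniform background pathways. Ground-truth core sets are derived
from the *designed* presence probabilities, so blocks engineered above
the threshold (dag, diet) are part of the designed core alongside the
core block. What the generator deliberately does **not** emulate:
phylogenetic correlation, sequencing error, compositional closure of
real library sizes, or realistic taxon-abundance tail behaviour —
passing the recovery experiments shows the estimators are correct under
their own assumptions, not that real data satisfy those assumptions.

# Numerical choices and degenerate inputs

Rounding to integers precedes every count likelihood. The truncated-NB
optimizer falls back from BFGS to Nelder–Mead on failure, and a child
with fewer positives than coefficients is scored with the
intercept-only count model while keeping the full parameter penalty, so
sparse children never reward spurious parents. Hill-climbing accepts
moves only above a $10^{-6}$ score gain; ties resolve to the
lexicographically first move. Equal-frequency discretization collapses
tied quantile breaks and adjusts the degrees of freedom to the realized
table. Zero-depth samples, all-zero tables, single-class labels,
classes of one sample, cyclic move proposals and annotation references
to undeclared pathways are all rejected with named errors; the all-zero
ZINB input and the zero-correlation edge sign are the two deliberate
boundary returns.

# Validation conditions

The test suite validates each stage against independent oracles and
planted ground truth at fixed problem sizes, chosen so the full suite
runs on a laptop-class single core: exhaustive hypergeometric
agreement with log-binomial brute-force summation for all backgrounds
up to 200; VIP identities on 50 random fits plus a hand-coded oracle on
a 6×4 toy; permutation-test calibration on 20 null datasets at 100
permutations; Hotelling flag rates on 20 homogeneous datasets;
structure-learning false positives on 20 independent-ZINB datasets (20
taxa, n = 300) and skeleton recovery on 20 planted 10-node/8-edge DAGs
(n = 300, median F1 ≥ 0.8); ZINB parameter recovery at n = 5000;
Leiden exactness on disjoint cliques and a bridged 4-clique ring; and
enrichment null calibration over 20 random annotation draws. The
bundled `fixture_small()` (20 taxa × 30 samples) exercises the entire
pipeline end to end.

A published per-cluster enrichment table provides deterministic worked
examples: recomputing the upper-tail hypergeometric from each row's
printed Ratio and BgRatio cells reproduces the printed p-values at
their three-decimal precision.

# Known limitations

Headline quantities of any real study (shared-taxon counts, core sizes,
VIP counts, R2Y/Q2, network and cluster counts, coverage percentages)
are properties of that study's data; on synthetic data the pipeline
reports their synthetic analogues, and no claim is made that those
numbers transfer. Hill-climbing with restarts is a heuristic: it
returns a local BIC optimum, and the true search settings of upstream
BN platforms are unpublished, so our in-degree cap, restart count and
conditional family are explicit, documented substitutes. The Leiden
resolution and the question of whether edge weights should enter the
clustering are similarly open in the source protocol; we cluster the
unweighted skeleton at resolution 1. The enrichment background is
trusted as given; reconciling background size conventions across
annotation pipelines is out of scope.
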
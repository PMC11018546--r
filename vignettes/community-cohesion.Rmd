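---
title: "Individualized gene networks and community cohesion scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized gene networks and community cohesion scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesionet)
```

## The problem

Bulk co-expression networks describe a population, not a patient. Two tumours
with the same marginal expression of a gene can differ radically in whether
that gene still *co-varies* with its usual partners — i.e. whether the
regulatory neighbourhood around it is intact. `cohesionet` estimates, for a
single expression sample, which interactions of a normal-tissue co-expression
network that sample has lost, and summarizes the damage at the level of
co-expressed gene communities. The resulting per-sample, per-community
**cohesion scores** support three uses: flagging the functional unit a tumour
has most disrupted, ranking druggable genes inside it by how much connectivity
they personally lost, and stratifying a cohort into prognostic subgroups by a
cohesion-score threshold.

## The model

### Reference network

From control (normal-tissue) samples we build a weighted co-expression
network in the classic unsigned-WGCNA style:

1. adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$, with $\beta$ chosen by
   scale-free topology fit (`pick_soft_power()`, candidates 1–20, signed
   $R^2 \ge 0.8$, smallest qualifying power; falls back to the best fit with a
   warning when no power qualifies — which is expected on the synthetic
   equicorrelated blocks below, since they are deliberately *not*
   scale-free);
2. topological overlap
   $\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}{\min(k_i,k_j) + 1 - a_{ij}}$;
3. average-linkage hierarchical clustering of $1-\mathrm{TOM}$, cut at the
   partition (over $k = 1..30$ clusters) maximizing weighted modularity of the
   TOM graph. We use a static modularity-maximizing cut rather than a dynamic
   tree cutter because it is deterministic, testable, and the downstream
   mathematics is agnostic to the cutter. Clusters under `min_community_size`
   (default 30) are set aside as unassigned;
4. a permutation preservation filter: controls are split 80/20 (seeded,
   default seed 17), and each community's mean intra-community TOM density in
   the held-out split plus the train/test correlation of intra-community
   connectivity are standardized against random same-size gene sets.
   Communities are kept when the mean of the two z statistics — a
   deliberately compact two-statistic `Zsummary` — exceeds 10. Note that for
   perfectly exchangeable communities (every member statistically identical,
   as in the synthetic blocks) the connectivity statistic carries no signal,
   so `Zsummary` is driven by density alone; real modules with hub structure
   gain from both;
5. within each kept community, only the top 10% of gene pairs by TOM weight
   are retained as edges (`top_fraction`). Inter-community pairs are never
   retained, because every downstream quantity is defined within a community.

### Per-interaction regression and perpendicular distances

Each retained interaction $(X, Y)$ — $X$ the lexicographically smaller gene,
a documented orientation convention, since the perpendicular distance is not
orientation-invariant — is modelled over **all** control samples by ordinary
least squares $\hat Y = \beta_0 + \beta_1 X$. The control samples' orthogonal
distances from the line,

$$d_i = \frac{|\beta_1 x_i - y_i + \beta_0|}{\sqrt{\beta_1^2 + 1}},$$

are summarized by their median $\tilde d$ and MAD. The 80/20 split serves
only the preservation filter; the distance distributions use every control.

### Individualized perturbed interactions

For a case sample the same distance $d_j$ is standardized robustly:

$$z_j = \frac{d_j - \tilde d}{1.486 \cdot \mathrm{MAD}},$$

and converted to a one-tailed upper-tail standard-normal p-value; interactions
with $p < \alpha$ (default 0.001, i.e. $z > 3.09$) are that sample's
individualized perturbed interactions, and removing them from the reference
yields the individualized gene network. Only unusually *large* distances are
flagged; the method deliberately does not distinguish strengthened from
weakened co-expression. No multiple-testing correction is applied across
edges — the fixed per-edge threshold is part of the procedure.

**Calibration caveat.** The distances are absolute values of residuals, so
under a Gaussian control model they are half-normal: their MAD is
$0.399\sigma$, not $0.675\sigma$, and $1.486\cdot\mathrm{MAD}$ estimates
$0.59\sigma_\perp$ rather than $\sigma_\perp$. The normal upper-tail p-value
on this robust z is therefore **anti-conservative by construction**: the true
null flag rate sits a few-fold above the nominal $\alpha$ (about $4\alpha$ at
$\alpha = 0.01$; about $12\alpha$ at $\alpha = 0.001$, plus estimation noise).
The package implements the procedure as defined — the constant and the normal
reference are the method — and the test suite asserts the actual behaviour
(inflated but bounded, monotone in $\alpha$). Interpret $\alpha$ as a ranking
knob, not a false-positive rate. `mad_constant = 1.4826` is available for the
exact normal-consistency value; it does not change this caveat.

### Community cohesion scores

Community $k$ with node set $G_k$, $N = |G_k|$, is scored by weighted global
efficiency,

$$E_k = \frac{1}{N(N-1)} \sum_{X \ne Y \in G_k} \frac{1}{d(X,Y)},$$

where $d(X,Y)$ is the shortest-path length under edge lengths $1/w$ (strong
interactions are short) computed strictly within the community subgraph, and
disconnected pairs contribute 0 to the sum. The literal convention "set
$d(X,Y) = 0$ for disconnected pairs" would make $1/d$ infinite and contradict
the boundedness of the measure; the only coherent reading — and the standard
definition of global efficiency — is that a disconnected pair contributes
zero efficiency, which is what the package implements. The cohesion score

$$S_k = \frac{E_k(\text{individualized})}{E_k(\text{reference})} \in [0,1]$$

is 1 for an intact community and 0 for a fully disconnected one, and is
invariant to any common rescaling of the edge weights. Since
individualization only removes edges, $S_k$ is monotone: removing more edges
can never raise it.

### Connectivity loss and target prioritization

For gene $x$ with reference incident edges $E_x$ and flagged incident edges
$e_x \subseteq E_x$,

$$L_x = \frac{\sum_{m \in e_x} w_m}{\sum_{m \in E_x} w_m} \in [0,1].$$

Druggable genes in the selected community (default: the community with the
sample's minimum cohesion score) are ranked by $L_x$ descending; ties break by
normal-network connectivity. "Connectivity" in the tie-break could mean degree
or strength; the package uses strength ($\sum w$ over $E_x$) as primary and
records degree alongside, since weighted connectivity is the quantity the
loss score itself is built from. Remaining ties break lexicographically, so
rankings are deterministic.

### Prognostic stratification

`threshold_sweep()` slides a threshold $t$ over $\{0, 0.001, \dots, 1\}$,
splits a cohort into low ($S_k < t$) and high cohesion groups, truncates
follow-up at a horizon (default 5 years; events beyond it become censored at
the horizon), and evaluates each admissible split by the log-rank test
(`survival::survdiff`). Splits leaving either group under `min_group`
(default 10) are skipped — the unconstrained optimum can otherwise be a
degenerate 1-vs-rest split; the full grid is returned so users can inspect
any other cut. The reported optimum p-value is threshold-optimized and is
printed as such; no selection correction is applied, matching the procedure
it implements. Ties in minimum p resolve to the smaller threshold.
Internally one log-rank test is computed per distinct induced partition
(thresholds between consecutive order statistics give identical splits),
which makes the 0.001-step grid cheap without changing any result.

## The synthetic study

`simulation_config()` defines the conditions every test runs under:

* **Controls** (default 500 samples, 300 genes): five equicorrelated Gaussian
  blocks of 80/60/60/40/40 genes at within-block correlation 0.9, plus 20
  independent background genes. Equicorrelation makes the planted truth
  unambiguous, at the price of no hub structure and no scale-free topology
  (hence the soft-power fallback warning; the study fixes $\beta = 6$, the
  conventional unsigned default).
* **Cases** (default 200): drawn from the control model, then one target
  community is perturbed. Broken genes are re-drawn *independently* —
  destroying co-expression — rather than mean-shifted, because the method
  detects co-expression deviation, not expression level; a mean-shifted
  negative control (`perturbation_mode = "mean_shift"`) is included.
  Re-drawn values are $\pm(\mu + |N(0,1)|)$ with $\mu = 3$: gross
  dysregulation bounded away from the normal range. A centered re-draw would
  land where co-expression predicts with substantial probability, leaving the
  "broken" pairs geometrically intact in those samples — the perturbation is
  meant to actually break them. The `fraction_edges_broken` request is
  realized by re-drawing $n_k(1 - \sqrt{1-f})$ genes per sample, so the
  expected fraction of pairs with a re-drawn member equals $f$. In hub mode
  the single designated hub — the target community's highest-degree network
  gene — is re-drawn, breaking exactly its incident pairs.
* **Survival** (default $n = 300$): exponential event times, hazard 0.3/yr
  for high-cohesion samples and 0.9/yr (hazard ratio 3) below the true
  threshold 0.5, censoring uniform on (0, 10) years. This is a deliberately
  event-rich design (≈ 70% of the reference group has an event by 5 years)
  chosen so the planted cutpoint is identifiable by the sweep; a
  realism-first design with 5-year recurrence-free survival around 85% has
  too few events for *any* cutpoint search to localize the threshold
  sharply.

What passing tests on this fixture do **not** show: robustness to RNA-seq
count noise, batch effects, correlated-but-not-equicorrelated modules,
overlapping communities, or non-Gaussian marginals. The generator emulates
the statistical skeleton the method assumes, nothing more.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
controls <- generate_controls(cfg)
fit <- cohesion_fit(controls, power = 6)
summary(fit)

cases <- generate_cases(cfg, fit)
profile <- predict(fit, cases$expr)
summary(profile)

targets <- prioritize_targets(fit$network,
                              profile$scores[1, ],
                              profile$perturbations[[1]],
                              druggable = rownames(controls)[1:50])
head(targets)
```

## Numerical and design notes

* Shortest paths use Dijkstra (`igraph::distances`) — all lengths $1/w$ are
  positive since weights live in $(0,1]$. The test suite cross-checks
  efficiencies against an independent Floyd–Warshall implementation to
  1e-10.
* Edge retention ranks pairs by weight with lexicographic gene-pair
  tie-breaks, and keeps exactly $\lceil f \cdot \binom{n_k}{2} \rceil$ pairs
  per community: builds are bit-reproducible.
* Zero-variance genes are dropped at load with a warning; an edge whose
  regressor is degenerate is removed from the reference before any scoring,
  so reference and individualized networks always share one edge universe
  (more than 10% such edges aborts, signalling malformed input).
* `MAD = 0` edges get $z = +\infty$ above the median and 0 otherwise, and are
  logged; missing case values skip the affected edges loudly rather than
  silently passing them as unperturbed.
* Communities dropped by the preservation filter are never scored; a sample
  equal to the control median profile flags nothing.
* Whether community detection should run on the full TOM or only retained
  edges is ambiguous in the underlying procedure; the package clusters the
  full TOM and applies edge retention afterwards, matching the stated order
  of operations.
* Test and acceptance runs use a 300-gene / 500-control / 200-case study and
  100 sweep replicates; these sizes make the whole suite run in a few
  minutes while leaving every rate estimate's Monte-Carlo error well inside
  the asserted margins.
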
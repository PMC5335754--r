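---
title: "Network-conditioned simulation of differential expression: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-conditioned simulation of differential expression: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnetbench)
```

## Why condition the simulation on a network

Active-subnetwork detection methods claim to find connected sets of genes
in a protein-protein interaction (PPI) network whose expression changes
jointly between two phenotypes. Evaluating such methods with
independently simulated per-gene effects is unfair to them: nothing in
such data ties the differential signal to the network, so network-aware
methods cannot show their advantage and the planted "truth" is an
arbitrary gene list. `subnetbench` instead plants a *connected*
ground-truth subnetwork and lets the differential states diffuse from it
through the network via a Markov random field (MRF), before generating
expression values gene-by-gene from a hierarchical Gamma model. The
result is a benchmark in which both the signal and the noise have
network structure.

## Stage 1: the planted truth

`sample_ground_truth()` grows a connected gene set of size `m`
(default 274) by random-walk expansion on the largest connected
component: starting from a uniformly chosen gene, it repeatedly adds a
uniformly chosen neighbor of the current set. A connected induced
subgraph is required because the planted object is a *subnetwork of
interactions*, not a bag of genes; plain uniform sampling (almost surely
disconnected at these sizes) remains available as
`mode = "uniform"` for sensitivity analysis. Random-walk expansion
favors high-degree boundary nodes, as any connectivity-constrained
sampler must favor something; we chose it for its simplicity and
because the searchers are never told the sampling rule.

## Stage 2: differential states from a Markov random field

Each gene carries a binary state, DE (1) or EE (0). States are
initialized to 1 exactly on the planted subnetwork and then resampled by
single-site Gibbs updates with conditional

$$p_i(k \mid \cdot) \propto \exp\!\big(\gamma_k - \beta\, \mu_i(1-k)\big),$$

where the neighborhood statistic in the default `discordance` mode is

$$\mu_i(1-k) = \frac{w\, X_i^{1-k} + \sum_{j \in N_i} X_j^{1-k}}{w + |N_i|},
\qquad X^1 = X,\; X^0 = 1 - X .$$

The numerator counts disagreement with the candidate state $k$ — the
gene's own current state weighted by $w$, plus its neighbors — and the
denominator normalizes by total weight, so $\mu_i \in [0,1]$. High
$\mu_i(1-k)$ (much disagreement) lowers the probability of state $k$:
the field $\beta$ smooths states along edges, while the self-retention
weight $w$ anchors genes to their current (initially, planted) states.
This is how false positives and false negatives are introduced *with*
network structure: flips are likeliest at the boundary of the planted
subnetwork, where neighborhood evidence is mixed.

**The `literal` mode.** An algebraically mirrored variant replaces each
numerator term $X^{1-k}$ by its complement $X^k$ (the denominator is
unchanged, since each gene contributes exactly 1 to it either way).
Under that form larger $w$ *flips* initial states instead of keeping
them. We expose it as `mu_mode = "literal"` rather than choosing
silently, but the default is the discordance form, which matches both
the standard MRF convention (energy penalizes disagreement) and the
declared purpose of $w$ as a retention weight.

**What $w$ can and cannot do.** Because $\mu$ is normalized,
$w \to \infty$ pins $\mu(\text{flip}) = 1$ and $\mu(\text{keep}) = 0$,
so the per-update keep-probability *saturates* at
$1/(1 + e^{-\beta})$ — about 0.73 at the default $\beta = 1$, i.e.
roughly a quarter of background genes acquire the DE label per sweep no
matter how large $w$ is. Keep-probability is monotone non-decreasing in
$w$ (tested), but exact retention of the initialization is a joint
limit: it additionally needs $\beta$ large enough that the residual flip
mass $e^{-\beta}$ is negligible. The test suite asserts both facts —
the saturation level at $\beta = 1$ and the exact identity at
$\beta = 60$, where $e^{-60}$ is far below any uniform draw. Defaults
are $w = 50$, $\beta = 1$, $\gamma_0 = \gamma_1 = 0$, one sweep in
deterministic sorted node order (a `random_scan` switch exists);
per-sweep DE counts are logged so users can judge burn-in for longer
chains.

**A subtlety worth knowing.** The conditionals are normalized by
$w + |N_i|$, which differs across nodes of different degree. The implied
pairwise coupling is therefore asymmetric ($\beta/(w+d_i)$ from $i$'s
side, $\beta/(w+d_j)$ from $j$'s), so these conditionals are *not* the
conditionals of any single joint Boltzmann measure. The sampler is
still a perfectly well-defined Markov chain; it just means correctness
cannot be checked against a closed-form joint. Our small-instance
oracle instead enumerates all $2^n$ states of a toy graph and composes
the exact single-site kernels sweep by sweep, then compares 10,000
independent chains to that exact distribution by a chi-square test.

## Stage 3: expression from the Gamma-Gamma model

Given states, expression is generated per gene from the classic
hierarchical Gamma model for intensity data: a latent scale
$\beta_g \sim \mathrm{Gamma}(\alpha_0, \nu)$ (shape-scale
parameterization, matching the printed observation density; a
`nu_is_rate` switch covers the other reading), then observations
$y \sim \mathrm{Gamma}(\alpha, \beta_g)$ with mean
$\mu_g = \alpha\beta_g$. Defaults $\alpha = 10$, $\alpha_0 = 0.9$,
$\nu = 0.5$ are the standard calibration of this model, giving marginal
mean $\alpha\,\alpha_0\,\nu = 4.5$. An EE gene draws one $\beta_g$
shared by both phenotypes; a DE gene draws independent case and control
scales from the same prior — the Gamma-Gamma differential-expression
convention — so its group means differ by the luck of two prior draws.
This makes DE effect sizes heavy-tailed and occasionally tiny, which is
realistic and keeps recall below 1 even for good searchers. Samples
default to 50 per phenotype.

The per-gene test is Welch's two-sample t (pooled-variance t and
Wilcoxon selectable), reporting the two-sided p-value and a signed
z-score $\Phi^{-1}(1-p/2)\,\mathrm{sign}(t)$. p-values are clamped at
$10^{-300}$, and the quantile is computed as an upper-tail quantile of
$p/2$ directly, because $\Phi^{-1}(1 - p/2)$ overflows to $\infty$ in
double precision once $p < 10^{-16}$. Genes with zero variance in both
groups get $p = 1$, $z = 0$, with a warning.

## Stage 4: reference searchers

Both searchers maximize the classic aggregate module score
$z_A = \sum_{i \in A} z_i / \sqrt{|A|}$.

By default the pipeline feeds them the *one-sided* transform
$z_i = \Phi^{-1}(1 - p_i)$ rather than the signed z. The signed version
makes up- and down-regulated genes cancel inside a module, which is
wrong for this generator: a DE gene's direction is the sign of the
difference of two latent scale draws, so planted modules contain both
directions and would self-cancel. The one-sided transform scores any
strong change positively and genes with $p > 0.5$ negatively. The
signed alternative is kept under `z_transform = "signed"`.

*Greedy search* starts from the highest-z gene (or user seeds) and adds
the score-maximizing neighbor until no addition improves the score; with
`max_depth` 2 or 3 a candidate within that hop radius is added together
with one shortest connecting path (our definition of "search depth"),
so results are always connected. All ties break lexicographically, and
the score trajectory is strictly increasing by construction.
*Simulated annealing* flips random inclusion bits, scores the largest
included connected component, accepts improvements always and
deteriorations with probability $e^{\Delta/T}$ under geometric cooling
(defaults $T_0 = 1$, factor 0.995, 2000 iterations), and returns the
best component ever seen — so its reported score is monotone in
iteration count.

Two honest limitations. First, no Monte-Carlo background calibration of
$z_A$ is applied, so scores of different-sized modules are compared
raw; this favors extreme small modules. Second, as a consequence, the
greedy searcher is bimodal across simulation seeds: when the top gene's
z towers over its neighbors (after clamping, $z$ can reach
$\approx 37$), no single addition can improve on the singleton and the
search stops at one gene, while in other runs an early addition
triggers a snowball into a large module. Both behaviors are faithful to
the uncalibrated score; the annealing searcher is the stabler
reference. Depths beyond 1 mitigate the singleton trap at a cost in
candidate-generation time.

## Evaluation

Recovered node sets are scored against the planted truth by precision
$TP/(TP+FP)$, recall $TP/(TP+FN)$, and their harmonic mean (F-measure);
an empty recovery gets precision 0 with a warning rather than NaN so
that tables always tabulate. Against a reference disease-gene list,
fold enrichment is
$(\text{recovered} \cdot n_{\text{network}})/(n_{\text{reference}} \cdot \text{selected})$,
the over-representation of reference genes in the selection; it is
undefined (an error) for an empty selection. Metrics operate on nodes
only; induced edge counts are reported but never scored. Table output
rounds half-even to 3 decimals; full precision is kept internally.

## Reproducibility machinery

A single global seed drives everything. Per-stage seeds are derived by
a stable string hash of the stage name (`stage_seed()`), so disabling
one searcher never perturbs the simulated data — a property the test
suite checks. Every run can write all stage outputs plus a YAML
manifest of the global seed, derived seeds and all parameters, from
which the run is reproducible byte for byte.

## What the generator does and does not emulate

The fixture generator produces Erdos-Renyi, preferential-attachment or
grid graphs; the default benchmark fixture is an Erdos-Renyi graph of
5195 nodes with mean degree 7, matching the size and density of the
curated human PPI subnetwork this design emulates. Real PPI networks
are far more clustered and hub-dominated than Erdos-Renyi graphs, and
real expression data carry probe-level noise, normalization artifacts
and correlated samples that the Gamma-Gamma model does not represent.
Passing benchmarks here therefore demonstrates correctness of the
machinery and sane relative behavior of searchers, not performance on
any real data set.

## Problem sizes used by the shipped tests

The test suite exercises exact enumeration oracles on graphs of up to
12 nodes (4095 subsets), sampler-vs-enumeration comparisons with
10,000 chains on a 3-node path, calibration checks on 1000-2000 gene
simulations, and two full-scale end-to-end runs (5000 nodes, planted
274, 50+50 samples) whose reports must be byte-identical. These sizes
were chosen to make every statistical assertion sharp (binomial and
chi-square error bounds well below the asserted tolerances) while the
whole suite stays comfortably interactive.
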
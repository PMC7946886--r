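---
title: "Consensus hub discovery: methods and design choices"
author: "coexhub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus hub discovery: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexhub)
```

## The analysis

`coexhub` prioritizes drug targets for a perturbation studied across
several independent expression cohorts — the motivating application is
acute radiation syndrome (ARS), where several irradiated-versus-control
blood transcriptome cohorts exist but no single one is large enough to be
trusted alone. The pipeline runs five stages:

1. **Preprocess** each dataset: quantile normalization across samples,
   then a coefficient-of-variation (CV) filter that keeps the most
   variable genes.
2. **Build one weighted coexpression network per dataset**: Pearson
   correlations, a soft-thresholding power chosen by scale-free topology
   fit, topological overlap (TOM), average-linkage module detection,
   module eigengenes, and intramodular connectivity.
3. **Select hub genes** (top 20% of intramodular connectivity per
   network) and form the **cross-network consensus**: genes that are hubs
   in at least two networks.
4. **Screen differential expression**: per condition, the
   irradiated-minus-control mean difference on the log2 scale with a
   2-fold significance rule; a gene is *directionally consistent* when it
   is called in at least 25% of all conditions with a strict majority of
   calls in one direction.
5. **Integrate**: consensus hubs that are directionally consistent and
   appear in a drug–target catalog form the candidate table; gene sets
   along the way are scored by hypergeometric over-representation with
   Benjamini–Hochberg FDR control.

A synthetic multi-dataset generator with planted ground truth stands in
for the original public cohorts, so every stage is testable end to end
without any download.

## Network model

For genes $i,j$ with expression correlation $r_{ij}$ across the samples
of one dataset, the unsigned weighted adjacency is

$$a_{ij} = |r_{ij}|^\beta, \qquad a_{ii} = 0 .$$

The power $\beta$ is the smallest integer in $1..20$ whose network passes
the scale-free topology fit at signed $R^2 \ge 0.80$: connectivities
$k_i = \sum_j a_{ij}$ are binned into 10 equal-width bins and
$\log_{10} p(k)$ is regressed on $\log_{10} \bar k$ over non-empty bins;
the fit index is $-\mathrm{sign}(\text{slope}) \cdot R^2$, so a network
whose degree frequency *increases* with connectivity can never qualify.
If no power qualifies, the power with the best fit is used and flagged.
The adjacency diagonal is zero so that connectivity sums exclude the gene
itself.

Topological overlap smooths the adjacency by shared neighbourhood:

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
{\min(k_i,k_j) + 1 - a_{ij}} .$$

### Module detection

Genes are clustered by average-linkage agglomeration on $1-\mathrm{TOM}$.
Two departures from a textbook static dendrogram cut proved necessary and
are deliberate design choices of this package:

* **Range-normalized cut height.** Raising correlations to power
  $\beta \approx 5..7$ compresses all $1-\mathrm{TOM}$ merge heights into
  a thin band just below 1, so a fixed absolute cut is meaningless — at
  these powers *every* merge can sit above 0.99. Average-linkage tree
  topology is invariant under affine rescaling of the dissimilarity, so
  the cut parameter (default 0.99) is interpreted on the range-normalized
  height scale $h_{\min} + c\,(h_{\max}-h_{\min})$. The tree itself is
  the ordinary TOM dendrogram.
* **kME membership refinement.** The clusters from the cut are treated as
  module *cores*. Each core's eigengene (below) is computed, every gene
  is assigned to the module whose eigengene it correlates with most
  strongly in absolute value provided $|kME| \ge 0.35$, and the process
  is iterated (at most three passes) because eigengenes sharpen as
  membership completes. This is the module-membership cleanup familiar
  from established coexpression workflows; without it, dendrogram cores
  are simultaneously too impure in small cohorts (genes attach to a core
  by sampling noise) and too incomplete in large ones (moderately loaded
  members never merge below any sensible cut).

Two guards keep degenerate inputs honest: clusters whose mean
within-cluster TOM does not exceed twice their mean TOM to the rest of
the network are discarded (pure noise stays fully unassigned), and
modules below `min_module_size` (default 30) are dissolved. Surviving
modules are labeled `1..M` by decreasing size, ties broken by smallest
member gene id; label `0` means unassigned.

### Eigengenes and connectivity

A module eigengene is the first principal component of the module's
per-gene standardized expression, scaled to unit variance, with its sign
fixed so it correlates non-negatively with the module's mean standardized
profile. Intramodular connectivity is
$k^{\mathrm{in}}_i = \sum_{j \in \mathrm{module}(i)} a_{ij}$ (zero for
unassigned genes).

## Hub selection and consensus

Within one network, module-assigned genes are ranked by $k^{\mathrm{in}}$
and the top 20% are hubs; genes tied with the boundary value are all
included so selection never depends on input order. Ranking is performed
over assigned genes only — unassigned genes have no intramodular
connectivity to rank. Across networks, a gene's *hub count* is the number
of networks selecting it; the consensus set keeps genes with hub count
$\ge 2$. `overlap_profile()` recomputes the overlap-degree histogram at
5%, 10% and 20% to show why the 20% cut maximizes genes shared by many
networks.

## Differential expression and direction

Per condition, `log2FC = mean(irradiated) − mean(control)`; a gene is
called up when `log2FC ≥ 1` and down when `log2FC ≤ −1` (2-fold rule,
boundary inclusive; fold change is the decision rule — Welch t p-values
are recorded as annotation only, never as a gate). Across all $C$
conditions pooled over datasets, a gene needs calls in at least
$\lceil 0.25\,C \rceil$ conditions to be significant (8 of 32 under the
default design), and its status is `consistent_up`/`consistent_down` by
strict majority; an exact tie is `inconsistent` and excluded from
candidates.

## Target integration and enrichment

Candidates are the three-way intersection: consensus hub ∧ at least one
drug in the catalog ∧ directionally consistent, ordered by hub count,
then total directional calls, then gene id. Proposed modulation is left
`unassigned`; assigning inhibition versus activation requires curation
outside the package's scope. Enrichment is the one-sided hypergeometric
upper tail $P(X \ge k)$ for a query of size $n$ against a term of size
$K$ in a universe of size $N$, with fold enrichment $(k/n)/(K/N)$,
Benjamini–Hochberg adjustment across terms and a 0.05 FDR gate. Terms
smaller than 3 genes after restriction to the universe are dropped as
unstable. When one term is enriched in two or more networks its fold
enrichments are averaged; terms enriched once are excluded with a signal
rather than silently.

## The synthetic study

`synthetic_config()` defines the simulated study; `generate_collection()`
produces the datasets, the planted truth, and a drug–target catalog.

The expression model for gene $g$ in module $m$ of dataset $d$ is

$$x_g = \mu_g + s_g\,|u_g|\,e_m + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

with baseline $\mu_g \sim N(7, 1.5^2)$ (log2 scale), loading magnitude
$|u_g|$ drawn from the hub band $[0.88, 0.96]$ for planted hubs and
$[0.40, 0.60]$ otherwise, random sign $s_g$, and residual noise
$\sigma = 1$. Hub identity and module membership are shared across
datasets; loadings and signs are re-drawn per dataset, which is what
makes the cross-network consensus informative. Background genes are pure
noise.

The module eigengene over a dataset's samples is the standardized sum of

* a saturating, monotone radiation response
  $0.4 \cdot \frac{\mathrm{dose}}{\mathrm{dose} + d_{50,m}} \cdot
  e^{-t/\tau_m}$ with per-module $d_{50}$ near 2 Gy and decay time near
  36 h (controls have dose 0),
* a condition-level random effect (sd 0.5) shared by both arms of a
  condition — cohort-level biological and batch variability that, being
  arm-balanced, cancels exactly in the fold-change contrast, and
* sample-level noise (sd 0.9).

Placing most eigengene variance at the sample level keeps the effective
sample size for correlation estimation near the actual sample count;
when condition-level variance dominates instead, correlations are
effectively estimated from as few points as there are conditions and
per-dataset module strength fluctuates wildly — the realism trade-off is
discussed under limitations.

Planted differential expression adds $\pm 1.5$ (log2) to the irradiated
samples of 12–16 of the 32 conditions for each planted gene: every hub
with probability 0.9 (hubs of radiation-responsive modules are themselves
strongly responsive) and 25% of the remaining genes. Each planted shift
follows the gene's majority direction with probability 0.75 and the
opposite direction otherwise, emulating dose/time-dependent reversals;
this mixing also prevents the planted response patterns from forming
their own spurious coexpression modules, which they otherwise do once
many genes share many shifted conditions. Half of all genes carry 1–3
catalog drugs with realistic development statuses.

The default design is five datasets of 168/168/144/144/144 samples with
7/7/6/6/6 conditions (32 irradiated-versus-control comparisons in total,
12 samples per arm per condition), mirroring the multi-cohort scale of
public ARS blood transcriptome series. Doses span 1–10 Gy and times 4–48
h. Deterministic given the seed.

**What the generator does not emulate:** microarray probe effects and
probe-to-gene mapping, cross-species ortholog mapping, batch and
missing-value mechanisms, heavy-tailed expression distributions,
correlated noise between modules, and catalog errors. Tests passing on
this generator therefore demonstrate the pipeline's statistical
machinery, not robustness to platform artifacts.

## Numerical choices

* Quantile normalization resolves within-column ties by averaging the
  reference values over the tied ranks — deterministic, and idempotent on
  tie-free data.
* CV is computed on the unlogged scale ($2^x$) by default because the CV
  of log-scale values is not invariant to rescaling the underlying
  abundances; genes with non-positive unlogged mean are an error.
* The scale-free fit needs at least 3 non-empty bins and a non-constant
  degree distribution; otherwise it is *undefined*, a state distinct from
  a low $R^2$.
* The dendrogram snaps sub-`1e-8` height inversions (exact merge ties)
  before cutting and refuses larger ones.
* Eigengene sign and hierarchical-clustering tie-breaks are fixed rules,
  so repeated runs are bit-identical; the pipeline fans a single seed out
  to per-stage child seeds through a fixed integer scheme.
* Boundary rules are inclusive everywhere they matter: `log2FC` exactly
  ±1 is a call, hub-selection boundary ties are all kept, and
  `ceiling(0.25 × 32) = 8` gates significance exactly.

## Validation problem sizes

The test suite validates TOM and intramodular connectivity against
brute-force loop oracles on 25–30-gene instances, the hypergeometric
tail against exact combinatorial summation for all parameter
combinations with universe size up to 30, module recovery on a dedicated
five-module design (5 × 100 genes, 60 samples, residual noise sd 1,
generated without planted differential expression so that module
detection is tested in isolation), and hub/candidate recovery on the
full default study. These sizes were chosen so the whole suite exercises
every stage at meaningful scale while remaining quick to run.

## Known limitations

* The unsigned network cannot distinguish activation from repression
  within a module; signed networks are out of scope.
* The static-plus-refinement module detector has no concept of nested or
  overlapping modules; deeply split dendrograms with genuinely
  hierarchical structure will be flattened.
* With condition-level variance dominating a real cohort's eigengenes,
  per-dataset hub rankings become unstable in exactly the way the
  consensus step is designed to absorb — per-network results should not
  be over-interpreted.
* The 2-fold mean-difference rule ignores gene-level variance; it is the
  decision rule this pipeline models, not a recommendation against
  moderated statistics.
* Consensus operates on shared gene identifiers; ortholog mapping between
  species must happen upstream.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(outdir = "coexhub_run", seed = 1)
report <- run_pipeline(cfg)
report
```

The run directory contains per-dataset soft-threshold tables, module
membership and eigengene TSVs, hub lists, the consensus table, the
fold-change and consistency tables, the candidate table, enrichment
results, the resolved configuration and a JSON run report whose counts
match the files row for row.
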
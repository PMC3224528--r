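---
title: "Testing clade placements by exhaustive re-grafting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing clade placements by exhaustive re-grafting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regraft)
```

# The question the package answers

A single-gene phylogeny sometimes places a clade far from where its host's
evolutionary history says it should be — for instance, genes from algae
with green secondary plastids falling inside a stramenopile or red-algal
clade. Before interpreting such a placement as horizontal or endosymbiotic
gene transfer, one must ask which placements the alignment can actually
*exclude*. `regraft` formalises this as a constrained model-comparison
problem: hold the backbone topology of all other taxa fixed, enumerate
every edge onto which the query clade could re-graft, and compare the
resulting topologies through their site-wise log-likelihoods.

# Substitution model

All likelihoods use a reversible amino-acid model assembled from

* the WAG exchangeability matrix $S$ (published values bundled with the
  package),
* stationary frequencies $\pi$ — WAG's published frequencies by default,
  or empirical "+F" frequencies computed from the alignment with add-one
  pseudocounts (the pseudocount guarantees $\pi_i > 0$, which the
  symmetric eigendecomposition requires),
* a discrete-gamma distribution of relative rates with $K$ equal-weight
  categories (default $K = 4$), each category carrying the *conditional
  mean* of its inter-quantile slice of the Gamma$(\alpha,\alpha)$ density
  — the dominant convention in the ML tools this workflow descends from,
* a proportion $p_{\mathrm{inv}}$ of invariant sites; the gamma rates are
  rescaled by $1/(1-p_{\mathrm{inv}})$ so the mixture keeps unit mean rate
  and branch lengths stay in expected substitutions per site.

The generator is $Q_{ij} = S_{ij}\pi_j$ with rows summing to zero,
normalised to unit expected rate. Transition matrices come from the
symmetric eigendecomposition in the $\pi^{1/2}$ inner product,
$P(t) = B\,e^{\Lambda t}B^{-1}$, with entries clipped to $[0,1]$ after
exponentiation. Defaults follow the two model strings used at different
stages of the classic workflow: WAG frequencies for tree estimation and
"+F" for the site-likelihood/AU stage, both exposed in the configuration.

# Likelihood engine

Site likelihoods use Felsenstein pruning over the unrooted tree
(trifurcating-root storage convention), with one partial-likelihood pass
per gamma category and per-node column rescaling against underflow
(accumulated log-scalers rather than log-space arithmetic throughout — the
standard speed/accuracy compromise). Gaps and `X` are missing data
(partial vectors of ones). The rate-zero invariant class reduces to a
branch-length-free term: a column contributes $p_{\mathrm{inv}}\pi_a$ iff
its non-missing states all equal $a$ (gaps do not break constancy). The
correctness anchor is exact agreement (relative error below $10^{-10}$)
with brute-force enumeration of all $20^2$ internal-state assignments on
four-taxon trees, which the test suite and the acceptance script both
recompute on random instances.

Branch lengths are optimized by round-robin bounded scalar search on
$[10^{-8}, 10]$. For each edge the tree is split into the two *directional*
partial likelihoods facing the edge, so the profile likelihood in that
edge's length costs one small matrix product per category per evaluation;
the incumbent is kept whenever a proposal does not improve, making the
total log-likelihood monotone across sweeps (tolerance $10^{-4}$, maximum
20 sweeps). $\alpha \in [0.02, 100]$ (log scale) and
$p_{\mathrm{inv}} \in [0, 0.99]$ are optimized the same way, alternated,
optionally interleaved with branch sweeps. Zero-length input branches are
floored at $10^{-8}$ (configurable) to keep transition matrices
nonsingular. The optimizer tolerances are package decisions — the
upstream tools this emulates do not document theirs — and are exposed as
arguments.

# Placement enumeration and evaluation

`prune_clade()` removes the (monophyletic) query clade, suppresses the
degree-2 attachment node (summing the two incident branch lengths — path
lengths among backbone taxa are preserved exactly), and keeps the clade
subtree intact. `enumerate_placements()` generates one candidate per
backbone edge by bisecting the edge and attaching the clade's root by a
new branch (initial length 0.1): $2m-3$ candidates for $m$ backbone
leaves, pairwise distinct, exactly one reproducing the input topology.
The clade subtree is never re-rooted — the enumeration treats the clade
as a rigid unit, matching the "all other relationships fixed" design.
Candidates are ordered by the backbone's canonical (cladewise) edge order.

Evaluation has two modes. `all_branches` re-optimizes every branch of
every candidate — the conservative choice for a final analysis.
`graft_only` keeps the backbone lengths fixed (each bisected edge keeps
its halves) and optimizes only the new attachment branch, exploiting the
directional partials: after two traversals of the backbone, each candidate
costs one cheap profile optimization, so scanning a hundred placements
takes about a second at the study's data shape. Both modes were verified
to produce site vectors identical (to $10^{-10}$) to a full pruning pass
on the corresponding grafted tree. Whether the original analyses
re-optimized per-candidate branch lengths is not recoverable; offering
both modes brackets the possibilities.

# Topology tests

From the topologies × sites matrix of log-likelihoods, the multiscale RELL
bootstrap resamples columns at scale factors
$r \in \{0.5, 0.6, \ldots, 1.4\}$ (the classic ten-scale grid), with
$B$ replicates per scale, implemented as multinomial column counts so each
replicate sum is one matrix–vector product. Argmax ties are broken by the
lowest row index (documented because short matrices do tie). For tiny
matrices an exhaustive mode enumerates all column-count compositions with
multinomial weights and is exact.

The AU p-value fits $z_r = \Phi^{-1}(1 - \mathrm{BP}(r))$ by weighted
least squares to $d\sqrt{r} + c/\sqrt{r}$, with weights
$B\,\phi(z_r)^2/(\mathrm{BP}(1-\mathrm{BP}))$, and reports
$p = 1 - \Phi(d - c)$. Bootstrap proportions are clamped to
$[1/(2B),\,1 - 1/(2B)]$ as a continuity correction rather than dropping
degenerate scales — this keeps the fit well-posed; curves degenerate at a
boundary on nearly all scales receive the boundary p-value (0 or 1) and an
`untestable` flag. This clamping rule is a package decision, stated as
such, not a claim about any particular legacy implementation. KH and SH
p-values use centered RELL replicate sums; within `topology_tests()` all
three tests share one scale-1 replicate set, which preserves the exact
dominance SH ≥ KH per topology. The 5% rejection flag in the report is a
reporting convention mirroring the thick/thin-branch style of published
placement figures.

# Tree search and bootstrap support

The search is deliberately modest: ML pairwise distances (two-taxon
likelihood optimization; pairs without shared sites receive a cap of 5
substitutions/site), neighbor joining, then hill climbing over all
nearest-neighbor interchanges, scoring candidates at inherited branch
lengths and re-optimizing after each accepted move (ties broken by
enumeration order). NNI matches the move set named in the workflow this
package systematises and keeps desk-scale runtime; it is acknowledged as
weaker than the SPR searches of dedicated ML programs. Bootstrap
replicates resample columns, re-fit NJ + NNI, and support is the
percentage of replicate trees containing each bipartition; replicate $r$
seeds its own RNG stream from `seed + r`, so replicates are
order-independent. Model parameters are fixed across replicates by
default, with a flag to re-estimate per replicate.

# Indel scanner

Per-taxon maximal gap runs are clustered when both boundaries agree within
`boundary_slack` columns (default 1; the published comparisons were done
by eye, so the slack formalises "the same gap"). A cluster of core length
at least `min_len` (default 2) becomes a signal when at least one named
taxon group is fully present and one fully absent; signals are labelled
deletion-like when the gapped taxa are a minority of the alignment and
insertion-like otherwise, and carry the coordinates of a designated
reference protein (the convention used to number alignment features in
published figures). No statistical significance is attached — there is no
accepted null model for indel sharing, and none is attempted.

# The simulator and what passing tests mean

`simulate_hgt_dataset()` emulates the study conditions: 56 taxa — a
14-taxon outgroup block plus donor (10), sister (8), green (12) and red
(9) ingroup groups — 327 columns, $\alpha = 0.8$,
$p_{\mathrm{inv}} = 0.1$, WAG frequencies, a 3-taxon query clade grafted
onto an internal edge of the donor group, and two planted deletion
blocks (query + donor at columns 41–45; green at 201–203). Group subtrees
get branch lengths uniform on $[0.02, 0.25]$ and are joined by internal
stems of 0.2–0.5 expected substitutions per site — values typical of a
conserved single-protein alignment spanning photosynthetic eukaryotes and
cyanobacteria. Sites are simulated under the exact inference model
(invariant flag, gamma category, root state from $\pi$, propagation by
$P(t)$); indels are overwritten post hoc rather than evolved under an
indel process — sufficient for scanner validation, and stated as a
simplification. Simulated data therefore cannot reveal model
misspecification effects (site-heterogeneous profiles, among-site rate
autocorrelation, alignment error) that real data may carry; passing tests
demonstrate internal correctness and calibration, not robustness to those
violations.

# Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

* pruning vs brute force on 100 random quartets (rel. error $<10^{-10}$);
* the transition-matrix algebra to $10^{-10}$;
* enumeration completeness on 50 random trees with up to 30 leaves;
* the AU closed-form round trip (to $10^{-3}$) and exact agreement of the
  exhaustive RELL mode with direct enumeration of all $6^6$ resamples;
* null calibration: 200 datasets simulated on the fixture's true tree,
  placements evaluated in graft-only mode with the AU test at
  $B = 1000$ per scale; the true placement must be rejected at the 5%
  level in at most 10% of runs ($B$ is scaled down from the
  conventional 10,000 to keep the 200-dataset experiment at desk scale;
  at $B=1000$ the Monte Carlo error of a bootstrap proportion is about
  0.016, small relative to the band being tested);
* planted-transfer recovery: in 20 fixture replicates the true edge must
  be top-ranked and not rejected in at least 90%;
* parameter recovery at 56 taxa × 5000 sites ($\alpha$ within 0.15,
  $p_{\mathrm{inv}}$ within 0.05, estimated on the known tree) and
  two-taxon distance recovery at 20,000 sites (within 10%);
* exact recovery of planted indel blocks.

Unit tests exercise the same properties at smaller sizes chosen for
sub-second runtimes (e.g. NNI recovery on 8 taxa × 1500 sites, bootstrap
support on constructed strong-signal alignments); the sizes above are the
package's validation conditions, stated here so they can be reproduced.

# Known limitations

* The NJ + NNI search can be trapped by local optima that SPR-based
  searches escape; bootstrap values from different search strategies are
  not strictly comparable.
* `graft_only` evaluation conditions on the backbone branch lengths; if
  those are poor, its site vectors inherit the bias (use `all_branches`
  for final numbers).
* The AU implementation follows the published multiscale-bootstrap
  theory but is not a byte-level reimplementation of any legacy tool;
  degenerate-curve handling in particular is a documented local decision.
* Only amino-acid data and the WAG family are supported; no partitioned
  or profile-mixture models.
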
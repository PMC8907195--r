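---
title: "Hemispheric connectome analysis: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric connectome analysis: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hemiconn` analyses weighted structural connectivity matrices of a single
cerebral hemisphere — the setting of paediatric perinatal-stroke
connectomics, where the hemisphere contralateral to the lesion is compared
between two stroke aetiologies (arterial ischemic stroke, AIS;
periventricular venous infarction, PVI) and typically developing controls
(TDC). This vignette documents the model, every consequential numerical
choice, and what the synthetic cohort generator does and does not emulate.

## The data model

The unit of analysis is a `weighted_adjacency`: a symmetric, non-negative
47 × 47 matrix of streamline counts between atlas regions of the hemisphere
of interest, with a zero diagonal. Matrices arrive either from a
tractography pipeline (imported as labelled CSV; anything upstream of the
adjacency matrix is out of scope) or from the synthetic generator. A
`node_atlas` names the 47 regions, the sensorimotor subset (M1, S1, SMA,
thalamus, caudate, putamen, pallidum) and a negative-control region, the
inferior occipital gyrus (IOG), chosen because no sensorimotor group
difference is expected there.

Processing order per subject: subset to the atlas, zero the diagonal, then
density thresholding. Thresholding removes the weakest 25% of the
*non-zero* edges — zeros are absent edges, not weak ones, so including them
would make the operation a no-op on sparse matrices. With `m` non-zero
upper-triangle edges, exactly `floor(0.25 m)` are removed. Ties at the cut
weight are resolved by ascending (weight, row index, column index), which
makes the operation deterministic and reproducible; for integer streamline
counts ties at the cut are common enough that an unspecified rule would make
runs irreproducible. Surviving weights are never altered.

## Graph metrics

**Betweenness centrality.** For node $i$,
$$b_i = \sum_{h \ne j,\; h,j \ne i} \frac{\rho_{hj}(i)}{\rho_{hj}},$$
the sum over ordered pairs of the fraction of shortest $h$–$j$ paths passing
through $i$; the normalised variant divides by $(n-1)(n-2)$. Both variants
are exposed, and the *raw* sum is the default: nodal values of order
10²–10³ (the scale reported for real cohorts) can only arise from the raw
sum, since the normalised variant is bounded by 1. Shortest paths use edge
lengths $1/w$ — streamline count is a connection *strength*, so stronger
connections are shorter — which is the standard transform for
structural-connectivity matrices; a unit-length transform is available for
purely topological distances. Path-length ties are detected with an
absolute tolerance of $10^{-10}$: exact for unit lengths, and conservative
for $1/w$ lengths, where exact ties have probability zero under continuous
weights. Unreachable pairs contribute nothing, so disconnected graphs are
handled without error.

**Weighted clustering.** For node $i$ with degree $k_i \ge 2$,
$$c_i = \frac{2 t_i^w}{k_i (k_i - 1)}, \qquad
t_i^w = \sum_{\text{triangles } (i,j,h)} (w_{ij} w_{ih} w_{jh})^{1/3},$$
the geometric-mean triplet mass relative to possible triplets, and the
hemispheric coefficient $C^W$ is the mean of the $c_i$. Weights enter
*unrescaled*: dividing by the maximum weight (as some toolboxes do) would
bound $c_i$ by 1, whereas values of order 10² on streamline-count data
require the raw scale; `rescale = TRUE` restores the bounded variant.
Nodes with $k_i < 2$ have no possible triplets and score 0. With unit
weights the definition reduces to the classic binary local clustering
coefficient (verified against igraph in the test suite).

**Hierarchical complexity.** On the binarized graph, let $K_p$ be the set
of nodes with degree $p$ and $s_i^p$ the ascending sequence of neighbour
degrees of node $i \in K_p$. Each class with $|K_p| > 1$ contributes the
entrywise squared deviation of its members' sequences from the class mean
sequence $\mu^p$, scaled by $1/(p(|K_p|-1))$, and
$$R = \frac{1}{D} \sum_{p\,:\,|K_p|>1} \frac{1}{p(|K_p|-1)}
\sum_{j=1}^{p} \sum_{i \in K_p} \left(s_i^p(j) - \mu^p(j)\right)^2,$$
with $D$ the number of distinct degrees in the network. $R = 0$ exactly
when nodes of equal degree have identical (ordered) neighbourhoods — every
regular graph scores 0 — and grows as same-degree nodes attach to more
diverse neighbourhoods. Sequences must be sorted ascending before the
entrywise comparison; without ordering, $\mu^p$ is not meaningful. The
published rendering of this formula is typographically garbled in its
bracketing; the implementation follows the construction above, which
matches the accompanying prose and the metric's original definition.

**Neighbourhood complexity** is the nodal decomposition of $R$:
$nc_i = \frac{1}{p(|K_p|-1)} \sum_j (s_i^p(j) - \mu^p(j))^2$ for nodes
whose degree class has at least two members, undefined (`NA`) otherwise — a
node whose degree is unique has no within-class reference. Summing defined
$nc_i$ recovers $R \cdot D$, a relation the test suite asserts. The
hemispheric value is the mean over defined nodes. The nodal formula is a
documented design choice: the source material describes the metric only
qualitatively ("each node's unique neighbourhood ... relative complexity"),
and the class-scaled per-node variance is the unique decomposition
consistent with $R$.

Both complexity metrics are computed on the binarized post-threshold graph:
they are functions of integer degrees, and binarization is the only reading
under which their defining quantities exist.

## Null models and statistics

Null graphs are Erdős–Rényi: each pair connected independently with
probability `p_edge`, defaulting to the cohort's mean pre-threshold density
(the source material does not state the parameter). The ensemble size
defaults to the rounded mean group size — 28 for 27/26/32 — and weights are
unit by default (ER is a binary model), with an option to bootstrap weights
from the pooled empirical distribution when weighted-metric comparability
matters. Null graphs pass through the *identical* thresholding path as
empirical matrices before metrics are computed.

Every comparison is normality-gated: Shapiro–Wilk per group at α = 0.05,
with one-way ANOVA / pooled-variance t tests on the parametric branch and
Kruskal–Wallis / Wilcoxon rank-sum otherwise. A single non-normal group
routes the whole comparison to the nonparametric branch, and a
constant-valued sample (Shapiro–Wilk undefined) fails the gate. Pairwise
post hocs are Bonferroni-corrected with family 3 — the three pairwise
comparisons within each metric × node; correction *across* nodes is not
applied, matching per-node reporting conventions, and the family size is
configurable. If all values are identical across groups the omnibus
statistic is 0 with p = 1 (the rank-test tie correction would otherwise
produce NaN). Correlations use Pearson or Spearman by the same gate, with
pairwise deletion so each correlation carries its own n. Effect sizes are
Cohen's d with the root-mean-square SD denominator; post-hoc power uses the
exact noncentral-t distribution. All tests are two-sided at α = 0.05.

The Kruskal–Wallis statistic is reported with its true df ($k - 1$)
alongside the total sample size; the `H(2, 82)` notation seen in some
software reports is an error-df label, not the statistic's df.

## The synthetic cohort generator

No subject-level data are publicly deposited, so the generator is the
test-bed for the entire pipeline. It emulates the *statistical structure*
the analysis assumes, not any subject's data:

* **Scaffold.** One shared background graph per cohort at density 0.45
  with log-normal weights (meanlog = log 150, sdlog = 0.8), giving
  heavy-tailed streamline-like counts whose clustering values land on the
  scale of 10².
* **Hubs.** In controls, M1 and S1 are wired as inter-community hubs
  (connected to 85% of eligible nodes with boosted weights), putting them on
  many shortest paths. Under `hub_suppression`, stroke subjects have the hub
  role displaced onto two fixed non-sensorimotor background nodes while
  M1/S1 lose most long-range edges. Displacement rather than plain removal
  keeps the *global* routing environment comparable across groups, so
  betweenness differences concentrate at the manipulated nodes instead of
  leaking into every background node.
* **Local clustering.** Under `local_clustering_boost`, stroke subjects get
  a strongly interconnected sensorimotor community around M1/S1/SMA — high
  closed-triplet mass, peripheral position. The boost is deliberately
  *weight-dominant*: only the three cortical motor nodes gain edge
  *presence* (wired into the community at 95% density), while edges among
  the supporting members keep their scaffold presence and only gain weight.
  Binary degrees drive the complexity metrics globally through each degree
  class's reference mean, so an effect that added edges throughout the
  community would leak a spurious group difference into the control node's
  neighbourhood complexity; confining the degree footprint to three nodes
  keeps the class structure clean. A shared per-subject severity factor
  (log-normal, sdlog 0.3) scales the whole community, making M1, S1 and SMA
  clustering co-vary across subjects; it is this latent severity that the
  clinical scores couple to.
* **Thalamus.** The subcortical motor loop is strongly wired in everyone;
  `thalamus_clustering_drop` detaches the stroke thalamus from it,
  lowering thalamic clustering in stroke groups.
* **Degree order.** `hemispheric_order_increase` removes edges between
  high-degree deep-background nodes in stroke subjects, compressing the
  degree distribution and lowering hierarchical complexity. The strength
  (0.3) is deliberately gentle: degree-class metrics are global, so
  aggressive homogenisation would bleed a group effect into the
  negative-control node's neighbourhood complexity.
* **Control-node neutrality.** The IOG carries no edges to
  sensorimotor-community or surrogate-hub nodes in any group, and no
  group-gated edit touches edges between IOG neighbours. Its group
  differences are therefore chance-level by construction — the property the
  negative control exists to certify. Perfect isolation of *global* metrics
  (betweenness, neighbourhood complexity) is impossible for a connected
  graph; the residual coupling is kept below the within-group dispersion.
* **Noise.** Subject-level multiplicative weight noise (sdlog 0.5) and
  topological jitter (10% edge resampling) set the within-group dispersion;
  the noise scales are chosen so nodal metric SDs are a substantial
  fraction of their means, as reported for real cohorts, and so the broad
  degree classes keep diffuse global shifts below any single node's
  dispersion.
* **Clinical scores.** AHA and MA are drawn through a Gaussian copula on
  the ranks of each stroke subject's realised (post-threshold) mean
  M1/S1/SMA clustering, with configured rank correlation −0.5 and the
  published group means and SDs; scores are clipped to [0, 100]. BBT scores
  are drawn independently of all metrics (the study found no BBT
  associations) as non-negative integer counts. Missingness mirrors the
  published completion counts (49 AHA, 34 MA, 49 BBT of 53 stroke
  subjects). Controls carry no scores and no lesion volume.

With all effect toggles off, the construction provably ignores group
labels — subject matrices depend only on the shared scaffold and the
subject's derived seed — which the test suite exploits for an exact
exchangeability check alongside a rejection-rate calibration.

**What the generator does not emulate.** Absolute metric magnitudes are not
calibrated to any real cohort (real values derive from diffusion MRI of 85
children and are not reproducible at desk scale); only directions, relative
scales and correlation structure are designed in. Spatial embedding,
distance-dependent connection probabilities, lesion geometry and
acquisition artefacts are absent. The SMA betweenness elevation in stroke
groups emerges from the community densification rather than being an
explicit lever, and the hemispheric complexity group directions are only
weakly controlled: the homogenisation strength that would sharpen them
measurably contaminates the negative control, and the control's neutrality
is the more important property. Passing recovery tests therefore shows the
*pipeline* detects the designed structure, not that real data would show
it.

## Problem sizes and runtime choices

Default study conditions are used throughout: 26/27/32 subjects, 47 nodes,
25% thresholding, 28 null graphs. The oracle-equivalence suite sweeps 200
seeded random graphs with n ≤ 7 against exhaustive path/triangle/definition
enumeration; type-I calibration uses 1000 null replicates at the study's
group sizes; parameter recovery runs 100 full synthetic cohorts through the
metric pipeline. Betweenness is computed via per-source Dijkstra with path
counts (O(n³) per subject at these sizes), which keeps a full 85-subject
cohort under a few seconds.

## Known limitations

* The tie tolerance makes near-degenerate shortest-path ties (length
  difference below 10⁻¹⁰) count as exact ties; with continuous weights this
  is the intended behaviour, but adversarial rational weights could be
  constructed to disagree with exact arithmetic.
* Neighbourhood complexity is undefined at unique-degree nodes; group
  comparisons at a node are reported as untestable when a group has fewer
  than three defined values rather than being silently dropped.
* The pipeline assumes one hemisphere per matrix; whole-brain 120-region
  matrices are supported only through atlas subsetting.
* Covariate-adjusted models (age, sex, lesion size as regressors) are out
  of scope; simple correlation screening is provided instead.
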
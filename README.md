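# hemiconn

Graph-theoretic analysis of hemispheric structural connectomes, built for
paediatric perinatal-stroke studies in which the *non-lesioned* hemisphere
of children with arterial ischemic stroke (AIS) or periventricular venous
infarction (PVI) is compared with the dominant hemisphere of typically
developing controls (TDC). Starting from one weighted, region-labelled
47 × 47 streamline-count matrix per subject, the package answers three
questions: do sensorimotor nodes (M1, S1, SMA, thalamus, caudate, putamen,
pallidum) occupy different topological positions in the stroke groups, do
hemisphere-wide network properties differ, and do those properties relate
to clinical motor function (AHA, MA, BBT scores)?

## What it computes

For each subject matrix, after density thresholding (the weakest 25% of
non-zero edges removed):

* **Betweenness centrality** — for node *i*,
  `b_i = Σ_{h≠j≠i} ρ_hj(i) / ρ_hj`, the sum over ordered pairs of the
  fraction of shortest paths through *i*, with edge lengths `1/w`; raw and
  `(n−1)(n−2)`-normalised variants.
* **Weighted clustering coefficient** —
  `c_i = 2 t_i^w / (k_i (k_i − 1))`, with `t_i^w` the sum of geometric-mean
  triangle weights around *i*; hemispheric `C^W = mean(c_i)`.
* **Hierarchical complexity** — `R`, the per-degree-class entrywise
  variance of ascending neighbourhood degree sequences, averaged over the
  `D` distinct degrees; 0 for regular graphs.
* **Neighbourhood complexity** — the nodal decomposition of `R`
  (`Σ nc_i = R · D`), undefined at unique-degree nodes.

Groups are compared with a normality-gated battery (Shapiro–Wilk →
ANOVA/Kruskal–Wallis, Bonferroni-corrected pairwise post hocs, Cohen's d),
metrics are correlated with clinical scores (Pearson/Spearman by the same
gate, pooled and per stroke group), and every hemispheric metric is
compared against an Erdős–Rényi null ensemble (28 graphs, density matched,
identically thresholded). A seeded synthetic cohort generator reproduces
the statistical structure of the study conditions — hub-like M1/S1 in
controls, locally hyperconnected M1/S1/SMA in stroke, a neutral
inferior-occipital control node, and motor scores negatively rank-correlated
with sensorimotor clustering — so the full pipeline is testable without any
subject data.

## Worked example

```r
library(hemiconn)

cohort <- generate_cohort(cohort_config(), seed = 1)
cohort
#> <synthetic_cohort> 85 subjects (26 AIS, 27 PVI, 32 TDC), 47 nodes, seed = 1

bundle <- run_pipeline(run_config(mode = "simulate", seed = 1))
cat(summarize_run(bundle)[2:3], sep = "\n")
#> M1   betweenness_raw            kruskal: AIS 122 ± 108 | PVI 101 ± 70.3 | TDC 409 ± 174 | kruskal p = 8.28e-11
#> M1   clustering                 anova: AIS 188 ± 53.3 | PVI 168 ± 35.9 | TDC 108 ± 11.9 | anova p = 1.334e-12
```

The non-lesioned M1 of both stroke groups is far less central than the
control M1 (its shortest-path load collapses from ~409 to ~100–120) while
its weighted clustering is much higher (~170–190 vs ~108): the node has
moved from a hub-like to a locally hyperconnected, peripheral position.
Correlations with motor function carry the expected negative sign:

```r
corr <- bundle$correlations
corr[corr$level == "hemispheric" & corr$metric == "clustering" &
       corr$score == "AHA", c("pooling", "method", "estimate", "p", "n")]
#>    pooling   method estimate        p  n
#> 13  pooled spearman   -0.454 0.001060 49
#> 14     AIS  pearson   -0.661 0.000238 26
#> 15     PVI  pearson   -0.189 0.388879 23
```

Higher sensorimotor clustering goes with poorer bimanual hand function
(more negative AHA), and every hemispheric metric separates cleanly from
the Erdős–Rényi null ensemble (all p < 0.001 in `bundle$null_comparisons`).
Desk-scale statistics are available directly:

```r
posthoc_power(alpha = 0.05, d = 1.0, n1 = 26, n2 = 27)  # 0.9463112
cohens_d(46.5, 15.7, 29.3, 16.4)                        # 1.071396
null_ensemble_size(c(27, 26, 32))                       # 28
```

Real cohorts enter through `read_manifest()` + `read_adjacency()` (labelled
CSV matrices) and `run_config(mode = "manifest", ...)`; a thin command-line
wrapper lives at `inst/scripts/hemiconn-cli.R`.

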
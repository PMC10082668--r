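# flexms — local-alignment phylogenetic beta-diversity for microbiomes

Standard beta-diversity metrics compare whole communities. When a host
phenotype is associated with only a small, low-abundance fraction of taxa,
that fraction cannot move a whole-community distance: ordinations show
nothing, PERMANOVA comes back non-significant, and distance-based
classifiers sit at chance. Restricting the comparison to just the
differential taxa fails differently — samples often share few markers, and
the restricted distance degenerates.

flexms implements the *local alignment* of microbiomes. For communities
profiled against a common reference:

1. **Exact markers** are selected per feature by two-sided Wilcoxon
   rank-sum (two groups) or Kruskal–Wallis (≥ 3 groups) at *p* < 0.01, or
   supplied by the user.
2. **Approximate markers** are recruited from a precomputed neighbor
   index: features with sequence similarity ≥ *t*ₛ (0.92) *and* identical
   taxonomy (phylogeny neighbors, *PN*) *and* hierarchical functional
   distance ≤ *d*_f (0.11) (functional neighbors, *FN*); the approximate
   neighbors are *AN = PN ∩ FN*. Each approximate marker *j* contributes
   abundance `Abd'_j = max_i similarity(i, j) × Abd_j` over the exact
   markers *i* that index it.
3. The **consistency-score distance** is computed over the merged target
   member set *T*: per-sample weighted vectors renormalized over *T*,
   matched mass `min(S1, S2)` at each leaf of the reference phylogeny,
   surpluses climbing the tree attenuated by `max(0, 1 − branch length)`
   and matched against opposite-sample surpluses at each node; with
   consistency `Con(root)` accumulated at the root, the distance is
   `D = 1 − Con(root) ∈ [0, 1]`.

With *T* = all features at weight 1 the same recursion gives the
whole-community (global) distance, which serves as the built-in baseline.
The package also ships the downstream battery (PCoA, PERMANOVA, ANOSIM,
multivariate dispersion, leave-one-out KNN classification with ROC/AUC),
readers/writers for all the plain-text formats involved, index
construction from FASTA + taxonomy + KO profiles, a synthetic two-group
community generator used for validation, and a command-line front end
(`exec/flexms`) with `simulate`, `markers`, `dist`, `eval` and `run-all`
subcommands.

## Worked example

Simulate the bundled two-group scenario (50 samples per group, 30 shared
background taxa, 4 low-abundance markers enriched in group A whose sibling
relatives may carry the mass in group B), then run the full analysis in
all three distance modes:

```r
library(flexms)

ds  <- simulate_dataset(scenario_config(seed = 11))
fit <- fms_analysis(ds$table, ds$metadata$group, ds$tree, ds$index, seed = 11)
print(fit)
#> Local-alignment beta-diversity analysis
#> Marker set: 4 exact marker(s) of 38 tested (wilcoxon test, p < 0.01)
#> Target member set: 4 exact + 4 approximate marker(s)
#> Distance modes: fms, exact, global; groups: A vs B
#>     mode permanova_F permanova_R2 permanova_p anosim_R anosim_p dispersion_F
#> 1    fms       8.745      0.08193       0.001  0.14148    0.001       1.6993
#> 2  exact      40.894      0.29443       0.001  0.50000    0.001    1103.0036
#> 3 global       1.326      0.01335       0.181  0.01298    0.148       0.3676
#>   dispersion_p knn_auc
#> 1        0.196  0.9100
#> 2        0.001  0.5000
#> 3        0.552  0.4546
```

Reading the summary: the global distance sees nothing (PERMANOVA
*p* = 0.181, KNN AUC ≈ 0.45 — the 2–4% of marker mass is buried under
background noise). The exact-markers-only distance detects *a* difference
but is degenerate — in this draw every marker was replaced by its relative
in group B, so all 50 group-B samples carry zero marker mass (the emitted
warning), classification collapses to chance (AUC 0.50) and the huge
dispersion F reflects the distortion. The local alignment recruits the
four relatives at weight ≈ 0.95, restores a well-behaved distance
(homogeneous dispersion, *p* = 0.196), and separates the groups (PERMANOVA
*p* = 0.001, AUC 0.91). `plot(fit, mode = "fms")` draws the corresponding
PCoA.

The same pipeline runs from the shell:

```sh
flexms simulate --n-per-group 50 --seed 11 -o sim/
flexms run-all -i sim/table.tsv -t sim/tree.nwk -x sim/index.tsv \
       -m sim/metadata.tsv --group-col group -o summary.tsv
```

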
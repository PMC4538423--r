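# bmkc — module-level differential coexpression analysis

`bmkc` finds **overlapping gene modules whose coexpression changes between
two conditions** (e.g. normal vs. disease). Many disease processes leave
individual genes' expression levels nearly untouched while dissolving the
*correlation structure* of a pathway; per-gene differential expression is
blind to this. `bmkc` targets it directly, for anyone with two
expression matrices over the same genes: transcriptomics analysts,
network biologists, methods developers benchmarking differential
coexpression tools.

## Method

Four stages, composed by `runPipeline()`:

1. **Biweight midcorrelation (bicor).** For each condition, all pairwise
   robust correlations. With u_i = (x_i − med(x)) / (9·mad(x)) (unscaled
   MAD) and Tukey weights w_i = (1 − u_i²)² · I(|u_i| < 1),

   bicor(x, y) = Σ (x_i − med x) w_i⁽ˣ⁾ (y_i − med y) w_i⁽ʸ⁾ /
   ( ‖(x − med x) w⁽ˣ⁾‖ · ‖(y − med y) w⁽ʸ⁾‖ ).

   Points ≥ 9 MADs from the median get weight 0 — a gross outlier that
   would wreck a Pearson correlation is simply ignored.
2. **Threshold binarization.** The two correlation matrices C_N, C_D
   become one binary differential graph: *gain* mode (edge iff
   C_N ≥ T1 and C_D ≤ T2), *loss* mode (mirrored), or *absdiff* mode
   (edge iff |C_N − C_D| ≥ T3 and |C_N| ≥ |C_D|, capturing correlation
   reversals). Cleanup: drop isolated genes, optionally discard the
   lowest-degree half.
3. **k-clique percolation.** Modules are unions of chains of adjacent
   k-cliques (complete subgraphs of size k sharing k − 1 genes) — an
   overlapping community definition, computed from the maximal-clique
   overlap graph. Default k = 4.
4. **Permutation significance.** Shuffle each gene's values within each
   condition (destroying all covariance), re-run the *whole* pipeline per
   permutation, and compare the observed global score
   S = Σ_modules Σ_pairs |C_N − C_D| against the null scores:
   p = #(null ≥ observed) / n.

A seeded synthetic benchmark (`generateBenchmark()`) plants a 20-gene
coexpressed block (pairwise correlation 1/(1 + σ²)) among 100 noise genes
with a pure-noise second condition, for power and recovery studies.

## Worked example

```r
library(bmkc)

b   <- generateBenchmark(sigma = 0.1, seed = 42)   # 20 + 100 genes, 30 + 30 samples
cfg <- pipelineConfig(mode = "gain", t1 = 0.8, t2 = 0.4,
                      filterFraction = 0, k = 4)
res <- runPipeline(b$control, b$disease, cfg)
res$modules
#> ModuleSet: 1 module(s) at k = 4
#>   [1] 20 genes, 4 clique(s): gene0001, gene0013, gene0017, gene0035, gene0038, gene0041, ...
res$stats
#> PercolationStats (k = 4): N = 20, d(k) = 0.1228
#>   largest cluster: N* = 20 (phi = 1.000); k-cliques: L = 4153, L* = 4153 (varphi = 1.000)
evaluateRecovery(res$modules, b$truth)
#> size 20, jaccard 1

pr <- permutationTest(b$control, b$disease, cfg, nPermutations = 200, seed = 42)
pr
#> PermutationResult: observed score 192 over 200 permutations
#>   p = 0 (plain), 0.004975 (add-one); seed 42
```

Reading: the pipeline found exactly one module at k = 4 — all 20 planted
genes, no false positives (Jaccard 1 against the truth). The percolation
cluster spans the whole detected graph (phi = varphi = 1). The observed
differential-coexpression score (192: the summed |ΔC| over the module's
190 gene pairs, each near 1) exceeds every one of 200 group-wise
permutation scores, so the plain empirical p is 0 (add-one: 1/201).

A thin CLI mirrors the functions
(`inst/scripts/bmkc simulate|correlate|network|modules|permute|run`),
reading/writing TSV matrices, edge lists, module tables and JSON, with a
YAML config file overridable by flags.

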
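# semidriver

Cancer driver-gene prioritization by mutation effects and semi-local
network centrality.

Most somatic mutations in a tumor are functionally neutral passengers; the
few driver mutations that confer a growth advantage are the ones worth
finding, and frequency-based callers miss drivers mutated in only a handful
of patients. `semidriver` ranks mutated genes by combining three signals on
a protein–protein interaction (PPI) network:

1. **Mutation score.** From a binary gene × patient matrix *M*, each gene
   gets
   
   M(i) = Σ_{k ∈ K_i} 1/N_k
   
   where *K_i* is the set of patients mutated in gene *i* and *N_k* the
   number of mutated genes in patient *k* — a mutation in a quiet genome
   counts more than one among hundreds. Never-mutated genes get the
   background score BMS = 1/N_max.

2. **Mutation impact function.** Pairs of mutated genes interact through a
   gravity-style score,
   
   MIF(i, j) = M(i) · M(j) / d(i, j)²
   
   with d the Euclidean distance between the genes' patient profiles
   (√Hamming for binary rows): high scores and similar patient sets mean
   high mutual impact.

3. **Semi-local centrality.** Per-patient differentially expressed genes
   (|log2 tumor/normal fold change| > 1, strict) are pooled into a cohort
   DEG set; the PPI is restricted to mutated genes ∪ DEGs; and each mutated
   gene *v* is scored inside its two-hop ego network by
   
   score(v) = N(v) + Σ_{u ∈ Γ(v), mut} c(u)·MIF(v, u) + Σ_{u ∈ Γ(v), DEG} b(u)
   
   where mutated neighbors contribute MIF-weighted centrality (`c`) and DEG
   neighbors pure centrality (`b`); genes that are both mutated and
   differentially expressed contribute to both branches. Genes are ranked
   by descending score; top-ranked genes mutated in < 2 % of patients are
   flagged as rare-driver candidates.

The package is aimed at computational cancer-genomics analysts who have a
cohort's somatic mutation calls (matrix or MAF-like TSV), paired
tumor/normal expression, a PPI edge list, and optionally a benchmark
catalog such as the Cancer Gene Census. A seeded synthetic-cohort
generator reproduces the statistical structure of all four inputs, so the
whole pipeline runs and is tested without any downloads.

## Worked example

```r
library(semidriver)

co <- generate_cohort(seed = 7)   # 300 genes, 60 patients, 5 hub drivers
m  <- co$mutation
sc <- mutation_scores(m)
degs <- call_degs(co$expression)
mutated <- rownames(m)[rowSums(m) > 0]

g <- build_merged_graph(co$ppi, mutated, degs)
r <- rank_drivers(g, sc, m)
print(tidy(r), n = 5)
#>    rank gene   score mutation_score degree role
#>   <int> <chr>  <dbl>          <dbl>  <int> <chr>
#> 1     1 G0003 10282.          2.62      29 BOTH
#> 2     2 G0001  7378.          1.96      18 BOTH
#> 3     3 G0014  4639.          0.143     19 BOTH
#> 4     4 G0012  4423.          1.83      18 BOTH
#> 5     5 G0019  4338.          3.48      19 BOTH
```

The five planted drivers of this cohort are G0001, G0003, G0012, G0014 and
G0019 — they occupy the top five ranks. Note G0014: its mutation score
(0.143) is tiny because it is mutated in a single patient, yet its network
position still ranks it third; this is the rare-driver behavior the method
is built for. Benchmarking against the planted set and flagging rare
candidates:

```r
ev <- evaluate_ranking(r, co$planted_drivers, mutated = mutated, max_k = 20)
glance(ev)
#>   max_k benchmark_size best_f1 best_f1_k final_precision final_recall
#> 1    20              5       1         5            0.25            1

flag_rare_drivers(r, m, co$planted_drivers, top_n = 10)
#>    rank gene  mut_count frequency_pct in_benchmark
#> 1     3 G0014         1          1.67 TRUE
#> 2     6 G0002         1          1.67 FALSE
#> ...
```

All five drivers are recovered by rank 5 (F1 = 1 at k = 5), and the
rare-driver table lists top-ranked genes mutated in under 2 % of the 60
patients (1/60 ≈ 1.67 %). `autoplot(ev)` draws the precision/recall/F1
curves; `autoplot(r)` the score profile.

`run_pipeline(run_config(...))` wires every stage from files on disk to
`ranking.tsv`, `evaluation.tsv`, `rare_drivers.tsv` and an auditable
`run.log`. The same pipeline is scriptable from a shell via
`inst/cli/semidriver-cli.R` (`simulate`, `run`, `evaluate` subcommands).

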
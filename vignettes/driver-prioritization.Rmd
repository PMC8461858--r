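---
title: "Driver-gene prioritization by mutation effects and semi-local centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver-gene prioritization by mutation effects and semi-local centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semidriver)
```

## The model

`semidriver` ranks somatically mutated genes as candidate cancer drivers by
scoring each one inside a small, gene-specific subnetwork. The premise is
that driver mutations dysregulate the expression of their network
neighborhood, so a mutated gene that sits centrally among differentially
expressed genes (DEGs) and other mutated genes on a protein–protein
interaction (PPI) network is a stronger driver candidate than an equally
mutated but peripheral gene.

Three quantities combine:

**Mutation score.** With a binary gene × patient matrix $M$, gene $i$
scores $M(i) = \sum_{k \in K_i} 1/N_k$, where $K_i$ are the patients
mutated in $i$ and $N_k$ is patient $k$'s total mutated-gene count.
Dividing by $N_k$ discounts mutations in hypermutated samples. Genes never
mutated in the cohort receive the background score $1/N_{max}$, which
cannot exceed any mutated gene's score. One subtlety worth noting: the
score of an *already mutated* gene can only grow when it gains another
mutation (each term of the sum is positive), but a gene moving off the
background branch by acquiring its first mutation in a heavily mutated
patient can land below the old background constant — the monotonicity
guarantee belongs to the sum branch only.

**Mutation impact.** Pairs of mutated genes interact via
$MIF(i,j) = M(i)M(j)/d_{ij}^2$, a gravity-style law in which the
Euclidean distance $d_{ij}$ between the two genes' patient-profile rows
(equal to $\sqrt{\text{Hamming}}$ for binary rows) plays the role of
separation: similar mutation profiles mean strong interaction.

**Semi-local score.** Per-patient DEGs ($|\log_2 FC| > 1$, strict) are
pooled into a cohort set; the PPI is restricted to the union of mutated
genes and cohort DEGs; and every mutated gene $v$ is scored inside its
two-hop ego network by

$$score(v) = N(v) + \sum_{u \in \Gamma(v),\,mut} c(u)\,MIF(v,u)
           + \sum_{u \in \Gamma(v),\,DEG} b(u),$$

with $c(u)$ aggregating MIF-weighted centrality over $u$'s mutated
neighbors plus the degrees of its DEG neighbors, and $b(u)$ aggregating
$c$-values of mutated neighbors plus DEG degrees (see `?score_gene` for
the full formulas). Two hops is the deliberate horizon: it sees beyond
direct interactors — where pure neighbor-counting methods stop — while
staying far cheaper than global centralities like betweenness.

## Design decisions at ambiguous corners

The scoring function leaves several details open; each is resolved by a
documented default with the alternative kept behind a flag, and every
choice is echoed into `run.log` by `run_pipeline()` for auditability.

* **MIF orientation (`mif_mode`).** One reading of the impact function has
  separation as the *reciprocal* of the Euclidean distance, which would
  make dissimilar profiles interact more strongly — the opposite of the
  gravity analogy and of the stated intent that similar, high-scoring
  pairs interact most. The default `"gravity"` divides by the distance
  squared; `"literal"` implements the reciprocal reading for comparison.
  On synthetic cohorts both modes are exercised by the test oracle; only
  the default is recommended for analysis.
* **Zero distance.** Two genes with identical mutation profiles have
  $d = 0$. The distance is floored at 1 — the smallest nonzero distance
  achievable between distinct binary rows — keeping MIF finite and
  maximal rather than infinite.
* **Scalar $N(x)$ (`neighbor_count`).** The score uses $N(x)$ both as a
  neighbor *set* and as a *number*. The default scalarization is the
  degree of $x$ inside the semi-local network; `"two_hop"` (the count of
  nodes within two hops) is available as the natural alternative from the
  local-centrality literature.
* **The $N(u)\,MIF(u,w)$ factor (`c_variant`).** Inside $c(u)$ the printed
  weight on a mutated neighbor $w$ is $N(u)$, constant in $w$. The default
  `"literal"` implements it as printed; `"nw"` substitutes $N(w)$ for
  symmetry with the DEG branch. No intent is guessed.
* **Dual-role genes.** A gene both mutated and differentially expressed
  (`BOTH`) contributes to the mutation branch *and* the DEG branch of
  every sum — the only reading under which such genes' scores increase,
  as intended.
* **Degrees in the ego graph.** Degrees and neighborhoods are evaluated
  inside each source's semi-local network, not the full merged graph,
  because the objective is defined on the local network. The merged-graph
  degree is reported alongside the score for context.
* **Recall denominator (`recall_denominator`).** Recall against all
  benchmark genes penalizes a cohort-restricted ranker for drivers it
  could never surface, so the default denominator is the benchmark genes
  actually mutated in the cohort (`"in_dataset"`); `"full_set"` gives the
  literal formula.
* **Rare drivers.** Rarity is frequency-only (strictly below 2 % of
  patients among the top-ranked genes); benchmark membership is reported
  as an annotation, not used as a filter, because curated catalogs
  themselves contain low-frequency drivers.
* **Ties.** Rankings break score ties by higher mutation score, then
  alphabetically, making output byte-reproducible.

## Tunables

| parameter | default | meaning |
|---|---|---|
| `deg_threshold` | 1 | log2 fold-change cutoff for DEGs (strict `>`) |
| `pseudocount` | 1 | added to both expression values before the ratio; makes zero cells well-defined |
| `mif_mode` | `"gravity"` | MIF orientation (see above) |
| `c_variant` | `"literal"` | weight in the mutated branch of $c(u)$ |
| `neighbor_count` | `"degree"` | scalarization of $N(x)$ |
| `recall_denominator` | `"in_dataset"` | recall baseline |
| `rare_threshold_pct` | 2 | rare-driver frequency cutoff, percent of patients |
| `uppercase` | `FALSE` | case-fold gene symbols in *all* inputs at once |

Gene symbols are matched by exact string equality after whitespace
trimming; the single `uppercase` flag applies to every input
simultaneously because symbol-case mismatch between sources silently
empties intersections otherwise. Genes present in the mutation or
expression data but absent from the PPI are retained in the matrices and
excluded from network construction, with dropped counts logged.

Degenerate inputs fail loudly: an all-zero mutation matrix (background
score undefined), an empty merged node set, a zero recall denominator, a
zero expression cell with `pseudocount = 0`, and a non-mutated source gene
are all errors rather than silent zeros.

## What the synthetic generator emulates

`generate_cohort()` produces the four inputs with the structure the method
assumes: a preferential-attachment PPI (heavy-tailed degrees, as in real
interactomes); drivers planted on the highest-degree hubs, each mutated at
its own frequency drawn uniformly from 1–20 % of patients (the low end
deliberately below the 2 % rarity cutoff); passengers mutated independently
at 1 %; log-normal expression baselines; and a ±2.5 log2-unit expression
shift applied to a driver's PPI neighbors in exactly the patients carrying
that driver, with 0.3 sd log-space noise. A driver that by chance hits no
patient is assigned one carrier, since an unobserved driver cannot be
ranked. The default sizes (300 genes × 60 patients, 5 drivers) keep a full
pipeline run around a second while leaving ~150 mutated genes to rank —
large enough that hub drivers are not trivially the only ranked genes.

Because the score is degree-anchored and drivers are planted on hubs,
recovery is only meaningful against *degree-matched* mutated passenger
controls; the acceptance script and tests compare mean ranks this way
rather than against arbitrary passengers.

What the generator does **not** emulate: mutational signatures, gene
length effects, copy-number segment structure, count-based expression
noise (negative binomial), correlated DEG programs, or incomplete/biased
PPI coverage. Passing recovery tests on synthetic cohorts therefore shows
the pipeline implements its own model faithfully — not that the model's
assumptions hold in any given tumor cohort.

## Numerical notes

Log fold changes are computed as `log2(num/denom)` rather than a
difference of logs so exactly representable ratios (e.g. a 2-fold change
at the default threshold) sit exactly on the boundary and are excluded by
the strict inequality. MIF values are memoized per mutation matrix and
computed lazily on the edges of each semi-local network, never as a dense
all-pairs table. All randomness in the generator flows through one seeded
RNG whose state is restored afterwards, so cohorts are bit-identical given
a seed and independent of surrounding RNG use.

## Problem sizes used by the test suite

Unit and property tests run on matrices up to ~50 × 20 and attributed
graphs of ≤ 15 nodes, where a naive triple-loop oracle of the scoring
function is exact and fast; the oracle-equivalence suite covers 100 random
graphs in all four mode combinations. Recovery checks average ten default
synthetic cohorts. These sizes were chosen so the complete suite documents
the method's behavior in well under a minute of compute.

## Limitations

The method ranks genes for a cohort, not per patient; unpaired expression
designs are out of scope (the DEG rule requires matched tumor/normal
columns); the DEG call is a pure fold-change cutoff with no variance model
or FDR control; and evidence from SNVs and CNVs is collapsed by a binary
OR per gene and sample, discarding multiplicity and variant class.
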
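# consig — cross-study consensus marker signatures for hippocampal NSCs

Single-cell RNA-seq studies of the adult hippocampal dentate gyrus disagree
on how to name their stem and progenitor populations: transcriptionally
similar clusters appear as "RGL", "qNSC", "NSC stage 1", "nIPC" or even
"astrocyte" depending on the study. `consig` is an R package for
comparing such studies through their **published marker gene lists**
rather than through integrated count matrices. It is aimed at
neuroscientists and computational biologists who want reproducible,
list-level cross-study comparisons and per-cell signature scoring.

The pipeline:

1. **Filter** each study's differential-expression table with a common
   criterion: linear fold change > 1.5 and adjusted p < 0.05 (studies
   reporting natural-log fold changes use ln FC > 0.25; log2 values are
   back-transformed).
2. **Compare** gene lists pairwise (common-gene count, Jaccard index or
   overlap coefficient), convert similarity to distance, and cluster
   populations hierarchically (`stats::hclust`; Newick export).
3. **Intersect**: exclusive (UpSet-style) intersection counts, and the
   *k*-of-*n* consensus signature — genes recurring in ≥ k independent
   studies. S_ij = |A_i ∩ A_j|; a gene g enters the consensus when
   |{i : g ∈ A_i}| ≥ k.
4. **Score** cells against a signature: mean per-gene z-score, or a
   capped-rank Mann–Whitney-U module score
   `1 − (Σ r_g − n_s(n_s+1)/2) / (n_s · r_max)` in [0, 1] (ties averaged,
   ranks capped at `r_max`, default 1500), with an inclusive high-score
   cutoff (default 0.4) — the construction used for senescence/SASP
   (SenMayo-style) scoring.
5. **Profile** signature scores along a supplied pseudotime axis (binned
   means, Spearman trend statistics), and account signature genes against
   external gene-module collections.

A synthetic-data generator (`simulate_marker_lists()`,
`simulate_expression()`) plants known consensus cores, monotone
quiescence/activation programs and a senescent subpopulation, so every
stage is testable end-to-end without any download. `run_pipeline()`
orchestrates the stages from a YAML config and writes a checksummed run
manifest; `inst/cli/consig.R` is a thin command-line wrapper.

## Worked example

```r
library(consig)

# seven synthetic studies with a planted 28-gene NSC core (>= 5 studies)
sim <- simulate_marker_lists(marker_sim_config(seed = 1))
filtered <- filter_markers(sim$markers)          # FC > 1.5, p.adj < 0.05
nsc_lists <- gene_lists_by_class(filtered, "NSC")

consensus_signature(nsc_lists, min_studies = 5)
#> <gene_set> consensus_k5: 28 genes
#>  G000001, G000002, G000004, G000007, G000011, G000012, G000018, ...

consensus_signature(nsc_lists, min_studies = 7)$genes
#> [1] "G000001" "G000002"

round(pairwise_similarity(nsc_lists, metric = "jaccard")[1:3, 1:3], 3)
#>        study1 study2 study3
#> study1  1.000  0.026  0.043
#> study2  0.026  1.000  0.030
#> study3  0.043  0.030  1.000
```

The 28 recovered genes are exactly the planted core; only the two genes
planted in all seven studies survive the strictest (k = 7) cut, and the
off-diagonal Jaccard values are small because each study carries 200
private genes.

```r
# expression with a planted senescent subpopulation and pseudotime
ex <- simulate_expression(expr_sim_config(seed = 1))
sen <- rank_signature_score(ex$lognorm,
                            gene_set("senescence", ex$truth$programs$senescence),
                            score_params(max_rank = 1500, cutoff = 0.4))
attr(threshold_cells(sen, 0.4, ex$annotation), "group_high_fraction")
#> NORM  SEN
#> 0.00 0.48

q <- zscore_signature_score(ex$lognorm,
                            gene_set("quiescence", ex$truth$programs$quiescence))
trend(profile_signature(q, ex$annotation, n_bins = 50))
#> quiescence trend: rho = -0.999 (DECREASING)
```

48% of the planted senescent cells — and none of the normal cells — exceed
the 0.4 senescence-score cutoff, and the quiescence program declines
monotonically along pseudotime, as planted.

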
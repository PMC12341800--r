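---
title: "Cross-study consensus marker signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study consensus marker signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consig)
```

## The problem

Adult hippocampal neural stem cells (NSCs), neural progenitors (NPs) and
neuroblasts are annotated inconsistently across single-cell RNA-seq studies:
the same transcriptional state may be called "RGL", "qNSC", "astrocyte
AST4" or "NSC stage 1" depending on the lab. `consig` implements a
comparison pipeline that works from each study's *published marker gene
lists* rather than from integrated count matrices: filter each list with a
common statistical criterion, quantify pairwise list similarity, cluster
populations by that similarity, count exclusive intersections, and extract
the genes recurring in at least *k* independent studies as a consensus
signature. The consensus signatures are then scored per cell and profiled
along pseudotime, and a rank-based senescence score with a high-score
cutoff identifies putatively senescent cells.

## Marker filtering

A record is retained when its linear fold change is **strictly greater
than 1.5** and its adjusted p-value **strictly below 0.05**. Studies that
report log2 fold changes are back-transformed (`2^fc`) before the linear
threshold is applied; studies that report natural-log fold changes are
instead thresholded at **ln FC > 0.25**, matching the original selection
criteria of those data. Both inequalities are strict because the criteria
are stated as strict ("> 1.5", "< 0.05"). A missing adjusted p-value is
treated conservatively as failing any p-threshold; such records are kept
at parse time (with a warning) but never pass `filter_markers()`.

## Similarity, distance and clustering

`pairwise_similarity()` supports three metrics. The number of common genes
(`common_count`) is the literal statistic the cross-study dendrogram was
described with; because raw counts are strongly driven by list size (the
seven studies' lists differ by an order of magnitude), the default pipeline
metric is the scale-free **Jaccard index** with `one_minus` distance
conversion. `common_count` with `max_minus` conversion (`d = max(S) - s`)
remains available to mimic the literal construction. `one_minus` on raw
counts is rejected outright — it would produce negative distances.

Clustering delegates to `stats::hclust()`, the routine the original
analysis used. Linkage is unspecified in that description, so the default
is `complete` (hclust's own default), overridable to `average` or
`single`. For determinism under tied merge heights, leaf labels are sorted
lexicographically (C collation) before clustering; `hclust` is
deterministic given input order, so equal-height merges resolve by label
order. The dendrogram exports to Newick with merge heights as branch
lengths via `ape`.

## Exclusive intersections and k-of-n consensus

`exclusive_intersections()` assigns every gene of the union to exactly one
membership pattern — the exact subset of lists containing it — which is the
quantity UpSet plots display; counts therefore sum to the union size.
`consensus_signature()` returns the genes present in at least
`min_studies` distinct counting units. The default counting unit is the
**study** (a gene found in several clusters of one study counts once),
matching the "shared in at least five *studies*" reading; per-cluster
counting is available behind a flag since the source text mixes "clusters"
and "studies". With the seven-study inputs this operation yields the
28-gene NSC signature at k = 5, the 62-gene NP signature at k = 3, the two
universally shared NSC genes (*Fabp7*, *Hopx*) at k = 7, and the ten NP
genes found in all studies.

Gene symbols are matched case-insensitively after whitespace trimming and
stored with their first-seen spelling. No alias or ortholog resolution is
applied: the comparison is of published mouse symbol lists verbatim, and
aliasing would silently change intersection counts (the published NP list's
"Cdks6", a likely variant of *Cdk6*, is deliberately left as-is).

## Signature scoring

`summarize_by_cluster()` computes the two dot-plot statistics exactly: the
percentage of a cluster's cells with nonzero expression and the mean
expression over all of the cluster's cells, zeros included.
`marker_specificity()` turns these into a single number — the
percent-expressed gap between the target cluster and the best other
cluster — quantifying "restricted expression" claims such as the one behind
proposing *Ecrg4* and *Tnc* as NSC markers.

Two per-cell signature scores are provided:

* **Z-score mean** (`zscore_signature_score()`): each signature gene is
  z-scored across cells with the sample (n−1) standard deviation;
  zero-variance genes are dropped with a warning rather than imputed; a
  cell's score is the mean z over retained genes. This is the statistic
  used for pseudotime profiles.
* **Capped-rank U score** (`rank_signature_score()`): per cell, all genes
  are ranked by decreasing expression with average ranks for ties; ranks
  beyond `max_rank` are truncated to `max_rank + 1`; with signature ranks
  \(r_g\) and size \(n_s\), the score is
  \(1 - \bigl(\sum_g r_g - n_s(n_s+1)/2\bigr)/(n_s\,r_{max})\), clipped to
  \([0, 1]\). This is the Mann–Whitney-U construction of the rank-score
  tool named in the senescence analysis; `max_rank` defaults to 1500, that
  tool's published default, since the analysis itself states no value. The
  main engineering subtlety is tie handling in sparse data: all
  zero-expression genes share one large average rank which is then capped —
  this is unit-tested explicitly. Being rank-based, the score is invariant
  to strictly monotone per-cell transforms, and for a random signature of
  size \(n_s\) with \(r_{max} = G\) distinct values its expectation is
  exactly \(1/2 + n_s/(2G)\), which the test suite verifies by simulation.

The high-score cutoff (default 0.4, the stringent senescence threshold) is
applied **inclusively** (`score >= cutoff`); the source description gives
no direction, and inclusive is the convention that makes "cutoff 0" flag
everything. Scores are applied to raw, not rescaled, score values. Both
scores are computed on the log-normalized layer; raw counts are first
log1p-CP10K normalized with a message (ranks are unaffected by this
monotone transform).

## Pseudotime profiles

Pseudotime is consumed as provided (the original analyses reused Waterfall
and Slingshot values); trajectory inference is out of scope.
`profile_signature()` bins cells into `n_bins` equal-width bins over the
observed pseudotime range (default 50) and reports per-bin mean scores;
empty bins propagate as `NA`, never zero. Smoothing is off by default —
the published curves' smoothing method is unreported, so raw bin means are
the reproducible primitive and the optional centered rolling mean is
cosmetic. `trend()` reports the Spearman correlation between bin centers
and bin means over non-empty bins (at least 3 required) and classifies
DECREASING / INCREASING at |rho| ≥ 0.3, capturing the expected pattern:
quiescence-associated NSC signatures decline along the trajectory while
NP/activation signatures rise. `module_overlap()` counts signature genes
per external module (e.g. age-conserved module sets) and reports the genes
captured by none.

## The synthetic-data generator

Real inputs (seven GEO-deposited marker lists and count matrices) cannot
be bundled, so every pipeline stage is validated against generated data
with planted ground truth.

`simulate_marker_lists()` plants, per cell class, a small core of genes
shared by a configured number of studies plus large study-private
remainders and filter-failing decoys. Defaults mirror the real
comparison's scale: 7 studies; a 28-gene NSC core in ≥ 5 studies with 2
genes in all 7; a 62-gene NP core in ≥ 3 studies with 10 genes in all 7; a
20-gene neuroblast core; 200 private genes per study and class; 60 decoys
per study and class. One study reports ln fold changes and one log2,
exercising the scale handling. Planted records draw fold changes and
p-values that pass the default filter; decoys fail it either on fold
change or on p-value.

`simulate_expression()` draws per-cell pseudotime t ~ Uniform(0, 1) (a
linear trajectory, matching the pipeline's single-lineage framing —
branching is a non-goal) and negative-binomial counts with a single global
dispersion (per-gene dispersion is deliberately out of scope). Program
means follow `baseline * (1 + amplitude * (1 - t))` for decreasing
programs and `baseline * (1 + amplitude * t)` for increasing ones.
Defaults: 2000 cells x 2000 genes, baseline mean 2, dispersion 2, a
50-gene quiescence (decreasing) and a 50-gene activation (increasing)
program with amplitude 5, and a 125-gene senescence program — sized like
the SenMayo senescence list — with a planted senescent subpopulation
(fraction 0.2) whose senescence-gene means are multiplied by 4. The
senescence program's baseline is set to a quarter of the global baseline
in non-senescent cells: SASP genes are largely silent outside senescent
cells, and without this reduced baseline a 125-gene signature drawn at the
global baseline would score near the random expectation in *every* cell,
which is not what senescence-scored data look like. These sizes keep the
full suite under a minute on one core while leaving per-bin sampling noise
far below the planted effects.

What the generator does **not** emulate: library-size variation, doublets,
batch effects, ambient RNA, branching trajectories, per-gene dispersion,
and correlated program membership. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
robustness to every artifact of real single-cell data.

## Numerical and degenerate-input choices

* Empty filtered marker lists remain as counting units (they deflate
  similarity) rather than being dropped silently; a warning is emitted.
* A Jaccard similarity between two empty lists is defined as 0 with a
  warning (the 0/0 case).
* A consensus threshold no gene reaches yields an empty signature with a
  warning, so threshold sweeps (and the nesting property
  `consensus(k) ⊇ consensus(k+1)`) behave smoothly.
* Score clipping events outside [0, 1] are counted and exposed as an
  attribute.
* `profile_signature()` accepts 2 cells/2 bins at minimum; `trend()`
  requires ≥ 3 non-empty bins.
* Simulators set the RNG seed from their config, so identical
  configurations are byte-identical, cross-platform, via R's default
  generator.

## Known limitations

The pipeline compares published marker lists, so it inherits their upstream
choices (each study's own DE test and preprocessing); it does not
re-derive markers from counts. Symbol-level matching cannot bridge
aliases. The rank score's `max_rank` default reproduces the referenced
tool's behavior but remains a free parameter whose optimum depends on
matrix sparsity. Trend classification at |rho| ≥ 0.3 is a convention, and
with few bins the Spearman null is wide — use ≥ 30 bins where feasible.
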
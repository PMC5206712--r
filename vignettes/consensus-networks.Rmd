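---
title: "Consensus inference of miRNA-miRNA interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus inference of miRNA-miRNA interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircons)
```

## The problem and the model

Curated miRNA-disease databases record, per published study, how strongly a
miRNA is differentially expressed in a disease — typically as a minimum
fold-change, sometimes accompanied by a maximum. Groups of miRNAs tend to be
co-deregulated, and a recurring hypothesis is that such groups form
co-regulatory modules whose joint expression pattern is a *signature* of a
disease or of a class of related diseases.

`mircons` treats every (miRNA, disease) pair as one network vertex, an *MD
node*: the same miRNA observed under two diseases is two nodes, because its
expression profile is disease-specific. The observations form a samples
(studies) by MD-nodes fold-change matrix, and the question "which MD nodes
co-vary?" becomes a network-inference problem on that matrix. Because no
single inference algorithm dominates across data types, the package follows
the *wisdom-of-crowds* design: six algorithms with complementary
assumptions each score all ordered node pairs, and their rankings — not
their incommensurable raw scores — are fused by Borda-count averaging into
one confidence per interaction:

$$\mathrm{confidence}(e) \;=\; \frac{1}{K}\sum_{k=1}^{K}
  \frac{n - r_k(e)}{n - 1},$$

where $r_k(e)$ is edge $e$'s rank (1 = strongest) under algorithm $k$, $n$
is the number of ranked edges and $K$ the number of algorithms (default
six). An edge ranked first by every algorithm scores 1; ranked last
everywhere, 0.

The six scorers are: absolute Pearson and Spearman correlation; distance
correlation (sensitive to non-monotone dependence); CLR, which z-scores a
mutual-information matrix against each node's background MI distribution
and combines the two contexts as $\sqrt{z_i^2 + z_j^2}$; MRNETB, which
selects per target the predictor subset maximizing relevance minus mean
redundancy; and a GENIE3-style ensemble of randomized regression trees
whose per-target importances give directed scores. Correlations enter as
absolute values because the consensus ranks interaction *strength*, and
signed scores would not be comparable with the nonnegative MI family.

## From records to matrices

Records with no fold-change value at all, and malformed rows, are dropped
(and counted); a row carrying only a maximum keeps that value as its single
fold-change. Three schemes turn dual-valued records into matrix cells:

* **average** — the mean of minimum and maximum (a `(2.3, 2.9)` record
  becomes 2.6); the single value otherwise. This is the default and the
  best-validated scheme.
* **maxmin** — no averaging: a study containing any dual-valued record is
  expanded into a `:min` and a `:max` row, so both observations survive as
  separate samples.
* **missingmax** — records lacking a maximum first receive one: the
  arithmetic mean of the same MD node's maxima in all other studies, or
  the record's own minimum when no maximum exists anywhere. The average
  rule is then applied to the completed records — imputation strictly
  precedes averaging.

Cells never observed (a study simply did not assay that MD node) are kept
as an explicit missing mask, never silently zero. At scoring time the
default policy scores them 0 — no reported differential expression — since
the mutual-information and tree scorers need a complete matrix; the
correlation scorers alternatively accept `pairwise_complete`. Fold-changes
are used exactly as recorded: no log transform, no up/down sign injection.

## Numerical and estimator choices

* **Discretization for MI**: equal-frequency binning with
  $\max(2, \lfloor\sqrt{m}\rfloor)$ bins for $m$ samples, natural-log
  plug-in estimator. Equal-frequency bins make the MI (and hence CLR and
  MRNETB) invariant to positive affine rescaling of any column; heavy ties
  collapse bins rather than being split, so a constant column carries zero
  information. The plug-in estimator's positive bias
  (about $(b-1)^2/2m$ for $b$ bins) affects all pairs alike and largely
  cancels under ranking.
* **CLR backgrounds** use the off-diagonal row entries only; a zero-spread
  background yields z = 0 rather than a division by zero.
* **MRNETB** is a heuristic for an NP-hard subset-selection problem:
  backward elimination from the full predictor set, then sequential
  replacement; this implementation also allows re-admission of an
  eliminated variable whenever that improves the objective. The search
  improves the objective monotonically and is bounded by the exhaustive
  optimum, but — like any local search — it can terminate in a local
  optimum, so the test suite asserts the bound and structured-case
  attainment rather than universal optimality. Negative per-variable
  objectives clamp to 0 so every score matrix is nonnegative and rankable
  on a common footing.
* **Tree ensemble**: 100 trees per target, $\sqrt{p}$ candidate predictors
  per split, importances normalized to sum to one per target; per-target
  seeds derive from the run seed, so identical seeds reproduce identical
  score matrices.
* **Ranking universe**: all ordered node pairs excluding self-loops (both
  orientations of each pair are ranked). Symmetric scorers rank the two
  orientations identically; keeping both makes the edge universe uniform
  across symmetric and directed scorers. When disease networks are built,
  the two orientations collapse to one undirected edge with the larger
  confidence.
* **Ties** share fractional average ranks, hence fractional Borda points —
  the standard Borda tie resolution.
* **Truncated arithmetic mode**: published worked examples of this
  consensus scheme print normalized Borda ranks truncated to two decimals
  and average the printed values (so 2/3 enters as 0.66 and four
  candidates ranked 1,3,4,2,2,3 average to 0.49, where exact arithmetic
  gives 0.50). `average_rank_consensus(mode = "paper_truncated")` makes
  that display arithmetic first-class so it can be pinned in tests;
  production runs default to `mode = "exact"`.

## Validation against co-citation

A same-disease miRNA pair counts as literature-validated when one single
PubMed identifier carries records associating both miRNAs with that
disease; records are deduplicated by (PMID, miRNA, disease) first. The
precision-recall and ROC sweep treats unverified pairs as negatives, but an
unverified pair may simply not have been studied yet — precision at the
high-confidence end, not recall, is the informative axis. The negative
universe is the same-disease (type-3) edge set of the consensus output,
not the full quadratic pair space.

## Disease networks and signatures

Edges are classified by endpoint identity: self-loops (type 1), same miRNA
across diseases (2), different miRNAs within one disease (3), and fully
mixed (4). Only type-3 edges feed the disease-specific network (DMIN) of
each disease, filtered at a confidence threshold — default 0.9; a
`top_fraction` mode instead keeps the top decile (or any fraction) of the
global consensus, since an explicit threshold and a quantile coincide only
on one particular dataset. The *signature component* of a disease class is
the intersection of the member DMIN edge sets: an edge survives only if it
passes the filter in *every* member disease. Intersection is over edges,
not vertices — the stricter reading of a conserved interaction component —
and the surviving edge set is split into connected components, each
reported separately, because a class can harbour more than one conserved
subnetwork. Intersection is idempotent, commutative and monotone: adding a
disease to a class can only shrink its signature.

## What the synthetic generator emulates

`generate_dataset()` emulates the record structure of a curated
fold-change compendium: several studies per disease, dual- and
single-valued fold-changes, missing measurements, and PMIDs shared by the
records of a study. A planted module of `module_size` miRNAs draws its
fold-changes from a shared per-study latent factor,
$x = \sqrt{\rho}\, z + \sqrt{1-\rho}\,\varepsilon$, giving within-disease
pairwise correlation $\approx \rho$; background miRNAs are independent
noise. The defaults — 30 miRNAs, 3 diseases in one class, 60 studies per
disease, a 3-miRNA module at $\rho = 0.9$, 30% dual-valued records, 10%
missing cells, 80% co-citation — are the package's benchmark conditions: a
latent-factor module is detectable by every scorer family, which is
precisely the premise of a consensus method, and the scale keeps a full
six-algorithm run to a few seconds.

The generator deliberately does **not** emulate realistic fold-change
marginals (beyond a positive shift), disease vocabularies, study-size
heterogeneity, or correlated missingness. Passing the end-to-end recovery
test therefore shows that the pipeline's machinery — matrix construction,
six scorers, rank fusion, thresholding, intersection — recovers a planted
linear-latent module under noise and missingness; it does not certify
performance on real compendia, whose modules are weaker, sparser and
confounded by study effects.

## Known limitations

* The 0.9 confidence filter is deliberately strict; a genuine module edge
  whose confidence lands marginally below the cutoff in a single member
  disease is dropped from the class signature. Because the signature is an
  intersection, recovery degrades abruptly, not gracefully, at the
  threshold — the `top_fraction` filter softens this when comparability
  across diseases matters more than an absolute confidence.
* Zero-filling unobserved cells induces shared-support correlation between
  nodes of the same disease; this inflates all same-disease backgrounds
  alike, and the within-disease *ranking* — which is all the consensus
  uses — remains driven by genuine co-variation.
* The plug-in MI estimator with $\sqrt{m}$ bins is biased upward at small
  sample counts; CLR's background standardization absorbs most of the
  common bias.
* Scoring all $n^2$ ordered pairs is quadratic in nodes; the package is
  designed for desk-scale analyses (hundreds to a few thousand nodes), not
  for the multi-million-edge regime, which would require blocked or
  parallel scoring.

## A minimal run

```{r, eval = FALSE}
g <- generate_dataset(synth_config())
cfg <- run_config(input = g$dataset, out_dir = tempfile("mircons_run_"),
                  classes = g$class_layout)
manifest <- run_pipeline(cfg)
manifest$objects$signatures$class1
signature_recovery(g$truth, manifest$objects$signatures$class1)
```
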
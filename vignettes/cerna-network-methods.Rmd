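---
title: "Methods: ceRNA network inference, topological ranking and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference, topological ranking and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernakit)
```

## The model

Competing endogenous RNA (ceRNA) regulation posits that a lncRNA can
de-repress an mRNA by titrating away a shared miRNA. In two-group
(case vs control) expression data this predicts *competing triplets*
(lncRNA, miRNA, mRNA) in which

* both the lncRNA and the mRNA are predicted targets of the miRNA, and
* the lncRNA and mRNA are deregulated in the same direction while the
  miRNA moves in the opposite direction.

`cernakit` assembles all such triplets from screened
differential-expression (DE) lists and consensus target predictions, and
summarizes the resulting tripartite network with a per-lncRNA topological
score to nominate key lncRNAs.

A deliberate modeling choice: "negatively co-expressed" is
operationalized as **opposite DE direction**, not as a sample-level
correlation coefficient. The miRNA profiles and the lncRNA/mRNA profiles
that motivate this design come from different cohorts, so cross-sample
correlation is not computable; direction opposition is the only
executable reading. For same-cohort data, `build_pairs()` accepts an
optional expression matrix and a Pearson threshold (default −0.3) as an
additional filter.

## Differential-expression screening

`test_differential()` is a simple two-group surrogate, not a replication
of a count-model fit: counts are normalized to counts-per-million (CPM),
the effect is `log2((mean case CPM + 1) / (mean control CPM + 1))`
(pseudocount 1 avoids log(0); case over control, so positive means up in
disease), and the p-value is a two-sided Welch test on `log2(CPM + 1)`.
Benjamini–Hochberg adjustment is applied *within* each RNA class because
the three classes represent separately screened series. The screen keeps
genes with |log2FC| strictly greater than 1 and adjusted p strictly below
0.05; both inequalities are strict because the thresholds are quoted as
"< 0.05" and "> 1". The contribution of this package is downstream of DE
testing, so a full negative-binomial/empirical-Bayes fit is intentionally
out of scope; tables produced by such tools can be imported through
`read_de_table()` and combined with `merge_external_de()`, which unions
literature genes and treats a direction conflict as a hard error.

Genes that are constant within both groups receive p = 1 when group means
agree and p = 0 otherwise (the zero-variance limit).

## Target consensus

Three mRNA-target tables emulate miRDB-, miRTarBase- and TargetScan-style
exports. The TargetScan-style table is score-bearing: records with
cumulative context score ≥ −0.1 are discarded *before* counting support,
so a sub-threshold record can never count toward consensus (the order of
filtering and consensus is not dictated by the source procedure; filtering
first is the conservative choice and is what `run_cerna_pipeline()`
does). A (miRNA, mRNA) pair becomes an edge when it appears in at least
two *distinct* databases — record multiplicity within a database never
counts. The lncRNA side uses a single starBase-style table with no
consensus rule; this asymmetry mirrors the data sources and is
deliberate.

## Network assembly and topology

Triplets are the join of direction-opposed lncRNA–miRNA and miRNA–mRNA
pairs on the shared miRNA, partitioned by the lncRNA's direction into the
lncRNA-up and lncRNA-down group networks (a partition of triplets, not of
genes: a miRNA may appear in both groups). Each network is validated as
tripartite with no isolated nodes, and every edge records how many
triplets induced it.

For a lncRNA *L*:

* **first relationship pairs** — distinct lncRNA–miRNA edges at *L*
  (equal to its node degree in a tripartite network);
* **secondary relationship pairs** — distinct miRNA–mRNA edges whose
  miRNA neighbors *L*. These are counted as *edges*, not paths: an mRNA
  reachable through two miRNAs contributes twice, which is the only
  reading under which the published top-10 table's arithmetic
  (total = first + secondary) is consistent;
* **total pairs** = first + secondary.

Hub nodes have degree strictly exceeding 5 ("exceeding" read strictly;
the threshold is an argument). Because the published hub tally pools
ambiguously over groups, `hub_nodes()` accepts a single group network or
a list to pool. Key lncRNAs are the intersection of the top-k by degree
and the top-k by total pairs (k = 3 by default, matching the size of the
published selection); the rule is stated loosely in the source narrative
("both higher"), so the top-k intersection is this package's explicit
formalization. All rankings break ties by the other statistic and then
lexicographically by gene id, so results are deterministic; note that for
exact ties this can transpose neighboring rows relative to the published
ordering (e.g. two bottom rows with identical degree and total).

`extract_subnetwork()` returns the lncRNA, its miRNA neighbors and their
mRNA neighbors with all connecting edges — exactly the triplets through
that lncRNA — and is idempotent.

## Enrichment

`enrich()` is a local hypergeometric over-representation analysis
replacing web-service calls: for each gene set, p = P(X ≥ k) with overlap
k, set size K (after intersection with the universe), query size n and
universe size N, computed through the log-space-stable distribution
function. The significance flag uses the raw p < 0.05 convention of the
count-based web tools; BH-adjusted p-values are always reported because
raw-p screening across many sets inflates findings. The universe is an
explicit argument. In the synthetic pipeline the background is all
*assayed* mRNAs rather than the screened ones: at the planted effect
sizes the screened mRNA list coincides with the network mRNA list, and a
query equal to its universe makes every p-value 1. With a real cohort and
a genome-scale background either choice can be passed.

## Survival and qPCR

Prognostic screening dichotomizes each gene at the median of
log2(CPM + 1) — ties to the "low" arm, deterministically; an unsplittable
(constant) gene is reported NA and never flagged — and compares arms with
the two-group log-rank test (χ² with 1 df). P-values are uncorrected
across genes, mirroring the per-gene p < 0.05 screening convention; the
output labels them as such. Kaplan–Meier estimation and the log-rank
statistic are delegated to the `survival` package behind this interface;
the test suite checks them against hand-computed product-limit and O/E/V
tabulations.

`delta_delta_ct()` averages technical replicates on the Ct scale, forms
ΔCt = Ct(target) − Ct(reference) per sample, ΔΔCt against the mean
control ΔCt, and folds 2^−ΔΔCt. The group comparison is the classical
equal-variance Student's t test (named explicitly in the motivating
protocol), with Welch available by flag.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; the defaults are the
conditions under which all recovery properties are tested:

| parameter | default | meaning |
|---|---|---|
| `n_lnc`, `n_mirna`, `n_mrna` | 60 / 30 / 80 | genes per RNA class |
| `n_case`, `n_control` | 20 / 20 | samples per group (the source series never state cohort sizes; 20 vs 20 is a typical GEO-scale two-group design) |
| `baseline_mean`, `dispersion` | 100, 0.1 | log-normal gene means; shared NB dispersion φ (variance μ + φμ²), the overdispersed-Poisson noise model assumed by count-based DE testing |
| `n_triplets`, `effect_log2fc` | 5, 4 | disjoint planted triplets; ±4 log2 shift of case means (a saturating effect, so recovery failures indicate logic errors, not power) |
| `decoy_edges`, `decoy_lnc_edges` | 30, 10 | single-database decoy edges |
| `db_support` | P(2) = P(3) = 0.5 | databases supporting each true mRNA edge (≥ 2 by construction, so planted edges always survive consensus) |
| `hazard_log_ratio`, `n_prognostic` | 1.5, 2 | log hazard ratio per SD of expression; planted prognostic genes |
| `censor_frac` | 0.3 | uniform-censoring target (typical of AML cohorts); the upper bound solves (1 − e^−u)/u = 0.3 at the baseline hazard |

Counts are negative binomial with gene-specific log-normal means; planted
genes shift the case mean by ±`effect_log2fc` on the log2 scale, with the
lncRNA and mRNA of a triplet sharing a random direction and the miRNA
opposed. Planting is disjoint (one lncRNA/miRNA/mRNA per triplet) so
recovery scoring is unambiguous. Prognostic genes default to the lncRNA
and mRNA of the *same* triplet: they share a DE direction, so their
standardized-expression hazard contributions reinforce; picking
opposite-direction genes would cancel the per-sample log hazard by
construction. Survival times are exponential with per-sample log hazard
Σ β_g·z_g over prognostic genes.

What the generator emulates: two-group overdispersed counts, multi-source
target tables with controllable overlap and score-distributed decoys,
survival tied to expression. What it does not: library-size imbalance and
batch effects, microarray noise, overlapping ceRNA competition for a
shared miRNA pool (a kinetic sponging simulator is a different artifact),
and realistic correlation structure among null genes. Passing recovery
tests therefore demonstrates the *logic* of the pipeline, not its power
on real cohorts.

## Numerical and degenerate-input choices

* Strict inequalities at every published threshold (|log2FC| > 1,
  adj. p < 0.05, score < −0.1, degree > 5, p < α).
* BH within RNA class; `p.adjust` step-up.
* Hypergeometric tails via `phyper` on the log scale; exhaustively
  checked against combinatorial enumeration for all universes N ≤ 12.
* Median-split ties to "low"; all-equal expression is an error surfaced
  as NA in the screen.
* Empty triplet sets yield empty (but valid) networks; isolated lncRNAs
  count (0, 0, 0, 0) pairs and extract to singleton sub-networks.
* Gene identifiers are opaque, case-sensitive strings; no alias
  resolution is attempted.

## Problem sizes

The shipped tests and the acceptance script use 170–300-gene cohorts at
20–100 samples per arm, 20-seed recovery loops, and exhaustive
enumeration up to N = 12 — sizes chosen so every property is checked by
brute force where a brute-force oracle exists, with the whole suite
completing in well under a minute of compute per module.

## Known limitations

* The DE surrogate is a t-test on transformed CPM: adequate for planted
  log2-scale shifts, underpowered and less calibrated than count-model
  fits at small counts — use the import path for real data.
* Direction opposition is a weaker criterion than negative sample-level
  correlation and will admit co-deregulated but unrelated genes; the
  correlation flag exists for same-cohort data.
* Enrichment ignores term hierarchy (flat sets) and the raw-p
  significance convention is anti-conservative by design.
* The prognostic screen is uncorrected across genes and dichotomizes at
  the median, discarding within-arm expression information.
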
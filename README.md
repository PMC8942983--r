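# cernakit

Reconstruction and topological analysis of lncRNA–miRNA–mRNA competing
endogenous RNA (ceRNA) networks, as applied to cytogenetically normal
acute myeloid leukemia (CN-AML).

## The problem

Under the ceRNA hypothesis, lncRNAs regulate mRNAs indirectly by
sequestering the miRNAs that repress them. A signature of this competition
in case/control expression data is the *direction-opposed triplet*: a
lncRNA and an mRNA that are both predicted targets of the same miRNA, with
the lncRNA and mRNA deregulated in one direction and the miRNA in the
other. `cernakit` implements the full inference chain from count matrices
(or precomputed differential-expression tables) to a ranked list of
candidate key lncRNAs:

1. **DE screening** — per-class screening at |log2FC| > 1 and
   BH-adjusted p < 0.05 (both strict), with a simple Welch-on-log2-CPM
   surrogate test and an import path for external (e.g. edgeR) results.
2. **Target consensus** — miRNA→mRNA predictions kept only when they
   appear in ≥ 2 of the emulated databases, after discarding
   TargetScan-style records with context score ≥ −0.1; miRNA→lncRNA
   interactions come from a single starBase-style table.
3. **Triplet assembly** — an edge survives only if both endpoints passed
   screening with opposite directions; triplets are the join of
   lncRNA–miRNA and miRNA–mRNA pairs on the shared miRNA, partitioned
   into lncRNA-up and lncRNA-down group networks.
4. **Topological ranking** — for each lncRNA: node degree, first
   relationship pairs (distinct lncRNA–miRNA edges), secondary
   relationship pairs (distinct miRNA–mRNA edges through its miRNA
   neighbors) and total pairs = first + secondary. Hubs are nodes with
   degree strictly > 5. Key lncRNAs are those in the top-k of **both**
   the degree and the total-pairs rankings.
5. **Enrichment** — hypergeometric over-representation (upper tail
   P(X ≥ k)) of network mRNAs against a user-supplied GMT collection.
6. **Survival** — per-gene median-expression split and two-group
   log-rank test (χ², 1 df), flagging genes at p < 0.05.
7. **qPCR arithmetic** — 2^−ΔΔCt relative quantification and the
   equal-variance Student's t comparison.

Because the original GEO series and web-database versions are not
desk-reproducible, the package ships a synthetic-data generator
(`simulate_counts()`, `simulate_interactions()`, `simulate_survival()`)
that plants known triplets, decoy edges and prognostic genes in
negative-binomial two-group data, so the whole pipeline can be tested for
exact recovery against ground truth.

## Worked example

The `analysis/` directory holds the staged workflow (each script takes a
seed, default 1, and reads/writes `results/run_seed<seed>/`):

```sh
for s in analysis/0*.R; do Rscript "$s" 1; done
```

Stage output for seed 1:

```
simulated 170 genes x 40 samples (seed 1): 5 planted triplets, 30 decoy mRNA edges, 2 prognostic genes
screened 15 of 170 genes as differentially expressed
score filter: 8 of 11 TargetScan records kept (score < -0.1)
consensus: 5 miRNA-mRNA edges (>= 2 databases), 15 miRNA-lncRNA edges
assembled 5 competing triplets; recovered 5/5 planted, 0 spurious
ranked 5 lncRNAs; 0 hub nodes (degree > 5); key lncRNAs: LNC0001, LNC0002, LNC0003
tested 13 sets with overlap; 1 significant at raw p < 0.05
screened 8 genes; 8 flagged at log-rank p < 0.05
planted prognostic genes recovered: 2/2
case fold: 4.14 +/- 0.21; control: 1.00 +/- 0.07
```

Reading: all 5 planted triplets were recovered with no false positives
(the 30 decoy edges were removed by the score filter and the two-database
consensus), the planted enriched gene set (`SIG_PLANTED`, p = 2.3e-06)
was the only significant one, and both planted prognostic genes were
flagged by the log-rank screen. The same run is available in one call:

```r
library(cernakit)
res <- run_cerna_pipeline(simulation_config(seed = 1), out_dir = "results/run")
res$ranking        # the per-lncRNA topology table
res$key_lncrnas    # top-k intersection of degree and total-pairs rankings
```

On a network shaped to the published top-10 lncRNA topology table, the
same functions reproduce the printed arithmetic — e.g.
`count_pairs(net, "XIST")` gives degree 20, 20 first + 38 secondary = 58
total pairs, and `select_key_lncrnas(rank_lncrnas(net), k = 3)` returns
XIST, TUG1 and GABPB1-AS1.

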
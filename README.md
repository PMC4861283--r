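# oleofind

Candidate-gene discovery for seed-oil accumulation from comparative
orthology and co-expression.

## The scientific problem

Oilseed dicots (soybean, cotton, castor bean, Arabidopsis) store 20–50%
oil in their seeds; grasses (sorghum, foxtail millet, rice) store < 3%.
One route to explaining the difference is to ask which gene families exist
*only* in the high-oil dicot lineage, which of those genes are switched on
during the seed's oil-filling stages, which behave like members of the
acyl-lipid machinery, and which are expressed differently between high-
and low-oil accessions of the same crop. `oleofind` implements that
inference chain as a tested, reusable R pipeline, together with a
synthetic-data generator that plants known truth at every step so the
whole chain can be validated end to end.

The pipeline's core statistics:

* **Markov clustering (MCL)** of weighted graphs: iterated expansion
  (matrix power) and inflation (entrywise power, column renormalisation)
  of the column-stochastic adjacency matrix until an attractor structure
  defines the clusters. Used on protein-similarity graphs (ortholog
  groups) and on expression-correlation graphs.
* **Lineage-specificity rule**: an ortholog group (OG) is dicot-specific
  iff every one of the four dicot species is represented and no grass gene
  is present.
* **Expression clustering**: genes × 7 developmental stages (2 replicates,
  RPKM); edges where |Pearson r| > 0.7; MCL clusters; clusters whose mean
  profile peaks during the oil-accumulation window (stages 4–6) carry the
  candidates.
* **Pathway-level co-expression (PLC)**: a gene is a candidate pathway
  member when it is co-expressed with ≥ 2 known acyl-lipid genes at
  p < 1e-4, where p is the two-sided t-test on r with df = n − 2
  (sign-agnostic: strong negative correlations count).
* **Differential expression**: per-stage two-sided Fisher exact test on
  the 2×2 table `[count, lib − count]` for the two libraries, at
  α = 0.01; DEGs common to both high-vs-low comparisons validate the
  candidates.
* **Supporting evidence**: GO hypergeometric enrichment (P < 0.01) with
  GO-slim summaries, AW-box (`CNTNG(N)7CG`) promoter scanning, and
  neighbor-joining gene-family trees with bootstrap support and
  species-overlap duplication labeling.

## Worked example

```r
library(oleofind)

cfg <- sim_config(seed = 1)   # the default synthetic study
ledger <- run_pipeline(cfg)
print(ledger)
```

```
candidate_ledger (seed 1):
  dicot_specific             269 genes
  pathway_orthologs          150 genes
  pathway_dicot_specific       9 genes
  clusters_3_5              1246 genes
  go_filtered                646 genes
  plc_candidates              66 genes
  core_upregulated_1x         60 genes
  core_upregulated_2x         17 genes
  tf_plc                     139 genes
  tf_dicot_specific           12 genes
  tf_upregulated              51 genes
  tf_seed_specific             8 genes
  degs_pair1                 369 genes
  degs_pair2                 373 genes
  degs_common                260 genes
  validated_candidates         9 genes
  validated_tfs               42 genes
```

Reading the ledger top to bottom: of 3,000 simulated soybean genes, 269
fall in dicot-specific OGs; 1,246 sit in expression clusters peaking in
the oil window; 646 of those carry a GO process of interest; 66 of the
dicot-specific ones are co-expressed with ≥ 2 pathway genes at p < 1e-4
(the PLC candidates); and 9 of these are also differentially expressed in
both high-vs-low-oil comparisons — the validated candidates. `make_report(ledger)`
prints the same sets with percentages in the two-decimal convention
(e.g. `format_pct(1534, 29095)` → `"5.27%"`) and a set-algebra audit.

Because the study is synthetic, every number can be checked against the
planted truth: the expression clustering recovers the 8 planted archetype
clusters with adjusted Rand index 1.0 at the default noise (σ = 0.2
log2), all 30 planted regulators pass the PLC screen, and 99.5% of the
planted 4-fold DEGs are recalled at α = 0.01 (seed 1).

A thin command-line front end is included:

```sh
Rscript inst/scripts/oleofind.R simulate --seed 1 --out-dir sim/
Rscript inst/scripts/oleofind.R run      --seed 1 --out-dir run/
```

## Package layout

* `R/mcl.R` — MCL engine and graph/cluster I/O
* `R/orthology.R` — species panels, groups-dialect I/O, lineage classes
* `R/expression.R` — RPKM, filters, correlation graphs, MCL expression
  clustering, sample dendrograms
* `R/coexpression.R` — correlation significance, PLC, TF screens
* `R/enrichment.R` — OBO parsing, annotation propagation, hypergeometric
  enrichment, GO-slim summaries
* `R/diffexpr.R` — Fisher-exact DE, DEG calling, intersections
* `R/motif.R` — AW-box scanning and per-gene counts
* `R/phylo.R` — protein distances, NJ, bootstrap, duplication labeling
* `R/simulate.R` — the synthetic-data generator (planted truth)
* `R/pipeline.R` — the orchestrated run, candidate ledger, report
* `vignettes/candidate-gene-pipeline.Rmd` — the methods vignette
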
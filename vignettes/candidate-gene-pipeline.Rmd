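---
title: "Methods: the candidate-gene pipeline for seed-oil accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the candidate-gene pipeline for seed-oil accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`oleofind` chains comparative orthology, seed-development expression
clustering, pathway-level co-expression (PLC), and two-library
differential expression into a single candidate-gene inference for seed
oil content, and ships a synthetic-data generator that plants known truth
at every step. This vignette documents the models, the tunable
parameters, the design choices made where the design was genuinely open,
and what passing the planted-truth tests does and does not demonstrate
about real data.

## The models and their assumptions

### Markov clustering

`mcl()` implements the standard Markov Cluster algorithm on a
column-stochastic matrix: *expansion* (matrix power, default 2) spreads
flow along paths, *inflation* (entrywise power followed by column
renormalisation, default 2.0) sharpens it, and small entries (below
`prune_threshold = 1e-5`) are zeroed to keep the flow matrix sparse.
Iteration stops when the largest entry change falls below `tol = 1e-6`
(or at `max_iter = 200` with a warning). Clusters are read off the
converged attractor structure: attractors are nodes with positive return
flow; attractor systems are connected components of the symmetrised flow
among attractors; each node joins the system of the lexicographically
smallest attractor it flows to, which makes the output deterministic.
Self-loops are added with weight equal to the node's maximum incident
edge weight, a common stabilisation that bounds the influence of degree.

The historical ortholog-clustering default inflation (1.5) is exposed on
`build_ogs()`; which inflation the original tools used differs between
implementations, so both are configurable and neither is claimed to
reproduce any particular software version. The implementation is dense
linear algebra on sparse matrices and is intended for graphs up to a few
thousand nodes, not for proteome-scale similarity graphs.

### Lineage classification

`classify_og()` is a pure function of the species-presence pattern: an OG
is *dicot_specific* iff all four dicot species are present and no grass
gene is; *grass_specific* symmetrically; *shared* if both lineages occur;
single-lineage patterns missing at least one species of their lineage are
*dicot_partial*/*grass_partial*. The partial and *other* labels extend
the published rule (which names only the specific classes) so that
classification is total; they are flagged as extensions in the
documentation. The generator's `other` composition class produces
single-species singleton OGs; by the presence-pattern rule these classify
as partial, which is intended — the truth label records the generative
recipe, the classifier records the pattern.

### Expression clustering and the oil window

Profiles are per-stage replicate means of log2(RPKM + 1) — seven points
per gene. The choice of scale was open (the source tools do not state
it); log2(RPKM + 1) is the field's default for correlation-based
clustering and is exposed via `stage_profiles(log2p1 =)`. Edges connect
genes with |Pearson r| strictly greater than 0.7; the absolute value
matters because strong negative co-expression is biologically
informative and is counted by the PLC rule. The "oil window" is stages
4–6 of the seven (5–6 mg through 400–500 mg seed weight), when lipids
accumulate fastest; cluster selection in the pipeline is by *property*
(clusters whose mean profile peaks inside the window), not by index, with
an index-based override.

"Up-regulated" means the maximum per-stage mean inside the window is at
least `fold` times the mean over **all seven** stages; the overall mean
(rather than the mean over all samples) matches plotting per-stage
averages, and the `>=` comparison makes `fold = 1` the "higher than
average" rule and `fold = 2` the "twice average" rule, with the called
set monotone decreasing in `fold`.

### Correlation significance and PLC

`corr_pvalue()` is the standard two-sided t-test of zero correlation,
t = |r|·sqrt((n−2)/(1−r²)) with df = n − 2. For n = 8 this has the closed
form p = 1 − (15/8)|r| + (5/4)|r|³ − (3/8)|r|⁵, which the test suite
re-derives by numerical integration of the t density before using it.
`n` is always an explicit argument, never hard-coded: published tables in
this area sometimes imply a different n than the stated stage count, and
printed p-values from legacy tools do not always match the exact test, so
the package implements the standard test and leaves n to the caller. No
multiple-testing correction is applied to PLC p-values by default (none
is standard in the PLC literature); the audit edge list is emitted so any
correction can be applied downstream.

The PLC partner threshold is **inclusive** ≥ 2: the published screens
are worded both as "more than two" and "at least two", and the worked
tables contain two-partner candidates, so the inclusive reading is the
default, with both thresholds configurable.

### Differential expression

`fisher_de()` conditions on the 2×2 table
`[count_a, lib_a − count_a; count_b, lib_b − count_b]` and computes the
two-sided p by the point-probability method (all tables whose
hypergeometric probability is ≤ that of the observed table, with a
1 + 1e-7 relative slack for floating ties) — the convention of common
Fisher implementations, verified against `stats::fisher.test` in the
suite. Genes sharing margins share one hypergeometric computation, so
10⁵-gene tables are tested in seconds. A gene is a DEG when significant
in at least one stage (`rule = "any"`, default) — the per-stage testing
is stated in the source methods but the aggregation rule is not, so both
`any` and `all` are implemented. Replicates within an accession, if
present, should be pooled by summation before testing (the convention of
count-based exact tests without dispersion estimation). The test assumes
Poisson sampling; it is anti-conservative for overdispersed data, which
is why the generator's counts are Poisson by design (below).

### Motif scanning

The AW-box consensus `CNTNG(N)7CG` has five fixed positions; on uniform
random sequence the expected hit rate is 4⁻⁵ ≈ 9.77e-4 per position per
strand. Matching is position-exact, overlapping hits are all reported,
and an ambiguous `N` in the *sequence* matches pattern `N` positions but
never a fixed position. The default scans the forward strand only (the
AW-box is a promoter-strand element in the WRI1 literature); both-strand
mode exists because published counts do not state their policy, and no
claim is made that either setting reproduces any published table.

### Gene trees

`neighbor_joining()` delegates to `ape::nj` (taxa sorted first so input
order cannot matter); additive matrices are reconstructed exactly, which
the suite checks to 1e-9. Protein distances default to the Poisson
correction −ln(1−p) with pairwise deletion of gaps, the conventional
amino-acid default when the original software settings are unknown; the
uncorrected p-distance is available. Bootstrap support resamples
alignment columns and scores bipartitions of the full-data tree.
Duplication labeling uses the species-overlap rule — an internal node of
the rooted tree is a duplication iff its children's species sets
intersect — with midpoint rooting by default and an outgroup option,
since the original rooting is unstated. Species-overlap is known to
undercount duplications when losses erase the overlap; the planted-truth
test therefore runs at zero loss, where the rule is exact.

## The synthetic-data generator

`simulate_study()` emulates the structure of the real inputs: a
7-species OG table in six composition classes; 3,000 focal-species genes
with 7-stage × 2-replicate expression; count tables for one high-oil and
two low-oil accessions at 4 stages; 2-kb promoters with planted AW-boxes;
gene families evolved on a fixed dated species tree; and a miniature GO
DAG with slim terms. Defaults (and why):

| parameter | default | rationale |
|---|---|---|
| `n_ogs` | 5,000 | large enough for stable class frequencies, small enough for seconds-scale runs |
| `composition_probs` | dicot_specific 5.3% | mirrors the published dicot-specific share (5.27%) |
| `n_genes_expr` / `n_clusters` | 3,000 / 8 | the published expression-clustering scale |
| `sigma_gene`, `sigma_rep` | 0.2, 0.2 log2 | moderate biological + replicate noise; per-gene offset SD 0.5 |
| `n_de_genes`, `lib_size` | 2,000, 2e5 | mean count 100 per gene per library |
| `de_fraction`, `fold_change` | 0.1, 4 | planted effects strong enough to be individually detectable |
| `promoter_length` | 2,000 bp | the 2-kb-upstream promoter convention |
| `family_dup_rate`, `family_loss_rate` | 0.3, 0.2 per branch | gene families with a few visible events |

**Archetype design.** The published per-cluster expression curves are not
printed numerically, so the eight archetypes are qualitative stand-ins:
three monotone declines, peaks at each of stages 4–7, and an early
stage-2 peak. Their free parameters were fixed once, at design time, by
annealing within those shape constraints to minimise the maximum
inter-archetype |Pearson r| (0.645 — the analytic floor for step declines
breaking after stages 1 and 2). This matters because the clustering
edge rule is |r| > 0.7: two monotone declines are intrinsically
correlated near 0.65, and a planted partition whose archetypes exceed the
edge threshold would be unidentifiable by *any* graph clustering, not a
defect of MCL. The archetypes are documented as illustrative and make no
claim of calibration to measured profiles.

**Counts are Poisson, not negative binomial,** to match the Fisher
test's sampling model — the generator validates the implementation, so
implementation and generator must share a null. Overdispersion can be
added by the user for robustness studies, with the caveat that exact
tests are anti-conservative there. Planted fold-changes are split half
up-/half down-regulated in the high-oil accession and each library is
rescaled to `lib_size`: because proportions must sum to one, planting
*any* signal shifts every null gene's proportion slightly (the closure
effect); balancing directions bounds that shift to a few percent, small
relative to the planted 4-fold effects but visible as a mildly inflated
null DEG rate in the full pipeline run. The dedicated type-I-error check
therefore uses a fold-free null, where the Fisher test is conservative
(empirically ≈ 0.009 at α = 0.01).

**What the generator does not emulate:** read-level sequencing noise and
mapping artefacts, realistic substitution models (family sequences evolve
by per-site Poisson substitution), linkage between neighbouring genes,
overdispersion, isoform structure, and annotation incompleteness.
Passing the planted-truth tests shows the *inference chain* is
implemented correctly and recovers truth under its own assumptions; it
does not show the assumptions hold for any real dataset.

## Numerical and degenerate-input choices

* Ties everywhere are broken lexicographically (isoform selection, MCL
  attractor assignment, NJ taxon order), so every result is reproducible
  from a seed.
* Constant expression profiles have undefined correlation; they are
  excluded with a warning and surface as `unclustered`.
* Isolated graph nodes are reported `unclustered`, never as singleton
  clusters; singleton MCL clusters from `build_ogs` are reported as
  singletons, not OGs.
* Negative NJ branch lengths are kept (clamping would break the
  additivity checks); display-level clamping is left to the caller.
* The GO universe defaults to all genes with at least one annotation;
  "all annotated genes" is ambiguous in the source description, so the
  universe is an explicit argument.
* Hypergeometric upper tails use `phyper(k − 1, …, lower.tail = FALSE)`;
  `k = 0` gives p = 1 and can never be reported as enriched.
* `fisher_de` clamps p into (0, 1]; the relative tie slack 1e-7 matches
  the reference implementation convention.

## Problem sizes used by the shipped tests

The default study (5,000 OGs, 3,000 expression genes, 2,000 count-table
genes, 200 promoters, 20 families) runs the full pipeline in well under a
minute on one CPU; the acceptance checks use 200 random graphs (≤ 30
nodes) for the MCL oracle, all 2×2 tables with margins ≤ 50 for the
Fisher oracle, 10⁵ genes for the type-I error, 10⁶ positions for the
motif background, and ≤ 12-taxon matrices for NJ additivity. These sizes
were chosen as the smallest that make the statistical assertions sharp.

## Known limitations

* MCL here is dense-block sparse algebra; proteome-scale graphs
  (hundreds of thousands of nodes) need the dedicated external tool.
* The Fisher DE test ignores biological replication; with replicates a
  dispersion-aware model is preferable, and the package deliberately does
  not reimplement one.
* Species-overlap duplication labeling undercounts under loss, and
  midpoint rooting can misplace the root on clock-violating families.
* PLC p-values are uncorrected for multiplicity by design; treat
  candidate lists as rankings, not discoveries.
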
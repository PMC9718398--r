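---
title: "Methods: multi-bait BioID interactomics with screen, enrichment and survival integration"
author: "proxitome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-bait BioID interactomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxitome)
```

# Scope and model

`proxitome` analyses proximity-dependent biotinylation (BioID) experiments
run with several related baits — here the five classical RAD51 paralogs,
which assemble into the BCDX2 (RAD51B–RAD51C–RAD51D–XRCC2) and CX3
(RAD51C–XRCC3) complexes of the homologous-recombination pathway. The
package starts after the database search: its inputs are post-search prey
tables (one row per bait/condition/prey with average spectral count,
unique-peptide count, iProphet probability and protein length), gene-level
CRISPR NormZ tables or guide-level counts, GMT gene-set collections,
interaction-catalogue edge tables, and expression-linked patient cohorts.
Raw spectra, read files and the search engines themselves are out of
scope.

# Confidence filtering

A prey observation is retained when its iProphet probability is at least
0.9 **and** it has at least one unique peptide **and** it is not a
classical BioID contaminant. Both thresholds are inclusive, read literally
from the conventional filter. The unique-peptide count is interpreted as
pooled across the two biological replicates; `minUnique` is exposed should
a per-replicate reading be preferred upstream.

No complete machine-readable contaminant list accompanies the convention,
so the package ships an explicit default: the recurrent promiscuous
binders AHNAK, PRKDC, TOP1, HLCS, FLNB, PRKAA1, PRKAA2; lysozyme (LYZ);
the endogenously biotinylated carboxylases (ACACA, ACACB, PC, PCCA, PCCB,
MCCC1, MCCC2, and HLCS above); and the prefix classes `KRT*`, `RPL*`,
`RPS*` for keratins and ribosomal subunits. The list is replaceable by
file (`defaultContaminants(file = ...)`), because reproducibility requires
the list to be explicit rather than illustrative. Filtering is idempotent,
monotone in the probability threshold, and commutes with contaminant
removal; the test suite asserts all three.

Gene symbols are normalised once at ingest (upper case, whitespace
stripped, optional isoform-suffix truncation at a configurable delimiter,
default `"."` so dash-containing HGNC symbols survive). One namespace is
what makes the joins across BioID, screen, GMT and cohort tables
well-defined.

# Abundance

The spectral abundance factor divides the average spectral count by the
protein length in amino acids, `SAF = AvgSpec / L`, correcting the
peptide-count advantage of long proteins. Heatmap matrices use
`log2(SAF)` with preys undetected by a bait imputed at a spectral count of
zero. Zero has no finite logarithm, so imputed cells are carried as an
explicit `-Inf` sentinel plus a logical `imputed` assay in a
`SummarizedExperiment`; `flooredLog2SAF()` replaces them by a finite floor
(default: minimum observed log2-SAF − 1) so that distances and displays
are deterministic and the imputation is never silently confounded with a
measured low count. Plain SAF is the default; NSAF (per-column
normalisation to unit total) is available behind `normalize = "nsaf"`.

The differential statistic under replication stress is computed on raw
average spectral counts, not SAF:

$$\log_2 \mathrm{FC} = \log_2 \frac{\mathrm{AvgSpec}_{HU} + 1}{\mathrm{AvgSpec}_{untreated} + 1}$$

over the union of both conditions' prey sets, with absent preys
contributing zero. The +1 offsets make the ratio defined at zero. The
statistic is antisymmetric under swapping conditions and strictly
increasing in the HU count; both are asserted as properties. The
significance rule pairs `|log2FC| > 1` with `|NormZ| > 2` in the
chronic-hydroxyurea CRISPR screen; the one-sided-looking form
"log2FC < 1 or > 1" that sometimes appears in figure legends is vacuous as
printed and is implemented as the symmetric two-sided rule (both cuts are
arguments).

# Complex-level set algebra

A complex-level interactome is an inclusion/exclusion intersection: preys
present in every `include` bait and absent from every `exclude` bait.
The shipped definitions read the "exclusive" wording literally:

- all-common: include all five paralogs;
- BCDX2-exclusive: include RAD51B, RAD51C, RAD51D, XRCC2; exclude XRCC3;
- CX3-exclusive: include RAD51C, XRCC3; exclude the other three.

The non-exclusive reading is one flag away (`exclusive = FALSE`), since
the exclusivity of published intersection counts cannot always be settled
from prose. Set operations default to the steady-state condition;
condition is a parameter. Upset decomposition assigns each prey to the
signature of exactly the baits detecting it; the cells partition the union
by construction, and tests verify them against per-prey brute-force
enumeration.

# CRISPR screen integration

The in-house dropout screen is scored from guide-level day-0/day-14 counts
with a deliberately simple, fully documented **drugZ-style** scheme:

1. depth-normalise each sample's counts to a common library size;
2. per replicate, guide fold changes `log2((d14 + 0.5)/(d0 + 0.5))`;
3. z-score the fold changes against the replicate's empirical mean and SD;
4. gene score = sum of its guide z-scores across guides and replicates,
   divided by the square root of the number summed;
5. rank-based inverse-normal transform of gene scores into NormZ.

Depleted genes get negative NormZ. The published drugZ algorithm adds
empirical-Bayes variance moderation and paired-replicate handling that the
downstream analyses here do not require — they consume only NormZ ranks and
thresholds — and externally computed NormZ tables can be supplied directly
(`readNormZTable()`), bypassing the scorer entirely. The transform fixes
the null behaviour by construction: absent planted effects, the fraction
of genes below −1.5 is the normal tail (≈ 6.7%), and the scorer is
invariant to per-sample count scaling; both are tested.

Threshold classifiers use strict inequalities at the published cuts
(sensitization NormZ < −1 in ≥ 2 of the named screens; essentiality
NormZ < −1.5), with missing cells never counting. Where a legend and body
text disagree on the sign of the sensitization cut, the negative cut is
used — the positive one would call nearly the whole genome.

Chemogenomic clustering is agglomerative (`stats::hclust`) on the
gene × screen NormZ matrix, default Euclidean distance and complete
linkage — the common heatmap default, since no distance/linkage is part of
the published convention — cut at a configurable `k` (4 for the all-common
sub-grouping, 3 where a coarser cut is wanted). Missing cells are excluded
pairwise from distances or imputed at zero (`missing = "zero"`); rows may
be standardised. Cluster ids are renumbered by first appearance in input
order, which, together with fixed parameters, makes assignments
deterministic; ties in the dendrogram follow `hclust`'s input-order
behaviour.

# Overrepresentation analysis

For a term with $K$ genes in a universe of $N$, a query of size $n$ and
overlap $k$, the enrichment p-value is the hypergeometric upper tail
$P(X \ge k)$, one-sided, with Benjamini–Hochberg q-values across tested
terms. The default universe is the union of the collection's genes — in
pipeline use, intersected with the preys detectable in the experiment —
because the published analyses delegate the universe to an enrichment
service without stating it; the choice is conservative and configurable.
"Excluding electronic annotations" is an input-side concern: GMT carries
no evidence codes, so IEA filtering belongs to whoever prepares the GMT.

Because the hypergeometric distribution is discrete, the achieved size of
the 0.05-level test sits below 0.05 and depends on the (N, K, n) geometry.
The calibration simulations therefore use a universe of 400, queries of
100 and twenty terms of sizes 30–300 (the range typical of annotation
collections), where the achieved size is ≈ 0.038–0.04 and the
significant-fraction band 0.05 ± 0.02 is meaningful; with much smaller
terms the discreteness alone pushes the achieved level below 0.03.

# Survival screening

The prognostic screen re-implements the dichotomize-and-test procedure of
web survival services: per gene, patients are split into low/high
expression and the two curves compared with the unweighted two-group
log-rank test (hypergeometric variance, 1-df chi-square). The
Kaplan–Meier product-limit estimator and the log-rank statistic are
implemented in the package and cross-checked in the tests against the
`survival` package as an independent oracle, plus a permutation oracle on
small instances.

Two cutoff modes exist because the services' auto-cutoff is not part of
the published text: `median` (default) and `best`, which scans every
distinct expression value with quantile in [0.25, 0.75] and keeps the
minimum p. The scan makes `best` anti-conservative by construction —
its null significant fraction exceeds the nominal level — so the number of
scanned cutoffs is reported per gene, and the default stays `median`.
Significance is flagged at raw p < 0.05 to mirror the published screen;
a BH column is emitted for transparency, without affecting the flag.
The endpoint (overall vs relapse-free survival) is a cohort-level tag; the
screen itself is endpoint-agnostic.

# Networks

BioID networks are undirected stars (bait–prey edges, provenance
`bioid`). Augmentation adds catalogue prey–prey edges only between
proteins already in the network, never changing the node set; edge pairs
are canonicalised by sorting, duplicates merged with provenance tags
unioned, making augmentation idempotent. Exports are GraphML and plain
edge lists for Cytoscape-class tools; layout and rendering are out of
scope.

# The synthetic-data generator

`generatorConfig()` fixes the study conditions once; every generator
derives its RNG stream from the single mandatory seed, and identical seeds
reproduce identical datasets byte for byte.

- **Design**: five baits × two conditions × two biological replicates.
  Planted complex structure at the published interactome sizes — 945
  all-common, 97 BCDX2-exclusive, 46 CX3-exclusive — plus 60 bait-specific
  preys per bait and 300 background preys with random 1–3-bait membership
  signatures constrained to be disjoint from the planted complex
  signatures, so that noiseless set recovery is exact by construction.
- **Counts**: negative binomial (overdispersion is the norm in spectral
  counting) with per-prey log-normal means around 10; the count model is
  the generator's own choice, not a claim about any particular dataset.
- **Confidence**: planted preys draw iProphet probabilities in
  [0.92, 1]; decoy rows fail either the probability or the unique-peptide
  rule; contaminant rows come from the default contaminant list.
- **HU effect**: 80 of the all-common preys shift their spectral mean by
  log2 effect 2 (4-fold) under hydroxyurea — a strong but realistic
  replication-stress response chosen once.
- **Screen**: 2000 genes × 4 guides × 2 replicates at negative-binomial
  mean 500 per guide — a scaled-down library at per-guide depth comparable
  to a 600-fold-coverage screen; planted essentials are depleted to 10% of
  the day-0 expectation.
- **NormZ profile**: three olaparib screens, one essentiality screen, one
  chronic-HU screen and three genotoxic screens; planted sensitizers score
  below −1.5 in ≥ 2 olaparib screens, planted essentials below −2, planted
  HU hits above 2 in absolute value; in noiseless mode background scores
  are bounded in (−1.5, 1.5) so the −1.5 and ±2 threshold recoveries are
  exact.
- **Cohort**: 500 patients, log-normal expression, exponential survival
  with baseline hazard 0.02/month multiplied by hazard ratio 2 per planted
  hazardous gene above its median, independent exponential censoring
  (0.01/month) plus administrative cut-off at 120 months.

What the generator deliberately does **not** emulate: peptide-level
identification noise, correlated prey detection within complexes, batch
effects between runs, guide-efficiency heterogeneity, non-proportional
hazards, cohort covariates. Passing recovery tests therefore demonstrates
the correctness of the computations and thresholds under the stated
model, not robustness to every pathology of real data.

# Numerical choices and degenerate inputs

- Thresholds are inclusive for the confidence filter (≥ 0.9, ≥ 1) and
  strict for the NormZ/log2FC classifiers (< −1, < −1.5, > 2), exactly as
  the conventions print them; boundary cases are unit-tested.
- Guide z-scoring with zero fold-change spread falls back to unit SD,
  keeping the null case finite and centred.
- A survival screen gene with constant expression returns p = 1 with a
  warning; a log-rank comparison with no events (or no variance) returns
  statistic 0, p = 1.
- Imputed abundance cells are never fed to distances as `-Inf`; they are
  floored explicitly.
- Intersections, classifier outputs and upset cells are returned sorted,
  so outputs are stable across platforms.

# Problem sizes used in validation

The test suite exercises the generator at two scales: reduced designs
(tens of preys, 120–300 screen genes, cohorts of 50–120) for unit and
property tests, and the full study-scale design (1688 planted preys, 2000
screen genes, 500 patients) for the end-to-end recovery checks and the
acceptance script. Calibration simulations use 1000 ORA null replicates,
a 200-gene null survival screen at n = 500, and 40 replicate cohorts for
the planted-hazard power estimate; these sizes put Monte-Carlo error
comfortably inside the asserted bands while keeping a full run in tens of
seconds.

# Known limitations

- The drugZ-style scorer is intentionally simplified; for publication-grade
  screen analysis, supply externally computed NormZ tables.
- The ORA universe convention matters and published service defaults vary;
  enrichment p-values are not comparable across universes, and annotation
  releases shift term contents over time.
- `best`-cutoff survival screening is anti-conservative and should be read
  as hypothesis generation, as the multiplicity disclosure column reminds.
- The "similarity to anchor-gene depletion" reading of chemogenomic
  sub-groups is implemented as cluster co-membership with the anchors — an
  interpretation, flagged as such, since no formal criterion is published.
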
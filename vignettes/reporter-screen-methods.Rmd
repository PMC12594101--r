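---
title: "Models and methods behind ReporterScreen"
author: "ReporterScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ReporterScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

ReporterScreen analyses pooled CRISPR-Cas9 loss-of-function screens read
out through a fluorescent transcriptional reporter: cells carrying a
genome-wide sgRNA library are FACS-sorted into the bottom and top tails
of reporter intensity, each tail is deep-sequenced, and genes whose
guides enrich in the low tail are called *activators* of the reporter
gene (their loss lowers expression), those enriching in the high tail
*repressors*. The package covers the full path from amplicon reads (or
simulated screens) to per-gene scores, filtered hit tables, a directed
regulatory network over many screens, and cross-screen co-regulation
analyses. This vignette records the models, parameter choices and
numerical decisions.

# The screen simulator

The simulator (`makeGenome`, `makeLibrary`, `makeTrueNetwork`,
`simulateScreen`, `emitReads`) exists so that every downstream stage is
testable without external data, under the statistical structure the
analysis assumes.

**Cell model.** Each sorted cell carries exactly one guide. At MOI 0.3,
roughly 86% of infected cells carry a single provirus and antibiotic
selection removes the uninfected, so multi-infection is rare enough that
we do not model it; `moi` is kept in `screenConfig()` as recorded
provenance. Guide frequencies are drawn once per screen from a Dirichlet
distribution with concentration vector `300 * runif(n)`, which produces
the mild (~2-fold interquartile) skew typical of amplified plasmid
libraries; per-replicate infection adds multinomial noise on top.

**Reporter model.** Baseline reporter intensity is log-normal
(`reporterMeanlog = log(1000)`, `reporterSdlog = 0.5`, natural-log
scale), matching the roughly log-normal shape of FACS intensity
distributions. A knockout multiplies intensity by `2^effect`, where
`effect` is the log2 fold-change of the reporter upon knockout of the
guide's gene: *negative* for activators (knockout lowers the reporter),
positive for repressors, zero for nulls. With `reporterSdlog = 0.5` a
planted |effect| of 1.5–2 log2 units shifts the distribution by 2–2.8
baseline standard deviations, i.e. a strong but not trivial hit.

**Artifact model.** Genes lying between the centromere and the reporter
locus can produce reporter-loss artifacts: Cas9 cutting there can
destabilise the chromosome arm and delete the knock-in allele in a
subset of cells, which then sort into the low bin regardless of
regulation. We model this bimodally — with per-cell probability
`penetrance` (default 0.3) the reporter signal is abolished entirely,
otherwise the cell is unaffected — mirroring the observed complete loss
of signal in a cell subset rather than a graded shift.

**Sorting and sequencing.** Per replicate, the bottom and top
`sortFraction` (default 5%) of cells by reporter value are selected, and
each bin is sequenced as one multinomial draw of `readsPerBin` reads
over the within-bin guide frequencies. Production screens sort tens of
millions of cells per replicate and sequence far deeper; the defaults
(`cellsPerReplicate = 2e6`, `readsPerBin = 2e5`) are scaled down to
desk size while keeping per-bin cell counts above 10x the library size
(the simulator warns when they are not). PCR duplication, doublets and
quality-score effects are deliberately out of scope; `emitReads` offers
only a uniform substitution error.

**What passing tests do and do not show.** The simulator reproduces the
sampling structure (tail sorting, multinomial depth, library skew,
control guides, the reporter-loss artifact) but not every property of
real screens: no guide-efficiency heterogeneity, no copy-number or
cut-site toxicity confounders, no PCR jackpotting, and real MAGeCK runs
on real data involve a negative-binomial guide test this package
deliberately replaces (below). Recovery rates measured here therefore
characterise the scoring machinery under its own assumptions, not
expected sensitivity on laboratory data.

# Amplicon reference and counting

Sequencing libraries multiplex up to twelve samples per lane with
staggered readout primers. Each amplicon is
`stagger + 8-nt index + Template1 (24 nt) + sgRNA (20 nt) + Template2`;
`buildReference()` materialises every (primer, guide) combination —
929,292 records for a 77,441-guide genome-wide library — and
`countReads()` assigns reads by fixed-position, substitution-only
matching:

* stagger + index must match exactly one primer exactly;
* Template1 may carry up to 2 substitutions (configurable);
* the guide region needs a unique best library match within
  `maxMismatch` (default 2) substitutions; ties are discarded, not
  fractionally assigned.

This replaces short-read alignment of the original protocol. Because
amplicon structure is fixed-position, Hamming matching is sufficient,
exactly reproducible, and makes the emit/count round trip an identity
at mismatch 0. Reads shorter than the full amplicon (75-nt reads of a
~260-nt construct) are matched on their available prefix. Indels and
quality-aware matching are out of scope. Unassigned reads are never an
error; they are tallied with reason codes
(`unknown_index`, `too_short`, `template_mismatch`, `guide_no_match`,
`guide_ambiguous`) so that assigned plus unassigned always equals
total.

# Scoring: alpha-RRA with a control-guide empirical null

**Normalization.** Median-of-ratios: the size factor of sample *j* is
the median over guides with positive counts in all samples of
`count[i,j] / geomean_i`; with fewer than 100 such guides the factors
fall back to total-count scaling. This preserves within-sample rank
order and is cross-checked in the tests against DESeq2's estimator.

**Guide statistic.** For each guide, the replicate-mean
`log2((low + 0.5) / (high + 0.5))` of normalized counts. Each guide
gets a one-sided empirical p-value against the non-targeting controls
in each direction with the add-one rule, `p = (1 + #{controls at least
as extreme}) / (1 + #controls)`, and a percentile rank over all guides
per direction (descending score for the activator/pos direction,
ascending for repressor/neg; ties broken by sgRNA id for stability).
This control-based statistic replaces MAGeCK's negative-binomial guide
test: it is fully specified, deterministic, and uses the control list
exactly as the screening protocol's scoring command implies. It is the
package's largest deliberate divergence from the original toolchain,
and exact numeric equality with any particular MAGeCK build is not
claimed — only rank-level agreement on strong hits.

**Gene statistic.** For a gene with guide ranks
`r(1) <= ... <= r(m)`, with only guides whose empirical p < alpha
"selected", the alpha-RRA score is

    rho = min over selected k of  P( Beta(k, m - k + 1) <= r(k) )

and `rho = 1` when nothing is selected. `alpha = 0.05` by default; the
original screen analysis does not print its selection threshold, and
0.05 is the conventional choice for this statistic. The permutation
p-value redraws `m` (rank, p) pairs uniformly without replacement from
the observed pool and recomputes rho under the same selection;
permutation nulls are shared across genes with equal `m` (equivalent
under exchangeability, and ~gene-count times cheaper). With
`nPermutations = 10000` the p-value floor is exactly `1/10001`.
Benjamini-Hochberg FDR is applied per direction.

A consequence of alpha-selection worth stating: under the null, a
four-guide gene has ~`0.95^4 ≈ 81%` probability of zero selected
guides, hence `rho = 1` and `p = 1`. Null p-values are therefore
uniform *conditionally on selection*, with a large atom at 1 — the
suite tests strict KS-uniformity at `alpha = 1` (where no truncation
occurs) and tail calibration (fraction of null genes with p < 1e-3) at
the default alpha.

# Hit filtering

Three filters, each a pure predicate on gene attributes (hence
order-independent, with complete removal provenance):

* **RRA cutoff** (default 1e-3, strict `<`): the operating point at
  which single-guide follow-up validated 72% of activators and 97% of
  repressors. The cutoff must lie strictly inside (0, 1); `rho = 1`
  (nothing selected) is never a hit.
* **Centromere span**: remove hits whose gene body overlaps the closed
  span from the centromere boundary nearest the target gene through the
  target's far end. The original description gives no endpoint
  convention; we chose overlap of the gene body with the closed span
  (not midpoint containment), anchored at the gene body regardless of
  N- vs C-terminal knock-in. Coordinates are 1-based inclusive
  (GRanges convention) internally and in reports.
* **Expression**: remove hits with rpkm < 0.1 (strict; 0.1 itself is
  retained). Genes missing from the expression table are retained with
  a warning, since the filter should act only on *measured* inactivity.
  The expression table of the unperturbed cell line is assumed.

Validation calls (`classifyValidation`) follow the >5% mean-intensity
rule: relative MFI < 0.95 confirms an activator, > 1.05 a repressor.

# Network assembly and co-regulation

Each retained hit becomes one directed edge regulator -> target screen,
sense activation/repression, weight `-log10(score)` (> 3 at the default
cutoff). A regulator with at least one edge of each sense is
*context-dependent*. Self-loops (a screen detecting its own gene) are
kept and flagged; a regulator hitting one target in both senses keeps
both edges. Exports: lossless TSV, Cytoscape SIF
(`activates`/`represses`), GraphML via igraph.

Cross-screen overlap matrices count shared regulators per sense;
companion Jaccard matrices divide by the union so that hit-rich screens
do not dominate. Screen clustering uses average-linkage hierarchical
clustering on `1 - mean(Jaccard_act, Jaccard_rep)` cut at k = 2; the
cluster with the higher within-group activator Jaccard is group 1
(activator-sharing screens), the other group 2 (repressor-sharing). The
original two-group arrangement was partly manual ("arranged to best
separate"); we substitute this deterministic rule and report the mean
silhouette of the split so partition strength is explicit. Degenerate
inputs (all screens identical) return `unassigned`. Condition-specific
regulators are the intersection over treated screens minus the union
over untreated; Venn-style queries are limited to 2–4 screens.

# Problem sizes and reproducibility

All randomness flows through explicit seeds (`withSeed` restores the
caller's RNG state, so generators compose deterministically), and
`runPipeline()` writes a manifest of output hashes so a rerun with the
same config is bit-identical except for the timestamp. The test suite
and the acceptance script run the scoring calibration at 2,000 genes x
4 guides + 100 controls, 6 replicates, 2e6 cells and 2e5 reads per bin,
with 10,000 permutations — sizes chosen to keep a full run at minutes
on one core while leaving the binomial tolerances of the stochastic
checks comfortably tight. The artifact-filter simulation uses 500 genes
on two chromosomes with penetrance 0.3; the planted-partition check
uses ten screens of 30 shared + unique regulators per block.

# Known limitations

* The guide-level statistic is not MAGeCK's negative-binomial test;
  published screens scored with MAGeCK will agree at the level of
  strong-hit ranks, not exact scores.
* The simulator omits guide-efficiency variation, copy-number effects
  and PCR artifacts (see above), so absolute recovery rates are
  optimistic relative to laboratory data.
* Functional classification of regulators (protein-interaction
  clustering, enrichment) is intentionally out of scope; supply a
  gene-to-class map to `classDistribution()`.
* `supplementaryHitTables()` expects the published per-screen hit
  tables to be provided by the user; they are not redistributed with
  the package, so analyses of the published 47-screen network require
  that one-time download.
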
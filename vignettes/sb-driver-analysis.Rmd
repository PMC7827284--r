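---
title: "Statistical driver discovery in Sleeping Beauty gene-trap screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical driver discovery in Sleeping Beauty gene-trap screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbdriver)
```

## The screen and the question

Sleeping Beauty (SB) is a cut-and-paste DNA transposon that reintegrates
exclusively at TA dinucleotides. In a whole-body screen, a multi-copy
transgene concatemer (the *donor locus*, on the order of hundreds of
transposon copies) is mobilized in somatic cells; each tumor that arises
carries a private collection of insertion sites, read out by capture
sequencing of transposon–genome junctions (SBCapSeq) with quantitative read
depths. A promoterless gene-trap cargo can only *inactivate* the gene it
lands in, so genes recurrently hit across tumors more often than chance
allows are candidate tumor suppressor genes (TSGs).

"More often than chance" needs a null model, and the null is unusual:
insertions are confined to TA sites, tumors differ hugely in insertion
burden, and the donor chromosome is contaminated by *local hopping* —
excised transposons preferentially reintegrate near the donor locus. The
package implements the full desk-side workflow around that null, plus a
synthetic-cohort generator with the same structure, so every statistical
property can be exercised against known truth.

## The recurrence null and the driver tiers

Let `ta_count(g)` be the number of TA sites inside gene *g*'s footprint and
`T` the total number of TA sites outside the donor chromosome. The per-gene
TA fraction is

    p_g = ta_count(g) / T.

A tumor *i* carries `n_i` insertions after donor filtering (counted
genome-wide, before per-gene collapse, including intergenic events —
the null asks where each independent insertion lands). Under uniform
placement on TA sites, tumor *i* hits gene *g* with probability

    pi_i = 1 - (1 - p_g)^(n_i).

The number of tumors with at least one hit in *g* is then a sum of
independent, heterogeneous Bernoulli draws — a Poisson-binomial variable.
`poisson_binomial_tail()` computes the exact upper tail P(X ≥ k) by dynamic
programming over the count distribution (no normal or Poisson
approximation), and is validated in the test suite against full outcome
enumeration.

Three nested stringency tiers classify the genes that are hit at all:

* **discovery**: Benjamini–Hochberg FDR q < 0.05 on the unfiltered matrix;
* **genome-significant progression**: Holm FWER p < 0.05, same matrix;
* **trunk**: Holm FWER p < 0.05 after keeping only insertions with ≥ 100
  reads (inclusive boundary), and recurrence in ≥ 3 tumors. High read depth
  proxies for clonality, so trunk drivers are the early / strongly selected
  events.

Progression drivers are a subset of discovery drivers by construction (Holm
dominates BH pointwise). Trunk drivers need not be: the depth filter
shrinks each tumor's `n_i`, so a gene with few but uniformly deep hits can
reach trunk significance while remaining unremarkable in the unfiltered
pass. The number of tests *m* in each pass counts only genes with at least
one hit (in that pass) and at least one TA site; untestable genes are
excluded symmetrically from every tier.

This instantiation uses exactly the quantities the workflow produces —
per-gene TA content, per-tumor burden, per-gene tumor recurrence — and is
exactly computable. It does not model insertion hotspots, chromatin
accessibility or capture-efficiency bias; on real data those would make the
null optimistic for genes in accessible regions.

## Donor inference and filtering

Local hopping inflates insertion density on the donor chromosome.
`infer_donor_chromosome()` normalizes per chromosome by the number of
*legal* sites — insertions per TA site, not per base — because TA content
varies between chromosomes and is the only place an insertion can go. The
donor call is the density-maximizing chromosome (ties broken by name and
flagged), and `filter_donor()` removes the whole chromosome before any
statistics, trading the loss of real donor-chromosome drivers for a null
that is honest on the remaining genome.

## Per-gene collapse and orientation patterns

Within one tumor, multiple insertions in the same gene are collapsed to the
single insertion with the highest read count (`assign_and_collapse`); ties
keep the 5'-most site, a deterministic and documented choice. Gene
footprints are gene bodies only — no promoter flank — and an insertion
inside two overlapping footprints counts for both genes.

Orientation patterns distinguish *inactivating* from *activating*
recurrences. Under `allele_mode = "gene_trap_only"` every call is
inactivating: a promoterless cargo cannot drive expression regardless of
orientation. Under `promoter_bearing`, a gene is called activating when its
collapsed insertions are significantly sense-biased: exact two-sided
binomial test of the sense count against 0.5, BH-corrected across tested
genes, requiring corrected p < 0.05 **and** a sense fraction ≥ 0.7. The 0.7
floor matches the degree of directional bias seen in strongly activated
targets of promoter-bearing screens and keeps marginally significant but
weakly biased genes out; both thresholds are arguments.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; `simulate_genome()` /
`simulate_cohort()` / `simulate_reads()` realize them hierarchically from
one master seed (separate derived streams for genome, cohort and reads, so
identical configurations are byte-identical end to end).

Default conditions, chosen once as a realistic compact screen:

* genome: 4 chromosomes × 500 kb, TA density 0.0625 (the
  uniform-composition expectation), 1000 non-overlapping genes of 1.4 kb;
* donor: chr1, concatemer locus at its midpoint; each tumor's non-selected
  insertions are a 50/50 mixture of a local-hopping kernel (geometric
  distance decay, mean 10 kb, snapped to the nearest donor-chromosome TA
  site) and a uniform draw over all genomic TA sites. The concatemer itself
  is not sequence-modeled — only its local-hopping consequence;
* cohort: 30 tumors, Poisson(250) non-selected insertions each — an
  order-of-magnitude choice for SBCapSeq clonotype counts in a solid-tumor
  screen, exposed in the configuration;
* planted drivers: three genes off the donor chromosome with per-tumor
  selection probabilities 0.6 / 0.5 / 0.4 and unbiased orientation;
* read depths: clonal (selected) insertions draw 100 + NegBinom(size 2,
  mu 150), putting all mass at ≥ 100 reads with a heavy tail; background
  insertions draw 1 + Geometric(0.5), concentrating mass at one read. This
  reproduces the operational clonal/background split without claiming any
  empirical depth distribution.

The generator emulates the structure the statistics assume: uniform
placement on TA sites given burden, independent tumors, and a clean
clonal/background depth separation. It does **not** model sequencing
error, PCR duplication, capture bias, insertion hotspots or chromatin
context — so passing calibration here demonstrates internal correctness of
the statistics, not robustness to those real-data artifacts.

`simulate_reads()` emits error-free junction reads ([IRDR motif][genomic
flank from the TA site]); `extract_junctions()` inverts it by exact
placement of flanks on both genome strands, requiring a unique placement
beginning at an indexed TA site. On error-free data the round trip is the
identity, which the tests assert exactly; ambiguous or truncated flanks are
tallied, never silently dropped.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open (BED) everywhere; a TA site is its
  leftmost base. TA is its own reverse complement, so a forward-strand scan
  enumerates all sites once.
* The Poisson-binomial DP works on the full count distribution in ordinary
  double arithmetic; tails are exact sums, and the suite cross-checks
  against `pbinom` in the homogeneous case at n = 5000.
* Yates' correction clamps |O − E| − 0.5 at zero, so a perfectly
  proportional table scores exactly 0 and the statistic is non-negative;
  a zero row/column marginal is an error, surfaced rather than patched.
* The curated-list chi-square requires an explicit gene universe. There is
  no defensible default universe, and the statistic is sensitive to it, so
  the module refuses to assume one.
* Empty cohorts, tumors with zero insertions, genes with zero TA sites and
  empty driver lists all flow through with defined results (empty tables,
  all-absent columns, exclusion from testing) rather than errors.
* Cohort burden ratios round half-to-even to 2 decimals.

## Problem sizes in the test suite

Calibration and recovery suites run at the default study scale (1000
genes, 30 tumors): 25 driver-free cohorts for false-positive control
(mean BH-discovery fraction and the share of replicates with any
Holm-significant gene both at most 5%), 25 planted-driver cohorts for
recovery (all three planted drivers discovery-significant in at least 90%
of seeds), and 50 cohorts for donor-chromosome identification (at least
95% correct at hop fraction 0.5). Read round trips use a 180 kb /
30-gene world where exact FASTQ-level identity is asserted.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
gen <- simulate_genome(cfg)
idx <- build_ta_index(gen$genome)
genes <- load_gene_models(gen$genes, idx)
co <- simulate_cohort(cfg, idx, genes)

donor <- infer_donor_chromosome(co$insertions, idx)$donor
m <- assign_and_collapse(filter_donor(co$insertions, donor), genes,
                         tumors = co$tumors)
drivers <- call_drivers(m, genes, idx, donor)
head(drivers)
```

The three planted drivers surface in all three tiers with Poisson-binomial
p-values many orders of magnitude below every background gene; the bundled
tumor-spectrum tables reproduce the whole-body screen burdens (0.74, 2.72
and 1.44 tumors per mouse) via `summarize_cohort()`.

## Known limitations

* The recurrence null conditions on observed burdens `n_i` and TA content
  only; real screens add hotspot and accessibility structure that would
  require a hierarchical or permutation null.
* Whole-chromosome donor filtering discards any true driver on the donor
  chromosome.
* Junction extraction is exact-match only (by design, paired with the
  error-free read simulator); it is not a read aligner and makes no attempt
  at mismatch tolerance or multi-mapping resolution beyond discarding
  ambiguous flanks.
* Gene footprints are bodies only; insertions in promoters or distal
  regulatory elements are counted as intergenic.
```
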
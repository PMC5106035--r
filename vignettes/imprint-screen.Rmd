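---
title: "Screening germline DMRs and tracking their developmental fate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening germline DMRs and tracking their developmental fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintfate)
library(dplyr)
```

## The problem

Sperm and oocyte methylomes disagree over thousands of genomic intervals.
After fertilization a genome-wide wave of demethylation erases most of these
germline differences, but a subset survives: intervals that stay
differentially methylated between the parental alleles act as imprinting
control regions, and in primates a further class survives only in the
placenta (transient imprints). `imprintfate` implements the whole chain of
inference from per-CpG bisulfite calls to those verdicts:

1. read and filter per-CpG methylation call tables (`methylome_io`
   functions: `read_cpg_table()`, `combine_replicates()`);
2. scan each gamete methylome with 25-CpG sliding windows and classify
   window states (`slide_windows()`, `classify_windows()`);
3. merge same-state windows into regions and intersect opposing-state
   region sets into germline DMRs (`merge_windows()`, `call_gdmrs()`);
4. flag each gDMR as partially methylated or not in blastocyst, placenta
   and a somatic panel, and classify its fate (`partial_regions()`,
   `persistence_matrix()`, `classify_fate()`);
5. independently, stage allele-specific expression trajectories across
   preimplantation development (`classify_trajectory()`).

A synthetic methylome generator (`generate_panel()`) produces panels with
planted gDMRs of known fate, so every step is testable against a manifest.

## The window classifier

Methylation ratios are `meth / (meth + unmeth)`, pooling reads from both
strands of a CpG dyad; sites with fewer than `coverage_min = 5` reads are
treated as missing, not as zero. Windows are 25 consecutive CpGs of the
*universe* — the union of CpG positions across the panel — so that window
frames are identical in every tissue; this is what makes cross-tissue
persistence comparisons well defined. A window is evaluated only when at
least 10 member CpGs carry a ratio.

With `m` and `s` the mean and standard deviation of the informative member
ratios, a gamete window is

* **methylated** when `m − s > 0.75`,
* **unmethylated** when `m + s < 0.25`,

and a tissue window is **intermediate** (partially methylated — the
signature of one methylated and one unmethylated allele) when

* `m − 1.5·s > 0.2` **and** `m + 1.5·s < 0.8`.

The SD terms demand within-window consistency, not just an average. We read
the `± 1.5·s` criterion as two-sided: the whole band must sit inside
(0.2, 0.8), which is the only reading under which the criterion describes an
interval. All four comparisons are strict, so a window exactly at a boundary
is unclassified. `s` is the sample standard deviation (n−1 denominator) by
default; the choice is exposed (`sd_type = "population"`) because calls near
the thresholds can flip with the denominator, and nothing in the screen's
definition fixes it.

## Regions and gDMR calls

Same-state windows that touch or overlap are merged into maximal regions
(`merge_windows()`, `fuse_regions()`; "consecutive" is interpreted as
touching-or-overlapping in genomic coordinates — with step-1 windows a
CpG-index adjacency rule gives the same result). Coordinates are 0-based
half-open throughout; a CpG belongs to a region iff `start <= pos < end`.
Bismark coverage input is 1-based and converted on read.

A germline DMR is the genomic **intersection** of an oocyte-methylated
region with a sperm-unmethylated region (maternal) or vice versa (paternal),
accepted when the intersection contains strictly more than 25 universe
CpGs. The intersection is the only interpretation of an "overlap-defined"
position under which every gDMR is contained in both parental source
regions; when one region overlaps two opposing partners, two gDMRs are
emitted so that per-overlap CpG counts are preserved.

## Fate classification

Each tissue's intermediate-state regions are fused, regions of 500 bp or
less are discarded (strict `>`), and a gDMR is flagged *partial* in a tissue
when it overlaps a surviving region by at least 1 bp (the merge-then-
attribute convention implies interval overlap rather than containment).
Fates are assigned in decision order:

| fate | rule |
|---|---|
| `reprogrammed_preimplantation` | not partial in blastocyst |
| `ubiquitous_candidate` | partial in blastocyst and ≥ 12 of 14 somatic tissues |
| `placenta_specific` | partial in blastocyst and placenta, 0 somatic tissues |
| `tissue_restricted` | partial in blastocyst and 1–11 somatic tissues |
| `other` | partial in blastocyst only |

The placenta is tracked separately and never counted as somatic: whether it
belongs in the merged "15 tissues" set is not fixed by the screen's
definition, and keeping it out makes `placenta_specific` independent of the
ubiquitous threshold. For panels with `N ≠ 14` somatic tracks the threshold
scales as `ceiling(12/14 · N)`. These five categories are mutually exclusive
and exhaustive over the flag space (a test enumerates all
2 × 2 × (N+1) combinations).

## Allelic expression staging

Zygotic genome activation occurs in waves with the major transition at the
4–8-cell stage; before it, transcripts are maternal oocyte stores, so
maternal-appearing expression is uninformative about imprinting. Stage
calls use two conventional allele-specific-expression cutoffs, exposed as
arguments and reported with the output because the staging logic itself does
not fix them: a stage needs `min_reads = 10` total reads, and an allele
fraction `>= mono_frac = 0.9` is monoallelic. Trajectory classes:

* `imprinted_paternal`: paternal-only at any stage at or after activation
  (default `8cell`, configurable to `4cell`). Earlier maternal dominance
  never vetoes the call, since maternal stores and embryonic paternal
  transcripts co-exist until late cleavage.
* `biallelic_embryonic`: biallelic post-activation, without post-activation
  paternal-only evidence.
* `maternal_store_decay`: maternal-only before activation, non-increasing
  stage totals, and no post-activation paternal or biallelic signal. The
  decay test (non-increasing totals) is a choice: nothing quantifies
  "decreasing", and we prefer the weakest test that separates the decay
  template from re-activation.
* `uninformative`: everything else, including non-informative embryos.

## What the generator emulates — and what it does not

`generate_panel()` draws a shared CpG universe (gaps of
2 + rounded-exponential bp, mean 100), then per tissue a *true* methylation
level per CpG, then observations in two stages: clipped Gaussian biological
noise (`noise_sd`, default 0.02) on the true level, and read sampling
(depth ~ Poisson(`mean_depth`, default 20); methylated reads ~ Binomial).
Two stages matter: the coverage filter is exercised by the depth model and
the SD-gated window criteria by the per-CpG noise.

Backgrounds are wide uniform bands — sperm and somatic tissues high
U(0.6, 1), oocyte alternating high/low domains of 500 CpGs (bimodal),
blastocyst globally low U(0, 0.5), placenta globally reduced and
heterogeneous U(0, 0.9). The width is deliberate: wide bands give background
windows a large SD, so the SD-gated criteria reject them and only planted
intervals — tightly consistent around their target, as true DMRs are —
classify. Planted DMRs get gamete targets 0.95/0.05 and fate-determined
tissue targets (partial 0.5, reprogrammed 0.05 or 0.95); placenta-specific
DMRs are modelled somatically unmethylated (0.05), matching the observation
that confirmed placenta-specific regions are mostly CpG-rich intervals
robustly unmethylated in somatic tissues. An option splits the oocyte into
two half-depth replicates to exercise the pooled-counts replicate path used
for low-coverage oocyte libraries.

The generator does **not** emulate realistic CpG density maps, repeat
families, partially methylated domains (>100 kb placental PMDs), bisulfite
conversion failure, copy-number structure, or cell-type mosaicism. Passing
tests therefore demonstrate the correctness of the screen's logic under its
own statistical assumptions — not its operating characteristics on real
WGBS data, where thresholds interact with sequence context and coverage
heterogeneity.

## Numerical choices and degenerate inputs

* Strict inequalities exactly as the criteria state; boundary windows are
  unclassified (tested at `m − s = 0.75`, `m + s = 0.25`, band edges 0.2 and
  0.8, 25 shared CpGs, 500 bp regions).
* Missing sites are absent, never zero; windows count only informative CpGs.
* Strand collapsing pairs records at positions `p`, `p+1` (a CpG dyad);
  genuine neighbouring CpGs are ≥ 2 bp apart, so the rule is unambiguous,
  and pre-collapsed tracks pass through unchanged.
* The oocyte pooled-counts rule re-applies the 5-read filter **after**
  pooling (an assumption; the alternative would admit sites no single
  replicate covers adequately, which is the point of pooling).
* Rolling window sums guard against negative variance residue from floating
  point (`max(ss, 0)`).
* Repeat-content tiles of 20 CpGs label `unique` sequence as repeat fraction
  < 25%; the contradictory literal convention (">25% repeats") is available
  behind `literal_unique = TRUE`.
* Interval merging, intersection and overlap counting delegate to
  IRanges/GenomicRanges; tests compare every result against naive all-pairs
  oracles.

## Problem sizes used by the test suite

The acceptance-level tests run on panels of 2 chromosomes × 20,000 CpGs
with 18 tissue tracks (oocyte, sperm, blastocyst, placenta, 14 somatic) and
70 planted gDMRs; window-classifier oracle equivalence uses 50 random
tracks of 5,000 CpGs; interval algebra is checked on 1,000 random region
fixtures; trajectory classification on 100 genes per class. These sizes keep
the whole suite under a few minutes while giving every code path thousands
of cases.

## Known limitations

* The screen is threshold-based by design: no smoothing, no beta-binomial
  shrinkage, no replicate variance modelling, no per-CpG differential tests.
* Fate calls are per-interval flags; partial methylation in a tissue is not
  evidence of *allelic* methylation without genotype data, which is why the
  expression module exists.
* The published genome-wide tallies for the human panel depend on the
  specific public datasets and are not reproduced here; the package will run
  on such data if the user supplies the call tables, but its tests and
  acceptance checks are entirely synthetic.
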
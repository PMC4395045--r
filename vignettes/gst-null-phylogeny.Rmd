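---
title: "Phylogenetic analysis of GST M1/T1 null allele frequencies"
author: "gstpatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic analysis of GST M1/T1 null allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gstpatterns)
```

## The problem

The glutathione-S-transferase genes *GSTM1* and *GSTT1* commonly carry
whole-gene deletion ("null") alleles that abolish the enzyme and are screened
by presence/absence PCR.  Null frequencies vary strongly among human
populations, which matters both for pharmacogenetics (detoxification
capacity) and for population history.  `gstpatterns` implements a compact
comparative workflow over a compiled survey of 45 geographically assorted
human populations (plus seven printed continental-average rows):

1. count null-genotype frequencies from per-individual calls;
2. compute pairwise Nei (1972) standard genetic distances over the two
   presence/absence loci;
3. cluster populations by UPGMA, with a locus-resampling bootstrap and
   majority-rule consensus;
4. assign each population to one of seven least-distance frequency
   "patterns" anchored at Xhosa, Zimbabwe, Ethiopia, Egypt, Afghanistan,
   Caucasian and Andhra Pradesh, grouped into three geographic splits
   (Africa / out of Africa / other than Africa), and export the
   longitude/latitude scatter behind the split map.

The packaged survey is the unit of input: the underlying genotypes of the
44 literature cohorts were never deposited, so the table's printed `q`
(null frequency) and `n` (sample size) pairs are treated as data, and a
synthetic genotype generator recreates individual-level sampling when the
pipeline itself needs to be validated.

## Model and statistics

**Frequency counting.** For one locus, `q_hat = (#null calls) /
(#non-missing calls)`, with binomial standard error
`sqrt(q_hat (1 - q_hat) / n)`.  Missing calls are excluded per locus
(pairwise deletion), which is why a population can have different sample
sizes at the two loci.  Regional aggregates use the sample-size-weighted
mean `sum(q_i n_i) / sum(n_i)`.  The survey's own printed aggregates are
*not* recomputed: for India the weighted mean of the printed member rows is
0.2953 while the printed aggregate is 0.296 (and its printed sample sizes
do not equal the member sums), so aggregate rows are stored exactly as
printed and the discrepancy is documented rather than forced.  The weighted
(not unweighted) scheme is the one offered because it approximates the
printed aggregate closely; the unweighted mean (0.284) does not.

**Nei (1972) standard distance.** Each locus is biallelic (null vs
present).  With `x = (q_x, 1 - q_x)` and `y = (q_y, 1 - q_y)` the per-locus
identities are `j_x = sum(x^2)`, `j_y = sum(y^2)`, `j_xy = sum(x y)`, and

```
I = sum_l j_xy / sqrt( sum_l j_x * sum_l j_y ),   D = -ln I.
```

The ratio-of-sums form (not the mean of per-locus ratios) is Nei's
definition and the one used by PHYLIP's `gendist`; it is also the form that
reproduces the published distance matrices cell-for-cell.  No Hardy–Weinberg
square-root transformation is applied to the survey's frequencies: treating
the printed values directly as null-allele frequencies is the convention
that reproduces the published matrices, which fixes the intended reading.

**UPGMA.** Classic size-weighted average linkage: merge the closest pair at
height `d_min / 2`; the distance from the merged cluster to any other is
the size-weighted mean of member distances.  Heights are halved so the
leaf-to-leaf cophenetic distance equals the merge distance, and the output
is ultrametric by construction.

**Bootstrap and consensus.** The resampling unit is the locus (the
character of the distance computation), drawn with replacement per
replicate; each replicate recomputes the distance matrix and tree, and a
clade's support is the percentage of retained replicates containing it.
With only two loci the bootstrap is extremely coarse — a replicate can only
be {M1, T1}, {M1, M1} or {T1, T1} with exact probabilities 0.5/0.25/0.25,
so at most three distinct trees occur and supports converge to sums of
those weights.  This coarseness is a property of the design, not hidden:
the test suite checks supports against the exact enumeration.  The
majority-rule consensus keeps clades with support *strictly* above the
threshold ("more than 50%"), so a clade at exactly 50.0 is excluded;
retained clades are mutually compatible by the majority-rule theorem and
compatibility is still asserted at run time.

**Patterns and splits.** The source analysis reads seven recurring clusters
off the consensus trees.  The package operationalizes that reading as a
deterministic rule: every population receives the pattern of the anchor
population at minimal Nei distance (anchors label themselves), with ties
broken in anchor order I–VII.  This rule reproduces the narrated
memberships (Nigeria, Cameroon, Namibia and Gujarat attach to Xhosa; Iran
and Somalia to Ethiopia; the bulk of Europe to Afghanistan).  No formal
rule is stated in the source for the tree-to-pattern mapping; the
least-distance rule is this package's explicit choice, and the tree itself
remains available for clade-based cross-checks.  In the 20-region analysis
only six anchors exist (the Andhra Pradesh pattern emerges only among the
45 individual populations), and `run_analysis()` drops absent anchors with
a message.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `replicates` | 1000 | bootstrap replicates, as in the source analysis |
| `threshold` | 0.5 | strict majority fraction for consensus clades |
| `seed` | 1 | single documented RNG stream for resampling/simulation |
| `missing_rate` | 0 | per-call no-call probability in simulations |
| `default_n` | 100 | substituted sample size where the survey prints none (Iran); reported loudly |
| `n_scale` | 1 | multiplier on simulated sample sizes for recovery studies |

## Numerical choices and degenerate inputs

* Floating-point noise can push `I` marginally above 1; `D` is clamped to 0.
  `I = 0` (fixed opposite alleles at every resampled locus) yields `+Inf`
  rather than an error, so downstream stages can reject explicitly: UPGMA
  refuses non-finite input naming the offending pair, and bootstrap
  replicates with non-finite matrices are skipped, counted, and reported,
  with supports computed over retained replicates only.
* UPGMA ties are broken by the smallest (row, column) index pair in current
  label order; with all-equal distances this yields a left-to-right
  caterpillar.  Identical input and label order give byte-identical Newick
  output.
* Distance matrices are symmetrized exactly (`(d + t(d))/2`) before use;
  published-layout exports round to 6 decimals, mirroring the printed
  tables, while CSV exports keep full precision.
* Anchor ties in pattern assignment resolve to the earlier pattern in
  I–VII order.

## What the synthetic generator does and does not emulate

`simulation_scenario()` / `simulate_calls()` draw each individual's call at
each locus as an independent Bernoulli event at the population's true null
frequency, with optional uniform missingness — exactly the sampling model
behind a frequency-counting survey with printed `q` and `n`.  It does
**not** model linkage between *GSTM1* and *GSTT1*, genotyping error,
within-population structure, or any forward-time population genetics
(drift, migration, admixture).  Passing recovery tests therefore shows that
the estimation and distance pipeline is correct and consistent under the
survey's own sampling assumptions; it does not validate those assumptions
against real cohorts.

## Known limitations and data quirks

* The published distance cells involving the Caucasian aggregate
  (`wAs_Cau`) cannot be derived from that row's printed frequencies
  (0.529/0.197); every other printed cell of both matrices reproduces
  exactly at 6 decimals.  The package computes what the frequencies imply,
  and flags pattern assignments won by the Caucasian anchor
  (`flagged = TRUE`) instead of fitting the printed values.
* The survey's printed India aggregate and grand totals are internally
  inconsistent with its member rows (see above); aggregates are used as
  printed.
* In both the printed and recomputed 45-population matrices, Maharashtra's
  single nearest neighbour is Kerala (0.000540), so the tree shows
  Maharashtra–West Bengal (0.000574) inside the four-population Indian
  clade {Kerala, Maharashtra, Uttar Pradesh, West Bengal} rather than as a
  two-leaf pair; structural checks are phrased as clade membership for this
  reason.
* A two-locus bootstrap cannot grade support finely; supports are reported
  as computed, and the published figure percentages are not used as numeric
  targets.

## Problem sizes used by the test suite

The routine suite exercises the full 45-population matrix, bootstrap runs
of B = 1000 (deduplicated by resample composition, so they cost three tree
builds), and simulation recovery on the full survey at sample-size scales 5
and 50 — sizes chosen so the whole suite documents the analysis at full
fidelity while remaining quick to run.  At those scales the recovery checks
use binomial theory for their bands: at least 95% of the 90
population-by-locus estimates within 3 standard errors, no estimate beyond
5, and the maximum entrywise distance error shrinking between the two
scales (bounded at 0.02, the magnitude implied by the smallest cohorts of
~60 subjects at scale 50).

## Reproducing the headline numbers

```{r, eval = FALSE}
out <- run_analysis("populations45", outdir = tempdir(), replicates = 1000)
round(out$dist["Ind_Guj", "sAf_Xho"], 6)   # 0.002144
round(out$dist["Ind_Kar", "Ind_Tn"], 6)    # 0.000355
subset(out$patterns, id == "sAf_Nam")      # pattern I, Africa split
```

`scripts/acceptance.R` (repository root) recomputes the quoted pairwise
distances from scratch and writes them as JSON; see the README.
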
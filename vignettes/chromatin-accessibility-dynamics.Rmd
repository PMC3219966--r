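---
title: "Mapping developmentally dynamic chromatin accessibility with DNaseDynamics"
author: "DNaseDynamics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping developmentally dynamic chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DNaseDynamics)
```

# The problem

DNaseI preferentially cleaves nucleosome-depleted, regulatory-factor-bound
DNA. Sequencing the released fragments turns each cleavage event into a
single-base genomic tag, and the local density of tags into a quantitative
readout of chromatin accessibility. Profiling five embryonic stages (5, 9,
10, 11 and 14 in the conventional staging of fly embryogenesis — blastoderm
through head involution) with two replicate digestions per stage gives a
five-point time course of the regulatory landscape. DNaseDynamics implements
the full analysis stack for such data:

1. **Density tracks** — 20-bp bins scored by the tag count in a 150-bp
   window centred on each bin midpoint (`binDensity`).
2. **Accessible regions** — a 250-bp scanning window is compared with a
   binomial model of the surrounding 50 kb to give a per-tag enrichment
   z-score; a threshold is set so that an equal-size uniform-random tag set
   yields at most 1% as many calls (`scanZ`, `fdrThreshold`,
   `callAccessibleRegions`, together `callHotspots`).
3. **DHSs** — 150-bp peaks in density within accessible regions, several
   per region if the density supports them; replicate concordance demands a
   75-bp overlap between replicates; per-stage lists are unioned into a
   non-overlapping consensus with per-stage presence flags and a stage of
   temporal origin (`callDHSPeaks`, `replicateConcordant`, `unionConsensus`,
   `stageOfOrigin`).
4. **Developmentally dynamic elements (DDEs)** — for each ordered stage
   pair, the rank-expectation statistic scores every bin for enrichment;
   3-of-4 replicate-cross-comparison voting at a Benjamini-Hochberg q of
   0.05 flags consistent bins; adjacent bins with identical enrichment
   signatures merge into DDEs, which receive a temporal class and can be
   clustered by 5-stage profile (`rankExpectation`, `consistentEnrichment`,
   `mergeDDEBins`, `classifyTemporal`, `clusterProfiles`).
5. **Developmentally dynamic domains (DDDs)** — the base pairs covered by
   DDEs within 10 kb of each bin form a density track whose peaks are tested
   against a binomial-placement bootstrap null and BH-controlled at 0.05
   (`ddeDensity`, `dddNull`, `callDDDs`), with the rho temporal score and a
   neighbour-agreement binomial test characterizing the temporal coherence
   of nearby elements (`rhoScore`, `neighborPatternTest`).
6. **Annotation statistics** — genomic category assignment by DHS centre,
   binomial interval-overlap tests, conservation comparison against matched
   random placements, hypergeometric term enrichment, core-promoter
   (-60..+40) accessibility clustering with motif fractions, and
   peri-exonic profile clustering (`assignCategory`, `overlapBinomial`,
   `conservationCompare`, `hypergeomEnrichment`, `promoterProfiles`,
   `clusterPromoters`, `periexonicAnalysis`).

All coordinates in memory follow the Bioconductor convention (GRanges,
1-based closed); BED and bedGraph files on disk are 0-based half-open, and
cleavage tags are stored 0-based to match their 4-column BED interchange
format.

# The rank-expectation statistic

The centrepiece is a differential statistic for two matched genome-wide
signals A and B on the same 20-bp binning. The bins of B are ranked from low
to high (ties broken by genomic order) and A is reordered by that ranking to
give A'. If A and B agree, A' is close to monotone and every bin resembles
its rank neighbours; a bin where A is high while B is low lands among
low-rank neighbours and stands out. For each rank position we take the
median $m_i$ of A' over a centred window of `localWindow` positions and a
robust scale $s_i = 1.4826 \cdot \mathrm{med}_j |A'_j - m_j|$ over the same
window, and score $z_i = (A'_i - m_i)/s_i$ with a one-sided upper-tail
normal p-value.

Numerical choices worth recording:

* **Windowed scale.** The scale is the running median of absolute
  deviations, where each deviation is taken from its *own* centred running
  median rather than from the centre bin's median. For windows of thousands
  of bins the running median drifts negligibly across one window, so the
  two definitions agree to high precision, and this form admits an exact
  O(n log w) sliding computation (a C++ dual-multiset rolling median). The
  test suite checks the production path against a plain-loop
  reimplementation of the same definition.
* **Degenerate scale.** When the window MAD is zero (constant data, or one
  signal compared with itself on heavily tied integer counts) the z-score
  is defined as 0 and the p-value as 0.5: identical signals can never be
  called different.
* **Zero bins.** Bins where both signals are zero are excluded from the
  ranking by default. Most of the genome is empty; including the zero bins
  would concentrate enormous tied blocks in the low ranks and distort the
  local windows. A flag restores them.
* **Window size.** `localWindow` defaults to 10,001 bins (about 200 kb of
  ranked genome). The window must be large enough that the median/MAD are
  stable and small enough to track slow changes in the score distribution
  along the ranking; at desk scale results are insensitive between 5,001
  and 20,001.
* **End handling.** Windows are truncated at the ends of the ranking, not
  reflected, keeping the estimator honest where coverage is thinnest.
* **BH scope.** Multiple-testing control is applied genome-wide per
  comparison (one test family per ordered stage pair per replicate pair).

Voting then demands that at least 3 of the 4 replicate cross-comparisons
(2 replicates of A crossed with 2 of B) be significant, which makes the
procedure conservative: on replicate-exchangeable null simulations the
flagged fraction stays far below the nominal q.

## Temporal classification

Merged DDEs carry an enrichment signature over the 20 ordered stage pairs.
The classification rules are an explicit reconstruction of the class
definitions:

* *stage-s-specific*: s is enriched over every other stage;
* *early*: the density peak falls in stages 5-10 and no later stage is
  enriched over an earlier one;
* *late*: the peak falls in stages 11-14 and no earlier stage is enriched
  over a later one;
* *mixed*: everything else (e.g. U-shaped profiles where both ends are
  enriched over the middle).

The classes partition every DDE exactly once. Note that a steeply declining
element whose stage-5 signal is significantly above *all* later stages is,
by these rules, stage-5-specific even if it retains residual accessibility
later: stage specificity is an enrichment statement, not a presence
statement.

# Hotspot calling choices

* The scanning window W = 250 bp, local background L = 50 kb and FDR target
  1% are the method's reference operating points; the per-position success
  probability is p = W/L, recomputed against the truncated background span
  at chromosome ends.
* z-scores are computed at tag positions (regions are collections of tags),
  and the FDR threshold is chosen on the per-tag z lists of the observed
  set versus an equal-size uniform-random set: the smallest observed z such
  that random values at or above it number at most 1% of observed values.
  The region-level false-call ratio at that threshold is verified
  empirically in the tests.
* Qualifying tags within `mergeGap` (default W) merge into one region,
  expanded by W/2 on each side. DHSs are fixed at 150 bp, centred on local
  density maxima taken greedily by height (ties to the left), with later
  peaks suppressed if their window would overlap an accepted one.

# Bootstrap null for domains

Each resample draws the number of DDEs hitting a 20-kb window from
Binomial(n, span/genome), gives each a size resampled from the empirical
DDE size distribution, places them uniformly, and records the covered base
pairs. Empirical p-values use the add-one estimator (r+1)/(B+1), so no peak
gets p = 0. Significant peaks (BH 0.05) grow outward over the run of bins
above the null's 95th percentile — genome-scale analyses report domain
extents, so a boundary rule is required even though only peaks are tested;
runs above the null quantile are the least arbitrary choice consistent with
the peak test. Overlapping domains merge.

The rho score summarizes a 5-stage profile as
$\rho = \sum_s w_s d_s / \sum_s d_s$ with weights (+2, +1, 0, -1, -2): +2
for pure stage-5 accessibility, 0 for a flat (constitutive) profile,
negative for late-weighted profiles. The weight vector is the package's
definition, fixed by the score's required behaviour at the two extremes
(maximal for a purely early element, zero for a constitutive one,
antisymmetric in time); rho is scale-invariant by construction.

# What the simulator emulates — and what it does not

`simulateTags` draws an inhomogeneous Poisson process: a uniform background
(default 0.025 tags/bp, i.e. 50,000 tags per megabase per sample, a
desk-scale stand-in for tens of millions of reads genome-wide) plus
triangular intensity bumps of 150 bp at planted sites, scaled by a per-site
5-stage profile and a peak fold-enrichment. "Camelback" sites superimpose
two bumps 150 bp apart, reproducing the double-peaked promoter morphology.
Replicates are independent draws from the same intensity — matching
replicate digestions of pooled nuclei — and all randomness descends from
one integer seed through a documented splitting scheme (`splitSeed`).

Stage profiles per truth class: stage-specific classes are non-zero at one
stage only; *early* declines gradually (1, 0.9, 0.7, 0.45, 0.2) and *late*
mirrors it — gradual monotone fading rather than a step, as developmental
accessibility profiles decay over stages; *mixed* is U-shaped
(1, 0.4, 0.1, 0.4, 1); *constitutive* is flat. Where tests speak of an
"f-fold" site they mean the mean tag-density ratio over the site's 150-bp
footprint, so a 5-fold site has peak enrichment 2(f-1) = 8 under the
triangular shape.

The simulator does *not* emulate mappability, GC or cut-site sequence bias,
duplicate-read artefacts, copy-number variation, or cell-population
heterogeneity within a stage. Passing tests therefore demonstrate that the
algorithms recover planted structure under Poisson sampling noise at
realistic densities — not that real libraries are free of the systematic
biases listed above.

The toy annotation (`makeAnnotation`) places non-overlapping gene models
with UTRs, 2-3 CDS exons and introns on alternating strands, with exact
planted fractions for promoter motifs, regulator labels and elevated-
expression exons; exon and intron sizes are drawn so that the peri-exonic
length/flank filters retain a meaningful subset.

# Other defaults and degenerate-input behaviour

* Replicate concordance minimum overlap: 75 bp; concordant pairs merge to
  their union (preserving at least the 150-bp footprint for downstream
  overlap tests).
* Genomic category precedence: TSS (±100 bp) > 5'UTR > CDS > intron >
  3'UTR > intergenic; assignment is by the DHS centre nucleotide
  (left-rounded). The promoter ±100-bp window is the categorization rule;
  promoter *profiling* uses the oriented -60..+40 core promoter window.
* Promoter metaclusters: a cluster's mean profile is "up" when its stage-14
  mean exceeds 1.5x its stage-5 mean, "down" in reverse, else
  constitutive. The 1.5x ratio operationalizes the three observed trend
  groups; it is a parameter.
* Peri-exonic filters default to exon length ≥ 320 bp and clear flanks of
  ≥ 300 bp, with the elevated-expression threshold at signal > 25; the
  stricter variants (> 600 bp length, > 50 signal) reported alongside the
  analysis are reachable through the parameters. The stage whose density is
  clustered defaults to the blastoderm stage, the stage relevant to
  maternal-transcript comparisons.
* k-means degeneracy: when fewer distinct profiles than clusters exist,
  assignment falls back deterministically to one cluster per distinct
  profile; all-zero promoter profiles are dropped before clustering.
* Empty inputs return empty (typed) results rather than errors wherever a
  downstream stage can proceed; genuinely undefined requests (z-score with
  an empty background, rho of an all-zero profile, thresholding an empty
  z list) raise errors or NA skip signals as documented.

# Problem sizes used by the packaged analyses

The shipped pipeline demo and the reproduction script run on a 2-Mb
single-chromosome genome at 0.025 tags/bp with 12 planted sites per
temporal class, two replicates per stage, 10,000 bootstrap resamples and
10,001-bin rank windows; the end-to-end determinism check uses a 0.5-Mb
variant. These sizes were chosen so a complete run takes about a minute on
one CPU while every statistic still operates far from small-sample corner
cases. Genome-scale headline counts (tens of thousands of DHSs, hundreds
of domains) are functions of the real sequencing data and are out of scope
for the synthetic conditions.

# Known limitations

* The binomial interval-overlap test conditions only on merged subject
  coverage; for wide query intervals the success probability is
  approximate (the tests validate it against Monte-Carlo placement for
  point-like queries).
* The rank-expectation statistic assumes the local score distribution in
  rank space is approximately Gaussian after robust standardization;
  heavily discrete, low-count data weaken this approximation, which the
  3-of-4 voting absorbs in practice.
* Motif handling is presence/absence of IUPAC consensus strings — a
  deliberate plumbing stand-in for PWM scanning with calibrated p-values.
* The temporal-origin analysis treats detection as presence: an element
  below threshold at an early stage but accessible in a small cell
  subpopulation will be assigned a later origin.

# A minimal session

```{r example, eval = FALSE}
cfg <- readRunConfig()           # reference operating defaults
res <- runPipeline(cfg, outDir = "demo_out", seed = 1)
res$classTable                   # DDE temporal classes
res$originTable                  # stage-of-origin composition
length(res$ddd)                  # dynamic domains found
```
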
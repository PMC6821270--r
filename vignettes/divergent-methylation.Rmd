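---
title: "Methylation analysis across divergent genotypes: models and choices"
author: "methdiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation analysis across divergent genotypes: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdiverge)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) quantifies methylation by counting
converted (T) versus protected (C) reads at CpG dinucleotides of a reference
genome. When the sample's genome differs from the reference at millions of
positions -- distant inbred mouse strains, rearranged cancer genomes -- two
things go wrong. First, at positions where the sample carries a CG-to-TG (or
CG-to-CA) variant, reads align without mismatch and every read looks
"unmethylated": the site is scored 0% methylated although the sample has no
CpG there at all. Averaged over a genome where ~10% of CpGs differ between
genotypes, this *quantification bias* depresses apparent global methylation
by several percentage points and floods differential analysis with false
positives. Second, even after aligning each sample to its own (pseudo)genome,
the genomes no longer share a coordinate system, and CpGs that exist in only
one genotype have no obvious place in a joint analysis: dropping them
sacrifices real signal, since genotype-unique CpGs often carry the largest
methylation differences.

`methdiverge` implements the full corrective pipeline: build personal
genomes from variant calls, lift all samples into one coordinate system,
classify every CpG by its cross-genome status, and -- the central idea --
*smooth over all CpGs of each sample's own genome*, so that data at
genotype-unique sites shapes the imputed methylation curve at the shared
sites where groups are actually compared.

## Coordinate maps and CpG classification

A personal genome is built by applying a curated variant set (SNVs and
indels, VCF conventions) to the reference. Only indels change coordinates,
so the induced map is a short list of colinear blocks per chromosome; a
position inside a deleted span (or, in the reverse direction, inside an
inserted span) is *unmappable*. In memory the unmappable result is `NA`;
files use the conventional `-1`. The map is exactly invertible on mappable
positions, a property the test suite checks on randomized genome pairs.

A CpG is identified by the position of its forward-strand C; reads from
both strands are combined into that one site. Lifting a CpG requires both
the C and the G position to map (a dinucleotide split or swallowed by an
indel is discarded). Classification of genome A's CpGs against genome B
reads the mapped dinucleotide in B:

* `COMMON_CG` -- B also has CG: the shared sites where groups are compared;
* `TG_CA` -- the deamination signature, the dominant and most insidious
  class, because reads align mismatch-free and are called unmethylated;
* `OTHER_MUT` -- any other dinucleotide (including N): reads mismatch, the
  site is simply lost;
* `UNMAPPABLE` -- the dinucleotide cannot be placed in B at all.

The four categories partition the CpG set, which makes table arithmetic
(mutation rate, per-bin and per-feature rates) well defined. The CpG
mutation rate is the non-common fraction; for the published mouse strain
pair (C57BL/6J vs CAST/EiJ) the printed counts give 10.7%
(`mutation_rate_from_counts(mouse_strain_cpg_counts())`).

## Heterozygosity

Inbred strains are effectively homozygous, but cell lines and human samples
are not. The policy implemented here: heterozygous loci keep one allele in
the personal genome (`het_policy = "reference"` by default, so the
coordinate map depends only on homozygous indels), the loci are recorded,
and every CpG overlapping a heterozygous variant is removed *per sample*
before smoothing (`filter_heterozygous()`). This keeps homozygous
sample-unique CpGs -- the informative ones -- while removing exactly the
sites where a C/T allele mix is indistinguishable from partial methylation.
The allele choice is configurable because no single choice is right for
every variant caller's conventions.

## The smoother

Each sample's observed proportions $p_i = M_i/\mathrm{Cov}_i$ are smoothed
with a kernel-weighted local quadratic regression evaluated site by site.
At site $j$ the window half-width is

$$ w_j = \max\bigl(h,\; d_{(ns)}(j)\bigr), $$

where $d_{(ns)}(j)$ is the distance from site $j$ to its $ns$-th nearest
*covered* site in the same cluster -- so the window always holds at least
$ns$ informative sites and is at least $h$ bp to each side. Weights are
coverage times the tricube kernel $(1-u^3)^3$ on $u = |x_i - x_j|/w_j$
(zero at and beyond $u = 1$). Defaults $ns = 70$, $h = 1000$ suit focal
DMR analysis; the `blocks` preset ($ns = 500$, $h = 20\,000$) targets
large-scale structure. Sites further apart than `maxGap` (default $10^8$,
i.e. chromosome-level) never share a window.

Zero-coverage sites -- unmeasured sites *and CpGs that do not exist in the
sample's genome* -- get weight zero but still receive a fitted value. This
is the imputation mechanism: a genotype carrying dense, highly methylated
unique CpGs in a region will have its smoothed curve pulled up at the
flanking shared sites, so the unique sites contribute to the group
comparison even though the comparison itself is evaluated only where both
groups have data.

Numerical choices: windows truncate at cluster (and chromosome) edges
rather than extending; on rank deficiency (fewer than three distinct
covered positions with positive weight) the polynomial degree falls back
2 → 1 → 0 rather than failing; fitted values are clamped to $[0, 1]$; a
cluster with no covered site for a sample yields missing values, recorded
but not fatal. The implementation solves the weighted normal equations on
a window-scaled design; the test suite pins it against an independent
`lm.wfit`-based solver to $10^{-8}$ and checks exactness on constant
signals to $10^{-10}$. This closed-form weighted-least-squares fit on
proportions was chosen over an iteratively reweighted binomial likelihood
because it is exactly testable against an independent oracle and the two
differ only at second order at these coverages.

## Differential analysis

At each analysable site (coverage mask: at least 3 samples per group with
coverage ≥ 2, the conventional BSmooth-style filter) the statistic is

$$ t_j = \frac{\bar{f}_{2j} - \bar{f}_{1j}}
             {\tilde{s}_j\sqrt{1/n_1 + 1/n_2}}, $$

with $\bar f_{gj}$ the group means of smoothed values and $\tilde s_j$ a
stabilised pooled standard deviation: the raw pooled sd is floored at its
75th percentile across masked sites (so near-zero local variance cannot
inflate $t$), then smoothed by a running mean over 101 masked sites. The
variance floor and window are the established conventions of this analysis
family, exposed as parameters; the running mean is taken over masked sites
because only those enter the statistic.

Candidate regions are maximal runs of masked sites with $|t|$ above the
cutoff and constant sign, split at gaps larger than `maxGap`; regions need
at least `min_cpgs` = 3 member CpGs and an absolute mean methylation
difference of at least `min_meandiff` = 0.10. Focal DMRs use cutoff 4.6
with `maxGap` 300; blocks use cutoff 2 with `maxGap` 10 000 on
block-smoothed data. Each region carries `areaStat`, the sum of its member
$t$ values.

Significance uses *balanced permutations*: in a two-genotype design, all
relabelings in which each group holds exactly half of each genotype,
de-duplicated under group swap and excluding the observed assignment. For
a 4+4 genotype-vs-genotype design there are exactly 18. Genotype effects
cancel within every permuted group, so the permuted statistics probe the
null. Each permutation re-runs the full statistic (including the sd floor
and smoothing of sds) and region segmentation; smoothing of methylation
itself is label-free and reused. A null region is *better* than an
observed one if it has at least as many CpGs **and** at least as large an
absolute `areaStat` (ties count against the observed region -- the
conservative reading). The genome-wide family-wise error rate of a region,

$$ \mathrm{gFWER}(d) \;=\; \frac{\#\{\text{permutations with a better null
region anywhere}\}}{\#\text{permutations}}, $$

is reported per region; no threshold is imposed, though the natural
stringent choice is $\mathrm{gFWER} = 0$.

## Diagnostics

*Global methylation* is the unweighted mean of per-site proportions over
read-covered sites: counting CpGs, not reads, makes it insensitive to
coverage fluctuations and a cheap first screen -- a multi-point gap between
genotype groups is the signature of quantification bias.
`category_methylation()` resolves the gap by CpG class, and
`simulate_wrong_reference()` reproduces, from correctly quantified data,
what a single-reference pipeline would have reported: at reference-unique
TG/CA sites the non-reference samples keep coverage (drawn Poisson at the
sample's mean coverage where the correct pipeline has none) but all calls
become unmethylated; at their own unique sites their data disappears.
Filtering the variant CpGs out of both matrices restores equality exactly,
which the suite asserts to $10^{-12}$ -- the "variation filtering" fallback
for studies without personal genomes.

For a candidate region, `raw_region_diff()` works on unsmoothed counts,
pooling counts within a group ($\sum M/\sum \mathrm{Cov}$; stable at
coverage 2, and exposed as the choice it is) before differencing
(group 2 − group 1). At genotype-unique sites only one group carries data;
the unique-site "difference" is taken as (mean over group-2-unique sites
within group 2) − (mean over group-1-unique sites within group 1), falling
back to the other group's shared-site mean when a side is absent. This
one-sided rule is an interpretive choice, documented and kept switchable
in spirit: the region-level conclusion only needs the contrast between
unique and shared behaviour, the *unique-shared disparity*
(unique difference − shared difference). A disparity aligned with the
region's direction marks a DMR whose evidence lives in genotype-unique
CpGs -- exactly the regions a shared-only analysis cannot see.

## The synthetic study

The generator emulates the structure of a two-strain WGBS comparison, not
its sequence content. Defaults define the package's desk-scale study and
are used by the acceptance machinery:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 2 Mb | one toy chromosome |
| `cpg_rate` | 0.01 /bp | CG start frequency, ≈ 20k CpGs |
| `cpg_mut_rate` | 0.10 | fraction of A's CpGs destroyed in B |
| `tgca_fraction` | 0.75 | destroyed CpGs showing the TG/CA signature |
| `cpg_gain_rate` | 0.10 | B-unique CpGs as a fraction of A's count |
| `snv_rate`, `indel_rate` | 0.002, 1e-4 /bp | background divergence |
| `n_per_genotype` | 4 | samples per genotype |
| `mean_coverage` | 15 | Poisson coverage |
| `baseline_meth` | 0.72 | typical somatic-tissue CpG methylation |
| `autocorr_bp` | 2000 | latent-field correlation length |
| `dmr_delta` | 0.4 | planted group-2 methylation shift |

The reference sequence suppresses CG formation and then plants CG
dinucleotides at `cpg_rate`, because a uniform random sequence would be
CpG-rich (1/16 of dinucleotides) where mammalian genomes are CpG-sparse;
the parameter is therefore the *target* CG frequency, and the generator's
recovery of it is what the tests assert. CpG mutation rates of 10% and the
75/25 split between TG/CA and other losses mirror the proportions reported
for highly divergent mouse strains. Background SNVs are placed away from
CpG context so that CpG loss and gain are governed solely by their own two
rates.

Methylation is a single logistic-transformed moving-average Gaussian field
shared by both genotypes (a full Gaussian process buys nothing at this
scale), with planted regions adding `dmr_delta` for genotype B at the
targeted site class: *shared*-target regions span 20 consecutive shared
CpGs; *unique*-target regions plant 25 B-unique CpG gains at 60 bp spacing
and put the whole effect on them, instantiating differential methylation
carried entirely by genotype-unique sites. The planted effect's sign
points away from the saturation boundary (hyper- where the local baseline
is low, hypo- where it is high), since adding +0.4 to a baseline of 0.85
would clamp to almost nothing and make "planted truth" a misnomer; truth
records the signed value. Counts are Binomial(Poisson coverage, latent
level) at every CpG of each sample's own genome, in that genome's own
coordinates -- so the lift, union, presence annotation and discard rule are
all exercised on the way in.

What the generator does *not* model: read-level effects (alignment error,
mapping ambiguity, M-bias, incomplete bisulfite conversion),
coverage-methylation coupling, and real CpG clustering (islands). Passing
tests therefore demonstrate the statistical machinery -- bias mechanism,
imputation, error control -- not robustness to alignment artifacts, which
the diagnostics can only flag (unusually high coverage, exact-0%
signatures) rather than prevent.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline on the 2 Mb
default study (~20k CpGs, 8 samples, 18 permutations), which completes in
well under a minute; property checks (smoother oracle, map round-trips,
partition invariants, segmentation oracle, gFWER monotonicity) use many
small randomized instances under fixed seeds. Every stage of the generator
is deterministic given `sim_config(seed = )`, and all CLI entry points
accept explicit seeds or parameter files, so any reported number can be
regenerated from a one-line call.

## Known limitations

* Maps derive from variant sets only; chain/net whole-genome alignments
  between independent assemblies are out of scope.
* Two groups, no covariates, no paired designs; the gFWER is the only
  error-control currency.
* The smoother is not bit-compatible with iteratively reweighted
  local-likelihood implementations; agreement is structural, not numeric.
* Balanced permutation requires an even number of samples of each genotype
  and equal group sizes; 4+4 gives only 18 permutations, so the smallest
  attainable non-zero gFWER is 1/18.
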
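---
title: "Rare CNV burden analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare CNV burden analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

## The analysis

`cnvburden` implements a segment-level rare copy-number-variant (CNV)
case–control analysis of the kind used in SNP-array studies of autism
spectrum disorder (ASD) and other neurodevelopmental conditions. The input
is a table of called CNV segments (one row per call: subject, interval,
deletion/duplication, supporting probe count) plus a sample manifest; the
output is a stratified burden comparison between cases and controls,
classification of individual rare CNVs as clinically relevant, and
per-family inheritance calls.

The stages run in this order:

1. **QC filtering.** A call survives when it is supported by at least 20
   contiguous probes, is at least 10 kb, and does not touch a blacklist
   region (centromeres, antibody variable regions, T-cell receptor loci —
   regions where array CNV calls are unreliable). All three filters are
   pure per-call predicates, so they commute and are idempotent; calls
   are removed, never trimmed.
2. **Locus clustering.** Calls of the same type on the same chromosome are
   the same *locus* when they overlap by at least 80% of their length.
   Loci are connected components of this relation (single linkage).
3. **Rarity selection.** A locus is *rare* when its carrier frequency in
   the reference group — the patients, by default — is strictly below 1%.
   A subject carrying two member calls counts once.
4. **Burden comparison.** Rare-CNV event counts are stratified by CNV type
   (deletion, duplication, both) and size (<100 kb, 100–400 kb, >400 kb,
   total), separately for the autosomes (all subjects) and the X
   chromosome (male subjects only). Each stratum is tested with a
   two-sample rate likelihood-ratio chi-square test and flagged against a
   Bonferroni-corrected threshold.
5. **Classification.** Rare CNVs are flagged pathogenic when they hit an
   ASD *hot-spot* region (any size), or when they are at least 400 kb and
   overlap a curated pathogenic reference region (ClinGen/DECIPHER style).
   Trio links in the manifest drive inheritance calls
   (maternal/paternal/de novo), and subjects with two pathogenic CNVs at
   distinct loci are reported as *two-hit* carriers.

## Coordinate and size conventions

Coordinates are 1-based inclusive (UCSC browser style) internally; BED
files (0-based half-open) are converted by `read_region_bed()` at the
reader boundary. Overlap lengths count shared integer positions, so the
length entering the reciprocal-overlap fraction is `end − start + 1`.

Size in kb is `(end − start) / 1000` rounded half away from zero. This
choice reproduces the printed "Size (kb)" column of the published CNV
tables packaged as fixtures for 72 of their 73 transcribed rows; the
tables themselves are internally inconsistent on the remaining row (the
same interval is printed with two different sizes in two tables, and one
of them conflicts with every rounding rule that fits the rest). The
inclusive-length alternative `end − start + 1` is indistinguishable at kb
rounding; the subtractive form is used for exact consistency with the
printed sizes.

## The 80% overlap rule

The phrase "overlapped by at least 80% of their length" is ambiguous
between a unilateral and a reciprocal reading. The package adopts the
**reciprocal** convention — `min(overlap/len(a), overlap/len(b)) ≥ 0.8` —
which is the standard CNV-matching rule in array studies; a unilateral
mode (`mode = "unilateral"` in `cluster_loci()`) is available for
sensitivity analysis. Clustering is single-linkage over the pairwise
relation, so a transitive chain can join two calls whose direct overlap
is below 80%; no tie-breaking rule is published, and single linkage is
the only order-free choice that needs none. Output is made deterministic
by canonically sorting calls (chromosome, start, end, type, sample)
before component labeling.

The same 0.8 threshold is reused for inheritance matching (a child call
"present in a parent" means a same-type parental call at reciprocal
overlap ≥ 0.8) and for the distinct-locus requirement of two-hit
detection. Interval matching here is a desk-scale surrogate for the
family qPCR used to validate origins in the laboratory.

## The burden test

The published analysis names a "Likelihood Ratio Chi-square test" for
comparing per-subject CNV rates but not the underlying model. The package
adopts the canonical interpretation for event counts with unequal group
sizes: group counts are Poisson with exposures equal to the subject
counts, and the statistic is

$$
G = 2\left[c_1 \log\frac{\hat\lambda_1}{\hat\lambda_0}
        + c_2 \log\frac{\hat\lambda_2}{\hat\lambda_0}\right],
\qquad
\hat\lambda_i = c_i/n_i,\quad
\hat\lambda_0 = \frac{c_1+c_2}{n_1+n_2},
$$

referred to $\chi^2_1$. It is zero exactly when the observed rates are
equal, scales linearly when counts and exposures are scaled together, and
its empirical type-I error at $\alpha = 0.05$ is checked by simulation
(2000 null cohorts at the control rate; the acceptance band is
0.03–0.07). The published chi-square values could not be re-derived
unambiguously from the printed margins under any single standard
formulation, so the package treats counts and rates — which do reproduce
exactly — as the comparable quantities, and reports its own statistic. An
exploratory contingency G-test variant (`method = "contingency"`) is
included for comparison only.

Significance uses the published corrected threshold **P < 0.005** (strict)
by default. The exact Bonferroni quotient 0.05/12 ≈ 0.00417 is available
via `apply_bonferroni(threshold = NULL)`; the stated 0.005 is kept as the
default because it is the criterion the published tables actually apply.

Size bins are assigned from the rounded kb size as [min, 100), [100, 400],
(400, ∞), so each call lands in exactly one bin and 400 kb belongs to the
middle bin, matching the "100–400 Kb" row label. The separate ≥ 400 kb
threshold of the pathogenicity screen is an independent parameter
(`classify_pathogenic(min_size_kb = 400)`); the two are not coupled.

## X chromosome handling

X-chromosome CNVs are analyzed in male subjects only (random X
inactivation makes female dosage interpretation unreliable, and the
female arms of a typical case–control design are size-skewed). Female X
calls are retained through clustering but excluded from rarity numerators
and denominators and from the male-X burden scope; control carrier
lookups on X use the male-control denominator. Y and MT calls are
excluded from burden scopes with a logged count.

## Pathogenic classification and two-hit scope

Hot-spot and pathogenic-reference matching default to any-overlap
(≥ 1 bp) because the operative published wording is simply "overlapped
with"; a minimum fraction-of-call option exists for stricter use. The
packaged hot-spot and pathogenic-reference BEDs are *synthetic fixtures*
derived from the loci named in the transcribed tables — they are not
redistributions of ClinGen or DECIPHER, and production use should supply
real exports.

Two-hit detection defaults to autosomal scope. Under the published
definition, the five two-hit patients are exactly the subjects with two
autosomal pathogenic CNVs; a patient carrying one autosomal and one
X-chromosome pathogenic CNV is not counted. The package surfaces this
choice rather than resolving it silently: `detect_two_hit(scope = "all")`
includes sex chromosomes and reports that patient too.

## The synthetic cohort generator

`simulate_cohort()` emulates the data-generating structure the burden
analysis assumes: 335 cases (299 male) versus 1093 controls (525 male) by
default, with per-subject event counts Poisson per stratum at rates
calibrated to the published tables (autosomal totals 2.71 and 0.77 events
per subject; male-X totals 0.217 and 0.011). Per-subject Poisson counts
are the simplest law consistent with rate-per-subject reporting. Within
each size bin, sizes are log-uniform (no size distribution is published);
the sampling ranges stay clear of the kb-rounding boundaries so a
planted stratum is always the realized one. Probe support is
`max(20, 1.4 × size_kb)` — the SNP 6.0 array's ~0.7 kb median probe
spacing implies ~1.4 probes/kb. Background calls are placed uniformly on
length-weighted chromosomes and are guaranteed QC-clean; optional planted
*common loci* (fixed coordinates, Bernoulli carriers) test rarity
exclusion, and optional *decoys* (low probe support, sub-10 kb, blacklist
placement) test that QC removes exactly the violating calls.
`simulate_trios()` adds genotyped parents and copies each child call into
one parent with the configured transmission probability, recording the
planted origin.

What the generator does **not** emulate: probe-level intensities and
segmentation noise (boundary jitter between a transmitted call and its
parental copy), locus-specific mutation hot spots, sex-specific rate
differences within a group, batch effects, and overdispersion of
per-subject counts. Passing recovery tests on these cohorts therefore
shows the pipeline's arithmetic and selection logic are correct under the
stated model, not that the model captures every property of real array
data.

`make_paper_fixture_cohort()` is the deterministic counterpart: a cohort
whose per-stratum rare-call counts equal the published margins exactly,
built by placing bin-representative calls (50/250/500 kb) at
non-overlapping private positions round-robin over subjects and
chromosomes. Running the pipeline on it reproduces the published rate
columns after display rounding; it is exact arithmetic, not estimation.

## Numerical and degenerate-input choices

* Empty call tables flow through every stage and give zero-count burden
  tables with statistic 0, p-value 1 and nothing significant.
* A cohort with a zero denominator (no controls, or no male cases for an
  X locus) raises a "degenerate cohort" error rather than returning NaN.
* `rate_lr_test` defines `0 · log 0 = 0`; the statistic is clamped at 0
  against floating-point cancellation.
* Validation errors name the offending rows (missing `n_probes`,
  inverted coordinates, dangling trio links, copy-state/type conflicts).
* Regions on unrecognized chromosomes are skipped with a warning.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to finish in minutes on one CPU
while keeping Monte-Carlo bands meaningful: clustering is verified against
a brute-force O(n²) oracle on 200-call sets over 20 seeds; the rate test
against a numeric likelihood-maximization oracle on 100 random
configurations and a 2000-replicate null simulation; cohort-rate recovery
over 50 full-size simulated cohorts (3 Monte-Carlo standard errors); trio
recovery on ~200-family simulations with exact checks at transmission
probabilities 0 and 1.

## Known limitations

* The likelihood-ratio statistic is the package's canonical Poisson-rate
  formulation; published chi-square values from other software will
  differ even when counts and rates agree.
* Carrier-based rarity uses presence/absence; integer copy-number
  genotype frequencies are out of scope.
* No liftover: the genome build of inputs is declared and trusted.
* Gene annotations depend entirely on the supplied gene region set;
  published gene counts are annotation-release-dependent and are not
  reproduced.
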
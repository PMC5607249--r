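# cnvburden

Rare copy-number-variant (CNV) burden analysis for case–control cohorts.

SNP-array studies of autism spectrum disorder (ASD) and related conditions
routinely ask whether patients carry an excess of *rare* CNVs — deletions
and duplications whose carrier frequency in the patient group is below 1% —
and which individual rare CNVs are clinically relevant. `cnvburden` is a
tested, reusable R implementation of that analysis for people who have
segment-level CNV calls (from any caller) and a sample manifest:
geneticists running their own case–control array cohorts, and method
developers who need a transparent reference pipeline with a calibrated
simulator.

The pipeline, in study order:

1. **QC filtering** — keep calls with ≥ 20 supporting probes and ≥ 10 kb;
   drop calls touching blacklist regions (centromeres, antibody variable
   regions, T-cell receptor loci).
2. **Locus clustering** — calls of the same type are the same locus when
   they overlap reciprocally by ≥ 80% of their length
   (`min(ov/len(a), ov/len(b)) ≥ 0.8`); loci are single-linkage connected
   components.
3. **Rarity selection** — keep loci with carrier frequency strictly < 1%
   in the patients (X-chromosome loci assessed in males only).
4. **Burden comparison** — per CNV type × size bin
   (<100 kb, 100–400 kb, >400 kb, total) and scope (autosomal: all
   subjects; X: males only), compare per-subject event rates with a
   two-sample Poisson-rate likelihood-ratio chi-square test
   `G = 2[c₁ log(λ̂₁/λ̂₀) + c₂ log(λ̂₂/λ̂₀)]`, `λ̂ᵢ = cᵢ/nᵢ`,
   `λ̂₀ = (c₁+c₂)/(n₁+n₂)`, df = 1, with Bonferroni-corrected
   significance (P < 0.005 for a family of 12 tests).
5. **Classification** — a rare CNV is pathogenic when it hits an ASD
   hot-spot region (any size) or is ≥ 400 kb and overlaps a curated
   pathogenic reference region; trio links drive
   maternal/paternal/de-novo inheritance calls (matched at ≥ 80%
   reciprocal overlap), and subjects with two pathogenic CNVs at distinct
   loci are reported as two-hit carriers.

A synthetic-cohort generator (`simulate_cohort()`, `simulate_trios()`)
reproduces the statistical structure the analysis assumes — Poisson
per-subject event counts at published case/control rates, planted common
loci, planted QC decoys, trio transmission — so every stage is testable
without raw array data. See the vignette
(`vignettes/rare-cnv-burden.Rmd`) for the model, conventions and design
choices.

## Worked example

The deterministic cohort from `make_paper_fixture_cohort()` — 335 cases
(299 male) vs 1093 controls (525 male), with rare-call counts per stratum
equal to a published ASD cohort's burden-table margins — run through the
full pipeline:

```r
library(cnvburden)
fx  <- make_paper_fixture_cohort()
res <- run_pipeline(fx$calls, fx$manifest,
                    hotspots   = fixture_hotspot_regions(),
                    pathogenic = fixture_pathogenic_regions())
format_burden_table(res$burden_autosomal)
```

```
    cnv_type   size_bin case_count control_count case_rate control_rate lr_chisq  p_value significant
    deletion    lt100kb        333           394      0.99         0.36   173.59  1.2e-39        TRUE
    deletion 100to400kb         88            43      0.26         0.04   112.35  3.0e-26        TRUE
    deletion    gt400kb         18            14      0.05         0.01    15.82  7.0e-05        TRUE
    deletion      total        439           451      1.31         0.41   280.52  5.8e-63        TRUE
 duplication    lt100kb        263           229      0.79         0.21   205.39  1.4e-46        TRUE
 duplication 100to400kb        150           144      0.45         0.13   104.52  1.6e-24        TRUE
 duplication    gt400kb         55            19      0.16         0.02    85.34  2.5e-20        TRUE
 duplication      total        468           392      1.40         0.36   381.22  6.8e-85        TRUE
        both    lt100kb        596           623      1.78         0.57   372.10  6.5e-83        TRUE
        both 100to400kb        238           187      0.71         0.17   207.10  5.9e-47        TRUE
        both    gt400kb         73            33      0.22         0.03    97.86  4.5e-23        TRUE
        both      total        907           843      2.71         0.77   657.19 6.1e-145        TRUE
```

Cases carry 2.71 rare autosomal CNVs per subject against 0.77 in controls,
and the excess holds in every type × size stratum at the corrected
threshold. The male-X table (`res$burden_x_male`) shows the same pattern at
rates 0.217 vs 0.011. The chi-square column is this package's Poisson-rate
statistic; counts and rates are the quantities comparable across software.

Classifying the packaged CNV fixtures (transcribed from the same study's
result tables):

```r
t3 <- annotate_hot_spots(fixture_hotspot_cnvs(), fixture_hotspot_regions())
length(unique(t3$sample_id[lengths(t3$hot_spot_hits) > 0]))
#> [1] 14        # patients with hot-spot CNVs

t4 <- classify_pathogenic(fixture_pathogenic_cnvs(), fixture_pathogenic_regions())
sum(t4$pathogenic)
#> [1] 49        # rare >= 400 kb pathogenic CNVs

unique(detect_two_hit(t4, scope = "autosomal")$sample_id)
#> [1] "U-1255" "U-1414" "U-1753" "U-1999" "U-2075"   # the five two-hit patients

round(100 * carrier_frequency(5, 1093), 2)
#> [1] 0.46      # % of controls carrying the 18p11.31-p11.23 duplication
```

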
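# lipidmrm

Design and evaluation toolkit for high-throughput **scheduled multiple
reaction monitoring (MRM) lipidomics** on triple-quadrupole instruments.

Targeted lipidomics panels monitor a Q1/Q3 transition per lipid species —
or per sn-position isomer — and quickly outgrow the instrument duty cycle:
a thousand-transition panel in a 24-minute gradient is only feasible if
each transition is monitored in a retention-time window around its elution
and the per-cycle scan time is allocated deliberately. `lipidmrm` is for
assay developers and computational mass spectrometrists who want that
design loop as code: build the transition list from first-principles ion
chemistry, schedule it under an explicit cycle-time budget, quantify what
the schedule buys via simulation, and run the downstream validation and
two-group screening statistics.

## What it computes

**Transition chemistry.** Neutral formulas for 17 lipid classes
(glycerol + *n* acyls − *n* H2O for glycerolipids, headgroup +
glycerophosphate backbone for phospholipids, fixed d18:1 sphingoid
backbone for SM/Cer), monoisotopic masses, class adducts
([M+H]+, [M+NH4]+, [M−H]−, [M+CH3COO]−), and product ions: headgroup
fragments (phosphocholine 184.073, sphingoid 264.269, cholestadienyl
369.352), fatty-acyl neutral losses (RCOOH + NH3 from ammoniated
glycerolipids — the rule that resolves TAG sn-isomers), and fatty-acid
carboxylate anions for phospholipids.

**Scheduling.** Variable window half-widths
`clamp(max(h_min, 3·rt_sd + base_halfwidth), h_max)` and relative dwell
weights `clamp(sqrt(median_abundance / abundance), 1, 10)`, allocated each
cycle by deterministic water-filling under a budget of 0.5 s target scan
time with 5 ms settling + 5.007 ms pause per transition and a 1 ms dwell
floor. Points-per-peak predictions use the realized acquisition clock and
agree with simulation within ±1 sample.

**Simulation.** Plasma-like synthetic runs (class-clustered retention,
Gaussian peaks of 0.05–0.3 min base width, abundances spanning five
decades, retention jitter, Poisson shot noise with counts-per-second
normalization so dwell buys signal-to-noise, not bias), XIC-style peak
integration, and the ≥10 points / <30% CV detectability filter — enough to
reproduce the unscheduled vs fixed-window vs variable-window comparison as
a testable property.

**Validation statistics.** LoB/LoD/LoQ (mean blank + 1.645/3/10 SD),
dilution-series detection limits and linearity (R² over the range from the
LoQ concentration up), spike recovery, and class-sum-normalized CVs.

**Differential screening.** Missingness filtering (≥10 samples) and median
imputation, class-sum normalization, in-package empirical-Bayes
(ComBat-style) batch adjustment preserving group and sex, two-sided
Wilcoxon + 1.3× fold-change screening, Benjamini–Hochberg adjustment, and
shadow-feature random-forest (Boruta-style) selection — plus a seeded
synthetic cohort generator (47 vs 46 samples, 759 species, planted fold
changes, batch and sex effects) for end-to-end verification.

## Worked example

```r
library(lipidmrm)
library(dplyr)

lib <- assemble_library()
library_summary(lib)$totals
#>   n_species_entries n_standards n_transitions
#> 1              1218          12          1230

filter(lib, species == "TAG 52:6") |> select(transition_id, q1, q3)
#>   transition_id      q1    q3
#> 1 TAG 52:6/FA14:0  869.  624.
#> 2 TAG 52:6/FA16:0  869.  595.
#> ...                              (9 isomer transitions, one shared Q1)
```

The default panel carries 1218 species entries (TAG at sn-isomer
granularity: 445 isomer transitions from 96 TAG species) plus the 12
deuterated class standards — 611 positive-mode and 619 negative-mode
transitions. Precursors come straight from the chemistry layer:
`precursor_mz("TAG", 52, 6)` gives 868.74 ([M+NH4]+), and losing palmitic
acid plus NH3 gives the isomer product
`neutral_loss_product_mz(868.74, 16, 0)` = 595.47.

Simulating five technical replicates of a plasma-like run under each
acquisition mode:

```r
cmp <- compare_modes(lib, seed = 1, replicates = 5)
glance(cmp)
#>   mode     n_detected median_cv_pct
#> 1 mrm               0         NA
#> 2 smrm            152          4.12
#> 3 variable        448          4.64
```

Variable windows with dwell weighting detect ~3× more transitions than
fixed 1-minute windows under the same cycle budget, and unscheduled MRM
collapses entirely (1230 concurrent transitions force a ≈13.5 s cycle, so
no peak reaches 10 points). `autoplot(cmp)` and `plot_area_scatter(cmp)`
visualise the comparison.

End-to-end screening on a synthetic cohort:

```r
coh <- generate_cohort(cohort_design(), seed = 1)   # 47 vs 46, 759 species, 18 planted
res <- run_differential_pipeline(coh, seed = 1)
glance(res)
#>   n_species n_candidates n_confirmed n_rejected
#> 1       759           20          17          1

arrange(tidy(res), p_value) |> head(3)
#>   species fold_change  p_value candidate  q_value decision
#> 1 PC_033        2.47  2.14e-14 TRUE      1.47e-11 confirmed
#> 2 PC_048        2.37  3.88e-14 TRUE      1.47e-11 confirmed
#> 3 TAG_073       2.35  1.49e-13 TRUE      3.76e-11 confirmed
```

All 17 confirmed species here are planted effects (17 of the 18 planted
are recovered; the 18th missed the fold-change gate in this draw).

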
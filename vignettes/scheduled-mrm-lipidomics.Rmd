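---
title: "Designing and evaluating scheduled-MRM lipidomics assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating scheduled-MRM lipidomics assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(lipidmrm)
library(dplyr)
```

Targeted lipidomics on a triple-quadrupole instrument monitors a fixed list
of precursor/product ion pairs (Q1/Q3 "transitions"), one pair per lipid
species or per structural isomer. A large panel — on the order of a
thousand transitions in a 24-minute gradient — only fits into the
instrument's duty cycle if each transition is monitored in a retention-time
window around its expected elution, and the scan time within each cycle is
divided deliberately. This package implements that whole design loop:

1. **Transition chemistry** — molecular formulas and monoisotopic m/z for
   17 lipid classes, their class-specific adducts and product ions.
2. **Library assembly** — a configurable panel builder, including
   sn-position isomer transitions for triacylglycerols.
3. **Scheduling** — variable retention-time windows and relative dwell-time
   weights under a fixed cycle-time budget.
4. **Acquisition simulation** — synthetic plasma-like runs with Poisson
   shot noise, used to compare unscheduled, fixed-window and
   variable-window acquisition as measurable properties.
5. **Method validation** — limits of blank/detection/quantitation,
   linearity, spike recovery, coefficients of variation.
6. **Differential screening** — class-sum normalization, empirical-Bayes
   batch adjustment, Wilcoxon + fold-change screening with BH correction,
   and shadow-feature random-forest selection, with a synthetic cohort
   generator for end-to-end testing.

# Ion chemistry

Formulas are assembled from class backbones plus the stated acyl
composition: glycerolipids are glycerol plus *n* acyls minus *n* H2O;
diacyl phospholipids add their headgroup to the glycerophosphate backbone;
lyso-species carry a single acyl (equivalently the diacyl formula minus an
acyl ketene); sphingomyelins and ceramides use a fixed d18:1 sphingoid
backbone (the panel never varies it); cholesteryl esters esterify
cholesterol with one chain. Monoisotopic element masses are shipped as a
data file; charged-species arithmetic uses the proton mass (1.00728 Da)
and neglects the electron mass, an error below 0.0006 Da — far below the
unit-resolution reporting of a triple quadrupole.

Class rules fix the adduct and polarity: SM and Cer are measured as [M+H]+,
the neutral lipids (CE, MAG, DAG, TAG) as ammonium adducts [M+NH4]+, and
phospholipids as [M−H]− except phosphatidylcholines, which are measured as
acetate adducts [M+CH3COO]−. Product ions follow the class: the
phosphocholine fragment (184.073) for SM, the sphingoid fragment (264.269)
for Cer, the cholestadienyl cation (369.352) for CE, fatty-acyl neutral
loss (RCOOH + NH3) for ammoniated glycerolipids, and fatty-acid carboxylate
anions for phospholipids.

```{r chemistry}
precursor_mz("TAG", 52, 6) # [M+NH4]+
neutral_loss_product_mz(precursor_mz("TAG", 52, 6), 16, 0) # lose 16:0 + NH3
precursor_mz("PC", 38, 4) # acetate adduct
```

The neutral-loss design is what resolves sn-position isomers: every isomer
of TAG 52:6 shares the same precursor, but each lost chain gives a distinct
product mass. Two caveats are inherited from nominal-mass MRM and are *not*
modelled here: isotopologue (M+2) overlap between species two double bonds
apart, and double-bond positional isomers (an omega-3 and an omega-6 chain
of the same length and unsaturation are indistinguishable).

# The default panel

The shipped configuration enumerates 1218 species over the 17 classes plus
the 12 deuterated class standards (the Splash mix plus ceramide d18:1/17:0)
— 1230 transitions, 611 positive and 619 negative. Species lists of real
assays are instrument- and matrix-specific, so the default panel is
explicit configuration, not a claim about plasma: each class has a
(carbons × double bonds) grid and a species count, enumerated in a fixed
order. Chains are bounded at 14–22 carbons and 0–6 double bonds. TAG
species are expanded into isomer transitions against a nine-chain
fatty-acyl pool (14:0, 16:0, 18:1, 18:2, 18:3, 20:3, 20:4, 20:5, 22:5 —
the abundant saturated, mono- and polyunsaturated plasma chains), giving
445 isomer transitions from 96 TAG species, nine of them for TAG 52:6.
A feasibility rule guards every expansion: the remaining carbons and double
bonds after a loss must be attainable by the remaining chains.

```{r library}
lib <- assemble_library()
library_summary(lib)$totals
filter(lib, species == "TAG 52:6") |> select(transition_id, q1, q3)
```

Expected retention times are class anchors (the class standard's retention
time on the amide-HILIC gradient) plus a small linear offset in carbons and
double bonds, clipped to the class elution band; the bands for PC
(9.09–11.59 min) and SM (11.74–12.38 min) are known, the others default to
anchor ± 0.75 min. The offsets are configuration in
`default_class_rules()`; only class-level clustering matters for the
scheduling questions studied here. Assembly enforces uniqueness of
(Q1, Q3, polarity) at 4-decimal resolution and reports colliding species.

# Scheduling under a cycle budget

The instrument budget is a target scan time of 0.5 s per cycle with 5 ms
settling and 5.007 ms inter-scan pause charged once per transition per
cycle, and a 1 ms minimum dwell. For `n` concurrent transitions the cycle
therefore carries `n × 10.007 ms` of overhead; what remains is divided as
dwell time.

Two per-transition policies turn pilot peak statistics into a schedule:

* **Windows**: half-width `clamp(max(0.15, 3·rt_sd + base_halfwidth), 1.0)`
  minutes — wider for peaks with more run-to-run retention drift or broader
  bases, floored and capped. The vendor tooling that inspired this policy
  does not publish its formulas; all constants here are explicit arguments.
* **Dwell weights**: `clamp(sqrt(median_abundance / abundance), 1, 10)`,
  rounded to two decimals, weight 1 when abundance is unknown. The square
  root spreads benefit across the low-abundance stratum instead of
  spending the whole budget on the single faintest peak.

`allocate_dwell()` divides the available time proportionally to weights
with a minimum-dwell floor (excess redistributed proportionally — a
deterministic water-filling). If overheads alone exceed the target the
cycle runs over budget at minimum dwell and is flagged. Conservation
(dwell + overhead = cycle) holds exactly by construction and is asserted
over randomized cycle compositions in the tests.

`predict_points_per_peak()` answers the planning question "will this peak
be sampled often enough?": it dry-runs the acquisition clock (no signals
involved), then divides each peak's base width by the harmonic-mean actual
cycle time across its span. That estimate provably agrees with the realized
sample count within ±1 for any span, which the tests verify against the
simulator.

# The acquisition simulator

`generate_ground_truth_run()` draws, per transition: a true area log-uniform
over five decades (10^2–10^7 counts·s), a Gaussian peak sigma of
0.0125–0.075 min (base width 0.05–0.3 min, defining base = 4σ), and a
run-to-run retention jitter SD of 0.005–0.04 min — comfortably inside the
<5% retention-time CV a stable HILIC gradient achieves, since only an upper
bound is reported for the platform this emulates. A constant chemical
baseline (2 counts/s) is added. Replicates share the per-transition
properties and differ in jitter and shot noise; every random draw takes an
explicit seed.

Acquisition advances cycle by cycle: active transitions are sampled once
per cycle, expected counts are `(intensity + baseline) × dwell`, observed
counts are Poisson, and reported signals are normalized to counts per
second. The normalization is the crux of the design: areas are unbiased
with respect to dwell, so extra dwell time buys signal-to-noise
(CV ∝ 1/√dwell) rather than a bias — which is exactly the property that
makes relative dwell weighting worthwhile, and is asserted in the tests
(doubling one transition's dwell share improves its replicate CV by ≈ √2).

`integrate_peaks()` mirrors simple XIC integration: baseline = median of
the lowest quartile of samples, peak region = the contiguous block above
baseline + 3·noise around the maximum, area = trapezoidal integral of the
baseline-subtracted signal. Points per peak are counted across the expected
peak base, the quantity the "≥10 points" detectability rule refers to. The
estimator assumes the window is wide enough that the lowest-quartile
samples are genuinely off-peak; with windows at least 2.5× the base
half-width (and ≥10 points), noiseless areas recover truth within 1%. At
the policy floor (window = peak base exactly) the quartile sits on the
peak's own tails and areas bias low by tens of percent — a real property of
quartile baselines on tight windows, worth knowing when choosing window
floors. The detectability filter then requires presence in every technical
replicate, ≥10 points per peak everywhere, and an area CV below 30%.

`compare_modes()` runs the whole loop for the three acquisition modes on a
common ground truth. On the default fixture the detected counts order
variable-window ≥ fixed-window ≥ unscheduled, with unscheduled acquisition
collapsing almost entirely: 1230 concurrent transitions imply a ≈13.5 s
cycle against peak bases of 3–18 s. The real-plasma detection counts of the
platform this emulates are not recoverable from synthetic data; the
ordering, the noiseless recovery and the points-per-peak agreement are the
testable properties that stand in for them.

```{r compare, eval = FALSE}
cmp <- compare_modes(lib, seed = 1, replicates = 5)
glance(cmp)
autoplot(cmp)
plot_area_scatter(cmp) # variable vs fixed-window areas, log-log
```

Simplifications worth noting: peaks are pure Gaussians (no tailing), there
is no ion suppression or matrix effect, polarity switching shares the clock
at no extra cost, and detector saturation is not modelled. Passing the
simulation properties therefore validates the scheduling arithmetic and the
noise model, not chromatography.

# Method validation

The blank-based limits use the standard formulas on raw analytical signal:
LoB = mean + 1.645·SD, LoD = mean + 3·SD, LoQ = mean + 10·SD, with sample
(n−1) standard deviations throughout. Against a serial dilution, the LoD
(LoQ) concentration is the lowest calibrator whose replicate-mean signal
strictly exceeds the corresponding threshold; if none does, the analyte is
reported as not detected rather than extrapolated. Linearity is the R² of
an ordinary least-squares fit of signal against concentration over the
linear range from the LoQ concentration to the top calibrator — on raw
signal, not logs (log-log axes are presentation); replicate means are
fitted by default, all points optionally. Spike recovery is the ratio of
mean areas spiked before versus after extraction (×100), with spread
reported as the percent RSD of per-replicate ratios. Per-species CVs are
computed after class-sum normalization (each species' area divided by its
class total within the replicate), which makes them invariant to
per-replicate global scaling of a class — the property that motivates the
normalization.

# Differential screening

The pipeline mirrors a two-group case/control lipidomics analysis:

1. **Filter and impute**: species missing in ≥10 samples are dropped;
   remaining gaps are imputed with the species median across all samples
   (pooled across groups; a per-group variant is a documented alternative,
   but pooled is the plainer reading and avoids biasing the group contrast
   with the imputation itself).
2. **Class-sum normalization**, as above.
3. **Batch adjustment**: a parametric empirical-Bayes location/scale
   adjustment per species, applied to log-normalized values — standardize
   under a model preserving the group (and sex) effects, estimate per-batch
   per-species means and variances, shrink them across species (normal
   prior on locations, inverse-gamma on scales, moment-matched), remove
   them, and back-transform. The implementation is self-contained and is
   cross-checked in the tests against the reference ComBat implementation
   to ~1e-6. Confounded batch/group designs are rejected.
4. **Wilcoxon + fold-change screen**: fold change is the ratio of group
   means of adjusted normalized values (deficient over normal; a median
   variant is exposed — the mean is the default because planted-effect
   recovery is assessed on mean ratios); the two-sided rank-sum test uses
   the exact null for combined n ≤ 20 without ties and the tie-corrected
   normal approximation otherwise. Candidates need fold change beyond
   1.3× in either direction *and* p < 0.05; the fold-change gate is what
   keeps chance correlations out of the selection stage.
5. **BH adjustment** of the screen p-values (step-up, reported as
   q-values).
6. **Shadow-feature selection** on the candidates: each iteration appends a
   column-permuted copy of every feature, fits a 100-tree random forest,
   and scores a hit for every real feature whose impurity importance beats
   the best shadow. Features are confirmed or rejected by a two-sided
   binomial test of their hit count against chance, Bonferroni-adjusted
   across features (as the reference implementation does) at α = 0.01;
   survivors after 100 iterations stay tentative. Fixed seeds make the
   whole stage deterministic.

The synthetic cohort generator plays the role of the study population: 47
deficient vs 46 normal samples, 759 species in the default library's class
proportions, log-normal areas with sdlog 0.4, three round-robin batches
with location/scale effects, a sex covariate with a small effect on 10% of
species (so the preserved-covariate machinery has something to preserve),
0.5% missingness, and 18 planted fold changes of 1.5–2.5× (two thirds up,
mirroring the preponderance of upregulated TAGs in the motivating
application), placed in the large classes so that class-sum normalization
is barely perturbed by the planted species themselves. On ten seeds the
full pipeline recovers ≥80% of planted species (observed ≈97%) with at
most two false confirmations per seed, and null cohorts pass the p < 0.05
gate at 5% ± 2%. At much smaller cohort sizes two caveats appear that the
tests document: chance-correlated species can survive selection, and
planting large effects in small classes induces real (not false)
opposite-direction effects in their class-mates through the normalization.

# Problem sizes and numerical choices

The test suite exercises the full 1230-transition library for accounting
and simulation properties (five technical replicates × three seeds for the
mode comparison) and the full 93 × 759 cohort for ten seeds in the
end-to-end recovery check; unit tests use smaller fixtures chosen for the
property under test. Tolerances follow the printed precision of reference
values (±0.1 m/z at unit resolution, ±0.005 where three decimals are
printed), exact identities are asserted to 1e-9 or tighter, and EB
iterations converge at a relative tolerance of 1e-6. Ties in dwell
redistribution are resolved proportionally to weights, deterministically;
no stage consults global RNG state except under an explicit seed.
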
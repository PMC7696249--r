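---
title: "Methods: cross-species drug-screen analysis with crosskill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species drug-screen analysis with crosskill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosskill)
```

crosskill analyses high-throughput viability screens run on cell-line
panels from two species, and the downstream validation experiments that
follow a screen: dose-response, drug-combination synergy, xenograft
growth curves, and survival stratification by marker expression. This
vignette is the package's own account of the models it fits, the
defaults it chooses where the underlying study protocols leave choices
open, and what its synthetic-data tests do and do not demonstrate.

## The screen model and percent-killing normalization

The screening readout is luminescent ATP quantitation (CellTiter-Glo
style): one luminescence value per well, proportional to viable cell
mass, after ~72 h of compound exposure at a single dose (1 µM in the
emulated screens). Plates carry vehicle (DMSO) control wells in fixed
outer columns. The response variable throughout is **percent killing**,

$$\kappa = 100\,\Big(1 - \frac{S_\text{treated}}{S_\text{control}}\Big),$$

with the control center taken as the **median** of the plate's vehicle
wells (robust to an occasional dead control well; the mean is available
by flag). Two points deserve emphasis:

* Normalization is strictly per plate. Plate-to-plate level differences
  (dispense volume, reader gain, cell number drift) cancel exactly;
  scaling a plate's luminescence by any positive factor leaves its
  killing values unchanged, and the tests assert this invariance.
* Killing is **not clipped** to [0, 100] by default. Values below 0
  (growth stimulation) and above 100 (signal below blank level) are
  retained as signal; a clipping flag exists for display. Downstream
  thresholds operate on the raw values.
* Normalization is against concurrent DMSO controls only, not against a
  day-0 baseline; killing here conflates cytostatic and cytotoxic
  effects, as single-endpoint ATP screens do.

Replicates (triplicate wells in the emulated layout) are averaged;
entries whose replicate luminescence coefficient of variation exceeds
20% are flagged `high_cv`, single-well entries `n=1`. Flags mark, never
drop: downstream stages decide (clustering mean-imputes flagged/missing
entries per compound and reports the count).

## Hit calling, Analysis of Means, and the target roll-up

A (line, compound) pair is a **hit** when killing meets the threshold
θ = 50. Two comparator conventions coexist in screening practice —
"at least 50%" for per-line hit fractions and "more than 50%" for the
target filter — so both are exposed: `call_hits()` defaults to `>=`,
`rollup()` to `>`. The boundary case is decided by the operator, and the
monotonicity property (raising θ never adds hits) is tested.

**Analysis of Means** selects top compounds: with k compound groups,
group i of size $n_i$, N observations total, pooled within-group
standard deviation $s_p$ (df = N − k), the decision limits are

$$\bar{\bar y} \pm t_{1-\alpha/(2k),\,N-k}\; s_p
  \sqrt{\frac{N-n_i}{N\,n_i}},$$

reducing to $s_p\sqrt{(k-1)/(kn)}$ with df = k(n − 1) when balanced.
The exact ANOM critical value is a multivariate-t quantile (Nelson's
tables); the Bonferroni-t quantile used here is a conservative,
reproducible approximation — family-wise flag rate at the null stays at
or below α, which the tests verify by simulation (2000 null data sets),
and decisions are checked case-by-case against an independently coded
oracle over a grid of designs. Unbalanced designs use the per-group
$n_i$ form above with a warning, a documented departure from classical
ANOM. α defaults to 0.05; the screening analysis that inspired this
stage names the procedure but not its settings, so the default is a
declared assumption, not an inference.

The **target roll-up** is the screen's headline selector: a drug counts
toward each of its annotated targets (multi-target drugs count fully
toward every target; no fractional weighting) when it kills > θ in
*all* required cell lines, and a target passes when at least m = 3 of
its drugs qualify. "All lines" is the default because the motivating
analysis required hits in both screened lines; `any` and named-line
variants are exposed. No enrichment p-value is attached — the filter is
a count rule, not a test — and lowering θ or m can only grow the
passing set (tested monotonicity).

## Species structure

Cell lines are clustered on their raw killing profiles with euclidean
distance and average linkage (both knobs exposed and recorded; the
source analyses name neither). **Species purity** is scored on the
k = 2 dendrogram cut: the best assignment of the two clades to the two
species labels, so 1.0 means the cut separates species exactly.
Euclidean clustering is invariant to compound order and to adding a
constant to all entries; degenerate all-tied inputs are flagged rather
than broken silently.

**Concordance** between species is the Pearson correlation of
per-compound killing, using species-mean profiles when a species
contributes several lines, with the usual t-approximation p-value
($t = r\sqrt{(n-2)/(1-r^2)}$, n − 2 df). Both r and R² are reported
because R² discards the sign.

## The synthetic screens

All inputs can be simulated with planted ground truth; the generator is
first-class, tested code, and its defaults *are* the emulated study
conditions: 384-well plates (16 × 24) with two outer control columns
(32 vehicle wells, 352 treated wells per plate), triplicate wells per
compound, per-plate control level drawn log-normally around 10⁶ RLU
(the raw scale is arbitrary and documented as such; nothing downstream
depends on it), well noise expressed in percentage points of killing
(default sd 8 pp), and additive truth
$\kappa_{lj} = \mu_j + a_{s(l)j} + b_{lj}$ (shared compound effect +
species offset + line offset). A 2100-compound two-line screen at
triplicate occupies ⌈2100·3/352⌉ = 18 plates per line. Negative
post-noise luminescence is clipped at zero and counted. Edge-effect
attenuation exists as an off-by-default toggle; no spatial correction
(B-score/loess) is implemented, deliberately.

Planting conventions:

* **Drivers** (`driver_spec`): each sensitive driver drug kills > 50 in
  every line (base 65–90 with ±4 line jitter); non-sensitive driver
  drugs stay below 50 everywhere.
* **Background compounds** never exceed 50 in *all* lines — their
  across-line minimum is capped at 45 pp. The 5-point margin keeps
  noise-induced false multi-line hits rare, so that with triplicate
  wells at 8 pp noise the roll-up recovers exactly the planted drivers
  with at most ~one false target on average (tested over 200 seeds).
  Single-line sensitivity is allowed and used to emulate realistic
  per-line hit fractions: `line_hit_counts` forces the exact number of
  compounds with true killing > 50 per line (the emulated screen's
  ~11.9% and ~8.7%), choosing forced hits disjointly across lines.
* **Pan-line near-complete killers** (`super_killers`) plant compounds
  at > 95% killing in every line, mirroring the strongest proteasome
  inhibitors a real screen surfaces; `summarize_screen()` flags them
  via the cross-line mean > 95 bar.
* **Planted concordance**: `screen_truth_concordant(target_r2 = …)`
  sizes the shared-effect variance so the *expected R²* between
  species-mean killing vectors equals the knob. Note the algebra: if
  the shared effect contributes fraction f of the per-species total
  variance, the expected correlation is r = f, so R² = f²; the helper
  therefore sets f = √(target R²), after accounting for
  replicate-averaged well noise and per-line offsets. (A specification
  that plants "variance fraction 0.54" and expects R² = 0.54 conflates
  r with r²; this package plants the R² itself.)

What the synthetic screens deliberately do **not** model: spatial plate
artifacts (unless toggled), compound carry-over, batch effects between
screens, heavy-tailed or signal-dependent noise, polypharmacology
beyond the annotation, and any pharmacology linking the 1 µM screen to
the dose-response stage. Passing tests therefore demonstrate that the
pipeline's inference is correct *under its stated model*, not that the
model captures every artifact of a physical screen.

## Dose response, synergy, growth

`fit_4pl()` fits $v = b + (t - b)/(1 + (c/e)^h)$ by least squares
(Levenberg–Marquardt) with the Hill slope constrained positive via a
log parameterization, multi-start initialization (5 IC50 starts on a
geometric grid over the tested range × Hill starts 0.5/1/2; best RSS
wins). Non-convergence returns best-effort parameters with
`converged = FALSE`, never silently; flat responses (top ≈ bottom)
force `ic50_in_range = FALSE`. The reported `ic50` is the model
inflection (relative EC50); the absolute 50%-viability crossing
`ic50_abs` is reported alongside when the curve brackets 50. The
default dilution design is the screening protocol's 4-fold series from
20 µM (8 points). Noiseless round trips recover all four parameters to
relative error < 10⁻⁶; at 5% response noise the median |log₄ IC50
ratio| stays ≤ 0.25 (tested, 200 seeds).

**Synergy** uses Bliss independence — expected combined inhibition
$E_a + E_b - E_aE_b$ from the checkerboard's zero-dose margins, excess
= observed − expected, summarized as the interior-cell mean. Bliss was
chosen because it needs only the data a single checkerboard provides;
Loewe/Chou–Talalay combination indices are out of scope. Additive grids
give zero excess exactly without noise and a mean excess within ±0.02
at noise sd 0.05 (100 seeds); a planted excess of 0.10 is recovered
within ±0.03.

**Doubling time** is ln 2 divided by the slope of ln(abundance) on
time; constant cultures yield Inf, shrinking cultures a negative value
flagged `declining`.

## In-vivo growth statistics

Caliper pairs convert to volume by the xenograft ellipsoid rule
$(L \times W^2)/2$ with W the smaller reading (auto-swapped and
counted). Study bookkeeping mirrors the standard protocol: each mouse's
study day 0 is the first measurement at ≥ 100 mm³ (mice never reaching
it are excluded and listed), and rows after day 18 or after the first
crossing of 1500 mm³ are excluded into a ledger; the rules are
idempotent. The group comparison is a fixed-effects group × day two-way
ANOVA with day categorical, computed from nested-model residual sums of
squares — Type II under imbalance (noted in the output), coinciding
with the classical decomposition
$SS_\text{tot} = SS_g + SS_d + SS_{g\times d} + SS_\text{res}$ on
balanced data (identity tested to 10⁻⁹). Repeated measures within mouse
are *not* modeled — that is the stated analysis being reproduced, and
the printout carries the caveat; with five mice per arm the group test
is calibrated under the generator's additive-noise null (type-I error
0.05 ± 0.01 at 2000 simulations, tested) but real within-mouse
correlation would inflate it. Full-curve ANOVA is the default; an
endpoint-only contrast can be had by subsetting to the final shared
day. When endpoint rules truncate arms at different days,
`days = "shared"` restricts to days observed in every group.

## Survival cutoff scan

`scan_cutoff()` reproduces the "scan" modus of Kaplan–Meier-by-
expression tools: every midpoint between consecutive distinct
expression values leaving both groups with ≥ 10% of the cohort is
tested with the standard log-rank statistic
$(\sum O_1 - \sum E_1)^2/\sum V$ (hypergeometric variance per distinct
event time, chi-square 1 df), and the cutoff minimizing p is reported.
The minimum over a scan is **anti-conservative by construction**; the
scan count is always reported so users can Bonferroni-correct, and the
null behavior (min-p stochastically below uniform) is itself a tested
property. Ties in p break toward the cutoff nearest the median
expression. The 10% admissibility floor is a declared default — the
cited tool's exact rule is not published.

## Numerical choices and limitations

* All generators are pure functions of (parameters, seed); the pipeline
  derives per-stage sub-seeds from one master seed, and identical
  config + seed reruns are bit-identical (hash-verified manifest).
* Problem sizes in the test suite match the emulated designs (2100 × 2
  and 119 × 9 screens, 5 mice/arm, cohorts of ~60–300) with seed counts
  of 100–200 for Monte-Carlo properties and 2000 for calibration
  checks; these sizes are the package's chosen study conditions.
* The log-rank p is asymptotic. Cross-checks against a 10⁴-permutation
  oracle on cohorts of n ≤ 20 show the chi-square approximation
  anti-conservative by up to ≈ 0.04 in mid-p ranges (median gap ≈ 0.02)
  — an intrinsic property of the approximation at such sizes, visible
  in the test suite, not an implementation artifact (the statistic
  matches an independent implementation to 10⁻⁹). For small cohorts,
  interpret scan p-values with that bias and the multiplicity note in
  mind.
* ANOM limits are Bonferroni-conservative, slightly wide relative to
  Nelson's exact values, increasingly so for large k.
* The 4PL canonicalizes top ≥ bottom and assumes viability decreasing
  in dose; ascending responses surface as non-convergence flags rather
  than negative-Hill fits.
* Percent killing beyond [0, 100] is legitimate signal here; any
  consumer requiring bounded values must opt into clipping.
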
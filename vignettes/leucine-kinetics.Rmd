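---
title: "Arteriovenous leucine tracer kinetics: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arteriovenous leucine tracer kinetics: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leuflux)
```

## The measurement problem

Limb protein turnover cannot be observed directly. The arteriovenous (AV)
balance technique estimates it from what the limb does to the blood flowing
through it: plasma is sampled upstream (carotid artery) and downstream
(femoral vein) of the hindlimb while a `[1-13C]leucine` tracer is infused to
isotopic steady state. Because label enters limb protein but unlabeled
leucine is also released by proteolysis, the combination of net
concentration differences and enrichment dilution separates gross synthesis
from gross degradation — something a net balance alone cannot do.

`leuflux` implements this pipeline for the primed-continuous infusion design
it emulates: hourly feeding, a NaH^13^CO~3~ phase (0–2 h) to place labeled
bicarbonate in the CO~2~ pool, a `[1-13C]leucine` phase (2–8 h), and a
continuous upstream p-aminohippurate (PAH) infusion for plasma flow, with
hourly arterial/venous sampling.

## The two-pool tracer-balance model

With plasma flow $PF$ (L·kg^-1^·h^-1^), plateau concentrations $C_a$, $C_v$
(µmol/L) and fractional enrichments $E_a$, $E_v$:

$$
\begin{aligned}
Ra_{in} &= C_a \, PF &\text{(arterial input)}\\
NB &= PF\,(C_a - C_v) &\text{(net uptake)}\\
U_{13} &= PF\,(C_a E_a - C_v E_v) &\text{(labeled-leucine uptake)}\\
Rd &= U_{13}/E_a &\text{(utilization, total disposal)}\\
PD &= Rd - NB &\text{(protein degradation)}\\
T_{net} &= PF\,(C_{v,KIC} - C_{a,KIC}) &\text{(net transamination)}\\
P_{13} &= PF\,(C_{v,KIC}E_{v,KIC} - C_{a,KIC}E_{a,KIC}) &\text{(labeled KIC production)}\\
F_{13CO_2} &= PF\,(C_{v,CO_2}E_{v,CO_2} - C_{a,CO_2}E_{a,CO_2}) &\text{(labeled CO}_2\text{ release)}\\
Ox &= F_{13CO_2}/(E_{prec}\cdot r) &\text{(oxidation)}\\
PS &= Rd - Ox - T_{net} &\text{(protein synthesis)}\\
PDep &= PS - PD &\text{(protein deposition)}
\end{aligned}
$$

Four identities hold exactly by construction and are enforced in tests:
$PDep = PS - PD$, $PD = Rd - NB$, $Rd = PS + Ox + T_{net}$ and
$PDep = NB - Ox - T_{net}$. The published group-mean panel the package ships
as a worked example (`demo_kinetics_means()`) satisfies all four to its
printed 0.01 rounding, which is the strongest available confirmation that
this reconstruction matches the calculations used to produce it.

Assumptions inherited from the design: isotopic and metabolic steady state
over the plateau window; a single well-mixed plasma pool on each side; no
label recycling within the infusion; and plasma flow representative of the
tissue drained by the femoral vein.

### Precursor pool and recovery

Oxidation needs the enrichment of the intracellular leucine pool feeding
decarboxylation, which is not sampled. The conventional surrogate is the
venous `[1-13C]KIC` enrichment (the "reciprocal pool": KIC is made from
intracellular leucine and released), and that is the default
(`precursor = "venous_kic"`); arterial leucine enrichment is selectable.
A fractional ^13^CO~2~ recovery $r$ can be applied as a divisor; it defaults
to 1 (no correction) because the emulated study does not state one. The limb
label recovery during the bicarbonate phase,
`F13CO2(bicarbonate) / infusion rate`, is computed and reported
(`co2_recovery_limb`) so users can inspect and, if they wish, apply it.

A reconstruction caveat documented rather than hidden: the design takes the
CO~2~ steady state from the 2-h sample — the end of the bicarbonate phase,
before the leucine infusion starts — and the published oxidation values
cannot be reproduced from the published steady-state group means under any
standard precursor choice (venous KIC gives ≈ 45 µmol·kg^-1^·h^-1^ on the
control means, arterial leucine ≈ 15, printed 8.96). Per-animal variability
(the printed pooled SEM is 7.47) and/or an unstated recovery correction are
the plausible explanations. The package therefore (a) computes kinetics per
animal, never from group means, and (b) records the precursor and recovery
choices in the output metadata.

### Per-animal, then average

All kinetics are ratios or products of per-animal quantities. Means of
per-animal ratios are not ratios of group means: plugging the published
steady-state group means into the formulas gives, e.g., net uptake 14.47
µmol·kg^-1^·h^-1^ where the published per-animal mean is 14.90. This is
expected behavior, not error, and `kinetics_from_means()` exists only to
demonstrate it; its output carries `flag_group_mean_input = TRUE`.
`analyze_cohort()` raises the same flag when any group contains a single
animal record, the signature of aggregated input (a genuine single-animal
group could not yield a within-group SEM either).

## Plateau identification

The default rule mirrors the emulated design exactly: the arithmetic mean of
the last three hourly samples for leucine and KIC (hours 6–8 of a 0–8 h
protocol) and the single 2-h sample for CO~2~
(`fixed_timepoint_summary()`). "Last three" is defined as the final three
available samples; the window is configurable (`k`, `co2_time`) since a
design could also justify hours 5–7.

`detect_plateau()` is a stricter optional mode: the longest trailing window
whose least-squares slope is not significantly different from zero
(`alpha = 0.05`) and whose CV is at most 15% (both configurable). When no
window qualifies — e.g. a still-rising series — it falls back to the final
`min_window` points with a warning, so a pipeline run never silently uses a
different rule. For a noise-free exponential approach
$X(t) = X_{ss}(1 - e^{-kt})$ the trailing-window mean undershoots the
asymptote by the mean remainder $X_{ss}\,\overline{e^{-kt}}$ over the
window; tests assert this closed-form bound. The mean is numerically equal
to the asymptote (1 part in 10^9^) only once the window sits ≳ 28 time
constants past the infusate start, which is how the exact round-trip tests
choose their rise constants (below).

## Hemodynamics

Plasma flow uses indicator dilution: PAH infused into the femoral artery is
diluted by limb plasma flow, so
$PF = \dot m_{PAH} / (C_{v,PAH} - C_{a,PAH}) / BW$ with the mass rate
$\dot m_{PAH}$ (mg/h) = mL/min × 60 × solution mg/mL. The solution
concentration is a required protocol field; the default 20 mg/mL is a
package convention chosen to give flows of realistic magnitude (the emulated
study prints only the volumetric rate), and the protocol file makes it
explicit. An inverted or absent gradient is a hard error for the scalar
operation and an exclusion-with-warning per animal in `analyze_cohort()`.

## The synthetic cohort generator

`simulate_cohort()` forward-simulates the full design so that every stage of
the pipeline can be verified without animal data:

* **Truths.** A `sim_truth()` fixes plasma flow, arterial plateaus and the
  true fluxes $\{NB, Rd, T_{net}, Ox, P_{13}\}$; the venous plateaus are the
  exact algebraic inverse of the model (`invert_truth_to_venous()`), so a
  noise-free simulation analyzed by the pipeline returns the truth to
  machine precision. Group defaults are seeded from the published
  steady-state and kinetics tables (plasma flow back-solved as arterial
  input / arterial concentration: control 1.2999, treatment 1.7518
  L·kg^-1^·h^-1^), so the default cohort looks like the emulated study out
  of the box. Because the published oxidation value is not reproducible from
  the published steady-state means (above), the derived venous CO~2~
  enrichment (0.0240% control) differs from the printed one (0.0259%) —
  internal consistency of the simulator was chosen over matching that single
  cell.
* **Time courses.** Each series rises exponentially to plateau after its
  infusate starts (primed-continuous behavior with a well-chosen prime; no
  overshoot), concentrations from a baseline at 80% of plateau from the
  first meal, enrichments from zero. Default rise constants (1.5 h^-1^
  leucine, 1.2 KIC, 3 CO~2~) put the sampling windows 5–19 time constants
  past the start, reproducing "steady state between 5 and 8 h" with a
  plateau shortfall below 0.3%. The exact round-trip tests draw rise
  constants in [7, 10] (leucine/KIC) and [14, 18] (CO~2~) so the windows are
  ≳ 28 time constants out and the identity holds to 10^-9^.
* **Between-animal variability.** Animals vary around the group truth by a
  truncated (±2 SD) log-normal factor with CV 25% applied per parameter.
  This is what carries the group SEMs: assay noise alone (below) is far too
  small to explain the published pooled SEMs (~13–19% of means).
* **Assay noise.** Multiplicative Gaussian on concentrations and additive
  Gaussian on MPE, truncated at physical bounds, per analyte: 8%
  concentration CV and MPE SD 10% of plateau for the chromatographic
  leucine/KIC (and PAH) assays; 1% for the ^13^CO~2~ IRMS and total-CO~2~
  measurements, whose instrument precision is far higher and whose AV
  content difference is ~40-fold smaller than the contents themselves — an
  8%/10% noise there would give simulated oxidation spreads ~3× the
  published pooled SEM. With these defaults the simulated pooled SEMs of
  all eight fluxes land within about 2× of the published ones (a test
  asserts this), while two steady-state cells (KIC MPE, CO~2~
  concentration) imply per-cell between-animal CVs ~2.5× away from the flat
  25% — a flat single-knob jitter cannot match every cell and was preferred
  to per-cell tuning.
* **Determinism.** All randomness flows from the config seed; identical
  configs give byte-identical tables.

### What passing simulation tests does and does not show

The generator emulates the design's sampling structure, steady-state logic
and noise magnitudes. It does not model meal-absorption dynamics, label
recycling, blood-to-plasma CO~2~ partitioning, catheter failures, or
non-exponential approach to plateau. Parameter recovery on simulated
cohorts therefore validates the *estimator algebra and its statistical
behavior under the stated noise model* — not the physiological adequacy of
the two-pool model for real muscle, which only tracer-methodology studies
can address.

## Statistical conventions

Two-sample comparisons use pooled-variance Student's t-tests (Welch
selectable), two-tailed, with no multiple-testing correction — matching the
per-variable reporting style of the tables the package mirrors. The
"pooled SEM" column is the pooled standard error of the difference,
$\sqrt{s_p^2(1/n_a + 1/n_b)}$: dividing the published group-mean differences
by the published pooled SEMs reproduces the published p-values, which pins
down the convention. `t_from_summary()` supports mean ± SEM inputs for
published summaries. Correlation tables use Pearson r with two-tailed
p-values from the t transform and the conventional star annotation.

Monte-Carlo validation in the tests and the acceptance script uses
antithetic noise pairs (the same per-animal truths with exactly negated
measurement noise) when estimating recovery bias and simulated group means:
odd-order noise terms cancel within a pair, so the pair average isolates the
estimator bias itself at a fraction of the replicates plain sampling would
need. Problem sizes used: 1000 sampled truths for the exact round trip, 500
cohorts (250 antithetic pairs) for recovery bias, 2500 null cohorts for the
empirical test size, 400 cohorts for simulated group means.

## Numerical choices and degenerate inputs

* Canonical internal units: µmol/L, fractional enrichment, hours,
  L·kg^-1^·h^-1^ — chosen so the flux panel comes out in µmol·kg^-1^·h^-1^
  with no trailing conversions. CO~2~ is accepted in mmol/L and PAH in mg/L
  with unit tags; `normalize_units()` is idempotent.
* Negative background-corrected tracer-to-tracee ratios are clamped to zero
  and flagged by default (measurement noise near natural abundance makes
  small negatives routine); a strict error policy is available.
* Negative fluxes (net release, negative labeled-CO~2~ gradients) are
  propagated and flagged, never truncated.
* Division guards: zero arterial enrichment, zero precursor enrichment and
  a non-positive PAH gradient are classed errors, not NaNs.
* Partition fractions are set to `NA` with a flag for animals whose noisy
  utilization or arterial input is non-positive, rather than aborting a
  cohort for one bad draw.
* Zero-variance t-test inputs: equal means give $t = 0, p = 1$; unequal
  means are flagged degenerate.

## Limitations

Individual-animal data for the emulated study are not published, so the
published per-animal tables cannot be reproduced directly; the package's
claims rest on the printed-mean identities, the worked-example p-values,
and simulation-based parameter recovery. The two-pool model ignores the
intracellular free pool (a three-pool model would need muscle biopsies) and
reports limb-bed aggregate fluxes, not fractional synthesis rates.
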
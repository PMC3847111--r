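---
title: "A receptor-mediated meta-model of methylprednisolone effects on glucose regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A receptor-mediated meta-model of methylprednisolone effects on glucose regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 4)
library(mplgluc)
```

## The problem

Chronic glucocorticoid therapy causes hyperglycemia and insulin resistance
through coordinated effects in liver, skeletal muscle and white adipose
tissue. `mplgluc` implements a mechanistic pharmacokinetic/pharmacodynamic
(PK/PD) systems model of methylprednisolone (MPL) action on glucose
regulation in rats, spanning five experimental designs: single intramuscular
(IM, 50 mg/kg) and intravenous (IV, 10 and 50 mg/kg) doses, 7-day infusions
(0.1, 0.3 mg/kg/h), and chronic subcutaneous infusions (0.03–0.4 mg/kg/h
over 7–21 days). The package provides (i) simulation of the full coupled
system or any sub-model, (ii) a synthetic destructive-sampling data
generator with a power-of-the-mean variance model, and (iii)
maximum-likelihood fitting with the staged ("piecewise") workflow that makes
a model of this size tractable.

## Model structure

The model is a chain of turnover (indirect-response) systems driven by the
plasma drug concentration.

**Pharmacokinetics.** MPL disposition is a linear two-compartment model. IV
and infusion regimens are parameterized by clearance and central volume
(`CL = 4.91` L/h/kg, `Vp = 1.17` L/kg, `k12 = 0.39`, `k21 = 0.78` 1/h); the
IM route uses `kel = 5.57` 1/h with two parallel first-order absorption
pathways (`ka1 = 1.255`, `ka2 = 0.219` 1/h, fraction `Fr = 0.725` through
the fast pathway, bioavailability `F = 0.214`), producing flip-flop kinetics
in the terminal phase. Because the system is linear we solve the PK in
closed form (biexponential bolus response, its convolution with zero-order
or first-order inputs, washout by superposition) and hand the analytic
concentration to the ODE solver as a forcing function. Concentrations are
converted to nM with a molecular weight of 374.47 g/mol (a named,
overridable constant).

**Receptor dynamics.** Each tissue runs the same fifth-generation
glucocorticoid-receptor gene-mediated model: GR mRNA (`GRm`) is synthesized
at a zero-order rate inhibited by the nuclear drug–receptor complex (`DRn`)
with potency `IC50_Rm`; free cytosolic receptor (`R`) is translated from the
mRNA, binds drug at `kon·C`, and is partially recycled (`Rf·kre·DRn`); the
cytosolic complex translocates to the nucleus at `kT` and the nuclear
complex is lost at `kre`. `DRn` is the driver of every downstream cascade.
Parameters are tissue-specific (e.g. adipose `kon = 0.016` 1/nM/h vs liver
`0.0033`); liver baselines are additionally study-specific.

**Adipose: leptin and food intake.** `DRn` stimulates leptin mRNA
transcription linearly (`S_Lepm = 0.0989` per unit `DRn`); plasma leptin
turns over rapidly (`kd_Lep = 4.95` 1/h) in proportion to its mRNA
(`kd_Lepm = 0.0427` 1/h). The rise of plasma leptin above its study baseline
inhibits the food input rate (IDR-I, `IC50_Lep = 11550` pg/mL). The input
rate itself declines exponentially from `kin_Food0 = 171` to
`kin_FoodSS = 147` kcal/day² (`kd = 1.21` 1/day), describing the control
animals' stress-related decline, and a slow feedback signal (`kFB = 0.0426`
1/day) relaxing toward `Food0/Food` multiplies the input, giving the
observed partial recovery of intake (tolerance). Food loss is first order
with `kout_Food = kin_Food0/Food_max`, `Food_max = 57.9` kcal/day.

**Liver: cAMP and PEPCK.** `DRn` inhibits cAMP degradation (Emax-type, with
`IC50_cAMP` = 433 fmol/mg protein for infusion studies and 17.8 for
injection studies), drives a first-order transduction biosignal (`k1 = 0.75`
1/h), and together with that biosignal scales PEPCK mRNA production and
degradation (`Ss_Pm = 2.11`, `Sd_Pm = 2.90`). PEPCK activity is synthesized
from the λ-amplified mRNA (`λ = 0.004`) under Emax stimulation by the rise
of cAMP above baseline (`Smax_P = 2.11`, `SC50 = 0.0055`).

**Muscle: IL6R1 → IRS-1.** `DRn` stimulates IL6R1 mRNA through an Emax
function (`Smax = 3.05`, `SC50 = 1.09` fmol/mg protein); the signal passes
through 5 transit compartments (`ke = 0.144` 1/h, median delay ≈ `N/ke` ≈ 35
h) and, together with direct `DRn` inhibition (`IC50 = 5.95`), suppresses
IRS-1 mRNA synthesis. IL6R1/IRS-1 mRNA are tracked in baseline-relative
units because absolute baselines are not reported; downstream use is purely
ratio-based.

**Systemic glucose–insulin–FFA.** Glucose production is scaled by the rise
of PEPCK activity (linear, `S_PEPCK = 0.013`), of cAMP (Emax,
`Smax = 3.45`, `SC50 = 1.82` pmol/g liver), and by food intake (linear,
`S_Food = 0.000346` per kcal/h — at 120 kcal/day this is a 0.2% gain);
utilization is stimulated by the insulin excursion with sensitivity
`S_IG = 2.87` (ng/mL)⁻¹ attenuated by `(IRS1m/IRS1m⁰)^λ₁`, `λ₁ = 1.55`.
Insulin secretion is driven by the glucose and FFA rises (`S_GI = 0.0305`
(mg/dL)⁻¹; `S_FI`); FFA production is stimulated by adipose `DRn`
(`Smax_F = 15`, `SC50_F = 2.23` fmol/mg protein) and FFA disposal by the
insulin rise (`S_IF = 0.315` (ng/mL)⁻¹). Zero-order production rates are
derived in closed form from the steady-state condition at time zero, so the
drug-free system is stationary by construction at the per-group baselines
`(G⁰, I⁰, FFA⁰)`, which are never pooled across groups.

```{r schematic-sim}
sim <- simulate_study(study_design("chronic_infusion", "0.3"))
sapply(c("DRn_adipose", "FFA", "I", "G"), function(a) {
  s <- summarize_analyte(sim, a)
  c(t_peak = s$t_peak, peak = s$peak, terminal = s$terminal)
})
```

```{r figure, fig.alt = "FFA and glucose time courses under chronic infusion"}
op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
tr <- analyte_trace(sim, "FFA")
plot(tr$time_h, tr$value, type = "l", xlab = "time (h)", ylab = "FFA (mM)",
  main = "0.3 mg/kg/h infusion")
tr <- analyte_trace(sim, "G")
plot(tr$time_h, tr$value, type = "l", xlab = "time (h)",
  ylab = "glucose (mg/dL)", main = "")
par(op)
```

## Design choices in genuinely open places

Several aspects of the reported parameterization are ambiguous or
internally inconsistent; each resolution below was made on
internal-consistency grounds and is isolated in the code so the
alternative can be examined.

* **Baseline harmonization.** The fixed receptor constants are only
  approximately steady-state consistent (and adipose GR mRNA is normalized
  in different units than its printed synthesis rate). At configuration
  load we recompute `ks_Rm = kd_Rm·GRm0` (or `kd_Rm = ks_Rm/GRm0` for liver,
  where only the synthesis rate is printed — yielding 0.112 1/h, the
  canonical liver value) and `ks_R = kd_R·R0/GRm0`, so drug-free
  simulations are exactly flat. Raw printed values are retained in the
  `"raw"` attribute. The muscle row is exactly consistent as printed
  (0.139 × 2.99 = 0.416), which confirms the footnote assignments.
* **`S_FI` regimen split.** The reported tables attach the two
  FFA→insulin sensitivities to study groups in a way that contradicts the
  accompanying text (twice stated: 13.3 (mM)⁻¹ for single dosing, 28.9 for
  chronic dosing). We follow the text: acute regimens use 13.3 without
  time modulation; infusion regimens use 28.9 with the empirical
  `exp(-kFI·t)` damping (`kFI = 0.183` 1/h, clock starting at infusion
  start). The symbol collision with the insulin→FFA constant is resolved
  so that `S_FI` drives insulin secretion and `S_IF = 0.315` drives FFA
  disposal.
* **Leptin inhibition acts on the excursion.** Driving the food-intake
  inhibition with absolute leptin is inconsistent across studies: the
  infusion-study control (baseline 5170 pg/mL) would be 31% inhibited at
  rest — its steady intake would be ~34 kcal/day instead of
  `kin_FoodSS/kout_Food ≈ 49.8`, the value the printed `Food_max` implies —
  and the circadian-study baseline (23,650 pg/mL) exceeds `IC50_Lep`
  outright. The implementation therefore inhibits with
  `max(Lep − Lep⁰, 0)`, which makes every control arm settle at the same
  drug-free fixed point.
* **Stimulation-only deviations.** ΔcAMP, ΔPEPCK, ΔG and ΔFFA enter their
  stimulation terms floored at zero; the insulin deviation on glucose
  disposal is signed (insulin below baseline reduces utilization, which is
  what lets glucose return to baseline on washout), with the utilization
  factor floored at zero to forbid a negative loss term.
* **Units left as printed.** `SC50` for PEPCK synthesis is printed in
  fmol/g while cAMP is carried in pmol/g; since observed cAMP excursions
  are two to three orders of magnitude above either reading of the
  constant, the stimulation is effectively saturated and the 1000×
  ambiguity is immaterial; the printed number is used. Similarly `S_Lepm`
  (printed 1/nM) is applied per unit of `DRn` in fmol/mg protein, and the
  muscle transit-signal `IC50 = 0.196` is taken in the same
  baseline-relative unit as the transit compartments.

## Numerical choices

All modules share one clock in hours; day-based food parameters are
converted once at configuration load. The coupled system (30 states) is
integrated with `deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-10`, with
dose start/stop times inserted into the output grid (states are continuous
across an infusion stop; only derivatives jump). The default output grid is
0.05 h over the first day — resolving the ~20–30 min adipose `DRn` peak —
and 0.5 h thereafter. Solver overshoot below zero is clamped before
evaluating the right-hand sides; user-facing `*_rhs` functions reject
negative inputs outright. A sequential "modular" mode (receptor systems
first, cascades driven by splined `DRn` traces, systemic system last)
reproduces the monolithic integration to better than 1e-5 relative and
serves as a structural cross-check; its driver splines are built on a
5 ms-resolution early grid because interpolation, not integration, is the
accuracy bottleneck. Extremum times are refined by a parabolic fit through
the three bracketing grid points; flat traces are flagged rather than
given spurious extrema. The IRS-1 ratio is floored at 1e-6 before
exponentiation by `λ₁`.

## Estimation

Observations are pooled naive data: destructive sampling means every time
point is a different animal, so records are independent. The likelihood is
Gaussian with the power-of-the-mean variance `V = σ₁²·Y^σ₂` evaluated at
the model prediction; `σ₂ = 0` recovers least squares and `σ₂ = 2` a
constant CV. Each analyte may carry its own `(σ₁, σ₂)` pair — an extension
of the printed single variance model, appropriate because the pooled assays
differ in scale by several orders of magnitude. Predictions at `Y ≤ 0`
have their variance floored at `σ₁²·ε^σ₂` (`ε = 1e-6`) with a warning, and
simulation failures return a penalty value rather than crashing the
optimizer. Fitting uses bounded L-BFGS-B from seeded multi-starts (default
8) with per-parameter scaling; CV% come from the observed-information
matrix (no claim of matching any particular software's CV% algorithm), and
AIC is reported for model comparison. `run_piecewise_workflow()` executes a
DAG of fitting stages, freezing each stage's estimates for its dependents
and emitting a provenance manifest — the strategy that makes the full
system identifiable in stages: receptor → adipose cascade → food intake →
systemic.

## Synthetic data

`generate_study()` emulates the five designs: it simulates the true curves,
then draws `n` independent observations per analyte and time point from the
power variance model, truncated at zero (at the default CV of 10% the
truncation perturbs the mean by far less than 1%). Food intake is sampled
only at 24-h marks, because daily weighing is the fastest observation the
destructive designs made. Defaults: 4 animals per time point (typical of
the source experiments' subgroup sizes) and `σ₁ = 0.1, σ₂ = 2` (~10% CV) —
the actual variance estimates are not reported, so these are explicitly
synthetic conventions chosen to be realistic for the assays involved. The
generator reproduces pooling structure and noise; it does **not** simulate
inter-animal parameter variability (no random effects are defined by the
naive-pooled analysis), circadian rhythms, or assay-specific biases, so
passing recovery tests demonstrate identifiability under the stated noise
model, not robustness to those unmodeled features.

Problem sizes used in the shipped tests were chosen to exercise the
methods at desk scale: recovery studies use 9 sampling times × 4 animals ×
3 analytes over a 7-day design and 20 noise replicates.

## Known limitations

* With the printed adipose parameters the simulated GR mRNA nadir after a
  single IM dose falls near 6 h, earlier than the ~10 h reported for the
  circadian-sampled experiment; with the mRNA loss rate at
  the muscle-like value 0.139 1/h the nadir moves to ~10.4 h. Because the
  mRNA half-life at 0.427 1/h is ~1.6 h, a 10-h nadir cannot trail a
  30-min `DRn` peak under this structure; the printed description most
  likely reflects the circadian synthesis term that was deliberately
  dropped from this model.
* Circadian oscillations, adiponectin, the antilipolytic action of insulin,
  FFA-induced peripheral insulin resistance, and stress effects on glucose
  after IM dosing are deliberately outside the model.
* Exact reproduction of the published fitted estimates is not possible
  without the underlying animal data; estimation is validated by
  simulation-based parameter recovery instead.
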
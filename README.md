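# mplgluc

A mechanistic PK/PD systems model of methylprednisolone (MPL) effects on
glucose regulation in rats, implemented as a tested simulation and
estimation package.

Synthetic glucocorticoids such as MPL cause hyperglycemia and insulin
resistance through receptor/gene-mediated effects in three organs at once.
`mplgluc` is for pharmacometricians and systems pharmacologists who want to
simulate, probe, or refit that multi-tissue cascade:

- **Pharmacokinetics** — two-compartment disposition with IV bolus,
  zero-order infusion, and dual-pathway IM absorption (flip-flop kinetics),
  solved in closed form and used as the forcing function.
- **Receptor dynamics** — the fifth-generation glucocorticoid receptor
  model (GR mRNA autoregulation, drug binding, nuclear translocation,
  recycling) instantiated per tissue: liver, skeletal muscle, white adipose.
  The nuclear complex DRn drives everything downstream.
- **Adipose cascade** — leptin mRNA induction, plasma leptin, and
  leptin-driven suppression of food intake with slow tolerance feedback.
- **Liver cascade** — cAMP (inhibition of degradation), a transduction
  biosignal, PEPCK mRNA (dual stimulation of production and degradation)
  and PEPCK activity.
- **Muscle cascade** — IL6R1 mRNA induction relayed through a 5-compartment
  transit chain, with dual inhibition of IRS-1 mRNA transcription.
- **Systemic turnover** — coupled plasma glucose, insulin and free fatty
  acids: PEPCK/cAMP/food-stimulated glucose production, insulin-stimulated
  disposal attenuated by `(IRS1m/IRS1m⁰)^λ₁`, glucose/FFA-stimulated
  insulin secretion, DRn-driven lipolysis, insulin-stimulated FFA disposal.
- **Estimation** — naive-pooled maximum likelihood under the power variance
  model `V = σ₁²·Y^σ₂`, with bounded multi-start optimization, CV% from the
  observed information, AIC, and a staged ("piecewise") workflow that
  freezes upstream estimates for downstream stages.
- **Synthetic data** — a destructive-sampling generator (independent
  animals per time point) reproducing the designs of the five source
  experiments, with the noise-free truth returned for oracle checks.

The core state equations are turnover (indirect-response) models; for
glucose, e.g.,

    dG/dt = ks_G · (1 + S_PEPCK·ΔPEPCK) · (1 + Smax·ΔcAMP/(SC50 + ΔcAMP))
                 · (1 + S_Food·Food/24)
          − kd_G · (1 + S_IG · (IRS1m/IRS1m⁰)^λ₁ · ΔI) · G

with all zero-order production rates derived from the steady-state
condition at time zero, so every drug-free simulation is stationary at its
printed group baselines by construction. All fixed parameters ship in
`inst/extdata/parameters.yaml`, keyed by study and arm exactly as reported.

## Worked example

Simulate the single 50 mg/kg IM study and summarize the dynamic signatures:

```r
library(mplgluc)
sim <- simulate_study(study_design("circadian_nadir", "im50", t_end = 48))
for (a in c("DRn_adipose", "GRm_adipose", "Lep", "FFA", "I")) {
  s <- summarize_analyte(sim, a)
  cat(sprintf("%-12s t_peak = %6.2f h  peak = %10.3f   t_nadir = %6.2f h\n",
    a, s$t_peak, s$peak, s$t_nadir))
}
```

```
DRn_adipose  t_peak =   0.31 h  peak =     73.235   t_nadir =   0.00 h
GRm_adipose  t_peak =   0.00 h  peak =   2200.000   t_nadir =   5.78 h
Lep          t_peak =  10.95 h  peak =  57529.333   t_nadir =   0.00 h
FFA          t_peak =   5.74 h  peak =      0.632   t_nadir =   0.00 h
I            t_peak =  10.72 h  peak =      9.723   t_nadir =   0.00 h
```

Reading the output: the adipose nuclear drug–receptor complex peaks ~20 min
after dosing (73 fmol/mg protein) and drives the cascade; GR mRNA is
transiently down-regulated (nadir ~6 h); plasma leptin peaks near 11 h at
~2.3× its 25,000 pg/mL baseline; plasma FFA peaks at ~5.7 h (0.63 mM from a
0.12 mM baseline) and insulin rises ~6-fold before everything relaxes back
to baseline — the acute-dose signature of glucocorticoid-stimulated
lipolysis with compensatory insulin secretion.

Parameter recovery on synthetic data follows the same pattern:

```r
des <- study_design("chronic_infusion", "0.3")
sim <- simulate_study(des)
sd  <- synthetic_design(des, sampling_times = c(6, 12, 24, 48, 96, 168),
                        analytes = c("G", "I", "FFA"), seed = 1)
obs <- generate_study(sd, simulation = sim)$observations
spec <- fit_spec(systemic_stage_predict(sim),
                 free = c(S_GI = 0.01, S_IG = 1, SC50_F = 1),
                 lower = c(1e-4, 0.1, 0.05), upper = c(0.5, 30, 30))
fit_stage(obs, spec, variance_params(0.1, 2), seed = 1)
```

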
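# metaflex

Whole-body postprandial metabolism under insulin resistance, as a
twelve-state dimensionless ODE model in R.

## The problem

After a mixed meal, glucose, triglyceride (TAG) and free fatty acids
(FFA) are transported between the blood plasma, the liver, adipose
tissue and skeletal muscle, stored as glycogen and TAG, and oxidised.
Insulin orchestrates almost every one of these fluxes, so *insulin
resistance* — a blunted tissue response to insulin, characteristic of
obesity and type 2 diabetes — reshapes the entire postprandial response:
which tissue resists, and how the others compensate, determines fasting
lipid levels, liver fat accumulation, and the muscle's ability to switch
fuel between fat (fasted) and glucose (fed), its *metabolic
flexibility*.

`metaflex` is for modellers and quantitative physiologists who want to
simulate and compare these situations on a common footing.  It
implements a compartmental model of plasma insulin `I`, glucose `G_b`,
TAG `T_b` and FFA `A_b`; hepatic glycogen `Y_L`, FFA `A_L` and TAG
`T_L`; and muscle AMP `P`, glucose `G_m`, glycogen `Y_m`, FFA `A_m` and
TAG `T_m`.  All concentrations are scaled by their healthy fasting
values (the healthy fasting state is the unit vector) and insulin
sensitivity of each pathway is a multiplicative factor σ, φ ∈ (0, 1] —
for example the plasma-glucose balance reads

    α dG_b/dt = β_G f₁(Y_L)/(1 + σ_L k_GL I²) − S_G G_b
                − k_G (1 + σ_G k_GI I) G_b − k_L σ_Y I G_b f₂(Y_L)
                − k_AL I G_b + F_G(t)

with hepatic glycogen saturating at a capacity `Y_max` through smooth
factors f₁, f₂, and a meal source `F_G(t) = F θ_G t/B_G² exp(−t²/2B_G²)`.
Scenarios set the resistant tissues' factors to published values
(adipose: σ_A = σ_AT = 0.1, φ_A = φ_AT = 0.4; liver: σ_Y = 0.5,
σ_L = 0.06, σ_T = 0.25; muscle: σ_G = 0.2) and leave the rest at 1.
See the vignette (`vignettes/metaflex-model.Rmd`) for the full model,
the calibration of the fasting state, and the default parameter regime.

## Worked example

```r
library(metaflex)

p <- mf_params()            # registry defaults + fasting-state calibration
cmp <- compare_scenarios(c("healthy", "adipose", "liver", "muscle", "all"),
                         params = p, meal = mf_meal(550, 150), t_end = 12)
cmp[, c("scenario", "peak_G_b", "peak_I", "peak_T_b", "min_A_b",
        "n_glucose_peaks", "recovered")]
```

```
  scenario peak_G_b peak_I peak_T_b min_A_b n_glucose_peaks recovered
   healthy    1.610  1.503    1.932   0.600               1      TRUE
   adipose    1.601  1.513    6.603   0.844               1     FALSE
     liver    2.016  1.891    2.070   0.438               1     FALSE
    muscle    3.169  2.815    1.316   0.273               3     FALSE
       all    2.951  2.773    7.448   0.530               1     FALSE
```

Reading the table: the healthy subject's glucose peaks at 1.61× fasting
and everything is back within 1% of fasting by 11.3 h.  Adipose
resistance barely moves glucose but triples the TAG peak and halves the
FFA dip (0.844 vs 0.600), because insulin no longer suppresses adipose
FFA release nor stimulates TAG uptake.  Hepatic resistance pushes the
glucose that the liver fails to store into muscle.  Muscle resistance
produces the highest glucose and insulin peaks and more than one
prominent glucose maximum — the liver glycogen store hits its capacity
`Y_max`, hepatic uptake shuts off, and plasma glucose spikes again.
Whole-body resistance keeps the store *below* capacity (the liver's own
uptake is impaired), raises the fasting TAG baseline
(`steady_state(p, scenario_sensitivities("all"))[["T_b"]]` ≈ 4.0),
narrows the metabolic-flexibility range, and is still not recovered
12 h after the meal.

Single runs, plots and files:

```r
tr <- mf_simulate(p, scenario_sensitivities("muscle"), t_end = 12)
plot(tr, which = "plasma", reference = mf_simulate(p, t_end = 12))
write_trajectory_csv(tr, "muscle.csv")
```

or from a shell:

```sh
Rscript inst/cli/metaflex.R --scenario muscle --carb-kcal 550 \
    --fat-kcal 150 --duration 12 --out run/
Rscript inst/cli/metaflex.R --compare healthy,adipose,liver,muscle,all --out cmp/
```

which writes the trajectory CSV (columns `t`, the twelve states,
`frac_glucose_oxidation`, `adipose_tag_clearance`), a summary JSON, and
a provenance log stating which parameter values are published, package
defaults, calibrated, or overridden.

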
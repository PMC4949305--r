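---
title: "The metaflex model: whole-body postprandial metabolism under insulin resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metaflex model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`metaflex` integrates a twelve-state compartmental model of human
carbohydrate and fat metabolism over the hours following a mixed meal.
Three compartments exchange substrates through the blood plasma:

* **plasma**: insulin $I$, glucose $G_b$, triglyceride $T_b$, free fatty
  acids $A_b$;
* **liver**: glycogen $Y_L$, FFA $A_L$, TAG $T_L$;
* **skeletal muscle**: an AMP marker $P$ (a proxy for cellular energy
  demand), glucose $G_m$, glycogen $Y_m$, FFA $A_m$, TAG $T_m$.

All concentrations are dimensionless — each variable is scaled by its
healthy fasting value, so the healthy fasting state is the unit vector —
and time is in hours.  The kinetics are mass-action rates modulated by
insulin and by the AMP marker:

$$
\begin{aligned}
\dot I &= f_0(G_b) + k_{IA}A_b - \lambda_I I,\\
\alpha\,\dot G_b &= \frac{\beta_G f_1(Y_L)}{1+\sigma_L k_{GL}I^2}
  - S_G G_b - k_G(1+\sigma_G k_{GI}I)G_b
  - k_L\,\sigma_Y I G_b f_2(Y_L) - k_{AL} I G_b + F_G(t),\\
\alpha\,\dot T_b &= \frac{\beta_T f_3(T_L)}{1+\sigma_T k_{TL}I}
  - k_T T_b - \phi_{AT}k_{TA}(1+\sigma_{AT}k_{AI}I)T_b + F_T(t),\\
\alpha\,\dot A_b &= \frac{\phi_A\beta_A}{1+\sigma_A k_{AA}I^2}
  - k_A A_b - k_{BL}A_b + k_{LB}A_L,\\
\eta\,\dot Y_L &= k_L\,\sigma_Y I G_b f_2(Y_L)
  - \frac{\beta_G f_1(Y_L)}{1+\sigma_L k_{GL}I^2},\\
\eta\,\dot A_L &= k_{AL}IG_b - \frac{S_L A_L}{1+k_{AS}I}
  + k_{BL}A_b - k_{LB}A_L - k_{TH}IA_L,\\
\eta\,\dot T_L &= k_{TH}IA_L - \frac{\beta_T f_3(T_L)}{1+\sigma_T k_{TL}I},\\
\dot P &= \mu - \lambda_P P - \gamma_a M_A A_m P
  - \sigma_G\gamma_g M_G P I G_m,\\
\dot G_m &= k_G(1+\sigma_G k_{GI}I)G_b - \sigma_G M_G P I G_m
  - k_Y\frac{1+\sigma_G k_{YI}I}{1+k_{YP}P}G_m
  + \frac{k_{CP}PY_m}{1+\sigma_G k_{CI}I},\\
\dot Y_m &= k_Y\frac{1+\sigma_G k_{YI}I}{1+k_{YP}P}G_m
  - \frac{k_{CP}PY_m}{1+\sigma_G k_{CI}I},\\
\dot A_m &= k_T T_b + k_A A_b - M_A P A_m
  - k_X\frac{1+k_{XI}I}{1+k_{XP}P}A_m + \frac{k_{DP}PT_m}{1+k_{DI}I},\\
\dot T_m &= k_X\frac{1+k_{XI}I}{1+k_{XP}P}A_m - \frac{k_{DP}PT_m}{1+k_{DI}I}.
\end{aligned}
$$

The liver saturation factors are
$f_1(Y_L)=Y_L/(Y_0+Y_L)$,
$f_2(Y_L)=(Y_{\max}-Y_L)/(Y_0+Y_{\max}-Y_L)$ and
$f_3(T_L)=T_L/(T_0+T_L)$: glucose output requires glycogen, glycogen
synthesis stops smoothly at the capacity $Y_{\max}$, and TAG output
requires hepatic TAG.  The meal eaten at $t=0$ enters the plasma through
$$
F_G(t)=\frac{F\theta_G\,t}{B_G^2}e^{-t^2/2B_G^2},\qquad
F_T(t)=\frac{F\theta_T\,t}{B_T^2}e^{-t^2/2B_T^2},
$$
which integrate exactly to $F\theta_G$ and $F\theta_T$; the delays $B_G <
B_T$ make glucose arrive before fat.  The reference meal is 550 kcal of
carbohydrate and 150 kcal of fat, so $\theta_G = 550/700$ and $\theta_T =
150/700$.

Insulin production $f_0$ has two forms: a sigmoid
$k_1+k_2\,\mathrm{erf}((G_b-v)/c)$, and the quadratic approximation
$k_{IG}G_b+k_{I2}G_b^2$ that the numerical work uses (the default in this
package; select with `insulin_model`).

In `metaflex` every right-hand side is assembled from a set of *named
fluxes* (`compute_fluxes()`), one per arrow of the reaction network, so
each transport rate enters its two compartments with opposite signs by
construction; the test suite verifies this assembly against an
independent literal transcription of the equations.

## Insulin-resistance parametrisation

Insulin resistance is modelled by multiplicative sensitivity factors on
the insulin-modulated pathways, all equal to 1 in health:

| factor | pathway | resistant value |
|---|---|---|
| $\sigma_Y$ | hepatic glucose uptake | 0.5 |
| $\sigma_L$ | insulin suppression of hepatic glucose output | 0.06 |
| $\sigma_T$ | insulin suppression of hepatic TAG output | 0.25 |
| $\sigma_A=\sigma_{AT}$ | insulin action on adipose FFA output / TAG uptake | 0.1 |
| $\phi_A=\phi_{AT}$ | basal adipose FFA output / TAG uptake | 0.4 |
| $\sigma_G$ | muscle glucose uptake, oxidation and glycogen handling | 0.2 |

`apply_insulin_resistance()` sets exactly the factors of the listed
tissues and leaves the rest at 1, so scenarios compose commutatively.
Two published readings disagree in two places, and both are exposed
rather than resolved: the muscle factor is tabulated as 0.2 but the
muscle-scenario text uses 0.15 (`sigma_G_text_value = TRUE`), and the
liver-scenario text can be read as keeping $\sigma_Y = 1$
(`strict_liver_text = TRUE`).  The defaults follow the tabulated values.

Scenario simulations all start from the unity state — the shared initial
condition of the comparisons — rather than from each scenario's own
shifted fasting baseline; the baselines themselves are available from
`steady_state()`.

## Calibration and the fasting state

All rate constants are on the dimensionless model scale.  The published
dimensional values (mmol/l/min and similar) cannot be transferred
directly because the per-variable concentration scales of the
non-dimensionalisation are not published; the registry therefore records
documented defaults, every one overridable, with provenance
(`parameter_provenance()`).

`calibrate_to_unity_steady_state()` closes the model around the unity
fasting state by solving one designated coefficient per balance
equation: $\lambda_I$, $\beta_G$, $T_0$, $k_A$, $k_{BL}$, $k_{TH}$,
$\mu$, $M_G$, $k_{CP}$, $M_A$, $k_{DP}$.  Eleven of the twelve equations
then have residual $\sim 10^{-15}$ at the unity state.

The twelfth cannot be closed, and this is a structural property of the
kinetics, not a numerical shortcoming.  Multiplying the plasma-glucose
equation by $\alpha$ and the hepatic-glycogen equation by $\eta$ and
adding them cancels the two shared hepatic fluxes and leaves
$$
\alpha\dot G_b + \eta\dot Y_L = -\bigl(S_G + k_G(1+\sigma_G k_{GI}I) +
k_{AL}I\bigr)G_b + F_G(t) ,
$$
which is strictly negative at any positive fasting state: with the meal
off, whole-body glucose consumption can only be met by draining liver
glycogen.  An exact interior equilibrium would require zero body glucose
consumption, zero muscle uptake and zero lipogenesis — a dead model.
Calibration therefore balances the plasma equation exactly and reports
the irreducible glycogen drift $-(S_G+k_G(1+k_{GI})+k_{AL})/\eta$ as the
`fasting_drift` attribute.  With the default parameters the drift is
$4.3\times10^{-4}\,\mathrm{h^{-1}}$: about 0.5% of the store over a 12 h
fast, so fasting baselines are flat to within 1% over any physiological
window.  The fasting *baseline* of a scenario (`steady_state()`) is
correspondingly defined on the fast subsystem, with the slow glycogen
store frozen at its reference value: the remaining eleven balances are
solved by Levenberg–Marquardt iteration, seeded from a short relaxation
of the reduced system and solved in volume-weighted (flux-balance) form
because the $1/\eta$ factor otherwise makes the liver residuals
ill-scaled.  Local stability of every scenario baseline is verified by
the eigenvalues of the reduced Jacobian.

## Default parameter regime

Where the printed tables leave rate constants blank, the package ships a
single documented regime, chosen once on physiological grounds:

* **Time unit**: hours; the meal delays are $B_G = 0.75$ h and $B_T =
  1.5$ h, putting the glucose peak under an hour after the meal and the
  TAG peak several hours later.
* **Turnover hierarchy**: plasma states turn over in minutes to an hour
  ($\alpha = 0.17$ with fasting clearance coefficients near 1/h), muscle
  pools in hours ($M_G \approx 1$, $M_A \approx 0.6$), and the liver
  stores much more slowly.  $\eta$ is the liver volume ratio *times* the
  store-to-plasma concentration-scale ratio — liver glycogen is a large
  store measured against plasma glucose — giving the liver equations a
  large effective capacitance ($\eta = 2400$).  This is what makes the
  fasting drift above small.
* **Insulin**: the quadratic production is nearly linear over the
  simulated glucose range ($k_{IG} = 3.2$, $k_{I2} = 0.2$), with
  degradation calibrated to $\lambda_I = 3.8$/h (a response time of
  about 15 minutes).
* **Glycogen capacity**: $Y_{\max}$ sits just above the healthy
  postprandial glycogen peak with $Y_0 \ll Y_{\max}-1$, so $f_2$ acts as
  a sharp (but smooth) switch.  In the muscle-resistant scenario the
  glucose that muscle fails to take up is diverted to the liver, the
  store saturates, hepatic uptake shuts off and plasma glucose spikes a
  second time; in whole-body resistance the liver's own reduced
  sensitivity keeps the store below capacity.  This is the mechanism the
  scenario comparisons probe, and the reason the capacity margin is
  deliberately tight.
* **Oxidation weights**: the AMP stoichiometries are $\gamma_a = 1$ and
  $\gamma_g = 0.06$, reflecting the much larger energy yield per unit of
  fat flux; the fractional-glucose-oxidation observable uses the same
  weights by default (`gamma_weighted = FALSE` gives the raw flux
  ratio).

The generator of test fixtures (`generate_fixture()`) jitters the
non-calibrated defaults by ±20% and recalibrates, which is how the test
suite checks that conclusions do not hinge on one numeric accident.

## Observables and summaries

* **Fractional glucose oxidation** — the glucose share of muscle
  substrate oxidation, $x/(x+y)$ with $x = \gamma_g\sigma_G M_G P I G_m$
  and $y = \gamma_a M_A P A_m$.  Its range over the postprandial window
  is the model's measure of *metabolic flexibility*: a healthy subject
  swings from fat-dominated fasting oxidation to glucose-dominated
  postprandial oxidation and back.
* **Adipose TAG clearance** — $\phi_{AT}k_{TA}(1+\sigma_{AT}k_{AI}I)T_b$,
  the insulin-stimulated disposal of plasma TAG into adipose tissue.
* **Summaries** (`summarise_trajectory()`): per-variable peaks and peak
  times, net hepatic TAG gain $T_L(t_{\rm end})-T_L(0)$ (the steatosis
  readout), the flexibility range, total oxidation (the time integral of
  $\gamma_g$- and $\gamma_a$-weighted oxidation fluxes), the number of
  prominent plasma-glucose maxima, and the recovery time.  Recovery is
  the first time after the largest excursion at which *every* state
  stays within 1% (configurable) of its fasting value for the rest of
  the window; a trajectory that never does is flagged "not recovered".
  Prominent maxima must be separated by at least 5 minutes and by a dip
  of at least 0.1% of the global peak, so the shallow minutes-long dip
  of a genuine double spike counts while solver-level ripples do not.

## Numerical choices

Integration uses `deSolve` with dense output on a fixed grid (default
1-minute spacing), so summaries do not depend on internal step
placement.  The default integrator is `lsoda` (stiffness-switching);
`ode45` is the explicit cross-check family, and the two agree on all
scenario summaries to better than $10^{-6}$ at the default tolerances
(`rtol = 1e-8`, `atol = 1e-10`).  State non-negativity is enforced
structurally (every sink carries its own variable as a factor); the
integrator wrapper clamps sub-tolerance negative excursions and permits
the glycogen store to overshoot its cap only within a small tolerance,
erroring on anything larger.  The cap itself is handled by the smooth
$f_2$ factor rather than a hard event — in reality the shut-off of
hepatic glucose uptake would be smoothed by intermediate processes, and
the shallow inter-spike dip should be read with that in mind.

Test problem sizes: scenario runs integrate 12 h at 1-minute output
resolution (721 points); structural identities are checked at 100 random
states; baseline cross-checks relax the reduced system to equilibrium.

## What the model does and does not capture

The simulations reproduce the qualitative physiology of single-tissue
and whole-body insulin resistance: adipose resistance blunts FFA
suppression and raises plasma and liver fat; hepatic resistance shifts
glucose storage from liver to muscle; muscle resistance overloads the
liver store and prolongs the glycaemic excursion; whole-body resistance
raises fasting TAG, blunts metabolic flexibility and total oxidation,
and leaves the system unrecovered 12 h after a meal.

Limitations to keep in mind.  Protein metabolism, fructose, and
glucose-sensing adaptation of pancreatic insulin secretion are outside
the model.  Sensitivity factors are fixed per run — resistance does not
progress within a simulation.  The dimensionless scales mean amplitudes
are comparable *between scenarios*, not directly against clinical
concentrations, and the liver-capacitance choice compresses hepatic
store excursions to small relative amplitudes; directional comparisons
between scenarios are the intended readout.  Finally, the fasting state
is quasi-steady, not steady (see the calibration section): over windows
much longer than ~24 h the slow glycogen drain dominates, which is the
model's honest statement that nobody fasts at equilibrium forever.
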
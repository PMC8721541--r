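---
title: "In silico trials of a DIY hybrid closed loop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico trials of a DIY hybrid closed loop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopsim)
```

`loopsim` runs desk-scale in silico trials of a do-it-yourself hybrid
closed-loop (HCL) insulin delivery algorithm: a virtual type 1 diabetes
cohort is driven through a scripted two-day meal protocol by an oref-style
controller, and glycemic control is scored with the consensus CGM metrics.
This vignette explains the models, the tunable parameters and the design
choices, so a reader can judge what the simulations do — and do not — show.

## The virtual patient

The plant is a minimal-model glucose–insulin system with two-compartment
subcutaneous insulin absorption and two-compartment gut carbohydrate
absorption:

$$\dot S_1 = u - S_1/\tau_i,\qquad \dot S_2 = (S_1-S_2)/\tau_i$$
$$\dot I = -nI + S_2\,10^6/(\tau_i V_I\,BW),\qquad
  \dot X = -p_2 X + p_3 (I - I_b)$$
$$\dot Q_1 = d - Q_1/\tau_m,\qquad \dot Q_2=(Q_1-Q_2)/\tau_m,\qquad
  R_a = f_{bio} Q_2/\tau_m$$
$$\dot G = -p_1 (G - G_b) - X G + R_a/(V_G\,BW)$$

with insulin infusion $u$ (U/min) and ingestion $d$ (mg/min). $G$ is plasma
glucose (mg/dl), $X$ remote insulin action (1/min), $I$ plasma insulin
(µU/ml). The basal equilibrium is closed-form: at a constant infusion of
`basal_ref` U/h the plasma insulin settles at
$I_b = \mathrm{basal\_ref}\cdot 10^6/(60\,n\,V_I\,BW)$, and $(G_b, 0, I_b)$
is the unique attracting fixed point — `init_steady_state()` starts every
run there. The licensed research simulators in this field are closed; this
plant is deliberately simple, fully open and testable, and the closed-loop
results are read as properties of the *controller-protocol* combination on
a plausible population, not as a reproduction of any proprietary
population.

Integration is fixed-step RK4 at 1 min. Boluses and rescue carbohydrates
enter as impulses on $S_1$ and $Q_1$ at step boundaries; compartments are
clamped at zero and glucose floored at 1 mg/dl. Halving the step moves a
48-h endpoint by well under 0.01 mg/dl (tested), so 1 min is comfortably
inside the asymptotic regime for these dynamics.

## The cohort generator

`generate_cohort()` draws three age groups (children 2–12, adolescents
13–18, adults), ten patients each by default, with parameters sampled
uniformly per group — body weight 20–50 / 45–75 / 60–100 kg, basal
0.4–0.7 / 0.7–1.2 / 0.8–1.4 U/h — and shared ranges for the metabolic
constants ($G_b$ 110–140 mg/dl, $p_1$ 0.003–0.010, $p_2$ 0.01–0.04,
insulin sensitivity $SI = p_3/p_2$ log-uniform in 2–8·10⁻⁴ ml/µU/min,
$n$ 0.10–0.20, $\tau_i$ 50–70 min, $\tau_m$ 30–60 min, $f_{bio}$
0.80–0.95, $V_G$ 1.4–1.8 dl/kg, $V_I$ 100–140 ml/kg). The cohort is a
deterministic function of its seed.

A plausibility filter rejects and redraws (at most 100 times) any candidate
whose open-loop peak excursion after a probe meal falls outside
30–200 mg/dl. The probe is **weight-scaled** — $50\cdot BW/70$ g, i.e.
about 0.7 g/kg, 50 g at the 70-kg reference. This matters: the glucose rise
per gram scales as $1/(V_G BW)$, so a fixed adult-sized probe would reject
essentially every small child on body size alone rather than on implausible
metabolism. With the weight-scaled probe the filter accepts roughly 40 % of
raw draws in *every* age group, so it trims metabolic outliers uniformly.

## The controller

The controller re-specifies the core of the oref0/AndroidAPS hybrid
closed loop in a closed, testable form. Per 5-min CGM sample it computes:

* **IOB/activity** — every bolus and every 5-min temp-basal deviation from
  the scheduled basal contributes through one exponential insulin curve
  (defaults DIA 300 min, peak 75 min) whose activity integrates to exactly
  1 over a DIA; `insulin_curve()` documents the closed form.
* **Deviation** — the observed 5-min CGM change minus the insulin-explained
  change, scaled to 30 min. This drives carb-absorption estimation and
  unannounced-meal (UAM) dosing.
* **COB** — announced carbs decay at
  $\max(\mathrm{deviation}\cdot 5/30,\ \mathrm{min\_5m\_carbimpact})/CSF$
  per 5 min with $CSF = ISF/CR$; the floor (default 8 mg/dl per 5 min)
  guarantees carbs-on-board cannot persist forever.
* **Autosens** — mean deviation over carb-free intervals of the last 8 h,
  scaled to mg/dl per hour, mapped to a ratio
  $1 + \bar D/(\mathrm{basal}\cdot ISF)$ and clamped to [0.7, 1.2]
  (upstream's default bounds); ISF is divided and basal multiplied by it.
* **Prediction arrays** — four 4-h forecasts (48 points): insulin-only,
  zero-temp, carb-impact and UAM (current deviation decaying linearly to
  zero over 60 min). The dosing decision uses the eventual glucose of the
  governing array (carbs outrank UAM, which outranks insulin-only) and the
  forecast minima as guards.
* **Dosing** — below 65 mg/dl (measured or guard-predicted): 30-min
  zero-temp. Eventual glucose below target: proportional low-temp. Above
  target: the insulin required to reach target, limited by the forecast
  minimum and by the 10 U IOB cap, delivered as a super micro bolus (SMB,
  capped at 30 basal-minutes, floored to the 0.05 U pump grid) riding on a
  30-min zero-temp, or as a temp up to min(10 U/h, 4·basal). A delivered
  SMB is always paired with the zero-temp; if the required microbolus
  floors to 0 U the controller falls back to the temp branch — answering a
  sub-grid insulin *need* by suspending basal would invert the feedback
  loop (we verified this destabilizes the no-meal equilibrium).

Therapy profiles come from the plant's basal rate via the familiar rules
TDD = 24·basal/0.5, ISF = 1800/TDD, CR = 500/TDD, with target 100 mg/dl
and the trial's safety caps (10 U/h maximum basal, 10 U maximum IOB). The
profile target, the SMB limit, autosens bounds, the carb-impact floor and
the suspend threshold are framework defaults, all configurable — the
reference study did not publish its preference values.

## Devices

The CGM samples every 5 min with AR(1) noise
($\varepsilon_t = 0.7\varepsilon_{t-1} + e_t$, $e_t\sim N(0, 2^2)$ mg/dl)
clamped to 39–400 mg/dl; σ = 0 gives a deterministic sensor for tests. The
noise scale is deliberately small — the reference sensor-error model is
unknown — and is a framework choice, not a reproduction. The pump
quantizes basal rates to 0.05 U/h (nearest) and boluses to 0.05 U (floor);
temps last 30 min and are replaced on every controller cycle.

## The trial protocol

The default scenario covers 48 h from midnight. The daily meal plan —
07:00 breakfast 45 g, 12:30 lunch 70 g, 16:00 snack 20 g, 19:00 dinner
60 g, 22:00 snack 15 g, repeated on day 2 — is an explicit placeholder for
a protocol whose exact grams are published only graphically; it ships as
an editable YAML file (`inst/extdata/scenario-two-day.yaml`). Announced
meals receive half of the calculated bolus (carbs/CR) 15 min before
intake; corrections are left entirely to the loop. A 16 g rescue
carbohydrate (hypotreatment) is given whenever the *measured* glucose
falls below 65 mg/dl, with a 30-min lockout; rescue carbs reach the plant
but are not entered into the controller — rescue sugar is not bolused in
practice. Both conventions are configurable.

All randomness flows through one seed hierarchy: the master seed fixes the
cohort and the per-patient sensor streams, which are derived before any
work is dispatched — results are bit-identical for any worker count.

## Metrics

Metrics are computed on the CGM series by default (what the controller and
a clinic observe; `use_true_bg = TRUE` switches to plant glucose) in three
blocks: overall, night (midnight–08:00) and post-prandial (union of
(meal, meal+4 h] windows). Range bands follow the consensus thresholds
(≤54, 54–70, 70–180, 180–250, >250 mg/dl, tight range 70–140), LBGI/HBGI
use the standard logarithmic risk transform
$f(BG)=1.509((\ln BG)^{1.084}-5.381)$, and cohort aggregation reports
median and IQR (linear-interpolation percentiles) for everything except
mean glucose in the overall and post-prandial blocks, which is reported as
mean (±SD) by convention. CV is reported as a fraction.

## What the simulations show — and what they do not

The generator emulates a three-age-group population with realistic fasting
equilibria and meal excursions, but not circadian insulin-sensitivity
rhythms, exercise, stress, sensor dropout or pump faults. Because the
1800/500 rules tie the controller profile to the plant's basal rate alone
— while insulin sensitivity, weight and basal are sampled independently —
small-bodied patients receive profiles whose implied carb sensitivity
(a fixed 3.6 mg/dl per g) understates their true carb impact
($f_{bio}\cdot 1000/(V_G BW)$, ~15 mg/dl/g at 40 kg) several-fold. The
half-bolus protocol plus the SMB cap then saturates the insulin-delivery
channel during large meals, so children run post-prandially hyperglycemic
while nights and hypoglycemia safety remain excellent. This mirrors the
age-group gradient reported for such trials and should be read as a
property of rule-derived profiles on this population, not as a controller
defect; passing tests certify protocol fidelity and safety behavior, not
clinical performance on real patients.

Problem sizes used throughout: 30 patients × 48 h at a 1-min plant step
and 5-min controller cadence (a full trial is a few minutes of CPU time);
unit tests use single patients and 12–16 h scenarios.

## Reproducing the headline numbers

```{r, eval = FALSE}
cohort <- generate_cohort(10, seed = 1)
trial <- run_cohort(cohort, default_scenario(), master_seed = 1)
met <- trial_metrics(trial)
print(met$summary)
```

`scripts/acceptance.R` runs exactly this pipeline and writes the cohort
medians (nocturnal time in range, overall time above 250 mg/dl, time at or
below 54 mg/dl, hypotreatment counts) to JSON.
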
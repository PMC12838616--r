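---
title: "Hybrid closed-loop insulin dosing: models, safety layers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid closed-loop insulin dosing: models, safety layers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucontrol)
```

## The control problem

A person with type 1 diabetes wears a continuous glucose monitor (CGM)
that reports interstitial glucose every 5 minutes with sensor noise, and
an insulin pump that infuses insulin continuously (U/min). A fully
closed-loop "artificial pancreas" controller must map the observed CGM
and pump history onto the next infusion rate so that glucose stays in
the clinical target range of 70–180 mg/dL — without meal announcements,
carbohydrate counting, or a patient-specific physiological model.

The controller only sees noisy glucose readings and its own past doses,
never the physiological state (gut carbohydrates, remote insulin
effect), so the task is a partially observable Markov decision process.
The state presented to all learners is a sliding window of the last
k = 12 paired (CGM glucose, insulin rate) samples, i.e. one hour of
history.

Reinforcement learning fits this problem well — it needs no prior model
and adapts per patient — but its trial-and-error exploration is exactly
what a safety-critical application cannot tolerate. The package
therefore implements a *hybrid* controller: a recurrent PPO policy whose
every decision can be screened by a sampling-based model-predictive
(MPC) layer driven by a *learned* glucose forecaster, with a rule-based
safety controller as the last line of defence.

## Action space and pump transform

Policies emit actions $a \in [-1, 1]$, mapped to an infusion rate by the
exponential transform

$$I = I_{\max}\, e^{\tau (a - 1)},\qquad I_{\max} = 5\ \text{U/min},\ \tau = 4,$$

so the ceiling is reached exactly at $a = 1$ while most of the action
interval resolves clinically relevant low rates. Note that the neutral
action $a = 0$ already corresponds to $5e^{-4} \approx 0.09$ U/min
(≈ 130 U/day) — an untrained policy therefore *overdoses*, which is the
safety problem the hybrid layer exists to contain.

## Reward: risk index with a smoothed hypoglycaemia ramp

The per-step reward derives from the Kovatchev blood-glucose risk index

$$\mathrm{risk}(g) = 10\,\bigl(1.509\,[(\ln g)^{1.084} - 5.381]\bigr)^2,$$

which is zero at ≈ 112.517 mg/dL and rises steeply toward
hypoglycaemia. The reward is the risk normalised against the worst risk
on the 20–600 mg/dL CGM reporting range and flipped into $[0, 1]$
(`normalized_reward()`), so a perfect in-range day of 288 five-minute
steps has a cumulative-reward ceiling of 288; a severe hypoglycaemic
event (glucose < 40 mg/dL) terminates the episode with a −15 penalty,
giving the attainable range $[-15, 288]$. The −15 penalty is tied to
that termination event, which is judged on *true* glucose: a noisy CGM
reading that dips below 40 mg/dL on a step the patient survives floors
the step reward at 0 instead, so no episode can accumulate more than one
penalty and the cumulative-reward bounds hold exactly.

Three variants of the hypoglycaemic branch (40–70 mg/dL) are
implemented (`reward_spec()`):

* `original` — flat normalised reward down to 40, then the hard penalty;
* `linear_v1` — the reward on (40, 70] additionally multiplied by a
  0.5 linear decay ramp;
* `spline_v2` (default) — a cubic Hermite ramp from 0 at 40 mg/dL up to
  the normalised reward at 70 mg/dL with zero end slopes, i.e. a C¹
  join at both knots.

The spline's zero end slopes are a deliberate choice: the point of the
smoothing is to remove jump discontinuities ("mutation points") from the
reward signal, and zero boundary slopes give the flattest C¹ join to
both the penalty floor and the in-range plateau. The value of the
reward at 70 mg/dL is *computed* from the normalisation (≈ 0.922), not
assumed. Two textual conventions disagree on whether the penalty
applies at exactly 40 mg/dL; we resolve it per variant (`original`
penalises $g \le 40$, the spline is defined at exactly 40 and returns
0), a measure-zero difference.

## The virtual patient

No external simulator is required (and none is bundled): the package
ships a deliberately minimal synthetic patient so that every result is
reproducible from code. It is a Bergman-style minimal model with three
states — plasma glucose $G$, remote insulin effect $X$, gut
carbohydrate mass $D$:

$$\dot G = -p_1 (G - G_b) - X G + k_{abs} D\, c_g,\qquad
  \dot X = \frac{s_x (u - u_b) - X}{\tau_I},\qquad
  \dot D = -k_{abs} D,$$

integrated by fixed-step RK4 at 1-minute substeps inside each 5-minute
control step (stiff-free dynamics; deterministic tests). Defaults
(`patient_params()`): basal glucose 140 mg/dL, glucose effectiveness
0.01/min, insulin-action delay 50 min, gut absorption 0.02/min, TDI
50 U/day with the basal rate $0.48\cdot TDI/1440$, insulin sensitivity
36 (mg/dL)/U (the 1800 rule at TDI 50), carb potency tied to the 500
rule. With these values basal insulin holds glucose at basal, a 50 g
meal peaks roughly 90 mg/dL above basal about 70 minutes after eating,
and a few steps of maximal infusion cause severe hypoglycaemia — the
qualitative behaviours a glucose controller must handle. The CGM adds
i.i.d. Gaussian noise (SD 5 mg/dL, a realistic consumer-sensor error;
no autocorrelated drift), clamped at 1 mg/dL. The child preset only
raises insulin sensitivity and lowers weight/TDI; it makes no claim of
paediatric fidelity.

Meals follow the canonical plan 07:00/40 g, 12:00/80 g, 19:00/60 g.
`meal_scenario()` adds disturbances: portion jitter (multiplier within
±30 %), meal-time jitter, and 1–3 random snacks. Because "time jitter of
±20–30 %" is ambiguous (percent of what?), time jitter is expressed as a
fraction of a 100-minute window, so 0.3 means a uniform shift within
±30 minutes — configurable if a different convention is wanted. The four
benchmark scenarios (`dietary_scenarios()`): fixed, fluctuating
portion, fluctuating time, random snacks.

## Learners

All three learners (`agent_init()`) share one recurrent feature
extractor: a 2-layer LSTM with 16 hidden units over the scaled
12-step window; the final hidden state feeds small tanh MLP heads.
Gradients from *both* the actor and critic losses flow into the shared
encoder (verified by finite differences in the tests).

* **PPO** (primary): squashed-Gaussian policy (tanh with log-density
  correction), state-independent log-σ, GAE ($\gamma = 0.99$,
  $\lambda = 0.95$), clipped surrogate with $\varepsilon = 0.2$, critic
  fit by halved squared error.
* **DDPG**: deterministic tanh actor, single Q critic, target copies
  with Polyak rate 0.005, Gaussian exploration noise.
* **SAC**: state-dependent (μ, log σ) head, twin Q critics with twin
  targets, fixed entropy temperature 0.2, reparameterised actor update.

γ, λ, ε, the soft-update rate, replay capacity and the entropy
temperature are not dictated by the study conditions; the defaults above
are the values standard in the continuous-control literature, and all
are exposed in `learner_config()`.

Batch size 1024, 12-step history, LSTM 2×16, encoder layer count 1,
4 attention heads, embedding 64 and feed-forward width 128 follow the
study's tuned configuration. The learning rate follows a linear warm-up
over the first 20 000 steps to 3×10⁻⁴; afterwards a cosine envelope
multiplied by 0.998 per training iteration (one iteration = 10 simulated
days = 2880 steps), floored at 1 % of the target rate. The prescription
"cosine annealing with a 0.998 decay coefficient" mixes two decay
families; multiplying the cosine envelope by the geometric factor
honours both pieces and remains monotone, and the schedule is
configurable if another reading is preferred.

All neural components are implemented in the package itself (vectorised
R for training with hand-derived gradients, compiled C++ for the
inference-only forward passes). The two routes are asserted equal to
machine precision in the tests, and every backward pass is checked
against central finite differences.

## The glucose predictor and the auxiliary buffer

Transitions (window, action, next true glucose) generated during RL
interaction accumulate in a bounded auxiliary buffer; when it reaches
its trigger threshold (default 5000 samples, retraining every further
5000 — the threshold is not dictated by the study conditions) the
one-step forecaster is (re)trained. The forecaster embeds the 12
(glucose, insulin) tokens plus an action token (64-dim embeddings,
learned positions), runs one self-attention encoder layer (4 heads,
feed-forward 128) and maps the action-token output to the mean and
log-variance of the next glucose, parameterised as a residual on the
last observed glucose in 50 mg/dL units. Training minimises the
Gaussian negative log-likelihood rather than plain squared error because
the variance is consumed downstream (rollout sampling); the reported
gate metric stays RMSE in mg/dL on a held-out 20 % split — held-out
rather than training error, since the gate exists to certify
generalisation.

Prob-sparse attention (top-u queries by the max-minus-mean score, mean
value for the rest) is selectable; at sequence length 13 it is
near-identical to dense attention (and exactly identical when u covers
all queries, which the tests assert), so dense is the default.

The MPC stage activates through a latched gate when the held-out RMSE
drops to 15 mg/dL, with a 2 mg/dL hysteresis so borderline retrainings
do not toggle the planner on and off.

## MPC screening and the safety controller

Once the gate is active, each decision runs 30 rollouts of horizon 6
(30 minutes) through the predictor: actions are sampled from the
stochastic policy (that is where candidate diversity comes from), each
predicted glucose feeds back as the next pseudo-state, and per-step
rewards accumulate. A trajectory is marked unsafe if any *predicted
mean* falls strictly below 54 mg/dL — the mean, not a sample, so that an
optimistic draw can never unmark a dangerous candidate; samples are used
only to diversify the reward accumulation. (An alternative wide preset
marks outside (70, 250) mg/dL; the two thresholds coexist in the source
material and the hard 54 filter from the algorithm description is the
default.) The best safe trajectory by cumulative reward supplies the
executed first-step action; ties break deterministically to the lowest
trajectory index.

If *no* trajectory is safe, the analytic safety controller takes over
and rescales the policy's insulin rate by

$$cf = \mathrm{coef} \times \frac{obs_0}{112.517} \times
      \Bigl(\frac{obs_0}{obs_1}\Bigr)^2,$$

with $obs_0, obs_1$ the current and previous CGM readings: above the
zero-risk glucose and rising ⇒ $cf > 1$ (more insulin), below and
falling ⇒ $cf < 1$. The nocturnal coefficient is 0.8 between 20:00 and
23:00 and 0.6 between 00:00 and 03:00; below 54 mg/dL the coefficient is
forced to 0 (full suspension). The correction is applied
multiplicatively to the insulin *rate* (not the pre-transform action),
because it is a dosage adjustment factor. Planner- and safety-selected
actions are queued as imitation targets, and the negative log-likelihood
of those actions under the current policy is added to the PPO loss with
weight 0.5 (config-exposed; the weight is a package choice). Safety-
controller actions are imitated by default — they are exactly the
conservative behaviour the policy should internalise — with a switch to
exclude them.

## Evaluation

`time_in_ranges()` reports the five clinical bins (TBR2 < 54,
TBR1 54–<70, TIR 70–180, TAR1 >180–250, TAR2 > 250 mg/dL; ties assigned
to the less severe bin so the bins partition exactly), `lbgi_hbgi()`
the low/high risk indices whose sum is the mean risk index, and
`scenario_suite()` the four-scenario benchmark with per-scenario
glycemic reports. Metrics are computed on CGM readings by default (what
a clinic sees), with a switch for true glucose. Paired t tests compare
matched evaluation runs.

## Reproducibility and problem sizes

One run seed fans out to named per-component streams (environment,
policy, planner, predictor), so ablating one component does not perturb
the draws of another; noise-free runs are bit-identical. The package's
own test and acceptance workloads use desk-scale budgets chosen to
exercise every mechanism end to end: 20 000-step training runs over
three seeds for the learning-speed comparison, ~10 000 auxiliary
transitions for predictor training, 20 matched episodes for the
safety-dominance check, and 100-episode evaluations in the scenario
harness. Full-scale runs (400 000 steps per patient, three seeds,
per-patient models) use the same code paths via `learner_config()` and
`run_config()`.

## What the synthetic patient does and does not show

The virtual patient reproduces the qualitative control landscape —
meal excursions, delayed insulin action, noise-corrupted observations,
overdose-induced hypoglycaemia — but it is far milder than a
UVA/Padova-class simulator: its dynamics are low-dimensional and
time-invariant, absorption is single-compartment, there is no
intra-patient variability, exercise, stress, sensor drift or pump
faults. Consequently absolute clinical numbers here (e.g. near-100 %
TIR for the basal-bolus baseline) exceed what any controller achieves
on realistic physiology, and passing tests demonstrate *mechanism
correctness and relative behaviour* (screening reduces hypoglycaemia;
guidance accelerates learning), not clinical performance. An adapter
contract (`env_reset()`/`env_step_insulin()` plus the controller
interface) lets the same controllers run against an external simulator
unchanged.

## Known limitations

* The deterministic tie-break and the strict-below-54 marking convention
  are package decisions where the source conventions are silent.
* At the desk-scale 20 000-step budget the hybrid policy still spends
  appreciable time between 54 and 70 mg/dL in frozen-policy evaluation:
  the hard screen only vetoes candidates predicted below 54 mg/dL, and
  correcting the remaining mild-hypoglycaemia preference is the slow
  part of policy learning. Training-curve comparisons (the package's
  acceptance property) are unaffected; absolute clinical numbers at
  this budget should not be over-read.
* DDPG and SAC are implemented as baselines and tested for contract
  correctness and bandit-scale convergence, not tuned for the glucose
  task.
* The imitation queue stores at most 512 recent pairs; very long gaps
  between PPO updates can therefore forget early guidance.
* `paired_t()` requires non-degenerate differences and refuses
  zero-variance input rather than returning NaN.

## A worked example

```{r example, eval = FALSE}
library(glucontrol)

# train the hybrid controller on the default adult patient (short run)
fit <- train_controller("ppo_mpc", n_train_steps = 20000, seed = 1)
print(fit)

# evaluate 20 one-day episodes on the fixed-meal scenario
traces <- simulate(fit, nsim = 20, seed = 99)
glycemic_report(traces)

# clinical baseline on the same patient
bbi <- scenario_suite(bbi_controller(), n_episodes = 20, seed = 99)
report_table(list(bbi = bbi))
```
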
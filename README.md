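# glucontrol

Hybrid closed-loop insulin dosing for type 1 diabetes: deep
reinforcement learning screened by model-predictive safety rollouts.

## The problem

An artificial pancreas couples a continuous glucose monitor (CGM,
5-minute samples with sensor noise) to an insulin pump through a control
algorithm. Reinforcement learning can control glucose without meal
announcements or a patient-specific physiological model, but its
trial-and-error exploration is unacceptable on a safety-critical organ
system: an untrained policy overdoses insulin. This package implements,
end to end, a hybrid controller that keeps the adaptivity of
reinforcement learning while containing its unsafe exploration:

1. **Recurrent PPO agent** — a shared 2-layer LSTM (16 units) encodes
   the last 12 paired (CGM, insulin) samples; a squashed-Gaussian policy
   emits actions `a ∈ [-1, 1]` mapped to pump rates by
   `I = Imax · exp(τ(a − 1))` (`Imax = 5` U/min, `τ = 4`). DDPG and SAC
   baselines share the same encoder contract.
2. **Learned glucose forecaster** — transitions harvested during
   training feed a self-attention encoder (1 layer, 4 heads, embedding
   64) with a Gaussian head predicting the next-step glucose mean and
   variance.
3. **MPC safety screen** — once the forecaster's held-out RMSE reaches
   15 mg/dL, every decision is screened: 30 policy rollouts of horizon 6
   (30 min) through the forecaster; any trajectory whose predicted
   glucose dips below 54 mg/dL is marked unsafe; the best safe
   trajectory's first action is executed and fed back to the policy
   through an imitation loss.
4. **Safety controller fallback** — if no trajectory is safe, the
   insulin rate is rescaled by
   `cf = coef · (obs0/112.517) · (obs0/obs1)²` (nocturnal `coef` 0.8
   from 20:00–23:00, 0.6 from 00:00–03:00), with full suspension below
   54 mg/dL.

The per-step reward is the Kovatchev risk index
`risk(g) = 10·(1.509·((ln g)^1.084 − 5.381))²` (zero at 112.517 mg/dL)
normalised into [0, 1], with a cubic-spline ramp over the 40–70 mg/dL
hypoglycaemia band and a −15 terminal penalty below 40 mg/dL; a one-day
episode (288 steps) has cumulative reward in [−15, 288].

A synthetic virtual patient (Bergman-style minimal model, RK4 at 1-min
substeps, meal disturbances, noisy CGM) makes everything reproducible
from code, and a basal–bolus (BBI) clinical baseline
(`BR = 0.48·TDI`, `CIR = 500/TDI`, `ISF = 1800/TDI`, 20-min meal
announcements) plus TIR/TBR/TAR + LBGI/HBGI metrics complete the
evaluation suite. See the vignette
(`vignettes/hybrid-closed-loop-control.Rmd`) for the models, parameter
choices and limitations.

## A worked example

```r
library(glucontrol)

fit <- train_controller("ppo_mpc", n_train_steps = 20000, seed = 1)
print(fit)
#> <glucontrol_agent> algo=ppo_mpc, trained 20000 steps, 424 episodes
#>   final training reward (last 10 ep): 281.3
#>   predictor RMSE 4.62 mg/dL, MPC gate active
#>   action provenance: rl 0.25, mpc 0.70, safety 0.05

traces <- simulate(fit, nsim = 20, seed = 99)
glycemic_report(traces)
#> Glycemic report over 20 episode(s)
#>   TBR2  11.02%  TBR1  19.79%  TIR  68.99%  TAR1   0.19%  TAR2   0.00%
#>   LBGI  6.334  HBGI  0.120  reward  238.30 +/- 34.35
```

Reading the output: the controller was trained for 20 000 environment
steps (about 70 simulated days, a desk-scale budget; full runs use
400 000). The glucose forecaster converged to a 4.6 mg/dL held-out
error, so the MPC screen handled 70 % of decisions (`mpc` provenance)
with the rule-based fallback taking over on 5 %; the last training
episodes approach the 288 cumulative-reward ceiling. The frozen policy
evaluated on fresh episodes holds glucose in or below the target band
with essentially no hyperglycemia; the residual time below 70 mg/dL is
what a 70-day budget leaves uncorrected — the hard safety screen only
vetoes candidates predicted below 54 mg/dL. For comparison, the
basal–bolus baseline on the same episode seeds —

```r
bbi <- lapply(1:20, function(e)
  run_episode(patient_env(), bbi_controller(),
              seed = derive_seed(99, paste0("sim", e))))
glycemic_report(bbi)
#> Glycemic report over 20 episode(s)
#>   TBR2   0.00%  TBR1   0.00%  TIR 100.00%  TAR1   0.00%  TAR2   0.00%
#>   LBGI  0.028  HBGI  2.202  reward  281.58 +/- 0.14
```

— is near-perfect here because it receives 20-minute meal announcements
and the synthetic patient is far milder than real physiology (see the
vignette's limitations section); the fully closed-loop controller gets
no announcements at all. `scenario_suite()` runs the same comparison
under the four dietary-disturbance scenarios.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/glucontrol.R train --config run.yaml
Rscript inst/cli/glucontrol.R evaluate --config run.yaml --checkpoint ckpt.rds
Rscript inst/cli/glucontrol.R compare --rewards a.csv,b.csv
```

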
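# socialFT

Forward-thinking models of social controllability in iterated ultimatum
games.

## The problem

In repeated social exchange, a responder's current choice can shape what
partners offer next: rejecting a low offer can act as negotiation pressure,
accepting it can invite lower offers. `socialFT` is for computational
cognitive modellers who want to study how people *estimate and exploit*
that controllability. It implements:

- the two-condition task environment — a **Controllable** block in which
  rejecting raises and accepting lowers the partner's next offer by $0–2
  (probability ⅓ each, offers clamped to $1–$9), and an **Uncontrollable**
  block whose offers are choice-independent (a rounded truncated Gaussian,
  μ = $5, σ = $1.2, clipped to $2–$8, or a fixed 30-offer list);
- an n-step **forward-thinking (FT) responder model** (horizons 0–4);
- per-subject bounded maximum-likelihood fitting, information-criterion
  comparison across planning horizons, and choice-prediction accuracy;
- parameter- and model-recovery pipelines on synthetic agent cohorts;
- model-agnostic behavioral summaries (mean offers, trajectories,
  rejection rates binned low $1–3 / medium $4–6 / high $7–9) with Welch /
  paired t-tests.

## The model

On trial *i* the responder sees offer *s_i* (a split of $20), holds an
internal fairness norm *f* updated by a Rescorla–Wagner rule

    f_i = f_{i-1} + ε (s_i − f_{i-1}),

and values accepting as the money received minus an envy penalty,

    U(s, f) = s − α · max(f − s, 0),      U(reject) = 0.

An n-step planner augments the current utility with a single deterministic
greedy rollout of future trials: a simulated rejection raises the imagined
next offer by the **expected influence** δ (no ceiling), a simulated
acceptance lowers it by δ (floored at $1), future actions are greedy
(accept iff utility > 0), and future utilities are discounted by γ = 0.8:

    v(a_i) = U_i + Σ_{j=1..n} γ^j · U(simulated trial i+j)
    Q_i = v(accept) − v(reject),    P(accept) = 1 / (1 + e^{−β Q_i}).

Free parameters (all estimated through scaled-sigmoid transforms):
β ∈ [0, 20] inverse temperature, α ∈ [0, 1] norm-violation sensitivity,
f₀ ∈ [0, 20] initial norm, ε ∈ [0, 1] adaptation rate, δ ∈ [−2, 2]
expected influence. Fitting uses the middle trials only (first and last
five excluded; 30 of 40, or 20 of 30).

## Worked example

```r
library(socialFT)

# one synthetic agent in the controllable condition
agent <- ft_params(beta = 8, alpha = 0.76, f0 = 8.2, eps = 0.24,
                   delta = 1.33, n_steps = 2)
session <- run_session(ft_policy(agent), env_config("controllable", 40),
                       subject_id = "s01", seed = 7)
session
#> <session_data> subject s01, controllable, 40 trials, 48% accepted

# refit the 2-step model to the middle 30 trials
fit <- fit_subject(session, n_steps = 2, config = fit_config(n_restarts = 20))
fit$params_hat
#> <ft_params> beta=20 alpha=1 f0=5.36e-16 eps=0.703 delta=1.24 (gamma=0.8, 2-step)
round(c(neg_loglik = fit$neg_loglik, dic = fit$dic, accuracy = fit$accuracy), 3)
#> neg_loglik        dic   accuracy
#>      0.485      8.786      1.000
```

The fitted expected influence (δ̂ = 1.24) is close to the generating value
(1.33): this agent's tendency to reject in order to raise future offers is
identifiable from 30 choices. The other utility parameters land on a
likelihood plateau (many (β, α, f₀) combinations reproduce the same
near-deterministic choices), which is why recovery studies below focus on
δ. `export_value_regressors(session, fit$params_hat)` then yields the
trial-level (z-scored) total value of the chosen action with its
current/future decomposition, the norm, and the norm prediction error —
the quantities used as parametric modulators in model-based neural
analyses.

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline on
synthetic cohorts and write their tables under `results/`:

1. `01_simulate_cohort.R` — 48 FT agents per condition, 40-trial blocks,
   parameters drawn from the published group moments (`published_moments()`).
2. `02_behavioral_analysis.R` — mean offers, trajectories, binned
   rejection rates, Welch tests between conditions.
3. `03_fit_horizons.R` — fits horizons 0–4 and compares penalized fit
   (DIC) per horizon; on 2-step-generated cohorts the 2-step model wins
   and deeper planning adds nothing, mirroring the published ordering.
4. `04_parameter_recovery.R` — simulate → refit → correlate generating
   with recovered parameters.
5. `05_value_regressors.R` — trial-level value-regressor export for all
   recovered subjects.

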
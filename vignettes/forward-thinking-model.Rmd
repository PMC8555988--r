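---
title: "Forward-thinking models of social controllability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward-thinking models of social controllability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialFT)
```

## The task and what the package models

`socialFT` models the responder in an iterated ultimatum game played
against a social environment that is either controllable or not. On every
trial a partner proposes a split of \$20; the responder accepts (split
enacted) or rejects (both sides get nothing). In the **Controllable**
condition the responder's choice moves the next offer: rejecting raises it
and accepting lowers it by \$0, \$1 or \$2 with probability 1/3 each,
clamped to \$1–\$9, starting at \$5. In the **Uncontrollable** condition
offers are exogenous — drawn on the fly from a Normal(\$5, \$1.2), rounded
to the nearest dollar and clipped to \$2–\$8 (laboratory variant, also
starting at \$5), or presented as a shuffled fixed list of 30 offers with
mean \$5.0 and SD \$2.3 (online variant). Blocks are 40 trials
(laboratory) or 30 (online).

## The choice model

The responder carries an internal fairness norm $f$, initialized at a free
parameter $f_0 \in [0, 20]$ and updated after observing each offer $s_i$
by a Rescorla–Wagner rule with adaptation rate
$\varepsilon \in [0, 1]$:

$$f_i = f_{i-1} + \varepsilon\,(s_i - f_{i-1}).$$

The norm prediction error $s_i - f_{i-1}$ is the learning signal. Utility
is money minus an envy-only penalty for offers below the norm, scaled by
the norm-violation sensitivity $\alpha \in [0, 1]$:

$$U(s, f) = s - \alpha \max(f - s, 0), \qquad U(\text{reject}) = 0.$$

Rejection yields exactly zero — the known consequence of rejecting — so no
aversion term applies on that branch.

An $n$-step forward thinker values each current action by adding a mental
simulation of the next $n$ trials along a **single deterministic greedy
path**. The simulated environment is governed by the expected influence
$\delta \in [-2, 2]$: a (simulated) rejection raises the imagined next
offer by $\delta$ with no ceiling, a (simulated) acceptance lowers it by
$\delta$, floored at \$1. Simulated future actions are greedy — accept iff
the acceptance utility is strictly positive, with a tie at exactly zero
resolved to reject — and future utilities are discounted by
$\gamma^j$:

$$v(a_i) = U_i(a_i) + \sum_{j=1}^{n} \gamma^j\,
  U(\hat{s}_{i+j}, f_i), \qquad
  Q_i = v(\text{accept}) - v(\text{reject}),$$

with the acceptance probability given by a softmax with inverse
temperature $\beta \in [0, 20]$:
$P_i(\text{accept}) = 1/(1 + e^{-\beta Q_i})$. The horizon $n$ ranges over
0 (no forward thinking, pure norm adaptation) to 4.

### Parameters at a glance

| parameter | meaning | units | range | default handling |
|---|---|---|---|---|
| $\beta$ | inverse temperature | — | $[0, 20]$ | fitted |
| $\alpha$ | norm-violation sensitivity | — | $[0, 1]$ | fitted |
| $f_0$ | initial norm | dollars | $[0, 20]$ | fitted |
| $\varepsilon$ | norm adaptation rate | — | $[0, 1]$ | fitted |
| $\delta$ | expected influence | dollars/trial | $[-2, 2]$ | fitted |
| $\gamma$ | temporal discount | — | fixed $0.8$ | fixed |
| $n$ | planning horizon | trials | $\{0,\dots,4\}$ | compared by DIC |

$\delta$'s range matches what a responder could actually observe in the
controllable condition (\$0–2 per choice) and mirrors it on the negative
side. $\gamma$ is fixed to avoid collinearity with $\delta$ — both scale
the weight of simulated futures.

## Design choices where the design was open

**Norm-update timing.** The package updates the norm with the current
offer *before* computing that trial's utilities (the indexing of the
update rule reads most naturally that way), so trial $i$ is valued against
$f_i$. The alternative — value against $f_{i-1}$, update afterwards — is
available via `norm_timing = "after"` in every relevant function. The norm
prediction error is always $s_i - f_{i-1}$ regardless of timing.

**Norm frozen during rollout.** All simulated future utilities are
evaluated against the trial's norm $f_i$. A within-rollout norm update
(each hypothetical offer also updating the simulated norm) is available as
`rollout_norm_update = TRUE` for sensitivity analysis; it is off by
default because the valuation sums future utilities against the current
norm.

**Boundary handling in the controllable rule.** The step is sampled first
and the resulting offer clamped into \$1–\$9, rather than renormalizing
the step distribution over feasible steps at the boundaries. At \$9 a
rejection therefore leaves the offer at \$9 with probability 1.

**Gaussian truncation.** Offers are rounded first, then clipped into
\$2–\$8 (not redrawn). The resulting distribution is symmetric about \$5,
so the generator's mean offer is \$5 by construction; empirical samples of
human-facing runs need not match it.

**Hypothetical offers are unbounded above and may go below zero.** The
simulated reject branch has no ceiling (a responder has no evidence the
environment caps offers until offers hit the cap repeatedly) and, when
$\delta < 0$, can drive imagined offers below zero; the utility function
accepts any real offer for that reason. Only the simulated accept branch
is floored, at \$1.

**Ties.** Simulated greedy actions use a strict inequality: utility
exactly zero simulates a rejection. Choice prediction uses the same
convention: predicted accept iff $P(\text{accept}) > 0.5$.

## Estimation

Fitting is per-subject maximum likelihood. Each of the five free
parameters is mapped from an unconstrained real through a scaled logistic,
$\theta = \mathrm{lo} + (\mathrm{hi} - \mathrm{lo})\,
\mathrm{logistic}(x)$, and the negative log-likelihood of the observed
choices is minimized by Nelder–Mead (derivative-free; the max and
indicator terms in the rollout make the surface piecewise-smooth) from 20
Latin-hypercube start points, keeping the best restart. The spread of
restart optima is returned as a multimodality diagnostic.

The likelihood iterates every trial in order — the norm learns through
excluded trials too — but scores only the middle trials, dropping the
first five (contingency still being learned) and the last five
(end-of-block incentives differ). A 40-trial block contributes 30 fitted
trials; a 30-trial block, 20.

Numerical safeguards: the softmax is evaluated with `plogis` (no overflow
at $\beta |Q|$ in the hundreds), per-trial probabilities are floored at
$10^{-12}$ before the log, and the unconstrained optimum is clipped to
$\pm 36$ where the logistic has saturated in doubles.

Planning horizons are compared by a penalized fit score,
$2\,\mathrm{negLL} + k(\ln n_\mathrm{trials} - \ln 2\pi)$ with $k = 5$,
computed per subject and compared across horizons by paired t-tests. The
additive convention is isolated in `dic_score()`; horizon orderings do not
depend on it.

## The synthetic cohort generator

`simulate_cohort()` draws agents from per-parameter normal distributions
truncated to the model bounds (inverse-CDF sampling, so cohorts are
bit-reproducible under a seed) and plays each agent through the task, with
choices sampled from the agent's own softmax probabilities. The default
moments are the published group-level estimates of the 2-step model
(`published_moments()`), i.e. the generator emulates a cohort that behaves
like the fitted study population: 48 agents, 40-trial blocks, Controllable
cohorts whose offers are driven up by high-$\delta$ agents, Uncontrollable
cohorts with exogenous offers.

What it deliberately does **not** emulate: correlations between
parameters across subjects (draws are independent), emotion ratings,
self-reported controllability, reaction times, and any guarantee that
behavioral aggregates (e.g. mean received offer) match the human data —
passing recovery tests on these cohorts demonstrates identifiability of
the model on data *generated by the model*, not model validity for human
behavior.

Agents who accept or reject everything in a block ("flat responders") are
excluded from recovery correlations and counted, mirroring the study's
data-cleaning rule for online participants.

## Problem sizes and what the checks show

The test suite validates the rollout against an independently coded
recursive enumerator (1,000 random states across horizons 0–4, agreement
to $10^{-10}$), the collapse of all horizons onto the myopic value when
$\delta = 0$, the softmax and norm-update identities, the offer-range
invariants of both environments, and the exact occupancy-weighted
decomposition of rejection rates into offer bins.

End-to-end identifiability checks run at the study's scale: 48-agent
cohorts per condition, 20-restart fits, with the expected-influence
recovery correlation estimated as the mean over two replicate cohorts.
Typical values are $r \approx 0.74\text{–}0.89$ (Controllable) and
$r \approx 0.70\text{–}0.80$ (Uncontrollable). Model recovery
(16-agent cohorts, horizons $\{0, 2\}$) confirms that 2-step-generated
cohorts are better fit by the 2-step model than the 0-step model. The
long-session consistency check uses a single 2,000-trial stress session;
the near-deterministic identifiability check uses eight 1,000-trial
sessions.

## Known limitations

- **Weak identifiability of the static utility parameters at 30 fitted
  trials.** $\alpha$ and $f_0$ recover poorly (correlations near zero to
  0.3 on 48-agent cohorts): with few trials and an evolving norm, many
  $(\beta, \alpha, f_0)$ combinations produce near-identical choice
  probabilities. $\delta$ and $\beta$ carry most of the recoverable
  signal.
- **Likelihood plateaus for near-deterministic subjects.** When a
  subject's choices are perfectly explained (accuracy 1), the likelihood
  is flat over an interval of parameter sets reproducing those choices and
  the fitted point within that interval is arbitrary — occasionally at a
  bound. This caps recovery correlations even for long sessions and is a
  property of bounded MLE on deterministic data, not of the optimizer.
- **Recovery depends on the generating distribution.** Independent
  truncated normals at the published group moments are a declared stand-in
  for the study's fitted subjects; recovery correlations computed under
  them scatter around, and slightly below, the published values.
- **The generator does not reproduce human aggregate behavior.**
  Simulated Controllable cohorts at the default moments do not necessarily
  raise offers as strongly as human participants did; the monotone
  relation between $\delta$ and mean received offer holds, the levels are
  not calibrated.
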
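---
title: "Modelling advice-taking with delta-rule reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling advice-taking with delta-rule reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In the two-card advice task a participant repeatedly chooses between a
green and a blue card. One card is correct on every trial; the probability
that it is the green card alternates between 0.7 and 0.3 across blocks of
twenty trials, so the learner faces both outcome noise within a block and
unsignalled reversals between blocks. Before every choice a computerised
adviser recommends a card, and the adviser is right on a fixed 60% of
trials. The recommendation is phrased either positively (reward-focused)
or negatively (loss-focused), interleaved within a session, and the
outcome structure of the task — its frame — either mixes rewards and
losses, offers reward-or-nothing (gain frame), or nothing-or-loss (loss
frame).

The question the package addresses is *how much weight people give the
advice, and how that weight depends on phrasing and frame*. Because simple
advice-following rates conflate advice use with self-learning, the weight
is estimated inside a generative cognitive model fitted to the
trial-by-trial choices.

## The model family

Two delta-rule learners run in parallel. The self-learner tracks card
values: after choosing card $i$ and receiving frame-coded reward $R^c_t$,

$$V^c_{t+1}(i) = V^c_t(i) + \alpha_c \,\bigl(R^c_t - V^c_t(i)\bigr),$$

and the advice-learner tracks the value of following versus not following
the adviser, driven by the observed correctness of the advice
($R^a_t = +1$ when the advised card was correct, $-1$ otherwise):

$$V^a_{t+1}(F) = V^a_t(F) + \alpha_a \,\bigl(R^a_t - V^a_t(F)\bigr).$$

Advice correctness is revealed by feedback on every trial whether or not
the advice was followed, so the advice values update unconditionally.
Each channel is turned into a choice probability by a softmax with its own
inverse temperature,

$$P_c = \mathrm{logistic}\bigl(\tau_c (V^c(G) - V^c(B))\bigr), \qquad
  P_a = \mathrm{logistic}\bigl(\tau_a (V^a(F) - V^a(U))\bigr),$$

and the two are mixed by the advice reference weight $\omega \in [0,1]$:

$$P(\text{green}) = \omega A + (1 - \omega)\, P_c,$$

where $A = P_a$ when the advised card is green and $1 - P_a$ otherwise.
$\omega$ and $\alpha_a$ are indexed by the trial's phrasing condition;
$\alpha_c$, $\tau_c$ and $\tau_a$ are shared within a participant. The
model family crosses two structural options per channel:

* **fictitious updating** — because exactly one card is correct per
  trial, the unchosen card's counterfactual outcome is known and can be
  learned from simultaneously;
* **asymmetric learning rates** — separate rates for positive and
  negative prediction errors.

The eight members M1, M2a–c, M3a–c and M4 are listed in
`?model_spec`; M4 (fictitious + asymmetric self-learning, fictitious
advice-learning) is the winning model in the analyses this package
reproduces.

### The signed combination variant

A literal signed combination rule,
$P(\text{green}) = \beta\,\omega P_a + (1-\omega) P_c$ with $\beta = -1$
for blue advice, produces values outside $[0,1]$ whenever the advice
channel is confident and points to blue. A generative model must emit
valid probabilities, so the package's default (`combination_mode =
"normalized"`) redirects the advice channel's probability mass toward the
advised card; the two rules coincide exactly whenever the advice points to
green. The literal rule is retained (`"literal_clipped"`, clipped into
$[10^{-6}, 1-10^{-6}]$) for fidelity experiments, and is not used by any
default.

### Frame coding

| frame | reward correct | reward incorrect | $V^c$ init | counterfactual |
|-------|----------------|------------------|-----------|----------------|
| mixed | $+1$ | $-1$ | $0$ | $-R$ |
| gain  | $+1$ | $0$  | $0.5$ | $1 - R$ |
| loss  | $0$  | $-1$ | $-0.5$ | $-1 - R$ |

Advice outcomes are coded $\pm 1$ with advice values initialised at 0 in
all frames. The counterfactual rules follow from the one-correct-card
structure. Ties ($\mathrm{PE} = 0$, possible only in the gain and loss
frames) use the negative-PE learning rate; this is a fixed convention
with no measurable consequence under $\pm 1$ advice coding.

## Hierarchical estimation

Individual parameters are drawn from group-level truncated normal
distributions with weakly informative hyperpriors: group means uniform
over the parameter bounds ($[0,1]$ for learning rates and weights,
$[0,3]$ for inverse temperatures), group standard deviations half-Cauchy
with scale 1 (scale 3 for temperatures). Condition-specific parameters
($\omega$, $\alpha_a$) get independent group-level distributions per
phrasing condition; frame groups are fitted as separate hierarchical
models, matching the between-subjects design.

The posterior is sampled by an adaptive Metropolis-within-Gibbs scheme
implemented in C++:

* every individual parameter is updated by a bounded Gaussian random walk
  or, with probability one half, an independence proposal from its own
  truncated-normal population distribution (the population terms cancel,
  so acceptance depends only on the likelihood — this decorrelates weakly
  identified parameters quickly);
* group means and sds are updated by random walks and by independence
  draws from their priors;
* two joint moves handle the hierarchical funnel: a *translation* move
  shifts a group mean together with all its individual values, and a
  *scale* move rescales a group sd together with all individual
  deviations. Both are plain Metropolis moves with the appropriate
  Jacobians and truncation-mass corrections;
* asymmetric-rate models have a mirrored posterior mode in which the
  positive- and negative-PE rates trade roles (nearly equivalent when the
  true asymmetry is weak). Dedicated *exchange* moves propose swapping
  the paired rates — for one participant at a time and for the whole
  hierarchy at once — so chains traverse both modes instead of sticking
  in one.

Proposal scales adapt toward 44% acceptance during warmup and are frozen
afterwards. `n_iterations` counts *stored* draws per chain; between
stored draws the chain advances `thin` full sweeps (default 25). At the
default thinning the stored draws are nearly independent, so the split
Gelman–Rubin statistic (`rhat()`, computed on half-chains; exactly 1 for
draws constant across chains) sits at its estimator noise floor. The
reference configuration is 4 chains of 4,000 stored iterations with the
first half discarded; the convergence bar is $\hat R < 1.01$ everywhere.
Reduced runs (2 chains, 1,000–2,000 stored iterations) are adequate for
recovery studies and are what the test suite uses.

A practical note on reading $\hat R$ at reduced scale: with 2 chains of
500 retained draws the *maximum* split-$\hat R$ across a hundred-plus
parameters has a noise floor around 1.008 even for perfectly independent
draws, so convergence checks in the tests retain 1,000 draws per chain,
where the floor drops to about 1.004.

All randomness flows through R's RNG: a fit is a deterministic function
of the data and the `sampler_config()` (including its seed).

## Synthetic cohorts

`generate_cohort()` mirrors the hierarchical structure: individual
parameters are truncated-normal around group means, each participant
plays one session on a freshly generated environment, and the ground
truth is stored alongside the simulated choices. Participant sub-seeds
are derived stably from the master seed, so enlarging a cohort never
reshuffles earlier participants.

`replica_configs()` returns cohorts calibrated to the reported
group-level posterior means of the winning model: a 38-participant
mixed-frame cohort with $\omega$ means 0.18 (positive phrasing) and 0.12
(negative), and 19/20-participant gain/loss cohorts whose $\omega$ means
encode the phrasing-by-frame crossover. Where only within-frame mean
differences are reported (gain: positive − negative = 0.212; loss:
negative − positive = 0.042), the absolute levels were fixed once so that
the reported main effects also hold: gain (0.30, 0.09), loss (0.26,
0.30). Self-learning rates and temperatures are not tabulated in the
reports, so representative mid-range values are used ($\alpha^+_c = 0.40$,
$\alpha^-_c = 0.30$, $\tau_c = \tau_a = 1.5$). Group sds default to 0.05
for rates and weights and 0.3 for temperatures — individual-level spread
is not reported anywhere, and these values keep most of the mass inside
the bounds while giving participants distinguishable parameters. The
advice learning-rate means are entered as printed (positive 0.46,
negative 0.48) even though the accompanying directional claim suggests
the two labels may be swapped at the source; no conclusion in this
package depends on that direction.

What the generator deliberately does *not* emulate: lapses, side or
colour biases, reaction times, fatigue or learning-to-learn across the
session, and any drift in adviser reliability. Passing recovery and
model-comparison tests on these cohorts therefore shows that the
estimation machinery works when the model class is correct — it cannot
certify the model class against real human data.

## Model comparison and validation

LOOIC is estimated by Pareto-smoothed importance sampling over per-trial
pointwise log-likelihoods (`psis_loo()`): per observation, the largest
20% of importance ratios are replaced by quantiles of a generalized
Pareto distribution fitted to them (profile-likelihood estimator with a
weak prior on the shape), weights are truncated at the raw maximum, and
tail shapes $k > 0.7$ trigger a warning. The implementation is checked
in the tests against the closed-form leave-one-out predictive of a
conjugate Bernoulli–Beta toy model. One trial (not one participant) is
the observation unit, matching the trial-wise granularity of the
posterior predictive check; `compare_models()` reports pairwise elpd
differences with standard errors from the pointwise terms.

The posterior predictive check re-simulates every participant on their
own recorded environment under sub-sampled posterior draws and compares
the across-participant mean green-choice rate per trial with a central
credible band (default 200 replicates, 95% band). Coverage — the
fraction of trials whose observed mean falls inside the band — is the
summary statistic; a fit whose advice weight is forced to zero on a
cohort generated with strong advice reliance visibly loses coverage.

## Condition-level statistics

`summarize_conditions()` computes per-participant accuracy and
advice-choice consistency by phrasing; `paired_t()` reports Cohen's
$d_z$ with a noncentral-$t$ confidence interval; `mixed_anova()` runs
the univariate mixed-design ANOVA (one within factor, optionally one
between factor) and reports partial $\eta^2$ with a noncentral-$F$
confidence interval — the reported $\eta^2$ flavour is partial, a
deliberate choice where reports leave the flavour unstated. With a
single frame the design degenerates to the one-factor repeated-measures
ANOVA, whose $F$ equals the squared paired-$t$ statistic (asserted to
$10^{-9}$ in the tests). Significance is fixed at two-sided 0.05 with no
multiplicity correction, matching the analyses being reproduced.
Zero-variance nonzero differences raise an error rather than returning
an infinite statistic, to surface misconfigured synthetic data early.

## Numerical choices

* Choice probabilities are floored at $10^{-12}$ before logs in the
  likelihood; the normalized combination rule needs no clipping.
* Truncated-normal draws use inverse-CDF sampling, so they respect the
  bounds exactly and are reproducible.
* The PE = 0 tie rule, the PSIS tail fraction (20%), the Pareto-$k$
  warning threshold (0.7), and the translation/scale move design are
  fixed, not tunable.

## Problem sizes used by the tests

The test suite favours small, fast configurations chosen as the smallest
sizes at which each property is informative: simulator fidelity at $10^4$
pooled trials; recovery and convergence on 20 agents × 100 trials with
2 chains × 1,000 retained draws; model recovery on five replicate
cohorts per generator at 2 chains × 600 stored draws; the
phrasing-effect replication on five 38-agent cohorts. The acceptance
script fits the full model to a 20-agent cohort with 4 chains × 600
retained draws each.

## Known limitations

* The advice weight is a trait-level constant per condition; state-based
  or time-varying advice evaluation is out of scope.
* Volatility-adaptive (Bayesian learner) models are deliberately not
  implemented; the package's scope is the simple delta-rule family.
* The Metropolis sampler is robust but not gradient-based; very large
  cohorts would benefit from HMC, at the cost of a heavyweight
  dependency.
* Between-frame comparisons fit separate hierarchical models per frame;
  a joint model with frame as a group-level covariate is not provided.
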
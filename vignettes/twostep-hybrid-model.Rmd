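---
title: "Hybrid model-based/model-free modelling of two-step choice behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid model-based/model-free modelling of two-step choice behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the scientific question

The two-stage Markov decision task ("two-step task") dissociates two modes
of instrumental control. On every trial a first-stage choice between two
stimuli leads probabilistically to one of two second-stage states — each
first-stage action reaches its associated state on 70% of trials (a
*common* transition) and the other state otherwise (*rare*). Each of the
four second-stage stimuli pays a unit reward with a probability that
drifts across trials as a bounded Gaussian random walk, forcing continuous
learning.

A *model-free* learner caches action values updated by reward prediction
errors and is blind to the transition structure: reward raises the
tendency to repeat the first-stage choice regardless of how the reward was
reached. A *model-based* learner evaluates first-stage actions by forward
planning over the known transition probabilities: a reward obtained after
a rare transition favours *switching*, because the rewarded state is more
reliably reached through the other first-stage action. Human behaviour
mixes both, and the mixture weight is a target for pharmacological
manipulation (e.g. dopaminergic drugs in a within-subject crossover).
This package provides the full computational pipeline for such studies:
the generative task environment, the hybrid model family, trial-by-trial
likelihoods with hierarchical estimation, the stay–switch behavioural
analysis, and synthetic cohorts for parameter-recovery validation.

## The hybrid model

Second-stage action values $Q_2(s, a)$ are learnt by a delta rule from the
reward prediction error $\delta_2 = r - Q_2(s_2, a_2)$ with learning rate
$\alpha$. First-stage model-free values follow a SARSA-style rule: the
stage-one error $\delta_1 = Q_2(s_2, a_2) - Q_{MF}(a_1)$ updates
$Q_{MF}(a_1)$ with rate $\alpha$, and the second-stage error is passed
back with an eligibility constant $\lambda$,

$$ Q_{MF}(a_1) \leftarrow Q_{MF}(a_1) + \alpha\,\delta_1
   + \lambda\,\alpha\,\delta_2 . $$

Model-based first-stage values are computed by forward evaluation,

$$ Q_{MB}(a) = P(\text{common})\max_{a'}Q_2(S(a), a')
  + (1 - P(\text{common}))\max_{a'}Q_2(\bar S(a), a') , $$

where $S(a)$ is the state commonly reached by $a$. The two are mixed by
the model-based weight $\omega$,
$Q(a) = \omega Q_{MB}(a) + (1-\omega) Q_{MF}(a)$, and the first-stage
choice follows a softmax with inverse temperature $\beta$ and an additive
perseveration bonus $\pi$ for repeating the previous first-stage choice:

$$ P(a) \propto \exp\{\beta\,Q(a) + \pi\,[a = a_1^{prev}]\} . $$

Second-stage choices use a plain softmax on $Q_2(s_2, \cdot)$ with the
same $\beta$. All value tables start at zero and there is no decay of
unchosen values.

Three alternative variants probe where a drug effect might act:
`dual_rate` splits $\alpha$ into $\alpha^+$/$\alpha^-$ applied by the sign
of each prediction error; `separate_values` gives the model-based system
its own second-stage table and learning rate $\alpha_{MB}$ (stage-two
choice still uses the model-free table, the minimal departure from the
winning model); `actor_critic` replaces the model-free component with a
critic learning state values (rate $\alpha$) and an actor accumulating
action preferences (step $\eta$). Because the model-based term still needs
second-stage *action* values, the actor-critic variant maintains a
$Q_2$ table by the same delta rule for the model-based system, and its
stage-two choice uses the stage-two actor preferences — the equations for
this variant are not uniquely pinned down in the literature, so we chose
the minimal internally consistent completion.

### Parameters, defaults, and transforms

| parameter | meaning | range | typical value |
|---|---|---|---|
| $\alpha$ | learning rate | $(0,1)$ | 0.37–0.45 |
| $\beta$ | softmax inverse temperature (units of 1/value) | $\ge 0$ | 4.7–5.4 |
| $\pi$ | perseveration bonus (exponent scale) | $\ge 0$ | 0.7–1.4 |
| $\omega$ | model-based weight | $(0,1)$ | 0.58–0.78 |
| $\lambda$ | eligibility constant | $[0,1]$ | fixed at 1 |

The "typical values" are the per-condition median estimates reported for
this task with the winning four-parameter model; they are the default
population means of the synthetic cohort generator. Two modelling
conventions deserve note, both genuinely open choices:

* **Eligibility.** The winning model estimates a single $\alpha$;
  we fix $\lambda = 1$ (full pass-back of the second-stage error) rather
  than estimating it, matching the reduced parameterisation.
* **Perseveration scale.** $\pi$ enters the exponent additively, *not*
  multiplied by $\beta$. This keeps $\pi$ interpretable on the exponent
  scale independently of the temperature, and the typical fitted
  magnitudes (0.3–2.2) are consistent with that scale.

For fitting and parametric testing, bounded parameters are mapped to
unbounded, approximately Gaussian coordinates: the logit for
unit-interval parameters ($a = \mathrm{logit}\,\alpha$,
$w = \mathrm{logit}\,\omega$, likewise rates and $\eta$) and the log for
positive ones ($b = \log\beta$, $p = \log\pi$). Natural values are
clamped to $[10^{-6}, 1-10^{-6}]$ (unit interval) before transforming so
boundary values never produce infinities.

## Likelihood and hierarchical estimation

The likelihood of a session multiplies the model's probability of every
observed first- and second-stage choice, with the agent's values updated
after each trial exactly as in simulation. `session_nll()` evaluates the
negative log-likelihood in a compiled kernel; an R path composed from the
exported per-operation functions is retained and tested for equality.

Estimation follows the two-stage empirical-Bayes scheme that is the
standard simplification of iterative expectation–maximisation:

1. **Stage 1 (MLE).** Each subject × condition session is fitted by
   maximum likelihood in transformed space. The likelihood surface is
   multi-modal, so each fit runs from 10 starting points (the first at the
   centre of a fixed box spanning the plausible regimes — rates and
   weights well inside the unit interval, $\beta$ roughly 0.5–12, $\pi$
   roughly 0.05–3 — the rest drawn uniformly from it, reproducibly from
   the seed), using BFGS with a Nelder–Mead fallback.
2. **Population prior.** Per-parameter Gaussian moments of the stage-1
   estimates, pooled across subjects *and conditions* so the prior cannot
   manufacture a condition difference. Prior variances are floored at
   $10^{-3}$ to prevent collapse on small cohorts.
3. **Stage 2 (MAP).** Each session is refitted with the Gaussian prior as
   a penalty, starting from its stage-1 estimate, the prior mean, and two
   prior draws. Further prior/MAP iterations are available
   (`fit_controls(max_iters = )`) but off by default: two stages is the
   procedure as described.

The MAP estimates shrink toward the population mean, which reduces the
recovery error of poorly identified coordinates (the test suite checks
that the root-mean-square error of the recovered transformed $w$ under
MAP does not exceed the MLE's). Because the likelihood is not concave,
an occasional MAP coordinate can fall slightly outside the segment
between its MLE and the prior mean; the shrinkage property is therefore
asserted as a strong-majority property, not coordinate-by-coordinate.

Model comparison fits every candidate by MLE and sums BIC over subjects,
counting both choices of each trial as observations. The original
selection criterion for this task is not recoverable from the main text;
BIC is declared as this package's criterion, not claimed as the original.
Nested reductions (e.g. pure model-free, $\omega \equiv 0$) are expressed
by fixing natural parameters (`fixed = c(omega = 0)`), which guarantees
the likelihood identity between the hybrid at $\omega = 0$ and the pure
model-free model.

Between-condition inference uses classical two-tailed paired t tests on
the transformed per-subject estimates. Degenerate inputs are signalled
rather than silently propagated: zero-variance differences give $t = 0,
p = 1$ (identical vectors) or $t = \pm\infty, p = 0$ (constant nonzero
differences), each with a warning.

## Stay–switch analysis

`stay_table()` conditions each trial's stay/switch outcome (repeat of the
previous first-stage choice) on the *previous* trial's reward and
transition type; the first trial contributes nothing, and trials
following the two in-session breaks are treated like any other pair
(no exclusion is stated for the original procedure). Cells with no
eligible trials are flagged missing, never scored 0. Per-subject cell
means enter a 2×2×2 within-subject ANOVA (condition × reward ×
transition) via `stats::aov` with the subject error strata; in this
all-two-level design every F equals the squared paired t of the
corresponding contrast score, an identity the test suite verifies to
1e-8 against an independently coded contrast oracle. The
condition-difference profile subtracts the grand mean of the four cell
differences ("corrected for the main effect of drug"), and
`hypothesis_templates()` provides the qualitative sign patterns of four
hypothetical drug effects for sign-agreement classification.

## The synthetic cohort generator

`generate_cohort()` emulates an 18-subject, two-condition within-subject
crossover, 201 trials per session, with per-subject parameters drawn
around condition-specific population means in transformed space
(between-subject standard deviation 0.5 on every transformed coordinate
by default, which spans the reported interquartile ranges without
boundary pile-up). Two design choices matter:

* **Shared subject deviations.** Each subject's Gaussian deviation is
  drawn once and added to both conditions' transformed means, so the
  condition manipulation is a pure within-subject mean shift. Independent
  per-condition draws would destroy the pairing that the crossover design
  exists to exploit and make paired tests needlessly conservative.
* **Independent reward walks** per session (walks are not shared across
  subjects or conditions), bounds $[0.2, 0.8]$ with reflection,
  per-trial step standard deviation 0.025, initial probabilities uniform
  within the bounds. The original task states only a "slightly larger
  dynamic range" than its precursor (which used $[0.25, 0.75]$); these
  are config defaults, not claims about the original stimuli.

What the generator does *not* emulate: session-order effects (the
original found none), response times, mood ratings, drop-out, lapses or
attention fluctuations, and any subject-level correlation between
parameters. Passing recovery tests therefore show that the estimation
machinery is consistent for data generated by the model itself — the
necessary validity check for this class of analysis — not that the model
captures every feature of human data.

### What recovery can and cannot show

Two empirical properties of this task design surfaced in validation and
are worth knowing:

* **Earnings are almost flat in $\omega$.** Simulated earnings barely
  increase with the model-based weight at realistic $\beta$ and $\pi$,
  so a positive earnings–$\omega$ correlation across subjects is not a
  reliable property of the generative model, and the suite does not
  assert one (it checks instead that value-guided agents outearn a
  random-choice agent on identical reward walks).
* **A pure $\omega$ shift also moves overall stay rates.** More
  model-based control means more structure-driven switching, so the
  ANOVA's main effect of drug carries real signal under an $\omega$-only
  manipulation and competes with the three-way interaction for
  dominance in moderate samples. This is why the profile analysis
  mean-corrects the drug main effect before comparing against the
  hypothesis templates.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-probability choices make
the likelihood $+\infty$ rather than erroring; non-finite optimiser
objectives are replaced by a large penalty; softmaxes are evaluated via
log-sum-exp; optimiser failures fall back from BFGS to Nelder–Mead and a
completely failed session is returned flagged, not thrown. Reproducibility
is end-to-end: every stochastic function takes a seed, derived seeds are
folded with a fixed multiplier, and the caller's RNG state is restored.

The validation suite uses problem sizes chosen to make each property
sharply testable at interactive runtimes: 100–201-trial sessions for unit
checks, 5,000–6,000-trial sessions for the asymptotic signatures
(single-subject $\omega$ recovery within ±0.1; the model-free reward main
effect and the model-based crossover), 18-subject cohorts for recovery of
the reported parameter regimes, and 20-replicate batteries for
pipeline-direction properties.

## Worked example

```{r}
library(twostepRL)

cohort <- generate_cohort(cohort_config(seed = 1))
fit <- fit_twostep(cohort, model = "hybrid", method = "map", seed = 1)
summary(fit)

tabs <- stay_tables(cohort)
rm_anova_2x2x2(tabs)
drug_difference_profile(tabs, conditions = c("placebo", "ldopa"))
```

## Known limitations

* The hierarchical procedure is the two-stage empirical-Bayes
  simplification, not full EM with analytic E-steps or MCMC; posterior
  uncertainty of individual parameters is not quantified.
* Transition probabilities are assumed known to the model-based system;
  transition learning, separate temperatures per stage, and Bayesian
  reward tracking are out of scope.
* BIC model comparison treats subjects as fixed units; group-level
  Bayesian model selection is not implemented.
* With 201 trials per session, single-subject estimates of $\omega$ are
  noisy; cohort-level medians and paired contrasts are the intended unit
  of inference.
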
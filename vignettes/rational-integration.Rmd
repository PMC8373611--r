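---
title: "Rational integration of information sources in early word learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rational integration of information sources in early word learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pragword)
library(dplyr)
```

## The inference problem

A speaker utters a novel word while two candidate referents are in view: a
familiar object (say, a duck) and an unfamiliar one. Children as young as
two tend to map the novel word onto the novel object. `pragword` implements
a computational account of this inference in which three information
sources are combined by Bayesian inference:

* **Speaker informativeness** (`alpha`, a non-negative soft-max exponent):
  the expectation that a speaker chooses informative utterances. A speaker
  who meant the duck would have said "duck".
* **Semantic knowledge** (`theta`, a probability per familiar object): how
  likely the child is to actually know the conventional word for that
  object. The inference above only works if "duck" is in the lexicon.
* **Common ground** (`rho`, a probability): discourse novelty built up in
  the conversation. An object that is new to the speaker is a more likely
  referent of their new word.

The pragmatic listener `L1` infers the referent `r` of the novel utterance
`u` by weighting a speaker likelihood against the conversational prior:

$$P_{L_1}(r \mid u) \propto P_{S_1}(u \mid r; \alpha, \theta)\, P(r \mid \rho).$$

The speaker term is a standard rational-speech-act recursion: `S1` soft-
maximises the informativity each utterance would have for a literal
listener `L0`, i.e. $P_{S_1}(u \mid r) \propto P_{L_0}(r \mid u)^{\alpha}$.

### Literal semantics under graded knowledge

`L0`'s lexicon has to reflect *graded* knowledge of the familiar word. We
use a lexicon-uncertainty mixture: with probability `theta` the familiar
word denotes the familiar object exclusively; with probability `1 - theta`
it is unknown and applies to both referents equally; the novel word always
applies to both equally. This choice gives exactly the limiting behaviour
the theory requires — at `theta = 0` the utterance carries no information
and the posterior equals the prior, at `theta = 1` the classic mutual
exclusivity inference emerges — and it needs only a single number per
object. The closed form for the whole recursion follows:

$$P_{L_1}(\text{novel}) =
  \frac{q \, k_N}{q\,k_N + (1-q)\,k_F}, \qquad
  k_N = \frac{1}{1 + (1-\theta)^\alpha},\;
  k_F = \frac{1}{1 + (1+\theta)^\alpha},$$

with `q` the prior probability of the novel referent. The test suite
verifies this closed form against a brute-force enumeration of the
two-utterance-by-two-referent scene on a thousand random parameter
triples.

```{r}
pragmatic_listener(alpha = 1, theta = 1, prior_novel = 0.5)
```

### The model family

Six variants share this machinery (`model_names()`):

* **integration** — the full model above.
* **no_word_knowledge** — replaces the object-specific `theta` with the
  pooled age-level trajectory (gross vocabulary, no object variation).
* **no_common_ground** — fixes the referent prior at 1/2.
* **no_speaker_informativeness** — sets `alpha = 0`; the likelihood is flat
  and the posterior is the prior.
* **biased** — a modular alternative:
  $\phi\, P_{\mathrm{ME}} + (1-\phi)\, P(r \mid \rho)$, where
  $P_{\mathrm{ME}}$ is the mutual-exclusivity inference (the integration
  model at a uniform prior) and `phi` is a bias weight.
* **developmental_bias** — the biased model with `phi` changing with age.
  Its printed definition elsewhere omits the prior factor after
  $(1-\phi_i)$; we treat that as a typesetting omission and implement it
  structurally identically to the biased model, which is how it is
  described in prose.

Because the biased models are convex mixtures, their prediction is always
bounded by the two component inferences — they can never be *stronger* than
the strongest component, whereas in the full model the cues reinforce one
another. This boundedness is a tested invariant.

## Age trajectories

Development enters through regression submodels that map age to the
parameters: a linear model for `alpha` (slope per year) and logistic models
for `rho`, `theta` and `phi`. Semantic knowledge additionally carries
per-object random intercepts and slopes around the main trajectory, one
pair for each of the 12 familiar objects, ordered by rated age of
acquisition.

Numerical/structural choices, each of which was genuinely open:

* **Age centring**: ages are centred at 3.0 years (the middle of the 2–5
  range) in every submodel, so intercepts are interpretable as the value
  for a three-year-old. One shared constant (`age_center`).
* **Positivity of `alpha`**: the linear predictor is clipped at zero
  (`alpha_link = "identity_clip"`). A log link is available as a
  configuration switch for users who prefer strict positivity without a
  kink; the clipped link is the default because it keeps the submodel an
  actual linear regression and reaches `alpha = 0` exactly, which the
  no-speaker-informativeness lesion requires.
* **Condition priors**: in the congruent alignment the contextually new
  object is the novel one, so the prior of the novel referent is `rho`; in
  the incongruent alignment it is `1 - rho`; mutual-exclusivity-only scenes
  carry no common-ground manipulation and use 1/2. Congruent and
  incongruent priors are complementary by construction.
* **ME prior in the biased models**: uniform (1/2), since that inference
  takes in only informativeness and semantic knowledge.

```{r, fig.width = 7, fig.height = 2.8}
autoplot(default_truth())
```

## Synthetic experiments

`simulate_experiment()` generates trial tables with the structure of the
three designs the models are evaluated on: 12 mutual-exclusivity trials
per child (one per familiar object; `exp1`), 10 discourse-novelty trials
(`exp2`), and up to 12 combined trials (six per alignment, each familiar
object at most once; `exp3`). Children are drawn per whole-year age bin
(2-, 3- and 4-year-olds) with ages uniform within the bin; observed
samples in such studies end before age five, so no five-year-olds are
generated. Responses are Bernoulli draws from the generating model's
choice probability at the child's age, object and condition. Two
deliberate simplifications: discourse-novelty trials are generated from
`rho(age)` directly (that design measures common-ground sensitivity alone,
and its analysis model is a simple logistic regression), and dropout is
not simulated because real protocols replace dropouts to hit target
counts.

`default_truth()` fixes the generating coefficients used across the test
suite: all three sensitivities increase with age (`rho` from ~0.54 at age
two to ~0.74 at age four; `alpha` from 0.5 to 1.5; pooled `theta` from 0.5
to 0.83), object offsets spread evenly from +2.5 to −2.5 on the logit
scale so the roster spans words known by most two-year-olds down to words
few four-year-olds know, and the bias trajectory crosses 1/2 just before
age three. These values were chosen once to be developmentally plausible
and are not tuned to any test outcome.

What passing tests on these data do *not* show: real children contribute
per-child correlation (the generator pools within age), real object
difficulty is not evenly spaced, attention and side biases exist, and real
ages are not uniform within year bins. The generator validates the
machinery, not the psychology.

## Estimation

`fit_model()` estimates all trajectory coefficients jointly from trial
tables in a fully Bayesian way. Every trial contributes a Bernoulli
likelihood at the probability the model variant assigns to its row;
mutual-exclusivity rows use the uniform-prior submodel, discourse-novelty
rows inform `rho` directly, and combined rows use the variant's full
mapping. The variant therefore only changes the likelihood of combined
rows: stage-1 estimation is shared across the prediction models, exactly
as in the two-stage workflow the package mirrors (`stage = "prediction"`
drops combined rows entirely and never lets them touch the likelihood —
this is enforced and tested, preserving the out-of-sample character of the
predictions; `stage = "explanation"` constrains the parameters with all
rows).

Priors (`prior_spec()`) are weakly informative: Normal(0, 2.5) on
logit-scale intercepts and slopes, Normal(1, 1) and Normal(0, 1) on the
`alpha` intercept and slope (negativity absorbed by the link), and
half-Normal(1) hyperpriors on the standard deviations of the object
offsets. All are configurable; they are not claimed to match any
particular published analysis, whose exact priors live in supplementary
material.

The sampler is an adaptive Metropolis-within-Gibbs scheme over a single
compiled likelihood kernel: scalar random-walk updates per coordinate
(proposal scales adapted toward 44% acceptance during warmup) plus an
adaptive full-covariance block proposal (Haario-style, adapted toward 23%
acceptance) that traverses the posterior ridge between informativeness and
semantic knowledge, which scalar updates cross slowly. The object offsets
are parameterized non-centred (standardized offsets scaled by
`exp(log sd)` inside the likelihood) to avoid the funnel that arises when
the true offset spread is small. Convergence is summarised by split-Rhat
and Geyer effective sample sizes per parameter; fits flag a warning (but
still return, with `converged = FALSE`) when max Rhat exceeds 1.05 or any
ESS falls below 100. Defaults are 2 chains of 1000 warmup + 1000 retained
draws; reported results should rest on at least 1000 retained draws.

```{r, eval = FALSE}
trials <- simulate_study(60, default_truth(), "integration", seed = 1)
fit1 <- fit_model(filter(trials, experiment != "exp3"),
                  "integration", stage = "prediction", seed = 2)
tidy(fit1)
glance(fit1)
```

## Prediction, evidence and evaluation

`posterior_predict()` and `bin_predictions()` map posterior draws to
predicted choice probabilities — for a cell grid or for the cells actually
occupied by a dataset (predictions are evaluated at each trial's real age
and averaged within cell, then summarised across draws by the mean and a
95% highest density interval). The HDI is the shortest contiguous interval
containing the requested mass of sorted draws; clearly multimodal inputs
trigger a warning rather than a disjoint interval.

`marginal_likelihood()` implements model evidence as a naive Monte-Carlo
average of the data likelihood over a parameter distribution, computed in
log space with log-sum-exp and reported with its standard error. Two
sampling distributions correspond to the two stages: the stage-1 posterior
for prediction models (evidence of the *new* combined-design data under
the a-priori predictions — the package's default reading of the
comparison), or the prior for explanation models. Naive Monte Carlo is
auditable and matches the definition of the quantity directly; for
high-dimensional prior sampling its variance is large, which is why the
standard error is always attached and why bridge-type estimators are noted
as a possible upgrade rather than silently substituted. Shared machinery:
the same compiled likelihood kernel serves fitting, evidence and
prediction, so the three can never drift apart (a test asserts this
against an independent slow oracle).

`bin_responses()` bins trials by whole age year (half-open bins), condition
and object; `pearson_r()` and `compare_report()` compute the correlation
and variance explained between binned predictions and observations over
the 72 combined-design cells (12 objects × 2 alignments × 3 age years),
with cells weighted equally by default (an `n`-weighted option exists —
published analyses do not state which weighting they use).

## Numerical notes

* Exact 0/1 referent priors propagate exactly through the listener.
* Extreme `alpha` is guarded: overflowed speaker weights are renormalised
  in log space; `x^0 = 1` conventions keep `alpha = 0` exact.
* Choice probabilities are never clamped in likelihood evaluation: a
  structural zero yields `-Inf` honestly (and Monte-Carlo evidence warns
  when every sampled likelihood is zero).
* All simulation and fitting functions require an explicit integer seed
  and are bit-reproducible given it.

## Problem sizes used by the checks

The packaged checks simulate 60 children per age-year bin (2040 trials per
replicate across the three designs), fit 2 chains of 700–1000 retained
draws, and use 20 seeded replicates for the coverage and model-selection
studies; these sizes give decisive Bayes factors and stable coverage for
the machinery being validated. Parameter-recovery coverage is assessed as
the pooled proportion of generating coefficients inside their 95%
credible intervals across replicates.

## Known limitations

* The scene is fixed at two referents and two utterances; utterance costs
  and lexicon learning across trials are out of scope.
* No response-noise (guessing) layer is modelled on top of the listener.
* The sampler is random-walk based; posteriors with much higher
  dimensionality than this model family would warrant a gradient-based
  sampler.
* Explanation-stage evidence by prior Monte Carlo is high-variance in this
  dimensionality; prediction-stage comparisons (posterior-averaged) are
  the reliable ones here.
* The per-cell dominance of the full model over the pooled-knowledge
  lesion holds where an object is better known than the pooled trajectory
  assumes; for below-average objects that lesion *over*-predicts, so
  aggregate claims about it are claims about typical, not all, cells.
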
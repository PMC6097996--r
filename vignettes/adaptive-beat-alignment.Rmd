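---
title: "Adaptive beat alignment testing: model, engine and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive beat alignment testing: model, engine and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatcat)
```

## The measurement problem

Beat perception — inferring a regular pulse from music — is usually
measured with beat alignment tasks: a listener hears a musical excerpt
overlaid with a metronome-like beep track and judges whether the beeps
sit on the beat. `beatcat` implements a modern, item-response-theoretic
version of this paradigm as a reusable engine: automatic item
generation, adaptive administration, calibration, diagnostics, stimulus
construction and simulation.

Each trial is a two-alternative forced choice (2-AFC). Two versions of
the same excerpt are played, separated by two seconds of silence: the
*target*, whose beeps fall exactly on the annotated beat locations, and
the *lure*, whose beeps are displaced by a fixed proportion of a beat.
The listener picks the target. Guessing blindly succeeds half the time,
which anchors the response model's lower asymptote at 0.5.

## The response model

The probability that a listener of ability $\theta$ answers item $j$
correctly is

$$P(X_j = 1 \mid \theta) \;=\; \tfrac12 + \tfrac12\,
  \mathrm{logistic}\!\bigl(a(\theta - b_j)\bigr),$$

a four-parameter logistic model with the guessing parameter fixed at
$1/2$ (the 2-AFC chance rate), the inattention ceiling fixed at 1
(sessions are short), and one discrimination $a$ shared by all items.
Ability and difficulty share a scale standardised so the test-taker
population is approximately $N(0,1)$.

Item difficulty is not a free parameter per item. It is predicted from
two structural stimulus features:

* **beep-track accuracy** $d = \cos^4(\pi P)$, where
  $P \in (0, 0.5]$ is the lure's displacement as a fraction of one
  beat. The quartic-cosine transform linearises the relationship
  between displacement and difficulty; raw displacement does not.
  Half a beat is the maximal meaningful displacement because the beat
  is periodic.
* **displacement direction** (ahead of or behind the beat), dummy-coded
  1 for *behind*.

With the shipped calibration,

$$b \;=\; -5.393 \;+\; 7.247\,d \;-\; 0.576\,[\text{behind}],
  \qquad a = 1.166 .$$

Higher accuracy means a lure more similar to the target, hence a harder
item; behind-the-beat lures are slightly easier to reject than
ahead-of-the-beat ones. Musical track and stimulus order do not enter
the prediction: track-level effects were estimated during calibration
(their standard deviations are retained as metadata in
`difficulty_coefficients()`) but are deliberately omitted from
prediction — the intercept–slope correlation of $-1$ leaves them only
one effective degree of freedom, and including them was found to
degrade reliability. Because difficulty is a deterministic function of
features, the factorial item bank is effectively unlimited:

```{r bank}
bank <- standard_bank()   # 25 tracks x 100 accuracy levels x 2 x 2
bank
```

## Ability estimation

Three estimators operate on a scored pattern
(`estimate_bayes_modal()`, `estimate_weighted_likelihood()`,
`estimate_eap()`):

* **Bayes modal** (posterior mode, Gaussian prior of mean 0, SD 1) for
  interim scoring during a session; it is defined for the empty
  pattern (the prior mode) and stable after surprising early
  responses. Its standard error includes the prior's information,
  $\mathrm{SE} = (I(\hat\theta) + 1/\sigma_0^2)^{-1/2}$.
* **Weighted likelihood** (Warm's bias correction: the root of
  $S(\theta) + J(\theta)/2I(\theta)$, with $S$ the score, $I$ the test
  information and $J = \sum_j P_j' P_j'' / P_j(1-P_j)$) for final
  scoring; it removes the prior's shrinkage and stays finite for
  all-correct and all-incorrect patterns. Its SE uses test information
  only. Both SE conventions are configurable because either choice is
  defensible; the package's defaults are stated here and used
  throughout.
* **EAP** (posterior mean, 61 Gauss–Hermite nodes by default) for
  batch scoring during calibration; its SE is the posterior SD.

All estimators search $[-6, 6]$, which covers the population and the
bank's difficulty range ($[-2.35, 1.82]$) with a wide margin. The
information function is the expected (Fisher) form
$a^2\frac{1-P}{P}\bigl(\frac{P-c}{1-c}\bigr)^2$; which information
formula backed the original standard-error figures is not documented
anywhere we know of, and the expected form is the standard choice for
IRT standard errors. A caveat worth knowing: under the 0.5 guessing
floor the likelihood is *not* symmetric in correct/incorrect responses
(an all-incorrect pattern is far less informative than an all-correct
one), so mirrored response patterns do not produce mirrored estimates
except in the zero-guessing special case.

## The adaptive session

`run_session()` implements the session loop. The first item targets
difficulty $-0.01$ (an average-ability start; the exact printed value
depends on the accuracy grid, so the target is configurable — with the
100-level grid the nearest difficulty is $0.006$). After each response
the ability is re-estimated by Bayes modal estimation, and the next
item is drawn from the unused-track items nearest in difficulty to the
estimate (the Urry criterion). A musical track is never heard twice in
a session, so the default length of 25 equals the number of tracks.
Exact distance ties are resolved by a seeded uniform draw, and the
candidate set can be widened ("randomesque" selection) since the size
of the original selection subset is not documented; the default is the
exact-minimum set only. After the last item the final score is the
weighted likelihood estimate over the whole pattern.

```{r session}
responder <- simulate_responder(0.5, seed = 7)   # a virtual participant
sess <- run_session(bank, responder, session_config(seed = 7))
sess
```

Sessions are fully reproducible from (bank, seed, responder), and
`rescore_at_length()` recomputes the weighted likelihood score after
the first $k$ items, which is how SE-versus-length curves are built.

## Calibration on new data

`fit_constrained_3pl()` estimates per-item difficulties and the shared
discrimination by marginal maximum likelihood, integrating ability over
$N(0,1)$ with fixed Gauss–Hermite quadrature (61 nodes by default;
nodes and weights are computed by the Golub–Welsch eigendecomposition
and validated against dense numerical integration in the test suite).
The optimiser is L-BFGS-B with analytic gradients and a relative
log-likelihood tolerance of $10^{-8}$; standard errors come from the
observed information. Items answered all-correct or all-incorrect are
unidentifiable and are flagged, with difficulties reported at the
search bounds. Missing responses are treated as ignorable, which is
consistent with adaptive administration under the fitted model.

`fit_explanatory_model()` fits the explanatory model directly: the
per-item difficulty is replaced by the linear predictor in accuracy and
direction. This is exactly a logistic mixed model with a Gaussian
person intercept under the 2-AFC link; effects are reported on both the
raw logit scale ($B = -a\,c$) and the difficulty scale, with
delta-method standard errors. The test suite cross-checks the fit
against `lme4::glmer` with a custom 2-AFC link at `nAGQ = 10`; the two
routes agree to about two decimals on a 150-person fixture.
`regress_difficulty_on_features()` provides the two-stage alternative
(per-item calibration, then OLS of difficulty on features).

## Diagnostics

* `screen_tracks()` aggregates success rates per musical track and
  flags tracks at or below chance plus a margin (default 0.05, so a
  52% track is flagged while a 56% track is not).
* `yen_q1()` is Yen's Q1 item-fit statistic with 10 EAP-ranked ability
  groups and parametric-bootstrap significance (default 500 Monte
  Carlo samples, Bonferroni across items). The Monte Carlo floor on
  p-values is $1/(n_{mc}+1)$, so the sample count must be large enough
  for the Bonferroni threshold to be reachable. Empty ability groups
  collapse out of the sum. Power is best when the model is calibrated
  on clean data: a misfitting item also drags the shared
  discrimination, which spreads misfit across all items.
* `margins_check()` compares observed and model-implied frequencies of
  all joint response patterns of item pairs and triplets
  ($\binom{J}{2}\cdot 4$ and $\binom{J}{3}\cdot 8$ combinations). The
  flagging rule is a squared standardised residual exceeding a
  threshold (default 4); the criterion referenced in the original
  margins literature is not given in closed form, so this documented
  stand-in is exposed as a parameter.
* `modified_parallel_analysis()` tests unidimensionality: the second
  eigenvalue of the tetrachoric correlation matrix against its Monte
  Carlo null under the fitted model. Tetrachorics are pairwise maximum
  likelihood with thresholds fixed at the margins; empty cells receive
  a 0.5 continuity correction (declared and logged via an attribute);
  the bivariate normal CDF uses fixed Gauss–Legendre quadrature on the
  correlation-integral representation.

## Stimulus construction

`consensus_beats()` turns drummers' tap recordings into canonical beat
annotations: after latency correction, each drummer's two takes with
the closest mean inter-tap intervals are aligned beat-for-beat
(nearest-neighbour within half a period, robust to a missing first or
last tap) and averaged, then drummer averages are averaged. Consistency
is screened with a circular phase difference, defined here as
$2\pi \cdot |\text{mean signed onset discrepancy}| / \text{mean
period}$ — the thresholds (0.6 rad within drummers, i.e. 9.5% of a
beat; 0.7 rad between drummers, 11.1%) are standard for this paradigm,
and the formula is our documented choice since only the thresholds, not
the statistic, are conventionally reported.

`beep_schedule()` places target beeps on the beats and lure beeps at
$\pm P$ times the *local* inter-beat interval (the interval following
each beat; the last beat reuses the preceding interval), so tempo drift
displaces proportionally. `render_beep_track()` synthesises each beep
as a 20 ms, 1000 Hz sine with a linear 10 ms fade-out (the fade curve
is not conventionally specified; linear is the simplest choice),
peak-normalises, and `assemble_trial()` concatenates the two versions
around two seconds of silence — five-second excerpts give the familiar
12-second trial. Mixing with copyrighted music tracks and manual
salience adjustment are out of scope; the renderer emits the beep track
alone, and audio is written as mono PCM16/float32 WAV.

## Simulation and what it does (not) show

`reliability_experiment()` runs virtual cohorts through the full
adaptive pipeline: each participant's responses are Bernoulli draws
from the response model at their true ability, every participant takes
the test `n_sessions` times with independent streams derived from one
master seed, and for each test length $k$ the first $k$ responses are
rescored by weighted likelihood. Reported are the mean SE and the
between-session Pearson correlation per length, with percentile
bootstrap bands over participants (1000 resamples by default).

The default validation cohort draws abilities from the standard normal
— the model's own population assumption — rather than from any
empirical ability distribution. With 500 such participants, the
standard bank and the shipped coefficients, the mean weighted
likelihood SE is about 0.67 after 25 items and 0.88 after 15, and the
simulated test-retest correlation after 25 items is about 0.65–0.70
(`scripts/acceptance.R` recomputes these quantities end to end; the
classical identity $r \approx 1/(1 + \overline{SE}^2)$ gives a
consistency check). These simulations validate the *engine* — that the
adaptive loop, estimators and bank deliver the reliability the model
implies. They cannot validate the model against human listeners:
real cohorts have heavier low-ability tails, real tracks differ in
difficulty (the omitted random effects), and real sessions include
lapses, learning and listening-condition effects that the generator
deliberately does not emulate.

## Numerical and design choices, collected

* Working precision is double; closed-form identities are tested at
  $10^{-9}$ or tighter; the logistic is evaluated in an overflow-safe
  form because adaptive sessions can visit extreme $\theta - b$.
* Accuracy grids start at `low` with step `(high - low) / n` and an
  excluded endpoint, matching ranges like $0.5 \le d < 1$; the exact
  spacing convention used originally is not documented, so the grid
  helper is parameterised.
* Item identifiers are deterministic functions of the features, so
  session logs are reproducible across runs; every source of
  randomness flows from explicit integer seeds, and generator streams
  are isolated from the caller's RNG state.
* Ties (item selection, ability grouping) are broken by seeded draws
  or stable sorts, never by platform-dependent ordering.
* Problem sizes in the test suite are chosen to keep statistical
  assertions sharp at desk scale: recovery tests use 300–500 persons
  by 27 items (matching the calibration designs), the reliability
  check uses a 500-person cohort, and Monte Carlo diagnostics use
  60–400 samples depending on the p-value floor the assertion needs.

## Known limitations

Track-level difficulty effects are metadata, not predictions; the
engine is unidimensional and dichotomous by design; variable-length
termination rules and exposure control beyond track exclusion are not
implemented; and the simulation harness's agreement with printed
reliability figures is evidence of correct mechanics, not of validity
for any particular listener population.
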
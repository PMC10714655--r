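---
title: "Individual fuzzy cognitive maps: model, learning and scenario methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual fuzzy cognitive maps: model, learning and scenario methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmlearn)
```

## The dynamical model

A fuzzy cognitive map (FCM) is a signed, weighted digraph over concepts
(here: behavioural determinants and one outcome) whose states
$A_i \in [0,1]$ evolve synchronously:

$$A_i^{t+1} = f\Big(A_i^t + \sum_{j=1}^{n} A_j^t\,W_{ji}\Big),
\qquad f(x) = \frac{1}{1 + e^{-\lambda x}}.$$

Two modelling commitments deserve spelling out.

*Self-memory.* The update keeps the concept's own current value inside the
transfer argument. Without this additive self-term the recursion would
discard each concept's history; with it, a concept with no incoming edges
still relaxes smoothly toward the sigmoid's fixed point instead of
jumping. All learning and simulation in this package uses this form, and
only this form — alternative transfer functions (tanh, bivalent) and
rescaled update rules are deliberately out of scope.

*Steepness.* $\lambda$ controls how sharply the weighted input saturates;
it is constrained to $(0, 10]$ and defaults to 1, which keeps the map's
dynamics contractive for the moderate weights typical of behavioural
networks (and is why simulations below converge in tens of steps, not
thousands). $\lambda$ travels inside `fcm_sim_control()` and is recorded
with every fit, so no result is ever ambiguous about the transfer used.

Simulations stop when *all* concepts move less than a convergence
threshold between steps (max-norm; default 0.001) or when an iteration cap
(default 2000) is hit; unconverged runs are flagged, never silently
truncated. Because the sigmoid maps into $(0,1)$, states cannot escape the
unit cube and non-finite values are impossible; the engine still asserts
this.

With a zero weight matrix and $\lambda = 1$ every concept must converge to
the unique root of $x = 1/(1+e^{-x}) \approx 0.6590$; the test suite
checks the engine against an independent bisection root-finder rather than
against its own output.

### Exactness of identities

Several contracts in this package are *exact*, not approximate: a map that
generated a noise-free trajectory must score fitness 1 and in-sample error
0; adding an intervention node with all-zero weights must reproduce the
baseline equilibrium bit-for-bit. BLAS matrix products do not guarantee
this (a one-row product and a multi-row product may sum in different
orders), so all state propagation goes through a single ordered-summation
primitive. This makes appending a zero-weight source node an exact no-op
and makes one-step predictions agree bit-for-bit with rollouts, at a cost
that is irrelevant at $n \le 20$ concepts.

## Learning one map per person

Each participant contributes a short trajectory: $T$ measurement waves
($T \ge 2$) of $n$ determinants, normalized to $[0,1]$. The learner is a
real-coded genetic algorithm over full $n \times n$ weight matrices whose
fitness is evaluated at *every* observed transition:

$$E(W) = \frac{1}{(T-1)\,n} \sum_{t=1}^{T-1} \sum_i
  \big|\,\hat A_i^{t} - A_i^{t}\,\big|, \qquad
  \text{fitness}(W) = \frac{1}{1 + 100\,E(W)},$$

where $\hat A^{t}$ is one update step applied to the *observed* state at
$t-1$ (teacher forcing). Fitting per transition is what lets a map follow
an individual's whole trajectory instead of merely hitting its final
wave. The $1/(1+100E)$ envelope is a convention for a bounded $(0,1]$
score; the factor 100 places the default early-stopping goal of 0.99 at a
mean one-step error of about $10^{-4}$.

Two error metrics complement the fitness:

* **In-sample error** is free-running: simulate $T-1$ steps from the
  observed baseline and average the absolute deviation from the
  observations. Teacher-forced fitness and free-running error answer
  different questions (local transition fit vs. trajectory replay), and
  both are reported on every fit.
* **Out-of-sample error** compares rollouts from random initial states
  under the learned map against rollouts under an explicit *reference*
  dynamics. The reference must be supplied because "error from random
  initial conditions" is not well-posed against observed data that carries
  its own initial condition: in synthetic experiments the natural
  reference is the generating map; in cohort runs the pipeline scores each
  participant against the next participant's learned map (cyclic held-out
  pairing). Output metadata always states which reference was used.

### Genetic operators

* *Initialization*: all cells i.i.d. Uniform$[-1,1]$.
* *Crossover* (probability 0.9): one cell chosen uniformly at random is
  exchanged between the two offspring — the multiset of cell values across
  the pair is conserved.
* *Mutation* (probability 0.1): one cell chosen uniformly at random is
  redrawn from Uniform$[-1,1]$.
* *Selection*: tournaments of 3 distinct competitors, drawn with
  replacement across slots, plus elitism of one — the generation's best
  chromosome always survives unchanged, so the best-fitness history is
  non-decreasing by construction.
* *Bookkeeping*: offspring untouched by either operator inherit their
  parent's evaluated fitness instead of being re-evaluated.

Population 100 and 200 generations are the defaults; they recover sparse
4-concept maps from 5-wave noise-free trajectories in well under a second
per run. All hyperparameters are exposed in `fcm_control()`, and a single
integer seed makes a fit bit-reproducible.

## Fuzzy elicitation of intervention weights

Experts rate each intervention→determinant impact with one of six
linguistic terms — *non-existent, very-low, low, medium, high, very-high*
— plus a polarity ($\pm 1$). Four steps turn a panel's ratings into one
signed weight:

1. each term maps to a triangular membership function on the magnitude
   universe $[0,1]$;
2. each rated term is *activated* at the fraction of experts endorsing it
   (three experts rating {low, medium, medium} activate *low* at 1/3 and
   *medium* at 2/3);
3. the activated functions are clipped at their activation level and
   aggregated by pointwise maximum (family-max);
4. the aggregate is defuzzified by its centroid, and the shared polarity
   signs the result.

*Vocabulary placement.* Peaks sit at 0.1, 0.25, 0.5, 0.75, 0.9 — an expert
saying "medium" tends to mean 0.5 — with each triangle's feet at the
neighbouring peaks, so adjacent terms overlap and close-but-different
ratings reinforce each other. The placement is fully overridable in
`fcm_vocabulary()` and recorded with elicited outputs.

*Non-existent.* The term contributes no membership function but counts in
the endorsement denominator. A unanimous *non-existent* panel yields
weight exactly 0 (no intervention edge), by convention rather than by
integration.

*Polarity.* The vocabulary rates magnitudes only, so direction is a
separate $\pm 1$. Experts disagreeing on the *sign* of an effect is a
substantive conflict; the package raises an error instead of averaging it
away. *Non-existent* ratings are sign-neutral.

*Resolution.* The centroid is computed on a 1001-point grid over $[0,1]$;
the suite verifies it against a $10^6$-point integration oracle to within
$10^{-3}$ for every 3-expert multiset of terms.

*A known non-monotonicity.* One might expect that upgrading a single
expert's term can never lower the elicited weight. That is false under
this (standard) scheme, for two reasons: upgrading out of *non-existent*
adds low-end mass where there was none, and an upgraded term's clipped
triangle can be *narrower* than the original's (the default supports are
asymmetric), shifting relative mass toward the panel's lower terms — e.g.
{very-low, very-low, high} → {very-low, very-low, very-high} moves the
centroid from 0.413 to 0.411. Unanimous panels, by contrast, are strictly
monotone in the term order, and that weaker property is what the suite
asserts.

## Intervention scenarios

An intervention is an extra concept appended to a participant's map with
outgoing edges equal to the elicited weights and no incoming edges. In
**continuous** mode (the default, matching sustained-exposure programmes)
the node starts at its activation level (default 1) and is clamped there
on every step; in **single-shot** mode the target determinants' baseline
values are perturbed once instead and no node is added. The scenario run
simulates both conditions to equilibrium from the participant's observed
baseline (wave 0) measurement — the natural seed when no other time point
is privileged — and reports

$$\%\Delta_c = 100 \cdot
  \frac{A_c^{\text{int}} - A_c^{\text{base}}}{A_c^{\text{base}}}$$

between the two *equilibria*. Comparing equilibrium against the raw
observed baseline instead would conflate the intervention's effect with
the map's endogenous drift, so it is not the default. Baseline equilibria
below $10^{-6}$ are flagged `NA` rather than reported as explosive
percentages (with $\lambda = 1$ the sigmoid makes such values nearly
impossible, but the guard is cheap).

Cohort summaries average percent change per concept over participants
whose baseline and intervention runs both converged (non-converged runs
are counted and excluded); SD uses the sample ($n-1$) convention, reported
as 0 with a flag for a single participant.

## The synthetic cohort generator

Real determinant panels of this kind are rarely redistributable, so the
generator produces cohorts with the same *structure*: by default 257
participants, 15 determinants plus a fruit-intake outcome, 3 measurement
waves, 5-point-Likert-discretized observations. The generative model is:

* one base map: off-diagonal edges present with probability 0.2, weights
  Uniform$[-0.5, 0.5]$ — sparse, moderate couplings that keep the dynamics
  well inside the sigmoid's responsive range;
* per participant, cellwise Gaussian perturbation of the base map
  (SD 0.1, clipped to $[-1,1]$) — individuals are related but distinct, so
  per-person learning is meaningful;
* baseline states Uniform$[0.2, 0.8]$, bounded away from sigmoid
  saturation;
* deterministic rollout for the remaining waves, plus Gaussian observation
  noise (SD 0.05) and snapping to the nearest Likert level.

What this emulates is the data's shape and noise character, not its
science: there is no sociodemographic structure, no missingness, no
theory-driven edge pattern, and the "true" per-person maps are known. A
passing recovery test therefore shows the learner can invert this
generative process — a necessary check, not evidence about any real
population. Ground-truth maps are written separately from the observable
cohort files and never leak into them.

## Problem sizes and budgets

The suite and the acceptance script choose sizes a desktop run completes
comfortably: operator and elicitation checks run at full spec (e.g. all 56
three-expert multisets, $10^4$ mutation draws); recovery uses 20 seeded
4-concept, 5-wave participants at default GA settings; the end-to-end
determinism check runs the full 257 × 16 × 3 cohort with a reduced search
budget (population 20, 15 generations) declared in its config, since the
point there is reproducibility and report shape, not fit quality; the
acceptance script's noisy-cohort error summary uses 25 participants at
population 30 / 40 generations. Every random draw in tests, pipeline and
script descends from one explicit integer seed.

## Limitations

* The learned maps are dense by construction; no sparsity prior or
  theory-derived structural constraint is imposed.
* Fitness is one-step-ahead; a map can fit transitions well yet drift in
  long free runs (the in-sample error makes this visible but the search
  does not optimize it).
* The out-of-sample metric depends on the chosen reference dynamics and is
  a surrogate, clearly labelled as such in outputs.
* Elicitation handles one intervention node per scenario; interacting
  simultaneous interventions are only supported as separate scenarios.
* Equilibrium reporting assumes the maps converge; oscillatory maps are
  flagged and excluded rather than analysed.
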
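# fcmlearn

Individual-level fuzzy cognitive maps (FCMs) for planning health-behaviour
interventions.

Intervention planners describe how a behaviour such as fruit intake arises
from a web of psychosocial and environmental determinants — awareness,
attitudes, self-efficacy, social influence, availability at home, and so
on. When these webs contain feedback loops, the consequences of an
intervention can no longer be traced by hand: they have to be simulated.
`fcmlearn` supports that workflow end to end:

1. **Learn** one signed, weighted causal network per person from their
   short longitudinal record of determinant measurements, with a
   real-coded genetic algorithm (RCGA) that fits every observed transition
   of the trajectory rather than only its endpoint.
2. **Elicit** the strength of a hypothetical intervention from expert
   panels who rate each intervention→determinant impact with linguistic
   terms (*non-existent* … *very high*) plus a direction, converted to a
   numeric weight by fuzzy inference (triangular membership functions,
   endorsement activation, family-max aggregation, centroid
   defuzzification).
3. **Simulate** the intervention as an always-active extra node clamped
   onto each personal network, run both conditions to equilibrium, and
   report the percent change of every determinant per person and across
   the cohort (mean ± SD).

## The model

An FCM over concepts \(i = 1..n\) holds states \(A_i \in [0,1]\) and
signed weights \(W_{ji} \in [-1,1]\) (impact of concept \(j\) on concept
\(i\)). States update synchronously by

    A_i(t+1) = f( A_i(t) + Σ_j A_j(t) · W_ji ),   f(x) = 1 / (1 + e^(−λx)),

with sigmoid steepness \(0 < λ ≤ 10\) (default 1). A simulation stops when
no concept moves by more than a threshold (default 0.001) or after a
maximum number of steps (default 2000).

Learning maximises a bounded trajectory fitness. With \(E\) the mean
absolute one-step-ahead error over all observed transitions,

    fitness(W) = 1 / (1 + 100·E),

so fitness is 1 exactly when every transition is reproduced. Candidate
matrices evolve by tournament selection with elitism, single-edge
crossover and uniform single-edge mutation.

## A worked example

```r
library(fcmlearn)

# 1. a small synthetic participant with a known causal map
spec <- fcm_cohort_spec(n_participants = 1,
                        concepts = c("awareness", "attitude", "intention",
                                     "fruit_intake"),
                        n_timepoints = 5, density = 0.3, noise_sd = 0,
                        individual_variation_sd = 0, discretize = FALSE,
                        seed = 42)
cohort <- fcm_generate_cohort(spec)

# 2. learn the map back from the observed trajectory
fit <- fcm_learn(cohort$trajectories[[1]], fcm_control(seed = 1))
print(fit)
#> Fuzzy cognitive map fit (real-coded genetic algorithm)
#>   participant:      p001
#>   concepts:         4
#>   time points:      5
#>   generations run:  200
#>   fitness:          0.5401
#>   in-sample error:  0.008603

# 3. elicit an intervention weight from three experts
fcm_elicit_weight(c("low", "medium", "medium"))
#> [1] 0.4418885

# 4. simulate a continuous intervention on awareness
scenario <- fcm_intervention(c(awareness = 0.591), name = "basic")
res <- fcm_run_scenario(coef(fit), cohort$trajectories[[1]][1, ], scenario)
print(res)
#> Scenario 'basic'
#>   percent change vs baseline equilibrium:
#>    awareness     attitude    intention fruit_intake
#>        14.75        -3.32         3.21         4.01
```

The fitness of 0.54 corresponds to a mean one-step error under 0.01 on the
[0,1] state scale; the free-running in-sample error of 0.0086 says the
learned network replays the whole 5-wave trajectory from baseline to
within about 1% of the scale. The elicited weight 0.44 is the centroid of
the *low*(⅓)/*medium*(⅔) aggregated membership curve. The scenario output
reads: holding an awareness-targeting intervention permanently active
raises this participant's equilibrium awareness by ~15% and fruit intake
by ~4% relative to the no-intervention equilibrium.

Cohort-scale runs go through `fcm_pipeline()` (or the CLI at
`inst/scripts/fcmlearn-cli.R`): synthesize or read trajectories, fit every
participant, elicit scenarios, and write the report tables
(`report.csv` with per-concept mean ± SD percent change per scenario, and
per-participant outcome tables).

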
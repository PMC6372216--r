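# revlearn

Behavioral models of decision making in changing environments, built around
an **explicit-duration hidden Markov model** (ED-HMM, a hidden semi-Markov
model) of the probabilistic reversal-learning task.

## The problem

In a reversal-learning task a participant chooses between two options; one
pays a reward with probability $p_H = 0.8$, the other with $p_L = 0.2$, and
at hidden moments the contingencies reverse. Most models of this task —
Rescorla–Wagner learners, plain hidden-Markov filters — assume nothing
about *when* reversals happen: implicitly, the interval between reversals
is geometric and change is equally likely on every trial. The ED-HMM agent
instead carries an explicit prior over the dwell time $d$ between
reversals,

$$p_0(d) = \binom{d+r-2}{d-1}(1-\delta)^{d-1}\delta^r, \qquad d \ge 1,$$

a negative binomial with mean $\mu$ and variance $\sigma$. With
$\sigma = \mu(\mu-1)$ ($r = 1$) this is geometric and the agent reduces
exactly to a 2-state HMM; with $\sigma = \mu$ the prior is peaked and the
agent *anticipates* reversals at semi-regular intervals. Fitting $\delta$
and $r$ to behavior therefore measures a participant's belief in the
temporal regularity of the environment.

The package provides, for researchers in computational cognitive
science/psychiatry:

* **Duration priors** — negative-binomial interval beliefs, moment
  inversion, and the forward reversal-probability profile they induce
  (`duration_prior()`, `expected_reversal_probability()`);
* **Agents** — the ED-HMM agent with variational belief updating over
  states, durations and Beta reward beliefs (`edhmm_agent()`,
  `agent_step()`), plus single- and dual-update Rescorla–Wagner baselines
  (`rw_agent()`);
* **Task simulation** — the fixed 160-trial experimental schedule and
  stochastic irregular/semi-regular environments, with performance and
  reversal-locked analyses (`performance_experiment()`,
  `reversal_locked_average()`);
* **Hierarchical fitting** — all six free parameters per subject under a
  horseshoe prior, fitted by mean-field stochastic variational inference
  (`fit_hierarchical()`), with posterior predictive model evidence on
  held-out trials (`posterior_predictive_evidence()`);
* **Model comparison** — random-effects Bayesian comparison with
  per-subject model attributions and exceedance probabilities
  (`random_effects_comparison()`), model-identification (confusion)
  experiments (`confusion_experiment()`), and synthetic cohorts for
  recovery studies (`generate_cohort()`);
* a small **command line** (`inst/cli/revlearn`, `rl_dispatch()`) wrapping
  the above: `simulate`, `fit`, `compare`, `synth`, `recover`.

## Worked example

A regular-interval prior with mean 20 and variance 20 anticipates
reversals 20–30 trials after the last one:

```r
library(revlearn)
prior <- duration_prior(mu = 20, sigma = 20)
print(prior)
#> Duration prior: NB(delta = 0.95, r = 361), mu = 20, sigma = 20, d_max = 200

dtau <- expected_reversal_probability(prior, 40)
round(dtau[c(4, 19, 27)], 3)   # reversal probability at tau = 5, 20, 28
#> 0.000 0.144 0.280
```

The probability of an imminent reversal is essentially zero five trials
after a change and rises to 0.28 around trial 28 — the agent "expects"
change in that window. Simulating 200 blocks in a semi-regular environment
(intervals drawn from NB(20, 20)) shows what this anticipation is worth:

```r
res <- performance_experiment(
  list(iri = agent_spec("iri"), rri = agent_spec("rri")),
  environment = "semiregular", n_blocks = 200, seed = 1)
print(res)
#> Simulation result: 200 blocks, environment "semiregular"
#>  agent     q25  median       q75
#>    iri 0.77500 0.80625 0.8375000
#>    rri 0.84375 0.86875 0.8890625
```

The agent whose prior matches the environment's regularity (RRI) makes the
correct choice on a median 86.9% of trials; the agent with geometric
(maximally uncertain) interval beliefs (IRI) reaches 80.6%. That 6-point
gap is the behavioral value of representing temporal structure.

Fitting the model hierarchically to a small synthetic cohort recovers the
individual duration-prior rates:

```r
coh <- generate_cohort(cohort_spec(n_subjects = 6, model = "ed_hmm", seed = 8))
post <- fit_hierarchical(coh$data, "ed_hmm", n_iter = 800, seed = 2,
                         beta_transform = "positive")
round(cbind(true_delta = coh$ground_truth$delta,
            est_delta  = posterior_mean_native(post)[, "delta"]), 3)
#>        true_delta est_delta
#> sub001      0.093     0.094
#> sub002      0.070     0.051
#> sub003      0.326     0.245
#> sub004      0.134     0.120
#> sub005      0.070     0.071
#> sub006      0.097     0.036
```

See `vignettes/edhmm-reversal-learning.Rmd` for the model derivation,
the fitting engine, and every design decision with its rationale.

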
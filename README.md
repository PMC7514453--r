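# sgais

Online estimation of the Bayesian marginal likelihood (evidence) for models
of conditionally i.i.d. data, by **stochastic gradient annealed importance
sampling** (SGAIS): sequential Bayesian updating, adaptive thermal
annealing, and mini-batch stochastic gradient Hamiltonian Monte Carlo
(SGHMC) combined into a single streaming estimator. Vanilla annealed
importance sampling (AIS) and nested sampling (NS) are included as
reference estimators.

## Who this is for

The evidence `Z = ∫ p(D|θ) p(θ) dθ` is the normalizing constant behind
Bayesian model comparison and weighted model averaging. Classical
estimators (NS, AIS) evaluate the full-data likelihood thousands of times
and become impractical on large or streaming datasets. When the data are
conditionally i.i.d., `Z` factorizes into one-step-ahead predictive
probabilities,

    log Z = Σₙ log p(yₙ | y₍₁..n−1₎),

and each predictive integral is far smoother than the full likelihood.
`sgais` estimates these predictives one chunk of data at a time:

* **particles** `θᵢ` with importance weights `wᵢ` track the running
  posterior; after each chunk, `Ẑ = (1/M) Σᵢ wᵢ`;
* a chunk is absorbed through tempered targets
  `p(chunk|θ)^λ · p(y₍past₎|θ) · p(θ)` with the increment in `λ` chosen
  adaptively so the effective sample size `ESS = (Σω)²/Σω²` of the
  incremental weights stays at a target;
* between increments, particles move by SGHMC whose potential-energy
  gradient uses a mini-batch of past observations scaled by
  `(n−1)/|B|` — the marginal cost of absorbing new data does not grow
  with the history, and a fixed-size uniform reservoir of the history
  supports true streaming.

A drop in the per-observation predictive, or a spike in annealing effort,
marks a change-point in the stream (`detect_shift()`).

## Worked example

Six-parameter Bayesian linear regression (5 weights + intercept, known
noise), for which the evidence is available in closed form:

```r
library(sgais)
model <- make_linreg_model()                 # 6 parameters
set.seed(1)
theta_true <- drop(model$sample_prior(1))
data <- simulate_dataset(model, theta_true, 10000, seed = 2)
trace <- sgais_run(model, data, sgais_config(seed = 3))
print(trace)
#> <sgais_trace> linreg-6d: 20 chunk(s), n = 10000, log Z = -14254.9
head(as.data.frame(trace), 3)
#>   n_seen log_evidence annealing_steps predictive_logprob cum_grad_evals
#> 1    500    -707.7782              19          -707.7782        2000000
#> 2   1000   -1411.4827               1          -703.7046        2400000
#> 3   1500   -2118.9187               1          -707.4360        2800000
linreg_exact_log_evidence(data)
#> [1] -14233.15
```

Each row is one 500-observation chunk: the running `log Ẑ`, the number of
intermediate annealing distributions the adaptive schedule needed (19 for
the first chunk, where prior and posterior differ most, then almost none),
the chunk's predictive log-probability (the increments telescope to
`log Ẑ`), and cumulative per-record gradient evaluations — a
hardware-independent cost measure. Here the final estimate is within
0.15% of the exact `log Z`; at a million observations the default
configuration lands near 0.1%.

`ais_run()` and `ns_run()` provide the reference estimators,
`compare_estimators()` tabulates all three, `cli_sweep()` drives
one-parameter sensitivity sweeps, and `simulate_shift_dataset()` generates
the non-stationary 3 → 5 → 7-cluster stream used to demonstrate
change-point detection. A command-line front end with `simulate`, `sgais`,
`ais`, `ns`, `compare` and `sweep` subcommands is installed at
`inst/cli/sgais.R`.

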
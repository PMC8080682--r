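# coopnet

Agent-based simulation of how a cooperative behavioural norm spreads
through a social network that is also exposed to a weak global influence.

## The problem

Conserving a very large common-pool resource — a stable climate, global
biodiversity, surge capacity in public health care — is a collective action
dilemma in which the resource gives no usable feedback: by the time
overuse is visible, restraint is too late. What decides the outcome is
whether a pro-conservation norm spreads through the population fast
enough. `coopnet` simulates the transient dynamics of that spreading
process: the emergence of polarised clusters, their slow dissolution, the
social tipping point in the strength of the surrounding sociopolitical
environment, and the effect of interventions (campaign-style changes to
the environment, or pinning a highly connected "influencer").

## The model

Each of *N* agents carries a continuous cooperativity *b<sub>i</sub>* ∈
[−1, 1] (−1 total defection, +1 total cooperation). One event: pick an
agent *i* uniformly, a neighbour *j* of *i* uniformly, and update *i*
(updating the selected agent makes hubs influential — they are someone's
neighbour far more often):

Δb<sub>i</sub> = |b<sub>i</sub> − b<sub>j</sub>| · (2·f(x<sub>ij</sub>) − b<sub>i</sub> − 1),  x<sub>ij</sub> = w<sub>i</sub> b<sub>i</sub> + w<sub>ij</sub> b<sub>j</sub> + φ

where *w<sub>i</sub>* is self-weight (stubbornness), *w<sub>ij</sub>* ~
Normal(0.5, 0.15) a fixed tie strength (negative values = animosity), φ a
weak global field representing media, regulation and morals, and *f* the
response function: 0 below −*r*, 1 above +*r*, and noise-dominated in
between (noise ξ ~ Uniform(−*r*, *r*), *r* = 0.1). The prefactor
|b<sub>i</sub> − b<sub>j</sub>| means only disagreeing agents move each
other — there is *no* bounded-confidence cutoff, so polarisation here is
transient, not terminal. Time is measured in sweeps (*N* events).

Networks are clustered scale-free graphs grown by preferential attachment
with triad formation (1089 nodes, growth degree 8, mean degree ≈ 16 by
default) or periodic lattices at matching degree; custom weighted edge
lists can be loaded.

## Worked example

```r
library(coopnet)
cfg <- network_config()   # 1089-node clustered scale-free graph, <k> ~ 16
par <- model_params()     # phi = 0.05, w_i = 0.6, r = 0.1, b0 ~ N(-0.25, 0.15)
sch <- sim_schedule(max_sweeps = 3000, absorption_tol = 1e-2,
                    n_realizations = 10, base_seed = 1)
res <- run_ensemble(cfg, par, sch)
res
#> <ensemble_result> 10 realizations x 3001 record points (3000.0 sweeps)
#>   terminal: 100% cooperative, 0% defective, 0% unresolved
m <- ensemble_mean_trajectory(res)
est <- convergence_rate(m$mean_b, m$time)
sprintf("rate at the consensus crossing: %.3f per sweep (t_cross = %.1f)",
        est$rate, est$crossing_time)
#> [1] "rate at the consensus crossing: 0.102 per sweep (t_cross = 13.0)"
quantile(res$absorb_time)
#>     0%    25%    50%    75%   100%
#> 161.00 162.75 169.00 174.50 188.00
```

Despite the initial defector majority (mean −0.25), every realization
reaches the fully cooperative steady state: the mean first *falls* while
polarised clusters form, crosses zero near sweep 13, and the ensemble
absorbs after a few hundred sweeps. The rate 0.102/sweep is the slope of
the ensemble mean at its zero crossing (10-point regression), the
quantity used to compare network connectivities, field strengths and
influencer interventions. Key analysis entry points:
`estimate_tipping_point()` (stochastic bisection on φ),
`rate_vs_parameter()`, `apply_field_switch()`, `pin_influencer()`,
`exponential_stage_diagnostics()`.

A command-line interface with the same functionality is installed at
`exec/coopnet`:

```sh
Rscript exec/coopnet ensemble --realizations 10 --seed 1 --out runs/demo
Rscript exec/coopnet tipping --bracket 0 0.05 --realizations 36 --max-sweeps 1500 --out runs/tip
```

Every output directory contains a `manifest.json` (flat config + seeds)
from which the run can be regenerated byte-identically.

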
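---
title: "Norm-spreading dynamics on social networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norm-spreading dynamics on social networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coopnet` simulates the spread of a cooperative behavioural norm through a
structured population under a weak global influence. This vignette is the
package's own account of the model, the parameters that matter, the
numerical choices that were genuinely open, and what the test suite does
and does not establish.

## The interaction rule

Each agent carries a cooperativity $b_i \in [-1, 1]$. A single event picks
agent $i$ uniformly, one of its neighbours $j$ uniformly, and updates $i$
only:

$$\Delta b_i \;=\; |b_i - b_j|\,\bigl(2 f(x_{ij}) - b_i - 1\bigr),
\qquad x_{ij} = w_i b_i + w_{ij} b_j + \phi .$$

This is the compact form of a two-weight exchange
$|b_i-b_j|\,[w^+(1-b_i) - w^-(1+b_i)]$ with $w^- = 1 - w^+$ and
$w^+ = f(x_{ij})$; the two forms are algebraically identical and the test
suite asserts it to machine precision. The prefactor $|b_i-b_j|$ encodes
that an agent can only move toward an opinion actually presented to it:
agreeing agents reinforce each other (no change), so every homogeneous
state — at *any* common value — is frozen. Updating the *selected* agent,
not its neighbour, is what makes hubs influential: a hub is someone's
neighbour in nearly every event.

The response function saturates outside a noise window of half-width
$r$:

$$f(x) = \begin{cases} 0 & x \le -r \\ \text{noise-dominated} & -r < x < r \\ 1 & x \ge r. \end{cases}$$

with $\xi \sim \mathrm{Uniform}(-r, r)$ drawn fresh per event. Two
middle-branch semantics are implemented because the published piecewise
form leaves the coupling of $\xi$ to $x$ open:

* `pure_noise` (default): $f = (r+\xi)/2r$, independent of $x$ between the
  branches. The field then acts through how often the stimulus saturates
  to 0 or 1, and the middle branch is an unbiased coin with mean 1/2.
* `ramp_plus_noise`: $f = \mathrm{clip}\!\bigl((r+x+\xi)/2r,\,0,\,1\bigr)$,
  whose mean joins the saturated branches continuously.

The literal form is the default because it reproduces the reference
phenomenology exercised by the test suite — every standard-parameter
realization reaches full cooperation, and the tipping field lands near
0.010 — whereas the ramp variant couples the middle branch to the (mostly
negative) early stimuli and thereby strengthens the initial defector
takeover. Both modes share every structural property the suite checks
(range preservation, monotone mean response, mirror symmetry, identical
compiled/reference trajectories).

Updates are clipped to $[-1,1]$: the raw jump can overshoot (a full
defector meeting a full cooperator at $f=1$ has raw $\Delta b_i = 4$), and
the behaviour scale is defined on the closed interval, so projection is
the only consistent completion.

## Parameters and defaults

| Parameter | Meaning | Default |
|---|---|---|
| $\phi$ | global field (media, regulation, morals) | 0.05 |
| $w_i$ | self-weight / stubbornness, shared by all agents | 0.6 |
| $w_{ij}$ | tie strength, one draw per undirected edge | Normal(0.5, 0.15) |
| $r$ | noise half-width and response window | 0.1 |
| $b_i(0)$ | initial cooperativity, i.i.d., clipped | Normal(−0.25, 0.15) |
| network | clustered scale-free, $n = 33^2 = 1089$, growth degree 8, triad probability 0.5 | mean degree ≈ 16 |
| ensemble | realizations per condition | 500 |

These defaults are the reference study conditions and are encoded in
`network_config()`, `model_params()`, `sim_schedule()` and
`default_config()`. Negative tie weights are retained (animosity). Edge
weights are quenched: drawn once per undirected edge and used
symmetrically in both directions (a per-draw switch would make the
disorder annealed, which is a different model; the susceptibility is a
property of the tie, not of the moment).

One documented discrepancy: the source text describes the clustering
control once as a clustering parameter "$k_t = 3.5$" and once, in its
parameter table, as 0.5. The generator exposes a single triad-formation
probability with default 0.5 — the table value, and the only reading that
is a valid probability in the standard growth-plus-triad-formation
algorithm.

## Networks

**Clustered scale-free.** Growth with preferential attachment: each new
node attaches `growth_degree` ($k_0$) edges; after each
preferential-attachment step, with probability `triad_probability` the
next edge instead closes a triangle with a neighbour of the just-linked
node. Triad formation raises local clustering at essentially unchanged
degree sequence (the suite verifies this against igraph's clustering
coefficient over 100 seeds). Mean degree is
$2k_0(1-k_0/n)$ — 15.88 at the defaults — because only the $n-k_0$ grown
nodes add edges; the acceptance script reproduces 16 ± 0.5. The graph is
connected by construction.

**Periodic grids.** Toroidal lattices with five symmetric neighbourhoods
(degrees 4, 8, 12, 16, 24). The degree-16 variant — used as the
equal-degree contrast to the default scale-free graph — is the Moore shell
plus the orthogonal and diagonal distance-2 sites; it is one natural
16-neighbour completion, chosen for its symmetry, and documented rather
than canonical. Distance-2 neighbourhoods require side ≥ 5 so the
neighbourhood cannot wrap onto itself.

## Time, absorption and classification

One sweep = $N$ events. A realization records the mean and SD of
cooperativity every `record_interval` sweeps (default 1) and stops at
absorption or `max_sweeps`.

**Frozen dissenters.** The model's absorbing structure is subtler than
"all agents at +1". An agent at the minority extreme whose every incident
tie satisfies $|w_{ij}| \le w_i - \phi - r$ can never move again: its
stimulus saturates against change for every possible neighbour behaviour.
At the defaults the bound is 0.45, and a low-degree node with all-weak
ties occurs at a rate of roughly one agent per thousand — so a fraction of
realizations converge to a steady state that is fully cooperative *except*
for one or two exactly-frozen dissenters. Terminal classification
therefore tests the steady state of the mobile agents and exempts
provably frozen opposite-extreme holdouts (their count is reported as
`holdouts`). Without the exemption, "always reaches full cooperation"
would be false for a reason that is structural, not dynamical.

**Absorption tolerance.** Near homogeneity the dynamics slow down
critically: an agent at distance $\varepsilon$ from the consensus extreme
moves by $O(\varepsilon^2)$ per interaction, so $\varepsilon$ decays
roughly like $1/t$ and tolerances much below $10^{-3}$ are unreachable in
any practical horizon. The default `absorption_tol` is $10^{-3}$;
classification is tolerance-robust (the suite's ensembles classify
identically at $10^{-2}$, which the heavier acceptance blocks use for
speed). Runs that hit `max_sweeps` are classified `unresolved`, never
raised as errors.

**Capped-horizon classification.** Near the tipping point full absorption
takes arbitrarily long; the tipping search classifies each realization by
its absorbed state or, if unresolved at the horizon (1500 sweeps in the
acceptance runs), by the sign of its mean — `cooperative_fraction()`
documents exactly this convention.

## Ensembles and reproducibility

A fresh network (topology *and* weights) is drawn per realization;
realization $i$ uses seed `base_seed + i` and its network
`base_seed + 1000000 + i`, so any realization can be regenerated in
isolation. All event randomness flows through R's global RNG in a
documented order (three uniforms per event: agent, neighbour, noise), and
the compiled event loop consumes the stream identically to the pure-R
reference stepper `simulation_step()` — the suite asserts bit-identical
trajectories between the two engines. Aggregation is by realization index,
so results do not depend on execution order. Absorbed realizations are
carried forward at their terminal values on the common time grid, which
keeps ensemble averages defined at all times.

The polarisation statistic is the ensemble average of *per-realization*
SDs — never the pooled SD, which would count between-realization
disagreement (half the ensemble at +1, half at −1) as polarisation.

## Interventions

Two protocols, both applied mid-run: switching the field to `new_phi`, and
pinning the maximum-degree agent (ties broken toward the lowest id) at a
fixed behaviour while it keeps persuading its neighbours.

The trigger deserves care. A per-realization online detector can confirm a
minimum of the mean only in hindsight (default: smoothed with a 5-point
trailing average, confirmed after 10 record points without a new minimum),
and at the standard field the ensemble mean crosses zero *before* such
confirmation is possible — an intervention triggered online cannot affect
the measured crossing rate. Rate comparisons therefore use the
ensemble-level protocol: `polarisation_time()` locates the minimum of a
pilot ensemble mean, and the intervention is applied at that fixed time in
all realizations. With `new_phi` equal to the original field the switched
run is bit-identical to the control at matched seeds — the no-op contract
the suite asserts.

The influencer contrast uses the 1089-node degree-16 grid (the same size
and degree as the scale-free default) rather than a small lattice: at 169
nodes a substantial fraction of grid realizations fails to nucleate
cooperation at the standard field, and a pinned cooperator then acts as a
guaranteed nucleus — a size effect, not a connectivity effect, and not the
comparison of interest.

## Analysis

* `convergence_rate()`: OLS slope over 10 recorded points centred on the
  point closest to the first zero crossing of the mean (later
  re-crossings ignored; window shifted inward at series ends). Ten points
  suppress single-record noise without leaving the locally-exponential
  region; the estimate rescales exactly under affine time re-indexing.
  Standard errors come from a 200-resample bootstrap over realizations.
* `estimate_tipping_point()`: bisection on $\phi$ of the cooperative
  fraction, ≥ 30 seeded realizations per candidate (48 in the acceptance
  script), bracket ends checked to straddle 0.5, final bracket width
  0.004. Each candidate gets its own seed block, so the whole search is
  reproducible from one base seed.
* `exponential_stage_diagnostics()`: two-segment least-squares fit of
  $\log(1 - \bar b)$ after the crossing, breakpoint chosen by grid search;
  the late-stage slope smaller in magnitude than the mid-stage slope is
  the critical-slowing-down signature.

## What the simulated conditions do and do not show

The package's "data" are its own simulated study conditions; no empirical
network or survey is involved. Several properties of the model under those
conditions, established while building the suite, bound what a passing
test means:

* **Nucleation is a race.** Recovery from the initial defector majority
  requires cooperative nuclei to form out of the noise window. Outcome
  variability is dynamical, not quenched: repeating realizations on a
  single fixed network spreads outcomes essentially as much as fresh
  networks do. Small networks (a few hundred nodes) frequently fail to
  nucleate at the standard field — unit-test fixtures therefore use either
  stronger fields or the full-size network.
* **The tipping transition has finite width.** The 50/50 point sits near
  $\phi \approx 0.011$ under the defaults, but the cooperative fraction
  rises gradually (about 0.64 at $\phi = 0.015$ at a 4000-sweep horizon,
  as the suite's transient block computes). The two-stage transient at a
  weak favourable field — dip below the initial mean, polarisation peak
  trailing the cooperativity minimum — is robust; a plain ensemble mean
  approaching +1 at $\phi = 0.015$ is not, because a minority of
  realizations genuinely absorbs defectively.
* **Figure-scale quantities are internal.** The source reports no time
  units or absolute rates, so rate values here are comparable only within
  the package's own time normalization (sweeps); all rate-based checks are
  internal-consistency contrasts (monotonicity, saturation, significance),
  not absolute reproductions.

Test ensembles are scaled for a single CPU — typically 36–100 realizations
per condition and horizons of 400–4000 sweeps, stated in each test — as
the package's own study sizes; the full 500-realization defaults remain
one flag away.

## Known limitations

* No link rewiring, no directed ties, no agent-heterogeneous
  self-weights, no bounded-confidence threshold: the model is
  deliberately the minimal unbounded-confidence contrast case.
* The degree-16 grid neighbourhood is one documented choice among several
  symmetric completions.
* The tipping search assumes the cooperative fraction is monotone in
  $\phi$ across the bracket (true in all measured conditions).
* Influencer placement is degree-greedy only; no optimisation over sets
  of pinned agents.
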
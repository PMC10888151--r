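# bindsim

Simulation and spectral analysis of **bound oscillatory process systems** —
a mechanistic model of perceptual binding in which an "internal space"
block of oscillating processes and an "internal time" block are coupled
with a tunable binding strength, and the question is how robust the bound
dynamics are to intrinsic (demographic) noise.

The package is for computational neuroscientists and systems biologists
who want to reproduce or extend this class of models: linear negative
feedback oscillator networks, exact Gillespie stochastic simulation, and
spectral-entropy readouts.

## The model

Two processes `p1, p2` encode space and two processes `q1, q2` encode
time. Within a block, processes are related by a hollow symmetric
squared-distance matrix (entries `(i-j)^2 ε`, mutual inhibition for
`ε < 0`), damped by their own value, and integrate into auxiliaries
`x_i, z_i` that feed back negatively:

```
dp1/dt = ε p2 − p1 − x1 + ω f1(q1, q2)      dx_i/dt = p_i
dp2/dt = ε p1 − p2 − x2 + ω f2(q1, q2)      dz_i/dt = q_i
dq1/dt = α q2 − q1 − z1 + ω g1(p1, p2)
dq2/dt = α q1 − q2 − z2 + ω g2(p1, p2)
```

with direct coupling `f_i = q_i`, `g_i = −p_i` (binding strength `ω`).
The model is linear, so `exp(Mt) S(0)` solves it exactly; the stochastic
version decomposes every additive term into a unit-step Gillespie event
channel with propensity `|term(S)|`, which reproduces the deterministic
drift identically in the mean. Noise robustness is quantified by the
spectral entropy of the `p1` power spectrum,

```
H = −k Σ_j PSD̂_j log2(PSD̂_j),   k = 1/log2(2048) = 1/11,
```

computed from 4096-point trajectories (`H = 0`: pure line spectrum;
`H = 1`: flat/noise spectrum).

## Worked example

```r
library(bindsim)

cfg <- binding_config(omega = 0.5)       # ε = α = −1, direct coupling
cfg
#> <binding_config>
#>   space block: n = 2, epsilon = -1
#>   time block:  m = 2, alpha = -1
#>   binding:     omega = 0.5, scheme = direct

glance(system_matrix(cfg))[, 1:4]
#>     dim max_real_part n_sustained_frequencies dominant_angular_frequency
#> 1     8      5.55e-16                       2                       1.28
```

No eigenvalue has positive real part (bounded dynamics) and the dominant
sustained mode has angular frequency 1.28 — period `2π/1.28 ≈ 4.9` time
units, up from `2π ≈ 6.3` for the uncoupled system: binding shifts the
oscillation to higher frequency.

```r
s0  <- binding_state(p = c(1000, 0), q = c(1000, 0))
rep1 <- run_single_replicate(cfg, s0, seed = 1)
rep1[, c("omega", "entropy", "dominant_frequency", "n_events")]
#>   omega entropy dominant_frequency n_events
#> 1   0.5   0.608              0.112  4911104
```

One stochastic replicate (4.9 million events, 4096 recorded samples over
~930 time units) gives spectral entropy ≈ 0.61: roughly half the spectral
power sits in oscillation lines, half in the noise background. The
binding-strength sweep is one call:

```r
sw <- run_entropy_sweep(replicates = 10, base_seed = 1)
tidy(sw)      # per-omega mean and SD of spectral entropy
autoplot(sw)  # mean ± SD versus binding strength
```

with per-`ω` mean entropies around 0.52–0.62 across
`ω ∈ {0, 0.25, 0.5, 0.75, 1}` — weak or strong binding changes the
noise robustness of the system only mildly.

Deterministic runs, exact solutions, PSDs, and histograms are available
as `simulate_deterministic()`, `closed_form_solution()`,
`spectral_density()`, and `trajectory_histogram()`; a thin command-line
wrapper with `ode` / `ssa` / `entropy` / `sweep` subcommands lives at
`inst/cli/bindsim.R`. See the vignette (`vignettes/binding-model.Rmd`)
for the model's assumptions, the event-recording convention used for
entropy analyses (it matters), and known limitations.

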
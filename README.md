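# sptdomains

Diffusion-state inference, membrane nanodomain mapping and steady-state
flux analysis for high-throughput single-particle tracking (spt-PALM).

## The problem

spt-PALM movies of membrane proteins — the motivating case is an active
Ras-family GTPase on the plasma membrane — yield tens to hundreds of
thousands of very short trajectories (4–5 frames at 12–35 ms per frame).
Pooled, these tracks determine a multi-state Brownian diffusion model, map
each diffusion state onto membrane space, and reveal whether the membrane
pool is at equilibrium. `sptdomains` implements that pipeline end to end:

1. **Linking** — greedy frame-to-frame connection of localizations under a
   hard distance threshold with symmetric ambiguity termination, a
   step-size survey to choose the threshold, and a per-frame density gate
   (< 0.03 µm⁻²) against misconnections.
2. **State inference** — two independent routes. CDF fitting:
   `P(r² ≤ u) = 1 − Σₖ αₖ exp(−u / 4(Dₖ Δt + σ²))` least-squares fitted to
   the empirical CDF of squared displacements. HMM: per-step displacements
   as isotropic 2D Gaussian emissions with per-axis variance
   `2(Dₖ Δt + σ²)`, EM across all trajectories jointly, penalized-score
   model-size selection, Viterbi per-step state assignment.
3. **Spatial mapping** — same-state runs collapsed to averaged state
   coordinates; auto/cross pair correlation g(r) in 10 nm annuli (periodic
   or rectangle-corrected); amplitude-versus-interval time course (domain
   lifetime); max-span lower bounds on domain size; deflection-angle
   distributions (0° = reversal; acute excess = confinement).
4. **Flux analysis** — occupancies π and transition matrix A give net flow
   per state `Σⱼ πⱼAⱼᵢ − πᵢ ΣⱼAᵢⱼ`, influx/outflux ratios, signed arm flows
   (F→N, N→I, I→F), the stationary distribution A would relax to, and
   detailed-balance residuals `πᵢAᵢⱼ − πⱼAⱼᵢ` — the non-equilibrium
   steady-state (NESS) diagnostics.
5. **Simulators** — a 2D Markov generator (negative control / recovery
   oracle) and a nested-nanodomain generator (~70 nm immobilization sites
   inside ~200 nm intermediate domains, with trapping, sink/source
   exchange and finite lifetimes) as the positive control.

## Worked example

```r
library(sptdomains)

model <- demo_three_state_model()     # canonical 3-state membrane model
trajs <- simulate_markov_trajectories(model, n_traj = 10000, seed = 42)
fit   <- fit_hmm(trajs, K = 3, loc_sigma = 0, seed = 1)
fit
#> diffusion HMM fit: K = 3, logLik = 56219.78, score = -112322.96 (40108 steps, 10000 trajectories)
#> 3-state diffusion model (dt = 0.012 s, sigma = 0 um)
#>   state 1 (F): D = 0.9926 um^2/s, occupancy = 0.578
#>   state 2 (N): D = 0.3046 um^2/s, occupancy = 0.302
#>   state 3 (I): D = 0.08262 um^2/s, occupancy = 0.119
#>   per-frame transition matrix:
#>     to
#> from      F      N      I
#>    F 0.9489 0.0506 0.0005
#>    N 0.0898 0.8816 0.0286
#>    I 0.0043 0.0677 0.9280
```

The fit recovers the generating model: fast/intermediate/immobile
coefficients 1.0/0.3/0.08 µm²/s within a few percent, occupancies
58/30/12% against 58/31/11%, and per-frame transition probabilities within
±0.01 — including the near-zero direct fast↔immobile exchange that routes
all traffic through the intermediate state.

```r
flux_report(model = fit$model)
#> flux report (source: fitted model)
#>   occupancies: F=0.578, N=0.302, I=0.119
#>   net flow/frame: F=-1.885e-03, N=+1.533e-03, I=+3.514e-04
#>   influx/outflux: F=0.936, N=1.043, I=1.041
#>   arm flows: F->N=+2.082e-03, N->I=+5.489e-04, I->F=+1.976e-04
#>   stationary (relaxed): F=0.560, N=0.312, I=0.128
#>   detailed balance: violated (max |residual| = 2.082e-03)
```

Here the flows are small (this control is simulated at equilibrium, so the
nonzero values are estimation noise); on a source/sink simulation — or the
real system — the same report shows a positive net flow into the immobile
state, a matching outflow from the fast state, influx/outflux ratio > 1
for immobile and < 1 for fast, and a relaxed stationary distribution far
more immobile-heavy than the observed occupancies: the signature of
continuous removal via the immobile state balanced by reinsertion of fast
molecules.

The spatial stages follow the same pattern
(`assign_states()` → `collapse_state_segments()` → `pair_correlation()` /
`gr_time_course()` / `domain_span_histogram()` / `deflection_angles()`);
`run_pipeline(pipeline_config(...), out_dir)` chains
simulate → link → infer → assign → flux with one master seed and writes
every artifact plus a provenance manifest. A thin command-line wrapper is
installed at `inst/scripts/spt-pipeline.R`. The methods vignette
(`vignettes/spt-diffusion-domains.Rmd`) documents the model, the estimator
choices and the simulators' scope.

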
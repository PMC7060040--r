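---
title: "Diffusion states, membrane nanodomains, and mass flux from single-particle tracking"
author: "sptdomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion states, membrane nanodomains, and mass flux from single-particle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-throughput single-particle tracking (spt-PALM) of a membrane protein —
the motivating system is an oncogenic, constitutively active Ras-family
GTPase on the plasma membrane of cultured human cells — produces hundreds of
thousands of short trajectories (4–5 frames on average at 12–35 ms frame
intervals). Individual tracks are far too short to classify on their own,
but pooled across a movie they carry enough information to answer four
questions this package addresses in sequence:

1. **How many diffusion states are there, and what are their parameters?**
   Multi-state Brownian models are inferred two independent ways and the
   model size is selected explicitly.
2. **Where do the states live on the membrane?** State labels are mapped
   back onto space and analyzed with pair correlation functions, revealing
   nanodomains and their nesting.
3. **How big and how long-lived are the domains?** Span statistics give
   size lower bounds; the decay of clustering amplitude with analysis
   interval gives lifetimes.
4. **Is the system at equilibrium?** Occupancies plus the transition matrix
   give net mass flows; persistent directional flow at a stable steady
   state diagnoses exchange with a reservoir (a non-equilibrium steady
   state, NESS).

## The model

All units are micrometres, seconds and frames; diffusion coefficients are
in µm²/s.

A K-state diffusion model consists of diffusion coefficients $D_1 > D_2 >
\dots > D_K$, occupancies $\pi$ (fractions of steps), a per-frame transition
matrix $A$ (rows sum to one), the frame interval $\Delta t$ and the
localization error $\sigma$ (standard deviation per coordinate). For a step
of a particle in state $k$, each displacement component is
$N(0,\, 2 D_k \Delta t)$; independent localization errors at the two ends of
a step add $2\sigma^2$ per axis, so the per-axis displacement variance is

$$ v_k = 2 (D_k \Delta t + \sigma^2). $$

Two consequences used throughout: the squared step length $r^2$ is
exponential with mean $2 v_k$ within one state, and a truly immobile
particle still shows an apparent diffusion coefficient $\sigma^2/\Delta t$
(`apparent_immobile_D()`), about 0.13 µm²/s at 40 nm and 12 ms — which is
why slow-state coefficients measured at fast frame rates must be read as
upper bounds and why the canonical model's immobile state carries a small
apparent $D$.

### CDF fitting

`fit_cdf_mixture()` fits
$P(r^2 \le u) = 1 - \sum_k \alpha_k e^{-u / (4 (D_k \Delta t + \sigma^2))}$
to the empirical CDF of all squared displacements by unweighted least
squares on 200 log-spaced points between the 1st and 99th percentiles, with
softmax/log parametrization and ten deterministic multi-start BFGS runs.
`select_cdf_K()` grows K while the RMSE improves by more than 10%
(configurable) per added state. The CDF route estimates $D$ and $\alpha$
but not transitions.

### Hidden Markov model

`fit_hmm()` treats each trajectory as an independent chain whose
observations are the per-step displacements, with state-k emission an
isotropic 2D Gaussian of per-axis variance $v_k$ ($r^2$ is the sufficient
statistic). Parameters are estimated with EM (Baum–Welch), vectorized
across chains of equal length, with ten short-burn-in restarts and
refinement of the best. Model size is selected by the penalized score
$-2\log L + p\,\log n_\text{steps}$ with $p = K^2 + K - 1$ free parameters,
reported relative to the best candidate so the best model scores zero
(`select_hmm_K()`; ties break toward the smaller model).
`assign_states()` decodes the most probable state path per trajectory
(Viterbi); labels are always in descending-$D$ order.

Numerical choices: emission variances are floored at $2\sigma^2$ (via
$D \ge 0$) and $10^{-12}$ µm²; convergence is declared at a relative
log-likelihood change of $10^{-7}$; the EM trace is retained and is
monotone within $10^{-8}$. Two deliberate approximations are documented
rather than modelled: $\sigma$ is a fixed user input, not estimated
(identifiability against slow states is poor at 4–5-frame tracks; defaults
0.04 µm at 12 ms, 0.02 µm at 35 ms), and the negative correlation between
consecutive steps induced by the shared localization error of their common
endpoint is ignored in the likelihood, as in the established tooling for
this analysis. Both biases are shared by the CDF route, which is why the
two routes serve as mutual cross-checks, not as an error bound.

### Spatial mapping

`collapse_state_segments()` replaces every maximal run of same-state steps
by one averaged coordinate (all member positions, including both endpoints;
a position at a state boundary belongs to both adjacent runs). This
prevents a molecule dwelling in a domain from being counted once per frame.
A minimum-run-length filter is exposed (`min_run_len`, default 1) because
the alternative reading — only runs longer than two time points qualify —
is also defensible; the default follows the averaging rule, and the filter
reproduces the stricter variant.

`pair_correlation()` computes $g(r)$ in 10 nm annuli: observed pairs over
pairs expected under complete spatial randomness; $g = 1$ is random,
$g > 1$ clustered. Auto mode excludes self-pairs; cross mode correlates two
states. Edge handling is one of:

* `"periodic"` — minimum-image distances; exact for the simulators'
  statistically homogeneous fields, requires $r_{max} \le$ field/2.
* `"rect"` — plain distances with the isotropised set-covariance
  correction for an $a\times b$ rectangle,
  $\gamma(r) = ab - 2(a+b)r/\pi + r^2/\pi$, applied to the expected count.
  This is exact in expectation for uniformly positioned reference points
  and valid for $r < \min(a, b)$; it was chosen over per-point
  annulus-window intersection areas because it is the standard stationary
  estimator, is orders of magnitude cheaper, and at $r_{max} = 1$ µm on
  ≥ 5 µm fields the two differ negligibly.

The **amplitude** is the maximum of $g$ over bins with $r \ge$ 10 nm (the
self-localization bin is excluded). `gr_time_course()` slices the movie
into non-overlapping windows (1/5/10/20 min by default), collapses runs
within windows, and averages per-window amplitudes: clustering produced by
domains with finite lifetimes decays once the window outlives the domain,
while static structure stays flat. `domain_span_histogram()` summarizes the
largest pairwise distance travelled while continuously in a state — a lower
bound on domain size, since short tracks undersample the domain.
`deflection_angles()` measures the angle between successive same-state
steps, oriented so 0° is a full reversal and 180° straight continuation:
free Brownian motion is uniform on [0°, 180°]; boundary reflections in
confining domains bias toward acute ("returning") angles.

### Flux analysis

With occupancies $\pi$ and transition matrix $A$ (fitted, or empirical from
decoded states via `occupancies_and_transitions()`):

* net flow per state $f_i = \sum_{j \ne i} \pi_j A_{ji} - \pi_i \sum_{j \ne i} A_{ij}$
  (fraction of the tracked population per frame; $\sum_i f_i = 0$ exactly);
* influx/outflux ratio per state (1 = balanced);
* arm flows $\pi_i A_{ij} - \pi_j A_{ji}$, reported in the cycle order
  F→N, N→I, I→F for three states;
* the stationary distribution of $A$ (eigenvector, cross-checked against
  the iterated fixed point within $10^{-9}$) — the occupancies the system
  would relax to if it were closed;
* detailed-balance residuals $\pi_i A_{ij} - \pi_j A_{ji}$ evaluated at any
  $\pi$; zero at equilibrium of a reversible chain, nonzero at the
  stationary point of a chain with a one-way cycle.

The NESS diagnosis is the joint pattern: occupancies stable in time
(`quarter_stability()` refits contiguous acquisition-time blocks), yet net
flow into one state and out of another at those observed occupancies, with
the relaxed (stationary) distribution markedly different — here immobile-
heavy. Mass conservation then requires exchange with a reservoir: removal
from the immobile state and reinsertion as fast molecules, matching
endocytic removal and recycling of membrane Ras. Bootstrap CIs resample
trajectories with replacement (percentile intervals, 1000 replicates by
default for the empirical route).

## The simulators and what they do (not) emulate

`simulate_markov_trajectories()` is the negative control and parameter-
recovery oracle: displacement draws per state, Markov state switching per
frame, geometric track lengths (memoryless photobleaching; default mean 5
positions, minimum 2), uniform start positions and times, field size set so
the per-frame density matches the request. It draws displacements only —
localization error is added separately by `add_localization_noise()`
(applied to positions, so consecutive steps are error-correlated as in real
data), and the recovery analyses in the tests run noise-free to match that
control's definition. Positions are continuous and unbounded (starts
uniform in the field); the pair-correlation control uses minimum-image
distances, which is exact for this construction. The canonical design point
`demo_three_state_model()` is $D = (1.0, 0.3, 0.08)$ µm²/s, $\pi = (0.58,
0.31, 0.11)$, $\Delta t = 12$ ms, with a reversible transition matrix
(F↔N rate 0.05/frame from F, N↔I rate 0.03/frame from N, no direct F↔I)
whose stationary distribution is exactly $\pi$ — transition rates of this
order are what the fitted models show, and the zero direct F–I exchange
encodes the obligatory transition path through the intermediate state.

`simulate_domain_trajectories()` is the positive control for everything
spatial: ~200 nm intermediate domains each nesting a ~70 nm immobilization
site; region-dependent $D$; trapping at the site (reachable only from
inside the parent domain, which realizes the nested-access picture and
makes direct F↔I transitions vanish); confined motion with boundary
reflection while trapped; per-frame escape, sink (membrane removal) and
source (insertion of fast molecules); finite domain lifetimes with
replacement at fresh positions. The field boundary is reflecting rather
than periodic so that no recorded step is corrupted by a wrap-around jump;
the rectangular $g(r)$ correction handles the finite window. For the NESS
control the mean track length is raised to 40 positions so the sink/source
exchange — not photobleaching — dominates the mass bookkeeping; with
realistic 5-position tracks the flow signs are unchanged but the
intermediate state's net flow is no longer the smallest of the three.

Neither simulator emulates blinking/reactivation photophysics, detection
noise upstream of the localization table, anomalous (non-Brownian) motion,
or 3D effects; passing tests therefore validate the analysis chain, not
those aspects of real data.

## Linking

`link_trajectories()` implements greedy frame-to-frame linking under a hard
threshold with mutual uniqueness: a track extends only when exactly one
candidate lies within `max_step` of its head *and* no competing head lies
within `max_step` of that candidate; any ambiguity terminates the track and
unclaimed detections seed new tracks. The symmetric rule (rather than
forward-only) is what makes the resulting tracks unambiguous; there is no
gap closing. Defaults: 0.5 µm at 12 ms, 0.8 µm at 35 ms, chosen from the
step-size survey (`step_size_survey()`: link once with a ~2 µm provisional
threshold, histogram the steps, cut at the valley between the Rayleigh-like
signal segment and the rising misconnection tail). `frame_density()` gates
datasets at 0.03 µm⁻² per frame (strictly below); above it, misconnections
bias model inference.

## Problem sizes used in the checks

The automated checks run the analyses at sizes chosen to make each claim
statistically resolvable on a single CPU: 10,000 trajectories for parameter
recovery (transition-matrix entries to ±0.02), 40,000 for the four-quarter
stability analysis, 160,000 for the spatial-randomness control (so that
every annulus passing the ≥50-expected-pairs filter estimates $g$ with
standard error below ~0.09), 3,000 for the model-size robustness check
under 100 nm noise, and 10–17 thousand frames of nested-domain simulation
for the positive spatial controls. Quarter-to-quarter occupancy spread at
10,000 trajectories per quarter is dominated by genuine sampling variation
(~±0.02), so the ±0.03 stability band is close to the information limit at
that scale.

## Known limitations

* $\sigma$ is global and state-independent; strongly state-dependent
  localization error would bias slow-state coefficients.
* The likelihood ignores step-to-step error correlation; at
  $\sigma^2 \approx D\Delta t$ this inflates apparent slow-state $D$
  slightly in both inference routes.
* The empirical transition matrix is conditioned on observed (surviving)
  steps; removal processes are invisible to it — which is exactly what the
  flux analysis exploits, but it means $A$ is not the generator of the
  full physical process.
* Span statistics are lower bounds with a bias that depends on track
  length; comparisons are meaningful at matched track-length
  distributions.
* Model-size selection with the Bayesian-type penalty needs tens of
  thousands of trajectories to resolve a three-state model at realistic
  noise; with a few thousand noisy trajectories it conservatively returns
  two states.
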
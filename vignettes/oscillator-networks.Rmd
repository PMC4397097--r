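---
title: "Topology, local dynamics and directionality in coupled oscillator networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology, local dynamics and directionality in coupled oscillator networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscnet)
```

## The model

`oscnet` studies how the wiring of a network shapes what each node does.
Every node `j` of an undirected graph carries a Stuart-Landau oscillator,
the normal form of a Hopf bifurcation, written as a complex state
`z_j = r_j exp(i theta_j)`:

```
dz_j/dt = (lambda + i w_j - |z_j|^2) z_j
          + (S / g_j^gamma) * sum_k K_jk z_k(t - tau_jk) + noise
```

`lambda` (default 2) sets the uncoupled limit-cycle radius `sqrt(lambda)`;
`w_j` are Gaussian natural frequencies (default mean 10 Hz, sd 1 Hz, the
EEG alpha band); `K_jk` is the binary adjacency matrix; `S` the global
coupling; `tau_jk` per-edge conduction delays (a constant 2-50 ms, or
distance/speed with speeds of 5-10 m/s); and `gamma` divides each node's
coupling by its degree `g_j` raised to `gamma`. Separating modulus and
argument gives paired amplitude and phase equations; freezing all
amplitudes at a common value reduces the phase equation to the
delay-coupled Kuramoto model, which `simulate_kuramoto()` integrates
directly.

The claim under test is a mean-field prediction: with sufficient coupling
and delays below a quarter oscillation period, `(K_j R)^2` (effective
coupling `K_j ~ k_j S` times the order parameter `R`) increases
monotonically with the squared steady amplitude, so higher-degree nodes
have **larger amplitudes**, and their steady phases satisfy a tangent
relation that makes them **phase lag** lower-degree nodes. Directionality
is quantified by the directed phase lag index,

```
dPLI_ij = < sign(wrap(theta_i - theta_j)) >_t ,
```

positive when `i` consistently leads. Hubs should therefore have negative
node-averaged dPLI (directional sinks) and peripheral nodes positive
(sources); dividing the coupling by degree (`gamma = 1`) homogenizes the
effective network and should erase both patterns.

## Numerical scheme

The integrator (`simulate_stuart_landau()`) works in Cartesian
coordinates with a stochastic Euler step (default `dt` = 1 ms, optional
substeps for convergence checks) and a ring-buffer history for the
delayed states, held at the initial condition for `t < 0`. Two details
matter:

* **Exact rotation.** The linear oscillation `exp(i w dt)` is applied as
  an exact rotation each step (an integrating-factor step). A naive Euler
  step inflates the limit-cycle radius by `(w dt)^2 / 2` per step, which
  at 10 Hz and 1 ms moves the uncoupled radius from 1.414 to about 2.0 —
  a 40% bias that corrupts every amplitude comparison. With the exact
  rotation the uncoupled fixed point is reproduced to machine precision.
* **No polar singularity.** The separated amplitude/phase form divides by
  `r_j`. With the default noise (sd 2) the amplitude regularly visits
  zero, where a polar integrator blows up; the Cartesian form is the same
  vector field without the singularity. Noise is still applied in polar
  coordinates (independent Gaussian increments of sd `noise_sd *
  sqrt(dt)` on modulus and angle, the modulus clipped at zero), with a
  complex-additive alternative via `noise_mode = "complex"`.

Phases are returned unwrapped. Delays are rounded to the nearest integer
number of (sub)steps. A run defaults to 10,000 samples at 1000 Hz with the
first half discarded as burn-in; initial phases are uniform on
`(-pi, pi]` and amplitudes start on the uncoupled limit cycle, so any
directionality in the output is created by the topology, not the
initialization.

### Ties in the sign function

`dpli()` maps wrapped phase differences smaller than `tie_tol` (default
1e-8 rad) to sign 0. The tolerance is irrelevant for any physically
resolvable signal; it exists for one degenerate case: exactly symmetric
noise-free oscillators (e.g. the leaves of a star) whose phase
differences decay exponentially to the integrator's rounding floor
(~1e-10 rad) while keeping an arbitrary persistent sign. Without the tie
band those meaningless residuals masquerade as perfect directionality.
Setting `tie_tol = 0` restores the literal sign rule.

## Network generators

* `generate_random_gilbert(n, epsilon)` links each pair with
  `p = (1 + epsilon) log(n) / n`, just above the connectivity threshold
  (`epsilon` = 0.1 by default), and redraws until connected.
* `generate_scale_free(n, exponent)` draws degrees from a *continuous*
  power law `x^-exponent` on `[1, n-1]` rounded to integers, then samples
  a uniform connected simple realization (Viger-Latapy, via `igraph`).
  The continuous-rounded law is used deliberately: at `exponent = 2.2` it
  gives a degree-1 fraction near 0.40 and occasional large hubs, matching
  published realizations of this generator class, whereas the discrete
  zeta law with a `sqrt(n)` cutoff puts 70% of nodes at degree 1 and caps
  hubs at degree 8, leaving a 78-node network too sparse to synchronize
  at the couplings studied here. Degree sequences with fewer than `n - 1`
  edges cannot be connected and are redrawn, which is exactly the
  conditioning that demanding a connected realization imposes.
* `make_brainlike_network()` emulates a 78-region cortical
  anatomical network: degrees from a power law with exponential cutoff
  (`P(k) ~ k^-1 exp(-k/8)` on `[3, n-1]` by default, giving mean degree
  ~7, largest hubs ~25 and no leaf nodes, the density regime of published
  DTI parcellations), and synthetic coordinates that place the
  high-degree tercile in a posterior band (negative y), the low-degree
  tercile anterior, with overlap in between. The bands guarantee the
  posterior-hub invariant by construction while keeping distance (and
  hence delay) structure non-monotone in degree; an earlier design that
  mapped degree rank monotonically onto the axis made delays a function
  of degree and distorted the directionality pattern under distance-based
  delays. The coordinates are a 1-D convention, not anatomy.

## The functional pipeline

`summarize_nodes()` reproduces an EEG-style analysis: 10-s epochs,
fifth-order Butterworth band-pass applied forward and backward (zero
phase), Hilbert instantaneous phases, PLI between all channel pairs
averaged over epochs, a binary functional graph from the top 30% of PLI
pairs (quota `ceiling(f * n(n-1)/2)`, ties broken in lexicographic pair
order for reproducibility), Welch band amplitude (Hamming window, 2-s
segments, 50% overlap, mean in-band PSD), and Spearman correlations with
t-approximation p-values. The functional-graph band defaults to the whole
band (0.5-55 Hz) and the dPLI/amplitude band to alpha, the pairing used
for the headline correlation; both are arguments.

`make_two_state_recordings()` produces the matching synthetic dataset:
the same network run intact (`gamma = 0`, "wake-like") and with
degree-normalized coupling (`gamma = 1`, "anesthesia-like", emulating
preferential hub disruption), identical frequencies, initial conditions
and noise stream, emitted as `r cos(theta)` channels decimated to 500 Hz.
The default coupling is `S = 3`, the value at which the anatomical-network
analysis reports its quantitative degree-dPLI and degree-amplitude
correlations; delays default to a constant 10 ms per edge (the model
network convention), with distance-based delays at 6 m/s as an option.
What the fixture does *not* emulate: volume conduction, referencing,
artifacts, or any spatial leakage between channels — passing tests show
the pipeline recovers the model's directionality from clean channel
signals, not that it would from scalp EEG.

## What the ensembles show at desk scale

The package's own checks run single realizations (one 10-s run per
network; ensembles of 30-100 networks in the tests and acceptance
script; two-state fixtures of 60 s at 8-20 seeds). At these sizes the
dense anatomical-like network at `S = 3` shows the full pattern per run
(degree-dPLI Spearman around -0.5, degree-amplitude around +0.85, both
near zero after `gamma = 1`), and the wake/anesthesia contrast survives
the entire functional pipeline. On the *sparse* 78-node scale-free and
random model networks at `S = 1.5` the amplitude correlation is clearly
positive per run (mean ~+0.5) but the per-run degree-dPLI correlation is
weak and sign-unstable: with mean degree near 2-3 these graphs sit below
the synchronization onset at that coupling, and the hub-lag ordering has
not yet formed (it appears cleanly from `S ~ 3` upward, and in
ensemble-averaged per-degree curves). Reported ensemble statistics
average per-run Spearman coefficients; single-run values on sparse
networks should be interpreted with that caveat.

## Other numerical choices

* Spearman p-values use the large-sample t approximation, ties get
  average ranks; no multiple-testing correction.
* Symbolic transfer entropy uses ordinal patterns of length 3 and scans
  prediction times 1-50 samples, reporting the maximum.
* Granger causality is ordinary least squares at model order 12, log
  variance ratio, no small-sample correction. Node-level summaries for
  both directed measures use each node's *mean incoming* value, the
  convention that makes the three directionality measures comparable
  (net in-minus-out flow behaves differently for Granger causality,
  because hubs both receive and exert strong prediction).
* The order parameter is the time-averaged modulus of the *mean* complex
  state `(1/N) sum_j z_j`, so values are comparable across network sizes.
* The mean-field tangent relation is only monotone for relative phases
  within `(-pi/2, pi/2)`; `check_orderings()` restricts the phase tally
  to nodes inside that band and treats the delay phase `beta` as mean
  natural frequency times mean edge delay.
* The quarter-period delay warning uses a 10 Hz reference (25 ms).

## Limitations

Degree sequences conditioned on connectivity are not exactly the
unconditioned law (the conditioning is unavoidable: disconnected-support
sequences admit no connected graph). Very steep power laws
(exponent >> 3) are incompatible with connectivity at these sizes — a
connected graph needs mean degree at least `2(n-1)/n` — and the generator
reports failure rather than silently densifying. The Euler scheme is
first-order; all headline orderings were checked against 10x-substepped
runs. At noise sd 2 the directionality of an 11-node star is marginal
(the lock angle is ~0.4 rad against ~1.1 rad of phase-difference
fluctuation); robustness of directionality to that noise level is a
property of larger, denser networks.
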
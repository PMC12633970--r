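---
title: "Models and methods: simulating in vivo burst firing of ELL pyramidal cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating in vivo burst firing of ELL pyramidal cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghostburst)
```

## The scientific problem

Pyramidal cells of the electrosensory lateral line lobe (ELL) of weakly
electric fish fire short, irregular bursts in vivo: runs of two or more
spikes separated by interspike intervals (ISIs) below ~12 ms, alternating
with isolated spikes at ~100 ms intervals, at mean rates of roughly
5-60 Hz.  In vitro, the same cells "ghostburst": bursts terminate near the
ghost of a saddle-node bifurcation, with a growing depolarising
afterpotential (DAP) that finally fails.  In vivo the DAP is suppressed
and burst statistics change qualitatively.  This package implements two
complementary models of the in vivo condition and the complete analysis
stack needed to compare them with intracellular recordings:

* a **two-compartment conductance-based model** (soma + proximal dendrite)
  with fast Na+/K+ spiking currents in both compartments, dendritic
  SK (calcium-activated K+) and NMDA currents, Markov-chain NMDA receptor
  kinetics driven by Poisson glutamate release, Li-Rinzel IP3-receptor
  calcium mobilisation, and additive 1/f^beta background synaptic noise;
* a **modified four-variable stochastic Hindmarsh-Rose (HR) model** with a
  second slow adaptation variable gated by tanh sigmoids of the voltage
  and of the classic slow variable.

Both are integrated with a fixed-step Euler-Maruyama scheme, analysed
with a common spike/burst pipeline, mapped over their firing regimes by
brute-force simulation, and fitted to feature targets by a
multi-objective (NSGA-II) search with a normalised-error loss and a
Kolmogorov-Smirnov acceptance gate.

## The biophysical model

The somatic and dendritic membrane equations are

$$C_m \dot V_S = I_{app} - I_{Na,S} - I_{K,S} - \tfrac{g_c}{\kappa}(V_S - V_D) - I_{leak,S},$$
$$C_m \dot V_D = I_{syn} - I_{Na,D} - I_{K,D} - I_{SK} - I_{NMDA} - \tfrac{g_c}{1-\kappa}(V_D - V_S) - I_{leak,D},$$

with $\kappa$ the somatic-to-dendritic area ratio.  The somatic Na+
current uses an instantaneous activation $m_{\infty,S}^2$ with $(1-n_S)$
as its inactivation surrogate; the dendritic Na+ current carries an
explicit inactivation gate.  All gates follow first-order kinetics
towards Boltzmann steady states.  Two currents distinguish the in vivo
configuration: the SK current
$I_{SK} = g_{SK}\,\frac{[Ca]_i^2}{[Ca]_i^2 + k_{Ca}^2}(V_D - V_K)$
and the calcium component of the NMDA current
$I_{NMDA} = g_{NMDA}\,B(V_D)\,[O]\,(V_D - V_{Ca})$, where
$B(V) = 1/(1 + e^{-0.062V}[Mg^{2+}]_o/3.57)$ is the magnesium block and
$[O]$ the open probability of a five-state receptor scheme
(C0 = C1 = C2 = O, with desensitised D branching from C2; both binding
steps proceed at $l_b[glu]$).  The driving force $(V_D - V_{Ca})$ is
deliberately the calcium component only, since it is this flux that
activates SK and terminates bursts.  Glutamate transients are alpha
functions triggered by a Poisson release process.

Dendritic calcium follows a flux-balance formulation: NMDA influx
($-\alpha I_{NMDA}$, inward current producing positive flux), Hill-type
PMCA and SERCA pumps, a Li-Rinzel IP3 receptor
($\nu_{IP3R} m_\infty^3 n_\infty^3 h^3 (Ca_{ER} - Ca_i)$ with the slow
inactivation gate $h$), and linear membrane/ER leaks.  In a closed-cell
configuration the combination $Ca_i/f_c + Ca_{ER}/(f_{ER}\gamma)$ is
exactly conserved, which the test suite verifies to below $10^{-8}$
relative drift over 10 simulated seconds.

### Units and time bases

Voltages are in mV, time in ms inside the membrane model, conductances
in mS/cm^2, currents in uA/cm^2 and calcium in uM.  Calcium flux rates
are specified in uM/s, the conventional unit for pump rates, and
converted to the ms base inside the right-hand side.  The public
simulation API uses seconds throughout.

### The reference parameter set is a calibration

The source publications for this model family do not print the full
parameter table in accessible text, so the package ships a documented
reference set: the spiking backbone (Na/K/leak/coupling conductances and
gate parameters) uses the classical two-compartment ghostbursting
values, and the additions specific to the in vivo configuration
(g_SK = 0.2, g_NMDA = 0.5, k_Ca = 0.6 uM, the current-to-flux factor
alpha = 40 uM cm^2/(uA s), nu_PMCA = 120 uM/s, I_app = 8) were calibrated
once so that the deterministic model passes through quiescence
(I_app below ~5.5), tonic firing (~6-7.5) and bursting (>= 8), that
increasing g_SK lowers the firing rate, and that blocking both SK and
NMDA produces the long DAP-carrying bursts of the in vitro ghostburster.
These values are calibration stand-ins, not fitted constants, and every
one can be overridden in `biophys_params()` or the JSON parameter
document.

Two readings of the source equations deserve a note.  First, the
integration step: the methods convention is a 100 kHz stepping rate with
traces downsampled to 10 kHz; at a 10x coarser step forward Euler cannot
resolve the fast Na+ upstroke (we observed voltage excursions beyond
+-800 mV), so `simulate_biophys()` steps at 0.01 ms by default.  Second,
the inward membrane leak: as printed, the flux
$J_{INleak} = \nu_{INleak}([Ca]_o - [Ca]_i)$ enters the cytosolic
balance with a minus sign, making it a net efflux.  We implement the
printed form; its consequence is that the resting calcium level is
maintained by tonic NMDA influx rather than by a passive inward leak,
and the calcium subsystem on its own (no NMDA drive) has no
non-negative steady state.  Steady-state tests therefore supply a small
tonic NMDA current, which is also the physiologically relevant
condition in vivo.

## Background synaptic noise

The synaptic bombardment is additive current noise with a $1/f^\beta$
power spectrum, synthesised in the frequency domain: the one-sided
magnitude is $f^{-\beta/2}$ inside a band (zero at DC and outside), each
bin gets a uniformly random phase, and the inverse transform is
standardised to unit variance and scaled by the total intensity
$\sigma_\eta$.  The normalisation is a package choice — the source
specifies the spectral shape, not the amplitude convention — and makes
$\sigma_\eta$ exactly the sample standard deviation of the injected
current.  The spectral exponent defaults to $\beta = 1$; per-cell values
are fit parameters in the original study and are not printed, so the
default is flagged as a calibration.  Band edges default to
$[1/T, f_{Nyquist}]$, avoiding the DC divergence.

## The modified Hindmarsh-Rose model

The classic three-variable HR model bursts with decelerating intra-burst
spikes and jumps abruptly from quiescence to bursting under increasing
current — both at odds with ELL pyramidal cells in vivo.  The modified
model adds a second slow variable $u$:

$$dV = [y - aV^3 + bV^2 - z - u + I_{app}]\,dt + \sigma_V dW_V,$$
$$dy = [c - dV^2 - y]\,dt + \sigma_y dW_y,$$
$$dz = [r(s(V - V_R) - z)]\,dt + \sigma_z dW_z,$$
$$du = [-\gamma_u n_\infty(V) + \alpha_z h_\infty(z) - \gamma_d u]\,dt + \sigma_u dW_u,$$

with $n_\infty(V) = \frac12(1 + \tanh((V - x_V)/k_n))$ and
$h_\infty(z) = \frac12(1 + \tanh((z - x_z)/k_h))$.  With
$\gamma_u = \alpha_z = 0$ and $u(0) = 0$ the system reduces exactly to
the classic model; the test suite verifies that the compiled integrator
tracks an independent classic-HR reference step for step to $10^{-10}$.

The model is dimensionless except for time.  "Time in seconds" is
implemented through an explicit scale factor `t_scale` (default 1000
per second, i.e. one HR time unit per millisecond), chosen so firing
rates land in the recorded 5-60 Hz envelope; noise intensities are
expressed per square-root HR time unit so drift and diffusion rescale
together.  The classic coefficients take their literature values
(a = 1, b = 3, c = 1, d = 5, s = 4, V_R = -1.6, r = 0.006); the new
coefficients ($\gamma_u = 0.1$, $\alpha_z = 0.3$, $\gamma_d = 0.1$,
$x_V = -0.4$, $x_z = 2.8$, $k_n = k_h = 0.4$, default $I_{app} = 2.6$)
are again a one-time calibration, chosen so that an increasing-current
sweep passes through quiescence (below ~1.2), regular tonic firing
(~1.3), and bursting (from ~1.8-2.6), with bistability between rest and
sustained firing just below the firing onset and single-spike
(type-IV-like) responses to subthreshold perturbations.  The published
anchor currents for the three example regimes (tonic 0.4, chaotic 1.1,
doublets 1.9) depend on an unavailable supplementary parameter table;
with this calibration the same phenomenology appears shifted to
slightly higher currents, which we treat as acceptable for a
calibration stand-in.

## Integration engine

Both models use fixed-step Euler-Maruyama:
$X_{k+1} = X_k + f(X_k)\,dt + \sigma\sqrt{dt}\,\xi_k$ with independent
standard-normal deviates per noisy variable per step, drawn from R's
seeded generator so any run is reproducible from one master seed (child
streams are derived deterministically with `derive_seed()`).  With all
intensities zero the scheme is exactly forward Euler and bit
reproducible.  Output is downsampled by pure decimation — every k-th
integration step, no anti-alias filtering — which preserves spike peaks
exactly; the biophysical model records at 10 kHz from 100 kHz stepping
and the HR model at 10 kHz from 20 kHz stepping.  Because all noise in
both models is additive, the Itô/Stratonovich distinction is moot.
The engine's statistics are validated on the Ornstein-Uhlenbeck
benchmark (stationary variance $\sigma^2/2\theta$) and on deterministic
exponential decay (first-order error, halving with the step).

## Analysis pipeline

The same pipeline applies to recordings (CSV traces at 10 kHz) and
simulations:

* **Spike detection** at a fixed threshold (-30 mV for biophysical/data
  traces whose baseline sits near -70 mV; 0 for the dimensionless HR
  voltage), placing spikes at the local maxima of threshold-exceeding
  excursions and merging detections closer than 1 ms (an
  artifact-refractory rule; the alternative baseline-relative mode takes
  a positive excursion above the trace median).
* **Waveform features** in a +-4 ms window: dV/dt-onset threshold
  (20 V/s default), peak, post-peak trough, 50%-amplitude upstroke and
  downstroke voltages, and the ADP voltage (post-trough local maximum,
  NA when the segment is monotone; NA rows are excluded from ADP
  statistics).  Boundary-clipped spikes are excluded.
* **ISI distributions**: 2 ms histograms, Gaussian KDE with Scott's-rule
  bandwidth $\hat\sigma n^{-1/5}$, and a bootstrap band from 50
  resamples of random 4-s segments.
* **Burst statistics**: maximal runs of >= 2 spikes with all consecutive
  ISIs under 12 ms (per-cell thresholds can instead be estimated from
  the KDE minimum between the two largest modes); burst fraction =
  spikes in bursts / total spikes.  The implementation is checked
  against a brute-force run-enumeration oracle on 1000 random trains.
* **Two-sample KS test** (asymptotic), used as the distribution gate for
  accepted fits and checked against an exhaustive ECDF-sup oracle.

## Regime mapping

Numerical continuation is out of scope; firing-regime maps are
brute-force.  `sweep_1d()` simulates each grid point deterministically
(20 s windows after a 2 s transient in the full protocol; shorter
windows in the examples here), classifies the spike train — quiescent,
tonic (ISI CV < 0.05 and no intra-burst-range ISI), doublet (all bursts
of exactly two spikes recurring periodically), burst, or depolarisation
block (no spikes with a supra-threshold mean voltage) — and records a
rate map.  Warm starts follow an attractor branch; comparing warm
against cold starts, or probing fixed parameters from several initial
states (`bistability_probe()`), exposes multistability.  This recovers
the topology of the regime regions but not exact bifurcation loci, a
documented limitation of replacing continuation with simulation.  The
classification CV cutoff (0.05) is an implementation constant,
configurable per call.  Chaotic versus periodic bursting is
distinguished only through ISI dispersion diagnostics, not Lyapunov
exponents.

## Fitting and sensitivity analysis

`fit_model()` minimises per-feature normalised errors
$|sim - target|/scale$ as separate objectives with an in-package
NSGA-II (fast non-dominated sort, crowding distance, SBX crossover,
polynomial mutation; population 50 by default).  Scales default to the
absolute target value with a floor of $10^{-3}$, weights to equal;
with equal weights a total loss below 0.1 means less than 10% average
normalised error, the acceptance criterion.  A fit is accepted when the
loss gate passes and, if the target carries an ISI sample, the
simulated ISI distribution is statistically indistinguishable from it
(KS p > 0.05).  Each trial simulates under a fixed seed (common random
numbers) to stabilise ranking of stochastic objectives.  Biophysical
fits may include waveform features; HR fits use spike-train features
only, matching the phenomenological character of that model.

Sensitivity analysis has two routes.  `sobol_fit_archive()` implements
the archive-ratio estimator: trials with loss >= 0.1 are discarded, and
$S_i = \mathrm{var}_i/\mathrm{var}_{total}$ where $\mathrm{var}_i$ is
the variance of the binned conditional expectation of the loss on
parameter $i$ (the source does not specify the estimator of
"variance attributable to parameter i"; this ANOVA-style choice is
validated against closed-form additive models).  `sobol_model()` is a
standard Saltelli first-order estimator on Latin-hypercube designs,
validated against the Ishigami closed form (indices within 0.05 at
$n = 2^{14}$).

## The synthetic-data generator

Recorded traces from the original study are not public.
`generate_reference_recording()` and `population_preset()` therefore
emulate the recording protocol — 5-s traces at 10 kHz — with known
ground truth.  The population preset draws modified-HR parameter sets
(applied current in [2.0, 3.2], slow-adaptation decay in [0.07, 0.13],
voltage-noise intensity in [0.1, 0.4], u-noise in [0, 0.02]) and keeps,
by rejection, draws whose mean rate falls in 5-60 Hz with burst
fraction strictly inside (0, 1); most accepted cells show bimodal ISI
densities with the short mode under 12 ms.  These synthetic cells
reproduce the envelope-level statistics of the recorded population
(rates, burst fractions, ISI bimodality) but not per-cell waveform
detail, electrode noise, or slow nonstationarities of real recordings —
passing tests on them demonstrates the pipeline and the models'
phenomenology, not agreement with the unavailable data.

## Numerical choices and degenerate inputs

* Parameter validation rejects kappa outside (0, 1) (the coupling
  divides by kappa and 1-kappa), non-positive time constants, zero gate
  slopes, and unknown JSON keys (typo protection).
* Gating variables stay in [0, 1] without clipping because each Euler
  update is a convex combination whenever $dt < \tau$; the Markov
  occupancy simplex is likewise forward-invariant, and both properties
  are tested rather than enforced.
* Simulations abort with the offending step index on non-finite states;
  regime sweeps record such points as failed and continue.
* The glutamate release-to-concentration convolution is evaluated by
  FFT on the integration grid (events snapped to the 0.01 ms grid); the
  alpha-function tail is truncated at 40 decay constants.
* Problem sizes in the test suite and acceptance script (10-20 s
  regime windows, 500-trial fits, $2^{14}$-sample Sobol designs,
  32-cell populations) were chosen as the smallest sizes at which the
  statistical assertions are stable under the fixed seeds; all scale up
  through function arguments.

## Known limitations

* All SK/NMDA/calcium constants and the modified-HR extension
  coefficients are calibration stand-ins for an unavailable parameter
  table; quantitative bifurcation anchors are therefore not reproduced,
  only the regime phenomenology.
* No cable morphology, spine-level calcium diffusion, IP3 metabolism,
  or conductance-based (multiplicative) synaptic noise.
* Desensitisation branches from C2 in the NMDA scheme; the alternative
  (from O) is not distinguishable from the available description.
* Regime maps are simulation-based; exact bifurcation loci, Floquet
  multipliers and homoclinic structure are out of scope.
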
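---
title: "Warm-started parameter inference for the hERG channel model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Warm-started parameter inference for the hERG channel model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The rapid delayed-rectifier potassium current I\_Kr, carried by the hERG
channel, terminates the cardiac action potential, and drug block of hERG is
the central concern of proarrhythmia safety assessment (the CiPA paradigm).
Model-based characterisation of hERG kinetics fits a mechanistic model to a
voltage-clamp recording; the fit is slow and can fail in local minima, and
both problems are dominated by the choice of starting point. `hergfit`
implements a complete pipeline around that observation: a neural regressor is
trained on simulated currents to predict model parameters directly from a
recording, and its prediction is used to warm-start a CMA-ES fit, which is
benchmarked against naive initialisations.

## The channel model

The model is the two-gate Hodgkin–Huxley description of I\_Kr:

$$I_{Kr} = g_{Kr} \, a \, r \, (V - E_K),$$

with activation gate $a$ and inactivation gate $r$ relaxing as
$da/dt = (a_\infty - a)/\tau_a$, $dr/dt = (r_\infty - r)/\tau_r$, where

$$k_1 = p_1 e^{p_2 V},\quad k_2 = p_3 e^{-p_4 V},\quad
  k_3 = p_5 e^{p_6 V},\quad k_4 = p_7 e^{-p_8 V},$$
$$a_\infty = \frac{k_1}{k_1+k_2},\ \ \tau_a = \frac{1}{k_1+k_2},\ \
  r_\infty = \frac{k_4}{k_3+k_4},\ \ \tau_r = \frac{1}{k_3+k_4}.$$

The nine free parameters are $\theta = (g_{Kr}, p_1, \dots, p_8)$:
conductance in pA/V, prefactors in s$^{-1}$, voltage sensitivities in
V$^{-1}$. $E_K$ is the Nernst potential, $(RT/zF)\ln([K^+]_o/[K^+]_i)
\approx -85.2$ mV at the default room-temperature constants
(R = 8.314472 J/(K·mol), T = 298.15 K, F = 96485.3415 C/mol, z = +1,
4 mM external / 110 mM internal potassium). Internally all voltages are in
volts, times in seconds, currents in pA.

### Exact simulation

Voltage-clamp commands are piecewise constant (`VoltageProtocol`). Within a
constant-voltage segment both gate ODEs are linear with constant
coefficients, so the trajectory is the exact exponential relaxation
$x(t) = x_\infty + (x_0 - x_\infty)e^{-(t-t_0)/\tau}$ chained across
segments. `simulateCurrent(method = "analytic")` evaluates this closed form
— no discretisation error, microseconds per trace — and is the default
everywhere. A conventional adaptive stiff integrator
(`method = "ode"`, `deSolve::lsoda` at abs/rel tolerances 1e-8/1e-10, both
configurable) is retained as an independent numerical route; the test suite
checks the two agree to better than 1e-4 relative RMS and that the ODE route
is stable under tolerance refinement. We adopt the printed tolerance pair
verbatim even though a relative tolerance tighter than the absolute one is
unusual.

Gates start at equilibrium for the first segment's voltage, the standard
electrophysiology convention; it makes traces a deterministic function of
(parameters, protocol). Rate-law exponents beyond ±700 would overflow double
precision; they raise a simulation-infeasibility condition that the fitters
treat as a worst-case objective value.

### The staircase protocol

The recordings this pipeline emulates use a staircase protocol: 500 ms
constant-voltage steps spanning −120 to +60 mV over 15.4 s, sampled at
5 kHz. The exact published step sequence is distributed graphically rather
than as a table, so `staircaseProtocol()` ships a documented approximation
honouring the printed constraints (500 ms core steps, the
[−0.12, 0.06] V window, 15.4 s total): leading/trailing −80 mV holds around
a full ascending and a full descending staircase in 20 mV increments plus
alternating activation/deactivation probe steps. Protocols are first-class
inputs (`duration_s,voltage_V` CSV, written at full precision so round trips
are exact); users with the published table should supply it via
`readProtocolCSV()` for fidelity work. Segment boundaries follow the
half-open convention, so V(t) is right-continuous and single-valued.

## Prior, constraints and normalisation

The prior is componentwise over the box g ∈ [100, 5·10^5] pA/V,
prefactors ∈ [10^-4, 10^6] s^-1, sensitivities ∈ [10^-4, 400] V^-1,
intersected with four physiological constraints: each transition rate,
evaluated at the extreme voltage where it is largest (+60 mV for k1, k3;
−120 mV for k2, k4), must lie strictly inside (1.67·10^-2, 10^6) s^-1 —
no kinetic process slower than ~a minute or faster than a microsecond.

Two sampler design points deserve note:

* **Log-uniform prefactors.** The conductance and the sensitivities are
  uniform on the raw scale. For the decade-spanning prefactors we sample
  uniformly in log10. A raw-uniform draw would put ~90 % of its mass in the
  top decade; after the constraints the accepted prefactors would sit near
  10^5 s^-1 — microsecond kinetics ten decades away from measured hERG
  rates (p1 ≈ 0.2 s^-1), so a regressor trained on such data could never
  predict a physiological cell. Log-uniform sampling spreads the accepted
  mass across the decades (and it is what the accepted marginals of this
  prior family look like when plotted on log axes), restoring coverage of
  the kinetics the pipeline exists to infer.
* **Pairwise rejection.** The four constraints factorise over the
  independent pairs (p1,p2), …, (p7,p8), so each pair is rejection-sampled
  against its own constraint. This is exactly equivalent to joint rejection
  — the acceptance indicator is a product — and about six orders of
  magnitude cheaper. Seeding is counter-based per draw/pair/attempt, so
  draw *i* under a given seed is reproducible regardless of how many draws
  are requested.

For learning, parameters are mapped to [0,1]^9: log10 on the log-flagged
components (prefactors, and g\_Kr since it spans 3.7 decades — configurable),
then min–max normalisation with bounds derived from the prior, never from a
data batch, so training, validation and inference share one fixed transform.

## Synthetic data

A training example is (decimated noisy trace, normalised θ): draw θ from the
constrained prior, simulate 15.4 s at 5 kHz, add iid zero-mean Gaussian
noise with σ = 10.84 pA (the value measured at steady-state current in the
emulated recordings) on the full-rate trace, then keep-first decimate by 50
to 1,540 samples at 100 Hz. Decimation by 50 (not "every 100th point") is
the choice consistent with the 129-frame spectrogram geometry below. Failed
simulations are resampled rather than clamped, preserving the prior's
support. Counter-based per-example seeding makes containers bit-identical
across runs.

The generator emulates additive recording noise only — no leak, series
resistance, capacitance transients or drift. Passing tests therefore show
parameter recovery under the model's own noise assumptions, not robustness
to the artefacts of real patch-clamp data.

**Benchmark cells** (`sampleBenchmarkCells()`) play the role of the
experimental cell population: log-uniform ×/÷2 perturbations of a
literature-typical hERG parameter set (`demoParams()`), conductance varied
over a decade, clipped to the prior box, constraint-checked, and passed
through a peak-current quality filter (clean peak ≥ 250 pA ≈ 25σ). This
mirrors a population of biological replicates that has passed experimental
QC; raw prior draws are not used as cells because they include dead channels
and microsecond kinetics that no QC'd recording would retain.

## Spectrogram features

Traces are featurised as magnitude STFT spectrograms with n\_fft = 256,
hop = 12, win = 48: centred framing on the reflect-padded signal, periodic
Hann window zero-padded to n\_fft, one-sided spectrum. A 1,540-sample trace
yields exactly 129 frames × 129 bins. Design points the source description
leaves open, resolved here: magnitude (not power or dB) with log1p
compression — bounded at zero and stable for silent regions; Hann window
(the de facto STFT default); traces are divided by a fixed global scale of
10^4 pA rather than per-trace maxima, so absolute amplitude — the signal
for g\_Kr — survives featurisation. Lower resolutions are obtained by
corner-aligned bilinear resizing (identity at equal shape, constants and
non-negativity preserved).

## The regressor

The reference pipeline this package scales down used a pretrained
EfficientNetV2-M behind a CNN encoder, 500,000 training examples and GPU
epochs; its printed errors depend on that scale and on external experimental
data, and are out of scope here. `hergfit`'s default backbone is a small CNN
(three 3×3 conv blocks of 12/24/48 channels with 2×2 max pooling, adaptive
average pooling to a fixed 6×6 grid, and a 96-unit dense head; ~180k
weights) trained with Adam on the mean squared error
$J = \frac{1}{N}\sum_i \lVert f(x_i) - y_i\rVert^2$ in normalised parameter
space. The adaptive pooling makes the conv stack independent of input
resolution, which is what lets the two-stage schedule transfer weights:
stage one trains at 33×33 on 60 % of the data, stage two continues at 49×49
on the full set at a halved learning rate — the same
low-resolution-subset-then-transfer pattern as the reference schedule
(97×97 on 300k, then 129×129 on 500k), at desk scale. At the default sizes
(2,000 examples) training takes a few minutes on one CPU and the validation
MSE lands well below the constant-mean-predictor baseline; per-parameter
rank correlations are positive for all nine parameters, weakest for g\_Kr
and the inactivation sensitivities.

Training/validation discipline mirrors the reference: the network only ever
sees synthetic data; a held-out synthetic split stands in for the
experimental validation set (an odd/even split utility is provided for users
with ordered real cells). Predictions are clipped to [0,1]^9 and
de-normalised to a valid parameter object.

## Fitting

`objectiveRMSE()` is the root-mean-square difference (pA) between the
observed decimated trace and the clean model current evaluated exactly on
the observed sample grid (for the analytic simulator, identical to
simulate-then-decimate). `fitCMAES()` minimises it with a standard
(μ/μ\_w, λ)-CMA-ES written for this package (no CMA-ES implementation is
available in the environment's R stack), in normalised space so steps are
commensurate across ten-decade parameter ranges, with σ₀ = 0.1, candidates
clamped to the box under a quadratic out-of-box penalty, and
constraint-violating candidates given a large violation-distance penalty
instead of a simulation. Infeasible *initialisers* are projected into the
feasible region (minimal prefactor rescaling) with a message.

Optimiser defaults that differ from the obvious textbook choices, chosen
for this landscape and applied identically to every initialiser:

* population λ = 16 (double the 4+⌊3 ln 9⌋ = 10 default): the normalised
  objective is strongly anisotropic and the larger population makes
  covariance learning reliable; the initialiser benchmark uses λ = 32 so
  iteration counts spread well below the cap instead of saturating it;
* stagnation stop when the best objective improves by < 10^-3 pA (0.01 % of
  the noise floor) over 60 iterations, rather than 10^-6 over 30: the
  tolerance is meaningful in the objective's physical units and the longer
  window stops slow covariance learning from being mistaken for a stall;
* iteration cap 1,000 (300 in the benchmark harness).

Outcomes are classified against the noise floor: a clean termination with
RMSE ≤ 1.2σ is **converged** (on a correctly fitted noisy trace the best
attainable RMSE concentrates near σ); a clean termination above that is a
**local minimum**; an optimiser/simulator breakdown is a **failure**. The
1.2 multiplier is configurable.

**Parameter-recovery harness.** Recovery benchmarks fit traces decimated by
10 (500 Hz, 7,700 points) rather than 50: hERG inactivation relaxes in
~5–20 ms, which 100 Hz sampling under-resolves — at factor 50 the
maximum-likelihood optimum itself can sit >10 % away from the truth in the
inactivation parameters, a data limit no optimiser can cross. At 500 Hz,
fits from ×/÷1.5-perturbed starts recover every kinetic parameter within
10 % on ≥ 9 of 10 noisy cells. The warm-start benchmark keeps factor 50,
matching the training data the regressor saw.

**Initialiser benchmark.** `benchmarkInits()` fits every cell three ways —
the regressor's prediction, a fixed "prior" vector (default: the midpoint
of the normalised box, since a canonical prior point is otherwise
undefined), and a fresh random prior draw — under common random numbers
(one optimiser seed per cell shared by all three arms) so the comparison is
paired. Mean iterations and wall time are reported both over converged fits
(the fitting-rate comparison for cells that succeeded) and over all fits;
wall times are reported for completeness but never asserted in tests
(hardware-dependent). At the desk scale (20 cells, 2,000 training
examples, cap 300) warm-starting converges more cells and needs ~10 %
fewer iterations than random initialisation with zero failures; the
reference pipeline's much larger margins come with its much larger
training scale and its experimental cells.

## Posterior exploration

`adaptiveMetropolis()` runs random-walk Metropolis in normalised space under
the iid Gaussian likelihood with known σ (matching the noise model; σ
estimation is out of scope) times the box-and-constraints prior. The
proposal follows the Haario adaptive scheme — covariance 2.38²/d times the
running chain covariance with a small regulariser, refreshed every 50
iterations after a 500-iteration warm-up — plus a diminishing global-scale
adaptation toward 0.25 acceptance. A thousand consecutive rejections raise
a stall error. On synthetic cells, 20,000 iterations take ~15 s, acceptance
sits near 0.27, and posterior means fall within 3 posterior SDs of the
generating parameters.

## Problem sizes and determinism

Defaults used by the test suite and the acceptance script, chosen as
desk-scale analogues of the reference study: 2,000 training examples
(1,600/400 split), 20 benchmark cells, 10 recovery cells, 50×5 steady-state
checks, 10,000 prior draws, 20,000 MCMC iterations. Every stochastic step
takes an explicit integer seed and derives counter-based substreams from
it, so datasets are bit-reproducible and fits deterministic given their
seed.

## Known limitations

* The default staircase is an approximation; quantitative comparison with
  published per-cell estimates requires the published protocol table.
* The noise model is additive white Gaussian only; real recordings add
  leak, drift and filtering artefacts the regressor has never seen.
* The small CNN at 2,000 examples predicts coarse parameter locations, not
  the near-perfect warm starts a 500k-example pretrained backbone can
  deliver; the warm-start margin scales accordingly.
* The analytic simulator covers piecewise-constant protocols only; ramp or
  sinusoidal commands would need the ODE route with a time-dependent
  voltage term (not implemented).
* Per-parameter identifiability at heavy decimation is data-limited for
  the fast inactivation gate (hence the factor-10 recovery harness).
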
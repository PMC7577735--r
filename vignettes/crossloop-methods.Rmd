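---
title: "Models and methods behind crossloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crossloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossloop)
```

`crossloop` analyses one-degree-of-freedom visuomotor behaviour in two
paradigms: continuous tracking of an unpredictable target, and discrete
30° elbow reaches under altered visual feedback. This vignette explains the
models, the parameters that matter, what the synthetic-data generators do
and do not emulate, and the numerical choices that were genuinely open.

## The tracking stimulus

The sum-of-sines target is
$\theta(t) = \sum_{i=1}^{15} A_i \sin(2\pi f_i t + \phi_i)$ with
$f_i = m_i \cdot 0.05$ Hz and $m_i$ the first fifteen primes from 2 to 47.
Primality guarantees that no stimulated frequency is an integer multiple of
another, so the target has no short periodicity a subject could exploit,
while every component falls on an exact DFT bin of the 20 s fundamental
period (five periods tile the 100 s trial). Amplitudes obey
$A_i = \min(2°,\, 720°/s \,/\, 2\pi f_i)$; with the default caps the
positional limit binds everywhere in 0.1–2.35 Hz, so all amplitudes are 2°.
The per-component amplitudes are a design choice — only the two caps are
fixed by the paradigm — and the min-rule is the least-informative choice
consistent with both. Phases are drawn uniformly on $[0, 2\pi)$ from a named
seed, one draw per component, so a realisation can be replayed exactly.

## The tracking subject and its loop

A tracking subject is a McRuer-style crossover controller: it integrates,
with gain $k$, the error between a gain-scaled delayed view of the target
($G$, $T_v$) and a delayed view of its own displayed cursor ($T_f$), while
the experiment multiplies the displayed cursor by a feedback gain
$g_{fb} \in \{0.65, 1, 1.35\}$:

$$H(j\omega) \;=\;
  \frac{G\, e^{-j\omega T_v}\, k/(j\omega)}
       {1 + g_{fb}\, e^{-j\omega T_f}\, k/(j\omega)}.$$

The apparatus display latency (46 ms) is applied to both the target and the
cursor display, so *fitted* delays are totals that absorb it; the reference
parameter set (`referenceParams()`) therefore quotes visual delays of
210/141 ms as totals, and simulated subjects subtract the display latency
from their intrinsic delays to reproduce those totals.

The simulator runs the loop at 1 kHz with forward Euler and integer-sample
delay buffers; motor noise is additive white Gaussian on the commanded
velocity. Delays are quantised to whole samples (at most 0.5 ms rounding).
One numerical point deserves emphasis: a forward-Euler integrator's
frequency response is $k\Delta t/(z-1)$, which deviates from $k/(j\omega)$
by ~0.7% at 2.35 Hz. `closedLoopFR()` therefore offers two conventions —
`"matched"`, the exact z-domain response of the simulated loop (phasors
estimated from noiseless trials agree with it to ~1e-14), and
`"continuous"`, the ideal formula used by the model-fitting layer. Tests of
the estimator use the matched oracle; fits of simulated *phasor* cohorts use
the continuous form throughout, so the two conventions never mix.

With `use_smith_predictor = TRUE` the subject maintains an internal copy of
its plant and a matched delay buffer, feeding back the predicted cursor plus
the delayed prediction error. Noiselessly this cancels the self-feedback
delay exactly, which is the content of the Smith equivalence: the matched
predictor reduces to the delay-free-feedback (control-like) structure, and
removing the predictor leaves the delayed-feedback (patient-like) structure.
Only the lumped cascade $CP = k/s$ matters for this identity, so the
controller/plant split is kept symbolic. The diagram is implemented as
drawn, with one shared visual delay on both inputs; the internal plant scale
and delay copy are exposed so mismatch sensitivity can be probed.

## Phasor estimation

The estimator discards the first fundamental period (20 s) as transient,
averages the elbow series across trials per time instant (samples masked in
a trial are excluded from that mean; samples masked in *every* trial are
linearly interpolated), removes offset and linear trend, and takes the ratio
of response to target DFTs at the stimulated bins. With 80 s retained at
1 kHz the frequency resolution is 0.0125 Hz and every default frequency is
an exact bin, so rectangular windowing is leakage-free.

Detrending needed care: an ordinary least-squares line is not orthogonal to
finite-length sinusoids, so naive detrending perturbs every stimulated bin
by a few parts in a thousand. The package estimates the trend *jointly* with
sinusoids at the stimulated frequencies and subtracts only the trend part;
this leaves the periodic content untouched and makes the estimator exactly
invariant to added linear trends. Single-sine trials skip averaging and
masking and average per-trial phasors instead (with an identical target this
is algebraically the same operation).

Derived quantities follow the phasor-plane geometry: tracking error
$|H - 1|$ per frequency and summed over the five lowest; classification
against the effort/error circle $|H - 0.5| \lessgtr 0.5$ with a configurable
"on" band (1e-6 by default, appropriate for synthetic data; widen it for
empirical phasors); and the scaling factor
$s = \sum \mathrm{Re}(\bar p_i v_i) / \sum |p_i|^2$ over the five lowest
frequencies, a real scalar so phase is untouched. Phase lags are reported
clockwise in $[0, 360)$; group summaries use the argument of the unit-vector
sum (circular mean).

## Model fitting and selection

A model structure is a set partition of the four gains and a set partition
of the four delays (gains yoke with gains, delays with delays), with any
delay class optionally pinned to zero. Canonicalising the zero-pinned
patterns leaves 780 distinct closed-loop structures
(`enumerateStructures()`), plus named degenerate forms (pure gain, delayed
gain, open-loop integrator). Fitting minimises the frequency-domain error —
the plain, unweighted sum of squared complex differences over the 15
frequencies, patient and control terms added — with Nelder–Mead from 100
random restarts by default (k log-uniform on [0.1, 20] 1/s, visual gains
uniform on [0, 1.5], delays uniform on [0, 0.5] s; reltol 1e-10).
Non-negativity is enforced by optimising through an absolute-value
transform, which is benign because fitted values sit well inside the
positive orthant.

Generalisation is gauged by leave-one-pair-out error: fit on the average of
the remaining pairs, evaluate on the held-out pair, average over folds.
Consistency is the largest singular value of the fold-parameter residual
matrix, computed on raw parameter units (1/s and s mixed, no rescaling) —
deliberately so, since rescaling would change which structures look
consistent. Selection takes the Pareto front over (leave-one-out error,
consistency), breaking exact ties toward fewer free parameters, and labels
front members per free-parameter stratum. Bootstrap confidence intervals
resample patient–control *pairs* with replacement (pairs move together)
and take percentile intervals over refits. Time-domain validation
re-simulates the fitted loop against the target trajectory and scores the
mean squared elbow-angle difference over the last 80 s.

Evaluating the leave-one-out/consistency trade-off across all 780
structures at full restart counts is a cluster-scale computation; the
package's own demonstrations and checks run the selection on a
representative candidate set (`referenceStructures()`: the full 8-parameter
model, the four top reduced structures, the a-priori hypothesised model, a
delay-free loop and the degenerates) at 10–20 restarts, which a single CPU
completes in seconds. Synthetic-cohort experiments use 11 pairs with
circular complex phasor noise of sd 0.05 per subject and frequency, the
scale at which recovery of the reference reduced model (shared $k = 2.7$/s,
shared $G = 0.39$, patient visual delay 210 ms, control visual delay and
patient feedback delay 141 ms, control feedback delay 0) is accurate to a
few percent in $k$ and ~1 ms in delays.

Under an applied feedback gain $g_{fb} = 1.35$, a subject that compensates
partially — rescaling movement as if the gain were 1.2 — is exactly the
parameter change $k \to k/1.35$, $G \to G \cdot 1.35/1.2$ (the loop term
$g_{fb} k$ is unchanged, the forward numerator shrinks by 1/1.2). This is
how the generators produce gain-condition cohorts, and fitting them moves
$k$ down and $G$ up with delays unchanged, the expected direction pattern.

## Reaches, altered feedback and PEST

The displayed cursor during reaches is
$\mathrm{cursor}(t) = \mathrm{elbow}(t) + k_a \hat a(t)$, where $\hat a$ is
the real-time acceleration estimate: a causal second difference passed
through a trailing 100-sample moving average, whose group delay is exactly
$(W-1)/2$ samples = 49.5 ms at 1 kHz. Samples before the series start are
treated as zero acceleration (the limb starts at rest).

The reach simulator is deliberately kinematic. The primary movement is a
minimum-jerk plan whose executed acceleration is scaled by the internal
model mismatch $\hat J / J$ — over-estimating inertia commands too much
torque and overshoots. In-flight corrections are modelled as *amplitude
regulation*: during the deceleration phase the subject integrates, with a
single rate gain, the delayed discrepancy between the displayed cursor and
its forward-model prediction of the arm. Two consequences are intended.
First, the inertial mismatch is invisible to this process (the same
miscalibrated internal model generates both the command and the
prediction), so dysmetria persists into the first correction rather than
being servo-ed away — a linear goal-seeking servo can never stop short of
its target and therefore cannot produce hypometric stops at all, which is
why a torque-level corrective loop was rejected. Second, with $k_a > 0$ the
cursor lags the predicted arm during deceleration (estimated acceleration is
negative), so the regulation extends the reach — positive gains push toward
hypermetria and negative gains toward hypometria, monotonically.
Corrections cease once the delayed view of the completed movement has
arrived or the arm has stopped; later corrections belong to subsequent
submovements and cannot move the angle of first correction. Motor noise is
mean-reverting (OU) velocity noise, so noisy reaches still terminate in a
genuine stop. The simulator reproduces the required sign behaviours — the
mismatch direction, the monotone dose–response in $k_a$ — but it does not
emulate torque-level dynamics, oscillation around the target after the
first correction, or the mid-reach pausing seen at extreme gains, so
passing tests certify the analysis pipeline and the staircase logic, not
musculoskeletal realism.

Dysmetria is quantified as the elbow excursion at the first velocity
zero-crossing after initiation; initiation is the first sample whose
goal-directed velocity exceeds 5% of peak (the threshold is a package
choice; the zero-crossing rule is the paradigm's). The ratio to the 30°
goal classifies reaches with thresholds 0.97 and 1.03.

PEST adjusts $k_a$ from block modes of 10 reaches: hypermetric blocks
decrease the gain, hypometric blocks increase it, on-target blocks leave it
in place, and two consecutive on-target blocks at the same gain terminate.
Step sizing follows the classical staircase rules — halve on reversal; the
second same-direction step repeats the first; the fourth and later steps
double; the third doubles unless the step before the last reversal was
itself a doubling — clipped to [0.0035, 0.01] with the gain clamped to
±0.02. Tie-breaking of block modes (on-target wins ties; a
hypometric/hypermetric tie falls back to the previous step direction) and
the 40-block budget standing in for a human time/fatigue stop are package
choices, as is the best-so-far rule (most on-target reaches, latest block
on ties) when the budget runs out. The gain grid is kept continuous rather
than snapped to step multiples.

## Reference reachers and study conditions

`referenceReachers()` fixes the synthetic reach conditions: inertia 0.11
kg·m² (forearm plus manipulandum about the elbow), ±5% internal-inertia
mismatch for the dysmetric templates, a 0.7 s / 30° minimum-jerk plan,
150 ms visual delay, correction-rate gain 4/s, and OU motor noise scaled so
the angle of first correction jitters by ~0.3–0.4° between reaches —
enough to make block modes probabilistic, as in practice, without swamping
the ±0.9° on-target band. These values were chosen once, for physiological
plausibility, and are not tuning knobs.

## Known limitations

* The tracking simulator's motor noise is white on velocity; real motor
  noise is signal-dependent. Noise enters the phasor cohort generators as
  circular complex perturbations, which matches the estimator's asymptotics
  but not trial-level artefacts (coughs, pauses); masks must be supplied
  explicitly, as no automatic artefact detection is attempted.
* Leave-one-out selection is demonstrated on candidate structure sets, not
  the full 780-structure enumeration, which is provided but costly.
* The reach model is single-joint and kinematic by design; multi-joint
  extensions and damping-based suppression of post-correction oscillation
  are out of scope.
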
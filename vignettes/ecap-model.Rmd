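---
title: "A 2-D model of eCAP amplitude-growth functions in the implanted cochlea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 2-D model of eCAP amplitude-growth functions in the implanted cochlea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecapsim)
```

## The problem

Cochlear-implant telemetry can record electrically evoked compound action
potentials (eCAPs): the summed extracellular response of the auditory nerve
fibers (ANFs) to a current pulse, picked up on an intracochlear electrode.
The growth of the eCAP amplitude with stimulus charge — the amplitude-growth
function (AGF) — and its change when the inter-phase gap (IPG) of the
biphasic pulse is prolonged are widely used as proxies for the health of the
electrode-neuron interface. The difficulty is that non-neural factors
(distance between the electrode array and the neurons, distance between
stimulating and recording contacts) also shape the AGF. `ecapsim` implements
a deliberately simple, fully controllable 2-D model of an implanted cochlea
in which neural survival, electrode-neuron distance, IPG and recording site
can be varied independently, so that the sensitivity of AGF-derived metrics
to each factor can be quantified.

## Model components

### Geometry

The cochlear duct is unrolled into a 1-D longitudinal axis of 33.9 mm
(corresponding to an angular span of 900°). ANFs sit on the neural axis
(height 0), equidistantly covering the whole duct; 2000 fibers represent a
healthy nerve and 500/1000/1500 emulate poorer survival. Twelve point-source
electrode contacts lie on the lateral wall at exactly 2 mm longitudinal
spacing (contact #12 most basal, 4 mm from the base, so that contact #6 sits
mid-cochlea at 16 mm); an alternative entry path accepts per-contact
characteristic frequencies, converted to positions with the inverse
Greenwood map `F = A(10^{ax} - k)` (A = 165.4 Hz, a = 2.1, k = 0.88, x the
fractional distance from the apex).

The height of each contact above the neural axis follows one of two cubic
scala-tympani height profiles, representing the 10% ("short") and 90%
("long") quantiles of inter-individual variation. The exact polynomials are
configuration, not anatomy: the defaults span 0.39–0.75 mm (short) and
0.85–1.30 mm (long), a plausible lateral-wall range, with the long profile
everywhere above the short one. Analyses that depend on the *difference*
between profiles are normalized per mm of that difference, which makes them
robust to the particular coefficients; the chosen coefficients are written
into every output's metadata sidecar.

All electrode-to-fiber interactions use plain Euclidean distance in the 2-D
(longitudinal, height) plane. Both the stimulus reaching a fiber and the
fiber's response reaching a recording contact are attenuated by 2 dB/mm:
a factor `10^(-2 d / 20)` at distance `d` mm.

### Stimulus

Stimuli are symmetric charge-balanced biphasic pulses: phase duration 40 µs,
IPG 2.1 or 30 µs, anodic- or cathodic-leading, phase amplitude
`charge / phase duration`. AGFs are measured with a fine-grain paradigm:
pulses at 80 Hz while the charge ramps from 0 to 30 nC at 1.5 nC/s. At each
charge level one anodic-leading and one cathodic-leading pulse are presented
and their eCAP traces averaged. Because the polarity average requires equal
charge within a pair, the default schedule increments the charge per
polarity *pair* (0.0375 nC); a per-slot mode is available. A coarse grid
(default 0.25 nC steps, 121 levels, 242 pulses) runs the identical analysis
at ~13× less compute and is the default for the condition grid; AGF fits are
insensitive to the grid density at this scale.

### Single-fiber model

Each ANF is one excitation site modeled phenomenologically as a stochastic
leaky integrate-and-fire unit:

* **Integration.** The attenuated current is low-pass filtered by a
  first-order recursive (IIR) filter, `v[n] = a v[n-1] + b0 I[n] + b1
  I[n-1]` with `a = exp(-dt/τ)`; the gain coefficients carry the published
  single-fiber values, modified for the compound model (b0 = b1 = 602.6e-6,
  three times the original 200.9e-6 to the printed precision). The membrane
  time constant τ defaults to 100 µs, a typical electrical time constant of
  ANF excitation sites.
* **Stochastic threshold.** For every pulse each polarity channel draws a
  threshold from a normal law (SD δ = 9.2 µV, twice the original
  single-fiber value) truncated below at 20% of the mean threshold; the
  anodic channel compares the positive membrane excursion against its draw,
  the cathodic channel the negative excursion. Both channels share the same
  mean, so anodic- and cathodic-leading pulses are statistically identical
  by construction.
* **Critical period.** A threshold crossing only commits to a spike if the
  membrane stays above the drawn threshold for a full critical period
  (default 20 µs). This is the mechanism of the IPG effect: with a 2.1 µs
  gap the charge-balancing phase repolarizes the membrane almost
  immediately after the leading phase, cancelling near-threshold crossings,
  whereas a 30 µs gap leaves the crossing time to complete. Taking the
  alternative reading — cancellation any time before the full spike latency
  (hundreds of µs) elapses — would abolish essentially all near-threshold
  spikes and with them the model's behavior, so the short committal window
  is used and exposed as a parameter.
* **Latency.** A committed crossing at time `t_c` produces a spike at
  `t_c + L(r)` where `r` is the peak-drive-to-threshold ratio and
  `L(r) = 320 + 130·exp(-2(r-1))` µs, a monotone map chosen so that spike
  latencies fall in the physiological 0.3–0.5 ms range and decrease with
  stimulus amplitude; together with the unitary response below it places N1
  inside its search window at all simulated charges.
* **Threshold dynamics.** A spike raises both channels' thresholds by a
  refractory increment (5 µV, τ = 2 ms) and a slowly decaying adaptation
  increment (0.5 µV, τ = 50 ms); no spike is possible within the absolute
  refractory period (0.5 ms). Subthreshold stimulation lowers the
  leading-polarity threshold by a facilitation decrement (1 µV,
  τ = 0.5 ms). At the 12.5 ms pulse spacing of the fine-grain paradigm
  these dynamics are deliberately mild; they matter for denser custom
  schedules.

The **mean threshold** (default 75 µV) is the one calibrated constant: it is
not printed for the compound model and was fixed once, with
`scripts/calibrate.R`, so that the fitted eCAP thresholds of the full model
fall in the 10.01 ± 3.31 nC range reported for CI users. All other unlisted
constants are exposed as `fiber_params()` arguments with the defaults above.

### Time step

The fiber simulation uses dt = 0.1 µs. Two reasons. First, the 2.1 µs IPG —
the study's central variable — is realized exactly on that grid rather than
rounded by ±0.5 µs. Second, the IIR gains are per-sample quantities, so the
membrane's µV scale (and with it the *relative* width δ/drive of the
stochastic threshold) is proportional to the sample rate. At dt = 1 µs one
charge unit produces ~1.2 µV of drive and δ corresponds to ~8 nC of
per-fiber spread: spatial recruitment becomes so diffuse that eCAP
thresholds acquire a strong recording-electrode dependence and the distance
effect collapses far below the 2 dB/mm attenuation that generates it. At
dt = 0.1 µs (~12 µV per nC, ~0.8 nC spread) the model reproduces the
intended behavior. The eCAP traces themselves are assembled on a 1 µs grid —
the unitary response varies on a millisecond scale — which keeps the
convolutions cheap.

### Compound recording

Each spike contributes a unitary response
`U(t) = (u_X/∂_X²)(t-t₀) exp(0.5 - (t-t₀)²/(2∂_X²))`
(negative lobe `X = N` before t₀, positive lobe `X = P` after;
u_N = 12 µV, u_P = 45 µV, ∂_N = 0.12 ms, ∂_P = 0.15 ms, support −0.6 to
1.1 ms), attenuated by 2 dB/mm over the fiber-to-recording-contact distance
and summed over fibers (an FFT convolution of the per-electrode weighted
spike histograms; a brute-force per-spike oracle verifies it in the tests).
The printed source constant "t₀ = −60 ms" is inconsistent with the stated
support and is interpreted as −60 µs (configurable). The recording window
starts `d_R = 145 + (IPG − 2.1)` µs after pulse onset and lasts 1.7 ms; N1
is the minimum in the first 300 µs of the window, P2 the maximum within
400 µs after N1, and the eCAP amplitude is `V(P2) − V(N1)`. Polarity pairs
are averaged at the trace level before peak extraction. Zero-amplitude
template subtraction is omitted (the simulated recording chain has no
stimulation-independent signature), and recording noise is off by default
(an optional Gaussian noise hook was considered and dropped as out of the
package's analysis path).

### AGF analysis

Each AGF is fitted with the asymmetric sigmoid
`y(x) = y₀ + B/(1+e^{−D(x−C)})^z` by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`). Initialization: y₀ = min(y), B = max(y) − min(y), C
at the half-maximum charge, D from a rough finite-difference slope, z = 1.
B, D and z are bounded below by small positive values; z is *not* bounded
above, because simulated AGFs often converge into the large-z
(Gompertz-limit) regime where the derived quantities remain numerically
stable — flagging those fits would discard usable results. Non-convergence
or a pinned lower bound flags a fit, and flagged fits are excluded from all
metrics. Derived closed forms:

* inflection `x₀ = C + ln(z)/D`,
* slope `θ = B·D·(z/(z+1))^{z+1}` (the derivative at x₀),
* threshold `x_THR = C + (ln z − (z+1)/z)/D`.

`x_THR` is algebraically the charge at which the tangent through the
steepest point meets the baseline `y₀`; the identity
`(y(x₀) − y₀)/θ = (z+1)/(zD)` makes the printed closed form exact, and the
test suite verifies the geometry numerically against the formula at 1e-6
relative tolerance.

Three IPG-effect metrics compare the 2.1 µs and 30 µs AGFs of a condition:
the **absolute** effect `θ(30) − θ(2.1)`, the **relative** effect
`θ(30)/θ(2.1)`, and the **IPG offset** — the mean horizontal distance, in dB
re 1 nC, between the two AGFs expressed in log-log scale over the vertical
range where both grow linearly. The offset's applicable range defaults to
the growth region common to both curves, from 20 dB to 3 dB below the
smaller of the two maximum amplitudes. A per-curve rule based on the local
log-log slope staying within a tolerance band of its median was implemented
first and rejected: the log-log slope of a sigmoidal AGF declines
continuously, so on stochastic data the rule selects narrow, unstable,
often non-overlapping spans. A manual range override remains available and
the automatic rule is tested against manually chosen ranges.

## The condition grid

`run_grid()` crosses survival (500/1000/1500/2000 fibers), height profile
(short/long) and IPG (2.1/30 µs): 16 simulation runs, each stimulating at
contact #6 and recording simultaneously at the 11 other contacts — 176 AGFs
on the coarse charge grid. Each condition derives its own RNG sub-seed from
the experiment seed, runs are bit-reproducible given the seed, and every
output carries its provenance (seed, schedule, geometry coefficients). A
single experiment-level R RNG stream drives the vectorized per-pulse
threshold draws of all fibers; per-fiber generator streams were considered
and rejected because they would force a fiber-level loop where a
population-level vector operation suffices (reproducibility is unaffected).
The full grid takes well under a minute on one CPU at these sizes; the
fine-grain ramp (1602 pulses per condition) is available via
`schedule_mode = "fine"`.

The per-condition summary quantities are: fitted thresholds and slopes per
recording electrode; the mean rate (dB/mm) at which thresholds grow between
the two height profiles, normalized by the mean nearest-fiber distance
difference between the profiles at the contacts; the three IPG-effect
metrics; and maximum eCAP amplitudes normalized within each condition.

One structural observation, visible in `summarize_thresholds_slopes()`: the
threshold growth rate between the profiles settles slightly *below* the
configured 2 dB/mm attenuation (≈1.75–1.85 dB/mm across seeds). The cause
is geometric: fibers recruited at a longitudinal offset Δx from the
stimulating contact see a distance `sqrt(Δx² + h²)` that changes by less
than the height change itself, so the recruitment-weighted distance
difference is smaller than the nearest-fiber difference used as the
denominator.

## What the simulations do and do not emulate

The generator produces noise-free, artifact-free recordings from
statistically identical, independent, equidistant fibers. It captures the
interplay of neural survival, field attenuation, IPG and electrode position
on AGF shape. It does not emulate: measurement noise and stimulation
artifacts (so thresholds are cleaner than clinical ones, where log-scale
noise notoriously hampers threshold reading); asymmetric field spread or
cross-turn stimulation; polarity-dependent sensitivity, demyelination
gradients or dead regions; electrode orientation and size; non-uniform
fiber density. Passing tests therefore show internal consistency of the
model and analysis chain, not fidelity to any individual ear.

## Numerical notes

* Charge balance of every generated pulse is exact (equal sample counts of
  opposite sign); the tests assert < 1e-9 nC.
* Threshold draws use inverse-CDF sampling of the truncated normal — no
  atom at the floor, so single-fiber probability curves are smooth.
* Crossing search and critical-period commitment are implemented with a
  rolling minimum and cumulative maximum over the per-unit-charge membrane
  trace, so all fibers of a pulse are handled in one vectorized pass;
  ties (equal spike times on both polarity channels) resolve to the
  anodic channel via `pmin`.
* Degenerate inputs: flat traces yield amplitude 0 with a `degenerate`
  flag; all-zero AGFs are refused by `ipg_offset()` with an informative
  error and excluded from summaries; failed conditions are isolated per
  grid cell and reported in `ecap_grid$errors`.
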
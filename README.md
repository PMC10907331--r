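# ecapsim

Simulation of electrically evoked compound action potential (eCAP)
amplitude-growth functions (AGFs) in a simplified 2-D model of an implanted
cochlea, and computation of inter-phase-gap (IPG) effect metrics of cochlear
neural health.

## The problem

Cochlear-implant audiologists read two things off eCAP telemetry: the AGF —
eCAP amplitude (µV) versus stimulus charge (nC) — and how it changes when
the inter-phase gap of the biphasic pulse is prolonged (the "IPG effect", a
candidate proxy for neural survival). Both are confounded by non-neural
factors: the distance between the electrode array and the auditory nerve
fibers (ANFs), and the distance between stimulating and recording contacts.
`ecapsim` provides a controlled in-silico test bench in which each factor
can be varied independently: ANF count (500–2000), scala-tympani height
profile ("short"/"long" electrode-neuron distance), IPG (2.1/30 µs) and
recording electrode (11 contacts around the stimulating contact #6).

## The model

* **Geometry.** The cochlear duct is unrolled to 33.9 mm (900°). Twelve
  point-source contacts lie on the lateral wall at 2 mm spacing on one of
  two cubic height profiles; N equidistant ANFs sit on the neural axis.
  Current spreads with a 2 dB/mm attenuation: `Ĩ(t) = I(t)·10^(−2|r_s|/20)`
  for stimulation, and the same law for the neural response reaching the
  recording contact.
* **Fibers.** Each ANF is a stochastic leaky integrate-and-fire excitation
  site: a first-order IIR filter (gains b₀ = b₁ = 602.6e-6) integrates the
  attenuated current; per pulse, each polarity channel draws a threshold
  from a truncated normal law (SD δ = 9.2 µV); a crossing spikes only if the
  membrane stays suprathreshold through a ~20 µs critical period — which is
  why a longer IPG, delaying the charge-balancing phase, recruits more
  fibers. Refractoriness, adaptation and polarity-specific facilitation
  modulate the thresholds across the pulse train.
* **Recording.** Spikes are convolved with a biphasic unitary response
  `U(t) = (u_X/∂_X²)(t−t₀)·e^{0.5−(t−t₀)²/(2∂_X²)}` and summed with 2 dB/mm
  attenuation: `V(t) = Σᵢ (oᵢ∗U)(t)·10^(−2|r_r(i)|/20)`. The N1 trough and
  P2 peak are searched in fixed windows of a 1.7 ms recording window
  starting `d_R = 145 + (IPG − 2.1)` µs after pulse onset.
* **Analysis.** Each AGF is fitted with the asymmetric sigmoid
  `y(x) = y₀ + B/(1+e^{−D(x−C)})^z` (Levenberg–Marquardt), from which the
  slope at the inflection `θ = B·D·(z/(z+1))^{z+1}` and the eCAP threshold
  `x_THR = C + (ln z − (z+1)/z)/D` follow in closed form. The IPG effect is
  computed three ways: absolute (`θ₃₀ − θ₂.₁`), relative (`θ₃₀/θ₂.₁`) and
  as the log-log horizontal offset (dB re 1 nC) between the two AGFs.

See the methods vignette (`vignettes/ecap-model.Rmd`) for assumptions,
parameter defaults and numerical choices.

## Worked example

Simulate one neural-survival condition at both IPGs and compare the AGFs
recorded at contact #5:

```r
library(ecapsim)

cfg <- experiment_config(n_fibers = 500, profiles = "short", seed = 7)
agf_short <- run_condition(cfg, 500, "short", ipg_us = 2.1)
agf_long  <- run_condition(cfg, 500, "short", ipg_us = 30)

a5s <- agf_short[agf_short$electrode == 5, ]
a5l <- agf_long[agf_long$electrode == 5, ]
fit_s <- fit_sigmoid(a5s$charge_nc, a5s$amplitude_uv)
fit_l <- fit_sigmoid(a5l$charge_nc, a5l$amplitude_uv)
print(fit_s)
#> sigmoid fit: y0=-212 B=2.999e+04 C=-16.34 D=0.2162 z=868.9
#>   x0 = 14.96 nC, slope = 2383 uV/nC, threshold = 10.33 nC
```

The fitted threshold sits in the ~10 nC range typical of CI users, and
prolonging the IPG from 2.1 to 30 µs lowers it and steepens the AGF:

```r
agf_threshold(fit_s)                 # 10.33 nC at IPG 2.1 us
agf_threshold(fit_l)                 #  8.33 nC at IPG 30 us
ipg_effect_absolute(fit_s, fit_l)    # 71.1 uV/nC
ipg_effect_relative(fit_s, fit_l)    # 1.030
ipg_offset(a5s, a5l)$offset_db       # 1.36 dB re 1 nC
```

The full condition grid (4 survival levels × 2 height profiles × 2 IPGs,
recording at all 11 non-stimulating contacts) with its summary tables:

```r
grid <- run_grid(experiment_config(seed = 1))
fits <- fit_grid(grid)
summarize_thresholds_slopes(fits, grid$config)$threshold_shift_db_per_mm
summarize_ipg_effects(grid, fits)
summarize_max_amplitudes(grid)
```

A thin command-line front end with `simulate` / `fit` / `report`
subcommands is installed at `exec/ecapsim.R` (source:
`inst/exec/ecapsim.R`), configured by a YAML file mirroring
`experiment_config()`.

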
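# phasorgate

Phasor analysis of time-gated single-photon FLIM data.

Wide-field fluorescence lifetime imaging (FLIM) with large-format gated
SPAD array cameras works differently from classical TCSPC: the detector
accumulates 1-bit frames — any photon during the gate sets the pixel memory
to 1, later photons in the same frame are lost — into 8- or 10-bit gate
images, while a long rectangular gate (longer than most fluorophore
lifetimes, e.g. 10.8–22.8 ns against a 50 ns laser period) is stepped in
picosecond increments across the period. `phasorgate` implements the full
analysis chain for such data, for microscopists and detector developers who
want fitting-free lifetime estimation from gated single-photon stacks:

* **Pile-up linearization.** The 1-bit storage saturates the recorded count
  `I_rec`; the incident count is recovered as
  `I_corr = -I_max · ln(1 - I_rec / I_max)`.
* **Background handling.** Tail-window estimation of the uncorrelated
  background and unclamped subtraction; hot-pixel masking by intensity
  percentile with 4-neighbor interpolation.
* **Phasor analysis.** The phasor of a decay recorded through gates at
  delays `t_k` is `z = g + i·s = Σ I_k e^{i2πf t_k} / Σ I_k`; the phase
  lifetime is `τ_φ = tan(φ) / (2πf)`. Gate shape and IRF are removed by a
  single complex calibration factor measured on a reference dye of known
  lifetime (global, per-ROI or per-pixel). Two-species mixtures are
  unmixed by projection onto the segment between the pure-species phasors
  (`r_1 = d_2/(d_1+d_2)`), with the volume fraction obtained through
  `r_1^{-1} = 1 + (μχ)^{-1}(v_1^{-1} - 1)`.
* **Photon economy.** The F-value `F = √N σ_τ / τ`, the analytic
  gate-width bound `F_W = √(1 + (W/τ)²/12)`, and a Monte Carlo simulator of
  the complete measurement chain (photon emission, stochastic gate
  assignment, phasor computation, calibration with a shot-noise-limited
  reference) that estimates the achievable lifetime precision.
* **Forward simulator and I/O.** Synthetic gate stacks with pile-up, dark
  counts, hot pixels and optional gate skew generated from first
  principles; multi-page 16-bit TIFF stacks with validated JSON sidecars.

## Worked example

Simulate a 4.08 ns dye and a 2.8 ns calibration dye through the same gate
configuration (140 gates of 13.1 ns width scanning a 50 ns period), then
run the standard pipeline — pile-up correction, 4×4 ROI binning, phasor
computation, per-ROI calibration, phase lifetimes:

```r
library(phasorgate)

laser <- laser_config(period_ns = 50)              # 20 MHz, f = 20 MHz
gates <- gate_config(width_ns = 13.1, step_ns = 50 / 140, num_gates = 140)

mk <- function(tau, seed)
  simulate_gate_stack(
    sim_params(laser, gates, decay_model(tau), height = 32, width = 32,
               brightness = 0.1, frames_per_gate = 255), seed)

sample_stack <- mk(4.08, 202)   # dye under study
cal_stack    <- mk(2.80, 201)   # reference dye of known lifetime

res  <- run_pipeline(sample_stack, cal_stack, tau_cal_ns = 2.8, roi_bin = 4)
taus <- res$tau_ns[!is.na(res$tau_ns)]
sprintf("recovered tau: %.3f +/- %.3f ns over %d ROIs",
        mean(taus), sd(taus), length(taus))
#> [1] "recovered tau: 4.072 +/- 0.082 ns over 64 ROIs"
```

The mean phase lifetime recovers the simulated 4.08 ns within its standard
error; the spread across ROIs is the shot-noise-limited precision at this
photon budget.

Photon-economy analysis at the same settings, with 2000 photons each for
sample and calibration:

```r
monte_carlo_f(4.08, 2.8, width_ns = 13.1, num_gates = 140, period_ns = 50,
              n_i = 2000, n_c = 2000, replicates = 200, seed = 223)
#> <fvalue_report> tau_i = 4.08 ns, W = 13.1 ns, G = 140, N_i = 2000
#>   MC:       F = 2.2771 +/- 0.1129 (sigma_tau = 0.2077 ns)
#>   analytic: F_W = 1.3635 (sigma_tau = 0.1244 ns)
```

The Monte Carlo F-value sits above the analytic bound, as it must: the
bound neglects both the calibration sample's shot noise and the phasor
estimator's departure from plain timestamp averaging. `F ≈ 2.3` means this
configuration needs about `F² ≈ 5` times more photons than an ideal TCSPC
system for the same precision.

Acquisition timing arithmetic:

```r
frame_rate(10.2e-6, 10e-6, b = 255, g = 16)   # 12.13 fps
frame_rate(10.2e-6, 10e-6, b = 255, g = 1)    # 194.1 fps
sequence_time(10.2e-6, 10e-6, 255, 2800)      # 14.42 s
```

A thin command-line interface over the same functions is installed at
`inst/cli/phasorgate.R` (subcommands `simulate`, `phasor`, `pipeline`,
`fvalue-mc`, `framerate`).

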
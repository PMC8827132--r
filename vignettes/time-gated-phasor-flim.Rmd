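---
title: "Phasor FLIM with long, overlapping time gates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor FLIM with long, overlapping time gates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorgate)
```

This vignette is the package's account of the science it implements: the
acquisition model of a time-gated 1-bit SPAD array camera, the corrections
that linearize its data, the phasor formalism used to extract lifetimes
without fitting, and the shot-noise framework that predicts the achievable
precision. It also records the numerical and design choices a maintainer
would want to know about, and what the synthetic-data tests do and do not
demonstrate about real data.

## The acquisition model

A pulsed laser with period $T$ (50 ns at 20 MHz throughout the examples)
excites the sample; the detector is sensitive only during a rectangular
gate of width $W$ opened at delay $t_k$ after each pulse. One *binary
frame* spans many laser pulses (200 for a 10 µs exposure); any photon
detected while the gate is open sets the pixel's 1-bit memory, and all
later photons of that frame are lost. $b$ binary frames (255 for 8-bit,
1020 for 10-bit images) are accumulated into one *gate image*, the gate is
stepped by $\delta t$ (down to 17.86 ps, i.e. $G = 2800$ positions over a
50 ns period), and the resulting stack of $G$ gate images is the raw data.

Under steady-state periodic excitation a single-exponential decay has the
per-period arrival density

$$p(t) = \frac{e^{-t/\tau}}{\tau\,(1 - e^{-T/\tau})}, \qquad t \in [0, T),$$

and `expected_gate_fraction()` integrates it in closed form over a gate,
splitting the window at the period boundary when the gate wraps. With an
expected fluorescence flux $\Lambda$ photons per binary frame, the expected
in-gate count is $\lambda_k = \Lambda \cdot \mathrm{frac}(t_k) + r_b W n_p$
(background rate $r_b$ per ns of open gate, $n_p$ pulses per frame), and
the accumulated gate image is Binomial$(b,\, 1 - e^{-\lambda_k})$:
saturation (pile-up) is an emergent property of the model, not an add-on.

Gates are ideal rectangles by default. Real gate edges are neither
instantaneous nor specified by a functional form, so an opt-in trapezoid
mode (`edge_ns`) with linear rise/fall around each boundary is provided for
sensitivity studies; the rectangle remains the reference model because
calibration (below) absorbs stationary gate-shape effects anyway.

All internal times are nanoseconds and frequencies are converted to
ns$^{-1}$ at the constructor boundary (`laser_config()`): acquisition
literature mixes ps, ns, µs and MHz, and a single canonical unit avoids
silent thousand-fold errors. Sidecar files mirror times in seconds for SI
tooling.

## Corrections

**Pile-up.** The recorded count saturates as
$I_{rec} = I_{max}(1 - e^{-I/I_{max}})$; `pileup_correct()` inverts this
with $I_{corr} = -I_{max}\ln(1 - I_{rec}/I_{max})$. The inversion is exact
in expectation but cannot restore the signal-to-noise lost to missed
photons; that degradation is deliberately not modelled. Fully saturated
bins ($I_{rec} = I_{max}$) have no finite correction: they are clamped to
$I_{max} - \tfrac12$ (half a count below the ceiling, the resolution limit
of an integer counter) and flagged `saturated`, so downstream analysis can
drop or inspect them. The roundtrip saturate-then-correct is tested to
$10^{-9}$ relative over $I/I_{max} \le 0.99$.

**Background.** Uncorrelated background (dark counts, ambient light) adds
a per-gate offset. When $\tau \ll T - W$, gates opening in the decay tail
see only this offset, and `estimate_background_tail()` averages them per
pixel. The estimator is biased high for long-lived samples whose decay
never reaches the background level within the period; no quantitative
validity threshold is imposed — the choice of tail window is the user's,
and the documentation states the assumption. Subtraction is applied to the
pile-up-corrected signal (the correction is nonlinear and only valid on
raw per-pixel counts, which fixes the order of operations:
pile-up → background → binning → phasor) and negative residuals are
**retained**: clamping at zero would rectify noise and bias phasor sums.

**Noisy pixels.** A small fraction of SPADs have dark count rates above
1 kcps. `hot_pixel_mask()` flags the top intensity percentile (ties at the
threshold are all flagged; percentile 0 flags nothing) and
`interpolate_masked()` replaces flagged pixels by the mean of their
unmasked 4-neighbors, iterating so that fully-masked neighborhoods resolve
from the outside in. Percentile masking also rejects genuinely bright
sample regions, so it is off by default in `run_pipeline()`.

## Phasors, calibration, lifetimes

The phasor of gate intensities $I_k$ at delays $t_k$ is

$$z = g + is = \frac{\sum_k I_k e^{i 2\pi f t_k}}{\sum_k I_k},$$

with $f$ the phasor frequency (default: the laser repetition rate; higher
harmonics are accepted but unused by default). Single-exponential decays
lie on the universal semicircle $(g-\tfrac12)^2 + s^2 = \tfrac14$, running
from $(1,0)$ at $\tau = 0$ to the origin as $\tau \to \infty$, and the
phase lifetime is $\tau_\varphi = \tan(\varphi)/(2\pi f)$. The phase is
taken with `atan2`, and non-first-quadrant phasors yield `NA` rather than
negative lifetimes. Zero-intensity pixels carry a validity flag instead of
propagating `NaN` through maps.

Both the instrument response and the gate integration multiply every
phasor by a common complex factor, so measuring a reference dye of known
lifetime $\tau_{cal}$ and computing
$z = z_{exp} \cdot z_{cal,theo}/z_{cal,exp}$ removes both at once. The
theoretical reference phasor has modulus $(1 + (2\pi f\tau_{cal})^2)^{-1/2}$
and phase $\arctan(2\pi f \tau_{cal})$ — the exponent $-\tfrac12$ is forced
by the universal-semicircle constraint. Calibration granularity is the
caller's choice (`global`, per-ROI, per-pixel); the reference workflow uses
4×4-pixel ROI maps (`bin_rois()`), which averages gate-skew variation at
the scale where it matters, and 8×8 binning for mixture work where
signal-to-noise dominates. Partial edge tiles are dropped rather than
padded — a 472×256 sensor yields 118×64 ROIs.

**Mixtures.** A two-species mixture's phasor lies on the segment between
the pure-species phasors. `phasor_ratio()` projects the measured phasor
orthogonally onto that segment (clamping out-of-segment projections to the
nearest endpoint) and reports $r_1 = d_2/(d_1+d_2)$. The volume fraction
follows from $r_1^{-1} = 1 + (\mu\chi)^{-1}(v_1^{-1}-1)$, where $\mu$ is
the stock concentration ratio and $\chi$ the brightness (extinction ×
quantum yield) ratio; `fit_mu_chi()` estimates $\mu\chi$ from a dilution
series by one-parameter least squares on the log scale, with a standard
error from the analytic Jacobian. The relation is linear only when
$\mu\chi = 1$, which is why a naive linear reading of phasor ratios
misestimates strongly unequal mixtures.

**Maps.** `lifetime_map()` color-codes pixels by phasor ratio between two
user-chosen reference phasors (red at ratio 0 to blue at ratio 1 through a
spectrum ramp), either at constant luminance or with luminance scaled by
normalized intensity; reference selection is a user input, since the
appropriate anchors depend on the sample. Invalid pixels render in a
designated null color rather than black, which `scaled` mode reserves for
genuinely dark pixels.

## Photon economy

The F-value $F = \sqrt{N}\sigma_\tau/\tau$ normalizes lifetime precision
to the photon budget; an ideal TCSPC measurement of a single-exponential
decay achieves $F = 1$. Approximating the photons inside a gate of width
$W$ as uniformly distributed adds an independent timestamp variance
$W^2/12$ (the mean of $N$ such terms is Bates-distributed), giving

$$\sigma_\tau(W, N) = \frac{\tau}{\sqrt N}\sqrt{1 + \frac{1}{12}
\left(\frac{W}{\tau}\right)^2}, \qquad
F_W(\tau) = \sqrt{1 + \frac{1}{12}\left(\frac{W}{\tau}\right)^2}.$$

The uniformity assumption degrades once $W \gtrsim \tau$, but the
expression remains a lower bound on what a gated measurement can achieve,
and a useful design rule: $F_W$ grows monotonically with $W/\tau$, so at
fixed detected photons shorter gates are always at least as precise.

`monte_carlo_f()` estimates the actual precision by simulating the whole
chain per replicate: $N_i$ photon arrivals from the sample and $N_c$ from
the calibration dye, each photon recorded at **one** gate position, phasor
computation, calibration with the replicate's own reference phasor, phase
lifetime. The spread over replicates is $\tilde\sigma_\tau$, which by
construction includes the calibration sample's shot noise — the two
variances add because the samples are measured independently
(`combined_sigma()`). A deliberate modelling point: in a scanned-gate
acquisition every gate position is a separate exposure, so a detected
photon carries only its gate's timestamp, and conditional on detection the
recording gate is uniform among the gates containing the arrival time
(`sample_gate_counts()`). This is what produces the $W/\sqrt{12}$ blur
physically; counting each photon into *every* containing gate
(`gate_bin_timestamps()`, the right operation for expected-profile
arithmetic) would make the gate factor per photon deterministic and
underestimate the variance — with dense gates it yields F-values *below*
$F_W$, which is how the distinction was caught. The Monte Carlo and the
image pipeline share the same phasor and calibration code path; there is
no parallel analytic implementation to drift out of sync.

Replicate standard errors come from bootstrap resampling of the replicate
lifetimes. The documented default is 1000 replicates
($\mathrm{SE}(\sigma) \approx \sigma/\sqrt{2R}$, about 2%); the examples
and tests use 200–600 replicates, which resolves the effects they assert
at 3–4 standard errors.

Acquisition-rate arithmetic is provided by `frame_rate()` (inverse of
$(T_{read}+T_{exp})\,b\,G$), `sequence_time()`, and `exposure_time()`
($T_{exp} = 400n - 50$ ns from the firmware counter — note a nominal
"10 µs" exposure is not exactly representable by an integer $n$, so
$T_{exp}$ is accepted as a free parameter everywhere else), together with
the microlens concentration-factor and effective-fill-factor helpers.
Firmware-restart dead time between long sub-sequences is intentionally
outside `frame_rate()`.

## The simulator as a test instrument

`simulate_gate_stack()` emulates the study conditions of the reference
workflow: 50 ns period, 13.1 ns gates scanned uniformly across the period,
255 binary frames per gate image, 200 pulses per frame, dark counts
uniform in time and counted only while the gate is open, hot pixels as a
user-set fraction with elevated DCR (default 10 kcps — the distribution is
not standardized, so it is a parameter), and optional deterministic
per-pixel gate-start skew. Brightness defaults in tests (0.05–0.5 expected
photons per frame) span the regimes from shot-noise-starved to visibly
piled-up. One global seed drives a single RNG stream, so identical
parameters and seed give bit-identical stacks.

What the simulator does *not* reproduce: afterpulsing and crosstalk,
readout non-idealities, the measured gate-edge skew physics (skew enters
only as a static offset), IRF convolution with a finite laser pulse (the
calibration step absorbs it in reality, so simulated decays are generated
IRF-free), and the non-Poisson variance inflation of pile-up-corrected
counts. Passing tests therefore demonstrate the *analysis chain* is
correct under its stated model, not that every detector non-ideality is
handled; on real data the calibration reference must be measured under the
same gate configuration as the sample for the cancellation to hold.

## Problem sizes and numerical choices

The test suite runs entirely on synthetic data generated at test time, at
sizes chosen to resolve each assertion at 3–4 standard errors on a
single CPU in seconds: lifetime recovery on 32×32-pixel stacks with 140
gates (64 ROIs); the $G^{-1/2}$ precision-scaling law on a 128×128-pixel,
512-gate stack decimated to 256…16 gates (1024 ROIs per point, slope
asserted within ±0.05 of −0.5); the analytic-bound sweep over
$W \in \{10.8, \dots, 22.8\}$ ns with 2000 photons per replicate and 200
replicates; Monte Carlo scaling checks at 300–600 replicates. Numerical
tie-breaks and degenerate inputs are fixed as: percentile ties all
flagged; saturated bins clamped and flagged; empty tail windows,
coincident mixture references, all-true interpolation masks and
zero-total-intensity scalar phasors are errors; zero-intensity pixels in
maps are flagged invalid instead. Gate decimation requires the target to
divide the available gate count, so the retained gates remain uniform.

## Known limitations

* The tail-average background estimator is invalid for lifetimes
  approaching $T - W$; a multi-point background model is out of scope.
* The F-value framework ignores pile-up's variance inflation; at high
  flux the Monte Carlo is optimistic about real precision.
* `fit_mu_chi()` assumes a single $\mu\chi$ across the dilution series, as
  holds when mixtures are prepared volumetrically from two stocks.
* Phasor unmixing covers two species; multi-harmonic unmixing of three or
  more is out of scope.
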
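#' Photon-economy F-value
#'
#' The normalized relative error of a lifetime estimate,
#' \eqn{F = \sqrt{N}\,\sigma_\tau / \tau}. An ideal time-correlated
#' single-photon counting measurement of a single-exponential decay (delta
#' IRF, no jitter, lifetime estimated as the mean arrival time) achieves
#' \eqn{F = 1}; every non-ideality raises it. \eqn{F^2} is the photon
#' multiple required to match ideal precision.
#'
#' @param n Number of detected photons, at least 1.
#' @param sigma_tau_ns Lifetime standard deviation in ns, nonnegative.
#' @param tau_ns Lifetime in ns, positive.
#' @return The dimensionless F-value.
#' @examples
#' f_value(1e4, 0.05, 4.08)
#' f_value(100, 4.08 / 10, 4.08)  # ideal: exactly 1
#' @export
f_value <- function(n, sigma_tau_ns, tau_ns) {
  stopifnot(n >= 1, sigma_tau_ns >= 0, tau_ns > 0)
  sqrt(n) * sigma_tau_ns / tau_ns
}

#' Timestamp spread added by a uniform gate
#'
#' Photons assumed uniformly distributed across a gate of width \eqn{W}
#' carry a timestamp uncertainty with standard deviation \eqn{\sigma_W =
#' W/\sqrt{12}}; the mean of \eqn{N} such timestamps (a Bates distribution)
#' has \eqn{\sigma_{W,N} = W/\sqrt{12 N}}.
#'
#' @param width_ns Gate width \eqn{W} in ns, positive.
#' @param n Number of photons (for `sigma_gate_mean`), at least 1.
#' @return Standard deviation in ns.
#' @export
sigma_gate <- function(width_ns) {
  stopifnot(width_ns > 0)
  width_ns / sqrt(12)
}

#' @rdname sigma_gate
#' @export
sigma_gate_mean <- function(width_ns, n) {
  stopifnot(n >= 1)
  sigma_gate(width_ns) / sqrt(n)
}

#' Analytic lifetime standard deviation for gated photon averaging
#'
#' First-order shot-noise model for a lifetime measured as the average of
#' \eqn{N} photon timestamps blurred by a gate (or bin) of width \eqn{W}:
#' the Poisson spread \eqn{\tau/\sqrt N} and the gating spread
#' \eqn{W/\sqrt{12N}} are uncorrelated, so
#' \deqn{\sigma_\tau(W, N) = \frac{\tau}{\sqrt N}
#'   \sqrt{1 + \frac{1}{12}\left(\frac{W}{\tau}\right)^2}.}
#' The uniform-within-gate assumption degrades as \eqn{W} grows beyond
#' \eqn{\tau}, but the expression remains a lower bound on the phase-lifetime
#' standard deviation actually measured.
#'
#' @param width_ns Gate width in ns, positive.
#' @param n Number of photons, at least 1.
#' @param tau_ns Lifetime in ns, positive.
#' @return \eqn{\sigma_\tau} in ns.
#' @export
analytic_sigma_tau <- function(width_ns, n, tau_ns) {
  stopifnot(width_ns > 0, n >= 1, tau_ns > 0)
  tau_ns / sqrt(n) * sqrt(1 + (width_ns / tau_ns)^2 / 12)
}

#' Analytic F-value lower bound for a finite gate width
#'
#' \deqn{F_W(\tau) = \sqrt{1 + \frac{1}{12}\left(\frac{W}{\tau}\right)^2},}
#' the F-value implied by [analytic_sigma_tau()]: monotone increasing in
#' \eqn{W}, decreasing in \eqn{\tau}, and a lower bound on the measured
#' F-value of a gated phasor measurement.
#'
#' @param width_ns Gate width in ns, positive.
#' @param tau_ns Lifetime in ns, positive.
#' @return The dimensionless \eqn{F_W}.
#' @examples
#' analytic_f(13.1, 4.08)  # ~1.3635
#' @export
analytic_f <- function(width_ns, tau_ns) {
  stopifnot(width_ns > 0, tau_ns > 0)
  sqrt(1 + (width_ns / tau_ns)^2 / 12)
}

#' Combine sample and calibration uncertainties
#'
#' Sample and calibration are measured independently, so their lifetime
#' variances add: \eqn{\tilde\sigma = \sqrt{\sigma_i^2 + \sigma_c^2}}, and
#' the combined F-value is \eqn{\tilde F = \sqrt{N_i}\,\tilde\sigma/\tau_i}.
#'
#' @param sigma_i_ns,sigma_c_ns Sample and calibration lifetime standard
#'   deviations in ns, nonnegative.
#' @return `combined_sigma`: \eqn{\tilde\sigma} in ns.
#' @export
combined_sigma <- function(sigma_i_ns, sigma_c_ns) {
  stopifnot(all(sigma_i_ns >= 0), all(sigma_c_ns >= 0))
  sqrt(sigma_i_ns^2 + sigma_c_ns^2)
}

#' @rdname combined_sigma
#' @param n_i Photons detected from the sample of interest.
#' @param sigma_combined_ns \eqn{\tilde\sigma} in ns.
#' @param tau_i_ns Sample lifetime in ns.
#' @return `combined_f`: \eqn{\tilde F}.
#' @export
combined_f <- function(n_i, sigma_combined_ns, tau_i_ns) {
  f_value(n_i, sigma_combined_ns, tau_i_ns)
}

#' Monte Carlo F-value of a calibrated gated phasor measurement
#'
#' Simulates the full measurement chain per replicate: `n_i` photon
#' timestamps from the sample decay and `n_c` from the calibration decay,
#' each photon stochastically recorded at one scanned gate position
#' ([sample_gate_counts()]), phasors computed from the per-gate counts, the
#' sample phasor calibrated with the replicate's own calibration phasor, and
#' the phase lifetime extracted. The standard deviation of the calibrated lifetime
#' across replicates gives \eqn{\tilde\sigma_\tau} — automatically including
#' the calibration sample's shot noise — and the F-value follows as
#' \eqn{\tilde F = \sqrt{N_i}\,\tilde\sigma_\tau/\tau_i}. The same phasor
#' and calibration code path is used as for image data; there is no parallel
#' analytic shortcut. The standard error is obtained by bootstrap resampling
#' of the replicate lifetimes.
#'
#' @param tau_i_ns Sample lifetime in ns.
#' @param tau_c_ns Calibration lifetime in ns.
#' @param width_ns Gate width in ns.
#' @param num_gates Number of gate positions, uniformly spanning the period.
#' @param period_ns Laser period in ns.
#' @param n_i,n_c Photons per replicate for sample and calibration.
#' @param freq_per_ns Phasor frequency in 1/ns (default `1/period_ns`).
#' @param replicates Number of Monte Carlo replicates (default 1000).
#' @param seed Master seed; per-replicate draws come from the one stream it
#'   starts.
#' @param n_boot Bootstrap resamples for the standard errors (default 200).
#' @return An object of class `fvalue_report`: list with `mc_f`, `mc_f_se`,
#'   `sigma_tau_ns`, `sigma_tau_se_ns`, `mean_tau_ns`, `analytic_f`,
#'   `analytic_sigma_tau_ns`, `lifetimes_ns` (the replicate values), and the
#'   call parameters.
#' @export
monte_carlo_f <- function(tau_i_ns, tau_c_ns, width_ns, num_gates, period_ns,
                          n_i, n_c, freq_per_ns = 1 / period_ns,
                          replicates = 1000, seed = 1, n_boot = 200) {
  stopifnot(tau_i_ns > 0, tau_c_ns > 0, width_ns > 0, num_gates >= 2,
            period_ns > 0, n_i >= 1, n_c >= 1, replicates >= 2)
  gates <- gate_config(width_ns, period_ns / num_gates, num_gates)
  ts <- gate_timestamps(gates)
  set.seed(seed)
  taus <- numeric(replicates)
  for (r in seq_len(replicates)) {
    t_i <- simulate_photon_timestamps(tau_i_ns, period_ns, n_i)
    t_c <- simulate_photon_timestamps(tau_c_ns, period_ns, n_c)
    z_i <- compute_phasor(sample_gate_counts(t_i, gates, period_ns), ts,
                          freq_per_ns)
    z_c <- compute_phasor(sample_gate_counts(t_c, gates, period_ns), ts,
                          freq_per_ns)
    z <- calibrate_phasor(z_i, z_c, tau_c_ns, freq_per_ns)
    taus[r] <- phase_lifetime(z, freq_per_ns)
  }
  ok <- !is.na(taus)
  taus_ok <- taus[ok]
  sigma <- stats::sd(taus_ok)
  boot <- vapply(seq_len(n_boot), function(i)
    stats::sd(sample(taus_ok, replace = TRUE)), numeric(1))
  sigma_se <- stats::sd(boot)
  fmul <- sqrt(n_i) / tau_i_ns
  structure(
    list(mc_f = fmul * sigma, mc_f_se = fmul * sigma_se,
         sigma_tau_ns = sigma, sigma_tau_se_ns = sigma_se,
         mean_tau_ns = mean(taus_ok),
         analytic_f = analytic_f(width_ns, tau_i_ns),
         analytic_sigma_tau_ns = analytic_sigma_tau(width_ns, n_i, tau_i_ns),
         lifetimes_ns = taus,
         params = list(tau_i_ns = tau_i_ns, tau_c_ns = tau_c_ns,
                       width_ns = width_ns, num_gates = num_gates,
                       period_ns = period_ns, n_i = n_i, n_c = n_c,
                       freq_per_ns = freq_per_ns, replicates = replicates,
                       seed = seed)),
    class = "fvalue_report")
}

#' @export
print.fvalue_report <- function(x, ...) {
  p <- x$params
  cat(sprintf("<fvalue_report> tau_i = %g ns, W = %g ns, G = %d, N_i = %g\n",
              p$tau_i_ns, p$width_ns, p$num_gates, p$n_i))
  cat(sprintf("  MC:       F = %.4f +/- %.4f (sigma_tau = %.4g ns)\n",
              x$mc_f, x$mc_f_se, x$sigma_tau_ns))
  cat(sprintf("  analytic: F_W = %.4f (sigma_tau = %.4g ns)\n",
              x$analytic_f, x$analytic_sigma_tau_ns))
  invisible(x)
}

#' Decimate the gates of a stack
#'
#' Retains every `keep_every`-th gate (starting from the first) with its
#' timestamp, emulating an acquisition with fewer gate positions and
#' proportionally shorter total exposure — a "virtual" faster frame rate.
#' Alternatively give `target_g`; it must divide the available gate count.
#'
#' @param stack A [gate_stack()] or [corrected_stack()].
#' @param keep_every Keep one gate in `keep_every` (default from `target_g`).
#' @param target_g Desired number of gates.
#' @return The reduced stack, same class as the input.
#' @examples
#' ## 2800 gates decimated to every 20th -> 140; every 175th -> 16
#' @export
decimate_gates <- function(stack, keep_every = NULL, target_g = NULL) {
  G <- length(stack$timestamps)
  if (is.null(keep_every)) {
    if (is.null(target_g)) stop("give `keep_every` or `target_g`")
    if (target_g > G) stop("target_g exceeds the available gate count")
    if (G %% target_g != 0)
      stop("target_g must divide the available gate count for even subsampling")
    keep_every <- G %/% target_g
  }
  stopifnot(keep_every >= 1, keep_every == as.integer(keep_every))
  idx <- seq(1L, G, by = keep_every)
  vals <- stack_values(stack)[, , idx, drop = FALSE]
  ts <- stack$timestamps[idx]
  g2 <- gate_config(stack$gates$width_ns, stack$gates$step_ns * keep_every,
                    length(idx), stack$gates$first_offset_ns)
  prov <- c(stack$provenance, sprintf("decimate(keep_every=%d)", keep_every))
  if (inherits(stack, "gate_stack"))
    gate_stack(vals, ts, stack$i_max, stack$bit_depth, stack$laser, g2, prov)
  else
    corrected_stack(vals, ts, stack$laser, g2, prov,
                    saturated = stack$saturated, hot = stack$hot,
                    interpolated = stack$interpolated,
                    background = stack$background)
}

#' Acquisition frame rate of a binary-accumulating sequence
#'
#' In global shutter mode every binary frame is exposed then read out, so a
#' full sequence of `g` gate images of `b` binary frames each takes
#' \eqn{(T_{read} + T_{exp})\,b\,G} and the effective frame rate is its
#' inverse:
#' \deqn{f_{read} = \left[(T_{read} + T_{exp})\, b\, G\right]^{-1}.}
#' Firmware restart dead time between long sub-sequences is not part of this
#' formula; see `sequence_time` for the raw duration.
#'
#' @param t_read_s Binary frame readout time in seconds (10.2e-6 at full
#'   frame size).
#' @param t_exp_s Binary frame exposure time in seconds.
#' @param b Binary frames per gate image (255 or 1020).
#' @param g Number of gate positions.
#' @return `frame_rate`: frames per second; `sequence_time`: seconds.
#' @examples
#' frame_rate(10.2e-6, 10e-6, 255, 16)   # ~12.1 fps
#' frame_rate(10.2e-6, 10e-6, 255, 1)    # ~194 fps
#' @export
frame_rate <- function(t_read_s, t_exp_s, b, g) {
  stopifnot(t_read_s > 0, t_exp_s > 0, b >= 1, g >= 1)
  1 / ((t_read_s + t_exp_s) * b * g)
}

#' @rdname frame_rate
#' @export
sequence_time <- function(t_read_s, t_exp_s, b, g) {
  (t_read_s + t_exp_s) * b * g
}

#' Exposure time from the firmware counter
#'
#' The binary frame exposure is set by an on-FPGA counter:
#' \eqn{T_{exp} = n\,\theta_1 - \theta_0} with \eqn{\theta_1 = 400} ns and
#' \eqn{\theta_0 = 50} ns.
#'
#' @param n Counter value, positive integer.
#' @param theta1_ns,theta0_ns Firmware constants in ns.
#' @return Exposure time in ns.
#' @examples
#' exposure_time(25)  # 9950 ns
#' @export
exposure_time <- function(n, theta1_ns = 400, theta0_ns = 50) {
  stopifnot(n >= 1, n == as.integer(n))
  n * theta1_ns - theta0_ns
}

#' Microlens concentration factor and effective fill factor
#'
#' The concentration factor is the ratio of dark-subtracted mean photon
#' counts recorded with and without microlenses under identical conditions,
#' \eqn{CF = (\mu_m - d_m)/(\mu_{nm} - d_{nm})}; multiplying the native fill
#' factor by \eqn{CF} gives the effective fill factor.
#'
#' @param mean_with Mean photon count with microlenses.
#' @param mean_without Mean photon count without microlenses.
#' @param dark_with,dark_without Corresponding dark counts (default 0).
#' @return `concentration_factor`: the dimensionless CF.
#' @examples
#' concentration_factor(109.6, 41.4)           # ~2.65
#' effective_fill_factor(2.65, 10.5)           # ~27.8 (%)
#' @export
concentration_factor <- function(mean_with, mean_without,
                                 dark_with = 0, dark_without = 0) {
  num <- mean_with - dark_with
  den <- mean_without - dark_without
  if (den <= 0) stop("denominator (dark-subtracted mean without lenses) must be positive")
  num / den
}

#' @rdname concentration_factor
#' @param cf Concentration factor.
#' @param native_ff_percent Native fill factor in percent.
#' @return `effective_fill_factor`: effective fill factor in percent.
#' @export
effective_fill_factor <- function(cf, native_ff_percent) {
  stopifnot(cf > 0, native_ff_percent > 0)
  cf * native_ff_percent
}
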
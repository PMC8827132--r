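#' Laser excitation configuration
#'
#' Describes the pulsed excitation source: the laser period and the frequency
#' at which phasors are evaluated. All times are carried internally in
#' nanoseconds and all frequencies in reciprocal nanoseconds; constructor
#' arguments in Hz are converted at this boundary.
#'
#' @param period_ns Laser period \eqn{T} in ns (e.g. 50 ns for a 20 MHz
#'   laser). Exactly one of `period_ns` and `rep_rate_hz` must be given.
#' @param rep_rate_hz Repetition rate in Hz; converted to `period_ns = 1e9 /
#'   rep_rate_hz`.
#' @param phasor_freq_hz Phasor frequency \eqn{f} in Hz. Defaults to the
#'   repetition rate (the first harmonic), which is the standard choice; higher
#'   harmonics are supported by passing a multiple of the repetition rate.
#' @return An object of class `laser_config` with fields `period_ns`,
#'   `rep_rate_hz` and `phasor_freq_per_ns` (\eqn{f} in 1/ns).
#' @examples
#' laser_config(period_ns = 50)            # 20 MHz laser, f = 20 MHz
#' laser_config(rep_rate_hz = 20e6)
#' @export
laser_config <- function(period_ns = NULL, rep_rate_hz = NULL,
                         phasor_freq_hz = NULL) {
  if (is.null(period_ns) == is.null(rep_rate_hz))
    stop("give exactly one of `period_ns` and `rep_rate_hz`")
  if (is.null(period_ns)) period_ns <- 1e9 / rep_rate_hz
  if (is.null(rep_rate_hz)) rep_rate_hz <- 1e9 / period_ns
  if (!is.numeric(period_ns) || length(period_ns) != 1L || period_ns <= 0)
    stop("`period_ns` must be a single positive number")
  stopifnot(abs(rep_rate_hz * period_ns * 1e-9 - 1) < 1e-9)
  if (is.null(phasor_freq_hz)) phasor_freq_hz <- rep_rate_hz
  if (phasor_freq_hz <= 0) stop("`phasor_freq_hz` must be positive")
  structure(
    list(period_ns = period_ns, rep_rate_hz = rep_rate_hz,
         phasor_freq_hz = phasor_freq_hz,
         phasor_freq_per_ns = phasor_freq_hz * 1e-9),
    class = "laser_config")
}

#' Time-gate configuration
#'
#' Describes a sequence of rectangular detector gates of common width
#' \eqn{W}, opened at delays \eqn{t_k = t_0 + (k - 1)\,\delta t} after the
#' laser pulse, for \eqn{k = 1, \dots, G}. Gate delays may exceed the laser
#' period; gates are treated modulo the period wherever a decay is observed
#' through them.
#'
#' @param width_ns Gate width \eqn{W} in ns, positive.
#' @param step_ns Delay step \eqn{\delta t} between consecutive gates in ns,
#'   positive.
#' @param num_gates Number of gate positions \eqn{G}, at least 1.
#' @param first_offset_ns Delay of the first gate relative to the laser pulse
#'   in ns (default 0).
#' @return An object of class `gate_config`.
#' @seealso [gate_timestamps()], [ss2_gate_config()]
#' @export
gate_config <- function(width_ns, step_ns, num_gates, first_offset_ns = 0) {
  stopifnot(is.numeric(width_ns), length(width_ns) == 1L, width_ns > 0,
            is.numeric(step_ns), length(step_ns) == 1L, step_ns > 0,
            is.numeric(num_gates), length(num_gates) == 1L, num_gates >= 1,
            num_gates == as.integer(num_gates),
            is.numeric(first_offset_ns), length(first_offset_ns) == 1L)
  structure(
    list(width_ns = width_ns, step_ns = step_ns,
         num_gates = as.integer(num_gates),
         first_offset_ns = first_offset_ns),
    class = "gate_config")
}

#' SwissSPAD2-style full gate scan
#'
#' Convenience constructor for the acquisition geometry used throughout this
#' package's reference workflow: `num_gates` positions stepped uniformly
#' across one laser period (step = period / G; 2800 gates over 50 ns gives
#' the 17.86 ps step of the full-resolution scan).
#'
#' @param width_ns Gate width in ns (default 13.1 ns).
#' @param num_gates Number of gate positions (default 2800).
#' @param period_ns Laser period in ns (default 50 ns).
#' @export
ss2_gate_config <- function(width_ns = 13.1, num_gates = 2800,
                            period_ns = 50) {
  gate_config(width_ns = width_ns, step_ns = period_ns / num_gates,
              num_gates = num_gates, first_offset_ns = 0)
}

#' Gate opening timestamps
#'
#' @param cfg A [gate_config()].
#' @return Numeric vector of length \eqn{G}: \eqn{t_k = t_0 + (k-1)\delta t}
#'   in ns, strictly increasing.
#' @examples
#' gate_timestamps(gate_config(13.1, 3.125, 16))
#' @export
gate_timestamps <- function(cfg) {
  stopifnot(inherits(cfg, "gate_config"))
  cfg$first_offset_ns + (seq_len(cfg$num_gates) - 1) * cfg$step_ns
}

#' Fluorescence decay model
#'
#' A (multi-)exponential decay under steady-state periodic excitation, plus
#' an uncorrelated background rate. Multi-exponential decays are represented
#' as amplitude-weighted sums of single-exponential photon fractions, which
#' is what two-species mixtures require; amplitudes are interpreted as
#' relative photon yields and are normalized internally.
#'
#' @param lifetimes_ns Vector of lifetimes \eqn{\tau_j} in ns, all positive.
#' @param amplitudes Nonnegative weights, same length, summing to a positive
#'   value (default: equal weights).
#' @param background_rate_per_ns Uncorrelated background intensity in counts
#'   per ns of gate-open time, nonnegative (default 0).
#' @return An object of class `decay_model`.
#' @export
decay_model <- function(lifetimes_ns, amplitudes = NULL,
                        background_rate_per_ns = 0) {
  stopifnot(is.numeric(lifetimes_ns), length(lifetimes_ns) >= 1L,
            all(lifetimes_ns > 0))
  if (is.null(amplitudes)) amplitudes <- rep(1, length(lifetimes_ns))
  stopifnot(length(amplitudes) == length(lifetimes_ns),
            all(amplitudes >= 0), sum(amplitudes) > 0,
            background_rate_per_ns >= 0)
  structure(
    list(lifetimes_ns = lifetimes_ns,
         amplitudes = amplitudes / sum(amplitudes),
         background_rate_per_ns = background_rate_per_ns),
    class = "decay_model")
}

#' @export
print.laser_config <- function(x, ...) {
  cat(sprintf("<laser_config> T = %g ns (%.4g MHz), phasor f = %.4g MHz\n",
              x$period_ns, x$rep_rate_hz / 1e6, x$phasor_freq_hz / 1e6))
  invisible(x)
}

#' @export
print.gate_config <- function(x, ...) {
  cat(sprintf("<gate_config> W = %g ns, step = %g ns, G = %d, offset = %g ns\n",
              x$width_ns, x$step_ns, x$num_gates, x$first_offset_ns))
  invisible(x)
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("<decay_model> tau = {%s} ns, amplitudes = {%s}, bkg = %g /ns\n",
              paste(signif(x$lifetimes_ns, 4), collapse = ", "),
              paste(signif(x$amplitudes, 4), collapse = ", "),
              x$background_rate_per_ns))
  invisible(x)
}

# CDF of the steady-state periodic single-exponential arrival density on
# [0, T): integral of p(t) = exp(-t/tau) / (tau (1 - exp(-T/tau))).
periodic_exp_cdf <- function(t, tau, T) {
  (1 - exp(-t / tau)) / (1 - exp(-T / tau))
}

#' Fraction of decay photons captured by one rectangular gate
#'
#' Under periodic excitation with a pulse at \eqn{t = 0} every period, the
#' steady-state per-period arrival density of a single-exponential decay is
#' \deqn{p(t) = \frac{e^{-t/\tau}}{\tau\,(1 - e^{-T/\tau})}, \quad
#'   t \in [0, T).}
#' This returns the closed-form integral of \eqn{p} over a rectangular gate
#' `[gate_start, gate_start + width_ns)`, treated modulo the period: a gate
#' reaching past \eqn{T} wraps around and also captures the early part of the
#' next period's decay. Multi-exponential models are amplitude-weighted sums
#' of single-exponential fractions; the background term of the model is not
#' included (it is handled by the profile/simulation layer).
#'
#' An optional trapezoidal gate shape with linear rise/fall edges is
#' available through `edge_ns`: the gate transmission then ramps linearly
#' over `edge_ns` at each boundary while keeping the same full-width at half
#' maximum. The ideal rectangle (`edge_ns = 0`) is the reference model.
#'
#' @param decay A [decay_model()].
#' @param gate_start Gate opening time in ns, in `[0, T)`.
#' @param width_ns Gate width in ns, `0 < width_ns <= T`.
#' @param period_ns Laser period \eqn{T} in ns.
#' @param edge_ns Linear rise/fall edge duration in ns (default 0 =
#'   rectangular); must satisfy `edge_ns <= width_ns`.
#' @return The expected fraction of fluorescence photons in the gate, in
#'   `[0, 1]`; exactly 1 when `width_ns == period_ns`.
#' @examples
#' d <- decay_model(2.8)
#' expected_gate_fraction(d, 0, 13.1, 50)
#' expected_gate_fraction(d, 0, 50, 50)   # full-period gate: 1
#' @export
expected_gate_fraction <- function(decay, gate_start, width_ns, period_ns,
                                   edge_ns = 0) {
  stopifnot(inherits(decay, "decay_model"),
            width_ns > 0, period_ns > 0,
            gate_start >= 0, gate_start < period_ns,
            width_ns <= period_ns,
            edge_ns >= 0, edge_ns <= width_ns)
  if (edge_ns > 0)
    return(trapezoid_gate_fraction(decay, gate_start, width_ns, period_ns,
                                   edge_ns))
  frac_one <- function(tau) {
    a <- gate_start
    b <- gate_start + width_ns
    if (b <= period_ns) {
      periodic_exp_cdf(b, tau, period_ns) - periodic_exp_cdf(a, tau, period_ns)
    } else {
      # wraps past the period boundary: [a, T) plus [0, b - T)
      (1 - periodic_exp_cdf(a, tau, period_ns)) +
        periodic_exp_cdf(b - period_ns, tau, period_ns)
    }
  }
  sum(decay$amplitudes * vapply(decay$lifetimes_ns, frac_one, numeric(1)))
}

# Trapezoidal gate: transmission ramps 0 -> 1 over edge_ns centred on each
# boundary, preserving the rectangle's area (same FWHM). Computed by exact
# integration of w(t) * p(t) with w piecewise linear, using antiderivatives
# of exp(-t/tau) and t exp(-t/tau) on the wrapped segments.
trapezoid_gate_fraction <- function(decay, gate_start, width_ns, period_ns,
                                    edge_ns) {
  T <- period_ns
  h <- edge_ns / 2
  # breakpoints of the trapezoid relative to gate_start
  # rising: [-h, h] from 0 to 1; flat: [h, W - h]; falling: [W - h, W + h]
  frac_one <- function(tau) {
    Z <- tau * (1 - exp(-T / tau))
    # integral of exp(-t/tau) over wrapped [u, v] (v - u <= T)
    int_e <- function(u, v) {
      seg <- function(a, b) tau * (exp(-a / tau) - exp(-b / tau))
      u <- u %% T; v2 <- u + (v - u)
      if (v2 <= T) seg(u, v2) else seg(u, T) + seg(0, v2 - T)
    }
    # integral of (t - t_ref_line form) handled via local coordinates:
    # integral over wrapped window of (alpha + beta * t_local) exp(-t/tau)
    # where t_local measures time from the window start (unwrapped).
    int_lin <- function(u, len, alpha, beta) {
      # integral_{x=0}^{len} (alpha + beta x) exp(-((u + x) mod T)/tau) dx
      f <- function(x0, x1, shift) {
        # integral of (alpha + beta x) exp(-(u + x - shift)/tau) dx, x0..x1
        A <- function(x) -tau * exp(-(u + x - shift) / tau)
        B <- function(x) -tau * (x + tau) * exp(-(u + x - shift) / tau)
        alpha * (A(x1) - A(x0)) + beta * (B(x1) - B(x0))
      }
      u <- u %% T
      if (u + len <= T) f(0, len, 0)
      else f(0, T - u, 0) + f(T - u, len, T)
    }
    a <- gate_start
    W <- width_ns
    val <- 0
    # rising edge on [a - h, a + h]: w = (x)/(2h), x local in [0, 2h]
    if (h > 0) {
      val <- val + int_lin(a - h, 2 * h, 0, 1 / (2 * h))
      # falling edge on [a + W - h, a + W + h]: w = 1 - x/(2h)
      val <- val + int_lin(a + W - h, 2 * h, 1, -1 / (2 * h))
      # flat top
      if (W - 2 * h > 0) val <- val + int_e(a + h, a + W - h)
    } else {
      val <- int_e(a, a + W)
    }
    val / Z
  }
  v <- sum(decay$amplitudes *
             vapply(decay$lifetimes_ns, frac_one, numeric(1)))
  min(max(v, 0), 1)
}

#' Expected per-gate detection intensity profile
#'
#' The noiseless forward model of one pixel: for each gate position
#' \eqn{t_k}, the expected number of detected photons per binary frame is
#' \deqn{\lambda_k = \Lambda \cdot
#'   \mathrm{frac}(t_k \bmod T, W) + r_b \cdot W \cdot n_p,}
#' where \eqn{\Lambda} is the expected fluorescence photon flux per frame
#' (`photons_per_frame`), \eqn{r_b} the model's uncorrelated background rate
#' per ns of open gate, and \eqn{n_p} the number of laser pulses per frame
#' (background accrues during every gate opening of the frame). The profile
#' is periodic: gates delayed by a whole period see the same intensity.
#'
#' @param decay A [decay_model()].
#' @param gates A [gate_config()].
#' @param laser A [laser_config()].
#' @param photons_per_frame Expected fluorescence photons incident per binary
#'   frame (before gating), nonnegative.
#' @param pulses_per_frame Laser pulses per binary frame (default 1).
#' @param edge_ns Optional trapezoidal gate edge, see
#'   [expected_gate_fraction()].
#' @return Numeric vector of \eqn{\lambda_k}, one per gate.
#' @export
expected_gate_profile <- function(decay, gates, laser, photons_per_frame,
                                  pulses_per_frame = 1, edge_ns = 0) {
  stopifnot(inherits(decay, "decay_model"), inherits(gates, "gate_config"),
            inherits(laser, "laser_config"), photons_per_frame >= 0,
            pulses_per_frame >= 1)
  T <- laser$period_ns
  ts <- gate_timestamps(gates) %% T
  fl <- vapply(ts, function(t0)
    expected_gate_fraction(decay, t0, gates$width_ns, T, edge_ns),
    numeric(1))
  photons_per_frame * fl +
    decay$background_rate_per_ns * gates$width_ns * pulses_per_frame
}
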
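#' Probability that a 1-bit pixel memory is set
#'
#' A gated SPAD pixel with a 1-bit in-pixel memory records at most one photon
#' per binary frame: the first detection sets the memory, later photons in
#' the same frame are lost. With Poisson arrivals at expected count
#' \eqn{\lambda} inside the gate, the probability the bit is set is
#' \eqn{1 - e^{-\lambda}}. This saturation is the origin of pile-up.
#'
#' @param lambda Expected detected photons per binary frame inside the gate;
#'   nonnegative (vectorized).
#' @return `1 - exp(-lambda)`, in `[0, 1)`.
#' @export
binary_detection_probability <- function(lambda) {
  if (any(lambda < 0)) stop("`lambda` must be nonnegative")
  1 - exp(-lambda)
}

#' Simulation parameters for a gated SPAD acquisition
#'
#' Bundles everything the forward simulator needs. Per-pixel fields
#' (`brightness`, `dark_count_rate_cps`, `skew_ns`) may be scalars (uniform
#' across the array) or `height x width` matrices.
#'
#' @param laser A [laser_config()].
#' @param gates A [gate_config()].
#' @param decay A [decay_model()] applied to every pixel.
#' @param height,width Sensor dimensions in pixels.
#' @param brightness Expected fluorescence photons incident per binary frame
#'   per pixel (before gating); scalar or matrix.
#' @param frames_per_gate Number of 1-bit frames accumulated per gate image
#'   \eqn{b}; 255 for 8-bit and 1020 for 10-bit gate images.
#' @param pulses_per_frame Laser pulses per binary frame exposure (default
#'   200, i.e. a 10 us exposure at a 50 ns period).
#' @param dark_count_rate_cps Dark count rate in counts per second; scalar or
#'   matrix. Dark counts are uniform in time and contribute only while the
#'   gate is open.
#' @param hot_pixel_fraction Fraction of pixels replaced by "hot" pixels with
#'   elevated dark count rate, in `[0, 1)` (default 0).
#' @param hot_pixel_dcr_cps Dark count rate assigned to hot pixels (default
#'   1e4 cps; hot pixels are conventionally those above 1 kcps). May be a
#'   function `function(n)` drawing `n` rates, to model a DCR distribution.
#' @param skew_ns Per-pixel static offset added to every gate opening time
#'   (deterministic gate-edge skew); scalar or matrix (default 0).
#' @param bit_depth 8 or 10; must be consistent with `frames_per_gate`
#'   (255 -> 8, 1020 -> 10). Defaults from `frames_per_gate`.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(laser, gates, decay, height, width,
                       brightness, frames_per_gate = 255,
                       pulses_per_frame = 200,
                       dark_count_rate_cps = 0,
                       hot_pixel_fraction = 0,
                       hot_pixel_dcr_cps = 1e4,
                       skew_ns = 0, bit_depth = NULL) {
  stopifnot(inherits(laser, "laser_config"), inherits(gates, "gate_config"),
            inherits(decay, "decay_model"),
            height >= 1, width >= 1, frames_per_gate >= 1,
            pulses_per_frame >= 1,
            hot_pixel_fraction >= 0, hot_pixel_fraction < 1)
  as_map <- function(x, what) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(height, width)))
        stop(sprintf("`%s` matrix must be %d x %d", what, height, width))
      x
    } else matrix(x, height, width)
  }
  brightness <- as_map(brightness, "brightness")
  dcr <- as_map(dark_count_rate_cps, "dark_count_rate_cps")
  skew <- as_map(skew_ns, "skew_ns")
  if (any(brightness < 0) || any(dcr < 0))
    stop("brightness and dark count rates must be nonnegative")
  if (is.null(bit_depth))
    bit_depth <- if (frames_per_gate > 255) 10L else 8L
  structure(
    list(laser = laser, gates = gates, decay = decay,
         height = as.integer(height), width = as.integer(width),
         brightness = brightness, frames_per_gate = as.integer(frames_per_gate),
         pulses_per_frame = pulses_per_frame,
         dark_count_rate_cps = dcr,
         hot_pixel_fraction = hot_pixel_fraction,
         hot_pixel_dcr_cps = hot_pixel_dcr_cps,
         skew_ns = skew, bit_depth = as.integer(bit_depth)),
    class = "sim_params")
}

#' Gate-image stack
#'
#' Container for a stack of accumulated gate images: a `height x width x G`
#' array of counts in `[0, I_max]`, per-gate timestamps, and acquisition
#' metadata. `I_max` equals the number of binary frames per gate image.
#'
#' @param counts `H x W x G` numeric array of nonnegative integers.
#' @param timestamps Gate opening times in ns, length `G`.
#' @param i_max Maximum recordable count per gate image (= frames per gate).
#' @param bit_depth 8 or 10.
#' @param laser A [laser_config()].
#' @param gates A [gate_config()].
#' @param provenance Character vector of processing steps applied so far.
#' @return An object of class `gate_stack`.
#' @export
gate_stack <- function(counts, timestamps, i_max, bit_depth, laser, gates,
                       provenance = character()) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  if (length(timestamps) != dim(counts)[3L])
    stop("length(timestamps) must equal the number of gate planes")
  if (any(counts < 0) || any(counts > i_max))
    stop("counts must lie in [0, i_max]")
  structure(
    list(counts = counts, timestamps = timestamps,
         i_max = i_max, bit_depth = as.integer(bit_depth),
         laser = laser, gates = gates, provenance = provenance),
    class = "gate_stack")
}

#' @export
print.gate_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<gate_stack> %d x %d pixels, %d gates, I_max = %g (%d-bit)\n",
    d[1], d[2], d[3], x$i_max, x$bit_depth))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Simulate a gated SPAD gate-image stack
#'
#' Forward-simulates the 1-bit accumulation acquisition: for each pixel and
#' gate position, the expected detected photons per binary frame are
#' \eqn{\lambda_k =} brightness \eqn{\times} gate fraction (evaluated at the
#' pixel's skewed gate delay) \eqn{+} DCR \eqn{\times} gate-open time per
#' frame, and the accumulated count is a draw from
#' \eqn{\mathrm{Binomial}(b,\ 1 - e^{-\lambda_k})}. Pile-up therefore arises
#' naturally from the model rather than being imposed. Identical parameters
#' and seed yield a bit-identical stack.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed for reproducibility.
#' @return A [gate_stack()].
#' @export
simulate_gate_stack <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  laser <- params$laser; gates <- params$gates
  T <- laser$period_ns
  H <- params$height; W <- params$width; G <- gates$num_gates
  b <- params$frames_per_gate
  ts <- gate_timestamps(gates)

  # hot pixels: replace DCR of a random subset
  dcr <- params$dark_count_rate_cps
  if (params$hot_pixel_fraction > 0) {
    n_hot <- round(params$hot_pixel_fraction * H * W)
    if (n_hot > 0) {
      idx <- sample.int(H * W, n_hot)
      rates <- if (is.function(params$hot_pixel_dcr_cps))
        params$hot_pixel_dcr_cps(n_hot) else rep(params$hot_pixel_dcr_cps, n_hot)
      dcr[idx] <- rates
    }
  }
  # dark expectation per frame: DCR [1/s] * 1e-9 [s/ns] * W_ns * pulses
  dark_lambda <- dcr * 1e-9 * gates$width_ns * params$pulses_per_frame

  skew <- params$skew_ns
  uniform_skew <- length(unique(as.vector(skew))) == 1L
  counts <- array(0, dim = c(H, W, G))
  if (uniform_skew) {
    s0 <- skew[1L]
    frac <- vapply(ts, function(t0)
      expected_gate_fraction(params$decay, (t0 + s0) %% T, gates$width_ns, T),
      numeric(1))
    for (k in seq_len(G)) {
      lam <- params$brightness * frac[k] + dark_lambda
      counts[, , k] <- matrix(
        stats::rbinom(H * W, b, binary_detection_probability(lam)), H, W)
    }
  } else {
    # per-pixel skew: gate fraction depends on the pixel
    for (k in seq_len(G)) {
      starts <- (ts[k] + skew) %% T
      frac <- vapply(as.vector(starts), function(t0)
        expected_gate_fraction(params$decay, t0, gates$width_ns, T),
        numeric(1))
      lam <- params$brightness * matrix(frac, H, W) + dark_lambda
      counts[, , k] <- matrix(
        stats::rbinom(H * W, b, binary_detection_probability(lam)), H, W)
    }
  }
  gate_stack(counts, ts, i_max = b, bit_depth = params$bit_depth,
             laser = laser, gates = gates,
             provenance = sprintf("simulate(seed=%d)", seed))
}

#' Simulate photon arrival timestamps under periodic excitation
#'
#' Draws `n` single-exponential arrival times with lifetime `tau_ns` and
#' folds them modulo the laser period, giving the steady-state arrival
#' density of periodic pulsed excitation. This is the photon-level primitive
#' of the Monte Carlo precision machinery.
#'
#' @param tau_ns Lifetime in ns, positive.
#' @param period_ns Laser period in ns, positive.
#' @param n Number of photons, at least 1.
#' @param seed Optional integer seed; if `NULL`, the current RNG stream is
#'   used (so that callers can manage a single master stream).
#' @return Numeric vector of `n` timestamps in `[0, period_ns)`.
#' @export
simulate_photon_timestamps <- function(tau_ns, period_ns, n, seed = NULL) {
  stopifnot(tau_ns > 0, period_ns > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rexp(n, rate = 1 / tau_ns) %% period_ns
}

#' Bin photon timestamps into scanned, possibly overlapping gates
#'
#' Each timestamp contributes to every gate whose window (taken modulo the
#' laser period) contains it. Overlapping gates therefore count the same
#' photon several times — exactly what a scanned-gate acquisition records,
#' since each gate position is a separate exposure of the same decay.
#'
#' @param timestamps Photon times in `[0, period_ns)`.
#' @param gates A [gate_config()].
#' @param period_ns Laser period in ns.
#' @return Integer vector of per-gate counts, length `G`.
#' @export
gate_bin_timestamps <- function(timestamps, gates, period_ns) {
  stopifnot(inherits(gates, "gate_config"))
  if (any(timestamps < 0) || any(timestamps >= period_ns))
    stop("timestamps must lie in [0, period_ns)")
  ts <- gate_timestamps(gates) %% period_ns
  W <- gates$width_ns
  # photon at x is in gate k iff (x - t_k) mod T < W
  vapply(ts, function(t0)
    sum(((timestamps - t0) %% period_ns) < W), numeric(1))
}

#' Stochastically assign photons to single gate positions
#'
#' In a scanned-gate acquisition every gate position is a separate exposure,
#' so each detected photon is recorded at exactly one gate position — the
#' one whose window happened to be open — and the only timing information it
#' carries is that gate's timestamp. Conditional on detection, the recording
#' gate is uniform among the gates whose windows contain the photon's
#' arrival time, which is what blurs effective timestamps by the gate width.
#' This operation performs that assignment and returns per-gate counts; it
#' is the stochastic counterpart of [gate_bin_timestamps()] (which counts
#' every containing gate) and the photon-level model behind the Monte Carlo
#' precision machinery.
#'
#' The gates must tile the period uniformly: `first_offset_ns = 0` and
#' `step_ns * num_gates = period_ns`. Photons contained in no gate (possible
#' only when the gate width is below the step) are simply not detected.
#'
#' @param timestamps Photon times in `[0, period_ns)`.
#' @param gates A [gate_config()] tiling the period.
#' @param period_ns Laser period in ns.
#' @return Integer vector of per-gate counts; the sum equals the number of
#'   detected photons.
#' @export
sample_gate_counts <- function(timestamps, gates, period_ns) {
  stopifnot(inherits(gates, "gate_config"))
  if (any(timestamps < 0) || any(timestamps >= period_ns))
    stop("timestamps must lie in [0, period_ns)")
  G <- gates$num_gates
  dt <- gates$step_ns
  if (abs(dt * G - period_ns) > 1e-9 * period_ns ||
      abs(gates$first_offset_ns) > 1e-12)
    stop("gates must tile the period: offset 0, step * num_gates = period")
  W <- gates$width_ns
  r <- timestamps %% dt
  m <- floor((W - r) / dt) + 1          # gate starts in (x - W, x], on grid
  keep <- m >= 1
  x <- timestamps[keep]; r <- r[keep]; m <- m[keep]
  j <- floor(stats::runif(length(x)) * m)
  start <- (x - r - j * dt) %% period_ns
  k <- (round(start / dt) %% G) + 1
  tabulate(k, nbins = G)
}
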
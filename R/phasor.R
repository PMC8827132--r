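#' Phasor of a gated decay profile
#'
#' The phasor of a decay recorded as gate intensities \eqn{I_k} at gate
#' delays \eqn{t_k} is its normalized first Fourier coefficient at the
#' phasor frequency \eqn{f}:
#' \deqn{z = g + i s = m e^{i\varphi} =
#'   \frac{\sum_k I_k e^{i 2\pi f t_k}}{\sum_k I_k}.}
#'
#' @param intensities Gate intensities \eqn{I_k} (may be fractional or
#'   negative after background subtraction).
#' @param timestamps_ns Gate delays \eqn{t_k} in ns, same length.
#' @param freq_per_ns Phasor frequency \eqn{f} in 1/ns (0.02 for 20 MHz), or
#'   a [laser_config()] whose phasor frequency is used.
#' @return An object of class `phasor`: a complex scalar with accessors
#'   `Re`/`Im` giving `g`/`s`.
#' @examples
#' compute_phasor(c(4, 3, 2, 1), c(0, 12.5, 25, 37.5), 1 / 50)  # 0.2 + 0.2i
#' @export
compute_phasor <- function(intensities, timestamps_ns, freq_per_ns) {
  f <- as_freq_per_ns(freq_per_ns)
  if (length(intensities) != length(timestamps_ns))
    stop("intensities and timestamps differ in length")
  tot <- sum(intensities)
  if (tot == 0) stop("zero total intensity: phasor undefined")
  z <- sum(intensities * exp(2i * pi * f * timestamps_ns)) / tot
  new_phasor(z)
}

new_phasor <- function(z) structure(z, class = "phasor")

as_freq_per_ns <- function(f) {
  if (inherits(f, "laser_config")) f$phasor_freq_per_ns
  else { stopifnot(is.numeric(f), f > 0); f }
}

#' @export
print.phasor <- function(x, ...) {
  cat(sprintf("<phasor> g = %.6g, s = %.6g (m = %.6g, phi = %.6g rad)\n",
              Re(x), Im(x), Mod(x), Arg(x)))
  invisible(x)
}

#' Phase lifetime from a phasor
#'
#' The phase lifetime is read off the phasor's phase:
#' \eqn{\tau_\varphi = \tan(\varphi) / (2\pi f) = (s/g) / (2\pi f)}.
#' It is only defined for first-quadrant phasors; `g <= 0` (or `s < 0`)
#' yields `NA` rather than a negative lifetime.
#'
#' @param p A `phasor`, complex value, or complex vector/matrix (per-pixel
#'   use).
#' @param freq_per_ns Phasor frequency in 1/ns, or a [laser_config()].
#' @return Lifetime(s) in ns; `NA` where the phase lifetime is undefined.
#' @export
phase_lifetime <- function(p, freq_per_ns) {
  f <- as_freq_per_ns(freq_per_ns)
  g <- Re(p); s <- Im(p)
  out <- ifelse(g > 0, s / g / (2 * pi * f), NA_real_)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Theoretical phasor of a single-exponential decay
#'
#' With \eqn{u = 2\pi f \tau}: modulus \eqn{m = (1 + u^2)^{-1/2}}, phase
#' \eqn{\varphi = \arctan(u)}, hence \eqn{g = 1/(1+u^2)}, \eqn{s =
#' u/(1+u^2)}. These lie on the universal semicircle
#' \eqn{(g - 1/2)^2 + s^2 = 1/4}, running from \eqn{(1, 0)} at \eqn{\tau = 0}
#' to \eqn{(0, 0)} as \eqn{\tau \to \infty}.
#'
#' @param tau_ns Lifetime in ns, nonnegative (vectorized).
#' @param freq_per_ns Phasor frequency in 1/ns, or a [laser_config()].
#' @return A `phasor` (complex, vectorized over `tau_ns`).
#' @export
single_exp_phasor <- function(tau_ns, freq_per_ns) {
  f <- as_freq_per_ns(freq_per_ns)
  stopifnot(all(tau_ns >= 0))
  u <- 2 * pi * f * tau_ns
  new_phasor(complex(real = 1 / (1 + u^2), imaginary = u / (1 + u^2)))
}

#' Calibrate an experimental phasor with a known-lifetime reference
#'
#' The instrument response and the gate integration rescale and rotate every
#' phasor by a common complex factor: \eqn{z_{exp} \simeq z_{theo} \cdot
#' z_{IRF+gate}}. Measuring a calibration sample of known lifetime
#' \eqn{\tau_{cal}} determines that factor, and the corrected phasor is
#' \deqn{z = z_{exp} \cdot \frac{z_{cal,theo}}{z_{cal,exp}},}
#' with \eqn{z_{cal,theo}} from [single_exp_phasor()]. Works per scalar
#' phasor or elementwise on matching phasor maps (global, per-ROI or
#' per-pixel calibration, depending on what is passed).
#'
#' @param z_exp Uncalibrated phasor(s): complex scalar, vector or matrix.
#' @param z_cal_exp Measured phasor(s) of the calibration sample; scalar or
#'   same shape as `z_exp`; must be nonzero.
#' @param tau_cal_ns Known lifetime of the calibration sample in ns.
#' @param freq_per_ns Phasor frequency in 1/ns, or a [laser_config()].
#' @return Calibrated phasor(s), same shape as `z_exp`.
#' @export
calibrate_phasor <- function(z_exp, z_cal_exp, tau_cal_ns, freq_per_ns) {
  if (any(z_cal_exp == 0)) stop("calibration phasor is zero")
  z_theo <- single_exp_phasor(tau_cal_ns, freq_per_ns)
  new_phasor(unclass(z_exp) * unclass(z_theo) / unclass(z_cal_exp))
}

#' Sum a stack or image over square regions of interest
#'
#' Sums counts over contiguous `n x n` pixel tiles (4x4 is the usual choice
#' for per-ROI calibration maps; 8x8 for mixture analysis). Trailing rows or
#' columns that do not fill a tile are dropped.
#'
#' @param x A [gate_stack()], [corrected_stack()], or `H x W` matrix.
#' @param n ROI side in pixels; `n = 1` is the identity.
#' @return Same type as the input, with dimensions `floor(H/n) x floor(W/n)`.
#' @export
bin_rois <- function(x, n) {
  stopifnot(n >= 1, n == as.integer(n))
  bin_mat <- function(m) {
    H <- (nrow(m) %/% n) * n; W <- (ncol(m) %/% n) * n
    if (H < n || W < n) stop("ROI side larger than the image")
    m <- m[seq_len(H), seq_len(W), drop = FALSE]
    # sum over n x n tiles via two rolled-up matrix products
    rowagg <- diag(H %/% n)[rep(seq_len(H %/% n), each = n), , drop = FALSE]
    colagg <- diag(W %/% n)[rep(seq_len(W %/% n), each = n), , drop = FALSE]
    t(rowagg) %*% m %*% colagg
  }
  if (is.matrix(x)) return(bin_mat(x))
  vals <- stack_values(x)
  G <- dim(vals)[3]
  planes <- lapply(seq_len(G), function(k) bin_mat(vals[, , k]))
  out <- array(unlist(planes), dim = c(dim(planes[[1]]), G))
  if (inherits(x, "gate_stack")) {
    gate_stack(out, x$timestamps, i_max = x$i_max * n^2,
               bit_depth = x$bit_depth, laser = x$laser, gates = x$gates,
               provenance = c(x$provenance, sprintf("bin_rois(%d)", n)))
  } else {
    corrected_stack(out, x$timestamps, x$laser, x$gates,
                    provenance = c(x$provenance, sprintf("bin_rois(%d)", n)))
  }
}

#' Per-pixel (or per-ROI) phasor image
#'
#' Computes the phasor of every pixel of a stack. Pixels with non-positive
#' total intensity get an invalid flag instead of propagating NaN.
#'
#' @param stack A [gate_stack()] or [corrected_stack()].
#' @param freq_per_ns Phasor frequency in 1/ns, or a [laser_config()];
#'   default: the stack's laser configuration.
#' @return An object of class `phasor_image`: list with complex matrix `z`,
#'   matrices `g`, `s`, `intensity`, logical `valid`, and `freq_per_ns`.
#' @export
phasor_image <- function(stack, freq_per_ns = NULL) {
  vals <- stack_values(stack)
  f <- as_freq_per_ns(if (is.null(freq_per_ns)) stack$laser else freq_per_ns)
  G <- dim(vals)[3]
  ph <- exp(2i * pi * f * stack$timestamps)
  H <- dim(vals)[1]; W <- dim(vals)[2]
  flat <- matrix(vals, H * W, G)
  num <- flat %*% ph
  tot <- rowSums(flat)
  valid <- tot > 0
  z <- matrix(complex(real = NA_real_, imaginary = NA_real_), H, W)
  z[valid] <- num[valid] / tot[valid]
  structure(
    list(z = z, g = Re(z), s = Im(z),
         intensity = matrix(tot, H, W), valid = matrix(valid, H, W),
         freq_per_ns = f),
    class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf("<phasor_image> %d x %d, %d valid pixels, f = %g /ns\n",
              nrow(x$z), ncol(x$z), sum(x$valid), x$freq_per_ns))
  invisible(x)
}

#' Calibrate a phasor image
#'
#' Applies [calibrate_phasor()] across a phasor image, with the calibration
#' factor resolved at the requested granularity:
#' * `"global"` — one factor from the calibration image's intensity-weighted
#'   mean phasor;
#' * `"roi"` — the calibration image is already at ROI resolution and is
#'   used elementwise (the default workflow bins both images 4x4 first);
#' * `"pixel"` — elementwise, full resolution.
#' `"roi"` and `"pixel"` differ only in what the caller binned; both require
#' matching shapes.
#'
#' @param pim Phasor image of the sample ([phasor_image()]).
#' @param cal_pim Phasor image of the calibration sample, same gate
#'   configuration.
#' @param tau_cal_ns Known calibration lifetime in ns.
#' @param granularity `"global"`, `"roi"` or `"pixel"`.
#' @return A calibrated `phasor_image`; pixels where either input is invalid
#'   are invalid.
#' @export
calibrate_phasor_image <- function(pim, cal_pim, tau_cal_ns,
                                   granularity = c("roi", "global", "pixel")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(pim, "phasor_image"), inherits(cal_pim, "phasor_image"))
  if (granularity == "global") {
    w <- cal_pim$intensity[cal_pim$valid]
    zc <- sum(cal_pim$z[cal_pim$valid] * w) / sum(w)
    valid <- pim$valid
  } else {
    if (!all(dim(pim$z) == dim(cal_pim$z)))
      stop("sample and calibration phasor images differ in shape")
    zc <- cal_pim$z
    valid <- pim$valid & cal_pim$valid
  }
  z <- matrix(complex(real = NA_real_, imaginary = NA_real_),
              nrow(pim$z), ncol(pim$z))
  zcal <- if (is.matrix(zc)) zc[valid] else zc
  z[valid] <- unclass(calibrate_phasor(pim$z[valid], zcal, tau_cal_ns,
                                       pim$freq_per_ns))
  structure(
    list(z = z, g = Re(z), s = Im(z), intensity = pim$intensity,
         valid = valid & !is.na(Re(z)), freq_per_ns = pim$freq_per_ns),
    class = "phasor_image")
}

#' Phasor ratio of a mixture between two reference phasors
#'
#' The phasor of a two-species mixture lies on the segment joining the pure
#' species' phasors. The phasor ratio of species 1 is computed by orthogonal
#' projection of `z` onto the line through `z1` and `z2`, clamping the
#' projection to the segment, and taking
#' \eqn{r_1 = d_2 / (d_1 + d_2)} with \eqn{d_j} the distance from the
#' projection to reference \eqn{j}. `z = z1` gives \eqn{r_1 = 1}; points
#' projecting beyond an endpoint clamp to 0 or 1.
#'
#' @param z Mixture phasor(s): complex scalar, vector or matrix.
#' @param z1,z2 Pure-species reference phasors (distinct).
#' @return List with `r1` (same shape as `z`) and `projection` (complex,
#'   the clamped projection points).
#' @export
phasor_ratio <- function(z, z1, z2) {
  z1 <- unclass(z1); z2 <- unclass(z2); z <- unclass(z)
  if (z1 == z2) stop("reference phasors coincide")
  d <- z2 - z1
  t <- Re((z - z1) * Conj(d)) / Mod(d)^2   # position along z1 -> z2
  t <- pmin(pmax(t, 0), 1)
  proj <- z1 + t * d
  list(r1 = 1 - t, projection = proj)
}

#' Volume fraction from a phasor ratio, and the inverse relation
#'
#' The phasor ratio \eqn{r_1} and the volume fraction \eqn{v_1} of species 1
#' are related through the product \eqn{\mu\chi} of the concentration ratio
#' \eqn{\mu} and brightness ratio \eqn{\chi}:
#' \deqn{r_1^{-1} = 1 + (\mu\chi)^{-1}\,(v_1^{-1} - 1)
#'   \quad\Longleftrightarrow\quad
#'   r_1 = \frac{\mu\chi\, v_1}{\mu\chi\, v_1 + 1 - v_1}.}
#' The relation is linear only when \eqn{\mu\chi = 1}.
#'
#' @param r1 Phasor ratio(s) in `[0, 1]`.
#' @param mu_chi The product \eqn{\mu\chi}, positive.
#' @return `volume_fraction`: \eqn{v_1}; endpoints map exactly (`r1 = 0 ->
#'   0`, `r1 = 1 -> 1`).
#' @export
volume_fraction <- function(r1, mu_chi) {
  stopifnot(mu_chi > 0, all(r1 >= 0), all(r1 <= 1))
  ifelse(r1 %in% c(0, 1), r1,
         1 / (1 + mu_chi * (1 / r1 - 1)))
}

#' @rdname volume_fraction
#' @param v1 Volume fraction(s) in `[0, 1]`.
#' @return `phasor_ratio_from_fraction`: the forward relation \eqn{r_1(v_1)}.
#' @export
phasor_ratio_from_fraction <- function(v1, mu_chi) {
  stopifnot(mu_chi > 0, all(v1 >= 0), all(v1 <= 1))
  mu_chi * v1 / (mu_chi * v1 + 1 - v1)
}

#' Fit the brightness-concentration product from a dilution series
#'
#' Least-squares fit of the phasor-ratio/volume-fraction relation to
#' observed pairs, returning the \eqn{\mu\chi} estimate and its standard
#' error. Given an independently known brightness ratio \eqn{\chi}, the
#' concentration ratio follows as \eqn{\mu = (\mu\chi)/\chi}.
#'
#' @param v1 Known volume fractions, length at least 2, values in `(0, 1)`
#'   or at the endpoints (endpoints carry no information and are dropped).
#' @param r1 Observed phasor ratios, same length.
#' @return List with `mu_chi`, `se` (standard error; 0 for an exact fit),
#'   `residuals`, and `n` (pairs used).
#' @export
fit_mu_chi <- function(v1, r1) {
  stopifnot(length(v1) == length(r1), length(v1) >= 2,
            all(v1 >= 0), all(v1 <= 1), all(r1 >= 0), all(r1 <= 1))
  keep <- v1 > 0 & v1 < 1
  v <- v1[keep]; r <- r1[keep]
  if (length(v) < 2) stop("need at least 2 interior (v1, r1) pairs")
  ss <- function(loga) sum((r - phasor_ratio_from_fraction(v, exp(loga)))^2)
  opt <- stats::optimize(ss, interval = log(c(1e-4, 1e4)), tol = 1e-12)
  a <- exp(opt$minimum)
  res <- r - phasor_ratio_from_fraction(v, a)
  # SE from the Jacobian of the 1-parameter model: dr/da = v(1-v)/(av+1-v)^2
  J <- v * (1 - v) / (a * v + 1 - v)^2
  dof <- max(length(v) - 1L, 1L)
  sigma2 <- sum(res^2) / dof
  se <- sqrt(sigma2 / sum(J^2))
  list(mu_chi = a, se = se, residuals = res, n = length(v))
}

#' Phasor-ratio lifetime map
#'
#' Color-codes every pixel of a phasor image by its phasor ratio between two
#' reference phasors: `r = 0` renders red (the short-lifetime reference),
#' `r = 1` blue (the long-lifetime reference), with a spectrum scale in
#' between. Mode `"flat"` keeps luminance constant; mode `"scaled"`
#' multiplies luminance by the normalized total intensity, so dark pixels
#' render black regardless of phasor. Invalid phasors get a designated null
#' color.
#'
#' @param pim A [phasor_image()] (usually calibrated).
#' @param ref_red,ref_blue Reference phasors for ratio 0 and 1.
#' @param mode `"flat"` or `"scaled"`.
#' @param null_color RGB triple in `[0, 1]` for invalid pixels (default
#'   mid gray).
#' @return `H x W x 3` array of RGB values in `[0, 1]`, plus attribute
#'   `ratio` holding the `H x W` ratio matrix.
#' @export
lifetime_map <- function(pim, ref_red, ref_blue, mode = c("flat", "scaled"),
                         null_color = c(0.5, 0.5, 0.5)) {
  mode <- match.arg(mode)
  stopifnot(inherits(pim, "phasor_image"))
  pr <- phasor_ratio(pim$z, ref_blue, ref_red)  # r1 = 1 at ref_blue
  r <- matrix(pr$r1, nrow(pim$z), ncol(pim$z))
  ramp <- grDevices::colorRamp(
    c("red", "orange", "yellow", "green", "cyan", "blue"))
  H <- nrow(r); W <- ncol(r)
  rgb <- array(0, dim = c(H, W, 3))
  ok <- pim$valid & !is.na(r)
  cols <- ramp(r[ok]) / 255  # ramp argument 0 = red end, 1 = blue end
  lum <- if (mode == "scaled") {
    mx <- max(pim$intensity[ok], 0)
    if (mx > 0) pim$intensity[ok] / mx else rep(0, sum(ok))
  } else rep(1, sum(ok))
  for (ch in 1:3) {
    plane <- matrix(null_color[ch], H, W)
    plane[ok] <- cols[, ch] * lum
    rgb[, , ch] <- plane
  }
  attr(rgb, "ratio") <- ifelse(ok, r, NA_real_)
  rgb
}

#' Two-dimensional phasor histogram
#'
#' Bins the valid per-pixel phasors of a phasor image into a `(g, s)` grid.
#' Total mass equals the number of valid pixels; phasors outside the range
#' are counted into the edge bins.
#'
#' @param pim A [phasor_image()].
#' @param bins Number of bins per axis (scalar or length 2).
#' @param range List with `g = c(min, max)`, `s = c(min, max)`; default the
#'   usual phasor-plot window `g` in `[0, 1]`, `s` in `[0, 0.75]`.
#' @return List with `counts` (bins_g x bins_s matrix), and bin-center
#'   vectors `g_mid`, `s_mid`.
#' @export
phasor_histogram2d <- function(pim, bins = 100,
                               range = list(g = c(0, 1), s = c(0, 0.75))) {
  stopifnot(inherits(pim, "phasor_image"), all(bins >= 1))
  bins <- rep(as.integer(bins), length.out = 2)
  g <- pim$g[pim$valid]; s <- pim$s[pim$valid]
  cut_idx <- function(x, rng, nb) {
    i <- floor((x - rng[1]) / diff(rng) * nb) + 1
    pmin(pmax(i, 1), nb)
  }
  gi <- cut_idx(g, range$g, bins[1])
  si <- cut_idx(s, range$s, bins[2])
  counts <- matrix(0, bins[1], bins[2])
  for (i in seq_along(gi))
    counts[gi[i], si[i]] <- counts[gi[i], si[i]] + 1
  mids <- function(rng, nb) rng[1] + (seq_len(nb) - 0.5) * diff(rng) / nb
  list(counts = counts,
       g_mid = mids(range$g, bins[1]), s_mid = mids(range$s, bins[2]))
}
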
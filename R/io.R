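#' Write a gate stack to a multi-page TIFF with a JSON sidecar
#'
#' The image payload is a multi-page 16-bit grayscale TIFF, one page per
#' gate in ascending timestamp order. Acquisition metadata and processing
#' provenance go to `<path>.json`: keys `period_ns`, `gate_width_ns`,
#' `gate_step_ns`, `num_gates`, `first_offset_ns`, `phasor_freq_hz`,
#' `bit_depth`, `i_max`, `timestamps_ns`, `provenance`. Times are also
#' mirrored in seconds (`period_s`, ...) for tooling that expects SI units.
#' The roundtrip through [read_gate_stack()] is lossless.
#'
#' @param stack A [gate_stack()] with integer counts (I_max at most 65535).
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_gate_stack <- function(stack, path) {
  stopifnot(inherits(stack, "gate_stack"))
  if (stack$i_max > 65535) stop("counts exceed 16-bit TIFF range")
  G <- dim(stack$counts)[3]
  pages <- lapply(seq_len(G), function(k) stack$counts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  sidecar <- list(
    period_ns = stack$laser$period_ns,
    period_s = stack$laser$period_ns * 1e-9,
    gate_width_ns = stack$gates$width_ns,
    gate_width_s = stack$gates$width_ns * 1e-9,
    gate_step_ns = stack$gates$step_ns,
    gate_step_s = stack$gates$step_ns * 1e-9,
    num_gates = stack$gates$num_gates,
    first_offset_ns = stack$gates$first_offset_ns,
    phasor_freq_hz = stack$laser$phasor_freq_hz,
    bit_depth = stack$bit_depth,
    i_max = stack$i_max,
    timestamps_ns = stack$timestamps,
    provenance = as.list(stack$provenance))
  jsonlite::write_json(sidecar, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

# Field-by-field sidecar validation; returns the parsed sidecar or stops
# with the offending field.
validate_sidecar <- function(sc) {
  need_num <- c("period_ns", "gate_width_ns", "gate_step_ns",
                "first_offset_ns", "phasor_freq_hz", "i_max")
  for (f in need_num) {
    if (is.null(sc[[f]]) || !is.numeric(sc[[f]]) || length(sc[[f]]) != 1L)
      stop(sprintf("sidecar field `%s` missing or not a number", f))
  }
  for (f in c("num_gates", "bit_depth")) {
    v <- sc[[f]]
    if (is.null(v) || !is.numeric(v) || v != as.integer(v))
      stop(sprintf("sidecar field `%s` missing or not an integer", f))
  }
  if (sc$period_ns <= 0 || sc$gate_width_ns <= 0 || sc$gate_step_ns <= 0)
    stop("sidecar times must be positive")
  if (!sc$bit_depth %in% c(8L, 10L, 16L))
    stop("sidecar `bit_depth` must be 8, 10 or 16")
  if (is.null(sc$timestamps_ns) ||
      length(sc$timestamps_ns) != sc$num_gates)
    stop("sidecar `timestamps_ns` missing or wrong length")
  sc
}

#' Read a gate stack written by [write_gate_stack()]
#'
#' The sidecar is validated before any pixel data is touched; a missing or
#' malformed sidecar, a page count disagreeing with `num_gates`, or counts
#' above `i_max` are errors.
#'
#' @param path TIFF path with a `<path>.json` sidecar next to it.
#' @return A [gate_stack()].
#' @export
read_gate_stack <- function(path) {
  scp <- sidecar_path(path)
  if (!file.exists(scp)) stop("missing sidecar: ", scp)
  sc <- validate_sidecar(jsonlite::read_json(scp, simplifyVector = TRUE))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != sc$num_gates)
    stop(sprintf("TIFF has %d pages but sidecar declares %d gates",
                 length(pages), sc$num_gates))
  counts <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- round(pages[[k]] * 65535)
  if (any(counts > sc$i_max))
    stop("counts exceed the sidecar's i_max")
  laser <- laser_config(period_ns = sc$period_ns,
                        phasor_freq_hz = sc$phasor_freq_hz)
  gates <- gate_config(sc$gate_width_ns, sc$gate_step_ns, sc$num_gates,
                       sc$first_offset_ns)
  gate_stack(counts, sc$timestamps_ns, i_max = sc$i_max,
             bit_depth = sc$bit_depth, laser = laser, gates = gates,
             provenance = unlist(sc$provenance))
}

#' Ingest a four-sub-frame 10-bit acquisition
#'
#' Some acquisition firmware stores each 10-bit gate image as four
#' consecutive 8-bit gate images at the same gate position. This converter
#' sums each run of four consecutive pages into one native 10-bit gate
#' image (I_max 1020).
#'
#' @param stack A [gate_stack()] whose gate planes are 4 consecutive 8-bit
#'   sub-frames per gate position (page count divisible by 4); timestamps of
#'   the 4 sub-frames of one position must be equal.
#' @param subframes Sub-frames per gate position (default 4).
#' @return A [gate_stack()] with a quarter of the pages and `i_max = 4 *`
#'   the input's.
#' @export
combine_subframes <- function(stack, subframes = 4L) {
  stopifnot(inherits(stack, "gate_stack"))
  G <- dim(stack$counts)[3]
  if (G %% subframes != 0)
    stop("page count is not a multiple of the sub-frame count")
  Gout <- G %/% subframes
  d <- dim(stack$counts)
  out <- array(0, dim = c(d[1], d[2], Gout))
  ts <- numeric(Gout)
  for (j in seq_len(Gout)) {
    idx <- ((j - 1) * subframes + 1):(j * subframes)
    if (length(unique(stack$timestamps[idx])) != 1L)
      stop("sub-frames of one gate position must share a timestamp")
    out[, , j] <- apply(stack$counts[, , idx, drop = FALSE], c(1, 2), sum)
    ts[j] <- stack$timestamps[idx[1]]
  }
  g2 <- gate_config(stack$gates$width_ns, stack$gates$step_ns * subframes,
                    Gout, stack$gates$first_offset_ns)
  gate_stack(out, ts, i_max = stack$i_max * subframes, bit_depth = 10L,
             laser = stack$laser, gates = g2,
             provenance = c(stack$provenance,
                            sprintf("combine_subframes(%d)", subframes)))
}

#' Run the standard correction-to-phasor pipeline
#'
#' Executes the canonical analysis order — pile-up correction, optional
#' background subtraction, optional hot-pixel handling, ROI binning, phasor
#' computation, calibration, phase lifetimes, and optionally a mixture or
#' lifetime-map step. The nonlinear pile-up correction is always applied to
#' per-pixel recorded counts before any summation, and background is
#' subtracted from the pile-up-corrected signal.
#'
#' @param sample_stack A [gate_stack()] of the sample of interest.
#' @param cal_stack A [gate_stack()] of the calibration sample, same gate
#'   configuration; `NULL` skips calibration.
#' @param tau_cal_ns Known calibration lifetime in ns (required with
#'   `cal_stack`).
#' @param pileup Apply pile-up correction (default `TRUE`).
#' @param background_window_ns `c(from, to)` tail window in ns for
#'   background estimation, or `NULL` to skip; or a single number used as a
#'   constant per-gate background.
#' @param hot_percentile Top intensity percentile to mask and interpolate
#'   (default 0 = off).
#' @param roi_bin ROI side for binning (default 4; 1 = per pixel).
#' @param mixture Optional list `list(z1 =, z2 =, mu_chi =)` to add phasor
#'   ratios (and volume fractions when `mu_chi` is given).
#' @param map Optional list `list(ref_red =, ref_blue =, mode =)` to add a
#'   phasor-ratio color map.
#' @return List with `phasors` (calibrated [phasor_image()] or uncalibrated
#'   when no reference is given), `uncalibrated`, `tau_ns` (phase-lifetime
#'   matrix), `sample_corrected`, and optional `mixture`/`map` components.
#' @export
run_pipeline <- function(sample_stack, cal_stack = NULL, tau_cal_ns = NULL,
                         pileup = TRUE, background_window_ns = NULL,
                         hot_percentile = 0, roi_bin = 4,
                         mixture = NULL, map = NULL) {
  prep <- function(stk) {
    cur <- stk
    if (pileup) cur <- pileup_correct_stack(cur)
    if (!is.null(background_window_ns)) {
      bg <- if (length(background_window_ns) == 2L)
        estimate_background_tail(cur, background_window_ns)
      else matrix(background_window_ns,
                  dim(stack_values(cur))[1], dim(stack_values(cur))[2])
      cur <- subtract_background(cur, bg)
    }
    if (hot_percentile > 0) cur <- correct_hot_pixels(cur, hot_percentile)
    if (roi_bin > 1) cur <- bin_rois(cur, roi_bin)
    cur
  }
  sample_c <- prep(sample_stack)
  pim <- phasor_image(sample_c)
  out <- list(uncalibrated = pim, sample_corrected = sample_c)
  if (!is.null(cal_stack)) {
    if (is.null(tau_cal_ns)) stop("`tau_cal_ns` is required with a calibration stack")
    cal_pim <- phasor_image(prep(cal_stack))
    pim <- calibrate_phasor_image(pim, cal_pim, tau_cal_ns,
                                  granularity = "roi")
  }
  out$phasors <- pim
  out$tau_ns <- matrix(phase_lifetime(pim$z, pim$freq_per_ns),
                       nrow(pim$z), ncol(pim$z))
  if (!is.null(mixture)) {
    pr <- phasor_ratio(pim$z, mixture$z1, mixture$z2)
    r1 <- matrix(pr$r1, nrow(pim$z), ncol(pim$z))
    r1[!pim$valid] <- NA_real_
    out$mixture <- list(r1 = r1)
    if (!is.null(mixture$mu_chi)) {
      v1 <- r1
      ok <- !is.na(r1)
      v1[ok] <- volume_fraction(r1[ok], mixture$mu_chi)
      out$mixture$v1 <- v1
    }
  }
  if (!is.null(map)) {
    out$map <- lifetime_map(pim, ref_red = map$ref_red,
                            ref_blue = map$ref_blue,
                            mode = if (is.null(map$mode)) "flat" else map$mode)
  }
  out
}

#' Export a phasor image as a tidy CSV table
#'
#' Columns: `x`, `y` (0-based column/row), `g`, `s`, `intensity`,
#' `tau_phase_ns`, `valid`.
#'
#' @param pim A [phasor_image()].
#' @param path CSV destination.
#' @return The data frame, invisibly.
#' @export
write_phasor_csv <- function(pim, path) {
  stopifnot(inherits(pim, "phasor_image"))
  H <- nrow(pim$z); W <- ncol(pim$z)
  df <- data.frame(
    x = rep(seq_len(W) - 1L, each = H),
    y = rep(seq_len(H) - 1L, times = W),
    g = as.vector(pim$g), s = as.vector(pim$s),
    intensity = as.vector(pim$intensity),
    tau_phase_ns = as.vector(phase_lifetime(pim$z, pim$freq_per_ns)),
    valid = as.vector(pim$valid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
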
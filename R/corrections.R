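#' Pile-up correction of binary-accumulated counts
#'
#' The 1-bit per-frame storage of a gated SPAD pixel saturates: with
#' recorded count \eqn{I_{rec}} out of \eqn{I_{max}} binary frames, the
#' linearized estimate of the incident count is
#' \deqn{I_{corr} = -I_{max} \ln\!\left(1 - I_{rec}/I_{max}\right).}
#' The correction is monotone increasing and never below the recorded count.
#' Fully saturated entries (\eqn{I_{rec} = I_{max}}) have no finite
#' correction; they are clamped to \eqn{I_{max} - 1/2} before the logarithm
#' and flagged, since the true incident count is unbounded there.
#'
#' @param i_rec Recorded counts; scalar, vector or array, in `[0, i_max]`.
#' @param i_max Maximum recordable count (number of binary frames), positive.
#' @return For atomic input, corrected counts with an attribute `saturated`
#'   (logical, same shape) marking clamped entries.
#' @examples
#' pileup_correct(128, 255)             # ~177.76
#' pileup_correct(255 * (1 - exp(-1)), 255)  # exactly 255
#' @export
pileup_correct <- function(i_rec, i_max) {
  stopifnot(i_max > 0)
  if (any(i_rec < 0)) stop("recorded counts must be nonnegative")
  if (any(i_rec > i_max)) stop("recorded counts exceed i_max")
  saturated <- i_rec >= i_max
  i_eff <- ifelse(saturated, i_max - 0.5, i_rec)
  out <- -i_max * log(1 - i_eff / i_max)
  attr(out, "saturated") <- saturated
  out
}

#' Forward pile-up saturation model
#'
#' The inverse of [pileup_correct()]: the expected recorded count when
#' `i_true` photons per gate image are incident on a 1-bit accumulating
#' pixel, \eqn{I_{rec} = I_{max}(1 - e^{-I_{true}/I_{max}})}.
#'
#' @param i_true Incident counts, nonnegative.
#' @param i_max Maximum recordable count.
#' @export
pileup_saturate <- function(i_true, i_max) {
  stopifnot(i_max > 0)
  if (any(i_true < 0)) stop("incident counts must be nonnegative")
  i_max * (1 - exp(-i_true / i_max))
}

#' Corrected gate stack
#'
#' Like [gate_stack()] but holding real-valued (possibly fractional or, after
#' background subtraction, negative) intensities together with per-pixel
#' provenance flags and the background map that was removed.
#'
#' @param values `H x W x G` numeric array.
#' @param timestamps,laser,gates,provenance As in [gate_stack()].
#' @param saturated,hot,interpolated Optional `H x W` logical flag matrices.
#' @param background Optional `H x W` matrix of the per-gate background that
#'   was subtracted.
#' @return An object of class `corrected_stack`.
#' @export
corrected_stack <- function(values, timestamps, laser, gates,
                            provenance = character(),
                            saturated = NULL, hot = NULL,
                            interpolated = NULL, background = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            length(timestamps) == dim(values)[3L])
  hw <- dim(values)[1:2]
  blank <- matrix(FALSE, hw[1], hw[2])
  chk <- function(m, what) {
    if (is.null(m)) return(blank)
    if (!is.matrix(m) || !all(dim(m) == hw))
      stop(sprintf("`%s` must be a %d x %d matrix", what, hw[1], hw[2]))
    m
  }
  structure(
    list(values = values, timestamps = timestamps, laser = laser,
         gates = gates, provenance = provenance,
         saturated = chk(saturated, "saturated"),
         hot = chk(hot, "hot"),
         interpolated = chk(interpolated, "interpolated"),
         background = if (is.null(background)) NULL
                      else chk(background, "background")),
    class = "corrected_stack")
}

#' @export
print.corrected_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<corrected_stack> %d x %d pixels, %d gates\n", d[1], d[2], d[3]))
  cat(sprintf("  flags: %d saturated, %d hot, %d interpolated pixels\n",
              sum(x$saturated), sum(x$hot), sum(x$interpolated)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# shared accessors over gate_stack / corrected_stack
stack_values <- function(stack) {
  if (inherits(stack, "gate_stack")) stack$counts
  else if (inherits(stack, "corrected_stack")) stack$values
  else stop("expected a gate_stack or corrected_stack")
}

#' Apply the pile-up correction to a whole stack
#'
#' @param stack A [gate_stack()].
#' @return A [corrected_stack()] with `saturated` flagging any pixel that had
#'   at least one fully saturated gate.
#' @export
pileup_correct_stack <- function(stack) {
  stopifnot(inherits(stack, "gate_stack"))
  corr <- pileup_correct(stack$counts, stack$i_max)
  sat <- attr(corr, "saturated")
  attr(corr, "saturated") <- NULL
  corrected_stack(corr, stack$timestamps, stack$laser, stack$gates,
                  provenance = c(stack$provenance, "pileup_correct"),
                  saturated = apply(sat, c(1, 2), any))
}

#' Estimate uncorrelated background from the decay tail
#'
#' Uncorrelated background (dark counts, ambient light) adds an offset to
#' every gate. When the lifetime is much shorter than the un-gated part of
#' the period, gates opening in the decay tail see essentially only this
#' offset; its per-pixel level is estimated as the mean of the gate values
#' whose opening timestamps fall inside `tail_window_ns`. The method is only
#' unbiased when the fluorescence contribution in the window is negligible
#' (lifetime much smaller than period minus gate width); for long-lived
#' samples a different estimator is required and this one will overestimate.
#'
#' @param stack A [gate_stack()] or [corrected_stack()].
#' @param tail_window_ns Length-2 numeric `c(from, to)` in ns; gates with
#'   `from <= t_k <= to` enter the average. Must contain at least one gate.
#' @return `H x W` matrix: per-pixel background per gate image.
#' @export
estimate_background_tail <- function(stack, tail_window_ns) {
  vals <- stack_values(stack)
  stopifnot(length(tail_window_ns) == 2L,
            tail_window_ns[1] <= tail_window_ns[2])
  sel <- stack$timestamps >= tail_window_ns[1] &
         stack$timestamps <= tail_window_ns[2]
  if (!any(sel)) stop("tail window contains no gate timestamps")
  apply(vals[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Subtract a per-pixel background from every gate
#'
#' Values are not clamped at zero: clamping would bias downstream phasor
#' sums, whereas zero-mean residual noise cancels.
#'
#' @param stack A [gate_stack()] or [corrected_stack()].
#' @param background `H x W` matrix (or scalar) of per-gate background.
#' @return A [corrected_stack()].
#' @export
subtract_background <- function(stack, background) {
  vals <- stack_values(stack)
  hw <- dim(vals)[1:2]
  if (length(background) == 1L) background <- matrix(background, hw[1], hw[2])
  if (!all(dim(background) == hw))
    stop("background map shape does not match the image")
  out <- sweep(vals, c(1, 2), background, `-`)
  prev <- if (inherits(stack, "corrected_stack")) stack else NULL
  corrected_stack(out, stack$timestamps, stack$laser, stack$gates,
                  provenance = c(stack$provenance, "subtract_background"),
                  saturated = prev$saturated, hot = prev$hot,
                  interpolated = prev$interpolated,
                  background = background)
}

#' Flag the brightest pixels as noisy
#'
#' Pixels in the top `p` intensity percentile of the total-intensity image
#' are flagged (typically hot SPADs with dark count rates above 1 kcps).
#' Ties at the threshold are all flagged. Note the caveat that this also
#' rejects genuinely bright sample regions.
#'
#' @param intensity `H x W` matrix of total (summed over gates) intensity.
#' @param percentile `p` in `[0, 100)`; `p = 0` flags nothing.
#' @return `H x W` logical mask.
#' @export
hot_pixel_mask <- function(intensity, percentile) {
  stopifnot(is.matrix(intensity), percentile >= 0, percentile < 100)
  if (percentile == 0) return(matrix(FALSE, nrow(intensity), ncol(intensity)))
  thr <- stats::quantile(intensity, probs = 1 - percentile / 100,
                         names = FALSE, type = 7)
  intensity >= thr
}

#' Replace masked pixels by their 4-neighbor mean
#'
#' Each masked pixel is replaced by the mean of its unmasked neighbors above,
#' below, left and right; edge pixels use whichever neighbors exist. Masked
#' pixels whose neighbors are all masked are resolved iteratively, each pass
#' using the values filled in by the previous one.
#'
#' @param image `H x W` numeric matrix.
#' @param mask `H x W` logical; `TRUE` entries are replaced. Must not be
#'   all `TRUE`.
#' @return The image with masked entries interpolated.
#' @export
interpolate_masked <- function(image, mask) {
  stopifnot(is.matrix(image), is.logical(mask), all(dim(mask) == dim(image)))
  if (all(mask)) stop("mask covers the whole image; nothing to interpolate from")
  H <- nrow(image); W <- ncol(image)
  out <- image
  todo <- which(mask, arr.ind = TRUE)
  known <- !mask
  while (nrow(todo) > 0) {
    filled_this_pass <- logical(nrow(todo))
    newvals <- numeric(nrow(todo))
    for (i in seq_len(nrow(todo))) {
      r <- todo[i, 1]; c <- todo[i, 2]
      nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= H & nb[, 2] >= 1 & nb[, 2] <= W, ,
               drop = FALSE]
      ok <- known[nb]
      if (any(ok)) {
        newvals[i] <- mean(out[nb[ok, , drop = FALSE]])
        filled_this_pass[i] <- TRUE
      }
    }
    if (!any(filled_this_pass))
      stop("masked region is disconnected from any unmasked pixel")
    out[todo[filled_this_pass, , drop = FALSE]] <-
      newvals[filled_this_pass]
    known[todo[filled_this_pass, , drop = FALSE]] <- TRUE
    todo <- todo[!filled_this_pass, , drop = FALSE]
  }
  out
}

#' Mask and interpolate hot pixels across a whole stack
#'
#' Convenience wrapper: builds the hot-pixel mask from the total-intensity
#' image and interpolates every gate plane.
#'
#' @param stack A [gate_stack()] or [corrected_stack()].
#' @param percentile Passed to [hot_pixel_mask()].
#' @return A [corrected_stack()] with `hot` and `interpolated` flags set.
#' @export
correct_hot_pixels <- function(stack, percentile) {
  vals <- stack_values(stack)
  total <- apply(vals, c(1, 2), sum)
  mask <- hot_pixel_mask(total, percentile)
  out <- vals
  if (any(mask))
    for (k in seq_len(dim(vals)[3]))
      out[, , k] <- interpolate_masked(vals[, , k], mask)
  prev <- if (inherits(stack, "corrected_stack")) stack else NULL
  corrected_stack(out, stack$timestamps, stack$laser, stack$gates,
                  provenance = c(stack$provenance,
                                 sprintf("hot_pixels(p=%g)", percentile)),
                  saturated = prev$saturated, hot = mask,
                  interpolated = mask, background = prev$background)
}
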
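#' Quantification parameters
#'
#' The vesicular threshold is an operator-chosen fixed intensity applied to
#' background-subtracted values; a named vector gives per-channel values
#' (channels not named fall back to the first value, mirroring reuse of the
#' cytokine threshold for the marker channel unless overridden).
#'
#' @param vesicular_threshold non-negative fixed intensity (scalar or named
#'   per-channel vector), applied after background subtraction.
#' @return a `quant_params` list.
#' @export
quant_params <- function(vesicular_threshold = 1000) {
  stopifnot(all(vesicular_threshold >= 0))
  structure(list(vesicular_threshold = vesicular_threshold),
            class = "quant_params")
}

vesicular_threshold_for <- function(params, channel) {
  v <- params$vesicular_threshold
  if (!is.null(names(v)) && channel %in% names(v)) return(as.numeric(v[[channel]]))
  as.numeric(v[[1]])
}

#' Estimate the per-image background from the nuclear region
#'
#' The background of a channel is the arithmetic mean of that channel's
#' intensities over the nuclear-mask pixels: one value per image per
#' channel. With an empty nuclear mask the estimate is undefined; supply
#' `fallback` (a configured constant background) or an error is raised.
#'
#' @param stack an [image_stack()].
#' @param channel channel to estimate the background for.
#' @param nuclear_mask logical matrix from [nuclear_mask()].
#' @param fallback constant background used when the nuclear mask is empty.
#' @return background intensity (scalar).
#' @export
estimate_background <- function(stack, channel, nuclear_mask,
                                fallback = NULL) {
  img <- get_channel(stack, channel)
  if (is.null(nuclear_mask) || !any(nuclear_mask)) {
    if (!is.null(fallback)) return(as.numeric(fallback))
    stop("empty nuclear mask: configure a constant fallback background ",
         "(`fallback`) or provide a nuclear channel", call. = FALSE)
  }
  mean(img[nuclear_mask > 0])
}

#' Subtract a scalar background, clamping at zero
#'
#' Each pixel becomes `max(intensity - background, 0)`; clamping keeps
#' integrated densities non-negative and the compartment ordering valid.
#'
#' @param grid numeric matrix (one channel).
#' @param background non-negative scalar.
#' @return corrected matrix.
#' @export
subtract_background <- function(grid, background) {
  stopifnot(background >= 0)
  pmax(grid - background, 0)
}

#' Vesicular mask of one cell
#'
#' ROI pixels whose background-subtracted intensity is at or above the
#' vesicular threshold.
#'
#' @param corrected background-subtracted channel matrix.
#' @param roi a `cell_roi`.
#' @param params a [quant_params()] list.
#' @param channel channel name used to look up a per-channel threshold.
#' @return logical matrix (full field size).
#' @export
vesicular_mask <- function(corrected, roi, params = quant_params(),
                           channel = NULL) {
  stopifnot(inherits(roi, "cell_roi"))
  thr <- if (is.null(channel)) as.numeric(params$vesicular_threshold[[1]])
         else vesicular_threshold_for(params, channel)
  m <- matrix(FALSE, nrow(corrected), ncol(corrected))
  sel <- roi$pixels[corrected[roi$pixels] >= thr]
  m[sel] <- TRUE
  m
}

#' Integrated density over a mask
#'
#' Sum of (corrected) intensities over the mask pixels — the arbitrary
#' units of fluorescence (AUF) quantity.
#'
#' @param grid numeric matrix.
#' @param mask logical matrix of the same dimensions, or integer pixel
#'   indices.
#' @return scalar intensity-times-pixels.
#' @export
integrated_density <- function(grid, mask) {
  if (is.logical(mask)) {
    stopifnot(identical(dim(grid), dim(mask)))
    return(sum(grid[mask]))
  }
  sum(grid[mask])
}

#' Measure one cell's compartments in one channel
#'
#' The cellular compartment is the full ROI; the vesicular compartment is
#' the above-threshold subset of it (so vesicular is contained in cellular
#' and the vesicular percentage is at most 100). Intensities are
#' background-subtracted before both measurements.
#'
#' @param stack an [image_stack()].
#' @param channel measurement channel name.
#' @param roi a `cell_roi`.
#' @param nuclear_mask logical matrix (may be `NULL` with `background`
#'   supplied).
#' @param params a [quant_params()] list.
#' @param background precomputed background for this image/channel; when
#'   `NULL` it is estimated from `nuclear_mask`.
#' @param fallback constant background if the nuclear mask is empty.
#' @return a `compartment_measurement`: `cell_label`, `channel`,
#'   `background`, `id_vesicular`, `id_cellular`, `vesicular_percent`.
#' @export
measure_cell <- function(stack, channel, roi, nuclear_mask = NULL,
                         params = quant_params(), background = NULL,
                         fallback = NULL) {
  stopifnot(inherits(roi, "cell_roi"))
  bg <- background %||%
    estimate_background(stack, channel, nuclear_mask, fallback = fallback)
  corrected <- subtract_background(get_channel(stack, channel), bg)
  thr <- vesicular_threshold_for(params, channel)
  vals <- corrected[roi$pixels]
  id_cell <- sum(vals)
  id_ves <- sum(vals[vals >= thr])
  structure(list(
    cell_label = roi$label, channel = channel, background = bg,
    id_vesicular = id_ves, id_cellular = id_cell,
    vesicular_percent = if (id_cell > 0) 100 * id_ves / id_cell else 0),
    class = "compartment_measurement")
}

#' @export
print.compartment_measurement <- function(x, ...) {
  cat(sprintf(
    "<compartment_measurement> cell %d [%s]: bg %.2f, ID ves %.1f / cell %.1f (%.1f%%)\n",
    x$cell_label, x$channel, x$background, x$id_vesicular, x$id_cellular,
    x$vesicular_percent))
  invisible(x)
}
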
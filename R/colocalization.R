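#' Manders' M1/M2 colocalization coefficients of one cell
#'
#' Computed over the ROI pixels of the raw (non-background-subtracted)
#' channels with explicit per-channel thresholds and strict inequality:
#'
#' \deqn{M1 = \frac{\sum_p ch1_p \, [ch2_p > t_2]}{\sum_p ch1_p \, [ch1_p > t_1]}}
#'
#' and M2 symmetrically with the channels swapped. Both coefficients lie in
#' \[0, 1\]: 0 for no colocalization, 1 for perfect colocalization. A zero
#' denominator (no above-threshold signal in the cell) leaves that
#' coefficient undefined (`NA`, flagged) rather than coercing it to 0,
#' which would bias group means.
#'
#' @param ch1,ch2 raw channel matrices of identical shape.
#' @param roi a `cell_roi`.
#' @param threshold_ch1,threshold_ch2 non-negative intensity thresholds.
#' @return a `coloc_result` list: `cell_label`, `m1`, `m2`, `m1_defined`,
#'   `m2_defined`, `threshold_ch1`, `threshold_ch2`.
#' @export
manders_coefficients <- function(ch1, ch2, roi, threshold_ch1,
                                 threshold_ch2) {
  stopifnot(identical(dim(ch1), dim(ch2)),
            inherits(roi, "cell_roi"),
            threshold_ch1 >= 0, threshold_ch2 >= 0)
  a <- ch1[roi$pixels]
  b <- ch2[roi$pixels]
  den1 <- sum(a[a > threshold_ch1])
  den2 <- sum(b[b > threshold_ch2])
  m1 <- if (den1 > 0) sum(a[b > threshold_ch2]) / den1 else NA_real_
  m2 <- if (den2 > 0) sum(b[a > threshold_ch1]) / den2 else NA_real_
  structure(list(cell_label = roi$label, m1 = m1, m2 = m2,
                 m1_defined = den1 > 0, m2_defined = den2 > 0,
                 threshold_ch1 = as.numeric(threshold_ch1),
                 threshold_ch2 = as.numeric(threshold_ch2)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  fmt <- function(v, def) if (def) sprintf("%.4f", v) else "undefined"
  cat(sprintf("<coloc_result> cell %d: M1 = %s, M2 = %s\n",
              x$cell_label, fmt(x$m1, x$m1_defined), fmt(x$m2, x$m2_defined)))
  invisible(x)
}

#' Colocalizing area as a percentage of the cell area
#'
#' Area of the intersection of the two (vesicular) masks within the ROI,
#' expressed as a percentage of the total cell area. By convention the two
#' masks are the per-channel vesicular masks from [vesicular_mask()], so
#' this is the vesicular overlap of the two signals per cell.
#'
#' @param mask1,mask2 logical matrices (full field size).
#' @param roi a `cell_roi` with non-empty pixel set.
#' @return percentage in \[0, 100\].
#' @export
coloc_area_percent <- function(mask1, mask2, roi) {
  stopifnot(inherits(roi, "cell_roi"),
            identical(dim(mask1), dim(mask2)))
  if (roi$area_px == 0L) stop("empty ROI", call. = FALSE)
  inter <- sum(mask1[roi$pixels] & mask2[roi$pixels])
  100 * inter / roi$area_px
}
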
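# Confocal quantifications: 3D Manders coefficients, ROI percent-volume
# and mean-intensity.

#' Define an axis-aligned ROI box on a confocal stack
#'
#' ROIs correspond to the zones quantified along a pollen tube: the tip
#' (~5 um wide), the shank just below it (~20 um) and a distal region
#' (~15 um). Ranges are half-open voxel index ranges `[from, to)`,
#' 1-based `from`.
#'
#' @param z,y,x integer length-2 ranges `c(from, to)`.
#' @param label one of `"tip"`, `"shank"`, `"distal"`.
#' @return An `roi_box` object.
#' @export
roi_box <- function(z, y, x, label = c("tip", "shank", "distal")) {
  label <- match.arg(label)
  for (nm in c("z", "y", "x")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 2L || r[2L] <= r[1L] || r[1L] < 1)
      stop_field(nm, "must be a half-open range c(from, to) with to > from >= 1")
  }
  structure(list(z = as.integer(z), y = as.integer(y), x = as.integer(x),
                 label = label), class = "roi_box")
}

#' Convert a physical ROI width (um) to a voxel count
#'
#' Rounds half up, as manual ROI drawing effectively does.
#'
#' @param width_um width in micrometres.
#' @param voxel_size_nm voxel edge along the relevant axis, nm.
#' @return integer voxel count (at least 1).
#' @export
um_to_voxels <- function(width_um, voxel_size_nm) {
  max(1L, as.integer(floor(width_um * 1000 / voxel_size_nm + 0.5)))
}

roi_slice <- function(a, roi) {
  if (is.null(roi)) return(a)
  a[roi$z[1L]:(roi$z[2L] - 1L), roi$y[1L]:(roi$y[2L] - 1L),
    roi$x[1L]:(roi$x[2L] - 1L), drop = FALSE]
}

check_roi_bounds <- function(a, roi) {
  if (is.null(roi)) return(invisible())
  d <- dim(a)
  if (roi$z[2L] - 1L > d[1L] || roi$y[2L] - 1L > d[2L] || roi$x[2L] - 1L > d[3L])
    stop("ROI exceeds stack bounds", call. = FALSE)
  invisible()
}

#' Manders colocalization coefficients M1 and M2
#'
#' `M1` is the fraction of channel-A intensity (restricted to voxels where
#' A exceeds its threshold) lying in voxels where channel B exceeds its
#' threshold; `M2` swaps the roles. With both thresholds 0 this is the
#' plain Manders definition. Sums are restricted to the ROI when given.
#'
#' @param ch_a,ch_b congruent 3D (or 2D) intensity arrays.
#' @param thresh_a,thresh_b channel thresholds, >= 0 (default 0).
#' @param roi optional [roi_box()].
#' @return list with `m1`, `m2` (each in `[0, 1]`, or `NA` with
#'   `undefined = TRUE` when the corresponding denominator is zero).
#' @export
manders_coefficients <- function(ch_a, ch_b, thresh_a = 0, thresh_b = 0,
                                 roi = NULL) {
  if (!identical(dim(ch_a), dim(ch_b)))
    stop("channels must have identical dimensions", call. = FALSE)
  check_scalar(thresh_a, "thresh_a", min = 0)
  check_scalar(thresh_b, "thresh_b", min = 0)
  if (!is.null(roi) && length(dim(ch_a)) == 3L) {
    check_roi_bounds(ch_a, roi)
    ch_a <- roi_slice(ch_a, roi)
    ch_b <- roi_slice(ch_b, roi)
  }
  den1 <- sum(ch_a[ch_a > thresh_a])
  den2 <- sum(ch_b[ch_b > thresh_b])
  num1 <- sum(ch_a[ch_a > thresh_a & ch_b > thresh_b])
  num2 <- sum(ch_b[ch_b > thresh_b & ch_a > thresh_a])
  m1 <- if (den1 > 0) num1 / den1 else NA_real_
  m2 <- if (den2 > 0) num2 / den2 else NA_real_
  res <- list(m1 = m1, m2 = m2, undefined = den1 == 0 || den2 == 0)
  if (res$undefined)
    warning("Manders coefficient undefined: a channel has no ",
            "above-threshold signal", call. = FALSE)
  res
}

#' Percent volume occupied by structures within an ROI
#'
#' The "full object" (whole tube volume) is everything above a permissive
#' low threshold; structures (microtubules) are everything above a
#' structure-specific threshold. Returns 100 x structure voxels / full
#' voxels within the ROI.
#'
#' @param stack 3D intensity array (z, y, x).
#' @param roi optional [roi_box()].
#' @param low_threshold permissive full-object threshold.
#' @param mt_threshold structure threshold, >= `low_threshold`.
#' @return percent in `[0, 100]`, or `NA` (with a warning) if no voxel
#'   exceeds the low threshold.
#' @export
percent_volume <- function(stack, roi = NULL, low_threshold, mt_threshold) {
  check_scalar(low_threshold, "low_threshold")
  check_scalar(mt_threshold, "mt_threshold")
  if (mt_threshold < low_threshold)
    stop_field("mt_threshold", "must be >= low_threshold")
  check_roi_bounds(stack, roi)
  v <- roi_slice(stack, roi)
  full <- sum(v > low_threshold)
  if (full == 0) {
    warning("percent_volume undefined: no voxel above the low threshold",
            call. = FALSE)
    return(NA_real_)
  }
  100 * sum(v > mt_threshold) / full
}

#' Mean intensity over medial planes of an ROI
#'
#' @param stack 3D intensity array (z, y, x).
#' @param roi optional [roi_box()].
#' @param planes z indices (into the full stack) to average; default the
#'   five central planes, the usual medial-section readout.
#' @return arithmetic mean voxel intensity.
#' @export
mean_roi_intensity <- function(stack, roi = NULL, planes = NULL) {
  nz <- dim(stack)[1L]
  if (is.null(planes)) planes <- central_planes(nz, 5L)
  planes <- as.integer(planes)
  if (length(planes) == 0 || any(planes < 1L) || any(planes > nz))
    stop("planes outside stack z range [1, ", nz, "]", call. = FALSE)
  check_roi_bounds(stack, roi)
  v <- roi_slice(stack, roi)
  if (!is.null(roi)) {
    planes_local <- planes - roi$z[1L] + 1L
    planes_local <- planes_local[planes_local >= 1L & planes_local <= dim(v)[1L]]
    if (length(planes_local) == 0)
      stop("no requested plane intersects the ROI", call. = FALSE)
  } else planes_local <- planes
  mean(v[planes_local, , , drop = FALSE])
}

# The n-plane window centered on ceil(nz / 2).
central_planes <- function(nz, n = 5L) {
  mid <- ceiling(nz / 2)
  lo <- mid - (n - 1L) %/% 2L
  planes <- lo:(lo + n - 1L)
  planes[planes >= 1L & planes <= nz]
}
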
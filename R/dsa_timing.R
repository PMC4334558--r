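## DSA timing: mask-frame subtraction, time-to-peak estimation, ROI-based
## cerebral circulation time, and color-coded circulation-time images.
##
## CCT is the difference between the peak-contrast times of the cortical
## parietal veins and the carotid siphon: the arterio-venous transit of the
## bolus through the cerebral circulation.

#' Subtract the pre-contrast mask frame from every frame
#'
#' @param seq `dsa_sequence` with `mask_frame_index` set
#' @return `dsa_sequence` of contrast-only frames; the mask frame itself
#'   becomes all zeros
#' @export
subtracted_contrast <- function(seq) {
  stopifnot_msg(inherits(seq, "dsa_sequence"), "seq must be a dsa_sequence")
  mask <- seq$frames[, , seq$mask_frame_index]
  out <- sweep(seq$frames, c(1, 2), mask, "-")
  s <- dsa_sequence(out, seq$frame_times_s, seq$mask_frame_index)
  s$subtracted <- TRUE
  s
}

#' Time of peak contrast of a time-intensity curve
#'
#' Without interpolation: the time of the maximal sample, first frame on
#' ties (whole-frame reading, the default used by human raters). With
#' interpolation: the vertex of the parabola through the maximum and its two
#' neighbors, clamped to the neighbor interval; a maximum at the first or
#' last sample is returned un-interpolated with `boundary = TRUE`.
#'
#' @param curve numeric vector of contrast samples (>= 3)
#' @param times_s sample times (s), strictly increasing
#' @param interpolate logical; sub-frame parabolic refinement
#' @return peak time in seconds; attribute `boundary` flags a boundary
#'   maximum
#' @examples
#' peak_time(c(0, 1, 3, 9, 3, 1), seq(0, 2.5, by = 0.5))
#' @export
peak_time <- function(curve, times_s, interpolate = FALSE) {
  stopifnot_msg(length(curve) >= 3, "need at least 3 samples")
  stopifnot_msg(length(curve) == length(times_s), "curve/times length mismatch")
  if (max(curve) - min(curve) <= 0) abort("no contrast arrival: curve is constant")
  i <- which.max(curve)  # first maximum on ties
  boundary <- i == 1L || i == length(curve)
  t_hat <- times_s[i]
  if (interpolate && !boundary) {
    ## exact quadratic through (t1,y1), (t2,y2), (t3,y3); vertex closed form
    t1 <- times_s[i - 1]; t2 <- times_s[i]; t3 <- times_s[i + 1]
    y1 <- curve[i - 1]; y2 <- curve[i]; y3 <- curve[i + 1]
    denom <- y1 * (t2 - t3) + y2 * (t3 - t1) + y3 * (t1 - t2)
    if (abs(denom) > 0) {
      vertex <- (y1 * (t2^2 - t3^2) + y2 * (t3^2 - t1^2) + y3 * (t1^2 - t2^2)) /
        (2 * denom)
      t_hat <- min(max(vertex, t1), t3)
    }
  }
  structure(t_hat, boundary = boundary)
}

#' Per-pixel time-to-peak map of a subtracted DSA sequence
#'
#' A pixel is considered enhancing when its curve maximum reaches
#' `arrival_threshold` times the global maximum of the subtracted sequence;
#' other pixels are marked invalid (contrast never arrives there).
#'
#' @param seq `dsa_sequence`; subtracted internally if it still carries the
#'   anatomical baseline
#' @param arrival_threshold fraction of the global maximum a pixel must reach
#'   to be assigned a TTP (default 0.2)
#' @param interpolate sub-frame parabolic refinement per pixel
#' @return list of class `ttp_map`: `ttp_s` (H x W seconds, `NA` where
#'   invalid), `valid` (logical H x W)
#' @export
estimate_ttp_map <- function(seq, arrival_threshold = 0.2, interpolate = FALSE) {
  if (!isTRUE(seq$subtracted)) seq <- subtracted_contrast(seq)
  d <- dim(seq$frames)
  flat <- matrix(seq$frames, nrow = d[1] * d[2], ncol = d[3])
  pixmax <- do.call(pmax, as.data.frame(flat))
  gmax <- max(pixmax)
  if (gmax <= 0) abort("no contrast arrival anywhere in the sequence")
  valid <- pixmax >= arrival_threshold * gmax
  if (!any(valid)) abort("no pixel reaches the arrival threshold")
  ttp <- rep(NA_real_, d[1] * d[2])
  idx <- which(valid)
  if (interpolate) {
    for (p in idx) {
      ttp[p] <- as.numeric(peak_time(flat[p, ], seq$frame_times_s, interpolate = TRUE))
    }
  } else {
    ttp[idx] <- seq$frame_times_s[max.col(flat[idx, , drop = FALSE],
                                          ties.method = "first")]
  }
  structure(list(ttp_s = matrix(ttp, d[1], d[2]),
                 valid = matrix(valid, d[1], d[2]),
                 frame_times_s = seq$frame_times_s),
            class = "ttp_map")
}

#' Cerebral circulation time from siphon and vein ROIs
#'
#' Averages the subtracted signal over each ROI into one time-intensity
#' curve per structure (the noise-robust equivalent of reading "the frame"
#' of maximum opacification), locates each curve's peak, and returns the
#' venous minus the arterial peak time.
#'
#' @param seq `dsa_sequence`
#' @param roi_siphon,roi_vein logical H x W masks (see [roi_mask()])
#' @param interpolate sub-frame parabolic peak refinement (default off:
#'   whole-frame reading)
#' @param side "right" or "left" injection side annotation
#' @param rater_id annotation carried into the result
#' @return list of class `cct_measurement` with `cct_s`, `siphon_peak_s`,
#'   `vein_peak_s`, `side`, `rater_id`, `flags` (character vector, e.g.
#'   "non_physiological_order" when the venous peak precedes the arterial)
#' @export
compute_cct <- function(seq, roi_siphon, roi_vein, interpolate = FALSE,
                        side = "right", rater_id = "r1") {
  stopifnot_msg(inherits(seq, "dsa_sequence"), "seq must be a dsa_sequence")
  d <- dim(seq$frames)
  for (nm in c("roi_siphon", "roi_vein")) {
    m <- get(nm)
    stopifnot_msg(is.matrix(m) && all(dim(m) == d[1:2]),
                  "%s must match the frame grid", nm)
    stopifnot_msg(any(m), "%s is empty", nm)
  }
  if (!isTRUE(seq$subtracted)) seq <- subtracted_contrast(seq)
  flat <- matrix(seq$frames, nrow = d[1] * d[2], ncol = d[3])
  curve_siphon <- colMeans(flat[as.vector(roi_siphon), , drop = FALSE])
  curve_vein <- colMeans(flat[as.vector(roi_vein), , drop = FALSE])
  tp_s <- peak_time(curve_siphon, seq$frame_times_s, interpolate)
  tp_v <- peak_time(curve_vein, seq$frame_times_s, interpolate)
  cct <- as.numeric(tp_v) - as.numeric(tp_s)
  flags <- character()
  if (cct < 0) {
    warning("venous peak precedes arterial peak: non-physiological ordering",
            call. = FALSE)
    flags <- c(flags, "non_physiological_order")
  }
  if (isTRUE(attr(tp_s, "boundary")) || isTRUE(attr(tp_v, "boundary"))) {
    flags <- c(flags, "boundary_peak")
  }
  structure(list(cct_s = cct, siphon_peak_s = as.numeric(tp_s),
                 vein_peak_s = as.numeric(tp_v), side = side,
                 rater_id = rater_id, flags = flags),
            class = "cct_measurement")
}

#' @export
print.cct_measurement <- function(x, ...) {
  cat(sprintf("CCT = %.3f s (siphon peak %.3f s, vein peak %.3f s; side %s, rater %s)\n",
              x$cct_s, x$siphon_peak_s, x$vein_peak_s, x$side, x$rater_id))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Color-code a time-to-peak map
#'
#' Maps TTP monotonically onto a fixed early-to-late hue ramp
#' (red - yellow - green - blue); values outside `[t_min_s, t_max_s]` are
#' clamped, invalid pixels are black. Equal TTP always maps to equal color,
#' so a delayed venous phase shows as veins shifted toward the blue end.
#'
#' @param ttp `ttp_map` from [estimate_ttp_map()]
#' @param t_min_s,t_max_s ramp endpoints in seconds (`t_min_s < t_max_s`)
#' @return H x W x 3 RGB array in `[0, 1]`
#' @export
color_code <- function(ttp, t_min_s = NULL, t_max_s = NULL) {
  stopifnot_msg(inherits(ttp, "ttp_map"), "ttp must be a ttp_map")
  if (is.null(t_min_s)) t_min_s <- min(ttp$frame_times_s)
  if (is.null(t_max_s)) t_max_s <- max(ttp$frame_times_s)
  stopifnot_msg(t_min_s < t_max_s, "t_min_s must be < t_max_s")
  frac <- (ttp$ttp_s - t_min_s) / (t_max_s - t_min_s)
  frac <- pmin(pmax(frac, 0), 1)
  h <- nrow(frac); w <- ncol(frac)
  rgb <- array(0, c(h, w, 3))
  ok <- which(ttp$valid & !is.na(frac))
  if (length(ok)) {
    ## hue 0 (red) -> 2/3 (blue) in HSV: red, yellow, green, blue quartiles
    cols <- grDevices::hsv(h = frac[ok] * 2 / 3, s = 1, v = 1)
    m <- grDevices::col2rgb(cols) / 255
    r <- g <- b <- matrix(0, h, w)
    r[ok] <- m[1, ]; g[ok] <- m[2, ]; b[ok] <- m[3, ]
    rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  }
  rgb
}
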
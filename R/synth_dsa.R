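## Synthetic DSA sequences: a gamma-variate contrast bolus travels through
## four compartments (carotid siphon -> capillary bed -> cortical veins, over
## a static background), sampled at an angiographic frame rate of 2-4 frames/s
## on top of a deterministic anatomical baseline, plus Gaussian noise.

#' Parameters of a gamma-variate contrast bolus
#'
#' The time-intensity curve of a compartment is
#' `A * u^alpha * exp(alpha * (1 - u))` with `u = (t - onset) / peak_delay`,
#' zero before onset. The curve attains its maximum `A` exactly at
#' `t = onset_s + peak_delay_s`, which is what makes ground-truth peak times
#' analytic.
#'
#' @param onset_s bolus arrival time (s), >= 0
#' @param peak_delay_s time from onset to the curve maximum (s), > 0
#' @param amplitude peak contrast (arbitrary units), > 0 (0 allowed for a
#'   compartment with no enhancement)
#' @param shape_alpha dimensionless gamma-variate exponent, > 0; larger
#'   values give a sharper bolus
#' @return list of class `bolus_params`
#' @export
bolus_params <- function(onset_s, peak_delay_s, amplitude, shape_alpha = 3) {
  stopifnot_msg(onset_s >= 0, "onset_s must be >= 0")
  stopifnot_msg(peak_delay_s > 0, "peak_delay_s must be > 0")
  stopifnot_msg(amplitude >= 0, "amplitude must be >= 0")
  stopifnot_msg(shape_alpha > 0, "shape_alpha must be > 0")
  structure(list(onset_s = onset_s, peak_delay_s = peak_delay_s,
                 amplitude = amplitude, shape_alpha = shape_alpha),
            class = "bolus_params")
}

#' Evaluate a gamma-variate bolus curve
#' @param t times (s)
#' @param bolus `bolus_params`
#' @return contrast at `t`
#' @export
gamma_variate <- function(t, bolus) {
  u <- (t - bolus$onset_s) / bolus$peak_delay_s
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- bolus$amplitude * u[pos]^bolus$shape_alpha *
    exp(bolus$shape_alpha * (1 - u[pos]))
  out
}

## Compartment geometry on an H x W grid (rows = image rows, top = row 1):
## cortical parietal veins run as a band near the vertex, the siphon is a
## small focus at the skull base, the capillary blush fills the hemisphere.
dsa_region_masks <- function(dim = c(64, 64)) {
  h <- dim[1]; w <- dim[2]
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  siphon <- (row - round(0.72 * h))^2 + (col - round(0.32 * w))^2 <= (0.05 * h)^2
  vein <- row >= round(0.08 * h) & row <= round(0.16 * h) &
    col >= round(0.25 * w) & col <= round(0.75 * w)
  capillary <- ((row - 0.45 * h) / (0.28 * h))^2 +
    ((col - 0.5 * w) / (0.32 * w))^2 <= 1
  capillary <- capillary & !vein & !siphon
  list(siphon = siphon, capillary = capillary, vein = vein,
       background = !(siphon | vein | capillary))
}

#' Create an ROI mask
#' @param mask logical H x W matrix with at least one `TRUE` pixel
#' @param label one of "siphon", "cortical_parietal_vein", "other"
#' @return logical matrix of class `roi_mask`
#' @export
roi_mask <- function(mask, label = c("other", "siphon", "cortical_parietal_vein")) {
  label <- match.arg(label)
  stopifnot_msg(is.matrix(mask) && is.logical(mask), "mask must be a logical matrix")
  stopifnot_msg(any(mask), "ROI mask must contain at least one pixel")
  structure(mask, label = label, class = c("roi_mask", "matrix", "array"))
}

#' Construct a DSA frame sequence object
#' @param frames H x W x T numeric array of frames
#' @param frame_times_s strictly increasing acquisition times (s), length T
#' @param mask_frame_index index of the pre-contrast mask frame
#' @return list of class `dsa_sequence`
#' @export
dsa_sequence <- function(frames, frame_times_s, mask_frame_index = 1L) {
  stopifnot_msg(is.array(frames) && length(dim(frames)) == 3,
                "frames must be an H x W x T array")
  nt <- dim(frames)[3]
  stopifnot_msg(nt >= 3, "a DSA sequence needs at least 3 frames")
  stopifnot_msg(length(frame_times_s) == nt, "frame_times_s length mismatch")
  stopifnot_msg(all(diff(frame_times_s) > 0), "frame_times_s must be strictly increasing")
  stopifnot_msg(mask_frame_index >= 1 && mask_frame_index <= nt,
                "mask_frame_index out of range")
  structure(list(frames = frames, frame_times_s = as.numeric(frame_times_s),
                 mask_frame_index = as.integer(mask_frame_index)),
            class = "dsa_sequence")
}

#' Bolus presets for the two study groups
#'
#' The "ms" preset has a venous peak delayed to yield a true CCT of 4.9 s
#' (siphon peak 0.5 s, vein peak 5.4 s); the "control" preset yields 2.8 s.
#' These match the group mean circulation times the pipeline is designed to
#' reproduce.
#'
#' @param group "ms" or "control"
#' @return named list of `bolus_params` for compartments siphon, capillary,
#'   vein, background
#' @export
dsa_preset <- function(group = c("ms", "control")) {
  group <- match.arg(group)
  vein_peak <- if (group == "ms") 5.4 else 3.3
  list(
    siphon = bolus_params(onset_s = 0.2, peak_delay_s = 0.3, amplitude = 80,
                          shape_alpha = 4),
    capillary = bolus_params(onset_s = 0.5,
                             peak_delay_s = 0.55 * (vein_peak - 0.5),
                             amplitude = 30, shape_alpha = 2.5),
    vein = bolus_params(onset_s = vein_peak * 0.35,
                        peak_delay_s = vein_peak * 0.65, amplitude = 60,
                        shape_alpha = 3),
    background = bolus_params(onset_s = 0.1, peak_delay_s = 1, amplitude = 0)
  )
}

#' Generate a synthetic DSA sequence with known ground truth
#'
#' Each pixel follows the gamma-variate curve of its compartment (siphon,
#' capillary bed, cortical veins, background) on top of a fixed anatomical
#' baseline, with additive Gaussian noise. The returned ground truth records
#' the analytic peak times, so downstream CCT estimates can be validated to
#' sub-frame accuracy.
#'
#' @param bolus named list of `bolus_params` for `siphon`, `capillary`,
#'   `vein` and optionally `background`; see [dsa_preset()]
#' @param frame_rate_hz frames per second, within `[2, 4]`
#' @param duration_s acquisition duration (s); must cover every compartment's
#'   peak time
#' @param noise_sd Gaussian noise SD (contrast units)
#' @param seed integer RNG seed; equal seeds give bit-identical sequences
#' @param dim image grid `c(H, W)`
#' @return list with elements `seq` (`dsa_sequence`) and `truth` (list with
#'   `cct_true_s`, `siphon_peak_s`, `vein_peak_s`, `roi_siphon`, `roi_vein`)
#' @examples
#' g <- gen_dsa_sequence(dsa_preset("control"), frame_rate_hz = 4,
#'                       duration_s = 8, noise_sd = 0, seed = 1)
#' g$truth$cct_true_s
#' @export
gen_dsa_sequence <- function(bolus = dsa_preset("ms"), frame_rate_hz = 4,
                             duration_s = 8, noise_sd = 2, seed = 1,
                             dim = c(64, 64)) {
  stopifnot_msg(frame_rate_hz >= 2 && frame_rate_hz <= 4,
                "frame_rate_hz must lie in [2, 4]")
  for (r in c("siphon", "capillary", "vein")) {
    b <- bolus[[r]]
    stopifnot_msg(!is.null(b), "missing bolus parameters for region '%s'", r)
    peak <- b$onset_s + b$peak_delay_s
    if (peak > duration_s) {
      abort("peak of region '%s' at %.2f s falls outside the %.2f s acquisition window",
            r, peak, duration_s)
    }
  }
  if (is.null(bolus$background)) {
    bolus$background <- bolus_params(0.1, 1, 0)
  }
  masks <- dsa_region_masks(dim)
  h <- dim[1]; w <- dim[2]
  times <- seq(0, duration_s, by = 1 / frame_rate_hz)
  nt <- length(times)
  ## deterministic anatomical baseline (removed again by mask subtraction)
  row <- matrix(seq_len(h), h, w); col <- matrix(seq_len(w), h, w, byrow = TRUE)
  baseline <- 100 + 15 * sin(row / h * pi) * sin(col / w * pi)
  frames <- array(0, c(h, w, nt))
  region_curves <- lapply(masks, function(m) NULL)
  for (r in names(masks)) {
    region_curves[[r]] <- gamma_variate(times, bolus[[r]])
  }
  for (ti in seq_len(nt)) {
    f <- baseline
    for (r in names(masks)) {
      f <- f + masks[[r]] * region_curves[[r]][ti]
    }
    frames[, , ti] <- f
  }
  if (noise_sd > 0) {
    frames <- frames + with_seed(seed, array(rnorm(length(frames), 0, noise_sd),
                                             dim(frames)))
  }
  siphon_peak <- bolus$siphon$onset_s + bolus$siphon$peak_delay_s
  vein_peak <- bolus$vein$onset_s + bolus$vein$peak_delay_s
  truth <- list(
    cct_true_s = vein_peak - siphon_peak,
    siphon_peak_s = siphon_peak,
    vein_peak_s = vein_peak,
    roi_siphon = roi_mask(masks$siphon, "siphon"),
    roi_vein = roi_mask(masks$vein, "cortical_parietal_vein")
  )
  list(seq = dsa_sequence(frames, times, 1L), truth = truth)
}

#' Write a DSA sequence as a directory of plain PGM frames plus JSON sidecar
#'
#' @param seq `dsa_sequence`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dsa_sequence <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- dim(seq$frames)[3]
  rng <- range(seq$frames)
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
  files <- sprintf("frame_%03d.pgm", seq_len(nt))
  for (ti in seq_len(nt)) {
    write_pgm(seq$frames[, , ti], file.path(dir, files[ti]), range = rng)
  }
  sidecar <- list(
    frame_rate_hz = 1 / mean(diff(seq$frame_times_s)),
    frame_times_s = seq$frame_times_s,
    mask_frame_index = seq$mask_frame_index,
    intensity_range = rng,
    frames = files
  )
  jsonlite::write_json(sidecar, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a DSA sequence written by [write_dsa_sequence()]
#' @param dir directory containing PGM frames and `sequence.json`
#' @return `dsa_sequence`
#' @export
read_dsa_sequence <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sequence.json"), simplifyVector = TRUE)
  mats <- lapply(side$frames, function(f) {
    read_pgm(file.path(dir, f), range = side$intensity_range)
  })
  frames <- array(0, c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  for (ti in seq_along(mats)) frames[, , ti] <- mats[[ti]]
  dsa_sequence(frames, side$frame_times_s, side$mask_frame_index %||% 1L)
}
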
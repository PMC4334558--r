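## Synthetic T1/FLAIR head phantoms with known ground truth.
##
## Anatomy is analytic: a brain ellipsoid with a cortical gray-matter shell,
## a deep white-matter core, lateral ventricles, deep gray nuclei (thalamus,
## caudate, putamen), cerebellum and brainstem, wrapped in a CSF rim and a
## skull shell. Because every membership function is evaluated directly at
## voxel-center world coordinates, any grid (T1, FLAIR, template) samples
## the same underlying anatomy and ground truth is exact.
##
## Geometry is full head scale by default: the deep white matter compartment
## holds roughly 310 ml, so the default lesion load (15.3 ml, the reported
## mean of the modeled study) sits at about 5% of the retained white matter
## - exactly the operating point of 95th-percentile lesion thresholding.

TISSUE_CODES <- c(background = 0L, skull = 1L, csf = 2L, gm = 3L, wm = 4L)
STRUCTURE_CODES <- c(none = 0L, cerebellum = 1L, brainstem = 2L,
                     thalamus = 3L, caudate = 4L, putamen = 5L)

## shape table at scale 1 (mm); l/r pairs mirrored in x
phantom_shapes <- function() {
  list(
    brain     = list(center = c(0, 0, 0),      semi = c(65, 80, 60)),
    vent_r    = list(center = c(10, -15, 8),   semi = c(6, 20, 8)),
    vent_l    = list(center = c(-10, -15, 8),  semi = c(6, 20, 8)),
    thal_r    = list(center = c(14, -24, 0),   semi = c(9, 11, 8)),
    thal_l    = list(center = c(-14, -24, 0),  semi = c(9, 11, 8)),
    caud_r    = list(center = c(14, 2, 12),    semi = c(6, 13, 7)),
    caud_l    = list(center = c(-14, 2, 12),   semi = c(6, 13, 7)),
    put_r     = list(center = c(25, 0, 0),     semi = c(8, 13, 9)),
    put_l     = list(center = c(-25, 0, 0),    semi = c(8, 13, 9)),
    cerebellum = list(center = c(0, -52, -38), semi = c(42, 32, 26)),
    brainstem = list(center = c(0, -20, -45),  semi = c(11, 13, 28))
  )
}

in_ellipsoid <- function(pts, center, semi) {
  ((pts[1, ] - center[1]) / semi[1])^2 +
  ((pts[2, ] - center[2]) / semi[2])^2 +
  ((pts[3, ] - center[3]) / semi[3])^2 <= 1
}

## ellipsoidal radial coordinate of the brain ellipsoid
brain_rho <- function(pts, scale) {
  s <- phantom_shapes()$brain$semi * scale
  sqrt((pts[1, ] / s[1])^2 + (pts[2, ] / s[2])^2 + (pts[3, ] / s[3])^2)
}

## radii (in rho units) of the tissue shells
PHANTOM_R_WM <- 0.646    # white-matter core; ~352 ml raw at scale 1
PHANTOM_R_BRAIN <- 0.965 # brain surface (inside the CSF rim)
PHANTOM_R_SKULL_IN <- 1.0
PHANTOM_R_SKULL_OUT <- 1.10

#' Evaluate phantom anatomy at world coordinates
#'
#' @param pts 3 x N matrix of points (mm) in the phantom's template frame
#' @param scale global head scale factor (1 = adult head)
#' @param dilate factor applied to the named-structure shapes (used when
#'   building atlas exclusion masks)
#' @return list with integer vectors `tissue` (0 background, 1 skull, 2 CSF,
#'   3 GM, 4 WM) and `structure` (0 none, 1 cerebellum, 2 brainstem,
#'   3 thalamus, 4 caudate, 5 putamen), and numeric `rho` (ellipsoidal
#'   radius, 1 = inner skull surface)
#' @export
phantom_eval <- function(pts, scale = 1, dilate = 1) {
  sh <- phantom_shapes()
  rho <- brain_rho(pts, scale)
  n <- length(rho)
  tissue <- integer(n)
  structure_id <- integer(n)

  tissue[rho <= PHANTOM_R_SKULL_OUT & rho > PHANTOM_R_SKULL_IN] <- TISSUE_CODES[["skull"]]
  tissue[rho <= PHANTOM_R_SKULL_IN & rho > PHANTOM_R_BRAIN] <- TISSUE_CODES[["csf"]]
  core_idx <- which(rho <= PHANTOM_R_BRAIN)
  tissue[core_idx] <- ifelse(rho[core_idx] > PHANTOM_R_WM,
                             TISSUE_CODES[["gm"]], TISSUE_CODES[["wm"]])

  ## structure shapes only matter inside the brain: evaluate on that subset
  sub <- pts[, core_idx, drop = FALSE]
  t_sub <- tissue[core_idx]
  s_sub <- integer(length(core_idx))
  memb <- function(name, d = 1) {
    s <- sh[[name]]
    in_ellipsoid(sub, s$center * scale, s$semi * scale * d)
  }
  dilated <- function(m_plain, name) {
    if (dilate == 1) m_plain else memb(name, dilate)
  }

  cereb <- memb("cerebellum")
  t_sub[cereb] <- TISSUE_CODES[["gm"]]
  t_sub[memb("cerebellum", 0.65)] <- TISSUE_CODES[["wm"]]
  s_sub[dilated(cereb, "cerebellum")] <- STRUCTURE_CODES[["cerebellum"]]

  stem <- memb("brainstem")
  t_sub[stem] <- TISSUE_CODES[["wm"]]
  s_sub[dilated(stem, "brainstem")] <- STRUCTURE_CODES[["brainstem"]]

  for (pair in list(c("thal_r", "thal_l", "thalamus"),
                    c("caud_r", "caud_l", "caudate"),
                    c("put_r", "put_l", "putamen"))) {
    m1 <- memb(pair[1]); m2 <- memb(pair[2])
    t_sub[m1 | m2] <- TISSUE_CODES[["gm"]]
    s_sub[dilated(m1, pair[1]) | dilated(m2, pair[2])] <- STRUCTURE_CODES[[pair[3]]]
  }

  t_sub[memb("vent_r") | memb("vent_l")] <- TISSUE_CODES[["csf"]]

  tissue[core_idx] <- t_sub
  structure_id[core_idx] <- s_sub
  list(tissue = tissue, structure = structure_id, rho = rho)
}

## deterministic intra-tissue texture, a function of anatomy coordinates:
## real parenchyma is not flat, and a smooth featureless phantom leaves
## intensity-based rotation estimation ill-posed (MI is flat within ~1 deg)
phantom_texture <- function(pts, scale) {
  (sin(2 * pi * pts[1, ] / (17 * scale)) +
   sin(2 * pi * pts[2, ] / (19 * scale)) +
   sin(2 * pi * pts[3, ] / (23 * scale))) / sqrt(3)
}

phantom_intensity <- function(tissue, means, skull_value) {
  out <- numeric(length(tissue))
  out[tissue == TISSUE_CODES[["skull"]]] <- skull_value
  out[tissue == TISSUE_CODES[["csf"]]] <- means[["csf"]]
  out[tissue == TISSUE_CODES[["gm"]]] <- means[["gm"]]
  out[tissue == TISSUE_CODES[["wm"]]] <- means[["wm"]]
  out
}

auto_grid <- function(voxel_mm, scale, margin = 1.14) {
  semi <- phantom_shapes()$brain$semi * scale * PHANTOM_R_SKULL_OUT * margin
  as.integer(2 * ceiling(semi / voxel_mm) + 1)
}

#' Phantom generation parameters
#'
#' Defaults use the acquisition geometry the package models: FLAIR voxels of
#' 1 x 0.9 x 5 mm and near-isotropic T1 voxels of 1.3 x 1.3 x 1.2 mm, at
#' full head scale, with a total planted lesion load of 15.3 ml spread over
#' `lesion_count` foci. `applied_rigid` displaces the FLAIR anatomy relative
#' to its stored affine (simulated T1/FLAIR mis-registration);
#' `applied_affine` warps the subject's anatomy relative to the template
#' (simulated inter-subject variability).
#'
#' @param t1_voxel_mm,flair_voxel_mm voxel sizes (mm)
#' @param t1_grid,flair_grid grid shapes; `NULL` = smallest grid covering
#'   the head
#' @param head_scale global anatomy scale (1 = adult head; smaller values
#'   give fast test phantoms)
#' @param tissue_means list with `t1` and `flair` named vectors
#'   (`csf`, `gm`, `wm`) of mean intensities
#' @param skull_value length-2 skull intensity `c(t1, flair)`
#' @param noise_sd Gaussian noise SD added to both modalities
#' @param texture_amp amplitude of the deterministic intra-parenchyma
#'   texture (intensity units); rides on the anatomy in both modalities,
#'   giving intensity-based registration realistic structure to lock onto
#' @param lesion_count number of lesion foci
#' @param lesion_total_ml total lesion volume (ml) across foci
#' @param lesion_contrast FLAIR intensity added to lesion voxels over the WM
#'   mean (must stay positive so lesions are hyperintense)
#' @param applied_rigid length-6 rigid parameters (deg, mm) mis-registering
#'   the FLAIR; see [rigid_matrix()]
#' @param applied_affine 4x4 template-to-subject affine (default identity)
#' @return list of class `phantom_params`
#' @export
phantom_params <- function(t1_voxel_mm = c(1.3, 1.3, 1.2),
                           flair_voxel_mm = c(1, 0.9, 5),
                           t1_grid = NULL, flair_grid = NULL,
                           head_scale = 1,
                           tissue_means = list(
                             t1 = c(csf = 30, gm = 60, wm = 90),
                             flair = c(csf = 15, gm = 70, wm = 60)),
                           skull_value = c(25, 20),
                           noise_sd = 3,
                           texture_amp = 5,
                           lesion_count = 8,
                           lesion_total_ml = 15.3,
                           lesion_contrast = 50,
                           applied_rigid = c(1.5, -1, 2, 3, -2, 1),
                           applied_affine = diag(4)) {
  stopifnot_msg(all(t1_voxel_mm > 0) && all(flair_voxel_mm > 0),
                "voxel sizes must be positive")
  stopifnot_msg(lesion_total_ml >= 0, "lesion_total_ml must be >= 0")
  stopifnot_msg(lesion_contrast > 0, "lesion_contrast must be > 0 (FLAIR lesions are hyperintense)")
  stopifnot_msg(length(applied_rigid) == 6, "applied_rigid needs 6 parameters")
  if (is.null(t1_grid)) t1_grid <- auto_grid(t1_voxel_mm, head_scale)
  if (is.null(flair_grid)) flair_grid <- auto_grid(flair_voxel_mm, head_scale)
  structure(as.list(environment()), class = "phantom_params")
}

#' The canonical template phantom (noise-free T1)
#'
#' The package's stand-in for a population template: the phantom anatomy at
#' its canonical pose, rendered noise-free on an isotropic grid. Used as the
#' fixed image for affine spatial normalization.
#'
#' @param head_scale anatomy scale (must match the subjects')
#' @param voxel_mm template grid resolution (default 2 mm isotropic)
#' @return `volume3d`
#' @export
canonical_template <- function(head_scale = 1, voxel_mm = c(2, 2, 2)) {
  grid <- auto_grid(voxel_mm, head_scale)
  A <- centered_affine(grid, voxel_mm)
  vol <- volume3d(array(0, grid), affine = A)
  pts <- vox_world_coords(vol)
  ev <- phantom_eval(pts, scale = head_scale)
  t1m <- c(csf = 30, gm = 60, wm = 90)
  intens <- phantom_intensity(ev$tissue, as.list(t1m), 25)
  paren <- ev$tissue %in% TISSUE_CODES[c("gm", "wm")]
  intens[paren] <- intens[paren] + 5 * phantom_texture(pts, head_scale)[paren]
  vol$voxels <- array(intens, grid)
  vol
}

#' Template-space atlas exclusion masks
#'
#' Geometric stand-ins for the atlas structures excluded before lesion
#' thresholding: cerebellum, brainstem, thalamus, caudate and putamen. Each
#' mask is the structure's shape dilated by `roi_dilate` so that small
#' registration errors cannot leak structure voxels into the retained white
#' matter.
#'
#' @param head_scale anatomy scale
#' @param voxel_mm template grid resolution
#' @param roi_dilate dilation factor applied to each structure shape
#' @return named list of binary `volume3d` masks in template space
#' @export
atlas_rois <- function(head_scale = 1, voxel_mm = c(2, 2, 2), roi_dilate = 1.15) {
  grid <- auto_grid(voxel_mm, head_scale)
  A <- centered_affine(grid, voxel_mm)
  ref <- volume3d(array(0, grid), affine = A)
  pts <- vox_world_coords(ref)
  ev <- phantom_eval(pts, scale = head_scale, dilate = roi_dilate)
  out <- list()
  for (nm in c("cerebellum", "brainstem", "thalamus", "caudate", "putamen")) {
    code <- STRUCTURE_CODES[[nm]]
    out[[nm]] <- volume3d(array(as.double(ev$structure == code), grid), affine = A)
  }
  out
}

#' Generate a synthetic T1/FLAIR subject with ground truth
#'
#' Renders the phantom anatomy (optionally warped by `applied_affine`) on
#' the T1 grid, and on the FLAIR grid displaced by `applied_rigid` (so the
#' FLAIR header affine no longer matches the anatomy - the mis-registration
#' a coregistration step must recover). Plants `lesion_count` hyperintense
#' lesion foci in the deep cerebral white matter by growing each focus
#' voxel-wise around a seed (nearest eligible voxels first, ties by
#' distance) until the total target volume is met; the realized truth volume
#' matches `lesion_total_ml` within one voxel volume.
#'
#' @param params `phantom_params`
#' @param seed integer RNG seed (noise and lesion placement)
#' @return list of class `mri_subject`: `t1`, `flair` (`volume3d`),
#'   `truth` (tissue code volume, crisp probability maps, brain mask, lesion
#'   mask on the FLAIR grid, lesion volume), `applied_rigid`,
#'   `applied_affine`, `params`
#' @export
gen_mri_subject <- function(params = phantom_params(), seed = 1L) {
  stopifnot_msg(inherits(params, "phantom_params"), "params must be phantom_params")
  p <- params
  A_t1 <- centered_affine(p$t1_grid, p$t1_voxel_mm)
  A_fl <- centered_affine(p$flair_grid, p$flair_voxel_mm)
  R <- rigid_matrix(p$applied_rigid)
  Ainv <- solve(p$applied_affine)

  ## --- T1: anatomy at template coords of each voxel center
  t1_ref <- volume3d(array(0, p$t1_grid), affine = A_t1)
  pts_t1 <- apply_affine_pts(Ainv, vox_world_coords(t1_ref))
  ev_t1 <- phantom_eval(pts_t1, scale = p$head_scale)
  stopifnot_msg(any(ev_t1$tissue > 0), "grid does not contain the head")
  t1_int <- phantom_intensity(ev_t1$tissue, as.list(p$tissue_means$t1),
                              p$skull_value[1])
  if (p$texture_amp > 0) {
    paren <- ev_t1$tissue %in% TISSUE_CODES[c("gm", "wm")]
    t1_int[paren] <- t1_int[paren] +
      p$texture_amp * phantom_texture(pts_t1, p$head_scale)[paren]
  }

  ## --- FLAIR: header world -> rigidly displaced anatomy world -> template
  fl_ref <- volume3d(array(0, p$flair_grid), affine = A_fl)
  pts_fl_anat <- apply_affine_pts(R, vox_world_coords(fl_ref))
  pts_fl <- apply_affine_pts(Ainv, pts_fl_anat)
  ev_fl <- phantom_eval(pts_fl, scale = p$head_scale)
  fl_int <- phantom_intensity(ev_fl$tissue, as.list(p$tissue_means$flair),
                              p$skull_value[2])
  if (p$texture_amp > 0) {
    paren <- ev_fl$tissue %in% TISSUE_CODES[c("gm", "wm")]
    fl_int[paren] <- fl_int[paren] +
      p$texture_amp * phantom_texture(pts_fl, p$head_scale)[paren]
  }

  ## --- lesions on the FLAIR grid, inside deep cerebral WM
  vox_ml <- prod(p$flair_voxel_mm) / 1000
  lesion_vec <- logical(length(fl_int))
  if (p$lesion_total_ml > 0 && p$lesion_count > 0) {
    cand <- which(ev_fl$tissue == TISSUE_CODES[["wm"]] &
                    ev_fl$structure == 0L & ev_fl$rho <= 0.60)
    ## keep a safety margin from the excluded structures (dilate 1.35)
    sh <- phantom_shapes()
    near_struct <- rep(FALSE, length(cand))
    sub <- pts_fl[, cand, drop = FALSE]
    for (nm in c("vent_r", "vent_l", "thal_r", "thal_l", "caud_r", "caud_l",
                 "put_r", "put_l", "cerebellum", "brainstem")) {
      near_struct <- near_struct |
        in_ellipsoid(sub, sh[[nm]]$center * p$head_scale,
                     sh[[nm]]$semi * p$head_scale * 1.35)
    }
    eligible <- cand[!near_struct]
    n_target <- round(p$lesion_total_ml / vox_ml)
    if (n_target > length(eligible)) {
      abort("lesion_total_ml = %.1f ml exceeds the available white-matter volume (%.1f ml)",
            p$lesion_total_ml, length(eligible) * vox_ml)
    }
    seeds <- with_seed(child_seed(seed, 2L),
                       sample(eligible, p$lesion_count))
    share <- rep(n_target %/% p$lesion_count, p$lesion_count)
    if (n_target %% p$lesion_count > 0) {
      share[seq_len(n_target %% p$lesion_count)] <-
        share[seq_len(n_target %% p$lesion_count)] + 1
    }
    used <- logical(length(eligible))
    el_pts <- pts_fl_anat[, eligible, drop = FALSE]
    ## anisotropic voxels: grow in mm, but compress z so foci span few slices
    for (si in seq_len(p$lesion_count)) {
      if (share[si] == 0) next
      ctr <- pts_fl_anat[, seeds[si]]
      d2 <- (el_pts[1, ] - ctr[1])^2 + (el_pts[2, ] - ctr[2])^2 +
        ((el_pts[3, ] - ctr[3]) * 1.6)^2
      d2[used] <- Inf
      take <- order(d2, seq_along(d2))[seq_len(min(share[si], sum(!used)))]
      used[take] <- TRUE
    }
    lesion_vec[eligible[used]] <- TRUE
    fl_int[lesion_vec] <- p$tissue_means$flair[["wm"]] + p$lesion_contrast
  }

  ## --- noise
  if (p$noise_sd > 0) {
    t1_int <- t1_int + with_seed(child_seed(seed, 3L),
                                 stats::rnorm(length(t1_int), 0, p$noise_sd))
    fl_int <- fl_int + with_seed(child_seed(seed, 4L),
                                 stats::rnorm(length(fl_int), 0, p$noise_sd))
  }

  tissue_arr <- array(ev_t1$tissue, p$t1_grid)
  mk_prob <- function(code) {
    volume3d(array(as.double(ev_t1$tissue == code), p$t1_grid), affine = A_t1)
  }
  brain_mask <- ev_t1$tissue %in% TISSUE_CODES[c("gm", "wm")] |
    (ev_t1$tissue == TISSUE_CODES[["csf"]] & ev_t1$rho <= PHANTOM_R_BRAIN)

  structure(list(
    t1 = volume3d(array(t1_int, p$t1_grid), affine = A_t1),
    flair = volume3d(array(fl_int, p$flair_grid), affine = A_fl),
    truth = list(
      tissue = volume3d(tissue_arr * 1.0, affine = A_t1),
      prob_csf = mk_prob(TISSUE_CODES[["csf"]]),
      prob_gm = mk_prob(TISSUE_CODES[["gm"]]),
      prob_wm = mk_prob(TISSUE_CODES[["wm"]]),
      brain_mask = volume3d(array(as.double(brain_mask), p$t1_grid), affine = A_t1),
      lesion_mask = volume3d(array(as.double(lesion_vec), p$flair_grid), affine = A_fl),
      lesion_volume_ml = sum(lesion_vec) * vox_ml
    ),
    applied_rigid = p$applied_rigid,
    applied_affine = p$applied_affine,
    params = p
  ), class = "mri_subject")
}
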
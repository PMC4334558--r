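## Native-space FLAIR lesion segmentation: mask the FLAIR to the white
## matter, exclude atlas structures mapped from template space, threshold at
## a percentile of the retained intensities, and quantify in ml. The FLAIR
## itself is never resampled - all maps are pulled onto its grid.

#' White-matter-masked FLAIR with atlas structures excluded
#'
#' Resamples the WM posterior onto the FLAIR grid through the rigid
#' coregistration (trilinear, binarized at `wm_prob_cut`), pulls the
#' template-space atlas masks into FLAIR native space through the inverse
#' affine and the rigid (nearest-neighbor), and retains FLAIR voxels inside
#' the WM but outside every atlas structure.
#'
#' @param flair `volume3d` in native space
#' @param tissues `tissue_maps` on the T1 grid
#' @param rigid `rigid_transform` mapping FLAIR world to T1 world (from
#'   `register_rigid(moving = t1, fixed = flair)`)
#' @param atlas named list of template-space binary `volume3d` masks
#'   ([atlas_rois()]); may be empty
#' @param affine affine normalization result ([register_affine_to_template()]);
#'   its `forward` maps T1 world to template world. May be `NULL` when
#'   `atlas` is empty.
#' @param wm_prob_cut WM posterior threshold for the binarized mask
#' @return list of class `wm_flair`: `flair` (input volume), `retained`
#'   (logical array on the FLAIR grid), `values` (retained intensities),
#'   `inbrain_values` (intensities of all in-brain FLAIR voxels, for the
#'   whole-brain percentile variant), `masked` (`volume3d`, FLAIR inside the
#'   retained region, `NA` elsewhere)
#' @export
prepare_wm_flair <- function(flair, tissues, rigid, atlas = list(),
                             affine = NULL, wm_prob_cut = 0.5) {
  stopifnot_msg(inherits(flair, "volume3d"), "flair must be a volume3d")
  stopifnot_msg(inherits(tissues, "tissue_maps"), "tissues must be tissue_maps")
  d <- dim(flair$voxels)
  fl_ref <- volume3d(array(0, d), affine = flair$affine)
  w_fl <- vox_world_coords(fl_ref)
  w_t1 <- apply_affine_pts(rigid, w_fl)
  t1_inv <- solve(tissues$prob_wm$affine)
  pv_t1 <- apply_affine_pts(t1_inv, w_t1)
  wm <- trilinear_sample(tissues$prob_wm, pv_t1, outside = 0)
  brain <- trilinear_sample(tissues$brain_mask, pv_t1, outside = 0)
  wm_bin <- wm >= wm_prob_cut

  excluded <- rep(FALSE, length(wm))
  if (length(atlas)) {
    stopifnot_msg(inherits(affine, "affine_result"),
                  "affine normalization result required to map atlas masks")
    w_tmpl <- apply_affine_pts(affine$forward, w_t1)
    for (m in atlas) {
      pv <- apply_affine_pts(solve(m$affine), w_tmpl)
      excluded <- excluded | (nearest_sample(m, pv, outside = 0) > 0)
    }
  }
  retained <- wm_bin & !excluded
  if (!any(retained)) abort("no white-matter voxels retained after masking")

  vals <- as.vector(flair$voxels)
  masked <- array(NA_real_, d)
  masked[retained] <- vals[retained]
  structure(list(
    flair = flair,
    retained = array(retained, d),
    values = vals[retained],
    inbrain_values = vals[brain >= 0.5],
    masked = volume3d(array(ifelse(is.na(masked), 0, masked), d),
                      affine = flair$affine),
    na_masked = masked
  ), class = "wm_flair")
}

#' Segment lesions by percentile thresholding
#'
#' The threshold is the given percentile (linear-interpolation definition)
#' of the FLAIR intensities over the chosen support; lesion voxels are the
#' retained voxels strictly above it. With all-distinct retained values and
#' the default support, exactly `(100 - percentile)%` of the retained voxels
#' are flagged - percentile thresholding measures a fixed intensity-rank
#' fraction, which is why its estimates are accurate only when the true
#' lesion load is near that fraction of the retained white matter.
#'
#' @param wm_flair `wm_flair` from [prepare_wm_flair()]
#' @param percentile percentile of the support distribution (default 95)
#' @param support "retained" (WM-only, ROI-excluded; the default) or
#'   "brain" (all in-brain FLAIR voxels) - the two readings of
#'   "percentile of the FLAIR image"
#' @return list of class `lesion_result`: `mask` (`volume3d` 0/1 on the
#'   FLAIR grid), `volume_ml`, `threshold_value`, `percentile`, `support`,
#'   `n_retained`, `n_flagged`
#' @export
segment_lesions <- function(wm_flair, percentile = 95,
                            support = c("retained", "brain")) {
  support <- match.arg(support)
  stopifnot_msg(inherits(wm_flair, "wm_flair"), "wm_flair must come from prepare_wm_flair")
  vals <- wm_flair$values
  stopifnot_msg(length(vals) >= 20,
                "need at least 20 retained voxels for a meaningful percentile")
  sup_vals <- if (support == "retained") vals else wm_flair$inbrain_values
  threshold <- stats::quantile(sup_vals, percentile / 100, type = 7, names = FALSE)
  flag_vec <- wm_flair$retained & (wm_flair$flair$voxels > threshold)
  if (!any(flag_vec) && max(vals) == min(vals)) {
    warning("constant retained image: no voxel exceeds the percentile threshold",
            call. = FALSE)
  }
  d <- dim(wm_flair$flair$voxels)
  mask <- volume3d(array(as.double(flag_vec), d), affine = wm_flair$flair$affine)
  structure(list(
    mask = mask,
    volume_ml = lesion_volume_ml(mask),
    threshold_value = threshold,
    percentile = percentile,
    support = support,
    n_retained = length(vals),
    n_flagged = sum(flag_vec)
  ), class = "lesion_result")
}

#' Lesion volume in ml
#' @param mask `volume3d` binary mask, or a logical/0-1 array
#' @param voxel_mm voxel size (mm); taken from the volume when omitted
#' @return volume in ml (`count * voxel volume / 1000`)
#' @export
lesion_volume_ml <- function(mask, voxel_mm = NULL) {
  if (inherits(mask, "volume3d")) {
    if (is.null(voxel_mm)) voxel_mm <- mask$voxel_mm
    mask <- mask$voxels
  }
  stopifnot_msg(!is.null(voxel_mm) && all(voxel_mm > 0), "voxel_mm must be positive")
  sum(mask != 0) * prod(voxel_mm) / 1000
}

#' Run the full native-space lesion pipeline on one subject
#'
#' Chains brain extraction, tissue segmentation, rigid T1-to-FLAIR
#' coregistration, affine normalization to the template (for atlas-ROI
#' exclusion only), WM masking, percentile lesion segmentation and
#' volumetry.
#'
#' @param t1,flair `volume3d` inputs
#' @param template template volume (default [canonical_template()] at
#'   `head_scale`)
#' @param atlas template-space masks (default [atlas_rois()] at `head_scale`)
#' @param head_scale phantom scale used for the default template/atlas
#' @param percentile,support,wm_prob_cut see [segment_lesions()] /
#'   [prepare_wm_flair()]
#' @return list of class `lesion_report`: `rigid`, `affine`, `tissues`,
#'   `wm_flair`, `lesions`, `volumes` (tissue volumes in cm3)
#' @export
run_lesion_pipeline <- function(t1, flair, template = NULL, atlas = NULL,
                                head_scale = 1, percentile = 95,
                                support = "retained", wm_prob_cut = 0.5) {
  if (is.null(template)) template <- canonical_template(head_scale)
  if (is.null(atlas)) atlas <- atlas_rois(head_scale)
  brain <- extract_brain(t1)
  tissues <- segment_tissues(t1, brain)
  rigid <- register_rigid(moving = t1, fixed = flair)
  affine <- register_affine_to_template(t1, template)
  wmf <- prepare_wm_flair(flair, tissues, rigid, atlas, affine,
                          wm_prob_cut = wm_prob_cut)
  lesions <- segment_lesions(wmf, percentile = percentile, support = support)
  structure(list(rigid = rigid, affine = affine, tissues = tissues,
                 wm_flair = wmf, lesions = lesions,
                 volumes = tissue_volumes_cm3(tissues)),
            class = "lesion_report")
}
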
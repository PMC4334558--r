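# MRI phantom generator: ground-truth accounting, determinism, contracts.

test_that("planted lesion volume matches the target within one voxel", {
  subj <- small_subject()
  vox_ml <- prod(subj$flair$voxel_mm) / 1000
  expect_lte(abs(subj$truth$lesion_volume_ml - 1.4), vox_ml)
  expect_equal(sum(subj$truth$lesion_mask$voxels != 0) * vox_ml,
               subj$truth$lesion_volume_ml)
})

test_that("full-scale default hits the reported mean lesion load", {
  # geometry only - no intensities - so this stays fast
  p <- phantom_params()
  expect_equal(p$flair_voxel_mm, c(1, 0.9, 5))
  expect_equal(p$lesion_total_ml, 15.3)
  vox_ml <- prod(p$flair_voxel_mm) / 1000
  expect_lte(abs(round(15.3 / vox_ml) * vox_ml - 15.3), vox_ml)
})

test_that("lesions are hyperintense, inside white matter, and optional", {
  subj <- small_subject()
  les <- subj$truth$lesion_mask$voxels != 0
  expect_gt(sum(les), 0)
  wm_mean <- subj$params$tissue_means$flair[["wm"]]
  expect_true(all(subj$flair$voxels[les] >
                    wm_mean + subj$params$lesion_contrast / 2))
  none <- gen_mri_subject(small_phantom_params(lesion_count = 0), seed = 2)
  expect_equal(sum(none$truth$lesion_mask$voxels), 0)
  expect_error(
    gen_mri_subject(small_phantom_params(lesion_total_ml = 500), seed = 2),
    "exceeds")
})

test_that("truth tissue probabilities sum to 1 inside the brain", {
  subj <- small_subject()
  total <- subj$truth$prob_csf$voxels + subj$truth$prob_gm$voxels +
    subj$truth$prob_wm$voxels
  inb <- subj$truth$tissue$voxels >= 2  # CSF, GM or WM
  expect_true(all(total[inb] == 1))
  expect_true(all(total[!inb] == 0))
})

test_that("generator is deterministic in the seed", {
  a <- gen_mri_subject(small_phantom_params(), seed = 5)
  b <- gen_mri_subject(small_phantom_params(), seed = 5)
  expect_identical(a$t1$voxels, b$t1$voxels)
  expect_identical(a$flair$voxels, b$flair$voxels)
  expect_identical(a$truth$lesion_mask$voxels, b$truth$lesion_mask$voxels)
  c <- gen_mri_subject(small_phantom_params(), seed = 6)
  expect_false(identical(a$flair$voxels, c$flair$voxels))
})

test_that("atlas masks cover their structures and respect dilation", {
  atl <- small_atlas()
  expect_named(atl, c("cerebellum", "brainstem", "thalamus", "caudate", "putamen"))
  for (m in atl) expect_gt(sum(m$voxels), 0)
  tight <- atlas_rois(0.45, voxel_mm = c(1.5, 1.5, 1.5), roi_dilate = 1)
  # the union (what the exclusion step uses) grows with dilation and
  # contains the undilated union; individual labels may trade voxels where
  # dilated neighbors overlap
  un <- function(rois) Reduce(`|`, lapply(rois, function(m) m$voxels > 0))
  expect_true(all(un(tight) <= un(atl)))
  expect_gt(sum(un(atl)), sum(un(tight)))
})
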
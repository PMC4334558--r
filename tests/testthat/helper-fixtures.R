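# Shared fixtures. Heavy objects (small-scale phantoms) are built once per
# test run and memoized here; everything is generated in code - no binary
# fixtures ship with the package.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small-scale head phantom: fast enough for unit tests, large enough for
# registration and segmentation to behave
small_phantom_params <- function(...) {
  defaults <- list(head_scale = 0.45,
                   t1_voxel_mm = c(1.5, 1.5, 1.5),
                   flair_voxel_mm = c(1.2, 1.2, 3),
                   lesion_total_ml = 1.4, lesion_count = 3)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

small_subject <- function() {
  fixture("small_subject", function() gen_mri_subject(small_phantom_params(), seed = 9))
}

small_template <- function() {
  fixture("small_template", function() canonical_template(0.45, voxel_mm = c(1.5, 1.5, 1.5)))
}

small_atlas <- function() {
  fixture("small_atlas", function() atlas_rois(0.45, voxel_mm = c(1.5, 1.5, 1.5)))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
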
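test_that("phantom generation is deterministic and hits the target BV/TV", {
  cfg <- small_phantom(seed = 1, dimn = 64, n_cracks = 2, n_lacunae = 3)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$labels$data, b$truth$labels$data)

  cfg2 <- phantom_config(dim = c(128, 128, 128), bvtv = 0.2, n_cracks = 0,
                         n_lacunae = 0, seed = 4)
  ph <- generate_phantom(cfg2)
  expect_gte(mean(ph$truth$bone), 0.17)
  expect_lte(mean(ph$truth$bone), 0.23)
})

test_that("a fully clean configuration yields a two-valued volume", {
  cfg <- phantom_config(dim = c(48, 48, 48), n_cracks = 0, n_lacunae = 0,
                        noise_sd = 0, ring_amplitude = 0,
                        band_amplitude = 0, cement_contrast = 0,
                        blur_sigma_vox = 0, seed = 2)
  ph <- generate_phantom(cfg)
  expect_setequal(unique(as.numeric(ph$volume$data)), c(60, 160))
  expect_identical(ph$volume$data >= 100, ph$truth$bone)
})

test_that("embed_crack voxelises a measurable planar lens", {
  # unconstrained 100 x 50 x 2.8 um crack: moment-fit length within 10%
  vox <- embed_crack(NULL, center = c(60, 60, 60),
                     normal = c(0.3, -0.5, 0.81), length_um = 100,
                     width_um = 50, thickness_um = 2.8, voxel_size_um = 1.4)
  fit <- fit_ellipsoid(vox, 1.4)
  expect_gte(fit$cr_le_um, 90)
  expect_lte(fit$cr_le_um, 110)

  # minimal representable crack: a one-voxel-thick sheet
  vox1 <- embed_crack(NULL, center = c(30, 30, 30), normal = c(0, 0, 1),
                      length_um = 40, width_um = 30, thickness_um = 1.4,
                      voxel_size_um = 1.4)
  expect_identical(length(unique(vox1[, 3])), 1L)

  # axis-aligned normal, thickness 2 voxels: one z band of 2 slices
  # (centre placed half a voxel off the lattice plane)
  vox2 <- embed_crack(NULL, center = c(30, 30, 30), normal = c(0, 0, 1),
                      length_um = 40, width_um = 30, thickness_um = 2.8,
                      voxel_size_um = 1.4)
  expect_lte(diff(range(vox2[, 3])) + 1, ceiling(2.8 / 1.4) + 1)

  bone <- array(FALSE, c(20, 20, 20))
  expect_error(
    embed_crack(bone, c(10, 10, 10), c(0, 0, 1), 10, 5, 1.4, voxel_size_um = 1.4),
    "placement error")
  expect_error(
    embed_crack(NULL, c(10, 10, 10), c(0, 0, 1), 10, 5, 0.7, voxel_size_um = 1.4),
    "voxel")
})

test_that("truth_to_labels renders disjoint records and counts voxels", {
  bone <- array(TRUE, c(24, 24, 24))
  mk <- function(i) list(kind = "lacuna", voxels = cbind(i, 1:3, 1))
  truth <- structure(list(records = list(mk(1), mk(5), mk(9)), bone = bone,
                          voxel_size_um = 1.4),
                     class = "phantom_truth")
  lab <- truth_to_labels(truth)
  expect_setequal(unique(as.integer(lab$data)), c(0L, 1L, 2L, 3L))

  empty <- structure(list(records = list(), bone = bone, voxel_size_um = 1.4),
                     class = "phantom_truth")
  expect_true(all(truth_to_labels(empty)$data == 0))

  vox <- embed_crack(NULL, c(40, 40, 40), c(0, 0, 1), 80, 50, 2.8,
                     voxel_size_um = 1.4)
  one <- structure(list(records = list(list(kind = "crack", voxels = vox)),
                        bone = array(TRUE, c(80, 80, 80)),
                        voxel_size_um = 1.4),
                   class = "phantom_truth")
  lab1 <- truth_to_labels(one)
  expect_identical(sum(lab1$data == 1L), nrow(vox))
})

test_that("default-config truth cracks satisfy the microcrack rule", {
  cfg <- small_phantom(seed = 7, dimn = 96, n_cracks = 6, n_lacunae = 0)
  ph <- generate_phantom(cfg)
  for (rec in ph$truth$records) {
    if (rec$kind != "crack") next
    vol_um3 <- nrow(rec$voxels) * 1.4^3
    expect_gt(vol_um3, 500)
    expect_lt(rec$thickness_fit_um / rec$width_fit_um, 1 / 3)
  }
})
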
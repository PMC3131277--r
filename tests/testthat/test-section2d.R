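test_that("virtual sections average the right slices", {
  set.seed(31)
  vol <- grey_volume(array(runif(16 * 16 * 60), c(16, 16, 60)), 1.4)
  raw <- make_virtual_sections(vol, slices_averaged = 1, spacing_slices = 10,
                               n = 4)
  for (k in 1:4)
    expect_equal(raw$images[[k]], vol$data[, , (k - 1) * 10 + 1])

  cst <- grey_volume(array(5, c(8, 8, 40)), 1.4)
  secs <- make_virtual_sections(cst, 3, 8, 4)
  expect_true(all(vapply(secs$images, function(m) all(m == 5), TRUE)))

  # reference acquisition geometry: 1400 slices, defaults -> 8 sections,
  # 7 um thick, last starting at slice 896 (0-based)
  big <- grey_volume(array(0, c(2, 2, 1400)), 1.4)
  ss <- make_virtual_sections(big)
  expect_identical(length(ss$images), 8L)
  expect_equal(ss$thickness_um, 7)
  expect_identical(ss$z_start[8], 897L)  # 1-based
  expect_error(make_virtual_sections(big, n = 12), "extent error")
})

test_that("section counting reproduces the 2D over- and under-counting", {
  # one vertical crack spanning three sections vs. one between sections
  d <- c(72, 72, 72)
  bone <- array(TRUE, d)
  vol_grey <- array(160, d)
  mk_crack <- function(vg, z_range) {
    # crack plane normal along x (in-plane axes y and z)
    vg[30:40, 36:38, z_range] <- 60
    vg
  }
  spanning <- grey_volume(mk_crack(vol_grey, 3:45), 1.4)
  between <- grey_volume(mk_crack(vol_grey, 27:40), 1.4)

  run2d <- function(vol) {
    ss <- make_virtual_sections(vol, slices_averaged = 3,
                                spacing_slices = 20, n = 3, z0 = 2)
    measure_sections(ss, list(bone_threshold = 110))
  }
  expect_identical(run2d(spanning)$cr_n_2d, 3L)
  expect_identical(run2d(between)$cr_n_2d, 0L)

  run3d <- function(vol) {
    env <- binary_mask(array(TRUE, d), 1.4, "envelope")
    resp <- porosity_response(vol, env, 110)
    poro <- hysteresis_segment(resp, 0.3, 0.5, envelope = env)
    label_porosities(poro)$n_labels
  }
  expect_identical(run3d(spanning), 1L)
  expect_identical(run3d(between), 1L)
})

test_that("2D bone fraction estimates the 3D fraction without bias", {
  # sectional sampling of the truth mask is unbiased across phantoms
  sample_bias <- vapply(1:30, function(seed) {
    cfg <- phantom_config(dim = c(64, 64, 96), bvtv = 0.2, n_cracks = 0,
                          n_lacunae = 0, noise_sd = 0, ring_amplitude = 0,
                          blur_sigma_vox = 0, seed = 100 + seed)
    ph <- generate_phantom(cfg)
    z_sampled <- as.vector(outer(0:2, c(3, 25, 47, 69, 91), `+`))
    mean(ph$truth$bone[, , z_sampled]) - mean(ph$truth$bone)
  }, numeric(1))
  expect_lt(abs(mean(sample_bias)), 0.01)

  # the measured 2D fraction tracks the truth-mask fraction of the same
  # sections on a clean two-phase phantom
  cfg <- phantom_config(dim = c(64, 64, 64), bvtv = 0.2, n_cracks = 0,
                        n_lacunae = 0, noise_sd = 0, ring_amplitude = 0,
                        blur_sigma_vox = 0, seed = 121)
  ph <- generate_phantom(cfg)
  ss <- make_virtual_sections(ph$volume, slices_averaged = 3,
                              spacing_slices = 14, n = 4, z0 = 2)
  rep <- measure_sections(ss)
  z_sampled <- as.vector(outer(0:2, ss$z_start, `+`))
  expect_lt(abs(rep$bvtv_2d - mean(ph$truth$bone[, , z_sampled])), 0.03)
})

test_that("the pooled-bone-area 2D density convention is self-consistent", {
  tab <- reference_specimens()
  pred <- crack_density_2d(tab$cr_n_2d, section_area_mm2 = 2.8 * 2.8,
                           n_sections = 8, bvtv_2d = tab$bvtv_2d)
  expect_lt(max(abs(pred - tab$cr_dn_2d_mm2) / tab$cr_dn_2d_mm2), 0.10)
})
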
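test_that("bone thresholding separates well-contrasted phases", {
  cfg <- phantom_config(dim = c(48, 48, 48), n_cracks = 0, n_lacunae = 0,
                        noise_sd = 0, ring_amplitude = 0, band_amplitude = 0,
                        cement_contrast = 0, blur_sigma_vox = 0, seed = 2)
  ph <- generate_phantom(cfg)
  bone <- segment_bone(ph$volume, "auto")
  expect_identical(bone$data, ph$truth$bone)

  all_in <- segment_bone(ph$volume, 0)
  expect_true(all(all_in$data))

  noisy <- grey_volume(ph$volume$data + rnorm(48^3, 0, 10), 1.4)
  bn <- segment_bone(noisy, "auto")
  expect_lt(mean(bn$data != ph$truth$bone), 0.01)

  flat <- grey_volume(array(3, c(8, 8, 8)), 1.4)
  expect_error(segment_bone(flat, "auto"), "thresholding error")
})

test_that("the envelope closes thin slots and restores carved cavities", {
  cube <- array(FALSE, c(40, 40, 40))
  cube[5:36, 5:36, 5:36] <- TRUE
  slot <- cube
  slot[5:36, 5:36, 20:22] <- FALSE   # 3-voxel slot, open at the sides
  env <- compute_envelope(binary_mask(slot, 1.4, "bone"), 14)
  # the slot is closed (up to a sub-voxel meniscus at its open mouth)
  # and the envelope never grows beyond the original solid
  interior <- array(FALSE, c(40, 40, 40))
  interior[7:34, 7:34, 20:22] <- TRUE
  expect_true(all(env$data[interior]))
  expect_false(any(env$data & !cube))
  expect_true(all(env$data[slot]))   # envelope contains bone

  solid <- binary_mask(cube, 1.4, "bone")
  expect_identical(compute_envelope(solid, 14)$data, cube)

  lac <- make_ellipsoid(c(6, 4, 3), dims = c(40, 40, 40))
  carved <- cube & !lac
  env2 <- compute_envelope(binary_mask(carved, 1.4, "bone"), 14)
  restored <- env2$data & !carved
  expect_identical(restored, lac & cube)
})

test_that("planarity scores single out dark sheets and find their normal", {
  flat <- grey_volume(array(7, c(24, 24, 24)), 1.4)
  pf <- planarity_field(flat, 2.1)
  expect_true(all(pf$score == 0))

  vol <- make_sheet_volume(40, z_on = 20:21)
  pf2 <- planarity_field(vol, 2.1)
  on_plane <- pf2$score[, , 20:21]
  off_plane <- pf2$score[, , c(5:14, 27:36)]
  expect_gt(mean(on_plane), 5 * mean(off_plane))
  # recovered normal on the sheet is within 5 degrees of +z
  core <- pf2$normal[10:30, 10:30, 20, ]
  nz <- abs(core[, , 3])
  expect_gt(min(nz), cos(5 * pi / 180))

  # a compact dark blob (lacuna-like) scores well below the sheet
  blobv <- array(200, c(40, 40, 40))
  blobv[make_ball(40, 6)] <- 50
  pfb <- planarity_field(grey_volume(blobv, 1.4), 2.1)
  ball <- make_ball(40, 6)
  expect_lt(mean(pfb$score[ball]), 0.5 * mean(on_plane))
})

test_that("planarity scores match a finite-difference Hessian oracle", {
  vol <- make_sheet_volume(20, z_on = 10)
  s <- 2.1 / 1.4
  sm <- array(cpp_gaussian_blur(vol$data, c(20L, 20L, 20L), rep(s, 3)),
              c(20, 20, 20))
  # oracle: explicit finite differences + base eigen at a probe voxel
  at <- function(i, j, k) sm[i, j, k]
  i <- 10; j <- 10; k <- 10
  H <- matrix(0, 3, 3)
  H[1, 1] <- at(i + 1, j, k) - 2 * at(i, j, k) + at(i - 1, j, k)
  H[2, 2] <- at(i, j + 1, k) - 2 * at(i, j, k) + at(i, j - 1, k)
  H[3, 3] <- at(i, j, k + 1) - 2 * at(i, j, k) + at(i, j, k - 1)
  H[1, 2] <- H[2, 1] <- (at(i + 1, j + 1, k) - at(i + 1, j - 1, k) -
                           at(i - 1, j + 1, k) + at(i - 1, j - 1, k)) / 4
  H[1, 3] <- H[3, 1] <- (at(i + 1, j, k + 1) - at(i + 1, j, k - 1) -
                           at(i - 1, j, k + 1) + at(i - 1, j, k - 1)) / 4
  H[2, 3] <- H[3, 2] <- (at(i, j + 1, k + 1) - at(i, j + 1, k - 1) -
                           at(i, j - 1, k + 1) + at(i, j - 1, k - 1)) / 4
  ev <- eigen(H, symmetric = TRUE)
  h <- ev$values[order(abs(ev$values), decreasing = TRUE)]
  raw_oracle <- h[1] * exp(-(h[2]^2 + h[3]^2) / (2 * (0.5 * h[1])^2))

  res <- cpp_sheet_filter(sm, c(20L, 20L, 20L), 0.5, FALSE)
  raw_impl <- array(res$score, c(20, 20, 20))[i, j, k]
  expect_equal(raw_impl, raw_oracle, tolerance = 1e-10)
})

test_that("the planarity-guided filter preserves structure and raises CNR", {
  flat <- grey_volume(array(3, c(16, 16, 16)), 1.4)
  pf <- planarity_field(flat, 2.1)
  out <- planarity_guided_filter(flat, pf)
  expect_lt(max(abs(out$data - 3)), 1e-9)

  # infinite bandwidths collapse to plain truncated-Gaussian smoothing
  set.seed(42)
  vol <- grey_volume(array(rnorm(16^3, 100, 10), c(16, 16, 16)), 1.4)
  pfv <- planarity_field(vol, 2.1)
  lim <- planarity_guided_filter(vol, pfv, spatial_radius_um = 2.8,
                                 planarity_bandwidth = Inf,
                                 intensity_bandwidth = Inf)
  # oracle: direct truncated-kernel convolution at an interior voxel
  rad <- 2
  offs <- as.matrix(expand.grid(-rad:rad, -rad:rad, -rad:rad))
  offs <- offs[rowSums(offs^2) <= rad^2, ]
  wts <- exp(-rowSums(offs^2) / (2 * 1^2))
  probe <- c(8, 8, 8)
  vals <- vol$data[sweep(offs, 2, probe, `+`)]
  expect_equal(lim$data[8, 8, 8], sum(wts * vals) / sum(wts),
               tolerance = 1e-9)

  # crack CNR improves on a noisy sheet
  set.seed(7)
  sheet <- make_sheet_volume(40, z_on = 20:21)
  truthv <- array(FALSE, c(40, 40, 40)); truthv[, , 20:21] <- TRUE
  noisy <- grey_volume(sheet$data + rnorm(40^3, 0, 15), 1.4)
  pfn <- planarity_field(noisy, 2.1)
  filt <- planarity_guided_filter(noisy, pfn)
  cnr <- function(v) {
    (mean(v[!truthv]) - mean(v[truthv])) / sd(v[!truthv] - sheet$data[!truthv])
  }
  expect_gt(cnr(filt$data), 1.5 * cnr(noisy$data))
})

test_that("hysteresis keeps low-threshold voxels connected to seeds", {
  prof <- array(c(0, 3, 9, 4, 0, 4, 0), c(7, 1, 1))
  out <- hysteresis_segment(prof, low = 2, high = 8, voxel_size_um = 1)
  expect_identical(which(out$data), c(2L, 3L, 4L))

  # low == high collapses to plain thresholding
  set.seed(3)
  resp <- array(runif(10^3), c(10, 10, 10))
  a <- hysteresis_segment(resp, 0.6, 0.6, voxel_size_um = 1)
  expect_identical(a$data, array(resp >= 0.6, dim(resp)))

  expect_error(hysteresis_segment(resp, 0.8, 0.2, voxel_size_um = 1),
               "config error")
})

test_that("hysteresis equals the flood-fill oracle on random fields", {
  set.seed(11)
  for (rep in 1:25) {
    d <- sample(4:16, 3, replace = TRUE)
    resp <- array(runif(prod(d)), d)
    got <- hysteresis_segment(resp, 0.4, 0.75, voxel_size_um = 1)$data
    expect_identical(got, oracle_hysteresis(resp, 0.4, 0.75))
  }
})

test_that("component labelling follows the configured connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE   # touch only diagonally
  bm <- binary_mask(m, 1.4)
  expect_identical(label_porosities(bm, 26)$n_labels, 1L)
  expect_identical(label_porosities(bm, 6)$n_labels, 2L)

  empty <- binary_mask(array(FALSE, c(4, 4, 4)), 1.4)
  expect_identical(label_porosities(empty)$n_labels, 0L)
})

test_that("segmentation recovers each disjoint truth object at zero noise", {
  cfg <- small_phantom(seed = 13, dimn = 96, n_cracks = 4, n_lacunae = 8)
  ph <- generate_phantom(cfg)
  pre <- preprocess_volume(ph$volume)
  seg <- segment_porosities(pre)
  # porosity mask stays inside the envelope and never overlaps final bone
  expect_true(all(seg$envelope$data[seg$porosity$data]))
  expect_false(any(seg$porosity$data & seg$bone$data))
  # every truth object is found; allow a few spurious small components
  det <- score_detection(seg$labels, ph$truth$labels,
                         truth_records = ph$truth$records)
  expect_true(all(det$matches$overlap >= 0.5))
  # determinism of the full chain
  seg2 <- segment_porosities(pre)
  expect_identical(seg$labels$data, seg2$labels$data)
})
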
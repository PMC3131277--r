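test_that("moment fit matches the brute-force oracle and analytic shapes", {
  one <- fit_ellipsoid(matrix(c(3, 4, 5), 1), 1.4)
  expect_equal(one$cr_le_um, 0)
  expect_equal(one$cr_w_um, 0)

  set.seed(21)
  for (rep in 1:10) {
    blob <- make_blob(24, 3)
    vox <- which(blob, arr.ind = TRUE)
    fit <- fit_ellipsoid(vox, 1.4)
    M_oracle <- oracle_moments(vox, 1.4)
    expect_equal(fit$moment, M_oracle, tolerance = 1e-9)
    expect_equal(fit$semi_axes_um,
                 sqrt(5 * pmax(eigen(M_oracle, symmetric = TRUE)$values, 0)),
                 tolerance = 1e-9)
  }

  el <- make_ellipsoid(c(50, 25, 5), dims = c(107, 57, 17))
  f <- fit_ellipsoid(el, 1)
  expect_lt(max(abs(f$semi_axes_um - c(50, 25, 5)) / c(50, 25, 5)), 0.02)

  th <- 30 * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  el_r <- make_ellipsoid(c(50, 25, 5), dims = c(107, 107, 17), rot = rot)
  f_r <- fit_ellipsoid(el_r, 1)
  expect_lt(abs(f_r$cr_le_um - f$cr_le_um) / f$cr_le_um, 0.03)
  expect_lt(abs(f_r$cr_w_um - f$cr_w_um) / f$cr_w_um, 0.03)

  ball <- make_ball(27, 9.2)
  fb <- fit_ellipsoid(ball, 1)
  expect_lt(max(abs(fb$semi_axes_um - 9.2) / 9.2), 0.02)
})

test_that("length and width are invariant under lattice rotations", {
  el <- make_ellipsoid(c(20, 9, 3), dims = c(45, 45, 45))
  f0 <- fit_ellipsoid(el, 1.4)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))) {
    f1 <- fit_ellipsoid(aperm(el, perm), 1.4)
    expect_lt(abs(f1$cr_le_um - f0$cr_le_um) / f0$cr_le_um, 0.03)
    expect_lt(abs(f1$cr_w_um - f0$cr_w_um) / f0$cr_w_um, 0.03)
  }
})

test_that("the thickness map is exact on balls and slabs", {
  ball <- make_ball(31, 10.5)   # digitised ball, diameter 21 voxels
  th <- thickness_map(ball, 1.4)
  expect_lt(max(abs(th[ball] - 21 * 1.4)), 1.4)

  slab <- make_slab(32, 9, 4:6)
  th2 <- thickness_map(slab, 1.4)
  expect_lt(max(abs(th2[slab] - 3 * 1.4)), 1.4)

  expect_error(thickness_map(array(FALSE, c(4, 4, 4)), 1.4), "empty-object")
})

test_that("object thickness averages the map over the object", {
  ball <- make_ball(27, 9.2)
  th <- thickness_map(ball, 1.4)
  expect_lt(abs(object_thickness(ball, th) - 2 * 9.2 * 1.4), 1.5 * 1.4)

  # L-shaped slab with halves of thickness t and 2t, equal voxel counts,
  # padded with background on both z sides
  t1 <- 4L
  arr <- array(FALSE, c(40, 80, 2 * t1 + 6))
  arr[, 1:40, 4:(3 + t1)] <- TRUE           # thin half: 40*40*t1 voxels
  arr[, 41:60, 4:(3 + 2 * t1)] <- TRUE      # thick half: 40*20*2t1 voxels
  th3 <- thickness_map(arr, 1)
  got <- object_thickness(arr, th3)
  expect_lt(abs(got - 1.5 * t1), 1.5)
})

test_that("crack surface area reproduces the published per-crack table", {
  tab <- reference_cracks()
  cr_v_um3 <- tab$cr_v_1e6mm3 * 1e3    # 1e-6 mm^3 -> um^3
  cr_s_um2 <- crack_surface(cr_v_um3, tab$cr_th_um)
  printed_scale <- cr_s_um2 * 1e-3     # um^2 -> 1e-3 mm^2
  expect_equal(trunc(printed_scale * 100) / 100, tab$cr_s_1e3mm2)

  expect_equal(crack_surface(7.5, 7.5), 1)
  expect_error(crack_surface(10, 0), "undefined-surface")
})

test_that("the microcrack/lacuna rule matches its truth table", {
  # the four quadrants of (volume >< 500 um^3) x (ratio >< 1/3)
  expect_identical(classify_porosity(1000, 2, 60), "microcrack")
  expect_identical(classify_porosity(1000, 30, 60), "lacuna")
  expect_identical(classify_porosity(400, 2, 60), "other")
  expect_identical(classify_porosity(400, 30, 60), "other")
  # boundary semantics: strictly greater / strictly smaller
  expect_identical(classify_porosity(500, 2, 60), "other")
  expect_identical(classify_porosity(1000, 20, 60), "lacuna")
  # published crack L1 and a sphere-like porosity
  expect_identical(classify_porosity(89100, 3.11, 201), "microcrack")
  expect_identical(classify_porosity(2000, 15, 15), "lacuna")
  expect_identical(classify_porosity(1000, 2, 0), "other")
})

test_that("specimen metrics aggregate counts, densities and fractions", {
  d <- c(40, 40, 40)
  env <- binary_mask(array(TRUE, d), 10, "envelope")  # 0.064 mm^3
  poro <- binary_mask(array(FALSE, d), 10, "porosity")
  recs <- data.frame(label = 1:12,
                     class = c(rep("microcrack", 10), "lacuna", "other"),
                     cr_le_um = rnorm(12, 100), cr_w_um = rnorm(12, 50),
                     cr_th_um = rnorm(12, 3), cr_v_um3 = 1000,
                     n_vox = 10)
  rep <- specimen_metrics(recs, env, poro, smi = FALSE)
  expect_equal(rep$bvtv, 1)
  expect_equal(rep$cr_n, 10)
  expect_equal(rep$cr_dn_mm3, 10 / rep$bv_mm3)
  expect_equal(rep$la_dn_mm3, 1 / rep$bv_mm3)
  expect_equal(rep$cr_le_sd_um,
               sqrt(mean((recs$cr_le_um[1:10] - mean(recs$cr_le_um[1:10]))^2)))

  none <- recs[recs$class == "lacuna", ]
  rep0 <- specimen_metrics(none, env, poro, smi = FALSE)
  expect_equal(rep0$cr_dn_mm3, 0)
})

test_that("SMI lands near its canonical values for plate, rod and sphere", {
  plate <- array(FALSE, c(60, 60, 41)); plate[, , 17:25] <- TRUE
  expect_lt(abs(compute_smi(plate) - 0), 0.5)
  expect_lt(abs(compute_smi(make_rod(41, 60, 10.5)) - 3), 0.5)
  expect_lt(abs(compute_smi(make_ball(31, 10.5)) - 4), 0.5)
})

test_that("local trabecular thickness reads the envelope at the crack site", {
  # uniform plate of thickness 20 voxels (28 um at 1.4 um voxels)
  d <- c(60, 60, 40)
  plate <- array(FALSE, d); plate[, , 11:30] <- TRUE
  env <- binary_mask(plate, 1.4, "envelope")
  th <- thickness_map(env)
  ctr <- c(30, 30, 20) * 1.4
  got <- local_trabecular_thickness(th, env, ctr, cr_w_um = 30)
  expect_lt(abs(got - 20 * 1.4), 1.5 * 1.4)

  # a plate-like and a rod-like trabecula are told apart by Tb.Th.lo
  rod <- make_rod(81, 40, 57 / 1.4 / 2)     # rod diameter 57 voxels
  plate2 <- array(FALSE, c(81, 81, 90))
  plate2[, , 6:84] <- TRUE                  # plate thickness 79 voxels
  env_r <- binary_mask(rod, 1.4, "envelope")
  env_p <- binary_mask(plate2, 1.4, "envelope")
  t_rod <- local_trabecular_thickness(thickness_map(env_r), env_r,
                                      c(41, 41, 20) * 1.4, 30)
  t_plate <- local_trabecular_thickness(thickness_map(env_p), env_p,
                                        c(41, 41, 45) * 1.4, 30)
  expect_gt(t_plate, t_rod)

  empty <- binary_mask(array(FALSE, c(30, 30, 30)), 1.4, "envelope")
  expect_error(
    local_trabecular_thickness(array(0, c(30, 30, 30)), empty,
                               c(15, 15, 15) * 1.4, 30),
    "site error")
})

test_that("local topology classifies plates, rods and junctions", {
  slab <- array(FALSE, c(80, 80, 40)); slab[, , 16:24] <- TRUE
  env_s <- binary_mask(slab, 1.4, "envelope")
  expect_identical(trabecular_shape(env_s, c(40, 40, 20) * 1.4, 40), "plate")

  rod <- make_rod(61, 80, 8)
  env_r <- binary_mask(rod, 1.4, "envelope")
  expect_identical(trabecular_shape(env_r, c(31, 31, 40) * 1.4, 40), "rod")

  # Y junction: three rods meeting at the window centre
  d <- c(81, 81, 41)
  jn <- array(FALSE, d)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  ctr <- c(41, 41, 21)
  dirs <- rbind(c(0, 1, 0), c(0.87, -0.5, 0), c(-0.87, -0.5, 0))
  for (t in 1:3) {
    u <- dirs[t, ]
    rel <- sweep(idx, 2, ctr)
    proj <- rel %*% u
    perp2 <- rowSums(rel^2) - proj^2
    jn[idx[proj > -3 & perp2 <= 36, , drop = FALSE]] <- TRUE
  }
  env_j <- binary_mask(jn, 1.4, "envelope")
  expect_identical(trabecular_shape(env_j, ctr * 1.4, 40), "junction")
})
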
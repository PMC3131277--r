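# Synthetic trabecular micro-CT phantoms with voxel-level ground truth.
#
# The generator emulates the image properties the segmentation pipeline has
# to cope with: plate/rod trabecular architecture at a prescribed BV/TV,
# heterogeneous mineralisation (slow grey-level bands and darker cement-line
# shells), ellipsoidal osteocyte lacunae, micrometre-thin planar cracks
# (optionally twisted or crossing), partial-volume blur, Gaussian noise and
# concentric ring artifacts.

#' Phantom configuration
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: a 256^3 grid at 1.4 um/voxel (358 um cube), BV/TV 0.20, 20 cracks
#' with dimensions drawn from the published morphometric ranges (lengths
#' truncated so cracks fit in the grid), 30 lacunae (reduced density), 10%
#' contrast Gaussian noise and mild ring artifacts.
#'
#' @param dim grid dimensions `c(ny, nx, nz)`.
#' @param voxel_size_um isotropic voxel size.
#' @param bvtv target bone volume fraction (0, 1).
#' @param architecture `"mixed"`, `"plate"` or `"rod"` dominant.
#' @param marrow_grey,bone_grey phase mean grey levels (arbitrary units).
#' @param band_amplitude relative amplitude of slow mineralisation bands.
#' @param cement_contrast grey decrement on cement-line shells (0 disables).
#' @param n_lacunae number of lacunae; `lacuna_semiaxes_um` is a 3 x 2
#'   matrix of (min, max) semi-axis ranges, rows = (a, b, c).
#' @param n_cracks number of cracks; `crack_length_um`, `crack_width_um`,
#'   `crack_thickness_um` are (min, max) ranges of the full length, full
#'   width and maximal thickness.
#' @param crack_types vector of types sampled uniformly per crack, from
#'   `"linear"`, `"twisted"`, `"cross-hatch"`, `"parallel"`.
#' @param twist_deg total normal rotation along the major axis for
#'   `"twisted"` cracks.
#' @param crack_grey grey level inside cracks/lacunae (default: marrow --
#'   cracks are void-filled porosities).
#' @param min_separation_um minimum clearance between distinct truth
#'   objects (default 5 um) so each porosity is an isolated, individually
#'   measurable object; the paired sheets of one cross-hatch or parallel
#'   record are exempt.
#' @param noise_sd Gaussian noise SD in grey units.
#' @param ring_amplitude,ring_wavelength_um concentric ring modulation.
#' @param blur_sigma_vox partial-volume surrogate blur (voxels).
#' @param extra_structures optional list of explicit primitives, each
#'   `list(type = "plate", z_um =, thickness_um =)` or
#'   `list(type = "rod", x_um =, y_um =, radius_um =)` (rod axis along z).
#' @param seed RNG seed fixing all randomness.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(dim = c(256, 256, 256), voxel_size_um = 1.4,
                           bvtv = 0.20, architecture = c("mixed", "plate", "rod"),
                           marrow_grey = 60, bone_grey = 160,
                           band_amplitude = 0.05, cement_contrast = 5,
                           n_lacunae = 30,
                           lacuna_semiaxes_um = cbind(min = c(9, 5, 3.5),
                                                      max = c(13, 7, 5)),
                           n_cracks = 20,
                           crack_length_um = c(88, 250),
                           crack_width_um = c(48, 130),
                           crack_thickness_um = c(1.4, 7),
                           crack_types = "linear", twist_deg = 60,
                           min_separation_um = 5,
                           crack_grey = NULL, noise_sd = 10,
                           ring_amplitude = 3, ring_wavelength_um = 16.8,
                           blur_sigma_vox = 1, extra_structures = list(),
                           seed = 1) {
  architecture <- match.arg(architecture)
  if (bvtv <= 0 || bvtv >= 1) stop("bvtv must lie strictly in (0, 1)")
  if (is.null(crack_grey)) crack_grey <- marrow_grey
  cfg <- list(dim = as.integer(dim), voxel_size_um = voxel_size_um,
              bvtv = bvtv, architecture = architecture,
              marrow_grey = marrow_grey, bone_grey = bone_grey,
              band_amplitude = band_amplitude,
              cement_contrast = cement_contrast, n_lacunae = n_lacunae,
              lacuna_semiaxes_um = lacuna_semiaxes_um, n_cracks = n_cracks,
              crack_length_um = crack_length_um,
              crack_width_um = crack_width_um,
              crack_thickness_um = crack_thickness_um,
              crack_types = crack_types, twist_deg = twist_deg,
              min_separation_um = min_separation_um,
              crack_grey = crack_grey, noise_sd = noise_sd,
              ring_amplitude = ring_amplitude,
              ring_wavelength_um = ring_wavelength_um,
              blur_sigma_vox = blur_sigma_vox,
              extra_structures = extra_structures, seed = seed)
  class(cfg) <- "phantom_config"
  cfg
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

orthonormal_basis <- function(n) {
  # n = sheet normal; returns u (major, in-plane), w (minor, = u x n)
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  w <- c(u[2] * n[3] - u[3] * n[2],
         u[3] * n[1] - u[1] * n[3],
         u[1] * n[2] - u[2] * n[1])
  list(u = u, w = w)
}

#' Voxelise one planar (optionally twisted) crack
#'
#' The crack is a flattened solid ellipsoid (lens): in-plane semi-axes
#' `length_um/2` and `width_um/2`, thickness profile
#' `t(u, w) = thickness_um * sqrt(1 - (u/a)^2 - (w/b)^2)` with a one-voxel
#' floor so even the rim is representable. With `twist_deg != 0` the sheet
#' normal rotates smoothly about the major axis along the crack. The voxel
#' set is clipped to the bone phase and reduced to the connected component
#' containing the centre.
#'
#' @param bone 3D logical array of the bone phase (or `NULL` to skip
#'   clipping).
#' @param center 1-based voxel index `(i, j, k)` of the crack centre; must
#'   lie in bone when `bone` is given.
#' @param normal sheet normal (unit 3-vector, array axis order).
#' @param length_um,width_um,thickness_um crack dimensions.
#' @param twist_deg total rotation of the normal across the length.
#' @param voxel_size_um voxel size.
#' @param u_axis optional in-plane major-axis direction.
#' @return integer n x 3 matrix of voxel indices.
#' @export
embed_crack <- function(bone, center, normal, length_um, width_um,
                        thickness_um, twist_deg = 0, voxel_size_um = 1.4,
                        u_axis = NULL) {
  if (thickness_um < voxel_size_um - 1e-9)
    stop("thickness_um must be at least one voxel size")
  if (!is.null(bone)) {
    if (!bone[center[1], center[2], center[3]])
      stop("placement error: crack centre lies outside bone")
    dims <- dim(bone)
  } else dims <- NULL
  v <- voxel_size_um
  n <- normal / sqrt(sum(normal^2))
  basis <- orthonormal_basis(n)
  u <- basis$u; w <- basis$w
  if (!is.null(u_axis)) {
    u <- u_axis - sum(u_axis * n) * n
    u <- u / sqrt(sum(u^2))
    w <- c(u[2] * n[3] - u[3] * n[2], u[3] * n[1] - u[1] * n[3],
           u[1] * n[2] - u[2] * n[1])
  }
  a <- length_um / 2; b <- width_um / 2; tmax <- thickness_um
  slack <- tmax / 2 + 2 * v
  half_um <- abs(u) * a + abs(w) * b + abs(n) * slack + v
  # twist exchanges the roles of w and n along the crack; bound generously
  if (twist_deg != 0)
    half_um <- abs(u) * a + (abs(w) + abs(n)) * (b + slack) + v

  c_um <- (center - 0.5) * v
  lo <- floor((c_um - half_um) / v + 0.5)
  hi <- ceiling((c_um + half_um) / v + 0.5)
  if (!is.null(dims)) {
    lo <- pmax(lo, 1); hi <- pmin(hi, dims)
  }
  gi <- lo[1]:hi[1]; gj <- lo[2]:hi[2]; gk <- lo[3]:hi[3]
  grid <- as.matrix(expand.grid(i = gi, j = gj, k = gk))
  rel <- sweep(voxel_centers_um(grid, v), 2, c_um)
  pu <- rel %*% u
  pw0 <- rel %*% w
  pn0 <- rel %*% n
  theta <- if (twist_deg != 0) (pi * twist_deg / 180) * (pu / (2 * a)) else 0
  pn <- pn0 * cos(theta) + pw0 * sin(theta)
  pw <- pw0 * cos(theta) - pn0 * sin(theta)
  r2 <- (pu / a)^2 + (pw / b)^2
  tloc <- ifelse(r2 < 1, tmax * sqrt(pmax(1 - r2, 0)), 0)
  teff <- pmax(tloc, v)
  keep <- r2 < 1 & abs(pn) < teff / 2
  vox <- grid[keep, , drop = FALSE]
  if (!nrow(vox)) stop("placement error: crack produced no voxels")
  if (!is.null(bone)) {
    inbone <- bone[vox]
    vox <- vox[inbone, , drop = FALSE]
    if (!nrow(vox)) stop("placement error: crack entirely outside bone")
    vox <- connected_subset(vox, center, dims)
  }
  storage.mode(vox) <- "integer"
  vox
}

# reduce a voxel index set to the 26-connected component containing `center`
connected_subset <- function(vox, center, dims) {
  lo <- pmin(apply(vox, 2, min), center)
  hi <- pmax(apply(vox, 2, max), center)
  sub <- array(FALSE, hi - lo + 1)
  sub[sweep(vox, 2, lo - 1L)] <- TRUE
  lab <- array(cpp_label3d(as.logical(sub), as.integer(dim(sub)), 26L),
               dim(sub))
  cc <- lab[matrix(center - lo + 1L, 1)]
  if (cc == 0) { # centre voxel itself got clipped: keep largest component
    cc <- which.max(tabulate(lab[lab > 0]))
  }
  keep <- lab[sweep(vox, 2, lo - 1L)] == cc
  vox[keep, , drop = FALSE]
}

voxelise_ellipsoid <- function(center, semi_axes_um, axes, voxel_size_um,
                               dims) {
  v <- voxel_size_um
  c_um <- (center - 0.5) * v
  half_um <- sqrt((axes^2) %*% (semi_axes_um^2))[, 1] + v
  lo <- pmax(floor((c_um - half_um) / v + 0.5), 1)
  hi <- pmin(ceiling((c_um + half_um) / v + 0.5), dims)
  grid <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  rel <- sweep(voxel_centers_um(grid, v), 2, c_um)
  p <- rel %*% axes  # coordinates along principal axes
  keep <- (p[, 1] / semi_axes_um[1])^2 + (p[, 2] / semi_axes_um[2])^2 +
    (p[, 3] / semi_axes_um[3])^2 <= 1
  vox <- grid[keep, , drop = FALSE]
  storage.mode(vox) <- "integer"
  vox
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

# mean direct thickness of an isolated voxel set, computed on its local
# bounding box
object_mean_thickness <- function(vox, voxel_size_um) {
  lo <- apply(vox, 2, min) - 2L
  hi <- apply(vox, 2, max) + 2L
  sub <- array(FALSE, hi - lo + 1L)
  sub[sweep(vox, 2, lo - 1L)] <- TRUE
  th <- thickness_map(sub, voxel_size_um)
  mean(th[sub])
}

# mark `vox` dilated by `rad_vox` into the occupancy mask, working on the
# local bounding box only
paint_dilated <- function(occ, vox, rad_vox) {
  d <- dim(occ)
  pad <- ceiling(rad_vox) + 1L
  lo <- pmax(apply(vox, 2, min) - pad, 1L)
  hi <- pmin(apply(vox, 2, max) + pad, d)
  sub <- array(FALSE, hi - lo + 1L)
  sub[sweep(vox, 2, lo - 1L)] <- TRUE
  dil <- sqrt(cpp_edt_sq(as.logical(sub), as.integer(dim(sub)))) <= rad_vox
  occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | array(dil, dim(sub))
  occ
}

#' Generate a synthetic trabecular phantom
#'
#' @param config a [phantom_config()].
#' @param max_retries placement retries per object before a placement
#'   error is raised.
#' @return list with `volume` (a [grey_volume()]) and `truth` (a
#'   `phantom_truth`: `records` (per-object list with kind, analytic
#'   parameters and voxel set), `bone` (ground-truth bone array before
#'   porosity carving), `labels` (a [label_map()] of the truth objects)).
#' @export
generate_phantom <- function(config = phantom_config(), max_retries = 200) {
  set.seed(config$seed)
  d <- config$dim
  v <- config$voxel_size_um
  n_tot <- prod(d)

  # --- architecture: thresholded smoothed random field (+ explicit bits) --
  rad <- switch(config$architecture,
                mixed = c(12L, 12L, 12L),
                plate = c(14L, 14L, 5L),
                rod   = c(5L, 5L, 16L))
  field <- array(stats::rnorm(n_tot), d)
  field <- array(cpp_box_blur(field, as.integer(d), rad, 3L, TRUE), d)

  extra <- array(FALSE, d)
  for (st in config$extra_structures) {
    if (st$type == "plate") {
      zc <- st$z_um / v + 0.5
      hz <- st$thickness_um / (2 * v)
      ks <- which(abs(seq_len(d[3]) - zc) <= hz)
      extra[, , ks] <- TRUE
    } else if (st$type == "rod") {
      yc <- st$y_um / v + 0.5; xc <- st$x_um / v + 0.5
      r <- st$radius_um / v
      dy <- (seq_len(d[1]) - yc)^2
      dx <- (seq_len(d[2]) - xc)^2
      disk <- outer(dy, dx, `+`) <= r^2
      extra <- extra | array(rep(disk, d[3]), d)
    } else stop("unknown structure type: ", st$type)
  }
  n_extra <- sum(extra)
  need <- config$bvtv * n_tot - n_extra
  if (need <= 0) {
    bone <- extra
  } else {
    thr <- stats::quantile(field[!extra], 1 - need / (n_tot - n_extra))
    bone <- extra | (field >= thr)
  }

  depth <- distance_to(!bone)  # distance to marrow, in voxels

  records <- list()
  sep_vox <- config$min_separation_um / v
  occ <- array(FALSE, d)  # existing objects dilated by the separation

  # --- lacunae ------------------------------------------------------------
  rng_lac <- config$lacuna_semiaxes_um
  for (il in seq_len(config$n_lacunae)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      ax <- sort(stats::runif(3, rng_lac[, 1], rng_lac[, 2]),
                 decreasing = TRUE)
      # fully interior: clearance at least the largest semi-axis
      cand <- which(depth >= ax[1] / v + 2)
      if (!length(cand)) break
      ctr_lin <- cand[sample.int(length(cand), 1)]
      ctr <- arrayInd(ctr_lin, d)[1, ]
      R <- random_rotation()
      vox <- voxelise_ellipsoid(ctr, ax, R, v, d)
      inb <- bone[vox]
      ideal <- (4 / 3) * pi * prod(ax) / v^3
      if (sum(inb) >= 0.8 * ideal && sum(inb) * v^3 > 600) {
        vox <- vox[inb, , drop = FALSE]
        if (any(occ[vox])) next
        records[[length(records) + 1]] <- list(
          kind = "lacuna", center = ctr, semi_axes_um = ax, axes = R,
          voxels = vox)
        occ <- paint_dilated(occ, vox, sep_vox)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      warning("lacuna ", il, " could not be placed; skipped")
  }

  # --- cracks ---------------------------------------------------------------
  for (ic in seq_len(config$n_cracks)) {
    type <- sample(config$crack_types, 1)
    placed <- FALSE
    err <- NULL
    for (try in seq_len(max_retries)) {
      L <- stats::runif(1, config$crack_length_um[1], config$crack_length_um[2])
      W <- stats::runif(1, config$crack_width_um[1],
                        min(config$crack_width_um[2], L))
      Tt <- stats::runif(1, max(config$crack_thickness_um[1], v),
                         config$crack_thickness_um[2])
      if (L > max(d) * v) {
        err <- "placement error: requested crack longer than the grid"
        next
      }
      cand <- which(depth >= max(3, Tt / v))
      if (!length(cand)) { err <- "placement error: no bone deep enough"; next }
      ctr <- arrayInd(cand[sample.int(length(cand), 1)], d)[1, ]
      nrm <- random_unit_vector()
      twist <- if (type == "twisted") config$twist_deg else 0
      vox <- tryCatch(
        embed_crack(bone, ctr, nrm, L, W, Tt, twist_deg = twist,
                    voxel_size_um = v),
        error = function(e) NULL)
      if (is.null(vox)) next
      if (type == "cross-hatch") {
        basis <- orthonormal_basis(nrm)
        nrm2 <- nrm * cos(pi / 3) + basis$w * sin(pi / 3)
        vox2 <- tryCatch(
          embed_crack(bone, ctr, nrm2, L, W, Tt, voxel_size_um = v,
                      u_axis = basis$u),
          error = function(e) NULL)
        if (!is.null(vox2)) vox <- unique(rbind(vox, vox2))
      }
      ideal <- max((2 / 3) * pi * (L / 2) * (W / 2) * Tt,
                   pi * (L / 2) * (W / 2) * v) / v^3
      if (nrow(vox) >= 0.5 * ideal && !any(occ[vox])) {
        occ_before <- occ
        occ <- paint_dilated(occ, vox, sep_vox)
        fit <- fit_ellipsoid(vox, v)
        records[[length(records) + 1]] <- list(
          kind = "crack", type = type, center = ctr, normal = nrm,
          length_um = L, width_um = W, thickness_um = Tt,
          # morphometry of the realised (bone-clipped) voxel set: the
          # ground truth a perfect segmentation would recover
          length_fit_um = fit$cr_le_um, width_fit_um = fit$cr_w_um,
          thickness_fit_um = object_mean_thickness(vox, v),
          twist_deg = twist, voxels = vox)
        placed <- TRUE
        if (type == "parallel") {
          # companion sheet offset along the normal
          off <- round(nrm * stats::runif(1, 6, 12) / v)
          ctr2 <- ctr + off
          if (all(ctr2 >= 1) && all(ctr2 <= d) &&
              bone[ctr2[1], ctr2[2], ctr2[3]]) {
            vox2 <- tryCatch(
              embed_crack(bone, ctr2, nrm, L, W, Tt, voxel_size_um = v),
              error = function(e) NULL)
            if (!is.null(vox2) && nrow(vox2) >= 0.5 * ideal &&
                !any(occ_before[vox2])) {
              fit2 <- fit_ellipsoid(vox2, v)
              records[[length(records) + 1]] <- list(
                kind = "crack", type = "parallel", center = ctr2,
                normal = nrm, length_um = L, width_um = W,
                length_fit_um = fit2$cr_le_um, width_fit_um = fit2$cr_w_um,
                thickness_fit_um = object_mean_thickness(vox2, v),
                thickness_um = Tt, twist_deg = 0, voxels = vox2)
              occ <- paint_dilated(occ, vox2, sep_vox)
            }
          }
        }
        break
      }
    }
    if (!placed)
      stop(err %||% paste0("placement error: crack ", ic,
                           " could not be placed after ", max_retries,
                           " retries"))
  }

  truth <- structure(list(records = records, bone = bone,
                          voxel_size_um = v, config = config),
                     class = "phantom_truth")
  truth$labels <- truth_to_labels(truth)

  # --- grey-level synthesis -------------------------------------------------
  grey <- array(config$marrow_grey, d)
  grey[bone] <- config$bone_grey
  if (config$band_amplitude > 0) {
    band <- array(stats::rnorm(n_tot), d)
    band <- array(cpp_box_blur(band, as.integer(d), c(10L, 10L, 10L), 3L, TRUE), d)
    band <- band / max(stats::sd(band), 1e-12)
    grey[bone] <- grey[bone] *
      (1 + config$band_amplitude * band[bone])
  }
  if (config$cement_contrast > 0) {
    shell <- bone & depth >= 3 & depth < 4.2
    grey[shell] <- grey[shell] - config$cement_contrast
  }
  for (rec in records) grey[rec$voxels] <- config$crack_grey
  if (config$blur_sigma_vox > 0)
    grey <- array(cpp_gaussian_blur(grey, as.integer(d),
                                    rep(config$blur_sigma_vox, 3)), d)
  if (config$ring_amplitude > 0) {
    cx <- (d[2] + 1) / 2; cy <- (d[1] + 1) / 2
    xs <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    ys <- matrix(seq_len(d[1]), d[1], d[2])
    r_um <- sqrt((xs - cx)^2 + (ys - cy)^2) * v
    ring <- config$ring_amplitude *
      sin(2 * pi * r_um / config$ring_wavelength_um)
    grey <- grey + array(rep(ring, d[3]), d)
  }
  if (config$noise_sd > 0)
    grey <- grey + array(stats::rnorm(n_tot, 0, config$noise_sd), d)

  list(volume = grey_volume(grey, v), truth = truth)
}

#' Render ground-truth records to a label map
#'
#' Cracks take priority over lacunae where truth objects overlap (a warning
#' is raised for any overlap).
#'
#' @param truth a `phantom_truth`.
#' @return a [label_map()] with one label per truth record, in record order.
#' @export
truth_to_labels <- function(truth) {
  d <- dim(truth$bone)
  lab <- array(0L, d)
  overlap <- FALSE
  ord <- order(vapply(truth$records, function(r) r$kind == "crack", TRUE))
  # lacunae first, cracks afterwards so cracks overwrite (priority)
  for (i in ord) {
    vox <- truth$records[[i]]$voxels
    if (any(lab[vox] != 0L)) overlap <- TRUE
    lab[vox] <- i
  }
  if (overlap)
    warning("overlapping truth objects; cracks take priority over lacunae")
  label_map(lab, truth$voxel_size_um, n_labels = length(truth$records))
}

#' @export
print.phantom_truth <- function(x, ...) {
  kinds <- vapply(x$records, `[[`, "", "kind")
  cat(sprintf("phantom_truth: %d cracks, %d lacunae, BV/TV %.3f\n",
              sum(kinds == "crack"), sum(kinds == "lacuna"),
              mean(x$bone)))
  invisible(x)
}
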
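# Pre-processing: ring-artifact removal and global intensity normalisation.
# Both run before any crack enhancement.

#' Remove concentric ring artifacts
#'
#' Ring artifacts from non-uniform detector response appear as concentric
#' grey-level rings about the rotation axis in every reconstructed slice.
#' Per slice, the image is resampled to polar coordinates about the
#' rotation axis (bilinear interpolation on a dense angular grid every
#' quarter voxel of radius) and the angular median gives a radial profile
#' that captures the rings but is insensitive to anatomy. The profile is
#' high-pass filtered radially -- its low-frequency part is a
#' least-squares natural-spline fit with knots every `radial_smooth_um`,
#' a projection, which makes the correction idempotent -- and the
#' per-slice artifact estimates are combined by a per-radius median across
#' slices (detector response, hence the rings, is stable along z while
#' anatomy decorrelates); radii where the cross-slice spread dominates the
#' consensus carry anatomy rather than rings and are left untouched. The
#' combined artifact is subtracted from every pixel at its exact radius;
#' each slice mean is preserved exactly.
#'
#' @param vol a [grey_volume()].
#' @param center_xy optional rotation-axis position `(x, y)` in voxel units;
#'   defaults to the slice centre.
#' The estimate-subtract cycle runs twice internally; the second pass
#' removes the small component the polar resampling misses, so applying
#' the operation again changes essentially nothing.
#'
#' @param radial_smooth_um radial scale separating anatomy from artifact
#'   (spline knot spacing; default 42 um = 30 voxels at 1.4 um, several
#'   ring periods but well below anatomical trend scales).
#' @return corrected [grey_volume()].
#' @export
remove_ring_artifacts <- function(vol, center_xy = NULL,
                                  radial_smooth_um = 42) {
  d <- dim(vol$data)
  ny <- d[1]; nx <- d[2]
  if (is.null(center_xy)) center_xy <- c((nx + 1) / 2, (ny + 1) / 2)
  # polar resampling: per radius, the slice is sampled bilinearly on a
  # dense angular grid and the angular median gives the radial profile;
  # its low-frequency part is a least-squares natural-spline fit with
  # knots every radial_smooth_um (a projection, so the correction is
  # idempotent), and the high-frequency remainder is the ring artifact
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny), ny, nx)
  r_pix <- sqrt((xs - center_xy[1])^2 + (ys - center_xy[2])^2)

  dr <- 0.25
  rg <- seq(0, max(r_pix), by = dr)
  nr <- length(rg)
  # angular sample coordinates per radius, clipped to the grid
  samp <- lapply(seq_len(nr), function(i) {
    r <- rg[i]
    nth <- max(8L, ceiling(2 * pi * r / 0.5))
    th <- (seq_len(nth) - 0.5) * 2 * pi / nth
    x <- center_xy[1] + r * cos(th)
    y <- center_xy[2] + r * sin(th)
    ok <- x >= 1 & x <= nx & y >= 1 & y <= ny
    cbind(x[ok], y[ok])
  })
  ns_per_r <- vapply(samp, nrow, integer(1))
  pts <- do.call(rbind, samp)
  ix <- pmin(floor(pts[, 1]), nx - 1); fx <- pts[, 1] - ix
  iy <- pmin(floor(pts[, 2]), ny - 1); fy <- pts[, 2] - iy
  i00 <- cbind(iy, ix); i10 <- cbind(iy + 1, ix)
  i01 <- cbind(iy, ix + 1); i11 <- cbind(iy + 1, ix + 1)
  rfac <- factor(rep.int(seq_len(nr), ns_per_r), levels = seq_len(nr))

  knot_sp <- max(8, radial_smooth_um / vol$voxel_size_um / dr)
  basis <- if (nr > 2 * knot_sp) {
    knots <- seq(knot_sp, nr - knot_sp / 2, by = knot_sp)
    cbind(1, splines::ns(seq_len(nr), knots = knots))
  } else cbind(1, seq_len(nr))
  basis_qr <- qr(basis)

  out <- vol$data
  for (pass in 1:2) {
    artifacts <- matrix(0, nr, d[3])
    for (k in seq_len(d[3])) {
      sl <- out[, , k]
      vals <- (1 - fx) * (1 - fy) * sl[i00] + (1 - fx) * fy * sl[i10] +
        fx * (1 - fy) * sl[i01] + fx * fy * sl[i11]
      prof <- as.numeric(tapply(vals, rfac, stats::median))
      if (anyNA(prof)) {
        ok <- which(!is.na(prof))
        prof <- stats::approx(ok, prof[ok], xout = seq_along(prof),
                              rule = 2)$y
      }
      smooth <- basis %*% qr.coef(basis_qr, prof)
      artifacts[, k] <- as.numeric(prof - smooth)
    }
    # combined across slices: detector response (hence the rings) is
    # stable along z while anatomy decorrelates, so the per-radius median
    # over slices isolates the artifact; radii where the cross-slice
    # spread dominates the consensus carry anatomy, not rings, and are
    # left untouched
    artifact <- apply(artifacts, 1, stats::median)
    if (d[3] >= 3) {
      spread <- apply(artifacts, 1, stats::mad)
      artifact[abs(artifact) <= 1.5 * spread] <- 0
    }

    corr_map <- array(stats::approx(rg, artifact, xout = r_pix, rule = 2)$y,
                      dim(r_pix))
    for (k in seq_len(d[3])) {
      sl <- out[, , k]
      corr <- sl - corr_map
      out[, , k] <- corr + (mean(sl) - mean(corr))
    }
  }
  grey_volume(out, vol$voxel_size_um, vol$origin_um)
}

#' Normalise slowly varying global intensity
#'
#' Estimates the global low-frequency bias as a quadratic polynomial field
#' fitted to the bone-phase voxels (grey values at or above a rough bone
#' threshold) and removes it by subtraction (default) or division.
#' Modelling the bias as a low-order trend removes scanner-scale intensity
#' drifts exactly, including at the volume boundary, while leaving local
#' anatomy (mineralisation bands, cement lines, porosities) untouched; on
#' an unbiased volume the fitted trend is flat and the operation is the
#' identity. The global mean of the volume is preserved.
#'
#' @param vol a [grey_volume()].
#' @param window_um shortest variation scale still treated as "global"
#'   (default 200 um); must exceed 3 voxels. Retained for interface
#'   stability; the quadratic trend only removes variation at or above the
#'   volume scale.
#' @param mode `"subtract"` or `"divide"`.
#' @param bone_threshold rough bone threshold; `"auto"` (default) uses the
#'   inter-class-variance criterion.
#' @return normalised [grey_volume()].
#' @export
normalize_intensity <- function(vol, window_um = 200,
                                mode = c("subtract", "divide"),
                                bone_threshold = "auto") {
  mode <- match.arg(mode)
  d <- dim(vol$data)
  wv <- window_um / vol$voxel_size_um
  if (wv < 3) stop("config error: window_um must be at least 3 voxels")
  if (stats::sd(vol$data) == 0) return(vol)

  thr <- if (identical(bone_threshold, "auto")) {
    tryCatch(otsu_threshold(vol$data), error = function(e) min(vol$data))
  } else bone_threshold
  sel <- which(vol$data >= thr)
  if (!length(sel)) sel <- seq_along(vol$data)
  # deterministic thinning keeps the normal equations small on big volumes
  if (length(sel) > 300000L)
    sel <- sel[seq(1L, length(sel), by = ceiling(length(sel) / 300000L))]

  idx <- arrayInd(sel, d)
  nc <- function(i, n) 2 * (i - 1) / (max(n - 1, 1)) - 1  # [-1, 1]
  X <- cbind(1, nc(idx[, 1], d[1]), nc(idx[, 2], d[2]), nc(idx[, 3], d[3]))
  X <- cbind(X, X[, 2]^2, X[, 3]^2, X[, 4]^2,
             X[, 2] * X[, 3], X[, 2] * X[, 4], X[, 3] * X[, 4])
  beta <- stats::lm.fit(X, vol$data[sel])$coefficients
  beta[is.na(beta)] <- 0

  # evaluate the trend on the full grid, axis by axis
  y <- nc(seq_len(d[1]), d[1])
  x <- nc(seq_len(d[2]), d[2])
  z <- nc(seq_len(d[3]), d[3])
  Y <- array(rep(y, times = d[2] * d[3]), d)
  Xa <- array(rep(rep(x, each = d[1]), times = d[3]), d)
  Za <- array(rep(z, each = d[1] * d[2]), d)
  bias <- beta[1] + beta[2] * Y + beta[3] * Xa + beta[4] * Za +
    beta[5] * Y^2 + beta[6] * Xa^2 + beta[7] * Za^2 +
    beta[8] * Y * Xa + beta[9] * Y * Za + beta[10] * Xa * Za
  gmean <- mean(vol$data[sel])

  out <- if (mode == "subtract") vol$data - (bias - gmean)
         else vol$data / pmax(bias / gmean, 1e-6)
  out <- out + (mean(vol$data) - mean(out))
  grey_volume(out, vol$voxel_size_um, vol$origin_um)
}

#' Run the standard pre-processing chain
#'
#' @param vol a [grey_volume()].
#' @param config list of keys `ring.enabled`, `ring.radial_smooth_um`,
#'   `norm.enabled`, `norm.window_um`, `norm.mode` (see
#'   [default_pipeline_config()]).
#' @return pre-processed [grey_volume()].
#' @export
preprocess_volume <- function(vol, config = list()) {
  cfg <- utils::modifyList(default_pipeline_config()$preprocess, config)
  if (isTRUE(cfg$ring.enabled))
    vol <- remove_ring_artifacts(vol, radial_smooth_um = cfg$ring.radial_smooth_um)
  if (isTRUE(cfg$norm.enabled))
    vol <- normalize_intensity(vol, window_um = cfg$norm.window_um,
                               mode = cfg$norm.mode)
  vol
}
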
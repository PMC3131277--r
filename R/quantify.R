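# Per-porosity and per-specimen 3D morphometry.

#' Best-fitting ellipsoid of a voxel set by second-order moments
#'
#' The centered second-order moment matrix of the object,
#' `M = (1/N) * sum (x - xbar)(x - xbar)^T` over voxel centres (in um), is
#' diagonalised; its eigenvectors give the principal directions and the
#' semi-axes of the uniform solid ellipsoid with the same moment matrix are
#' `a_i = sqrt(5 * lambda_i)`. Crack length and width are the two largest
#' ellipsoid diameters: `Cr.Le = 2 a1`, `Cr.W = 2 a2`.
#'
#' @param voxels n x 3 matrix of 1-based voxel indices `(i, j, k)`, or a
#'   3D logical array.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @return list with `n_vox`, `centroid_um`, `moment` (3x3, um^2),
#'   `lambda` (decreasing, um^2), `axes` (unit column vectors, sign fixed so
#'   the largest-magnitude component is positive), `semi_axes_um`
#'   (`a1 >= a2 >= a3`), `cr_le_um`, `cr_w_um`.
#' @export
fit_ellipsoid <- function(voxels, voxel_size_um) {
  if (is.array(voxels) && is.logical(voxels))
    voxels <- which(voxels, arr.ind = TRUE)
  voxels <- matrix(as.numeric(voxels), ncol = 3)
  n <- nrow(voxels)
  if (n < 1) stop("empty voxel set")
  xyz <- voxel_centers_um(voxels, voxel_size_um)
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  M <- crossprod(cc) / n
  eg <- eigen(M, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  axes <- eg$vectors
  for (i in 1:3) {
    v <- axes[, i]
    if (v[which.max(abs(v))] < 0) axes[, i] <- -v
  }
  a <- sqrt(5 * lambda)
  list(n_vox = n, centroid_um = ctr, moment = M, lambda = lambda,
       axes = axes, semi_axes_um = a, cr_le_um = 2 * a[1],
       cr_w_um = 2 * a[2])
}

#' Mean object thickness from a thickness map
#'
#' @param voxels n x 3 matrix of voxel indices or a 3D logical array.
#' @param thickness 3D numeric array from [thickness_map()] (um).
#' @return mean thickness over the object's voxels, in micrometres.
#' @export
object_thickness <- function(voxels, thickness) {
  if (is.array(voxels) && is.logical(voxels))
    return(mean(thickness[voxels]))
  mean(thickness[voxels])
}

#' Crack surface area
#'
#' `Cr.S = Cr.V / Cr.Th`: the area of the equivalent sheet of uniform
#' thickness `Cr.Th` and volume `Cr.V`.
#'
#' @param cr_v_um3 crack volume in um^3.
#' @param cr_th_um mean crack thickness in um.
#' @return surface area in um^2.
#' @export
crack_surface <- function(cr_v_um3, cr_th_um) {
  if (any(cr_th_um <= 0))
    stop("undefined-surface error: Cr.Th must be positive")
  cr_v_um3 / cr_th_um
}

#' Classify a porosity as microcrack, lacuna or other
#'
#' Porosities with volume above `min_volume_um3` and thickness-to-width
#' ratio below `max_ratio` are microcracks; porosities above the volume cut
#' that fail the ratio test are lacunae; everything else (sub-threshold
#' porosity, noise specks) is `other`. A zero width makes the ratio
#' undefined and classifies the object as `other`.
#'
#' @param cr_v_um3 volume (um^3).
#' @param cr_th_um mean thickness (um).
#' @param cr_w_um width `2 a2` (um).
#' @param min_volume_um3 volume cut, default 500 um^3.
#' @param max_ratio thickness/width cut, default 1/3.
#' @return character vector in `{"microcrack", "lacuna", "other"}`.
#' @export
classify_porosity <- function(cr_v_um3, cr_th_um, cr_w_um,
                              min_volume_um3 = 500, max_ratio = 1 / 3) {
  n <- max(length(cr_v_um3), length(cr_th_um), length(cr_w_um))
  cr_v_um3 <- rep_len(cr_v_um3, n)
  cr_th_um <- rep_len(cr_th_um, n)
  cr_w_um <- rep_len(cr_w_um, n)
  out <- rep("other", n)
  big <- cr_v_um3 > min_volume_um3
  ok_ratio <- cr_w_um > 0 & (cr_th_um / pmax(cr_w_um, 1e-12)) < max_ratio
  out[big & ok_ratio & cr_w_um > 0] <- "microcrack"
  out[big & !(ok_ratio & cr_w_um > 0)] <- "lacuna"
  out[big & cr_w_um == 0] <- "other"
  out
}

#' Quantify all labelled porosities
#'
#' Computes, for every component of the label map: voxel count, volume
#' `Cr.V = N * voxel^3`, centroid, moment-fit semi-axes, length `Cr.Le`,
#' width `Cr.W`, mean direct thickness `Cr.Th`, surface `Cr.S = Cr.V/Cr.Th`
#' and the microcrack/lacuna/other class.
#'
#' @param labels a [label_map()] of segmented porosities.
#' @param min_volume_um3,max_ratio classification cut-offs.
#' @return a `data.frame` with one row per component (a porosity record).
#' @export
quantify_porosities <- function(labels, min_volume_um3 = 500,
                                max_ratio = 1 / 3) {
  v <- labels$voxel_size_um
  n <- labels$n_labels
  cols <- c("label", "class", "n_vox", "centroid_y_um", "centroid_x_um",
            "centroid_z_um", "cr_v_um3", "cr_le_um", "cr_w_um", "cr_th_um",
            "cr_s_um2", "a3_um")
  if (n == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    out$class <- character(0)
    return(out)
  }
  idx <- which(labels$data > 0, arr.ind = TRUE)
  lab <- labels$data[labels$data > 0]
  th <- thickness_map(labels$data > 0, v)
  thv <- th[labels$data > 0]
  ord <- order(lab)
  idx <- idx[ord, , drop = FALSE]
  thv <- thv[ord]
  lab <- lab[ord]
  bounds <- c(0, cumsum(tabulate(lab, n)))

  rows <- vector("list", n)
  for (l in seq_len(n)) {
    sel <- (bounds[l] + 1):bounds[l + 1]
    vox <- idx[sel, , drop = FALSE]
    fit <- fit_ellipsoid(vox, v)
    cr_v <- fit$n_vox * v^3
    cr_th <- mean(thv[sel])
    rows[[l]] <- data.frame(
      label = l, class = NA_character_, n_vox = fit$n_vox,
      centroid_y_um = fit$centroid_um[1], centroid_x_um = fit$centroid_um[2],
      centroid_z_um = fit$centroid_um[3], cr_v_um3 = cr_v,
      cr_le_um = fit$cr_le_um, cr_w_um = fit$cr_w_um, cr_th_um = cr_th,
      cr_s_um2 = crack_surface(cr_v, cr_th), a3_um = fit$semi_axes_um[3])
  }
  out <- do.call(rbind, rows)
  out$class <- classify_porosity(out$cr_v_um3, out$cr_th_um, out$cr_w_um,
                                 min_volume_um3, max_ratio)
  out
}

#' Structure Model Index of the trabecular envelope
#'
#' `SMI = 6 V S' / S^2` with `S` the surface area and `S'` its derivative
#' under infinitesimal surface dilation: 0 for ideal plates, 3 for rods,
#' 4 for spheres. `V(r)`, the volume of the structure offset by a signed
#' distance `r`, is sampled from the exact Euclidean distance transform
#' over `r` in `[-r_max, r_max]` voxels and fitted with a cubic polynomial
#' (exact for planes, cylinders and spheres); then `S = V'(0)` and
#' `S' = V''(0)`. Structures are clipped at the grid boundary, so plates
#' and rods spanning the volume behave as unbounded.
#'
#' @param envelope a [binary_mask()] (or 3D logical array).
#' @param r_max_vox half-range of the offset sampling, in voxels.
#' @return the (dimensionless) SMI.
#' @export
compute_smi <- function(envelope, r_max_vox = 3) {
  m <- if (inherits(envelope, "binary_mask")) envelope$data else envelope
  if (!any(m)) stop("empty-object error: envelope is empty")
  d_in <- distance_to(!m)   # 0 on background, >=1 inside
  d_out <- distance_to(m)   # 0 on object, >=1 outside
  s <- array(0, dim(m))
  s[m] <- -(d_in[m] - 0.5)    # boundary object voxel: -0.5
  s[!m] <- d_out[!m] - 0.5    # adjacent background voxel: +0.5
  rs <- seq(-r_max_vox, r_max_vox, by = 0.25)
  sv <- as.numeric(s)
  # partial-volume counting: a voxel contributes the fraction of its unit
  # depth the offset surface has passed, which removes the lattice-shell
  # staircase from V(r) without biasing the low-order derivatives
  Vr <- vapply(rs, function(r) sum(pmin(pmax(r - sv + 0.5, 0), 1)),
               numeric(1))
  fit <- stats::lm(Vr ~ rs + I(rs^2) + I(rs^3))
  b <- coef(fit)
  V0 <- b[[1]]
  S <- b[[2]]
  Sp <- 2 * b[[3]]
  if (S <= 0) stop("degenerate surface estimate")
  6 * V0 * Sp / S^2
}

#' Local trabecular thickness at a crack site
#'
#' Mean of the envelope's direct thickness map over envelope voxels within
#' one crack-width (at least 50 um) of the crack centroid.
#'
#' @param env_thickness 3D numeric array from [thickness_map()] of the
#'   envelope (um).
#' @param envelope a [binary_mask()] of the envelope.
#' @param centroid_um crack centroid (um, `(y, x, z)` order).
#' @param cr_w_um crack width (um); the site window radius is
#'   `max(cr_w_um, 50)`.
#' @return `Tb.Th.lo` in micrometres.
#' @export
local_trabecular_thickness <- function(env_thickness, envelope, centroid_um,
                                       cr_w_um) {
  sel <- site_window(envelope, centroid_um, cr_w_um)
  vals <- env_thickness[sel$index][envelope$data[sel$index]]
  if (!length(vals))
    stop("site error: no envelope voxel within the site window")
  mean(vals)
}

# indices of grid voxels within the site window (ball of radius
# max(cr_w_um, 50 um) about the centroid); returns linear indices plus the
# window geometry
site_window <- function(envelope, centroid_um, cr_w_um, min_radius_um = 50) {
  v <- envelope$voxel_size_um
  d <- dim(envelope$data)
  r_um <- max(cr_w_um, min_radius_um)
  r <- r_um / v
  c_vox <- centroid_um / v + 0.5
  lo <- pmax(1, floor(c_vox - r))
  hi <- pmin(d, ceiling(c_vox + r))
  if (any(lo > hi)) stop("site error: window falls outside the grid")
  gy <- lo[1]:hi[1]; gx <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  dist2 <- outer(outer((gy - c_vox[1])^2, (gx - c_vox[2])^2, `+`),
                 (gz - c_vox[3])^2, `+`)
  inside <- dist2 <= r^2
  idx <- expand.grid(i = gy, j = gx, k = gz)
  lin <- (idx$k - 1) * d[1] * d[2] + (idx$j - 1) * d[1] + idx$i
  list(index = lin[as.vector(inside)], lo = lo, hi = hi, radius_vox = r,
       center_vox = c_vox)
}

#' Local trabecular shape at a crack site
#'
#' Classifies the trabecula hosting a crack as `rod`, `plate` or
#' `junction` from the envelope geometry inside the site window: the
#' number of separate envelope patches on the window's spherical shell
#' counts the branches leaving the site (3 or more = junction); otherwise
#' the window moments decide between rod (elongated, `a1/a2 >= 2`) and
#' plate.
#'
#' @param envelope a [binary_mask()] of the envelope.
#' @param centroid_um crack centroid (um).
#' @param cr_w_um crack width (um).
#' @return one of `"rod"`, `"plate"`, `"junction"`.
#' @export
trabecular_shape <- function(envelope, centroid_um, cr_w_um) {
  sel <- site_window(envelope, centroid_um, cr_w_um)
  v <- envelope$voxel_size_um
  d <- dim(envelope$data)
  win <- array(FALSE, d)
  win[sel$index] <- TRUE
  site <- win & envelope$data
  if (!any(site)) stop("site error: empty site window")

  # branches: envelope patches on the shell of the window
  c_vox <- sel$center_vox
  idx <- which(win, arr.ind = TRUE)
  dist <- sqrt((idx[, 1] - c_vox[1])^2 + (idx[, 2] - c_vox[2])^2 +
               (idx[, 3] - c_vox[3])^2)
  shell_sel <- idx[dist >= sel$radius_vox - 1.5, , drop = FALSE]
  shell <- array(FALSE, d)
  shell[shell_sel] <- TRUE
  shell <- shell & envelope$data
  n_patch <- 0
  if (any(shell)) {
    lo <- sel$lo; hi <- sel$hi
    sub <- shell[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    lab <- cpp_label3d(as.logical(sub), as.integer(dim(sub)), 26L)
    n_patch <- attr(lab, "n_labels")
  }
  if (n_patch >= 3) return("junction")
  fit <- fit_ellipsoid(which(site, arr.ind = TRUE), v)
  a <- fit$semi_axes_um
  if (a[2] > 0 && a[1] / a[2] >= 2 && (a[3] == 0 || a[2] / pmax(a[3], 1e-9) < 2))
    return("rod")
  "plate"
}

#' Specimen-level morphometric report
#'
#' Aggregates the porosity records into the specimen summary: bone volume
#' `BV` (envelope minus porosities, i.e. the bone phase), total volume
#' `TV`, `BV/TV`, `SMI`, microcrack and lacuna counts and densities
#' (`Cr.Dn = Cr.N / BV`, `La.Dn = La.N / BV`, in 1/mm^3 -- each object
#' counted once regardless of how many slices it crosses), and means/SDs
#' (population SD) of the microcrack dimensions.
#'
#' @param records porosity records from [quantify_porosities()].
#' @param envelope a [binary_mask()] of the trabecular envelope.
#' @param porosity a [binary_mask()] of all segmented porosities.
#' @param smi optional precomputed SMI (computed from the envelope when
#'   `NULL`; set `FALSE` to skip).
#' @return a list of class `specimen_report`.
#' @export
specimen_metrics <- function(records, envelope, porosity, smi = NULL) {
  v <- envelope$voxel_size_um
  vox_mm3 <- (v * 1e-3)^3
  tv <- prod(dim(envelope$data)) * vox_mm3
  bv <- (sum(envelope$data) - sum(porosity$data & envelope$data)) * vox_mm3
  if (bv <= 0) stop("density error: BV is zero")
  cracks <- records[records$class == "microcrack", , drop = FALSE]
  lacunae <- records[records$class == "lacuna", , drop = FALSE]
  pop_sd <- function(x) if (length(x) > 0) sqrt(mean((x - mean(x))^2)) else NA_real_
  smi_val <- if (isFALSE(smi)) NA_real_
             else if (is.null(smi)) compute_smi(envelope) else smi
  structure(list(
    bv_mm3 = bv, tv_mm3 = tv, bvtv = bv / tv, smi = smi_val,
    cr_n = nrow(cracks), la_n = nrow(lacunae),
    other_n = sum(records$class == "other"),
    cr_dn_mm3 = nrow(cracks) / bv, la_dn_mm3 = nrow(lacunae) / bv,
    cr_le_mean_um = if (nrow(cracks)) mean(cracks$cr_le_um) else NA_real_,
    cr_le_sd_um = pop_sd(cracks$cr_le_um),
    cr_w_mean_um = if (nrow(cracks)) mean(cracks$cr_w_um) else NA_real_,
    cr_w_sd_um = pop_sd(cracks$cr_w_um),
    cr_th_mean_um = if (nrow(cracks)) mean(cracks$cr_th_um) else NA_real_),
    class = "specimen_report")
}

#' @export
print.specimen_report <- function(x, ...) {
  cat("specimen report\n")
  cat(sprintf("  BV/TV %.3f (BV %.3g mm^3, TV %.3g mm^3), SMI %.2f\n",
              x$bvtv, x$bv_mm3, x$tv_mm3, x$smi))
  cat(sprintf("  Cr.N %d (Cr.Dn %.2f /mm^3), La.N %d (La.Dn %.1f /mm^3), other %d\n",
              x$cr_n, x$cr_dn_mm3, x$la_n, x$la_dn_mm3, x$other_n))
  if (x$cr_n > 0)
    cat(sprintf("  Cr.Le %.1f +/- %.1f um, Cr.W %.1f +/- %.1f um, Cr.Th %.2f um\n",
                x$cr_le_mean_um, x$cr_le_sd_um, x$cr_w_mean_um,
                x$cr_w_sd_um, x$cr_th_mean_um))
  invisible(x)
}

#' Porosity records on the printed reporting scale
#'
#' Mirrors the field's table conventions: per-object metrics in um, volume
#' in 1e-6 mm^3, surface in 1e-3 mm^2, both truncated (not rounded) to two
#' decimals as in the published tables.
#'
#' @param records records from [quantify_porosities()].
#' @return data.frame with columns `Cr.Le`, `Cr.W`, `Cr.Th`, `Cr.V`,
#'   `Cr.S`, `class` (and `Tb.Th.lo`, `shape` when present).
#' @export
format_record_table <- function(records) {
  trunc2 <- function(x) trunc(x * 100) / 100
  out <- data.frame(
    label = records$label,
    class = records$class,
    Cr.Le = round(records$cr_le_um),
    Cr.W = round(records$cr_w_um),
    Cr.Th = round(records$cr_th_um, 2),
    Cr.V = trunc2(records$cr_v_um3 * 1e-3),         # um^3 -> 1e-6 mm^3
    Cr.S = trunc2(records$cr_s_um2 * 1e-6 * 1e3))   # um^2 -> 1e-3 mm^2
  if (!is.null(records$tbthlo_um)) out$Tb.Th.lo <- round(records$tbthlo_um)
  if (!is.null(records$shape)) out$shape <- records$shape
  out
}
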
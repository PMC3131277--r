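#' Grey-level micro-CT volume
#'
#' A `grey_volume` is a 3D numeric array of attenuation values (arbitrary
#' units) with an isotropic physical voxel size. Storage follows the natural
#' slice-stack layout in R: `dim = c(ny, nx, nz)`, so `vol$data[, , k]` is
#' slice `k` (slice 1 = bottom of the scan). The physical centre of voxel
#' `(i, j, k)` (1-based) is `(i - 0.5, j - 0.5, k - 0.5) * voxel_size_um +
#' origin_um`.
#'
#' @param data 3D numeric array (y, x, z).
#' @param voxel_size_um positive scalar, isotropic voxel edge length in
#'   micrometres (1.4 um for the synchrotron acquisitions this package
#'   targets).
#' @param origin_um numeric 3-vector, physical offset in micrometres.
#' @return An object of class `grey_volume`.
#' @export
grey_volume <- function(data, voxel_size_um, origin_um = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L))
    stop("all three grid dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  if (length(origin_um) != 3L)
    stop("`origin_um` must have length 3")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         origin_um = as.numeric(origin_um)),
    class = "grey_volume")
}

#' Binary voxel mask
#'
#' Boolean field aligned to a [grey_volume()]; used for the bone phase, the
#' trabecular envelope and the segmented porosities.
#'
#' @param data 3D logical array.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param semantics one of `"bone"`, `"envelope"`, `"porosity"`, `"generic"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_size_um,
                        semantics = c("generic", "bone", "envelope",
                                      "porosity")) {
  semantics <- match.arg(semantics)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         semantics = semantics),
    class = "binary_mask")
}

#' Labelled component map
#'
#' Non-negative integer field; 0 is background, components are labelled
#' 1..N in deterministic scan order.
#'
#' @param data 3D integer array.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param n_labels number of components; defaults to `max(data)`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(data, voxel_size_um, n_labels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "integer"
  if (is.null(n_labels)) n_labels <- if (length(data)) max(data) else 0L
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         n_labels = as.integer(n_labels)),
    class = "label_map")
}

#' @export
print.grey_volume <- function(x, ...) {
  d <- dim(x$data)
  ext <- d * x$voxel_size_um
  cat(sprintf(
    "grey_volume: %d x %d x %d voxels, %.4g um/voxel (%.3g x %.3g x %.3g um)\n",
    d[1], d[2], d[3], x$voxel_size_um, ext[1], ext[2], ext[3]))
  cat(sprintf("  grey range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("binary_mask (%s): %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              x$semantics, d[1], d[2], d[3], sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_map: %d x %d x %d voxels, %d components\n",
              d[1], d[2], d[3], x$n_labels))
  invisible(x)
}

#' @export
dim.grey_volume <- function(x) dim(x$data)
#' @export
dim.binary_mask <- function(x) dim(x$data)
#' @export
dim.label_map <- function(x) dim(x$data)

vol_dims <- function(x) dim(x$data)

check_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volume dimensions differ")
  if (abs(a$voxel_size_um - b$voxel_size_um) > 1e-9)
    stop("voxel sizes differ")
  invisible(TRUE)
}

#' Physical voxel-centre coordinates of a voxel index matrix
#'
#' @param idx n x 3 matrix of 1-based array indices (i, j, k).
#' @param voxel_size_um voxel size in micrometres.
#' @return n x 3 matrix of coordinates in micrometres.
#' @export
voxel_centers_um <- function(idx, voxel_size_um) {
  (idx - 0.5) * voxel_size_um
}
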
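#' Read a grey-level volume, mask or label map from disk
#'
#' Supported layouts: a multi-page TIFF stack, a directory of single-page
#' TIFF slices (sorted by file name, slice 1 = bottom), or an MHD-style
#' raw volume (`.mhd` text header + `.raw` binary). TIFF stacks written by
#' [write_volume()] carry a YAML sidecar (`<file>.yml`) holding the voxel
#' size and the value scaling; without a sidecar the voxel size must be
#' supplied through `meta`.
#'
#' @param path file or directory to read.
#' @param meta optional list with at least `voxel_size_um`, used when no
#'   sidecar metadata is found.
#' @return a [grey_volume()], [binary_mask()] or [label_map()] depending on
#'   the stored kind (plain TIFF stacks without sidecar are read as grey
#'   volumes).
#' @export
read_volume <- function(path, meta = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("metadata error: no TIFF slices in ", path)
    sidecar <- file.path(path, "volume.yml")
    sc <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
    # without a sidecar, raw integer sample values are the natural reading
    slices <- lapply(files, function(f)
      tiff::readTIFF(f, as.is = is.null(sc)))
    return(assemble_tiff_volume(slices, sc, meta, names = basename(files)))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") return(read_mhd(path))
  if (ext %in% c("tif", "tiff")) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".yml")
    sc <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
    slices <- tiff::readTIFF(path, all = TRUE, as.is = is.null(sc))
    if (!is.list(slices)) slices <- list(slices)
    return(assemble_tiff_volume(slices, sc, meta,
                                names = as.character(seq_along(slices))))
  }
  stop("format error: unsupported volume format: ", path)
}

assemble_tiff_volume <- function(slices, sc, meta, names) {
  shapes <- vapply(slices, function(s) dim(s)[1:2], integer(2))
  ref <- shapes[, 1]
  bad <- which(shapes[1, ] != ref[1] | shapes[2, ] != ref[2])
  if (length(bad))
    stop(sprintf("format error: slice %s has shape %dx%d, expected %dx%d",
                 names[bad[1]], shapes[1, bad[1]], shapes[2, bad[1]],
                 ref[1], ref[2]))
  arr <- array(0, dim = c(ref[1], ref[2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]

  voxel <- if (!is.null(sc$voxel_size_um)) sc$voxel_size_um
           else if (!is.null(meta$voxel_size_um)) meta$voxel_size_um
           else stop("metadata error: voxel size not found (no sidecar, no meta)")
  if (!is.null(sc$dim) && !identical(as.integer(unlist(sc$dim)), dim(arr)))
    stop("metadata error: sidecar dimensions do not match stored grid")
  kind <- if (!is.null(sc$kind)) sc$kind else "grey"
  # sidecar-written stacks hold values in [0, 1]; undo the recorded scaling
  if (!is.null(sc$scale)) arr <- arr * sc$scale + (sc$offset %||% 0)
  if (isTRUE(sc$integer_values)) arr <- round(arr)

  switch(kind,
    mask  = binary_mask(arr > 0, voxel, semantics = sc$semantics %||% "generic"),
    label = label_map(array(as.integer(round(arr)), dim(arr)), voxel),
    grey_volume(arr, voxel))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume, mask or label map to disk
#'
#' TIFF output (`.tif`/`.tiff`): grey volumes with non-negative integer
#' values are stored as 8- or 16-bit integer pages; other grey values are
#' rescaled to a 32-bit float stack (scale and offset recorded in the YAML
#' sidecar). Masks are stored 8-bit with values 0/255. Label maps are stored
#' 16-bit when the label count allows, otherwise as scaled 32-bit pages;
#' label counts beyond 32-bit float integer capacity (2^24) raise a capacity
#' error. MHD output (`.mhd`): raw binary with exact dtypes (double for grey,
#' uint8 for masks, uint32 for labels).
#'
#' @param vol a [grey_volume()], [binary_mask()] or [label_map()].
#' @param path output path ending in `.tif`, `.tiff` or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") return(write_mhd(vol, path))
  if (!ext %in% c("tif", "tiff"))
    stop("format error: unsupported output format: ", path)

  arr <- vol$data
  sidecar <- list(dim = dim(arr), voxel_size_um = vol$voxel_size_um)

  if (inherits(vol, "binary_mask")) {
    bits <- 8L
    sidecar$kind <- "mask"
    sidecar$semantics <- vol$semantics
    sidecar$scale <- 255
    stored <- lapply(seq_len(dim(arr)[3]), function(k) (arr[, , k] * 1.0))
  } else if (inherits(vol, "label_map")) {
    mx <- max(arr)
    sidecar$kind <- "label"
    if (mx <= 65535) {
      bits <- 16L
      sidecar$scale <- 65535
      stored <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 65535)
    } else if (mx < 2^24) {
      bits <- 32L
      sidecar$scale <- mx
      stored <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / mx)
    } else {
      stop("capacity error: label count ", mx,
           " exceeds 32-bit float integer capacity")
    }
    sidecar$integer_values <- TRUE
  } else {
    sidecar$kind <- "grey"
    intlike <- all(arr >= 0) && all(arr == round(arr))
    if (intlike && max(arr) <= 255) {
      bits <- 8L
      sidecar$scale <- 255
      stored <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 255)
      sidecar$integer_values <- TRUE
    } else if (intlike && max(arr) <= 65535) {
      bits <- 16L
      sidecar$scale <- 65535
      stored <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 65535)
      sidecar$integer_values <- TRUE
    } else {
      bits <- 32L
      lo <- min(arr); hi <- max(arr)
      scale <- if (hi > lo) hi - lo else 1
      sidecar$scale <- scale
      sidecar$offset <- lo
      stored <- lapply(seq_len(dim(arr)[3]),
                       function(k) (arr[, , k] - lo) / scale)
    }
  }
  tiff::writeTIFF(stored, path, bits.per.sample = bits, compression = "none")
  yaml::write_yaml(sidecar, paste0(tools::file_path_sans_ext(path), ".yml"))
  invisible(path)
}

# ---- MHD-style raw volumes ------------------------------------------------

mhd_types <- c(grey = "MET_DOUBLE", mask = "MET_UCHAR", label = "MET_UINT")

write_mhd <- function(vol, path) {
  arr <- vol$data
  kind <- if (inherits(vol, "binary_mask")) "mask"
          else if (inherits(vol, "label_map")) "label" else "grey"
  if (kind == "label" && max(arr) > 2^32 - 1)
    stop("capacity error: label count exceeds uint32 capacity")
  rawfile <- paste0(tools::file_path_sans_ext(path), ".raw")
  d <- dim(arr)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementType = %s", mhd_types[[kind]]),
    sprintf("ElementSpacing = %g %g %g", vol$voxel_size_um,
            vol$voxel_size_um, vol$voxel_size_um),
    "ElementByteOrderMSB = False",
    sprintf("VolumeKind = %s", kind),
    sprintf("ElementDataFile = %s", basename(rawfile)))
  writeLines(hdr, path)
  con <- file(rawfile, "wb")
  on.exit(close(con))
  switch(kind,
    grey  = writeBin(as.numeric(arr), con, size = 8, endian = "little"),
    mask  = writeBin(as.integer(arr) * 255L, con, size = 1, endian = "little"),
    label = writeBin(as.integer(arr), con, size = 4, endian = "little"))
  invisible(path)
}

read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  get <- function(k) vals[match(k, keys)]
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  if (length(d) != 3 || any(is.na(d)))
    stop("metadata error: bad DimSize in ", path)
  sp <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  if (any(is.na(sp))) stop("metadata error: bad ElementSpacing in ", path)
  if (max(sp) - min(sp) > 1e-9)
    stop("metadata error: anisotropic voxels are not supported")
  etype <- get("ElementType")
  kind <- get("VolumeKind")
  if (is.na(kind)) kind <- "grey"
  rawfile <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(d)
  con <- file(rawfile, "rb")
  on.exit(close(con))
  vals <- switch(etype,
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    MET_FLOAT  = readBin(con, "numeric", n, size = 4, endian = "little"),
    MET_UCHAR  = readBin(con, "integer", n, size = 1, signed = FALSE,
                         endian = "little"),
    MET_USHORT = readBin(con, "integer", n, size = 2, signed = FALSE,
                         endian = "little"),
    MET_UINT   = readBin(con, "integer", n, size = 4, endian = "little"),
    stop("metadata error: unsupported ElementType ", etype))
  if (length(vals) != n)
    stop("format error: raw file shorter than DimSize implies")
  arr <- array(vals, dim = d)
  switch(kind,
    mask  = binary_mask(arr > 0, sp[1]),
    label = label_map(arr, sp[1]),
    grey_volume(arr, sp[1]))
}

#' Merge two vertically adjacent scans
#'
#' High-resolution acquisitions cover the specimen height with two scans
#' overlapping by a fixed number of slices (280 um = 200 slices at 1.4 um);
#' the merged volume spans `nz_lower + nz_upper - overlap_slices` slices.
#' Within the overlap the grey values are blended with a linear ramp from
#' the lower to the upper scan (or the lower scan is kept verbatim with
#' `blend = "take-lower"`).
#'
#' @param lower,upper [grey_volume()]s with identical x/y dimensions and
#'   voxel size; `lower` is the bottom scan.
#' @param overlap_slices number of shared slices, `0 < overlap <= min(nz)`.
#' @param blend `"ramp"` (default) or `"take-lower"`.
#' @return the merged [grey_volume()].
#' @export
merge_scans <- function(lower, upper, overlap_slices,
                        blend = c("ramp", "take-lower")) {
  blend <- match.arg(blend)
  if (abs(lower$voxel_size_um - upper$voxel_size_um) > 1e-9)
    stop("unit error: voxel sizes differ")
  dl <- dim(lower$data); du <- dim(upper$data)
  if (dl[1] != du[1] || dl[2] != du[2])
    stop("dimension error: x/y extents differ")
  overlap_slices <- as.integer(overlap_slices)
  if (overlap_slices <= 0 || overlap_slices > min(dl[3], du[3]))
    stop("overlap_slices must satisfy 0 < overlap <= min z-extent")

  nz <- dl[3] + du[3] - overlap_slices
  out <- array(0, dim = c(dl[1], dl[2], nz))
  out[, , seq_len(dl[3] - overlap_slices)] <-
    lower$data[, , seq_len(dl[3] - overlap_slices)]
  if (overlap_slices < du[3])
    out[, , (dl[3] + 1):nz] <-
      upper$data[, , (overlap_slices + 1):du[3]]
  ov_lo <- dl[3] - overlap_slices + 1
  for (t in seq_len(overlap_slices)) {
    w <- if (blend == "ramp" && overlap_slices > 1)
           (t - 1) / (overlap_slices - 1) else 0
    if (blend == "take-lower") w <- 0
    out[, , ov_lo + t - 1] <-
      (1 - w) * lower$data[, , ov_lo + t - 1] + w * upper$data[, , t]
  }
  grey_volume(out, lower$voxel_size_um, lower$origin_um)
}
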
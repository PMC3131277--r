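# Bone segmentation, planarity enhancement and porosity extraction.

#' Inter-class-variance (Otsu) threshold
#'
#' @param x numeric vector or array of grey values.
#' @param n_bins histogram resolution.
#' @return the threshold maximising the between-class variance.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop("thresholding error: constant image has no bimodal histogram")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma_b)
  thr <- breaks[k + 1L]
  # bimodality guard: both classes must hold a non-trivial share
  w <- w0[k]
  if (w < 0.001 || w > 0.999)
    stop("thresholding error: histogram is effectively unimodal")
  thr
}

#' Segment the bone phase by thresholding
#'
#' Mineralised bone is much brighter than marrow in the reconstructed
#' volumes, so a single global threshold separates the phases; `"auto"`
#' maximises the inter-class variance of the grey histogram.
#'
#' @param vol a [grey_volume()].
#' @param threshold numeric threshold or `"auto"`.
#' @return a [binary_mask()] with semantics `"bone"`; the threshold used is
#'   stored in the `threshold` element.
#' @export
segment_bone <- function(vol, threshold = "auto") {
  thr <- if (identical(threshold, "auto")) otsu_threshold(vol$data)
         else as.numeric(threshold)
  m <- binary_mask(vol$data >= thr, vol$voxel_size_um, semantics = "bone")
  m$threshold <- thr
  m
}

#' Compute the trabecular bone envelope
#'
#' Morphological closing with a ball whose radius exceeds the largest
#' expected crack thickness, followed by filling of cavities completely
#' enclosed in bone. The envelope is the filled solid of the trabeculae:
#' bone plus all internal porosities (cracks, lacunae). It always contains
#' the bone mask.
#'
#' @param bone a [binary_mask()] of the bone phase.
#' @param closing_radius_um ball radius in micrometres (default 14 um,
#'   an order of magnitude above typical crack thickness).
#' @return a [binary_mask()] with semantics `"envelope"`.
#' @export
compute_envelope <- function(bone, closing_radius_um = 14) {
  r <- closing_radius_um / bone$voxel_size_um
  env <- close_ball(bone$data, r)
  env <- fill_cavities(env)
  env <- env | bone$data
  binary_mask(env, bone$voxel_size_um, semantics = "envelope")
}

#' Hessian-based planarity field
#'
#' Enhances thin dark planar structures (microcracks) inside the bone
#' envelope. The volume is Gaussian-smoothed at scale `sigma_um` and the
#' Hessian matrix is evaluated at every envelope voxel; with eigenvalues
#' ordered `|h1| >= |h2| >= |h3|`, a dark sheet in bright material gives a
#' large positive `h1` (grey minimum across the sheet) with `|h2|, |h3|`
#' small. The sheetness response `h1 * exp(-(h2^2 + h3^2) / (2 (alpha h1)^2))`
#' is normalised to `[0, 1]` over the volume; the unit plane normal is the
#' eigenvector of `h1`. Voxels outside the envelope score 0.
#'
#' @param vol a [grey_volume()] (pre-processed).
#' @param sigma_um Gaussian derivative scale; must be at least one voxel
#'   (default 2.1 um = 1.5 voxels at 1.4 um).
#' @param envelope optional [binary_mask()] restricting the support.
#' @param alpha eigenvalue-ratio selectivity (dimensionless, default 0.5).
#' @param normals return per-voxel plane normals (memory-heavy on large
#'   volumes).
#' @return a `planarity_field`: list with `score` (3D array in `[0, 1]`)
#'   and, if requested, `normal` (4D array `c(dim, 3)`).
#' @export
planarity_field <- function(vol, sigma_um = 2.1, envelope = NULL,
                            alpha = 0.5, normals = TRUE) {
  if (sigma_um < vol$voxel_size_um)
    stop("config error: sigma_um must be at least one voxel size")
  d <- dim(vol$data)
  s <- sigma_um / vol$voxel_size_um
  sm <- array(cpp_gaussian_blur(vol$data, as.integer(d), rep(s, 3)), d)
  res <- cpp_sheet_filter(sm, as.integer(d), alpha, normals)
  score <- array(res$score, d)
  if (!is.null(envelope)) score[!envelope$data] <- 0
  # robust normalisation: a single extreme response must not flatten the
  # rest of the volume, so scale by a high quantile and clip
  pos <- score[score > 0]
  if (length(pos)) {
    q <- stats::quantile(pos, 0.999, names = FALSE)
    if (q > 0) score <- pmin(score / q, 1)
    score <- array(score, d)
  }
  out <- list(score = score, sigma_um = sigma_um,
              voxel_size_um = vol$voxel_size_um)
  if (normals) {
    nrm <- array(0, c(d, 3))
    nrm[, , , 1] <- res$nx; nrm[, , , 2] <- res$ny; nrm[, , , 3] <- res$nz
    out$normal <- nrm
  }
  structure(out, class = "planarity_field")
}

#' @export
print.planarity_field <- function(x, ...) {
  d <- dim(x$score)
  cat(sprintf("planarity_field: %d x %d x %d, scale %.3g um, %d voxels > 0.5\n",
              d[1], d[2], d[3], x$sigma_um, sum(x$score > 0.5)))
  invisible(x)
}

#' Planarity-guided nonlinear filter
#'
#' Bilateral-type filter in which each voxel is replaced by a weighted mean
#' of its neighbours, with weights the product of a spatial Gaussian, a
#' Gaussian in planarity-score difference and a Gaussian in grey difference.
#' Crack voxels share high, similar planarity scores and similar (dark)
#' grey values, so they are averaged together: noise on the crack is
#' suppressed without bleeding grey values across the crack-bone interface,
#' which raises the crack contrast-to-noise ratio. With both bandwidths set
#' to `Inf` the filter degenerates to plain (truncated-kernel) Gaussian
#' smoothing.
#'
#' @param vol a [grey_volume()].
#' @param field a `planarity_field` from [planarity_field()].
#' @param spatial_radius_um neighbourhood radius (default 2.8 um = 2 voxels).
#' @param planarity_bandwidth Gaussian bandwidth on score differences
#'   (scores live in `[0, 1]`; default 0.2).
#' @param intensity_bandwidth Gaussian bandwidth on grey differences, in
#'   grey units; default half the overall grey standard deviation.
#' @param envelope optional [binary_mask()]; voxels outside it pass through
#'   unfiltered (saves time on large volumes).
#' @return filtered [grey_volume()].
#' @export
planarity_guided_filter <- function(vol, field, spatial_radius_um = 2.8,
                                    planarity_bandwidth = 0.2,
                                    intensity_bandwidth = NULL,
                                    envelope = NULL) {
  if (spatial_radius_um <= 0 || planarity_bandwidth <= 0)
    stop("config error: radii and bandwidths must be positive")
  d <- dim(vol$data)
  if (is.null(intensity_bandwidth))
    intensity_bandwidth <- stats::sd(vol$data) / 2
  if (intensity_bandwidth <= 0) intensity_bandwidth <- Inf
  rad <- spatial_radius_um / vol$voxel_size_um
  mask <- if (is.null(envelope)) array(TRUE, d) else envelope$data
  out <- cpp_guided_bilateral(vol$data, field$score, as.logical(mask),
                              as.integer(d), rad, rad / 2,
                              planarity_bandwidth, intensity_bandwidth)
  grey_volume(array(out, d), vol$voxel_size_um, vol$origin_um)
}

#' Porosity response field
#'
#' Converts the (enhanced) grey volume into a response in `[0, 1]` in which
#' porosities are high. Candidate voxels are envelope voxels whose grey
#' falls below the bone threshold (scaled by the bone-marrow contrast) OR
#' whose planarity score is high; this catches partial-volume crack voxels
#' whose grey is only slightly depressed but whose local geometry is
#' clearly planar.
#'
#' @param enhanced a [grey_volume()] (after [planarity_guided_filter()]).
#' @param envelope a [binary_mask()] of the trabecular envelope.
#' @param bone_threshold numeric bone threshold (grey units).
#' @param field optional `planarity_field`; its score is folded into the
#'   response as `max(darkness, score)`.
#' @return 3D numeric array in `[0, 1]`, zero outside the envelope.
#' @export
porosity_response <- function(enhanced, envelope, bone_threshold,
                              field = NULL) {
  g <- enhanced$data
  below <- g < bone_threshold
  marrow <- if (any(below)) mean(g[below]) else min(g)
  contrast <- max(bone_threshold - marrow, 1e-9)
  resp <- (bone_threshold - g) / contrast
  resp[resp < 0] <- 0
  resp[resp > 1] <- 1
  if (!is.null(field)) resp <- pmax(resp, field$score)
  resp[!envelope$data] <- 0
  array(resp, dim(g))
}

#' Hysteresis thresholding
#'
#' Voxels with response above `high` are seeds; voxels above `low` are
#' candidates. The segmented mask consists of every candidate voxel
#' connected (26-connectivity) to at least one seed. With `low == high`
#' this is plain thresholding.
#'
#' @param response 3D numeric array (high = porosity), e.g. from
#'   [porosity_response()].
#' @param low,high thresholds with `low <= high`.
#' @param envelope optional [binary_mask()] restricting candidates.
#' @param voxel_size_um voxel size for the returned mask (taken from
#'   `envelope` when given).
#' @return a [binary_mask()] with semantics `"porosity"`.
#' @export
hysteresis_segment <- function(response, low, high, envelope = NULL,
                               voxel_size_um = NULL) {
  if (low > high) stop("config error: low threshold exceeds high threshold")
  if (inherits(response, "grey_volume")) {
    voxel_size_um <- response$voxel_size_um
    response <- response$data
  }
  if (!is.null(envelope)) {
    voxel_size_um <- envelope$voxel_size_um
    cand <- response >= low & envelope$data
  } else cand <- response >= low
  if (is.null(voxel_size_um)) voxel_size_um <- 1
  d <- dim(response)
  lab <- array(cpp_label3d(as.logical(cand), as.integer(d), 26L), d)
  seeds <- unique(lab[response >= high & cand])
  seeds <- seeds[seeds > 0]
  binary_mask(array(lab %in% seeds, d), voxel_size_um,
              semantics = "porosity")
}

#' Label porosities by 3D connected components
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26 (default 26: thin tilted sheets
#'   disconnect under 6-connectivity).
#' @return a [label_map()] with deterministic scan-order labels 1..N.
#' @export
label_porosities <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  d <- dim(mask$data)
  lab <- cpp_label3d(as.logical(mask$data), as.integer(d),
                     as.integer(connectivity))
  label_map(array(lab, d), mask$voxel_size_um,
            n_labels = attr(lab, "n_labels"))
}

#' Full porosity segmentation chain
#'
#' Runs bone thresholding, envelope computation, planarity enhancement,
#' planarity-guided filtering, hysteresis segmentation and labelling with
#' the default (fewer than five) exposed tuning parameters: bone threshold,
#' planarity scale, hysteresis low/high, spatial radius.
#'
#' Components that are mostly open to the envelope exterior (surface
#' concavities sealed by the morphological closing, not internal
#' porosities) are discarded when `drop_open` is `TRUE`.
#'
#' @param vol a pre-processed [grey_volume()].
#' @param config segmentation configuration, see
#'   [default_pipeline_config()]`$segmentation`.
#' @return list with `bone`, `envelope` ([binary_mask()]s), `field`
#'   (`planarity_field`), `enhanced` ([grey_volume()]), `porosity`
#'   ([binary_mask()]), `labels` ([label_map()]), `bone_threshold`, and a
#'   `stage_counts` log of voxel counts per stage.
#' @export
segment_porosities <- function(vol, config = list()) {
  cfg <- utils::modifyList(default_pipeline_config()$segmentation, config)
  bone <- segment_bone(vol, cfg$bone_threshold)
  envelope <- compute_envelope(bone, cfg$closing_radius_um)
  field <- planarity_field(vol, cfg$planarity_sigma_um, envelope = envelope,
                           normals = FALSE)
  enhanced <- planarity_guided_filter(
    vol, field, spatial_radius_um = cfg$spatial_radius_um,
    planarity_bandwidth = cfg$planarity_bandwidth, envelope = envelope)
  resp <- porosity_response(enhanced, envelope, bone$threshold, field)
  poro <- hysteresis_segment(resp, cfg$hysteresis_low, cfg$hysteresis_high,
                             envelope = envelope)
  if (isTRUE(cfg$drop_open)) poro <- drop_open_porosities(poro, envelope)
  # partial-volume crack voxels may sit above the bone threshold; the final
  # bone phase is the thresholded mask minus the segmented porosities
  bone$data <- bone$data & !poro$data
  labels <- label_porosities(poro, cfg$connectivity)
  list(bone = bone, envelope = envelope, field = field, enhanced = enhanced,
       response = resp, porosity = poro, labels = labels,
       bone_threshold = bone$threshold,
       stage_counts = c(bone = sum(bone$data), envelope = sum(envelope$data),
                        porosity = sum(poro$data),
                        components = labels$n_labels))
}

# Discard components that are mostly within 2 voxels of the envelope
# exterior: these are sealed surface concavities, not internal porosities.
drop_open_porosities <- function(porosity, envelope, shell_vox = 2,
                                 max_fraction = 0.6) {
  d <- dim(porosity$data)
  shell <- distance_to(!envelope$data) <= shell_vox
  lab <- array(cpp_label3d(as.logical(porosity$data), as.integer(d), 26L), d)
  n <- max(lab)
  if (n == 0) return(porosity)
  tot <- tabulate(lab[lab > 0], n)
  insh <- tabulate(lab[lab > 0 & shell], n)
  open_ids <- which(insh / tot > max_fraction)
  if (length(open_ids))
    porosity$data <- porosity$data & !(lab %in% open_ids)
  porosity
}
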
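# Shared fixture builders and independent brute-force oracles.
# Oracles are deliberately naive (loops, exhaustive search) and never share
# code with the implementation they check.

make_ball <- function(n = 31, radius = 10.5, center = rep((n + 1) / 2, 3)) {
  idx <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
  r <- sqrt((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
            (idx[, 3] - center[3])^2)
  out <- array(FALSE, c(n, n, n))
  out[idx[r <= radius, , drop = FALSE]] <- TRUE
  out
}

make_slab <- function(nx = 32, nz = 9, z_on = 4:6) {
  out <- array(FALSE, c(nx, nx, nz))
  out[, , z_on] <- TRUE
  out
}

make_rod <- function(n = 41, len = 60, radius = 10.5) {
  ii <- which(matrix(TRUE, n, n), arr.ind = TRUE)
  rr <- sqrt((ii[, 1] - (n + 1) / 2)^2 + (ii[, 2] - (n + 1) / 2)^2)
  disk <- matrix(FALSE, n, n)
  disk[ii[rr <= radius, , drop = FALSE]] <- TRUE
  out <- array(FALSE, c(n, n, len))
  for (k in seq_len(len)) out[, , k] <- disk
  out
}

make_ellipsoid <- function(semi, dims = ceiling(2 * semi) + 5,
                           rot = diag(3)) {
  ctr <- (dims + 1) / 2 + 0.5   # off-lattice centre: unbiased digitisation
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  rel <- sweep(idx, 2, ctr) %*% rot
  keep <- (rel[, 1] / semi[1])^2 + (rel[, 2] / semi[2])^2 +
    (rel[, 3] / semi[3])^2 <= 1
  out <- array(FALSE, dims)
  out[idx[keep, , drop = FALSE]] <- TRUE
  out
}

# random connected blob: union of a few overlapping balls inside an n^3 grid
make_blob <- function(n = 32, n_balls = 4) {
  out <- array(FALSE, c(n, n, n))
  ctr0 <- runif(3, n * 0.3, n * 0.7)
  ctr <- ctr0
  for (b in seq_len(n_balls)) {
    r <- runif(1, 2.5, max(n / 5, 3))
    out <- out | make_ball(n, r, ctr)
    ctr <- pmin(pmax(ctr + runif(3, -r, r), 3), n - 3)
  }
  out
}

# --- brute-force second-order moment oracle --------------------------------
oracle_moments <- function(vox, voxel_size_um) {
  n <- nrow(vox)
  ctr <- c(0, 0, 0)
  for (i in seq_len(n)) ctr <- ctr + (vox[i, ] - 0.5) * voxel_size_um
  ctr <- ctr / n
  M <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    dx <- (vox[i, ] - 0.5) * voxel_size_um - ctr
    M <- M + outer(dx, dx)
  }
  unname(M / n)
}

# --- exhaustive maximal-inscribed-sphere thickness oracle ------------------
# r(c) = distance to nearest background voxel centre (exhaustive);
# thickness(u) = max over centres c with |u - c| < r(c) of (2 r(c) - 1).
oracle_thickness <- function(mask) {
  d <- dim(mask)
  obj <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  n <- nrow(obj)
  r2 <- numeric(n)  # squared radius, exact in integers
  chunk <- 500L
  for (s in seq(1, n, chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(obj[s:e, 1], bg[, 1], `-`)^2 +
      outer(obj[s:e, 2], bg[, 2], `-`)^2 +
      outer(obj[s:e, 3], bg[, 3], `-`)^2
    r2[s:e] <- apply(d2, 1, min)
  }
  th <- numeric(n)
  for (s in seq(1, n, chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(obj[s:e, 1], obj[, 1], `-`)^2 +
      outer(obj[s:e, 2], obj[, 2], `-`)^2 +
      outer(obj[s:e, 3], obj[, 3], `-`)^2
    inside <- d2 < matrix(r2, e - s + 1L, n, byrow = TRUE)
    vals <- matrix(2 * sqrt(r2) - 1, e - s + 1L, n, byrow = TRUE)
    vals[!inside] <- 0
    th[s:e] <- pmax(apply(vals, 1, max), 1)
  }
  out <- array(0, d)
  out[obj] <- th
  out
}

# --- flood-fill hysteresis oracle ------------------------------------------
# BFS from every seed voxel through the candidate set, 26-connectivity.
oracle_hysteresis <- function(response, low, high) {
  d <- dim(response)
  cand <- response >= low
  seen <- array(FALSE, d)
  queue <- which(response >= high & cand)
  seen[queue] <- TRUE
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (length(queue)) {
    idx <- queue[1]
    queue <- queue[-1]
    k <- (idx - 1) %/% (d[1] * d[2])
    j <- ((idx - 1) %/% d[1]) %% d[2]
    i <- (idx - 1) %% d[1]
    for (t in seq_len(nrow(offs))) {
      ii <- i + offs[t, 1]; jj <- j + offs[t, 2]; kk <- k + offs[t, 3]
      if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
          kk < 0 || kk >= d[3]) next
      q <- ii + jj * d[1] + kk * d[1] * d[2] + 1
      if (cand[q] && !seen[q]) {
        seen[q] <- TRUE
        queue <- c(queue, q)
      }
    }
  }
  seen
}

# small two-phase grey volume with one axis-aligned dark sheet
make_sheet_volume <- function(n = 40, z_on = 20:21, bright = 200, dark = 50,
                              voxel = 1.4) {
  g <- array(bright, c(n, n, n))
  g[, , z_on] <- dark
  grey_volume(g, voxel)
}

# quick small phantom config for pipeline tests
small_phantom <- function(seed = 3, noise = 0, dimn = 96, n_cracks = 5,
                          n_lacunae = 6, thickness = c(2.8, 7)) {
  phantom_config(dim = rep(dimn, 3), n_cracks = n_cracks,
                 n_lacunae = n_lacunae,
                 crack_length_um = c(50, 100), crack_width_um = c(25, 60),
                 crack_thickness_um = thickness,
                 noise_sd = noise,
                 ring_amplitude = if (noise > 0) 3 else 0, seed = seed)
}
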
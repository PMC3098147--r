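# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (loops, stacks, dense scans) and
# independent of the package's own computational paths.

# component count by iterative stack-based flood fill, full connectivity
# (8 in 2D, 26 in 3D)
flood_fill_count <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  visited <- array(FALSE, d)
  count <- 0L
  fg <- which(mask)
  for (start in fg) {
    if (visited[start]) next
    count <- count + 1L
    stack <- list(arrayInd(start, d)[1, ])
    visited[start] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        qm <- matrix(q, 1)
        if (mask[qm] && !visited[qm]) {
          visited[qm] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  count
}

# naive per-ray stepping line integrals (fine step, bilinear samples);
# returns the (nz x ndet) line-integral frame at one angle
ray_sum_oracle <- function(vol, theta_deg, pitch, step = 0.25) {
  d <- dim(vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  ndet <- ny
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2; cdet <- (ndet - 1) / 2
  ns <- ceiling(sqrt(nx^2 + ny^2) / step) + 4
  svals <- (seq_len(ns) - (ns + 1) / 2) * step
  out <- matrix(0, nz, ndet)
  for (j in seq_len(ndet)) {
    t <- j - 1 - cdet
    xs <- cx - t * st + svals * ct
    ys <- cy + t * ct + svals * st
    acc <- numeric(nz)
    for (k in seq_len(ns)) {
      x0 <- floor(xs[k]); y0 <- floor(ys[k])
      if (x0 < -1 || x0 > nx - 1 || y0 < -1 || y0 > ny - 1) next
      fx <- xs[k] - x0; fy <- ys[k] - y0
      corners <- list(c(y0, x0, (1 - fy) * (1 - fx)),
                      c(y0 + 1, x0, fy * (1 - fx)),
                      c(y0, x0 + 1, (1 - fy) * fx),
                      c(y0 + 1, x0 + 1, fy * fx))
      for (cn in corners) {
        yy <- cn[1]; xx <- cn[2]; w <- cn[3]
        if (yy >= 0 && yy < ny && xx >= 0 && xx < nx && w > 0)
          acc <- acc + w * vol[, yy + 1, xx + 1]
      }
    }
    out[, j] <- acc * step
  }
  out * pitch / 1000
}

# exhaustive 256-candidate Otsu search (explicit loop over split bins)
otsu_oracle <- function(v, levels = 256L) {
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- hist(v, breaks = br, plot = FALSE)$counts
  mids <- (br[-1] + br[-(levels + 1)]) / 2
  best <- -1; bt <- NA_real_
  for (k in seq_len(levels - 1)) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):levels] * mids[(k + 1):levels]) / w1
    bcv <- w0 * w1 * (m0 - m1)^2
    if (bcv > best) { best <- bcv; bt <- br[k + 1] }
  }
  bt
}

# per-value binary-search histogram binning ([e_i, e_{i+1}), last bin closed)
binning_oracle <- function(sizes, edges) {
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (s in sizes) {
    if (s < edges[1] || s > edges[nb + 1]) next
    lo <- 1L; hi <- nb
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if (s >= edges[mid]) lo <- mid else hi <- mid - 1L
    }
    if (s == edges[nb + 1]) lo <- nb
    counts[lo] <- counts[lo] + 1L
  }
  counts
}

# brute-force signed distance to the mask surface: minimum distance to any
# boundary voxel center (mask voxels with a face-adjacent background voxel)
boundary_scan_distance <- function(points_nm, mask, pitch) {
  d <- dim(mask)
  idx <- which(mask)
  coord <- arrayInd(idx, d)
  offs <- rbind(diag(3), -diag(3))
  is_boundary <- vapply(seq_along(idx), function(i) {
    p <- coord[i, ]
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (any(q < 1) || any(q > d)) return(TRUE)
      if (!mask[matrix(q, 1)]) return(TRUE)
    }
    FALSE
  }, logical(1))
  bvox <- (coord[is_boundary, , drop = FALSE] - 0.5) * pitch
  apply(matrix(points_nm, ncol = 3), 1, function(p) {
    dmin <- sqrt(min(colSums((t(bvox) - p)^2)))
    inside <- mask[matrix(pmin(pmax(round(p / pitch + 0.5), 1), d), 1)]
    if (inside) -dmin else dmin
  })
}

# smooth random test volume: sum of separable Gaussian blobs
blob_volume <- function(shape, n_blobs = 6, seed = 1, amplitude = 0.05) {
  set.seed(seed)
  vol <- array(0, shape)
  ax <- lapply(shape, seq_len)
  for (b in seq_len(n_blobs)) {
    cen <- runif(3, 0.3, 0.7) * shape
    sig <- runif(3, 0.06, 0.12) * shape
    g <- lapply(1:3, function(k) exp(-(ax[[k]] - cen[k])^2 / (2 * sig[k]^2)))
    vol <- vol + runif(1, 0.5, 1) * amplitude *
      outer(outer(g[[1]], g[[2]]), g[[3]])
  }
  vol
}

# voxelized ball of a given diameter (in voxels) centered in a padded grid
render_ball <- function(d_vox, pad = 3L) {
  n <- ceiling(d_vox) + 2L * pad
  cen <- (n + 1) / 2
  ax <- seq_len(n) - cen
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  r2 <= (d_vox / 2)^2
}

# voxel coordinates of an (optionally rotated) solid ellipsoid with
# semi-axes in voxels
render_ellipsoid_coords <- function(semi, rot = diag(3), n = NULL) {
  n <- n %||% (2L * ceiling(max(semi)) + 5L)
  cen <- (n + 1) / 2
  grid <- as.matrix(expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n)))
  u <- sweep(grid, 2, rep(cen, 3)) %*% rot
  q <- (u[, 1] / semi[1])^2 + (u[, 2] / semi[2])^2 + (u[, 3] / semi[3])^2
  grid[q <= 1, , drop = FALSE]
}

# rotation matrix about the given axis (degrees)
rot3 <- function(axis, deg) {
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
    z = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, byrow = TRUE),
    y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, byrow = TRUE),
    x = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, byrow = TRUE)
  )
}

# bare projection_set constructor for noise/normalization tests
new_ps_for_test <- function(images, angles, pitch) {
  txmquant:::new_projection_set(images, angles, pitch, NULL)
}

# small but non-trivial phantom configuration used by several tests
mini_phantom_config <- function(n_clusters = 15L, seed = 1L, ...) {
  phantom_config(shape = c(48L, 64L, 64L), voxel_pitch = 30,
                 cell_semiaxes = c(600, 850, 850),
                 nucleus_semiaxes = c(250, 300, 300),
                 n_clusters = n_clusters,
                 size_meanlog = log(160) + 0.3^2, size_sdlog = 0.3,
                 seed = seed, ...)
}
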
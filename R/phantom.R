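#' Configuration for a synthetic single-cell phantom
#'
#' Describes a voxelized scene containing one ellipsoidal cell with an
#' ellipsoidal nucleus and a population of gold-dense nanoparticle clusters
#' placed in the cytoplasm. Clusters never enter the nucleus, matching the
#' nuclear-membrane exclusion consistently observed for internalized gold
#' nanoparticles. All lengths are in nanometres; attenuation coefficients are
#' in 1/micrometre at 8 keV.
#'
#' @param shape integer volume shape `c(nz, ny, nx)` in voxels.
#' @param voxel_pitch isotropic voxel edge, nm. The default (15 nm) is half
#'   the 30 nm lateral resolution of a zone-plate TXM, so resolution-limited
#'   clusters span at least two voxels.
#' @param cell_semiaxes,nucleus_semiaxes ellipsoid semi-axes `c(z, y, x)`, nm.
#' @param nucleus_offset nucleus center offset from the cell center, nm.
#' @param n_clusters number of clusters to place (may be 0).
#' @param size_meanlog,size_sdlog log-normal parameters of the cluster size
#'   (mean of the three full axes), nm. The default targets a distribution
#'   mode `exp(meanlog - sdlog^2)` of 140 nm.
#' @param placement `"uniform_cytoplasm"` (anywhere in the cytoplasm) or
#'   `"perinuclear_shell"` (centroid within `shell` of the nuclear surface).
#' @param shell `c(inner, outer)` signed distances from the nuclear surface,
#'   nm, used when `placement = "perinuclear_shell"`.
#' @param mu_cytoplasm,mu_nucleus,mu_cluster linear attenuation, 1/um. The
#'   defaults follow tabulated mass-attenuation values at 8 keV: ~0.001/um
#'   for hydrated organic material and ~0.4/um for solid gold.
#' @param axis_anisotropy clusters are ellipsoids with axes drawn uniformly
#'   within `1 +/- axis_anisotropy` of the sampled size (then rescaled so the
#'   axis mean equals the sampled size) and randomly oriented.
#' @param min_gap_vox minimum gap, in voxels, enforced between distinct
#'   clusters so the ground-truth catalog stays unambiguous under
#'   resolution-limited imaging.
#' @param max_attempts rejection-sampling attempts per cluster before a
#'   placement-capacity error is raised.
#' @param seed integer seed; all stochastic draws of the generator flow from
#'   this one seed.
#' @return an object of class `phantom_config`.
#' @seealso [build_phantom()]
#' @export
phantom_config <- function(shape = c(128L, 160L, 160L),
                           voxel_pitch = 15,
                           cell_semiaxes = c(800, 1050, 1050),
                           nucleus_semiaxes = c(350, 420, 420),
                           nucleus_offset = c(0, 0, 0),
                           n_clusters = 50L,
                           size_meanlog = log(140) + 0.35^2,
                           size_sdlog = 0.35,
                           placement = c("uniform_cytoplasm", "perinuclear_shell"),
                           shell = c(500, 1500),
                           mu_cytoplasm = 0.001,
                           mu_nucleus = 0.0015,
                           mu_cluster = 0.4,
                           axis_anisotropy = 0.15,
                           min_gap_vox = 1,
                           max_attempts = 1000L,
                           seed = 1L) {
  placement <- match.arg(placement)
  if (length(shape) != 3L || any(shape < 8))
    stop_txq("txq_config_error", "shape must be 3 voxel counts >= 8")
  if (!is.finite(voxel_pitch) || voxel_pitch <= 0)
    stop_txq("txq_config_error", "voxel_pitch must be positive")
  if (any(cell_semiaxes <= 0) || any(nucleus_semiaxes <= 0))
    stop_txq("txq_config_error", "ellipsoid semi-axes must be positive")
  if (n_clusters < 0)
    stop_txq("txq_config_error", "n_clusters must be >= 0")
  if (!is.finite(size_sdlog) || size_sdlog < 0)
    stop_txq("txq_config_error", "size_sdlog must be >= 0")
  if (placement == "perinuclear_shell" &&
      !(length(shell) == 2L && shell[1] > 0 && shell[2] > shell[1]))
    stop_txq("txq_config_error",
             "shell must satisfy 0 < inner < outer (got [%s])",
             paste(shell, collapse = ", "))
  if (any(c(mu_cytoplasm, mu_nucleus, mu_cluster) < 0))
    stop_txq("txq_config_error", "attenuation values must be >= 0")
  if (mu_cluster <= mu_cytoplasm)
    stop_txq("txq_config_error", "mu_cluster must exceed mu_cytoplasm")
  if (axis_anisotropy < 0 || axis_anisotropy >= 1)
    stop_txq("txq_config_error", "axis_anisotropy must be in [0, 1)")
  structure(list(
    shape = as.integer(shape), voxel_pitch = voxel_pitch,
    cell_semiaxes = cell_semiaxes, nucleus_semiaxes = nucleus_semiaxes,
    nucleus_offset = nucleus_offset, n_clusters = as.integer(n_clusters),
    size_meanlog = size_meanlog, size_sdlog = size_sdlog,
    placement = placement, shell = shell,
    mu_cytoplasm = mu_cytoplasm, mu_nucleus = mu_nucleus,
    mu_cluster = mu_cluster, axis_anisotropy = axis_anisotropy,
    min_gap_vox = min_gap_vox, max_attempts = as.integer(max_attempts),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Draw cluster sizes from the log-normal size model
#'
#' @param n number of clusters (>= 1).
#' @param meanlog,sdlog log-normal parameters; `sdlog = 0` gives the
#'   degenerate distribution at `exp(meanlog)`.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return `n` positive sizes, nm.
#' @export
sample_cluster_sizes <- function(n, meanlog, sdlog, seed = NULL) {
  if (!is.finite(n) || n < 1)
    stop_txq("txq_config_error", "n must be >= 1")
  if (!is.finite(meanlog))
    stop_txq("txq_config_error", "meanlog must be finite")
  if (!is.finite(sdlog) || sdlog < 0)
    stop_txq("txq_config_error", "sdlog must be >= 0")
  with_seed(seed, rlnorm(n, meanlog = meanlog, sdlog = sdlog))
}

# logical ellipsoid mask on the full grid (axis-aligned)
#' @noRd
ellipsoid_mask <- function(shape, pitch, center_nm, semiaxes_nm) {
  qz <- ((index_to_nm(seq_len(shape[1]), pitch) - center_nm[1]) / semiaxes_nm[1])^2
  qy <- ((index_to_nm(seq_len(shape[2]), pitch) - center_nm[2]) / semiaxes_nm[2])^2
  qx <- ((index_to_nm(seq_len(shape[3]), pitch) - center_nm[3]) / semiaxes_nm[3])^2
  outer(outer(qz, qy, "+"), qx, "+") <= 1
}

# Signed distance (nm) to the surface of a voxel mask: positive outside,
# negative inside, ~zero on surface voxels. Returns a vectorized evaluator
# over physical points. The exact Euclidean distance transform (with nearest
# site tracking) of the mask and of its complement gives point-to-region
# distances; half a voxel pitch is subtracted from each so the zero level
# sits on the voxel faces separating mask from background.
#' @noRd
surface_distance_fun <- function(mask, pitch) {
  d <- dim(mask)
  nd <- length(d)
  mask <- as.logical(mask)
  dim(mask) <- d
  sm <- cpp_sqedt_sites(mask, as.integer(d))
  sb <- cpp_sqedt_sites(!mask, as.integer(d))
  function(pts) {
    pts <- matrix(pts, ncol = nd)
    vi <- round(nm_to_index(pts, pitch))
    for (k in seq_len(nd)) vi[, k] <- pmin(pmax(vi[, k], 1), d[k])
    lin <- vi[, 1]
    mult <- 1
    for (k in seq_len(nd - 1)) {
      mult <- mult * d[k]
      lin <- lin + mult * (vi[, k + 1] - 1)
    }
    p_in <- index_to_nm(arrayInd(sm$site[lin] + 1L, d), pitch)
    p_bg <- index_to_nm(arrayInd(sb$site[lin] + 1L, d), pitch)
    d_in <- sqrt(rowSums((pts - p_in)^2))
    d_bg <- sqrt(rowSums((pts - p_bg)^2))
    inside <- mask[cbind(vi)]
    ifelse(inside, -pmax(d_bg - 0.5 * pitch, 0), pmax(d_in - 0.5 * pitch, 0))
  }
}

#' Signed distance from points to a nuclear surface
#'
#' Positive distances are outside the nucleus, negative inside, approximately
#' zero on surface voxels. The field is an exact Euclidean distance transform
#' of the voxel mask, interpolated at the query points, so values are accurate
#' to about one voxel pitch.
#'
#' @param points matrix of physical coordinates in nm, one row per point,
#'   columns ordered like the mask dimensions (z, y, x in 3D).
#' @param nucleus_mask logical 2D or 3D array; must contain at least one
#'   `TRUE` voxel.
#' @param voxel_pitch voxel edge, nm.
#' @return signed distances in nm, one per row of `points`.
#' @export
nucleus_distance <- function(points, nucleus_mask, voxel_pitch) {
  if (!any(nucleus_mask))
    stop_txq("txq_input_error", "nucleus mask is empty")
  if (all(nucleus_mask))
    stop_txq("txq_input_error", "nucleus mask has no surface (all TRUE)")
  fn <- surface_distance_fun(nucleus_mask, voxel_pitch)
  fn(matrix(points, ncol = length(dim(nucleus_mask))))
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
#' @noRd
random_rotation <- function(d = 3L) {
  qr_ <- qr(matrix(rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Build a synthetic cell phantom with ground-truth cluster catalog
#'
#' Renders the scene described by a [phantom_config()]: labels 0 (background),
#' 1 (cytoplasm), 2 (nucleus) and `2 + i` for cluster `i`. Clusters are
#' randomly oriented ellipsoids placed by rejection sampling so that every
#' cluster voxel lies in the cytoplasm (never in the nucleus) and distinct
#' clusters stay voxel-disjoint with at least `min_gap_vox` voxels between
#' them. The ground-truth catalog describes the *rendered* voxel geometry:
#' centroids, moment-equivalent ellipsoid axes, sizes (mean of the three
#' axes) and signed nucleus distances are all measured on the voxelized
#' cluster, not on the pre-voxelization request.
#'
#' @param config a [phantom_config()].
#' @return an object of class `cell_phantom` with elements `labels`
#'   (integer array), `attenuation` (1/um), `voxel_pitch` (nm), `truth`
#'   (data frame: `id, cz, cy, cx, ax1, ax2, ax3, size, nucleus_distance`,
#'   nm) and `config`.
#' @export
build_phantom <- function(config) {
  if (!inherits(config, "phantom_config"))
    stop_txq("txq_config_error", "config must be a phantom_config")
  with_seed(config$seed, build_phantom_impl(config))
}

#' @noRd
build_phantom_impl <- function(config) {
  shape <- config$shape
  pitch <- config$voxel_pitch
  center <- shape / 2 * pitch # volume center, nm (z, y, x)

  cell <- ellipsoid_mask(shape, pitch, center, config$cell_semiaxes)
  ncenter <- center + config$nucleus_offset
  nucleus <- ellipsoid_mask(shape, pitch, ncenter, config$nucleus_semiaxes)
  if (any(nucleus & !cell))
    stop_txq("txq_config_error", "nucleus ellipsoid is not inside the cell")
  if (!any(cell & !nucleus))
    stop_txq("txq_config_error", "cell has no cytoplasm")

  labels <- array(0L, shape)
  labels[cell] <- 1L
  labels[nucleus] <- 2L

  sdfun <- surface_distance_fun(nucleus, pitch)
  gap_nm <- config$min_gap_vox * pitch

  n <- config$n_clusters
  truth <- data.frame(
    id = integer(0), cz = numeric(0), cy = numeric(0), cx = numeric(0),
    ax1 = numeric(0), ax2 = numeric(0), ax3 = numeric(0),
    size = numeric(0), nucleus_distance = numeric(0)
  )

  if (n > 0) {
    # candidate centers: cytoplasm voxels, restricted to the shell when asked
    cand <- which(labels == 1L)
    cand_idx <- arrayInd(cand, shape)
    if (config$placement == "perinuclear_shell") {
      s <- sdfun(index_to_nm(cand_idx, pitch))
      keep <- s >= config$shell[1] & s <= config$shell[2]
      cand_idx <- cand_idx[keep, , drop = FALSE]
      if (nrow(cand_idx) == 0L)
        stop_txq("txq_placement_error",
                 "perinuclear shell [%g, %g] nm contains no cytoplasm voxels",
                 config$shell[1], config$shell[2])
    }

    sizes <- sort(rlnorm(n, config$size_meanlog, config$size_sdlog),
                  decreasing = TRUE) # place big clusters first
    rows <- vector("list", n)

    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(config$max_attempts)) {
        ci <- cand_idx[sample.int(nrow(cand_idx), 1L), ]
        cen <- index_to_nm(ci, pitch) + runif(3, -0.5, 0.5) * pitch
        f <- runif(3, 1 - config$axis_anisotropy, 1 + config$axis_anisotropy)
        semi <- sizes[i] * (f / mean(f)) / 2
        rot <- random_rotation()

        vox <- voxelize_ellipsoid(shape, pitch, cen, semi, rot, gap_nm)
        if (is.null(vox) || nrow(vox$inside) == 0L) next
        lab_in <- labels[vox$inside]
        if (any(lab_in != 1L)) next
        if (any(labels[vox$margin] >= 3L)) next

        centroid <- colMeans(index_to_nm(vox$inside, pitch))
        d <- sdfun(rbind(centroid))
        if (d <= 0) next
        if (config$placement == "perinuclear_shell" &&
            (d < config$shell[1] || d > config$shell[2])) next

        fit <- fit_ellipsoid(vox$inside, pitch)
        labels[vox$inside] <- 2L + i
        rows[[i]] <- data.frame(
          id = i, cz = centroid[1], cy = centroid[2], cx = centroid[3],
          ax1 = fit[1], ax2 = fit[2], ax3 = fit[3],
          size = mean(fit), nucleus_distance = d
        )
        placed <- TRUE
        break
      }
      if (!placed)
        stop_txq("txq_placement_error",
                 paste0("could not place cluster %d of %d (size %.0f nm) after ",
                        "%d attempts; the %s region is too small"),
                 i, n, sizes[i], config$max_attempts, config$placement)
    }
    truth <- do.call(rbind, rows)
  }

  attenuation <- array(0, shape)
  attenuation[labels == 1L] <- config$mu_cytoplasm
  attenuation[labels == 2L] <- config$mu_nucleus
  attenuation[labels >= 3L] <- config$mu_cluster

  structure(list(
    labels = labels, attenuation = attenuation, voxel_pitch = pitch,
    truth = truth, config = config
  ), class = "cell_phantom")
}

# voxel index sets of a rotated ellipsoid: `inside` (the cluster itself) and
# `margin` (ellipsoid grown by gap_nm, used for the inter-cluster gap test);
# returns NULL when the bounding box leaves the grid
#' @noRd
voxelize_ellipsoid <- function(shape, pitch, center_nm, semi_nm, rot, gap_nm) {
  r_out <- max(semi_nm) + gap_nm
  lo <- floor(nm_to_index(center_nm - r_out, pitch))
  hi <- ceiling(nm_to_index(center_nm + r_out, pitch))
  if (any(lo < 1) || any(hi > shape)) return(NULL)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  grid <- as.matrix(expand.grid(z = iz, y = iy, x = ix))
  p <- sweep(index_to_nm(grid, pitch), 2, center_nm)
  u <- p %*% rot # body-frame coordinates
  q_in <- (u[, 1] / semi_nm[1])^2 + (u[, 2] / semi_nm[2])^2 +
    (u[, 3] / semi_nm[3])^2
  sg <- semi_nm + gap_nm
  q_mg <- (u[, 1] / sg[1])^2 + (u[, 2] / sg[2])^2 + (u[, 3] / sg[3])^2
  list(inside = grid[q_in <= 1, , drop = FALSE],
       margin = grid[q_mg <= 1, , drop = FALSE])
}

#' Cell and nucleus masks of a phantom
#'
#' @param phantom a `cell_phantom`.
#' @return logical array: the whole cell (cytoplasm + nucleus + clusters) for
#'   `cell_mask()`, the nucleus for `phantom_nucleus_mask()`.
#' @export
cell_mask <- function(phantom) phantom$labels >= 1L

#' @rdname cell_mask
#' @export
phantom_nucleus_mask <- function(phantom) phantom$labels == 2L

#' @export
print.cell_phantom <- function(x, ...) {
  cat("<cell_phantom>\n")
  cat(sprintf("  volume: %s voxels @ %g nm (%.2f x %.2f x %.2f um)\n",
              paste(dim(x$labels), collapse = " x "), x$voxel_pitch,
              dim(x$labels)[1] * x$voxel_pitch / 1e3,
              dim(x$labels)[2] * x$voxel_pitch / 1e3,
              dim(x$labels)[3] * x$voxel_pitch / 1e3))
  cat(sprintf("  clusters: %d (%s placement)\n", nrow(x$truth),
              x$config$placement))
  if (nrow(x$truth) > 0)
    cat(sprintf("  size: %.0f-%.0f nm (median %.0f); nucleus distance %.0f-%.0f nm\n",
                min(x$truth$size), max(x$truth$size), stats::median(x$truth$size),
                min(x$truth$nucleus_distance), max(x$truth$nucleus_distance)))
  invisible(x)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  str <- utils::capture.output(utils::str(unclass(x), give.attr = FALSE))
  cat(paste0(" ", str[-1]), sep = "\n")
  invisible(x)
}
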
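#' Reproducible grey-value threshold (Otsu)
#'
#' The interactive grey-value selection used when segmenting TXM images by
#' eye is replaced here by Otsu's rule: the threshold maximizing the
#' between-class variance of a 256-bin histogram over the observed grey-value
#' range. When a mask is supplied only the masked pixels enter the histogram,
#' which keeps the empty background from dominating the statistics.
#'
#' @param x numeric matrix or array of grey values with at least two
#'   distinct values.
#' @param mask optional logical array of the same shape restricting the
#'   histogram.
#' @param levels number of histogram bins.
#' @return the threshold grey value.
#' @export
auto_threshold <- function(x, mask = NULL, levels = 256L) {
  vals <- if (is.null(mask)) as.numeric(x) else as.numeric(x[mask])
  vals <- vals[is.finite(vals)]
  rng <- range(vals)
  if (length(vals) < 2L || diff(rng) <= 0)
    stop_txq("txq_threshold_error",
             "cannot threshold a (near-)constant image: degenerate histogram")
  levels <- as.integer(levels)
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- as.numeric(tabulate(findInterval(vals, br, rightmost.closed = TRUE,
                                             all.inside = TRUE),
                                nbins = levels))
  mids <- (br[-1] + br[-(levels + 1L)]) / 2
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  m1 <- cumsum(counts * mids)
  mu1 <- m1 / w1
  mu2 <- (m1[levels] - m1) / w2
  bcv <- w1 * w2 * (mu1 - mu2)^2 # between-class variance, split after bin k
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv[-levels]) # first maximum: ties break low
  br[k + 1L]
}

#' Segment nanoparticle clusters by grey-value thresholding
#'
#' Thresholds the image (2D) or volume (3D) and labels connected components
#' of the cluster-side mask: 8-connectivity in 2D, 26-connectivity in 3D.
#' Components smaller than `min_size` pixels/voxels are below the instrument
#' resolution, and are discarded from the label map but counted.
#'
#' @param x numeric matrix (2D image) or 3D array (volume).
#' @param threshold grey value separating clusters from everything else.
#' @param polarity `"below"` when clusters are darker than the threshold
#'   (absorbing clusters in transmission images) or `"above"` when they are
#'   brighter (dense clusters in attenuation volumes).
#' @param min_size smallest component retained, in pixels/voxels.
#' @return an object of class `segmentation`: `labels` (integer array with
#'   components labeled `1..K`), `threshold`, `polarity`, `connectivity`,
#'   `px_counts` (pixels per retained label), `n_components`,
#'   `n_discarded` (sub-resolution components) and `ndim`.
#' @export
segment_clusters <- function(x, threshold, polarity = c("above", "below"),
                             min_size = 2L) {
  polarity <- match.arg(polarity)
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% 2:3))
    stop_txq("txq_input_error", "x must be a 2D matrix or 3D array")
  mask <- if (polarity == "below") x < threshold else x > threshold
  labels <- cpp_label_components(as.logical(mask), as.integer(d))
  k0 <- max(labels)
  counts <- if (k0 > 0) tabulate(labels[labels > 0L], nbins = k0) else integer(0)
  keep <- which(counts >= min_size)
  lut <- integer(k0 + 1L)
  lut[keep + 1L] <- seq_along(keep)
  labels <- array(lut[labels + 1L], d)
  structure(list(
    labels = labels, threshold = threshold, polarity = polarity,
    connectivity = if (length(d) == 2L) 8L else 26L,
    px_counts = counts[keep], n_components = length(keep),
    n_discarded = k0 - length(keep), min_size = as.integer(min_size),
    ndim = length(d)
  ), class = "segmentation")
}

# population second-central-moment matrix of pixel/voxel index coordinates,
# with the 1/12 per-cell variance of a unit square/cube added on the diagonal
#' @noRd
pixel_moments <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  cc <- sweep(coords, 2, colMeans(coords))
  crossprod(cc) / n + diag(1 / 12, ncol(coords))
}

#' Moment-equivalent ellipse axes of a 2D component
#'
#' Full axis lengths (descending) of the ellipse sharing the second central
#' moments of the pixel set, using the solid-ellipse convention
#' `axis = 4 * sqrt(eigenvalue)`. Each pixel contributes the 1/12 variance of
#' a unit square, so degenerate pixel lines keep a positive minor axis. A
#' single-pixel component is reported with both axes equal to the pixel pitch
#' and flagged sub-resolution.
#'
#' @param coords integer matrix of pixel indices `(row, col)`, one per pixel.
#' @param pixel_pitch pixel edge, nm.
#' @return two axes in nm, descending, with attribute `sub_resolution`.
#' @export
fit_ellipse <- function(coords, pixel_pitch) {
  coords <- matrix(coords, ncol = 2)
  if (nrow(coords) < 2L)
    return(structure(c(pixel_pitch, pixel_pitch), sub_resolution = TRUE))
  ev <- eigen(pixel_moments(coords), symmetric = TRUE, only.values = TRUE)$values
  structure(sort(4 * sqrt(pmax(ev, 0)) * pixel_pitch, decreasing = TRUE),
            sub_resolution = FALSE)
}

#' Moment-equivalent ellipsoid axes of a 3D component
#'
#' Full axis lengths (descending) from the eigenvalues of the second
#' central moment tensor of the voxel set, using the solid-ellipsoid
#' convention `axis = 2 * sqrt(5) * sqrt(eigenvalue)` (a homogeneous
#' ellipsoid of semi-axis `a` has variance `a^2 / 5` along that axis).
#' Voxels contribute the 1/12 variance of a unit cube. Components that are
#' coplanar (or smaller than 3 voxels) have their smallest axes floored at
#' one voxel pitch and are flagged degenerate.
#'
#' @param coords integer matrix of voxel indices `(z, y, x)`, one per voxel.
#' @param voxel_pitch voxel edge, nm.
#' @return three axes in nm, descending, with attributes `degenerate` and
#'   `sub_resolution`.
#' @export
fit_ellipsoid <- function(coords, voxel_pitch) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n < 2L)
    return(structure(rep(voxel_pitch, 3), degenerate = TRUE,
                     sub_resolution = TRUE))
  M <- pixel_moments(coords)
  raw <- M - diag(1 / 12, 3)
  degen <- min(eigen(raw, symmetric = TRUE, only.values = TRUE)$values) < 1e-9
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  ax <- sort(2 * sqrt(5) * sqrt(pmax(ev, 0)) * voxel_pitch, decreasing = TRUE)
  if (degen) ax <- pmax(ax, voxel_pitch)
  structure(ax, degenerate = degen, sub_resolution = n < 3L)
}

#' Scalar cluster size from fitted axes
#'
#' The size of a cluster is the arithmetic mean of its fitted ellipse (2D)
#' or ellipsoid (3D) full axis lengths.
#'
#' @param axes two or three positive axis lengths, nm.
#' @return size in nm.
#' @export
cluster_size <- function(axes) {
  axes <- as.numeric(axes)
  if (!(length(axes) %in% 2:3) || any(!is.finite(axes)) || any(axes <= 0))
    stop_txq("txq_input_error", "axes must be 2 or 3 positive lengths")
  mean(axes)
}

#' Measure every segmented cluster
#'
#' Builds one record per labeled component: centroid (nm, voxel-center
#' convention), moment-equivalent ellipse/ellipsoid axes, scalar size and
#' pixel/voxel count. 2D records carry `dim = "2D"` and `cz = ax3 = NA`; the
#' two dimensionalities are never mixed silently.
#'
#' @param segmentation a [segment_clusters()] result.
#' @param pixel_pitch pixel/voxel edge, nm.
#' @return data frame with columns `id, dim, cz, cy, cx, ax1, ax2, ax3,
#'   size_nm, nucleus_distance_nm, inside_cell, area_or_volume_px,
#'   sub_resolution`.
#' @export
measure_clusters <- function(segmentation, pixel_pitch) {
  stopifnot(inherits(segmentation, "segmentation"))
  lab <- segmentation$labels
  k <- segmentation$n_components
  nd <- segmentation$ndim
  empty <- data.frame(
    id = integer(0), dim = character(0), cz = numeric(0), cy = numeric(0),
    cx = numeric(0), ax1 = numeric(0), ax2 = numeric(0), ax3 = numeric(0),
    size_nm = numeric(0), nucleus_distance_nm = numeric(0),
    inside_cell = logical(0), area_or_volume_px = integer(0),
    sub_resolution = logical(0)
  )
  attr(empty, "pixel_pitch") <- pixel_pitch
  if (k == 0L) return(empty)

  fg <- which(lab > 0L)
  coords <- arrayInd(fg, dim(lab))
  by_label <- split(seq_along(fg), lab[fg])

  rows <- lapply(seq_len(k), function(i) {
    cc <- coords[by_label[[as.character(i)]], , drop = FALSE]
    cen <- index_to_nm(colMeans(cc), pixel_pitch)
    if (nd == 3L) {
      ax <- fit_ellipsoid(cc, pixel_pitch)
      data.frame(id = i, dim = "3D", cz = cen[1], cy = cen[2], cx = cen[3],
                 ax1 = ax[1], ax2 = ax[2], ax3 = ax[3],
                 size_nm = mean(ax), nucleus_distance_nm = NA_real_,
                 inside_cell = NA, area_or_volume_px = nrow(cc),
                 sub_resolution = isTRUE(attr(ax, "sub_resolution")))
    } else {
      ax <- fit_ellipse(cc, pixel_pitch)
      data.frame(id = i, dim = "2D", cz = NA_real_, cy = cen[1], cx = cen[2],
                 ax1 = ax[1], ax2 = ax[2], ax3 = NA_real_,
                 size_nm = mean(ax), nucleus_distance_nm = NA_real_,
                 inside_cell = NA, area_or_volume_px = nrow(cc),
                 sub_resolution = isTRUE(attr(ax, "sub_resolution")))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "pixel_pitch") <- pixel_pitch
  out
}

#' Keep only clusters clearly inside the cell
#'
#' Operationalizes the sampling rule that only particles clearly residing
#' inside a cell are quantified: a cluster is retained iff its centroid lies
#' in the cell mask and at least `min_fraction` of its pixels/voxels do.
#'
#' @param segmentation the [segment_clusters()] result the records came from.
#' @param records data frame from [measure_clusters()].
#' @param cell_mask logical array on the segmentation grid.
#' @param min_fraction containment fraction defining "clearly inside".
#' @return the retained records (with `inside_cell = TRUE`), with attribute
#'   `n_rejected`. An empty mask rejects everything with a warning.
#' @export
filter_inside_cell <- function(segmentation, records, cell_mask,
                               min_fraction = 0.9) {
  stopifnot(inherits(segmentation, "segmentation"))
  if (!identical(dim(cell_mask), dim(segmentation$labels)))
    stop_txq("txq_input_error", "cell mask is not aligned with the label grid")
  if (nrow(records) == 0L)
    return(structure(records, n_rejected = 0L))
  if (!any(cell_mask)) {
    warning("cell mask is empty: all clusters rejected", call. = FALSE)
    records$inside_cell <- FALSE
    return(structure(records[0, ], n_rejected = nrow(records)))
  }
  lab <- segmentation$labels
  k <- segmentation$n_components
  in_counts <- tabulate(lab[cell_mask & lab > 0L], nbins = k)
  frac <- in_counts / segmentation$px_counts

  pitch_cols <- if (segmentation$ndim == 3L) c("cz", "cy", "cx") else c("cy", "cx")
  cen_idx <- round(nm_to_index(as.matrix(records[, pitch_cols]),
                               attr_pitch(records, segmentation)))
  cen_idx <- pmin(pmax(cen_idx, 1L),
                  matrix(rep(dim(lab), each = nrow(cen_idx)), ncol = length(dim(lab))))
  centroid_in <- cell_mask[cen_idx]

  keep <- centroid_in & frac[records$id] >= min_fraction
  records$inside_cell <- keep
  structure(records[keep, , drop = FALSE], n_rejected = sum(!keep))
}

# pixel pitch is recoverable from any record: size_nm / size in px is not
# stored, so carry it via centroid round-trip; records are always produced
# by measure_clusters() on a known grid, so the caller passes it implicitly
# through the segmentation object when available
#' @noRd
attr_pitch <- function(records, segmentation) {
  p <- attr(records, "pixel_pitch")
  if (!is.null(p)) return(p)
  stop_txq("txq_input_error",
           "records carry no pixel_pitch attribute; use quantify helpers")
}

#' Discard segmented regions that are the nucleus, not particle clusters
#'
#' In stained specimens the nucleus itself is denser than the cytoplasm, so
#' with few or no particles present the grey-value threshold can segment
#' nuclear tissue instead of clusters. Internalized metal-nanoparticle
#' clusters never cross the nuclear membrane, which gives a structural test:
#' in 3D, a component with at least `frac` of its voxels inside the nucleus
#' mask is nuclear tissue; in 2D (where genuine clusters can legitimately
#' project onto the nucleus) a component is nuclear tissue when it covers at
#' least `frac` of the projected nucleus area.
#'
#' @param segmentation a [segment_clusters()] result.
#' @param records data frame from [measure_clusters()].
#' @param nucleus_mask logical array on the segmentation grid.
#' @param frac decision fraction.
#' @return records without nucleus regions, with attribute
#'   `n_nucleus_regions`.
#' @export
drop_nucleus_regions <- function(segmentation, records, nucleus_mask,
                                 frac = 0.5) {
  stopifnot(inherits(segmentation, "segmentation"))
  if (nrow(records) == 0L || !any(nucleus_mask))
    return(structure(records, n_nucleus_regions = 0L))
  lab <- segmentation$labels
  k <- segmentation$n_components
  overlap <- tabulate(lab[nucleus_mask & lab > 0L], nbins = k)
  is_nucleus <- if (segmentation$ndim == 3L) {
    overlap / segmentation$px_counts >= frac
  } else {
    overlap / sum(nucleus_mask) >= frac
  }
  keep <- !is_nucleus[records$id]
  structure(records[keep, , drop = FALSE],
            n_nucleus_regions = sum(!keep))
}

#' Fill nucleus-relative positions of measured clusters
#'
#' Signed centroid-to-nuclear-surface distance per cluster (positive outside
#' the nucleus), computed from the Euclidean distance transform of the
#' nucleus mask — the same geometry used by the phantom generator.
#'
#' @param records data frame from [measure_clusters()] (2D or 3D).
#' @param nucleus_mask logical array matching the records' dimensionality.
#' @param voxel_pitch grid pitch, nm.
#' @return `records` with `nucleus_distance_nm` filled, plus attribute
#'   `localization` (list: `mean`, `sd`, `frac_negative`). With an empty
#'   mask the distances are left `NA` and flagged `undefined`.
#' @export
localize_clusters <- function(records, nucleus_mask, voxel_pitch) {
  if (nrow(records) == 0L) {
    attr(records, "localization") <-
      list(mean = NA_real_, sd = NA_real_, frac_negative = NA_real_)
    return(records)
  }
  if (!any(nucleus_mask)) {
    warning("nucleus mask is empty: distances undefined", call. = FALSE)
    records$nucleus_distance_nm <- NA_real_
    attr(records, "localization") <-
      list(mean = NA_real_, sd = NA_real_, frac_negative = NA_real_,
           undefined = TRUE)
    return(records)
  }
  nd <- length(dim(nucleus_mask))
  cols <- if (nd == 3L) c("cz", "cy", "cx") else c("cy", "cx")
  pts <- as.matrix(records[, cols])
  d <- nucleus_distance(pts, nucleus_mask, voxel_pitch)
  records$nucleus_distance_nm <- d
  attr(records, "localization") <- list(
    mean = mean(d), sd = if (length(d) > 1) sd(d) else NA_real_,
    frac_negative = mean(d < 0)
  )
  records
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation>\n")
  cat(sprintf("  %dD, threshold %.4g (%s), %d-connectivity\n", x$ndim,
              x$threshold, x$polarity, x$connectivity))
  cat(sprintf("  %d component(s); %d sub-resolution component(s) discarded\n",
              x$n_components, x$n_discarded))
  invisible(x)
}
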
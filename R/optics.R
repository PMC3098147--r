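#' Forward-project a phantom into absorption-contrast transmission images
#'
#' Parallel-beam Beer-Lambert forward model: each frame is
#' `exp(-L(theta))` where `L(theta)` is the line integral of the attenuation
#' volume (1/um times path length in um) along ray direction `theta`. The
#' rotation axis is the z (first) array axis; at 0 degrees rays travel along
#' the x (third) axis and the detector column coordinate equals y. Rays are
#' integrated at one-voxel steps with bilinear in-plane interpolation.
#'
#' @param x a `cell_phantom` or a 3D attenuation array (1/um) with dimensions
#'   `(nz, ny, nx)`; slices must be square (`ny == nx`).
#' @param angles projection angles in degrees, strictly increasing, within
#'   `[0, 360)`.
#' @param pixel_pitch voxel/pixel pitch in nm (taken from the phantom when
#'   `x` is a `cell_phantom`). A vector of unequal pitches is rejected:
#'   only isotropic voxels are supported.
#' @param psf_fwhm optional Gaussian detector/optics blur, expressed as the
#'   full width at half maximum in nm and applied to each transmission frame
#'   (0 disables it).
#' @return an object of class `projection_set`: `images` is an
#'   `(nz, ndet, n_angles)` array of dimensionless transmission values,
#'   plus `angles` (degrees), `pixel_pitch` (nm) and `photon_count`
#'   (`NULL` for noiseless frames).
#' @export
project <- function(x, angles, pixel_pitch = NULL, psf_fwhm = 0) {
  if (inherits(x, "cell_phantom")) {
    vol <- x$attenuation
    pixel_pitch <- x$voxel_pitch
  } else {
    vol <- x
  }
  if (length(pixel_pitch) > 1) {
    if (diff(range(pixel_pitch)) > 1e-12)
      stop_txq("txq_geometry_error",
               "anisotropic voxel pitch is not supported")
    pixel_pitch <- pixel_pitch[1]
  }
  if (is.null(pixel_pitch) || pixel_pitch <= 0)
    stop_txq("txq_geometry_error", "pixel_pitch must be a positive scalar (nm)")
  d <- dim(vol)
  if (length(d) != 3L)
    stop_txq("txq_geometry_error", "attenuation volume must be 3D")
  if (d[2] != d[3])
    stop_txq("txq_geometry_error",
             "slices must be square (ny == nx); got %d x %d", d[2], d[3])
  if (any(vol < 0))
    stop_txq("txq_input_error", "attenuation must be non-negative")
  if (any(angles < 0 | angles >= 360))
    stop_txq("txq_input_error", "angles must lie in [0, 360)")

  raw <- cpp_project(as.numeric(vol), as.integer(d), angles * pi / 180)
  dim(raw) <- c(d[1], d[2], length(angles))
  frames <- exp(-raw * pixel_pitch / 1000) # path step in um

  if (psf_fwhm > 0) {
    sigma_px <- psf_fwhm / (2 * sqrt(2 * log(2))) / pixel_pitch
    if (sigma_px > 0.05)
      for (a in seq_len(dim(frames)[3]))
        frames[, , a] <- EBImage::gblur(frames[, , a], sigma = sigma_px)
  }

  new_projection_set(frames, angles, pixel_pitch, photon_count = NULL)
}

#' @noRd
new_projection_set <- function(images, angles, pixel_pitch, photon_count) {
  stopifnot(length(dim(images)) == 3L, dim(images)[3] == length(angles))
  structure(list(images = images, angles = angles, pixel_pitch = pixel_pitch,
                 photon_count = photon_count, geometry = "parallel"),
            class = "projection_set")
}

#' Apply Poisson photon-counting noise to transmission frames
#'
#' Each pixel with transmission `T` is replaced by
#' `Poisson(photon_count * T) / photon_count`, i.e. the flat-field-normalized
#' count recorded by a detector expecting `photon_count` photons per pixel in
#' the unobstructed background.
#'
#' @param projections a `projection_set`.
#' @param photon_count expected background photons per pixel (> 0).
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return a `projection_set` with noisy frames and `photon_count` recorded.
#' @export
add_photon_noise <- function(projections, photon_count, seed = NULL) {
  stopifnot(inherits(projections, "projection_set"))
  if (!is.finite(photon_count) || photon_count <= 0)
    stop_txq("txq_config_error", "photon_count must be > 0")
  imgs <- projections$images
  noisy <- with_seed(seed, {
    v <- rpois(length(imgs), lambda = photon_count * as.numeric(imgs))
    v / photon_count
  })
  dim(noisy) <- dim(imgs)
  new_projection_set(noisy, projections$angles, projections$pixel_pitch,
                     photon_count = photon_count)
}

#' Normalize a raw frame by the background illumination
#'
#' Element-wise division of a raw detector frame by a flat-field frame
#' recorded without the specimen.
#'
#' @param raw_frame,flatfield_frame numeric matrices of equal shape; the
#'   flat field must be strictly positive everywhere.
#' @return the normalized (dimensionless transmission) frame.
#' @export
normalize_background <- function(raw_frame, flatfield_frame) {
  if (!identical(dim(raw_frame), dim(flatfield_frame)))
    stop_txq("txq_input_error", "raw and flat-field frames differ in shape")
  nbad <- sum(flatfield_frame <= 0)
  if (nbad > 0)
    stop_txq("txq_normalization_error",
             "flat field has %d non-positive pixel(s)", nbad)
  raw_frame / flatfield_frame
}

#' Patchwork overlapping tiles into a mosaic frame
#'
#' Assembles several frames of the same pixel pitch into one mosaic, as done
#' when a whole cell exceeds the instrument field of view. Overlapping pixels
#' are averaged; uncovered pixels inside the mosaic bounds are reported.
#'
#' @param tiles list of numeric matrices.
#' @param offsets integer matrix (one row per tile) of 0-based `(row, col)`
#'   positions of each tile's upper-left pixel in the mosaic.
#' @return list with `mosaic` (uncovered pixels are `NA`) and `coverage`
#'   (integer tile count per pixel). A warning reports the number of
#'   uncovered gap pixels, if any.
#' @export
patchwork <- function(tiles, offsets) {
  stopifnot(is.list(tiles), length(tiles) >= 1)
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (nrow(offsets) != length(tiles))
    stop_txq("txq_input_error", "need one (row, col) offset per tile")
  if (any(offsets < 0))
    stop_txq("txq_input_error", "offsets must be non-negative")
  ext <- sapply(seq_along(tiles), function(i) offsets[i, ] + dim(tiles[[i]]))
  nr <- max(ext[1, ]); nc <- max(ext[2, ])
  acc <- matrix(0, nr, nc)
  cov <- matrix(0L, nr, nc)
  for (i in seq_along(tiles)) {
    ti <- tiles[[i]]
    r <- offsets[i, 1] + seq_len(nrow(ti))
    c_ <- offsets[i, 2] + seq_len(ncol(ti))
    acc[r, c_] <- acc[r, c_] + ti
    cov[r, c_] <- cov[r, c_] + 1L
  }
  gaps <- sum(cov == 0L)
  if (gaps > 0)
    warning(sprintf("patchwork mosaic has %d uncovered gap pixel(s)", gaps),
            call. = FALSE)
  mosaic <- acc / ifelse(cov > 0L, cov, NA_integer_)
  list(mosaic = mosaic, coverage = cov)
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images)
  cat("<projection_set>\n")
  cat(sprintf("  %d frame(s) of %d x %d px @ %g nm\n", d[3], d[1], d[2],
              x$pixel_pitch))
  cat(sprintf("  angles: %g..%g deg (%d); %s\n", min(x$angles), max(x$angles),
              length(x$angles),
              if (is.null(x$photon_count)) "noiseless"
              else sprintf("%g photons/px", x$photon_count)))
  invisible(x)
}

#' @export
plot.projection_set <- function(x, frame = 1L, ...) {
  f <- x$images[, , frame]
  image(t(f)[, nrow(f):1], col = grey.colors(256), asp = 1, axes = FALSE,
        main = sprintf("projection @ %g deg", x$angles[frame]), ...)
  invisible(x)
}
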
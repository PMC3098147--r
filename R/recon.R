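#' Convert transmission frames to per-slice sinograms
#'
#' Applies `-log` element-wise and reorders axes to
#' `(slice, angle, detector column)`. Non-positive or sub-floor pixels (which
#' can occur in photon-starved noisy frames) are clamped to `floor` and
#' counted.
#'
#' @param projections a `projection_set`.
#' @param floor smallest transmission admitted before taking the logarithm.
#' @return an object of class `sinogram_set` with `sinograms`
#'   (`(nz, n_angles, ndet)` array of line integrals), `angles`,
#'   `pixel_pitch` and `n_clamped`.
#' @export
sinogramify <- function(projections, floor = 1e-6) {
  stopifnot(inherits(projections, "projection_set"))
  imgs <- projections$images
  n_clamped <- sum(imgs < floor)
  sino <- -log(pmax(imgs, floor))
  sino <- aperm(sino, c(1, 3, 2)) # (slice, angle, detector column)
  structure(list(sinograms = sino, angles = projections$angles,
                 pixel_pitch = projections$pixel_pitch,
                 n_clamped = n_clamped, floor = floor),
            class = "sinogram_set")
}

# ramp-filter sinogram rows along the detector axis (frequency domain,
# zero-padded to a power of two); sino is (nz, nA, ndet)
#' @noRd
ramp_filter <- function(sino, pixel_pitch, apodization = "none") {
  d <- dim(sino)
  ndet <- d[3]
  dt <- pixel_pitch / 1000 # um
  N <- 2^ceiling(log2(2 * ndet))
  freq <- c(0:(N / 2), -((N / 2 - 1):1)) / (N * dt) # cycles/um
  H <- abs(freq)
  if (apodization == "hann") {
    fmax <- 1 / (2 * dt)
    H <- H * 0.5 * (1 + cos(pi * freq / fmax))
  }

  m <- d[1] * d[2]
  P <- matrix(aperm(sino, c(3, 1, 2)), nrow = ndet, ncol = m)
  out <- matrix(0, ndet, m)
  chunk <- max(1L, floor(2^22 / N)) # cap working memory of the FFT
  for (s in seq(1L, m, by = chunk)) {
    cols <- s:min(s + chunk - 1L, m)
    Pp <- rbind(P[, cols, drop = FALSE], matrix(0, N - ndet, length(cols)))
    Q <- Re(stats::mvfft(stats::mvfft(Pp) * H, inverse = TRUE)) / N
    out[, cols] <- Q[seq_len(ndet), , drop = FALSE]
  }
  aperm(array(out, c(ndet, d[1], d[2])), c(2, 3, 1))
}

#' Filtered back-projection of a limited-angle sinogram set
#'
#' Slice-by-slice parallel-beam filtered back-projection with a ramp filter
#' (optional Hann apodization for noisy data) over exactly the provided
#' angles: no angle in-painting is attempted, so a series spanning less than
#' 180 degrees keeps its missing wedge. Negative reconstructed values are
#' retained; clamping them would bias downstream threshold selection.
#'
#' @param x a `sinogram_set`, a `projection_set` (converted via
#'   [sinogramify()]), or a raw `(nz, n_angles, ndet)` sinogram array.
#' @param angles,pixel_pitch required when `x` is a raw array.
#' @param apodization `"none"` (default, preserves quantitative values) or
#'   `"hann"` (damps high-frequency noise).
#' @return an object of class `recon_volume` with `volume`
#'   (`(nz, ndet, ndet)` array, 1/um), `voxel_pitch` (nm), `angles`,
#'   `coverage` (see [coverage_report()]) and `method`.
#' @export
reconstruct_fbp <- function(x, angles = NULL, pixel_pitch = NULL,
                            apodization = c("none", "hann")) {
  apodization <- match.arg(apodization)
  if (inherits(x, "projection_set")) x <- sinogramify(x)
  if (inherits(x, "sinogram_set")) {
    sino <- x$sinograms
    angles <- x$angles
    pixel_pitch <- x$pixel_pitch
  } else {
    sino <- x
    if (is.null(angles) || is.null(pixel_pitch))
      stop_txq("txq_input_error",
               "angles and pixel_pitch are required with a raw sinogram array")
  }
  if (length(dim(sino)) != 3L || dim(sino)[2] != length(angles))
    stop_txq("txq_input_error",
             "sinogram must be (nz, n_angles, ndet) matching angles")
  if (length(unique(angles)) < 2L)
    stop_txq("txq_angles_error",
             "at least 2 distinct angles are required for reconstruction")

  filt <- ramp_filter(sino, pixel_pitch, apodization)
  d <- dim(filt)
  vol <- cpp_backproject(as.numeric(filt), as.integer(d), angles * pi / 180)
  dtheta <- mean(diff(sort(unique(angles)))) * pi / 180
  vol <- vol * dtheta
  dim(vol) <- c(d[1], d[3], d[3])

  structure(list(volume = vol, voxel_pitch = pixel_pitch, angles = angles,
                 coverage = coverage_report(angles),
                 method = paste0("fbp/ramp",
                                 if (apodization == "hann") "+hann" else "")),
            class = "recon_volume")
}

#' Summarize the angular coverage of a projection series
#'
#' The effective coverage of a regularly sampled series is its span plus one
#' angular step (180 frames at 1 degree starting from 0 cover the half
#' circle); a series is flagged `limited_angle` when that effective coverage
#' falls short of 180 degrees and the reconstruction has a missing wedge.
#'
#' @param angles projection angles, degrees.
#' @return list with `span`, `largest_gap`, `step` (modal spacing),
#'   `effective`, `n_angles` and `limited_angle`.
#' @export
coverage_report <- function(angles) {
  a <- sort(unique(angles))
  span <- max(a) - min(a)
  gaps <- diff(a)
  largest_gap <- if (length(gaps)) max(gaps) else NA_real_
  step <- if (length(gaps)) {
    tg <- table(signif(gaps, 10))
    as.numeric(names(tg)[which.max(tg)])
  } else NA_real_
  effective <- if (is.na(step)) span else span + step
  list(span = span, largest_gap = largest_gap, step = step,
       effective = effective, n_angles = length(a),
       limited_angle = isTRUE(effective < 180 - 1e-9))
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$volume)
  cat("<recon_volume>\n")
  cat(sprintf("  %d x %d x %d voxels @ %g nm (%s)\n", d[1], d[2], d[3],
              x$voxel_pitch, x$method))
  cat(sprintf("  angular coverage: %g deg over %d angles%s\n",
              x$coverage$effective, x$coverage$n_angles,
              if (x$coverage$limited_angle) " [limited angle]" else ""))
  invisible(x)
}

#' @export
plot.recon_volume <- function(x, slice = NULL, ...) {
  slice <- slice %||% (dim(x$volume)[1] %/% 2)
  f <- x$volume[slice, , ]
  image(t(f)[, nrow(f):1], col = grey.colors(256), asp = 1, axes = FALSE,
        main = sprintf("reconstruction, slice z = %d", slice), ...)
  invisible(x)
}
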
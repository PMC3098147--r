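# File I/O: multi-page 32-bit float TIFF stacks with YAML sidecars, 16-bit
# label stacks, and the CSV catalog/report formats.
#
# TIFF sample values are stored in [0, 1]; quantitative stacks therefore go
# through an affine map value = offset + scale * stored, recorded in the
# sidecar so every stack round-trips losslessly (to float32 precision).

#' @noRd
tiff_scale <- function(arr) {
  rng <- range(arr, finite = TRUE)
  offset <- rng[1]
  scale <- if (diff(rng) > 0) diff(rng) else 1
  list(offset = offset, scale = scale)
}

# pages along the first array dimension
#' @noRd
write_float_stack <- function(arr, path) {
  sc <- tiff_scale(arr)
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(i) (arr[i, , ] - sc$offset) / sc$scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sc
}

#' @noRd
read_float_stack <- function(path, offset = 0, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr * scale + offset
}

#' @noRd
write_label_stack <- function(labels, path) {
  if (max(labels) > 65535L)
    stop_txq("txq_io_error", "more than 65535 labels cannot be stored")
  pages <- lapply(seq_len(dim(labels)[1]), function(i) labels[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @noRd
read_label_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- as.integer(round(pages[[i]] * 65535))
  arr
}

#' @noRd
write_yaml_file <- function(x, path) {
  writeLines(yaml::as.yaml(x, precision = 15L), path)
  invisible(path)
}

#' Write / read a projection set (multi-page TIFF + YAML sidecar)
#'
#' One TIFF page per projection frame; the sidecar stores angles, pixel
#' pitch, photon count and the affine storage map.
#'
#' @param projections a `projection_set`.
#' @param path TIFF path; the sidecar is `<path>.yaml`.
#' @return the path (write) / a `projection_set` (read).
#' @export
write_projections <- function(projections, path) {
  stopifnot(inherits(projections, "projection_set"))
  imgs <- aperm(projections$images, c(3, 1, 2)) # page per frame
  sc <- write_float_stack(imgs, path)
  write_yaml_file(list(
    kind = "projection_set", angles = projections$angles,
    pixel_pitch_nm = projections$pixel_pitch,
    photon_count = projections$photon_count, geometry = "parallel",
    offset = sc$offset, scale = sc$scale
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  arr <- read_float_stack(path, meta$offset, meta$scale)
  new_projection_set(aperm(arr, c(2, 3, 1)), unlist(meta$angles),
                     meta$pixel_pitch_nm, meta$photon_count)
}

#' Write / read a reconstructed volume (multi-page TIFF + YAML sidecar)
#'
#' One 32-bit float page per z slice; voxel pitch, angular coverage and
#' method metadata round-trip through the sidecar unchanged.
#'
#' @param recon a `recon_volume`.
#' @param path TIFF path; the sidecar is `<path>.yaml`.
#' @return the path (write) / a `recon_volume` (read).
#' @export
write_volume <- function(recon, path) {
  stopifnot(inherits(recon, "recon_volume"))
  sc <- write_float_stack(recon$volume, path)
  write_yaml_file(list(
    kind = "recon_volume", voxel_pitch_nm = recon$voxel_pitch,
    angles = recon$angles, method = recon$method,
    offset = sc$offset, scale = sc$scale
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  vol <- read_float_stack(path, meta$offset, meta$scale)
  angles <- unlist(meta$angles)
  structure(list(volume = vol, voxel_pitch = meta$voxel_pitch_nm,
                 angles = angles, coverage = coverage_report(angles),
                 method = meta$method),
            class = "recon_volume")
}

#' Write a phantom to a run directory
#'
#' Writes `attenuation.tif` (32-bit float), `labels.tif` (16-bit),
#' `truth.csv` (header `id,cz,cy,cx,ax1,ax2,ax3,size,nucleus_distance`, nm)
#' and `phantom.yaml` (configuration + storage map).
#'
#' @param phantom a `cell_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly / the `cell_phantom` (read).
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "cell_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- write_float_stack(phantom$attenuation, file.path(dir, "attenuation.tif"))
  write_label_stack(phantom$labels, file.path(dir, "labels.tif"))
  write.csv(phantom$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write_yaml_file(list(kind = "cell_phantom",
                       config = unclass(phantom$config),
                       attenuation_offset = sc$offset,
                       attenuation_scale = sc$scale),
                  file.path(dir, "phantom.yaml"))
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "phantom.yaml"))
  cfg <- meta$config
  for (k in c("shape", "cell_semiaxes", "nucleus_semiaxes", "nucleus_offset",
              "shell"))
    cfg[[k]] <- unlist(cfg[[k]])
  cfg <- do.call(phantom_config, cfg)
  att <- read_float_stack(file.path(dir, "attenuation.tif"),
                          meta$attenuation_offset, meta$attenuation_scale)
  lab <- read_label_stack(file.path(dir, "labels.tif"))
  truth <- read.csv(file.path(dir, "truth.csv"))
  structure(list(labels = lab, attenuation = att,
                 voxel_pitch = cfg$voxel_pitch, truth = truth, config = cfg),
            class = "cell_phantom")
}

#' Write / read a cluster record catalog (CSV)
#'
#' Column layout `id, dim, cz, cy, cx, ax1, ax2, ax3, size_nm,
#' nucleus_distance_nm, inside_cell, area_or_volume_px` (lengths in nm).
#'
#' @param records data frame of cluster records.
#' @param path CSV path.
#' @return the path (write) / the records (read).
#' @export
write_cluster_csv <- function(records, path) {
  cols <- c("id", "dim", "cz", "cy", "cx", "ax1", "ax2", "ax3", "size_nm",
            "nucleus_distance_nm", "inside_cell", "area_or_volume_px")
  extra <- setdiff(cols, names(records))
  for (k in extra) records[[k]] <- NA
  write.csv(records[, c(cols, setdiff(names(records), cols))], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_csv
#' @export
read_cluster_csv <- function(path) read.csv(path)
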
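#' Configuration of a full simulate-image-reconstruct-quantify run
#'
#' One object collecting the per-stage settings; a single global `seed`
#' drives every stochastic stage (the phantom generator uses `seed`, photon
#' noise uses `seed + 1`).
#'
#' @param phantom a [phantom_config()].
#' @param angle_start,angle_step,n_angles acquisition geometry in degrees;
#'   the defaults reproduce a series at 1 degree intervals over 140 degrees,
#'   the span allowed by a typical TXM sample-holder geometry.
#' @param photon_count expected background photons per pixel, or `NULL` for
#'   noiseless frames.
#' @param psf_fwhm Gaussian optics blur FWHM, nm (30 nm matches the stated
#'   instrument resolution; 0 disables it).
#' @param apodization reconstruction filter window: `"auto"` picks Hann for
#'   noisy data and plain ramp otherwise.
#' @param threshold manual grey-value override for segmentation, or `NULL`
#'   for the Otsu rule.
#' @param min_size smallest retained component, px/voxels.
#' @param inside_fraction containment fraction for the inside-cell rule.
#' @param bin_width,bin_max size histogram bins, nm.
#' @param projection_2d_angle angle (deg) of the single projection used for
#'   the 2D quantification arm; must be one of the acquired angles.
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            angle_start = 0, angle_step = 1, n_angles = 140L,
                            photon_count = NULL, psf_fwhm = 30,
                            apodization = c("auto", "none", "hann"),
                            threshold = NULL, min_size = 2L,
                            inside_fraction = 0.9,
                            bin_width = 20, bin_max = 800,
                            projection_2d_angle = 0,
                            seed = 1L) {
  apodization <- match.arg(apodization)
  angles <- angle_start + angle_step * (seq_len(n_angles) - 1)
  if (any(angles < 0 | angles >= 360))
    stop_txq("txq_config_error", "acquisition angles must lie in [0, 360)")
  if (!projection_2d_angle %in% angles)
    stop_txq("txq_config_error",
             "projection_2d_angle must be one of the acquired angles")
  phantom$seed <- as.integer(seed)
  structure(list(
    phantom = phantom, angles = angles, photon_count = photon_count,
    psf_fwhm = psf_fwhm, apodization = apodization, threshold = threshold,
    min_size = as.integer(min_size), inside_fraction = inside_fraction,
    bin_width = bin_width, bin_max = bin_max,
    projection_2d_angle = projection_2d_angle, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Scenario presets
#'
#' Two ready-made scenes mirroring the qualitative contrast between the two
#' studied cell lines: `"emt-like"` has large clusters (size mode 140 nm)
#' spread uniformly through the cytoplasm; `"hela-like"` has small clusters
#' (size mode 30 nm) confined to a thin perinuclear shell about
#' 1 +/- 0.5 um outside the nuclear envelope. Scene extents are scaled to a
#' few micrometres so a full tomographic run stays desk-sized; densities and
#' size modes follow the observed cluster populations.
#'
#' @param preset `"emt-like"` or `"hela-like"`.
#' @param n_clusters cluster count for the scene.
#' @param seed global seed.
#' @return a `pipeline_config`.
#' @export
preset_config <- function(preset = c("emt-like", "hela-like"),
                          n_clusters = NULL, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "emt-like") {
    ph <- phantom_config(
      shape = c(96L, 192L, 192L), voxel_pitch = 30,
      cell_semiaxes = c(1250, 2650, 2650),
      nucleus_semiaxes = c(550, 900, 900),
      n_clusters = n_clusters %||% 120L,
      size_meanlog = log(140) + 0.35^2, size_sdlog = 0.35,
      placement = "uniform_cytoplasm", seed = seed
    )
  } else {
    ph <- phantom_config(
      shape = c(112L, 288L, 288L), voxel_pitch = 15,
      cell_semiaxes = c(700, 2250, 2250),
      nucleus_semiaxes = c(280, 650, 650),
      n_clusters = n_clusters %||% 60L,
      size_meanlog = log(30) + 0.35^2, size_sdlog = 0.35,
      placement = "perinuclear_shell", shell = c(500, 1500),
      mu_cluster = 0.8, seed = seed
    )
  }
  pipeline_config(phantom = ph, psf_fwhm = 0, seed = seed)
}

#' @noRd
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_txq("txq_stage_error", "stage '%s' failed: %s", name,
             conditionMessage(e))
  })
}

#' Run the full simulation and quantification pipeline
#'
#' simulate -> image -> reconstruct -> quantify -> report. Both
#' quantification arms are executed: 3D on the reconstructed volume
#' (clusters bright) and 2D on a single projection frame (clusters dark),
#' each with its own Otsu threshold estimated inside the cell mask, the
#' inside-cell rule, and nucleus-relative localization. When `out_dir` is
#' given every artifact is written as it is produced (TIFF stacks, CSV
#' catalogs, QC + manifest YAML), so a failing stage leaves the earlier
#' artifacts on disk; with `out_dir = NULL` the run stays in memory.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory or `NULL`.
#' @return list (class `txm_run`) with `phantom`, `projections`, `recon`,
#'   `records_3d`, `records_2d`, `dist_3d`, `dist_2d`, `comparison_2d_3d`,
#'   `report`, `qc` and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  writing <- !is.null(out_dir)
  if (writing) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  phantom <- run_stage("phantom", {
    ph <- build_phantom(config$phantom)
    if (writing) write_phantom(ph, file.path(out_dir, "phantom"))
    ph
  })

  projections <- run_stage("optics", {
    ps <- project(phantom, config$angles, psf_fwhm = config$psf_fwhm)
    if (!is.null(config$photon_count))
      ps <- add_photon_noise(ps, config$photon_count, seed = config$seed + 1L)
    if (writing) write_projections(ps, file.path(out_dir, "projections.tif"))
    ps
  })

  recon <- run_stage("recon", {
    apod <- config$apodization
    if (apod == "auto")
      apod <- if (is.null(config$photon_count)) "none" else "hann"
    rv <- reconstruct_fbp(projections, apodization = apod)
    if (writing) write_volume(rv, file.path(out_dir, "recon.tif"))
    rv
  })

  pitch <- phantom$voxel_pitch
  cmask3 <- cell_mask(phantom)
  nmask3 <- phantom_nucleus_mask(phantom)
  bins <- default_bins(config$bin_width, config$bin_max)

  q3 <- run_stage("quant3d", {
    th <- config$threshold %||% auto_threshold(recon$volume, mask = cmask3)
    seg <- segment_clusters(recon$volume, th, "above", config$min_size)
    rec <- measure_clusters(seg, pitch)
    rec <- drop_nucleus_regions(seg, rec, nmask3)
    n_nuc <- attr(rec, "n_nucleus_regions")
    rec <- filter_inside_cell(seg, rec, cmask3, config$inside_fraction)
    rec <- localize_clusters(rec, nmask3, pitch)
    list(seg = seg, rec = rec, threshold = th, n_nucleus_regions = n_nuc)
  })

  q2 <- run_stage("quant2d", {
    ai <- which(config$angles == config$projection_2d_angle)[1]
    frame <- projections$images[, , ai]
    cmask2 <- apply(cmask3, c(1, 2), any) # beam-axis projection of the cell
    nmask2 <- apply(nmask3, c(1, 2), any)
    th <- config$threshold %||% auto_threshold(frame, mask = cmask2)
    seg <- segment_clusters(frame, th, "below", config$min_size)
    rec <- measure_clusters(seg, pitch)
    rec <- drop_nucleus_regions(seg, rec, nmask2)
    n_nuc <- attr(rec, "n_nucleus_regions")
    rec <- filter_inside_cell(seg, rec, cmask2, config$inside_fraction)
    rec <- localize_clusters(rec, nmask2, pitch)
    list(seg = seg, rec = rec, threshold = th, n_nucleus_regions = n_nuc)
  })

  out <- run_stage("report", {
    rec3 <- q3$rec
    rec2 <- q2$rec
    rec3$cell_id <- rep("cell1", nrow(rec3))
    rec2$cell_id <- rep("cell1", nrow(rec2))
    d3 <- make_distribution(rec3$size_nm, bins, "cell1", "3D")
    d2 <- make_distribution(rec2$size_nm, bins, "cell1", "2D")
    cmp <- if (nrow(rec3) >= 1 && nrow(rec2) >= 1)
      compare_distributions(rec2$size_nm, rec3$size_nm) else NULL
    report <- uptake_report(rec3)
    loc3 <- attr(rec3, "localization")
    qc <- list(
      seed = config$seed,
      threshold_3d = q3$threshold, threshold_2d = q2$threshold,
      threshold_rule = if (is.null(config$threshold)) "otsu-256" else "manual",
      connectivity_3d = q3$seg$connectivity, connectivity_2d = q2$seg$connectivity,
      min_size_px = config$min_size,
      discarded_sub_resolution = c(d3 = q3$seg$n_discarded,
                                   d2 = q2$seg$n_discarded),
      rejected_outside_cell = c(d3 = attr(q3$rec, "n_rejected") %||% 0L,
                                d2 = attr(q2$rec, "n_rejected") %||% 0L),
      nucleus_regions_discarded = c(d3 = q3$n_nucleus_regions,
                                    d2 = q2$n_nucleus_regions),
      clamped_pixels = sinogramify(projections)$n_clamped,
      angular_coverage = recon$coverage,
      n_clusters_true = nrow(phantom$truth),
      n_clusters_3d = nrow(rec3), n_clusters_2d = nrow(rec2),
      frac_in_nucleus_3d = loc3$frac_negative,
      ks_2d_vs_3d = if (is.null(cmp)) NULL else
        list(statistic = cmp$statistic, p_value = cmp$p_value)
    )
    if (writing) {
      write_cluster_csv(rbind(rec3, rec2), file.path(out_dir, "clusters.csv"))
      write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
      write_yaml_file(qc, file.path(out_dir, "qc.yaml"))
      write_yaml_file(list(
        package = "txmquant",
        version = as.character(packageVersion("txmquant")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config = serialize_config(config), qc = qc
      ), file.path(out_dir, "manifest.yaml"))
    }
    list(records_3d = rec3, records_2d = rec2, dist_3d = d3, dist_2d = d2,
         comparison_2d_3d = cmp, report = report, qc = qc)
  })

  structure(c(list(phantom = phantom, projections = projections,
                   recon = recon, out_dir = out_dir), out),
            class = "txm_run")
}

#' @noRd
serialize_config <- function(config) {
  x <- unclass(config)
  x$phantom <- unclass(x$phantom)
  x
}

#' @export
print.txm_run <- function(x, ...) {
  cat("<txm_run>\n")
  cat(sprintf("  true clusters: %d | detected 3D: %d | detected 2D: %d\n",
              nrow(x$phantom$truth), nrow(x$records_3d), nrow(x$records_2d)))
  cat(sprintf("  size mode: 3D %.0f nm, 2D %.0f nm\n",
              x$dist_3d$mode_nm, x$dist_2d$mode_nm))
  if (!is.null(x$comparison_2d_3d))
    cat(sprintf("  2D vs 3D sizes: KS D = %.3f, p = %.3g\n",
                x$comparison_2d_3d$statistic, x$comparison_2d_3d$p_value))
  invisible(x)
}

#' Quantify a user-supplied grayscale TIFF image or stack
#'
#' Runs the segmentation/sizing/localization arm alone on an external image:
#' a single-page TIFF is treated as a 2D transmission image (clusters dark),
#' a multi-page stack as a 3D attenuation volume (clusters bright);
#' `dimensionality = "2D"` forces per-page 2D quantification of a stack.
#' Masks, when given, must be TIFFs (or arrays) on the same grid; without a
#' cell mask the inside-cell filter is skipped with an explicit QC warning.
#'
#' @param image path to a grayscale TIFF (or a numeric matrix/array).
#' @param pixel_pitch pixel/voxel pitch, nm.
#' @param cell_mask,nucleus_mask optional mask TIFF paths or logical arrays.
#' @param dimensionality `NULL` (infer from stack depth) or `"2D"`/`"3D"`.
#' @param threshold manual threshold (default: Otsu inside the cell mask,
#'   or over the whole image without one).
#' @param polarity cluster side of the threshold; default `"below"` in 2D,
#'   `"above"` in 3D.
#' @param min_size,inside_fraction,bin_edges quantification settings.
#' @return for a single image: list with `records`, `distribution`, `qc`.
#'   For a stack forced to 2D: a list of such results, one per page.
#' @export
quantify_external <- function(image, pixel_pitch, cell_mask = NULL,
                              nucleus_mask = NULL, dimensionality = NULL,
                              threshold = NULL, polarity = NULL,
                              min_size = 2L, inside_fraction = 0.9,
                              bin_edges = default_bins()) {
  img <- load_grayscale(image)
  if (!is.null(dimensionality) && dimensionality == "2D" &&
      length(dim(img)) == 3L) {
    return(lapply(seq_len(dim(img)[1]), function(i)
      quantify_external(img[i, , ], pixel_pitch, cell_mask = cell_mask,
                        nucleus_mask = nucleus_mask, dimensionality = "2D",
                        threshold = threshold, polarity = polarity,
                        min_size = min_size, inside_fraction = inside_fraction,
                        bin_edges = bin_edges)))
  }
  nd <- length(dim(img))
  dimtag <- if (nd == 3L) "3D" else "2D"
  polarity <- polarity %||% (if (dimtag == "3D") "above" else "below")
  cmask <- if (is.null(cell_mask)) NULL else load_mask(cell_mask, dim(img))
  nmask <- if (is.null(nucleus_mask)) NULL else load_mask(nucleus_mask, dim(img))

  th <- threshold %||% auto_threshold(img, mask = cmask)
  seg <- segment_clusters(img, th, polarity, min_size)
  rec <- measure_clusters(seg, pixel_pitch)
  if (!is.null(nmask)) rec <- drop_nucleus_regions(seg, rec, nmask)
  warnings <- character(0)
  if (is.null(cmask)) {
    warnings <- c(warnings, "no cell mask: inside-cell filter skipped")
    warning("no cell mask supplied: inside-cell filter skipped", call. = FALSE)
    rec$inside_cell <- NA
  } else {
    rec <- filter_inside_cell(seg, rec, cmask, inside_fraction)
  }
  if (!is.null(nmask)) rec <- localize_clusters(rec, nmask, pixel_pitch)
  dist <- make_distribution(rec$size_nm, bin_edges, dimensionality = dimtag)
  qc <- list(threshold = th, polarity = polarity,
             connectivity = seg$connectivity, dimensionality = dimtag,
             n_components = seg$n_components, n_discarded = seg$n_discarded,
             n_rejected = attr(rec, "n_rejected") %||% NA_integer_,
             warnings = warnings)
  list(records = rec, distribution = dist, qc = qc)
}

#' @noRd
load_grayscale <- function(image) {
  if (is.character(image)) {
    pages <- tiff::readTIFF(image, all = TRUE)
    if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
      stop_txq("txq_format_error",
               "'%s' is not a grayscale TIFF (multi-channel pages found)",
               image)
    if (length(pages) == 1L) return(pages[[1]])
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    return(arr)
  }
  if (!is.numeric(image) || !(length(dim(image)) %in% 2:3))
    stop_txq("txq_format_error", "image must be a 2D/3D numeric array or path")
  image
}

#' @noRd
load_mask <- function(mask, expected_dim) {
  m <- if (is.character(mask)) load_grayscale(mask) else mask
  m <- m > 0.5
  if (!identical(dim(m), as.integer(expected_dim)) &&
      !identical(dim(m), expected_dim))
    stop_txq("txq_format_error", "mask grid does not match the image grid")
  m
}
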
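test_that("projection sets round-trip through TIFF + sidecar", {
  vol <- blob_volume(c(4L, 24L, 24L), seed = 21)
  ps <- project(vol, angles = c(0, 45.5, 90), pixel_pitch = 60)
  path <- file.path(withr::local_tempdir(), "proj.tif")
  write_projections(ps, path)
  rd <- read_projections(path)
  expect_equal(rd$images, ps$images, tolerance = 1e-6) # float32 storage
  expect_equal(rd$angles, ps$angles)
  expect_identical(rd$pixel_pitch, ps$pixel_pitch)
  expect_null(rd$photon_count)
})

test_that("phantoms and cluster catalogs round-trip through disk", {
  ph <- build_phantom(mini_phantom_config(n_clusters = 6L, seed = 19L))
  dir <- file.path(withr::local_tempdir(), "ph")
  write_phantom(ph, dir)
  rd <- read_phantom(dir)
  expect_identical(rd$labels, ph$labels)
  expect_equal(rd$attenuation, ph$attenuation, tolerance = 1e-6)
  expect_equal(rd$truth$size, ph$truth$size)
  expect_identical(rd$config$placement, ph$config$placement)

  csv <- file.path(dir, "clusters.csv")
  seg <- segment_clusters(ph$attenuation, 0.2, "above")
  rec <- measure_clusters(seg, ph$voxel_pitch)
  write_cluster_csv(rec, csv)
  back <- read_cluster_csv(csv)
  expect_equal(back$size_nm, rec$size_nm)
  expect_equal(back$dim, rec$dim)
})

test_that("pipeline configuration round-trips through YAML losslessly", {
  cfg <- pipeline_config(phantom = mini_phantom_config(), photon_count = 1234,
                         psf_fwhm = 31.7, seed = 99L)
  path <- file.path(withr::local_tempdir(), "cfg.yaml")
  txmquant:::write_yaml_file(txmquant:::serialize_config(cfg), path)
  rd <- yaml::read_yaml(path)
  expect_equal(rd$seed, 99L)
  expect_equal(rd$psf_fwhm, 31.7)
  expect_equal(unlist(rd$phantom$cell_semiaxes), cfg$phantom$cell_semiaxes)
  expect_equal(rd$phantom$size_meanlog, cfg$phantom$size_meanlog,
               tolerance = 1e-12)
})

test_that("the pipeline runs with zero clusters and is deterministic", {
  cfg0 <- pipeline_config(phantom = mini_phantom_config(n_clusters = 0L),
                          psf_fwhm = 0, seed = 4L)
  run0 <- run_pipeline(cfg0)
  expect_equal(nrow(run0$records_3d), 0L)
  expect_equal(run0$report$n_clusters[run0$report$cell_id == "pooled"], 0L)

  cfg <- pipeline_config(phantom = mini_phantom_config(n_clusters = 8L),
                         psf_fwhm = 0, seed = 23L)
  d1 <- file.path(withr::local_tempdir(), "r1")
  d2 <- file.path(withr::local_tempdir(), "r2")
  run_pipeline(cfg, d1)
  run_pipeline(cfg, d2)
  f1 <- file.path(d1, "clusters.csv")
  f2 <- file.path(d2, "clusters.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # manifests differ at most in their timestamp line
  m1 <- readLines(file.path(d1, "manifest.yaml"))
  m2 <- readLines(file.path(d2, "manifest.yaml"))
  differ <- which(m1 != m2)
  expect_true(all(grepl("timestamp", m1[differ])))

  expected <- c("phantom", "projections.tif", "projections.tif.yaml",
                "recon.tif", "recon.tif.yaml", "clusters.csv", "report.csv",
                "qc.yaml", "manifest.yaml")
  expect_true(all(expected %in% list.files(d1)))
})

test_that("perinuclear scenes sit closer to the nucleus than uniform ones", {
  base <- list(shape = c(48L, 64L, 64L), voxel_pitch = 30,
               cell_semiaxes = c(600, 850, 850),
               nucleus_semiaxes = c(250, 300, 300),
               n_clusters = 12L, size_meanlog = log(120), size_sdlog = 0.2)
  uni <- do.call(phantom_config,
                 c(base, list(placement = "uniform_cytoplasm", seed = 31L)))
  peri <- do.call(phantom_config,
                  c(base, list(placement = "perinuclear_shell",
                               shell = c(100, 280), seed = 31L)))
  run_u <- run_pipeline(pipeline_config(phantom = uni, psf_fwhm = 0, seed = 31L))
  run_p <- run_pipeline(pipeline_config(phantom = peri, psf_fwhm = 0, seed = 31L))
  expect_lt(mean(run_p$records_3d$nucleus_distance_nm),
            mean(run_u$records_3d$nucleus_distance_nm))
})

test_that("external TIFF quantification matches the in-memory path", {
  ph <- build_phantom(mini_phantom_config(n_clusters = 10L, seed = 27L))
  ps <- project(ph, angles = 0)
  path <- file.path(withr::local_tempdir(), "frame.tif")
  write_projections(ps, path)

  cmask2 <- apply(cell_mask(ph), c(1, 2), any)
  nmask2 <- apply(phantom_nucleus_mask(ph), c(1, 2), any)

  ext <- quantify_external(path, pixel_pitch = ph$voxel_pitch,
                           cell_mask = cmask2, nucleus_mask = nmask2)
  th <- auto_threshold(ps$images[, , 1], mask = cmask2)
  seg <- segment_clusters(ps$images[, , 1], th, "below")
  rec <- measure_clusters(seg, ph$voxel_pitch)
  rec <- filter_inside_cell(seg, rec, cmask2)
  expect_equal(nrow(ext$records), nrow(rec))
  expect_equal(ext$records$size_nm, rec$size_nm, tolerance = 1e-5)
  expect_equal(ext$qc$dimensionality, "2D")

  # no cell mask: filter skipped with an explicit warning
  expect_warning(
    nomask <- quantify_external(ps$images[, , 1], pixel_pitch = 30),
    "inside-cell filter skipped"
  )
  expect_true("no cell mask: inside-cell filter skipped" %in%
                nomask$qc$warnings)

  # RGB input is refused with the file named
  rgb <- file.path(withr::local_tempdir(), "rgb.tif")
  tiff::writeTIFF(array(runif(48), c(4, 4, 3)), rgb)
  err <- tryCatch(quantify_external(rgb, pixel_pitch = 30), error = identity)
  expect_s3_class(err, "txq_format_error")
  expect_match(conditionMessage(err), "rgb.tif")

  # 3-page stack forced to 2D: one report per page
  stack <- array(runif(3 * 16 * 16), c(3, 16, 16))
  suppressWarnings(
    per_page <- quantify_external(stack, pixel_pitch = 30,
                                  dimensionality = "2D")
  )
  expect_length(per_page, 3L)
  expect_equal(per_page[[1]]$qc$dimensionality, "2D")
})
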
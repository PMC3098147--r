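test_that("cluster size sampling follows the log-normal model", {
  # degenerate distribution: sdlog = 0 collapses to exp(meanlog)
  expect_equal(sample_cluster_sizes(5, log(140), 0, seed = 1),
               rep(140, 5))

  # determinism under a fixed seed
  expect_identical(sample_cluster_sizes(1000, log(100), 0.4, seed = 42),
                   sample_cluster_sizes(1000, log(100), 0.4, seed = 42))

  # large-sample histogram mode near the analytic mode exp(mu - sigma^2)
  s <- sample_cluster_sizes(1e5, log(100), 0.4, seed = 7)
  h <- hist(s, breaks = seq(0, ceiling(max(s)) + 5, by = 5), plot = FALSE)
  emp_mode <- h$mids[which.max(h$counts)]
  expect_lt(abs(emp_mode - exp(log(100) - 0.4^2)) / exp(log(100) - 0.4^2), 0.1)

  expect_error(sample_cluster_sizes(0, log(100), 0.4), class = "txq_config_error")
  expect_error(sample_cluster_sizes(10, log(100), -1), class = "txq_config_error")
})

test_that("phantom generator enforces its geometric invariants", {
  cfg <- mini_phantom_config(n_clusters = 20L, seed = 5L)
  ph <- build_phantom(cfg)
  lab <- ph$labels

  # nucleus exclusion: zero cluster voxels inside the nucleus, exactly
  expect_identical(sum(lab[phantom_nucleus_mask(ph)] >= 3L), 0L)
  # every cluster voxel inside the cell
  expect_true(all(lab[lab >= 3L] >= 3L))
  expect_true(all(cell_mask(ph)[lab >= 3L]))
  # attenuation non-negative, clusters denser than cytoplasm
  expect_true(all(ph$attenuation >= 0))
  expect_gt(min(ph$attenuation[lab >= 3L]), max(ph$attenuation[lab == 1L]))
  # distinct ids voxel-disjoint by construction of the label map; count matches
  expect_identical(sort(unique(as.integer(lab[lab >= 3L]))), 2L + 1:20)

  # truth catalog invariants
  tr <- ph$truth
  expect_equal(nrow(tr), 20L)
  expect_true(all(tr$ax1 >= tr$ax2 & tr$ax2 >= tr$ax3))
  expect_true(all(tr$ax3 > 0))
  expect_equal(tr$size, (tr$ax1 + tr$ax2 + tr$ax3) / 3, tolerance = 1e-9)
  expect_true(all(tr$nucleus_distance > 0))
})

test_that("rendered truth sizes track the requested ellipsoid sizes", {
  # fixed-size population (sdlog = 0): every rendered cluster with
  # diameter >= 4 voxels must report a size within one voxel pitch
  cfg <- mini_phantom_config(n_clusters = 12L, seed = 9L)
  cfg$size_meanlog <- log(150) # 5 voxels at 30 nm
  cfg$size_sdlog <- 0
  ph <- build_phantom(cfg)
  expect_true(all(abs(ph$truth$size - 150) <= ph$voxel_pitch))
})

test_that("phantom generation is deterministic and honors placement modes", {
  cfg <- mini_phantom_config(n_clusters = 10L, seed = 3L)
  expect_identical(build_phantom(cfg)$labels, build_phantom(cfg)$labels)

  # n = 0: cell + nucleus only, empty catalog
  cfg0 <- mini_phantom_config(n_clusters = 0L)
  ph0 <- build_phantom(cfg0)
  expect_equal(nrow(ph0$truth), 0L)
  expect_identical(sort(unique(as.integer(ph0$labels))), c(0L, 1L, 2L))

  # perinuclear shell: every truth distance within the configured shell
  cfgp <- mini_phantom_config(n_clusters = 15L, seed = 2L,
                              placement = "perinuclear_shell",
                              shell = c(150, 450))
  cfgp$size_meanlog <- log(120)
  php <- build_phantom(cfgp)
  expect_true(all(php$truth$nucleus_distance >= 150 &
                  php$truth$nucleus_distance <= 450))

  # capacity error when the shell cannot host the request
  cfgx <- mini_phantom_config(n_clusters = 400L, seed = 1L,
                              placement = "perinuclear_shell",
                              shell = c(30, 120), max_attempts = 50L)
  expect_error(build_phantom(cfgx), class = "txq_placement_error")
})

test_that("config validation rejects impossible scenes", {
  expect_error(phantom_config(shell = c(500, 400),
                              placement = "perinuclear_shell"),
               class = "txq_config_error")
  expect_error(phantom_config(size_sdlog = -0.1), class = "txq_config_error")
  expect_error(phantom_config(mu_cluster = 0.0005), class = "txq_config_error")
  # nucleus poking out of the cell is caught at build time
  cfg <- phantom_config(shape = c(48L, 48L, 48L), voxel_pitch = 30,
                        cell_semiaxes = c(400, 400, 400),
                        nucleus_semiaxes = c(300, 300, 300),
                        nucleus_offset = c(250, 0, 0), n_clusters = 0L)
  expect_error(build_phantom(cfg), class = "txq_config_error")
})

test_that("signed nucleus distance matches geometry and a boundary-scan oracle", {
  # spherical nucleus, radius 300 nm, centered in the grid
  pitch <- 25
  shape <- c(40L, 40L, 40L)
  cen <- shape / 2 * pitch
  mask <- array(FALSE, shape)
  for (z in 1:shape[1]) {
    zz <- (z - 0.5) * pitch - cen[1]
    yy <- (seq_len(shape[2]) - 0.5) * pitch - cen[2]
    xx <- (seq_len(shape[3]) - 0.5) * pitch - cen[3]
    mask[z, , ] <- outer(yy^2, xx^2, "+") + zz^2 <= 300^2
  }

  d_out <- nucleus_distance(rbind(cen + c(450, 0, 0)), mask, pitch)
  expect_lt(abs(d_out - 150), pitch)
  d_in <- nucleus_distance(rbind(cen), mask, pitch)
  expect_lt(abs(d_in - (-300)), pitch)

  set.seed(11)
  pts <- cbind(runif(50, 5, 35), runif(50, 5, 35), runif(50, 5, 35)) * pitch
  impl <- nucleus_distance(pts, mask, pitch)
  oracle <- boundary_scan_distance(pts, mask, pitch)
  expect_true(all(abs(impl - oracle) <= pitch))

  expect_error(nucleus_distance(rbind(cen), array(FALSE, shape), pitch),
               class = "txq_input_error")
})
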
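test_that("Otsu thresholding separates classes and matches exhaustive search", {
  # two-valued image: threshold strictly between the two grey values
  img <- matrix(c(rep(0.2, 90), rep(0.9, 10)), 10)
  th <- auto_threshold(img)
  expect_gt(th, 0.2)
  expect_lt(th, 0.9)

  # affine equivariance up to one bin width
  set.seed(6)
  v <- c(rnorm(4000, 0.3, 0.05), rnorm(1500, 0.8, 0.07))
  t1 <- auto_threshold(matrix(v, ncol = 1))
  t2 <- auto_threshold(matrix(2.5 * v + 1, ncol = 1))
  expect_lt(abs(t2 - (2.5 * t1 + 1)), 2.5 * diff(range(v)) / 256)

  # exhaustive 256-candidate search oracle
  for (s in 1:5) {
    set.seed(s)
    v <- c(rnorm(3000, 0.25, 0.04), rnorm(1000, 0.75, 0.1))
    expect_equal(auto_threshold(matrix(v, ncol = 1)), otsu_oracle(v))
  }

  expect_error(auto_threshold(matrix(0.5, 4, 4)),
               class = "txq_threshold_error")
})

test_that("segmentation counts components like a flood-fill oracle", {
  # two disjoint dark blocks on a white field
  img <- matrix(1, 5, 5)
  img[1:2, 1:2] <- 0.1
  img[4:5, 4:5] <- 0.1
  seg <- segment_clusters(img, 0.5, "below")
  expect_equal(seg$n_components, 2L)
  expect_equal(seg$connectivity, 8L)

  # all background
  seg0 <- segment_clusters(matrix(1, 6, 6), 0.5, "below")
  expect_equal(seg0$n_components, 0L)
  expect_true(all(seg0$labels == 0L))

  # random 2D masks vs flood fill (min_size 1 so nothing is discarded)
  set.seed(9)
  for (i in 1:100) {
    m <- matrix(runif(16 * 16) < 0.35, 16)
    seg <- segment_clusters(m + 0, 0.5, "above", min_size = 1L)
    expect_identical(seg$n_components, flood_fill_count(m))
  }
  # random 3D masks vs flood fill
  for (i in 1:100) {
    m <- array(runif(8^3) < 0.2, c(8, 8, 8))
    seg <- segment_clusters(m + 0, 0.5, "above", min_size = 1L)
    expect_equal(seg$connectivity, 26L)
    expect_identical(seg$n_components, flood_fill_count(m))
  }
})

test_that("sub-resolution components are discarded but counted", {
  img <- matrix(0, 8, 8)
  img[2, 2] <- 1            # single pixel
  img[5:6, 5:6] <- 1        # 4-pixel block
  seg <- segment_clusters(img, 0.5, "above", min_size = 2L)
  expect_equal(seg$n_components, 1L)
  expect_equal(seg$n_discarded, 1L)
  expect_equal(seg$px_counts, 4L)
})

test_that("tightening the threshold never grows the segmented foreground", {
  set.seed(10)
  img <- matrix(runif(32 * 32), 32)
  areas <- vapply(seq(0.2, 0.8, 0.1), function(th)
    sum(segment_clusters(img, th, "above", min_size = 1L)$labels > 0L),
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("ellipse fits recover rendered 2D shapes from moments", {
  px <- 12 # nm per pixel
  # disk of diameter 20 pixels
  n <- 31
  cen <- (n + 1) / 2
  gg <- as.matrix(expand.grid(r = 1:n, c = 1:n))
  disk <- gg[(gg[, 1] - cen)^2 + (gg[, 2] - cen)^2 <= 100, ]
  ax <- fit_ellipse(disk, px)
  expect_equal(as.numeric(ax), c(20, 20) * px, tolerance = 0.05)

  # axis-aligned 40 x 10 ellipse, then rotated: same sorted axes
  n2 <- 51; cen2 <- (n2 + 1) / 2
  g2 <- as.matrix(expand.grid(r = 1:n2, c = 1:n2))
  ell <- g2[((g2[, 1] - cen2) / 5)^2 + ((g2[, 2] - cen2) / 20)^2 <= 1, ]
  ax2 <- fit_ellipse(ell, px)
  expect_equal(as.numeric(ax2), c(40, 10) * px, tolerance = 0.05)
  for (deg in c(30, 45, 120)) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    u <- sweep(g2, 2, cen2) %*% R
    rot <- g2[(u[, 1] / 5)^2 + (u[, 2] / 20)^2 <= 1, ]
    axr <- fit_ellipse(rot, px)
    expect_equal(as.numeric(axr), c(40, 10) * px, tolerance = 0.05)
    expect_gte(axr[1], axr[2])
  }

  # degenerate 1 x N line: closed-form discrete moments
  N <- 9
  axl <- fit_ellipse(cbind(1, 1:N), px)
  expect_equal(as.numeric(axl),
               c(4 * sqrt((N^2 - 1) / 12 + 1 / 12), 4 * sqrt(1 / 12)) * px,
               tolerance = 1e-9)

  # single pixel: both axes = pitch, flagged
  ax1p <- fit_ellipse(cbind(3, 3), px)
  expect_equal(as.numeric(ax1p), c(px, px))
  expect_true(attr(ax1p, "sub_resolution"))
})

test_that("ellipsoid fits recover rendered 3D shapes and are rotation invariant", {
  vp <- 15
  ball <- render_ellipsoid_coords(c(6, 6, 6))
  axb <- fit_ellipsoid(ball, vp)
  expect_equal(as.numeric(axb), c(12, 12, 12) * vp, tolerance = 0.08)

  ell <- render_ellipsoid_coords(c(12, 6, 3))
  axe <- fit_ellipsoid(ell, vp)
  expect_equal(as.numeric(axe), c(24, 12, 6) * vp, tolerance = 0.08)

  for (R in list(rot3("z", 30), rot3("y", 55) %*% rot3("x", 20))) {
    rot <- render_ellipsoid_coords(c(12, 6, 3), rot = R)
    axr <- fit_ellipsoid(rot, vp)
    expect_equal(as.numeric(axr), as.numeric(axe), tolerance = 0.08)
  }

  # coplanar component: smallest axis floored at one voxel pitch, flagged
  flat <- as.matrix(expand.grid(z = 3, y = 1:7, x = 1:7))
  axf <- fit_ellipsoid(flat, vp)
  expect_true(attr(axf, "degenerate"))
  expect_gte(min(axf), vp)
})

test_that("cluster size is the arithmetic mean of the fitted axes", {
  expect_identical(cluster_size(c(200, 100)), 150)
  expect_identical(cluster_size(c(3, 4, 5) * 15), 4 * 15)
  expect_identical(cluster_size(c(80, 80)), 80)
  expect_identical(cluster_size(c(80, 80, 80)), 80)
  expect_error(cluster_size(c(100)), class = "txq_input_error")
  expect_error(cluster_size(c(100, -5)), class = "txq_input_error")
})

test_that("2D and 3D sizes agree on rendered balls", {
  vp <- 20
  for (d_vox in c(4, 7, 12)) {
    ball <- render_ball(d_vox)
    n <- dim(ball)[1]
    mid <- as.integer(ceiling(n / 2))
    seg3 <- segment_clusters(ball + 0, 0.5, "above")
    r3 <- measure_clusters(seg3, vp)
    expect_equal(r3$size_nm, d_vox * vp, tolerance = 0.1)

    seg2 <- segment_clusters(ball[mid, , ] + 0, 0.5, "above")
    r2 <- measure_clusters(seg2, vp)
    expect_equal(r2$size_nm, d_vox * vp, tolerance = 0.1)
  }
})

test_that("the inside-cell rule keeps only clearly internal clusters", {
  img <- matrix(0, 12, 12)
  img[2:3, 2:3] <- 1     # fully inside the mask below
  img[6:7, 10:11] <- 1   # fully outside
  img[10:11, 5:8] <- 1   # half inside, centroid on the boundary column
  mask <- matrix(FALSE, 12, 12)
  mask[1:12, 1:6] <- TRUE
  mask[1:4, 1:12] <- TRUE

  seg <- segment_clusters(img, 0.5, "above")
  rec <- measure_clusters(seg, 10)
  kept <- filter_inside_cell(seg, rec, mask)
  expect_equal(nrow(kept), 1L)
  expect_equal(attr(kept, "n_rejected"), 2L)
  expect_true(all(kept$inside_cell))

  # a cluster with 50% containment fails the 90% rule even centroid-in
  img2 <- matrix(0, 10, 10)
  img2[4:5, 4:7] <- 1
  mask2 <- matrix(FALSE, 10, 10)
  mask2[, 1:5] <- TRUE # splits the cluster exactly in half
  seg2 <- segment_clusters(img2, 0.5, "above")
  rec2 <- measure_clusters(seg2, 10)
  kept2 <- filter_inside_cell(seg2, rec2, mask2)
  expect_equal(nrow(kept2), 0L)

  expect_warning(
    none <- filter_inside_cell(seg, rec, matrix(FALSE, 12, 12)),
    "empty"
  )
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "n_rejected"), 3L)
})

test_that("cluster localization reports signed nucleus distances", {
  # nucleus occupying the left half: a cluster centered on the surface
  mask <- array(FALSE, c(16, 16, 16))
  mask[, , 1:8] <- TRUE
  vp <- 25
  rec <- data.frame(id = 1L, dim = "3D",
                    cz = 8 * vp, cy = 8 * vp, cx = 8 * vp,
                    size_nm = 100)
  out <- localize_clusters(rec, mask, vp)
  expect_lt(abs(out$nucleus_distance_nm), vp + 1e-9)

  rec2 <- data.frame(id = 1:2, dim = "3D",
                     cz = c(8, 8) * vp, cy = c(8, 8) * vp,
                     cx = c(2, 14) * vp, size_nm = c(100, 100))
  out2 <- localize_clusters(rec2, mask, vp)
  expect_lt(out2$nucleus_distance_nm[1], 0) # deep inside
  expect_gt(out2$nucleus_distance_nm[2], 0) # outside
  loc <- attr(out2, "localization")
  expect_equal(loc$frac_negative, 0.5)

  expect_warning(
    und <- localize_clusters(rec, array(FALSE, c(16, 16, 16)), vp),
    "undefined"
  )
  expect_true(is.na(und$nucleus_distance_nm))
})
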
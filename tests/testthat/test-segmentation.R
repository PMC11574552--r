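test_that("argmax classification recovers one-hot labels and breaks ties in class order", {
  truth <- matrix(sample.int(5, 100, replace = TRUE), 10, 10)
  stack <- array(0, c(10, 10, 5))
  for (k in 1:5) stack[, , k][truth == k] <- 1
  expect_identical(argmax_classify(stack), truth)

  uniform <- array(0.2, c(4, 4, 5))
  expect_true(all(argmax_classify(uniform) == 1))  # PARTICLE wins ties

  bad <- stack; bad[1, 1, 1] <- NaN
  expect_error(argmax_classify(bad), "NaN")
  bad2 <- stack; bad2[1, 1, ] <- 0.3
  expect_error(argmax_classify(bad2), "sum to 1")
})

test_that("label-flip noise degrades pixel agreement by exactly the flip rate", {
  cfg <- scene_config(label_flip_rate = 0.05)
  sc_noisy <- simulate_scene(cfg, seed = 7, root_id = 1, timepoint_h = 24,
                             tile_id = 1)
  clean <- fixture_scene()  # same seed, flip rate 0
  agree <- mean(argmax_classify(sc_noisy$probstack) ==
                  argmax_classify(clean$probstack))
  expect_gte(agree, 0.94)
})

test_that("root rasterization follows pixel-center even-odd geometry", {
  # axis-aligned rectangle 300 x 800 um
  geom <- root_geometry(
    centreline = data.frame(x_um = c(150, 150), y_um = c(800, 0)),
    boundary = data.frame(x_um = c(0, 300, 300, 0), y_um = c(0, 0, 800, 800)))
  px <- 10
  mask <- rasterize_root(geom, c(60, 100), px)
  expect_equal(sum(mask) * px^2, 300 * 800, tolerance = 0.02)

  expect_error(root_geometry(data.frame(x_um = c(0, 1), y_um = c(0, 1)),
                             data.frame(x_um = numeric(0), y_um = numeric(0))),
               "at least 3 vertices")

  # the generator's mask is the same rasterization of the same polygon
  sc <- fixture_scene()
  expect_identical(sc$masks$root,
                   rasterize_root(sc$geometry, dim(sc$masks$root),
                                  sc$config$pixel_size_um))
})

test_that("root overlay overrides every classifier label inside the polygon", {
  sc <- fixture_scene()
  lab <- overlay_root(argmax_classify(sc$probstack), sc$geometry,
                      sc$config$pixel_size_um)
  inside <- rasterize_root(sc$geometry, dim(lab), sc$config$pixel_size_um)
  expect_true(all(lab[inside] == 6))
  expect_true(all(lab[!inside] != 6))
})

test_that("watershed splits bridged discs and conserves mask area", {
  mk_disc <- function(m, cx, cy, r) {
    idx <- which(outer(seq_len(nrow(m)) - cx, seq_len(ncol(m)) - cy,
                       function(a, b) a^2 + b^2) <= r^2)
    m[idx] <- 1L
    m
  }
  m <- matrix(0L, 60, 60)
  m <- mk_disc(m, 20, 30, 8)
  m <- mk_disc(m, 42, 30, 8)
  bridge <- cbind(21:41, 30)
  m[bridge] <- 1L
  ws <- watershed_decompose(m)
  expect_equal(max(ws), 2)
  expect_equal(sum(ws > 0), sum(m))  # exact partition
  # oracle: components after removing the bridge
  m2 <- m; m2[bridge] <- 0L
  disc_areas <- sort(tabulate(EBImage::bwlabel(m2)[m2 > 0]))
  got_areas <- sort(tabulate(ws[ws > 0]))
  expect_true(all(abs(got_areas - disc_areas) <= nrow(bridge)))

  single <- mk_disc(matrix(0L, 30, 30), 15, 15, 7)
  ws1 <- watershed_decompose(single)
  expect_equal(max(ws1), 1)
  expect_identical(ws1 > 0, single > 0)

  expect_equal(max(watershed_decompose(matrix(0L, 10, 10))), 0)
  expect_error(watershed_decompose(matrix(0L, 10, 10), matrix(0, 5, 5)),
               "different shapes")
})

test_that("watershed partitions random composite masks exactly", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(0L, 64, 64)
    for (k in 1:6) {
      cx <- sample(10:54, 1); cy <- sample(10:54, 1); r <- sample(3:9, 1)
      idx <- which(outer(seq_len(64) - cx, seq_len(64) - cy,
                         function(a, b) a^2 + b^2) <= r^2)
      m[idx] <- 1L
    }
    ws <- watershed_decompose(m)
    expect_equal(sum(ws > 0), sum(m))
    areas <- tabulate(ws[ws > 0])
    expect_equal(sum(areas), sum(m))
  }
})

test_that("patch extraction reports exact areas, intensities and centroids", {
  px <- 6.21
  lab <- matrix(2L, 40, 40)
  lab[11:20, 11:20] <- 3L  # 10x10 MB square
  intensity <- matrix(0, 40, 40)
  intensity[11:20, 11:20] <- 50
  geom <- root_geometry(
    centreline = data.frame(x_um = c(5, 5), y_um = c(40 * px, 0)),
    boundary = data.frame(x_um = c(1, 2, 2, 1), y_um = c(1, 1, 2, 2)))
  p <- extract_patches(lab, intensity, geom, px)
  expect_equal(nrow(p), 1)
  expect_equal(p$area_um2, 100 * px^2)  # 3856.41 um^2
  expect_equal(p$area_um2, 3856.41)
  expect_equal(p$mean_intensity, 50)
  expect_equal(p$total_intensity, 5000)
  expect_equal(p$cx_um, 15 * px)

  # mean intensity of a 3-pixel region is the arithmetic mean
  lab2 <- matrix(2L, 10, 10); lab2[3:5, 4] <- 3L
  int2 <- matrix(0, 10, 10); int2[3:5, 4] <- c(10, 20, 30)
  p2 <- extract_patches(lab2, int2, geom, px, min_area_px = 1)
  expect_equal(p2$mean_intensity, 20)

  # sub-resolution regions are discarded by the area threshold
  p3 <- extract_patches(lab2, int2, geom, px, min_area_px = 4)
  expect_equal(nrow(p3), 0)
})

test_that("distance covariates match brute force within half a pixel diagonal", {
  px <- 6.21
  set.seed(13)
  geom <- root_geometry(
    centreline = data.frame(x_um = c(32, 32) * px, y_um = c(64, 0) * px),
    boundary = data.frame(x_um = c(28, 36, 36, 28) * px,
                          y_um = c(0, 0, 64, 64) * px))
  for (rep in 1:5) {
    particle <- matrix(0L, 64, 64)
    particle[sample.int(64 * 64, 40)] <- 1L
    root <- matrix(FALSE, 64, 64)
    root[29:36, ] <- TRUE
    pts <- tibble::tibble(x_um = runif(20, 1, 63) * px,
                          y_um = runif(20, 1, 63) * px)
    cov <- compute_covariates(pts, particle, root, geom, px)
    for (i in 1:20) {
      ix <- floor(pts$x_um[i] / px) + 1
      iy <- floor(pts$y_um[i] / px) + 1
      center <- c((ix - 0.5) * px, (iy - 0.5) * px)
      bp <- brute_min_dist(center[1], center[2], particle, px)
      br <- brute_min_dist(center[1], center[2], root, px)
      if (particle[ix, iy] > 0) bp <- 0
      if (root[ix, iy]) br <- 0
      expect_lt(abs(cov$dp_um[i] - bp), px * sqrt(2) / 2 + 1e-9)
      expect_lt(abs(cov$dr_um[i] - br), px * sqrt(2) / 2 + 1e-9)
    }
  }
})

test_that("covariates hit their defining zero sets", {
  px <- 6.21
  particle <- matrix(0L, 30, 30); particle[10:14, 10:14] <- 1L
  root <- matrix(FALSE, 30, 30); root[1:4, ] <- TRUE
  geom <- root_geometry(
    centreline = data.frame(x_um = c(2, 2) * px, y_um = c(15, 150) * px),
    boundary = data.frame(x_um = c(0, 4, 4, 0) * px,
                          y_um = c(0, 0, 30, 30) * px))
  # a point on a particle pixel has dp = 0
  on_particle <- tibble::tibble(x_um = 11.5 * px, y_um = 11.5 * px)
  expect_equal(compute_covariates(on_particle, particle, root, geom, px)$dp_um, 0)
  # a point 10 pixels out from the flat root edge has dr = 10 px
  out10 <- tibble::tibble(x_um = 14.5 * px, y_um = 20.5 * px)
  cov <- compute_covariates(out10, particle, root, geom, px)
  expect_equal(cov$dr_um, 10 * px, tolerance = px / 2)
  # a point beside the tip vertex has da = 0
  at_tip <- tibble::tibble(x_um = 2 * px, y_um = 15 * px)
  expect_equal(compute_covariates(at_tip, particle, root, geom, px)$da_um, 0)
  # points outside the grid are rejected
  expect_error(compute_covariates(tibble::tibble(x_um = -5, y_um = 10),
                                  particle, root, geom, px),
               "outside")
})

test_that("dilating the particle mask never increases dp", {
  px <- 6.21
  set.seed(31)
  particle <- matrix(0L, 48, 48)
  particle[sample.int(48 * 48, 30)] <- 1L
  root <- matrix(FALSE, 48, 48); root[1, 1] <- TRUE
  geom <- root_geometry(
    centreline = data.frame(x_um = c(3, 3), y_um = c(3, 200)),
    boundary = data.frame(x_um = c(0, 6, 6, 0), y_um = c(0, 0, 6, 6)))
  grown <- EBImage::dilate(particle, EBImage::makeBrush(3, "box"))
  pts <- tibble::tibble(x_um = runif(30, 1, 47) * px,
                        y_um = runif(30, 1, 47) * px)
  d0 <- compute_covariates(pts, particle, root, geom, px)$dp_um
  d1 <- compute_covariates(pts, as.matrix(grown), root, geom, px)$dp_um
  expect_true(all(d1 <= d0 + 1e-9))
})

test_that("segmenting a noiseless synthetic scene recovers the planted patches", {
  sc <- fixture_scene()
  rec <- segment_scene(sc)
  truth <- sc$truth
  # total fluorescence and area are conserved class by class
  for (cls in unique(truth$class)) {
    t_tot <- sum(39 * truth$cells[truth$class == cls] + 331)
    r_tot <- sum(rec$total_intensity[rec$class == cls])
    expect_equal(r_tot, t_tot, tolerance = 1e-6)
    expect_equal(sum(rec$area_um2[rec$class == cls]),
                 sum(truth$area_um2[truth$class == cls]), tolerance = 1e-9)
  }
  # each planted patch has a recovered patch of its class within its radius
  # (watershed may occasionally split one planted patch into two regions)
  px <- sc$config$pixel_size_um
  for (i in seq_len(nrow(truth))) {
    same <- rec$class == truth$class[i]
    d <- sqrt((rec$cx_um[same] - truth$cx_um[i])^2 +
                (rec$cy_um[same] - truth$cy_um[i])^2)
    expect_lt(min(d), sqrt(truth$area_um2[i] / pi) + 2 * px)
  }
})
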
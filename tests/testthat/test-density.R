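test_that("top-hat kernel is constant inside its ellipsoid and zero outside", {
  expect_equal(kernel_value(c(0, 0), c(10, 10)), 1 / (pi * 100))
  expect_equal(kernel_value(c(10, 0), c(10, 10)), 1 / (pi * 100))  # boundary
  expect_equal(kernel_value(c(10.01, 0), c(10, 10)), 0)
  expect_equal(kernel_value(5, 10), 1 / 20)          # V_1 = 2
  expect_equal(kernel_value(c(0, 0, 0), c(5, 5, 5)), 1 / ((4 * pi / 3) * 125))
  expect_error(kernel_value(rep(0, 4), rep(1, 4)), "1, 2 or 3")
  expect_error(kernel_value(0, -1), "positive")
})

test_that("kernel integrates to one for random dimensions and bandwidths", {
  set.seed(17)
  for (n in 1:3) {
    h <- runif(n, 2, 12)
    step <- min(h) / (c(400, 40, 15)[n])
    g <- lapply(h, function(hh) seq(-hh - step, hh + step, by = step) + step / 2)
    if (n == 1) {
      s <- sum(kernel_value(matrix(g[[1]], ncol = 1), h)) * step
    } else if (n == 2) {
      q <- outer((g[[1]] / h[1])^2, (g[[2]] / h[2])^2, "+")
      s <- sum(q <= 1) / (pi * h[1] * h[2]) * step^2
    } else {
      s <- 0
      for (z in g[[3]]) {
        q <- outer((g[[1]] / h[1])^2, (g[[2]] / h[2])^2, "+") + (z / h[3])^2
        s <- s + sum(q <= 1)
      }
      s <- s / ((4 * pi / 3) * prod(h)) * step^3
    }
    expect_equal(s, 1, tolerance = 1e-3)
  }
})

test_that("a single patch yields its own normalized kernel as the field", {
  p <- tibble::tibble(area_um2 = pi * 30^2, mean_intensity = 5,
                      dp_um = 250, dr_um = 250)
  grid <- density_grid(c("dp", "dr"), dp = seq(0, 500, 2), dr = seq(0, 500, 2))
  f <- estimate_density(p, c("dp", "dr"), grid)
  h <- 30
  inside <- (f$dp - 250)^2 + (f$dr - 250)^2 <= h^2
  expect_true(all(f$p_tilde[inside] == 1 / (pi * h^2)))
  expect_true(all(f$p_tilde[!inside] == 0))
  # a single kernel carries the full quadrature error of its rim; the
  # multi-patch normalization criterion is tested in test-acceptance.R
  expect_equal(attr(f, "integral"), 1, tolerance = 0.03)
})

test_that("field mass splits by the fluorescence weights A_i * I_i", {
  p <- tibble::tibble(area_um2 = c(pi * 20^2, pi * 20^2),
                      mean_intensity = c(1 / (pi * 20^2), 3 / (pi * 20^2)),
                      dp_um = c(120, 380), dr_um = c(120, 380))
  grid <- density_grid(c("dp", "dr"), dp = seq(0, 500, 2), dr = seq(0, 500, 2))
  f <- estimate_density(p, c("dp", "dr"), grid)
  m1 <- sum(f$p_tilde[f$dp < 250] * f$cell_volume[f$dp < 250])
  m2 <- sum(f$p_tilde[f$dp >= 250] * f$cell_volume[f$dp >= 250])
  expect_equal(m1 / (m1 + m2), 0.25, tolerance = 0.02)
  expect_equal(m2 / (m1 + m2), 0.75, tolerance = 0.02)
  # weight conservation is exact by construction
  w <- p$area_um2 * p$mean_intensity
  expect_identical(sum(w / sum(w)), 1)
})

test_that("gridded field equals direct kernel summation at random cells", {
  set.seed(23)
  n <- 60
  A <- runif(n, 100, 8000); I <- runif(n, 1, 100)
  h <- pmax(sqrt(A / pi), 6.21)
  x <- runif(n, 0, 500); y <- runif(n, 0, 500)
  p <- tibble::tibble(area_um2 = A, mean_intensity = I, dp_um = x, dr_um = y)
  f <- estimate_density(p, c("dp", "dr"))
  M <- sum(A * I)
  cells <- sample(nrow(f), 100)
  for (i in cells) {
    direct <- sum(A * I / M / (pi * h^2) *
                    (((f$dp[i] - x)^2 + (f$dr[i] - y)^2) <= h^2))
    if (direct > 0)
      expect_equal(f$p_tilde[i], direct, tolerance = 1e-12)
    else expect_equal(f$p_tilde[i], 0)
  }
})

test_that("density is invariant to intensity rescaling and patch order", {
  set.seed(29)
  p <- tibble::tibble(area_um2 = runif(30, 200, 5000),
                      mean_intensity = runif(30, 1, 50),
                      dp_um = runif(30, 0, 500), dr_um = runif(30, 0, 500))
  f1 <- estimate_density(p, c("dp", "dr"))
  p2 <- p; p2$mean_intensity <- p2$mean_intensity * 7.3
  f2 <- estimate_density(p2, c("dp", "dr"))
  expect_equal(f1$p_tilde, f2$p_tilde, tolerance = 1e-12)
  f3 <- estimate_density(p[sample(nrow(p)), ], c("dp", "dr"))
  expect_identical(f1$p_tilde, f3$p_tilde)
})

test_that("degenerate weighting and missing covariates are rejected", {
  p <- tibble::tibble(area_um2 = c(100, 200), mean_intensity = c(0, 0),
                      dp_um = c(1, 2), dr_um = c(1, 2))
  expect_error(estimate_density(p, c("dp", "dr")), "degenerate")
  expect_error(estimate_density(p, c("dp", "da")), "da_um")
})

test_that("null model matches the exhaustive per-pixel covariate histogram", {
  sc <- fixture_scene()
  lab <- fixture_labelmap()
  px <- sc$config$pixel_size_um
  grid <- density_grid(c("dp", "dr"))
  nf <- null_model(lab, sc$geometry, px, covariates = c("dp", "dr"),
                   grid = grid)
  expect_equal(attr(nf, "flag"), "null")
  oracle <- exhaustive_histogram(lab, sc$geometry, px, code = 2,
                                 seq(0, 500, 10), seq(0, 500, 10))
  l1 <- sum(abs(nf$p_tilde - oracle) * nf$cell_volume)
  expect_lt(l1, 0.1)
})

test_that("null model is stable under seeded subsampling", {
  sc <- fixture_scene()
  lab <- fixture_labelmap()
  px <- sc$config$pixel_size_um
  grid <- density_grid(c("dp", "dr"))
  f1 <- null_model(lab, sc$geometry, px, grid = grid, subsample = 1)
  f2 <- null_model(lab, sc$geometry, px, grid = grid, subsample = 0.3,
                   seed = 5)
  expect_lt(sum(abs(f1$p_tilde - f2$p_tilde) * f1$cell_volume), 0.05)
  # determinism of the subsampling stream
  f3 <- null_model(lab, sc$geometry, px, grid = grid, subsample = 0.3,
                   seed = 5)
  expect_identical(f2$p_tilde, f3$p_tilde)
})

test_that("null model over a single-stratum support piles mass there", {
  sc <- fixture_scene()
  lab <- fixture_labelmap()
  px <- sc$config$pixel_size_um
  # particle pixels all have dp = 0: the single attainable stratum
  nf <- null_model(lab, sc$geometry, px, support = "PARTICLE",
                   covariates = "dp",
                   grid = density_grid("dp", dp = seq(0, 100, 10)),
                   subsample = 0.2, seed = 2)
  first_bin <- nf$p_tilde[1] * nf$cell_volume[1]
  expect_gt(first_bin / sum(nf$p_tilde * nf$cell_volume), 0.99)
  expect_error(null_model(matrix(2L, 5, 5), sc$geometry, px,
                          support = "PARTICLE"),
               "empty")
})

test_that("cell density scales the probability field by the per-root quantity", {
  cal <- calibration_model()
  p <- tibble::tibble(area_um2 = c(1000, 2000), mean_intensity = c(10, 20),
                      npx = c(26, 52),
                      total_intensity = predict_intensity(cal, c(4e5, 6e5)),
                      dp_um = c(100, 300), dr_um = c(100, 300))
  f <- estimate_density(p, c("dp", "dr"))
  cf <- mean_cell_density(f, p, cal, n_roots = 2)
  expect_equal(attr(cf, "Q_bar"), 5e5)
  expect_equal(cf$rho, cf$p_tilde * 5e5)
  expect_equal(sum(cf$rho * cf$cell_volume), 5e5 * attr(cf, "integral"),
               tolerance = 1e-9)
  expect_error(mean_cell_density(f, p, cal, n_roots = 0), "positive")
})

test_that("temporal fields are independent per-timepoint estimates", {
  set.seed(41)
  p <- tibble::tibble(area_um2 = runif(20, 500, 3000),
                      mean_intensity = runif(20, 5, 50),
                      dp_um = runif(20, 0, 400), dr_um = runif(20, 0, 400),
                      timepoint_h = 24)
  tf <- temporal_density(p, c("dp", "dr"), timepoints = c(12, 24))
  expect_equal(attr(tf[["12"]], "flag"), "empty")
  expect_true(all(tf[["12"]]$p_tilde == 0))
  ref <- estimate_density(p, c("dp", "dr"))
  expect_identical(tf[["24"]]$p_tilde, ref$p_tilde)
  # permuting patch order leaves every field bit-identical
  tf2 <- temporal_density(p[sample(nrow(p)), ], c("dp", "dr"),
                          timepoints = c(12, 24))
  expect_identical(tf[["24"]]$p_tilde, tf2[["24"]]$p_tilde)
})

test_that("planted placement scales are recovered from model vs null fields", {
  sc <- fixture_scene()
  cfg <- scene_config(placement = placement_model(
    mb = utils::modifyList(placement_model()$mb,
                           list(count_mean = c(`24` = 500),
                                lambda_tip_um = c(`24` = Inf)))))
  mb <- suppressWarnings(
    place_patches(cfg, sc$masks, sc$geometry, 24, seed = 11, paint = FALSE))
  mb <- mb[mb$class == "MB", ]
  mb$mean_intensity <- 1
  grid <- density_grid(c("dp", "dr"))
  f <- estimate_density(mb, c("dp", "dr"), grid)
  nf <- null_model(fixture_labelmap(), sc$geometry, sc$config$pixel_size_um,
                   grid = grid)
  sc_fit <- recover_placement_scales(f, nf)
  lam <- setNames(sc_fit$lambda_um, sc_fit$covariate)
  expect_lt(abs(lam[["dr"]] - 100) / 100, 0.2)
  expect_lt(abs(lam[["dp"]] - 100) / 100, 0.2)
})
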
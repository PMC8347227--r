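# Scalp-map rendering and the topogram stack.

test_that("interpolation is exact at electrode sites and masked outside", {
  mont <- standard_montage(16)
  geo <- topo_geometry(mont$xyz, c(41, 41))  # odd grid: center node at Cz
  vals <- seq(0.1, 1.6, by = 0.1)
  img <- render_topogram(vals, geo)
  # Cz projects to the origin = exact center pixel of a 41 x 41 grid;
  # the raw interpolant passes through the electrode value there
  cz <- which(mont$names == "Cz")
  raw <- as.vector(geo$B %*% vals)
  center <- (21 - 1) * 41 + 21           # column-major grid index
  expect_equal(raw[center], vals[cz], tolerance = 1e-10)
  # the image is the min-max normalization of the masked interpolant
  inside <- raw[geo$mask]
  expected <- (raw[center] - min(inside)) / diff(range(inside))
  expect_equal(img[21, 21], expected, tolerance = 1e-10)

  # corners lie outside the unit circle -> exactly zero
  expect_equal(img[1, 1], 0)
  expect_equal(img[41, 41], 0)
  expect_true(all(img >= 0 & img <= 1))

  # constant vector -> constant (zero) image inside the mask
  flat <- render_topogram(rep(3, 16), geo)
  expect_true(all(flat == 0))

  # idempotent under re-normalization
  img2 <- (img - min(img)) / (max(img) - min(img))
  expect_equal(img2, img, tolerance = 1e-12)
})

test_that("duplicate projected electrode positions are reported", {
  xyz <- standard_montage(8)$xyz
  xyz[2, ] <- xyz[1, ]
  expect_error(topo_geometry(xyz, c(16, 16)), "duplicate")
})

test_that("anterior channels render on top rows", {
  mont <- standard_montage(16)
  geo <- topo_geometry(mont$xyz, c(20, 20))
  v <- numeric(16)
  v[mont$names == "Fp1"] <- 1   # anterior-left electrode hot
  img <- render_topogram(v, geo)
  top <- mean(img[1:6, ]); bottom <- mean(img[15:20, ])
  expect_gt(top, bottom)
})

test_that("the stack has Z = R * N_tau * N_bands deterministic maps", {
  co <- tiny_cohort()
  ts <- bandpass_filter(co[[1]], c(8, 30), 4)
  cfg <- feature_config(grid_wh = c(16, 16), n_csp = 4)
  models <- fit_csp_models(ts, cfg, seq_len(10))
  st <- build_topogram_stack(ts, cfg, models)
  expect_equal(dim(st$maps), c(16, 16, 20, 12))  # 2 * 5 * 2 = 20
  expect_true(all(is.finite(st$maps)))
  expect_true(all(st$maps >= 0 & st$maps <= 1))
  expect_equal(st$index$method, rep(c("csp", "cwt"), each = 10))

  # single band, single segment, default two methods -> Z = 2
  cfg1 <- feature_config(band_edges = list(c(8, 12)), window_s = 6,
                         analysis_interval = c(0, 6),
                         grid_wh = c(16, 16), n_csp = 4)
  m1 <- fit_csp_models(ts, cfg1, seq_len(10))
  st1 <- build_topogram_stack(ts, cfg1, m1)
  expect_equal(dim(st1$maps)[3], 2)

  # missing CSP model is detected
  broken <- models
  broken$models[[1]][2] <- list(NULL)
  expect_error(build_topogram_stack(ts, cfg, broken), "missing CSP")
})

test_that("default configuration yields 40 x 40 maps", {
  cfg <- feature_config()
  expect_equal(cfg$grid_wh, c(40, 40))
  expect_equal(n_segments(cfg), 5)
  mont <- standard_montage(16)
  geo <- topo_geometry(mont$xyz, cfg$grid_wh)
  img <- render_topogram(rnorm(16), geo)
  expect_equal(dim(img), c(40, 40))
})
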
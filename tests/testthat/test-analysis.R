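# Shared fixture: a patterned phantom and its unfolded map.
local_fixture <- local({
  ph <- sphere_phantom(radius = 12, shape = 64,
                       pattern = list(type = "checkerboard", nlat = 4,
                                      nlon = 8))
  m <- unfold_intensity(ph$stack, ph$truth$ellipsoid,
                        unfold_options(map_width = 96,
                                       interpolated = FALSE))
  list(ph = ph, m = m)
})

test_that("ROI selection agrees with a brute-force even-odd oracle", {
  m <- local_fixture$m
  poly <- rbind(c(10.2, 5.3), c(40.7, 8.1), c(35.2, 30.4), c(12.8, 25.9))
  roi <- map_roi(poly, "quad")
  vox <- roi_to_voxels(m, roi, dedupe = FALSE)
  centers_x <- m$crossref$map_x + 0.5
  centers_y <- m$crossref$map_y + 0.5
  oracle <- pip_oracle(poly, centers_x, centers_y)
  expect_identical(attr(vox, "n_pixels"), sum(oracle))
  expect_identical(nrow(vox), sum(oracle))
})

test_that("a whole-mask ROI selects every referenced voxel", {
  m <- local_fixture$m
  h <- nrow(m$values); w <- ncol(m$values)
  roi <- map_roi(rbind(c(-1, -1), c(w + 1, -1), c(w + 1, h + 1),
                       c(-1, h + 1)), "all")
  vox <- roi_to_voxels(m, roi)
  expect_identical(attr(vox, "n_pixels"), nrow(m$crossref))
  expect_identical(nrow(vox),
                   nrow(unique(m$crossref[, c("t", "c", "z", "y", "x")])))
})

test_that("disjoint ROIs select disjoint map-pixel sets", {
  m <- local_fixture$m
  roi1 <- map_roi(rbind(c(5, 5), c(25, 5), c(25, 20), c(5, 20)), "left")
  roi2 <- map_roi(rbind(c(50, 25), c(80, 25), c(80, 40), c(50, 40)),
                  "right")
  px <- m$crossref$map_x + 0.5
  py <- m$crossref$map_y + 0.5
  in1 <- pip_oracle(roi1$vertices, px, py)
  in2 <- pip_oracle(roi2$vertices, px, py)
  expect_false(any(in1 & in2))
  v1 <- roi_to_voxels(m, roi1, dedupe = FALSE)
  v2 <- roi_to_voxels(m, roi2, dedupe = FALSE)
  expect_identical(attr(v1, "n_pixels"), sum(in1))
  expect_identical(attr(v2, "n_pixels"), sum(in2))
})

test_that("triangle ROI pixel count respects the rasterization bound", {
  m <- local_fixture$m
  poly <- rbind(c(10, 5), c(30, 8), c(18, 20))
  roi <- map_roi(poly, "tri")
  vox <- roi_to_voxels(m, roi, dedupe = FALSE)
  # shoelace area and perimeter bound
  x <- poly[, 1]; y <- poly[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per <- sum(sqrt(rowSums((poly - poly[c(2, 3, 1), ])^2)))
  expect_lt(abs(attr(vox, "n_pixels") - area), per)
})

test_that("measurement is invariant to ROI vertex rotation", {
  m <- local_fixture$m
  st <- local_fixture$ph$stack
  poly <- rbind(c(10.2, 5.3), c(40.7, 8.1), c(35.2, 30.4), c(12.8, 25.9))
  t1 <- measure_roi_timeseries(st, m, map_roi(poly, "a"))
  t2 <- measure_roi_timeseries(st, m, map_roi(poly[c(3, 4, 1, 2), ], "a"))
  expect_equal(t1$mean, t2$mean)
  expect_equal(t1$n_voxels, t2$n_voxels)
})

test_that("ROI means on a constant stack are that constant", {
  ph <- sphere_phantom(radius = 9, shape = 48)
  st <- ph$stack
  arr <- array(4, dim = c(3, 1, dim(st$values)[3:5]))
  st3 <- image_stack(arr, spacing = st$spacing, axes = "TCZYX")
  m <- unfold_intensity(st3, ph$truth$ellipsoid,
                        unfold_options(map_width = 48), t = 1)
  roi <- map_roi(rbind(c(2, 2), c(40, 2), c(40, 20), c(2, 20)), "r")
  ts <- measure_roi_timeseries(st3, m, roi)
  expect_identical(nrow(ts), 3L)
  expect_true(all(ts$mean == 4))
  expect_identical(ts$t, 0:2)
  expect_true(all(ts$mode == "map_crossref"))
})

test_that("ROI means match brute-force averages from the serialized table", {
  m <- local_fixture$m
  st <- local_fixture$ph$stack
  # off-grid vertices: no polygon edge passes through a pixel center, so
  # the even-odd tie-break at boundaries cannot differ between methods
  poly <- rbind(c(20.3, 10.1), c(70.2, 12.4), c(60.1, 35.3), c(25.2, 30.2))
  roi <- map_roi(poly, "p")
  ts <- measure_roi_timeseries(st, m, roi)
  # independent recomputation from the table on disk
  path <- tempfile(fileext = ".tsv")
  write_crossref(m, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  sel <- pip_oracle(poly, tab$map_x + 0.5, tab$map_y + 0.5)
  vox <- unique(tab[sel, c("t", "c", "z", "y", "x")])
  vals <- st$values[cbind(vox$t + 1, vox$c + 1, vox$z + 1, vox$y + 1,
                          vox$x + 1)]
  expect_equal(ts$mean, mean(vals))
  expect_identical(ts$n_voxels, nrow(vox))
})

test_that("whole-surface ROI mean grows monotonically under influx", {
  spec <- phantom_spec(shape = c(40, 40, 40),
                       spacing = voxel_spacing(0.5, 0.5, 0.5),
                       semi_axes = c(7.5, 7.5, 7.5), thickness = 1.5,
                       seed = 3)
  sim <- simulate_photoactivation_series(
    spec, source = c(0, 2, 0.5), D = 0.05, influx = 50, dt = 0.003,
    n_frames = 5, steps_per_frame = 30, grid = c(36, 72))
  e <- sim$truth$ellipsoid
  opts <- unfold_options(map_width = 48, interpolated = FALSE)
  tabs <- lapply(1:5, function(t)
    unfold_intensity(sim$stack, e, opts, t = t)$crossref)
  roi <- map_roi(rbind(c(-1, -1), c(49, -1), c(49, 25), c(-1, 25)), "whole")
  ts <- measure_roi_timeseries(sim$stack, tabs, roi)
  expect_identical(nrow(ts), 5L)
  expect_true(all(diff(ts$mean) > 0))
})

test_that("single-layer measurement matches brute-force masked means", {
  ph <- sphere_phantom(radius = 9, shape = 48)
  st <- ph$stack
  # uniform layer: mean equals the constant
  arr <- array(3, dim = c(2, 1, 8, 8, 8))
  stc <- image_stack(arr, axes = "TCZYX")
  ts <- single_layer_measure(stc, z = 4, threshold = 1)
  expect_true(all(ts$mean == 3))
  expect_true(all(ts$mode == "single_layer"))
  # brute force on the shell phantom
  z <- 24
  ts <- single_layer_measure(st, z = z)
  layer <- st$values[1, 1, z, , ]
  rng <- range(layer)
  thr <- EBImage::otsu(matrix(as.vector(layer), ncol = 1), range = rng)
  expect_equal(ts$mean, mean(layer[layer > thr]))
  # empty plane errors
  empty <- image_stack(array(0, dim = c(8, 8, 8)), axes = "ZYX")
  expect_error(suppressWarnings(
    single_layer_measure(empty, z = 1, threshold = 5)), "empty mask")
  expect_error(single_layer_measure(st, z = 1000), "out of range")
})

test_that("profiles sample the map raster with gaps outside the mask", {
  m <- local_fixture$m
  h <- nrow(m$values)
  # flat profile on a constant map
  mc <- m
  mc$values[mc$mask] <- 7
  line <- profile_line(rbind(c(0.5, h / 2 + 0.5), c(95.5, h / 2 + 0.5)))
  pr <- plot_profile(mc, line)
  expect_true(all(abs(pr$value - 7) < 1e-12, na.rm = TRUE))
  # profile length = arc length / step + 1
  expect_identical(nrow(pr), as.integer(95 %/% 1 + 1))
  pr2 <- plot_profile(mc, profile_line(rbind(c(0.5, 10.5), c(60.5, 10.5)),
                                       step = 0.5))
  expect_identical(nrow(pr2), as.integer(60 / 0.5 + 1))
  # square wave along a checkerboard band row: 8 alternations
  g <- build_direction_grid(m$options)
  row <- which.min(abs(g$phi[, 1] - 22.5 * pi / 180))
  line <- profile_line(rbind(c(0.5, row - 0.5), c(95.5, row - 0.5)))
  pr <- plot_profile(m, line)
  mid <- (max(pr$value, na.rm = TRUE) + min(pr$value, na.rm = TRUE)) / 2
  cls <- pr$value > mid
  expect_identical(sum(cls != c(cls[-1], cls[1])), 8L)
  # a line fully outside the mask errors
  mo <- unfold_intensity(local_fixture$ph$stack,
                         local_fixture$ph$truth$ellipsoid,
                         unfold_options(projection = "mollweide",
                                        map_width = 64))
  corner <- profile_line(rbind(c(0.6, 0.6), c(2.5, 0.6)))
  expect_error(plot_profile(mo, corner), "does not intersect")
})

test_that("ROI files and measurement CSVs round-trip", {
  poly <- rbind(c(1.5, 2.5), c(10, 2.5), c(6, 9.25))
  roi <- map_roi(poly, "demo")
  path <- tempfile(fileext = ".txt")
  write_map_roi(roi, path)
  back <- read_map_roi(path)
  expect_identical(back$label, "demo")
  expect_equal(back$vertices, roi$vertices)
  ts <- data.frame(t = 0:2, mean = c(1, 2, 3), n_voxels = c(5L, 5L, 5L),
                   roi = "demo", mode = "map_crossref")
  csv <- tempfile(fileext = ".csv")
  write_measurement(ts, csv)
  expect_equal(read.csv(csv)$mean, ts$mean)
})
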
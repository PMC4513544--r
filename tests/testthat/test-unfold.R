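test_that("the direction grid places pixel centers analytically", {
  opts <- unfold_options(projection = "equirectangular", map_width = 4,
                         map_height = 2)
  g <- build_direction_grid(opts)
  expect_equal(g$phi[, 1], c(pi / 4, -pi / 4))
  expect_equal(g$lambda[1, ], c(-3, -1, 1, 3) * pi / 4)
  expect_true(all(g$mask))
  # mask equals the projection domain mask by construction
  opts <- unfold_options(projection = "mollweide", map_width = 40,
                         map_height = 20)
  g <- build_direction_grid(opts)
  expect_identical(g$mask, projection_domain_mask("mollweide", 40, 20))
})

test_that("the unfold axis steers where a bright pole cap lands", {
  # cap along +X: at the map top edge for axis X, on the equator for Z
  cap <- function(phi, lambda) {
    u <- stackmap:::direction_from_latlon(phi, lambda, "Z")
    as.numeric(acos(pmin(pmax(u$ux, -1), 1)) < 0.35)
  }
  spec <- phantom_spec(shape = c(48, 48, 48),
                       spacing = voxel_spacing(0.5, 0.5, 0.5),
                       semi_axes = c(9, 9, 9), thickness = 1.5)
  ph <- make_spheroid_stack(spec, field = function(p, l) {
    # bright only inside the +X cap; pattern defined with pole Z
    cap(p, l)
  })
  e <- ph$truth$ellipsoid
  for (ax in c("X", "Z")) {
    m <- unfold_intensity(ph$stack, e,
                          unfold_options(map_width = 64, unfold_axis = ax))
    bright <- which(m$values > 500, arr.ind = TRUE)
    rows <- bright[, 1] / nrow(m$values)
    if (ax == "X") {
      expect_lt(max(rows), 0.25)       # top edge
    } else {
      expect_gt(min(rows), 0.3)        # straddles the equator band
      expect_lt(max(rows), 0.7)
    }
  }
})

test_that("ray sampling reduces correctly on a uniform volume", {
  st <- image_stack(array(7, dim = c(32, 32, 32)),
                    spacing = voxel_spacing(1), axes = "ZYX")
  e <- reference_ellipsoid(c(16, 16, 16), c(8, 8, 8))
  for (stat in c("max", "mean")) {
    r <- sample_radial_ray(st, e, 0.3, 0.7,
                           unfold_options(ray_statistic = stat))
    expect_equal(r$value, 7)
  }
  rs <- sample_radial_ray(st, e, 0.3, 0.7,
                          unfold_options(ray_statistic = "sum",
                                         radial_step = 0.5))
  expect_equal(rs$value %% 7, 0)       # constant x number of samples
  expect_gt(rs$value, 7)
})

test_that("a delta shell is localized at its true radius", {
  ph <- sphere_phantom(radius = 10, shape = 64, thickness = 1)
  e <- ph$truth$ellipsoid
  step <- 0.25
  r <- sample_radial_ray(ph$stack, e, 0.4, 1.1,
                         unfold_options(radial_step = step))
  expect_lt(abs(r$r_star - 10), step / 2 + sqrt(3) * 0.5 / 2)
})

test_that("rays that miss the volume report no valid sample", {
  st <- image_stack(array(1, dim = c(16, 16, 16)),
                    spacing = voxel_spacing(1), axes = "ZYX")
  # ellipsoid centered far outside: rays toward +z never cross the box
  e <- reference_ellipsoid(c(200, 200, 200), c(5, 5, 5))
  expect_null(sample_radial_ray(st, e, pi / 2, 0, unfold_options()))
  expect_error(
    unfold_intensity(st, e, unfold_options(map_width = 16)),
    "outside the stack volume")
})

test_that("a checkerboard shell maps to its exact tile layout", {
  ph <- sphere_phantom(radius = 12, shape = 64,
                       pattern = list(type = "checkerboard", nlat = 4,
                                      nlon = 8))
  opts <- unfold_options(projection = "equirectangular", map_width = 128)
  m <- unfold_intensity(ph$stack, ph$truth$ellipsoid, opts)
  v <- m$values / max(m$values[m$mask])
  g <- build_direction_grid(opts)
  # classify away from tile boundaries; truncate rows where the voxel
  # grid no longer resolves the pattern (|phi| > 75 deg)
  resolved <- m$mask & abs(g$phi) <= 75 * pi / 180
  bright <- resolved & v > 0.7
  dark <- resolved & v < 0.45
  expect_identical(
    stackmap:::count_components(bright, connectivity = 4L, wrap_x = TRUE),
    16L)
  expect_identical(
    stackmap:::count_components(dark, connectivity = 4L, wrap_x = TRUE),
    16L)
  # boundary columns: 8 alternations per band row, at the analytic
  # longitudes +/- 1 map pixel
  analytic_cols <- seq(0, 7) * 16 + 1
  for (band_phi in c(-67.5, -22.5, 22.5, 67.5) * pi / 180) {
    row <- which.min(abs(g$phi[, 1] - band_phi))
    cls <- v[row, ] > 0.625
    trans <- which(cls != cls[c(128, 1:127)])
    expect_identical(length(trans), 8L)
    err <- vapply(trans, function(tr) min(abs(tr - analytic_cols),
                                          128 - abs(tr - analytic_cols)), 0)
    expect_lte(max(err), 1)
  }
})

test_that("N disjoint rings give N map components for N in 3, 5, 9", {
  opts <- unfold_options(projection = "equirectangular", map_width = 128)
  for (n in c(3L, 5L, 9L)) {
    rings <- stackmap:::default_ring_layout(n)
    ph <- sphere_phantom(radius = 12, shape = 64,
                         pattern = list(type = "rings", rings = rings,
                                        width = 6 * pi / 180))
    m <- unfold_intensity(ph$stack, ph$truth$ellipsoid, opts)
    v <- m$values / max(m$values[m$mask])
    expect_identical(
      stackmap:::count_components(m$mask & v > 0.5, connectivity = 8L,
                                  wrap_x = TRUE),
      n)
  }
})

test_that("a feature straddling the seam splits onto both edges at equal rows", {
  rings <- rbind(c(0, pi, 15 * pi / 180))  # centered on the seam
  ph <- sphere_phantom(radius = 12, shape = 64,
                       pattern = list(type = "rings", rings = rings,
                                      width = 6 * pi / 180))
  m <- unfold_intensity(ph$stack, ph$truth$ellipsoid,
                        unfold_options(map_width = 128))
  v <- m$values / max(m$values[m$mask])
  bright <- m$mask & v > 0.5
  left_rows <- which(bright[, 1])
  right_rows <- which(bright[, ncol(bright)])
  expect_gt(length(left_rows), 0)
  expect_identical(left_rows, right_rows)
  # seam-aware labeling sees one ring, edge-blind labeling sees two parts
  expect_identical(stackmap:::count_components(bright, 8L, wrap_x = TRUE), 1L)
  expect_gt(stackmap:::count_components(bright, 8L, wrap_x = FALSE), 1L)
})

test_that("uniform shells give latitude-independent equal-area statistics", {
  ph <- sphere_phantom(radius = 10, shape = 64)
  opts <- unfold_options(projection = "mollweide", map_width = 120)
  m <- unfold_intensity(ph$stack, ph$truth$ellipsoid, opts)
  g <- build_direction_grid(opts)
  global <- mean(m$values[m$mask])
  bands <- seq(-pi / 2, pi / 2, by = pi / 6)
  for (b in seq_len(length(bands) - 1)) {
    sel <- m$mask & g$phi >= bands[b] & g$phi < bands[b + 1]
    expect_lt(abs(mean(m$values[sel]) / global - 1), 0.01)
  }
})

test_that("cross-references are exact under nearest-voxel max sampling", {
  ph <- sphere_phantom(radius = 12, shape = 64,
                       pattern = list(type = "checkerboard", nlat = 4,
                                      nlon = 8))
  m <- unfold_intensity(ph$stack, ph$truth$ellipsoid,
                        unfold_options(map_width = 96,
                                       interpolated = FALSE))
  cr <- m$crossref
  stack_vals <- ph$stack$values[cbind(cr$t + 1, cr$c + 1, cr$z + 1,
                                      cr$y + 1, cr$x + 1)]
  map_vals <- m$values[cbind(cr$map_y + 1, cr$map_x + 1)]
  expect_identical(stack_vals, map_vals)
  # every referenced voxel lies inside the stack bounds
  d <- dim(ph$stack$values)
  expect_true(all(cr$z >= 0 & cr$z < d[3]))
  expect_true(all(cr$y >= 0 & cr$y < d[4]))
  expect_true(all(cr$x >= 0 & cr$x < d[5]))
  # the table covers exactly the masked pixels
  expect_identical(nrow(cr), sum(m$mask))
  # crossref serialization round-trips
  path <- tempfile(fileext = ".tsv")
  write_crossref(m, path)
  expect_equal(read_crossref(path), cr, tolerance = 1e-12)
})

test_that("unfolding is deterministic", {
  ph <- sphere_phantom(radius = 9, shape = 48)
  opts <- unfold_options(projection = "sinusoidal", map_width = 72)
  m1 <- unfold_intensity(ph$stack, ph$truth$ellipsoid, opts)
  m2 <- unfold_intensity(ph$stack, ph$truth$ellipsoid, opts)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$crossref, m2$crossref)
})

test_that("height maps recover bumps and indentations to tolerance", {
  bumps <- rbind(c(0.6, 0.5, 3, 10 * pi / 180),
                 c(-0.5, -2.0, -3, 10 * pi / 180))
  spec <- phantom_spec(shape = c(96, 96, 96),
                       spacing = voxel_spacing(0.5, 0.5, 0.5),
                       semi_axes = c(15, 15, 15), thickness = 1.5,
                       bumps = bumps)
  ph <- make_spheroid_stack(spec)
  opts <- unfold_options(map_width = 128)
  hm <- unfold_height(ph$stack, ph$truth$ellipsoid, opts)
  step <- min(0.5, 0.5, 0.5) / 2
  tol <- step / 2 + sqrt(3) * 0.5 / 2
  expect_lt(abs(max(hm$elevation[hm$mask]) - 3), tol)
  expect_lt(abs(min(hm$elevation[hm$mask]) + 3), tol)
})

test_that("a shell on the ellipsoid has near-zero elevation", {
  ph <- sphere_phantom(radius = 10, shape = 64)
  hm <- unfold_height(ph$stack, ph$truth$ellipsoid,
                      unfold_options(map_width = 64, radial_step = 0.2))
  expect_lt(max(abs(hm$elevation[hm$mask])), 0.2 / 2 + sqrt(3) * 0.5 / 2)
})

test_that("hypsometric coloring is centered, symmetric and confinable", {
  ph <- sphere_phantom(radius = 10, shape = 48)
  hm <- unfold_height(ph$stack, ph$truth$ellipsoid,
                      unfold_options(map_width = 32))
  pal <- stackmap:::hypsometric_palette()
  mid <- pal[(length(pal) + 1) / 2]
  # all-zero elevations -> uniform midpoint color
  hm$elevation[hm$mask] <- 0
  rgb <- apply_hypsometric_lut(hm)
  midc <- grDevices::col2rgb(mid)[, 1] / 255
  for (k in 1:3) expect_true(all(abs(rgb[, , k][hm$mask] - midc[k]) < 1e-9))
  # endpoints hit at the extremes
  hm$elevation[hm$mask] <- 0
  hm$elevation[which(hm$mask)[1]] <- -3
  hm$elevation[which(hm$mask)[2]] <- 3
  rgb <- apply_hypsometric_lut(hm)
  lo <- unname(grDevices::col2rgb(pal[1])[, 1] / 255)
  hi <- unname(grDevices::col2rgb(pal[length(pal)])[, 1] / 255)
  expect_equal(rgb[, , 1][which(hm$mask)[1]], lo[1])
  expect_equal(rgb[, , 1][which(hm$mask)[2]], hi[1])
  # data in +/-3 with range +/-10 stays in the central 30% of the table
  set.seed(2)
  hm$elevation[hm$mask] <- runif(sum(hm$mask), -3, 3)
  rgb <- apply_hypsometric_lut(hm, symmetric_range = 10)
  n <- length(pal)
  central <- pal[round(n * 0.35):round(n * 0.65)]
  used <- grDevices::rgb(rgb[, , 1][hm$mask], rgb[, , 2][hm$mask],
                         rgb[, , 3][hm$mask])
  expect_true(all(toupper(used) %in% toupper(central)))
  # empty mask errors
  hm$mask[] <- FALSE
  expect_error(apply_hypsometric_lut(hm), "empty")
})
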
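#' Options controlling the unfolding of a stack onto a map
#'
#' @param projection a [projection_spec()] or projection name.
#' @param unfold_axis pole axis of the unfolding, `"X"`, `"Y"` or `"Z"`:
#'   the stack axis that maps to the top/bottom edges of the map.
#' @param map_width map raster width in pixels.
#' @param map_height map raster height in pixels; default: chosen from
#'   `map_width` and the projection's natural aspect ratio.
#' @param radial_window `(r_lo, r_hi)` sampling window as fractions of
#'   the local ellipsoid radius; must bracket 1.
#' @param radial_step radial sampling step in um; default: half the
#'   smallest voxel dimension of the stack being unfolded.
#' @param ray_statistic `"max"` (default; the surface is localized at the
#'   radial intensity peak), `"mean"` or `"sum"`.
#' @param interpolated `TRUE` (default) samples the stack trilinearly
#'   along each ray; `FALSE` samples the nearest voxel, which keeps map
#'   values exactly equal to stack values.
#' @return An object of class `unfold_options`.
#' @export
unfold_options <- function(projection = "equirectangular",
                           unfold_axis = "Z",
                           map_width = 256L, map_height = NULL,
                           radial_window = c(0.5, 1.5),
                           radial_step = NULL,
                           ray_statistic = c("max", "mean", "sum"),
                           interpolated = TRUE) {
  projection <- as_projection_spec(projection)
  unfold_axis <- toupper(unfold_axis)
  stopifnot(unfold_axis %in% c("X", "Y", "Z"))
  map_width <- as.integer(map_width)
  if (is.null(map_height)) {
    bb <- projection_bbox(projection)
    map_height <- max(2L, as.integer(round(
      map_width * diff(bb$ylim) / diff(bb$xlim))))
  }
  map_height <- as.integer(map_height)
  stopifnot(map_width >= 2L, map_height >= 2L)
  radial_window <- as.numeric(radial_window)
  if (length(radial_window) != 2 || radial_window[1] <= 0 ||
      radial_window[1] >= 1 || radial_window[2] <= 1) {
    stop("radial_window must satisfy 0 < r_lo < 1 < r_hi", call. = FALSE)
  }
  if (!is.null(radial_step) && radial_step <= 0) {
    stop("radial_step must be positive", call. = FALSE)
  }
  structure(list(
    projection = projection, unfold_axis = unfold_axis,
    map_width = map_width, map_height = map_height,
    radial_window = radial_window, radial_step = radial_step,
    ray_statistic = match.arg(ray_statistic),
    interpolated = isTRUE(interpolated)
  ), class = "unfold_options")
}

#' Per-pixel direction grid of a map raster
#'
#' Maps every pixel center linearly onto the projection's bounding box,
#' pulls it back through the inverse projection, and converts the
#' resulting (phi, lambda) to 3D unit directions under the unfold axis.
#'
#' @param options an [unfold_options()].
#' @return A list with matrices `phi`, `lambda` (radians, `NA` outside
#'   the domain), logical `mask`, and `ux`, `uy`, `uz` direction
#'   components (stack X, Y, Z).
#' @export
build_direction_grid <- function(options) {
  stopifnot(inherits(options, "unfold_options"))
  w <- options$map_width; h <- options$map_height
  g <- map_pixel_grid(options$projection, w, h)
  inv <- inverse_project(options$projection, g$x, g$y)
  phi <- matrix(inv$phi, h, w)
  lam <- matrix(inv$lambda, h, w)
  mask <- matrix(inv$inside, h, w)
  u <- direction_from_latlon(inv$phi, inv$lambda, options$unfold_axis)
  list(phi = phi, lambda = lam, mask = mask,
       ux = matrix(u$ux, h, w), uy = matrix(u$uy, h, w),
       uz = matrix(u$uz, h, w))
}

# Vectorized trilinear sampling of a (Z, Y, X) volume at physical
# positions (um). Positions whose 8-voxel-center neighborhood is not
# fully inside the volume return NA.
sample_trilinear <- function(vol, spacing, px, py, pz) {
  d <- dim(vol)
  fx <- px / spacing$dx - 0.5  # continuous 0-based voxel-center coords
  fy <- py / spacing$dy - 0.5
  fz <- pz / spacing$dz - 0.5
  x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
  ok <- x0 >= 0 & x0 <= d[3] - 2 & y0 >= 0 & y0 <= d[2] - 2 &
    z0 >= 0 & z0 <= d[1] - 2
  out <- rep(NA_real_, length(px))
  if (!any(ok)) return(out)
  wx <- (fx - x0)[ok]; wy <- (fy - y0)[ok]; wz <- (fz - z0)[ok]
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  base <- 1 + z0 + y0 * d[1] + x0 * d[1] * d[2]
  sy <- d[1]; sx <- d[1] * d[2]
  v000 <- vol[base];            v001 <- vol[base + sx]
  v010 <- vol[base + sy];       v011 <- vol[base + sy + sx]
  v100 <- vol[base + 1];        v101 <- vol[base + 1 + sx]
  v110 <- vol[base + 1 + sy];   v111 <- vol[base + 1 + sy + sx]
  c00 <- v000 * (1 - wx) + v001 * wx
  c01 <- v010 * (1 - wx) + v011 * wx
  c10 <- v100 * (1 - wx) + v101 * wx
  c11 <- v110 * (1 - wx) + v111 * wx
  c0 <- c00 * (1 - wy) + c01 * wy
  c1 <- c10 * (1 - wy) + c11 * wy
  out[ok] <- c0 * (1 - wz) + c1 * wz
  out
}

# Nearest-voxel sampling under the half-open box convention:
# voxel index = floor(position / spacing), 0-based.
sample_nearest <- function(vol, spacing, px, py, pz) {
  d <- dim(vol)
  ix <- floor(px / spacing$dx); iy <- floor(py / spacing$dy)
  iz <- floor(pz / spacing$dz)
  ok <- ix >= 0 & ix <= d[3] - 1 & iy >= 0 & iy <= d[2] - 1 &
    iz >= 0 & iz <= d[1] - 1
  out <- rep(NA_real_, length(px))
  out[ok] <- vol[1 + iz[ok] + iy[ok] * d[1] + ix[ok] * d[1] * d[2]]
  out
}

# Core radial sampler over many rays at once.
# dirs: list(ux, uy, uz) vectors (length n); R: local ellipsoid radius.
# Returns list(value, r_star, vz, vy, vx, valid) -- voxel indices 0-based.
sample_rays_core <- function(vol, spacing, center, ux, uy, uz, R, options,
                             radial_step) {
  n <- length(R)
  r_lo <- options$radial_window[1] * R
  r_hi <- options$radial_window[2] * R
  n_steps <- pmax(floor((r_hi - r_lo) / radial_step), 0) + 1
  N <- max(n_steps)
  k <- seq_len(N) - 1
  rr <- outer(r_lo, k * radial_step, `+`)          # n x N radii
  rr[rr > r_hi + 1e-9] <- NA
  px <- center[1] + rr * ux
  py <- center[2] + rr * uy
  pz <- center[3] + rr * uz
  sampler <- if (options$interpolated) sample_trilinear else sample_nearest
  val <- matrix(sampler(vol, spacing, as.vector(px), as.vector(py),
                        as.vector(pz)), n, N)
  val[is.na(rr)] <- NA
  stat <- options$ray_statistic
  if (stat == "max") {
    vneg <- val
    vneg[is.na(vneg)] <- -Inf
    kstar <- max.col(vneg, ties.method = "first")  # smallest radius wins ties
    sel <- cbind(seq_len(n), kstar)
    value <- vneg[sel]
    valid <- is.finite(value)
    r_star <- rr[sel]
  } else {
    nv <- rowSums(!is.na(val))
    valid <- nv > 0
    value <- if (stat == "mean") rowMeans(val, na.rm = TRUE) else
      rowSums(val, na.rm = TRUE)
    r_star <- (r_lo + r_hi) / 2                    # window center
  }
  value[!valid] <- NA
  r_star[!valid] <- NA
  d <- dim(vol)
  sx <- center[1] + r_star * ux
  sy <- center[2] + r_star * uy
  sz <- center[3] + r_star * uz
  vx <- pmin(pmax(floor(sx / spacing$dx), 0), d[3] - 1)
  vy <- pmin(pmax(floor(sy / spacing$dy), 0), d[2] - 1)
  vz <- pmin(pmax(floor(sz / spacing$dz), 0), d[1] - 1)
  list(value = value, r_star = r_star, vz = vz, vy = vy, vx = vx,
       valid = valid)
}

#' Sample the stack along one radial ray
#'
#' Samples intensities at radii `r_lo*R` to `r_hi*R` (R = local ellipsoid
#' radius) in steps of `radial_step` along `center + r * u(phi, lambda)`,
#' and reduces them with the configured ray statistic. For the `max`
#' statistic the returned radius and voxel are those of the intensity
#' peak (ties broken toward the smallest radius); for `mean`/`sum` they
#' refer to the window center. Samples outside the stack are skipped.
#'
#' @param stack an [image_stack()].
#' @param e a [reference_ellipsoid()].
#' @param phi,lambda spherical coordinates of the ray direction (under
#'   `options$unfold_axis`).
#' @param options an [unfold_options()].
#' @param t,c time/channel index (1-based).
#' @return A list with `value`, `r_star` (um), `voxel` (0-based
#'   `(t, c, z, y, x)`), or `NULL` when the whole ray misses the volume.
#' @export
sample_radial_ray <- function(stack, e, phi, lambda, options, t = 1L,
                              c = 1L) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(e, "reference_ellipsoid"),
            inherits(options, "unfold_options"))
  vol <- stack_volume(stack, t, c)
  sp <- stack$spacing
  step <- options$radial_step %||% (min(sp$dx, sp$dy, sp$dz) / 2)
  u <- direction_from_latlon(phi, normalize_longitude(lambda),
                             options$unfold_axis)
  R <- ellipsoid_radius_dir(e, u$ux, u$uy, u$uz)
  res <- sample_rays_core(vol, sp, e$center, u$ux, u$uy, u$uz, R, options,
                          step)
  if (!res$valid[1]) return(NULL)
  list(value = res$value[1], r_star = res$r_star[1],
       voxel = c(t = t - 1L, c = c - 1L, z = res$vz[1], y = res$vy[1],
                 x = res$vx[1]))
}

#' Unfold a stack channel onto a 2D map
#'
#' Rasterizes the map by pulling every pixel back to a sphere direction
#' and sampling the stack radially around the reference ellipsoid. The
#' result carries, for every valid map pixel, a cross-reference row
#' linking it to the source voxel, sampled radius, spherical coordinates
#' and elevation above the ellipsoid, so map-space selections can be
#' measured on the original voxel data.
#'
#' @param stack an [image_stack()].
#' @param e a [reference_ellipsoid()].
#' @param options an [unfold_options()].
#' @param t,c time/channel index (1-based). For 4D/5D stacks call once
#'   per (t, c) to obtain a map series.
#' @return An object of class `map_image`: `values` (map raster, `NA`
#'   outside the mask), `mask`, `crossref` (data frame, one row per valid
#'   pixel: `map_x`, `map_y` (0-based pixel column/row), `phi`, `lon`,
#'   `r_star`, `elevation_um`, `t`, `c`, `z`, `y`, `x` (0-based voxel)),
#'   `options`, `ellipsoid`.
#' @export
unfold_intensity <- function(stack, e, options = unfold_options(),
                             t = 1L, c = 1L) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(e, "reference_ellipsoid"),
            inherits(options, "unfold_options"))
  vol <- stack_volume(stack, t, c)
  sp <- stack$spacing
  step <- options$radial_step %||% (min(sp$dx, sp$dy, sp$dz) / 2)
  g <- build_direction_grid(options)
  h <- options$map_height; w <- options$map_width
  idx <- which(g$mask)
  ux <- g$ux[idx]; uy <- g$uy[idx]; uz <- g$uz[idx]
  R <- ellipsoid_radius_dir(e, ux, uy, uz)
  ext <- c(dim(vol)[3] * sp$dx, dim(vol)[2] * sp$dy, dim(vol)[1] * sp$dz)
  surf <- cbind(e$center[1] + R * ux, e$center[2] + R * uy,
                e$center[3] + R * uz)
  out_frac <- mean(surf[, 1] < 0 | surf[, 1] > ext[1] |
                     surf[, 2] < 0 | surf[, 2] > ext[2] |
                     surf[, 3] < 0 | surf[, 3] > ext[3])
  if (out_frac >= 1) {
    stop("reference ellipsoid lies entirely outside the stack volume",
         call. = FALSE)
  }
  if (out_frac > 0.5) {
    warning(sprintf(
      "%.0f%% of the ellipsoid surface lies outside the stack volume",
      100 * out_frac), call. = FALSE)
  }
  values <- matrix(NA_real_, h, w)
  mask <- matrix(FALSE, h, w)
  # chunk the pixel set to bound the n x N sampling matrices
  chunk <- max(1L, as.integer(2e6 / max(1, (options$radial_window[2] -
    options$radial_window[1]) * max(R) / step)))
  res_list <- list()
  for (start in seq(1L, length(idx), by = chunk)) {
    sl <- start:min(start + chunk - 1L, length(idx))
    r <- sample_rays_core(vol, sp, e$center, ux[sl], uy[sl], uz[sl],
                          R[sl], options, step)
    res_list[[length(res_list) + 1L]] <- c(r, list(idx = idx[sl]))
  }
  value <- unlist(lapply(res_list, `[[`, "value"))
  r_star <- unlist(lapply(res_list, `[[`, "r_star"))
  vzyx <- cbind(z = unlist(lapply(res_list, `[[`, "vz")),
                y = unlist(lapply(res_list, `[[`, "vy")),
                x = unlist(lapply(res_list, `[[`, "vx")))
  valid <- unlist(lapply(res_list, `[[`, "valid"))
  values[idx] <- value
  mask[idx] <- valid
  values[!mask] <- NA_real_

  keep <- which(valid)
  pix <- idx[keep]
  row0 <- (pix - 1L) %% h         # 0-based map row
  col0 <- (pix - 1L) %/% h        # 0-based map column
  phi <- g$phi[pix]; lon <- g$lambda[pix]
  elev <- r_star[keep] - R[keep]
  crossref <- data.frame(
    map_x = col0, map_y = row0, phi = phi, lon = lon,
    r_star = r_star[keep], elevation_um = elev,
    t = t - 1L, c = c - 1L,
    z = vzyx[keep, "z"], y = vzyx[keep, "y"], x = vzyx[keep, "x"]
  )
  structure(list(values = values, mask = mask, crossref = crossref,
                 options = options, ellipsoid = e),
            class = "map_image")
}

#' @export
print.map_image <- function(x, ...) {
  cat(sprintf(
    "Map image %dx%d (%s projection, %s statistic), %d/%d valid pixels\n",
    x$options$map_width, x$options$map_height, x$options$projection$name,
    x$options$ray_statistic, sum(x$mask), length(x$mask)))
  if (any(x$mask)) {
    cat(sprintf("  intensity range [%g, %g]\n",
                min(x$values[x$mask]), max(x$values[x$mask])))
  }
  invisible(x)
}

#' @export
plot.map_image <- function(x, ..., lut = "gray") {
  v <- x$values
  v[!x$mask] <- NA
  graphics::image(t(v)[, nrow(v):1], col = map_lut(lut), axes = FALSE,
                  asp = nrow(v) / ncol(v), ...)
  invisible(x)
}

#' Unfold the surface height above the reference ellipsoid
#'
#' Localizes the surface along each ray as the radial intensity peak
#' (the ray statistic is forced to `max`) and reports its signed
#' elevation `r* - R(phi, lambda)` in um: positive for protrusions,
#' negative for indentations.
#'
#' @inheritParams unfold_intensity
#' @return An object of class `height_map`: `elevation` (um raster),
#'   `mask`, `crossref`, `options`, `ellipsoid`.
#' @export
unfold_height <- function(stack, e, options = unfold_options(),
                          t = 1L, c = 1L) {
  options$ray_statistic <- "max"
  m <- unfold_intensity(stack, e, options, t, c)
  elev <- matrix(NA_real_, nrow(m$values), ncol(m$values))
  elev[cbind(m$crossref$map_y + 1L, m$crossref$map_x + 1L)] <-
    m$crossref$elevation_um
  structure(list(elevation = elev, mask = m$mask, crossref = m$crossref,
                 options = options, ellipsoid = e),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("Height map %dx%d, %d valid pixels\n",
              ncol(x$elevation), nrow(x$elevation), sum(x$mask)))
  if (any(x$mask)) {
    cat(sprintf("  elevation range [%+.3f, %+.3f] um\n",
                min(x$elevation[x$mask]), max(x$elevation[x$mask])))
  }
  invisible(x)
}

#' @export
plot.height_map <- function(x, ...) {
  v <- x$elevation
  v[!x$mask] <- NA
  rng <- max(abs(v[x$mask]), 1e-12)
  graphics::image(t(v)[, nrow(v):1], col = hypsometric_palette(),
                  zlim = c(-rng, rng), axes = FALSE,
                  asp = nrow(v) / ncol(v), ...)
  invisible(x)
}

#' Hypsometric coloring of a height map
#'
#' Applies a diverging elevation color table centered at zero elevation
#' (the neutral midpoint color maps to zero exactly), spanning
#' +/- `symmetric_range` um (default: the maximum absolute elevation).
#'
#' @param h a `height_map`.
#' @param symmetric_range optional color range half-width, um.
#' @return An `height x width x 3` RGB array in \[0, 1\]; out-of-mask
#'   pixels are mid-gray.
#' @export
apply_hypsometric_lut <- function(h, symmetric_range = NULL) {
  stopifnot(inherits(h, "height_map"))
  if (!any(h$mask)) stop("height map mask is empty", call. = FALSE)
  rng <- symmetric_range %||% max(abs(h$elevation[h$mask]))
  if (rng == 0) rng <- 1
  cols <- hypsometric_palette()
  n <- length(cols)
  u <- (h$elevation / rng + 1) / 2
  idx <- pmin(pmax(round(u * (n - 1)) + 1, 1), n)
  rgb <- array(0.25, dim = c(nrow(h$elevation), ncol(h$elevation), 3))
  chan <- col2rgb(cols) / 255
  for (k in 1:3) {
    plane <- rgb[, , k]
    plane[h$mask] <- chan[k, idx[h$mask]]
    rgb[, , k] <- plane
  }
  rgb
}

#' Serialize / read a cross-reference table
#'
#' Tab-separated text, one row per valid map pixel, so external tools can
#' audit the provenance of every map pixel.
#'
#' @param x a `map_image`/`height_map` or its `crossref` data frame.
#' @param path file path.
#' @return `write_crossref`: invisibly, the path; `read_crossref`: the
#'   data frame.
#' @export
write_crossref <- function(x, path) {
  tab <- if (is.data.frame(x)) x else x$crossref
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_crossref
#' @export
read_crossref <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
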
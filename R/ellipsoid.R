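#' Surface point cloud
#'
#' Intensity-weighted 3D points (physical um) extracted from a stack,
#' used as input to [fit_ellipsoid()].
#'
#' @param points numeric matrix, n x 3, columns (x, y, z) in um.
#' @param weights non-negative per-point weights; default 1.
#' @return An object of class `surface_point_cloud`.
#' @export
surface_point_cloud <- function(points, weights = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (any(!is.finite(points))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(points))
  weights <- as.numeric(weights)
  stopifnot(length(weights) == nrow(points))
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, weights = weights),
            class = "surface_point_cloud")
}

#' @export
print.surface_point_cloud <- function(x, ...) {
  cat(sprintf("Surface point cloud: %d points, weight range [%g, %g]\n",
              nrow(x$points), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Extract surface points from a stack
#'
#' Voxels above an automatic (Otsu) or user-given absolute threshold
#' become points at their voxel-center physical coordinates, weighted by
#' intensity. An optional largest-connected-component filter
#' (26-connectivity, on by default) removes disconnected debris such as
#' hot pixels before fitting.
#'
#' @param stack an [image_stack()].
#' @param t,c time and channel index (1-based).
#' @param method `"otsu"` (default) or a single numeric absolute
#'   threshold; voxels strictly above it are kept.
#' @param largest_component keep only the largest 26-connected component
#'   of the thresholded mask.
#' @return A [surface_point_cloud()].
#' @export
extract_surface_points <- function(stack, t = 1L, c = 1L, method = "otsu",
                                   largest_component = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  vol <- stack_volume(stack, t, c)
  if (identical(method, "otsu")) {
    rng <- range(vol)
    if (rng[1] == rng[2]) {
      stop("empty result: volume is constant, nothing to threshold",
           call. = FALSE)
    }
    thr <- EBImage::otsu(matrix(as.vector(vol), ncol = 1L), range = rng)
  } else if (is.numeric(method) && length(method) == 1L) {
    thr <- method
  } else {
    stop("method must be \"otsu\" or a single numeric threshold",
         call. = FALSE)
  }
  fg <- vol > thr
  if (!any(fg)) {
    stop("empty result: no voxels above the threshold", call. = FALSE)
  }
  if (largest_component) {
    lab <- label_components(fg, connectivity = 26L)
    keep <- which.max(tabulate(lab[lab > 0L]))
    fg <- lab == keep
  }
  idx <- which(fg)
  pos <- arrayInd(idx, dim(vol))  # (z, y, x), 1-based
  sp <- stack$spacing
  pts <- cbind(x = (pos[, 3] - 0.5) * sp$dx,
               y = (pos[, 2] - 0.5) * sp$dy,
               z = (pos[, 1] - 0.5) * sp$dz)
  surface_point_cloud(pts, weights = as.numeric(vol[idx]))
}

#' Axis-aligned reference ellipsoid
#'
#' The elevation baseline and unfolding geometry: center and semi-axes
#' (a, b, c) along X, Y, Z in um, plus the pole axis used when converting
#' between directions and (latitude, longitude).
#'
#' @param center numeric length-3, (x, y, z) um.
#' @param semi_axes numeric length-3, (a, b, c) um, all positive.
#' @param pole_axis `"X"`, `"Y"` or `"Z"`.
#' @return An object of class `reference_ellipsoid`.
#' @export
reference_ellipsoid <- function(center, semi_axes, pole_axis = "Z") {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  stopifnot(length(center) == 3, length(semi_axes) == 3)
  if (any(!is.finite(center)) || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0)) {
    stop("semi-axes must be positive and all parameters finite",
         call. = FALSE)
  }
  pole_axis <- toupper(pole_axis)
  stopifnot(pole_axis %in% c("X", "Y", "Z"))
  structure(list(center = stats::setNames(center, c("x", "y", "z")),
                 semi_axes = stats::setNames(semi_axes, c("a", "b", "c")),
                 pole_axis = pole_axis),
            class = "reference_ellipsoid")
}

#' @export
print.reference_ellipsoid <- function(x, ...) {
  cat(sprintf(
    "Reference ellipsoid: center (%.3f, %.3f, %.3f) um, semi-axes (%.3f, %.3f, %.3f) um, pole %s\n",
    x$center[1], x$center[2], x$center[3],
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$pole_axis))
  invisible(x)
}

#' @export
coef.reference_ellipsoid <- function(object, ...) {
  c(object$center, object$semi_axes)
}

#' Fit an axis-aligned ellipsoid to a surface point cloud
#'
#' Weighted linear least squares on the algebraic quadric form
#' \eqn{A x^2 + B y^2 + C z^2 + D x + E y + F z = 1}, followed by
#' conversion to center and semi-axes of
#' \eqn{((x-x_0)/a)^2 + ((y-y_0)/b)^2 + ((z-z_0)/c)^2 = 1}.
#'
#' @param cloud a [surface_point_cloud()] with at least 9 points, not all
#'   coplanar.
#' @param pole_axis pole axis recorded on the result (`"X"`, `"Y"`,
#'   `"Z"`).
#' @return A [reference_ellipsoid()].
#' @export
fit_ellipsoid <- function(cloud, pole_axis = "Z") {
  stopifnot(inherits(cloud, "surface_point_cloud"))
  P <- cloud$points
  w <- cloud$weights
  if (nrow(P) < 9) {
    stop("at least 9 points are required to fit the ellipsoid",
         call. = FALSE)
  }
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop("points are (nearly) coplanar; ellipsoid fit is degenerate",
         call. = FALSE)
  }
  X <- cbind(P[, 1]^2, P[, 2]^2, P[, 3]^2, P[, 1], P[, 2], P[, 3])
  fit <- stats::lm.wfit(X, rep(1, nrow(P)), w = w)
  q <- fit$coefficients
  if (any(is.na(q))) {
    stop("ellipsoid fit is rank-deficient", call. = FALSE)
  }
  ABC <- q[1:3]
  # the quadric is an ellipsoid iff the quadratic coefficients share a
  # sign and the completed-square constant S has that same sign, making
  # every semi-axis^2 = S/coefficient positive
  S <- 1 + sum(q[4:6]^2 / (4 * ABC))
  ax2 <- S / ABC
  bad <- which(!is.finite(ax2) | ax2 <= 0)
  if (length(bad)) {
    stop("degenerate fit: no real semi-axis along axis ",
         paste(c("X", "Y", "Z")[bad], collapse = ", "), call. = FALSE)
  }
  center <- -q[4:6] / (2 * ABC)
  reference_ellipsoid(center, sqrt(ax2), pole_axis = pole_axis)
}

#' Radius of the reference ellipsoid in a given direction
#'
#' Distance from the center to the ellipsoid surface along the unit
#' direction defined by (lat, lon) under the ellipsoid's pole axis:
#' lat = +/- pi/2 points along +/- the pole axis; (lat 0, lon 0) points
#' along the first of the remaining axes in X < Y < Z order. Closed form
#' \eqn{r = 1 / \sqrt{u_x^2/a^2 + u_y^2/b^2 + u_z^2/c^2}}.
#'
#' @param e a [reference_ellipsoid()].
#' @param lat latitude(s), radians in \eqn{[-\pi/2, \pi/2]}.
#' @param lon longitude(s), radians.
#' @return Radius (um), vectorized.
#' @export
ellipsoid_radius <- function(e, lat, lon) {
  stopifnot(inherits(e, "reference_ellipsoid"))
  if (any(abs(lat) > pi / 2 + 1e-9, na.rm = TRUE)) {
    stop("lat outside [-pi/2, pi/2]", call. = FALSE)
  }
  u <- direction_from_latlon(lat, normalize_longitude(lon), e$pole_axis)
  ax <- e$semi_axes
  1 / sqrt(u$ux^2 / ax[["a"]]^2 + u$uy^2 / ax[["b"]]^2 + u$uz^2 / ax[["c"]]^2)
}

# Radius along explicit unit directions (n x 3 components).
ellipsoid_radius_dir <- function(e, ux, uy, uz) {
  ax <- e$semi_axes
  1 / sqrt(ux^2 / ax[["a"]]^2 + uy^2 / ax[["b"]]^2 + uz^2 / ax[["c"]]^2)
}

#' Write / read a reference ellipsoid sidecar file
#'
#' Plain-text key/value serialization (um units) so a fitted ellipsoid can
#' be pinned across runs or supplied manually.
#'
#' @param e a [reference_ellipsoid()].
#' @param path file path.
#' @return `write_ellipsoid`: invisibly, the path. `read_ellipsoid`: the
#'   ellipsoid.
#' @export
write_ellipsoid <- function(e, path) {
  stopifnot(inherits(e, "reference_ellipsoid"))
  writeLines(c(
    "# stackmap reference ellipsoid (units: um)",
    paste0("center_x=", format(e$center[["x"]], digits = 17)),
    paste0("center_y=", format(e$center[["y"]], digits = 17)),
    paste0("center_z=", format(e$center[["z"]], digits = 17)),
    paste0("semi_a=", format(e$semi_axes[["a"]], digits = 17)),
    paste0("semi_b=", format(e$semi_axes[["b"]], digits = 17)),
    paste0("semi_c=", format(e$semi_axes[["c"]], digits = 17)),
    paste0("pole_axis=", e$pole_axis)
  ), path)
  invisible(path)
}

#' @rdname write_ellipsoid
#' @export
read_ellipsoid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(p) trimws(p[[2]]), ""),
                          vapply(kv, function(p) trimws(p[[1]]), ""))
  reference_ellipsoid(
    center = as.numeric(vals[c("center_x", "center_y", "center_z")]),
    semi_axes = as.numeric(vals[c("semi_a", "semi_b", "semi_c")]),
    pole_axis = vals[["pole_axis"]]
  )
}
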
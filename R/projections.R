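# Registry of the nine supported projections, in stable order.
# Display names follow common cartographic usage.
.PROJECTIONS <- c(
  equirectangular     = "Equirectangular",
  mercator            = "Mercator",
  braun               = "Braun",
  miller              = "Miller",
  lambert_cylindrical = "Lambert-cylindrical",
  sinusoidal          = "sinusoidal",
  mollweide           = "Mollweide",
  wagner6             = "Wagner VI",
  bonne               = "Bonne"
)

#' List the available map projections
#'
#' @param display logical; if `TRUE`, return the conventional cartographic
#'   display names instead of the internal identifiers.
#' @return Character vector of nine projection names, in stable order.
#' @export
#' @examples
#' list_projections()
list_projections <- function(display = FALSE) {
  if (display) unname(.PROJECTIONS) else names(.PROJECTIONS)
}

#' Specify a map projection
#'
#' Creates a projection specification used by [forward_project()],
#' [inverse_project()] and the unfolding pipeline.
#'
#' All projections operate on the unit sphere: latitude `phi` in
#' \eqn{[-\pi/2, \pi/2]}, longitude `lambda` in \eqn{(-\pi, \pi]}. Physical
#' scale enters only when the stack is sampled along the fitted reference
#' ellipsoid. The Mercator and Braun projections are clamped at
#' `lat_clamp` (default 85 degrees) because their planar extent is
#' unbounded (Mercator) or strongly stretched (Braun) near the poles. The
#' Bonne projection uses a standard parallel `bonne_parallel` (default 45
#' degrees) and is shifted vertically so the origin (0, 0) maps to (0, 0).
#'
#' @param name projection name, case-insensitive; one of
#'   `list_projections()`.
#' @param bonne_parallel standard parallel for the Bonne projection,
#'   radians, in (0, pi/2).
#' @param lat_clamp latitude clamp for Mercator/Braun, radians, in
#'   (0, pi/2).
#' @return An object of class `projection_spec`.
#' @export
projection_spec <- function(name, bonne_parallel = pi / 4,
                            lat_clamp = 85 * pi / 180) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(gsub("[ -]", "_", trimws(name)))
  key <- switch(key,
    "lambert" = "lambert_cylindrical",
    "wagner_vi" = "wagner6",
    key
  )
  if (!key %in% names(.PROJECTIONS)) {
    stop("unknown projection '", name, "'; see list_projections()",
         call. = FALSE)
  }
  if (!is.finite(bonne_parallel) || bonne_parallel <= 0 ||
      bonne_parallel >= pi / 2) {
    stop("bonne_parallel must lie in (0, pi/2)", call. = FALSE)
  }
  if (!is.finite(lat_clamp) || lat_clamp <= 0 || lat_clamp >= pi / 2) {
    stop("lat_clamp must lie in (0, pi/2)", call. = FALSE)
  }
  structure(
    list(name = key, bonne_parallel = bonne_parallel, lat_clamp = lat_clamp),
    class = "projection_spec"
  )
}

#' @export
print.projection_spec <- function(x, ...) {
  cat("Map projection:", .PROJECTIONS[[x$name]], sprintf("(%s)\n", x$name))
  if (x$name == "bonne") {
    cat(sprintf("  standard parallel: %.4f rad (%.1f deg)\n",
                x$bonne_parallel, x$bonne_parallel * 180 / pi))
  }
  if (x$name %in% c("mercator", "braun")) {
    cat(sprintf("  latitude clamp: %.4f rad (%.1f deg)\n",
                x$lat_clamp, x$lat_clamp * 180 / pi))
  }
  invisible(x)
}

as_projection_spec <- function(x) {
  if (inherits(x, "projection_spec")) x else projection_spec(x)
}

#' Normalize longitude into (-pi, pi]
#'
#' The map seam is fixed at the -pi side: -pi normalizes to +pi so every
#' direction has a unique longitude.
#'
#' @param lambda longitude(s), radians.
#' @return Normalized longitude(s).
#' @export
normalize_longitude <- function(lambda) {
  l <- (lambda + pi) %% (2 * pi) - pi
  l[l <= -pi + 1e-15] <- pi
  l
}

#' Solve the Mollweide auxiliary angle
#'
#' Newton iteration for theta in `2 theta + sin(2 theta) = pi sin(phi)`,
#' started at `theta = phi`. The poles are short-circuited to +/- pi/2
#' where the derivative of the defining equation vanishes.
#'
#' @param phi latitude(s), radians, |phi| <= pi/2.
#' @param tol convergence tolerance on the residual (default 1e-12).
#' @param max_iter maximum Newton iterations (default 50).
#' @return theta in radians, vectorized over `phi`.
#' @export
solve_mollweide_theta <- function(phi, tol = 1e-12, max_iter = 50L) {
  stopifnot(tol > 0, max_iter >= 1L)
  if (any(abs(phi) > pi / 2 + 1e-12, na.rm = TRUE)) {
    stop("|phi| must not exceed pi/2", call. = FALSE)
  }
  theta <- phi
  target <- pi * sin(phi)
  pole <- abs(abs(phi) - pi / 2) < 1e-12
  theta[pole] <- sign(phi[pole]) * pi / 2
  active <- which(!pole & is.finite(phi))
  for (it in seq_len(max_iter)) {
    if (!length(active)) break
    th <- theta[active]
    resid <- 2 * th + sin(2 * th) - target[active]
    theta[active] <- th - resid / (2 + 2 * cos(2 * th))
    th <- theta[active]
    done <- abs(2 * th + sin(2 * th) - target[active]) < tol
    active <- active[!done]
  }
  if (length(active)) {
    stop("Mollweide theta iteration failed to converge", call. = FALSE)
  }
  theta
}

cot <- function(x) 1 / tan(x)

#' Forward map projection
#'
#' Projects spherical coordinates onto the map plane (unit-sphere scale).
#'
#' @param spec a [projection_spec()] (or projection name).
#' @param phi latitude(s), radians in \eqn{[-\pi/2, \pi/2]}.
#' @param lambda longitude(s), radians; normalized into \eqn{(-\pi, \pi]}.
#' @return A list with numeric vectors `x` and `y`.
#' @export
#' @examples
#' forward_project("mollweide", pi / 2, 0)  # north pole -> (0, sqrt(2))
forward_project <- function(spec, phi, lambda) {
  spec <- as_projection_spec(spec)
  n <- max(length(phi), length(lambda))
  phi <- rep_len(phi, n)
  lambda <- normalize_longitude(rep_len(lambda, n))
  if (any(abs(phi) > pi / 2 + 1e-9, na.rm = TRUE)) {
    stop("latitude outside [-pi/2, pi/2]", call. = FALSE)
  }
  phi <- pmin(pmax(phi, -pi / 2), pi / 2)
  if (spec$name %in% c("mercator", "braun")) {
    clamp <- spec$lat_clamp
    if (any(abs(phi) > clamp + 1e-12, na.rm = TRUE)) {
      warning("latitudes beyond the clamp were clamped to +/- ",
              format(clamp * 180 / pi), " deg", call. = FALSE)
      phi <- pmin(pmax(phi, -clamp), clamp)
    }
  }
  switch(spec$name,
    equirectangular = list(x = lambda, y = phi),
    mercator = list(x = lambda, y = log(tan(pi / 4 + phi / 2))),
    braun = list(x = lambda, y = 2 * tan(phi / 2)),
    miller = list(x = lambda, y = 1.25 * log(tan(pi / 4 + 0.4 * phi))),
    lambert_cylindrical = list(x = lambda, y = sin(phi)),
    sinusoidal = list(x = lambda * cos(phi), y = phi),
    mollweide = {
      theta <- solve_mollweide_theta(phi)
      list(x = (2 * sqrt(2) / pi) * lambda * cos(theta),
           y = sqrt(2) * sin(theta))
    },
    wagner6 = list(x = lambda * sqrt(1 - 3 * (phi / pi)^2), y = phi),
    bonne = {
      p1 <- spec$bonne_parallel
      rho <- cot(p1) + p1 - phi
      E <- lambda * cos(phi) / rho
      # +p1 shift puts (phi=0, lambda=0) at the map origin
      list(x = rho * sin(E), y = cot(p1) - rho * cos(E) + p1)
    }
  )
}

#' Inverse map projection
#'
#' Pulls a map-plane point back to spherical coordinates. Points with no
#' spherical preimage are reported via `inside = FALSE` (their `phi` and
#' `lambda` are `NA`).
#'
#' @param spec a [projection_spec()] (or projection name).
#' @param x,y map-plane coordinates (unit-sphere scale).
#' @return A list with numeric vectors `phi`, `lambda` and logical
#'   `inside`.
#' @export
inverse_project <- function(spec, x, y) {
  spec <- as_projection_spec(spec)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  tol <- 1e-9
  res <- switch(spec$name,
    equirectangular = list(phi = y, lambda = x),
    mercator = list(phi = 2 * atan(exp(y)) - pi / 2, lambda = x),
    braun = list(phi = 2 * atan(y / 2), lambda = x),
    miller = list(phi = 2.5 * (atan(exp(0.8 * y)) - pi / 4), lambda = x),
    lambert_cylindrical = {
      phi <- rep(NA_real_, n)
      ok <- abs(y) <= 1 + tol
      phi[ok] <- asin(pmin(pmax(y[ok], -1), 1))
      list(phi = phi, lambda = x)
    },
    sinusoidal = {
      phi <- y
      lam <- rep(NA_real_, n)
      ok <- abs(phi) <= pi / 2 + tol
      lam[ok] <- ifelse(abs(cos(phi[ok])) < 1e-15,
                        ifelse(abs(x[ok]) < tol, 0, NA_real_),
                        x[ok] / cos(phi[ok]))
      list(phi = phi, lambda = lam)
    },
    mollweide = {
      phi <- rep(NA_real_, n)
      lam <- rep(NA_real_, n)
      ok <- abs(y) <= sqrt(2) + tol
      theta <- asin(pmin(pmax(y[ok] / sqrt(2), -1), 1))
      s <- (2 * theta + sin(2 * theta)) / pi
      okk <- abs(s) <= 1 + tol
      phi_ok <- rep(NA_real_, length(theta))
      phi_ok[okk] <- asin(pmin(pmax(s[okk], -1), 1))
      ct <- cos(theta)
      lam_ok <- ifelse(ct < 1e-15,
                       ifelse(abs(x[ok]) < tol, 0, NA_real_),
                       pi * x[ok] / (2 * sqrt(2) * ct))
      phi[ok] <- phi_ok
      lam[ok] <- lam_ok
      list(phi = phi, lambda = lam)
    },
    wagner6 = {
      phi <- y
      lam <- rep(NA_real_, n)
      ok <- abs(phi) <= pi / 2 + tol
      f <- sqrt(pmax(1 - 3 * (phi[ok] / pi)^2, 0))
      lam[ok] <- ifelse(f < 1e-15, ifelse(abs(x[ok]) < tol, 0, NA_real_),
                        x[ok] / f)
      list(phi = phi, lambda = lam)
    },
    bonne = {
      p1 <- spec$bonne_parallel
      y0 <- y - p1                      # undo the forward shift
      dy <- cot(p1) - y0
      rho <- sign(p1) * sqrt(x^2 + dy^2)
      phi <- cot(p1) + p1 - rho
      lam <- rep(NA_real_, n)
      ok <- abs(phi) <= pi / 2 + tol
      E <- atan2(x[ok], dy[ok])
      cph <- cos(phi[ok])
      lam[ok] <- ifelse(abs(cph) < 1e-15,
                        ifelse(abs(E) < tol, 0, NA_real_),
                        rho[ok] * E / cph)
      list(phi = phi, lambda = lam)
    }
  )
  phi <- res$phi
  lam <- res$lambda
  inside <- is.finite(phi) & is.finite(lam) &
    abs(phi) <= pi / 2 + tol & lam > -pi - tol & lam <= pi + tol
  inside[is.na(inside)] <- FALSE
  phi[!inside] <- NA_real_
  lam[!inside] <- NA_real_
  phi[inside] <- pmin(pmax(phi[inside], -pi / 2), pi / 2)
  lam[inside] <- normalize_longitude(pmin(pmax(lam[inside], -pi), pi))
  list(phi = phi, lambda = lam, inside = inside)
}

#' Map-plane bounding box of a projection
#'
#' The full planar extent of the projected sphere (after clamping, for
#' Mercator/Braun). Used to place the raster of map pixels.
#'
#' @param spec a [projection_spec()] (or projection name).
#' @return A list with `xlim` and `ylim` (length-2 numeric).
#' @export
projection_bbox <- function(spec) {
  spec <- as_projection_spec(spec)
  switch(spec$name,
    equirectangular = list(xlim = c(-pi, pi), ylim = c(-pi / 2, pi / 2)),
    mercator = {
      ym <- log(tan(pi / 4 + spec$lat_clamp / 2))
      list(xlim = c(-pi, pi), ylim = c(-ym, ym))
    },
    braun = {
      ym <- 2 * tan(spec$lat_clamp / 2)
      list(xlim = c(-pi, pi), ylim = c(-ym, ym))
    },
    miller = {
      ym <- 1.25 * log(tan(pi / 4 + 0.4 * pi / 2))
      list(xlim = c(-pi, pi), ylim = c(-ym, ym))
    },
    lambert_cylindrical = list(xlim = c(-pi, pi), ylim = c(-1, 1)),
    sinusoidal = list(xlim = c(-pi, pi), ylim = c(-pi / 2, pi / 2)),
    mollweide = list(xlim = c(-2 * sqrt(2), 2 * sqrt(2)),
                     ylim = c(-sqrt(2), sqrt(2))),
    wagner6 = list(xlim = c(-pi, pi), ylim = c(-pi / 2, pi / 2)),
    bonne = {
      phi <- seq(-pi / 2, pi / 2, length.out = 4001)
      edge <- forward_project(spec, c(phi, phi), c(rep(pi, 4001), rep(-pi, 4001)))
      pole <- forward_project(spec, c(-pi / 2, pi / 2), c(0, 0))
      xs <- c(edge$x, pole$x)
      ys <- c(edge$y, pole$y)
      list(xlim = range(xs), ylim = range(ys))
    }
  )
}

#' Domain mask of a projection raster
#'
#' Logical raster marking the map pixels whose centers pull back to a valid
#' direction on the sphere. Cylindrical projections fill the whole
#' rectangle; Mollweide yields its 2:1 ellipse, sinusoidal its
#' cosine-bounded lens, Wagner VI and Bonne their standard outlines.
#'
#' @param spec a [projection_spec()] (or projection name).
#' @param width,height raster size in pixels.
#' @return A `height x width` logical matrix; row 1 is the top of the map
#'   (maximum map-plane y).
#' @export
projection_domain_mask <- function(spec, width, height) {
  spec <- as_projection_spec(spec)
  stopifnot(width >= 1, height >= 1)
  g <- map_pixel_grid(spec, width, height)
  inv <- inverse_project(spec, g$x, g$y)
  matrix(inv$inside, nrow = height, ncol = width)
}

# Map-plane coordinates of all pixel centers, row-major top-down raster.
# Returns vectors x, y of length width*height ordered as R matrices are
# (column-major: index = row + (col-1)*height).
map_pixel_grid <- function(spec, width, height) {
  bb <- projection_bbox(spec)
  xs <- bb$xlim[1] + (seq_len(width) - 0.5) / width * diff(bb$xlim)
  ys <- bb$ylim[2] - (seq_len(height) - 0.5) / height * diff(bb$ylim)
  list(x = rep(xs, each = height), y = rep(ys, times = width),
       xs = xs, ys = ys, bbox = bb)
}

# Unit direction from (phi, lambda) under a chosen pole axis.
# Pole axis maps phi = +pi/2 to +axis; (phi=0, lambda=0) maps to the first
# of the remaining axes in X < Y < Z order.
direction_from_latlon <- function(phi, lambda, pole_axis = "Z") {
  cp <- cos(phi)
  a <- cp * cos(lambda)  # first remaining axis
  b <- cp * sin(lambda)  # second remaining axis
  p <- sin(phi)          # pole axis
  switch(toupper(pole_axis),
    Z = list(ux = a, uy = b, uz = p),
    Y = list(ux = a, uy = p, uz = b),
    X = list(ux = p, uy = a, uz = b),
    stop("pole_axis must be one of X, Y, Z", call. = FALSE)
  )
}

# Inverse of direction_from_latlon.
latlon_from_direction <- function(ux, uy, uz, pole_axis = "Z") {
  v <- switch(toupper(pole_axis),
    Z = list(a = ux, b = uy, p = uz),
    Y = list(a = ux, b = uz, p = uy),
    X = list(a = uy, b = uz, p = ux),
    stop("pole_axis must be one of X, Y, Z", call. = FALSE)
  )
  nrm <- sqrt(v$a^2 + v$b^2 + v$p^2)
  list(phi = asin(pmin(pmax(v$p / nrm, -1), 1)),
       lambda = normalize_longitude(atan2(v$b, v$a)))
}
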
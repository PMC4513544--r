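#' Specify a synthetic spheroid phantom
#'
#' Describes an artificial image stack carrying an ellipsoidal shell with
#' an optional geometric surface pattern, Gaussian bumps/indentations,
#' additive noise and per-layer intensity jitter. The generated stacks
#' stand in for acquired test specimens (uniform spheres, patterned
#' surfaces, sparse ring features, undulating shells) so every pipeline
#' stage can be validated against known ground truth.
#'
#' @param shape integer length-3 `(z, y, x)` voxel counts.
#' @param spacing a [voxel_spacing()].
#' @param center ellipsoid center in um; default: volume center.
#' @param semi_axes `(a, b, c)` um along X, Y, Z.
#' @param thickness radial shell thickness in um. For the Gaussian
#'   profile this is twice the radial sigma; for the binary profile the
#'   full width. Must be at least one voxel.
#' @param pattern surface pattern, one of
#'   `list(type = "uniform")`,
#'   `list(type = "checkerboard", nlat =, nlon =, low =)`,
#'   `list(type = "rings", rings = cbind(phi, lambda, radius), width =)`
#'   (angles in radians, bright annuli on dark background), or
#'   `list(type = "graticule", step =, width =)` (radians).
#' @param bumps optional matrix `cbind(phi, lambda, height_um, sigma)`
#'   of Gaussian radial displacements (sigma = angular width, radians;
#'   negative height = indentation).
#' @param noise_sd additive Gaussian noise sigma, intensity units.
#' @param layer_jitter per-z-slice multiplicative jitter amplitude
#'   (relative); emulates slice-to-slice acquisition variability.
#' @param amplitude peak shell intensity.
#' @param profile `"gaussian"` (smooth radial shell) or `"binary"`.
#' @param pole_axis pole used to define the pattern's (phi, lambda).
#' @param seed integer seed; mandatory, drives every stochastic field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         spacing = voxel_spacing(0.5, 0.5, 0.5),
                         center = NULL,
                         semi_axes = c(12, 12, 12),
                         thickness = 1.5,
                         pattern = list(type = "uniform"),
                         bumps = NULL,
                         noise_sd = 0,
                         layer_jitter = 0,
                         amplitude = 1000,
                         profile = c("gaussian", "binary"),
                         pole_axis = "Z",
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 4))
  if (!inherits(spacing, "voxel_spacing")) {
    spacing <- do.call(voxel_spacing, as.list(spacing))
  }
  if (is.null(center)) {
    center <- c(shape[3] * spacing$dx, shape[2] * spacing$dy,
                shape[1] * spacing$dz) / 2
  }
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  min_vox <- min(spacing$dx, spacing$dy, spacing$dz)
  if (thickness < min_vox) {
    stop("shell thickness must be at least one voxel (", min_vox, " um)",
         call. = FALSE)
  }
  if (!is.null(bumps)) {
    bumps <- matrix(as.numeric(bumps), ncol = 4)
    colnames(bumps) <- c("phi", "lambda", "height", "sigma")
    if (any(abs(bumps[, "height"]) >= 0.5 * min(semi_axes))) {
      stop("bump heights must stay below half the smallest semi-axis",
           call. = FALSE)
    }
  }
  profile <- match.arg(profile)
  stopifnot(is.list(pattern), !is.null(pattern$type))
  if ((noise_sd > 0 || layer_jitter > 0) && is.null(seed)) {
    stop("a seed is mandatory for stochastic phantoms", call. = FALSE)
  }
  structure(list(
    shape = shape, spacing = spacing, center = as.numeric(center),
    semi_axes = semi_axes, thickness = thickness, pattern = pattern,
    bumps = bumps, noise_sd = noise_sd, layer_jitter = layer_jitter,
    amplitude = amplitude, profile = profile,
    pole_axis = toupper(pole_axis), seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Pattern multiplier in [0, 1] at spherical coordinates (phi, lambda).
pattern_value <- function(pattern, phi, lambda) {
  switch(pattern$type,
    uniform = rep(1, length(phi)),
    checkerboard = {
      nlat <- pattern$nlat %||% 4L
      nlon <- pattern$nlon %||% 8L
      low <- pattern$low %||% 0.25
      i <- pmin(floor((phi + pi / 2) / pi * nlat), nlat - 1)
      j <- pmin(floor((lambda + pi) / (2 * pi) * nlon), nlon - 1)
      ifelse((i + j) %% 2 == 0, 1, low)
    },
    rings = {
      rings <- pattern$rings
      width <- pattern$width %||% (6 * pi / 180)
      v <- rep(pattern$background %||% 0, length(phi))
      u <- direction_from_latlon(phi, lambda, "Z")
      for (r in seq_len(nrow(rings))) {
        uc <- direction_from_latlon(rings[r, 1], rings[r, 2], "Z")
        dot <- u$ux * uc$ux + u$uy * uc$uy + u$uz * uc$uz
        ang <- acos(pmin(pmax(dot, -1), 1))
        v[abs(ang - rings[r, 3]) <= width / 2] <- 1
      }
      v
    },
    graticule = {
      step <- pattern$step %||% (30 * pi / 180)
      width <- pattern$width %||% (3 * pi / 180)
      bg <- pattern$background %||% 0.2
      on_lat <- abs(phi - round(phi / step) * step) <= width / 2
      on_lon <- abs(lambda - round(lambda / step) * step) <= width / 2
      ifelse(on_lat | on_lon, 1, bg)
    },
    stop("unknown pattern type '", pattern$type, "'", call. = FALSE)
  )
}

# Radial bump displacement (um) at (phi, lambda).
bump_displacement <- function(bumps, phi, lambda) {
  if (is.null(bumps) || nrow(bumps) == 0) return(rep(0, length(phi)))
  u <- direction_from_latlon(phi, lambda, "Z")
  disp <- rep(0, length(phi))
  for (r in seq_len(nrow(bumps))) {
    uc <- direction_from_latlon(bumps[r, "phi"], bumps[r, "lambda"], "Z")
    dot <- u$ux * uc$ux + u$uy * uc$uy + u$uz * uc$uz
    ang <- acos(pmin(pmax(dot, -1), 1))
    disp <- disp + bumps[r, "height"] *
      exp(-ang^2 / (2 * bumps[r, "sigma"]^2))
  }
  disp
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Render a synthetic spheroid phantom stack
#'
#' Voxel intensity is a radial shell profile centered on the (possibly
#' bump-displaced) ellipsoid surface, multiplied by the surface pattern at
#' the voxel's (phi, lambda), plus optional noise and per-layer jitter.
#'
#' @param spec a [phantom_spec()].
#' @param field optional function `f(phi, lambda)` multiplying the shell
#'   (used by the diffusion simulator); applied instead of the pattern
#'   when given.
#' @return A list with `stack` (an [image_stack()]) and `truth`
#'   (ground-truth record: the true [reference_ellipsoid()], pattern,
#'   bumps and the spec).
#' @export
make_spheroid_stack <- function(spec, field = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  d <- spec$shape  # (z, y, x)
  ext <- c(d[3] * sp$dx, d[2] * sp$dy, d[1] * sp$dz)
  if (any(spec$center + spec$semi_axes > ext + 1e-9) ||
      any(spec$center - spec$semi_axes < -1e-9)) {
    stop("ellipsoid exceeds the stack volume", call. = FALSE)
  }
  xs <- (seq_len(d[3]) - 0.5) * sp$dx - spec$center[1]
  ys <- (seq_len(d[2]) - 0.5) * sp$dy - spec$center[2]
  zs <- (seq_len(d[1]) - 0.5) * sp$dz - spec$center[3]
  # voxel-center offsets; array dim (z, y, x)
  Z <- array(zs, dim = d)
  Y <- array(rep(ys, each = d[1]), dim = d)
  X <- array(rep(xs, each = d[1] * d[2]), dim = d)
  r <- sqrt(X^2 + Y^2 + Z^2)
  ll <- latlon_from_direction(X, Y, Z, spec$pole_axis)
  phi <- ll$phi; lam <- ll$lambda
  # a voxel exactly at the center has no direction; any one will do
  # (the shell profile is ~0 at r = 0)
  phi[!is.finite(phi)] <- 0
  lam[!is.finite(lam)] <- 0
  e_true <- reference_ellipsoid(spec$center, spec$semi_axes,
                                pole_axis = spec$pole_axis)
  u <- direction_from_latlon(phi, lam, spec$pole_axis)
  R <- ellipsoid_radius_dir(e_true, u$ux, u$uy, u$uz)
  R <- R + bump_displacement(spec$bumps, as.vector(phi), as.vector(lam))
  delta <- as.vector(r) - R
  prof <- if (spec$profile == "gaussian") {
    s <- spec$thickness / 2
    exp(-delta^2 / (2 * s^2))
  } else {
    as.numeric(abs(delta) <= spec$thickness / 2)
  }
  mult <- if (is.null(field)) {
    pattern_value(spec$pattern, as.vector(phi), as.vector(lam))
  } else {
    field(as.vector(phi), as.vector(lam))
  }
  vol <- array(spec$amplitude * prof * mult, dim = d)
  if (spec$noise_sd > 0 || spec$layer_jitter > 0) {
    vol <- with_seed(spec$seed, {
      if (spec$layer_jitter > 0) {
        jit <- pmax(1 + spec$layer_jitter * rnorm(d[1]), 0)
        vol <- vol * array(jit, dim = d)
      }
      if (spec$noise_sd > 0) {
        vol <- vol + array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
      }
      vol
    })
  }
  stack <- image_stack(vol, spacing = sp, axes = "ZYX")
  list(stack = stack,
       truth = list(ellipsoid = e_true, pattern = spec$pattern,
                    bumps = spec$bumps, spec = spec))
}

#' Simulate a photoactivation-style diffusing surface signal
#'
#' A scalar concentration field on the sphere evolves by explicit
#' finite-difference diffusion (Laplace-Beltrami operator with
#' \eqn{1/\cos\phi} metric terms on a regular (phi, lambda) grid), with a
#' constant influx inside a source cap emulating continuous
#' photoactivation. Rows poleward of 80 degrees are zonally averaged each
#' step, which regularizes the metric singularity. Each saved frame is
#' rendered to a shell stack through the phantom machinery, so the result
#' is a 4D (T, Z, Y, X) series with full ground truth.
#'
#' @param spec a [phantom_spec()]; its pattern is ignored (the diffusing
#'   field multiplies the shell), its jitter/noise/seed apply per frame.
#' @param source numeric length-3 `(phi, lambda, angular_radius)` of the
#'   photoactivated cap, radians.
#' @param D diffusion coefficient, rad^2/s.
#' @param influx source strength, intensity/s, applied inside the cap.
#' @param dt simulation time step, s. Must satisfy the explicit-scheme
#'   stability (CFL) bound; otherwise an error reports the bound.
#' @param n_frames number of saved frames (T).
#' @param steps_per_frame simulation steps between saved frames
#'   (default 1, i.e. one step per frame).
#' @param grid integer `(nlat, nlon)` of the surface grid.
#' @param influx_frames number of frames during which the influx is on
#'   (default all frames).
#' @return A list with `stack` (4D [image_stack()]), `fields` (list of
#'   per-frame concentration grids), `grid` (phi/lambda cell centers and
#'   cell solid angles), `cap_area` (discrete cap area, sr),
#'   `cap_area_analytic` (\eqn{2\pi(1-\cos r)}), and `truth` from the
#'   phantom.
#' @export
simulate_photoactivation_series <- function(spec, source, D, influx, dt,
                                            n_frames,
                                            steps_per_frame = 1L,
                                            grid = c(48L, 96L),
                                            influx_frames = n_frames) {
  stopifnot(inherits(spec, "phantom_spec"),
            length(source) == 3, D >= 0, influx > 0, dt > 0, n_frames >= 1)
  nlat <- as.integer(grid[1]); nlon <- as.integer(grid[2])
  dphi <- pi / nlat
  dlam <- 2 * pi / nlon
  phi_c <- -pi / 2 + (seq_len(nlat) - 0.5) * dphi
  lam_c <- -pi + (seq_len(nlon) - 0.5) * dlam
  polar <- abs(phi_c) > 80 * pi / 180  # zonally averaged rows
  if (D > 0) {
    cmin <- min(cos(phi_c[!polar]))
    dt_stable <- 1 / (2 * D * (1 / dphi^2 + 1 / (cmin^2 * dlam^2)))
    if (dt > dt_stable) {
      stop(sprintf(
        "CFL violation: dt = %g exceeds the stable bound %g s for this grid and D",
        dt, dt_stable), call. = FALSE)
    }
  }
  # anti-aliased source-cap indicator (5x5 subsampling per cell)
  sub <- 5L
  off <- (seq_len(sub) - (sub + 1) / 2) / sub
  cap_u <- direction_from_latlon(source[1], source[2], "Z")
  w_cap <- matrix(0, nlat, nlon)
  for (a in off) for (b in off) {
    pf <- phi_c + a * dphi
    lf <- lam_c + b * dlam
    P <- matrix(pf, nlat, nlon)
    L <- matrix(lf, nlat, nlon, byrow = TRUE)
    u <- direction_from_latlon(P, L, "Z")
    ang <- acos(pmin(pmax(u$ux * cap_u$ux + u$uy * cap_u$uy +
                            u$uz * cap_u$uz, -1), 1))
    w_cap <- w_cap + (ang <= source[3]) / sub^2
  }
  cell_area <- matrix(cos(phi_c) * dphi * dlam, nlat, nlon)
  cap_area <- sum(w_cap * cell_area)

  # conservative flux-form discretization of the Laplace-Beltrami operator
  cphi <- cos(phi_c)
  cphi_half <- cos(-pi / 2 + seq_len(nlat - 1) * dphi)  # interfaces
  conc <- matrix(0, nlat, nlon)
  fields <- vector("list", n_frames)
  step_field <- function(cc, add_source) {
    if (D > 0) {
      dcc <- cc[-1, , drop = FALSE] - cc[-nlat, , drop = FALSE]
      Fphi <- dcc / dphi * cphi_half  # interface fluxes, zero at poles
      div <- matrix(0, nlat, nlon)
      div[1, ] <- Fphi[1, ] / dphi
      div[nlat, ] <- -Fphi[nlat - 1, ] / dphi
      if (nlat > 2) {
        div[2:(nlat - 1), ] <- (Fphi[2:(nlat - 1), , drop = FALSE] -
                                  Fphi[1:(nlat - 2), , drop = FALSE]) / dphi
      }
      div <- div / cphi
      lap_lam <- (cc[, c(2:nlon, 1), drop = FALSE] - 2 * cc +
                    cc[, c(nlon, 1:(nlon - 1)), drop = FALSE]) / dlam^2
      lap_lam <- lap_lam / cphi^2
      lap_lam[polar, ] <- 0
      cc <- cc + dt * D * (div + lap_lam)
      if (any(polar)) {
        cc[polar, ] <- rowMeans(cc[polar, , drop = FALSE])
      }
    }
    if (add_source) cc <- cc + dt * influx * w_cap
    cc
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    for (s in seq_len(steps_per_frame)) {
      conc <- step_field(conc, add_source = f <= influx_frames)
    }
    fields[[f]] <- conc
    fspec <- spec
    fspec$seed <- spec$seed + f  # fresh jitter/noise per frame
    interp_field <- function(p, l) {
      i <- pmin(pmax(round((p + pi / 2) / dphi + 0.5), 1), nlat)
      j <- pmin(pmax(round((l + pi) / dlam + 0.5), 1), nlon)
      conc[cbind(i, j)]
    }
    frames[[f]] <- make_spheroid_stack(fspec, field = interp_field)
  }
  d <- spec$shape
  arr <- array(0, dim = c(n_frames, 1, d[1], d[2], d[3]))
  for (f in seq_len(n_frames)) {
    arr[f, 1, , , ] <- frames[[f]]$stack$values[1, 1, , , ]
  }
  stack <- image_stack(arr, spacing = spec$spacing, axes = "TCZYX")
  stack$axes <- "TZYX"
  list(stack = stack, fields = fields,
       grid = list(phi = phi_c, lambda = lam_c, cell_area = cell_area,
                   cap_weight = w_cap),
       cap_area = cap_area,
       cap_area_analytic = 2 * pi * (1 - cos(source[3])),
       truth = frames[[1]]$truth)
}
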
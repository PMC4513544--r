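# Shared helpers and independent oracles for the test suite.

# Well-conditioned angular distance (radians) between two sets of
# spherical coordinates, via atan2 of the cross/dot products.
angular_distance <- function(phi1, lam1, phi2, lam2) {
  d1 <- cbind(cos(phi1) * cos(lam1), cos(phi1) * sin(lam1), sin(phi1))
  d2 <- cbind(cos(phi2) * cos(lam2), cos(phi2) * sin(lam2), sin(phi2))
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  atan2(sqrt(rowSums(cr^2)), rowSums(d1 * d2))
}

# Independent point-in-polygon oracle: classic crossing-number test,
# written directly from the even-odd definition.
pip_oracle <- function(poly, px, py) {
  n <- nrow(poly)
  inside <- logical(length(px))
  for (p in seq_along(px)) {
    cross <- 0L
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      if ((yi > py[p]) != (yj > py[p])) {
        xint <- xi + (py[p] - yi) / (yj - yi) * (xj - xi)
        if (px[p] < xint) cross <- cross + 1L
      }
      j <- i
    }
    inside[p] <- (cross %% 2L) == 1L
  }
  inside
}

# Independent 3D connected-component oracle: queue-based flood fill,
# 26-connectivity.
flood_fill_labels <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nextlab <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      p <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        lin <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nextlab
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# Standard small phantom used across tests: centered sphere in an
# isotropic stack.
sphere_phantom <- function(radius = 12, shape = 64, vox = 0.5,
                           pattern = list(type = "uniform"),
                           thickness = 1.5, ...) {
  make_spheroid_stack(phantom_spec(
    shape = rep(shape, 3), spacing = voxel_spacing(vox, vox, vox),
    semi_axes = rep(radius, 3), thickness = thickness, pattern = pattern,
    ...))
}
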
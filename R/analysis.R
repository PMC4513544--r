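#' Region of interest in map coordinates
#'
#' A simple polygon drawn on the map raster. Coordinates are in map pixel
#' units: the center of the pixel in (0-based) column `j`, row `i` is at
#' `(x = j + 0.5, y = i + 0.5)` with y increasing downward from the top
#' of the map.
#'
#' @param vertices numeric matrix, n x 2, columns (x, y), n >= 3.
#' @param label character label.
#' @return An object of class `map_roi`.
#' @export
map_roi <- function(vertices, label = "roi") {
  vertices <- matrix(as.numeric(as.matrix(vertices)), ncol = 2)
  if (nrow(vertices) < 3) {
    stop("a polygon ROI needs at least 3 vertices", call. = FALSE)
  }
  if (any(!is.finite(vertices))) {
    stop("vertices must be finite", call. = FALSE)
  }
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, label = as.character(label)),
            class = "map_roi")
}

#' Polyline for plot profiling on the map
#'
#' @param vertices numeric matrix, n x 2, columns (x, y) in map pixel
#'   units (see [map_roi()] for the convention), n >= 2.
#' @param step sampling step along the line, map pixels.
#' @return An object of class `profile_line`.
#' @export
profile_line <- function(vertices, step = 1) {
  vertices <- matrix(as.numeric(as.matrix(vertices)), ncol = 2)
  stopifnot(nrow(vertices) >= 2, step > 0)
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, step = step),
            class = "profile_line")
}

#' Voxels referenced by a map-space ROI
#'
#' Selects the map pixels whose centers fall inside the polygon (even-odd
#' rule) and returns the de-duplicated set of stack voxels they
#' cross-reference. Selection happens in map space; measurement always
#' happens on the original stack.
#'
#' @param crossref a `map_image`/`height_map` or its cross-reference data
#'   frame.
#' @param roi a [map_roi()].
#' @param dedupe drop duplicate voxels referenced by several map pixels
#'   (default `TRUE`; near the poles rasterized projections reference
#'   some voxels repeatedly).
#' @return Data frame of voxel indices `(t, c, z, y, x)`, 0-based, plus
#'   `n_pixels` attribute (number of selected map pixels).
#' @export
roi_to_voxels <- function(crossref, roi, dedupe = TRUE) {
  tab <- if (is.data.frame(crossref)) crossref else crossref$crossref
  stopifnot(inherits(roi, "map_roi"))
  centers <- cbind(tab$map_x + 0.5, tab$map_y + 0.5)
  inside <- mgcv::in.out(rbind(roi$vertices, roi$vertices[1, ]), centers)
  if (!any(inside)) {
    stop("ROI '", roi$label, "' selects no valid map pixels",
         call. = FALSE)
  }
  vox <- tab[inside, c("t", "c", "z", "y", "x")]
  if (dedupe) vox <- unique(vox)
  attr(vox, "n_pixels") <- sum(inside)
  vox
}

#' Mean ROI intensity over time, measured on the stack
#'
#' For each time point the ROI is mapped to stack voxels through that
#' frame's cross-reference table and the mean of the original voxel
#' intensities is reported (measurement mode `map_crossref`).
#'
#' @param stack an [image_stack()] with T >= 1.
#' @param tables a single cross-reference table (reused for every t) or
#'   a list of per-t tables (maps built per frame).
#' @param roi a [map_roi()].
#' @param c channel index (1-based).
#' @return Data frame of class `timeseries_measurement`: `t` (0-based),
#'   `mean`, `n_voxels`, `roi`, `mode`.
#' @export
measure_roi_timeseries <- function(stack, tables, roi, c = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$values)
  n_t <- d[1]
  get_tab <- function(t) {
    if (is.data.frame(tables) || inherits(tables, "map_image") ||
        inherits(tables, "height_map")) {
      tables
    } else {
      tables[[t]]
    }
  }
  rows <- list()
  for (t in seq_len(n_t)) {
    vox <- tryCatch(roi_to_voxels(get_tab(t), roi), error = function(e) NULL)
    if (is.null(vox) || nrow(vox) == 0) {
      warning("ROI '", roi$label, "' selects no voxels at t = ", t - 1,
              "; time point omitted", call. = FALSE)
      next
    }
    vals <- stack$values[cbind(t, c, vox$z + 1L, vox$y + 1L, vox$x + 1L)]
    rows[[length(rows) + 1L]] <- data.frame(
      t = t - 1L, mean = mean(vals), n_voxels = nrow(vox),
      roi = roi$label, mode = "map_crossref")
  }
  out <- do.call(rbind, rows)
  class(out) <- c("timeseries_measurement", class(out))
  out
}

#' Mean intensity of a single z-layer over time
#'
#' The conventional alternative to map-based measurement: per time point,
#' the mean intensity over the above-threshold pixels of one z-layer
#' (mode `single_layer`).
#'
#' @param stack an [image_stack()].
#' @param z layer index (1-based).
#' @param threshold `"otsu"` (computed per frame) or a numeric absolute
#'   threshold.
#' @param c channel index (1-based).
#' @param t_range optional integer vector of time indices (1-based).
#' @return Data frame as in [measure_roi_timeseries()].
#' @export
single_layer_measure <- function(stack, z, threshold = "otsu", c = 1L,
                                 t_range = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$values)
  if (z < 1 || z > d[3]) stop("z out of range", call. = FALSE)
  if (is.null(t_range)) t_range <- seq_len(d[1])
  rows <- list()
  for (t in t_range) {
    layer <- stack$values[t, c, z, , ]
    thr <- if (identical(threshold, "otsu")) {
      rng <- range(layer)
      if (rng[1] == rng[2]) rng[1] - 1 else
        EBImage::otsu(matrix(as.vector(layer), ncol = 1L), range = rng)
    } else threshold
    sel <- layer > thr
    if (!any(sel)) {
      warning("empty mask at t = ", t - 1, "; time point omitted",
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      t = t - 1L, mean = mean(layer[sel]), n_voxels = sum(sel),
      roi = paste0("z", z - 1L), mode = "single_layer")
  }
  if (!length(rows)) stop("empty mask at every time point", call. = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("timeseries_measurement", class(out))
  out
}

#' Intensity profile along a polyline on the map
#'
#' Samples the map raster along the polyline at fixed arc-length steps by
#' bilinear interpolation. Positions falling outside the projection
#' domain (or off the raster) are reported as `NA` gaps, never
#' zero-filled.
#'
#' @param map a `map_image` (or `height_map`; its elevation is profiled).
#' @param line a [profile_line()].
#' @return Data frame with `pos` (arc position, map pixels) and `value`.
#' @export
plot_profile <- function(map, line) {
  stopifnot(inherits(line, "profile_line"))
  vals <- if (inherits(map, "height_map")) map$elevation else map$values
  mask <- map$mask
  h <- nrow(vals); w <- ncol(vals)
  v <- line$vertices
  seg <- diff(v)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  pos <- seq(0, total, by = line$step)
  cum <- c(0, cumsum(seg_len))
  sx <- sy <- numeric(length(pos))
  for (i in seq_along(pos)) {
    k <- max(which(cum <= pos[i] + 1e-12))
    k <- min(k, nrow(seg))
    f <- if (seg_len[k] > 0) (pos[i] - cum[k]) / seg_len[k] else 0
    sx[i] <- v[k, 1] + f * seg[k, 1]
    sy[i] <- v[k, 2] + f * seg[k, 2]
  }
  vm <- vals
  vm[!mask] <- NA
  # pixel centers: x = col - 0.5, y = row - 0.5 (0-based: j + 0.5)
  xg <- seq_len(w) - 0.5
  yg <- seq_len(h) - 0.5
  inb <- sx >= xg[1] & sx <= xg[w] & sy >= yg[1] & sy <= yg[h]
  out <- rep(NA_real_, length(pos))
  if (any(inb)) {
    out[inb] <- pracma::interp2(xg, yg, vm, sx[inb], sy[inb],
                                method = "linear")
  }
  if (all(is.na(out))) {
    stop("profile line does not intersect the map mask", call. = FALSE)
  }
  data.frame(pos = pos, value = out)
}

#' Read / write ROIs and polylines as plain text
#'
#' Format: first line the label (ROI) or the step (polyline), then one
#' `x y` vertex pair per line.
#'
#' @param x a [map_roi()] or [profile_line()].
#' @param path file path.
#' @return `write_map_roi`: invisibly, the path. `read_map_roi`: a
#'   [map_roi()].
#' @export
write_map_roi <- function(x, path) {
  stopifnot(inherits(x, "map_roi"))
  writeLines(c(x$label,
               apply(x$vertices, 1, function(r) paste(r, collapse = " "))),
             path)
  invisible(path)
}

#' @rdname write_map_roi
#' @export
read_map_roi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  label <- lines[1]
  verts <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  map_roi(verts, label = label)
}

#' Write a measurement time series as CSV
#'
#' @param x a `timeseries_measurement` data frame (or a list of them,
#'   concatenated).
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_measurement <- function(x, path) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
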
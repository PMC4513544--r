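#' Voxel spacing in micrometres
#'
#' @param dx,dy lateral pixel size, um per pixel.
#' @param dz axial step, um per z-slice.
#' @return An object of class `voxel_spacing`.
#' @export
voxel_spacing <- function(dx = 1, dy = dx, dz = 1) {
  v <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("voxel spacing must be strictly positive and finite", call. = FALSE)
  }
  structure(as.list(v), class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("Voxel spacing: dx=%g, dy=%g, dz=%g um\n", x$dx, x$dy, x$dz))
  invisible(x)
}

#' Multidimensional image stack
#'
#' Wraps an up-to-5D intensity grid in the canonical internal axis order
#' (T, C, Z, Y, X); missing axes get size 1. Voxel indices reported by the
#' package are 0-based: voxel (z, y, x) occupies the half-open physical box
#' \eqn{[x \cdot dx, (x+1) dx) \times [y \cdot dy, (y+1) dy) \times
#' [z \cdot dz, (z+1) dz)} so its center sits at
#' \eqn{((x+0.5) dx, (y+0.5) dy, (z+0.5) dz)} um.
#'
#' @param values numeric array with 2 to 5 dimensions. Interpreted
#'   according to `axes`; permuted into (T, C, Z, Y, X) internally.
#' @param spacing a [voxel_spacing()]; defaults to 1 um isotropic.
#' @param axes axis-label string for `values`, e.g. `"ZYX"` or
#'   `"TCZYX"`; must contain `X` and `Y` and be an ordered subset of
#'   `TCZYX`.
#' @return An object of class `image_stack` with elements `values`
#'   (5D array, dim (T, C, Z, Y, X)), `spacing`, and `axes` (the axis
#'   labels originally present).
#' @export
image_stack <- function(values, spacing = voxel_spacing(), axes = NULL) {
  stopifnot(is.array(values) || is.matrix(values))
  nd <- length(dim(values))
  if (nd < 2 || nd > 5) {
    stop("image stacks must have between 2 and 5 axes", call. = FALSE)
  }
  if (is.null(axes)) {
    axes <- substring("TCZYX", 6 - nd)
  }
  axes <- toupper(axes)
  lab <- strsplit(axes, "")[[1]]
  if (length(lab) != nd) {
    stop("axes string length does not match array dimensionality",
         call. = FALSE)
  }
  if (anyDuplicated(lab) || !all(lab %in% c("T", "C", "Z", "Y", "X")) ||
      !all(c("X", "Y") %in% lab)) {
    stop("axes must be a subset of TCZYX containing X and Y", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("stack intensities must be finite", call. = FALSE)
  }
  full <- c("T", "C", "Z", "Y", "X")
  dims <- stats::setNames(rep(1L, 5), full)
  dims[lab] <- dim(values)
  # embed into 5D, then permute present axes into canonical order
  arr <- array(aperm(values, order(match(lab, full))),
               dim = unname(dims[full]))
  storage.mode(arr) <- "double"
  if (!inherits(spacing, "voxel_spacing")) {
    spacing <- do.call(voxel_spacing, as.list(spacing))
  }
  structure(list(values = arr, spacing = spacing,
                 axes = paste(full[full %in% lab], collapse = "")),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Image stack (T=%d, C=%d, Z=%d, Y=%d, X=%d), axes present: %s\n",
              d[1], d[2], d[3], d[4], d[5], x$axes))
  cat(sprintf("  spacing dx=%g dy=%g dz=%g um; intensity range [%g, %g]\n",
              x$spacing$dx, x$spacing$dy, x$spacing$dz,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$values)

# Extract one (Z, Y, X) volume.
stack_volume <- function(stack, t = 1L, c = 1L) {
  d <- dim(stack$values)
  if (t < 1 || t > d[1] || c < 1 || c > d[2]) {
    stop("t or c index out of range", call. = FALSE)
  }
  array(stack$values[t, c, , , ], dim = d[3:5])
}

# ---- TIFF reading -----------------------------------------------------------

# Parse an ImageJ-style description string into a key/value list.
parse_imagej_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(NULL)
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- strsplit(lines, "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, 1L) == 2L]
  out <- stats::setNames(lapply(kv, `[[`, 2L),
                         vapply(kv, `[[`, "", 1L))
  if (!("ImageJ" %in% names(out))) return(NULL)
  out
}

# Page index (1-based) -> (t, c, z) under the ImageJ hyperstack page order:
# channel fastest, then slice, then frame.
page_to_tcz <- function(page, n_c, n_z) {
  p <- page - 1L
  c <- p %% n_c
  z <- (p %/% n_c) %% n_z
  t <- p %/% (n_c * n_z)
  cbind(t = t + 1L, c = c + 1L, z = z + 1L)
}

read_meta_sidecar <- function(path) {
  sc <- paste0(path, ".meta")
  if (!file.exists(sc)) return(NULL)
  lines <- readLines(sc, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, 1L) == 2L]
  stats::setNames(lapply(kv, function(p) trimws(p[[2]])),
                  trimws(vapply(kv, `[[`, "", 1L)))
}

#' Read a multidimensional TIFF stack
#'
#' Reads a single multi-page TIFF — either a plain page stack, an
#' ImageJ-style hyperstack (axis sizes taken from the ImageDescription
#' metadata), or a stack written by [write_tiff_stack()] (axis sizes and
#' value scaling taken from its plain-text `.meta` sidecar). Pages are
#' ordered channel-fastest, then slice, then frame, following the ImageJ
#' hyperstack convention.
#'
#' @param path path to the TIFF file.
#' @param dim_order optional axis-label string for the page axes when the
#'   file carries no axis metadata, e.g. `"ZYX"` (all pages are slices) or
#'   `"TYX"` (all pages are frames). Required for multi-page files
#'   without metadata.
#' @param spacing optional [voxel_spacing()]; used when the file carries
#'   no spacing metadata. If neither is available, unit spacing is assumed
#'   with a warning.
#' @return An [image_stack()].
#' @export
read_tiff_stack <- function(path, dim_order = NULL, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop("not a readable TIFF: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  # undo readTIFF's [0,1] normalization for integer pages; float pages
  # (32 bits per sample) are returned as stored
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  if (bits %in% c(8L, 16L)) {
    pages <- lapply(pages, function(p) round(p * (2^bits - 1)))
  }
  npages <- length(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, TRUE))) {
    stop("only single-sample (grayscale) TIFF pages are supported",
         call. = FALSE)
  }
  at <- attributes(pages[[1]])
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])

  meta <- read_meta_sidecar(path)
  ij <- parse_imagej_description(at$description)

  n_t <- n_c <- n_z <- NA_integer_
  sp <- NULL
  axes_present <- NULL
  scale <- 1; offset <- 0

  if (!is.null(meta)) {
    n_t <- as.integer(meta$size_t %||% 1L)
    n_c <- as.integer(meta$size_c %||% 1L)
    n_z <- as.integer(meta$size_z %||% 1L)
    sp <- voxel_spacing(as.numeric(meta$dx %||% 1),
                        as.numeric(meta$dy %||% 1),
                        as.numeric(meta$dz %||% 1))
    axes_present <- meta$axes %||% NULL
    if (identical(meta$dtype, "float32")) {
      # float pages are stored normalized to [0, 1]; 16-bit pages are
      # read back as raw integers and need no rescaling
      scale <- as.numeric(meta$value_scale %||% 1)
      offset <- as.numeric(meta$value_offset %||% 0)
    }
  } else if (!is.null(ij)) {
    n_c <- as.integer(ij$channels %||% 1L)
    n_z <- as.integer(ij$slices %||% 1L)
    n_t <- as.integer(ij$frames %||% 1L)
    dz <- as.numeric(ij$spacing %||% NA)
    xres <- at$x.resolution
    dx <- if (!is.null(xres) && is.finite(xres) && xres > 0) 1 / xres else NA
    if (is.finite(dx) || is.finite(dz)) {
      if (!is.finite(dx)) dx <- 1
      if (!is.finite(dz)) dz <- 1
      sp <- voxel_spacing(dx, dx, dz)
    }
  } else if (!is.null(dim_order)) {
    lab <- strsplit(toupper(dim_order), "")[[1]]
    page_axes <- setdiff(lab, c("Y", "X"))
    if (!all(lab %in% c("T", "C", "Z", "Y", "X")) ||
        length(page_axes) > 1L) {
      stop("dim_order must name Y, X and at most one page axis ",
           "(multi-axis page layouts need file metadata)", call. = FALSE)
    }
    n_t <- n_c <- n_z <- 1L
    if (length(page_axes) == 1L) {
      if (page_axes == "T") n_t <- npages
      if (page_axes == "C") n_c <- npages
      if (page_axes == "Z") n_z <- npages
    }
  } else if (npages == 1L) {
    n_t <- n_c <- n_z <- 1L
  } else {
    stop("TIFF carries no axis metadata and dim_order was not given",
         call. = FALSE)
  }

  if (n_t * n_c * n_z != npages) {
    stop(sprintf(
      "declared axis sizes (T=%d, C=%d, Z=%d) are inconsistent with the %d pages",
      n_t, n_c, n_z, npages), call. = FALSE)
  }
  if (is.null(sp)) {
    if (!is.null(spacing)) {
      sp <- if (inherits(spacing, "voxel_spacing")) spacing else
        do.call(voxel_spacing, as.list(spacing))
    } else {
      warning("no voxel spacing available; assuming 1 um isotropic",
              call. = FALSE)
      sp <- voxel_spacing()
    }
  }

  arr <- array(0, dim = c(n_t, n_c, n_z, h, w))
  tcz <- page_to_tcz(seq_len(npages), n_c, n_z)
  for (p in seq_len(npages)) {
    arr[tcz[p, "t"], tcz[p, "c"], tcz[p, "z"], , ] <- pages[[p]]
  }
  if (scale != 1 || offset != 0) arr <- arr * scale + offset
  axes <- axes_present %||% {
    full <- c(if (n_t > 1) "T", if (n_c > 1) "C", if (n_z > 1) "Z", "Y", "X")
    paste(full, collapse = "")
  }
  st <- image_stack(array(arr, dim = c(n_t, n_c, n_z, h, w)),
                    spacing = sp, axes = "TCZYX")
  st$axes <- axes
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- TIFF writing -----------------------------------------------------------

#' Write an image stack as a multi-page TIFF
#'
#' Integer-valued stacks in \[0, 65535\] are written losslessly as 16-bit
#' pages; other stacks are min-max normalized and written as 32-bit float
#' pages. Axis sizes, voxel spacing and the value scaling are recorded in
#' a plain-text sidecar `<path>.meta` which [read_tiff_stack()] consumes;
#' pages follow the ImageJ hyperstack order (channel fastest, then slice,
#' then frame), so the pixel data also opens correctly as an ImageJ
#' hyperstack.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return Invisibly, the path.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$values)
  v <- stack$values
  integerish <- all(v >= 0) && all(v <= 65535) && all(v == round(v))
  if (integerish) {
    bits <- 16L; offset <- 0; scale <- 65535
    norm <- function(m) m / 65535
    dtype <- "uint16"
  } else {
    bits <- 32L
    offset <- min(v)
    scale <- max(v) - offset
    if (scale == 0) scale <- 1
    norm <- function(m) (m - offset) / scale
    dtype <- "float32"
  }
  pages <- vector("list", d[1] * d[2] * d[3])
  p <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[3])) for (c in seq_len(d[2])) {
    p <- p + 1L
    pages[[p]] <- norm(matrix(v[t, c, z, , ], d[4], d[5]))
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = bits,
                    compression = "none"),
    error = function(e) stop("cannot write TIFF at ", path, " (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  meta <- c(
    "# stackmap stack sidecar",
    paste0("axes=", stack$axes),
    paste0("size_t=", d[1]), paste0("size_c=", d[2]),
    paste0("size_z=", d[3]), paste0("size_y=", d[4]),
    paste0("size_x=", d[5]),
    paste0("dx=", format(stack$spacing$dx, digits = 17)),
    paste0("dy=", format(stack$spacing$dy, digits = 17)),
    paste0("dz=", format(stack$spacing$dz, digits = 17)),
    paste0("dtype=", dtype),
    paste0("value_offset=", format(offset, digits = 17)),
    paste0("value_scale=", format(scale, digits = 17))
  )
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

# ---- Map export -------------------------------------------------------------

map_lut <- function(name, n = 256L) {
  switch(name,
    gray = gray(seq(0, 1, length.out = n)),
    rainbow = colorRampPalette(c("#00007F", "#0000FF", "#00FFFF", "#00FF00",
                                 "#FFFF00", "#FF0000", "#7F0000"))(n),
    hypsometric = hypsometric_palette(n),
    stop("unknown lut '", name, "'", call. = FALSE)
  )
}

# Diverging elevation palette; odd length keeps an exact neutral midpoint.
hypsometric_palette <- function(n = 511L) {
  if (n %% 2L == 0L) n <- n + 1L
  colorRampPalette(c("#313695", "#4575B4", "#74ADD1", "#E0F3F8", "#FFFFFF",
                     "#FEE090", "#F46D43", "#D73027", "#A50026"))(n)
}

#' Export a rendered map to disk
#'
#' Writes two files: `<base>.tif`, a 16-bit grayscale TIFF of the raw map
#' values after the fixed-point scaling `stored = (value - offset)/scale`
#' (offset/scale recorded in `<base>.tif.meta`), and `<base>.png`, an
#' 8-bit RGB rendering with the chosen lookup table in which pixels
#' outside the projection domain are background-colored and fully
#' transparent.
#'
#' @param map a `map_image` or `height_map`.
#' @param path output path; the extension is replaced by `.tif`/`.png`.
#' @param lut lookup-table name: `"gray"`, `"rainbow"` or
#'   `"hypsometric"` (the latter is the default for height maps).
#' @param background background color for out-of-domain pixels.
#' @return Invisibly, a character vector of the two file paths.
#' @export
export_map <- function(map, path, lut = NULL,
                       background = "#404040") {
  if (inherits(map, "height_map")) {
    vals <- map$elevation
    if (is.null(lut)) lut <- "hypsometric"
  } else if (inherits(map, "map_image")) {
    vals <- map$values
    if (is.null(lut)) lut <- "gray"
  } else {
    stop("map must be a map_image or height_map", call. = FALSE)
  }
  cols <- map_lut(lut)  # errors early on unknown lut
  mask <- map$mask
  base <- sub("\\.(tif|tiff|png)$", "", path, ignore.case = TRUE)
  tif_path <- paste0(base, ".tif")
  png_path <- paste0(base, ".png")

  inside <- vals[mask]
  vmin <- if (length(inside)) min(inside) else 0
  vmax <- if (length(inside)) max(inside) else 1
  scale <- if (vmax > vmin) (vmax - vmin) else 1
  stored <- (vals - vmin) / scale
  stored[!mask | !is.finite(stored)] <- 0
  stored <- round(stored * 65535) / 65535
  tiff::writeTIFF(stored, tif_path, bits.per.sample = 16L,
                  compression = "none")
  writeLines(c("# stackmap map sidecar",
               paste0("value_offset=", format(vmin, digits = 17)),
               paste0("value_scale=", format(scale, digits = 17))),
             paste0(tif_path, ".meta"))

  if (inherits(map, "height_map")) {
    rng <- max(abs(inside), 0)
    if (rng == 0) rng <- 1
    u <- (vals / rng + 1) / 2
  } else {
    u <- (vals - vmin) / scale
  }
  n <- length(cols)
  idx <- pmin(pmax(round(u * (n - 1)) + 1, 1), n)
  idx[!mask | !is.finite(u)] <- NA
  rgb_bg <- col2rgb(background) / 255
  rgba <- array(0, dim = c(nrow(vals), ncol(vals), 4))
  chan <- col2rgb(cols) / 255
  for (k in 1:3) {
    plane <- matrix(rgb_bg[k], nrow(vals), ncol(vals))
    plane[mask] <- chan[k, idx[mask]]
    rgba[, , k] <- plane
  }
  rgba[, , 4] <- ifelse(mask, 1, 0)
  png::writePNG(rgba, png_path)
  invisible(c(tif_path, png_path))
}

#' Re-read an exported grayscale map TIFF as raw values
#'
#' Applies the fixed-point scaling recorded in the `.meta` sidecar written
#' by [export_map()].
#'
#' @param path the `.tif` written by [export_map()].
#' @return Numeric matrix of map values.
#' @export
read_map_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  meta <- read_meta_sidecar(path)
  off <- as.numeric(meta$value_offset %||% 0)
  sc <- as.numeric(meta$value_scale %||% 1)
  (m / 65535) * sc + off
}
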
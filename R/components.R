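# Connected-component labeling on logical 2D/3D masks via an adjacency
# graph (igraph). Supports 4/8-connectivity in 2D, 6/26 in 3D, and an
# optional periodic wrap in the last (x / column) dimension so features
# straddling the longitude seam of a map are labeled as one component.
label_components <- function(mask, connectivity = NULL, wrap_x = FALSE) {
  d <- dim(mask)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L), is.logical(mask))
  if (is.null(connectivity)) connectivity <- if (nd == 2L) 8L else 26L
  offsets <- switch(paste0(nd, "_", connectivity),
    "2_4"  = rbind(c(1, 0), c(0, 1)),
    "2_8"  = rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1)),
    "3_6"  = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    "3_26" = {
      g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      # half-space of offsets: each unordered neighbor pair appears once
      keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
        (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
      unname(g[keep, , drop = FALSE])
    },
    stop("unsupported connectivity", call. = FALSE)
  )
  idx <- which(mask)
  labels <- array(0L, dim = d)
  if (!length(idx)) return(labels)
  pos <- arrayInd(idx, d)
  edges <- NULL
  lin_mult <- cumprod(c(1, d[-nd]))
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    npos <- sweep(pos, 2, off, "+")
    ok <- rep(TRUE, nrow(npos))
    for (k in seq_len(nd)) {
      if (wrap_x && k == nd) {
        npos[, k] <- ((npos[, k] - 1L) %% d[k]) + 1L
      } else {
        ok <- ok & npos[, k] >= 1L & npos[, k] <= d[k]
      }
    }
    if (!any(ok)) next
    nlin <- as.integer((npos[ok, , drop = FALSE] - 1L) %*% lin_mult) + 1L
    src <- idx[ok]
    hit <- mask[nlin]
    if (!any(hit)) next
    edges <- rbind(edges, cbind(src[hit], nlin[hit]))
  }
  vid <- match(seq_along(idx), seq_along(idx))  # identity; vertices = idx
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) {
    e <- cbind(match(edges[, 1], idx), match(edges[, 2], idx))
    g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

# Number of connected components in a mask.
count_components <- function(mask, connectivity = NULL, wrap_x = FALSE) {
  max(label_components(mask, connectivity, wrap_x), 0L)
}
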
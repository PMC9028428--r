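# ---- segmentation loss functions --------------------------------------------

#' Pixel-wise binary cross-entropy loss
#'
#' `-(1/K) * sum(y * log(x) + (1 - y) * log(1 - x))` over all K pixels,
#' with the prediction clipped to `[eps, 1 - eps]` for numerical stability.
#'
#' @param x_p probability map, values in `[0, 1]`.
#' @param y_g binary label map of the same shape.
#' @param eps clipping constant (default 1e-7).
#' @return scalar loss.
#' @export
bce_loss <- function(x_p, y_g, eps = 1e-7) {
  x_p <- as.matrix(x_p); y_g <- as.matrix(y_g)
  if (!identical(dim(x_p), dim(y_g))) stop("probability and label map shapes differ")
  if (any(x_p < 0 | x_p > 1)) stop("probability map values outside [0, 1]")
  if (!all(y_g %in% c(0, 1))) stop("label map must be binary")
  x <- pmin(pmax(x_p, eps), 1 - eps)
  -mean(y_g * log(x) + (1 - y_g) * log(1 - x))
}

#' Euclidean distance map to a set of edge pixels
#'
#' For every pixel, the distance (in pixel units) to the nearest marked
#' edge pixel — zero exactly on edge pixels. Computed with the exact
#' Euclidean distance transform; the classic integer chamfer 3-4 scheme is
#' a coarser approximation of the same map and is not needed here.
#'
#' @param edges binary raster; nonzero marks edge pixels.
#' @return numeric matrix of distances, same shape.
#' @export
chamfer_distance_map <- function(edges) {
  edges <- as.matrix(edges)
  if (!any(edges != 0)) stop("empty edge set; distance map undefined")
  d <- EBImage::distmap(1 - (edges != 0))
  matrix(as.numeric(d), nrow(edges), ncol(edges))
}

#' Binary boundary (edge) pixels of a mask
#'
#' Foreground pixels with at least one 4-neighbour outside the mask
#' (image borders count as outside).
#'
#' @param mask binary raster.
#' @return binary matrix marking boundary pixels.
#' @export
mask_edges <- function(mask) {
  m <- as.matrix(mask) != 0
  pad <- function(shift_r, shift_c) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + shift_r
    cs <- seq_len(ncol(m)) + shift_c
    ok_r <- rs >= 1 & rs <= nrow(m)
    ok_c <- cs >= 1 & cs <= ncol(m)
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  nb_all <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  (m & !nb_all) * 1L
}

#' Chamfer shape loss between a predicted and a ground-truth mask
#'
#' The boundary penalty for elongated structures: the prediction is
#' binarized, its boundary extracted, and the loss is the sum over
#' prediction-boundary pixels of the smoothed ground-truth boundary
#' distance `sqrt(d^2 + eps^2)`, averaged over all K pixels of the raster.
#' It vanishes (up to `eps`) exactly when the two boundaries coincide.
#'
#' @param x_p probability map.
#' @param y_g binary ground-truth map.
#' @param threshold binarization threshold for `x_p` (default 0.5).
#' @param eps smoothing constant (default 1e-7).
#' @return scalar loss; carries attribute `empty_prediction = TRUE` (with a
#'   warning) when the binarized prediction has no foreground.
#' @export
shape_loss <- function(x_p, y_g, threshold = 0.5, eps = 1e-7) {
  x_p <- as.matrix(x_p); y_g <- as.matrix(y_g)
  if (!identical(dim(x_p), dim(y_g))) stop("map shapes differ")
  K <- length(y_g)
  xb <- x_p >= threshold
  if (!any(xb)) {
    warning("prediction has no foreground; shape loss is 0")
    return(structure(0, empty_prediction = TRUE))
  }
  if (!any(y_g != 0)) stop("ground truth has no foreground")
  yd <- chamfer_distance_map(mask_edges(y_g))
  xe <- mask_edges(xb)
  sum(sqrt((yd[xe != 0])^2 + eps^2)) / K
}

# ---- skeletonization ---------------------------------------------------------

# count of 8-neighbours, via shifted copies
neighbour_count <- function(m) {
  n <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- seq_len(nrow(m)) + dr
    cs <- seq_len(ncol(m)) + dc
    ok_r <- rs >= 1 & rs <= nrow(m)
    ok_c <- cs >= 1 & cs <= ncol(m)
    n[ok_r, ok_c] <- n[ok_r, ok_c] + m[rs[ok_r], cs[ok_c]]
  }
  n
}

shifted <- function(m, dr, dc, fill = 0L) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) + dr
  cs <- seq_len(ncol(m)) + dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Morphological skeleton of a binary mask (Guo-Hall thinning)
#'
#' Iteratively peels boundary pixels in two alternating subiterations
#' while preserving 8-connectivity, line ends and diagonal strokes,
#' leaving a one-pixel-wide medial skeleton. (The simpler Zhang-Suen
#' scheme deletes two-pixel-wide diagonal lines entirely, which vascular
#' masks are full of.)
#'
#' @param mask binary raster.
#' @return binary matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- (as.matrix(mask) != 0) * 1L
  # neighbours p2..p9 in circular order: N, NE, E, SE, S, SW, W, NW
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (phase in 0:1) {
      P <- lapply(offs, function(o) shifted(m, o[1L], o[2L]))
      p2 <- P[[1L]]; p3 <- P[[2L]]; p4 <- P[[3L]]; p5 <- P[[4L]]
      p6 <- P[[5L]]; p7 <- P[[6L]]; p8 <- P[[7L]]; p9 <- P[[8L]]
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      mm <- if (phase == 0L) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
      del <- m == 1L & C == 1 & N >= 2 & N <= 3 & mm == 0
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# ---- mask -> centerline graph ------------------------------------------------

#' Extract a 2D centerline graph from a binary vessel mask
#'
#' Skeletonizes the mask, classifies skeleton pixels by 8-neighbour degree
#' (1 = endpoint, >= 3 = branch node), and traces every maximal branch-free
#' pixel path into one smallest-unit edge. Per-point vessel thickness is
#' twice the Euclidean distance-transform value at the skeleton pixel,
#' converted to mm via the imager pixel spacing; coordinates are detector
#' mm with the origin at the raster centre.
#'
#' @param mask binary raster (rows x cols matching the geometry).
#' @param geometry a `carm_geometry`.
#' @return a 2D `vessel_tree` of smallest-unit segments with thickness.
#' @export
mask_to_centerlines <- function(mask, geometry) {
  m <- (as.matrix(mask) != 0) * 1L
  if (!any(m == 1L)) stop("empty mask")
  sk <- skeletonize(m)
  dt <- matrix(as.numeric(EBImage::distmap(m)), nrow(m), ncol(m))
  deg <- neighbour_count(sk) * sk
  nodes_mask <- sk == 1L & (deg == 1L | deg >= 3L)
  sk_idx <- which(sk == 1L, arr.ind = TRUE)
  if (nrow(sk_idx) < 2L) stop("skeleton degenerate")
  key <- function(rc) paste(rc[1L], rc[2L], sep = ",")
  is_on <- function(r, c) r >= 1 && c >= 1 && r <= nrow(sk) && c <= ncol(sk) &&
    sk[r, c] == 1L
  nbrs <- function(rc) {
    out <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- rc[1L] + dr; c <- rc[2L] + dc
      if (is_on(r, c)) out <- c(out, list(c(r, c)))
    }
    out
  }
  visited_edge <- new.env(hash = TRUE)
  edge_key <- function(a, b) paste(min(key(a), key(b)), max(key(a), key(b)))
  node_cells <- which(nodes_mask, arr.ind = TRUE)
  # isolated loops without any node: pick an arbitrary start on each
  paths <- list()
  trace_from <- function(start, first) {
    path <- list(start, first)
    mark <- edge_key(start, first)
    if (!is.null(visited_edge[[mark]])) return(NULL)
    visited_edge[[mark]] <- TRUE
    prev <- start; cur <- first
    while (!nodes_mask[cur[1L], cur[2L]]) {
      nx <- Filter(function(q) !(q[1L] == prev[1L] && q[2L] == prev[2L]),
                   nbrs(cur))
      if (!length(nx)) break # dead end (shouldn't happen: degree-1 is a node)
      # prefer unvisited steps; avoid immediate corner-cut duplicates
      nxt <- NULL
      for (q in nx) {
        if (is.null(visited_edge[[edge_key(cur, q)]])) { nxt <- q; break }
      }
      if (is.null(nxt)) break
      visited_edge[[edge_key(cur, nxt)]] <- TRUE
      path <- c(path, list(nxt))
      prev <- cur; cur <- nxt
    }
    do.call(rbind, path)
  }
  if (nrow(node_cells)) {
    for (i in seq_len(nrow(node_cells))) {
      nd <- node_cells[i, ]
      for (q in nbrs(nd)) {
        p <- trace_from(nd, q)
        if (!is.null(p) && nrow(p) >= 2L) paths <- c(paths, list(p))
      }
    }
  } else {
    p <- trace_from(sk_idx[1L, ], nbrs(sk_idx[1L, ])[[1L]])
    if (!is.null(p)) paths <- c(paths, list(p))
  }
  # drop tiny spurs shorter than 3 px that end at an endpoint
  vertices <- list()
  edges <- list()
  vid_of <- new.env(hash = TRUE)
  get_vid <- function(rc, mm) {
    k <- key(rc)
    if (is.null(vid_of[[k]])) {
      vid_of[[k]] <- paste0("n", length(vertices) + 1L)
      vertices[[vid_of[[k]]]] <<- mm
    }
    vid_of[[k]]
  }
  for (p in paths) {
    mm <- pixel_to_mm(p, geometry)
    if (nrow(mm) < 2L) next
    th <- 2 * dt[p] * geometry$pixel_spacing_mm
    a <- get_vid(p[1L, ], mm[1L, ])
    b <- get_vid(p[nrow(p), ], mm[nrow(mm), ])
    edges[[paste0("s", length(edges) + 1L)]] <-
      list(from = a, to = b, centerline = centerline2d(mm, th))
  }
  if (!length(edges)) stop("no traceable skeleton paths")
  vessel_tree(vertices, edges, root = NA_character_, validate = FALSE)
}
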
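# ---- centerline constructors -------------------------------------------------

as_point_matrix <- function(points, dim) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, as.numeric))
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != dim)
    stop("expected ", dim, "-column point matrix, got ", ncol(points))
  if (any(!is.finite(points))) stop("non-finite coordinates")
  points
}

check_centerline_points <- function(points) {
  if (nrow(points) < 2L) stop("a centerline needs at least 2 points")
  d <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(d == 0)) stop("consecutive centerline points must be distinct")
  invisible(points)
}

#' 3D vessel centerline
#'
#' An ordered polyline along one vessel branch in patient space, with a
#' per-point lumen radius. All coordinates and radii are in millimetres.
#'
#' @param points numeric n x 3 matrix (or list of length-3 vectors) of
#'   ordered 3D points, mm.
#' @param radius numeric vector of per-point radii, mm; strictly positive,
#'   same length as the number of points.
#' @return An object of class `centerline3d`: a list with elements `points`
#'   (n x 3 matrix) and `radius`.
#' @examples
#' c3 <- centerline3d(rbind(c(0, 0, 0), c(10, 0, 0)), radius = c(2, 1.8))
#' centerline_length(c3)
#' @export
centerline3d <- function(points, radius) {
  points <- as_point_matrix(points, 3L)
  check_centerline_points(points)
  radius <- as.numeric(radius)
  if (length(radius) != nrow(points))
    stop("radius must have one value per point")
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("radius must be positive and finite everywhere")
  structure(list(points = points, radius = radius),
            class = c("centerline3d", "centerline"))
}

#' 2D vessel centerline
#'
#' An ordered polyline on the detector plane. Coordinates are millimetres in
#' detector space (origin at the detector centre); `thickness` is the local
#' vessel width (diameter), typically recovered from a segmentation mask via
#' the distance transform.
#'
#' @param points numeric n x 2 matrix of ordered 2D points, mm.
#' @param thickness optional numeric vector of per-point widths, mm.
#' @return An object of class `centerline2d`.
#' @export
centerline2d <- function(points, thickness = NULL) {
  points <- as_point_matrix(points, 2L)
  check_centerline_points(points)
  if (!is.null(thickness)) {
    thickness <- as.numeric(thickness)
    if (length(thickness) != nrow(points))
      stop("thickness must have one value per point")
  }
  structure(list(points = points, thickness = thickness),
            class = c("centerline2d", "centerline"))
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<%s> %d points, length %.2f mm\n", class(x)[1L],
              nrow(x$points), centerline_length(x)))
  invisible(x)
}

centerline_dim <- function(c) ncol(c$points)

# ---- basic geometry ----------------------------------------------------------

#' Arc length of a centerline
#'
#' Sum of Euclidean distances between consecutive points of the polyline.
#'
#' @param c a `centerline2d`/`centerline3d`, or a bare point matrix.
#' @return length in mm.
#' @export
centerline_length <- function(c) {
  p <- if (is.matrix(c)) c else c$points
  if (nrow(p) < 2L) stop("need at least 2 points")
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Mean spacing between adjacent centerline points
#'
#' The average inter-point distance, `centerline_length(c) / (n - 1)`. This
#' is the reference spacing held fixed by the continuity energy during
#' nonrigid deformation.
#'
#' @inheritParams centerline_length
#' @return mean spacing, mm.
#' @export
mean_spacing <- function(c) {
  p <- if (is.matrix(c)) c else c$points
  centerline_length(p) / (nrow(p) - 1L)
}

cumulative_arclength <- function(p) {
  c(0, cumsum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                              p[-nrow(p), , drop = FALSE])^2))))
}

#' Resample a centerline at uniform arc-length spacing
#'
#' Walks the piecewise-linear curve and places points at arc-length
#' positions `0, spacing, 2*spacing, ...`; the final endpoint is always
#' kept, so the last interval may be shorter. Radii (3D) or thicknesses
#' (2D) are linearly interpolated in arc length.
#'
#' @param c a `centerline2d` or `centerline3d`.
#' @param spacing target spacing, mm (> 0).
#' @return a centerline of the same class with uniformly spaced points.
#' @export
resample_centerline <- function(c, spacing) {
  stopifnot(spacing > 0)
  p <- c$points
  s <- cumulative_arclength(p)
  L <- s[length(s)]
  if (L <= 0) stop("degenerate zero-length centerline")
  pos <- seq(0, L, by = spacing)
  if (L - pos[length(pos)] > 1e-9) pos <- c(pos, L) else pos[length(pos)] <- L
  if (length(pos) < 2L) pos <- c(0, L)
  newp <- vapply(seq_len(ncol(p)),
                 function(k) stats::approx(s, p[, k], xout = pos, ties = "ordered")$y,
                 numeric(length(pos)))
  newp <- matrix(newp, ncol = ncol(p))
  # guard against duplicated points when spacing >> curve detail
  keep <- c(TRUE, sqrt(rowSums((newp[-1L, , drop = FALSE] -
                                  newp[-nrow(newp), , drop = FALSE])^2)) > 1e-12)
  newp <- newp[keep, , drop = FALSE]
  pos <- pos[keep]
  if (inherits(c, "centerline3d")) {
    r <- stats::approx(s, c$radius, xout = pos, ties = "ordered")$y
    centerline3d(newp, r)
  } else {
    th <- if (!is.null(c$thickness))
      stats::approx(s, c$thickness, xout = pos, ties = "ordered")$y
    centerline2d(newp, th)
  }
}

#' Local tangent of a centerline by symmetric line fit
#'
#' Fits a total-least-squares line (first principal axis) through the points
#' in a symmetric index window around point `i` (clamped at the curve ends)
#' and returns the tangent as a unit direction vector plus the slope dy/dx.
#' The direction-vector form stays finite for vertical tangents, where the
#' slope is `Inf`. For 3D centerlines the principal axis is returned and the
#' slope refers to the first two coordinates.
#'
#' @param c a centerline.
#' @param i point index (1-based).
#' @param window half-width of the window in points (default 3).
#' @return list with `dir` (unit vector) and `slope` (dy/dx, may be `Inf`).
#' @export
tangent_slope <- function(c, i, window = 3L) {
  p <- if (is.matrix(c)) c else c$points
  n <- nrow(p)
  stopifnot(i >= 1L, i <= n)
  lo <- max(1L, i - window)
  hi <- min(n, i + window)
  w <- p[lo:hi, , drop = FALSE]
  ctr <- colMeans(w)
  wc <- sweep(w, 2L, ctr)
  if (max(abs(wc)) < 1e-12) stop("all window points identical; tangent undefined")
  sv <- svd(wc, nu = 0L, nv = 1L)
  dir <- sv$v[, 1L]
  # orient along increasing index for determinism
  chord <- p[hi, ] - p[lo, ]
  if (sum(dir * chord) < 0) dir <- -dir
  slope <- if (abs(dir[1L]) < 1e-12) Inf else dir[2L] / dir[1L]
  list(dir = dir, slope = slope)
}

# vectorized unit tangent directions for every point of a 2D polyline
tangent_directions <- function(p, window = 3L) {
  n <- nrow(p)
  out <- matrix(0, n, ncol(p))
  for (i in seq_len(n)) {
    lo <- max(1L, i - window); hi <- min(n, i + window)
    w <- p[lo:hi, , drop = FALSE]
    wc <- sweep(w, 2L, colMeans(w))
    if (max(abs(wc)) < 1e-12) {
      out[i, ] <- c(1, rep(0, ncol(p) - 1L))
      next
    }
    v <- svd(wc, nu = 0L, nv = 1L)$v[, 1L]
    chord <- p[hi, ] - p[lo, ]
    if (sum(v * chord) < 0) v <- -v
    out[i, ] <- v
  }
  out
}

# ---- vessel trees ------------------------------------------------------------

#' Vessel tree graph
#'
#' A graph `T = (V, E, r)` whose edges carry centerlines as shape
#' properties. 3D trees must be connected and acyclic with a single root;
#' 2D structures may be disconnected segment soups (the usual state of a
#' corrupted angiographic segmentation). Each edge's `from`/`to` vertex
#' coordinates must coincide with its centerline's first/last point.
#'
#' @param vertices named list mapping vertex id to a coordinate vector (mm).
#' @param edges named list of edges; each edge is a list with `from`, `to`
#'   (vertex ids) and `centerline` (a `centerline2d`/`centerline3d`).
#'   Additional fields (e.g. provenance labels) are preserved.
#' @param root id of the root vertex, or `NA` for 2D structures.
#' @param validate check the tree invariants (default TRUE).
#' @return an object of class `vessel_tree`.
#' @export
vessel_tree <- function(vertices, edges, root = NA_character_, validate = TRUE) {
  stopifnot(is.list(vertices), is.list(edges))
  if (is.null(names(edges)) || any(names(edges) == ""))
    names(edges) <- paste0("e", seq_along(edges))
  dim <- if (length(vertices)) length(vertices[[1L]]) else
    centerline_dim(edges[[1L]]$centerline)
  tr <- structure(list(vertices = vertices, edges = edges, root = root,
                       dim = dim), class = "vessel_tree")
  if (validate) validate_vessel_tree(tr)
  tr
}

validate_vessel_tree <- function(tr) {
  for (eid in names(tr$edges)) {
    e <- tr$edges[[eid]]
    cl <- e$centerline
    p <- cl$points
    a <- tr$vertices[[e$from]]; b <- tr$vertices[[e$to]]
    if (is.null(a) || is.null(b)) stop("edge ", eid, " references unknown vertex")
    if (max(abs(p[1L, ] - a)) > 1e-6 || max(abs(p[nrow(p), ] - b)) > 1e-6)
      stop("edge ", eid, " endpoints do not match its centerline")
  }
  if (tr$dim == 3L && length(tr$edges)) {
    if (is.na(tr$root) || is.null(tr$vertices[[tr$root]]))
      stop("3D vessel tree needs a valid root vertex")
    # connected + acyclic: |E| = |V| - 1 and all vertices reachable
    vs <- names(tr$vertices)
    if (length(tr$edges) != length(vs) - 1L)
      stop("3D vessel tree must be a tree (|E| = |V| - 1)")
    adj <- lapply(stats::setNames(vs, vs), function(v) character())
    for (e in tr$edges) {
      adj[[e$from]] <- c(adj[[e$from]], e$to)
      adj[[e$to]] <- c(adj[[e$to]], e$from)
    }
    seen <- stats::setNames(rep(FALSE, length(vs)), vs)
    queue <- tr$root; seen[tr$root] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (!all(seen)) stop("3D vessel tree is not connected")
  }
  invisible(tr)
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree %dD> %d vertices, %d edges%s\n", x$dim,
              length(x$vertices), length(x$edges),
              if (!is.na(x$root)) paste0(", root ", x$root) else ""))
  invisible(x)
}

#' Stack all centerline points of a tree into one matrix
#'
#' @param tr a `vessel_tree`.
#' @return matrix of all edge centerline points (edges concatenated in
#'   order; shared junction points appear once per incident edge).
#' @export
tree_points <- function(tr) {
  do.call(rbind, lapply(tr$edges, function(e) e$centerline$points))
}

# parent/child edge relations of a rooted 3D tree: for each edge, orient it
# away from the root and report its parent edge id (or NA for root edges)
tree_edge_relations <- function(tr) {
  stopifnot(tr$dim == 3L, !is.na(tr$root))
  inc <- list()
  for (eid in names(tr$edges)) {
    e <- tr$edges[[eid]]
    inc[[e$from]] <- c(inc[[e$from]], eid)
    inc[[e$to]] <- c(inc[[e$to]], eid)
  }
  parent <- stats::setNames(rep(NA_character_, length(tr$edges)), names(tr$edges))
  depth <- stats::setNames(rep(NA_integer_, length(tr$edges)), names(tr$edges))
  upstream <- stats::setNames(rep(NA_character_, length(tr$edges)), names(tr$edges))
  queue <- list(list(v = tr$root, via = NA_character_, d = 0L))
  seen_v <- tr$root
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (eid in inc[[cur$v]]) {
      e <- tr$edges[[eid]]
      other <- if (e$from == cur$v) e$to else e$from
      if (other %in% seen_v) next
      seen_v <- c(seen_v, other)
      parent[eid] <- cur$via
      depth[eid] <- cur$d
      upstream[eid] <- cur$v
      queue <- c(queue, list(list(v = other, via = eid, d = cur$d + 1L)))
    }
  }
  list(parent = parent, depth = depth, upstream_vertex = upstream)
}

#' Apply a point transformation to every centerline of a tree
#'
#' @param tr a `vessel_tree`.
#' @param f function mapping an n x d point matrix to an n x d matrix.
#' @return transformed tree (same topology; 3D radii preserved).
#' @export
transform_tree <- function(tr, f) {
  verts <- lapply(tr$vertices, function(v) as.numeric(f(matrix(v, 1L))))
  edges <- lapply(tr$edges, function(e) {
    p <- f(e$centerline$points)
    e$centerline <- if (inherits(e$centerline, "centerline3d"))
      centerline3d(p, e$centerline$radius)
    else centerline2d(p, e$centerline$thickness)
    e
  })
  vessel_tree(verts, edges, tr$root, validate = FALSE)
}

#' Marker pairs for registration evaluation
#'
#' Pairs of corresponding points (p on the registered model, q ground
#' truth) used by the average-distance-difference metric.
#'
#' @param p,q matrices of corresponding points (equal dimensions, M >= 1 rows).
#' @return object of class `marker_pairs`.
#' @export
marker_pairs <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  storage.mode(p) <- storage.mode(q) <- "double"
  if (nrow(p) < 1L || !identical(dim(p), dim(q)))
    stop("marker sets must be non-empty and of equal dimensions")
  structure(list(p = p, q = q, M = nrow(p)), class = "marker_pairs")
}
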
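# ---- direction-set (Powell) minimizer ---------------------------------------

# Derivative-free minimization by successive line searches along a set of
# directions, with the classic replacement of the direction of largest
# decrease by the net cycle displacement. Line searches use Brent's method
# (stats::optimize) on a bracket scaled per direction. No installed package
# provides Powell's direction-set method, so it is implemented here.
powell_minimize <- function(fn, x0, scale, tol = 1e-8, maxit = 40L,
                            bracket = 1.5, ls_tol = 5e-4) {
  n <- length(x0)
  stopifnot(length(scale) == n, all(scale > 0))
  dirs <- diag(scale, n, n)
  x <- x0
  fx <- fn(x)
  n_eval <- 1L
  for (it in seq_len(maxit)) {
    x_start <- x
    f_start <- fx
    biggest <- 0
    ibig <- 1L
    for (i in seq_len(n)) {
      d <- dirs[, i]
      f1 <- function(a) fn(x + a * d)
      opt <- stats::optimize(f1, interval = c(-bracket, bracket), tol = ls_tol)
      n_eval <- n_eval + 15L
      if (opt$objective < fx) {
        if (fx - opt$objective > biggest) {
          biggest <- fx - opt$objective
          ibig <- i
        }
        x <- x + opt$minimum * d
        fx <- opt$objective
      }
    }
    if (2 * abs(f_start - fx) <= tol * (abs(f_start) + abs(fx) + 1e-12)) break
    # direction replacement: net displacement of the cycle
    dnew <- x - x_start
    if (sqrt(sum(dnew^2)) > 1e-12) {
      f_extrap <- fn(x + dnew)
      n_eval <- n_eval + 1L
      if (f_extrap < f_start) {
        f1 <- function(a) fn(x + a * dnew)
        opt <- stats::optimize(f1, interval = c(-bracket, bracket))
        n_eval <- n_eval + 25L
        if (opt$objective < fx) {
          x <- x + opt$minimum * dnew
          fx <- opt$objective
        }
        dirs[, ibig] <- dnew
      }
    }
  }
  list(par = x, value = fx, iterations = it, evaluations = n_eval)
}

# ---- rigid parameters --------------------------------------------------------

#' Rigid transformation parameters
#'
#' Six-parameter rigid body motion: translation `T = (Tx, Ty, Tz)` in mm
#' and Euler rotation `R = (Rx, Ry, Rz)` in degrees applied about a rotation
#' center (conventionally the 3D centerline centroid).
#'
#' @param T length-3 translation, mm.
#' @param R length-3 rotation angles, degrees.
#' @param center rotation center, mm.
#' @return object of class `rigid_params`.
#' @export
rigid_params <- function(T = c(0, 0, 0), R = c(0, 0, 0), center = c(0, 0, 0)) {
  stopifnot(length(T) == 3L, length(R) == 3L, length(center) == 3L)
  structure(list(T = as.numeric(T), R = as.numeric(R),
                 center = as.numeric(center)), class = "rigid_params")
}

#' Search bounds for rigid registration
#'
#' Box constraints `|Ti| <= d_max`, `|Ri| <= th_R` that restrict the rigid
#' search around the DICOM-initialized pose. The acquisition geometry
#' already provides a coarse alignment, so only a bounded residual motion
#' has to be recovered; defaults are 30 mm and 10 degrees.
#'
#' @param d_max translation bound, mm.
#' @param th_R rotation bound, degrees.
#' @return object of class `rigid_bounds`.
#' @export
rigid_bounds <- function(d_max = 30, th_R = 10) {
  stopifnot(d_max > 0, th_R > 0)
  structure(list(d_max = as.numeric(d_max), th_R = as.numeric(th_R)),
            class = "rigid_bounds")
}

# z.y.x Euler product, angles in degrees
euler_zyx <- function(R_deg) {
  a <- R_deg * pi / 180
  cx <- cos(a[1L]); sx <- sin(a[1L])
  cy <- cos(a[2L]); sy <- sin(a[2L])
  cz <- cos(a[3L]); sz <- sin(a[3L])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3L, 3L, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3L, 3L, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3L, 3L, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transformation to 3D points
#'
#' `x' = M_R (x - center) + center + T` with `M_R` the z.y.x Euler rotation
#' built from the parameter angles.
#'
#' @param points n x 3 matrix, mm.
#' @param p a `rigid_params`.
#' @return transformed n x 3 matrix.
#' @export
rigid_transform <- function(points, p) {
  points <- as_point_matrix(points, 3L)
  M <- euler_zyx(p$R)
  sweep(sweep(points, 2L, p$center) %*% t(M), 2L, p$center + p$T, "+")
}

# ---- nearest-neighbour distances --------------------------------------------

# For each row of A, the distance to the nearest row of B (exact, vectorized).
nn_distances <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  a2 <- rowSums(A^2)
  # chunk to bound memory at ~ 4e6 doubles
  chunk <- max(1L, floor(4e6 / nrow(B)))
  out <- numeric(nrow(A))
  b2 <- rowSums(B^2)
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(nrow(A), i + chunk - 1L)
    D2 <- outer(a2[i:j], b2, "+") - 2 * A[i:j, , drop = FALSE] %*% t(B)
    out[i:j] <- sqrt(pmax(apply(D2, 1L, min), 0))
    i <- j + 1L
  }
  out
}

# index of nearest row of B for each row of A, plus the distance
nn_match <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  chunk <- max(1L, floor(4e6 / nrow(B)))
  idx <- integer(nrow(A)); dist <- numeric(nrow(A))
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(nrow(A), i + chunk - 1L)
    D2 <- outer(a2[i:j], b2, "+") - 2 * A[i:j, , drop = FALSE] %*% t(B)
    idx[i:j] <- apply(D2, 1L, which.min)
    dist[i:j] <- sqrt(pmax(D2[cbind(seq_len(j - i + 1L), idx[i:j])], 0))
    i <- j + 1L
  }
  list(index = idx, dist = dist)
}

#' Projected 3D-to-2D centerline distance
#'
#' Mean, over all projected (and rigidly transformed) 3D centerline points,
#' of the Euclidean distance to the nearest 2D centerline point. The
#' asymmetric direction (3D onto 2D) keeps background clutter and false 2D
#' branches from pulling on the model.
#'
#' @param tree3d 3D `vessel_tree`.
#' @param tree2d 2D `vessel_tree`, or an n x 2 point matrix.
#' @param geometry a `carm_geometry`.
#' @param params a `rigid_params` (identity by default).
#' @return mean distance, mm.
#' @export
projection_distance <- function(tree3d, tree2d, geometry,
                                params = rigid_params()) {
  p3 <- if (is.matrix(tree3d)) tree3d else tree_points(tree3d)
  p2 <- if (is.matrix(tree2d)) tree2d else tree_points(tree2d)
  if (!nrow(p3) || !nrow(p2)) stop("empty centerline set")
  proj <- project(rigid_transform(p3, params), geometry)
  mean(nn_distances(proj, p2))
}

# dense uniform resampling of all 2D edges, for a smooth objective
dense_2d_points <- function(tree2d, spacing = 0.5) {
  if (is.matrix(tree2d)) return(tree2d)
  do.call(rbind, lapply(tree2d$edges, function(e) {
    resample_centerline(e$centerline, spacing)$points
  }))
}

# ---- registration ------------------------------------------------------------

#' Bounded rigid registration of a 3D tree to a 2D centerline set
#'
#' Finds the six rigid parameters that minimize the mean projected
#' nearest-neighbour distance of the 3D centerline to the 2D centerline,
#' within the box `|T| <= d_max`, `|R| <= th_R`. Optimization is staged as
#' in the order translation-first: stage 1 searches `T` alone, stage 2
#' refines all six parameters, both with the derivative-free direction-set
#' (Powell) minimizer. Bounds are enforced by a smooth quadratic penalty so
#' the line searches stay well behaved, and the returned parameters are
#' clipped to the box.
#'
#' @param tree3d 3D `vessel_tree`.
#' @param tree2d 2D `vessel_tree` or n x 2 point matrix.
#' @param geometry a `carm_geometry`.
#' @param bounds a `rigid_bounds`.
#' @param init initial `rigid_params` (identity at the centroid by default).
#' @param n_starts 1 for the single deterministic start at `init`; 9 adds
#'   an 8-point translation grid at half the bound.
#' @param spacing2d resampling pitch of the 2D objective cloud, mm.
#' @return list with `params` (fitted `rigid_params`), `value` (final mean
#'   distance, mm), `initial_value`, and `evaluations`.
#' @export
register_rigid <- function(tree3d, tree2d, geometry,
                           bounds = rigid_bounds(), init = NULL,
                           n_starts = 1L, spacing2d = 0.5) {
  if (!length(tree3d$edges)) stop("empty 3D tree")
  p3 <- tree_points(tree3d)
  p2 <- dense_2d_points(tree2d, spacing2d)
  if (!nrow(p2)) stop("empty 2D centerline set")
  center <- colMeans(p3)
  if (is.null(init)) init <- rigid_params(center = center)
  sc <- c(rep(bounds$d_max, 3L), rep(bounds$th_R, 3L))
  objective <- function(x) {
    # quadratic penalty outside the box keeps Powell smooth
    pen <- sum(pmax(abs(x) - sc, 0)^2)
    xc <- pmax(pmin(x, sc), -sc)
    pr <- rigid_params(T = xc[1:3], R = xc[4:6], center = center)
    proj <- project(rigid_transform(p3, pr), geometry)
    mean(nn_distances(proj, p2)) + pen
  }
  x_init <- c(init$T, init$R)
  f_init <- objective(x_init)
  starts <- list(x_init)
  if (n_starts > 1L) {
    g <- bounds$d_max / 2
    corners <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
    for (k in seq_len(min(n_starts - 1L, nrow(corners))))
      starts <- c(starts, list(c(corners[k, ], init$R)))
  }
  best <- NULL
  n_eval <- 0L
  for (x0 in starts) {
    # stage 1: translation only
    obj_t <- function(t) objective(c(t, x0[4:6]))
    s1 <- powell_minimize(obj_t, x0[1:3], scale = rep(bounds$d_max / 4, 3L),
                          tol = 1e-6, maxit = 12L)
    # stage 2: all six parameters
    s2 <- powell_minimize(objective, c(s1$par, x0[4:6]),
                          scale = c(rep(bounds$d_max / 8, 3L),
                                    rep(bounds$th_R / 4, 3L)),
                          tol = 1e-7, maxit = 20L)
    n_eval <- n_eval + s1$evaluations + s2$evaluations
    if (is.null(best) || s2$value < best$value) best <- s2
  }
  x <- pmax(pmin(best$par, sc), -sc)
  params <- rigid_params(T = x[1:3], R = x[4:6], center = center)
  value <- projection_distance(tree3d, p2, geometry, params)
  if (value > f_init) { # never worse than the start
    params <- init
    value <- projection_distance(tree3d, p2, geometry, init)
  }
  list(params = params, value = value, initial_value = f_init,
       evaluations = n_eval)
}
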
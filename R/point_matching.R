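# ---- tangent-window point matching ------------------------------------------

# distances from each 2D point in `q` (m x 2) to the line through `anchor`
# with unit direction `dir`: |cross(q - anchor, dir)|
point_line_distances <- function(q, anchor, dir) {
  dx <- q[, 1L] - anchor[1L]
  dy <- q[, 2L] - anchor[2L]
  abs(dx * dir[2L] - dy * dir[1L])
}

#' Matching cost of one 3D point against one candidate 2D point
#'
#' The cost couples Euclidean proximity with tangential alignment: for a
#' window of `2n + 1` neighbouring points around the projected 3D point
#' `i`, the tangent line at each window point (symmetric least-squares fit,
#' anchored at that projected point) is built, and the mean exact
#' point-to-line distance of the candidate is added to the Euclidean
#' distance between the candidate and the projected point itself. A
#' candidate lying on all window tangents and coincident with the
#' projection costs zero.
#'
#' @param proj3d n x 2 matrix of projected 3D centerline points.
#' @param i index of the 3D point.
#' @param u length-2 candidate 2D point.
#' @param n window half-width in points (clamped at the curve ends).
#' @param w_line,w_d2 weights of the tangent-line and Euclidean terms.
#' @param tangents optional precomputed n x 2 unit tangent matrix from
#'   `tangent_directions(proj3d)`.
#' @return scalar cost (mm).
#' @export
match_cost <- function(proj3d, i, u, n = 3L, w_line = 1, w_d2 = 1,
                       tangents = NULL) {
  N <- nrow(proj3d)
  if (is.null(tangents)) tangents <- tangent_directions(proj3d, window = max(n, 1L))
  win <- max(1L, i - n):min(N, i + n)
  ld <- vapply(win, function(k)
    point_line_distances(matrix(u, 1L), proj3d[k, ], tangents[k, ]), numeric(1L))
  d2 <- sqrt(sum((u - proj3d[i, ])^2))
  w_line * mean(ld) + w_d2 * d2
}

# full cost matrix: rows = 3D points, cols = candidate 2D points
match_cost_matrix <- function(proj3d, cand, n = 3L, w_line = 1, w_d2 = 1,
                              tangents = NULL) {
  N <- nrow(proj3d)
  M <- nrow(cand)
  if (is.null(tangents)) tangents <- tangent_directions(proj3d, window = max(n, 1L))
  # Euclidean term
  d2 <- sqrt(pmax(outer(rowSums(proj3d^2), rowSums(cand^2), "+") -
                    2 * proj3d %*% t(cand), 0))
  if (w_line == 0 || n < 0L)
    return(list(cost = w_d2 * d2, d2 = d2))
  # line term: for each window offset, distance of every candidate to the
  # tangent line anchored at point (i + k)
  ld_at <- abs(outer(proj3d[, 1L] * tangents[, 2L] -
                       proj3d[, 2L] * tangents[, 1L], rep(1, M)) -
                 (tangents[, 2L, drop = FALSE] %*% t(cand[, 1L, drop = FALSE])) +
                 (tangents[, 1L, drop = FALSE] %*% t(cand[, 2L, drop = FALSE])))
  acc <- matrix(0, N, M)
  cnt <- numeric(N)
  for (k in -n:n) {
    idx <- pmin(pmax(seq_len(N) + k, 1L), N)
    use <- (seq_len(N) + k) >= 1L & (seq_len(N) + k) <= N
    acc[use, ] <- acc[use, ] + ld_at[idx[use], , drop = FALSE]
    cnt[use] <- cnt[use] + 1
  }
  lterm <- acc / cnt
  list(cost = w_line * lterm + w_d2 * d2, d2 = d2)
}

#' Match every projected 3D point to a candi-line point
#'
#' For each projected 3D centerline point, picks the candi-line point of
#' minimum tangent-window matching cost; ties break first by smaller
#' Euclidean distance, then by smaller point index. The validity flag
#' `H` is 0 wherever the Euclidean distance of the chosen match exceeds
#' `max_dist` (such points exert no image force during deformation).
#'
#' @param proj3d n x 2 matrix of projected 3D points.
#' @param candiline a candi-line (list with `points`), a `centerline2d`,
#'   or an m x 2 point matrix.
#' @param n window half-width.
#' @param max_dist validity cutoff on the Euclidean distance, mm.
#' @param w_line,w_d2 term weights.
#' @return a `correspondence_map`: data frame with columns `i`, `j`,
#'   `cost`, `d2`, `H`, plus attribute `points2d` (the candidate matrix).
#' @export
match_points <- function(proj3d, candiline, n = 3L, max_dist = 5,
                         w_line = 1, w_d2 = 1) {
  cand <- if (is.matrix(candiline)) candiline
  else if (inherits(candiline, "centerline2d")) candiline$points
  else candiline$points
  if (is.null(cand) || !nrow(cand)) stop("empty candi-line")
  proj3d <- as_point_matrix(proj3d, 2L)
  cm <- match_cost_matrix(proj3d, cand, n = n, w_line = w_line, w_d2 = w_d2)
  N <- nrow(proj3d)
  j <- integer(N); cost <- numeric(N); d2 <- numeric(N)
  for (i in seq_len(N)) {
    ci <- cm$cost[i, ]
    best <- which(ci <= min(ci) + 1e-12)
    if (length(best) > 1L) { # tie-break: smaller d2, then smaller index
      di <- cm$d2[i, best]
      best <- best[di <= min(di) + 1e-12]
      best <- best[1L]
    }
    j[i] <- best[1L]
    cost[i] <- cm$cost[i, j[i]]
    d2[i] <- cm$d2[i, j[i]]
  }
  out <- data.frame(i = seq_len(N), j = j, cost = cost, d2 = d2,
                    H = as.integer(d2 <= max_dist))
  attr(out, "points2d") <- cand
  class(out) <- c("correspondence_map", class(out))
  out
}

#' Aggregate statistics of a correspondence map
#'
#' @param map a `correspondence_map` from [match_points()].
#' @return list with `mean_d2` (mean Euclidean distance over valid
#'   matches; `NA` with `undefined = TRUE` when no match is valid) and
#'   `valid_fraction`.
#' @export
matched_distance_stats <- function(map) {
  valid <- map$H == 1L
  if (!any(valid))
    return(list(mean_d2 = NA_real_, valid_fraction = 0, undefined = TRUE))
  list(mean_d2 = mean(map$d2[valid]), valid_fraction = mean(valid),
       undefined = FALSE)
}
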
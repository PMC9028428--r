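# ---- multi-feature candi-line scoring ---------------------------------------

#' Similarity weights for candi-line selection
#'
#' Non-negative weights of the gradient, distance, thickness and length
#' terms of the candi-line score. Defaults are the simulation-calibrated
#' values alpha = 0.4, beta = 0.7, gamma = 0.25, delta = 0.15.
#'
#' @param alpha gradient-term weight.
#' @param beta distance-term weight.
#' @param gamma thickness-term weight.
#' @param delta length-term weight.
#' @return object of class `similarity_weights`.
#' @export
similarity_weights <- function(alpha = 0.4, beta = 0.7, gamma = 0.25,
                               delta = 0.15) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(w < 0)) stop("similarity weights must be non-negative")
  structure(as.list(w), class = "similarity_weights")
}

#' Gradient (tangent misalignment) term
#'
#' Mean over matched pairs of the exact distance of the matched 2D point
#' to the tangent line anchored at the projected 3D point, normalized per
#' pair by the Euclidean matching distance (floored at `d_floor` so nearly
#' coincident pairs cannot blow the ratio up). Coincident curves score 0;
#' parallel curves at constant offset score about 1.
#'
#' @param proj3d n x 2 projected 3D segment points.
#' @param map correspondence map from [match_points()].
#' @param tangents optional precomputed tangents of `proj3d`.
#' @param d_floor normalization floor, mm (default 0.1).
#' @return scalar `D_theta`; `Inf` when no valid matches exist.
#' @export
gradient_term <- function(proj3d, map, tangents = NULL, d_floor = 0.1) {
  valid <- map$H == 1L
  if (!any(valid)) return(Inf)
  if (is.null(tangents)) tangents <- tangent_directions(proj3d)
  cand <- attr(map, "points2d")
  idx <- which(valid)
  ld <- vapply(idx, function(i) {
    u <- cand[map$j[i], ]
    point_line_distances(matrix(u, 1L), proj3d[i, ], tangents[i, ])
  }, numeric(1L))
  mean(ld / pmax(map$d2[idx], d_floor))
}

#' Thickness term
#'
#' Root-mean-square difference (mm) between the projected 3D vessel
#' diameter and the 2D thickness at the matched points. With
#' `rms = FALSE` the raw mean squared difference is returned instead.
#'
#' @param th3d per-point projected 3D thickness (diameter), mm.
#' @param th2d per-point candi-line thickness, mm.
#' @param map correspondence map.
#' @param rms return the RMS (default) or the mean square.
#' @return scalar `D_Th`; `NA` with a `skipped` attribute when thickness
#'   is unavailable on either side.
#' @export
thickness_term <- function(th3d, th2d, map, rms = TRUE) {
  if (is.null(th3d) || is.null(th2d))
    return(structure(NA_real_, skipped = TRUE))
  valid <- map$H == 1L
  if (!any(valid)) return(Inf)
  idx <- which(valid)
  msq <- mean((th3d[idx] - th2d[map$j[idx]])^2)
  if (rms) sqrt(msq) else msq
}

#' Length term
#'
#' Relative length mismatch `|s_L - c_L| / s_L` between the projected 3D
#' segment (length `s_L`) and the candi-line (length `c_L`).
#'
#' @param proj3d n x 2 projected 3D segment points.
#' @param candiline candi-line (list with `points`) or point matrix.
#' @return scalar `D_L`.
#' @export
length_term <- function(proj3d, candiline) {
  s_L <- centerline_length(as_point_matrix(proj3d, 2L))
  if (s_L <= 0) stop("zero-length 3D segment")
  cpts <- if (is.matrix(candiline)) candiline else candiline$points
  c_L <- centerline_length(cpts)
  abs(s_L - c_L) / s_L
}

#' Score candi-lines and select the best one for a 3D segment
#'
#' Runs tangent-window point matching of the projected 3D segment against
#' every candi-line, computes the four similarity terms, and returns the
#' candi-line minimizing the weighted score
#' `SM = alpha * D_theta + beta * d2 + gamma * D_Th + delta * D_L`.
#' Ties break by smaller mean matching distance, then by candi-line order.
#'
#' @param proj3d n x 2 projected 3D segment points.
#' @param th3d per-point projected 3D thickness (diameter, mm), or NULL to
#'   skip the thickness term.
#' @param candilines list of candi-lines from [enumerate_candilines()].
#' @param weights a `similarity_weights`.
#' @param n,max_dist matching parameters (see [match_points()]).
#' @return list with `best` (index of the winning candi-line), `candiline`
#'   (the winner), `map` (its correspondence map), and `scores` (data
#'   frame of all four terms and `SM` per candi-line).
#' @export
select_candiline <- function(proj3d, th3d, candilines,
                             weights = similarity_weights(), n = 3L,
                             max_dist = 5) {
  if (!length(candilines)) stop("no candi-lines to select from")
  proj3d <- as_point_matrix(proj3d, 2L)
  tangents <- tangent_directions(proj3d)
  rows <- vector("list", length(candilines))
  maps <- vector("list", length(candilines))
  for (k in seq_along(candilines)) {
    cl <- candilines[[k]]
    map <- match_points(proj3d, cl, n = n, max_dist = max_dist)
    maps[[k]] <- map
    st <- matched_distance_stats(map)
    d2m <- if (isTRUE(st$undefined)) Inf else st$mean_d2
    Dth <- thickness_term(th3d, cl$thickness %||% NULL, map)
    Dth_use <- if (is.na(Dth)) 0 else Dth # skipped -> gamma effectively 0
    Dtheta <- gradient_term(proj3d, map, tangents = tangents)
    DL <- length_term(proj3d, cl)
    SM <- weights$alpha * Dtheta + weights$beta * d2m +
      weights$gamma * Dth_use + weights$delta * DL
    rows[[k]] <- data.frame(candiline = k, D_theta = Dtheta, d2 = d2m,
                            D_Th = if (is.na(Dth)) NA_real_ else Dth,
                            D_L = DL, SM = SM)
  }
  scores <- do.call(rbind, rows)
  best <- which(scores$SM <= min(scores$SM) + 1e-12)
  if (length(best) > 1L) {
    d2b <- scores$d2[best]
    best <- best[d2b <= min(d2b) + 1e-12]
  }
  best <- best[1L]
  list(best = best, candiline = candilines[[best]], map = maps[[best]],
       scores = scores)
}
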
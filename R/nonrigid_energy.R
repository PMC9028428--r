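# ---- snake energies ----------------------------------------------------------

#' Energy weights for nonrigid deformation
#'
#' Non-negative weights of the continuity, curvature and image energies.
#' Defaults are the simulation-calibrated values mu = 0.5, tau = 0.4,
#' phi = 0.6.
#'
#' @param mu continuity weight.
#' @param tau curvature weight.
#' @param phi image weight.
#' @return object of class `energy_weights`.
#' @export
energy_weights <- function(mu = 0.5, tau = 0.4, phi = 0.6) {
  w <- c(mu = mu, tau = tau, phi = phi)
  if (any(w < 0)) stop("energy weights must be non-negative")
  structure(as.list(w), class = "energy_weights")
}

#' Continuity energy of a centerline
#'
#' Keeps adjacent points at the reference spacing `dbar` (the mean spacing
#' of the undeformed centerline): `E_cont(v_i) = (dbar - ||v_i -
#' v_{i-1}||)^2`, with the first point contributing zero. The squared-gap
#' form makes a uniformly spaced curve a zero of the energy rather than
#' driving the spacing toward zero.
#'
#' @param points n x d matrix of centerline points.
#' @param dbar reference spacing, mm (frozen from the initial centerline).
#' @return list with `per_point` (length n) and `total`.
#' @export
energy_cont <- function(points, dbar) {
  p <- as.matrix(points)
  n <- nrow(p)
  stopifnot(n >= 2L)
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  per <- c(0, (dbar - seg)^2)
  list(per_point = per, total = sum(per))
}

#' Curvature energy of a centerline
#'
#' Discrete second-derivative (Laplacian) penalty: `E_curv(v_i) =
#' ||v_{i-1} - 2 v_i + v_{i+1}||^2` for interior points, endpoints
#' contributing zero. Collinear equispaced points have zero energy.
#'
#' @param points n x d matrix (n >= 3 for a nonzero value).
#' @return list with `per_point` and `total`.
#' @export
energy_curv <- function(points) {
  p <- as.matrix(points)
  n <- nrow(p)
  if (n < 3L) return(list(per_point = rep(0, n), total = 0))
  lap <- p[-c(n - 1L, n), , drop = FALSE] - 2 * p[-c(1L, n), , drop = FALSE] +
    p[-c(1L, 2L), , drop = FALSE]
  per <- c(0, rowSums(lap^2), 0)
  list(per_point = per, total = sum(per))
}

#' Image energy of a centerline against matched 2D points
#'
#' Pulls each valid 3D point toward the X-ray source ray through its
#' matched 2D point: `E_image(v_i) = H(v_i) * dist(v_i, ray(u_i))^2`.
#' Working with the back-projected ray deforms the centerline in 3D while
#' leaving the (single-view, unobservable) depth along the ray
#' unconstrained.
#'
#' @param points n x 3 matrix of current 3D points.
#' @param rays list with `origin` (n x 3) and `dir` (n x 3 unit rows) from
#'   `backproject_rays()` of the matched 2D points.
#' @param H integer 0/1 validity per point.
#' @return list with `per_point`, `total`, and `residual` (n x 3 matrix of
#'   perpendicular offsets from the rays, the image-energy gradient
#'   direction).
#' @export
energy_image <- function(points, rays, H) {
  p <- as.matrix(points)
  w <- p - rays$origin
  along <- rowSums(w * rays$dir)
  res <- w - along * rays$dir # perpendicular component
  per <- H * rowSums(res^2)
  list(per_point = per, total = sum(per), residual = res * H)
}

# ---- gradient-descent deformation -------------------------------------------

# analytic gradient of the three energies for one branch's points
branch_energy_gradient <- function(p, dbar, rays, H, w) {
  n <- nrow(p)
  g <- matrix(0, n, 3L)
  # continuity: E_i = (dbar - L_i)^2, L_i = |v_i - v_{i-1}|
  d <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
  L <- sqrt(rowSums(d^2))
  Ls <- pmax(L, 1e-12)
  coef <- -2 * (dbar - L) / Ls # d E_i / d L * dL/dv
  gc_ <- d * coef
  g[-1L, ] <- g[-1L, ] + w$mu * gc_
  g[-n, ] <- g[-n, ] - w$mu * gc_
  # curvature: E_i = |c_i|^2, c_i = v_{i-1} - 2 v_i + v_{i+1}
  if (n >= 3L) {
    lap <- p[-c(n - 1L, n), , drop = FALSE] - 2 * p[-c(1L, n), , drop = FALSE] +
      p[-c(1L, 2L), , drop = FALSE]
    g[-c(n - 1L, n), ] <- g[-c(n - 1L, n), ] + w$tau * 2 * lap
    g[-c(1L, n), ] <- g[-c(1L, n), ] - w$tau * 4 * lap
    g[-c(1L, 2L), ] <- g[-c(1L, 2L), ] + w$tau * 2 * lap
  }
  # image: E_i = H_i |res_i|^2, grad = 2 res_i
  ei <- energy_image(p, rays, H)
  g <- g + w$phi * 2 * ei$residual
  g
}

branch_energy_total <- function(p, dbar, rays, H, w) {
  w$mu * energy_cont(p, dbar)$total + w$tau * energy_curv(p)$total +
    w$phi * energy_image(p, rays, H)$total
}

#' Nonrigid deformation of a 3D tree by snake-energy minimization
#'
#' Deforms every branch of the (rigidly aligned) 3D tree by gradient
#' descent on the weighted sum of continuity, curvature and image
#' energies. Correspondences of each branch against its selected
#' candi-line are refreshed every `rematch_every` iterations and held
#' fixed in between so the descent direction is well defined; branch
#' junction points shared between edges receive the summed gradient of all
#' incident branches so bifurcations stay coincident. If the total energy
#' rises for five consecutive iterations the step is halved (at most five
#' times before erroring out).
#'
#' @param tree3d rigidly aligned 3D `vessel_tree` to deform.
#' @param selected named list (3D edge id -> candi-line with `points`);
#'   edges absent from the list keep H = 0 everywhere (internal energies
#'   only).
#' @param geometry a `carm_geometry`.
#' @param weights an `energy_weights`.
#' @param step gradient step size (default 0.05).
#' @param max_iter iteration cap (default 500).
#' @param tol relative energy-change stopping tolerance (default 1e-6).
#' @param rematch_every correspondence refresh period, iterations.
#' @param max_dist matching validity cutoff, mm.
#' @param n_window matching tangent-window half-width.
#' @param resample_mm pre-deformation resampling pitch, or NULL (default)
#'   to keep the input sampling. Resampling changes point counts, so leave
#'   it NULL when point indices (e.g. marker locations) must survive.
#' @return object of class `deformation_state`: list with `tree` (deformed
#'   `vessel_tree`), `trace` (data frame of per-iteration energies),
#'   `iterations`, and `step`.
#' @export
deform <- function(tree3d, selected, geometry,
                   weights = energy_weights(), step = 0.05,
                   max_iter = 500L, tol = 1e-6, rematch_every = 10L,
                   max_dist = 5, n_window = 3L, resample_mm = NULL) {
  if (!is.null(resample_mm)) {
    tree3d <- transform_tree(tree3d, identity)
    for (eid in names(tree3d$edges))
      tree3d$edges[[eid]]$centerline <-
        resample_centerline(tree3d$edges[[eid]]$centerline, resample_mm)
  }
  eids <- names(tree3d$edges)
  branches <- lapply(eids, function(eid) tree3d$edges[[eid]]$centerline$points)
  names(branches) <- eids
  dbars <- vapply(branches, mean_spacing, numeric(1L))
  # shared-vertex bookkeeping: branch endpoints mapping to the same tree
  # vertex are tied together
  vert_of <- lapply(eids, function(eid)
    c(first = tree3d$edges[[eid]]$from, last = tree3d$edges[[eid]]$to))
  names(vert_of) <- eids
  rays <- list(); Hs <- list()
  refresh <- function() {
    for (eid in eids) {
      p <- branches[[eid]]
      if (is.null(selected[[eid]])) {
        rays[[eid]] <<- list(origin = matrix(0, nrow(p), 3L),
                             dir = matrix(rep(c(0, 0, 1), each = nrow(p)),
                                          nrow(p), 3L))
        Hs[[eid]] <<- integer(nrow(p))
        next
      }
      proj <- project(p, geometry)
      map <- match_points(proj, selected[[eid]], n = n_window,
                          max_dist = max_dist)
      cand <- attr(map, "points2d")
      rays[[eid]] <<- backproject_rays(cand[map$j, , drop = FALSE], geometry)
      Hs[[eid]] <<- map$H
    }
  }
  total_energy <- function() {
    e <- c(cont = 0, curv = 0, image = 0)
    for (eid in eids) {
      p <- branches[[eid]]
      e["cont"] <- e["cont"] + weights$mu * energy_cont(p, dbars[eid])$total
      e["curv"] <- e["curv"] + weights$tau * energy_curv(p)$total
      e["image"] <- e["image"] +
        weights$phi * energy_image(p, rays[[eid]], Hs[[eid]])$total
    }
    e
  }
  refresh()
  trace <- list()
  e <- total_energy()
  E_prev <- sum(e)
  rises <- 0L
  halvings <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # accumulate gradients, summing at shared junction vertices
    grads <- lapply(eids, function(eid)
      branch_energy_gradient(branches[[eid]], dbars[eid], rays[[eid]],
                             Hs[[eid]], weights))
    names(grads) <- eids
    vsum <- list()
    for (eid in eids) {
      n <- nrow(branches[[eid]])
      for (pos in c("first", "last")) {
        v <- vert_of[[eid]][[pos]]
        row <- if (pos == "first") 1L else n
        vsum[[v]] <- (vsum[[v]] %||% c(0, 0, 0)) + grads[[eid]][row, ]
      }
    }
    for (eid in eids) {
      n <- nrow(branches[[eid]])
      grads[[eid]][1L, ] <- vsum[[vert_of[[eid]][["first"]]]]
      grads[[eid]][n, ] <- vsum[[vert_of[[eid]][["last"]]]]
    }
    for (eid in eids)
      branches[[eid]] <- branches[[eid]] - step * grads[[eid]]
    # re-tie shared vertices exactly (identical update, but guard drift)
    vpos <- list()
    for (eid in eids) {
      n <- nrow(branches[[eid]])
      for (pos in c("first", "last")) {
        v <- vert_of[[eid]][[pos]]
        row <- if (pos == "first") 1L else n
        if (is.null(vpos[[v]])) vpos[[v]] <- branches[[eid]][row, ]
        branches[[eid]][row, ] <- vpos[[v]]
      }
    }
    rematched <- FALSE
    if (it %% rematch_every == 0L) {
      refresh()
      rematched <- TRUE
    }
    e <- total_energy()
    E <- sum(e)
    trace[[it]] <- c(iter = it, cont = unname(e["cont"]),
                     curv = unname(e["curv"]), image = unname(e["image"]),
                     total = E, rematched = as.numeric(rematched))
    if (!rematched) {
      if (E > E_prev + 1e-12) {
        rises <- rises + 1L
        if (rises >= 5L) {
          step <- step / 2
          halvings <- halvings + 1L
          rises <- 0L
          if (halvings > 5L)
            stop("nonrigid deformation diverged despite step halving")
        }
      } else {
        rises <- 0L
        if (abs(E_prev - E) <= tol * max(E_prev, 1e-12)) {
          E_prev <- E
          break
        }
      }
    }
    E_prev <- E
  }
  # rebuild the tree with deformed points
  verts <- tree3d$vertices
  for (eid in eids) {
    n <- nrow(branches[[eid]])
    verts[[vert_of[[eid]][["first"]]]] <- branches[[eid]][1L, ]
    verts[[vert_of[[eid]][["last"]]]] <- branches[[eid]][n, ]
  }
  edges <- tree3d$edges
  for (eid in eids)
    edges[[eid]]$centerline <- centerline3d(branches[[eid]],
                                            edges[[eid]]$centerline$radius)
  out_tree <- vessel_tree(verts, edges, tree3d$root, validate = FALSE)
  structure(list(tree = out_tree,
                 trace = as.data.frame(do.call(rbind, trace)),
                 iterations = it, step = step),
            class = "deformation_state")
}

#' @export
print.deformation_state <- function(x, ...) {
  cat(sprintf("<deformation_state> %d iterations, final energy %.4g\n",
              x$iterations, x$trace$total[nrow(x$trace)]))
  invisible(x)
}
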
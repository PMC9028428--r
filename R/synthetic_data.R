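# ---- synthetic coronary-like tree generator ---------------------------------

# orthonormal frame completing a unit vector
perp_frame <- function(u) {
  a <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w1 <- a - sum(a * u) * u
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(u[2L] * w1[3L] - u[3L] * w1[2L],
          u[3L] * w1[1L] - u[1L] * w1[3L],
          u[1L] * w1[2L] - u[2L] * w1[1L])
  list(w1 = w1, w2 = w2)
}

# one smooth branch: straight run plus sinusoidal bending in the two
# perpendicular directions, sampled at ~1 mm pitch; bending vanishes at the
# start so branches attach exactly at their parent vertex
smooth_branch <- function(start, dir, length_mm, r_start, r_end,
                          wiggle = 0.08, pitch = 1) {
  n <- max(4L, ceiling(length_mm / pitch) + 1L)
  t <- seq(0, length_mm, length.out = n)
  fr <- perp_frame(dir)
  a1 <- stats::runif(1, 0.3, 1) * wiggle * length_mm
  a2 <- stats::runif(1, 0.3, 1) * wiggle * length_mm
  f1 <- sample(1:2, 1L)
  f2 <- sample(1:2, 1L)
  ph1 <- 0; ph2 <- 0 # sin(0) = 0 keeps the start exact
  p <- outer(t, dir) +
    outer(a1 * sin(pi * f1 * t / length_mm + ph1), fr$w1) +
    outer(a2 * sin(pi * f2 * t / length_mm + ph2), fr$w2)
  p <- sweep(p, 2L, start, "+")
  r <- seq(r_start, r_end, length.out = n)
  centerline3d(p, r)
}

# rotate unit vector u by angle_deg within the plane spanned by (u, axis hint)
tilt_direction <- function(u, angle_deg, azimuth_deg) {
  fr <- perp_frame(u)
  a <- angle_deg * pi / 180
  b <- azimuth_deg * pi / 180
  w <- cos(b) * fr$w1 + sin(b) * fr$w2
  v <- cos(a) * u + sin(a) * w
  v / sqrt(sum(v^2))
}

#' Generate a synthetic 3D coronary-like vessel tree
#'
#' Grows a binary-branching tree of smooth 3D curves. Each branch is a
#' sinusoidally perturbed straight run; children leave their parent's tip
#' at random divergence angles. Radii taper geometrically per generation
#' and linearly along each branch, so every root-to-leaf radius profile is
#' non-increasing. The tree is recentred so its centroid sits at the
#' origin (the default isocenter).
#'
#' @param seed integer RNG seed; the tree is a pure function of the
#'   arguments.
#' @param n_branches number of branches (edges) to grow.
#' @param depth_mm_range branch length range, mm.
#' @param radius_root_mm lumen radius at the root, mm.
#' @param taper per-generation radius factor in (0, 1].
#' @param wiggle bending amplitude as a fraction of branch length.
#' @return a 3D `vessel_tree`.
#' @export
generate_tree <- function(seed = 1L, n_branches = 7L,
                          depth_mm_range = c(22, 40), radius_root_mm = 2.5,
                          taper = 0.8, wiggle = 0.08) {
  stopifnot(n_branches >= 1L)
  set.seed(seed)
  vertices <- list(v1 = c(0, 0, 0))
  edges <- list()
  # growable tips: vertex id, outgoing direction, radius there, generation
  root_dir <- c(stats::runif(1, -0.3, 0.3), stats::runif(1, -0.3, 0.3), 1)
  root_dir <- root_dir / sqrt(sum(root_dir^2))
  tips <- list(list(v = "v1", dir = root_dir, r = radius_root_mm, gen = 0L))
  nv <- 1L
  while (length(edges) < n_branches) {
    # split the tip with the largest radius (front of the list after sort)
    ord <- order(vapply(tips, function(t) -t$r, numeric(1L)))
    tip <- tips[[ord[1L]]]
    tips <- tips[-ord[1L]]
    n_child <- if (length(edges) + 2L <= n_branches && tip$gen > 0L) 2L else 1L
    if (tip$gen == 0L) n_child <- 1L # root grows a single trunk first
    az0 <- stats::runif(1, 0, 360)
    for (k in seq_len(n_child)) {
      L <- stats::runif(1, depth_mm_range[1L], depth_mm_range[2L])
      r0 <- tip$r * if (tip$gen == 0L) 1 else taper
      r1 <- r0 * 0.85
      ang <- if (n_child == 1L) stats::runif(1, 0, 15) else stats::runif(1, 18, 40)
      az <- az0 + (k - 1L) * stats::runif(1, 120, 240)
      dir <- tilt_direction(tip$dir, ang, az)
      br <- smooth_branch(tip$v_pos %||% vertices[[tip$v]], dir, L, r0, r1,
                          wiggle = wiggle)
      nv <- nv + 1L
      vid <- paste0("v", nv)
      vertices[[vid]] <- br$points[nrow(br$points), ]
      eid <- paste0("e", length(edges) + 1L)
      edges[[eid]] <- list(from = tip$v, to = vid, centerline = br)
      end_dir <- br$points[nrow(br$points), ] - br$points[nrow(br$points) - 1L, ]
      end_dir <- end_dir / sqrt(sum(end_dir^2))
      tips <- c(tips, list(list(v = vid, dir = end_dir, r = r1,
                                gen = tip$gen + 1L)))
      if (length(edges) >= n_branches) break
    }
  }
  tr <- vessel_tree(vertices, edges, root = "v1")
  ctr <- colMeans(tree_points(tr))
  transform_tree(tr, function(p) sweep(p, 2L, ctr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- ground-truth deformations ----------------------------------------------

# smooth low-frequency sinusoidal displacement field, |d(p)| <= amp_mm
make_displacement_field <- function(amp_mm, seed, n_modes = 3L,
                                    wavelength_mm = 80) {
  set.seed(seed)
  k <- matrix(stats::rnorm(3L * n_modes), n_modes, 3L)
  k <- k / sqrt(rowSums(k^2)) * (2 * pi / wavelength_mm)
  phase <- stats::runif(n_modes, 0, 2 * pi)
  amps <- matrix(stats::runif(3L * n_modes, -1, 1), n_modes, 3L)
  raw <- function(p) {
    d <- matrix(0, nrow(p), 3L)
    for (m in seq_len(n_modes))
      d <- d + outer(sin(p %*% k[m, ] + phase[m])[, 1L], amps[m, ])
    d
  }
  # normalize the worst-case magnitude over a probe grid to amp_mm
  gr <- as.matrix(expand.grid(seq(-80, 80, by = 16), seq(-80, 80, by = 16),
                              seq(-80, 80, by = 16)))
  mx <- max(sqrt(rowSums(raw(gr)^2)))
  scale <- if (mx > 0) amp_mm / mx else 0
  function(p) raw(as_point_matrix(p, 3L)) * scale
}

#' Apply a known rigid plus smooth nonrigid deformation to a tree
#'
#' Rigid motion about the tree centroid followed by a smooth sinusoidal
#' displacement field of bounded amplitude (the stand-in for cardiac /
#' respiratory deformation between acquisitions). Topology and point
#' counts are unchanged; the per-point displacement is recorded.
#'
#' @param tree a 3D `vessel_tree`.
#' @param rigid a `rigid_params` (its center is overridden by the tree
#'   centroid).
#' @param amp_mm maximum displacement magnitude, mm (0 disables the field).
#' @param seed RNG seed for the field.
#' @return list with `tree` (deformed), `rigid` (center-resolved params),
#'   `field` (the displacement function), and `max_displacement`.
#' @export
apply_deformation <- function(tree, rigid = rigid_params(), amp_mm = 0,
                              seed = 1L) {
  ctr <- colMeans(tree_points(tree))
  rigid <- rigid_params(rigid$T, rigid$R, center = ctr)
  field <- if (amp_mm > 0) make_displacement_field(amp_mm, seed)
  else function(p) matrix(0, nrow(p), 3L)
  f <- function(p) {
    q <- rigid_transform(p, rigid)
    q + field(q)
  }
  out <- transform_tree(tree, f)
  disp <- sqrt(rowSums(field(rigid_transform(tree_points(tree), rigid))^2))
  list(tree = out, rigid = rigid, field = field,
       max_displacement = if (length(disp)) max(disp) else 0)
}

# ---- 2D corruption and rasterization ----------------------------------------

#' Corrupt a projected 2D vessel tree and rasterize it
#'
#' Emulates segmentation error on the projected centerlines: gaps split
#' edges into disconnected sub-segments, short false branches sprout from
#' true vessels at random angles, and (optionally) a translated copy of one
#' branch is overlaid to create a vessel crossing. Corruption acts on the
#' vector centerlines so every resulting 2D point keeps an exact
#' ground-truth label (`is_true`, `source3d`); the binary mask is rendered
#' afterwards from the corrupted centerlines with their local thickness.
#'
#' @param tree2d projected 2D `vessel_tree` (edges carry `source3d`).
#' @param geometry a `carm_geometry` (raster size and pixel spacing).
#' @param gap_rate expected number of gaps per true edge.
#' @param false_branch_rate expected number of false branches per true edge.
#' @param crossing overlay a shifted branch copy to force a crossing.
#' @param gap_mm length removed by each gap, mm.
#' @param seed RNG seed.
#' @param rasterize render the binary mask (set FALSE to skip).
#' @return list with `tree` (corrupted 2D `vessel_tree`) and `mask`
#'   (raster matrix of 0/1, or NULL).
#' @export
rasterize_and_corrupt <- function(tree2d, geometry, gap_rate = 0.2,
                                  false_branch_rate = 0.2, crossing = FALSE,
                                  gap_mm = 3, seed = 1L, rasterize = TRUE) {
  set.seed(seed)
  vertices <- tree2d$vertices
  edges <- list()
  nv <- length(vertices)
  new_vid <- function() {
    nv <<- nv + 1L
    paste0("g", nv)
  }
  add_edge <- function(cl, from, to, source3d, is_true) {
    eid <- paste0("s", length(edges) + 1L)
    edges[[eid]] <<- list(from = from, to = to, centerline = cl,
                          source3d = source3d, is_true = is_true)
  }
  for (eid in names(tree2d$edges)) {
    e <- tree2d$edges[[eid]]
    cl <- resample_centerline(e$centerline, 0.5)
    n_gaps <- stats::rpois(1L, gap_rate)
    p <- cl$points
    th <- cl$thickness
    n <- nrow(p)
    s <- cumulative_arclength(p)
    L <- s[n]
    cut <- rep(FALSE, n)
    if (n_gaps > 0 && L > 3 * gap_mm) {
      centers <- stats::runif(n_gaps, 0.15 * L, 0.85 * L)
      for (cc in centers)
        cut <- cut | (s > cc - gap_mm / 2 & s < cc + gap_mm / 2)
    }
    runs <- rle(!cut)
    idx <- 1L
    for (r in seq_along(runs$lengths)) {
      take <- idx:(idx + runs$lengths[r] - 1L)
      idx <- idx + runs$lengths[r]
      if (!runs$values[r] || length(take) < 3L) next
      sub <- centerline2d(p[take, , drop = FALSE],
                          if (!is.null(th)) th[take])
      a <- new_vid(); b <- new_vid()
      vertices[[a]] <- sub$points[1L, ]
      vertices[[b]] <- sub$points[nrow(sub$points), ]
      add_edge(sub, a, b, e$source3d %||% eid, TRUE)
    }
    # false branches: short stubs leaving a random point of the true edge
    n_false <- stats::rpois(1L, false_branch_rate)
    for (k in seq_len(n_false)) {
      cand_i <- seq(max(2L, round(n * 0.2)), min(n - 1L, round(n * 0.8)))
      i0 <- cand_i[sample.int(length(cand_i), 1L)]
      base <- p[i0, ]
      tang <- p[min(n, i0 + 1L), ] - p[max(1L, i0 - 1L), ]
      tang <- tang / sqrt(sum(tang^2))
      norm2 <- c(-tang[2L], tang[1L])
      ang <- stats::runif(1, 35, 90) * pi / 180 * sample(c(-1, 1), 1L)
      dir <- cos(ang) * tang + sin(ang) * norm2
      len <- stats::runif(1, 4, 9)
      tt <- seq(0, len, by = 0.5)
      bend <- stats::runif(1, -0.15, 0.15)
      fp <- sweep(outer(tt, dir) + outer(bend * tt^2 / len, c(-dir[2L], dir[1L])),
                  2L, base, "+")
      fth <- rep(if (!is.null(th)) th[i0] * 0.7 else 1, length(tt))
      a <- new_vid(); b <- new_vid()
      vertices[[a]] <- fp[1L, ]
      vertices[[b]] <- fp[nrow(fp), ]
      add_edge(centerline2d(fp, fth), a, b, NA_character_, FALSE)
    }
  }
  if (crossing && length(edges) >= 2L) {
    # overlay a shifted copy of one true edge across another
    true_ids <- names(edges)[vapply(edges, function(e) isTRUE(e$is_true), TRUE)]
    if (length(true_ids) >= 2L) {
      src <- edges[[true_ids[1L]]]
      tgt <- edges[[true_ids[2L]]]
      shift <- colMeans(tgt$centerline$points) - colMeans(src$centerline$points)
      pp <- sweep(src$centerline$points, 2L, shift, "+")
      a <- new_vid(); b <- new_vid()
      vertices[[a]] <- pp[1L, ]
      vertices[[b]] <- pp[nrow(pp), ]
      add_edge(centerline2d(pp, src$centerline$thickness), a, b,
               NA_character_, FALSE)
    }
  }
  out <- vessel_tree(vertices, edges, root = NA_character_, validate = FALSE)
  mask <- if (rasterize) rasterize_tree2d(out, geometry) else NULL
  list(tree = out, mask = mask)
}

#' Render a 2D vessel tree to a binary mask
#'
#' Stamps a disk of the local half-thickness at every (densely resampled)
#' centerline point into the detector raster.
#'
#' @param tree2d a 2D `vessel_tree` with per-point thickness.
#' @param geometry a `carm_geometry`.
#' @return integer matrix (rows x cols) of 0/1.
#' @export
rasterize_tree2d <- function(tree2d, geometry) {
  rows <- geometry$image_size_px[1L]
  cols <- geometry$image_size_px[2L]
  mask <- matrix(0L, rows, cols)
  sp <- geometry$pixel_spacing_mm
  for (e in tree2d$edges) {
    cl <- resample_centerline(e$centerline, sp / 2)
    px <- mm_to_pixel(cl$points, geometry)
    th_px <- (cl$thickness %||% rep(2, nrow(px))) / sp
    rad <- pmax(th_px / 2, 0.6)
    for (i in seq_len(nrow(px))) {
      r0 <- px[i, 1L]; c0 <- px[i, 2L]; rd <- rad[i]
      ri <- max(1L, floor(r0 - rd)):min(rows, ceiling(r0 + rd))
      ci <- max(1L, floor(c0 - rd)):min(cols, ceiling(c0 + rd))
      if (!length(ri) || !length(ci)) next
      d2 <- outer((ri - r0)^2, (ci - c0)^2, "+")
      mask[ri, ci][d2 <= rd^2] <- 1L
    }
  }
  mask
}

# ---- full simulation case ----------------------------------------------------

#' Default simulation configuration
#'
#' The study conditions of the built-in simulator: a 512 x 512 detector at
#' 0.279 mm pixel spacing (the midpoint of typical angiographic imager
#' spacings), SID 1000 mm / SOD 750 mm, a seven-branch tree with 2.5 mm
#' root radius, rigid offsets bounded by 30 mm / 10 degrees, a 2 mm
#' smooth displacement field, and mild segmentation corruption (0.2 gaps
#' and 0.2 false branches expected per edge).
#'
#' @return named list of simulator parameters.
#' @export
default_sim_config <- function() {
  list(n_branches = 7L, depth_mm_range = c(22, 40), radius_root_mm = 2.5,
       taper = 0.8, wiggle = 0.08,
       primary_angle_deg = -29.3, secondary_angle_deg = -18.7,
       pixel_spacing_mm = 0.279, sid_mm = 1000, sod_mm = 750,
       image_size_px = c(512L, 512L),
       rigid_frac = 0.8, d_max = 30, th_R = 10, rigid_enabled = TRUE,
       amp_mm = 2, gap_rate = 0.2, false_branch_rate = 0.2,
       crossing = FALSE, n_markers = 10L, rasterize = FALSE)
}

#' Generate one complete simulation case
#'
#' Builds a synthetic 3D tree, draws a ground-truth rigid offset uniformly
#' within `rigid_frac` of the registration bounds, adds a smooth nonrigid
#' displacement field, projects the deformed tree through the C-arm
#' geometry, corrupts and (optionally) rasterizes the projection, records
#' exact 3D-to-2D ground-truth correspondences, and samples marker pairs at
#' bifurcations and mid-branch points.
#'
#' @param config list as returned by [default_sim_config()]; entries can be
#'   overridden selectively.
#' @param seed integer seed controlling every random draw.
#' @return object of class `simulation_case`: a list with `tree3d` (the
#'   undeformed model), `tree3d_true` (after rigid + nonrigid truth),
#'   `true_rigid`, `field`, `geometry`, `tree2d` (corrupted projection),
#'   `tree2d_clean`, `mask`, `markers` (indices and true positions), and
#'   `seed`.
#' @export
make_case <- function(config = default_sim_config(), seed = 1L) {
  cfg <- utils::modifyList(default_sim_config(), config)
  tree3d <- generate_tree(seed = seed * 17L + 1L, n_branches = cfg$n_branches,
                          depth_mm_range = cfg$depth_mm_range,
                          radius_root_mm = cfg$radius_root_mm,
                          taper = cfg$taper, wiggle = cfg$wiggle)
  geometry <- carm_geometry(cfg$primary_angle_deg, cfg$secondary_angle_deg,
                            cfg$pixel_spacing_mm, cfg$sid_mm, cfg$sod_mm,
                            cfg$image_size_px, iso = c(0, 0, 0))
  set.seed(seed * 31L + 7L)
  true_rigid <- if (isTRUE(cfg$rigid_enabled))
    rigid_params(T = stats::runif(3, -1, 1) * cfg$rigid_frac * cfg$d_max,
                 R = stats::runif(3, -1, 1) * cfg$rigid_frac * cfg$th_R)
  else rigid_params()
  def <- apply_deformation(tree3d, true_rigid, amp_mm = cfg$amp_mm,
                           seed = seed * 13L + 3L)
  tree2d_clean <- project_tree(def$tree, geometry)
  cor <- rasterize_and_corrupt(tree2d_clean, geometry,
                               gap_rate = cfg$gap_rate,
                               false_branch_rate = cfg$false_branch_rate,
                               crossing = cfg$crossing,
                               seed = seed * 7L + 5L,
                               rasterize = isTRUE(cfg$rasterize))
  markers <- sample_markers(tree3d, def$tree, cfg$n_markers,
                            seed = seed * 11L + 9L)
  structure(list(tree3d = tree3d, tree3d_true = def$tree,
                 true_rigid = def$rigid, field = def$field,
                 geometry = geometry, tree2d = cor$tree,
                 tree2d_clean = tree2d_clean, mask = cor$mask,
                 markers = markers, config = cfg, seed = seed),
            class = "simulation_case")
}

# markers: all bifurcation vertices plus mid-branch points, up to n pairs;
# stored as (edge id, point index) with the true deformed position
sample_markers <- function(tree3d, tree3d_true, n_markers, seed) {
  set.seed(seed)
  rel <- tree_edge_relations(tree3d)
  locs <- list()
  # bifurcations: vertices with >= 2 child edges
  kids <- table(rel$upstream_vertex)
  bif <- names(kids)[kids >= 2L & names(kids) != tree3d$root]
  for (v in bif) {
    eid <- names(rel$upstream_vertex)[rel$upstream_vertex == v][1L]
    locs <- c(locs, list(list(edge = eid, index = 1L)))
  }
  for (eid in names(tree3d$edges)) {
    n <- nrow(tree3d$edges[[eid]]$centerline$points)
    locs <- c(locs, list(list(edge = eid, index = as.integer(ceiling(n / 2)))))
  }
  if (length(locs) > n_markers) locs <- locs[sample(length(locs), n_markers)]
  while (length(locs) < n_markers) {
    eid <- sample(names(tree3d$edges), 1L)
    n <- nrow(tree3d$edges[[eid]]$centerline$points)
    locs <- c(locs, list(list(edge = eid, index = sample(n, 1L))))
  }
  truth <- do.call(rbind, lapply(locs, function(l)
    tree3d_true$edges[[l$edge]]$centerline$points[l$index, ]))
  list(locations = locs, truth = truth)
}

#' Extract marker positions from a (deformed) tree
#'
#' @param tree a 3D `vessel_tree` with the same topology as the simulated
#'   model.
#' @param markers the `markers` element of a `simulation_case`.
#' @return M x 3 matrix of the marker positions on `tree`.
#' @export
marker_positions <- function(tree, markers) {
  do.call(rbind, lapply(markers$locations, function(l)
    tree$edges[[l$edge]]$centerline$points[l$index, ]))
}

#' @export
print.simulation_case <- function(x, ...) {
  cat(sprintf(paste0("<simulation_case seed %d> %d 3D edges, %d 2D segments, ",
                     "rigid |T| = %.1f mm, field <= %.1f mm\n"),
              x$seed, length(x$tree3d$edges), length(x$tree2d$edges),
              sqrt(sum(x$true_rigid$T^2)), x$config$amp_mm))
  invisible(x)
}
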
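# ---- smallest-unit 2D graph --------------------------------------------------

# 2D segment intersection; returns parameter pairs (t, u) in [0,1] or NULL
seg_intersect <- function(p1, p2, q1, q2) {
  r <- p2 - p1; s <- q2 - q1
  denom <- r[1L] * s[2L] - r[2L] * s[1L]
  if (abs(denom) < 1e-12) return(NULL)
  qp <- q1 - p1
  t <- (qp[1L] * s[2L] - qp[2L] * s[1L]) / denom
  u <- (qp[1L] * r[2L] - qp[2L] * r[1L]) / denom
  if (t < -1e-9 || t > 1 + 1e-9 || u < -1e-9 || u > 1 + 1e-9) return(NULL)
  c(t = min(max(t, 0), 1), u = min(max(u, 0), 1))
}

split_polyline_at <- function(p, th, arcs, tol = 0.75) {
  s <- cumulative_arclength(p)
  L <- s[length(s)]
  arcs <- sort(unique(arcs[arcs > tol & arcs < L - tol]))
  if (length(arcs) > 1L) arcs <- arcs[c(TRUE, diff(arcs) > tol)]
  cuts <- c(0, arcs, L)
  pieces <- list()
  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]; b <- cuts[i + 1L]
    sel <- which(s > a + 1e-9 & s < b - 1e-9)
    interp <- function(at) {
      j <- findInterval(at, s, rightmost.closed = TRUE)
      j <- min(max(j, 1L), nrow(p) - 1L)
      w <- (at - s[j]) / max(s[j + 1L] - s[j], 1e-12)
      list(pt = p[j, ] * (1 - w) + p[j + 1L, ] * w,
           th = if (!is.null(th)) th[j] * (1 - w) + th[j + 1L] * w)
    }
    ia <- interp(a); ib <- interp(b)
    pts <- rbind(ia$pt, p[sel, , drop = FALSE], ib$pt)
    ths <- if (!is.null(th)) c(ia$th, th[sel], ib$th)
    keep <- c(TRUE, sqrt(rowSums((pts[-1L, , drop = FALSE] -
                                    pts[-nrow(pts), , drop = FALSE])^2)) > 1e-9)
    pts <- pts[keep, , drop = FALSE]
    if (!is.null(ths)) ths <- ths[keep]
    if (nrow(pts) >= 2L) pieces <- c(pieces, list(list(points = pts, thickness = ths)))
  }
  pieces
}

#' Build the smallest-unit 2D vessel graph
#'
#' Splits a set of 2D centerline polylines at mutual crossings and shared
#' junctions so that every edge is a maximal branch-free segment, the atom
#' of the 2D topology reconstruction. Endpoints closer than `tol` are
#' merged into one vertex, which is where branch and crossing nodes (degree
#' three and higher) arise. Input polylines already split at junctions
#' (e.g. from the simulator or from [mask_to_centerlines()]) pass through
#' with their provenance labels intact.
#'
#' @param x a 2D `vessel_tree`, a list of `centerline2d`, or a single
#'   `centerline2d`.
#' @param tol vertex merge tolerance, mm (default 0.75).
#' @return a 2D `vessel_tree` of smallest-unit segments.
#' @export
build_2d_graph <- function(x, tol = 0.75) {
  polys <- if (inherits(x, "vessel_tree")) {
    lapply(names(x$edges), function(eid) {
      e <- x$edges[[eid]]
      list(points = e$centerline$points, thickness = e$centerline$thickness,
           source3d = e$source3d %||% NA_character_,
           is_true = e$is_true %||% TRUE)
    })
  } else if (inherits(x, "centerline2d")) {
    list(list(points = x$points, thickness = x$thickness,
              source3d = NA_character_, is_true = TRUE))
  } else {
    lapply(x, function(cl) list(points = cl$points, thickness = cl$thickness,
                                source3d = NA_character_, is_true = TRUE))
  }
  if (!length(polys)) stop("no 2D centerlines supplied")
  # find pairwise crossings between polylines (vectorized over segment pairs
  # would be overkill; polyline counts are small)
  cut_arcs <- vector("list", length(polys))
  for (i in seq_along(polys)) cut_arcs[[i]] <- numeric()
  for (i in seq_along(polys)) {
    pi_ <- polys[[i]]$points
    si <- cumulative_arclength(pi_)
    for (j in seq_along(polys)) {
      if (j <= i) next
      pj <- polys[[j]]$points
      sj <- cumulative_arclength(pj)
      # bounding-box prefilter
      if (max(pi_[, 1L]) < min(pj[, 1L]) - 1 || max(pj[, 1L]) < min(pi_[, 1L]) - 1 ||
          max(pi_[, 2L]) < min(pj[, 2L]) - 1 || max(pj[, 2L]) < min(pi_[, 2L]) - 1)
        next
      for (a in seq_len(nrow(pi_) - 1L)) {
        for (b in seq_len(nrow(pj) - 1L)) {
          hit <- seg_intersect(pi_[a, ], pi_[a + 1L, ], pj[b, ], pj[b + 1L, ])
          if (!is.null(hit)) {
            cut_arcs[[i]] <- c(cut_arcs[[i]],
                               si[a] + hit[["t"]] * (si[a + 1L] - si[a]))
            cut_arcs[[j]] <- c(cut_arcs[[j]],
                               sj[b] + hit[["u"]] * (sj[b + 1L] - sj[b]))
          }
        }
      }
    }
  }
  vertices <- list()
  edges <- list()
  vkey <- list() # vertex id -> coord for merge search
  get_vid <- function(pt) {
    for (vid in names(vertices)) {
      if (sqrt(sum((vertices[[vid]] - pt)^2)) <= tol) return(vid)
    }
    vid <- paste0("u", length(vertices) + 1L)
    vertices[[vid]] <<- pt
    vid
  }
  for (i in seq_along(polys)) {
    pieces <- split_polyline_at(polys[[i]]$points, polys[[i]]$thickness,
                                cut_arcs[[i]])
    for (pc in pieces) {
      a <- get_vid(pc$points[1L, ])
      b <- get_vid(pc$points[nrow(pc$points), ])
      # snap endpoints to the merged vertex coordinates
      pts <- pc$points
      pts[1L, ] <- vertices[[a]]
      pts[nrow(pts), ] <- vertices[[b]]
      keep <- c(TRUE, sqrt(rowSums((pts[-1L, , drop = FALSE] -
                                      pts[-nrow(pts), , drop = FALSE])^2)) > 1e-9)
      pts <- pts[keep, , drop = FALSE]
      if (nrow(pts) < 2L) next
      th <- pc$thickness
      if (!is.null(th)) th <- th[keep]
      edges[[paste0("q", length(edges) + 1L)]] <-
        list(from = a, to = b, centerline = centerline2d(pts, th),
             source3d = polys[[i]]$source3d, is_true = polys[[i]]$is_true)
    }
  }
  vessel_tree(vertices, edges, root = NA_character_, validate = FALSE)
}

# ---- candidate segments ------------------------------------------------------

#' Candidate 2D segments for each projected 3D edge
#'
#' After rigid alignment the true 2D counterpart of every 3D segment lies
#' within a bounded distance of its projection. For each projected 3D edge,
#' every 2D smallest-unit edge whose mean nearest-point distance to the
#' projected edge is below `D_cand` becomes a candidate, sorted by that
#' distance.
#'
#' @param tree3d_projected projected (and rigidly aligned) 2D `vessel_tree`
#'   from [project_tree()].
#' @param graph2d smallest-unit 2D `vessel_tree`.
#' @param D_cand distance threshold, mm (default 3).
#' @return named list (one entry per 3D edge id) of data frames with
#'   columns `edge2d` and `dist`, sorted ascending.
#' @export
candidate_segments <- function(tree3d_projected, graph2d, D_cand = 3) {
  cands <- list()
  e2_pts <- lapply(graph2d$edges, function(e)
    resample_centerline(e$centerline, 0.5)$points)
  for (eid in names(tree3d_projected$edges)) {
    p3 <- tree3d_projected$edges[[eid]]$centerline$points
    ids <- character()
    ds <- numeric()
    for (fid in names(graph2d$edges)) {
      d <- mean(nn_distances(e2_pts[[fid]], p3))
      if (d < D_cand) {
        ids <- c(ids, fid)
        ds <- c(ds, d)
      }
    }
    o <- order(ds)
    cands[[eid]] <- data.frame(edge2d = ids[o], dist = ds[o],
                               stringsAsFactors = FALSE)
  }
  cands
}

# ---- candi-line enumeration --------------------------------------------------

# endpoints of a 2D edge
edge_ends <- function(graph2d, fid) {
  p <- graph2d$edges[[fid]]$centerline$points
  list(a = p[1L, ], b = p[nrow(p), ])
}

# adjacency among a set of candidate edges: edges are connectable when any
# pair of their endpoints is within conn_tol
candidate_adjacency <- function(graph2d, ids, conn_tol) {
  ends <- lapply(ids, function(f) edge_ends(graph2d, f))
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dmin <- min(sqrt(sum((ends[[i]]$a - ends[[j]]$a)^2)),
                  sqrt(sum((ends[[i]]$a - ends[[j]]$b)^2)),
                  sqrt(sum((ends[[i]]$b - ends[[j]]$a)^2)),
                  sqrt(sum((ends[[i]]$b - ends[[j]]$b)^2)))
      adj[i, j] <- adj[j, i] <- dmin <= conn_tol
    }
  }
  dimnames(adj) <- list(ids, ids)
  adj
}

#' Enumerate all connectable candi-lines
#'
#' Exhaustive enumeration of every simple chain that can be formed from
#' one 3D edge's candidate set: an ordered sequence of distinct candidate
#' edges in which each appended edge touches the chain's current free
#' endpoint within `conn_tol` and exposes its other end for further
#' growth. Each distinct segment set (a candi-line, the connected
#' structure hypothesized for the 3D segment) is reported once, in
#' deterministic order.
#'
#' @param cand_ids character vector of candidate 2D edge ids for one 3D
#'   edge (e.g. one entry of [candidate_segments()]).
#' @param graph2d the smallest-unit 2D `vessel_tree`.
#' @param max_paths error out when more chains than this would be produced.
#' @param conn_tol endpoint connection tolerance, mm.
#' @return list of candi-lines; each is a list with `edges` (ordered ids),
#'   `points` (concatenated ordered points) and `thickness`.
#' @export
enumerate_candilines <- function(cand_ids, graph2d, max_paths = 10000L,
                                 conn_tol = 3.5) {
  ids <- sort(unique(as.character(cand_ids)))
  if (!length(ids)) return(list())
  r <- length(ids)
  if (r > 30L)
    stop("candi-line enumeration over ", r, " candidate segments would ",
         "exceed max_paths = ", max_paths, "; tighten the candidate threshold")
  ends <- lapply(ids, function(f) edge_ends(graph2d, f))
  near <- function(a, b) sqrt(sum((a - b)^2)) <= conn_tol
  # a candi-line is a connected chain identified by its segment set. The
  # chain grows only at its free end: appending a segment consumes the
  # current free endpoint and exposes the new segment's other end. States
  # (segment set, last segment, free end) are enumerated breadth-first, so
  # work is bounded by the number of distinct sets, not by orderings
  # within endpoint clusters.
  chain_of <- list() # set key -> first ordering found (deterministic)
  states <- new.env(hash = TRUE)
  frontier <- list()
  for (i in seq_len(r)) {
    mask <- bitwShiftL(1L, i - 1L)
    chain_of[[as.character(mask)]] <- i
    for (fe in 1:2) { # free end: 1 = first point, 2 = last point
      key <- paste0(mask, "|", i, "|", fe)
      states[[key]] <- TRUE
      frontier <- c(frontier, list(list(mask = mask, last = i, free = fe,
                                        chain = i)))
    }
  }
  while (length(frontier)) {
    nxt_frontier <- list()
    for (st in frontier) {
      fp <- if (st$free == 1L) ends[[st$last]]$a else ends[[st$last]]$b
      for (j in seq_len(r)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(st$mask, bit) != 0L) next
        hit_a <- near(fp, ends[[j]]$a)
        hit_b <- near(fp, ends[[j]]$b)
        if (!hit_a && !hit_b) next
        # the new free end is the far end of the appended segment; when
        # both ends touch (tiny segment) both orientations are explored
        for (new_free in c(if (hit_a) 2L, if (hit_b) 1L)) {
          mask2 <- bitwOr(st$mask, bit)
          key <- paste0(mask2, "|", j, "|", new_free)
          if (!is.null(states[[key]])) next
          states[[key]] <- TRUE
          ch <- c(st$chain, j)
          sk <- as.character(mask2)
          if (is.null(chain_of[[sk]])) {
            if (length(chain_of) >= max_paths)
              stop("candi-line enumeration exceeded max_paths = ", max_paths,
                   "; tighten the candidate threshold")
            chain_of[[sk]] <- ch
          }
          nxt_frontier <- c(nxt_frontier, list(list(mask = mask2, last = j,
                                                    free = new_free,
                                                    chain = ch)))
        }
      }
    }
    frontier <- nxt_frontier
  }
  chains <- lapply(chain_of, function(ix) ids[ix])
  chains <- chains[order(vapply(chains, function(ch)
    paste(sort(ch), collapse = "|"), ""))]
  lapply(unname(chains), function(ch) build_candiline(ch, graph2d))
}

# orient and concatenate the member edges of a chain into one polyline
build_candiline <- function(edge_ids, graph2d, conn_tol = Inf) {
  pts_list <- lapply(edge_ids, function(f) {
    e <- graph2d$edges[[f]]
    list(p = e$centerline$points, th = e$centerline$thickness)
  })
  n <- length(edge_ids)
  oriented <- vector("list", n)
  if (n == 1L) {
    oriented[[1L]] <- pts_list[[1L]]
  } else {
    for (i in seq_len(n)) {
      p <- pts_list[[i]]$p
      ref <- if (i < n) pts_list[[i + 1L]]$p else NULL
      prev_end <- if (i > 1L) {
        op <- oriented[[i - 1L]]$p
        op[nrow(op), ]
      } else NULL
      flip <- FALSE
      if (!is.null(prev_end)) {
        flip <- sqrt(sum((p[nrow(p), ] - prev_end)^2)) <
          sqrt(sum((p[1L, ] - prev_end)^2))
      } else if (!is.null(ref)) {
        # first edge: far end should be away from the next edge
        d_first <- min(sqrt(sum((p[1L, ] - ref[1L, ])^2)),
                       sqrt(sum((p[1L, ] - ref[nrow(ref), ])^2)))
        d_last <- min(sqrt(sum((p[nrow(p), ] - ref[1L, ])^2)),
                      sqrt(sum((p[nrow(p), ] - ref[nrow(ref), ])^2)))
        flip <- d_first < d_last
      }
      if (flip) {
        p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
        th <- pts_list[[i]]$th
        oriented[[i]] <- list(p = p, th = if (!is.null(th)) rev(th))
      } else {
        oriented[[i]] <- pts_list[[i]]
      }
    }
  }
  pts <- do.call(rbind, lapply(oriented, `[[`, "p"))
  ths <- lapply(oriented, `[[`, "th")
  th <- if (!any(vapply(ths, is.null, TRUE))) unlist(ths)
  keep <- c(TRUE, sqrt(rowSums((pts[-1L, , drop = FALSE] -
                                  pts[-nrow(pts), , drop = FALSE])^2)) > 1e-9)
  list(edges = edge_ids, points = pts[keep, , drop = FALSE],
       thickness = if (!is.null(th)) th[keep])
}

# Enumerate candi-lines for one 3D edge with adaptive threshold back-off:
# when the candidate set is so dense that enumeration would overflow
# max_paths (typically inside projected crossing clusters), the candidate
# distance threshold is tightened by 25% and the enumeration retried; the
# true segments, being the nearest, survive the tightening. As a last
# resort the nearest candidates are used as single-segment candi-lines.
enumerate_with_backoff <- function(cand_df, graph2d, max_paths = 10000L,
                                   conn_tol = 3.5, max_retries = 6L,
                                   budget = 400L) {
  df <- cand_df
  budget <- min(budget, max_paths)
  for (k in seq_len(max_retries)) {
    out <- tryCatch(
      enumerate_candilines(df$edge2d, graph2d, budget, conn_tol),
      error = function(e) NULL)
    if (!is.null(out)) return(out)
    keep <- df$dist < max(df$dist) * 0.75
    if (!any(keep)) break
    df <- df[keep, , drop = FALSE]
  }
  lapply(utils::head(df$edge2d, 10L), function(f)
    build_candiline(f, graph2d))
}

# ---- pruning by parent-child connectivity ------------------------------------

#' Prune candi-lines against the 3D parent-child structure
#'
#' The 3D tree is seamlessly connected, so a 2D candi-line hypothesized
#' for a child 3D edge must touch some surviving candi-line of its parent
#' edge. Root-edge candi-lines always survive; the tree is then walked
#' outward and every child candi-line whose endpoints come no closer than
#' `conn_tol` to any surviving parent candi-line is removed. The operation
#' is idempotent.
#'
#' @param candilines named list (3D edge id -> list of candi-lines as from
#'   [enumerate_candilines()]).
#' @param tree3d the rooted 3D `vessel_tree`.
#' @param conn_tol connection tolerance, mm.
#' @return the filtered candi-line list (same structure).
#' @export
prune_by_parent_connectivity <- function(candilines, tree3d,
                                         conn_tol = 3.5) {
  rel <- tree_edge_relations(tree3d)
  ord <- names(sort(rel$depth[names(candilines)]))
  out <- candilines
  for (eid in ord) {
    par <- rel$parent[[eid]]
    if (is.na(par) || is.null(out[[par]])) next # root edges always survive
    par_lines <- out[[par]]
    if (!length(par_lines)) { out[[eid]] <- list(); next }
    par_pts <- do.call(rbind, lapply(par_lines, `[[`, "points"))
    keep <- vapply(out[[eid]], function(cl) {
      ends <- rbind(cl$points[1L, ], cl$points[nrow(cl$points), ])
      min(nn_distances(ends, par_pts)) <= conn_tol
    }, TRUE)
    out[[eid]] <- out[[eid]][keep]
  }
  out
}
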
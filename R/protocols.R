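# ---- seeded validation protocols --------------------------------------------

# geodesic angle (deg) between two Euler-parameterized rotations
rotation_error_deg <- function(R_a, R_b) {
  M <- euler_zyx(R_a) %*% t(euler_zyx(R_b))
  acos(min(max((sum(diag(M)) - 1) / 2, -1), 1)) * 180 / pi
}

#' Rigid parameter-recovery protocol
#'
#' Generates clean cases (no nonrigid field, no 2D corruption) with rigid
#' offsets drawn uniformly within 0.8 of the search bounds, registers each
#' from the identity start, and reports the in-plane translation error
#' (the component perpendicular to the beam axis), the depth error along
#' the beam (weakly observable from a single view, reported unbounded),
#' the geodesic rotation error, and the final projected residual.
#'
#' @param n_cases number of seeded cases (default 20).
#' @param seed base seed.
#' @param bounds a `rigid_bounds`.
#' @return data frame with one row per case.
#' @export
protocol_rigid_recovery <- function(n_cases = 20L, seed = 1L,
                                    bounds = rigid_bounds()) {
  sim <- utils::modifyList(default_sim_config(),
                           list(amp_mm = 0, gap_rate = 0,
                                false_branch_rate = 0, rigid_frac = 0.8,
                                d_max = bounds$d_max, th_R = bounds$th_R))
  rows <- lapply(seq_len(n_cases), function(i) {
    case <- make_case(sim, seed = seed + i)
    res <- register_rigid(case$tree3d, case$tree2d, case$geometry, bounds)
    Rm <- carm_rotation(case$geometry)
    terr <- as.numeric(Rm %*% (res$params$T - case$true_rigid$T))
    data.frame(case = i, seed = seed + i,
               inplane_mm = sqrt(sum(terr[1:2]^2)),
               depth_mm = abs(terr[3]),
               rotation_deg = rotation_error_deg(res$params$R,
                                                 case$true_rigid$R),
               final_dist_mm = res$value,
               initial_dist_mm = res$initial_value)
  })
  do.call(rbind, rows)
}

#' Graph-reconstruction robustness protocol
#'
#' Generates corrupted cases at the default gap / false-branch rates,
#' aligns the 3D tree with the ground-truth rigid transform (isolating the
#' reconstruction stages from registration error), runs candidate search,
#' candi-line enumeration, pruning and similarity selection, and scores
#' per 3D edge whether (a) the ground-truth candi-line — built purely from
#' that edge's true 2D segments and containing its longest one — survives
#' the candidate and pruning stages, and (b) the selected candi-line
#' consists purely of that edge's true segments.
#'
#' @param n_cases number of seeded cases (default 40).
#' @param seed base seed.
#' @param config pipeline configuration (thresholds and weights).
#' @return data frame with per-case edge counts `n_edges`, `n_survived`,
#'   `n_selected`.
#' @export
protocol_graph_robustness <- function(n_cases = 40L, seed = 1L,
                                      config = pipeline_config()) {
  weights <- similarity_weights(config$alpha, config$beta, config$gamma,
                                config$delta)
  rows <- lapply(seq_len(n_cases), function(i) {
    case <- make_case(seed = seed + i)
    aligned <- transform_tree(case$tree3d,
                              function(p) rigid_transform(p, case$true_rigid))
    graph2d <- build_2d_graph(case$tree2d)
    proj <- project_tree(aligned, case$geometry)
    cands <- candidate_segments(proj, graph2d, config$D_cand)
    cls <- lapply(cands, function(cd)
      enumerate_with_backoff(cd, graph2d, config$max_paths, config$conn_tol))
    cls <- prune_by_parent_connectivity(cls, case$tree3d, config$conn_tol)
    n_surv <- 0L; n_sel <- 0L
    for (eid in names(proj$edges)) {
      true_segs <- names(graph2d$edges)[vapply(graph2d$edges, function(e)
        isTRUE(e$is_true) && identical(e$source3d, eid), logical(1L))]
      lens <- vapply(true_segs, function(f)
        centerline_length(graph2d$edges[[f]]$centerline), numeric(1L))
      main <- true_segs[which.max(lens)]
      if (any(vapply(cls[[eid]], function(cl)
        all(cl$edges %in% true_segs) && main %in% cl$edges, logical(1L))))
        n_surv <- n_surv + 1L
      if (length(cls[[eid]])) {
        e2 <- proj$edges[[eid]]$centerline
        sel <- select_candiline(e2$points, e2$thickness, cls[[eid]], weights,
                                n = config$n_window,
                                max_dist = config$max_dist)
        if (all(sel$candiline$edges %in% true_segs)) n_sel <- n_sel + 1L
      }
    }
    data.frame(case = i, seed = seed + i, n_edges = length(proj$edges),
               n_survived = n_surv, n_selected = n_sel)
  })
  do.call(rbind, rows)
}

#' Nonrigid recovery protocol
#'
#' Generates corrupted cases carrying a 2 mm smooth displacement field,
#' aligns each with the ground-truth rigid transform, and runs the
#' reconstruction / matching / deformation stages. Reports pre- and
#' post-deformation projected 2D residuals and the marker ADD on the
#' detector plane and in 3D.
#'
#' @param n_cases number of seeded cases (default 20).
#' @param seed base seed.
#' @param config pipeline configuration.
#' @return data frame with one row per case.
#' @export
protocol_nonrigid_recovery <- function(n_cases = 20L, seed = 1L,
                                       config = pipeline_config(run_rigid = FALSE)) {
  config$run_rigid <- FALSE
  rows <- lapply(seq_len(n_cases), function(i) {
    case <- make_case(seed = seed + i)
    res <- run_pipeline(case, config)
    data.frame(case = i, seed = seed + i,
               pre_2d_mm = res$report$pre_2d_mm,
               post_2d_mm = res$report$post_2d_mm,
               ratio = res$report$post_2d_mm / res$report$pre_2d_mm,
               add_2d_mm = res$report$add_2d_mm,
               add_3d_mm = res$report$add_3d_mm)
  })
  do.call(rbind, rows)
}
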
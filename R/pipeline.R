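# ---- configuration -----------------------------------------------------------

#' Default pipeline configuration
#'
#' Every tunable of the registration pipeline with its default: rigid
#' bounds (`d_max` 30 mm, `th_R` 10 deg), candidate threshold `D_cand`
#' 3 mm, candi-line connection tolerance `conn_tol` 3.5 mm (sized to
#' bridge typical segmentation gaps), matching window
#' `n` 3 and cutoff `max_dist` 5 mm, similarity weights (alpha 0.4, beta
#' 0.7, gamma 0.25, delta 0.15), energy weights (mu 0.5, tau 0.4, phi
#' 0.6), and the gradient-descent options. Unknown keys passed to
#' [pipeline_config()] are rejected.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(d_max = 30, th_R = 10, n_starts = 1L, spacing2d = 0.5,
       D_cand = 3, conn_tol = 3.5, max_paths = 10000L,
       n_window = 3L, max_dist = 5,
       alpha = 0.4, beta = 0.7, gamma = 0.25, delta = 0.15,
       mu = 0.5, tau = 0.4, phi = 0.6,
       step = 0.05, max_iter = 500L, tol = 1e-6, rematch_every = 10L,
       run_rigid = TRUE)
}

#' Validated pipeline configuration
#'
#' @param ... overrides of [default_config()] entries; unknown names are
#'   an error.
#' @return the merged configuration list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  base <- default_config()
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  utils::modifyList(base, over)
}

# ---- end-to-end pipeline -----------------------------------------------------

#' Run the full registration pipeline on one simulation case
#'
#' Stages, in order: bounded rigid registration of the undeformed 3D tree
#' to the corrupted 2D centerlines; smallest-unit 2D graph construction;
#' candidate-segment search, candi-line enumeration and parent-child
#' pruning; similarity-based candi-line selection per 3D edge; nonrigid
#' snake-energy deformation; evaluation against the simulation ground
#' truth (marker ADD, 2D/3D centerline errors, pre- vs post-deformation
#' residual).
#'
#' @param case a `simulation_case` from [make_case()].
#' @param config list from [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return list with `rigid` (registration result), `selected` (candi-line
#'   per 3D edge), `scores`, `deformation` (a `deformation_state`),
#'   `report` (named metrics), and `timings` (seconds per stage).
#' @export
run_pipeline <- function(case, config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(case, "simulation_case"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- tic()
  bounds <- rigid_bounds(config$d_max, config$th_R)
  graph2d <- build_2d_graph(case$tree2d)
  rigid <- if (isTRUE(config$run_rigid)) {
    register_rigid(case$tree3d, case$tree2d, case$geometry, bounds,
                   n_starts = config$n_starts, spacing2d = config$spacing2d)
  } else {
    list(params = case$true_rigid,
         value = projection_distance(case$tree3d, tree_points(graph2d),
                                     case$geometry, case$true_rigid),
         initial_value = NA_real_)
  }
  timings["rigid"] <- tic() - t0
  say("rigid: residual %.3f mm", rigid$value)
  aligned <- transform_tree(case$tree3d,
                            function(p) rigid_transform(p, rigid$params))
  t0 <- tic()
  proj_tree <- project_tree(aligned, case$geometry)
  cands <- candidate_segments(proj_tree, graph2d, config$D_cand)
  candilines <- lapply(cands, function(cd)
    enumerate_with_backoff(cd, graph2d, config$max_paths, config$conn_tol))
  candilines <- prune_by_parent_connectivity(candilines, case$tree3d,
                                             config$conn_tol)
  timings["reconstruct"] <- tic() - t0
  t0 <- tic()
  weights <- similarity_weights(config$alpha, config$beta, config$gamma,
                                config$delta)
  selected <- list()
  scores <- list()
  for (eid in names(proj_tree$edges)) {
    cls <- candilines[[eid]]
    if (!length(cls)) next
    e2 <- proj_tree$edges[[eid]]$centerline
    sel <- select_candiline(e2$points, e2$thickness, cls, weights,
                            n = config$n_window, max_dist = config$max_dist)
    selected[[eid]] <- sel$candiline
    scores[[eid]] <- sel$scores
  }
  timings["select"] <- tic() - t0
  say("selection: %d/%d edges matched", length(selected),
      length(proj_tree$edges))
  t0 <- tic()
  ew <- energy_weights(config$mu, config$tau, config$phi)
  defo <- deform(aligned, selected, case$geometry, ew, step = config$step,
                 max_iter = config$max_iter, tol = config$tol,
                 rematch_every = config$rematch_every,
                 max_dist = config$max_dist, n_window = config$n_window)
  timings["nonrigid"] <- tic() - t0
  t0 <- tic()
  gt2d <- do.call(rbind, lapply(case$tree2d_clean$edges, function(e)
    resample_centerline(e$centerline, 0.25)$points))
  pre <- centerline_distance_report(aligned, gt2d, case$geometry,
                                    case$tree3d_true)
  post <- centerline_distance_report(defo$tree, gt2d, case$geometry,
                                     case$tree3d_true)
  mk_rigid <- marker_pairs(marker_positions(aligned, case$markers),
                           case$markers$truth)
  mk_post <- marker_pairs(marker_positions(defo$tree, case$markers),
                          case$markers$truth)
  # ADD on the detector plane (the clinically measurable form) and in 3D
  # (simulation only; absorbs the single-view unobservable depth)
  q2 <- project(case$markers$truth, case$geometry)
  mk2_rigid <- marker_pairs(project(mk_rigid$p, case$geometry), q2)
  mk2_post <- marker_pairs(project(mk_post$p, case$geometry), q2)
  report <- list(
    rigid_residual_mm = rigid$value,
    pre_2d_mm = pre$mean_2d_mm, post_2d_mm = post$mean_2d_mm,
    pre_3d_mm = pre$mean_3d_mm, post_3d_mm = post$mean_3d_mm,
    add_2d_rigid_mm = add_metric(mk2_rigid), add_2d_mm = add_metric(mk2_post),
    add_3d_rigid_mm = add_metric(mk_rigid), add_3d_mm = add_metric(mk_post),
    matched_edges = length(selected), total_edges = length(proj_tree$edges))
  timings["evaluate"] <- tic() - t0
  say("nonrigid: 2D %.3f -> %.3f mm, ADD %.3f mm", pre$mean_2d_mm,
      post$mean_2d_mm, report$add_3d_mm)
  list(rigid = rigid, graph2d = graph2d, candilines = candilines,
       selected = selected, scores = scores, deformation = defo,
       report = report, timings = timings)
}

#' Run a seeded multi-case experiment
#'
#' Generates `n_cases` simulation cases with disjoint seeds, runs the full
#' pipeline on each, and aggregates the per-case reports.
#'
#' @param n_cases number of cases.
#' @param sim_config simulator configuration (see [default_sim_config()]).
#' @param config pipeline configuration.
#' @param seed base seed; case i uses `seed + i`.
#' @param verbose print per-case progress.
#' @return list with `per_case` (data frame, one row per case) and
#'   `summary` (mean and median of every metric).
#' @export
run_experiment <- function(n_cases, sim_config = default_sim_config(),
                           config = pipeline_config(), seed = 1L,
                           verbose = FALSE) {
  stopifnot(n_cases >= 1L)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case <- make_case(sim_config, seed = seed + i)
    res <- run_pipeline(case, config, verbose = FALSE)
    rows[[i]] <- data.frame(case = i, seed = seed + i,
                            as.data.frame(res$report))
    if (verbose)
      message(sprintf("case %d/%d: ADD %.3f mm, 2D %.3f mm", i, n_cases,
                      res$report$add_3d_mm, res$report$post_2d_mm))
  }
  per_case <- do.call(rbind, rows)
  num <- per_case[vapply(per_case, is.numeric, TRUE)]
  summary <- data.frame(metric = names(num),
                        mean = vapply(num, mean, numeric(1L)),
                        median = vapply(num, stats::median, numeric(1L)),
                        row.names = NULL)
  list(per_case = per_case, summary = summary)
}
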
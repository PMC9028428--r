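# Shared fixtures, built in code.

# straight 3D segment from a to b with n points and constant radius
straight3d <- function(a, b, n = 11L, radius = 1.5) {
  t <- seq(0, 1, length.out = n)
  centerline3d(outer(1 - t, a) + outer(t, b), rep(radius, n))
}

straight2d <- function(a, b, n = 11L, thickness = NULL) {
  t <- seq(0, 1, length.out = n)
  centerline2d(outer(1 - t, a) + outer(t, b),
               if (!is.null(thickness)) rep(thickness, n))
}

# quarter circle of radius r in the xy plane, sampled at n points
quarter_circle2d <- function(r = 10, n = 100L) {
  th <- seq(0, pi / 2, length.out = n)
  centerline2d(cbind(r * cos(th), r * sin(th)))
}

# independent brute-force nearest-neighbour mean distance
oracle_nn_mean <- function(A, B) {
  mean(vapply(seq_len(nrow(A)), function(i)
    min(sqrt(colSums((t(B) - A[i, ])^2))), numeric(1L)))
}

oracle_nn_dists <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i)
    min(sqrt(colSums((t(B) - A[i, ])^2))), numeric(1L))
}

# an aligned, clean simulation case (no corruption, no nonrigid field)
clean_case <- function(seed = 5L, rigid = TRUE) {
  make_case(utils::modifyList(default_sim_config(),
                              list(amp_mm = 0, gap_rate = 0,
                                   false_branch_rate = 0,
                                   rigid_enabled = rigid)),
            seed = seed)
}

# ground-truth 2D segments of a smallest-unit graph, per 3D edge id
true_segments_of <- function(graph2d, eid) {
  names(graph2d$edges)[vapply(graph2d$edges, function(e)
    isTRUE(e$is_true) && identical(e$source3d, eid), TRUE)]
}

# does any candi-line consist purely of true segments of `eid` and contain
# its longest true segment?
gt_candiline_present <- function(candilines, graph2d, eid) {
  true_segs <- true_segments_of(graph2d, eid)
  if (!length(true_segs)) return(NA)
  lens <- vapply(true_segs, function(f)
    centerline_length(graph2d$edges[[f]]$centerline), numeric(1L))
  main <- true_segs[which.max(lens)]
  any(vapply(candilines, function(cl)
    all(cl$edges %in% true_segs) && main %in% cl$edges, logical(1L)))
}
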
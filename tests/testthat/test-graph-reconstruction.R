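test_that("build_2d_graph keeps single polylines intact", {
  g <- build_2d_graph(straight2d(c(0, 0), c(20, 0), n = 21L))
  expect_equal(length(g$edges), 1L)
  expect_equal(length(g$vertices), 2L)
})

test_that("build_2d_graph splits an X crossing into four edges", {
  a <- straight2d(c(-10, 0), c(10, 0), n = 21L)
  b <- straight2d(c(0, -10), c(0, 10), n = 21L)
  g <- build_2d_graph(list(a, b), tol = 0.3)
  expect_equal(length(g$edges), 4L)
  # one degree-4 vertex at the crossing
  deg <- table(c(vapply(g$edges, `[[`, "", "from"),
                 vapply(g$edges, `[[`, "", "to")))
  expect_equal(sum(deg == 4), 1L)
  ctr <- g$vertices[[names(deg)[deg == 4]]]
  expect_lt(sqrt(sum(ctr^2)), 0.3)
})

test_that("graph edge count equals the simulator's segment bookkeeping", {
  case <- make_case(seed = 2L)
  g <- build_2d_graph(case$tree2d)
  # corruption operates on vector centerlines, so in the absence of new
  # crossings the smallest-unit count matches the corrupted segment count
  expect_gte(length(g$edges), length(case$tree2d$edges))
  src <- vapply(g$edges, function(e) e$source3d %||% NA_character_, "")
  expect_true(all(stats::na.omit(src) %in% names(case$tree3d$edges)))
})

test_that("candidate thresholds behave as distance semantics demand", {
  case <- clean_case(seed = 3L)
  aligned <- transform_tree(case$tree3d,
                            function(p) rigid_transform(p, case$true_rigid))
  graph2d <- build_2d_graph(case$tree2d)
  proj <- project_tree(aligned, case$geometry)
  cands <- candidate_segments(proj, graph2d, D_cand = 3)
  for (eid in names(proj$edges)) {
    true_segs <- true_segments_of(graph2d, eid)
    expect_true(all(true_segs %in% cands[[eid]]$edge2d))
    expect_true(all(diff(cands[[eid]]$dist) >= 0)) # sorted ascending
  }
  # D_cand = 0: nothing qualifies
  c0 <- candidate_segments(proj, graph2d, D_cand = 0)
  expect_true(all(vapply(c0, nrow, integer(1L)) == 0L))
  # a decoy edge far beyond the threshold never appears
  far <- straight2d(c(400, 400), c(430, 400), n = 11L)
  g2 <- build_2d_graph(c(lapply(graph2d$edges, `[[`, "centerline"),
                         list(far)))
  cf <- candidate_segments(proj, g2, D_cand = 3)
  far_id <- names(g2$edges)[vapply(g2$edges, function(e)
    min(e$centerline$points[, 1]) > 300, TRUE)]
  for (eid in names(cf)) expect_false(far_id %in% cf[[eid]]$edge2d)
})

test_that("enumeration produces every connectable structure exactly once", {
  # three chainable collinear segments a-b-c
  segs <- list(straight2d(c(0, 0), c(10, 0)),
               straight2d(c(10, 0), c(20, 0)),
               straight2d(c(20, 0), c(30, 0)))
  g <- build_2d_graph(segs, tol = 0.3)
  cl <- enumerate_candilines(names(g$edges), g, conn_tol = 0.5)
  expect_equal(length(cl), 6L) # {a},{b},{c},{ab},{bc},{abc}
  sets <- sort(unname(vapply(cl, function(x)
    paste(sort(x$edges), collapse = "+"), "")))
  ids <- names(g$edges)
  expect_equal(sets, sort(c(ids, paste(ids[1], ids[2], sep = "+"),
                            paste(ids[2], ids[3], sep = "+"),
                            paste(ids[1], ids[2], ids[3], sep = "+"))))
  # chains concatenate into a connected polyline
  abc <- cl[[which(vapply(cl, function(x) length(x$edges) == 3L, TRUE))]]
  expect_equal(centerline_length(abc$points), 30, tolerance = 1e-9)
  # no two candidates adjacent: singletons only
  far_segs <- list(straight2d(c(0, 0), c(5, 0)),
                   straight2d(c(20, 0), c(25, 0)))
  gf <- build_2d_graph(far_segs, tol = 0.3)
  expect_equal(length(enumerate_candilines(names(gf$edges), gf,
                                           conn_tol = 0.5)), 2L)
})

test_that("enumeration equals a brute-force subset oracle on small graphs", {
  # random geometric segment soups with <= 8 edges
  set.seed(77)
  for (rep in 1:4) {
    n_seg <- sample(4:8, 1L)
    pts <- matrix(runif(2 * n_seg, 0, 30), ncol = 2)
    segs <- lapply(seq_len(n_seg), function(i)
      straight2d(pts[i, ], pts[i, ] + runif(2, 3, 8), n = 5L))
    g <- build_2d_graph(segs, tol = 0.2)
    ids <- names(g$edges)
    tol <- 6
    cl <- enumerate_candilines(ids, g, conn_tol = tol)
    got <- sort(vapply(cl, function(x) paste(sort(x$edges), collapse = "+"), ""))
    # oracle: all edge subsets reachable by growing a chain at its free
    # endpoint (independent recursive construction)
    ends <- lapply(ids, function(f) {
      p <- g$edges[[f]]$centerline$points
      list(p[1L, ], p[nrow(p), ])
    })
    names(ends) <- ids
    near <- function(a, b) sqrt(sum((a - b)^2)) <= tol
    want <- character()
    grow <- function(chain, freept) {
      want <<- union(want, paste(sort(chain), collapse = "+"))
      for (nxt in setdiff(ids, chain)) {
        if (near(freept, ends[[nxt]][[1]])) grow(c(chain, nxt),
                                                 ends[[nxt]][[2]])
        if (near(freept, ends[[nxt]][[2]])) grow(c(chain, nxt),
                                                 ends[[nxt]][[1]])
      }
    }
    for (s in ids) {
      grow(s, ends[[s]][[1]])
      grow(s, ends[[s]][[2]])
    }
    expect_setequal(got, sort(unique(want)))
  }
})

test_that("pruning keeps connected children, drops orphans, is idempotent", {
  case <- clean_case(seed = 6L)
  aligned <- transform_tree(case$tree3d,
                            function(p) rigid_transform(p, case$true_rigid))
  graph2d <- build_2d_graph(case$tree2d)
  proj <- project_tree(aligned, case$geometry)
  cands <- candidate_segments(proj, graph2d, D_cand = 3)
  cl0 <- lapply(cands, function(cd) enumerate_candilines(cd$edge2d, graph2d))
  cl1 <- prune_by_parent_connectivity(cl0, case$tree3d)
  for (eid in names(proj$edges))
    expect_true(gt_candiline_present(cl1[[eid]], graph2d, eid))
  # idempotent
  cl2 <- prune_by_parent_connectivity(cl1, case$tree3d)
  expect_identical(vapply(cl2, length, integer(1L)),
                   vapply(cl1, length, integer(1L)))
  # an orphan candi-line far from any parent candi-line is removed:
  # fabricate one on a leaf edge
  rel <- cororeg:::tree_edge_relations(case$tree3d)
  leaf <- names(rel$parent)[!names(rel$parent) %in% rel$parent][1L]
  fake <- list(edges = "zz",
               points = matrix(c(300, 300, 320, 300), 2L, byrow = TRUE),
               thickness = NULL)
  cl1b <- cl1
  cl1b[[leaf]] <- c(cl1b[[leaf]], list(fake))
  cl3 <- prune_by_parent_connectivity(cl1b, case$tree3d)
  expect_false(any(vapply(cl3[[leaf]], function(x) "zz" %in% x$edges, TRUE)))
})
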
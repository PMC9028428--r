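test_that("generate_tree is deterministic and structurally valid", {
  t1 <- generate_tree(seed = 9L)
  t2 <- generate_tree(seed = 9L)
  expect_identical(t1, t2)
  expect_equal(length(t1$edges), 7L)
  expect_error(validate_obj <- cororeg:::validate_vessel_tree(t1), NA)
  single <- generate_tree(seed = 1L, n_branches = 1L)
  expect_equal(length(single$edges), 1L)
})

test_that("radius is non-increasing along every root-to-leaf path", {
  tr <- generate_tree(seed = 11L, n_branches = 9L)
  rel <- cororeg:::tree_edge_relations(tr)
  for (eid in names(tr$edges)) {
    # walk this edge's ancestry to the root, concatenating radii leaf-ward
    chain <- eid
    while (!is.na(rel$parent[[chain[1L]]])) chain <- c(rel$parent[[chain[1L]]], chain)
    rad <- unlist(lapply(chain, function(e) tr$edges[[e]]$centerline$radius))
    expect_true(all(diff(rad) <= 1e-9))
  }
})

test_that("apply_deformation honours identity, translation and amplitude", {
  tr <- generate_tree(seed = 3L, n_branches = 3L)
  id <- apply_deformation(tr, rigid_params(), amp_mm = 0)
  expect_equal(tree_points(id$tree), tree_points(tr), tolerance = 1e-12)
  sh <- apply_deformation(tr, rigid_params(T = c(5, 0, 0)), amp_mm = 0)
  expect_equal(tree_points(sh$tree) - tree_points(tr),
               matrix(rep(c(5, 0, 0), each = nrow(tree_points(tr))), ncol = 3),
               tolerance = 1e-12)
  de <- apply_deformation(tr, rigid_params(), amp_mm = 2, seed = 8L)
  disp <- sqrt(rowSums((tree_points(de$tree) - tree_points(tr))^2))
  expect_true(all(disp <= 2 + 1e-9))
  expect_gt(max(disp), 0.5) # the field actually moves the tree
})

test_that("zero corruption reproduces the projected tree exactly", {
  case <- clean_case(seed = 2L)
  g2 <- case$tree2d
  clean_pts <- do.call(rbind, lapply(case$tree2d_clean$edges, function(e)
    resample_centerline(e$centerline, 0.5)$points))
  for (e in g2$edges) {
    expect_true(isTRUE(e$is_true))
    d <- oracle_nn_dists(e$centerline$points, clean_pts)
    expect_lt(max(d), 1e-6)
  }
})

test_that("corruption bookkeeping labels every false point and splits edges", {
  case <- make_case(utils::modifyList(default_sim_config(),
                                      list(gap_rate = 1.2,
                                           false_branch_rate = 1.0)),
                    seed = 6L)
  segs <- case$tree2d$edges
  n_false <- sum(vapply(segs, function(e) !isTRUE(e$is_true), TRUE))
  n_true <- sum(vapply(segs, function(e) isTRUE(e$is_true), TRUE))
  expect_gt(n_false, 0L)
  expect_gte(n_true, length(case$tree3d$edges)) # gaps only ever add segments
  for (e in segs) {
    if (isTRUE(e$is_true)) {
      expect_true(e$source3d %in% names(case$tree3d$edges))
    } else {
      expect_true(is.na(e$source3d))
    }
  }
  # true segments stay on the clean projection (corruption never moves them)
  clean_pts <- do.call(rbind, lapply(case$tree2d_clean$edges, function(e)
    resample_centerline(e$centerline, 0.25)$points))
  for (e in segs) {
    if (!isTRUE(e$is_true)) next
    expect_lt(max(oracle_nn_dists(e$centerline$points, clean_pts)), 0.05)
  }
})

test_that("simulation cases are reproducible and carry 10 markers", {
  c1 <- make_case(seed = 12L)
  c2 <- make_case(seed = 12L)
  f1 <- tempfile(); f2 <- tempfile()
  write_tree_json(c1$tree2d, f1)
  write_tree_json(c2$tree2d, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(c1$true_rigid, c2$true_rigid)
  expect_equal(nrow(c1$markers$truth), 10L)
  expect_equal(length(c1$markers$locations), 10L)
  # markers sit on the deformed truth tree
  expect_equal(marker_positions(c1$tree3d_true, c1$markers), c1$markers$truth)
})

test_that("ground-truth projection consistency holds within a pixel", {
  case <- make_case(seed = 4L)
  # dense resampling of the projected deformed truth, so the check measures
  # perpendicular error rather than sampling pitch
  proj_truth <- do.call(rbind, lapply(case$tree3d_true$edges, function(e) {
    p2 <- project(e$centerline$points, case$geometry)
    resample_centerline(centerline2d(p2), 0.05)$points
  }))
  px <- case$geometry$pixel_spacing_mm
  for (e in case$tree2d$edges) {
    if (!isTRUE(e$is_true)) next
    d <- oracle_nn_dists(e$centerline$points, proj_truth)
    expect_lt(max(d), px) # within one pixel of the projected deformed tree
  }
})

test_that("rasterization draws tubes of the projected thickness", {
  cl <- straight2d(c(-20, 0), c(20, 0), n = 41L, thickness = 3)
  tr <- vessel_tree(list(a = c(-20, 0), b = c(20, 0)),
                    list(s1 = list(from = "a", to = "b", centerline = cl)),
                    root = NA_character_, validate = FALSE)
  g <- carm_geometry()
  mask <- rasterize_tree2d(tr, g)
  expect_equal(dim(mask), c(512L, 512L))
  # the tube is ~3 mm wide: area ~ length * width / pixel area
  area_mm2 <- sum(mask) * g$pixel_spacing_mm^2
  expect_gt(area_mm2, 40 * 3 * 0.8)
  expect_lt(area_mm2, 40 * 3 * 1.6)
})

test_that("case directories serialize completely", {
  case <- make_case(utils::modifyList(default_sim_config(),
                                      list(rasterize = TRUE)), seed = 3L)
  d <- tempfile()
  write_case(case, d)
  expect_true(all(file.exists(file.path(d, c(
    "tree3d.json", "tree3d_true.json", "tree2d.json", "geometry.yaml",
    "rigid.json", "markers.json", "mask.png")))))
  m <- read_mask_png(file.path(d, "mask.png"))
  expect_identical(m, case$mask)
})
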
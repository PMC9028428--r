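test_that("bce_loss matches analytic values and a per-pixel loop", {
  y <- matrix(c(0, 1, 1, 0, 1, 0, 0, 1, 1), 3, 3)
  expect_lt(bce_loss(y, y), 1e-6)
  expect_equal(bce_loss(matrix(0.5, 4, 4), matrix(rbinom(16, 1, 0.5), 4, 4)),
               log(2), tolerance = 1e-12)
  set.seed(21)
  x <- matrix(runif(64), 8, 8)
  yg <- matrix(rbinom(64, 1, 0.4), 8, 8)
  eps <- 1e-7
  oracle <- 0
  for (k in seq_len(64)) {
    xv <- min(max(x[k], eps), 1 - eps)
    oracle <- oracle - (yg[k] * log(xv) + (1 - yg[k]) * log(1 - xv))
  }
  expect_equal(bce_loss(x, yg), oracle / 64, tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shapes")
})

test_that("bce_loss decreases monotonically toward the label map", {
  set.seed(5)
  yg <- matrix(rbinom(36, 1, 0.5), 6, 6)
  x0 <- matrix(runif(36, 0.2, 0.8), 6, 6)
  losses <- vapply(seq(0, 1, by = 0.1), function(a)
    bce_loss(x0 + a * (yg - x0), yg), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("chamfer_distance_map equals exhaustive nearest-pixel search", {
  e <- matrix(0L, 5, 5); e[3, 3] <- 1L
  d <- chamfer_distance_map(e)
  expect_equal(d[1, 1], sqrt(8), tolerance = 1e-9)
  expect_equal(d[3, 3], 0)
  expect_equal(chamfer_distance_map(matrix(1L, 4, 4)),
               matrix(0, 4, 4))
  set.seed(13)
  for (rep in 1:3) {
    e <- matrix(rbinom(32 * 32, 1, 0.05), 32, 32)
    if (!any(e == 1)) e[7, 9] <- 1L
    d <- chamfer_distance_map(e)
    on <- which(e == 1, arr.ind = TRUE)
    brute <- matrix(0, 32, 32)
    for (r in seq_len(32)) for (c in seq_len(32))
      brute[r, c] <- sqrt(min((on[, 1] - r)^2 + (on[, 2] - c)^2))
    expect_lt(max(abs(d - brute)), 1e-9)
  }
  expect_error(chamfer_distance_map(matrix(0L, 4, 4)), "empty")
})

test_that("shape_loss is zero iff edges coincide and scales with offset", {
  strip <- function(cols, n = 16L) {
    m <- matrix(0L, n, n); m[, cols] <- 1L; m
  }
  gt <- strip(5:8)
  expect_lt(shape_loss(gt, gt), 1e-6)
  moved <- strip(8:11)
  # brute-force oracle: sum over prediction-edge pixels of the distance to
  # the nearest ground-truth edge pixel, averaged over all pixels
  xe <- which(mask_edges(moved) == 1, arr.ind = TRUE)
  ge <- which(mask_edges(gt) == 1, arr.ind = TRUE)
  oracle <- sum(vapply(seq_len(nrow(xe)), function(i)
    sqrt(min((ge[, 1] - xe[i, 1])^2 + (ge[, 2] - xe[i, 2])^2)),
    numeric(1))) / 256
  expect_equal(shape_loss(moved, gt), oracle, tolerance = 1e-6)
  expect_gt(shape_loss(moved, gt), 0)
  expect_warning(out <- shape_loss(matrix(0, 16, 16), gt), "no foreground")
  expect_equal(as.numeric(out), 0)
})

test_that("skeleton of a straight tube is a single centred line", {
  m <- matrix(0L, 32, 32)
  m[14:18, 4:28] <- 1L # width-5 horizontal tube
  sk <- skeletonize(m)
  on <- which(sk == 1, arr.ind = TRUE)
  expect_true(all(abs(on[, 1] - 16) <= 1))
  expect_gt(nrow(on), 18)
})

test_that("mask_to_centerlines recovers tube, Y and disjoint topology", {
  g <- carm_geometry(image_size_px = c(64L, 64L))
  tube <- matrix(0L, 64, 64)
  tube[30:34, 6:58] <- 1L
  tr <- mask_to_centerlines(tube, g)
  main <- which.max(vapply(tr$edges, function(e)
    centerline_length(e$centerline), numeric(1)))
  expect_equal(length(tr$edges), 1L)
  th <- tr$edges[[main]]$centerline$thickness
  mid <- th[th > 0]
  expect_true(all(abs(mid - 5 * g$pixel_spacing_mm) <=
                    2.2 * g$pixel_spacing_mm))
  # Y shape: 3 edges around one branch node
  y <- matrix(0L, 64, 64)
  y[32:34, 5:32] <- 1L
  for (k in 0:22) {
    y[32 - k + 0:1, 32 + k] <- 1L
    y[34 + k + 0:1, 32 + k] <- 1L
  }
  ty <- mask_to_centerlines(y, g)
  long_edges <- sum(vapply(ty$edges, function(e)
    centerline_length(e$centerline) > 1.5, logical(1)))
  expect_equal(long_edges, 3L)
  # two disjoint tubes: two components / edges
  two <- matrix(0L, 64, 64)
  two[10:13, 6:58] <- 1L
  two[50:53, 6:58] <- 1L
  t2 <- mask_to_centerlines(two, g)
  expect_equal(length(t2$edges), 2L)
  expect_error(mask_to_centerlines(matrix(0L, 8, 8), g), "empty")
})

test_that("skeleton extraction from a rasterized synthetic tree is faithful", {
  case <- make_case(utils::modifyList(default_sim_config(),
                                      list(gap_rate = 0, false_branch_rate = 0,
                                           amp_mm = 0, rigid_enabled = FALSE,
                                           rasterize = TRUE)), seed = 7L)
  tr <- mask_to_centerlines(case$mask, case$geometry)
  # every extracted centerline point lies close to the projected truth
  proj_pts <- do.call(rbind, lapply(case$tree2d_clean$edges, function(e)
    resample_centerline(e$centerline, 0.25)$points))
  d <- oracle_nn_dists(tree_points(tr), proj_pts)
  expect_lt(stats::median(d), case$geometry$pixel_spacing_mm)
  expect_lt(max(d), 2) # spur tips at junction blobs stay local
})
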
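test_that("centerline constructors enforce their invariants", {
  expect_error(centerline3d(rbind(c(0, 0, 0)), 1), "at least 2")
  expect_error(centerline3d(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1)),
               "distinct")
  expect_error(centerline3d(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, -1)),
               "positive")
  expect_error(centerline3d(rbind(c(0, 0, 0), c(1, 0, 0)), 1), "per point")
  expect_silent(centerline2d(rbind(c(0, 0), c(1, 1))))
})

test_that("centerline_length matches hand values and a loop oracle", {
  expect_equal(centerline_length(straight2d(c(0, 0), c(3, 4), n = 2L)), 5)
  sq <- centerline2d(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(centerline_length(sq), 3)
  set.seed(42)
  p <- matrix(rnorm(150), ncol = 3)
  oracle <- sum(vapply(seq_len(49), function(i)
    sqrt(sum((p[i + 1, ] - p[i, ])^2)), numeric(1)))
  expect_equal(centerline_length(centerline3d(p, rep(1, 50))), oracle)
})

test_that("centerline_length is rigid-invariant", {
  set.seed(7)
  p <- matrix(rnorm(90), ncol = 3)
  cl <- centerline3d(p, rep(1, 30))
  pr <- rigid_params(T = c(5, -3, 11), R = c(21, -34, 57), center = c(1, 2, 3))
  moved <- centerline3d(rigid_transform(p, pr), rep(1, 30))
  expect_equal(centerline_length(moved), centerline_length(cl),
               tolerance = 1e-9)
})

test_that("mean_spacing is length over intervals", {
  cl <- straight2d(c(0, 0), c(10, 0), n = 11L)
  expect_equal(mean_spacing(cl), 1)
  expect_equal(mean_spacing(straight2d(c(0, 0), c(7, 0), n = 2L)), 7)
})

test_that("resample_centerline places points by arc length", {
  cl <- straight3d(c(0, 0, 0), c(10, 0, 0), n = 2L)
  rs <- resample_centerline(cl, 1)
  expect_equal(nrow(rs$points), 11L)
  expect_equal(rs$points[, 1], 0:10)
  # L-shaped polyline of total length 20: dense arc-length table oracle
  L <- centerline2d(rbind(c(0, 0), c(12, 0), c(12, 8)))
  rs <- resample_centerline(L, 2)
  tt <- seq(0, 1, length.out = 10000)
  dense <- rbind(cbind(12 * tt[tt <= 0.6] / 0.6, 0),
                 cbind(12, 8 * (tt[tt > 0.6] - 0.6) / 0.4))
  s_d <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  for (k in seq_len(nrow(rs$points))) {
    target <- (k - 1) * 2
    i <- which.min(abs(s_d - target))
    expect_lt(sqrt(sum((rs$points[k, ] - dense[i, ])^2)), 0.01)
  }
  # spacing > curve length: endpoints only
  short <- straight2d(c(0, 0), c(1, 0), n = 5L)
  rs <- resample_centerline(short, 10)
  expect_equal(nrow(rs$points), 2L)
  expect_equal(rs$points[1, ], c(0, 0))
  expect_equal(rs$points[2, ], c(1, 0))
})

test_that("resampling honours the spacing contract and interpolates radii", {
  qc <- quarter_circle2d(r = 20, n = 200L)
  rs <- resample_centerline(qc, 1.5)
  gaps <- sqrt(rowSums(diff(rs$points)^2))
  expect_true(all(abs(gaps[-length(gaps)] - 1.5) < 0.15))
  expect_lt(abs(centerline_length(rs) - centerline_length(qc)),
            0.01 * centerline_length(qc))
  cl <- centerline3d(rbind(c(0, 0, 0), c(10, 0, 0)), c(2, 1))
  rs <- resample_centerline(cl, 2.5)
  expect_equal(rs$radius, 2 - rs$points[, 1] / 10)
})

test_that("tangent_slope recovers analytic tangents", {
  h <- straight2d(c(0, 0), c(10, 0), n = 21L)
  expect_equal(tangent_slope(h, 10L)$slope, 0, tolerance = 1e-12)
  d45 <- straight2d(c(0, 0), c(10, 10), n = 21L)
  expect_equal(tangent_slope(d45, 10L)$slope, 1, tolerance = 1e-9)
  qc <- quarter_circle2d(r = 10, n = 100L)
  i45 <- which.min(abs(atan2(qc$points[, 2], qc$points[, 1]) - pi / 4))
  ts <- tangent_slope(qc, i45, window = 3L)
  analytic <- -qc$points[i45, 1] / qc$points[i45, 2]
  expect_lt(abs(ts$slope - analytic), 0.05)
  # vertical tangent: finite direction, infinite slope
  v <- straight2d(c(0, 0), c(0, 10), n = 11L)
  ts <- tangent_slope(v, 5L)
  expect_true(is.infinite(ts$slope))
  expect_equal(abs(ts$dir), c(0, 1), tolerance = 1e-12)
  expect_error(tangent_slope(centerline2d(rbind(c(0, 0), c(1e-30, 0))), 1L),
               "identical")
})

test_that("tangent fit is symmetric under curve reversal", {
  qc <- quarter_circle2d(r = 10, n = 50L)
  rev_qc <- centerline2d(qc$points[50:1, ])
  for (i in c(5L, 20L, 40L)) {
    a <- tangent_slope(qc, i, window = 4L)
    b <- tangent_slope(rev_qc, 51L - i, window = 4L)
    expect_equal(abs(sum(a$dir * b$dir)), 1, tolerance = 1e-9)
  }
})

test_that("vessel_tree validates endpoint matching and tree structure", {
  cl <- straight3d(c(0, 0, 0), c(10, 0, 0))
  tr <- vessel_tree(list(v1 = c(0, 0, 0), v2 = c(10, 0, 0)),
                    list(e1 = list(from = "v1", to = "v2", centerline = cl)),
                    root = "v1")
  expect_s3_class(tr, "vessel_tree")
  expect_error(
    vessel_tree(list(v1 = c(0, 0, 0), v2 = c(9, 0, 0)),
                list(e1 = list(from = "v1", to = "v2", centerline = cl)),
                root = "v1"),
    "endpoints")
  expect_error(
    vessel_tree(list(v1 = c(0, 0, 0), v2 = c(10, 0, 0), v3 = c(5, 5, 5)),
                list(e1 = list(from = "v1", to = "v2", centerline = cl)),
                root = "v1"),
    "tree")
})

test_that("tree JSON and VTK round-trips preserve geometry", {
  tr <- generate_tree(seed = 2L, n_branches = 3L)
  f1 <- tempfile(fileext = ".json")
  write_tree_json(tr, f1)
  tr2 <- read_tree_json(f1)
  expect_equal(tree_points(tr2), tree_points(tr), tolerance = 1e-12)
  expect_equal(names(tr2$edges), names(tr$edges))
  f2 <- tempfile(fileext = ".vtk")
  write_tree_vtk(tr, f2)
  tr3 <- read_tree_vtk(f2)
  expect_equal(tree_points(tr3), unname(tree_points(tr)), tolerance = 1e-4)
})
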
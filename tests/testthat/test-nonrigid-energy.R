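test_that("continuity energy measures spacing deviations", {
  p <- cbind(seq(0, 10, by = 1), 0, 0)
  expect_equal(energy_cont(p, 1)$total, 0)
  # stretch one gap to dbar + 1
  p2 <- p
  p2[6:11, 1] <- p2[6:11, 1] + 1
  ec <- energy_cont(p2, 1)
  expect_equal(ec$per_point[6], 1)
  expect_equal(ec$total, 1)
  # loop oracle on random perturbations
  set.seed(19)
  q <- p + matrix(rnorm(33, sd = 0.2), ncol = 3)
  oracle <- sum(vapply(2:11, function(i)
    (1 - sqrt(sum((q[i, ] - q[i - 1, ])^2)))^2, numeric(1)))
  expect_equal(energy_cont(q, 1)$total, oracle, tolerance = 1e-12)
})

test_that("curvature energy vanishes on lines and spikes at corners", {
  p <- cbind(seq(0, 10, by = 1), 2 * seq(0, 10, by = 1), 0)
  expect_equal(energy_curv(p)$total, 0, tolerance = 1e-12)
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  ec <- energy_curv(corner)
  expect_equal(ec$per_point[2], 2) # ||(-1,1,0)||^2
  set.seed(20)
  q <- matrix(rnorm(36), ncol = 3)
  oracle <- sum(vapply(2:11, function(i)
    sum((q[i - 1, ] - 2 * q[i, ] + q[i + 1, ])^2), numeric(1)))
  expect_equal(energy_curv(q)$total, oracle, tolerance = 1e-12)
})

test_that("image energy is squared perpendicular ray distance gated by H", {
  g <- carm_geometry(10, -5)
  p <- rbind(c(5, 2, -4), c(-3, 8, 1))
  u <- project(p, g)
  rays <- cororeg:::backproject_rays(u, g)
  ei <- energy_image(p, rays, H = c(1L, 1L))
  expect_equal(ei$total, 0, tolerance = 1e-12) # points on their own rays
  # move one point 2 mm perpendicular to its ray
  perp <- c(-rays$dir[1, 2], rays$dir[1, 1], 0)
  perp <- perp - sum(perp * rays$dir[1, ]) * rays$dir[1, ]
  perp <- perp / sqrt(sum(perp^2))
  p2 <- p
  p2[1, ] <- p2[1, ] + 2 * perp
  ei2 <- energy_image(p2, rays, H = c(1L, 1L))
  expect_equal(ei2$per_point[1], 4, tolerance = 1e-9)
  expect_equal(energy_image(p2, rays, H = c(0L, 0L))$total, 0)
})

test_that("internal energies admit a uniform straight line as fixed point", {
  p <- cbind(seq(0, 30, by = 1), 0, 0)
  cl <- centerline3d(p, rep(1.5, nrow(p)))
  tr <- vessel_tree(list(v1 = p[1, ], v2 = p[nrow(p), ]),
                    list(e1 = list(from = "v1", to = "v2", centerline = cl)),
                    root = "v1")
  st <- deform(tr, selected = list(), geometry = carm_geometry(),
               weights = energy_weights(0.5, 0.4, 0), max_iter = 50L)
  expect_equal(tree_points(st$tree), p, tolerance = 1e-9)
  expect_equal(st$trace$total[nrow(st$trace)], 0, tolerance = 1e-12)
})

test_that("gradient descent matches a numerical gradient", {
  set.seed(33)
  p <- cbind(seq(0, 10, by = 1), rnorm(11, sd = 0.3), rnorm(11, sd = 0.3))
  g <- carm_geometry(5, 5)
  u <- project(sweep(p, 2, c(0.5, -0.3, 0.2), "+"), g)
  rays <- cororeg:::backproject_rays(u, g)
  H <- rep(1L, 11)
  w <- energy_weights(0.5, 0.4, 0.6)
  ana <- cororeg:::branch_energy_gradient(p, 1, rays, H, w)
  fn <- function(x) cororeg:::branch_energy_total(
    matrix(x, ncol = 3), 1, rays, H, w)
  num <- matrix(0, 11, 3)
  h <- 1e-6
  x0 <- as.numeric(p)
  for (k in seq_along(x0)) {
    xp <- x0; xp[k] <- xp[k] + h
    xm <- x0; xm[k] <- xm[k] - h
    num[k] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  expect_equal(ana, num, tolerance = 1e-5)
})

test_that("energy decreases monotonically between correspondence refreshes", {
  case <- make_case(utils::modifyList(default_sim_config(),
                                      list(rigid_enabled = FALSE)), seed = 9L)
  aligned <- case$tree3d
  graph2d <- build_2d_graph(case$tree2d)
  proj <- project_tree(aligned, case$geometry)
  cands <- candidate_segments(proj, graph2d, 3)
  cls <- prune_by_parent_connectivity(
    lapply(cands, function(cd) enumerate_candilines(cd$edge2d, graph2d)),
    case$tree3d)
  selected <- list()
  for (eid in names(proj$edges)) {
    if (!length(cls[[eid]])) next
    e2 <- proj$edges[[eid]]$centerline
    selected[[eid]] <- select_candiline(e2$points, e2$thickness,
                                        cls[[eid]])$candiline
  }
  st <- deform(aligned, selected, case$geometry, step = 1e-4,
               max_iter = 120L, rematch_every = 40L)
  tr <- st$trace
  within <- which(tr$rematched == 0)[-1]
  drops <- tr$total[within] - tr$total[within - 1]
  expect_true(all(drops <= 1e-9))
})

test_that("deformation preserves branch topology and point counts", {
  case <- make_case(utils::modifyList(default_sim_config(),
                                      list(rigid_enabled = FALSE)), seed = 10L)
  res <- run_pipeline(case, pipeline_config(run_rigid = FALSE, max_iter = 150L))
  defo <- res$deformation$tree
  for (eid in names(case$tree3d$edges)) {
    a <- case$tree3d$edges[[eid]]$centerline$points
    b <- defo$edges[[eid]]$centerline$points
    expect_equal(nrow(a), nrow(b))
    # ordering preserved: consecutive direction never reverses
    va <- diff(a); vb <- diff(b)
    expect_true(all(rowSums(va * vb) > 0))
  }
  # shared junctions stay coincident
  for (eid in names(defo$edges)) {
    e <- defo$edges[[eid]]
    expect_equal(e$centerline$points[1, ], defo$vertices[[e$from]],
                 tolerance = 1e-9)
    expect_equal(e$centerline$points[nrow(e$centerline$points), ],
                 defo$vertices[[e$to]], tolerance = 1e-9)
  }
})

test_that("a zero-displacement case converges with tiny residual forces", {
  case <- clean_case(seed = 12L, rigid = FALSE)
  res <- run_pipeline(case, pipeline_config(run_rigid = FALSE))
  tr <- res$deformation$trace
  # residual per-point ray distance (the image-energy floor set by the
  # 0.5 mm sampling pitch of the 2D segments) stays well below a pixel
  n_pts <- nrow(tree_points(res$deformation$tree))
  rms_residual <- sqrt(tr$image[nrow(tr)] / (0.6 * n_pts))
  expect_lt(rms_residual, 0.15)
  expect_lte(tr$image[nrow(tr)], tr$image[1] + 1e-9)
  expect_lt(res$report$post_2d_mm, 0.1)
})
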
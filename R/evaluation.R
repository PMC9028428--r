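# ---- registration / segmentation metrics ------------------------------------

#' Average distance difference (ADD) over marker pairs
#'
#' Mean Euclidean distance between corresponding markers on the registered
#' model and the ground truth.
#'
#' @param markers a `marker_pairs`.
#' @return ADD in mm.
#' @export
add_metric <- function(markers) {
  if (!inherits(markers, "marker_pairs")) stop("need a marker_pairs object")
  mean(sqrt(rowSums((markers$p - markers$q)^2)))
}

#' Point precision / recall / F1 at a metric tolerance
#'
#' A predicted point within `tol_mm` of a ground-truth point counts as a
#' true positive, otherwise a false positive; ground-truth points with no
#' prediction within tolerance are false negatives. With
#' `one_to_one = TRUE` (recommended for bifurcations) matches are assigned
#' greedily nearest-first so one ground-truth point absorbs at most one
#' prediction. Two recall conventions are reported: `recall` =
#' TP/(TP+FP+FN) (the printed convention this toolkit follows for
#' fidelity with its field's reporting) and `recall_standard`, the matched
#' fraction of ground-truth points (TP/(TP+FN) under one-to-one matching).
#'
#' @param pred n x d matrix of predicted points, mm.
#' @param gt m x d matrix of ground-truth points, mm.
#' @param tol_mm matching tolerance (1 mm for centerline points, 3 mm for
#'   bifurcations by convention).
#' @param one_to_one greedy one-to-one assignment instead of any-neighbour
#'   matching.
#' @return list with `precision`, `recall`, `recall_standard`, `f1`, and
#'   `counts` (TP/FP/FN).
#' @export
point_prf <- function(pred, gt, tol_mm = 1, one_to_one = FALSE) {
  stopifnot(tol_mm > 0)
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  if (!nrow(pred) && !nrow(gt))
    return(list(precision = NA_real_, recall = NA_real_,
                recall_standard = NA_real_, f1 = NA_real_,
                counts = c(TP = 0L, FP = 0L, FN = 0L), undefined = TRUE))
  if (!nrow(pred)) {
    cnt <- c(TP = 0L, FP = 0L, FN = nrow(gt))
  } else if (!nrow(gt)) {
    cnt <- c(TP = 0L, FP = nrow(pred), FN = 0L)
  } else if (!one_to_one) {
    dp <- nn_distances(pred, gt)
    dg <- nn_distances(gt, pred)
    TP <- sum(dp <= tol_mm)
    cnt <- c(TP = TP, FP = sum(dp > tol_mm), FN = sum(dg > tol_mm))
    matched_gt <- sum(dg <= tol_mm)
  } else {
    D <- sqrt(pmax(outer(rowSums(pred^2), rowSums(gt^2), "+") -
                     2 * pred %*% t(gt), 0))
    TP <- 0L
    used_p <- rep(FALSE, nrow(pred)); used_g <- rep(FALSE, nrow(gt))
    repeat {
      D_act <- D
      D_act[used_p, ] <- Inf
      D_act[, used_g] <- Inf
      mn <- min(D_act)
      if (!is.finite(mn) || mn > tol_mm) break
      w <- which(D_act == mn, arr.ind = TRUE)[1L, ]
      used_p[w[1L]] <- TRUE
      used_g[w[2L]] <- TRUE
      TP <- TP + 1L
    }
    cnt <- c(TP = TP, FP = sum(!used_p), FN = sum(!used_g))
  }
  TP <- cnt[["TP"]]; FP <- cnt[["FP"]]; FN <- cnt[["FN"]]
  # standard recall is the matched fraction of ground truth; with
  # any-neighbour matching the matched-gt count can differ from TP (several
  # predictions may share one gt point), so it is tracked separately
  if (!exists("matched_gt", inherits = FALSE)) matched_gt <- TP
  n_gt <- if (is.null(dim(gt))) 0L else nrow(gt)
  list(precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       recall = if (TP + FP + FN > 0) TP / (TP + FP + FN) else NA_real_,
       recall_standard = if (n_gt > 0) matched_gt / n_gt else NA_real_,
       f1 = if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_,
       counts = cnt)
}

#' Pixel-wise precision / recall / F1 between binary masks
#'
#' @param pred,gt binary rasters of identical shape.
#' @return list with `precision`, `recall` (TP/(TP+FP+FN) convention),
#'   `recall_standard`, `f1`, and `counts`.
#' @export
pixel_prf <- function(pred, gt) {
  pred <- as.matrix(pred) != 0
  gt <- as.matrix(gt) != 0
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  TP <- sum(pred & gt); FP <- sum(pred & !gt)
  FN <- sum(!pred & gt); TN <- sum(!pred & !gt)
  list(precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       recall = if (TP + FP + FN > 0) TP / (TP + FP + FN) else NA_real_,
       recall_standard = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       f1 = if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_,
       counts = c(TP = TP, FP = FP, TN = TN, FN = FN))
}

#' Centerline distance report for a deformed tree
#'
#' 2D error: mean nearest-point distance of the projected deformed
#' centerline to the ground-truth 2D centerline. 3D error (simulation
#' only, where the index correspondence is exact): mean per-point distance
#' to the ground-truth deformed 3D tree.
#'
#' @param deformed deformed 3D `vessel_tree`.
#' @param gt2d ground-truth 2D `vessel_tree` or point matrix.
#' @param geometry a `carm_geometry`.
#' @param gt3d optional ground-truth 3D `vessel_tree` with identical
#'   topology and sampling.
#' @return list with `mean_2d_mm` and `mean_3d_mm` (NA without 3D truth).
#' @export
centerline_distance_report <- function(deformed, gt2d, geometry,
                                       gt3d = NULL) {
  proj <- project(tree_points(deformed), geometry)
  p2 <- if (is.matrix(gt2d)) gt2d else
    do.call(rbind, lapply(gt2d$edges, function(e)
      resample_centerline(e$centerline, 0.25)$points))
  mean2d <- mean(nn_distances(proj, p2))
  mean3d <- NA_real_
  if (!is.null(gt3d)) {
    a <- tree_points(deformed)
    b <- tree_points(gt3d)
    if (!identical(dim(a), dim(b)))
      stop("3D ground truth has different sampling; index correspondence lost")
    mean3d <- mean(sqrt(rowSums((a - b)^2)))
  }
  list(mean_2d_mm = mean2d, mean_3d_mm = mean3d)
}
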
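# ---- C-arm acquisition geometry ---------------------------------------------

#' C-arm acquisition geometry
#'
#' The five DICOM quantities that define the cone-beam projection of an
#' X-ray angiography acquisition, plus the detector raster size and the
#' isocenter position in patient coordinates.
#'
#' @param primary_angle_deg PositionerPrimaryAngle, degrees (LAO positive,
#'   RAO negative); gantry rotation about the patient y axis.
#' @param secondary_angle_deg PositionerSecondaryAngle, degrees (cranial
#'   positive, caudal negative); rotation about the patient x axis.
#' @param pixel_spacing_mm ImagerPixelSpacing, mm per detector pixel.
#' @param sid_mm DistanceSourceToDetector (SID), mm.
#' @param sod_mm DistanceSourceToPatient (SOD), mm; must satisfy
#'   `sid_mm > sod_mm > 0`.
#' @param image_size_px detector raster size, `c(rows, cols)`.
#' @param iso isocenter in patient coordinates, mm (defaults to the
#'   origin; set it to the 3D centerline centroid before projecting).
#' @return an object of class `carm_geometry`.
#' @examples
#' g <- carm_geometry(-29.3, -18.7)
#' project(rbind(c(0, 0, 0)), g)  # isocenter maps to the detector centre
#' @export
carm_geometry <- function(primary_angle_deg = 0, secondary_angle_deg = 0,
                          pixel_spacing_mm = 0.279, sid_mm = 1000,
                          sod_mm = 750, image_size_px = c(512L, 512L),
                          iso = c(0, 0, 0)) {
  stopifnot(sid_mm > sod_mm, sod_mm > 0, pixel_spacing_mm > 0,
            length(image_size_px) == 2L, length(iso) == 3L)
  structure(list(primary_angle_deg = as.numeric(primary_angle_deg),
                 secondary_angle_deg = as.numeric(secondary_angle_deg),
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 sid_mm = as.numeric(sid_mm), sod_mm = as.numeric(sod_mm),
                 image_size_px = as.integer(image_size_px),
                 iso = as.numeric(iso)),
            class = "carm_geometry")
}

#' @export
print.carm_geometry <- function(x, ...) {
  cat(sprintf(paste0("<carm_geometry> primary %.1f deg, secondary %.1f deg, ",
                     "SID %.0f mm, SOD %.0f mm, %.3f mm/px, %dx%d px\n"),
              x$primary_angle_deg, x$secondary_angle_deg, x$sid_mm, x$sod_mm,
              x$pixel_spacing_mm, x$image_size_px[1L], x$image_size_px[2L]))
  invisible(x)
}

# DICOM keyword -> tag, standard angiography module
.carm_tags <- c(PositionerPrimaryAngle = "(0018,1510)",
                PositionerSecondaryAngle = "(0018,1511)",
                ImagerPixelSpacing = "(0018,1164)",
                DistanceSourceToDetector = "(0018,1110)",
                DistanceSourceToPatient = "(0018,1111)")

#' Build C-arm geometry from DICOM header values
#'
#' Accepts a named list (or the path of a YAML file holding one) keyed
#' either by DICOM keyword (`PositionerPrimaryAngle`, ...) or by tag string
#' (`"(0018,1510)"`, ...). Angles are taken in degrees as stored.
#' `ImagerPixelSpacing` may be a length-2 value (row/col spacing); square
#' pixels are assumed and the first component is used.
#'
#' @param header named list of DICOM values, or a YAML file path whose
#'   top-level `carm:` block (or the file itself) holds the keys
#'   `primary`, `secondary`, `pixel_spacing`, `sid`, `sod`, `size`.
#' @param image_size_px raster size used when the header does not carry one.
#' @param iso isocenter, mm.
#' @return a `carm_geometry`.
#' @export
parse_geometry <- function(header, image_size_px = c(512L, 512L),
                           iso = c(0, 0, 0)) {
  if (is.character(header) && length(header) == 1L) {
    y <- yaml::read_yaml(header)
    if (!is.null(y$carm)) y <- y$carm
    need <- c("primary", "secondary", "pixel_spacing", "sid", "sod")
    miss <- setdiff(need, names(y))
    if (length(miss)) stop("geometry config missing: ", paste(miss, collapse = ", "))
    return(carm_geometry(y$primary, y$secondary, y$pixel_spacing, y$sid, y$sod,
                         if (!is.null(y$size)) y$size else image_size_px, iso))
  }
  stopifnot(is.list(header))
  get_tag <- function(keyword) {
    tag <- .carm_tags[[keyword]]
    val <- header[[keyword]]
    if (is.null(val)) val <- header[[tag]]
    if (is.null(val)) stop("missing DICOM tag ", tag, " (", keyword, ")")
    as.numeric(val)
  }
  ps <- get_tag("ImagerPixelSpacing")[1L]
  sz <- image_size_px
  if (!is.null(header$Rows) && !is.null(header$Columns))
    sz <- c(as.integer(header$Rows), as.integer(header$Columns))
  carm_geometry(get_tag("PositionerPrimaryAngle")[1L],
                get_tag("PositionerSecondaryAngle")[1L],
                ps, get_tag("DistanceSourceToDetector")[1L],
                get_tag("DistanceSourceToPatient")[1L], sz, iso)
}

#' Write a C-arm geometry to a YAML config block
#'
#' @param g a `carm_geometry`.
#' @param path output file.
#' @export
write_geometry_yaml <- function(g, path) {
  yaml::write_yaml(list(carm = list(primary = g$primary_angle_deg,
                                    secondary = g$secondary_angle_deg,
                                    pixel_spacing = g$pixel_spacing_mm,
                                    sid = g$sid_mm, sod = g$sod_mm,
                                    size = as.integer(g$image_size_px))), path)
  invisible(path)
}

# gantry rotation: secondary (about patient x) after primary (about patient y);
# applied to points so the camera frame has +z running source -> detector
carm_rotation <- function(g) {
  a <- g$primary_angle_deg * pi / 180
  b <- g$secondary_angle_deg * pi / 180
  Ry <- matrix(c(cos(a), 0, -sin(a),
                 0, 1, 0,
                 sin(a), 0, cos(a)), 3L, 3L, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(b), sin(b),
                 0, -sin(b), cos(b)), 3L, 3L, byrow = TRUE)
  Rx %*% Ry
}

#' Perspective projection onto the detector plane
#'
#' Rotates patient-space points into the gantry frame (secondary rotation
#' about x composed after the primary rotation about y, both about the
#' isocenter), then maps them by the cone-beam similar-triangles rule
#' `(u, v) = sid / (sod + depth) * (x, y)` where `depth` is the distance of
#' the rotated point from the isocenter plane along the source-detector
#' axis. A point at the isocenter therefore maps to the detector centre
#' `(0, 0)` with magnification `sid / sod`.
#'
#' @param points n x 3 matrix of patient-space points, mm.
#' @param g a `carm_geometry`.
#' @return n x 2 matrix of detector-plane coordinates, mm.
#' @export
project <- function(points, g) {
  points <- as_point_matrix(points, 3L)
  R <- carm_rotation(g)
  pc <- sweep(points, 2L, g$iso) %*% t(R)
  denom <- g$sod_mm + pc[, 3L]
  if (any(denom <= 1e-6))
    stop("point at or behind the X-ray source; projection undefined")
  scale <- g$sid_mm / denom
  cbind(pc[, 1L] * scale, pc[, 2L] * scale)
}

# per-point cone-beam magnification (used to project radii to widths)
projection_magnification <- function(points, g) {
  points <- as_point_matrix(points, 3L)
  pc <- sweep(points, 2L, g$iso) %*% t(carm_rotation(g))
  g$sid_mm / (g$sod_mm + pc[, 3L])
}

#' Project every edge of a 3D vessel tree
#'
#' Projects all centerlines and vertices; each projected edge carries a
#' thickness equal to the local vessel diameter scaled by the per-point
#' cone-beam magnification.
#'
#' @param tr a 3D `vessel_tree`.
#' @param g a `carm_geometry`.
#' @return a 2D `vessel_tree` whose edges keep a `source3d` field naming
#'   the 3D edge they came from.
#' @export
project_tree <- function(tr, g) {
  verts <- lapply(tr$vertices, function(v) as.numeric(project(matrix(v, 1L), g)))
  edges <- lapply(names(tr$edges), function(eid) {
    e <- tr$edges[[eid]]
    p2 <- project(e$centerline$points, g)
    mag <- projection_magnification(e$centerline$points, g)
    list(from = e$from, to = e$to,
         centerline = centerline2d(p2, 2 * e$centerline$radius * mag),
         source3d = eid, is_true = TRUE)
  })
  names(edges) <- names(tr$edges)
  vessel_tree(verts, edges, tr$root, validate = FALSE)
}

#' Back-project a detector point to its source ray
#'
#' Returns the X-ray source position and the unit direction of the ray
#' through the given detector-plane point, in patient coordinates. Every
#' 3D point on the ray projects to `p2`.
#'
#' @param p2 length-2 detector coordinates, mm.
#' @param g a `carm_geometry`.
#' @return list with `origin` (source position, mm) and `dir` (unit vector).
#' @export
backproject_ray <- function(p2, g) {
  stopifnot(length(p2) == 2L, all(is.finite(p2)))
  R <- carm_rotation(g)
  src_cam <- c(0, 0, -g$sod_mm)
  det_cam <- c(p2[1L], p2[2L], g$sid_mm - g$sod_mm)
  d_cam <- det_cam - src_cam
  d_cam <- d_cam / sqrt(sum(d_cam^2))
  Rt <- t(R)
  list(origin = as.numeric(Rt %*% src_cam) + g$iso,
       dir = as.numeric(Rt %*% d_cam))
}

# vectorized version: rays for an n x 2 matrix of detector points
backproject_rays <- function(p2, g) {
  p2 <- as_point_matrix(p2, 2L)
  R <- carm_rotation(g)
  Rt <- t(R)
  src_cam <- c(0, 0, -g$sod_mm)
  d_cam <- cbind(p2[, 1L], p2[, 2L], g$sid_mm) # det - src in camera frame
  d_cam <- d_cam / sqrt(rowSums(d_cam^2))
  list(origin = matrix(as.numeric(Rt %*% src_cam) + g$iso,
                       nrow(p2), 3L, byrow = TRUE),
       dir = d_cam %*% R) # (Rt %*% t(d_cam))' = d_cam %*% R
}

#' Convert detector-plane mm to pixel coordinates
#'
#' The detector centre is at mm `(0, 0)`; pixels are indexed `(row, col)`
#' from 1 with +u rightward (columns) and +v downward (rows).
#'
#' @param p2 n x 2 matrix of detector mm coordinates.
#' @param g a `carm_geometry`.
#' @return n x 2 matrix of fractional `(row, col)` pixel coordinates.
#' @export
mm_to_pixel <- function(p2, g) {
  p2 <- as_point_matrix(p2, 2L)
  rows <- g$image_size_px[1L]; cols <- g$image_size_px[2L]
  cbind(p2[, 2L] / g$pixel_spacing_mm + (rows + 1) / 2,
        p2[, 1L] / g$pixel_spacing_mm + (cols + 1) / 2)
}

#' Convert pixel coordinates to detector-plane mm
#'
#' @param px n x 2 matrix of `(row, col)` pixel coordinates.
#' @param g a `carm_geometry`.
#' @return n x 2 matrix of detector mm coordinates.
#' @export
pixel_to_mm <- function(px, g) {
  px <- as_point_matrix(px, 2L)
  rows <- g$image_size_px[1L]; cols <- g$image_size_px[2L]
  cbind((px[, 2L] - (cols + 1) / 2) * g$pixel_spacing_mm,
        (px[, 1L] - (rows + 1) / 2) * g$pixel_spacing_mm)
}
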
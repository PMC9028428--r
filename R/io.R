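# ---- serialization -----------------------------------------------------------

#' Write a vessel tree to JSON
#'
#' Schema: `{"vertices": {id: [x, y(, z)]}, "edges": [{"from", "to",
#' "points": [[...], ...], "radius"|"thickness": [...]}], "root": id}`.
#'
#' @param tr a `vessel_tree`.
#' @param path output file.
#' @export
write_tree_json <- function(tr, path) {
  edges <- lapply(names(tr$edges), function(eid) {
    e <- tr$edges[[eid]]
    out <- list(id = eid, from = e$from, to = e$to,
                points = unname(apply(e$centerline$points, 1L, as.numeric,
                                      simplify = FALSE)))
    if (!is.null(e$centerline$radius)) out$radius <- e$centerline$radius
    if (!is.null(e$centerline$thickness)) out$thickness <- e$centerline$thickness
    if (!is.null(e$source3d)) out$source3d <- e$source3d
    if (!is.null(e$is_true)) out$is_true <- e$is_true
    out
  })
  obj <- list(vertices = lapply(tr$vertices, as.numeric), edges = edges,
              root = if (is.na(tr$root)) NULL else tr$root)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vessel tree from JSON
#'
#' @param path file written by [write_tree_json()].
#' @return a `vessel_tree`.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  vertices <- lapply(obj$vertices, function(v) as.numeric(unlist(v)))
  edges <- list()
  for (e in obj$edges) {
    p <- do.call(rbind, lapply(e$points, function(x) as.numeric(unlist(x))))
    cl <- if (!is.null(e$radius))
      centerline3d(p, as.numeric(unlist(e$radius)))
    else centerline2d(p, if (!is.null(e$thickness))
      as.numeric(unlist(e$thickness)))
    eid <- e$id %||% paste0("e", length(edges) + 1L)
    edges[[eid]] <- list(from = e$from, to = e$to, centerline = cl,
                         source3d = e$source3d %||% NULL,
                         is_true = e$is_true %||% NULL)
  }
  vessel_tree(vertices, edges, root = obj$root %||% NA_character_,
              validate = FALSE)
}

#' Write a 3D vessel tree as a VTK legacy polyline file
#'
#' ASCII `POLYDATA` with one `LINES` cell per edge and a `radius` point
#' scalar, readable by ParaView and most VTK-based viewers.
#'
#' @param tr a 3D `vessel_tree`.
#' @param path output `.vtk` file.
#' @export
write_tree_vtk <- function(tr, path) {
  stopifnot(tr$dim == 3L)
  pts <- list(); lines <- list(); rads <- list()
  offset <- 0L
  for (e in tr$edges) {
    p <- e$centerline$points
    pts <- c(pts, list(p))
    lines <- c(lines, list(c(nrow(p), seq_len(nrow(p)) - 1L + offset)))
    rads <- c(rads, list(e$centerline$radius))
    offset <- offset + nrow(p)
  }
  allp <- do.call(rbind, pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel centerline tree",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(allp))), con)
  utils::write.table(format(allp, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  total <- sum(vapply(lines, length, integer(1L)))
  writeLines(sprintf("LINES %d %d", length(lines), total), con)
  for (l in lines) writeLines(paste(l, collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(allp)),
               "SCALARS radius float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(unlist(rads), scientific = FALSE), con)
  invisible(path)
}

#' Read a 3D polyline tree from a VTK legacy file
#'
#' Counterpart of [write_tree_vtk()]; each `LINES` cell becomes one edge
#' with vertices created at its endpoints (shared coordinates are merged).
#'
#' @param path `.vtk` file.
#' @param root_vertex id of the root (default the first edge's start).
#' @return a 3D `vessel_tree`.
#' @export
read_tree_vtk <- function(path, root_vertex = NULL) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1L]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
  vals <- numeric(0)
  i <- ip + 1L
  while (length(vals) < 3L * np) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    i <- i + 1L
  }
  pts <- matrix(vals[seq_len(3L * np)], ncol = 3L, byrow = TRUE)
  il <- grep("^LINES", lines)[1L]
  ncell <- as.integer(strsplit(lines[il], "\\s+")[[1L]][2L])
  cells <- lapply(seq_len(ncell), function(k)
    as.integer(strsplit(trimws(lines[il + k]), "\\s+")[[1L]]))
  ir <- grep("^SCALARS radius", lines)
  rad <- rep(1, np)
  if (length(ir)) {
    vals <- numeric(0)
    i <- ir[1L] + 2L
    while (length(vals) < np && i <= length(lines)) {
      vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
      i <- i + 1L
    }
    rad <- vals[seq_len(np)]
  }
  vertices <- list()
  vid_at <- function(coord) {
    for (vid in names(vertices))
      if (max(abs(vertices[[vid]] - coord)) < 1e-6) return(vid)
    vid <- paste0("v", length(vertices) + 1L)
    vertices[[vid]] <<- coord
    vid
  }
  edges <- list()
  for (cell in cells) {
    idx <- cell[-1L] + 1L
    cl <- centerline3d(pts[idx, , drop = FALSE], rad[idx])
    a <- vid_at(pts[idx[1L], ])
    b <- vid_at(pts[idx[length(idx)], ])
    edges[[paste0("e", length(edges) + 1L)]] <-
      list(from = a, to = b, centerline = cl)
  }
  vessel_tree(vertices, edges,
              root = root_vertex %||% edges[[1L]]$from, validate = FALSE)
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask 0/1 matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(as.matrix(mask) != 0), nrow(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path PNG file; any nonzero (first-channel) value is foreground.
#' @return 0/1 integer matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  (img > 0.5) * 1L
}

#' Write a simulation case to a directory
#'
#' Emits `tree3d.json`, `tree3d_true.json`, `tree2d.json`, `geometry.yaml`,
#' `markers.json`, `rigid.json`, and `mask.png` when present.
#'
#' @param case a `simulation_case`.
#' @param dir output directory (created if needed).
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tree_json(case$tree3d, file.path(dir, "tree3d.json"))
  write_tree_json(case$tree3d_true, file.path(dir, "tree3d_true.json"))
  write_tree_json(case$tree2d, file.path(dir, "tree2d.json"))
  write_geometry_yaml(case$geometry, file.path(dir, "geometry.yaml"))
  jsonlite::write_json(list(T = case$true_rigid$T, R = case$true_rigid$R,
                            center = case$true_rigid$center,
                            seed = case$seed),
                       file.path(dir, "rigid.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(locations = case$markers$locations,
                            truth = unname(apply(case$markers$truth, 1L,
                                                 as.numeric,
                                                 simplify = FALSE))),
                       file.path(dir, "markers.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(case$mask)) write_mask_png(case$mask, file.path(dir, "mask.png"))
  invisible(dir)
}
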
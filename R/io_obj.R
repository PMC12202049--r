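# Wavefront OBJ export for triangle meshes (v/vn/f records, 1-based indices).

#' Write a triangle mesh as Wavefront OBJ
#'
#' @param mesh a `trimesh` (vertices, normals, triangles); see
#'   [marching_cubes()]
#' @param path output path
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices; vn <- mesh$normals; f <- mesh$triangles
  if (NROW(v) && !all(is.finite(v)))
    stop("mesh contains non-finite vertices", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# molray triangle mesh", con)
  if (!NROW(v)) return(invisible(path))
  writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  if (!is.null(vn))
    writeLines(sprintf("vn %.6f %.6f %.6f", vn[, 1], vn[, 2], vn[, 3]), con)
  if (NROW(f)) {
    fmt <- if (is.null(vn)) "f %d %d %d" else "f %1$d//%1$d %2$d//%2$d %3$d//%3$d"
    writeLines(sprintf(fmt, f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read vertices/normals/faces back from an OBJ file
#'
#' Minimal reader used for round-trip checks of [write_obj()].
#' @param path OBJ file path
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(prefix, n_fields) {
    sel <- startsWith(lines, prefix)
    if (!any(sel)) return(NULL)
    parts <- strsplit(sub(paste0("^", prefix), "", lines[sel]), "\\s+")
    do.call(rbind, lapply(parts, function(p)
      as.numeric(sub("//.*$", "", p[p != ""][1:n_fields]))))
  }
  list(vertices = grab("v ", 3), normals = grab("vn ", 3),
       triangles = {
         f <- grab("f ", 3)
         if (!is.null(f)) { storage.mode(f) <- "integer"; f } else f
       })
}
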
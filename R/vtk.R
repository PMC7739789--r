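#' Write a tendon mesh as a legacy VTK unstructured grid
#'
#' ASCII legacy VTK format (hexahedron cells). Subtendon labels, fiber
#' directions and any per-element or per-node fields can be attached as
#' cell/point data for inspection in ParaView or similar viewers.
#'
#' @param mesh a [generate_mesh()] mesh.
#' @param file output path.
#' @param cell_data named list of per-element vectors (numeric) or a
#'   per-element direction matrix (E x 3, written as vectors). The mesh's
#'   subtendon labels, if present, are written automatically as integer
#'   codes.
#' @param point_data named list of per-node vectors or N x 3 matrices.
#' @return the path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, file, cell_data = list(),
                           point_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  N <- nrow(mesh$nodes); E <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "tendon mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", N)), con)
  write(t(mesh$nodes), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", E, E * 9), con)
  write(t(cbind(8L, mesh$elems - 1L)), con, ncolumns = 9)
  writeLines(sprintf("CELL_TYPES %d", E), con)
  write(rep(12L, E), con, ncolumns = 1)

  if (!is.null(mesh$element_labels))
    cell_data$subtendon <- as.integer(factor(mesh$element_labels))
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", E), con)
    for (nm in names(cell_data)) write_vtk_field(con, nm, cell_data[[nm]])
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", N), con)
    for (nm in names(point_data)) write_vtk_field(con, nm, point_data[[nm]])
  }
  invisible(file)
}

write_vtk_field <- function(con, name, v) {
  if (is.matrix(v) && ncol(v) == 3) {
    writeLines(sprintf("VECTORS %s double", name), con)
    write(t(v), con, ncolumns = 3)
  } else {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    write(as.numeric(v), con, ncolumns = 1)
  }
}
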
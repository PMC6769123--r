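#' Write a mesh (with optional fields) as an ASCII VTU file
#'
#' Minimal VTK XML unstructured-grid writer for visualisation of meshes and
#' solution snapshots (hexahedra, VTK cell type 12).
#'
#' @param mesh a \code{cem_mesh}.
#' @param file output path (conventionally \code{.vtu}).
#' @param point_data named list of per-node fields (vectors of length n or
#'   n x 3 matrices).
#' @param cell_data named list of per-element fields.
#' @return the file path, invisibly.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 10, trim = TRUE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('<Points>')
  w('<DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(t(mesh$nodes)))
  w('</DataArray>')
  w('</Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(num(t(mesh$elems) - 1L))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(num(seq_len(m) * 8L))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(num(rep(12L, m)))
  w('</DataArray>')
  w('</Cells>')
  emit <- function(fields, nexp) {
    for (nm in names(fields)) {
      v <- fields[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, nc))
      w(num(if (is.matrix(v)) t(v) else v))
      w('</DataArray>')
    }
  }
  w('<PointData>')
  emit(point_data, n)
  w('</PointData>')
  w('<CellData>')
  emit(cell_data, m)
  w('</CellData>')
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Write a run manifest
#'
#' JSON record of the configuration, parameters and package version used in
#' a simulation run, for reproducibility of output directories.
#'
#' @param file output path.
#' @param ... named configuration objects to record.
#' @return the file path, invisibly.
#' @export
write_manifest <- function(file, ...) {
  obj <- lapply(list(...), function(x) {
    if (is.function(x)) "<function>" else unclass(x)
  })
  obj$package <- as.character(utils::packageVersion("cardioemx"))
  obj$units <- "mm-ms-kPa-mV"
  jsonlite::write_json(obj, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(file)
}
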
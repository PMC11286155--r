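# Export: VTK unstructured-grid (ASCII .vtu) meshes with cell/point data,
# node-set JSON sidecars, and the CSV surfaces of the pipeline.

#' Write a mesh (with optional fields) as an ASCII VTU file
#'
#' Writes a VTK XML unstructured grid: element region labels as cell data,
#' node-set membership masks as point data, plus any supplied per-element or
#' per-node arrays (e.g. von Mises fields, displacements).
#'
#' @param mesh a `skull_mesh`.
#' @param path output `.vtu` path.
#' @param cell_data named list of numeric per-element vectors.
#' @param point_data named list of per-node vectors, or N x 3 matrices
#'   (written as 3-component vectors, e.g. displacement).
#' @return `path`, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path, cell_data = list(),
                           point_data = list()) {
  nN <- nrow(mesh$nodes); nE <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x, perline = 6L) {
    x <- format(x, digits = 9, scientific = TRUE, trim = TRUE)
    paste(x, collapse = " ")
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nN, nE))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w("          ", num(as.vector(t(mesh$nodes))))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w("          ", paste(as.vector(t(mesh$tets)) - 1L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  w("          ", paste(seq_len(nE) * 4L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w("          ", paste(rep(10L, nE), collapse = " "))
  w('        </DataArray>')
  w('      </Cells>')
  labs <- sort(unique(mesh$label))
  w('      <CellData Scalars="region">')
  w('        <DataArray type="Int32" Name="region" format="ascii">')
  w("          ", paste(match(mesh$label, labs) - 1L, collapse = " "))
  w('        </DataArray>')
  for (nm in names(cell_data)) {
    w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">',
              nm))
    w("          ", num(cell_data[[nm]]))
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('      <PointData>')
  for (nm in names(mesh$node_sets)) {
    mask <- integer(nN); mask[mesh$node_sets[[nm]]] <- 1L
    w(sprintf('        <DataArray type="UInt8" Name="set_%s" format="ascii">',
              nm))
    w("          ", paste(mask, collapse = " "))
    w('        </DataArray>')
  }
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.matrix(v)) {
      w(sprintf(paste0('        <DataArray type="Float64" Name="%s" ',
                       'NumberOfComponents="3" format="ascii">'), nm))
      w("          ", num(as.vector(t(v))))
    } else {
      w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">',
                nm))
      w("          ", num(v))
    }
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('    </Piece>')
  w(sprintf('    <!-- region ids: %s -->',
            paste(sprintf("%d=%s", seq_along(labs) - 1L, labs),
                  collapse = " ")))
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write the node-set JSON sidecar of a mesh
#'
#' @param mesh a `skull_mesh`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_node_sets_json <- function(mesh, path) {
  sets <- lapply(mesh$node_sets, function(x) as.integer(x))
  out <- list(age_months = mesh$params$age_months,
              seed = mesh$params$seed,
              arch_length_mm = mesh$arch_length,
              node_sets = sets,
              landmarks = mesh$landmarks)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = 10)
  invisible(path)
}

#' Export a cohort CSA table as CSV
#'
#' @param cohort a `csa_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Export a growth model as CSV (mean force and 95% band per age)
#'
#' @param gm a [fit_growth()] model.
#' @param path output path.
#' @param ages ages to tabulate.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(gm, path, ages = gm$target_ages) {
  write.csv(predict(gm, age = ages), path, row.names = FALSE)
  invisible(path)
}

#' Export a vector set as CSV
#'
#' @param vectors a [build_vectors()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vectors_csv <- function(vectors, path) {
  df <- as.data.frame(vectors)[c("tag", "side", "station", "n_nodes",
                                 "dx", "dy", "dz", "magnitude_N")]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
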
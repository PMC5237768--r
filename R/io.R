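# Field export: per-day per-element CSV tables (full 17-significant-digit
# precision so a round trip is bit-exact) and XML VTK unstructured-grid
# (.vtu) snapshots with a .pvd series index for visualization.

trace_field_table <- function(mesh, trace) {
  ne <- n_elements(mesh)
  if (nrow(trace$density) != ne) {
    abort(sprintf("trace has %d elements but mesh has %d",
                  nrow(trace$density), ne))
  }
  if (ncol(trace$density) != length(trace$days)) {
    abort("trace density snapshots do not match its day list")
  }
  defect <- trace$defect %||% integer(0)
  cfg_coeff <- 2315; cfg_exp <- 3
  purrr::map(seq_along(trace$days), function(k) {
    t <- trace$days[k]
    rho <- trace$density[, k]
    E1 <- if (!is.null(trace$implant)) {
      remaining_modulus(t, trace$implant)
    } else 0
    rem <- rep(0, ne); rem[defect] <- E1
    osteo <- rep(NA_real_, ne)
    if (length(defect)) {
      osteo[defect] <- pmax(0, cfg_coeff * rho[defect]^cfg_exp - E1)
    }
    tibble(day = t, element_id = seq_len(ne), density = rho,
           remaining_implant_modulus = rem, osteo_score = osteo)
  }) |> dplyr::bind_rows()
}

#' Write simulation fields to disk
#'
#' Emits the per-day per-element density field of a trace as (a) a CSV
#' table with columns `day`, `element_id`, `density`,
#' `remaining_implant_modulus`, `osteo_score`, written at full precision
#' so that reading it back reproduces the densities bit-exactly, and/or
#' (b) a series of XML VTK unstructured-grid `.vtu` snapshots (one per
#' day, with one cell array per field) plus a `.pvd` collection index.
#'
#' @param mesh The [bone_mesh()] the trace was computed on.
#' @param trace A `simulation_trace`.
#' @param path Output directory (created if needed).
#' @param format `"csv"`, `"vtu"`, or `"both"`.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_fields <- function(mesh, trace, path, format = c("csv", "vtu", "both"),
                         prefix = "fields") {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tab <- trace_field_table(mesh, trace)
  written <- character(0)
  if (format %in% c("csv", "both")) {
    csv_path <- file.path(path, paste0(prefix, ".csv"))
    chr <- dplyr::mutate(tab, dplyr::across(
      c(density, remaining_implant_modulus, osteo_score),
      ~ sprintf("%.17g", .x)
    ))
    chr$osteo_score[is.na(tab$osteo_score)] <- NA
    readr::write_csv(chr, csv_path, na = "")
    written <- c(written, csv_path)
  }
  if (format %in% c("vtu", "both")) {
    vtu_paths <- vapply(seq_along(trace$days), function(k) {
      p <- file.path(path, sprintf("%s_day%04d.vtu", prefix, trace$days[k]))
      day_tab <- tab[tab$day == trace$days[k], ]
      write_vtu(mesh, p, list(
        density = day_tab$density,
        remaining_implant_modulus = day_tab$remaining_implant_modulus,
        osteo_score = ifelse(is.na(day_tab$osteo_score), -1,
                             day_tab$osteo_score)
      ))
      p
    }, character(1))
    pvd <- file.path(path, paste0(prefix, ".pvd"))
    lines <- c(
      '<?xml version="1.0"?>',
      '<VTKFile type="Collection" version="0.1" byte_order="LittleEndian">',
      "  <Collection>",
      sprintf('    <DataSet timestep="%g" group="" part="0" file="%s"/>',
              trace$days, basename(vtu_paths)),
      "  </Collection>",
      "</VTKFile>"
    )
    writeLines(lines, pvd)
    written <- c(written, vtu_paths, pvd)
  }
  invisible(written)
}

#' Read a field table written by [write_fields()]
#'
#' @param path Path to the CSV file.
#' @return Tibble with the columns written by [write_fields()].
#' @export
read_fields <- function(path) {
  # base read.csv parses doubles with correctly-rounded strtod, so the
  # 17-significant-digit round trip is bit-exact
  tab <- utils::read.csv(path, colClasses = c(
    day = "numeric", element_id = "integer", density = "numeric",
    remaining_implant_modulus = "numeric", osteo_score = "numeric"
  ))
  as_tibble(tab)
}

# minimal ASCII XML VTK unstructured grid writer (quad cells, cell data)
write_vtu <- function(mesh, path, cell_data = list()) {
  nn <- n_nodes(mesh); ne <- n_elements(mesh)
  conn <- as.matrix(mesh$elements[, c("n1", "n2", "n3", "n4")]) - 1L
  num <- function(x) paste(sprintf("%.9g", x), collapse = " ")
  arrays <- vapply(names(cell_data), function(nm) {
    paste0(
      sprintf('        <DataArray type="Float64" Name="%s" format="ascii">\n', nm),
      "          ", num(cell_data[[nm]]), "\n",
      "        </DataArray>\n"
    )
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    "  <UnstructuredGrid>\n",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">\n', nn, ne),
    "      <Points>\n",
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
    "          ", num(rbind(mesh$nodes$x, mesh$nodes$y, 0)), "\n",
    "        </DataArray>\n",
    "      </Points>\n",
    "      <Cells>\n",
    '        <DataArray type="Int32" Name="connectivity" format="ascii">\n',
    "          ", paste(as.vector(t(conn)), collapse = " "), "\n",
    "        </DataArray>\n",
    '        <DataArray type="Int32" Name="offsets" format="ascii">\n',
    "          ", paste(4L * seq_len(ne), collapse = " "), "\n",
    "        </DataArray>\n",
    '        <DataArray type="UInt8" Name="types" format="ascii">\n',
    "          ", paste(rep(9L, ne), collapse = " "), "\n",
    "        </DataArray>\n",
    "      </Cells>\n",
    "      <CellData>\n",
    paste(arrays, collapse = ""),
    "      </CellData>\n",
    "    </Piece>\n",
    "  </UnstructuredGrid>\n",
    "</VTKFile>\n"
  )
  writeLines(xml, path, sep = "")
  invisible(path)
}
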
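# Reading/writing labeled tetrahedral meshes.
#
# VTU (VTK XML UnstructuredGrid, ASCII): tetrahedra are cell type 10; the
# tissue class is an integer CellData array (name configurable) decoded
# through a class map. Gmsh MSH is supported in the legacy v2.2 ASCII layout
# (elements of type 4 with their first tag as class code) and the v4.1
# block layout (the block entity tag is the class code).

#' Load a tetrahedral tissue mesh from file
#'
#' @param path `.vtu` or `.msh` file (dialect inferred from extension).
#' @param class_field name of the integer cell-data array holding tissue
#'   class codes (VTU only).
#' @param class_map named character vector decoding integer codes to class
#'   labels, e.g. `c("1" = "gray", "2" = "white", "3" = "other")` (default).
#'   Codes absent from the map become `"other"`.
#' @return a [tissue_mesh()].
#' @export
load_mesh <- function(path, class_field = "class_id",
                      class_map = c("1" = "gray", "2" = "white",
                                    "3" = "other")) {
  if (!file.exists(path)) {
    stop_perfterra("file not found: ", path, class = "perfterra_format_error")
  }
  raw <- if (grepl("\\.msh$", path, ignore.case = TRUE)) read_msh(path)
         else read_vtu(path, class_field)
  cls <- class_map[as.character(raw$code)]
  cls[is.na(cls)] <- "other"
  tissue_mesh(raw$nodes, raw$elements, cls)
}

#' Save a tissue mesh as VTU
#'
#' Writes an ASCII VTK XML UnstructuredGrid with the tissue class encoded as
#' an integer cell array, plus an optional extra integer cell array (used
#' e.g. to export territory source ids for visualisation).
#'
#' @param mesh a [tissue_mesh()].
#' @param path output `.vtu` path.
#' @param class_field name for the class code array.
#' @param class_map named character vector, code -> class label; classes not
#'   present get consecutive new codes.
#' @param extra_cell_data optional named list of integer vectors (length =
#'   number of elements) written as additional CellData arrays.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, class_field = "class_id",
                      class_map = c("1" = "gray", "2" = "white",
                                    "3" = "other"),
                      extra_cell_data = NULL) {
  inv <- setNames(as.integer(names(class_map)), class_map)
  missing_cls <- setdiff(unique(mesh$class), names(inv))
  if (length(missing_cls)) {
    inv <- c(inv, setNames(max(c(0L, inv)) + seq_along(missing_cls),
                           missing_cls))
  }
  code <- inv[mesh$class]
  m <- nrow(mesh$elements)
  arrays <- c(list(setNames(list(code), class_field)[[1]]),
              unname(extra_cell_data %||% list()))
  names(arrays) <- c(class_field, names(extra_cell_data))
  cd <- paste(vapply(names(arrays), function(nm) {
    paste0('    <DataArray type="Int32" Name="', nm, '" format="ascii">\n',
           paste(as.integer(arrays[[nm]]), collapse = " "),
           '\n    </DataArray>\n')
  }, character(1)), collapse = "")
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    ' <UnstructuredGrid>\n',
    '  <Piece NumberOfPoints="', nrow(mesh$nodes),
    '" NumberOfCells="', m, '">\n',
    '   <CellData>\n', cd, '   </CellData>\n',
    '   <Points>\n',
    '    <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
    fmt_num(as.vector(t(mesh$nodes))), '\n    </DataArray>\n   </Points>\n',
    '   <Cells>\n',
    '    <DataArray type="Int64" Name="connectivity" format="ascii">\n',
    paste(as.vector(t(mesh$elements)) - 1L, collapse = " "),
    '\n    </DataArray>\n',
    '    <DataArray type="Int64" Name="offsets" format="ascii">\n',
    paste(seq_len(m) * 4L, collapse = " "), '\n    </DataArray>\n',
    '    <DataArray type="UInt8" Name="types" format="ascii">\n',
    paste(rep(10L, m), collapse = " "), '\n    </DataArray>\n   </Cells>\n',
    '  </Piece>\n </UnstructuredGrid>\n</VTKFile>\n')
  writeLines(xml, path)
  invisible(path)
}

read_vtu <- function(path, class_field) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  coords <- vtk_numbers(xml2::xml_find_first(piece, "./Points/DataArray"))
  nodes <- matrix(coords, ncol = 3, byrow = TRUE)
  cells <- xml2::xml_find_all(piece, "./Cells/DataArray")
  cnames <- vapply(cells, function(a) xml2::xml_attr(a, "Name"), character(1))
  conn <- as.integer(vtk_numbers(cells[[which(cnames == "connectivity")]]))
  offs <- as.integer(vtk_numbers(cells[[which(cnames == "offsets")]]))
  types <- as.integer(vtk_numbers(cells[[which(cnames == "types")]]))
  if (any(types != 10L)) {
    stop_perfterra("non-tetrahedral cells present (VTK types: ",
                   paste(unique(types[types != 10L]), collapse = ", "), ")",
                   class = "perfterra_format_error")
  }
  elements <- matrix(conn + 1L, ncol = 4, byrow = TRUE)
  cdata <- xml2::xml_find_all(piece, "./CellData/DataArray")
  dnames <- vapply(cdata, function(a) xml2::xml_attr(a, "Name"), character(1))
  if (!class_field %in% dnames) {
    stop_perfterra("no cell-data array named '", class_field, "'",
                   class = "perfterra_format_error")
  }
  code <- as.integer(vtk_numbers(cdata[[which(dnames == class_field)[1]]]))
  list(nodes = nodes, elements = elements, code = code)
}

read_msh <- function(path) {
  lines <- readLines(path)
  fmt <- lines[which(lines == "$MeshFormat") + 1]
  ver <- as.numeric(strsplit(trimws(fmt), "\\s+")[[1]][1])
  if (ver >= 4) read_msh4(lines) else read_msh2(lines)
}

read_msh2 <- function(lines) {
  i <- which(lines == "$Nodes")
  n <- as.integer(lines[i + 1])
  node_rows <- do.call(rbind, strsplit(trimws(lines[(i + 2):(i + 1 + n)]),
                                       "\\s+"))
  ids <- as.integer(node_rows[, 1])
  nodes <- matrix(0, max(ids), 3)
  nodes[ids, ] <- apply(node_rows[, 2:4, drop = FALSE], 2, as.numeric)
  j <- which(lines == "$Elements")
  m <- as.integer(lines[j + 1])
  el <- strsplit(trimws(lines[(j + 2):(j + 1 + m)]), "\\s+")
  elements <- list(); code <- integer()
  for (e in el) {
    v <- as.integer(e)
    if (v[2] != 4L) next # only tetrahedra
    ntags <- v[3]
    elements[[length(elements) + 1]] <- v[(4 + ntags):(7 + ntags)]
    code <- c(code, if (ntags >= 1) v[4] else 0L)
  }
  if (!length(elements)) {
    stop_perfterra("no tetrahedral elements in MSH file",
                   class = "perfterra_format_error")
  }
  list(nodes = nodes, elements = do.call(rbind, elements), code = code)
}

read_msh4 <- function(lines) {
  i <- which(lines == "$Nodes")
  hdr <- as.integer(strsplit(trimws(lines[i + 1]), "\\s+")[[1]])
  nblocks <- hdr[1]
  maxtag <- hdr[4]
  nodes <- matrix(0, maxtag, 3)
  cur <- i + 2
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(trimws(lines[cur]), "\\s+")[[1]])
    nb <- bh[4]
    if (nb > 0) {
      tags <- as.integer(lines[(cur + 1):(cur + nb)])
      xyz <- do.call(rbind, strsplit(trimws(lines[(cur + nb + 1):(cur + 2 * nb)]),
                                     "\\s+"))
      nodes[tags, ] <- apply(xyz[, 1:3, drop = FALSE], 2, as.numeric)
    }
    cur <- cur + 1 + 2 * nb
  }
  j <- which(lines == "$Elements")
  hdr <- as.integer(strsplit(trimws(lines[j + 1]), "\\s+")[[1]])
  nblocks <- hdr[1]
  cur <- j + 2
  elements <- list(); code <- integer()
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(trimws(lines[cur]), "\\s+")[[1]])
    etype <- bh[3]; nb <- bh[4]
    if (nb > 0 && etype == 4L) { # linear tetrahedra
      rows <- do.call(rbind, strsplit(trimws(lines[(cur + 1):(cur + nb)]),
                                      "\\s+"))
      elements[[length(elements) + 1]] <-
        matrix(as.integer(rows[, 2:5]), ncol = 4)
      code <- c(code, rep(bh[2], nb)) # entity tag as class code
    }
    cur <- cur + 1 + nb
  }
  if (!length(elements)) {
    stop_perfterra("no tetrahedral elements in MSH file",
                   class = "perfterra_format_error")
  }
  list(nodes = nodes, elements = do.call(rbind, elements), code = code)
}
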
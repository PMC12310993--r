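# Reading/writing centerline networks.
#
# Two dialects:
#  * VTP — VTK XML PolyData (ASCII): polylines as line cells, per-point radius
#    in a PointData array ("radius" or "MaximumInscribedSphereRadius"),
#    inlet point ids in a FieldData array "InletPointIds". Interoperable with
#    VMTK-style centerline outputs. Segment labels are not representable and
#    are dropped; use the JSON dialect for full round-trips.
#  * JSON — one document: points [{id, xyz, radius}], segments
#    [{id, point_ids, label}], inlets [point ids].

#' Load a vascular network from file
#'
#' @param path file path (`.vtp` or `.json`; dialect inferred from extension
#'   when `dialect = "auto"`).
#' @param dialect `"auto"`, `"vtp"` or `"json"`.
#' @param radius_field candidate names for the per-point radius array (VTP).
#' @param inlets optional integer vector of inlet point ids, overriding any
#'   inlet metadata in the file. Degree-1 nodes not flagged as inlets are
#'   classified outlets; nodes of degree >= 3 are junctions.
#' @return a validated [vascular_network()].
#' @export
load_network <- function(path, dialect = c("auto", "vtp", "json"),
                         radius_field = c("radius",
                                          "MaximumInscribedSphereRadius"),
                         inlets = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_perfterra("file not found: ", path, class = "perfterra_format_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vtp$", path, ignore.case = TRUE)) "vtp" else "json"
  }
  net <- if (dialect == "vtp") read_vtp_network(path, radius_field)
         else read_json_network(path)
  if (!is.null(inlets)) net$inlets <- as.integer(inlets)
  vascular_network(net$points, net$segments, net$inlets)
}

#' Save a vascular network to file
#'
#' @param net a [vascular_network()].
#' @param path output path.
#' @param dialect `"auto"` (from extension), `"vtp"` or `"json"`.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path, dialect = c("auto", "vtp", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vtp$", path, ignore.case = TRUE)) "vtp" else "json"
  }
  if (dialect == "vtp") write_vtp_network(net, path) else
    write_json_network(net, path)
  invisible(path)
}

read_json_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  pts <- do.call(rbind, lapply(doc$points, function(p) {
    data.frame(id = as.integer(p$id), x = p$xyz[[1]], y = p$xyz[[2]],
               z = p$xyz[[3]], radius = p$radius)
  }))
  segs <- lapply(doc$segments, function(s) {
    list(id = as.integer(s$id), point_ids = as.integer(unlist(s$point_ids)),
         label = if (is.null(s$label)) NA_character_ else s$label,
         is_virtual = isTRUE(s$is_virtual))
  })
  list(points = pts, segments = segs,
       inlets = as.integer(unlist(doc$inlets)))
}

write_json_network <- function(net, path) {
  doc <- list(
    points = lapply(seq_len(nrow(net$points)), function(i) {
      p <- net$points[i, ]
      list(id = p$id, xyz = c(p$x, p$y, p$z), radius = p$radius)
    }),
    segments = lapply(net$segments, function(s) {
      out <- list(id = s$id, point_ids = s$point_ids)
      if (!is.na(s$label)) out$label <- s$label
      if (isTRUE(s$is_virtual)) out$is_virtual <- TRUE
      out
    }),
    inlets = net$inlets)
  # digits = I(17): bit-faithful round-trips of coordinates and radii
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
}

# ---- VTP ----

vtk_numbers <- function(node) {
  as.numeric(strsplit(trimws(xml2::xml_text(node)), "[ \t\r\n]+")[[1]])
}

read_vtp_network <- function(path, radius_field) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  coords <- vtk_numbers(pts_node)
  n <- length(coords) / 3
  pos <- matrix(coords, ncol = 3, byrow = TRUE)
  pdata <- xml2::xml_find_all(piece, "./PointData/DataArray")
  pnames <- vapply(pdata, function(a) xml2::xml_attr(a, "Name"), character(1))
  hit <- which(pnames %in% radius_field)
  if (!length(hit)) {
    stop_perfterra("no radius point-data array (looked for: ",
                   paste(radius_field, collapse = ", "), ")",
                   class = "perfterra_format_error")
  }
  radius <- vtk_numbers(pdata[[hit[1]]])
  lines <- xml2::xml_find_all(piece, "./Lines/DataArray")
  lnames <- vapply(lines, function(a) xml2::xml_attr(a, "Name"), character(1))
  conn <- as.integer(vtk_numbers(lines[[which(lnames == "connectivity")]]))
  offs <- as.integer(vtk_numbers(lines[[which(lnames == "offsets")]]))
  starts <- c(1L, head(offs, -1) + 1L)
  polylines <- Map(function(a, b) conn[a:b] + 1L, starts, offs) # 1-based rows
  # split polylines at interior points used by any other cell
  usage <- tabulate(unlist(polylines), nbins = n)
  segs <- list()
  sid <- 0L
  for (pl in polylines) {
    cut <- which(usage[pl] > 1)
    cut <- sort(unique(c(1L, cut[cut > 1 & cut < length(pl)], length(pl))))
    for (j in seq_len(length(cut) - 1)) {
      sid <- sid + 1L
      segs[[sid]] <- list(id = sid, point_ids = pl[cut[j]:cut[j + 1]],
                          label = NA_character_, is_virtual = FALSE)
    }
  }
  fdata <- xml2::xml_find_all(doc, ".//FieldData/DataArray")
  fnames <- vapply(fdata, function(a) xml2::xml_attr(a, "Name"), character(1))
  inl <- integer()
  if ("InletPointIds" %in% fnames) {
    v <- vtk_numbers(fdata[[which(fnames == "InletPointIds")[1]]])
    inl <- as.integer(v) + 1L # 0-based in file -> 1-based point ids
    inl <- inl[!is.na(inl)]
  }
  pts <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    radius = radius)
  list(points = pts, segments = segs, inlets = inl)
}

fmt_num <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                    scientific = FALSE), collapse = " ")

write_vtp_network <- function(net, path) {
  # VTP point ids are 0-based positional; remap arbitrary ids to row order
  idx <- setNames(seq_len(nrow(net$points)) - 1L, as.character(net$points$id))
  conn <- unlist(lapply(net$segments, function(s) idx[as.character(s$point_ids)]))
  offs <- cumsum(vapply(net$segments, function(s) length(s$point_ids),
                        integer(1)))
  inl <- idx[as.character(net$inlets)] + 1L # saved as new 1-based ids
  xyz <- as.vector(t(as.matrix(net$points[, c("x", "y", "z")])))
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
    ' <PolyData>\n',
    '  <Piece NumberOfPoints="', nrow(net$points),
    '" NumberOfVerts="0" NumberOfLines="', length(net$segments),
    '" NumberOfStrips="0" NumberOfPolys="0">\n',
    '   <PointData Scalars="radius">\n',
    '    <DataArray type="Float64" Name="radius" format="ascii">\n',
    fmt_num(net$points$radius), '\n    </DataArray>\n   </PointData>\n',
    '   <Points>\n',
    '    <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
    fmt_num(xyz), '\n    </DataArray>\n   </Points>\n',
    '   <Lines>\n',
    '    <DataArray type="Int64" Name="connectivity" format="ascii">\n',
    paste(conn, collapse = " "), '\n    </DataArray>\n',
    '    <DataArray type="Int64" Name="offsets" format="ascii">\n',
    paste(offs, collapse = " "), '\n    </DataArray>\n   </Lines>\n',
    '  </Piece>\n',
    '  <FieldData>\n',
    '   <DataArray type="Int64" Name="InletPointIds" NumberOfTuples="',
    length(inl), '" format="ascii">\n',
    paste(inl - 1L, collapse = " "), '\n   </DataArray>\n  </FieldData>\n',
    ' </PolyData>\n</VTKFile>\n')
  writeLines(xml, path)
  invisible(path)
}
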
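#' Labeled tetrahedral tissue meshes
#'
#' A `tissue_mesh` stores the discretised tissue domain: node coordinates in
#' mm, tetrahedral elements as 4-tuples of node indices, and a free-form
#' tissue class per element (e.g. `"gray"`, `"white"`, `"other"`). Element
#' volumes (signed-determinant formula, orientation corrected), centroids and
#' the face-adjacency structure (two elements are adjacent iff they share a
#' triangular face) are computed on construction.
#'
#' @param nodes numeric matrix (n x 3), mm.
#' @param elements integer matrix (m x 4) of 1-based node row indices.
#' @param class character vector of length m of tissue class labels.
#' @return an object of class `tissue_mesh` with fields `nodes`, `elements`,
#'   `class`, `volume_mm3`, `centroid`, and `adjacency` (2-column matrix of
#'   face-adjacent element pairs).
#' @export
tissue_mesh <- function(nodes, elements, class = rep("other", nrow(elements))) {
  nodes <- as.matrix(nodes)
  elements <- matrix(as.integer(as.matrix(elements)), ncol = 4)
  stopifnot(ncol(nodes) == 3, length(class) == nrow(elements))
  v <- signed_tet_volumes(nodes, elements)
  flip <- which(v < 0)
  if (length(flip)) { # fix inverted orientation
    elements[flip, c(3, 4)] <- elements[flip, c(4, 3)]
    v[flip] <- -v[flip]
  }
  degen <- which(v <= 1e-12)
  if (length(degen)) {
    stop_perfterra("degenerate (zero-volume) elements: ",
                   paste(head(degen, 10), collapse = ", "),
                   class = "perfterra_validation_error")
  }
  centroid <- (nodes[elements[, 1], , drop = FALSE] +
               nodes[elements[, 2], , drop = FALSE] +
               nodes[elements[, 3], , drop = FALSE] +
               nodes[elements[, 4], , drop = FALSE]) / 4
  structure(list(nodes = nodes, elements = elements,
                 class = as.character(class),
                 volume_mm3 = v, centroid = centroid,
                 adjacency = face_adjacency(elements)),
            class = "tissue_mesh")
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat("<tissue_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elements),
      " tetrahedra, total volume ", format(sum(x$volume_mm3)), " mm^3; classes: ",
      paste(names(table(x$class)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

signed_tet_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE] - a
  c_ <- nodes[elements[, 3], , drop = FALSE] - a
  d <- nodes[elements[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# Element pairs sharing a triangular face (m x 2, both orders not included).
face_adjacency <- function(elements) {
  m <- nrow(elements)
  if (m < 2) return(matrix(integer(), 0, 2))
  combs <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- matrix(0L, 4 * m, 3)
  owner <- rep(seq_len(m), each = 4)
  for (k in 1:4) {
    a <- elements[, combs[k, 1]]
    b <- elements[, combs[k, 2]]
    c_ <- elements[, combs[k, 3]]
    lo <- pmin(a, b, c_)
    hi <- pmax(a, b, c_)
    faces[seq(k, 4 * m, by = 4), ] <- cbind(lo, a + b + c_ - lo - hi, hi)
  }
  ord <- order(faces[, 1], faces[, 2], faces[, 3])
  f <- faces[ord, , drop = FALSE]
  o <- owner[ord]
  same <- which(rowSums(f[-nrow(f), , drop = FALSE] ==
                        f[-1, , drop = FALSE]) == 3)
  cbind(o[same], o[same + 1])
}

#' Tissue class tables: CBF and density
#'
#' Maps tissue classes to cerebral blood flow demand (mL/min per g of tissue)
#' and fixes the tissue density. The default three-way scheme assigns
#' cerebral/cerebellar gray matter 0.8, white matter 0.2 and all remaining
#' tissue 0.5 mL/min/g, with a constant density of 1.04 g/mL; the `uniform`
#' alternative uses 0.5 mL/min/g everywhere (used to probe the influence of
#' regional CBF variation).
#'
#' @param cbf named numeric vector, class -> CBF (mL/min/g), all >= 0.
#' @param density tissue density, g/mL (> 0).
#' @return an object of class `tissue_class_table`.
#' @export
tissue_class_table <- function(cbf = c(gray = 0.8, white = 0.2, other = 0.5),
                               density = 1.04) {
  stopifnot(all(cbf >= 0), density > 0, !is.null(names(cbf)))
  structure(list(cbf = cbf, density = density), class = "tissue_class_table")
}

#' @rdname tissue_class_table
#' @param scheme `"regional"` (gray 0.8 / white 0.2 / other 0.5) or
#'   `"uniform"` (0.5 everywhere).
#' @export
default_tissue_table <- function(scheme = c("regional", "uniform")) {
  scheme <- match.arg(scheme)
  if (scheme == "uniform") {
    tissue_class_table(c(gray = 0.5, white = 0.5, other = 0.5))
  } else {
    tissue_class_table()
  }
}

# Per-element demand rho * v_mL * CBF (mL/min); the single source of truth
# for every demand summation so grouped and total sums agree.
element_demands <- function(mesh, table) {
  unknown <- setdiff(unique(mesh$class), names(table$cbf))
  if (length(unknown)) {
    stop_perfterra("tissue classes missing from table: ",
                   paste(unknown, collapse = ", "),
                   class = "perfterra_lookup_error")
  }
  table$density * (mesh$volume_mm3 * 1e-3) * table$cbf[mesh$class]
}

#' Total blood-flow demand of a tissue mesh
#'
#' \eqn{Q_{total} = \rho \sum_k v_k \cdot CBF_k} over the selected elements
#' (volumes in mL, CBF in mL/min/g, density in g/mL; result in mL/min).
#'
#' @param mesh a [tissue_mesh()].
#' @param table a [tissue_class_table()].
#' @param elements optional integer vector of element indices (default: all).
#' @return total demand in mL/min.
#' @export
total_demand <- function(mesh, table = default_tissue_table(),
                         elements = NULL) {
  if (nrow(mesh$elements) == 0) return(0)
  d <- element_demands(mesh, table)
  if (is.null(elements)) sum(d) else sum(d[sort(elements)])
}
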
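#' Select arterial source points
#'
#' Source points are the seeds of the perfusion tessellation: every vessel
#' outlet (unconditionally), plus — to model perforating arteries branching
#' straight off larger vessels — every centerline point lying within
#' `d_max` of the nearest tissue element (element location = centroid).
#' Propagation speeds are initialised uniform (c = 1); the tessellation is
#' invariant to a common rescaling of all speeds.
#'
#' @param network a [vascular_network()].
#' @param mesh a [tissue_mesh()] in the same coordinate frame.
#' @param d_max capture distance for perforator sources, mm (default 3).
#' @return data.frame of class `source_points` with columns `id`, `point_id`,
#'   `segment_id`, `kind` (`"outlet"`/`"perforator"`), `x`, `y`, `z`, `speed`.
#' @export
select_sources <- function(network, mesh, d_max = 3.0) {
  if (nrow(mesh$elements) == 0) {
    stop_perfterra("empty tissue mesh", class = "perfterra_validation_error")
  }
  outs <- outlet_nodes(network)
  pts <- network$points
  d <- cross_dist(as.matrix(pts[, c("x", "y", "z")]), mesh$centroid)
  nearest <- apply(d, 1, min)
  is_out <- pts$id %in% outs
  take <- is_out | nearest <= d_max
  if (!any(take)) {
    stop_perfterra("no source points found (nothing to perfuse from)",
                   class = "perfterra_validation_error")
  }
  # owning segment of each taken point (first containing segment)
  seg_of <- rep(NA_integer_, nrow(pts))
  for (s in network$segments) {
    hit <- match(s$point_ids, pts$id)
    seg_of[hit[is.na(seg_of[hit])]] <- s$id
  }
  out <- data.frame(
    id = seq_len(sum(take)),
    point_id = pts$id[take],
    segment_id = seg_of[take],
    kind = ifelse(is_out[take], "outlet", "perforator"),
    x = pts$x[take], y = pts$y[take], z = pts$z[take],
    speed = 1.0)
  class(out) <- c("source_points", class(out))
  out
}

#' Connectivity-constrained weighted Voronoi tessellation
#'
#' Partitions the tissue elements among the source points. Each element is
#' first assigned by the weighted Voronoi rule — to the source minimising
#' Euclidean distance from source position to element centroid divided by the
#' source's propagation speed (ties to the smallest source id). Territories
#' are then made face-connected: each source keeps the connected component of
#' its cell that contains its lowest-cost element, and orphaned elements are
#' regrown onto adjacent territories in increasing Euclidean-cost order. On a
#' convex mesh with uniform speeds every Voronoi cell is face-connected and
#' the result coincides exactly with the pure Euclidean rule; in folded
#' geometry the repair step keeps territories anatomically connected.
#'
#' The assignment depends only on source positions and speeds — never on
#' vessel radii — which is the mechanism behind the model's robustness to
#' segmentation variation in radius.
#'
#' @param mesh a [tissue_mesh()].
#' @param sources a `source_points` data.frame from [select_sources()]
#'   (or any data.frame with `id`, `x`, `y`, `z`, `speed`, `kind`,
#'   `segment_id`, `point_id`).
#' @param connectivity which mesh adjacency defines "connected growth":
#'   `"vertex"` (elements sharing any node; the default — the closest
#'   discrete analogue of continuum connectedness, under which convex-domain
#'   Voronoi cells stay connected) or `"face"` (elements sharing a triangular
#'   face; stricter, and occasionally severs thin slivers of a cell even on
#'   convex meshes).
#' @return object of class `territory_assignment`: list with
#'   `element_source` (per-element source id, `NA` when unreachable),
#'   `sources` (the input table), `connectivity`, and `unassigned` (element
#'   indices).
#' @export
tessellate <- function(mesh, sources, connectivity = c("vertex", "face")) {
  connectivity <- match.arg(connectivity)
  stopifnot(nrow(sources) >= 1, all(sources$speed > 0))
  sources <- sources[order(sources$id), , drop = FALSE]
  m <- nrow(mesh$elements)
  spos <- as.matrix(sources[, c("x", "y", "z")])
  cost <- cross_dist(spos, mesh$centroid) / sources$speed # S x E
  # weighted Voronoi rule; first max = smallest source id on ties
  best_row <- max.col(-t(cost), ties.method = "first")
  assign0 <- sources$id[best_row]
  # connectivity repair on the chosen adjacency graph
  adj <- if (connectivity == "face") mesh$adjacency else
    vertex_adjacency(mesh$elements)
  g <- igraph::make_graph(t(adj), n = m, directed = FALSE)
  assigned <- assign0
  for (si in seq_len(nrow(sources))) {
    cell <- which(assign0 == sources$id[si])
    if (length(cell) < 2) next
    sub <- igraph::induced_subgraph(g, cell)
    comp <- igraph::components(sub)$membership
    if (max(comp) == 1) next
    anchor <- comp[which.min(cost[si, cell])]
    assigned[cell[comp != anchor]] <- NA_integer_
  }
  orphans <- which(is.na(assigned))
  if (length(orphans)) {
    assigned <- regrow_orphans(assigned, orphans, cost, sources, adj, m)
  }
  structure(list(element_source = assigned, sources = sources,
                 connectivity = connectivity,
                 unassigned = which(is.na(assigned))),
            class = "territory_assignment")
}

# Element pairs sharing at least one node (may contain duplicates; harmless
# for connectivity and shortest growth fronts).
vertex_adjacency <- function(elements) {
  m <- nrow(elements)
  if (m < 2) return(matrix(integer(), 0, 2))
  by_node <- split(rep(seq_len(m), 4), as.vector(elements))
  edges <- lapply(by_node, function(es) {
    es <- unique(es)
    if (length(es) < 2) return(NULL)
    t(utils::combn(es, 2))
  })
  unique(do.call(rbind, edges))
}

# Assign orphaned elements to adjacent territories in increasing
# Euclidean-cost order (cost measured to the claiming source). Elements in
# components with no assigned neighbour at all remain NA.
regrow_orphans <- function(assigned, orphans, cost, sources, adj, m) {
  nbrs <- vector("list", m)
  for (k in seq_len(nrow(adj))) {
    a <- adj[k, 1]; b <- adj[k, 2]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  sid_row <- setNames(seq_len(nrow(sources)), as.character(sources$id))
  # candidate pool (element, source-row, cost); grown as territories expand
  cap <- 256L
  ce <- integer(cap); cs <- integer(cap); cc <- numeric(cap)
  ncand <- 0L
  push <- function(e, srow) {
    if (ncand == cap) {
      cap <<- cap * 2L
      length(ce) <<- cap; length(cs) <<- cap; length(cc) <<- cap
    }
    ncand <<- ncand + 1L
    ce[ncand] <<- e; cs[ncand] <<- srow; cc[ncand] <<- cost[srow, e]
  }
  is_orphan <- rep(FALSE, m)
  is_orphan[orphans] <- TRUE
  for (e in orphans) {
    for (nb in nbrs[[e]]) {
      if (!is.na(assigned[nb])) push(e, sid_row[as.character(assigned[nb])])
    }
  }
  while (ncand > 0L) {
    act <- which(is_orphan[ce[seq_len(ncand)]])
    if (!length(act)) break
    # lowest cost wins; ties to smaller source id then smaller element index
    sel <- act[order(cc[act], sources$id[cs[act]], ce[act])[1]]
    e <- ce[sel]; srow <- cs[sel]
    assigned[e] <- sources$id[srow]
    is_orphan[e] <- FALSE
    # drop consumed candidates lazily; push new frontier entries
    for (nb in nbrs[[e]]) if (is_orphan[nb]) push(nb, srow)
    keep <- which(is_orphan[ce[seq_len(ncand)]])
    ce[seq_along(keep)] <- ce[keep]
    cs[seq_along(keep)] <- cs[keep]
    cc[seq_along(keep)] <- cc[keep]
    ncand <- length(keep)
  }
  assigned
}

#' @export
print.territory_assignment <- function(x, ...) {
  cat("<territory_assignment> ", length(x$element_source) -
        length(x$unassigned), " of ", length(x$element_source),
      " elements assigned to ", nrow(x$sources), " sources",
      if (length(x$unassigned)) paste0(" (", length(x$unassigned),
                                       " unreachable)"), "\n", sep = "")
  invisible(x)
}

#' Per-source territory volumes, masses and flow demands
#'
#' For every source \eqn{i}, \eqn{Q_i = \rho \sum_{j \in R_i} v_j CBF_j}
#' (mL/min), with territory mass \eqn{\rho \sum v_j} (g) and volume in mL.
#' Element demands are summed in ascending element order so grouped and
#' total sums are reproducible.
#'
#' @param assignment a [tessellate()] result.
#' @param mesh the [tissue_mesh()] tessellated.
#' @param table a [tissue_class_table()].
#' @return the assignment with a `summary` data.frame added: `source_id`,
#'   `kind`, `segment_id`, `point_id`, `n_elements`, `volume_mL`, `mass_g`,
#'   `Q_mL_per_min`.
#' @export
territory_demand <- function(assignment, mesh, table = default_tissue_table()) {
  d <- element_demands(mesh, table)
  v <- mesh$volume_mm3 * 1e-3
  src <- assignment$sources
  idx <- assignment$element_source
  summ <- data.frame(source_id = src$id, kind = src$kind,
                     segment_id = src$segment_id, point_id = src$point_id,
                     n_elements = 0L, volume_mL = 0, mass_g = 0,
                     Q_mL_per_min = 0)
  for (i in seq_len(nrow(src))) {
    own <- sort(which(!is.na(idx) & idx == src$id[i]))
    summ$n_elements[i] <- length(own)
    summ$volume_mL[i] <- sum(v[own])
    summ$mass_g[i] <- table$density * sum(v[own])
    summ$Q_mL_per_min[i] <- sum(d[own])
  }
  assignment$summary <- summ
  assignment
}

#' Aggregate source demands into solver boundary sinks
#'
#' Outlet-source demands stay attached to their outlet nodes. All perforator
#' demands within one segment are lumped into a single sink placed at that
#' segment's arclength midpoint (realised in the solver by splitting the
#' segment there and withdrawing the flow at the new node, the zero-length
#' analogue of a virtual branch leaving the midpoint).
#'
#' @param sources the `source_points` table (with demands, see
#'   [territory_demand()]); pass `assignment$summary` implicitly via
#'   `assignment`.
#' @param assignment a [territory_demand()]-annotated assignment.
#' @param network the [vascular_network()] the sources came from.
#' @return list of class `boundary_sinks`: `outlet_flows` (named by outlet
#'   point id, mL/min), `midpoint_sinks` (named by segment id, mL/min),
#'   `total` (mL/min).
#' @export
aggregate_segment_sinks <- function(sources, assignment, network) {
  summ <- assignment$summary
  if (is.null(summ)) {
    stop_perfterra("demands not computed; call territory_demand() first",
                   class = "perfterra_validation_error")
  }
  out <- summ[summ$kind == "outlet", , drop = FALSE]
  perf <- summ[summ$kind == "perforator", , drop = FALSE]
  outlet_flows <- setNames(out$Q_mL_per_min, as.character(out$point_id))
  # merge duplicate outlet nodes defensively
  outlet_flows <- tapply(outlet_flows, names(outlet_flows), sum)
  outlet_flows <- setNames(as.numeric(outlet_flows), names(outlet_flows))
  mids <- if (nrow(perf)) {
    agg <- tapply(perf$Q_mL_per_min, as.character(perf$segment_id), sum)
    agg <- agg[agg > 0]
    setNames(as.numeric(agg), names(agg))
  } else setNames(numeric(0), character(0))
  structure(list(outlet_flows = outlet_flows, midpoint_sinks = mids,
                 total = sum(summ$Q_mL_per_min)),
            class = "boundary_sinks")
}
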
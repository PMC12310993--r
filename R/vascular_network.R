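#' Centerline vascular networks
#'
#' A `vascular_network` holds vessel centerlines as points (position + radius)
#' organised into segments — maximal point chains between junctions — plus the
#' set of inlet nodes (pressure boundary nodes, typically the internal carotid
#' and basilar arteries). All coordinates and radii are in millimetres.
#'
#' @param points data.frame with columns `id` (integer, unique), `x`, `y`,
#'   `z` (mm) and `radius` (mm, > 0).
#' @param segments list of segments; each a list with fields `id` (integer),
#'   `point_ids` (ordered integer vector, length >= 2, referencing `points$id`),
#'   optional `label` (anatomical name such as `"LMCA-M1"` or `"ACoA"`) and
#'   optional `is_virtual` flag.
#' @param inlets integer vector of point ids acting as inlet nodes.
#'
#' @return An object of class `vascular_network` with elements `points`,
#'   `segments` and `inlets`.
#' @export
vascular_network <- function(points, segments, inlets = integer()) {
  points <- as.data.frame(points)
  needed <- c("id", "x", "y", "z", "radius")
  if (!all(needed %in% names(points))) {
    stop_perfterra("points must have columns ", paste(needed, collapse = ", "),
                   class = "perfterra_format_error")
  }
  points$id <- as.integer(points$id)
  if (anyDuplicated(points$id)) {
    stop_perfterra("duplicate point ids", class = "perfterra_validation_error")
  }
  bad <- points$id[!is.finite(points$radius) | points$radius <= 0 |
                     !is.finite(points$x) | !is.finite(points$y) |
                     !is.finite(points$z)]
  if (length(bad)) {
    stop_perfterra("non-finite coordinates or non-positive radius at point ids: ",
                   paste(bad, collapse = ", "),
                   class = "perfterra_validation_error")
  }
  segments <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    list(id = as.integer(s$id %||% i),
         point_ids = as.integer(s$point_ids),
         label = if (is.null(s$label) || is.na(s$label[1])) NA_character_ else as.character(s$label),
         is_virtual = isTRUE(s$is_virtual))
  })
  ids <- vapply(segments, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) {
    stop_perfterra("duplicate segment ids", class = "perfterra_validation_error")
  }
  for (s in segments) {
    if (length(s$point_ids) < 2) {
      stop_perfterra("segment ", s$id, " has fewer than 2 points",
                     class = "perfterra_validation_error")
    }
    if (!all(s$point_ids %in% points$id)) {
      stop_perfterra("segment ", s$id, " references unknown point ids",
                     class = "perfterra_validation_error")
    }
  }
  net <- structure(list(points = points, segments = segments,
                        inlets = as.integer(inlets)),
                   class = "vascular_network")
  if (length(net$inlets) && !all(net$inlets %in% endpoint_ids(net))) {
    stop_perfterra("inlet ids must be segment endpoints",
                   class = "perfterra_validation_error")
  }
  net
}

#' @export
print.vascular_network <- function(x, ...) {
  roles <- node_roles(x)
  cat("<vascular_network> ", nrow(x$points), " points, ",
      length(x$segments), " segments; ",
      sum(roles$role == "inlet"), " inlet(s), ",
      sum(roles$role == "outlet"), " outlet(s), ",
      sum(roles$role == "junction"), " junction(s)\n", sep = "")
  invisible(x)
}

# Point-id -> row lookup for a network.
point_index <- function(net) {
  idx <- seq_len(nrow(net$points))
  names(idx) <- as.character(net$points$id)
  idx
}

# Position matrix (n x 3) for a vector of point ids.
point_xyz <- function(net, ids) {
  idx <- point_index(net)[as.character(ids)]
  as.matrix(net$points[idx, c("x", "y", "z"), drop = FALSE])
}

point_radius <- function(net, ids) {
  net$points$radius[point_index(net)[as.character(ids)]]
}

# First/last point ids of every segment (2-column matrix).
segment_endpoints <- function(net) {
  t(vapply(net$segments, function(s) c(s$point_ids[1],
                                       s$point_ids[length(s$point_ids)]),
           integer(2)))
}

endpoint_ids <- function(net) unique(as.vector(segment_endpoints(net)))

#' Node roles of a network
#'
#' Classifies every segment endpoint by graph degree: degree-1 nodes are
#' `outlet` unless flagged as inlets, nodes where two or more segments meet
#' are `junction` (degree >= 3 is an anatomical bifurcation; degree 2 a plain
#' connection).
#'
#' @param net a [vascular_network()].
#' @return data.frame with columns `point_id`, `degree`, `role`.
#' @export
node_roles <- function(net) {
  ep <- segment_endpoints(net)
  ids <- sort(unique(as.vector(ep)))
  deg <- tabulate(match(as.vector(ep), ids), nbins = length(ids))
  role <- ifelse(ids %in% net$inlets, "inlet",
                 ifelse(deg == 1, "outlet", "junction"))
  data.frame(point_id = ids, degree = deg, role = role)
}

#' Outlet node ids (degree-1 endpoints that are not inlets)
#' @param net a [vascular_network()].
#' @return integer vector of point ids.
#' @export
outlet_nodes <- function(net) {
  r <- node_roles(net)
  r$point_id[r$role == "outlet"]
}

# Arclength of a segment (sum of consecutive point distances, mm).
segment_arclength <- function(net, seg) {
  sum(interval_lengths(point_xyz(net, seg$point_ids)))
}

#' Arclength-weighted mean radius of a segment
#'
#' Trapezoidal average of point radii over the segment's arclength; this is
#' the radius whose circular cross-section stands in for the segment's
#' average cross-sectional area, and the quantity the truncation rule
#' compares against the truncation radius.
#'
#' @param segment a segment (element of `net$segments`) or a segment id.
#' @param net a [vascular_network()].
#' @return mean radius in mm.
#' @export
mean_segment_radius <- function(segment, net) {
  if (!is.list(segment)) segment <- get_segment(net, segment)
  pos <- point_xyz(net, segment$point_ids)
  r <- point_radius(net, segment$point_ids)
  len <- interval_lengths(pos)
  L <- sum(len)
  if (L <= 0) return(mean(r))
  sum((r[-length(r)] + r[-1]) / 2 * len) / L
}

get_segment <- function(net, id) {
  for (s in net$segments) if (s$id == id) return(s)
  stop_perfterra("no segment with id ", id, class = "perfterra_lookup_error")
}

segment_by_label <- function(net, label) {
  for (s in net$segments) if (identical(s$label, label)) return(s)
  NULL
}

segment_labels <- function(net) {
  vapply(net$segments, function(s) s$label %||% NA_character_, character(1))
}

# igraph over endpoint nodes, one edge per segment (edge attr sid).
endpoint_graph <- function(net, keep = rep(TRUE, length(net$segments))) {
  ep <- segment_endpoints(net)[keep, , drop = FALSE]
  ids <- endpoint_ids(net)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- as.character(ids)
  if (nrow(ep)) {
    g <- igraph::add_edges(g, rbind(match(ep[, 1], ids), match(ep[, 2], ids)))
    igraph::E(g)$sid <- vapply(net$segments[keep], `[[`, integer(1), "id")
  }
  g
}

#' Orient segments proximal-to-distal
#'
#' Reorders each segment's point list so the first point is the proximal end,
#' determined by breadth-first search from the inlet nodes over the segment
#' graph. Loop segments (communicating arteries) whose two endpoints are
#' equidistant from the inlets keep an arbitrary but fixed orientation
#' (smaller endpoint id proximal).
#'
#' @param net a [vascular_network()] with at least one inlet.
#' @return the network with consistently oriented segments.
#' @export
orient_network <- function(net) {
  if (!length(net$inlets)) return(net)
  g <- endpoint_graph(net)
  dist <- igraph::distances(g, v = as.character(net$inlets))
  d <- apply(dist, 2, min)
  names(d) <- igraph::V(g)$name
  net$segments <- lapply(net$segments, function(s) {
    a <- s$point_ids[1]
    b <- s$point_ids[length(s$point_ids)]
    da <- d[as.character(a)]
    db <- d[as.character(b)]
    flip <- if (is.finite(da) && is.finite(db)) {
      db < da || (db == da && b < a)
    } else FALSE
    if (flip) s$point_ids <- rev(s$point_ids)
    s
  })
  net
}

#' Resample centerlines to a uniform point spacing
#'
#' Each segment is resampled along its arclength at the requested spacing
#' (the final interval may be shorter); positions lie on the original
#' polyline and radii are linearly interpolated in arclength. Junction and
#' terminal points are preserved exactly. The canonical spacing for
#' image-derived centerlines is 0.5 mm.
#'
#' @param net a [vascular_network()].
#' @param spacing target spacing in mm (> 0).
#' @return the resampled network.
#' @export
resample_centerline <- function(net, spacing = 0.5) {
  stopifnot(spacing > 0)
  next_id <- max(net$points$id) + 1L
  keep_ids <- endpoint_ids(net)
  pts_new <- list(net$points[net$points$id %in% keep_ids, , drop = FALSE])
  segs_new <- vector("list", length(net$segments))
  for (k in seq_along(net$segments)) {
    s <- net$segments[[k]]
    pos <- point_xyz(net, s$point_ids)
    rad <- point_radius(net, s$point_ids)
    cs <- c(0, cumsum(interval_lengths(pos)))
    L <- cs[length(cs)]
    if (L <= spacing) {
      s$point_ids <- c(s$point_ids[1], s$point_ids[length(s$point_ids)])
      segs_new[[k]] <- s
      next
    }
    tgt <- seq(0, L, by = spacing)
    if (tgt[length(tgt)] < L - 1e-12) tgt <- c(tgt, L) else tgt[length(tgt)] <- L
    interior <- tgt[-c(1, length(tgt))]
    if (length(interior)) {
      xi <- stats::approx(cs, pos[, 1], xout = interior)$y
      yi <- stats::approx(cs, pos[, 2], xout = interior)$y
      zi <- stats::approx(cs, pos[, 3], xout = interior)$y
      ri <- stats::approx(cs, rad, xout = interior)$y
      new_ids <- seq.int(next_id, length.out = length(interior))
      next_id <- next_id + length(interior)
      pts_new[[length(pts_new) + 1]] <-
        data.frame(id = new_ids, x = xi, y = yi, z = zi, radius = ri)
      s$point_ids <- c(s$point_ids[1], new_ids,
                       s$point_ids[length(s$point_ids)])
    } else {
      s$point_ids <- c(s$point_ids[1], s$point_ids[length(s$point_ids)])
    }
    segs_new[[k]] <- s
  }
  pts <- do.call(rbind, pts_new)
  pts <- pts[!duplicated(pts$id), , drop = FALSE]
  vascular_network(pts, segs_new, net$inlets)
}

#' Remove vessels below a truncation radius
#'
#' Removes every segment whose arclength-weighted mean radius is below `r_t`
#' (unless its label is protected or excluded from truncation) together with
#' everything downstream of it — i.e. all segments that lose every path to an
#' inlet. Segments forming alternative routes (communicating-artery loops)
#' survive removal of one branch because they remain reachable the other way
#' around; they are only removed when they themselves fall below `r_t`.
#' Segments incident to an inlet node are never removed. New degree-1 distal
#' nodes become outlets.
#'
#' @param net a [vascular_network()] with at least one inlet.
#' @param r_t truncation radius, mm (>= 0; 0 leaves the network unchanged).
#' @param protected labels that must not be removed; removal that would
#'   disconnect them from all inlets is an error.
#' @param excluded labels exempt from truncation (kept if still connected).
#' @return the truncated [vascular_network()].
#' @export
truncate_network <- function(net, r_t, protected = character(),
                             excluded = character()) {
  stopifnot(r_t >= 0)
  if (r_t == 0) return(net)
  if (!length(net$inlets)) {
    stop_perfterra("truncation requires at least one inlet",
                   class = "perfterra_constraint_error")
  }
  labs <- segment_labels(net)
  meanr <- vapply(net$segments, mean_segment_radius, numeric(1), net = net)
  ep <- segment_endpoints(net)
  touches_inlet <- ep[, 1] %in% net$inlets | ep[, 2] %in% net$inlets
  exempt <- (!is.na(labs) & labs %in% c(protected, excluded)) | touches_inlet
  removed <- meanr < r_t & !exempt
  keep <- !removed
  # downstream pruning: drop segments with no remaining path to an inlet
  g <- endpoint_graph(net, keep)
  comp <- igraph::components(g)
  inlet_comps <- unique(comp$membership[as.character(net$inlets)])
  reachable <- igraph::V(g)$name[comp$membership %in% inlet_comps]
  reach <- as.integer(reachable)
  keep2 <- keep & (ep[, 1] %in% reach | ep[, 2] %in% reach)
  lost_protected <- !is.na(labs) & labs %in% protected & !keep2
  if (any(lost_protected)) {
    stop_perfterra("truncation would disconnect protected segment(s): ",
                   paste(labs[lost_protected], collapse = ", "),
                   class = "perfterra_constraint_error")
  }
  segs <- net$segments[keep2]
  used <- unique(unlist(lapply(segs, `[[`, "point_ids")))
  pts <- net$points[net$points$id %in% used, , drop = FALSE]
  vascular_network(pts, segs, net$inlets[net$inlets %in% used])
}

#' Radius of an outlet vessel
#'
#' The radius entering Murray's-law flow splitting. By default the
#' arclength-weighted mean radius over the distal-most 1 mm of the outlet's
#' segment (robust to single-point segmentation noise); alternatively the
#' radius stored at the terminal point itself.
#'
#' @param net an oriented [vascular_network()] (see [orient_network()]).
#' @param method `"distal_mean"` (default) or `"terminal"`.
#' @param window distal arclength window in mm for `"distal_mean"`.
#' @return named numeric vector of radii (mm), names = outlet point ids.
#' @export
outlet_radii <- function(net, method = c("distal_mean", "terminal"),
                         window = 1.0) {
  method <- match.arg(method)
  net <- orient_network(net)
  outs <- outlet_nodes(net)
  ep <- segment_endpoints(net)
  res <- numeric(length(outs))
  for (i in seq_along(outs)) {
    k <- which(ep[, 2] == outs[i] | ep[, 1] == outs[i])[1]
    s <- net$segments[[k]]
    ids <- s$point_ids
    if (ids[1] == outs[i]) ids <- rev(ids)
    if (method == "terminal") {
      res[i] <- point_radius(net, ids[length(ids)])
      next
    }
    pos <- point_xyz(net, ids)
    rad <- point_radius(net, ids)
    cs <- c(0, cumsum(interval_lengths(pos)))
    L <- cs[length(cs)]
    s0 <- max(0, L - window)
    # clip the polyline radius profile to [s0, L] and trapezoid-average
    sel <- cs >= s0
    ss <- c(s0, cs[sel])
    rr <- c(stats::approx(cs, rad, xout = s0)$y, rad[sel])
    dup <- duplicated(ss)
    ss <- ss[!dup]; rr <- rr[!dup]
    if (length(ss) < 2) {
      res[i] <- rad[length(rad)]
    } else {
      dl <- diff(ss)
      res[i] <- sum((rr[-length(rr)] + rr[-1]) / 2 * dl) / sum(dl)
    }
  }
  names(res) <- as.character(outs)
  res
}
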
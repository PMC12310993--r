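# Steady reduced 1D flow on the vascular network.
#
# Under the model's own assumptions — rigid walls, constant flow along each
# segment (continuity), uniform cross-sectional area per segment equal to its
# average — the convective and axial-diffusion terms of the 1D momentum
# balance vanish identically within segments and the momentum equation
# reduces to dp/dz = rho * N * Q / S^2 with N = -8*pi*nu. Integrated over a
# segment of length L and area S = pi*rbar^2 this is Poiseuille's law,
# delta_p = 8*mu*L*Q/(pi*rbar^4), so the steady problem is a linear nodal
# system: conductance-weighted Laplacian, Dirichlet pressures at inlets,
# prescribed flow withdrawals at outlets and midpoint sinks. The
# velocity-profile parameter delta (1/3 for a parabolic profile) is retained
# in the constants but does not enter the steady solution.
#
# Units: geometry mm, flows mL/min, pressures mmHg at the interface;
# internally CGS (cm, cm^3/s, dyn/cm^2) since the fluid constants are CGS.

MMHG_TO_DYN <- 1333.22      # 1 mmHg in dyn/cm^2
MLMIN_TO_CGS <- 1 / 60      # 1 mL/min in cm^3/s

#' Fluid constants for the 1D solver
#'
#' @param rho blood density, g/cm^3 (default 1.06).
#' @param mu dynamic viscosity, g/cm/s (default 0.04).
#' @param delta velocity-profile parameter (1/3 for a parabolic profile;
#'   kept for completeness, not used by the steady solution).
#' @return list of class `fluid_constants` with `rho`, `mu`, `delta`,
#'   kinematic viscosity `nu = mu/rho` and viscous loss parameter
#'   `N = -8*pi*nu`.
#' @export
fluid_constants <- function(rho = 1.06, mu = 0.04, delta = 1 / 3) {
  stopifnot(rho > 0, mu > 0)
  nu <- mu / rho
  structure(list(rho = rho, mu = mu, delta = delta, nu = nu, N = -8 * pi * nu),
            class = "fluid_constants")
}

#' Boundary conditions for the steady solve
#'
#' @param network a [vascular_network()] (supplies the inlet node set).
#' @param sinks a `boundary_sinks` object from [aggregate_segment_sinks()],
#'   or a list with `outlet_flows` (named by outlet point id, mL/min) and
#'   optionally `midpoint_sinks` (named by segment id, mL/min).
#' @param inlet_pressure inlet pressure(s) in mmHg: a single value applied to
#'   every inlet (default 93.33, the mean aortic pressure, assuming
#'   negligible loss between the aorta and the ICA/BA) or a named vector by
#'   inlet point id.
#' @return list of class `boundary_conditions`.
#' @export
boundary_conditions <- function(network, sinks, inlet_pressure = 93.33) {
  inl <- network$inlets
  if (!length(inl)) {
    stop_perfterra("network has no inlets", class = "perfterra_constraint_error")
  }
  p <- if (length(inlet_pressure) == 1 && is.null(names(inlet_pressure))) {
    setNames(rep(inlet_pressure, length(inl)), as.character(inl))
  } else {
    inlet_pressure[as.character(inl)]
  }
  if (anyNA(p)) {
    stop_perfterra("every inlet needs a pressure",
                   class = "perfterra_validation_error")
  }
  of <- sinks$outlet_flows %||% setNames(numeric(0), character(0))
  ms <- sinks$midpoint_sinks %||% setNames(numeric(0), character(0))
  if (any(of < 0) || any(ms < 0)) {
    stop_perfterra("sink flows must be >= 0",
                   class = "perfterra_validation_error")
  }
  structure(list(inlet_pressures = p, outlet_flows = of, midpoint_sinks = ms),
            class = "boundary_conditions")
}

#' Assemble the steady nodal flow system
#'
#' Builds the conductance-weighted nodal system for the network under the
#' given boundary conditions. Each segment becomes one resistive edge with
#' conductance \eqn{g = \pi \bar r^4 / (8 \mu L)} (CGS); segments carrying a
#' midpoint sink are split at their arclength midpoint into two
#' half-conductance edges and the sink is withdrawn at the new node (the
#' zero-length virtual-segment model).
#'
#' @param network a [vascular_network()] with at least one inlet per
#'   connected component.
#' @param bcs a [boundary_conditions()].
#' @param constants a [fluid_constants()].
#' @return list of class `flow_system` (nodes, edges, Laplacian, rhs, ...).
#' @export
build_system <- function(network, bcs, constants = fluid_constants()) {
  network <- orient_network(network)
  ep <- segment_endpoints(network)
  labs <- segment_labels(network)
  next_node <- max(network$points$id) + 1L
  edges <- list()
  sink_nodes <- setNames(numeric(0), character(0)) # node -> mL/min
  midpoint_node_of <- setNames(integer(0), character(0)) # segment -> node
  for (k in seq_along(network$segments)) {
    s <- network$segments[[k]]
    rbar <- mean_segment_radius(s, network)
    L <- segment_arclength(network, s)
    sid <- as.character(s$id)
    if (sid %in% names(bcs$midpoint_sinks)) {
      mid <- next_node
      next_node <- next_node + 1L
      midpoint_node_of[sid] <- mid
      g2 <- seg_conductance(rbar, L / 2, constants$mu)
      edges[[length(edges) + 1]] <- list(segment_id = s$id, part = "prox",
                                         from = ep[k, 1], to = mid, g = g2,
                                         label = labs[k])
      edges[[length(edges) + 1]] <- list(segment_id = s$id, part = "dist",
                                         from = mid, to = ep[k, 2], g = g2,
                                         label = labs[k])
      sink_nodes[as.character(mid)] <- bcs$midpoint_sinks[[sid]]
    } else {
      edges[[length(edges) + 1]] <- list(segment_id = s$id, part = "full",
                                         from = ep[k, 1], to = ep[k, 2],
                                         g = seg_conductance(rbar, L,
                                                             constants$mu),
                                         label = labs[k])
    }
  }
  for (nid in names(bcs$outlet_flows)) {
    prev <- if (nid %in% names(sink_nodes)) sink_nodes[[nid]] else 0
    sink_nodes[nid] <- prev + bcs$outlet_flows[[nid]]
  }
  ed <- data.frame(segment_id = vapply(edges, `[[`, integer(1), "segment_id"),
                   part = vapply(edges, `[[`, character(1), "part"),
                   from = vapply(edges, `[[`, numeric(1), "from"),
                   to = vapply(edges, `[[`, numeric(1), "to"),
                   g = vapply(edges, `[[`, numeric(1), "g"),
                   label = vapply(edges, function(e) e$label %||% NA_character_,
                                  character(1)))
  node_ids <- sort(unique(c(ed$from, ed$to)))
  check_components(ed, node_ids, network$inlets, labs, network)
  sys <- list(nodes = node_ids, edges = ed,
              inlet_nodes = network$inlets,
              inlet_pressures = bcs$inlet_pressures,
              sink_nodes = sink_nodes,
              midpoint_node_of = midpoint_node_of,
              constants = constants, network = network)
  class(sys) <- "flow_system"
  sys
}

seg_conductance <- function(rbar_mm, L_mm, mu) {
  r <- rbar_mm / 10 # cm
  L <- L_mm / 10
  pi * r^4 / (8 * mu * L)
}

check_components <- function(ed, node_ids, inlets, labs, network) {
  g <- igraph::make_empty_graph(length(node_ids), directed = FALSE)
  igraph::V(g)$name <- as.character(node_ids)
  g <- igraph::add_edges(g, rbind(match(ed$from, node_ids),
                                  match(ed$to, node_ids)))
  comp <- igraph::components(g)$membership
  inlet_comp <- unique(comp[as.character(inlets)])
  bad <- setdiff(unique(comp), inlet_comp)
  if (length(bad)) {
    bad_nodes <- node_ids[comp %in% bad]
    bad_segs <- unique(ed$segment_id[ed$from %in% bad_nodes |
                                     ed$to %in% bad_nodes])
    bl <- labs[vapply(network$segments, `[[`, integer(1), "id") %in% bad_segs]
    stop_perfterra("connected component without an inlet; segments: ",
                   paste(ifelse(is.na(bl), "<unlabeled>", bl), collapse = ", "),
                   class = "perfterra_unsolvable_component_error")
  }
}

#' Solve the steady flow system
#'
#' Solves the sparse symmetric nodal system for pressures, recovers signed
#' segment flows \eqn{Q = g (p_{prox} - p_{dist})} and inlet inflows, and
#' verifies mass conservation at every junction.
#'
#' @param system a [build_system()] result.
#' @return object of class `flow_solution`: `nodes` (node_id, pressure_mmHg),
#'   `edges` (segment_id, part, from, to, Q_mL_per_min, label),
#'   `inlet_inflows` (named, mL/min), `residual` (max relative junction
#'   imbalance), `midpoint_node_of`.
#' @export
solve_steady_flow <- function(system) {
  nid <- system$nodes
  n <- length(nid)
  idx <- setNames(seq_len(n), as.character(nid))
  ed <- system$edges
  i <- idx[as.character(ed$from)]
  j <- idx[as.character(ed$to)]
  G <- Matrix::sparseMatrix(
    i = c(i, j, i, j), j = c(j, i, i, j),
    x = c(-ed$g, -ed$g, ed$g, ed$g), dims = c(n, n))
  b <- rep(0, n)
  sk <- system$sink_nodes
  b[idx[names(sk)]] <- b[idx[names(sk)]] - sk * MLMIN_TO_CGS
  fixed <- idx[as.character(system$inlet_nodes)]
  pfix <- system$inlet_pressures[as.character(system$inlet_nodes)] * MMHG_TO_DYN
  free <- setdiff(seq_len(n), fixed)
  # solve for deviations from the mean inlet pressure: unknowns then live on
  # the scale of the pressure drops, not the absolute pressure, which keeps
  # rounding noise (and hence spurious left/right asymmetry) ~4 orders of
  # magnitude smaller
  pref <- mean(pfix)
  q_dev <- rep(0, n) # pressure deviation from pref; flows use this directly
  q_dev[fixed] <- pfix - pref
  if (length(free)) {
    rhs <- b[free] - as.numeric(G[free, fixed, drop = FALSE] %*% (pfix - pref))
    sol <- tryCatch(
      Matrix::solve(G[free, free, drop = FALSE], rhs),
      error = function(e) stop_perfterra(
        "singular flow system: ", conditionMessage(e),
        class = "perfterra_numerical_error"))
    q_dev[free] <- as.numeric(sol)
  }
  p <- pref + q_dev
  Q_cgs <- ed$g * (q_dev[i] - q_dev[j])
  Q <- Q_cgs / MLMIN_TO_CGS
  # inlet inflow = net flow leaving each inlet node
  inflow <- vapply(fixed, function(f) {
    sum(Q[i == f]) - sum(Q[j == f])
  }, numeric(1))
  names(inflow) <- as.character(nid[fixed])
  # junction residuals
  net_in <- rep(0, n)
  for (k in seq_along(i)) {
    net_in[j[k]] <- net_in[j[k]] + Q[k]
    net_in[i[k]] <- net_in[i[k]] - Q[k]
  }
  sink_full <- rep(0, n)
  sink_full[idx[names(sk)]] <- sk
  resid <- abs(net_in[free] - sink_full[free])
  total_in <- sum(inflow)
  residual <- if (total_in > 0) max(c(0, resid)) / total_in else max(c(0, resid))
  structure(list(
    nodes = data.frame(node_id = nid, pressure_mmHg = p / MMHG_TO_DYN),
    edges = data.frame(segment_id = ed$segment_id, part = ed$part,
                       from = ed$from, to = ed$to, Q_mL_per_min = Q,
                       label = ed$label),
    inlet_inflows = inflow, residual = residual,
    sink_nodes = sk,
    midpoint_node_of = system$midpoint_node_of),
    class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> ", nrow(x$edges), " edges; total inflow ",
      format(sum(x$inlet_inflows)), " mL/min; conservation residual ",
      format(x$residual), "\n", sep = "")
  invisible(x)
}

#' Flow of a labeled segment
#'
#' Signed flow along a segment's stored (proximal-to-distal) orientation.
#' For a segment split by a midpoint sink this is the proximal-half flow,
#' i.e. the flow entering the segment — the quantity measured at the M1/A1/P2
#' sites.
#'
#' @param solution a [solve_steady_flow()] result.
#' @param label segment label.
#' @return flow in mL/min, or `NA` if the label is absent.
#' @export
segment_flow <- function(solution, label) {
  ed <- solution$edges
  hit <- which(!is.na(ed$label) & ed$label == label &
                 ed$part %in% c("full", "prox"))
  if (!length(hit)) return(NA_real_)
  ed$Q_mL_per_min[hit[1]]
}

#' Relative flow distribution of the major cerebral arteries
#'
#' Cerebral ratios are each labeled artery's |Q| as a percentage of the sum
#' over the six M1/A1/P2 measurement segments; inlet ratios are each inlet's
#' inflow as a percentage of total inflow. Missing labels (anatomical
#' variants) are flagged and the ratios renormalised over the present ones.
#'
#' @param solution a [solve_steady_flow()] result.
#' @param network the solved [vascular_network()].
#' @param artery_labels named character vector, artery -> measurement-segment
#'   label.
#' @return object of class `flow_distribution`: `arteries` (artery, label,
#'   Q_mL_per_min, ratio_pct), `inlets` (name, inflow_mL_per_min, ratio_pct),
#'   `missing` (character).
#' @export
compute_distribution <- function(solution, network,
                                 artery_labels = c(LMCA = "LMCA-M1",
                                                   RMCA = "RMCA-M1",
                                                   LACA = "LACA-A1",
                                                   RACA = "RACA-A1",
                                                   LPCA = "LPCA-P2",
                                                   RPCA = "RPCA-P2")) {
  q <- vapply(artery_labels, function(l) segment_flow(solution, l), numeric(1))
  missing <- names(artery_labels)[is.na(q)]
  present <- !is.na(q)
  tot <- sum(abs(q[present]))
  ratio <- ifelse(present, abs(q) / tot * 100, NA_real_)
  inl <- solution$inlet_inflows
  inames <- vapply(names(inl), function(nid) {
    ep <- segment_endpoints(network)
    k <- which(ep[, 1] == as.integer(nid) | ep[, 2] == as.integer(nid))[1]
    network$segments[[k]]$label %||% nid
  }, character(1))
  structure(list(
    arteries = data.frame(artery = names(artery_labels),
                          label = unname(artery_labels),
                          Q_mL_per_min = unname(q),
                          ratio_pct = unname(ratio)),
    inlets = data.frame(name = unname(ifelse(is.na(inames), names(inl),
                                             inames)),
                        node_id = as.integer(names(inl)),
                        inflow_mL_per_min = unname(inl),
                        ratio_pct = unname(inl / sum(inl) * 100)),
    missing = missing),
    class = "flow_distribution")
}

#' @export
print.flow_distribution <- function(x, ...) {
  cat("<flow_distribution>\n")
  print(x$arteries, row.names = FALSE)
  print(x$inlets, row.names = FALSE)
  if (length(x$missing)) cat("missing labels:",
                             paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Per-territory inlet contribution fractions
#'
#' Traces each sink's flow back to the inlets by solving the linear mixing
#' system in which every node's outflow composition equals the flow-weighted
#' average of its inflow compositions (inlets carry unit composition of
#' themselves). On a tree every territory is 100% its unique upstream inlet;
#' across an open communicating artery contributions mix.
#'
#' @param solution a [solve_steady_flow()] result.
#' @param assignment optional [territory_demand()] result; when given, rows
#'   are returned per source, otherwise per sink node.
#' @return data.frame with one row per sink (or source) and one fraction
#'   column per inlet (fractions sum to 1 where flow is nonzero; `NA` in
#'   zero-flow regions).
#' @export
inlet_contribution_map <- function(solution, assignment = NULL) {
  nid <- solution$nodes$node_id
  n <- length(nid)
  idx <- setNames(seq_len(n), as.character(nid))
  ed <- solution$edges
  eps <- 1e-14 * max(1, sum(abs(solution$inlet_inflows)))
  from <- ifelse(ed$Q_mL_per_min >= 0, ed$from, ed$to)
  to <- ifelse(ed$Q_mL_per_min >= 0, ed$to, ed$from)
  q <- abs(ed$Q_mL_per_min)
  keep <- q > eps
  from <- idx[as.character(from[keep])]
  to <- idx[as.character(to[keep])]
  q <- q[keep]
  inlets <- names(solution$inlet_inflows)
  k <- length(inlets)
  fin <- rep(0, n)
  for (e in seq_along(q)) fin[to[e]] <- fin[to[e]] + q[e]
  inlet_idx <- idx[inlets]
  # A x = b per inlet: x_n * F_n - sum_in q_e x_src = 0; x fixed at inlets.
  # Nodes with no inflow get an identity row (x = 0, flagged NA below).
  diagv <- ifelse(fin > eps, fin, 1)
  trip_i <- c(seq_len(n), to)
  trip_j <- c(seq_len(n), from)
  trip_x <- c(diagv, -q)
  # Dirichlet rows at inlets: identity
  drop_row <- trip_i %in% inlet_idx
  trip_i <- c(trip_i[!drop_row], inlet_idx)
  trip_j <- c(trip_j[!drop_row], inlet_idx)
  trip_x <- c(trip_x[!drop_row], rep(1, k))
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x, dims = c(n, n))
  B <- matrix(0, n, k)
  B[cbind(inlet_idx, seq_len(k))] <- 1
  X <- as.matrix(Matrix::solve(A, B))
  X[fin <= eps & !(seq_len(n) %in% inlet_idx), ] <- NA # no inflow: undefined
  colnames(X) <- inlets
  sinks <- solution$sink_nodes
  out <- data.frame(node_id = as.integer(names(sinks)),
                    sink_mL_per_min = as.numeric(sinks))
  out <- cbind(out, X[idx[names(sinks)], , drop = FALSE])
  rownames(out) <- NULL
  if (!is.null(assignment) && !is.null(assignment$summary)) {
    summ <- assignment$summary
    node_of <- ifelse(summ$kind == "outlet",
                      as.integer(summ$point_id),
                      as.integer(solution$midpoint_node_of[
                        as.character(summ$segment_id)]))
    rows <- match(node_of, out$node_id)
    res <- cbind(summ[, c("source_id", "kind", "segment_id",
                          "Q_mL_per_min")],
                 out[rows, inlets, drop = FALSE])
    rownames(res) <- NULL
    return(res)
  }
  out
}
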
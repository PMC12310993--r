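#' Murray's-law outlet flow allocation
#'
#' The comparator boundary-condition model: the total tissue demand
#' \eqn{Q_{total} = \rho \sum_k v_k CBF_k} is split among the vessel outlets
#' in proportion to the cube of each outlet's radius,
#' \eqn{Q_i = Q_{total} \, r_i^3 / \sum_j r_j^3}. Perfusion through
#' perforating arteries is not considered under this model — no midpoint
#' sinks are generated — so the network solve uses outlet withdrawals only.
#'
#' @param radii named numeric vector of outlet radii (mm, > 0), names =
#'   outlet point ids (see [outlet_radii()]).
#' @param Q_total total demand, mL/min (see [total_demand()]).
#' @return object of class `murray_allocation`: list with `outlet_flows`
#'   (named, mL/min, summing to `Q_total`), `Q_total`, and an empty
#'   `midpoint_sinks` so it plugs directly into [boundary_conditions()].
#' @export
murray_flows <- function(radii, Q_total) {
  if (!length(radii)) {
    stop_perfterra("empty outlet set", class = "perfterra_validation_error")
  }
  stopifnot(all(radii > 0), Q_total >= 0)
  w <- radii^3
  flows <- Q_total * w / sum(w)
  structure(list(outlet_flows = flows,
                 midpoint_sinks = setNames(numeric(0), character(0)),
                 total = Q_total, Q_total = Q_total),
            class = c("murray_allocation", "boundary_sinks"))
}

#' End-to-end Murray's-law model on a network + mesh
#'
#' Convenience wrapper: outlet radii from the network, total demand from the
#' mesh, cubic split, steady solve, distribution.
#'
#' @param network a [vascular_network()].
#' @param mesh a [tissue_mesh()].
#' @param table a [tissue_class_table()].
#' @param constants a [fluid_constants()].
#' @param inlet_pressure mmHg (see [boundary_conditions()]).
#' @param radius_method passed to [outlet_radii()].
#' @param artery_labels passed to [compute_distribution()].
#' @return list with `allocation`, `solution`, `distribution`.
#' @export
run_murray <- function(network, mesh, table = default_tissue_table(),
                       constants = fluid_constants(), inlet_pressure = 93.33,
                       radius_method = "distal_mean",
                       artery_labels = NULL) {
  alloc <- murray_flows(outlet_radii(network, method = radius_method),
                        total_demand(mesh, table))
  bcs <- boundary_conditions(network, alloc, inlet_pressure)
  sol <- solve_steady_flow(build_system(network, bcs, constants))
  dist <- if (is.null(artery_labels)) compute_distribution(sol, network)
          else compute_distribution(sol, network, artery_labels)
  list(allocation = alloc, solution = sol, distribution = dist)
}
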
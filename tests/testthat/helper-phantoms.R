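# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

toy_cow <- function() fixture("toy_cow", make_phantom("toy_cow", seed = 1))

# full tessellation pipeline on the toy circle of Willis
cow_pipeline <- function() fixture("cow_pipeline", {
  ph <- toy_cow()
  src <- select_sources(ph$network, ph$mesh)
  asg <- territory_demand(tessellate(ph$mesh, src), ph$mesh)
  sinks <- aggregate_segment_sinks(src, asg, ph$network)
  bcs <- boundary_conditions(ph$network, sinks)
  sol <- solve_steady_flow(build_system(ph$network, bcs))
  list(ph = ph, src = src, asg = asg, sinks = sinks, sol = sol,
       dist = compute_distribution(sol, ph$network))
})

box_mesh <- function() fixture("box_mesh", make_tissue_phantom())

# straight-line two-point-per-segment network helper
line_network <- function(coords, radii, labels = NULL, inlets = 1L,
                         seg_points = NULL) {
  pts <- data.frame(id = seq_len(nrow(coords)), x = coords[, 1],
                    y = coords[, 2], z = coords[, 3], radius = radii)
  if (is.null(seg_points)) {
    seg_points <- lapply(seq_len(nrow(coords) - 1), function(i) c(i, i + 1))
  }
  segs <- lapply(seq_along(seg_points), function(i) {
    list(id = i, point_ids = seg_points[[i]],
         label = if (is.null(labels)) NA else labels[i])
  })
  vascular_network(pts, segs, inlets)
}

# tiny toy branching tree used by truncation tests:
# inlet -> trunk (r 1.2) -> junction -> branch A (mean r ~0.9) -> 2 leaves
#                                    -> branch B (mean r ~0.4) -> 2 leaves
# interior points 9/10 sit right after the junction so each branch's
# arclength-weighted mean is dominated by its own calibre
toy_tree <- function() {
  pts <- data.frame(
    id = 1:10,
    x = c(0, 0, -4, -6, -2, 4, 6, 2, -0.08, 0.08),
    y = 0,
    z = c(-10, 0, 4, 10, 10, 4, 10, 10, 0.08, 0.08),
    radius = c(1.2, 1.2, 0.9, 0.6, 0.6, 0.4, 0.3, 0.3, 0.9, 0.4))
  segs <- list(
    list(id = 1, point_ids = c(1, 2), label = "TRUNK"),
    list(id = 2, point_ids = c(2, 9, 3), label = "A"),
    list(id = 3, point_ids = c(3, 4), label = "A1"),
    list(id = 4, point_ids = c(3, 5), label = "A2"),
    list(id = 5, point_ids = c(2, 10, 6), label = "B"),
    list(id = 6, point_ids = c(6, 7), label = "B1"),
    list(id = 7, point_ids = c(6, 8), label = "B2"))
  vascular_network(pts, segs, inlets = 1L)
}

seg_label_set <- function(net) sort(stats::na.omit(
  vapply(net$segments, function(s) s$label, character(1))))

# free-floating source table (not tied to a network) for tessellation tests
fake_sources <- function(pos, speed = 1) {
  pos <- matrix(pos, ncol = 3)
  data.frame(id = seq_len(nrow(pos)), point_id = seq_len(nrow(pos)),
             segment_id = 1L, kind = "outlet",
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             speed = rep(speed, length.out = nrow(pos)))
}

# one small tetrahedron near `at`
unit_mesh_at <- function(at) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tissue_mesh(sweep(v, 2, at, `+`), matrix(1:4, 1), "other")
}

# raw lattice nodes/elements (2x2x2 cells) for composing disconnected meshes
kuhn_nodes_elements <- function(xlim, ylim, zlim) {
  perfterra:::kuhn_lattice(xlim, ylim, zlim, 2, 2, 2)
}

protected_cow <- c("LMCA-M1", "RMCA-M1", "LACA-A1", "RACA-A1",
                   "LPCA-P1", "RPCA-P1", "LPCA-P2", "RPCA-P2")

# default-protocol truncation sweep on the toy circle of Willis
cow_sweep <- function() fixture("cow_sweep", {
  ph <- toy_cow()
  truncation_sweep(ph$network, ph$mesh, model = "tessellation",
                   protected = protected_cow)
})

# scale each outlet segment's radii by its own +/-20% factor
perturb_outlet_radii <- function(net, seed = 1) {
  outs <- outlet_nodes(net)
  ep <- perfterra:::segment_endpoints(net)
  set.seed(seed)
  for (o in outs) {
    k <- which(ep[, 1] == o | ep[, 2] == o)[1]
    f <- sample(c(0.8, 1.2), 1)
    ids <- net$segments[[k]]$point_ids
    net <- perturb_radii(net, factor = f, point_ids = ids)
  }
  net
}
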
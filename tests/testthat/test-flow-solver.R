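test_that("single-segment pressure drop matches the Poiseuille closed form", {
  # r = 1 mm = 0.1 cm, L = 10 mm = 1 cm, mu = 0.04, Q = 1 cm^3/s = 60 mL/min
  net <- line_network(cbind(0, 0, c(0, 10)), radii = c(1, 1))
  bcs <- boundary_conditions(net, list(outlet_flows = c("2" = 60)))
  sol <- solve_steady_flow(build_system(net, bcs))
  dp <- sol$nodes$pressure_mmHg[1] - sol$nodes$pressure_mmHg[2]
  dp_oracle <- oracle_poiseuille_mmHg(0.1, 1, 0.04, 1) # ~0.764 mmHg
  expect_equal(dp, dp_oracle, tolerance = 1e-12)
  expect_equal(dp * 1333.22, 1018.59, tolerance = 1e-4)
  expect_equal(sol$edges$Q_mL_per_min, 60, tolerance = 1e-12)
  expect_equal(sol$nodes$pressure_mmHg[1], 93.33)
  # parameter grid
  for (r in c(0.5, 1, 2)) for (L in c(5, 20)) for (q in c(1, 7.5)) {
    netg <- line_network(cbind(0, 0, c(0, L)), radii = c(r, r))
    bg <- boundary_conditions(netg, list(outlet_flows = c("2" = q)))
    sg <- solve_steady_flow(build_system(netg, bg))
    dpg <- sg$nodes$pressure_mmHg[1] - sg$nodes$pressure_mmHg[2]
    expect_equal(dpg, oracle_poiseuille_mmHg(r / 10, L / 10, 0.04, q / 60),
                 tolerance = 1e-10)
  }
})

test_that("conductance follows the quartic radius law and series identity", {
  g1 <- perfterra:::seg_conductance(1, 10, 0.04)
  expect_equal(perfterra:::seg_conductance(2, 10, 0.04) / g1, 16)
  # splitting at the midpoint with zero sink changes nothing
  net <- line_network(cbind(0, 0, c(0, 10)), radii = c(1, 1))
  bcs <- boundary_conditions(net, list(outlet_flows = c("2" = 5)))
  sol <- solve_steady_flow(build_system(net, bcs))
  bcs2 <- boundary_conditions(net, list(outlet_flows = c("2" = 5),
                                        midpoint_sinks = c("1" = 0)))
  sol2 <- solve_steady_flow(build_system(net, bcs2))
  expect_equal(sol2$nodes$pressure_mmHg[match(2, sol2$nodes$node_id)],
               sol$nodes$pressure_mmHg[match(2, sol$nodes$node_id)],
               tolerance = 1e-14)
  expect_equal(sol2$edges$Q_mL_per_min, rep(5, 2), tolerance = 1e-12)
})

test_that("a symmetric Y carries twice the branch flow in the parent", {
  pts <- data.frame(id = 1:4, x = c(0, 0, -5, 5), y = 0,
                    z = c(-10, 0, 8, 8), radius = c(1.2, 1.2, 0.8, 0.8))
  net <- vascular_network(pts, list(
    list(id = 1, point_ids = c(1, 2), label = "P"),
    list(id = 2, point_ids = c(2, 3), label = "L"),
    list(id = 3, point_ids = c(2, 4), label = "R")), inlets = 1L)
  q <- 3.2
  bcs <- boundary_conditions(net, list(outlet_flows = c("3" = q, "4" = q)))
  sol <- solve_steady_flow(build_system(net, bcs))
  expect_equal(segment_flow(sol, "P"), 2 * q, tolerance = 1e-12)
  p <- setNames(sol$nodes$pressure_mmHg, sol$nodes$node_id)
  expect_equal(p[["3"]], p[["4"]], tolerance = 1e-14)
  expect_lt(sol$residual, 1e-10)
})

test_that("looped graphs match the independent mixed-formulation oracle", {
  # diamond with unequal arms and two inlets at different pressures
  pts <- data.frame(id = 1:6, x = c(0, 0, -6, 6, 0, 0),
                    y = c(0, 0, 2, 2, 4, 4),
                    z = c(-8, 0, 4, 4, 8, 14),
                    radius = c(1.5, 1.5, 0.9, 1.1, 1.0, 1.0))
  segs <- list(list(id = 1, point_ids = c(1, 2), label = "IN1"),
               list(id = 2, point_ids = c(2, 3), label = "armL"),
               list(id = 3, point_ids = c(2, 4), label = "armR"),
               list(id = 4, point_ids = c(3, 5), label = "armL2"),
               list(id = 5, point_ids = c(4, 5), label = "armR2"),
               list(id = 6, point_ids = c(5, 6), label = "OUT"))
  net <- vascular_network(pts, segs, inlets = 1L)
  sinks <- list(outlet_flows = c("6" = 4.4), midpoint_sinks = c("2" = 1.3))
  bcs <- boundary_conditions(net, sinks)
  sol <- solve_steady_flow(build_system(net, bcs))
  # oracle: rebuild the same graph with independently computed conductances
  seg_geo <- lapply(segs, function(s) {
    a <- pts[s$point_ids[1], ]; b <- pts[s$point_ids[2], ]
    list(L = sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2),
         r = mean(c(a$radius, b$radius)))
  })
  ed <- do.call(rbind, lapply(seq_along(segs), function(k) {
    s <- segs[[k]]; geo <- seg_geo[[k]]
    if (s$id == 2) { # split by midpoint sink
      data.frame(from = c("2", "mid"), to = c("mid", "3"),
                 g = g_mLmin_per_mmHg(geo$r, geo$L / 2))
    } else {
      data.frame(from = as.character(s$point_ids[1]),
                 to = as.character(s$point_ids[2]),
                 g = g_mLmin_per_mmHg(geo$r, geo$L))
    }
  }))
  oracle <- oracle_network_flow(ed, fixed_p = c("1" = 93.33),
                                sinks = c("6" = 4.4, "mid" = 1.3))
  p <- setNames(sol$nodes$pressure_mmHg, sol$nodes$node_id)
  for (n in as.character(2:6)) {
    expect_equal(p[[n]], oracle$p[[n]], tolerance = 1e-9)
  }
  expect_equal(segment_flow(sol, "armR"), oracle$q[4], tolerance = 1e-9)
  expect_equal(segment_flow(sol, "armL"), oracle$q[2], tolerance = 1e-9)

  # two-inlet loop (circle-of-Willis-like) with asymmetric demands
  pts2 <- data.frame(id = 1:6, x = c(-8, 8, -8, 8, -8, 8),
                     y = 0, z = c(-10, -10, 0, 0, 8, 8),
                     radius = c(1.5, 1.5, 1.5, 1.5, 0.8, 0.8))
  segs2 <- list(list(id = 1, point_ids = c(1, 3), label = "INL"),
                list(id = 2, point_ids = c(2, 4), label = "INR"),
                list(id = 3, point_ids = c(3, 4), label = "COMM"),
                list(id = 4, point_ids = c(3, 5), label = "OUTL"),
                list(id = 5, point_ids = c(4, 6), label = "OUTR"))
  net2 <- vascular_network(pts2, segs2, inlets = c(1L, 2L))
  bcs2 <- boundary_conditions(net2, list(outlet_flows = c("5" = 6, "6" = 2)))
  sol2 <- solve_steady_flow(build_system(net2, bcs2))
  ed2 <- do.call(rbind, lapply(segs2, function(s) {
    a <- pts2[s$point_ids[1], ]; b <- pts2[s$point_ids[2], ]
    data.frame(from = as.character(s$point_ids[1]),
               to = as.character(s$point_ids[2]),
               g = g_mLmin_per_mmHg(mean(c(a$radius, b$radius)),
                                    sqrt((a$x - b$x)^2 + (a$z - b$z)^2)))
  }))
  or2 <- oracle_network_flow(ed2, fixed_p = c("1" = 93.33, "2" = 93.33),
                             sinks = c("5" = 6, "6" = 2))
  expect_equal(segment_flow(sol2, "COMM"), or2$q[3], tolerance = 1e-9)
  # collateral flow crosses toward the heavier-demand side
  expect_gt(segment_flow(sol2, "COMM") * -1, 0) # flows 4 -> 3 i.e. negative
  expect_equal(sum(sol2$inlet_inflows), 8, tolerance = 1e-10)
})

test_that("conservation and the pressure maximum principle hold end-to-end", {
  pl <- cow_pipeline()
  sol <- pl$sol
  total <- sum(pl$sinks$outlet_flows) + sum(pl$sinks$midpoint_sinks)
  expect_lt(abs(sum(sol$inlet_inflows) - total) / total, 1e-10)
  expect_lt(sol$residual, 1e-10)
  expect_lte(max(sol$nodes$pressure_mmHg), 93.33 + 1e-12)
})

test_that("a component without an inlet refuses to solve, by name", {
  ph <- fixture("cow_disconnected",
                make_phantom("toy_cow", seed = 1, disconnect_lmca = TRUE))
  src <- select_sources(ph$network, ph$mesh)
  asg <- territory_demand(tessellate(ph$mesh, src), ph$mesh)
  expect_gt(sum(asg$summary$Q_mL_per_min), 0) # territories still computed
  sinks <- aggregate_segment_sinks(src, asg, ph$network)
  bcs <- boundary_conditions(ph$network, sinks)
  expect_error(build_system(ph$network, bcs), "LMCA-M1",
               class = "perfterra_unsolvable_component_error")
})

test_that("flow ratios are computed at the labeled measurement segments", {
  pl <- cow_pipeline()
  d <- pl$dist
  expect_equal(sum(d$arteries$ratio_pct), 100, tolerance = 1e-9)
  expect_equal(sum(d$inlets$ratio_pct), 100, tolerance = 1e-9)
  expect_setequal(d$inlets$name, c("LICA", "RICA", "BA"))
  # hand-computed: ratio = |Q| / sum(|Q|) over the six labels
  q <- vapply(d$arteries$label, function(l) abs(segment_flow(pl$sol, l)),
              numeric(1))
  expect_equal(d$arteries$ratio_pct, unname(q / sum(q) * 100),
               tolerance = 1e-12)
  # a missing label is flagged and ratios renormalise over the present ones
  d2 <- compute_distribution(pl$sol, pl$ph$network,
                             artery_labels = c(LMCA = "LMCA-M1",
                                               RMCA = "RMCA-M1",
                                               XACA = "NO-SUCH"))
  expect_equal(d2$missing, "XACA")
  expect_equal(sum(d2$arteries$ratio_pct, na.rm = TRUE), 100,
               tolerance = 1e-9)
})

test_that("inlet contributions: trees are single-origin, loops mix", {
  # pure tree: every sink is 100% the single inlet
  net <- toy_tree()
  bcs <- boundary_conditions(net, list(
    outlet_flows = c("4" = 1, "5" = 2, "7" = 0.5, "8" = 0.25)))
  sol <- solve_steady_flow(build_system(net, bcs))
  cm <- inlet_contribution_map(sol)
  expect_equal(unname(cm[["1"]]), rep(1, nrow(cm)))
  # symmetric two-inlet loop: far-side sink splits 50/50
  pts2 <- data.frame(id = 1:5, x = c(-8, 8, -8, 8, 0), y = 0,
                     z = c(-10, -10, 0, 0, 0.5),
                     radius = c(1.5, 1.5, 0.8, 0.8, 0.8))
  segs2 <- list(list(id = 1, point_ids = c(1, 3)),
                list(id = 2, point_ids = c(2, 4)),
                list(id = 3, point_ids = c(3, 5)),
                list(id = 4, point_ids = c(4, 5)))
  net2 <- vascular_network(pts2, segs2, inlets = c(1L, 2L))
  bcs2 <- boundary_conditions(net2, list(outlet_flows = c("5" = 4)))
  sol2 <- solve_steady_flow(build_system(net2, bcs2))
  cm2 <- inlet_contribution_map(sol2)
  expect_equal(unname(unlist(cm2[cm2$node_id == 5, c("1", "2")])),
               c(0.5, 0.5), tolerance = 1e-12)
})

test_that("opening the ACoA lets contralateral inflow cross when one side
           demands more", {
  pl <- cow_pipeline()
  summ <- pl$asg$summary
  # raise demand of every left-side source by 30%
  boost <- summ
  left <- boost$point_id %in% pl$ph$network$points$id[
    pl$ph$network$points$x < 0]
  boost$Q_mL_per_min[left] <- boost$Q_mL_per_min[left] * 1.3
  asg2 <- pl$asg
  asg2$summary <- boost
  sinks2 <- aggregate_segment_sinks(pl$src, asg2, pl$ph$network)
  bcs2 <- boundary_conditions(pl$ph$network, sinks2)
  sol2 <- solve_steady_flow(build_system(pl$ph$network, bcs2))
  q_acoa <- segment_flow(sol2, "ACoA")
  expect_gt(abs(q_acoa), 1e-4)
  # sign: the ACoA is stored L -> R, so flow must run R -> L (negative)
  expect_lt(q_acoa, 0)
  # and the right inlet now contributes to left-side territories
  cm <- inlet_contribution_map(sol2, asg2)
  rica <- as.character(pl$ph$network$inlets[2])
  pts <- pl$ph$network$points
  src_x <- pts$x[match(boost$point_id[match(cm$source_id, boost$source_id)],
                       pts$id)]
  left_rows <- src_x < 0
  expect_true(any(cm[left_rows, rica] > 1e-6, na.rm = TRUE))
  # every defined contribution row sums to 1
  inl_cols <- as.character(pl$ph$network$inlets)
  rs <- rowSums(cm[, inl_cols])
  expect_equal(rs[!is.na(rs)], rep(1, sum(!is.na(rs))), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("shrinking loop conductance recovers the tree solution smoothly", {
  # as the communicating segment's conductance -> 0 (longer and longer
  # detour), the inlet split converges to the tree split (6, 2)
  base_pts <- data.frame(id = 1:7, x = c(-8, 8, -8, 8, -8, 8, 0),
                         y = c(0, 0, 0, 0, 0, 0, 10),
                         z = c(-10, -10, 0, 0, 8, 8, 0),
                         radius = c(1.5, 1.5, 1.5, 1.5, 0.8, 0.8, 1.5))
  base_segs <- list(list(id = 1, point_ids = c(1, 3), label = "INL"),
                    list(id = 2, point_ids = c(2, 4), label = "INR"),
                    list(id = 4, point_ids = c(3, 5), label = "OUTL"),
                    list(id = 5, point_ids = c(4, 6), label = "OUTR"))
  sinks <- list(outlet_flows = c("5" = 6, "6" = 2))
  prev_gap <- Inf
  prev_q <- Inf
  for (detour in c(10, 40, 160, 640)) {
    pts <- base_pts
    pts$y[7] <- detour # comm routed through a far-away via point
    net <- vascular_network(
      pts, c(base_segs, list(list(id = 3, point_ids = c(3, 7, 4),
                                  label = "COMM"))), inlets = c(1L, 2L))
    sol <- solve_steady_flow(build_system(
      net, boundary_conditions(net, sinks)))
    q_comm <- abs(segment_flow(sol, "COMM"))
    gap <- max(abs(sol$inlet_inflows - c(6, 2)))
    expect_lt(q_comm, prev_q)
    expect_lt(gap, prev_gap)
    prev_q <- q_comm
    prev_gap <- gap
  }
  expect_lt(prev_gap, 0.05) # essentially the tree split
})
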
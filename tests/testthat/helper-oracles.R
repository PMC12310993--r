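# Independent oracles used by the tests. These deliberately avoid the
# package's solution paths: the flow oracle solves the mixed
# (pressure-drop + mass-balance) formulation densely with base R, and the
# tessellation oracle evaluates the weighted Voronoi rule exhaustively.

# Dense mixed-formulation resistive network solve.
#   edges: data.frame(from, to, g) — conductance in flow-units per
#          pressure-unit, flow positive from -> to, p_from - p_to = q/g.
#   fixed_p: named vector of pressures at pinned nodes.
#   sinks: named vector of withdrawals at nodes (same flow units).
# Returns list(q = per-edge flow, p = named node pressures).
oracle_network_flow <- function(edges, fixed_p, sinks = c()) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  free <- setdiff(nodes, names(fixed_p))
  E <- nrow(edges)
  nf <- length(free)
  A <- matrix(0, E + nf, E + nf)
  rhs <- numeric(E + nf)
  pcol <- function(n) E + match(n, free)
  for (e in seq_len(E)) {
    A[e, e] <- 1 / edges$g[e]
    a <- edges$from[e]; b <- edges$to[e]
    if (a %in% free) A[e, pcol(a)] <- -1 else rhs[e] <- rhs[e] + fixed_p[[a]]
    if (b %in% free) A[e, pcol(b)] <- 1 else rhs[e] <- rhs[e] - fixed_p[[b]]
  }
  for (i in seq_len(nf)) {
    n <- free[i]
    row <- E + i
    A[row, which(edges$to == n)] <- 1
    A[row, which(edges$from == n)] <- A[row, which(edges$from == n)] - 1
    rhs[row] <- if (n %in% names(sinks)) sinks[[n]] else 0
  }
  sol <- solve(A, rhs)
  p <- setNames(numeric(length(nodes)), nodes)
  p[names(fixed_p)] <- fixed_p
  if (nf) p[free] <- sol[(E + 1):(E + nf)]
  list(q = sol[seq_len(E)], p = p)
}

# Exhaustive weighted Voronoi rule: per element, argmin over sources of
# ||centroid - p_i|| / c_i, ties to the smallest source id. Also reports
# which elements are exact ties.
oracle_voronoi <- function(mesh, sources) {
  m <- nrow(mesh$centroid)
  best <- integer(m)
  tie <- logical(m)
  for (e in seq_len(m)) {
    costs <- vapply(seq_len(nrow(sources)), function(si) {
      sqrt(sum((mesh$centroid[e, ] -
                  c(sources$x[si], sources$y[si], sources$z[si]))^2)) /
        sources$speed[si]
    }, numeric(1))
    w <- which(costs == min(costs))
    best[e] <- sources$id[w[1]]
    tie[e] <- length(w) > 1
  }
  list(assign = best, tie = tie)
}

# Poiseuille pressure drop in mmHg for radius/length in cm, mu in g/cm/s,
# flow in cm^3/s.
oracle_poiseuille_mmHg <- function(r_cm, L_cm, mu, q_cgs) {
  8 * mu * L_cm * q_cgs / (pi * r_cm^4) / 1333.22
}

# conductance in (mL/min)/mmHg from mm geometry, for building oracle edges
g_mLmin_per_mmHg <- function(r_mm, L_mm, mu = 0.04) {
  g_cgs <- pi * (r_mm / 10)^4 / (8 * mu * (L_mm / 10))
  g_cgs * 1333.22 * 60
}
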
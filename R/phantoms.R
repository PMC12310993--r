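# Deterministic synthetic geometry: toy vascular networks (including a
# circle-of-Willis-like loop) and labeled box tissue phantoms, so every other
# module is testable without external data.
#
# The tissue phantom is a structured lattice split into 6 tetrahedra per cell
# (Kuhn triangulation, conforming across cells), built on the x >= 0 half and
# mirrored across x = 0 so that left/right symmetry is exact to the bit —
# mirrored elements have identical volumes, centroid distances and class
# labels. The domain is convex (jitter, when requested, moves interior nodes
# only), as required by the Euclidean-rule equivalence checks.

#' Structured tetrahedral box phantom
#'
#' @param xlim,ylim,zlim box extents, mm (`xlim` must be symmetric about 0
#'   when `mirror = TRUE`).
#' @param nx,ny,nz lattice cells per axis (`nx` even when mirrored).
#' @param layout `"shell_core"` (elements whose centroid lies within
#'   `shell_mm` of the box boundary are `"gray"`, the rest `"white"`) or
#'   `"uniform"` (all `"other"`).
#' @param shell_mm shell thickness for `"shell_core"`.
#' @param jitter interior-node jitter amplitude as a fraction of the smallest
#'   cell edge (0 = regular lattice; keep <= 0.2 to avoid degenerate
#'   elements). Boundary nodes are never moved, so the domain stays convex.
#' @param seed RNG seed for the jitter.
#' @param mirror build the x >= 0 half and mirror it (exact L/R symmetry).
#' @return a [tissue_mesh()].
#' @export
make_tissue_phantom <- function(xlim = c(-24, 24), ylim = c(-18, 18),
                                zlim = c(6, 34), nx = 8, ny = 6, nz = 5,
                                layout = c("shell_core", "uniform"),
                                shell_mm = NULL, jitter = 0, seed = 1L,
                                mirror = TRUE) {
  layout <- match.arg(layout)
  if (mirror) {
    stopifnot(abs(xlim[1] + xlim[2]) < 1e-12, nx %% 2 == 0)
    half <- kuhn_lattice(c(0, xlim[2]), ylim, zlim, nx / 2, ny, nz,
                         jitter, seed)
    mm <- mirror_mesh(half)
    nodes <- mm$nodes; elements <- mm$elements
  } else {
    half <- kuhn_lattice(xlim, ylim, zlim, nx, ny, nz, jitter, seed)
    nodes <- half$nodes; elements <- half$elements
  }
  centroid <- (nodes[elements[, 1], ] + nodes[elements[, 2], ] +
               nodes[elements[, 3], ] + nodes[elements[, 4], ]) / 4
  cls <- if (layout == "uniform") rep("other", nrow(elements)) else {
    sh <- shell_mm %||% (0.26 * min(diff(xlim), diff(ylim), diff(zlim)))
    b <- pmin(pmin(abs(centroid[, 1] - xlim[1]), abs(centroid[, 1] - xlim[2])),
              pmin(abs(centroid[, 2] - ylim[1]), abs(centroid[, 2] - ylim[2])),
              pmin(abs(centroid[, 3] - zlim[1]), abs(centroid[, 3] - zlim[2])))
    ifelse(b <= sh, "gray", "white")
  }
  tissue_mesh(nodes, elements, cls)
}

# 6-tets-per-cell Kuhn split of a structured lattice.
kuhn_lattice <- function(xlim, ylim, zlim, nx, ny, nz, jitter = 0, seed = 1L) {
  xs <- seq(xlim[1], xlim[2], length.out = nx + 1)
  ys <- seq(ylim[1], ylim[2], length.out = ny + 1)
  zs <- seq(zlim[1], zlim[2], length.out = nz + 1)
  nid <- function(i, j, k) i + (nx + 1) * (j - 1 + (ny + 1) * (k - 1))
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  colnames(nodes) <- NULL
  if (jitter > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    h <- jitter * min(diff(xs)[1], diff(ys)[1], diff(zs)[1])
    interior <- !(nodes[, 1] %in% xlim | nodes[, 2] %in% ylim |
                  nodes[, 3] %in% zlim)
    nodes[interior, ] <- nodes[interior, ] +
      matrix(stats::runif(3 * sum(interior), -h, h), ncol = 3)
  }
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ex <- diag(3)
  elements <- matrix(0L, 6 * nx * ny * nz, 4)
  row <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    corner <- c(i, j, k)
    v <- function(off) nid(corner[1] + off[1], corner[2] + off[2],
                           corner[3] + off[3])
    v0 <- v(c(0, 0, 0)); v7 <- v(c(1, 1, 1))
    for (p in seq_len(6)) {
      o1 <- ex[perms[p, 1], ]
      o2 <- o1 + ex[perms[p, 2], ]
      row <- row + 1L
      elements[row, ] <- c(v0, v(o1), v(o2), v7)
    }
  }
  list(nodes = nodes, elements = elements)
}

# Mirror a mesh across x = 0: nodes with x > 0 are duplicated with -x (x = 0
# nodes shared), elements copied with mapped indices; orientation is fixed
# by the tissue_mesh constructor.
mirror_mesh <- function(mesh) {
  nodes <- mesh$nodes
  n <- nrow(nodes)
  on_plane <- nodes[, 1] == 0
  map <- integer(n)
  map[on_plane] <- which(on_plane)
  extra <- nodes[!on_plane, , drop = FALSE]
  extra[, 1] <- -extra[, 1]
  map[!on_plane] <- n + seq_len(sum(!on_plane))
  all_nodes <- rbind(nodes, extra)
  mirrored <- matrix(map[mesh$elements], ncol = 4)
  list(nodes = all_nodes, elements = rbind(mesh$elements, mirrored))
}

# ---- network phantoms ----

# builder for centerline networks
net_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$pts <- list(); env$segs <- list()
  env$np <- 0L; env$ns <- 0L
  env$addp <- function(x, y, z, r) {
    env$np <- env$np + 1L
    env$pts[[env$np]] <- c(env$np, x, y, z, r)
    env$np
  }
  # polyline from existing point `from` to position `to` (or existing point
  # `to_id`), ~2 mm spacing, radius linear from r0 (default: radius at
  # `from`) to r1
  env$chain <- function(from, to = NULL, r1, label = NA, r0 = NULL,
                        to_id = NULL, virtual = FALSE) {
    p0 <- env$pts[[from]]
    r0 <- r0 %||% p0[5]
    if (!is.null(to_id)) to <- env$pts[[to_id]][2:4]
    a <- p0[2:4]
    L <- sqrt(sum((to - a)^2))
    nmid <- max(0L, as.integer(floor(L / 2)) - 1L)
    t <- seq(0, 1, length.out = nmid + 2)[-1]
    if (!is.null(to_id)) t <- t[-length(t)]
    ids <- from
    for (tt in t) {
      p <- a + tt * (to - a)
      ids <- c(ids, env$addp(p[1], p[2], p[3], r0 + tt * (r1 - r0)))
    }
    if (!is.null(to_id)) ids <- c(ids, to_id)
    env$ns <- env$ns + 1L
    env$segs[[env$ns]] <- list(id = env$ns, point_ids = ids, label = label,
                               is_virtual = virtual)
    ids[length(ids)]
  }
  env$build <- function(inlets) {
    pts <- do.call(rbind, env$pts)
    vascular_network(
      data.frame(id = as.integer(pts[, 1]), x = pts[, 2], y = pts[, 3],
                 z = pts[, 4], radius = pts[, 5]),
      env$segs, inlets)
  }
  env
}

#' Synthetic vascular network + tissue phantoms
#'
#' Deterministic toy geometries for development and testing:
#' \describe{
#'   \item{single_segment}{one straight inlet-to-outlet vessel.}
#'   \item{Y_tree}{one parent bifurcating into two equal daughters.}
#'   \item{binary_tree}{a symmetric dyadic tree of the given depth with
#'     cube-root radius tapering.}
#'   \item{toy_cow}{a circle-of-Willis-like network: three inlets (LICA,
#'     RICA, BA), the six measurement segments (L/R `MCA-M1`, `ACA-A1`,
#'     `PCA-P2`), communicating arteries (`ACoA`, `L/RPCoA`) and distal
#'     branch trees reaching into a box tissue phantom overhead. Exactly
#'     mirror-symmetric about x = 0 by construction. Anatomical-variant
#'     toggles: drop communicating arteries, or disconnect the LMCA from all
#'     inlets (an isolated diseased component whose territories are still
#'     tessellated but which refuses a pressure solve).}
#' }
#'
#' @param template phantom template name.
#' @param seed RNG seed (only the optional mesh jitter consumes randomness;
#'   the same seed always reproduces the phantom bit-for-bit).
#' @param depth binary-tree depth.
#' @param acoa,lpcoa,rpcoa include the communicating arteries (toy_cow).
#' @param disconnect_lmca detach the LMCA tree from the inlets (toy_cow).
#' @param tissue build the companion tissue phantom.
#' @param tissue_layout,jitter,nx,ny,nz passed to [make_tissue_phantom()].
#' @param spacing centerline resampling spacing, mm (`NULL` to skip).
#' @return list with `network`, `mesh` (or `NULL`), `template`, `seed`.
#' @export
make_phantom <- function(template = c("toy_cow", "single_segment", "Y_tree",
                                      "binary_tree"),
                         seed = 1L, depth = 3L,
                         acoa = TRUE, lpcoa = TRUE, rpcoa = TRUE,
                         disconnect_lmca = FALSE,
                         tissue = TRUE,
                         tissue_layout = "shell_core", jitter = 0,
                         nx = 8, ny = 6, nz = 5, spacing = 0.5) {
  template <- match.arg(template)
  b <- net_builder()
  box <- NULL
  if (template == "single_segment") {
    p0 <- b$addp(0, 0, -10, 1.0)
    b$chain(p0, c(0, 0, 10), 1.0, label = "TRUNK")
    net <- b$build(inlets = p0)
    box <- list(xlim = c(-10, 10), ylim = c(-8, 8), zlim = c(4, 16))
  } else if (template == "Y_tree") {
    p0 <- b$addp(0, 0, -10, 1.2)
    j <- b$chain(p0, c(0, 0, 0), 1.2, label = "PARENT")
    b$chain(j, c(-6.3, 0, 9.4), 0.8, label = "LEFT")
    b$chain(j, c(6.3, 0, 9.4), 0.8, label = "RIGHT")
    net <- b$build(inlets = p0)
    box <- list(xlim = c(-12, 12), ylim = c(-8, 8), zlim = c(4, 16))
  } else if (template == "binary_tree") {
    p0 <- b$addp(0, 0, -12, 1.6)
    root <- b$chain(p0, c(0, 0, 0), 1.6, label = "ROOT")
    grow_tree(b, root, depth, angle = pi / 5, len = 10, r = 1.6 * 2^(-1 / 3),
              dir = c(0, 0, 1), name = "B")
    net <- b$build(inlets = p0)
    box <- list(xlim = c(-22, 22), ylim = c(-8, 8), zlim = c(2, 30))
  } else {
    net <- build_toy_cow(b, acoa, lpcoa, rpcoa, disconnect_lmca)
    box <- list(xlim = c(-24, 24), ylim = c(-18, 18), zlim = c(6, 34))
  }
  if (!is.null(spacing)) net <- resample_centerline(net, spacing)
  mesh <- NULL
  if (tissue) {
    mesh <- make_tissue_phantom(box$xlim, box$ylim, box$zlim, nx, ny, nz,
                                layout = tissue_layout, jitter = jitter,
                                seed = seed)
  }
  list(network = net, mesh = mesh, template = template, seed = seed)
}

grow_tree <- function(b, node, depth, angle, len, r, dir, name) {
  if (depth == 0) return(invisible())
  p <- b$pts[[node]][2:4]
  for (s in c(-1, 1)) {
    th <- atan2(dir[1], dir[3]) + s * angle
    d2 <- c(sin(th), 0, cos(th))
    child <- b$chain(node, p + len * d2, r,
                     label = paste0(name, if (s < 0) "l" else "r"))
    grow_tree(b, child, depth - 1, angle, len * 0.75, r * 2^(-1 / 3), d2,
              paste0(name, if (s < 0) "l" else "r"))
  }
}

build_toy_cow <- function(b, acoa, lpcoa, rpcoa, disconnect_lmca) {
  inlets <- integer()
  a1_end <- list()
  for (side in c("L", "R")) {
    sg <- if (side == "L") -1 else 1
    X <- function(x) sg * x
    ica0 <- b$addp(X(8.3), -1.7, -13.5, 2.0)
    inlets <- c(inlets, ica0)
    ica_top <- b$chain(ica0, c(X(8.3), -1.7, 0.5), 2.0,
                       label = paste0(side, "ICA"))
    m1_from <- ica_top
    if (side == "L" && disconnect_lmca) {
      m1_from <- b$addp(X(8.3), -1.7, 1.7, 1.35) # detached stump
    }
    m1 <- b$chain(m1_from, c(X(15.7), -1.3, 2.3), 1.35,
                  label = paste0(side, "MCA-M1"), r0 = 1.35)
    # A1 tapers to the ACoA calibre at x = -/+2.0 so the ACoA spans exactly
    # 4 mm with a constant 0.7 mm radius — its resampled points then mirror
    # onto themselves bitwise
    a1 <- b$chain(ica_top, c(X(2.0), -7.6, 1.9), 0.7,
                  label = paste0(side, "ACA-A1"), r0 = 1.05)
    a1_end[[side]] <- a1
    # MCA distal tree
    m2a <- b$chain(m1, c(X(19.6), -9.2, 15.3), 0.8,
                   label = paste0(side, "MCA-M2a"))
    m2b <- b$chain(m1, c(X(19.2), 6.4, 15.1), 0.8,
                   label = paste0(side, "MCA-M2b"), r0 = 1.35)
    b$chain(m2a, c(X(21.4), -12.5, 26.2), 0.6)
    b$chain(m2a, c(X(14.8), -11.7, 24.9), 0.55, r0 = 0.8)
    b$chain(m2a, c(X(22.8), -6.9, 18.4), 0.38, r0 = 0.4)
    b$chain(m2b, c(X(21.0), 10.3, 26.0), 0.6)
    b$chain(m2b, c(X(14.2), 9.6, 25.3), 0.55, r0 = 0.8)
    # ACA distal
    a2 <- b$chain(a1, c(X(2.6), -13.8, 10.2), 0.9, r0 = 0.95)
    b$chain(a2, c(X(3.4), -15.2, 24.6), 0.6)
    b$chain(a2, c(X(5.9), -11.8, 27.3), 0.55, r0 = 0.9)
    b$chain(a2, c(X(1.3), -16.0, 16.8), 0.35, r0 = 0.38)
    a1_end[[paste0(side, "_ica_top")]] <- ica_top
  }
  # basilar trunk on the midline (self-mirror)
  ba0 <- b$addp(0, 6.3, -13.5, 1.6)
  inlets <- c(inlets, ba0)
  ba_top <- b$chain(ba0, c(0, 6.3, -0.5), 1.6, label = "BA")
  for (side in c("L", "R")) {
    sg <- if (side == "L") -1 else 1
    X <- function(x) sg * x
    p1 <- b$chain(ba_top, c(X(5.2), 6.1, 1.7), 0.85,
                  label = paste0(side, "PCA-P1"), r0 = 0.85)
    p2 <- b$chain(p1, c(X(9.8), 10.4, 4.1), 0.85,
                  label = paste0(side, "PCA-P2"))
    if ((side == "L" && lpcoa) || (side == "R" && rpcoa)) {
      ica_top <- a1_end[[paste0(side, "_ica_top")]]
      b$chain(ica_top, r1 = 0.55, label = paste0(side, "PCoA"),
              r0 = 0.55, to_id = p1)
    }
    b$chain(p2, c(X(12.6), 13.7, 17.9), 0.6, r0 = 0.85)
    b$chain(p2, c(X(7.4), 13.1, 19.6), 0.55, r0 = 0.85)
    b$chain(p2, c(X(13.8), 8.9, 12.2), 0.4, r0 = 0.42)
  }
  if (acoa) {
    b$chain(a1_end[["L"]], r1 = 0.7, label = "ACoA", r0 = 0.7,
            to_id = a1_end[["R"]])
  }
  b$build(inlets = inlets)
}

#' Perturb vessel radii
#'
#' Scales radii (all points, or those of selected points) by a fixed factor
#' or by multiplicative noise `1 + N(0, relative_sd)`; positions are never
#' touched. Tessellation territories are invariant under any such
#' perturbation (they depend on positions and speeds only), while
#' Murray's-law flow splits are not — the desk-scale robustness contrast.
#'
#' @param network a [vascular_network()].
#' @param factor fixed multiplicative factor.
#' @param relative_sd standard deviation of multiplicative Gaussian noise.
#' @param seed RNG seed for the noise.
#' @param point_ids optional subset of point ids to perturb (default: all).
#' @return the perturbed network.
#' @export
perturb_radii <- function(network, factor = 1, relative_sd = 0, seed = 1L,
                          point_ids = NULL) {
  sel <- if (is.null(point_ids)) rep(TRUE, nrow(network$points)) else
    network$points$id %in% point_ids
  r <- network$points$radius
  f <- rep(factor, sum(sel))
  if (relative_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    f <- f * (1 + stats::rnorm(sum(sel), 0, relative_sd))
  }
  r[sel] <- r[sel] * f
  if (any(r <= 0)) {
    stop_perfterra("perturbation produced non-positive radii",
                   class = "perfterra_validation_error")
  }
  network$points$radius <- r
  network
}
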
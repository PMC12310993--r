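test_that("a minimal polyline becomes one segment with two terminal nodes", {
  net <- line_network(cbind(c(0, 5, 10), 0, 0), radii = c(1, 1, 1),
                      seg_points = list(1:3), inlets = integer())
  expect_length(net$segments, 1)
  roles <- node_roles(net)
  expect_equal(nrow(roles), 2)
  expect_true(all(roles$degree == 1))
  expect_setequal(roles$role, "outlet")
})

test_that("three polylines sharing a point form a degree-3 junction", {
  pts <- data.frame(id = 1:4, x = c(0, 0, -5, 5), y = 0,
                    z = c(-10, 0, 8, 8), radius = 1)
  net <- vascular_network(pts, list(
    list(id = 1, point_ids = c(1, 2)),
    list(id = 2, point_ids = c(2, 3)),
    list(id = 3, point_ids = c(2, 4))), inlets = 1L)
  expect_length(net$segments, 3)
  roles <- node_roles(net)
  expect_equal(roles$role[roles$point_id == 2], "junction")
  expect_equal(roles$degree[roles$point_id == 2], 3)
  expect_equal(sum(roles$role == "outlet"), 2)
})

test_that("constructor rejects invalid geometry", {
  pts <- data.frame(id = 1:2, x = 0:1, y = 0, z = 0, radius = c(1, -0.5))
  expect_error(vascular_network(pts, list(list(id = 1, point_ids = 1:2))),
               class = "perfterra_validation_error")
  pts$radius <- c(1, 1)
  expect_error(vascular_network(pts, list(list(id = 1, point_ids = 1L))),
               "fewer than 2", class = "perfterra_validation_error")
  expect_error(vascular_network(pts, list(list(id = 1, point_ids = c(1, 9)))),
               "unknown point ids", class = "perfterra_validation_error")
})

test_that("resampling hits the requested spacing and preserves arclength", {
  net <- line_network(cbind(0, 0, c(0, 10)), radii = c(1, 2))
  rs <- resample_centerline(net, 0.5)
  s <- rs$segments[[1]]
  expect_length(s$point_ids, 21) # 10 mm / 0.5 mm + 1
  pos <- rs$points[match(s$point_ids, rs$points$id), c("x", "y", "z")]
  gaps <- unname(sqrt(rowSums(diff(as.matrix(pos))^2)))
  expect_equal(gaps, rep(0.5, 20), tolerance = 1e-12)
  # radii interpolate linearly: midpoint of 1 -> 2 is 1.5
  mid <- s$point_ids[11]
  expect_equal(rs$points$radius[rs$points$id == mid], 1.5)
  # endpoints exactly preserved
  expect_equal(unlist(rs$points[rs$points$id == s$point_ids[1],
                                c("x", "y", "z")], use.names = FALSE),
               c(0, 0, 0))
  # total arclength preserved
  expect_equal(sum(gaps), 10, tolerance = 1e-12)
})

test_that("resampling at the existing spacing is idempotent", {
  net <- resample_centerline(line_network(cbind(0, 0, c(0, 10)),
                                          radii = c(1, 1)), 0.5)
  again <- resample_centerline(net, 0.5)
  p1 <- net$points[order(net$points$x, net$points$y, net$points$z), ]
  p2 <- again$points[order(again$points$x, again$points$y, again$points$z), ]
  expect_equal(as.matrix(p1[, c("x", "y", "z", "radius")]),
               as.matrix(p2[, c("x", "y", "z", "radius")]),
               tolerance = 1e-9)
})

test_that("spacing larger than a segment keeps its two endpoints", {
  net <- line_network(cbind(c(0, 1, 2), 0, 0), radii = c(1, 1, 1),
                      seg_points = list(1:3))
  rs <- resample_centerline(net, 50)
  expect_length(rs$segments[[1]]$point_ids, 2)
})

test_that("mean segment radius is the arclength-weighted trapezoid", {
  net <- line_network(cbind(0, 0, c(0, 5, 10)), radii = c(0.7, 0.7, 0.7),
                      seg_points = list(1:3))
  expect_equal(mean_segment_radius(net$segments[[1]], net), 0.7)
  # two equal intervals, radii 1,1,3: (1+1)/2 * 1/2 + (1+3)/2 * 1/2 = 1.5
  net2 <- line_network(cbind(0, 0, c(0, 5, 10)), radii = c(1, 1, 3),
                       seg_points = list(1:3))
  expect_equal(mean_segment_radius(net2$segments[[1]], net2), 1.5)
  # unevenly spaced points are weighted by length, not counted
  net3 <- line_network(cbind(0, 0, c(0, 9, 10)), radii = c(1, 1, 3),
                       seg_points = list(1:3))
  expect_equal(mean_segment_radius(net3$segments[[1]], net3),
               (1 * 9 + 2 * 1) / 10)
  # convexity on random profiles
  set.seed(11)
  for (k in 1:10) {
    r <- runif(5, 0.3, 2)
    netr <- line_network(cbind(0, 0, sort(c(0, runif(3, 1, 9), 10))),
                         radii = r, seg_points = list(1:5))
    mr <- mean_segment_radius(netr$segments[[1]], netr)
    expect_gte(mr, min(r))
    expect_lte(mr, max(r))
  }
})

test_that("truncation removes sub-threshold branches with their subtrees", {
  net <- toy_tree()
  expect_identical(truncate_network(net, 0), net) # identity at r_t = 0
  tr <- truncate_network(net, 0.5)
  # branch B (mean r 0.4) and its children go; A side stays
  expect_setequal(seg_label_set(tr), c("TRUNK", "A", "A1", "A2"))
  # brute-force reachability oracle: segments kept iff connected to inlet
  # through segments with mean radius >= 0.5
  keep <- vapply(net$segments, function(s) mean_segment_radius(s, net) >= 0.5,
                 logical(1))
  expect_setequal(seg_label_set(tr),
                  vapply(net$segments[keep], `[[`, character(1), "label"))
  # new distal ends become outlets
  expect_true(all(outlet_nodes(tr) %in% c(4, 5, 6)))
})

test_that("truncation is monotone and outlet counts are non-increasing", {
  net <- toy_cow()$network
  grid <- seq(0, 1, by = 0.25)
  prev <- NULL
  prev_out <- Inf
  for (rt in grid) {
    tr <- truncate_network(net, rt)
    ids <- sort(vapply(tr$segments, `[[`, integer(1), "id"))
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
    nout <- length(outlet_nodes(tr))
    expect_lte(nout, prev_out)
    prev_out <- nout
  }
})

test_that("protected labels survive and disconnection of them errors", {
  net <- toy_tree()
  tr <- truncate_network(net, 0.5, protected = c("B"))
  expect_true("B" %in% seg_label_set(tr))
  # B survives but its sub-threshold children do not
  expect_false("B1" %in% seg_label_set(tr))
  # protecting a leaf whose parent is removed must error
  expect_error(truncate_network(net, 0.5, protected = c("B1")),
               class = "perfterra_constraint_error")
  # excluded labels are exempt from direct removal too
  tr2 <- truncate_network(net, 0.5, excluded = c("B", "B1", "B2"))
  expect_setequal(seg_label_set(tr2),
                  c("TRUNK", "A", "A1", "A2", "B", "B1", "B2"))
})

test_that("full truncation of the toy CoW leaves only near-loop vessels", {
  net <- toy_cow()$network
  protected <- c("LMCA-M1", "RMCA-M1", "LACA-A1", "RACA-A1",
                 "LPCA-P1", "RPCA-P1", "LPCA-P2", "RPCA-P2")
  tr <- truncate_network(net, 1.0, protected = protected)
  labs <- seg_label_set(tr)
  expect_true(all(protected %in% labs))
  # every distal branch is gone: all mean radii >= 1 except protected
  for (s in tr$segments) {
    if (!(s$label %in% protected) && !is.na(s$label)) {
      expect_gte(mean_segment_radius(s, tr), 1.0 - 1e-12)
    }
  }
  expect_lt(length(tr$segments), length(net$segments) / 2)
})

test_that("outlet radii use the distal window or the terminal point", {
  net <- line_network(cbind(0, 0, c(0, 9, 10)), radii = c(2, 1, 0.5),
                      seg_points = list(1:3))
  r_term <- outlet_radii(net, method = "terminal")
  expect_equal(unname(r_term), 0.5)
  r_mean <- outlet_radii(net, method = "distal_mean", window = 1)
  expect_equal(unname(r_mean), 0.75) # trapezoid of 1 -> 0.5 over last 1 mm
})
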
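test_that("axial positions are arc lengths of orthogonal projections", {
  straight <- midvein_axis(rbind(c(0, 0), c(0, 100)))
  expect_equal(axial_position(straight, c(5, 40)), 40)
  expect_equal(axial_position(straight, c(0, 0)), 0)
  expect_equal(axial_position(straight, c(-3, 100)), 100)
  bent <- midvein_axis(rbind(c(0, 0), c(0, 50), c(50, 50)))
  expect_equal(axial_position(bent, c(25, 55)), 75)
  expect_equal(bent$length, 100)
  expect_error(midvein_axis(rbind(c(0, 0), c(0, 0))), "distinct")
})

test_that("side labels follow the tangent-cross-offset sign and flip under reflection", {
  axis <- midvein_axis(rbind(c(0, 0), c(0, 100)))
  org <- tibble::tibble(x = c(-5, 5, -2), y = c(40, 40, 80))
  lab <- assign_sides(axis, org)
  expect_equal(lab$side, ifelse(org$x < 0, "left", "right"))
  mirrored <- assign_sides(axis, transform(org, x = -x))
  expect_true(all(mirrored$side != lab$side))
  expect_warning(onaxis <- assign_sides(axis, tibble::tibble(x = 0, y = 50)),
                 "excluded")
  expect_true(onaxis$excluded)
  expect_true(is.na(onaxis$side))
})

test_that("ordering along the midvein sorts by s and keeps exact opposite ties", {
  org <- tibble::tibble(s = c(30, 10, 20), side = "left", x = 0, y = 0)
  expect_equal(order_along_midvein(org)$s, c(10, 20, 30))
  tie <- tibble::tibble(s = c(10, 10), side = c("right", "left"), x = 0, y = 0)
  out <- order_along_midvein(tie)
  expect_equal(nrow(out), 2)
  expect_equal(out$side, c("left", "right"))  # deterministic tie-break
  expect_equal(out$index, c(0L, 1L))
})

test_that("spacing ratios reproduce the arrangement archetypes", {
  # alternate-like: left 0, right 1, left 2 -> r = 0.5 for the basal vein
  rr <- compute_ratios(toy_origins(c(0, 1, 2), c("left", "right", "left")),
                       metric = "axial")
  v0 <- rr[rr$s == 0, ]
  expect_equal(v0$d_opposite, 1)
  expect_equal(v0$d_same, 2)
  expect_equal(v0$r, 0.5)
  expect_false(v0$irregular)

  # opposite-like: exact pair at s = 0 gives d_opposite = 0, r = 0
  rr <- compute_ratios(
    toy_origins(c(0, 0, 1, 1), c("left", "right", "left", "right")),
    metric = "axial")
  expect_equal(rr$r[rr$s == 0 & rr$defined], c(0, 0))

  # irregular: two successive same-side veins, opposite partner far
  rr <- compute_ratios(toy_origins(c(0, 1, 3), c("left", "left", "right")),
                       metric = "axial")
  v0 <- rr[rr$vein_index == 0, ]
  expect_equal(v0$d_same, 1)
  expect_equal(v0$d_opposite, 3)
  expect_equal(v0$r, 3)
  expect_true(v0$irregular)

  # the most apical vein on each side has no defined ratio
  rr <- compute_ratios(toy_origins(c(0, 1, 2, 3),
                                   rep(c("left", "right"), 2)),
                       metric = "axial")
  expect_false(any(rr$defined[rr$s >= 2]))
  expect_lte(sum(rr$defined), nrow(rr) - 2)
})

test_that("duplicate same-side positions are invalidated with a warning", {
  expect_warning(
    rr <- compute_ratios(toy_origins(c(1, 1, 2), c("left", "left", "right")),
                         metric = "axial", leaf_id = "dup"),
    "dup")
  expect_false(rr$defined[1])
})

test_that("r is invariant under rigid motions, scaling and mirror reflection", {
  set.seed(42)
  p <- synthetic_params(n_pairs = 8, phase = 0.3, jitter_sd = 0.05,
                        irregular_prob = 0.1, lateral_offset = 3, seed = 9)
  leaf <- generate_arrangement(p)
  base_pts <- as.matrix(leaf$origins[, c("x", "y")])
  axis_nodes <- leaf$axis$nodes
  r_of <- function(pts, nodes, metric = "euclidean") {
    l <- list(leaf_id = "t", axis = midvein_axis(nodes),
              origins = tibble::tibble(x = pts[, 1], y = pts[, 2]))
    sort(leaf_ratios(l, metric = metric)$r, na.last = NA)
  }
  r0 <- r_of(base_pts, axis_nodes)
  for (metric in c("euclidean", "axial")) {
    r_ref <- r_of(base_pts, axis_nodes, metric)
    shifted <- r_of(base_pts + 13.7, axis_nodes + 13.7, metric)
    expect_equal(shifted, r_ref, tolerance = 1e-9)
    rot <- r_of(rotate_pts(base_pts, 0.7), rotate_pts(axis_nodes, 0.7), metric)
    expect_equal(rot, r_ref, tolerance = 1e-9)
    scaled <- r_of(base_pts * 3.2, axis_nodes * 3.2, metric)
    expect_equal(scaled, r_ref, tolerance = 1e-9)
    mirrored <- r_of(cbind(-base_pts[, 1], base_pts[, 2]),
                     cbind(-axis_nodes[, 1], axis_nodes[, 2]), metric)
    expect_equal(mirrored, r_ref, tolerance = 1e-9)
  }
  expect_gt(length(r0), 0)
})

test_that("euclidean and axial metrics agree for small lateral offsets", {
  # offsets at 2% of the internode should shift r by at most 0.05
  p_ax <- synthetic_params(n_pairs = 10, phase = 0.3, jitter_sd = 0.03,
                           internode_mean = 100, lateral_offset = 2, seed = 5)
  leaf <- generate_arrangement(p_ax)
  r_eu <- leaf_ratios(leaf, metric = "euclidean")
  r_ax <- leaf_ratios(leaf, metric = "axial")
  both <- r_eu$defined & r_ax$defined
  expect_true(all(abs(r_eu$r[both] - r_ax$r[both]) <= 0.05))
})

test_that("defined ratios are nonnegative and zero only for coincident partners", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    org <- toy_origins(sort(runif(n, 0, 100)),
                       sample(c("left", "right"), n, replace = TRUE))
    rr <- compute_ratios(org, metric = "axial")
    r <- rr$r[rr$defined]
    expect_true(all(r >= 0))
    expect_lte(sum(rr$defined), nrow(rr) - 2)
  }
  # r = 0 exactly iff the opposite partner coincides axially
  rr <- compute_ratios(toy_origins(c(5, 5, 9), c("left", "right", "left")),
                       metric = "axial")
  expect_equal(rr$r[rr$vein_index == 0], 0)
})
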
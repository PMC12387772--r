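test_that("cable length of three collinear nodes spaced 1000 nm is 2 um", {
  sk <- line_skeleton(3, step = 1000)
  expect_equal(cable_length(sk, prune_below = 0), 2.0)
})

test_that("short twigs are pruned, long backbones are kept", {
  # 10 um backbone with a single 1.5 um twig off the middle node
  nodes <- rbind(
    node_df(1:11, c(NA, 1:10), x = (0:10) * 1000, y = 0, z = 0,
            tags = c("soma", rep("", 10))),
    node_df(12:14, c(6L, 12L, 13L), x = 5000, y = c(500, 1000, 1500),
            z = 0))
  sk <- skeleton(1L, "Y", nodes)
  expect_equal(cable_length(sk, prune_below = 2), 10)    # twig removed
  expect_equal(cable_length(sk, prune_below = 0), 11.5)  # vacuous prune
  expect_equal(cable_length(sk, prune_below = 1), 11.5)  # twig above cut
})

test_that("an unbranched skeleton is never pruned away", {
  sk <- line_skeleton(3, step = 500)  # total 1 um < default threshold
  expect_equal(cable_length(sk, prune_below = 2), 1)
})

test_that("a single-node skeleton has zero cable length", {
  sk <- skeleton(1L, "dot", node_df(1L, NA_integer_, 0, 0, 0,
                                    tags = "soma"))
  expect_equal(cable_length(sk), 0)
})

test_that("cable length is invariant under rigid motions", {
  set.seed(12)
  for (i in 1:5) {
    sk <- random_skeleton(30)
    want <- cable_length(sk, prune_below = 2)
    theta <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(theta[1]), -sin(theta[1]), 0,
                   sin(theta[1]), cos(theta[1]), 0, 0, 0, 1), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(theta[2]), -sin(theta[2]),
                   0, sin(theta[2]), cos(theta[2])), 3, 3)
    xyz <- as.matrix(sk$nodes[, c("x", "y", "z")]) %*% (Rz %*% Rx)
    xyz <- sweep(xyz, 2, rnorm(3, 0, 5e4), "+")
    sk$nodes[, c("x", "y", "z")] <- xyz
    expect_equal(cable_length(sk, prune_below = 2), want,
                 tolerance = 1e-6)
  }
})

test_that("smoothing leaves straight lines unchanged and sigma 0 is identity", {
  sk <- line_skeleton(10, step = 800)
  sm <- smooth_skeleton(sk, sigma = 6000)
  expect_equal(sm$nodes$x, sk$nodes$x, tolerance = 1e-9)
  expect_equal(sm$nodes$y, sk$nodes$y, tolerance = 1e-9)
  expect_identical(smooth_skeleton(sk, sigma = 0), sk)
  expect_error(smooth_skeleton(sk, sigma = -1), "sigma")
})

test_that("smoothing never lengthens zig-zag paths (property over 100 paths)", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    nodes <- node_df(seq_len(n), c(NA, seq_len(n - 1)),
                     x = (seq_len(n) - 1) * 1000,
                     y = rnorm(n, 0, 700), z = rnorm(n, 0, 700),
                     tags = c("soma", rep("", n - 1)))
    sk <- skeleton(1L, "zig", nodes)
    before <- cable_length(sk, prune_below = 0)
    after <- cable_length(smooth_skeleton(sk, sigma = 3000),
                          prune_below = 0)
    expect_lte(after, before + 1e-9)
  }
})

test_that("smoothing preserves topology and anchors branch points", {
  sk <- star_skeleton(arms = 3, arm_nodes = 8, step = 600)
  sm <- smooth_skeleton(sk, sigma = 2000)
  expect_identical(sm$nodes$parent_id, sk$nodes$parent_id)
  expect_identical(sm$nodes$node_id, sk$nodes$node_id)
  root <- which(is.na(sk$nodes$parent_id))
  expect_equal(sm$nodes[root, c("x", "y", "z")],
               sk$nodes[root, c("x", "y", "z")])
})

test_that("sholl of an unbranched 10 um line: one crossing until the tip", {
  sk <- line_skeleton(11, step = 1000)  # nodes at 0..10 um
  p <- sholl(sk, step = 1000)
  expect_equal(p$crossings[p$radius <= 9000], rep(1L, 9))
  expect_equal(p$crossings[p$radius == 10000], 0L)
})

test_that("sholl of a 4-arm star counts every arm below the arm length", {
  sk <- star_skeleton(arms = 4, arm_nodes = 5, step = 1000)  # arms 5 um
  p <- sholl(sk, step = 1000)
  expect_equal(p$crossings[p$radius < 5000], rep(4L, 4))
  # near the root, crossings equal the root degree
  p2 <- sholl(sk, step = 100)
  expect_equal(p2$crossings[1], 4L)
})

test_that("sholl equals a brute-force straddle counter on random trees", {
  set.seed(41)
  for (i in 1:5) {
    sk <- random_skeleton(30)
    step <- 600
    p <- sholl(sk, step = step)
    n <- sk$nodes
    root <- n[is.na(n$parent_id), ]
    d <- setNames(sqrt((n$x - root$x)^2 + (n$y - root$y)^2 +
                         (n$z - root$z)^2), n$node_id)
    for (j in seq_len(nrow(p))) {
      r <- p$radius[j]
      cnt <- 0L
      for (k in which(!is.na(n$parent_id))) {
        dd <- sort(c(d[[as.character(n$node_id[k])]],
                     d[[as.character(n$parent_id[k])]]))
        if (dd[1] <= r && dd[2] > r) cnt <- cnt + 1L
      }
      expect_equal(p$crossings[j], cnt)
    }
    expect_true(all(p$crossings[p$radius > max(d)] == 0))
  }
})

test_that("radial density bins synapse distances from the soma", {
  sk <- line_skeleton(4, step = 500)  # nodes at 0, 500, 1000, 1500 nm
  conn <- data.frame(connector_id = 1:3, pre_skeleton = 1L,
                     pre_node = c(2L, 4L, 4L), post_skeleton = 1L,
                     post_node = 1L)
  p <- radial_synapse_density(sk, conn, bin = 1000, role = "pre")
  expect_equal(p$count[1:2], c(1L, 2L))  # 500 -> bin 1; 1500 x2 -> bin 2
  expect_equal(sum(p$count), 3)
  expect_equal(p$density[1:2], c(1 / 3, 2 / 3))
})

test_that("no synapses gives an all-zero profile; fragments are rejected", {
  sk <- line_skeleton(4, step = 500)
  p <- radial_synapse_density(sk, empty_connectors(), role = "post")
  expect_true(all(p$count == 0))
  frag <- skeleton(2L, "frag", node_df(1:2, c(NA, 1L), x = c(0, 500),
                                       y = 0, z = 0))
  expect_error(radial_synapse_density(frag, empty_connectors()),
               "no soma")
})

test_that("class-mean radial density equals an independent histogram oracle", {
  sim <- small_simulation(seed = 14)
  ds <- sim$dataset
  got <- class_radial_density(ds, "interneuron", bin = 2000, role = "pre")
  # oracle: loop over every IN cell and synapse, bin by floor division
  ids <- ds$cells$skeleton_id[ds$cells$cell_class == "interneuron"]
  counts <- matrix(0, nrow(got), length(ids))
  for (k in seq_along(ids)) {
    sk <- ds$skeletons[[as.character(ids[k])]]
    soma <- sk$nodes[sk$nodes$tags == "soma", ]
    rows <- ds$connectors[ds$connectors$pre_skeleton == ids[k], ]
    for (nd in rows$pre_node) {
      p <- sk$nodes[sk$nodes$node_id == nd, ]
      dist <- sqrt((p$x - soma$x)^2 + (p$y - soma$y)^2 +
                     (p$z - soma$z)^2)
      b <- floor(dist / 2000) + 1
      counts[b, k] <- counts[b, k] + 1
    }
  }
  expect_equal(got$mean_count, rowMeans(counts))
})

test_that("polarity: arithmetic, monadic conservation, per-class medians", {
  ds <- dataset_from_edges(pre = c(rep("A", 8), rep("B", 6)),
                           post = c(rep("B", 8), rep("A", 6)))
  pol <- polarity_table(ds)
  a <- pol$records[pol$records$cell_name == "A", ]
  expect_equal(a$n_pre, 8); expect_equal(a$n_post, 6)
  expect_equal(a$pre_fraction, 8 / 14)
  expect_equal(sum(pol$records$n_pre), nrow(ds$connectors))
  expect_equal(sum(pol$records$n_post), nrow(ds$connectors))
})

test_that("monadic conservation holds on every synthetic dataset", {
  for (s in 1:5) {
    ds <- small_simulation(seed = s)$dataset
    pol <- polarity_table(ds)
    expect_equal(sum(pol$records$n_pre), nrow(ds$connectors))
    expect_equal(sum(pol$records$n_post), nrow(ds$connectors))
  }
})
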
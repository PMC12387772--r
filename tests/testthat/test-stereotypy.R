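test_that("homolog pairing handles paired, midline and asymmetric types", {
  cells <- data.frame(
    cell_name = c("Xl", "Xr", "Ym", "Zl"),
    cell_type = c("X", "X", "Y", "Z"),
    side = c("left", "right", "middle", "left"),
    stringsAsFactors = FALSE)
  ph <- pair_homologs(cells)
  expect_equal(ph$pairs$cell_type, "X")
  expect_equal(ph$pairs$left, "Xl")
  expect_equal(ph$pairs$right, "Xr")
  expect_setequal(ph$unpaired$cell_type, c("Y", "Z"))
  expect_equal(ph$unpaired$reason[ph$unpaired$cell_type == "Y"], "middle")
  expect_equal(ph$unpaired$reason[ph$unpaired$cell_type == "Z"],
               "asymmetric")
})

test_that("pairing a synthetic larva reproduces the generator's ground truth", {
  sim <- small_simulation(seed = 2)
  ph <- pair_homologs(sim$dataset$cells)
  gt <- sim$ground_truth$homolog_pairs
  ord <- order(ph$pairs$cell_type)
  expect_equal(ph$pairs[ord, ],
               gt[order(gt$cell_type), c("cell_type", "left", "right")],
               ignore_attr = TRUE)
})

test_that("side matrices assign single-sided synapses to the correct side", {
  cells <- data.frame(
    cell_name = c("Xl", "Xr", "Yl", "Yr"), skeleton_id = 1:4,
    cell_class = "interneuron", cell_type = c("X", "X", "Y", "Y"),
    segment = "head", side = c("left", "right", "left", "right"),
    annotations = "", stringsAsFactors = FALSE)
  sides <- setNames(cells$side, cells$cell_name)
  types <- setNames(cells$cell_type, cells$cell_name)
  classes <- setNames(cells$cell_class, cells$cell_name)
  ds <- dataset_from_edges(pre = "Xl", post = "Yl", classes = classes,
                           sides = sides, types = types,
                           all_cells = cells$cell_name)
  g <- build_connectome(ds, min_synapses = 1)
  # lone X->Y synapse on the left; matrices must not mix sides
  sm <- side_matrices(g, ds$cells)
  expect_equal(sm$left_matrix["X", "Y"], 1)
  expect_equal(sm$right_matrix["X", "Y"], 0)
  expect_error(lr_correlation(sm), "constant")
})

test_that("lr_correlation: identity, exact anticorrelation, error paths", {
  m <- structure(list(types = c("X", "Y"),
                      left_matrix = matrix(c(0, 2, 2, 0), 2),
                      right_matrix = matrix(c(0, 2, 2, 0), 2)),
                 class = "side_matrices")
  expect_identical(lr_correlation(m), 1)
  m$right_matrix <- matrix(c(2, 0, 0, 2), 2)
  expect_equal(lr_correlation(m), -1)
  m$right_matrix <- matrix(1, 2, 2)
  expect_error(lr_correlation(m), "constant")
})

test_that("lr_correlation equals the textbook Pearson formula on noisy fixtures", {
  pearson <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  checked <- 0
  for (s in 1:8) {
    sim <- simulate_larva(cc = connectivity_config(mirror_noise = 0.5),
                          seed = 80 + s)
    g <- build_connectome(sim$dataset, min_synapses = 1)
    sm <- side_matrices(g, sim$dataset$cells)
    expect_equal(lr_correlation(sm),
                 pearson(as.numeric(sm$left_matrix),
                         as.numeric(sm$right_matrix)),
                 tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("side matrices equal a per-synapse tally oracle", {
  sim <- small_simulation(seed = 55, mirror_noise = 0.3)
  ds <- sim$dataset
  g <- build_connectome(ds, min_synapses = 1)
  sm <- side_matrices(g, ds$cells)
  ty <- setNames(ds$cells$cell_type, ds$cells$cell_name)
  sd <- setNames(ds$cells$side, ds$cells$cell_name)
  sk2c <- skeleton_to_cell(ds)
  left <- sm$left_matrix * 0L; right <- sm$right_matrix * 0L
  in_graph <- igraph::V(g)$name
  for (i in seq_len(nrow(ds$connectors))) {
    pre <- sk2c[[as.character(ds$connectors$pre_skeleton[i])]]
    post <- sk2c[[as.character(ds$connectors$post_skeleton[i])]]
    if (!pre %in% in_graph || !post %in% in_graph) next
    t1 <- ty[[pre]]; t2 <- ty[[post]]
    if (is.na(t1) || is.na(t2)) next
    if (!t1 %in% sm$types || !t2 %in% sm$types) next
    if (sd[[pre]] == "left") left[t1, t2] <- left[t1, t2] + 1L
    if (sd[[pre]] == "right") right[t1, t2] <- right[t1, t2] + 1L
  }
  expect_identical(sm$left_matrix, left)
  expect_identical(sm$right_matrix, right)
})

test_that("side matrices are invariant to synapse row order", {
  sim <- small_simulation(seed = 66, mirror_noise = 0.25)
  ds <- sim$dataset
  perm <- ds
  set.seed(2)
  perm$connectors <- perm$connectors[sample(nrow(perm$connectors)), ]
  sm1 <- side_matrices(build_connectome(ds, min_synapses = 1), ds$cells)
  sm2 <- side_matrices(build_connectome(perm, min_synapses = 1),
                       perm$cells)
  expect_identical(sm1$left_matrix, sm2$left_matrix)
  expect_identical(sm1$right_matrix, sm2$right_matrix)
})

test_that("mean left-right correlation decreases with mirror noise", {
  eps <- c(0, 0.5, 1)
  rs <- lapply(eps, function(e) {
    vapply(1:8, function(s) {
      sim <- small_simulation(seed = 200 + s, mirror_noise = e,
                              fragment_fraction = 0)
      g <- build_connectome(sim$dataset, min_synapses = 1)
      # a heavily resampled right side can disconnect into a side-pure
      # component whose matrix is constant; those draws are undefined
      tryCatch(lr_correlation(side_matrices(g, sim$dataset$cells)),
               error = function(e2) NA_real_)
    }, numeric(1))
  })
  expect_true(all(vapply(rs, function(x) sum(!is.na(x)), numeric(1)) >= 5))
  mean_r <- vapply(rs, mean, numeric(1), na.rm = TRUE)
  expect_true(all(diff(mean_r) < 0))
})

test_that("sholl similarity of a skeleton and its mirror image is 1", {
  set.seed(3)
  sk <- random_skeleton(30)
  mirrored <- sk
  mirrored$nodes$x <- -mirrored$nodes$x
  expect_equal(sholl_similarity(sk, mirrored, step = 500), 1)
})

test_that("constant Sholl profiles make similarity undefined", {
  # line and star of equal 10 um radius: profiles [1,1,...] vs [8,8,...]
  a <- line_skeleton(11, step = 1000, name = "lineA")
  b <- star_skeleton(arms = 8, arm_nodes = 10, step = 1000)
  expect_error(sholl_similarity(a, b, step = 1000), "constant")
  single <- skeleton(9L, "dot", node_df(1L, NA_integer_, 0, 0, 0,
                                        tags = "soma"))
  expect_error(sholl_similarity(single, a), "single-node")
})

test_that("sholl similarity matches an independent crossing counter", {
  set.seed(31)
  a <- random_skeleton(25, 1L, "a"); b <- random_skeleton(25, 2L, "b")
  step <- 700
  crossings <- function(sk, radii) {
    n <- sk$nodes
    root <- n[is.na(n$parent_id), ]
    d <- sqrt((n$x - root$x)^2 + (n$y - root$y)^2 + (n$z - root$z)^2)
    names(d) <- n$node_id
    sapply(radii, function(r) {
      cnt <- 0
      for (i in which(!is.na(n$parent_id))) {
        dd <- sort(c(d[[as.character(n$node_id[i])]],
                     d[[as.character(n$parent_id[i])]]))
        if (dd[1] <= r && dd[2] > r) cnt <- cnt + 1
      }
      cnt
    })
  }
  dmax <- function(sk) {
    n <- sk$nodes; root <- n[is.na(n$parent_id), ]
    max(sqrt((n$x - root$x)^2 + (n$y - root$y)^2 + (n$z - root$z)^2))
  }
  radii <- step * seq_len(max(1, ceiling(max(dmax(a), dmax(b)) / step -
                                           1e-9) - 1))
  want <- cor(crossings(a, radii), crossings(b, radii))
  expect_equal(sholl_similarity(a, b, step = step), want,
               tolerance = 1e-12)
})
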
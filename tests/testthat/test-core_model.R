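test_that("minimal SWC input reads into a one-skeleton dataset", {
  d <- withr::local_tempdir()
  writeLines(c("# index type x y z radius parent",
               "1 1 0 0 0 2000 -1",
               "2 0 1000 0 0 50 1",
               "3 0 2000 0 0 50 2"),
             file.path(d, "cellA.swc"))
  write.table(data.frame(connector_id = integer(), pre_skeleton = integer(),
                         pre_node = integer(), post_skeleton = integer(),
                         post_node = integer()),
              file.path(d, "connectors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(cell_name = "cellA", skeleton_id = 1,
                         cell_class = "sensory", cell_type = "t1",
                         segment = "head", side = "left",
                         annotations = ""),
              file.path(d, "annotations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ds <- read_dataset(d, file.path(d, "connectors.tsv"),
                     file.path(d, "annotations.tsv"))
  expect_length(ds$skeletons, 1)
  expect_equal(nrow(ds$connectors), 0)
  expect_true(ds$skeletons[["1"]]$has_soma)
  expect_equal(skeleton_root(ds$skeletons[["1"]]), 1L)
  expect_equal(nrow(validate_dataset(ds)), 0)
})

test_that("a connector referencing an absent skeleton is a hard error naming it", {
  sk <- list(line_skeleton(3, id = 1L, name = "A"))
  cells <- data.frame(cell_name = "A", skeleton_id = 1,
                      cell_class = "sensory", cell_type = "t1",
                      segment = "head", side = "left", annotations = "")
  conn <- data.frame(connector_id = 7L, pre_skeleton = 1L, pre_node = 1L,
                     post_skeleton = 999L, post_node = 1L)
  expect_error(larva_dataset(sk, conn, cells), "999")
  expect_error(larva_dataset(sk, conn, cells), "7")
})

test_that("duplicate cell names are rejected", {
  sk <- list(line_skeleton(2, id = 1L, name = "A"),
             line_skeleton(2, id = 2L, name = "A"))
  cells <- data.frame(cell_name = c("A", "A"), skeleton_id = 1:2,
                      cell_class = "sensory", cell_type = NA,
                      segment = "head", side = "left", annotations = "")
  expect_error(larva_dataset(sk, empty_connectors(), cells), "duplicate")
})

test_that("write_dataset/read_dataset round-trips a synthetic dataset", {
  sim <- small_simulation(seed = 11)
  ds <- sim$dataset
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  ds2 <- read_dataset(d, file.path(d, "connectors.tsv"),
                      file.path(d, "annotations.tsv"))
  expect_setequal(names(ds2$skeletons), names(ds$skeletons))
  for (id in names(ds$skeletons)) {
    a <- ds$skeletons[[id]]; b <- ds2$skeletons[[id]]
    expect_identical(b$cell_name, a$cell_name)
    expect_identical(b$has_soma, a$has_soma)
    expect_equal(b$nodes[, c("node_id", "parent_id", "radius", "tags")],
                 a$nodes[, c("node_id", "parent_id", "radius", "tags")])
    expect_equal(as.matrix(b$nodes[, c("x", "y", "z")]),
                 as.matrix(a$nodes[, c("x", "y", "z")]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(as.data.frame(ds2$connectors), as.data.frame(ds$connectors))
  ord <- match(ds$cells$cell_name, ds2$cells$cell_name)
  expect_equal(ds2$cells[ord, ], ds$cells, ignore_attr = TRUE)
})

test_that("node tags beyond soma survive the round trip", {
  sk <- line_skeleton(3, id = 1L, name = "A")
  sk$nodes$tags[2] <- "ends;uncertain"
  ds <- larva_dataset(list(sk),
                      cells = data.frame(cell_name = "A", skeleton_id = 1,
                                         cell_class = "sensory",
                                         cell_type = "t1", segment = "head",
                                         side = "left", annotations = ""))
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  ds2 <- read_dataset(d, file.path(d, "connectors.tsv"),
                      file.path(d, "annotations.tsv"))
  expect_equal(ds2$skeletons[["1"]]$nodes$tags, sk$nodes$tags)
})

test_that("serialisation is byte-stable across two runs", {
  ds <- small_simulation(seed = 3)$dataset
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds, d1); write_dataset(ds, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("an empty dataset writes empty tables and no SWC files", {
  ds <- larva_dataset(list(),
                      cells = data.frame(cell_name = character(),
                                         skeleton_id = integer(),
                                         cell_class = character(),
                                         cell_type = character(),
                                         segment = character(),
                                         side = character(),
                                         annotations = character()))
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  expect_length(list.files(d, pattern = "\\.swc$"), 0)
  expect_equal(nrow(read.delim(file.path(d, "connectors.tsv"))), 0)
})

test_that("SWC root rows use parent -1", {
  ds <- larva_dataset(list(line_skeleton(3, id = 1L, name = "A")),
                      cells = data.frame(cell_name = "A", skeleton_id = 1,
                                         cell_class = "sensory",
                                         cell_type = NA, segment = "head",
                                         side = "left", annotations = ""))
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  rows <- read.table(file.path(d, "A.swc"))
  expect_equal(sum(rows$V7 == -1), 1)
  expect_equal(rows$V2[rows$V7 == -1], 1)  # soma structure type
})

test_that("validate_dataset finds exactly the injected violations", {
  base <- function() {
    sk <- list(line_skeleton(3, id = 1L, name = "A"),
               line_skeleton(3, id = 2L, name = "B"))
    cells <- data.frame(cell_name = c("A", "B"), skeleton_id = 1:2,
                        cell_class = c("sensory", "fragment"),
                        cell_type = c("t1", NA), segment = c("head", NA),
                        side = c("left", NA), annotations = "")
    conn <- data.frame(connector_id = 1L, pre_skeleton = 1L, pre_node = 2L,
                       post_skeleton = 2L, post_node = 2L)
    larva_dataset(sk, conn, cells)
  }
  expect_equal(nrow(validate_dataset(base())), 0)

  ds <- base()  # parent cycle
  ds$skeletons[["1"]]$nodes$parent_id <- c(3L, 1L, 2L)
  v <- validate_dataset(ds)
  expect_setequal(v$rule, c("single root", "acyclicity"))

  ds <- base()  # connector post_node absent from post_skeleton
  ds$connectors$post_node <- 99L
  v <- validate_dataset(ds)
  expect_equal(v$rule, "endpoint resolution")
  expect_equal(v$entity, "1")

  ds <- base()  # duplicated node id
  ds$skeletons[["1"]]$nodes$node_id <- c(1L, 2L, 2L)
  expect_true("unique node ids" %in% validate_dataset(ds)$rule)

  ds <- base()  # two roots
  ds$skeletons[["1"]]$nodes$parent_id[2] <- NA_integer_
  expect_true("single root" %in% validate_dataset(ds)$rule)

  ds <- base()  # fragment carrying a type and segment
  ds$cells$cell_type[2] <- "t9"; ds$cells$segment[2] <- "head"
  expect_true("fragment annotation" %in% validate_dataset(ds)$rule)

  ds <- base()  # has_soma flag out of sync with tags
  ds$skeletons[["1"]]$has_soma <- FALSE
  expect_true("soma flag" %in% validate_dataset(ds)$rule)
})

test_that("generated datasets validate cleanly (property over seeds)", {
  for (s in 1:5)
    expect_equal(nrow(validate_dataset(small_simulation(seed = s)$dataset)),
                 0, info = paste("seed", s))
})
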
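test_that("point_cloud enforces its invariants", {
  expect_error(point_cloud(numeric(), numeric(), numeric()),
               "at least one point")
  expect_error(point_cloud(1, c(1, 2), 1), "equal length")
  expect_error(point_cloud(NA, 1, 1), "finite")
  expect_error(point_cloud(1, 1, 1, label = "canopy"), "unknown point label")
  pc <- point_cloud(1:3, 1:3, 1:3, label = c("stem", "crown", "ground"))
  expect_equal(n_points(pc), 3L)
})

test_that("XYZ files read, write and round-trip", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("# comment", "0.0 0.0 1.5", "1 2 3", "4 5 6 stem"), f)
  pc <- read_point_cloud(f)
  expect_equal(n_points(pc), 3L)
  expect_equal(pc$z, c(1.5, 3, 6))

  pc2 <- point_cloud(runif(25), runif(25), runif(25),
                     label = sample(c("stem", "crown"), 25, replace = TRUE),
                     tree_id = sample(1:3, 25, replace = TRUE))
  g <- withr::local_tempfile(fileext = ".xyz")
  write_point_cloud(pc2, g)
  back <- read_point_cloud(g)
  expect_equal(back$x, pc2$x, tolerance = 1e-6)
  expect_equal(back$z, pc2$z, tolerance = 1e-6)
  expect_equal(back$label, pc2$label)
  expect_equal(back$tree_id, pc2$tree_id)
})

test_that("malformed XYZ records raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1.0 2.0 3.0", "1.0 2.0"), f)
  expect_error(read_point_cloud(f), "line 2")
  writeLines(c("1.0 2.0 3.0", "1.0 two 3.0"), f)
  expect_error(read_point_cloud(f), "line 2")
  expect_error(read_point_cloud("no/such/file.xyz"), "no such file")
})

test_that("PLY round-trips coordinates and labels", {
  pc <- point_cloud(runif(30), runif(30), runif(30),
                    label = sample(c("stem", "crown", "ground"), 30,
                                   replace = TRUE))
  f <- withr::local_tempfile(fileext = ".ply")
  write_point_cloud(pc, f, format = "ply")
  back <- read_point_cloud(f)
  expect_equal(back$x, pc$x, tolerance = 1e-6)
  expect_equal(back$y, pc$y, tolerance = 1e-6)
  expect_equal(back$z, pc$z, tolerance = 1e-6)
  expect_equal(back$label, pc$label)
})

test_that("binary little-endian PLY vertices are read", {
  f <- withr::local_tempfile(fileext = ".ply")
  con <- file(f, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 2",
               "property float x", "property float y", "property float z",
               "end_header"), con)
  writeBin(as.numeric(c(1, 2, 3, 4, 5, 6)), con, size = 4,
           endian = "little")
  close(con)
  pc <- read_point_cloud(f)
  expect_equal(pc$x, c(1, 4), tolerance = 1e-6)
  expect_equal(pc$z, c(3, 6), tolerance = 1e-6)
})

test_that("LAS input is refused with a capability message", {
  expect_false(has_las_support())
  f <- withr::local_tempfile(fileext = ".las")
  writeLines("not really las", f)
  expect_error(read_point_cloud(f), "LAS/LAZ support")
})

test_that("writing an empty cloud errors", {
  pc <- point_cloud(1, 1, 1)
  expect_error(write_point_cloud(pc[0, ], withr::local_tempfile()),
               "empty")
})

test_that("normalize_heights flattens a horizontal plane to zero", {
  g <- expand.grid(x = seq(0, 10, 0.5), y = seq(0, 10, 0.5))
  pc <- point_cloud(g$x, g$y, rep(5, nrow(g)))
  out <- normalize_heights(pc)
  expect_lt(max(abs(out$z)), 1e-9)
  expect_true(all(out$label == "ground"))
})

test_that("normalize_heights reproduces a sloped plane exactly", {
  # oracle: an exact plane interpolates linearly between per-cell minima
  g <- expand.grid(x = seq(0, 20, 1), y = seq(0, 20, 1))
  pc <- point_cloud(g$x, g$y, 0.1 * g$x)
  out <- normalize_heights(pc, cell_size = 1)
  expect_lt(max(abs(out$z)), 1e-3)
})

test_that("a tree on flat ground keeps its height after normalization", {
  g <- expand.grid(x = seq(0, 12, 0.4), y = seq(0, 12, 0.4))
  ground <- point_cloud(g$x, g$y, rep(2, nrow(g)))
  tree <- make_tree(tree_model(dbh = 20, height = 20), point_spacing = 0.05,
                    seed = 1)
  tree$x <- tree$x + 6; tree$y <- tree$y + 6; tree$z <- tree$z + 2
  pc <- point_cloud(c(ground$x, tree$x), c(ground$y, tree$y),
                    c(ground$z, tree$z))
  out <- normalize_heights(pc)
  expect_equal(max(out$z), 20, tolerance = 0.01)
})

test_that("normalization is idempotent and xy-translation invariant", {
  set.seed(42)
  g <- expand.grid(x = seq(0, 15, 0.7), y = seq(0, 15, 0.7))
  pc <- point_cloud(g$x, g$y, 0.05 * g$x + 0.02 * g$y + runif(nrow(g), 0, 4))
  once <- normalize_heights(pc)
  twice <- normalize_heights(once)
  expect_lt(max(abs(twice$z - once$z)), 1e-6)

  shifted <- point_cloud(pc$x + 123.4, pc$y - 55.6, pc$z)
  out2 <- normalize_heights(shifted)
  expect_lt(max(abs(out2$z - once$z)), 1e-6)
})

test_that("degenerate planar extent falls back to min-z subtraction", {
  pc <- point_cloud(rep(0.1, 50), rep(0.2, 50), seq(3, 10, length.out = 50))
  expect_warning(out <- normalize_heights(pc), "degenerate")
  expect_equal(min(out$z), 0)
})
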
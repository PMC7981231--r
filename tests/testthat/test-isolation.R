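test_that("CHM cells take the per-cell maximum height", {
  pc <- point_cloud(c(0.1, 0.05, 0.15, 1.0), c(0.1, 0.12, 0.08, 1.0),
                    c(15, 3, 7, 2))
  chm <- rasterize_chm(pc, 0.2)
  expect_equal(chm$values[1, 1], 15)          # max of 15, 3, 7
  expect_equal(chm$resolution, 0.2)
  expect_error(rasterize_chm(pc, 0), "positive")
})

test_that("cells without points are nodata", {
  pc <- point_cloud(c(0.1, 2.1), c(0.1, 2.1), c(5, 6))
  chm <- rasterize_chm(pc, 0.2)
  expect_true(is.na(chm$values[5, 5]))
  expect_equal(sum(!is.na(chm$values)), 2L)
})

test_that("a single cone yields one top at its apex", {
  pc <- cone_canopy_cloud(5, 5, 18, 3)
  chm <- rasterize_chm(pc, 0.2)
  tops <- find_tree_tops(chm)
  expect_equal(nrow(tops), 1L)
  expect_lt(abs(tops$x - 5), 0.3)
  expect_lt(abs(tops$y - 5), 0.3)
})

test_that("two cones give two tops matching a brute-force maxima scan", {
  a <- cone_canopy_cloud(3, 5, 18, 2.8)
  b <- cone_canopy_cloud(8, 5, 20, 2.8)
  pc <- point_cloud(c(a$x, b$x), c(a$y, b$y), c(a$z, b$z))
  chm <- rasterize_chm(pc, 0.2)
  tops <- find_tree_tops(chm, smooth = FALSE)
  expect_equal(nrow(tops), 2L)
  expect_equal(sort(round(tops$height)), c(18, 20))
  expect_lt(abs(tops$x[tops$height > 19] - 8), 0.3)

  # oracle: exhaustive window check over every cell
  v <- chm$values
  wfun <- function(h) pmax(0.5, 0.05 * h)
  oracle <- 0L
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    h0 <- v[i, j]
    if (is.na(h0) || h0 < 5) next
    w <- ceiling(wfun(h0) / 0.2)
    ii <- max(1, i - w):min(nrow(v), i + w)
    jj <- max(1, j - w):min(ncol(v), j + w)
    is_max <- TRUE
    for (a2 in ii) for (b2 in jj) {
      if (a2 == i && b2 == j) next
      if (((a2 - i)^2 + (b2 - j)^2) * 0.04 > wfun(h0)^2) next
      h <- v[a2, b2]
      if (is.na(h)) next
      if (h > h0 || (h == h0 && (a2 < i || (a2 == i && b2 < j))))
        is_max <- FALSE
    }
    if (is_max) oracle <- oracle + 1L
  }
  expect_equal(nrow(tops), oracle)
})

test_that("a flat canopy keeps exactly one top under the tie rule", {
  g <- expand.grid(x = seq(0, 4, 0.1), y = seq(0, 4, 0.1))
  pc <- point_cloud(g$x, g$y, rep(10, nrow(g)))
  tops <- find_tree_tops(rasterize_chm(pc, 0.2), smooth = FALSE)
  expect_equal(nrow(tops), 1L)
  expect_equal(tops$i, 1L); expect_equal(tops$j, 1L)
})

test_that("raising min_tree_height never increases the number of tops", {
  set.seed(9)
  st <- make_stand(stand_config("intensive", plot_area = 400), seed = 12,
                   point_spacing = 0.08)
  chm <- rasterize_chm(normalize_heights(st$cloud), 0.2)
  n_prev <- Inf
  for (mth in c(2, 5, 10, 15, 20)) {
    n <- nrow(find_tree_tops(chm, min_tree_height = mth))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("watershed partitions canopy cells, one label per marker", {
  a <- cone_canopy_cloud(3, 5, 18, 2.8)
  b <- cone_canopy_cloud(8, 5, 18, 2.8)
  pc <- point_cloud(c(a$x, b$x), c(a$y, b$y), c(a$z, b$z))
  chm <- rasterize_chm(pc, 0.2)
  tops <- find_tree_tops(chm, smooth = FALSE)
  seg <- watershed_segments(chm, tops)
  expect_equal(length(seg$polygons), nrow(tops))
  canopy <- !is.na(chm$values) & chm$values >= 5
  expect_true(all(seg$labels[canopy] > 0L))     # no gap
  expect_true(all(seg$labels[!canopy & is.na(chm$values)] == 0L))

  # symmetry oracle: two equal interlocking cones split at the midline
  mid_x <- 5.5
  lab <- seg$labels
  xs <- chm$origin[1] + (row(lab) - 0.5) * chm$resolution
  left <- lab[canopy & xs < mid_x - 0.3]
  right <- lab[canopy & xs > mid_x + 0.3]
  expect_equal(length(unique(left)), 1L)
  expect_equal(length(unique(right)), 1L)
  expect_false(unique(left) == unique(right))
})

test_that("one marker claims all canopy cells", {
  pc <- cone_canopy_cloud(5, 5, 18, 3)
  chm <- rasterize_chm(pc, 0.2)
  seg <- watershed_segments(chm, find_tree_tops(chm))
  canopy <- !is.na(chm$values) & chm$values >= 5
  expect_true(all(seg$labels[canopy] == 1L))
  expect_error(watershed_segments(chm, data.frame(x = 99, y = 99)),
               "outside")
})

test_that("points are assigned to the segment containing them", {
  a <- cone_canopy_cloud(3, 5, 18, 2.5)
  b <- cone_canopy_cloud(9, 5, 18, 2.5)
  pc <- point_cloud(c(a$x, b$x), c(a$y, b$y), c(a$z, b$z))
  chm <- rasterize_chm(pc, 0.2)
  seg <- watershed_segments(chm, find_tree_tops(chm, smooth = FALSE))
  probe <- point_cloud(c(3, 9, 50), c(5, 5, 50), c(10, 10, 10))
  out <- assign_points(probe, seg)
  expect_equal(out$tree_id[3], NA_integer_)     # outside all segments
  expect_false(out$tree_id[1] == out$tree_id[2])
})

test_that("well-separated generator trees are segmented accurately", {
  m1 <- tree_model(dbh = 22, height = 20, crown_radius = 1.6,
                   stem_position = c(4, 4))
  m2 <- tree_model(dbh = 18, height = 17, crown_radius = 1.4,
                   stem_position = c(11, 4))
  pc1 <- make_tree(m1, point_spacing = 0.04, seed = 1)
  pc2 <- make_tree(m2, point_spacing = 0.04, seed = 2)
  truth <- c(rep(1L, n_points(pc1)), rep(2L, n_points(pc2)))
  pc <- point_cloud(c(pc1$x, pc2$x), c(pc1$y, pc2$y), c(pc1$z, pc2$z),
                    label = c(pc1$label, pc2$label))
  chm <- rasterize_chm(pc, 0.2)
  tops <- find_tree_tops(chm)
  expect_equal(nrow(tops), 2L)
  seg <- watershed_segments(chm, tops)
  out <- assign_points(pc, seg)
  # map detected ids to truth by the taller top
  id1 <- out$tree_id[which.max(pc$z)]
  pred <- ifelse(out$tree_id == id1, 1L, 2L)
  ok <- !is.na(out$tree_id)
  expect_gte(mean(pred[ok] == truth[ok]), 0.99)
  expect_gte(mean(ok), 0.95)
})

test_that("CHM and segment outlines serialize to ASCII grid and GeoJSON", {
  pc <- cone_canopy_cloud(5, 5, 18, 3)
  chm <- rasterize_chm(pc, 0.2)
  f <- withr::local_tempfile(fileext = ".asc")
  write_chm_asc(chm, f)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], "^ncols")
  expect_match(hdr[5], "^cellsize 0.2")
  seg <- watershed_segments(chm, find_tree_tops(chm))
  g <- withr::local_tempfile(fileext = ".geojson")
  write_segments_geojson(seg, g)
  js <- jsonlite::read_json(g)
  expect_equal(js$type, "FeatureCollection")
  expect_equal(length(js$features), 1L)
})
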
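test_that("circle fit matches a brute-force grid search on noisy rings", {
  set.seed(11)
  th <- runif(100, 0, 2 * pi)
  r_true <- 0.12
  x <- 0.3 + (r_true + rnorm(100, 0, 0.005)) * cos(th)
  y <- -0.1 + (r_true + rnorm(100, 0, 0.005)) * sin(th)
  f <- fit_circle(x, y)
  expect_lt(abs(f$r - r_true), 0.003)
  oracle <- grid_search_circle(x, y)
  expect_lt(abs(f$r - oracle$r), 0.002)
  expect_lt(abs(f$cx - oracle$cx), 0.002)
  expect_error(fit_circle(1:2, 1:2), "at least 3")
})

test_that("a branch-free cylinder is classified almost entirely as stem", {
  pc <- cylinder_cloud(0.10, 12)
  pc$label <- NULL
  out <- classify_stem_points(pc)
  expect_gte(mean(out$label == "stem"), 0.99)
  expect_false(attr(out, "classification_failed"))
})

test_that("generator trees are classified with high recall and precision", {
  m <- tree_model(dbh = 22, height = 20, crown_base_height = 10)
  pc <- make_tree(m, point_spacing = 0.025, seed = 4)
  out <- classify_stem_points(pc)
  below <- pc$z < 10 & pc$label == "stem"
  above <- pc$z >= 10 & pc$label == "crown"
  expect_gte(mean(out$label[below] == "stem"), 0.9)   # stem recall
  expect_gte(mean(out$label[above] == "crown"), 0.9)  # crown precision
})

test_that("a tree with no points near the base is flagged as failed", {
  pc <- cylinder_cloud(0.10, 12)
  pc <- pc[pc$z > 2.5, ]
  pc <- point_cloud(pc$x, pc$y, pc$z)
  expect_warning(out <- classify_stem_points(pc), "failed")
  expect_true(attr(out, "classification_failed"))
  expect_true(all(out$label == "crown"))
})

test_that("taper knots recover a cylinder radius within 2 mm", {
  tp <- fit_taper(cylinder_cloud(0.10, 12))
  expect_true(all(abs(tp$knots$radius_m - 0.10) < 0.002))
  expect_equal(dbh_from_taper(tp), 20, tolerance = 0.2)
})

test_that("taper recovers the analytic cone radius and DBH", {
  pc <- cone_stem_cloud(0.2, 20)
  tp <- fit_taper(pc, top_height = 20)
  expect_equal(tp$radius_fn(10), 0.10, tolerance = 0.005)
  # closed form: 2 * 0.2 * (1 - 1.3/20) * 100 cm = 37.4
  expect_equal(dbh_from_taper(tp), 37.4, tolerance = 0.5)
})

test_that("taper requires at least 3 bins and breast-height coverage", {
  shallow <- cylinder_cloud(0.1, 0.9)
  expect_error(fit_taper(shallow), "fewer than 3")
  high <- cylinder_cloud(0.1, 12)
  high <- point_cloud(high$x, high$y, high$z + 2,
                      label = rep("stem", n_points(high)))
  tp <- fit_taper(high, top_height = 14)
  expect_true(is.na(dbh_from_taper(tp)))    # taper starts at 2 m
})

test_that("stem volume matches closed forms for cylinder and cone", {
  tp_cyl <- fit_taper(cylinder_cloud(0.10, 10), top_height = 10)
  expect_equal(stem_volume_from_taper(tp_cyl), 1000 * pi * 0.01 * 10,
               tolerance = 0.01 * 314.2)
  tp_cone <- fit_taper(cone_stem_cloud(0.2, 20), top_height = 20)
  v_true <- 1000 * pi * 0.04 * 20 / 3
  expect_equal(stem_volume_from_taper(tp_cone), v_true,
               tolerance = 0.02 * v_true)
  # discretization convergence: halving the slice changes little
  v1 <- stem_volume_from_taper(tp_cone, slice = 0.1)
  v2 <- stem_volume_from_taper(tp_cone, slice = 0.05)
  expect_lt(abs(v2 - v1) / v1, 0.005)
  expect_error(stem_volume_from_taper(tp_cone, top_height = -1), "positive")
})

test_that("tree height is the highest non-ground point", {
  pc <- point_cloud(c(0, 1, 2), c(0, 1, 2), c(7, 3, 1))
  expect_equal(tree_height(pc), 7)
  pc2 <- point_cloud(c(0, 1), c(0, 1), c(7, 30),
                     label = c("crown", "ground"))
  expect_equal(tree_height(pc2), 7)
  # adding a lower point never changes the result
  pc3 <- rbind(pc, data.frame(x = 0, y = 0, z = 0.5))
  expect_equal(tree_height(pc3), 7)
})

test_that("crown hull metrics match unit-square and unit-cube geometry", {
  sq <- point_cloud(c(0, 1, 0, 1), c(0, 0, 1, 1), c(2, 3, 4, 5))
  cm <- crown_metrics(sq)
  expect_equal(cm$crown_projection_area_m2, 1.0)
  expect_equal(cm$crown_width_m, sqrt(2))
  cube <- point_cloud(c(0, 1, 0, 1, 0, 1, 0, 1),
                      c(0, 0, 1, 1, 0, 0, 1, 1),
                      c(0, 0, 0, 0, 1, 1, 1, 1))
  cm2 <- crown_metrics(cube)
  expect_equal(cm2$crown_volume_m3, 1.0, tolerance = 1e-9)
  expect_equal(cm2$crown_surface_area_m2, 6.0, tolerance = 1e-9)
})

test_that("hull area is monotone under taking subsets", {
  set.seed(21)
  pc <- point_cloud(runif(100), runif(100), runif(100))
  full <- crown_metrics(pc)$crown_projection_area_m2
  for (k in 1:5) {
    idx <- sample(100, 40)
    sub <- crown_metrics(pc[idx, ])$crown_projection_area_m2
    expect_lte(sub, full + 1e-12)
  }
})

test_that("degenerate crown point sets yield missing values with a reason", {
  line <- point_cloud(1:5, 1:5, 1:5)
  cm <- crown_metrics(line)
  expect_true(is.na(cm$crown_volume_m3))
  expect_match(cm$reason, "degenerate|collinear")
  two <- crown_metrics(point_cloud(1:2, 1:2, 1:2))
  expect_true(is.na(two$crown_projection_area_m2))
})

test_that("benefit-to-cost ratio converts stem volume to cubic meters", {
  expect_equal(benefit_to_cost(60, 400), 150)
  expect_equal(benefit_to_cost(120, 400), 300)   # doubling surface doubles
  expect_true(is.na(benefit_to_cost(60, 0)))
})

test_that("growth attributes reproduce the observed increments", {
  field <- data.frame(
    site = "S1", plot = "P1", tree_id = c(1, 1, 2),
    occasion = c("first", "last", "first"),
    dbh_cm = c(17.6, 22.2, 15), height_m = c(14.7, 20.0, 12),
    volume_dm3 = c(202.7, 408.3, 100))
  g <- growth_attributes(field)
  expect_equal(g$growth_dbh_cm[1], 4.6)
  expect_equal(g$growth_height_m[1], 5.3)
  expect_equal(g$growth_volume_dm3[1], 205.6)
  expect_equal(g$dH_over_DBH[1], 5.3 / 22.2)
  expect_true(all(is.na(g[g$tree_id == 2, -1])))  # single occasion
  g2 <- growth_attributes(field, dhdbh_denominator = "first")
  expect_equal(g2$dH_over_DBH[1], 5.3 / 17.6)
})

test_that("attributes are recovered across the size range", {
  # spans the observed DBH/height range of the survivor distributions
  cases <- data.frame(dbh = c(14, 22, 34), height = c(15, 21, 29))
  for (i in seq_len(nrow(cases))) {
    m <- tree_model(dbh = cases$dbh[i], height = cases$height[i])
    pc <- make_tree(m, point_spacing = 0.02, seed = 30 + i)
    cl <- classify_stem_points(pc)
    tp <- fit_taper(cl, top_height = tree_height(cl))
    truth <- true_attributes(m)
    expect_lt(abs(dbh_from_taper(tp) - truth$dbh_cm), 1)
    expect_lt(abs(tree_height(cl) - truth$height_m), 0.1)
    expect_lt(abs(stem_volume_from_taper(tp) / truth$stem_volume_dm3 - 1),
              0.05)
    cm <- crown_metrics(cl)
    expect_lt(abs(cm$crown_projection_area_m2 /
                    truth$crown_projection_area_m2 - 1), 0.10)
    # taper radii non-increasing for cone-family stems
    expect_true(all(diff(tp$knots$radius_m) < 0.01))
  }
})

test_that("tree_attributes assembles the full per-tree row", {
  m <- tree_model(dbh = 20, height = 18)
  pc <- make_tree(m, point_spacing = 0.03, seed = 2)
  row <- tree_attributes(pc)
  expect_equal(row$dbh_cm, 20, tolerance = 1)
  expect_equal(row$height_m, 18, tolerance = 0.1)
  expect_equal(row$benefit_to_cost,
               row$crown_surface_area_m2 / (row$stem_volume_dm3 / 1000))
  expect_gt(row$box_dimension, 1); expect_lt(row$box_dimension, 3)
  expect_gte(row$box_r_squared, 0.97)
})
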
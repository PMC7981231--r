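#' Geometric reference objects with known box dimension
#'
#' Generates point-cloud fixtures whose box-counting dimension is known
#' analytically: a thin vertical pole (dimension 1), a vertical plane
#' (dimension 2), a solid cube (dimension 3) and a Menger sponge
#' (dimension ln 20 / ln 3 ~ 2.727, the classical upper bound assumed for
#' tree crowns).
#'
#' @param kind `"pole"`, `"cube"`, `"plane"` or `"menger"`.
#' @param size edge length / height of the object in meters.
#' @param detail sampling density: number of points for `pole`, points per
#'   grid axis for `cube` and `plane`, points per retained smallest subcube
#'   for `menger`. Defaults: 20000 / 48 / 250 / 5.
#' @param level Menger recursion depth (1--4; deeper levels are refused
#'   because the subcube count grows as 20^level).
#' @param seed integer seed controlling all sampling jitter.
#' @param radius pole radius, m (default size/2000; must be <= size/100).
#' @return A [point_cloud()] occupying `[0, size]` in z.
#' @examples
#' sponge <- make_primitive("menger", size = 1, level = 2, seed = 1)
#' @export
make_primitive <- function(kind = c("pole", "cube", "plane", "menger"),
                           size = 1, detail = NULL, level = 3L, seed = 1L,
                           radius = NULL) {
  kind <- match.arg(kind)
  if (size <= 0) stop("size must be positive")
  set.seed(as.integer(seed))
  switch(kind,
    pole = {
      n <- if (is.null(detail)) 20000L else as.integer(detail)
      r <- if (is.null(radius)) size / 5000 else radius
      if (r > size / 100) stop("pole radius must not exceed size/100")
      z <- seq(0, size, length.out = n)
      # a gentle 1% sweep keeps the object pole-like while avoiding the
      # degenerate case of a perfectly symmetric vertical axis sitting
      # exactly on a corner of every counting grid (which inflates the
      # slope); the quadratic form keeps the axis' grid crossings away
      # from dyadic slab boundaries
      drift_x <- size / 100 * (z / size)^2
      drift_y <- size / 100 * (z / size)^3
      th <- stats::runif(n, 0, 2 * pi)
      point_cloud(r * cos(th) + drift_x, r * sin(th) + drift_y, z)
    },
    cube = {
      n <- if (is.null(detail)) 48L else as.integer(detail)
      g <- (seq_len(n) - 1) / n
      idx <- expand.grid(x = g, y = g, z = g)
      m <- nrow(idx)
      point_cloud((idx$x + stats::runif(m) / n) * size,
                  (idx$y + stats::runif(m) / n) * size,
                  (idx$z + stats::runif(m) / n) * size)
    },
    plane = {
      n <- if (is.null(detail)) 250L else as.integer(detail)
      g <- (seq_len(n) - 1) / n
      idx <- expand.grid(x = g, z = g)
      m <- nrow(idx)
      point_cloud((idx$x + stats::runif(m) / n) * size,
                  rep(size / 2, m),
                  (idx$z + stats::runif(m) / n) * size)
    },
    menger = {
      level <- as.integer(level)
      if (level < 1L) stop("menger level must be >= 1")
      if (level > 4L) stop("menger level > 4 refused: point count explodes")
      k <- if (is.null(detail)) 5L else as.integer(detail)
      corners <- menger_corners(level)     # in [0,1), edge 3^-level
      w <- 3^(-level)
      m <- nrow(corners)
      px <- rep(corners[, 1], each = k) + stats::runif(m * k) * w
      py <- rep(corners[, 2], each = k) + stats::runif(m * k) * w
      pz <- rep(corners[, 3], each = k) + stats::runif(m * k) * w
      # pin the global extremes so the initial box aligns with the fractal
      px <- c(px, 0, 1); py <- c(py, 0, 1); pz <- c(pz, 0, 1)
      point_cloud(px * size, py * size, pz * size)
    })
}

# min corners (unit cube) of the 20^level retained Menger subcubes
menger_corners <- function(level) {
  digit <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  digit <- digit[rowSums(digit == 1L) <= 1L, , drop = FALSE]  # 20 of 27
  corners <- matrix(0L, nrow = 1, ncol = 3)
  for (l in seq_len(level)) {
    n <- nrow(corners); d <- nrow(digit)
    corners <- corners[rep(seq_len(n), each = d), , drop = FALSE] * 3L +
      digit[rep(seq_len(d), times = n), , drop = FALSE]
  }
  corners / 3^level
}

#' Parametric individual-tree model
#'
#' Describes one synthetic conifer: a stem with power-law taper
#' `r(h) = r0 * (1 - h/H)^taper_exponent` calibrated so the diameter at
#' 1.3 m equals `dbh`, and a conical crown envelope from
#' `crown_base_height` to the tip populated by whorls of straight branches.
#'
#' @param dbh stem diameter at breast height, cm.
#' @param height tree height, m.
#' @param crown_base_height height of the lowest live branch, m
#'   (default 0.55 * height).
#' @param crown_radius maximal crown radius, m (default `0.55 + 0.06*dbh`,
#'   a generic even-aged pine allometry).
#' @param taper_exponent 0 = cylinder, 1 = cone (default 1).
#' @param whorl_spacing vertical distance between branch whorls, m.
#' @param stem_position (x, y) of the stem foot, m.
#' @return A `tree_model` list.
#' @export
tree_model <- function(dbh = 20, height = 18, crown_base_height = NULL,
                       crown_radius = NULL, taper_exponent = 1,
                       whorl_spacing = 0.4, stem_position = c(0, 0)) {
  if (dbh <= 0) stop("dbh must be positive")
  if (height <= 1.3) stop("height must exceed breast height (1.3 m)")
  if (is.null(crown_base_height)) crown_base_height <- 0.55 * height
  if (is.null(crown_radius)) crown_radius <- 0.55 + 0.06 * dbh
  if (crown_base_height <= 0 || crown_base_height >= height)
    stop("crown_base_height must lie strictly between 0 and height")
  if (crown_radius <= 0) stop("crown_radius must be positive")
  r0 <- (dbh / 200) / (1 - 1.3 / height)^taper_exponent
  structure(list(dbh = dbh, height = height,
                 crown_base_height = crown_base_height,
                 crown_radius = crown_radius,
                 taper_exponent = taper_exponent,
                 whorl_spacing = whorl_spacing,
                 stem_position = as.numeric(stem_position),
                 base_radius = r0),
            class = "tree_model")
}

# stem radius of a tree_model at height h (vectorized)
model_stem_radius <- function(model, h) {
  frac <- pmax(0, 1 - h / model$height)
  model$base_radius * frac^model$taper_exponent
}

# crown envelope radius at height h: cone from crown base to tip
model_crown_radius <- function(model, h) {
  ifelse(h < model$crown_base_height | h > model$height, 0,
         model$crown_radius * (model$height - h) /
           (model$height - model$crown_base_height))
}

# branch tip layout of a tree: whorl heights and deterministic azimuths.
# Used both by the sampler and by the analytic ground-truth attributes.
model_branch_tips <- function(model, n_branches = 6L) {
  zw <- seq(model$crown_base_height, model$height - 0.2,
            by = model$whorl_spacing)
  if (!length(zw)) zw <- model$crown_base_height
  golden <- pi * (3 - sqrt(5))
  tips <- do.call(rbind, lapply(seq_along(zw), function(w) {
    th <- golden * w + 2 * pi * (seq_len(n_branches) - 1) / n_branches
    R <- model_crown_radius(model, zw[w])
    cbind(x = model$stem_position[1] + R * cos(th),
          y = model$stem_position[2] + R * sin(th),
          z = zw[w])
  }))
  as.data.frame(tips)
}

#' Ground-truth attributes of a synthetic tree
#'
#' Closed-form stem attributes (the taper law integrates exactly) and
#' crown attributes computed from the designed branch-tip geometry, for
#' validating the measurement chain against known truth.
#'
#' @param model a [tree_model()].
#' @return one-row data.frame: dbh_cm, height_m, stem_volume_dm3,
#'   crown_width_m, crown_projection_area_m2.
#' @export
true_attributes <- function(model) {
  e <- model$taper_exponent
  vol_m3 <- pi * model$base_radius^2 * model$height / (2 * e + 1)
  tips <- model_branch_tips(model)
  xy <- unique(round(cbind(tips$x, tips$y), 10))
  hull <- grDevices::chull(xy)
  cpa <- polygon_area(xy[hull, 1], xy[hull, 2])
  width <- max_pairwise_distance(xy[hull, 1, drop = TRUE],
                                 xy[hull, 2, drop = TRUE])
  data.frame(dbh_cm = model$dbh, height_m = model$height,
             stem_volume_dm3 = vol_m3 * 1000,
             crown_width_m = width, crown_projection_area_m2 = cpa)
}

#' Sample a TLS-style point cloud from a tree model
#'
#' Stem points are sampled on the taper surface (with millimeter-scale
#' radial noise); crown points along straight whorl branches reaching the
#' conical envelope, with centimeter-scale jitter. Labels record the
#' ground-truth class of every point.
#'
#' @param model a [tree_model()].
#' @param point_spacing target spacing between neighboring samples, m.
#'   Attribute-recovery use assumes <= 0.05 m.
#' @param seed integer seed.
#' @param n_branches branches per whorl.
#' @return A labeled [point_cloud()] (`stem`/`crown`).
#' @export
make_tree <- function(model, point_spacing = 0.02, seed = 1L,
                      n_branches = 6L) {
  if (!inherits(model, "tree_model")) stop("model must be a tree_model")
  if (point_spacing <= 0) stop("point_spacing must be positive")
  set.seed(as.integer(seed))
  H <- model$height
  x0 <- model$stem_position[1]; y0 <- model$stem_position[2]

  # stem surface rings
  zs <- seq(0, H - point_spacing / 2, by = point_spacing)
  rs <- model_stem_radius(model, zs)
  m <- pmax(1L, round(2 * pi * rs / point_spacing))
  zz <- rep(zs, m)
  rr <- rep(rs, m) + stats::rnorm(sum(m), 0, 0.003)
  rr[rr < 0] <- 0
  th <- stats::runif(sum(m), 0, 2 * pi)
  stem <- cbind(x0 + rr * cos(th), y0 + rr * sin(th), zz)
  stem <- rbind(stem, c(x0, y0, H))      # apex pins the tree height

  # whorled branches out to the conical envelope
  zw <- seq(model$crown_base_height, H - 0.2, by = model$whorl_spacing)
  if (!length(zw)) zw <- model$crown_base_height
  golden <- pi * (3 - sqrt(5))
  crown <- vector("list", length(zw))
  for (w in seq_along(zw)) {
    R <- model_crown_radius(model, zw[w])
    r_in <- model_stem_radius(model, zw[w])
    if (R <= r_in) next
    th_b <- golden * w + 2 * pi * (seq_len(n_branches) - 1) / n_branches
    npt <- max(2L, ceiling((R - r_in) / point_spacing))
    tfrac <- (seq_len(npt) - 0.0) / npt   # include the branch tip
    rad <- r_in + (R - r_in) * rep(tfrac, times = n_branches)
    ang <- rep(th_b, each = npt)
    n <- length(rad)
    crown[[w]] <- cbind(
      x0 + rad * cos(ang) + stats::rnorm(n, 0, 0.02),
      y0 + rad * sin(ang) + stats::rnorm(n, 0, 0.02),
      zw[w] - 0.1 * (rad - r_in) + stats::rnorm(n, 0, 0.02))
  }
  crown <- do.call(rbind, crown)
  pts <- rbind(stem, crown)
  label <- c(rep("stem", nrow(stem)), rep("crown", NROW(crown)))
  keep <- pts[, 3] >= 0 & pts[, 3] <= H + 0.05
  point_cloud(pts[keep, 1], pts[keep, 2], pts[keep, 3], label = label[keep])
}

#' Stand configuration for the synthetic-plot generator
#'
#' Per-treatment defaults reproduce the study conditions of even-aged
#' managed Scots pine plots: post-thinning stem densities of 1,337 / 716 /
#' 289 stems per hectare for no treatment / moderate / intensive thinning,
#' and survivor DBH/height distributions (mean, SD, range) from the last
#' measurement occasion of the corresponding field inventory, with growth
#' increments matching the observed 13-year deltas. Thinning additionally
#' enlarges surviving crowns (factors 1.0 / 1.15 / 1.3) — released trees
#' keep deeper, wider crowns.
#'
#' @param treatment `"none"`, `"moderate"` or `"intensive"`.
#' @param plot_area plot area in m2 (100--10,000; study plots were
#'   900--1,200 m2).
#' @param stems_per_ha stem density after treatment; default per treatment.
#' @param dbh_mean,dbh_sd,dbh_range DBH distribution (cm), truncated.
#' @param height_mean,height_sd,height_range height distribution (m).
#' @param growth_dbh,growth_height mean 13-year increments (cm, m).
#' @param growth_years years between the two measurement occasions.
#' @param crown_factor crown-radius enlargement of survivors.
#' @param min_spacing hard-core minimum distance between stems, m.
#' @return A `stand_config` list.
#' @export
stand_config <- function(treatment = c("none", "moderate", "intensive"),
                         plot_area = 1000,
                         stems_per_ha = NULL,
                         dbh_mean = NULL, dbh_sd = NULL, dbh_range = NULL,
                         height_mean = NULL, height_sd = NULL,
                         height_range = NULL,
                         growth_dbh = NULL, growth_height = NULL,
                         growth_years = 13, crown_factor = NULL,
                         min_spacing = 1.5) {
  treatment <- match.arg(treatment)
  if (plot_area < 100 || plot_area > 10000)
    stop("plot_area must lie in [100, 10000] m2")
  preset <- switch(treatment,
    moderate = list(n = 716, dm = 22.2, ds = 3.7, dr = c(13.4, 35.3),
                    hm = 21.2, hs = 2.1, hr = c(14.7, 25.9),
                    gd = 4.6, gh = 5.3, cf = 1.15),
    intensive = list(n = 289, dm = 26.4, ds = 3.9, dr = c(17.9, 36.4),
                     hm = 21.2, hs = 1.7, hr = c(18.2, 25.3),
                     gd = 7.1, gh = 4.7, cf = 1.30),
    none = list(n = 1337, dm = 18.7, ds = 5.0, dr = c(6.5, 34.4),
                hm = 20.0, hs = 3.0, hr = c(13.2, 30.3),
                gd = 3.3, gh = 5.3, cf = 1.00))
  cfg <- list(
    treatment = treatment, plot_area = plot_area,
    stems_per_ha = if (is.null(stems_per_ha)) preset$n else stems_per_ha,
    dbh_mean = if (is.null(dbh_mean)) preset$dm else dbh_mean,
    dbh_sd = if (is.null(dbh_sd)) preset$ds else dbh_sd,
    dbh_range = if (is.null(dbh_range)) preset$dr else dbh_range,
    height_mean = if (is.null(height_mean)) preset$hm else height_mean,
    height_sd = if (is.null(height_sd)) preset$hs else height_sd,
    height_range = if (is.null(height_range)) preset$hr else height_range,
    growth_dbh = if (is.null(growth_dbh)) preset$gd else growth_dbh,
    growth_height = if (is.null(growth_height)) preset$gh else growth_height,
    growth_years = growth_years,
    crown_factor = if (is.null(crown_factor)) preset$cf else crown_factor,
    min_spacing = min_spacing)
  if (cfg$stems_per_ha <= 0) stop("stems_per_ha must be positive")
  structure(cfg, class = "stand_config")
}

# truncated-normal draws via inverse CDF (deterministic under set.seed)
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# sequential hard-core placement with bounded retries
hardcore_positions <- function(n, side, min_spacing, max_tries = 200L) {
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    if (tries > max_tries * n)
      stop("hard-core placement failed: density too high for min_spacing = ",
           min_spacing, " m")
    x <- stats::runif(1, 0, side); y <- stats::runif(1, 0, side)
    tries <- tries + 1L
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >=
        min_spacing^2) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic sample plot
#'
#' Draws surviving trees from the configured post-treatment DBH/height
#' distributions, places them with a hard-core (minimum-spacing) point
#' process on a square plot, samples a labeled TLS-style point cloud per
#' tree (plus a ground-point carpet), and builds a two-occasion field
#' table whose first occasion back-dates each tree by the configured
#' growth increments.
#'
#' @param config a [stand_config()].
#' @param seed integer seed; all randomness derives from it.
#' @param site,plot identifiers written to the field table.
#' @param point_spacing sampling density forwarded to [make_tree()]; set
#'   `make_clouds = FALSE` to skip point sampling.
#' @param make_clouds generate point clouds (TRUE) or geometry only.
#' @param ground_spacing spacing of the ground-point carpet, m.
#' @return list with elements `cloud` (labeled [point_cloud()] with
#'   tree_id, or NULL), `trees` (list of [tree_model()]), `truth`
#'   (per-tree ground-truth attribute data.frame) and `field` (the field
#'   table: site, plot, tree_id, treatment, occasion, dbh_cm, height_m,
#'   volume_dm3).
#' @export
make_stand <- function(config, seed = 1L, site = "S1", plot = "P1",
                       point_spacing = 0.05, make_clouds = TRUE,
                       ground_spacing = 0.25) {
  if (!inherits(config, "stand_config")) stop("config must be a stand_config")
  n <- round(config$stems_per_ha * config$plot_area / 10000)
  if (n < 2) stop("expected tree count < 2; enlarge plot_area or density")
  set.seed(as.integer(seed))
  side <- sqrt(config$plot_area)
  pos <- hardcore_positions(n, side, config$min_spacing)
  dbh <- rtnorm(n, config$dbh_mean, config$dbh_sd,
                config$dbh_range[1], config$dbh_range[2])
  rho <- 0.7                              # DBH-height correlation
  hz <- rho * (dbh - config$dbh_mean) / config$dbh_sd +
    sqrt(1 - rho^2) * stats::rnorm(n)
  height <- pmin(pmax(config$height_mean + config$height_sd * hz,
                      config$height_range[1]), config$height_range[2])
  height <- pmax(height, 2)
  cb_frac <- pmin(pmax(stats::rnorm(n, 0.55, 0.03), 0.4), 0.7)
  crad <- (0.55 + 0.06 * dbh) * config$crown_factor
  tree_seeds <- sample.int(.Machine$integer.max %/% 2L, n)

  trees <- lapply(seq_len(n), function(i)
    tree_model(dbh = dbh[i], height = height[i],
               crown_base_height = cb_frac[i] * height[i],
               crown_radius = crad[i],
               stem_position = pos[i, ]))

  # two measurement occasions; first = last minus the growth increment
  g_dbh <- pmax(stats::rnorm(n, config$growth_dbh, 0.8), 0.3)
  g_h <- pmax(stats::rnorm(n, config$growth_height, 0.8), 0.3)
  dbh1 <- pmax(dbh - g_dbh, 1); h1 <- pmax(height - g_h, 1.5)
  field <- rbind(
    data.frame(site = site, plot = plot, tree_id = seq_len(n),
               treatment = config$treatment, occasion = "first",
               dbh_cm = dbh1, height_m = h1,
               volume_dm3 = allometric_volume(dbh1, h1)),
    data.frame(site = site, plot = plot, tree_id = seq_len(n),
               treatment = config$treatment, occasion = "last",
               dbh_cm = dbh, height_m = height,
               volume_dm3 = allometric_volume(dbh, height)))
  field <- field[order(field$tree_id, field$occasion), ]
  rownames(field) <- NULL

  truth <- do.call(rbind, lapply(trees, true_attributes))
  truth <- cbind(data.frame(tree_id = seq_len(n),
                            x = pos[, 1], y = pos[, 2]), truth)

  cloud <- NULL
  if (make_clouds) {
    parts <- lapply(seq_len(n), function(i) {
      pc <- make_tree(trees[[i]], point_spacing = point_spacing,
                      seed = tree_seeds[i])
      pc$tree_id <- i
      pc
    })
    gx <- seq(0, side, by = ground_spacing)
    g <- expand.grid(x = gx, y = gx)
    ground <- point_cloud(g$x, g$y, abs(stats::rnorm(nrow(g), 0, 0.01)),
                          label = rep("ground", nrow(g)))
    ground$tree_id <- NA_integer_
    all <- rbind(do.call(rbind, parts), ground)
    cloud <- as_point_cloud(all)
  }
  list(cloud = cloud, trees = trees, truth = truth, field = field,
       config = config, side = side)
}

# generic conifer stem-volume allometry: form factor 0.5 over the
# breast-height cylinder; dbh in cm, height in m, volume in dm3
allometric_volume <- function(dbh_cm, height_m) {
  0.5 * (pi / 4) * (dbh_cm / 10)^2 * (height_m * 10)
}

#' Remove the smallest trees (thinning from below)
#'
#' @param trees data.frame with a `dbh` (or `dbh_cm`) column.
#' @param fraction fraction of stems to remove, smallest DBH first.
#' @return the surviving rows.
#' @export
thin_from_below <- function(trees, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  d <- if (!is.null(trees$dbh)) trees$dbh else trees$dbh_cm
  if (is.null(d)) stop("trees must have a dbh or dbh_cm column")
  k <- floor(nrow(trees) * fraction)
  if (k == 0) return(trees)
  trees[rank(d, ties.method = "first") > k, , drop = FALSE]
}

#' Simulate observations from the nested two-level treatment model
#'
#' Draws `y = beta[treatment] + a_site + c_plot(site) + e` with one plot
#' per treatment in every site (a split-plot layout), the structure used
#' for parameter-recovery and type-I-error checks of the analysis layer.
#'
#' @param means named treatment means (the fixed cell means).
#' @param sd_site,sd_plot,sd_resid standard deviations of the site random
#'   effect, plot-within-site random effect, and residual.
#' @param n_sites number of sites; each receives one plot per treatment.
#' @param n_trees trees per plot.
#' @param seed integer seed.
#' @return data.frame: site, plot, treatment, y.
#' @export
simulate_nested_trial <- function(means = c(none = 1.4, moderate = 1.5,
                                            intensive = 1.6),
                                  sd_site = 0.02, sd_plot = 0.03,
                                  sd_resid = 0.08, n_sites = 3,
                                  n_trees = 60, seed = 1L) {
  set.seed(as.integer(seed))
  treatments <- names(means)
  a <- stats::rnorm(n_sites, 0, sd_site)
  out <- vector("list", n_sites * length(treatments))
  k <- 0L
  for (i in seq_len(n_sites)) {
    for (t in seq_along(treatments)) {
      k <- k + 1L
      c_ij <- stats::rnorm(1, 0, sd_plot)
      out[[k]] <- data.frame(
        site = sprintf("S%d", i),
        plot = sprintf("S%d_P%d", i, t),
        treatment = treatments[t],
        y = means[[t]] + a[i] + c_ij + stats::rnorm(n_trees, 0, sd_resid))
    }
  }
  do.call(rbind, out)
}
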
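#' Algebraic circle fit with one robust reweighting pass
#'
#' Kasa-style least squares: minimizes the algebraic residual of
#' `x^2 + y^2 - 2ax - 2by - c`, then refits once with Tukey biweights on
#' the radial residuals. Deterministic (no iteration-count ambiguity).
#'
#' @param x,y point coordinates, m.
#' @param weights optional prior weights.
#' @return list(cx, cy, r, rmse, n).
#' @export
fit_circle <- function(x, y, weights = NULL) {
  n <- length(x)
  if (n < 3L) stop("circle fit needs at least 3 points")
  kasa <- function(w) {
    A <- cbind(2 * x, 2 * y, 1)
    b <- x^2 + y^2
    if (!is.null(w)) { A <- A * sqrt(w); b <- b * sqrt(w) }
    sol <- tryCatch(qr.solve(qr(A, tol = 1e-12), b), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    cx <- sol[1]; cy <- sol[2]
    r2 <- sol[3] + cx^2 + cy^2
    if (r2 <= 0) return(NULL)
    list(cx = cx, cy = cy, r = sqrt(r2))
  }
  f <- kasa(weights)
  if (is.null(f)) return(list(cx = mean(x), cy = mean(y), r = NA_real_,
                              rmse = NA_real_, n = n))
  res <- sqrt((x - f$cx)^2 + (y - f$cy)^2) - f$r
  s <- stats::median(abs(res)) / 0.6745
  if (is.finite(s) && s > 0) {
    u <- res / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) >= 3L) {
      f2 <- kasa(if (is.null(weights)) w else w * weights)
      if (!is.null(f2)) f <- f2
    }
  }
  res <- sqrt((x - f$cx)^2 + (y - f$cy)^2) - f$r
  list(cx = f$cx, cy = f$cy, r = f$r,
       rmse = sqrt(mean(res^2)), n = n)
}

#' Classify stem versus crown points of a single tree
#'
#' Iterative bottom-up procedure: starting at the tree base, a circle is
#' fitted in successive height bins to points near the tracked stem
#' center; points within a radial tolerance band of the local circle are
#' stem, the center and radius are carried upward, and the iteration
#' stops when the inlier fraction collapses or the fitted diameter loses
#' continuity. All remaining points are crown. Mirrors the planar/
#' vertical/cylindrical character that distinguishes stem returns from
#' branch and foliage returns.
#'
#' @param pc a height-normalized single-tree [point_cloud()].
#' @param bin_height bin height, m (default 0.5).
#' @param band radial inlier tolerance around the fitted circle, m.
#' @param min_inlier_frac minimum inlier fraction among candidate points
#'   before the track is abandoned.
#' @param max_radius_jump maximum relative radius change between bins.
#' @return the cloud relabeled `stem`/`crown` (`ground` kept), with
#'   attribute `classification_failed` set if no base was found.
#' @export
classify_stem_points <- function(pc, bin_height = 0.5, band = 0.025,
                                 min_inlier_frac = 0.25,
                                 max_radius_jump = 0.5) {
  z <- pc$z
  ground <- if (!is.null(pc$label)) !is.na(pc$label) & pc$label == "ground"
            else rep(FALSE, nrow(pc))
  lab <- ifelse(ground, "ground", "crown")
  base <- !ground & z >= 0.1 & z < 2
  if (!any(base)) {
    out <- point_cloud(pc$x, pc$y, pc$z, label = lab, tree_id = pc$tree_id)
    attr(out, "classification_failed") <- TRUE
    warning("no points below 2 m: stem classification failed; all points crown")
    return(out)
  }
  # seed the track from the base slab: center = median position of the
  # lowest candidates
  zmax <- max(z[!ground])
  bins <- seq(0.1, zmax, by = bin_height)
  cx <- stats::median(pc$x[base]); cy <- stats::median(pc$y[base])
  r_prev <- NA_real_
  for (b in bins) {
    inbin <- !ground & z >= b & z < b + bin_height
    if (!any(inbin)) next
    search <- if (is.na(r_prev)) 0.6 else max(3 * r_prev, r_prev + 0.15)
    d2 <- (pc$x - cx)^2 + (pc$y - cy)^2
    cand <- inbin & d2 <= search^2
    if (sum(cand) < 5L) break
    f <- fit_circle(pc$x[cand], pc$y[cand])
    if (is.na(f$r) || f$r <= 0) break
    if (!is.na(r_prev)) {
      if (abs(f$r - r_prev) > max_radius_jump * max(r_prev, 0.02)) break
      if (sqrt((f$cx - cx)^2 + (f$cy - cy)^2) > max(0.3, r_prev)) break
    }
    rd <- abs(sqrt((pc$x - f$cx)^2 + (pc$y - f$cy)^2) - f$r)
    inl <- cand & rd <= band
    if (sum(inl) / sum(cand) < min_inlier_frac) break
    lab[inl] <- "stem"
    cx <- f$cx; cy <- f$cy; r_prev <- f$r
  }
  out <- point_cloud(pc$x, pc$y, pc$z, label = lab, tree_id = pc$tree_id)
  attr(out, "classification_failed") <- FALSE
  out
}

#' Fit a stem taper curve
#'
#' Per-bin algebraic circle fits of the stem points give (height, radius)
#' knots; knots whose radius jumps more than 30% against the neighboring
#' bin are dropped as outliers; a cubic spline is passed through the
#' surviving knots. Above the last knot the curve tapers linearly to zero
#' radius at the tree top; below the first knot it extends linearly from
#' the first two knots (never below zero).
#'
#' @param pc a classified [point_cloud()]; only `stem` points are used
#'   (all points if unlabeled).
#' @param bin_height vertical bin size, m.
#' @param top_height tree top used for the upper extrapolation; default
#'   the maximum z of the cloud.
#' @return A `taper_curve`: list with `knots` (data.frame height_m,
#'   radius_m, rmse, n), `radius_fn` (vectorized), `top_height`.
#' @export
fit_taper <- function(pc, bin_height = 0.5, top_height = NULL) {
  stem <- if (!is.null(pc$label)) pc[!is.na(pc$label) & pc$label == "stem", ]
          else pc
  if (is.null(top_height)) top_height <- max(pc$z)
  zs <- stem$z
  if (!nrow(stem)) stop("no stem points to fit a taper to")
  bins <- seq(0.1, max(zs), by = bin_height)
  knots <- do.call(rbind, lapply(bins, function(b) {
    sel <- zs >= b & zs < b + bin_height
    if (sum(sel) < 5L) return(NULL)
    f <- fit_circle(stem$x[sel], stem$y[sel])
    if (is.na(f$r) || f$r <= 0) return(NULL)
    data.frame(height_m = mean(zs[sel]), radius_m = f$r,
               rmse = f$rmse, n = f$n)
  }))
  if (is.null(knots) || nrow(knots) < 3L)
    stop("taper failure: fewer than 3 populated bins")
  knots <- knots[order(knots$height_m), ]
  # drop outlier knots against the previous surviving knot: relative
  # jumps beyond 30%, and any radius increase beyond noise level — a
  # conifer stem tapers monotonically above the butt, so an upward jump
  # marks branch contamination of the circle fit
  keep <- rep(TRUE, nrow(knots))
  last <- 1L
  for (i in seq_len(nrow(knots))[-1L]) {
    jump <- abs(knots$radius_m[i] - knots$radius_m[last]) /
      max(knots$radius_m[last], 0.01)
    rise <- knots$radius_m[i] > knots$radius_m[last] * 1.05 + 0.002
    if (jump > 0.30 || rise) keep[i] <- FALSE else last <- i
  }
  knots <- knots[keep, , drop = FALSE]
  if (nrow(knots) < 3L) stop("taper failure: fewer than 3 knots after filtering")
  spl <- stats::splinefun(knots$height_m, knots$radius_m, method = "natural")
  h1 <- knots$height_m[1L]; h2 <- knots$height_m[2L]
  r1 <- knots$radius_m[1L]; r2 <- knots$radius_m[2L]
  hl <- knots$height_m[nrow(knots)]; rl <- knots$radius_m[nrow(knots)]
  radius_fn <- function(h) {
    r <- numeric(length(h))
    lo <- h < h1; hi <- h > hl; mid <- !lo & !hi
    r[mid] <- spl(h[mid])
    r[lo] <- r1 + (r1 - r2) / (h1 - h2) * (h[lo] - h1)
    if (top_height > hl) {
      r[hi] <- rl * pmax(0, (top_height - h[hi]) / (top_height - hl))
    } else r[hi] <- 0
    pmax(r, 0)
  }
  structure(list(knots = knots, radius_fn = radius_fn,
                 top_height = top_height, bin_height = bin_height),
            class = "taper_curve")
}

#' @export
print.taper_curve <- function(x, ...) {
  cat(sprintf("taper curve: %d knots over [%.2f, %.2f] m, top %.2f m\n",
              nrow(x$knots), min(x$knots$height_m), max(x$knots$height_m),
              x$top_height))
  invisible(x)
}

#' Diameter at breast height from a taper curve
#'
#' Twice the taper radius evaluated at 1.30 m, in centimeters. Missing
#' (NA) when the curve does not reach down to breast height.
#'
#' @param taper a [fit_taper()] curve.
#' @return DBH in cm, or NA.
#' @export
dbh_from_taper <- function(taper) {
  if (taper$knots$height_m[1L] > 1.3 + taper$bin_height / 2) return(NA_real_)
  200 * taper$radius_fn(1.3)
}

#' Stem volume by 10-cm cylinder slices of the taper curve
#'
#' @param taper a [fit_taper()] curve.
#' @param top_height stem top, m (default the taper's tree top).
#' @param slice slice height, m (default 0.1).
#' @return volume in dm3.
#' @export
stem_volume_from_taper <- function(taper, top_height = NULL, slice = 0.1) {
  if (is.null(top_height)) top_height <- taper$top_height
  if (top_height <= 0) stop("top_height must be positive")
  mids <- seq(slice / 2, top_height, by = slice)
  r <- taper$radius_fn(mids)
  1000 * sum(pi * r^2 * slice)
}

#' Tree height as the highest normalized point
#'
#' @param pc a height-normalized [point_cloud()]; ground points excluded.
#' @return height in m.
#' @export
tree_height <- function(pc) {
  z <- if (!is.null(pc$label)) pc$z[is.na(pc$label) | pc$label != "ground"]
       else pc$z
  if (!length(z)) return(NA_real_)
  max(z)
}
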
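# shared fixtures and independent oracles

# noise-free surface sampling of a cone-taper stem: r(h) = r0 * (1 - h/H)
cone_stem_cloud <- function(r0, H, dz = 0.02, pts_per_ring = 40,
                            label = "stem") {
  z <- seq(0, H - dz, by = dz)
  r <- r0 * (1 - z / H)
  th <- rep(seq(0, 2 * pi, length.out = pts_per_ring + 1)[-1],
            times = length(z))
  zz <- rep(z, each = pts_per_ring)
  rr <- rep(r, each = pts_per_ring)
  point_cloud(rr * cos(th), rr * sin(th), zz,
              label = rep(label, length(zz)))
}

cylinder_cloud <- function(r, H, dz = 0.02, pts_per_ring = 40) {
  z <- seq(0, H, by = dz)
  th <- rep(seq(0, 2 * pi, length.out = pts_per_ring + 1)[-1],
            times = length(z))
  zz <- rep(z, each = pts_per_ring)
  point_cloud(r * cos(th), r * sin(th), zz,
              label = rep("stem", length(zz)))
}

# independent brute-force box counter: explicit triple-loop enumeration
# over all grid cells intersecting the cloud's bounding box
brute_force_count <- function(pc, origin, edge) {
  lo <- c(min(pc$x), min(pc$y), min(pc$z))
  hi <- c(max(pc$x), max(pc$y), max(pc$z))
  i0 <- floor((lo[1] - origin[1]) / edge); i1 <- floor((hi[1] - origin[1]) / edge)
  j0 <- floor((lo[2] - origin[2]) / edge); j1 <- floor((hi[2] - origin[2]) / edge)
  k0 <- floor((lo[3] - origin[3]) / edge); k1 <- floor((hi[3] - origin[3]) / edge)
  count <- 0L
  for (i in i0:i1) for (j in j0:j1) for (k in k0:k1) {
    inx <- pc$x >= origin[1] + i * edge & pc$x < origin[1] + (i + 1) * edge
    iny <- pc$y >= origin[2] + j * edge & pc$y < origin[2] + (j + 1) * edge
    inz <- pc$z >= origin[3] + k * edge & pc$z < origin[3] + (k + 1) * edge
    if (any(inx & iny & inz)) count <- count + 1L
  }
  count
}

# brute-force circle fit: grid search minimizing sum of squared radial
# residuals (independent of the algebraic fit it checks)
grid_search_circle <- function(x, y, span = 0.05, step = 0.001) {
  cx0 <- mean(x); cy0 <- mean(y)
  best <- NULL; best_ss <- Inf
  for (cx in seq(cx0 - span, cx0 + span, by = step)) {
    for (cy in seq(cy0 - span, cy0 + span, by = step)) {
      d <- sqrt((x - cx)^2 + (y - cy)^2)
      r <- mean(d)
      ss <- sum((d - r)^2)
      if (ss < best_ss) { best_ss <- ss; best <- c(cx, cy, r) }
    }
  }
  list(cx = best[1], cy = best[2], r = best[3])
}

# a conical canopy sampled on a CHM-friendly dense xy grid
cone_canopy_cloud <- function(apex_x, apex_y, height, base_radius,
                              spacing = 0.1) {
  g <- expand.grid(x = seq(apex_x - base_radius, apex_x + base_radius,
                           by = spacing),
                   y = seq(apex_y - base_radius, apex_y + base_radius,
                           by = spacing))
  d <- sqrt((g$x - apex_x)^2 + (g$y - apex_y)^2)
  keep <- d <= base_radius
  z <- height * (1 - d[keep] / base_radius)
  point_cloud(g$x[keep], g$y[keep], pmax(z, 0.01))
}
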
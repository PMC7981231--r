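#' Rasterize a canopy height model
#'
#' Grids the per-cell maximum of normalized point heights at the given
#' resolution (default 0.20 m). Cells without points carry NA. Cell
#' membership is half-open, `[x0 + (i-1)*res, x0 + i*res)`, so every point
#' belongs to exactly one cell.
#'
#' @param pc a height-normalized [point_cloud()].
#' @param resolution cell size in meters.
#' @return A `chm_raster`: list with `values` (matrix, rows = x columns of
#'   the grid, cols = y), `origin`, `resolution`.
#' @export
rasterize_chm <- function(pc, resolution = 0.20) {
  if (resolution <= 0) stop("resolution must be positive")
  x0 <- min(pc$x); y0 <- min(pc$y)
  i <- floor((pc$x - x0) / resolution) + 1L
  j <- floor((pc$y - y0) / resolution) + 1L
  nx <- max(i); ny <- max(j)
  vals <- matrix(NA_real_, nx, ny)
  ord <- order(pc$z, decreasing = TRUE)   # highest point per cell wins
  key <- i + (j - 1L) * nx
  sel <- ord[!duplicated(key[ord])]
  vals[cbind(i[sel], j[sel])] <- pc$z[sel]
  structure(list(values = vals, origin = c(x0, y0), resolution = resolution),
            class = "chm_raster")
}

#' @export
print.chm_raster <- function(x, ...) {
  cat(sprintf("CHM raster: %d x %d cells @ %.2f m, max height %.2f m\n",
              nrow(x$values), ncol(x$values), x$resolution,
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

chm_cell_xy <- function(chm, i, j) {
  cbind(chm$origin[1] + (i - 0.5) * chm$resolution,
        chm$origin[2] + (j - 0.5) * chm$resolution)
}

median3x3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  out <- m
  for (i in seq_len(nx)) {
    ii <- max(1L, i - 1L):min(nx, i + 1L)
    for (j in seq_len(ny)) {
      jj <- max(1L, j - 1L):min(ny, j + 1L)
      v <- m[ii, jj]
      if (!all(is.na(v))) out[i, j] <- stats::median(v, na.rm = TRUE)
    }
  }
  # never invent canopy where there was none
  out[is.na(m)] <- NA_real_
  out
}

#' Detect tree tops with a variable window filter
#'
#' A cell is a tree top iff its (optionally 3x3-median-smoothed) CHM value
#' is at least `min_tree_height` and is not exceeded by any cell whose
#' center lies within the height-dependent window radius; ties are broken
#' by keeping the cell with the smaller (row, col) index.
#'
#' @param chm a [rasterize_chm()] raster.
#' @param window_fn function mapping height (m) to window radius (m);
#'   default `max(0.5, 0.05 * h)`.
#' @param min_tree_height minimum top height, m (default 5).
#' @param smooth apply a single 3x3 median pass before detection.
#' @return data.frame: x, y, height, i, j (one row per top, ordered by
#'   descending height).
#' @export
find_tree_tops <- function(chm, window_fn = function(h) pmax(0.5, 0.05 * h),
                           min_tree_height = 5, smooth = TRUE) {
  v <- chm$values
  if (!any(!is.na(v))) stop("CHM has no populated cells")
  if (smooth) v <- median3x3(v)
  nx <- nrow(v); ny <- ncol(v)
  res <- chm$resolution
  cand <- which(!is.na(v) & v >= min_tree_height, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_tops())
  # cheap prefilter: must be a 3x3 local maximum (with the tie rule)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    keep[r] <- is_window_max(v, i, j, 1L, 1L, res)
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty_tops())
  out <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    w <- window_fn(v[i, j])
    wi <- max(1L, ceiling(w / res))
    out[r] <- is_window_max(v, i, j, wi, wi, res, radius_m = w)
  }
  cand <- cand[out, , drop = FALSE]
  if (!nrow(cand)) return(empty_tops())
  xy <- chm_cell_xy(chm, cand[, 1], cand[, 2])
  tops <- data.frame(x = xy[, 1], y = xy[, 2],
                     height = v[cand], i = cand[, 1], j = cand[, 2])
  tops[order(-tops$height, tops$i, tops$j), , drop = FALSE]
}

empty_tops <- function() {
  data.frame(x = numeric(), y = numeric(), height = numeric(),
             i = integer(), j = integer())
}

# is cell (i,j) the maximum over cells within a circular window?
# Equal values lose to a smaller (row, col) order index elsewhere.
is_window_max <- function(v, i, j, wi, wj, res, radius_m = NULL) {
  nx <- nrow(v); ny <- ncol(v)
  ii <- max(1L, i - wi):min(nx, i + wi)
  jj <- max(1L, j - wj):min(ny, j + wj)
  h0 <- v[i, j]
  for (a in ii) for (b in jj) {
    if (a == i && b == j) next
    if (!is.null(radius_m) &&
        ((a - i)^2 + (b - j)^2) * res^2 > radius_m^2) next
    h <- v[a, b]
    if (is.na(h)) next
    if (h > h0) return(FALSE)
    if (h == h0 && (a < i || (a == i && b < j))) return(FALSE)
  }
  TRUE
}

#' Marker-controlled watershed segmentation of a CHM
#'
#' Floods the CHM downward from the supplied tree tops (watershed by
#' immersion on the inverted surface): cells at or above
#' `min_tree_height` are processed in order of decreasing height and each
#' is attached to the segment of its highest already-labeled 8-neighbor.
#' Every above-threshold cell connected to a marker receives exactly one
#' label.
#'
#' @param chm a [rasterize_chm()] raster.
#' @param tops data.frame from [find_tree_tops()] (columns i, j or x, y).
#' @param min_tree_height canopy threshold, m.
#' @return A `crown_segments` object: list with `labels` (integer matrix,
#'   0 = unsegmented), `tops`, `chm`, `polygons` (per-label convex outline
#'   of cell corners, diagnostic geometry).
#' @export
watershed_segments <- function(chm, tops, min_tree_height = 5) {
  if (NROW(tops) < 1L) stop("at least one tree top (marker) is required")
  v <- chm$values
  nx <- nrow(v); ny <- ncol(v)
  if (is.null(tops$i)) {
    tops$i <- floor((tops$x - chm$origin[1]) / chm$resolution) + 1L
    tops$j <- floor((tops$y - chm$origin[2]) / chm$resolution) + 1L
  }
  if (any(tops$i < 1L | tops$i > nx | tops$j < 1L | tops$j > ny))
    stop("marker outside the raster extent")
  lab <- matrix(0L, nx, ny)
  lab[cbind(tops$i, tops$j)] <- seq_len(nrow(tops))
  mask <- !is.na(v) & v >= min_tree_height
  mask[cbind(tops$i, tops$j)] <- TRUE
  cells <- which(mask)
  ord <- cells[order(v[cells], decreasing = TRUE)]
  # descending flood; regional maxima that are not markers get attached
  # on later sweeps once a labeled neighbor exists
  for (sweep in 1:50) {
    changed <- FALSE
    for (cell in ord) {
      if (lab[cell] != 0L) next
      i <- ((cell - 1L) %% nx) + 1L
      j <- ((cell - 1L) %/% nx) + 1L
      best <- 0L; besth <- -Inf
      for (a in max(1L, i - 1L):min(nx, i + 1L)) {
        for (b in max(1L, j - 1L):min(ny, j + 1L)) {
          l <- lab[a, b]
          if (l == 0L) next
          h <- v[a, b]
          if (is.na(h)) h <- -Inf
          if (h > besth || (h == besth && l < best)) { best <- l; besth <- h }
        }
      }
      if (best != 0L) { lab[cell] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  polys <- segment_polygons(chm, lab)
  structure(list(labels = lab, tops = tops, chm = chm, polygons = polys,
                 min_tree_height = min_tree_height),
            class = "crown_segments")
}

# convex outline of each segment's cell corners (diagnostic/export only;
# point assignment uses exact cell membership)
segment_polygons <- function(chm, lab) {
  res <- chm$resolution
  ids <- sort(unique(lab[lab > 0L]))
  lapply(stats::setNames(ids, paste0("segment_", ids)), function(id) {
    cells <- which(lab == id, arr.ind = TRUE)
    x0 <- chm$origin[1] + (cells[, 1] - 1L) * res
    y0 <- chm$origin[2] + (cells[, 2] - 1L) * res
    corners <- cbind(x = c(x0, x0 + res, x0, x0 + res),
                     y = c(y0, y0, y0 + res, y0 + res))
    hull <- grDevices::chull(corners)
    corners[hull, , drop = FALSE]
  })
}

#' @export
print.crown_segments <- function(x, ...) {
  cat(sprintf("crown segments: %d segments over %d canopy cells\n",
              length(x$polygons), sum(x$labels > 0L)))
  invisible(x)
}

#' Assign cloud points to crown segments
#'
#' Each non-ground point receives the tree id of the segment whose cell
#' footprint contains its (x, y); half-open cells make the assignment
#' unambiguous (a point on a shared boundary belongs to the cell on its
#' upper side, whose label is the one recorded there). Points outside all
#' segments, and ground points, stay unassigned (NA).
#'
#' @param pc a [point_cloud()].
#' @param segments a [watershed_segments()] result.
#' @return the cloud with a `tree_id` column.
#' @export
assign_points <- function(pc, segments) {
  chm <- segments$chm
  lab <- segments$labels
  i <- floor((pc$x - chm$origin[1]) / chm$resolution) + 1L
  j <- floor((pc$y - chm$origin[2]) / chm$resolution) + 1L
  ok <- i >= 1L & i <= nrow(lab) & j >= 1L & j <= ncol(lab)
  id <- rep(NA_integer_, nrow(pc))
  l <- lab[cbind(i[ok], j[ok])]
  l[l == 0L] <- NA_integer_
  id[ok] <- l
  if (!is.null(pc$label)) id[!is.na(pc$label) & pc$label == "ground"] <- NA_integer_
  pc$tree_id <- id
  pc
}

#' Split an assigned plot cloud into single-tree clouds
#'
#' @param pc a [point_cloud()] carrying `tree_id`.
#' @return named list of single-tree `point_cloud`s.
#' @export
split_trees <- function(pc) {
  if (is.null(pc$tree_id)) stop("cloud has no tree_id; run assign_points()")
  ids <- sort(unique(stats::na.omit(pc$tree_id)))
  stats::setNames(lapply(ids, function(k) {
    sub <- pc[!is.na(pc$tree_id) & pc$tree_id == k, , drop = FALSE]
    as_point_cloud(sub)
  }), paste0("tree_", ids))
}

#' Write a CHM as an ESRI ASCII grid
#'
#' @param chm a [rasterize_chm()] raster.
#' @param path destination file.
#' @param nodata no-data marker value.
#' @export
write_chm_asc <- function(chm, path, nodata = -9999) {
  v <- chm$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", nrow(v)),
           sprintf("nrows %d", ncol(v)),
           sprintf("xllcorner %.6f", chm$origin[1]),
           sprintf("yllcorner %.6f", chm$origin[2]),
           sprintf("cellsize %.6f", chm$resolution),
           sprintf("NODATA_value %s", format(nodata)))
  rows <- apply(t(v)[rev(seq_len(ncol(v))), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write crown segment outlines as GeoJSON
#'
#' @param segments a [watershed_segments()] result.
#' @param path destination file.
#' @export
write_segments_geojson <- function(segments, path) {
  feats <- lapply(names(segments$polygons), function(nm) {
    p <- segments$polygons[[nm]]
    ring <- rbind(p, p[1L, , drop = FALSE])
    list(type = "Feature",
         properties = list(id = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(r) as.numeric(ring[r, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
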
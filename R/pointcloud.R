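#' Point cloud objects
#'
#' A `point_cloud` is the package's container for a set of 3D points in a
#' local metric (planar) coordinate frame, optionally carrying a per-point
#' class label (`"ground"`, `"stem"`, `"crown"` or `"unassigned"`) and a
#' per-point integer tree id. It is a plain `data.frame` with columns
#' `x`, `y`, `z` (meters) and optionally `label` and `tree_id`, so all the
#' usual data-frame idioms apply.
#'
#' @param x,y,z numeric coordinate vectors of equal length (meters).
#' @param label optional character vector of per-point classes; one of
#'   `"ground"`, `"stem"`, `"crown"`, `"unassigned"`.
#' @param tree_id optional integer vector of per-point tree ids (NA =
#'   unassigned).
#' @return A `point_cloud` (a `data.frame` subclass).
#' @examples
#' pc <- point_cloud(runif(10), runif(10), runif(10))
#' n_points(pc)
#' @export
point_cloud <- function(x, y, z, label = NULL, tree_id = NULL) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (n < 1L) stop("a point cloud must contain at least one point")
  if (length(y) != n || length(z) != n)
    stop("x, y and z must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("all coordinates must be finite")
  df <- data.frame(x = x, y = y, z = z)
  if (!is.null(label)) {
    if (length(label) != n) stop("label must have one entry per point")
    bad <- setdiff(unique(label), c("ground", "stem", "crown", "unassigned", NA))
    if (length(bad)) stop("unknown point labels: ", paste(bad, collapse = ", "))
    df$label <- as.character(label)
  }
  if (!is.null(tree_id)) {
    if (length(tree_id) != n) stop("tree_id must have one entry per point")
    df$tree_id <- as.integer(tree_id)
  }
  class(df) <- c("point_cloud", "data.frame")
  df
}

#' @rdname point_cloud
#' @param pc a `point_cloud`.
#' @export
n_points <- function(pc) nrow(pc)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points\n", nrow(x)))
  cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f] m\n",
              min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  if (!is.null(x$label))
    cat("  labels: ", paste(sprintf("%s=%d", names(table(x$label)),
                                    table(x$label)), collapse = " "), "\n")
  if (!is.null(x$tree_id))
    cat(sprintf("  trees: %d\n", length(unique(stats::na.omit(x$tree_id)))))
  invisible(x)
}

as_point_cloud <- function(df) {
  point_cloud(df$x, df$y, df$z, label = df$label, tree_id = df$tree_id)
}

#' Is LAS/LAZ input supported in this installation?
#'
#' LAS support requires an external reader which is not bundled; this
#' capability flag lets callers test for it instead of failing mid-run.
#'
#' @return `FALSE` in this build.
#' @export
has_las_support <- function() FALSE

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         xyz = "xyz", txt = "xyz", asc = "xyz",
         ply = "ply",
         las = "las", laz = "las",
         "xyz")
}

#' Read a point cloud from disk
#'
#' Supported formats: whitespace-delimited XYZ text
#' (`x y z [label] [tree_id]`, `#` comments), PLY (ASCII or binary
#' little-endian vertex lists). LAS/LAZ is recognized but unavailable in
#' this build (see [has_las_support()]).
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"xyz"`, `"ply"` or `"las"`.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "ply", "las")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file: ", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         xyz = read_xyz(path),
         ply = read_ply(path),
         las = stop("LAS/LAZ support is not available in this installation ",
                    "(has_las_support() is FALSE); convert to XYZ or PLY"))
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("empty XYZ file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop(sprintf("malformed XYZ record at line %d of %s: need at least x y z",
                 lineno[bad], path))
  }
  m <- lengths(toks)[1L]
  x <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 2L)))
  z <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 3L)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1L]
    stop(sprintf("malformed XYZ record at line %d of %s: non-numeric coordinate",
                 lineno[bad], path))
  }
  label <- NULL; tree_id <- NULL
  if (all(nf >= 4L)) {
    col4 <- vapply(toks, `[`, "", 4L)
    if (all(col4 %in% c("ground", "stem", "crown", "unassigned", "NA"))) {
      label <- ifelse(col4 == "NA", NA_character_, col4)
      if (all(nf >= 5L)) {
        col5 <- vapply(toks, `[`, "", 5L)
        tree_id <- suppressWarnings(as.integer(ifelse(col5 == "NA", NA, col5)))
      }
    } else {
      tree_id <- suppressWarnings(as.integer(ifelse(col4 == "NA", NA, col4)))
    }
  }
  point_cloud(x, y, z, label = label, tree_id = tree_id)
}

#' Write a point cloud to disk
#'
#' @param pc a [point_cloud()].
#' @param path destination file.
#' @param format `"xyz"` or `"ply"` (ASCII).
#' @param digits decimal digits for text output.
#' @export
write_point_cloud <- function(pc, path, format = c("xyz", "ply"), digits = 6L) {
  if (!inherits(pc, "point_cloud")) pc <- as_point_cloud(pc)
  if (nrow(pc) < 1L) stop("refusing to write an empty point cloud")
  format <- match.arg(format)
  if (format == "xyz") {
    fmt <- paste0("%.", digits, "f")
    cols <- list(sprintf(fmt, pc$x), sprintf(fmt, pc$y), sprintf(fmt, pc$z))
    if (!is.null(pc$label)) cols <- c(cols, list(ifelse(is.na(pc$label), "NA", pc$label)))
    if (!is.null(pc$tree_id)) {
      if (is.null(pc$label)) cols <- c(cols, list(rep("unassigned", nrow(pc))))
      cols <- c(cols, list(ifelse(is.na(pc$tree_id), "NA", as.character(pc$tree_id))))
    }
    writeLines(do.call(paste, cols), path)
  } else {
    write_ply(pc, path, digits = digits)
  }
  invisible(path)
}

write_ply <- function(pc, path, digits = 6L) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           "comment written by treecomplexity",
           sprintf("element vertex %d", nrow(pc)),
           "property double x", "property double y", "property double z")
  if (!is.null(pc$label)) {
    # labels encoded as a small integer scalar property
    hdr <- c(hdr, "property uchar label")
  }
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  fmt <- paste0("%.", digits, "f")
  body <- paste(sprintf(fmt, pc$x), sprintf(fmt, pc$y), sprintf(fmt, pc$z))
  if (!is.null(pc$label)) {
    code <- match(pc$label, c("ground", "stem", "crown", "unassigned")) - 1L
    code[is.na(code)] <- 3L
    body <- paste(body, code)
  }
  writeLines(body, con)
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; nvert <- NA_integer_
  props <- character(); ptypes <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated PLY header in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (tok[1L] == "format") fmt <- tok[2L]
    else if (tok[1L] == "element") {
      in_vertex <- identical(tok[2L], "vertex")
      if (in_vertex) nvert <- as.integer(tok[3L])
    } else if (tok[1L] == "property" && in_vertex) {
      ptypes <- c(ptypes, tok[2L]); props <- c(props, tok[3L])
    } else if (tok[1L] == "end_header") break
  }
  if (is.na(nvert)) stop("PLY file has no vertex element: ", path)
  need <- c("x", "y", "z")
  if (!all(need %in% props)) stop("PLY vertex element lacks x/y/z in ", path)
  if (identical(fmt, "ascii")) {
    toks <- strsplit(trimws(readLines(con, n = nvert)), "\\s+")
    get <- function(p) as.numeric(vapply(toks, `[`, "", match(p, props)))
    label <- NULL
    if ("label" %in% props) {
      code <- as.integer(vapply(toks, `[`, "", match("label", props)))
      label <- c("ground", "stem", "crown", "unassigned")[code + 1L]
    }
    point_cloud(get("x"), get("y"), get("z"), label = label)
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    sz <- sizes[ptypes]
    if (anyNA(sz)) stop("unsupported PLY property type in ", path)
    stride <- sum(sz)
    raw <- readBin(con, "raw", n = stride * nvert)
    if (length(raw) < stride * nvert) stop("truncated PLY body in ", path)
    offs <- cumsum(c(0L, sz[-length(sz)]))
    read_col <- function(i) {
      idx <- rep(offs[i], nvert) + (seq_len(nvert) - 1L) * stride
      bytes <- raw[as.vector(outer(seq_len(sz[i]), idx, `+`))]
      what <- if (ptypes[i] %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      readBin(bytes, what, n = nvert, size = sz[i], endian = "little")
    }
    x <- read_col(match("x", props))
    y <- read_col(match("y", props))
    z <- read_col(match("z", props))
    point_cloud(x, y, z)
  } else stop("unsupported PLY format '", fmt, "' in ", path)
}

#' Remove topography: normalize point heights above ground
#'
#' Builds a ground model from per-cell minimum elevations on a square grid,
#' interpolates it bilinearly between cell centers (cells without points are
#' filled from the nearest populated cell), and replaces each point's z by
#' its height above that surface. Points ending up below 0.1 m are labeled
#' `"ground"`.
#'
#' @param pc a [point_cloud()].
#' @param cell_size ground-grid cell size in meters (default 1).
#' @param ground_height points below this normalized height are labeled
#'   ground (default 0.1 m).
#' @return A normalized `point_cloud`; `min(z)` is ~0.
#' @export
normalize_heights <- function(pc, cell_size = 1.0, ground_height = 0.1) {
  if (cell_size <= 0) stop("cell_size must be positive")
  ext_x <- diff(range(pc$x)); ext_y <- diff(range(pc$y))
  if (ext_x < cell_size && ext_y < cell_size) {
    warning("degenerate planar extent: falling back to global min-z subtraction")
    z <- pc$z - min(pc$z)
  } else {
    gm <- ground_model(pc, cell_size)
    z <- pc$z - eval_ground(gm, pc$x, pc$y)
    z[z < 0] <- 0
  }
  label <- pc$label
  if (is.null(label)) label <- rep("unassigned", nrow(pc))
  label[z < ground_height & label != "stem" & label != "crown"] <- "ground"
  point_cloud(pc$x, pc$y, z, label = label, tree_id = pc$tree_id)
}

# Ground grid: each cell carries a local plane anchored exactly at the
# cell's lowest point, with its slope estimated by least squares through
# the per-cell minimum points of the 3x3 neighborhood. Anchoring at the
# minimum makes normalization exactly idempotent (the minima map to
# height zero, so a second pass subtracts a zero surface) and the slope
# term reproduces an inclined terrain without the half-cell bias of a
# piecewise-constant minimum filter. Unpopulated cells inherit the plane
# of the nearest populated cell.
ground_model <- function(pc, cell_size) {
  x0 <- min(pc$x); y0 <- min(pc$y)
  ci <- pmax(1L, ceiling((pc$x - x0) / cell_size + 1e-12))
  cj <- pmax(1L, ceiling((pc$y - y0) / cell_size + 1e-12))
  nx <- max(ci); ny <- max(cj)
  key <- ci + (cj - 1L) * nx
  ord <- order(pc$z)                     # lowest point per cell
  sel <- ord[!duplicated(key[ord])]
  minx <- matrix(NA_real_, nx, ny); miny <- minx; minz <- minx
  minx[cbind(ci[sel], cj[sel])] <- pc$x[sel]
  miny[cbind(ci[sel], cj[sel])] <- pc$y[sel]
  minz[cbind(ci[sel], cj[sel])] <- pc$z[sel]
  ax <- matrix(NA_real_, nx, ny); ay <- ax
  max_slope <- 2                         # sanity cap on terrain gradient
  for (i in seq_len(nx)) {
    ii <- max(1L, i - 1L):min(nx, i + 1L)
    for (j in seq_len(ny)) {
      if (is.na(minz[i, j])) next
      jj <- max(1L, j - 1L):min(ny, j + 1L)
      px <- minx[ii, jj]; py <- miny[ii, jj]; pz <- minz[ii, jj]
      ok <- !is.na(pz)
      sx <- 0; sy <- 0
      if (sum(ok) >= 3L) {
        A <- cbind(1, px[ok] - minx[i, j], py[ok] - miny[i, j])
        fit <- tryCatch(qr.solve(qr(A, tol = 1e-8), pz[ok]),
                        error = function(e) NULL)
        if (!is.null(fit) && all(is.finite(fit)) &&
            max(abs(fit[2:3])) <= max_slope) {
          sx <- fit[2L]; sy <- fit[3L]
        }
      }
      ax[i, j] <- sx; ay[i, j] <- sy
    }
  }
  filled <- fill_nearest_cells(!is.na(minz))
  list(x0 = x0, y0 = y0, cell_size = cell_size, nx = nx, ny = ny,
       minx = minx, miny = miny, minz = minz, ax = ax, ay = ay,
       src = filled)
}

# for every cell, the index of the nearest populated cell (itself when
# populated), found by an expanding-ring grid sweep
fill_nearest_cells <- function(pop) {
  nx <- nrow(pop); ny <- ncol(pop)
  src <- matrix(NA_integer_, nx, ny)
  src[pop] <- which(pop)
  ring <- 1L
  while (anyNA(src) && ring <= max(nx, ny)) {
    prev <- src
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      shifted <- prev[pmin(pmax(seq_len(nx) + di, 1L), nx),
                      pmin(pmax(seq_len(ny) + dj, 1L), ny), drop = FALSE]
      take <- is.na(src) & !is.na(shifted)
      src[take] <- shifted[take]
    }
    ring <- ring + 1L
  }
  src
}

# evaluate the anchored-plane surface at arbitrary positions
eval_ground <- function(gm, x, y) {
  ci <- pmin(pmax(ceiling((x - gm$x0) / gm$cell_size + 1e-12), 1L), gm$nx)
  cj <- pmin(pmax(ceiling((y - gm$y0) / gm$cell_size + 1e-12), 1L), gm$ny)
  cell <- gm$src[cbind(ci, cj)]
  gm$minz[cell] + gm$ax[cell] * (x - gm$minx[cell]) +
    gm$ay[cell] * (y - gm$miny[cell])
}
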
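#' Hegyi distance-dependent competition index
#'
#' For subject tree i with competitors j within a fixed search radius,
#' the index sums `(DBH_j / DBH_i) / dist_ij`: larger and closer
#' neighbors mean more competition (a proxy for reduced light
#' availability). The inverted reading `(DBH_i / DBH_j) / dist_ij` is
#' available via `form`.
#'
#' @param subject_dbh subject DBH, cm (> 0).
#' @param comp_dbh competitor DBH vector, cm.
#' @param dist distances subject-competitor, m (> 0).
#' @param radius search radius, m; competitors strictly within it count
#'   (default 5).
#' @param form `"standard"` (neighbor over subject) or `"inverted"`.
#' @return the index (0 when no competitors are in range).
#' @export
hegyi_index <- function(subject_dbh, comp_dbh, dist, radius = 5,
                        form = c("standard", "inverted")) {
  form <- match.arg(form)
  if (subject_dbh <= 0) stop("subject dbh must be positive")
  if (length(comp_dbh) != length(dist))
    stop("comp_dbh and dist must have equal length")
  if (!length(comp_dbh)) return(0)
  if (any(dist <= 0))
    stop("competitor coincident with subject (distance 0) at index ",
         which(dist <= 0)[1L])
  keep <- dist < radius
  if (!any(keep)) return(0)
  ratio <- if (form == "standard") comp_dbh[keep] / subject_dbh
           else subject_dbh / comp_dbh[keep]
  sum(ratio / dist[keep])
}

#' Hegyi index for every tree of a plot
#'
#' Vectorizes [hegyi_index()] over a tree table with stem positions.
#' Trees closer than the search radius to the plot boundary are flagged
#' (`edge = TRUE`); no edge correction is applied.
#'
#' @param trees data.frame with columns x, y and dbh (or dbh_cm).
#' @param radius search radius, m.
#' @param bounds plot rectangle `c(xmin, xmax, ymin, ymax)`; default the
#'   bounding box of the positions.
#' @param form forwarded to [hegyi_index()].
#' @return the table with columns `hegyi` and `edge` added.
#' @export
plot_competition <- function(trees, radius = 5, bounds = NULL,
                             form = "standard") {
  if (nrow(trees) < 1L) stop("at least one tree required")
  d <- if (!is.null(trees$dbh)) trees$dbh else trees$dbh_cm
  if (is.null(d)) stop("trees must have a dbh or dbh_cm column")
  if (anyDuplicated(trees[, c("x", "y")]))
    stop("duplicate stem positions: ",
         paste(which(duplicated(trees[, c("x", "y")])), collapse = ", "))
  if (is.null(bounds))
    bounds <- c(min(trees$x), max(trees$x), min(trees$y), max(trees$y))
  n <- nrow(trees)
  dm <- as.matrix(stats::dist(cbind(trees$x, trees$y)))
  hg <- vapply(seq_len(n), function(i) {
    j <- setdiff(seq_len(n), i)
    hegyi_index(d[i], d[j], dm[i, j], radius = radius, form = form)
  }, 0.0)
  trees$hegyi <- hg
  trees$edge <- trees$x - bounds[1] < radius | bounds[2] - trees$x < radius |
    trees$y - bounds[3] < radius | bounds[4] - trees$y < radius
  trees
}
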
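polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

max_pairwise_distance <- function(x, y) {
  # hull vertices only; quadratic there is cheap
  if (length(x) < 2L) return(NA_real_)
  d <- stats::dist(cbind(x, y))
  max(d)
}

#' Crown size and shape metrics from convex hulls
#'
#' Crown width is the distance between the two most distant crown points
#' in the horizontal (xy) plane; crown projection area the area of the 2D
#' convex hull of the crown points; crown volume and crown surface area
#' come from the 3D convex hull enveloping the crown points.
#'
#' @param pc a classified [point_cloud()]; points labeled `crown` are
#'   used (all points if unlabeled).
#' @return list: crown_width_m, crown_projection_area_m2,
#'   crown_volume_m3, crown_surface_area_m2, reason (non-empty when a
#'   degenerate point set made a hull undefined).
#' @export
crown_metrics <- function(pc) {
  cr <- if (!is.null(pc$label)) pc[!is.na(pc$label) & pc$label == "crown", ]
        else pc
  out <- list(crown_width_m = NA_real_, crown_projection_area_m2 = NA_real_,
              crown_volume_m3 = NA_real_, crown_surface_area_m2 = NA_real_,
              reason = "")
  if (nrow(cr) < 3L) {
    out$reason <- "fewer than 3 crown points"
    return(out)
  }
  xy <- cbind(cr$x, cr$y)
  hull <- grDevices::chull(xy)
  if (length(hull) >= 3L) {
    out$crown_projection_area_m2 <- polygon_area(xy[hull, 1], xy[hull, 2])
    out$crown_width_m <- max_pairwise_distance(xy[hull, 1], xy[hull, 2])
  } else {
    out$crown_width_m <- max_pairwise_distance(xy[, 1], xy[, 2])
    out$reason <- "collinear crown points (no 2D hull)"
  }
  h <- .convhull3d(cr$x, cr$y, cr$z)
  if (is.na(h$volume)) {
    out$reason <- paste0(out$reason, if (nzchar(out$reason)) "; ",
                         "3D hull: ", h$reason)
  } else {
    out$crown_volume_m3 <- h$volume
    out$crown_surface_area_m2 <- h$area
  }
  out
}

#' Benefit-to-cost ratio (crown surface over stem volume)
#'
#' The photosynthetically active surface per unit of structural
#' investment: crown surface area divided by stem volume (converted from
#' dm3 to m3), in m2 per m3.
#'
#' @param crown_surface_area_m2 crown hull surface area, m2.
#' @param stem_volume_dm3 stem volume, dm3.
#' @return ratio in m2/m3, or NA when stem volume is not positive.
#' @export
benefit_to_cost <- function(crown_surface_area_m2, stem_volume_dm3) {
  ifelse(is.na(stem_volume_dm3) | stem_volume_dm3 <= 0, NA_real_,
         crown_surface_area_m2 / (stem_volume_dm3 / 1000))
}

#' Growth attributes from the two-occasion field table
#'
#' Last-minus-first increments of DBH, height and stem volume, plus the
#' height-growth-to-diameter ratio dH/DBH. The conventional definition of the
#' dH/DBH denominator is ambiguous; the default uses the last-occasion
#' DBH, configurable via `dhdbh_denominator`.
#'
#' @param field field table (site, plot, tree_id, occasion, dbh_cm,
#'   height_m, volume_dm3).
#' @param tree_id tree to summarize; omit for all trees.
#' @param dhdbh_denominator `"last"`, `"first"` or `"growth"`.
#' @return data.frame: tree_id, growth_dbh_cm, growth_height_m,
#'   growth_volume_dm3, dH_over_DBH. Trees lacking an occasion get NAs.
#' @export
growth_attributes <- function(field, tree_id = NULL,
                              dhdbh_denominator = c("last", "first",
                                                    "growth")) {
  dhdbh_denominator <- match.arg(dhdbh_denominator)
  ids <- if (is.null(tree_id)) sort(unique(field$tree_id)) else tree_id
  out <- lapply(ids, function(id) {
    fi <- field[field$tree_id == id & field$occasion == "first", ]
    la <- field[field$tree_id == id & field$occasion == "last", ]
    if (nrow(fi) != 1L || nrow(la) != 1L)
      return(data.frame(tree_id = id, growth_dbh_cm = NA_real_,
                        growth_height_m = NA_real_,
                        growth_volume_dm3 = NA_real_,
                        dH_over_DBH = NA_real_))
    gd <- la$dbh_cm - fi$dbh_cm
    gh <- la$height_m - fi$height_m
    gv <- la$volume_dm3 - fi$volume_dm3
    den <- switch(dhdbh_denominator, last = la$dbh_cm, first = fi$dbh_cm,
                  growth = gd)
    data.frame(tree_id = id, growth_dbh_cm = gd, growth_height_m = gh,
               growth_volume_dm3 = gv,
               dH_over_DBH = if (is.na(den) || den <= 0) NA_real_ else gh / den)
  })
  do.call(rbind, out)
}

#' All structural attributes of one segmented tree
#'
#' Runs the per-tree measurement chain: stem/crown classification, taper
#' fit, DBH, stem volume, tree height, crown hull metrics,
#' benefit-to-cost ratio, and box dimension.
#'
#' @param pc a height-normalized single-tree [point_cloud()].
#' @param classify re-run [classify_stem_points()] (default TRUE; set
#'   FALSE to trust existing labels, e.g. generator ground truth).
#' @param n_levels,schedule forwarded to [box_dimension()].
#' @return one-row data.frame of attributes (NA where a step failed) with
#'   a `note` column describing failures.
#' @export
tree_attributes <- function(pc, classify = TRUE, n_levels = 8L,
                            schedule = "dyadic") {
  note <- character()
  cl <- if (classify) tryCatch(classify_stem_points(pc),
                               warning = function(w) {
                                 note <<- c(note, conditionMessage(w))
                                 suppressWarnings(classify_stem_points(pc))
                               })
        else pc
  h <- tree_height(cl)
  taper <- tryCatch(fit_taper(cl, top_height = h), error = function(e) {
    note <<- c(note, conditionMessage(e)); NULL
  })
  dbh <- if (is.null(taper)) NA_real_ else dbh_from_taper(taper)
  vol <- if (is.null(taper)) NA_real_ else stem_volume_from_taper(taper)
  cm <- crown_metrics(cl)
  if (nzchar(cm$reason)) note <- c(note, cm$reason)
  bd <- box_dimension(cl, n_levels = n_levels, schedule = schedule)
  data.frame(
    dbh_cm = dbh, height_m = h, stem_volume_dm3 = vol,
    crown_width_m = cm$crown_width_m,
    crown_projection_area_m2 = cm$crown_projection_area_m2,
    crown_volume_m3 = cm$crown_volume_m3,
    crown_surface_area_m2 = cm$crown_surface_area_m2,
    benefit_to_cost = benefit_to_cost(cm$crown_surface_area_m2, vol),
    box_dimension = bd$slope, box_intercept = bd$intercept,
    box_r_squared = bd$r_squared,
    note = paste(note, collapse = "; "))
}
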
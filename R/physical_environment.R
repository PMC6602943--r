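# Physical-environment indicators: green-space area within a 900 m buffer of
# each postcode centroid, and zone-mean pollutant concentrations from 1x1 km
# raster grids.

#' Green-space area within a postcode buffer
#'
#' Area (m^2) of the intersection between a circular buffer around the
#' postcode centroid and the union of green-space polygons; overlapping
#' polygons are not double-counted. The 900 m default radius follows the
#' European Environment Agency recommendation of green space within a
#' 15-minute walk. The circle is a fixed 256-gon so results are deterministic.
#'
#' @param postcode list or one-row data frame with `easting_m`, `northing_m`.
#' @param green list of green polygons; each a list with `ring` (n x 2 matrix)
#'   and optionally `polygon_id`.
#' @param buffer_m buffer radius in metres (default 900).
#' @param mode `"clipped"` (default): area of the geometric intersection;
#'   `"whole_polygon"`: total union area of every polygon that touches the
#'   buffer, uncut.
#' @param segments_per_quarter circle approximation density.
#' @return area in m^2.
#' @export
greenspace_area <- function(postcode, green, buffer_m = 900,
                            mode = c("clipped", "whole_polygon"),
                            segments_per_quarter = 64L) {
  mode <- match.arg(mode)
  stopifnot(buffer_m > 0)
  cx <- as.numeric(postcode$easting_m)
  cy <- as.numeric(postcode$northing_m)
  if (length(green) == 0L) return(0)
  disc <- buffer_polygon(cx, cy, buffer_m, segments_per_quarter)
  keep_whole <- list()
  pieces <- list()
  for (gp in green) {
    id <- if (!is.null(gp$polygon_id)) gp$polygon_id else NULL
    ring <- tryCatch(as_ring(gp$ring, id = id), error = function(e) stop(e))
    if (ring_self_intersects(ring)) {
      stop(ring_msg("is self-intersecting", id))
    }
    bb <- ring_bbox(ring)
    # bbox prefilter: nearest point of the bbox to the centre
    dx <- max(bb[1L] - cx, 0, cx - bb[3L])
    dy <- max(bb[2L] - cy, 0, cy - bb[4L])
    if (dx * dx + dy * dy > buffer_m * buffer_m) next
    # corners all inside the circle => polygon bbox wholly inside, skip clip
    corners_in <- all(((c(bb[1L], bb[3L], bb[1L], bb[3L]) - cx)^2 +
                       (c(bb[2L], bb[2L], bb[4L], bb[4L]) - cy)^2) <= buffer_m^2)
    clipped <- if (corners_in) ring else clip_polygon(ring, disc)
    if (nrow(clipped) >= 3L && polygon_area(clipped) > 0) {
      pieces[[length(pieces) + 1L]] <- clipped
      keep_whole[[length(keep_whole) + 1L]] <- ring
    }
  }
  if (!length(pieces)) return(0)
  if (mode == "clipped") polygon_union_area(pieces) else polygon_union_area(keep_whole)
}

#' Green-space area for many postcodes
#'
#' @param postcodes data frame with `pcd`, `easting_m`, `northing_m`.
#' @param green list of green polygons (see [greenspace_area()]).
#' @param ... passed to [greenspace_area()].
#' @return data frame `pcd`, `green_area_m2`.
#' @export
greenspace_table <- function(postcodes, green, ...) {
  area <- vapply(seq_len(nrow(postcodes)), function(i) {
    greenspace_area(postcodes[i, ], green, ...)
  }, numeric(1))
  data.frame(pcd = as.character(postcodes$pcd), green_area_m2 = area,
             stringsAsFactors = FALSE)
}

# Square ring of raster cell (i = row from top, j = column).
cell_ring <- function(grid, i, j) {
  s <- grid$cellsize_m
  x0 <- grid$xll + (j - 1L) * s
  y0 <- grid$yll + (nrow(grid$values) - i) * s
  cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
}

#' Zonal mean of a pollutant raster
#'
#' Unweighted arithmetic mean of the values of every cell whose square
#' footprint overlaps the zone polygon with positive area (the default rule;
#' `rule = "centre"` selects cells whose centre lies in the zone instead).
#' Nodata cells are excluded.
#'
#' @param raster `raster_grid`.
#' @param zone list with `zone_code` and `ring` (n x 2 matrix).
#' @param rule cell-membership rule: `"overlap"` (default) or `"centre"`.
#' @return mean concentration of the contributing cells.
#' @export
raster_zone_mean <- function(raster, zone, rule = c("overlap", "centre")) {
  rule <- match.arg(rule)
  stopifnot(inherits(raster, "raster_grid"))
  ring <- as_ring(zone$ring, id = zone$zone_code)
  s <- raster$cellsize_m
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  bb <- ring_bbox(ring)
  # candidate cell window from the zone bbox
  j0 <- max(1L, floor((bb[1L] - raster$xll) / s) + 1L)
  j1 <- min(nc, ceiling((bb[3L] - raster$xll) / s))
  i_top <- max(1L, nr - ceiling((bb[4L] - raster$yll) / s) + 1L)
  i_bot <- min(nr, nr - floor((bb[2L] - raster$yll) / s))
  if (j0 > j1 || i_top > i_bot) {
    stop(sprintf("zone '%s' lies outside the '%s' raster extent",
                 zone$zone_code, raster$pollutant))
  }
  vals <- numeric(0)
  eps <- 1e-9 * s * s
  for (i in i_top:i_bot) {
    for (j in j0:j1) {
      hit <- if (rule == "centre") {
        cx <- raster$xll + (j - 0.5) * s
        cy <- raster$yll + (nr - i + 0.5) * s
        point_in_polygon(cx, cy, ring)
      } else {
        cr <- cell_ring(raster, i, j)
        clp <- clip_polygon(ring, cr)
        nrow(clp) >= 3L && polygon_area(clp) > eps
      }
      if (hit) vals <- c(vals, raster$values[i, j])
    }
  }
  if (!length(vals)) {
    stop(sprintf("zone '%s' overlaps no '%s' raster cells",
                 zone$zone_code, raster$pollutant))
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    stop(sprintf("all '%s' cells overlapping zone '%s' are nodata",
                 raster$pollutant, zone$zone_code))
  }
  mean(vals)
}

#' Zone-mean table for a set of pollutant rasters
#'
#' @param rasters named list of `raster_grid` objects (names become columns).
#' @param zones list of zones (each with `zone_code` and `ring`).
#' @param rule see [raster_zone_mean()].
#' @return data frame with `zone_code` and one column per pollutant.
#' @export
air_zone_table <- function(rasters, zones, rule = "overlap") {
  out <- data.frame(zone_code = vapply(zones, `[[`, character(1), "zone_code"),
                    stringsAsFactors = FALSE)
  for (pol in names(rasters)) {
    out[[pol]] <- vapply(zones, function(z) {
      raster_zone_mean(rasters[[pol]], z, rule = rule)
    }, numeric(1))
  }
  out
}
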
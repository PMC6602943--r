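# Zone x 14 indicator table: postcode-level measures are aggregated to zones
# by the unweighted mean; zone-level pollutant means are joined as-is.

#' The 14 indicator definitions
#'
#' Canonical order: five retail-hazard distances, five health-service
#' distances (leisure centres sit in the health-services domain), green-space
#' area, then the three pollutants. `orientation` records the sign convention
#' applied before standardisation: `flip` marks indicators whose larger raw
#' values are healthier (retail distances, green area) and which are negated
#' so that, after orientation, larger always means less healthy.
#'
#' @return data frame with columns `name`, `domain`, `unit`, `orientation`.
#' @export
indicator_specs <- function() {
  data.frame(
    name = c(retail_categories(), health_categories(), "green900",
             "no2", "pm10", "so2"),
    domain = c(rep("retail", 5L), rep("health", 5L), rep("physical", 4L)),
    unit = c(rep("km", 10L), "m2", rep("ugm3", 3L)),
    orientation = c(rep("flip", 5L), rep("keep", 5L), "flip",
                    rep("keep", 3L)),
    stringsAsFactors = FALSE)
}

#' Aggregate postcode values to zone means
#'
#' Unweighted arithmetic mean of the postcode values within each zone;
#' zone population plays no role.
#'
#' @param values data frame with columns `pcd` and `value`.
#' @param lookup data frame with columns `pcd` and `zone_code`.
#' @return data frame `zone_code`, `value` (one row per zone, sorted by code).
#' @export
aggregate_postcodes <- function(values, lookup) {
  stopifnot(is.data.frame(values), all(c("pcd", "value") %in% names(values)),
            all(c("pcd", "zone_code") %in% names(lookup)))
  zc <- lookup$zone_code[match(values$pcd, lookup$pcd)]
  if (anyNA(zc)) {
    stop(sprintf("postcode(s) without a zone: %s",
                 paste(values$pcd[is.na(zc)], collapse = ", ")))
  }
  empty <- setdiff(unique(lookup$zone_code), zc)
  if (length(empty)) {
    stop(sprintf("zone(s) with no postcode values: %s",
                 paste(sort(empty), collapse = ", ")))
  }
  agg <- tapply(values$value, zc, mean)
  data.frame(zone_code = names(agg), value = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Assemble the zone x 14 indicator table
#'
#' @param access long data frame `zone_code`, `category`, `distance_km` with
#'   the 10 per-zone mean distances.
#' @param green data frame `zone_code`, `green_area_m2`.
#' @param air data frame `zone_code`, `no2`, `pm10`, `so2`.
#' @return data frame of class `indicator_table`: `zone_code` plus the 14
#'   indicator columns in canonical order.
#' @export
assemble_table <- function(access, green, air) {
  specs <- indicator_specs()
  codes <- sort(unique(access$zone_code))
  check_codes <- function(other, label) {
    oc <- unique(other$zone_code)
    miss <- setdiff(codes, oc); extra <- setdiff(oc, codes)
    if (length(miss) || length(extra)) {
      stop(sprintf("zone_code mismatch in %s input (missing: %s; extra: %s)",
                   label,
                   if (length(miss)) paste(miss, collapse = ", ") else "none",
                   if (length(extra)) paste(extra, collapse = ", ") else "none"))
    }
  }
  check_codes(green, "green"); check_codes(air, "air")
  out <- data.frame(zone_code = codes, stringsAsFactors = FALSE)
  for (cat_name in service_categories()) {
    sub <- access[access$category == cat_name, ]
    if (nrow(sub) == 0L) stop(sprintf("missing access distances for category '%s'", cat_name))
    check_codes(sub, cat_name)
    out[[cat_name]] <- sub$distance_km[match(codes, sub$zone_code)]
  }
  out$green900 <- green$green_area_m2[match(codes, green$zone_code)]
  for (pol in c("no2", "pm10", "so2")) {
    if (is.null(air[[pol]])) stop(sprintf("air input missing column '%s'", pol))
    out[[pol]] <- air[[pol]][match(codes, air$zone_code)]
  }
  stopifnot(identical(names(out)[-1L], specs$name))
  if (anyNA(out)) stop("indicator table has missing cells")
  class(out) <- c("indicator_table", "data.frame")
  out
}

#' Run measurement stages of the pipeline on a region
#'
#' Computes the three indicator families (network access distances,
#' green-space buffer areas, zonal pollutant means), aggregates to zones,
#' and assembles the indicator table.
#'
#' @param region `synthetic_region`.
#' @param buffer_m green-space buffer radius (m).
#' @param green_area_mode `"clipped"` or `"whole_polygon"`.
#' @param overlap_rule raster cell membership rule, `"overlap"` or `"centre"`.
#' @param allow_unreachable passed to the routing stage.
#' @return list with `access` (postcode level), `green` (postcode level),
#'   `air` (zone level) and `table` (the `indicator_table`).
#' @export
measure_region <- function(region, buffer_m = 900,
                           green_area_mode = "clipped",
                           overlap_rule = "overlap",
                           allow_unreachable = FALSE) {
  stopifnot(inherits(region, "synthetic_region"))
  access_pc <- access_distances(region$network, region$postcodes,
                                region$services,
                                allow_unreachable = allow_unreachable)
  lookup <- region$postcodes[, c("pcd", "zone_code")]
  access_zone <- do.call(rbind, lapply(split(access_pc, access_pc$category), function(sub) {
    agg <- aggregate_postcodes(data.frame(pcd = sub$pcd, value = sub$distance_km),
                               lookup)
    data.frame(zone_code = agg$zone_code, category = sub$category[1L],
               distance_km = agg$value, stringsAsFactors = FALSE)
  }))
  rownames(access_zone) <- NULL

  green_pc <- greenspace_table(region$postcodes, region$green,
                               buffer_m = buffer_m, mode = green_area_mode)
  green_agg <- aggregate_postcodes(
    data.frame(pcd = green_pc$pcd, value = green_pc$green_area_m2), lookup)
  green_zone <- data.frame(zone_code = green_agg$zone_code,
                           green_area_m2 = green_agg$value,
                           stringsAsFactors = FALSE)

  air_zone <- air_zone_table(region$rasters, region$zones, rule = overlap_rule)

  list(access = access_pc, green = green_pc, air = air_zone,
       access_zone = access_zone,
       table = assemble_table(access_zone, green_zone, air_zone))
}
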
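# Seeded synthetic study region: a square planar extent with an urban core in
# which services AND retail hazards cluster and air pollution peaks, a
# suburban ring, and a remote periphery where green space is denser. Every
# downstream stage (routing, buffers, zonal means, index construction) is
# exercised on this stand-in world, so generation is fully deterministic:
# one global seed fans out to fixed per-component child seeds.

#' Service categories
#'
#' The ten accessibility categories: five health-negating retail types and
#' five health-promoting services (leisure centres sit in the health-services
#' domain).
#'
#' @return character vector of category names.
#' @export
service_categories <- function() c(retail_categories(), health_categories())

#' @rdname service_categories
#' @export
retail_categories <- function() {
  c("fastfood", "gambling", "offlicences", "tobacconists", "pubs")
}

#' @rdname service_categories
#' @export
health_categories <- function() {
  c("gp", "hospitals", "pharmacies", "dentists", "leisure")
}

default_category_counts <- function() {
  c(fastfood = 40L, gambling = 10L, offlicences = 12L, tobacconists = 6L,
    pubs = 35L, gp = 15L, hospitals = 3L, pharmacies = 18L, dentists = 12L,
    leisure = 8L)
}

green_tags <- function() {
  c("park", "wood", "meadow", "recreation_ground", "grassland", "common",
    "nature_reserve", "golf_course")
}

child_seed <- function(seed, offset) as.integer((as.numeric(seed) + offset) %% 2147483647)

#' Configuration of a synthetic study region
#'
#' Defaults describe a 20 km x 20 km mixed urban/rural region of 50 zones
#' (each 500-3,000 "residents", matching UK LSOA / Data Zone sizes), with
#' service counts scaled from national prevalence to a region of this size.
#'
#' @param seed integer master seed; fixed seed implies byte-identical outputs.
#' @param extent_km side of the square extent (km).
#' @param n_zones number of zones tiling the extent.
#' @param postcodes_per_zone integer range (length 2) of postcodes per zone.
#' @param category_counts named integer vector of point counts for the 10
#'   service categories; every count must be >= 1.
#' @param n_green_polygons number of green-space polygons.
#' @param raster_cell_km pollutant raster cell size (km).
#' @param urban_fraction clustering intensity: the core share of hazard
#'   outlets is `1 - (1 - urban_fraction)/2` and of health services
#'   `urban_fraction/2`; the remainder locates in the satellite towns.
#' @return object of class `region_config`.
#' @export
region_config <- function(seed = 1L,
                          extent_km = 20,
                          n_zones = 50L,
                          postcodes_per_zone = c(5L, 20L),
                          category_counts = default_category_counts(),
                          n_green_polygons = 150L,
                          raster_cell_km = 1,
                          urban_fraction = 0.7) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (extent_km <= 0) stop("configuration error: extent_km must be positive")
  if (n_zones < 1L) stop("configuration error: n_zones must be >= 1")
  if (length(postcodes_per_zone) != 2L || postcodes_per_zone[1L] < 1L ||
      postcodes_per_zone[2L] < postcodes_per_zone[1L]) {
    stop("configuration error: postcodes_per_zone must be an increasing integer range >= 1")
  }
  missing_cat <- setdiff(service_categories(), names(category_counts))
  if (length(missing_cat)) {
    stop(sprintf("configuration error: category_counts missing categories: %s",
                 paste(missing_cat, collapse = ", ")))
  }
  zero <- names(category_counts)[category_counts < 1L]
  if (length(zero)) {
    stop(sprintf("configuration error: category count must be >= 1 for: %s",
                 paste(zero, collapse = ", ")))
  }
  # zones tile the extent; require at least 1 km^2 per zone
  if (extent_km^2 < n_zones * 1) {
    stop(sprintf(
      "configuration error: extent_km^2 (%.1f) < n_zones x 1 km^2 minimum zone area (%d)",
      extent_km^2, n_zones))
  }
  if (urban_fraction <= 0 || urban_fraction >= 1) {
    stop("configuration error: urban_fraction must lie in (0, 1)")
  }
  if (raster_cell_km <= 0) stop("configuration error: raster_cell_km must be positive")
  structure(list(seed = as.integer(seed), extent_km = extent_km,
                 n_zones = as.integer(n_zones),
                 postcodes_per_zone = as.integer(postcodes_per_zone),
                 category_counts = category_counts,
                 n_green_polygons = as.integer(n_green_polygons),
                 raster_cell_km = raster_cell_km,
                 urban_fraction = urban_fraction),
            class = "region_config")
}

# pick the zone-grid dimensions: divisor of n closest to sqrt(n)
grid_dims <- function(n) {
  divs <- which(n %% seq_len(n) == 0)
  d <- divs[which.min(abs(divs - sqrt(n)))]
  c(d, n %/% d)
}

# Settlement system: services of every kind locate in settlements, never in
# open country. One urban core at the extent centre plus a fixed number of
# satellite towns seeded at 55-85% of the half-extent. Hazardous retail
# concentrates in the core (commercial density); health services disperse
# more evenly across core and towns (planned provision follows population).
n_satellite_towns <- function() 5L

make_settlements <- function(seed, extent_m) {
  set.seed(child_seed(seed, 397))
  half <- extent_m / 2
  k <- n_satellite_towns()
  rad <- stats::runif(k, 0.55, 0.85) * half
  # stratified angles: towns space themselves around the core to serve
  # hinterlands (central-place pattern), one per angular sector with jitter
  ang <- 2 * pi * (seq_len(k) - 1L + stats::runif(k)) / k
  tx <- pmin(pmax(half + rad * cos(ang), 0.02 * extent_m), 0.98 * extent_m)
  ty <- pmin(pmax(half + rad * sin(ang), 0.02 * extent_m), 0.98 * extent_m)
  list(x = c(half, tx), y = c(half, ty))
}

# Draw n service points: with prob `p_core` around the core (sd `sd_core_m`),
# otherwise around a uniformly chosen satellite town (sd `sd_town_m`).
sample_settlement_points <- function(n, extent_m, settlements, p_core,
                                     sd_core_m, sd_town_m) {
  out <- matrix(NA_real_, n, 2L)
  k <- length(settlements$x) - 1L
  for (i in seq_len(n)) {
    if (stats::runif(1) < p_core) {
      s <- 1L; sd_m <- sd_core_m
    } else {
      s <- 1L + sample.int(k, 1L); sd_m <- sd_town_m
    }
    repeat {
      p <- stats::rnorm(2L, mean = c(settlements$x[s], settlements$y[s]), sd = sd_m)
      if (all(p >= 0 & p <= extent_m)) break
    }
    out[i, ] <- p
  }
  round(out)  # OS-grid style 1 m resolution
}

build_lattice_network <- function(config, extent_m) {
  side <- max(3L, as.integer(round(config$extent_km)) + 1L)
  spacing <- extent_m / (side - 1L)
  set.seed(child_seed(config$seed, 101))
  gx <- rep(seq_len(side) - 1L, times = side) * spacing
  gy <- rep(seq_len(side) - 1L, each = side) * spacing
  jit <- 0.2 * spacing
  x <- pmin(pmax(gx + stats::runif(side * side, -jit, jit), 0), extent_m)
  y <- pmin(pmax(gy + stats::runif(side * side, -jit, jit), 0), extent_m)
  nodes <- data.frame(node_id = sprintf("n%04d", seq_len(side * side)),
                      easting_m = round(x), northing_m = round(y),
                      stringsAsFactors = FALSE)
  idx <- function(i, j) (j - 1L) * side + i   # i = column, j = row
  from <- integer(0); to <- integer(0)
  for (j in seq_len(side)) {
    for (i in seq_len(side)) {
      if (i < side) { from <- c(from, idx(i, j)); to <- c(to, idx(i + 1L, j)) }
      if (j < side) { from <- c(from, idx(i, j)); to <- c(to, idx(i, j + 1L)) }
    }
  }
  eucl_km <- sqrt((nodes$easting_m[from] - nodes$easting_m[to])^2 +
                  (nodes$northing_m[from] - nodes$northing_m[to])^2) / 1000
  # street lengths exceed straight-line separation by a 5-25% detour factor
  length_km <- round(eucl_km * stats::runif(length(from), 1.05, 1.25), 6)
  n_edge <- length(from)
  n_oneway <- floor(0.10 * n_edge)
  for (attempt in 0:19) {
    set.seed(child_seed(config$seed, 131 + attempt))
    oneway <- integer(n_edge)
    ow_idx <- sample.int(n_edge, n_oneway)
    oneway[ow_idx] <- 1L
    flip <- stats::runif(n_edge) < 0.5   # randomise one-way direction
    f2 <- ifelse(oneway == 1L & flip, to, from)
    t2 <- ifelse(oneway == 1L & flip, from, to)
    edges <- data.frame(edge_id = sprintf("e%05d", seq_len(n_edge)),
                        from_node = nodes$node_id[f2],
                        to_node = nodes$node_id[t2],
                        length_km = length_km, oneway = oneway,
                        stringsAsFactors = FALSE)
    net <- build_graph(edges, nodes)
    if (is_strongly_connected(net)) return(net)
  }
  # fall back to all two-way (always strongly connected for a lattice)
  edges$oneway <- 0L
  edges$from_node <- nodes$node_id[from]
  edges$to_node <- nodes$node_id[to]
  build_graph(edges, nodes)
}

#' Generate a synthetic study region
#'
#' Zones tile the extent as a rectangular grid and are classed by settlement
#' geography: `core` (centroid within 35% of the half-extent), `remote`
#' (beyond the half-extent radius AND more than 30% of the half-extent from
#' every satellite town — a service desert), `ring` otherwise (suburbs and
#' town neighbourhoods). Hazard outlets cluster tightly on the core, health
#' services spread across core and towns, pollutant surfaces are a localised
#' Gaussian plume on the core plus noise, and green-space density is
#' suppressed in the core and saturates outside it.
#'
#' @param config a [region_config()].
#' @return object of class `synthetic_region` with elements `network`,
#'   `postcodes`, `zones`, `services`, `green`, `rasters`, `config`.
#' @export
generate_region <- function(config) {
  stopifnot(inherits(config, "region_config"))
  extent_m <- config$extent_km * 1000
  centre <- c(extent_m / 2, extent_m / 2)

  # --- zones: rectangular tiling -------------------------------------------
  # Classes follow settlement geography: "core" is the urban centre; "ring"
  # is suburban (just outside the core) or a satellite-town neighbourhood;
  # "remote" zones are far from every settlement, i.e. service deserts.
  settlements <- make_settlements(config$seed, extent_m)
  dims <- grid_dims(config$n_zones)
  nx <- dims[1L]; ny <- dims[2L]
  wx <- extent_m / nx; wy <- extent_m / ny
  set.seed(child_seed(config$seed, 211))
  populations <- as.numeric(sample(500:3000, config$n_zones, replace = TRUE))
  zones <- vector("list", config$n_zones)
  half <- extent_m / 2
  k <- 0L
  for (jy in seq_len(ny)) {
    for (jx in seq_len(nx)) {
      k <- k + 1L
      x0 <- (jx - 1L) * wx; y0 <- (jy - 1L) * wy
      ring <- cbind(c(x0, x0 + wx, x0 + wx, x0), c(y0, y0, y0 + wy, y0 + wy))
      cen <- c(x0 + wx / 2, y0 + wy / 2)
      frac <- sqrt(sum((cen - centre)^2)) / half
      d_town <- sqrt(min((settlements$x[-1L] - cen[1L])^2 +
                         (settlements$y[-1L] - cen[2L])^2))
      # remote = the extreme periphery, far from the core AND from every
      # town (zone geographies are population-based, so genuinely remote
      # zones are a small minority of a region's zones)
      cls <- if (frac <= 0.35) "core"
             else if (frac > 1.0 && d_town > 0.30 * half) "remote"
             else "ring"
      zones[[k]] <- list(zone_code = sprintf("Z%03d", k), ring = ring,
                         population = populations[k], zone_class = cls,
                         centroid = cen)
    }
  }

  # --- road network ---------------------------------------------------------
  network <- build_lattice_network(config, extent_m)

  # --- postcodes: uniform within their zone --------------------------------
  set.seed(child_seed(config$seed, 307))
  pc_list <- vector("list", config$n_zones)
  counter <- 0L
  for (k in seq_len(config$n_zones)) {
    npc <- sample(config$postcodes_per_zone[1L]:config$postcodes_per_zone[2L], 1L)
    bb <- ring_bbox(zones[[k]]$ring)
    mx <- 0.01 * (bb[3L] - bb[1L]); my <- 0.01 * (bb[4L] - bb[2L])
    ex <- round(stats::runif(npc, bb[1L] + mx, bb[3L] - mx))
    ny_ <- round(stats::runif(npc, bb[2L] + my, bb[4L] - my))
    pc_list[[k]] <- data.frame(
      pcd = sprintf("PC%05d", counter + seq_len(npc)),
      easting_m = ex, northing_m = ny_,
      zone_code = zones[[k]]$zone_code, stringsAsFactors = FALSE)
    counter <- counter + npc
  }
  postcodes <- do.call(rbind, pc_list)
  rownames(postcodes) <- NULL

  # --- service points: settlement-based placement --------------------------
  # urban_fraction is the core share for hazards; health services put only
  # half of that share in the core, the rest in the satellite towns.
  is_hazard <- stats::setNames(c(rep(TRUE, 5L), rep(FALSE, 5L)), service_categories())
  services <- list()
  cats <- service_categories()
  for (ci in seq_along(cats)) {
    cat_name <- cats[ci]
    set.seed(child_seed(config$seed, 401 + ci))
    n <- as.integer(config$category_counts[[cat_name]])
    p_core <- if (is_hazard[[cat_name]]) 1 - (1 - config$urban_fraction) / 2 else config$urban_fraction / 2
    # hazards sit tightly in the commercial core; health provision follows
    # residential population out across the suburbs
    sd_core <- if (is_hazard[[cat_name]]) 0.075 * extent_m else 0.25 * extent_m
    pts <- sample_settlement_points(n, extent_m, settlements, p_core,
                                    sd_core, 0.03 * extent_m)
    services[[cat_name]] <- data.frame(
      site_id = sprintf("%s_%03d", cat_name, seq_len(n)),
      category = cat_name, easting_m = pts[, 1L], northing_m = pts[, 2L],
      stringsAsFactors = FALSE)
  }

  # --- green space: denser towards the periphery ---------------------------
  set.seed(child_seed(config$seed, 503))
  green <- vector("list", config$n_green_polygons)
  tags <- green_tags()
  g <- 0L
  while (g < config$n_green_polygons) {
    p <- stats::runif(2L, 0, extent_m)
    # public green space is scarce in the dense core; beyond it, suburbs and
    # open periphery are comparably endowed (saturating gradient)
    frac <- min(1, sqrt(sum((p - centre)^2)) / (0.45 * extent_m / 2))
    if (stats::runif(1) > 0.15 + 0.85 * frac^2) next
    side <- stats::runif(1, 100, 600)
    h <- side / 2
    cx <- min(max(p[1L], h), extent_m - h)
    cy <- min(max(p[2L], h), extent_m - h)
    ring <- round(cbind(c(cx - h, cx + h, cx + h, cx - h),
                        c(cy - h, cy - h, cy + h, cy + h)))
    g <- g + 1L
    green[[g]] <- list(polygon_id = sprintf("G%04d", g), ring = ring,
                       area_m2 = polygon_area(ring),
                       tag = sample(tags, 1L))
  }

  # --- pollutant rasters: Gaussian peak on the core plus noise -------------
  cell_m <- config$raster_cell_km * 1000
  ncell <- as.integer(ceiling(extent_m / cell_m))
  # urban pollution plume: localised to the core (suburban air is close to
  # rural background, differing mostly by noise)
  params <- list(no2 = c(base = 8, amp = 25, noise = 1.2),
                 pm10 = c(base = 12, amp = 10, noise = 1.0),
                 so2 = c(base = 2, amp = 4, noise = 0.35))
  sigma <- 0.06 * extent_m
  rasters <- list()
  for (ri in seq_along(params)) {
    pol <- names(params)[ri]
    pp <- params[[ri]]
    set.seed(child_seed(config$seed, 601 + ri))
    m <- matrix(NA_real_, ncell, ncell)
    for (i in seq_len(ncell)) {        # row 1 = north
      cyv <- (ncell - i + 0.5) * cell_m
      cxv <- (seq_len(ncell) - 0.5) * cell_m
      d2 <- (cxv - centre[1L])^2 + (cyv - centre[2L])^2
      m[i, ] <- pp[["base"]] + pp[["amp"]] * exp(-d2 / (2 * sigma^2)) +
        stats::rnorm(ncell, 0, pp[["noise"]])
    }
    m <- round(pmax(m, 0.1), 6)
    rasters[[pol]] <- raster_grid(m, 0, 0, cell_m, pol)
  }

  region <- structure(list(config = config, extent_m = extent_m,
                           centre = centre, network = network,
                           postcodes = postcodes, zones = zones,
                           services = services, green = green,
                           rasters = rasters),
                      class = "synthetic_region")
  validate_region(region)
  region
}

# structural invariants of a generated region
validate_region <- function(region) {
  if (!is_strongly_connected(region$network)) {
    stop("generated road network is not strongly connected")
  }
  # each postcode inside exactly one zone rectangle
  hits <- integer(nrow(region$postcodes))
  for (z in region$zones) {
    bb <- ring_bbox(z$ring)
    inside <- region$postcodes$easting_m > bb[1L] & region$postcodes$easting_m < bb[3L] &
      region$postcodes$northing_m > bb[2L] & region$postcodes$northing_m < bb[4L]
    hits <- hits + inside
  }
  if (any(hits != 1L)) stop("postcode centroid not inside exactly one zone")
  zc <- table(region$postcodes$zone_code)
  if (length(zc) != length(region$zones)) stop("zone without postcodes")
  ext <- region$extent_m
  for (svc in region$services) {
    if (any(svc$easting_m < 0 | svc$easting_m > ext |
            svc$northing_m < 0 | svc$northing_m > ext)) {
      stop("service site outside the extent")
    }
  }
  invisible(TRUE)
}

#' @export
print.synthetic_region <- function(x, ...) {
  cat(sprintf(paste0("synthetic_region: %.0f km x %.0f km, %d zones, %d postcodes,\n",
                     "  %d service categories (%d sites), %d green polygons, %d rasters\n"),
              x$extent_m / 1000, x$extent_m / 1000, length(x$zones),
              nrow(x$postcodes), length(x$services),
              sum(vapply(x$services, nrow, integer(1))), length(x$green),
              length(x$rasters)))
  cls <- table(vapply(x$zones, `[[`, character(1), "zone_class"))
  cat("  zone classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' Zone metadata as a data frame
#'
#' @param region `synthetic_region`.
#' @return data frame `zone_code`, `population`, `zone_class`, centroid coords.
#' @export
zone_table <- function(region) {
  data.frame(zone_code = vapply(region$zones, `[[`, character(1), "zone_code"),
             population = vapply(region$zones, `[[`, numeric(1), "population"),
             zone_class = vapply(region$zones, `[[`, character(1), "zone_class"),
             centroid_x = vapply(region$zones, function(z) z$centroid[1L], numeric(1)),
             centroid_y = vapply(region$zones, function(z) z$centroid[2L], numeric(1)),
             stringsAsFactors = FALSE)
}

#' Write a region to plain-text files
#'
#' Emits `nodes.csv`, `edges.csv`, `postcodes.csv`, `zones.geojson`,
#' `services_<category>.geojson`, `greenspace.geojson`, one `<pollutant>.asc`
#' per raster, and `manifest.json` recording the seed, configuration, a
#' config hash and the file list. Output is byte-stable for a fixed region.
#'
#' @param region `synthetic_region`.
#' @param directory output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_region <- function(region, directory) {
  stopifnot(inherits(region, "synthetic_region"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  if (file.access(directory, mode = 2L) != 0L) {
    stop(sprintf("directory not writable: %s", directory))
  }
  files <- character(0)
  wr <- function(name) { files <<- c(files, name); file.path(directory, name) }

  write_csv_table(region$network$nodes, wr("nodes.csv"))
  write_csv_table(region$network$edges, wr("edges.csv"))
  write_csv_table(region$postcodes, wr("postcodes.csv"))

  write_geojson(lapply(region$zones, function(z) {
    list(geometry = z$ring,
         properties = list(zone_code = z$zone_code, population = z$population,
                           zone_class = z$zone_class))
  }), "Polygon", wr("zones.geojson"))

  for (cat_name in names(region$services)) {
    svc <- region$services[[cat_name]]
    write_geojson(lapply(seq_len(nrow(svc)), function(i) {
      list(geometry = c(svc$easting_m[i], svc$northing_m[i]),
           properties = list(site_id = svc$site_id[i], category = svc$category[i]))
    }), "Point", wr(sprintf("services_%s.geojson", cat_name)))
  }

  write_geojson(lapply(region$green, function(gp) {
    list(geometry = gp$ring,
         properties = list(polygon_id = gp$polygon_id, tag = gp$tag,
                           area_m2 = gp$area_m2))
  }), "Polygon", wr("greenspace.geojson"))

  for (pol in names(region$rasters)) {
    write_ascii_grid(region$rasters[[pol]], wr(sprintf("%s.asc", pol)))
  }

  cfg_list <- unclass(region$config)
  # named atomic vectors serialise as nameless arrays; keep names via lists
  cfg_list$category_counts <- as.list(cfg_list$category_counts)
  cfg_json <- jsonlite::toJSON(cfg_list, auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = region$config$seed,
                   config = cfg_list,
                   config_hash = fnv1a32(as.character(cfg_json)),
                   files = files,
                   counts = list(zones = length(region$zones),
                                 postcodes = nrow(region$postcodes),
                                 green = length(region$green),
                                 rasters = length(region$rasters)))
  con <- file(file.path(directory, "manifest.json"), open = "wb")
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                           pretty = TRUE)), con, sep = "\n")
  close(con)
  invisible(manifest)
}

#' Read a region written by [write_region()]
#'
#' @param directory directory containing the region files and manifest.
#' @return `synthetic_region` equal to the one written.
#' @export
read_region <- function(directory) {
  mpath <- file.path(directory, "manifest.json")
  if (!file.exists(mpath)) stop(sprintf("manifest not found: %s", mpath))
  manifest <- jsonlite::fromJSON(mpath, simplifyVector = TRUE)
  cfg <- manifest$config
  config <- region_config(seed = cfg$seed, extent_km = cfg$extent_km,
                          n_zones = cfg$n_zones,
                          postcodes_per_zone = cfg$postcodes_per_zone,
                          category_counts = unlist(cfg$category_counts),
                          n_green_polygons = cfg$n_green_polygons,
                          raster_cell_km = cfg$raster_cell_km,
                          urban_fraction = cfg$urban_fraction)
  extent_m <- config$extent_km * 1000

  nodes <- read_csv_table(file.path(directory, "nodes.csv"),
                          c(node_id = "character", easting_m = "numeric",
                            northing_m = "numeric"))
  edges <- read_csv_table(file.path(directory, "edges.csv"),
                          c(edge_id = "character", from_node = "character",
                            to_node = "character", length_km = "numeric",
                            oneway = "integer"))
  network <- build_graph(edges, nodes)
  postcodes <- read_csv_table(file.path(directory, "postcodes.csv"),
                              c(pcd = "character", easting_m = "numeric",
                                northing_m = "numeric", zone_code = "character"))

  zj <- read_geojson(file.path(directory, "zones.geojson"))
  zones <- lapply(zj$features, function(f) {
    ring <- f$geometry
    bb <- ring_bbox(ring)
    list(zone_code = f$properties$zone_code, ring = ring,
         population = as.numeric(f$properties$population),
         zone_class = f$properties$zone_class,
         centroid = c((bb[1L] + bb[3L]) / 2, (bb[2L] + bb[4L]) / 2))
  })

  services <- list()
  for (cat_name in service_categories()) {
    path <- file.path(directory, sprintf("services_%s.geojson", cat_name))
    if (!file.exists(path)) next
    sj <- read_geojson(path)
    services[[cat_name]] <- data.frame(
      site_id = vapply(sj$features, function(f) f$properties$site_id, character(1)),
      category = cat_name,
      easting_m = vapply(sj$features, function(f) f$geometry[1L], numeric(1)),
      northing_m = vapply(sj$features, function(f) f$geometry[2L], numeric(1)),
      stringsAsFactors = FALSE)
  }

  gj <- read_geojson(file.path(directory, "greenspace.geojson"))
  green <- lapply(gj$features, function(f) {
    list(polygon_id = f$properties$polygon_id, ring = f$geometry,
         area_m2 = as.numeric(f$properties$area_m2), tag = f$properties$tag)
  })

  rasters <- list()
  for (pol in c("no2", "pm10", "so2")) {
    path <- file.path(directory, sprintf("%s.asc", pol))
    if (file.exists(path)) rasters[[pol]] <- read_ascii_grid(path, pollutant = pol)
  }

  structure(list(config = config, extent_m = extent_m,
                 centre = c(extent_m / 2, extent_m / 2), network = network,
                 postcodes = postcodes, zones = zones, services = services,
                 green = green, rasters = rasters),
            class = "synthetic_region")
}
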
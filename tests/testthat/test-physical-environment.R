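# Green-space buffer areas and zonal raster means, checked against closed
# forms, a Monte-Carlo area oracle and a fine-rasterisation oracle.

square <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
gp <- function(ring, id = "G1") list(polygon_id = id, ring = ring,
                                     area_m2 = polygon_area(ring), tag = "park")
pc <- function(x, y) list(easting_m = x, northing_m = y)

test_that("greenspace_area handles empty, contained and overlapping cases", {
  expect_equal(greenspace_area(pc(0, 0), list()), 0)
  # 100 m square fully inside the 900 m buffer
  expect_equal(greenspace_area(pc(0, 0), list(gp(square(100, 100, 100)))), 10000)
  # two overlapping squares: union, not sum
  a <- gp(square(0, 0, 100), "a"); b <- gp(square(50, 0, 100), "b")
  expect_equal(greenspace_area(pc(0, 0), list(a, b)), 15000)
  # polygon entirely outside the buffer
  expect_equal(greenspace_area(pc(0, 0), list(gp(square(2000, 2000, 100)))), 0)
  # self-intersecting ring rejected with its id
  bowtie <- cbind(c(0, 100, 0, 100), c(0, 100, 100, 0))
  expect_error(greenspace_area(pc(0, 0), list(gp(bowtie, "bad"))), "bad")
})

test_that("clipped area matches the Monte-Carlo oracle on a random scattering", {
  set.seed(11)
  rings <- lapply(1:25, function(i) {
    square(runif(1, -1500, 1300), runif(1, -1500, 1300), runif(1, 150, 450))
  })
  green <- lapply(seq_along(rings), function(i) gp(rings[[i]], sprintf("G%02d", i)))
  area <- greenspace_area(pc(0, 0), green, buffer_m = 900)
  mc <- oracle_mc_green_area(0, 0, 900, rings, n_samples = 4e5, seed = 5)
  expect_lt(abs(area - mc) / mc, 0.01)
})

test_that("greenspace_area is monotone in the buffer radius and bounded", {
  set.seed(21)
  green <- lapply(1:10, function(i) {
    gp(square(runif(1, -900, 700), runif(1, -900, 700), runif(1, 100, 300)),
       sprintf("G%d", i))
  })
  radii <- c(600, 700, 800, 900)   # the published sensitivity radii
  areas <- vapply(radii, function(r) greenspace_area(pc(0, 0), green, buffer_m = r),
                  numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_true(all(areas <= pi * radii^2))
  # saturation: green covering the whole buffer approaches the disc area
  big <- list(gp(square(-2000, -2000, 4000)))
  full <- greenspace_area(pc(0, 0), big, buffer_m = 900)
  expect_lt(abs(full - pi * 900^2) / (pi * 900^2), 1e-3)
})

test_that("whole_polygon mode counts intersecting polygons uncut", {
  half_in <- gp(square(800, -50, 300))   # straddles the 900 m boundary
  clipped <- greenspace_area(pc(0, 0), list(half_in), mode = "clipped")
  whole <- greenspace_area(pc(0, 0), list(half_in), mode = "whole_polygon")
  expect_lt(clipped, 90000)
  expect_equal(whole, 90000)
})

test_that("raster_zone_mean obeys closed-form cases and the membership rule", {
  vals <- matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE)   # row 1 = north
  grid <- raster_grid(vals, 0, 0, cellsize_m = 1000, pollutant = "no2")
  zone4 <- list(zone_code = "Z1", ring = square(0, 0, 2000))
  expect_equal(raster_zone_mean(grid, zone4), 2.5)
  # uniform raster -> the constant
  gu <- raster_grid(matrix(7, 3, 3), 0, 0, 1000, "so2")
  zirr <- list(zone_code = "Z2", ring = cbind(c(300, 2700, 1500), c(300, 600, 2500)))
  expect_equal(raster_zone_mean(gu, zirr), 7)
  # zone inside a single cell
  z1 <- list(zone_code = "Z3", ring = square(100, 1100, 300))
  expect_equal(raster_zone_mean(grid, z1), 1)
  # membership is positive-area overlap: zone slivers into cell 2 of the
  # north row but contains only cell 1's centre
  z2 <- list(zone_code = "Z4", ring = square(300, 1100, 800))
  expect_equal(raster_zone_mean(grid, z2), 1.5)
  expect_equal(raster_zone_mean(grid, z2, rule = "centre"), 1)
  # zone outside raster errors with zone and pollutant
  zout <- list(zone_code = "Zout", ring = square(5000, 5000, 100))
  expect_error(raster_zone_mean(grid, zout), "Zout")
  # all-nodata error
  gna <- raster_grid(matrix(NA_real_, 2, 2), 0, 0, 1000, "pm10")
  expect_error(raster_zone_mean(gna, zone4), "nodata")
})

test_that("zonal means match the 10 m fine-rasterisation oracle on seeded zones", {
  set.seed(123)
  vals <- matrix(round(runif(100, 2, 40), 3), 10, 10)
  grid <- raster_grid(vals, 0, 0, 1000, "no2")
  for (i in 1:10) {
    # irregular polygon, off-grid vertices, in general position for the oracle
    ring <- sample_generic_zone(grid, seed = 300 + i, centre_range = c(2500, 7500),
                                n_vertices = 5, rad_range = c(600, 1800))
    zone <- list(zone_code = sprintf("Z%02d", i), ring = ring)
    expect_equal(raster_zone_mean(grid, zone),
                 oracle_zone_mean_fine(grid, ring, fine_m = 10),
                 tolerance = 1e-12, label = sprintf("zone %d", i))
  }
})

test_that("zonal mean lies within the contributing cells' range", {
  reg <- tiny_region()
  for (pol in names(reg$rasters)) {
    rg <- reg$rasters[[pol]]
    for (z in reg$zones[1:6]) {
      m <- raster_zone_mean(rg, z)
      expect_gte(m, min(rg$values)); expect_lte(m, max(rg$values))
    }
  }
})
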
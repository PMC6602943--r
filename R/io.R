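# Plain-text interchange: schema-checked CSV, minimal GeoJSON (planar
# coordinates), and ESRI ASCII grids. All numeric output is fixed 6-decimal
# notation so byte-identical reruns are testable.

fmt6 <- function(x) formatC(x, format = "f", digits = 6)

# FNV-1a 32-bit over a character scalar; used to stamp configs into manifests.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor the low byte only; h is kept as a double in [0, 2^32)
    lo_b <- h %% 256
    h <- (h - lo_b) + bitwXor(as.integer(lo_b), b)
    # 32-bit multiply by 16777619 without overflow, via 16-bit halves
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a table as fixed-format CSV
#'
#' Numeric columns are written with 6 decimal places, integer and character
#' columns verbatim; rows in the order given. Line endings are LF.
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt6(col) else as.character(col)
  })
  header <- paste(names(df), collapse = ",")
  if (nrow(df) == 0L) {
    lines <- header
  } else {
    body <- do.call(paste, c(cols, sep = ","))
    lines <- c(header, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a schema-checked CSV table
#'
#' @param path CSV file with a header row.
#' @param schema named character vector mapping required column names to one
#'   of `"character"`, `"numeric"`, `"integer"`. Extra columns are kept as
#'   character.
#' @return data frame with columns coerced per schema.
#' @export
read_csv_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(df))
    if (length(missing)) {
      stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
    }
    for (nm in names(schema)) {
      type <- schema[[nm]]
      if (type %in% c("numeric", "integer")) {
        raw <- df[[nm]]
        val <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(val) & !(raw %in% c("NA", "")))
        if (length(bad)) {
          stop(sprintf("%s: column '%s' has non-numeric value '%s' at data row %d",
                       path, nm, raw[bad[1L]], bad[1L]))
        }
        df[[nm]] <- if (type == "integer") as.integer(val) else val
      }
    }
  }
  df
}

json_num <- function(x) {
  # full-precision numbers for GeoJSON coordinates
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE), character(1))
}

geojson_feature <- function(geometry_type, coords_json, properties) {
  props <- jsonlite::toJSON(properties, auto_unbox = TRUE, digits = NA)
  sprintf('{"type":"Feature","geometry":{"type":"%s","coordinates":%s},"properties":%s}',
          geometry_type, coords_json, props)
}

ring_coords_json <- function(ring) {
  m <- as_ring(ring)
  m <- rbind(m, m[1L, ])  # GeoJSON rings are explicitly closed
  pts <- paste0("[", json_num(m[, 1L]), ",", json_num(m[, 2L]), "]", collapse = ",")
  paste0("[[", pts, "]]")
}

#' Write point or polygon features as GeoJSON
#'
#' Coordinates are planar metres (no CRS member is written). `features` is a
#' list of lists with `geometry` (length-2 point or ring matrix) and
#' `properties` (named list).
#'
#' @param features list of features.
#' @param type `"Point"` or `"Polygon"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(features, type = c("Point", "Polygon"), path) {
  type <- match.arg(type)
  feats <- vapply(features, function(f) {
    cj <- if (type == "Point") {
      sprintf("[%s,%s]", json_num(f$geometry[1L]), json_num(f$geometry[2L]))
    } else {
      ring_coords_json(f$geometry)
    }
    geojson_feature(type, cj, f$properties)
  }, character(1))
  txt <- paste0('{"type":"FeatureCollection","features":[', paste(feats, collapse = ","), "]}")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(path)
}

#' Read a GeoJSON FeatureCollection written by this package
#'
#' @param path GeoJSON file of Point or Polygon features.
#' @return list with `type` and `features`; each feature has `geometry`
#'   (numeric length-2 for points, ring matrix for polygons) and `properties`.
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = FALSE)
  if (is.null(doc$type) || doc$type != "FeatureCollection") {
    stop(sprintf("%s: not a GeoJSON FeatureCollection", path))
  }
  feats <- lapply(doc$features, function(f) {
    gtype <- f$geometry$type
    if (gtype == "Point") {
      geom <- as.numeric(unlist(f$geometry$coordinates))
    } else if (gtype == "Polygon") {
      ring <- f$geometry$coordinates[[1L]]
      m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
      if (nrow(m) < 4L || any(m[1L, ] != m[nrow(m), ])) {
        stop(sprintf("%s: polygon ring not closed", path))
      }
      geom <- m[-nrow(m), , drop = FALSE]
    } else {
      stop(sprintf("%s: unsupported geometry type '%s'", path, gtype))
    }
    list(geometry = geom, properties = f$properties, type = gtype)
  })
  types <- unique(vapply(feats, `[[`, character(1), "type"))
  list(type = types, features = feats)
}

#' Raster grid constructor
#'
#' Row-major value matrix with row 1 the northernmost row, matching the ESRI
#' ASCII grid layout. Cell (i, j) covers
#' x in \[xll + (j-1)s, xll + js\], y in \[yll + (nrow-i)s, yll + (nrow-i+1)s\].
#'
#' @param values numeric matrix (row 1 = top/north row).
#' @param xll,yll lower-left corner of the grid (m).
#' @param cellsize_m cell side (m), positive.
#' @param pollutant label, e.g. `"no2"`.
#' @param nodata marker value for missing cells.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll, yll, cellsize_m = 1000, pollutant = "",
                        nodata = -9999) {
  stopifnot(is.matrix(values), cellsize_m > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize_m = cellsize_m, pollutant = pollutant, nodata = nodata),
            class = "raster_grid")
}

#' Write an ESRI ASCII grid
#'
#' @param grid `raster_grid` object.
#' @param path output `.asc` file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %s", fmt6(grid$xll)),
    sprintf("yllcorner %s", fmt6(grid$yll)),
    sprintf("cellsize %s", fmt6(grid$cellsize_m)),
    sprintf("NODATA_value %s", format(grid$nodata, scientific = FALSE))
  )
  rows <- apply(v, 1L, function(r) paste(fmt6(r), collapse = " "))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Honours all six header fields including `NODATA_value`; nodata cells are
#' stored as `NA` in the value matrix.
#'
#' @param path `.asc` file.
#' @param pollutant optional label to attach.
#' @return `raster_grid` object.
#' @export
read_ascii_grid <- function(path, pollutant = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2L])
      i <- i + 1L
    } else break
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[req]])) stop(sprintf("%s: missing header field '%s'", path, req))
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  toks <- unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) stop(sprintf("%s: non-numeric grid value '%s'", path, toks[which(is.na(vals))[1L]]))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr) {
    stop(sprintf("%s: expected %d values (%d x %d), found %d",
                 path, nc * nr, nr, nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, pollutant, nodata)
}
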
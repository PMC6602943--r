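# End-to-end pipeline: generate (or load) a region, measure the 14
# indicators, construct the index, and optionally write every interchange
# file. Given a fixed config and seed the output directory is byte-identical
# across runs.

#' Run the full pipeline
#'
#' Chains region generation, accessibility routing, physical-environment
#' measurement, zone aggregation and index construction. If `out_dir` is
#' given, writes the region files (under `region/`), the postcode-level
#' measures (`access_postcode.csv`, `green_postcode.csv`), zone-level air
#' means (`air_zone.csv`), the Table-4-shaped outputs (`ahah_components.csv`,
#' `ahah_index.csv`), correlation diagnostics
#' (`diagnostics_correlations.csv`) and the effective configuration
#' (`config.json`).
#'
#' @param config `region_config`, or an already generated/loaded
#'   `synthetic_region`.
#' @param out_dir optional output directory.
#' @param buffer_m green-space buffer radius (m), default 900.
#' @param green_area_mode `"clipped"` or `"whole_polygon"`.
#' @param overlap_rule `"overlap"` or `"centre"` raster cell membership.
#' @param corr correlation method for diagnostics.
#' @param weights weight structure, see [ahah_weights()].
#' @param allow_unreachable tolerate unreachable origins as `Inf` distances.
#' @param quiet suppress progress messages.
#' @return the `ahah` object, with the region and the measurement list
#'   attached as attributes `region` and `measures`.
#' @export
run_pipeline <- function(config, out_dir = NULL, buffer_m = 900,
                         green_area_mode = "clipped", overlap_rule = "overlap",
                         corr = "pearson", weights = ahah_weights(),
                         allow_unreachable = FALSE, quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  region <- if (inherits(config, "synthetic_region")) config else generate_region(config)
  say("region: %d zones, %d postcodes", length(region$zones), nrow(region$postcodes))

  meas <- measure_region(region, buffer_m = buffer_m,
                         green_area_mode = green_area_mode,
                         overlap_rule = overlap_rule,
                         allow_unreachable = allow_unreachable)
  say("measured %d postcode-category distances", nrow(meas$access))

  fit <- ahah(meas$table, weights = weights)
  diag <- ahah_diagnostics(meas$table, method = corr, fit = fit)
  attr(fit, "region") <- region
  attr(fit, "measures") <- meas
  attr(fit, "diagnostics") <- diag

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_region(region, file.path(out_dir, "region"))
    write_csv_table(meas$access[, c("pcd", "category", "distance_km")],
                    file.path(out_dir, "access_postcode.csv"))
    write_csv_table(meas$green, file.path(out_dir, "green_postcode.csv"))
    write_csv_table(meas$air, file.path(out_dir, "air_zone.csv"))
    write_ahah_outputs(fit, diag, out_dir)
    eff <- list(config = unclass(region$config), buffer_m = buffer_m,
                green_area_mode = green_area_mode, overlap_rule = overlap_rule,
                corr = corr,
                polarity = "higher score / decile = less healthy; rank 1 = healthiest",
                counts = list(zones = length(region$zones),
                              postcodes = nrow(region$postcodes),
                              access_rows = nrow(meas$access)))
    cfg_json <- jsonlite::toJSON(eff, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    eff$config_hash <- fnv1a32(as.character(cfg_json))
    con <- file(file.path(out_dir, "config.json"), open = "wb")
    writeLines(as.character(jsonlite::toJSON(eff, auto_unbox = TRUE, digits = NA,
                                             pretty = TRUE)), con, sep = "\n")
    close(con)
    say("wrote outputs to %s", out_dir)
  }
  fit
}

# Table-4-shaped CSV outputs plus the diagnostics matrix.
write_ahah_outputs <- function(fit, diag, out_dir) {
  idx <- merge(fit$index,
               fit$domains[, c("zone_code", "retail_X", "retail_decile",
                               "health_X", "health_decile",
                               "physical_X", "physical_decile")],
               by = "zone_code", sort = TRUE)
  idx <- idx[, c("zone_code", "index_score", "index_rank", "index_decile",
                 "retail_X", "retail_decile", "health_X", "health_decile",
                 "physical_X", "physical_decile")]
  write_csv_table(idx, file.path(out_dir, "ahah_index.csv"))

  full <- as.data.frame(fit)
  specs <- indicator_specs()
  comp_cols <- c("zone_code", specs$name, paste0(specs$name, "_decile"))
  write_csv_table(full[, comp_cols], file.path(out_dir, "ahah_components.csv"))

  cm <- diag$indicator_cor
  cdf <- data.frame(indicator = rownames(cm), stringsAsFactors = FALSE)
  for (j in colnames(cm)) cdf[[j]] <- cm[, j]
  write_csv_table(cdf, file.path(out_dir, "diagnostics_correlations.csv"))
  invisible(NULL)
}
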
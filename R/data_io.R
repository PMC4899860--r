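# Tabular I/O for the pipeline. Two plain delimited-text dialects are
# supported: a polygon table (one row per vertex of each mapped feature) and a
# genet table (one row per tracked genet-year, circle representation). Both
# carry the site / quadrat / group / year keys used throughout.

QUADRAT_CM <- 100          # quadrats are 1 m^2, coordinates in cm
QUADRAT_AREA_CM2 <- 1e4

climate_base_covariates <- c("pptLag", "ppt1", "ppt2", "T1", "T2")
climate_precip_covariates <- c("pptLag", "ppt1", "ppt2")
climate_temp_covariates <- c("T1", "T2")

#' Names of the climate covariates
#'
#' Five covariates describe each year-to-year transition: water-year
#' precipitation preceding the transition (`pptLag`), critical-season
#' precipitation and temperature in the first (`ppt1`, `T1`) and second
#' (`ppt2`, `T2`) year of the transition. Within-year precipitation x
#' temperature interactions are available as derived columns.
#'
#' @param interactions Include the derived interaction names.
#' @return Character vector of covariate names.
#' @export
climate_covariate_names <- function(interactions = FALSE) {
  if (interactions) c(climate_base_covariates, "ppt1_T1", "ppt2_T2")
  else climate_base_covariates
}

new_quadrat_map <- function(df) {
  structure(df, class = c("quadrat_map", class(tibble::tibble())))
}

#' Assemble a quadrat map from features
#'
#' @param features Tibble with columns `site, quadrat, group, year, species,
#'   feature_id, is_point, geom` where `geom` is a list of 2-column vertex
#'   matrices (a 1-row matrix for point plants).
#' @return A `quadrat_map` tibble.
#' @export
quadrat_map <- function(features) {
  req <- c("site", "quadrat", "group", "year", "species", "feature_id",
           "is_point", "geom")
  missing <- setdiff(req, names(features))
  if (length(missing)) {
    abort(paste("quadrat_map is missing columns:", paste(missing, collapse = ", ")))
  }
  for (g in features$geom) {
    v <- as.matrix(g)
    if (any(v < 0) || any(v > QUADRAT_CM)) {
      abort("coordinate outside the [0, 100] cm quadrat extent")
    }
  }
  new_quadrat_map(tibble::as_tibble(features))
}

#' Read mapped-quadrat data from delimited text
#'
#' The `polygon-table` dialect has one row per vertex with columns
#' `site,quadrat,group,year,species,feature_id,vertex_index,x,y`; a feature
#' with a single vertex is a point plant. The `genet-table` dialect holds
#' pre-tracked circle-represented genets
#' (`site,quadrat,group,year,species,genet_id,area_cm2,x,y`); these are
#' rendered back to exact-area polygons so both dialects yield the same map
#' structure.
#'
#' Features with malformed geometry (2 vertices, or self-intersecting
#' outlines) are dropped with a warning; coordinates outside the quadrat are a
#' hard error.
#'
#' @param path File path.
#' @param dialect `"polygon-table"` or `"genet-table"`.
#' @return A [quadrat_map()] tibble, one row per feature.
#' @export
read_quadrat_maps <- function(path, dialect = c("polygon-table", "genet-table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste("file not found:", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "genet-table") {
    return(genet_records_to_map(validate_genet_table(df)))
  }
  req <- c("site", "quadrat", "group", "year", "species", "feature_id",
           "vertex_index", "x", "y")
  missing <- setdiff(req, names(df))
  if (length(missing)) abort(paste("missing columns:", paste(missing, collapse = ", ")))
  if (any(df$x < 0 | df$x > QUADRAT_CM | df$y < 0 | df$y > QUADRAT_CM)) {
    abort("coordinate outside the [0, 100] cm quadrat extent")
  }
  keys <- c("site", "quadrat", "group", "year", "species", "feature_id")
  feats <- df |>
    arrange(.data$vertex_index) |>
    group_by(across(all_of(keys))) |>
    summarise(geom = list(cbind(x = .data$x, y = .data$y)), .groups = "drop")
  n_vert <- map_int(feats$geom, nrow)
  bad <- n_vert == 2 |
    (n_vert >= 3 & !map_lgl(feats$geom, poly_is_simple))
  if (any(bad)) {
    warn(sprintf("dropping %d feature(s) with malformed geometry", sum(bad)))
    feats <- feats[!bad, , drop = FALSE]
  }
  feats$is_point <- map_int(feats$geom, nrow) == 1L
  quadrat_map(feats)
}

#' Write a quadrat map as a polygon table
#'
#' @param maps A [quadrat_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quadrat_maps <- function(maps, path) {
  rows <- pmap(maps, function(site, quadrat, group, year, species, feature_id,
                               is_point, geom, ...) {
    v <- as.matrix(geom)
    tibble::tibble(site = site, quadrat = quadrat, group = group, year = year,
                   species = species, feature_id = feature_id,
                   vertex_index = seq_len(nrow(v)), x = v[, 1], y = v[, 2])
  })
  readr::write_csv(list_rbind(rows), path, progress = FALSE)
  invisible(path)
}

validate_genet_table <- function(df) {
  req <- c("site", "quadrat", "group", "year", "species", "genet_id",
           "area_cm2", "x", "y")
  missing <- setdiff(req, names(df))
  if (length(missing)) abort(paste("missing columns:", paste(missing, collapse = ", ")))
  if (any(df$x < 0 | df$x > QUADRAT_CM | df$y < 0 | df$y > QUADRAT_CM)) {
    abort("centroid outside the [0, 100] cm quadrat extent")
  }
  if (any(df$area_cm2 <= 0)) abort("genet area must be positive")
  dup <- df |>
    count(.data$site, .data$quadrat, .data$year, .data$species, .data$genet_id) |>
    filter(.data$n > 1)
  if (nrow(dup)) abort("duplicate genet id within species-quadrat-year")
  tibble::as_tibble(df)
}

genet_records_to_map <- function(records) {
  feats <- records |>
    mutate(
      feature_id = .data$genet_id,
      is_point = .data$area_cm2 <= POINT_AREA_CM2,
      geom = pmap(list(.data$x, .data$y, .data$area_cm2),
                  function(x, y, a) clip_polygon_to_quadrat(regular_polygon(x, y, a)))
    ) |>
    select("site", "quadrat", "group", "year", "species", "feature_id",
           "is_point", "geom")
  quadrat_map(feats)
}

# Genets rendered near the quadrat edge may poke outside; clamp vertices so
# map invariants hold (areas change negligibly for interior plants).
clip_polygon_to_quadrat <- function(xy) {
  xy[, 1] <- pmin(QUADRAT_CM, pmax(0, xy[, 1]))
  xy[, 2] <- pmin(QUADRAT_CM, pmax(0, xy[, 2]))
  xy
}

#' Read or write tracked genet records
#'
#' Genet tables hold one row per genet-year in the circle representation:
#' `site,quadrat,group,year,species,genet_id,area_cm2,x,y` (plus an optional
#' `is_recruit` flag).
#'
#' @param path File path.
#' @return A tibble of genet records.
#' @export
read_genet_records <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  validate_genet_table(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_genet_records
#' @param records Genet-record tibble.
#' @export
write_genet_records <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a climate covariate table
#'
#' One row per site and transition year with the five covariates of
#' [climate_covariate_names()]. Duplicate years within a site and gaps inside
#' the modelled span are hard errors; interaction columns are recomputed, not
#' read.
#'
#' @param path File path.
#' @return Climate tibble with columns `site, year` and the five covariates.
#' @export
read_climate <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_climate(df)
}

validate_climate <- function(df) {
  req <- c("site", "year", climate_base_covariates)
  missing <- setdiff(req, names(df))
  if (length(missing)) abort(paste("missing columns:", paste(missing, collapse = ", ")))
  dup <- df |> count(.data$site, .data$year) |> filter(.data$n > 1)
  if (nrow(dup)) abort("duplicate year key in climate table")
  gaps <- df |>
    group_by(.data$site) |>
    summarise(gap = length(setdiff(seq(min(.data$year), max(.data$year)), .data$year)))
  if (any(gaps$gap > 0)) abort("missing year within the modelled span of the climate table")
  if (anyNA(df[, climate_base_covariates])) abort("missing covariate values in climate table")
  tibble::as_tibble(df[, req])
}

#' @rdname read_climate
#' @param climate Climate tibble.
#' @export
write_climate <- function(climate, path) {
  readr::write_csv(climate[, c("site", "year", climate_base_covariates)], path,
                   progress = FALSE)
  invisible(path)
}

#' Add within-year precipitation x temperature interaction columns
#'
#' @param climate Climate tibble.
#' @return The tibble with `ppt1_T1` and `ppt2_T2` columns appended.
#' @export
climate_interactions <- function(climate) {
  climate |>
    mutate(ppt1_T1 = .data$ppt1 * .data$T1, ppt2_T2 = .data$ppt2 * .data$T2)
}

#' Pipeline configuration
#'
#' `default_config()` returns every tunable with its default;
#' `load_config()` overlays a YAML file on the defaults. Unknown keys are a
#' hard error so typos cannot silently fall back to defaults. The resolved
#' configuration is embedded in results objects for provenance.
#'
#' @return Nested named list of settings.
#' @export
default_config <- function() {
  list(
    tracking = list(buffer_cm = 5, raster_res_cm = 0.25, repair_polygons = TRUE),
    mesh = list(nodes = 100L, lower_cm2 = 0.2, upper_pad_log = 1),
    equilibrium = list(burn_in = 500L, window = 2000L),
    invasion = list(steps = 1000L, invader_cover_cm2 = 1e-6),
    perturbation = list(mean_pct = 1, variance_pct = 10, temp_mode = "additive"),
    ibm = list(reps = 50L, boundary = "absorbing"),
    recruitment = list(p_mix = 0.5),
    seed = 1L
  )
}

#' @rdname default_config
#' @param path Path to a YAML file; `NULL` or an empty file yields the
#'   defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste("config file not found:", path))
    user <- yaml::read_yaml(path)
    if (length(user)) {
      check_config_keys(user, cfg, prefix = NULL)
      cfg <- modifyList(cfg, user)
    }
  }
  validate_config(cfg)
  cfg
}

check_config_keys <- function(user, ref, prefix) {
  unknown <- setdiff(names(user), names(ref))
  if (length(unknown)) {
    key <- if (is.null(prefix)) unknown[1] else paste(prefix, unknown[1], sep = ".")
    abort(paste("unknown config key:", key))
  }
  for (k in names(user)) {
    if (is.list(ref[[k]]) && is.list(user[[k]])) {
      check_config_keys(user[[k]], ref[[k]], prefix = if (is.null(prefix)) k else paste(prefix, k, sep = "."))
    }
  }
}

validate_config <- function(cfg) {
  if (cfg$mesh$nodes < 2) abort("mesh.nodes must be at least 2")
  if (cfg$mesh$lower_cm2 <= 0) abort("mesh.lower_cm2 must be positive")
  if (cfg$tracking$buffer_cm < 0) abort("tracking.buffer_cm must be non-negative")
  if (cfg$recruitment$p_mix < 0 || cfg$recruitment$p_mix > 1) {
    abort("recruitment.p_mix must lie in [0, 1]")
  }
  if (!cfg$ibm$boundary %in% c("absorbing", "periodic")) {
    abort("ibm.boundary must be 'absorbing' or 'periodic'")
  }
  if (cfg$perturbation$mean_pct <= 0 || cfg$perturbation$variance_pct <= 0) {
    abort("perturbation magnitudes must be positive")
  }
  invisible(cfg)
}
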
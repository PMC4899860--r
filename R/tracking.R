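# Genet tracking across yearly maps. Polygons mapped in year t-1 are dilated
# by a fixed buffer (absorbing mapping error and short-distance clonal
# movement); each conspecific year-t polygon then inherits the identity of the
# buffered antecedent with which it shares the greatest overlap area, or is
# labelled a recruit if it overlaps none. Genets may fragment (several year-t
# polygons inheriting one identity) and coalesce.

feature_geoms <- function(map_rows) {
  pmap(list(map_rows$geom, map_rows$is_point), function(g, is_pt) {
    v <- as.matrix(g)
    if (is_pt || nrow(v) < 3) regular_polygon(v[1, 1], v[1, 2], POINT_AREA_CM2)
    else v
  })
}

feature_area <- function(map_rows) {
  map_dbl(feature_geoms(map_rows), poly_area)
}

#' Assign year-t features to antecedent genets
#'
#' Implements one step of the tracking algorithm for all quadrats and species
#' shared between two yearly maps. Ties on greatest overlap — typically a
#' small year-t polygon contained entirely within several buffered antecedent
#' regions — are broken by the nearest antecedent centroid, then larger
#' antecedent area, then lower genet id, so output is deterministic and a
#' stationary genet always reclaims its own identity.
#'
#' @param prev [quadrat_map()] for year t-1 with a `genet_id` column.
#' @param curr [quadrat_map()] for year t.
#' @param buffer_cm Buffer added to year t-1 polygons before overlap
#'   computation (cm).
#' @param res Raster resolution for overlap areas (cm).
#' @return `curr` with columns `genet_id` (NA for recruits), `is_recruit`,
#'   and `overlap_cm2` (overlap with the inherited antecedent).
#' @export
track_genets <- function(prev, curr, buffer_cm = 5, res = 0.25) {
  if (!"genet_id" %in% names(prev)) abort("`prev` must carry a genet_id column")
  out <- curr
  out$genet_id <- NA_character_
  out$is_recruit <- TRUE
  out$overlap_cm2 <- 0
  keys <- c("site", "quadrat", "species")
  curr_groups <- split(seq_len(nrow(curr)), interaction(curr$site, curr$quadrat, curr$species, drop = TRUE))
  prev_key <- interaction(prev$site, prev$quadrat, prev$species, drop = TRUE)
  for (idx in curr_groups) {
    k <- interaction(curr$site[idx[1]], curr$quadrat[idx[1]], curr$species[idx[1]])
    pidx <- which(as.character(prev_key) == as.character(k))
    if (!length(pidx)) next
    prev_rows <- prev[pidx, , drop = FALSE]
    prev_geoms <- buffer_polygons(feature_geoms(prev_rows), buffer = buffer_cm)
    prev_area <- feature_area(prev_rows)
    prev_cent <- map(feature_geoms(prev_rows), poly_centroid)
    curr_feats <- feature_geoms(curr[idx, , drop = FALSE])
    curr_geoms <- map(curr_feats, qd_geom)
    curr_cent <- map(curr_feats, poly_centroid)
    for (ci in seq_along(idx)) {
      ov <- map_dbl(prev_geoms, geom_overlap, b = curr_geoms[[ci]], res = res)
      if (!any(ov > 0)) next
      best <- which(ov == max(ov))
      if (length(best) > 1) {
        d2 <- map_dbl(prev_cent[best], function(p) {
          sum((p - curr_cent[[ci]])^2)
        })
        best <- best[order(d2, -prev_area[best],
                           as.character(prev_rows$genet_id[best]))][1]
      }
      out$genet_id[idx[ci]] <- as.character(prev_rows$genet_id[best])
      out$is_recruit[idx[ci]] <- FALSE
      out$overlap_cm2[idx[ci]] <- max(ov)
    }
  }
  out
}

#' Collapse a genet-year's polygons into the circle representation
#'
#' Each genet in each year is represented by a circle whose area is the sum of
#' the areas of all member polygons and whose location is the area-weighted
#' centroid of those polygons. Point plants contribute the fixed
#' [POINT_AREA_CM2].
#'
#' @param map_rows Feature rows (one genet-year; a `quadrat_map` subset).
#' @return One-row tibble with `area_cm2`, `x`, `y`.
#' @export
genets_to_circles <- function(map_rows) {
  if (nrow(map_rows) == 0) abort("genets_to_circles needs at least one polygon")
  areas <- feature_area(map_rows)
  cents <- map(feature_geoms(map_rows), poly_centroid)
  cx <- sum(areas * map_dbl(cents, 1)) / sum(areas)
  cy <- sum(areas * map_dbl(cents, 2)) / sum(areas)
  tibble::tibble(area_cm2 = sum(areas), x = cx, y = cy)
}

#' Track a multi-year map series into genet records
#'
#' Runs [track_genets()] over consecutive observed years of every quadrat and
#' reduces tracked features to circle-represented genet records. Years
#' following a gap in the census are re-seeded: every feature receives a fresh
#' identity and an undetermined recruit flag (`NA`), so no transition spans
#' the gap.
#'
#' @param maps [quadrat_map()] covering all years.
#' @param buffer_cm,res As in [track_genets()].
#' @return Genet-record tibble: `site, quadrat, group, species, genet_id,
#'   year, area_cm2, x, y, is_recruit`.
#' @export
track_series <- function(maps, buffer_cm = 5, res = 0.25) {
  out <- list()
  for (qd in split(maps, interaction(maps$site, maps$quadrat, drop = TRUE))) {
    years <- sort(unique(qd$year))
    counter <- new.env()
    assign_ids <- function(rows, recruit_flag) {
      ids <- character(nrow(rows))
      for (i in seq_len(nrow(rows))) {
        sp <- rows$species[i]
        n <- (get0(sp, envir = counter) %||% 0L) + 1L
        assign(sp, n, envir = counter)
        ids[i] <- sprintf("%s_%03d", sp, n)
      }
      rows$genet_id <- ids
      rows$is_recruit <- recruit_flag
      rows$overlap_cm2 <- NA_real_
      rows
    }
    prev <- assign_ids(qd[qd$year == years[1], , drop = FALSE], NA)
    out[[length(out) + 1]] <- reduce_to_records(prev)
    for (yi in seq_along(years)[-1]) {
      curr <- qd[qd$year == years[yi], , drop = FALSE]
      if (years[yi] - years[yi - 1] == 1L) {
        tracked <- track_genets(prev, curr, buffer_cm = buffer_cm, res = res)
        recruits <- which(tracked$is_recruit)
        if (length(recruits)) {
          tracked[recruits, ] <- assign_ids(tracked[recruits, , drop = FALSE], TRUE)
        }
      } else {
        tracked <- assign_ids(curr, NA)   # census gap: identities unresolvable
      }
      out[[length(out) + 1]] <- reduce_to_records(tracked)
      prev <- tracked
    }
  }
  list_rbind(out) |>
    arrange(.data$site, .data$quadrat, .data$species, .data$year, .data$genet_id)
}

reduce_to_records <- function(tracked) {
  tracked |>
    group_by(.data$site, .data$quadrat, .data$group, .data$species,
             .data$genet_id, .data$year) |>
    group_modify(function(rows, key) {
      circ <- genets_to_circles(rows)
      circ$is_recruit <- rows$is_recruit[1]
      circ
    }) |>
    ungroup()
}

#' Per-quadrat species cover
#'
#' @param records Genet-record tibble.
#' @return Tibble `site, quadrat, group, year, species, cover_cm2`.
#' @export
quadrat_cover <- function(records) {
  records |>
    group_by(.data$site, .data$quadrat, .data$group, .data$year, .data$species) |>
    summarise(cover_cm2 = sum(.data$area_cm2), .groups = "drop")
}

#' Build survival/growth transitions and recruit counts from genet records
#'
#' For every genet observed in year t with year t+1 also censused, emits a
#' transition row (survival flag; sizes in both years if it survived).
#' Recruit counts per quadrat, species and arrival year t+1 come from the
#' tracking recruit flags; transitions and counts never span census gaps.
#'
#' @param records Genet-record tibble from [track_series()] (or synthetic
#'   equivalents with an `is_recruit` column).
#' @return A `transition_table`: list with `transitions` and `recruits`
#'   tibbles.
#' @export
build_transitions <- function(records) {
  dup <- records |>
    count(.data$site, .data$quadrat, .data$species, .data$genet_id, .data$year) |>
    filter(.data$n > 1)
  if (nrow(dup)) abort("duplicate genet id within species-quadrat-year")
  obs_years <- records |>
    distinct(.data$site, .data$quadrat, .data$year) |>
    mutate(has_next = TRUE)
  nxt <- records |>
    select("site", "quadrat", "species", "genet_id",
           year1 = "year", area1 = "area_cm2")
  wcols <- grep("^w_", names(records), value = TRUE)   # crowding carries over
  transitions <- records |>
    inner_join(obs_years |> mutate(year = .data$year - 1L) |> select(-"has_next"),
               by = c("site", "quadrat", "year")) |>
    left_join(nxt |> mutate(year = .data$year1 - 1L),
              by = c("site", "quadrat", "species", "genet_id", "year")) |>
    mutate(area0 = .data$area_cm2, logarea0 = log(.data$area_cm2),
           survives = as.integer(!is.na(.data$area1)),
           logarea1 = ifelse(is.na(.data$area1), NA_real_, log(.data$area1))) |>
    select("site", "quadrat", "group", "species", "genet_id", "year",
           "area0", "logarea0", "x", "y", "survives", "area1", "logarea1",
           all_of(wcols))
  recruit_years <- records |>
    distinct(.data$site, .data$quadrat, .data$group, .data$year) |>
    semi_join(obs_years |> mutate(year = .data$year + 1L),
              by = c("site", "quadrat", "year"))
  recruits <- recruit_years |>
    crossing(species = sort(unique(records$species))) |>
    left_join(
      records |>
        filter(!is.na(.data$is_recruit), .data$is_recruit) |>
        count(.data$site, .data$quadrat, .data$group, .data$year, .data$species,
              name = "n_recruits"),
      by = c("site", "quadrat", "group", "year", "species")) |>
    mutate(n_recruits = ifelse(is.na(.data$n_recruits), 0L, .data$n_recruits))
  structure(list(transitions = transitions, recruits = recruits),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table: %d transitions (%d survivors), %d recruit-count rows>\n",
              nrow(x$transitions), sum(x$transitions$survives),
              nrow(x$recruits)))
  invisible(x)
}
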
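# Shared fixture builders: tiny quadrat maps and genet records constructed in
# code so every test is self-contained.

square_poly <- function(cx, cy, side) {
  h <- side / 2
  cbind(x = cx + c(-h, h, h, -h), y = cy + c(-h, -h, h, h))
}

make_map <- function(features, site = "S", quadrat = "Q1", group = "G1") {
  tibble::tibble(
    site = site, quadrat = quadrat, group = group,
    year = vapply(features, function(f) f$year, numeric(1)),
    species = vapply(features, function(f) f$species, character(1)),
    feature_id = vapply(features, function(f) f$id, character(1)),
    is_point = vapply(features, function(f) nrow(f$geom) == 1, logical(1)),
    geom = lapply(features, function(f) f$geom)
  ) |> quadrat_map()
}

feat <- function(id, species, year, geom) {
  list(id = id, species = species, year = year, geom = geom)
}

make_records <- function(df) {
  defaults <- tibble::tibble(site = "S", quadrat = "Q1", group = "G1",
                             is_recruit = FALSE)
  for (col in names(defaults)) if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  df
}

toy_climate <- function(n_years = 3, site = "S") {
  tibble::tibble(site = site, year = seq_len(n_years) + 2000L,
                 pptLag = 300 + 10 * seq_len(n_years), ppt1 = 150, ppt2 = 160,
                 T1 = 15, T2 = 16)
}
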
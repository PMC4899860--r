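test_that("polygon tables round-trip through write and read", {
  m <- make_map(list(
    feat("f1", "A", 2001, square_poly(10, 10, 6)),
    feat("f2", "B", 2001, square_poly(30, 30, 4)),
    feat("f3", "C", 2001, matrix(c(55, 55), 1, 2))
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_quadrat_maps(m, path)
  m2 <- read_quadrat_maps(path, dialect = "polygon-table")
  expect_equal(nrow(m2), 3L)
  expect_setequal(m2$species, c("A", "B", "C"))
  m2 <- m2 |> dplyr::arrange(feature_id)
  for (i in 1:3) expect_equal(unname(as.matrix(m2$geom[[i]])),
                              unname(as.matrix(m$geom[[i]])))
  expect_true(m2$is_point[m2$species == "C"])
})

test_that("coordinates outside the quadrat are a hard error", {
  bad <- tibble::tibble(site = "S", quadrat = "Q", group = "G", year = 2001,
                        species = "A", feature_id = "f", vertex_index = 1:3,
                        x = c(10, 150, 20), y = c(10, 10, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path)
  expect_error(read_quadrat_maps(path), "extent")
})

test_that("malformed geometry is rejected row-wise with a warning", {
  bowtie <- tibble::tibble(site = "S", quadrat = "Q", group = "G", year = 2001,
                           species = "A", feature_id = "bow", vertex_index = 1:4,
                           x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))
  good <- tibble::tibble(site = "S", quadrat = "Q", group = "G", year = 2001,
                         species = "A", feature_id = "ok", vertex_index = 1:4,
                         x = c(20, 24, 24, 20), y = c(20, 20, 24, 24))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::bind_rows(bowtie, good), path)
  expect_warning(m <- read_quadrat_maps(path), "malformed")
  expect_equal(m$feature_id, "ok")
})

test_that("genet tables round-trip and render to exact-area polygons", {
  rec <- make_records(tibble::tibble(
    year = 2001L, species = c("A", "A", "B"),
    genet_id = c("A_1", "A_2", "B_1"),
    area_cm2 = c(12, 0.25, 30), x = c(20, 60, 40), y = c(20, 60, 70)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_genet_records(rec, path)
  back <- read_genet_records(path)
  expect_equal(back$area_cm2, rec$area_cm2)
  m <- read_quadrat_maps(path, dialect = "genet-table")
  expect_equal(sort(sapply(m$geom, poly_area)), sort(rec$area_cm2),
               tolerance = 1e-8)
})

test_that("duplicate genet ids within a species-quadrat-year are rejected", {
  rec <- make_records(tibble::tibble(
    year = 2001L, species = "A", genet_id = c("A_1", "A_1"),
    area_cm2 = c(1, 2), x = c(10, 20), y = c(10, 20)))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rec, path)
  expect_error(read_genet_records(path), "duplicate")
})

test_that("climate tables validate keys and compute interactions on demand", {
  ct <- toy_climate(2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_climate(ct, path)
  back <- read_climate(path)
  expect_equal(nrow(back), 2L)
  withint <- climate_interactions(back)
  expect_equal(withint$ppt1_T1, back$ppt1 * back$T1)
  expect_equal(withint$ppt2_T2, back$ppt2 * back$T2)

  dup <- dplyr::bind_rows(ct, ct[1, ])
  readr::write_csv(dup, path)
  expect_error(read_climate(path), "duplicate")

  gap <- ct[c(1, 2), ]; gap$year[2] <- gap$year[2] + 5L
  readr::write_csv(gap, path)
  expect_error(read_climate(path), "missing year")
})

test_that("config defaults, unknown keys and invalid values behave", {
  cfg <- load_config(NULL)
  expect_equal(cfg$tracking$buffer_cm, 5)
  expect_equal(cfg$perturbation$mean_pct, 1)
  expect_equal(cfg$perturbation$variance_pct, 10)

  path <- withr::local_tempfile(fileext = ".yml")
  writeLines("", path)
  expect_equal(load_config(path), cfg)

  writeLines("mesh:\n  nodez: 50", path)
  expect_error(load_config(path), "unknown config key: mesh.nodez")

  writeLines("mesh:\n  nodes: 0", path)
  expect_error(load_config(path), "mesh.nodes")

  writeLines("equilibrium:\n  burn_in: 10\n  window: 20", path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$equilibrium$window, 20)
  expect_equal(cfg2$mesh$nodes, cfg$mesh$nodes)
})
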
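test_that("year-t polygons inherit the antecedent with greatest overlap", {
  prev <- make_map(list(
    feat("A1", "sp1", 2000, square_poly(20, 20, 10)),   # big, near focal
    feat("A2", "sp1", 2000, square_poly(34, 20, 6))     # small, farther
  ))
  prev$genet_id <- c("g1", "g2")
  curr <- make_map(list(
    feat("B1", "sp1", 2001, square_poly(24, 20, 10)),   # overlaps g1 most
    feat("B2", "sp1", 2001, square_poly(70, 70, 6))     # overlaps nothing
  ))
  out <- track_genets(prev, curr, buffer_cm = 5)
  b1 <- out[out$feature_id == "B1", ]
  b2 <- out[out$feature_id == "B2", ]
  expect_equal(b1$genet_id, "g1")
  expect_false(b1$is_recruit)
  expect_true(b2$is_recruit)
  expect_true(is.na(b2$genet_id))
})

test_that("tracking is conspecific only", {
  prev <- make_map(list(feat("A1", "sp1", 2000, square_poly(20, 20, 10))))
  prev$genet_id <- "g1"
  curr <- make_map(list(feat("B1", "sp2", 2001, square_poly(20, 20, 10))))
  out <- track_genets(prev, curr, buffer_cm = 5)
  expect_true(out$is_recruit)
})

test_that("fragments may coalesce under one inherited identity", {
  prev <- make_map(list(feat("A1", "sp1", 2000, square_poly(30, 30, 20))))
  prev$genet_id <- "g1"
  curr <- make_map(list(
    feat("B1", "sp1", 2001, square_poly(25, 30, 6)),
    feat("B2", "sp1", 2001, square_poly(35, 30, 6))
  ))
  out <- track_genets(prev, curr, buffer_cm = 5)
  expect_equal(out$genet_id, c("g1", "g1"))
})

test_that("overlap ties break by larger antecedent area then lower id", {
  prev <- make_map(list(
    feat("A1", "sp1", 2000, square_poly(20, 26, 8)),
    feat("A2", "sp1", 2000, square_poly(20, 14, 12))
  ))
  prev$genet_id <- c("g1", "g2")
  # symmetric focal: equal overlap with both buffered antecedents
  curr <- make_map(list(feat("B1", "sp1", 2001, square_poly(20, 20, 4))))
  out <- track_genets(prev, curr, buffer_cm = 5)
  expect_equal(out$genet_id, "g2")  # larger antecedent wins the tie
})

test_that("circle representation sums areas and area-weights centroids", {
  one <- make_map(list(feat("f1", "sp1", 2000, square_poly(10, 10, 2))))
  circ <- genets_to_circles(one)
  expect_equal(circ$area_cm2, 4)
  expect_equal(c(circ$x, circ$y), c(10, 10))

  two <- make_map(list(
    feat("f1", "sp1", 2000, square_poly(5, 5, sqrt(2))),
    feat("f2", "sp1", 2000, square_poly(15, 5, sqrt(2)))
  ))
  circ2 <- genets_to_circles(two)
  expect_equal(circ2$area_cm2, 4)
  expect_equal(c(circ2$x, circ2$y), c(10, 5))

  pt <- make_map(list(feat("f1", "sp1", 2000, matrix(c(40, 40), 1, 2))))
  expect_equal(genets_to_circles(pt)$area_cm2, POINT_AREA_CM2)
})

test_that("transitions record survival, size pairs and recruit counts", {
  rec <- make_records(tibble::tibble(
    species = "sp1",
    genet_id = c("g1", "g2", "g1", "r1", "r2", "r3"),
    year = c(2000L, 2000L, 2001L, 2001L, 2001L, 2001L),
    area_cm2 = c(4, 9, 6, 0.25, 0.25, 0.25),
    x = 50, y = 50,
    is_recruit = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)))
  tt <- build_transitions(rec)
  tr <- tt$transitions
  expect_equal(nrow(tr), 2L)
  g1 <- tr[tr$genet_id == "g1", ]
  expect_equal(g1$survives, 1L)
  expect_equal(g1$area1, 6)
  expect_equal(g1$logarea0, log(4))
  expect_equal(tr$survives[tr$genet_id == "g2"], 0L)
  rc <- tt$recruits
  expect_equal(rc$n_recruits[rc$year == 2001], 3L)
})

test_that("transitions never span census gaps", {
  rec <- make_records(tibble::tibble(
    species = "sp1", genet_id = "g1",
    year = c(2000L, 2003L), area_cm2 = c(4, 5), x = 50, y = 50,
    is_recruit = c(FALSE, NA)))
  tt <- build_transitions(rec)
  expect_equal(nrow(tt$transitions), 0L)
  expect_equal(nrow(tt$recruits), 0L)
})

test_that("duplicate genet ids are a hard error", {
  rec <- make_records(tibble::tibble(
    species = "sp1", genet_id = c("g1", "g1"), year = 2000L,
    area_cm2 = c(1, 2), x = c(10, 30), y = 10))
  expect_error(build_transitions(rec), "duplicate")
})

test_that("survivors plus recruits account for every genet after tracking", {
  maps <- make_map(list(
    feat("a", "sp1", 2000, square_poly(20, 20, 8)),
    feat("b", "sp1", 2000, square_poly(60, 60, 8)),
    feat("c", "sp1", 2001, square_poly(21, 20, 8)),    # survivor of a
    feat("d", "sp1", 2001, square_poly(80, 20, 4)),    # recruit
    feat("e", "sp2", 2001, square_poly(40, 80, 4))     # recruit (new species)
  ))
  rec <- track_series(maps, buffer_cm = 5)
  y1 <- rec[rec$year == 2001, ]
  expect_equal(nrow(y1), sum(!y1$is_recruit) + sum(y1$is_recruit))
  expect_equal(sum(!y1$is_recruit), 1L)
  expect_equal(sum(y1$is_recruit), 2L)
  # the survivor kept the identity assigned in year 2000
  expect_true(y1$genet_id[!y1$is_recruit] %in% rec$genet_id[rec$year == 2000])
})
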
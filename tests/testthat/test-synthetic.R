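test_that("climate generator hits its targets and is seed-stable", {
  zero_sd <- setNames(rep(0, 5), climate_covariate_names())
  const <- generate_climate(5, sds = zero_sd)
  expect_equal(const$pptLag, rep(300, 5))
  expect_equal(const$T2, rep(16, 5))

  set.seed(77)
  big <- generate_climate(4000)
  se <- 60 / sqrt(4000)
  expect_lt(abs(mean(big$pptLag) - 300), 3.5 * se)

  set.seed(5); a <- generate_climate(10)
  set.seed(5); b <- generate_climate(10)
  expect_identical(a, b)
  expect_error(generate_climate(3, sds = c(pptLag = -1, ppt1 = 1, ppt2 = 1,
                                           T1 = 1, T2 = 1)), "non-negative")
})

test_that("the scenario registry validates names and builds symmetric truths", {
  expect_error(scenario("no-such-scenario"), "unknown scenario")
  tr <- scenario("symmetric-2sp")
  expect_s3_class(tr, "ground_truth")
  expect_equal(tr$params$A$survival$intercept, tr$params$B$survival$intercept)
  expect_equal(unname(tr$params$A$recruitment$dd["B"]),
               unname(tr$params$B$recruitment$dd["A"]))
  # niche-partitioned has weaker interspecific interactions than neutral-ish
  np <- scenario("niche-partitioned"); ne <- scenario("neutral-ish")
  expect_lt(abs(np$params$A$survival$crowding["B"]),
            abs(ne$params$A$survival$crowding["B"]))
  # pure-indirect: focal has no climate terms, competitor does
  pi_tr <- scenario("pure-indirect")
  expect_equal(length(pi_tr$params$A$survival$climate), 0L)
  expect_gt(length(pi_tr$params$B$survival$climate), 0L)
  # null variant strips every climate coefficient
  null_tr <- scenario("symmetric-2sp", climate_effects = FALSE)
  expect_equal(length(null_tr$params$A$growth$climate), 0L)
})

test_that("one-year archives are just the initial communities", {
  tr <- scenario("symmetric-2sp")
  set.seed(2)
  sim <- simulate_quadrats(tr, n_quadrats = 3, n_years = 1, n_groups = 1)
  expect_equal(unique(sim$records$year), 2001L)
  expect_true(all(is.na(sim$records$is_recruit)))
  expect_equal(length(unique(sim$records$quadrat)), 3L)
})

test_that("synthetic records respect the quadrat geometry invariants", {
  tr <- scenario("symmetric-2sp")
  set.seed(4)
  sim <- simulate_quadrats(tr, n_quadrats = 2, n_years = 6, n_groups = 1)
  r <- sim$records
  expect_true(all(r$area_cm2 > 0))
  expect_true(all(r$x >= 0 & r$x <= 100 & r$y >= 0 & r$y <= 100))
  # recruit flags identify exactly the ids absent the year before
  for (yr in 2002:2006) {
    prev <- r |> dplyr::filter(year == yr - 1, quadrat == "Q01")
    curr <- r |> dplyr::filter(year == yr, quadrat == "Q01")
    truth <- !paste(curr$species, curr$genet_id) %in%
      paste(prev$species, prev$genet_id)
    expect_equal(curr$is_recruit, truth)
  }
})

test_that("rendered polygon areas equal the generating genet areas", {
  tr <- scenario("symmetric-2sp")
  set.seed(6)
  out <- generate_quadrat_series(tr, n_quadrats = 1, n_years = 3, n_groups = 1)
  polys <- out$maps |> dplyr::filter(!is_point)
  rec <- out$records
  key <- paste(rec$quadrat, rec$year, rec$species, rec$genet_id)
  for (i in seq_len(nrow(polys))) {
    j <- match(paste(polys$quadrat[i], polys$year[i], polys$species[i],
                     polys$feature_id[i]), key)
    a_true <- rec$area_cm2[j]
    r_max <- sqrt(2 * a_true / (16 * sin(2 * pi / 16)))
    interior <- rec$x[j] > r_max & rec$x[j] < 100 - r_max &
      rec$y[j] > r_max & rec$y[j] < 100 - r_max
    if (interior) {
      expect_equal(poly_area(polys$geom[[i]]), a_true, tolerance = 1e-9)
    }
  }
})

test_that("tracking recovers nearly all true identities on a rendered archive", {
  tr <- scenario("symmetric-2sp")
  set.seed(8)
  out <- generate_quadrat_series(tr, n_quadrats = 1, n_years = 4, n_groups = 1)
  maps <- out$maps
  years <- sort(unique(maps$year))
  n_surv <- 0; surv_ok <- 0; n_rec <- 0; rec_ok <- 0
  for (yi in seq_along(years)[-1]) {
    prev <- maps[maps$year == years[yi - 1], ]
    prev$genet_id <- prev$feature_id            # truth as antecedent ids
    curr <- maps[maps$year == years[yi], ]
    tracked <- track_genets(prev, curr, buffer_cm = 5, res = 0.4)
    truth_rec <- !curr$feature_id %in% prev$feature_id
    surv_hit <- !truth_rec & !tracked$is_recruit &
      tracked$genet_id == curr$feature_id
    n_surv <- n_surv + sum(!truth_rec); surv_ok <- surv_ok + sum(surv_hit)
    n_rec <- n_rec + sum(truth_rec)
    rec_ok <- rec_ok + sum(truth_rec & tracked$is_recruit)
  }
  expect_gt(n_surv, 100)
  # persisting genets (which never move here) must reclaim their identity
  expect_gte(surv_ok / n_surv, 0.99)
  # new recruits landing inside the buffered canopy of an established
  # conspecific are inherently ambiguous to the overlap rule; most recruits
  # must still be flagged, but perfection is not attainable
  expect_gte(rec_ok / max(n_rec, 1), 0.5)
})

test_that("a community doomed to extinction fails loudly after retries", {
  tr <- scenario("symmetric-2sp")
  for (j in c("A", "B")) {
    tr$params[[j]]$survival$intercept <- -50
    tr$params[[j]]$recruitment$intercept <- -50
  }
  set.seed(10)
  expect_error(
    suppressMessages(simulate_quadrats(tr, n_quadrats = 1, n_years = 4,
                                       n_groups = 1, max_retry = 2)),
    "extinct")
})
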
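# Immortal/immobile parameter sets give closed-form expectations that the
# stochastic engine must respect.

immortal_params <- function(species, other, lambda_intercept = -50,
                            groups = "G1") {
  gt <- tibble::tibble(group = groups, intercept_dev = 0)
  list(
    survival = survival_params(species, intercept = 50, group = gt),
    growth = growth_params(species, intercept = 0, size = 1, var_a = 1e-10,
                           group = gt),
    recruitment = recruit_params(species, intercept = lambda_intercept,
                                 theta = 1, p_mix = 1, group = gt)
  )
}

C0 <- c(pptLag = 0, ppt1 = 0, ppt2 = 0, T1 = 0, T2 = 0)

two_sp_state <- function(n = 5) {
  set.seed(1)
  ibm_state(tibble::tibble(
    species = rep(c("A", "B"), each = n),
    genet_id = sprintf("%s_%05d", rep(c("A", "B"), each = n), rep(1:n, 2)),
    logsize = runif(2 * n, 0, 3), x = runif(2 * n, 0, 100),
    y = runif(2 * n, 0, 100)))
}

test_that("certain survival, identity growth and zero recruitment conserve the state", {
  st <- two_sp_state()
  params <- list(A = immortal_params("A"), B = immortal_params("B"))
  al <- alpha_matrix(c("A", "B"), 0.01)
  out <- ibm_step(st, params, al, C0)
  expect_setequal(out$genet_id, st$genet_id)
  expect_equal(sort(out$logsize), sort(st$logsize), tolerance = 1e-3)
  expect_equal(out$x[order(out$genet_id)], st$x[order(st$genet_id)])
})

test_that("certain death and zero recruitment empty the state", {
  st <- two_sp_state()
  params <- list(A = immortal_params("A"), B = immortal_params("B"))
  params$A$survival$intercept <- -50
  params$B$survival$intercept <- -50
  out <- ibm_step(st, params, alpha_matrix(c("A", "B"), 0.01), C0)
  expect_equal(nrow(out), 0L)
  expect_equal(cover_of(out, species = c("A", "B"))$cover_cm2, c(0, 0))
})

test_that("ensemble-mean cover matches the Bernoulli survival expectation", {
  p_surv <- 0.7
  params <- list(A = list(
    survival = survival_params("A", intercept = qlogis(p_surv)),
    growth = growth_params("A", intercept = 0, size = 1, var_a = 1e-10),
    recruitment = recruit_params("A", intercept = -50, theta = 1)))
  al <- alpha_matrix("A", 0.01)
  st <- ibm_state(tibble::tibble(species = "A", genet_id = "A_00001",
                                 logsize = 2, x = 50, y = 50))
  set.seed(8)
  n_rep <- 4000
  covers <- vapply(seq_len(n_rep), function(i) {
    sum(exp(ibm_step(st, params, al, C0)$logsize))
  }, numeric(1))
  expected <- p_surv * exp(2)
  mc_se <- sd(covers) / sqrt(n_rep)
  expect_lt(abs(mean(covers) - expected), 4 * mc_se)
})

test_that("cover sums arithmetic areas and scales to quadrat fraction", {
  st <- ibm_state(tibble::tibble(species = c("A", "A"),
                                 genet_id = c("A_1", "A_2"),
                                 logsize = c(1, 2), x = 50, y = 50))
  cv <- cover_of(st)
  expect_equal(cv$cover_cm2, exp(1) + exp(2))
  expect_equal(cv$frac, (exp(1) + exp(2)) / 1e4)
  empty <- ibm_state(tibble::tibble(species = character(0),
                                    genet_id = character(0),
                                    logsize = numeric(0), x = numeric(0),
                                    y = numeric(0)))
  expect_equal(nrow(cover_of(empty)), 0L)
  expect_equal(cover_of(empty, species = "A")$cover_cm2, 0)
})

test_that("periodic and absorbing boundaries differ only through edge wrap", {
  st <- ibm_state(tibble::tibble(
    species = "A", genet_id = c("A_1", "A_2"),
    logsize = c(2, 2), x = c(1, 99), y = c(50, 50)))
  al <- alpha_matrix("A", 0.01)
  w_abs <- quadratdyn:::ibm_crowding(st, al, "absorbing")
  w_per <- quadratdyn:::ibm_crowding(st, al, "periodic")
  # torus distance is 2 cm, plane distance 98 cm
  expect_equal(unname(w_per[1, "A"]), exp(2) * exp(-0.01 * 4))
  expect_lt(w_abs[1, "A"], 1e-10)
})

test_that("historical hindcasts follow observations, chronology and gaps", {
  # deterministic community: certain survival, identity growth, no recruits
  rec <- make_records(tibble::tibble(
    species = "A", genet_id = c("g1", "g1", "g1"),
    year = c(2001L, 2002L, 2004L),      # gap after 2002
    area_cm2 = c(4, 4, 9), x = 50, y = 50, is_recruit = FALSE))
  params <- list(A = immortal_params("A"))
  params$A$survival$year <- tibble::tibble(year = 2001:2003, intercept_dev = 0,
                                           size_dev = 0)
  params$A$growth$year <- params$A$survival$year
  params$A$recruitment$year <- tibble::tibble(year = 2001:2003,
                                              intercept_dev = 0)
  cl <- toy_climate(4) |> dplyr::mutate(year = 2001:2004)
  out <- simulate_historical(rec, params, alpha_matrix("A", 0.01), cl,
                             n_reps = 2, mode = "full")
  expect_equal(out$cover_pred[out$year == 2001], 4)
  expect_equal(out$cover_pred[out$year == 2002], 4, tolerance = 1e-3)
  # year after the gap is re-initialised from the observation
  expect_equal(out$cover_pred[out$year == 2004], 9)
  # missing year effects are a hard error (drop the first modelled year)
  params$A$survival$year <- params$A$survival$year[-1, ]
  expect_error(simulate_historical(rec, params, alpha_matrix("A", 0.01), cl,
                                   n_reps = 1, mode = "full"),
               "missing year effects")
})

test_that("replicate averaging converges: 1 rep vs many reps agree in mean", {
  set.seed(303)
  tr <- scenario("symmetric-2sp")
  sim <- simulate_quadrats(tr, n_quadrats = 1, n_years = 6, n_groups = 1)
  hist1 <- simulate_historical(sim$records, sim$params, tr$alphas,
                               sim$climate, n_reps = 1, mode = "full")
  set.seed(304)
  hist20 <- simulate_historical(sim$records, sim$params, tr$alphas,
                                sim$climate, n_reps = 20, mode = "full")
  # same expectation: single-rep trajectory within wide MC bounds of the mean
  last1 <- hist1$cover_pred[hist1$year == max(hist1$year)]
  last20 <- hist20$cover_pred[hist20$year == max(hist20$year)]
  expect_lt(max(abs(last1 - last20) / pmax(last20, 1)), 0.5)
})
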
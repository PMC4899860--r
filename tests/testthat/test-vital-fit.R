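# Fitting machinery on small constructed data sets; the heavier
# parameter-recovery harnesses at realistic n live in the acceptance suite.

make_growth_frame <- function(n = 400, noise_sd = 1e-4, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    site = "S", quadrat = "Q1",
    group = rep(c("G1", "G2"), length.out = n),
    species = "A", genet_id = sprintf("g%04d", seq_len(n)),
    year = rep(2001:2004, length.out = n),
    logarea0 = runif(n, -1, 4), x = 50, y = 50,
    survives = 1L,
    logarea1 = 0.2 + 0.9 * runif(n, -1, 4) * 0 + 0.9 * 0, # placeholder
    w_A = runif(n, 0, 20)
  ) |>
    dplyr::mutate(logarea1 = 0.2 + 0.9 * logarea0 - 0.01 * w_A +
                    rnorm(n, 0, noise_sd),
                  area0 = exp(logarea0), area1 = exp(logarea1))
}

test_that("growth fit is exact in the noiseless limit", {
  df <- make_growth_frame(noise_sd = 1e-6)
  cl <- toy_climate(4) |> dplyr::mutate(year = 2001:2004)
  fit <- fit_growth(df, cl, "A")
  expect_true(fit$converged)
  r2 <- cor(fitted(fit$model), fit$data$logarea1)^2
  expect_gt(r2, 0.999999)
  expect_equal(fit$params$size, 0.9, tolerance = 1e-3)
  expect_equal(unname(fit$params$crowding["A"]), -0.01, tolerance = 1e-2)
})

test_that("fitted params plug into the predictors (round trip)", {
  df <- make_growth_frame(noise_sd = 0.2)
  cl <- toy_climate(4) |> dplyr::mutate(year = 2001:2004)
  fit <- fit_growth(df, cl, "A")
  p <- fit$params
  C <- unlist(cl[1, climate_covariate_names()])
  m <- growth_moments(2, C, c(A = 5), p, year = 2001L, group = "G1")
  # manual linear predictor from the same parameter object
  ydev <- p$year$intercept_dev[p$year$year == 2001]
  sdev <- p$year$size_dev[p$year$year == 2001]
  gdev <- p$group$intercept_dev[p$group$group == "G1"]
  lp <- p$intercept + ydev + gdev + (p$size + sdev) * 2 + p$crowding["A"] * 5
  expect_equal(m$mean, unname(lp))
  expect_equal(m$var, p$var_a * exp(p$var_b * m$mean))
})

test_that("survival fit recovers a known logistic structure", {
  set.seed(21)
  n <- 3000
  df <- tibble::tibble(
    site = "S", quadrat = "Q1", group = rep(c("G1", "G2"), length.out = n),
    species = "A", genet_id = sprintf("g%05d", seq_len(n)),
    year = rep(2001:2006, length.out = n),
    logarea0 = runif(n, -1, 4), x = 50, y = 50, w_A = runif(n, 0, 30))
  lp <- 0.5 + 0.6 * df$logarea0 - 0.03 * df$w_A
  df$survives <- rbinom(n, 1, plogis(lp))
  df$area0 <- exp(df$logarea0); df$area1 <- NA; df$logarea1 <- NA
  cl <- toy_climate(6) |> dplyr::mutate(year = 2001:2006)
  fit <- fit_survival(df, cl, "A")
  td <- tidy(fit)
  z <- function(term, truth) {
    (td$estimate[td$term == term] - truth) / td$std.error[td$term == term]
  }
  expect_lt(abs(z("logarea0", 0.6)), 3)
  expect_lt(abs(z("w_A", -0.03)), 3)
})

test_that("variance-explained proportion follows the triplet formula", {
  expect_equal(variance_explained(10, 4, 2), 0.75)
  expect_equal(variance_explained(10, 2, 2), 1)   # climate == full
  expect_equal(variance_explained(10, 10, 2), 0)  # climate == constant
  # scale invariance
  expect_equal(variance_explained(50, 20, 10), variance_explained(5, 2, 1))
  expect_warning(out <- variance_explained(10, 12, 2), "clipping")
  expect_equal(out, 0)
  expect_warning(nores <- variance_explained(5, 5, 5), "undefined")
  expect_true(is.na(nores))
})

test_that("stepwise selection reduces to an AIC comparison for one candidate", {
  set.seed(33)
  n <- 2000
  df <- tibble::tibble(
    site = "S", quadrat = "Q1", group = "G1", species = "A",
    genet_id = sprintf("g%05d", seq_len(n)),
    year = rep(2001:2010, length.out = n),
    logarea0 = runif(n, -1, 4), x = 50, y = 50, w_A = 0)
  cl <- toy_climate(10) |> dplyr::mutate(year = 2001:2010,
                                         ppt1 = rnorm(10, 150, 40))
  df <- attach_climate(df, cl)
  df$survives <- rbinom(n, 1, plogis(0.3 + 0.4 * df$logarea0 +
                                       0.01 * (df$ppt1 - 150)))
  df$area0 <- exp(df$logarea0); df$area1 <- NA; df$logarea1 <- NA
  sel <- select_climate_covariates(df, "survival", "A", objective = "fixed")
  # strong planted effect: ppt1 must be in
  expect_true("ppt1" %in% sel$selected)
  # the trace is a valid bidirectional search record
  expect_equal(sel$trace$action[1], "start")
  expect_true(all(diff(sel$trace$AIC) < 0))
})

test_that("interactions only become eligible with both parents present", {
  calls <- list()
  fitter <- function(terms) {
    calls[[length(calls) + 1]] <<- terms
    structure(list(), class = "fake_fit")
  }
  # AIC method that rewards nothing: search stops immediately
  assign("AIC.fake_fit", function(object, ...) 0, envir = globalenv())
  on.exit(rm("AIC.fake_fit", envir = globalenv()))
  out <- stepwise_aic(fitter, c("ppt1", "T1", "ppt1_T1"))
  tried <- unique(unlist(calls))
  expect_false("ppt1_T1" %in% tried)
  expect_equal(out$selected, character(0))
})

test_that("alpha grid search prefers the generating spatial scale", {
  # strong planted crowding effect so the likelihood surface over alpha is
  # informative: survival p = logit^{-1}(2 + 0.5 u - 0.08 w) with w computed
  # at the true alpha = 0.01
  set.seed(60)
  n_q <- 15; n_per <- 100
  rec <- purrr::list_rbind(purrr::map(seq_len(n_q), function(q) {
    tibble::tibble(site = "S", quadrat = sprintf("Q%02d", q), group = "G1",
                   species = "A", genet_id = sprintf("g%03d", seq_len(n_per)),
                   year = 2000L + (q %% 2), area_cm2 = exp(runif(n_per, -1, 3)),
                   x = runif(n_per, 0, 100), y = runif(n_per, 0, 100))
  }))
  al <- alpha_matrix("A", 0.01)
  cw <- crowding_table(rec, al)
  p <- plogis(2 + 0.5 * log(cw$area_cm2) - 0.08 * cw$w_A)
  rec$survives <- rbinom(nrow(rec), 1, p)
  trn <- rec
  trn$logarea0 <- log(trn$area_cm2); trn$area0 <- trn$area_cm2
  trn$area1 <- NA; trn$logarea1 <- NA
  grid <- estimate_alpha(rec, trn, "A", candidates = c(0.001, 0.01, 0.1),
                         vital = "survival")
  expect_equal(attr(grid, "best"), 0.01)
  expect_true(all(is.finite(grid$logLik)))
})
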
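C0 <- c(pptLag = 0, ppt1 = 0, ppt2 = 0, T1 = 0, T2 = 0)

test_that("mesh invariants hold", {
  m <- size_mesh(100, log(0.2), log(400) + 1)
  expect_equal(m$h * m$n, m$U - m$L)      # weights sum to U - L
  expect_true(all(diff(m$nodes) > 0))
  expect_true(min(m$nodes) > m$L && max(m$nodes) < m$U)
  expect_error(size_mesh(1), "at least 2")
  expect_error(size_mesh(10, 1, 0), "exceed")
})

test_that("heterospecific mean crowding matches a Monte-Carlo placement oracle", {
  mesh <- size_mesh(60, log(0.2), log(200))
  st <- ipm_state(mesh, c("A", "B"))
  # species B: fixed cover spread over k plants of area a
  a <- 12; k <- 40
  kb <- which.min(abs(mesh$nodes - log(a)))
  st$n["B", kb] <- k / mesh$h
  alpha <- 0.01
  al <- alpha_matrix(c("A", "B"), alpha)
  W <- mean_crowding(st, al, "A")
  coverB <- cover_of(st)$cover_cm2[2]
  closed <- (pi / alpha) * coverB / 1e4
  expect_equal(unname(W[1, "B"]), closed, tolerance = 1e-10)
  # oracle: average crowding over random torus placements of the k neighbours
  set.seed(1234)
  n_mc <- 10000
  ab <- exp(mesh$nodes[kb])
  wmc <- vapply(seq_len(n_mc), function(i) {
    dx <- abs(runif(k, 0, 100) - 50); dy <- abs(runif(k, 0, 100) - 50)
    dx <- pmin(dx, 100 - dx); dy <- pmin(dy, 100 - dy)
    sum(ab * exp(-alpha * (dx^2 + dy^2)))
  }, numeric(1))
  mc_se <- sd(wmc) / sqrt(n_mc)
  expect_lt(abs(mean(wmc) - closed), 3 * mc_se)
})

test_that("conspecific no-overlap crowding never exceeds the random value", {
  mesh <- size_mesh(60, log(0.2), log(200))
  st <- ipm_state(mesh, "A")
  st$n["A", ] <- runif(mesh$n, 0, 0.5)
  al <- alpha_matrix("A", 0.02)
  W_excl <- mean_crowding(st, al, "A", no_overlap = TRUE)
  W_rand <- mean_crowding(st, al, "A", no_overlap = FALSE)
  expect_true(all(W_excl[, "A"] <= W_rand[, "A"] + 1e-12))
  # exclusion bites harder for larger focal plants
  expect_lt(W_excl[mesh$n, "A"], W_excl[1, "A"])
  # no heterospecifics at zero cover
  st2 <- ipm_state(mesh, c("A", "B"))
  st2$n["A", ] <- 0.1
  expect_equal(mean_crowding(st2, alpha_matrix(c("A", "B"), 0.02), "A")[, "B"],
               rep(0, mesh$n))
})

test_that("kernel column mass reproduces survival on a fine mesh", {
  mesh <- size_mesh(300, log(0.2) - 2, log(400) + 3)
  params <- list(A = list(
    survival = survival_params("A", intercept = 0.4, size = 0.3),
    growth = growth_params("A", intercept = 0.4, size = 0.8, var_a = 0.3,
                           var_b = 0)))
  W <- matrix(0, mesh$n, 1, dimnames = list(NULL, "A"))
  kern <- build_kernel("A", params, C0, W, mesh)
  mass <- colSums(kern$K) * mesh$h
  interior <- mesh$nodes > mesh$L + 2 & mesh$nodes < mesh$U - 3
  expect_lt(max(abs(mass[interior] - kern$S[interior])), 1e-3)
})

test_that("an all-zero state is absorbing and the geometric regime is exact", {
  mesh <- size_mesh(100, log(0.2), log(400))
  al <- alpha_matrix("A", 0.01)
  # growth shifts mean log size up by 0.5 (size slope 1) with constant
  # variance a, so cover of survivors multiplies by exp(0.5 + a / 2); the
  # variance must stay resolvable on the mesh (sd > cell width) and the mass
  # away from the mesh edges for the midpoint rule to conserve it
  a_var <- 0.09
  params <- list(A = list(
    survival = survival_params("A", intercept = qlogis(0.8)),   # size-free
    growth = growth_params("A", intercept = 0.5, size = 1, var_a = a_var),
    recruitment = recruit_params("A", intercept = -2, theta = 1, p_mix = 1)))
  st0 <- ipm_state(mesh, "A")
  expect_equal(cover_of(ipm_step(st0, params, al, C0))$cover_cm2, 0)

  st <- ipm_state(mesh, "A")
  k0 <- which.min(abs(mesh$nodes - 2))
  st$n["A", k0] <- 50 / (exp(mesh$nodes[k0]) * mesh$h)
  kr <- recruit_node(mesh)
  # cover multiplies by s * e^{0.5 + a/2} + exp(gamma) * e^{u_r} each step
  growth_factor <- 0.8 * exp(0.5 + a_var / 2) + exp(-2) * exp(mesh$nodes[kr])
  c0 <- cover_of(st)$cover_cm2
  st1 <- ipm_step(st, params, al, C0)
  st2 <- ipm_step(st1, params, al, C0)
  expect_equal(cover_of(st1)$cover_cm2 / c0, growth_factor, tolerance = 5e-3)
  expect_equal(cover_of(st2)$cover_cm2 / cover_of(st1)$cover_cm2,
               growth_factor, tolerance = 5e-3)
})

test_that("with zero fecundity the survivor count integrates S(u) n(u)", {
  mesh <- size_mesh(150, log(0.2) - 1, log(400) + 2)
  al <- alpha_matrix("A", 0.01)
  params <- list(A = list(
    survival = survival_params("A", intercept = 0.2, size = 0.4),
    growth = growth_params("A", intercept = 0.5, size = 0.8, var_a = 0.3),
    recruitment = recruit_params("A", intercept = -80, theta = 1)))
  st <- ipm_state(mesh, "A")
  st$n["A", ] <- dnorm(mesh$nodes, 2, 0.5)
  W <- mean_crowding(st, al, "A")
  S <- survival_prob(mesh$nodes, C0, W, params$A$survival, marginal = TRUE)
  expected <- sum(S * st$n["A", ]) * mesh$h
  out <- ipm_step(st, params, al, C0)
  expect_equal(sum(out$n["A", ]) * mesh$h, expected, tolerance = 1e-6)
})

test_that("stochastic runs are seed-reproducible and step-0 is the input", {
  tr <- scenario("symmetric-2sp")
  mesh <- size_mesh(60, log(0.2), log(400))
  cl <- toy_climate(5)
  st <- ipm_seed_state(mesh, tr$species, 10)
  expect_equal(run_ipm(st, tr$params, tr$alphas, cl, 0)$step, c(0L, 0L))
  set.seed(99)
  t1 <- run_ipm(st, tr$params, tr$alphas, cl, 10)
  set.seed(99)
  t2 <- run_ipm(st, tr$params, tr$alphas, cl, 10)
  expect_identical(t1, t2)
})

test_that("species labels permute exactly (symmetry of the engine)", {
  tr <- scenario("pure-indirect")   # asymmetric parameters
  mesh <- size_mesh(50, log(0.2), log(400))
  cl <- toy_climate(4)
  st <- ipm_seed_state(mesh, c("A", "B"), c(20, 10))
  set.seed(7)
  fwd <- run_ipm(st, tr$params, tr$alphas, cl, 8)
  # relabel: A <-> B everywhere
  params_swap <- list(A = tr$params$B, B = tr$params$A)
  for (v in c("survival", "growth", "recruitment")) {
    for (j in c("A", "B")) {
      p <- params_swap[[j]][[v]]
      p$species <- j
      for (slot in c("crowding", "crowding_size", "dd")) {
        if (!is.null(p[[slot]]) && length(p[[slot]])) {
          names(p[[slot]]) <- c(A = "B", B = "A")[names(p[[slot]])]
        }
      }
      params_swap[[j]][[v]] <- p
    }
  }
  st_swap <- ipm_seed_state(mesh, c("A", "B"), c(10, 20))
  set.seed(7)
  swp <- run_ipm(st_swap, params_swap, tr$alphas, cl, 8)
  a_fwd <- fwd$cover_cm2[fwd$species == "A"]
  b_swp <- swp$cover_cm2[swp$species == "B"]
  expect_equal(a_fwd, b_swp, tolerance = 1e-12)
})

test_that("equilibrium matches a fixed-point oracle in a constant environment", {
  tr <- scenario("symmetric-2sp")
  mesh <- size_mesh(80, log(0.2), log(400) + 1)
  clc <- generate_climate(1, tr$climate_means,
                          sds = setNames(rep(0, 5), names(tr$climate_sds)))
  # oracle: iterate the deterministic one-species map to its fixed point
  params1 <- tr$params["A"]
  al1 <- alpha_matrix("A", 0.01)
  st <- ipm_seed_state(mesh, "A", 1)
  caches <- quadratdyn:::ipm_caches(mesh, "A", al1)
  C <- unlist(clc[1, climate_covariate_names()])
  for (i in 1:600) st <- ipm_step(st, params1, al1, C, caches = caches)
  fp <- cover_of(st)$cover_cm2
  set.seed(42)
  eq <- equilibrium_cover(mesh, "A", params1, al1, clc, burn_in = 300,
                          window = 200)
  expect_equal(eq$cover_cm2, fp, tolerance = 1e-3)
  expect_lt(eq$se, 1e-6)    # deterministic climate: window variance -> 0
  expect_false(eq$extinct)
})
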
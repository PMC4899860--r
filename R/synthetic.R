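# Ground-truth synthetic data. A scenario bundles per-species vital-rate
# parameters, interaction scales and climate-generator settings chosen to
# yield persistent two-species communities; the quadrat-series generator runs
# the IBM from random initial communities and emits both polygon maps (for
# the tracking module) and the hidden true identities (for tracking-accuracy
# tests). Climate covariates are drawn independently across years, matching
# the simulation protocol of independent annual draws.

#' Generate a synthetic climate covariate table
#'
#' Independent Normal draws per covariate per year.
#'
#' @param n_years Number of years.
#' @param means,sds Named vectors over [climate_covariate_names()].
#' @param site Site label.
#' @param start_year First year label.
#' @return Climate tibble.
#' @export
generate_climate <- function(n_years,
                             means = c(pptLag = 300, ppt1 = 150, ppt2 = 150,
                                       T1 = 15, T2 = 16),
                             sds = c(pptLag = 60, ppt1 = 40, ppt2 = 40,
                                     T1 = 1.2, T2 = 1.2),
                             site = "S", start_year = 2001L) {
  if (any(sds < 0)) abort("climate sds must be non-negative")
  out <- tibble::tibble(site = site,
                        year = seq(start_year, length.out = n_years))
  for (cv in climate_base_covariates) {
    out[[cv]] <- rnorm(n_years, means[[cv]], sds[[cv]])
  }
  out
}

# Intercepts are specified "at mean climate" (the behaviour of an average
# year); the stored intercept subtracts the climate-effect contribution of
# the mean covariates so raw covariates can be used in prediction.
intercept_from_mean <- function(at_mean, climate_eff, means) {
  if (length(climate_eff) == 0) return(at_mean)
  at_mean - sum(climate_eff * means[names(climate_eff)])
}

template_species <- function(code, rho, climate_surv, climate_grow,
                             climate_rec, means, surv_at_mean = 1.8,
                             grow_at_mean = 0.55, rec_at_mean = -1.5,
                             other = NULL, w_intra_s = -0.012,
                             w_intra_g = -0.004, dd_intra = -0.12,
                             w_inter_s = NULL, w_inter_g = NULL,
                             dd_inter = NULL) {
  others <- setdiff(other, code)
  crowd_s <- setNames(c(w_intra_s, rep(w_inter_s %||% (w_intra_s * rho),
                                       length(others))), c(code, others))
  crowd_g <- setNames(c(w_intra_g, rep(w_inter_g %||% (w_intra_g * rho),
                                       length(others))), c(code, others))
  dd <- setNames(c(dd_intra, rep(dd_inter %||% (dd_intra * rho),
                                 length(others))), c(code, others))
  list(
    survival = survival_params(
      code,
      intercept = intercept_from_mean(surv_at_mean, climate_surv, means),
      size = 0.6, crowding = crowd_s,
      climate = if (length(climate_surv)) climate_surv else NULL),
    growth = growth_params(
      code,
      intercept = intercept_from_mean(grow_at_mean, climate_grow, means),
      size = 0.8, crowding = crowd_g, var_a = 0.35, var_b = -0.15,
      climate = if (length(climate_grow)) climate_grow else NULL),
    recruitment = recruit_params(
      code,
      intercept = intercept_from_mean(rec_at_mean, climate_rec, means),
      dd = dd, theta = 2, p_mix = 0.5,
      climate = if (length(climate_rec)) climate_rec else NULL)
  )
}

#' Ground-truth scenario registry
#'
#' Pre-validated two-species parameter sets:
#' \describe{
#'   \item{symmetric-2sp}{Identical species with interspecific interactions
#'     at 60% of intraspecific strength; equilibrium frequencies are 0.5 by
#'     symmetry.}
#'   \item{niche-partitioned}{Interspecific interactions at 20% of
#'     intraspecific strength: strong niche differences, strongly negative
#'     frequency dependence.}
#'   \item{neutral-ish}{Interspecific interactions at 90% of intraspecific
#'     strength: weak niche differences, weak frequency dependence.}
#'   \item{pure-indirect}{Climate-insensitive focal species `A` competing
#'     with a strongly climate-sensitive `B` that suppresses `A` as strongly
#'     as `A` suppresses itself, while `A` barely affects `B`; climate
#'     perturbations reach `A` almost entirely through `B`.}
#'   \item{variance-gradient}{Species with opposite-signed precipitation
#'     responses, generating large community-level variance in direct
#'     effects.}
#' }
#'
#' @param name Scenario name.
#' @param climate_effects Set to `FALSE` for a null variant in which no vital
#'   rate responds to climate (all climate coefficients zero); used to
#'   calibrate covariate-selection false positives.
#' @return Object of class `ground_truth`: `species`, `params`, `alphas`,
#'   `climate_means`, `climate_sds`, `year_sd`, `group_sd`, `init`, `tag`.
#' @export
scenario <- function(name = c("symmetric-2sp", "niche-partitioned",
                              "neutral-ish", "pure-indirect",
                              "variance-gradient"), climate_effects = TRUE) {
  if (!is.character(name) || !name[1] %in% c("symmetric-2sp", "niche-partitioned",
                                             "neutral-ish", "pure-indirect",
                                             "variance-gradient")) {
    abort(paste("unknown scenario:", name[1]))
  }
  name <- match.arg(name)
  means <- c(pptLag = 300, ppt1 = 150, ppt2 = 150, T1 = 15, T2 = 16)
  sds <- c(pptLag = 60, ppt1 = 40, ppt2 = 40, T1 = 1.2, T2 = 1.2)
  sp <- c("A", "B")
  cl_s <- c(ppt1 = 0.004, T1 = -0.05)
  cl_g <- c(ppt1 = 0.002)
  cl_r <- c(pptLag = 0.003)
  if (!climate_effects) cl_s <- cl_g <- cl_r <- numeric()
  rho <- switch(name, "symmetric-2sp" = 0.6, "niche-partitioned" = 0.2,
                "neutral-ish" = 0.9, 0.6)
  params <- switch(
    name,
    "pure-indirect" = list(
      # focal A: no climate terms; B suppresses A at full intraspecific
      # strength while A barely affects B
      A = template_species("A", rho = 1, climate_surv = numeric(),
                           climate_grow = numeric(), climate_rec = numeric(),
                           means = means, other = sp),
      B = template_species("B", rho = 0.1,
                           climate_surv = c(ppt1 = 0.008, T1 = -0.05),
                           climate_grow = c(ppt1 = 0.004),
                           climate_rec = c(pptLag = 0.006),
                           means = means, other = sp)),
    "variance-gradient" = list(
      A = template_species("A", rho = 0.6, climate_surv = c(ppt1 = 0.005),
                           climate_grow = c(ppt1 = 0.0025),
                           climate_rec = c(pptLag = 0.003),
                           means = means, other = sp),
      B = template_species("B", rho = 0.6, climate_surv = c(ppt1 = -0.005),
                           climate_grow = c(ppt1 = -0.0025),
                           climate_rec = c(pptLag = -0.003),
                           means = means, other = sp)),
    setNames(lapply(sp, function(code) {
      template_species(code, rho = rho, climate_surv = cl_s,
                       climate_grow = cl_g, climate_rec = cl_r,
                       means = means, other = sp)
    }), sp)
  )
  structure(list(
    name = name, species = sp, params = params,
    alphas = alpha_matrix(sp, 0.01),
    climate_means = means, climate_sds = sds,
    year_sd = list(surv_int = 0.25, surv_size = 0.05, grow_int = 0.12,
                   grow_size = 0.03, rec_int = 0.3),
    group_sd = list(surv = 0.1, grow = 0.05, rec = 0.15),
    init = list(n_per_species = 25L, logsize_mean = 2, logsize_sd = 0.8)
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth '%s': %d species>\n", x$name, length(x$species)))
  invisible(x)
}

#' Draw random year and group effects for a ground-truth scenario
#'
#' @param truth A [scenario()].
#' @param years Year labels.
#' @param groups Group labels.
#' @return The per-species parameter list with year/group deviation tables
#'   filled in (these are the generating values recovery tests target).
#' @export
truth_with_effects <- function(truth, years, groups) {
  ys <- truth$year_sd; gs <- truth$group_sd
  params <- truth$params
  for (j in names(params)) {
    params[[j]]$survival$year <- tibble::tibble(
      year = years, intercept_dev = rnorm(length(years), 0, ys$surv_int),
      size_dev = rnorm(length(years), 0, ys$surv_size))
    params[[j]]$survival$group <- tibble::tibble(
      group = groups, intercept_dev = rnorm(length(groups), 0, gs$surv))
    params[[j]]$growth$year <- tibble::tibble(
      year = years, intercept_dev = rnorm(length(years), 0, ys$grow_int),
      size_dev = rnorm(length(years), 0, ys$grow_size))
    params[[j]]$growth$group <- tibble::tibble(
      group = groups, intercept_dev = rnorm(length(groups), 0, gs$grow))
    params[[j]]$recruitment$year <- tibble::tibble(
      year = years, intercept_dev = rnorm(length(years), 0, ys$rec_int))
    params[[j]]$recruitment$group <- tibble::tibble(
      group = groups, intercept_dev = rnorm(length(groups), 0, gs$rec))
  }
  params
}

random_init_state <- function(truth) {
  ini <- truth$init
  n <- ini$n_per_species * length(truth$species)
  logsize <- pmax(log(POINT_AREA_CM2),
                  rnorm(n, ini$logsize_mean, ini$logsize_sd))
  ibm_state(tibble::tibble(
    species = rep(truth$species, each = ini$n_per_species),
    genet_id = sprintf("%s_%05d", rep(truth$species, each = ini$n_per_species),
                       rep(seq_len(ini$n_per_species), length(truth$species))),
    logsize = logsize, x = runif(n, 0, QUADRAT_CM), y = runif(n, 0, QUADRAT_CM)))
}

#' Simulate ground-truth quadrat records with the IBM
#'
#' Runs one IBM per quadrat (quadrats of a group share the group-mean cover
#' entering effective cover) under drawn climate and year/group effects, and
#' returns circle-represented genet records with true identities and recruit
#' flags — the labelled archive every downstream module can be tested
#' against. Communities that lose a species entirely are regenerated with a
#' fresh RNG substream up to `max_retry` times, then fail loudly.
#'
#' @param truth A [scenario()].
#' @param n_quadrats,n_years Archive dimensions.
#' @param n_groups Number of quadrat groups (quadrats assigned round-robin).
#' @param max_retry Regeneration attempts on community extinction.
#' @return List: `records` (genet records with `is_recruit`), `climate`,
#'   `params` (generating parameters incl. year/group effects), `truth`.
#' @export
simulate_quadrats <- function(truth, n_quadrats = 10, n_years = 20,
                              n_groups = 2, max_retry = 5) {
  for (attempt in seq_len(max_retry)) {
    res <- try_simulate_quadrats(truth, n_quadrats, n_years, n_groups)
    if (!is.null(res)) return(res)
    inform(sprintf("community extinction in synthetic archive; retry %d", attempt))
  }
  abort("community went extinct in every synthetic-archive attempt")
}

try_simulate_quadrats <- function(truth, n_quadrats, n_years, n_groups) {
  years <- seq(2001L, length.out = n_years)
  groups <- sprintf("G%d", seq_len(n_groups))
  quadrats <- sprintf("Q%02d", seq_len(n_quadrats))
  qgroup <- setNames(rep(groups, length.out = n_quadrats), quadrats)
  climate <- generate_climate(n_years, truth$climate_means, truth$climate_sds)
  params <- truth_with_effects(truth, years, groups)
  states <- setNames(lapply(quadrats, function(q) random_init_state(truth)),
                     quadrats)
  recs <- list()
  snapshot <- function(state, q, yr, prev_ids) {
    tibble::tibble(site = "S", quadrat = q, group = qgroup[[q]],
                   species = state$species, genet_id = state$genet_id,
                   year = yr, area_cm2 = exp(state$logsize),
                   x = state$x, y = state$y,
                   is_recruit = if (is.null(prev_ids)) NA
                                else !paste(state$species, state$genet_id) %in% prev_ids)
  }
  for (q in quadrats) recs[[paste(q, years[1])]] <- snapshot(states[[q]], q, years[1], NULL)
  for (yi in seq_along(years)[-1]) {
    yr_from <- years[yi - 1]
    C <- unlist(climate[climate$year == yr_from, climate_base_covariates])
    gm_cover <- lapply(groups, function(g) {
      member <- quadrats[qgroup == g]
      covs <- vapply(member, function(q) cover_vec(states[[q]], truth$species),
                     numeric(length(truth$species)))
      rowMeans(matrix(covs, nrow = length(truth$species),
                      dimnames = list(truth$species, NULL)))
    })
    names(gm_cover) <- groups
    for (q in quadrats) {
      prev_ids <- paste(states[[q]]$species, states[[q]]$genet_id)
      states[[q]] <- ibm_step(states[[q]], params, truth$alphas, C,
                              year = yr_from, group = qgroup[[q]],
                              group_mean_cover = gm_cover[[qgroup[[q]]]],
                              boundary = "absorbing")
      recs[[paste(q, years[yi])]] <- snapshot(states[[q]], q, years[yi], prev_ids)
    }
  }
  records <- list_rbind(recs)
  final <- records |> filter(.data$year == max(years)) |> count(.data$species)
  if (nrow(final) < length(truth$species)) return(NULL)
  list(records = records, climate = climate, params = params, truth = truth)
}

#' Render genet records as a polygon-map archive
#'
#' Each circle-represented genet is emitted as an exact-area regular polygon
#' (point-sized plants as single points); vertices are clamped to the quadrat
#' extent, so shapes hugging the edge lose a sliver of area. The hidden true
#' identities stay in the accompanying records.
#'
#' @param truth A [scenario()].
#' @param n_quadrats,n_years,n_groups,max_retry As in [simulate_quadrats()].
#' @return List `maps` ([quadrat_map()]), `records`, `climate`, `params`,
#'   `truth`.
#' @export
generate_quadrat_series <- function(truth, n_quadrats = 10, n_years = 20,
                                    n_groups = 2, max_retry = 5) {
  sim <- simulate_quadrats(truth, n_quadrats, n_years, n_groups, max_retry)
  rec <- sim$records
  feats <- rec |>
    mutate(feature_id = .data$genet_id,
           is_point = .data$area_cm2 <= POINT_AREA_CM2,
           geom = pmap(list(.data$x, .data$y, .data$area_cm2, .data$is_point),
                       function(x, y, a, pt) {
                         if (pt) matrix(c(x, y), 1, 2)
                         else clip_polygon_to_quadrat(regular_polygon(x, y, a, n = 16))
                       })) |>
    select("site", "quadrat", "group", "year", "species", "feature_id",
           "is_point", "geom")
  sim$maps <- quadrat_map(feats)
  sim
}
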
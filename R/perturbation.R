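# Climate-perturbation experiments. Equilibrium cover is compared between a
# baseline run (observed climate) and runs with perturbed climate applied to
# all species ("full" effect) or only to a focal species ("direct" effect);
# the indirect effect is their difference. All paired runs share the same
# sequence of drawn climate years and random year effects (common random
# numbers), so a zero-magnitude perturbation yields exactly zero effects.

#' Perturb a climate covariate table
#'
#' Three perturbation kinds: `"precip-mean"` multiplies the precipitation
#' covariates by `1 + mean_pct/100`; `"temp-mean"` shifts the temperature
#' covariates (additively by `mean_pct`% of the site mean by default, or
#' multiplicatively); `"variability"` scales every covariate's anomalies
#' about its site mean by `sqrt(1 + variance_pct/100)`, multiplying each
#' sample variance by exactly `1 + variance_pct/100` while leaving the means
#' unchanged.
#'
#' @param climate Climate tibble.
#' @param kind `"precip-mean"`, `"temp-mean"`, or `"variability"`.
#' @param mean_pct Mean perturbation magnitude (percent).
#' @param variance_pct Variance perturbation magnitude (percent).
#' @param temp_mode `"additive"` (shift by a fraction of the site mean, which
#'   does not depend on the temperature origin) or `"multiplicative"`.
#' @return The perturbed climate tibble.
#' @export
perturb_climate <- function(climate, kind = c("precip-mean", "temp-mean",
                                              "variability"),
                            mean_pct = 1, variance_pct = 10,
                            temp_mode = c("additive", "multiplicative")) {
  kind <- match.arg(kind)
  temp_mode <- match.arg(temp_mode)
  if (mean_pct <= 0 || variance_pct <= 0) abort("perturbation magnitude must be positive")
  out <- climate
  if (kind == "precip-mean") {
    out <- out |> mutate(across(all_of(climate_precip_covariates),
                                ~ .x * (1 + mean_pct / 100)))
  } else if (kind == "temp-mean") {
    out <- out |>
      group_by(.data$site) |>
      mutate(across(all_of(climate_temp_covariates), function(x) {
        if (temp_mode == "additive") x + (mean_pct / 100) * mean(x)
        else x * (1 + mean_pct / 100)
      })) |>
      ungroup()
  } else {
    sf <- sqrt(1 + variance_pct / 100)
    out <- out |>
      group_by(.data$site) |>
      mutate(across(all_of(climate_base_covariates),
                    ~ mean(.x) + sf * (.x - mean(.x)))) |>
      ungroup()
  }
  out
}

run_paired_equilibrium <- function(mesh, species, params, alphas, climate_by_sp,
                                   seed, year_library, burn_in, window,
                                   no_overlap) {
  set.seed(seed)
  equilibrium_cover(mesh, species, params, alphas, climate_by_sp,
                    year_library = year_library, burn_in = burn_in,
                    window = window, no_overlap = no_overlap)
}

#' Full effect of a climate perturbation
#'
#' Equilibrium cover when every species experiences the perturbed climate,
#' minus the baseline equilibrium cover, run with common random numbers.
#'
#' @inheritParams equilibrium_cover
#' @param perturbed Perturbed climate tibble (from [perturb_climate()]).
#' @param seed Integer seed shared by the paired runs.
#' @param baseline Optional precomputed baseline equilibrium (from an
#'   [equilibrium_cover()] run started at the same seed); avoids repeating
#'   the identical baseline run.
#' @return Tibble `species, baseline, perturbed_cover, full` (raw cover
#'   units), with a `trend_ok` flag from each equilibrium diagnostic.
#' @export
full_effect <- function(mesh, species, params, alphas, climate, perturbed,
                        seed, year_library = NULL, burn_in = 500,
                        window = 2000, no_overlap = TRUE, baseline = NULL) {
  base <- baseline %||%
    run_paired_equilibrium(mesh, species, params, alphas, climate, seed,
                           year_library, burn_in, window, no_overlap)
  pert <- run_paired_equilibrium(mesh, species, params, alphas, perturbed, seed,
                                 year_library, burn_in, window, no_overlap)
  tibble::tibble(species = base$species, baseline = base$cover_cm2,
                 perturbed_cover = pert$cover_cm2,
                 full = pert$cover_cm2 - base$cover_cm2,
                 trend_ok = base$trend_ok & pert$trend_ok)
}

#' Direct effect of a climate perturbation on one focal species
#'
#' The focal species' vital rates see the perturbed climate while every other
#' species sees the observed climate; the paired simulations share the same
#' drawn sequence of climate years and year effects.
#'
#' @inheritParams full_effect
#' @param focal Focal species code.
#' @inheritParams full_effect
#' @return One-row tibble `species, baseline, mixed_cover, direct`.
#' @export
direct_effect <- function(focal, mesh, species, params, alphas, climate,
                          perturbed, seed, year_library = NULL, burn_in = 500,
                          window = 2000, no_overlap = TRUE, baseline = NULL) {
  if (!focal %in% species) abort("focal species not in the community")
  base <- baseline %||%
    run_paired_equilibrium(mesh, species, params, alphas, climate, seed,
                           year_library, burn_in, window, no_overlap)
  mixed_climate <- setNames(
    lapply(species, function(j) if (j == focal) perturbed else climate), species)
  mix <- run_paired_equilibrium(mesh, species, params, alphas, mixed_climate,
                                seed, year_library, burn_in, window, no_overlap)
  i <- match(focal, base$species)
  tibble::tibble(species = focal, baseline = base$cover_cm2[i],
                 mixed_cover = mix$cover_cm2[i],
                 direct = mix$cover_cm2[i] - base$cover_cm2[i])
}

#' Decompose a perturbation response into direct and indirect parts
#'
#' The indirect effect is defined as `full - direct` (exact under common
#' random numbers). Proportional effects divide the raw effects by the
#' species' baseline equilibrium cover; the log ratio
#' `log(|prop indirect| / |prop direct|)` is positive when indirect effects
#' dominate.
#'
#' @param full,direct Raw effects (cover units).
#' @param baseline Baseline equilibrium cover (> 0).
#' @return One-row tibble with raw, proportional and log-ratio columns.
#' @export
decompose_effects <- function(full, direct, baseline) {
  if (any(baseline <= 0)) abort("baseline cover must be positive")
  indirect <- full - direct
  prop_full <- full / baseline
  prop_direct <- direct / baseline
  prop_indirect <- indirect / baseline
  log_ratio <- ifelse(direct == 0, NA_real_,
                      log(abs(prop_indirect) / abs(prop_direct)))
  tibble::tibble(baseline = baseline, full = full, direct = direct,
                 indirect = indirect, prop_full = prop_full,
                 prop_direct = prop_direct, prop_indirect = prop_indirect,
                 log_ratio = log_ratio)
}

#' Run a full perturbation experiment for one community
#'
#' For each requested perturbation kind: perturbs the climate, computes full
#' effects (all species simultaneously) and per-species direct effects, and
#' decomposes the responses. The community-level variance of raw direct
#' effects (shared by all species of a site x perturbation) is attached.
#'
#' @inheritParams full_effect
#' @param kinds Perturbation kinds to run.
#' @param mean_pct,variance_pct,temp_mode Passed to [perturb_climate()].
#' @param site Site label recorded in the output.
#' @return Tibble of class `perturbation_result`, one row per species x
#'   perturbation.
#' @export
perturbation_experiment <- function(mesh, species, params, alphas, climate,
                                    seed, kinds = c("precip-mean", "temp-mean",
                                                    "variability"),
                                    mean_pct = 1, variance_pct = 10,
                                    temp_mode = "additive",
                                    year_library = NULL, burn_in = 500,
                                    window = 2000, no_overlap = TRUE,
                                    site = "site") {
  base <- run_paired_equilibrium(mesh, species, params, alphas, climate, seed,
                                 year_library, burn_in, window, no_overlap)
  rows <- list()
  for (kind in kinds) {
    pert <- perturb_climate(climate, kind, mean_pct = mean_pct,
                            variance_pct = variance_pct, temp_mode = temp_mode)
    fe <- full_effect(mesh, species, params, alphas, climate, pert, seed,
                      year_library, burn_in, window, no_overlap,
                      baseline = base)
    de <- list_rbind(map(species, function(j) {
      direct_effect(j, mesh, species, params, alphas, climate, pert, seed,
                    year_library, burn_in, window, no_overlap,
                    baseline = base)
    }))
    merged <- fe |>
      left_join(de |> select("species", "direct"), by = "species")
    dec <- decompose_effects(merged$full, merged$direct, merged$baseline)
    rows[[kind]] <- bind_cols(
      tibble::tibble(site = site, perturbation = kind,
                     species = merged$species), dec) |>
      mutate(var_direct = direct_effect_variance(dec$direct))
  }
  out <- list_rbind(rows)
  class(out) <- c("perturbation_result", class(out))
  out
}

#' Community-level variance of raw direct effects
#'
#' Sample variance (n - 1 denominator) across the species of one site and
#' perturbation; every species row of that site x perturbation carries the
#' same value. `NA` with fewer than two species.
#'
#' @param direct Vector of raw direct effects (one per species).
#' @return Scalar variance.
#' @export
direct_effect_variance <- function(direct) {
  if (length(direct) < 2) return(NA_real_)
  var(direct)
}

#' Mixed-effects synthesis of indirect-effect magnitudes
#'
#' Linear mixed-effects model in which the absolute magnitude of raw
#' indirect effects is explained by the species' negative-frequency-
#' dependence slope and the community-level variance of raw direct effects,
#' with random intercepts for site and for perturbation nested within site;
#' fitted by maximum likelihood. If the nested random structure is singular
#' the model falls back, with a warning, to a site-only random intercept.
#'
#' @param data Tibble with columns `abs_indirect`, `nfd`, `var_direct`,
#'   `site`, `perturbation` (one row per species x perturbation).
#' @return An `nlme::lme` fit.
#' @export
indirect_effects_model <- function(data) {
  req <- c("abs_indirect", "nfd", "var_direct", "site", "perturbation")
  miss <- setdiff(req, names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  fit_lme <- function(random) {
    nlme::lme(abs_indirect ~ nfd + var_direct, random = random,
              data = data, method = "ML",
              control = nlme::lmeControl(opt = "optim", returnObject = TRUE))
  }
  tryCatch(
    fit_lme(~ 1 | site / perturbation),
    error = function(e) {
      warn(paste("nested random-effects fit failed;",
                 "falling back to a simpler structure:", conditionMessage(e)))
      tryCatch(fit_lme(~ 1 | site), error = function(e2) {
        warn("site-level random intercept also failed; using ordinary least squares")
        lm(abs_indirect ~ nfd + var_direct, data = data)
      })
    })
}

#' Tidy fixed-effect table for the indirect-effects synthesis model
#'
#' @param x An `nlme::lme` fit from [indirect_effects_model()] (or the `lm`
#'   it degenerates to).
#' @param ... Unused.
#' @return Tibble `term, estimate, std.error, df, statistic, p.value`.
#' @export
tidy_lme <- function(x, ...) {
  if (inherits(x, "lme")) {
    tt <- summary(x)$tTable
    return(tibble::tibble(term = rownames(tt), estimate = tt[, "Value"],
                          std.error = tt[, "Std.Error"], df = tt[, "DF"],
                          statistic = tt[, "t-value"], p.value = tt[, "p-value"]))
  }
  s <- summary(x)$coefficients
  tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                 std.error = unname(s[, 2]), df = x$df.residual,
                 statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}
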
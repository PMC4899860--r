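# Parameter containers and predictors for the three vital rates.
#
# Survival: logistic regression on log size u with year intercepts, per-year
# size-slope deviations, group intercepts, crowding effects (per neighbour
# species), crowding x size interactions, climate effects and climate x size
# interactions.
# Growth: same linear-predictor structure for the mean change in log size,
# plus a size-dependent variance function var(v) = a * exp(b * v) about the
# growth curve.
# Recruitment: quadrat-level counts, negative binomial with Ricker-type mean
# lambda_j = N'_j * exp(intercept + dd . sqrt(N') + eta . C), where N' is
# "effective cover" mixing focal-quadrat cover with the group mean.

named_or_empty <- function(x) {
  if (is.null(x) || length(x) == 0) return(setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(names(x) == "")) abort("coefficient vectors must be named")
  x
}

re_table <- function(tbl, cols) {
  if (is.null(tbl)) return(tibble::tibble(!!!setNames(rep(list(numeric(0)), length(cols)), cols)))
  tibble::as_tibble(tbl)
}

#' Survival model parameters
#'
#' @param species Focal species code.
#' @param intercept Baseline logit-scale intercept.
#' @param size Size slope (on log area).
#' @param crowding Named vector of crowding effects, one per neighbour species.
#' @param crowding_size Named vector of crowding x size interaction effects.
#' @param climate Named vector of climate effects (names from
#'   [climate_covariate_names()], interactions allowed).
#' @param climate_size Named vector of climate x size interaction effects.
#' @param year Tibble `year, intercept_dev, size_dev` of per-year random
#'   deviations.
#' @param group Tibble `group, intercept_dev`.
#' @return Object of class `c("survival_params", "vital_params")`.
#' @export
survival_params <- function(species, intercept = 0, size = 0, crowding = NULL,
                            crowding_size = NULL, climate = NULL,
                            climate_size = NULL, year = NULL, group = NULL) {
  structure(list(vital = "survival", species = species, intercept = intercept,
                 size = size, crowding = named_or_empty(crowding),
                 crowding_size = named_or_empty(crowding_size),
                 climate = named_or_empty(climate),
                 climate_size = named_or_empty(climate_size),
                 year = re_table(year, c("year", "intercept_dev", "size_dev")),
                 group = re_table(group, c("group", "intercept_dev"))),
            class = c("survival_params", "vital_params"))
}

#' Growth model parameters
#'
#' Same structure as [survival_params()] for the mean of next log size, plus
#' the variance function `var(v) = var_a * exp(var_b * v)` evaluated at the
#' predicted size.
#'
#' @inheritParams survival_params
#' @param var_a,var_b Variance-function parameters; `var_a` must be positive.
#' @return Object of class `c("growth_params", "vital_params")`.
#' @export
growth_params <- function(species, intercept = 0, size = 1, crowding = NULL,
                          crowding_size = NULL, climate = NULL,
                          climate_size = NULL, var_a = 1, var_b = 0,
                          year = NULL, group = NULL) {
  if (var_a <= 0) abort("var_a must be positive (growth variance)")
  structure(list(vital = "growth", species = species, intercept = intercept,
                 size = size, crowding = named_or_empty(crowding),
                 crowding_size = named_or_empty(crowding_size),
                 climate = named_or_empty(climate),
                 climate_size = named_or_empty(climate_size),
                 var_a = var_a, var_b = var_b,
                 year = re_table(year, c("year", "intercept_dev", "size_dev")),
                 group = re_table(group, c("group", "intercept_dev"))),
            class = c("growth_params", "vital_params"))
}

#' Recruitment model parameters
#'
#' @inheritParams survival_params
#' @param dd Named vector of density-dependence coefficients on the square
#'   root of effective cover (intra- and interspecific).
#' @param theta Negative-binomial size parameter (> 0).
#' @param p_mix Mixing fraction between focal-quadrat cover and group-mean
#'   cover in the effective-cover computation, in [0, 1].
#' @param year Tibble `year, intercept_dev`.
#' @return Object of class `c("recruit_params", "vital_params")`.
#' @export
recruit_params <- function(species, intercept = 0, dd = NULL, climate = NULL,
                           theta = 1, p_mix = 0.5, year = NULL, group = NULL) {
  if (theta <= 0) abort("theta must be positive")
  if (p_mix < 0 || p_mix > 1) abort("p_mix must lie in [0, 1]")
  structure(list(vital = "recruitment", species = species, intercept = intercept,
                 dd = named_or_empty(dd), climate = named_or_empty(climate),
                 theta = theta, p_mix = p_mix,
                 year = re_table(year, c("year", "intercept_dev")),
                 group = re_table(group, c("group", "intercept_dev"))),
            class = c("recruit_params", "vital_params"))
}

#' @export
print.vital_params <- function(x, ...) {
  cat(sprintf("<%s_params for %s: %d climate terms, %d year levels, %d groups>\n",
              substr(x$vital, 1, 6), x$species, length(x$climate),
              nrow(x$year), nrow(x$group)))
  invisible(x)
}

# Random-effect deviation lookup. `key = NULL` gives the marginal prediction
# (deviation 0); an unknown key is a hard error unless marginal = TRUE.
re_dev <- function(tbl, key, col, what, marginal = FALSE) {
  if (is.null(key)) return(0)
  hit <- match(key, tbl[[what]])
  if (is.na(hit)) {
    if (marginal) return(0)
    abort(sprintf("unknown %s '%s' in fitted parameters (use %s = NULL for marginal predictions)",
                  what, key, what))
  }
  tbl[[col]][hit]
}

# Full covariate vector with interaction terms available on demand.
climate_terms <- function(C) {
  C <- unlist(C)[climate_base_covariates]
  if (anyNA(C)) abort("climate vector must contain the five named covariates")
  c(C, ppt1_T1 = unname(C["ppt1"] * C["T1"]), ppt2_T2 = unname(C["ppt2"] * C["T2"]))
}

dot_named <- function(coefs, values) {
  if (length(coefs) == 0) return(0)
  miss <- setdiff(names(coefs), names(values))
  if (length(miss)) abort(paste("values missing for coefficients:", paste(miss, collapse = ", ")))
  sum(coefs * values[names(coefs)])
}

# Crowding input as a matrix n x species (named columns); accepts a single
# named vector too. Columns are padded with zeros for coefficient species not
# present (a species absent from the community exerts zero crowding).
crowding_matrix <- function(w, n, needed = character(0)) {
  if (is.null(w)) w <- matrix(0, n, 0)
  if (is.null(dim(w))) w <- matrix(w, n, length(w), byrow = TRUE, dimnames = list(NULL, names(w)))
  missing <- setdiff(needed, colnames(w))
  if (length(missing)) {
    pad <- matrix(0, n, length(missing), dimnames = list(NULL, missing))
    w <- cbind(w, pad)
  }
  w
}

sg_linear_predictor <- function(u, C, w, params, year, group, marginal) {
  n <- length(u)
  w <- crowding_matrix(w, n, needed = union(names(params$crowding),
                                            names(params$crowding_size)))
  Cv <- climate_terms(C)
  g_y <- re_dev(params$year, year, "intercept_dev", "year", marginal)
  b_y <- re_dev(params$year, year, "size_dev", "year", marginal)
  g_g <- re_dev(params$group, group, "intercept_dev", "group", marginal)
  lp <- params$intercept + g_y + g_g + (params$size + b_y) * u
  if (length(params$crowding)) {
    lp <- lp + as.vector(w[, names(params$crowding), drop = FALSE] %*% params$crowding)
  }
  if (length(params$crowding_size)) {
    lp <- lp + u * as.vector(w[, names(params$crowding_size), drop = FALSE] %*% params$crowding_size)
  }
  lp + dot_named(params$climate, Cv) + u * dot_named(params$climate_size, Cv)
}

#' Survival probability of a genet
#'
#' Inverse-logit of the survival linear predictor.
#'
#' @param u Log area (vectorised).
#' @param C Named climate covariate vector for the transition.
#' @param w Crowding: named vector, or matrix with one row per element of `u`
#'   and one named column per neighbour species.
#' @param params A [survival_params()].
#' @param year,group Random-effect levels; `NULL` for marginal predictions.
#' @param marginal Treat unknown year/group levels as zero deviations.
#' @return Survival probabilities in (0, 1).
#' @export
survival_prob <- function(u, C, w, params, year = NULL, group = NULL,
                          marginal = FALSE) {
  stopifnot(inherits(params, "survival_params"))
  plogis(sg_linear_predictor(u, C, w, params, year, group, marginal))
}

#' Mean and variance of next log size
#'
#' The mean is the growth linear predictor; the variance is the
#' size-dependent function `var_a * exp(var_b * mean)` evaluated at the
#' predicted size.
#'
#' @inheritParams survival_prob
#' @param params A [growth_params()].
#' @return Tibble with columns `mean` and `var`.
#' @export
growth_moments <- function(u, C, w, params, year = NULL, group = NULL,
                           marginal = FALSE) {
  stopifnot(inherits(params, "growth_params"))
  m <- sg_linear_predictor(u, C, w, params, year, group, marginal)
  tibble::tibble(mean = m, var = params$var_a * exp(params$var_b * m))
}

#' Effective cover for recruitment
#'
#' Mixture of the observed cover in the focal quadrat and the mean cover
#' across the quadrat's group, acknowledging seed input from outside the
#' mapped square.
#'
#' @param N Cover in the focal quadrat (cm^2).
#' @param group_mean Mean cover across the group (cm^2).
#' @param p Mixing fraction in [0, 1]; 1 uses only the focal quadrat.
#' @return Effective cover `p * N + (1 - p) * group_mean`.
#' @export
effective_cover <- function(N, group_mean, p) {
  if (any(p < 0 | p > 1)) abort("mixing fraction p must lie in [0, 1]")
  if (any(N < 0 | group_mean < 0)) abort("covers must be non-negative")
  p * N + (1 - p) * group_mean
}

#' Expected recruit count (negative-binomial mean intensity)
#'
#' Ricker-type: proportional to the focal species' effective cover, with
#' intra- and interspecific density dependence entering through the square
#' root of effective cover.
#'
#' @param Nprime Named vector of per-species effective cover (cm^2), or a
#'   matrix with named columns (one row per quadrat).
#' @param C Named climate covariate vector.
#' @param params A [recruit_params()].
#' @param year,group Random-effect levels (`NULL` for marginal).
#' @param marginal Treat unknown levels as zero deviations.
#' @return Mean intensity lambda for the focal species (vectorised over
#'   matrix rows). Zero effective cover gives exactly zero.
#' @export
recruit_intensity <- function(Nprime, C, params, year = NULL, group = NULL,
                              marginal = FALSE) {
  stopifnot(inherits(params, "recruit_params"))
  if (is.null(dim(Nprime))) Nprime <- matrix(Nprime, 1, length(Nprime),
                                             dimnames = list(NULL, names(Nprime)))
  if (any(Nprime < 0)) abort("effective cover must be non-negative")
  # species absent from the community have zero cover
  Nprime <- crowding_matrix(Nprime, nrow(Nprime),
                            needed = c(params$species, names(params$dd)))
  Cv <- climate_terms(C)
  g_y <- re_dev(params$year, year, "intercept_dev", "year", marginal)
  g_g <- re_dev(params$group, group, "intercept_dev", "group", marginal)
  lp <- params$intercept + g_y + g_g + dot_named(params$climate, Cv)
  if (length(params$dd)) {
    lp <- lp + as.vector(sqrt(Nprime[, names(params$dd), drop = FALSE]) %*% params$dd)
  }
  as.vector(Nprime[, params$species] * exp(lp))
}

#' Draw recruit counts
#'
#' Negative-binomial draws with mean `lambda` and variance
#' `lambda + lambda^2 / theta`.
#'
#' @param n Number of draws.
#' @param lambda Mean intensity (recycled).
#' @param theta Size parameter (> 0).
#' @return Integer vector of counts.
#' @export
sample_recruits <- function(n, lambda, theta) {
  if (any(lambda < 0)) abort("lambda must be non-negative")
  if (theta <= 0) abort("theta must be positive")
  rnbinom(n, size = theta, mu = lambda)
}
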
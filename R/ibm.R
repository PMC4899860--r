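# Spatially explicit, demographically stochastic individual-based model.
# Each time step: every genet survives by a Bernoulli draw on its fitted
# survival probability, survivors draw a new log size from the fitted growth
# distribution (Normal with size-dependent variance), and each species
# produces a negative-binomial number of recruits from the quadrat-level
# recruitment model; recruits appear at uniform-random locations at the
# point-plant size. Crowding is recomputed from the current geometry each
# step. Boundaries are absorbing by default (neighbours outside the quadrat
# simply do not exist); a periodic mode is available for comparisons against
# the spatially implicit integral projection model, whose mean-field crowding
# assumes a homogeneous (edge-free) plane.

#' Construct an IBM community state
#'
#' @param df Tibble with `species, genet_id, logsize, x, y`.
#' @param quadrat_cm Quadrat side length (cm).
#' @return An `ibm_state` tibble.
#' @export
ibm_state <- function(df, quadrat_cm = QUADRAT_CM) {
  req <- c("species", "genet_id", "logsize", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) abort(paste("ibm_state missing columns:", paste(miss, collapse = ", ")))
  if (nrow(df) && (any(df$x < 0 | df$x > quadrat_cm | df$y < 0 | df$y > quadrat_cm))) {
    abort("locations must lie within the quadrat extent")
  }
  if (any(!is.finite(df$logsize))) abort("sizes must be finite")
  out <- tibble::as_tibble(df[, req])
  attr(out, "quadrat_cm") <- quadrat_cm
  class(out) <- c("ibm_state", class(out))
  out
}

#' Per-species cover of a community state
#'
#' Cover is the summed arithmetic area of all individuals of the species;
#' the fraction is relative to the quadrat area.
#'
#' @param state An [ibm_state()] (or an IPM state).
#' @param species Optional species universe; absent species report 0.
#' @return Tibble `species, cover_cm2, frac`.
#' @export
cover_of <- function(state, species = NULL) {
  UseMethod("cover_of")
}

#' @export
cover_of.ibm_state <- function(state, species = NULL) {
  qa <- (attr(state, "quadrat_cm") %||% QUADRAT_CM)^2
  if (nrow(state)) {
    sums <- rowsum(exp(state$logsize), state$species)
    out <- tibble::tibble(species = rownames(sums),
                          cover_cm2 = unname(sums[, 1]))
  } else {
    out <- tibble::tibble(species = character(0), cover_cm2 = numeric(0))
  }
  if (!is.null(species)) {
    hit <- match(species, out$species)
    out <- tibble::tibble(species = species,
                          cover_cm2 = ifelse(is.na(hit), 0, out$cover_cm2[hit]))
  }
  out$frac <- out$cover_cm2 / qa
  out
}

# Crowding matrix (individuals x neighbour species) for a single-quadrat
# state; periodic boundaries wrap distances on the torus.
ibm_crowding <- function(state, alphas, boundary = "absorbing") {
  n <- nrow(state)
  sp_all <- colnames(alphas)
  w <- matrix(0, n, length(sp_all), dimnames = list(NULL, sp_all))
  if (n < 2) return(w)
  L <- attr(state, "quadrat_cm") %||% QUADRAT_CM
  dx <- abs(outer(state$x, state$x, "-"))
  dy <- abs(outer(state$y, state$y, "-"))
  if (boundary == "periodic") {
    dx <- pmin(dx, L - dx)
    dy <- pmin(dy, L - dy)
  }
  d2 <- dx^2 + dy^2
  u <- exp(state$logsize)
  for (j in unique(state$species)) {
    rows <- which(state$species == j)
    for (m in unique(state$species)) {
      a <- alpha_lookup(alphas, j, m)
      sel <- state$species == m
      wv <- exp(-a * d2[rows, sel, drop = FALSE]) %*% u[sel]
      if (m == j) wv <- wv - u[rows]
      w[rows, m] <- wv
    }
  }
  w
}

next_genet_counter <- function(state) {
  ids <- suppressWarnings(as.integer(sub("^.*_", "", state$genet_id)))
  max(c(0L, ids[!is.na(ids)]))
}

#' Advance an IBM community one time step
#'
#' @param state An [ibm_state()].
#' @param params Named list (by species) of lists with elements `survival`
#'   ([survival_params()]), `growth` ([growth_params()]) and `recruitment`
#'   ([recruit_params()]).
#' @param alphas An [alpha_matrix()] covering all species in `params`.
#' @param C Named climate covariate vector for the transition.
#' @param year,group Random-effect levels applied to all three vital rates
#'   (`NULL` for marginal dynamics driven by climate only).
#' @param group_mean_cover Optional named per-species group-mean cover used
#'   in the effective-cover mixture; defaults to the quadrat's own cover
#'   (making the mixture irrelevant).
#' @param boundary `"absorbing"` or `"periodic"`.
#' @param recruit_logsize Initial log size of recruits.
#' @param marginal Treat unknown year/group levels as zero deviations.
#' @return The next [ibm_state()].
#' @export
ibm_step <- function(state, params, alphas, C, year = NULL, group = NULL,
                     group_mean_cover = NULL, boundary = "absorbing",
                     recruit_logsize = log(POINT_AREA_CM2), marginal = FALSE) {
  sp_params <- names(params)
  present <- unique(state$species)
  if (length(setdiff(present, sp_params))) {
    abort("params must cover all species present in the state")
  }
  L <- attr(state, "quadrat_cm") %||% QUADRAT_CM
  ord <- order(state$species, state$genet_id)
  state <- state[ord, , drop = FALSE]
  attr(state, "quadrat_cm") <- L
  w <- ibm_crowding(state, alphas, boundary = boundary)
  sp_out <- character(0); id_out <- character(0)
  ls_out <- numeric(0); x_out <- numeric(0); y_out <- numeric(0)
  for (j in sp_params) {
    rows <- which(state$species == j)
    if (!length(rows)) next
    u <- state$logsize[rows]
    p <- survival_prob(u, C, w[rows, , drop = FALSE], params[[j]]$survival,
                       year = year, group = group, marginal = marginal)
    alive <- rbinom(length(rows), 1, p) == 1
    if (!any(alive)) next
    gm <- growth_moments(u[alive], C, w[rows[alive], , drop = FALSE],
                         params[[j]]$growth, year = year, group = group,
                         marginal = marginal)
    k <- sum(alive)
    sp_out <- c(sp_out, rep(j, k))
    id_out <- c(id_out, state$genet_id[rows[alive]])
    ls_out <- c(ls_out, rnorm(k, gm$mean, sqrt(gm$var)))
    x_out <- c(x_out, state$x[rows[alive]])
    y_out <- c(y_out, state$y[rows[alive]])
  }
  N <- setNames(numeric(length(sp_params)), sp_params)
  if (nrow(state)) {
    sums <- rowsum(exp(state$logsize), state$species)
    N[rownames(sums)] <- sums[, 1]
  }
  counter <- next_genet_counter(state)
  for (j in sp_params) {
    pj <- params[[j]]$recruitment
    gmc <- if (is.null(group_mean_cover)) N else group_mean_cover
    Nprime <- effective_cover(N, gmc[names(N)], pj$p_mix)
    lambda <- recruit_intensity(Nprime, C, pj, year = year, group = group,
                                marginal = marginal)
    ny <- sample_recruits(1, lambda, pj$theta)
    if (ny > 0) {
      counter <- counter + ny
      sp_out <- c(sp_out, rep(j, ny))
      id_out <- c(id_out, sprintf("%s_%05d", j, seq_len(ny) + counter - ny))
      ls_out <- c(ls_out, rep(recruit_logsize, ny))
      x_out <- c(x_out, runif(ny, 0, L))
      y_out <- c(y_out, runif(ny, 0, L))
    }
  }
  ibm_state(tibble::tibble(species = sp_out, genet_id = id_out,
                           logsize = ls_out, x = x_out, y = y_out),
            quadrat_cm = L)
}

#' Simulate an IBM community trajectory
#'
#' Advances the community `n_steps` times, at each step drawing one climate
#' year and, independently, one year of random year effects from the supplied
#' libraries (or using constant conditions when a single climate row and no
#' year library are given).
#'
#' @inheritParams ibm_step
#' @param climate Climate tibble (rows are the observed years to draw from).
#' @param year_library Vector of year labels to draw random year effects
#'   from; `NULL` runs on climate only (year deviations at zero).
#' @param n_steps Number of transitions.
#' @return Tibble `step, species, cover_cm2, frac` (step 0 is the initial
#'   state).
#' @export
simulate_ibm <- function(state, params, alphas, climate, n_steps,
                         year_library = NULL, group = NULL,
                         boundary = "absorbing") {
  sp <- names(params)
  out <- list(cover_of(state, species = sp) |> mutate(step = 0L))
  for (s in seq_len(n_steps)) {
    Crow <- climate[sample.int(nrow(climate), 1), ]
    yr <- if (is.null(year_library)) NULL else sample(year_library, 1)
    state <- ibm_step(state, params, alphas, unlist(Crow[climate_base_covariates]),
                      year = yr, group = group, boundary = boundary,
                      marginal = TRUE)
    out[[s + 1]] <- cover_of(state, species = sp) |> mutate(step = s)
  }
  list_rbind(out) |> select("step", "species", "cover_cm2", "frac")
}

#' Hindcast observed quadrats with the IBM
#'
#' Initialises the IBM with the plant sizes and locations observed in the
#' first census year of each quadrat, projects forward drawing year-specific
#' parameters in chronological order, and re-initialises from the
#' observations after census gaps. Cover is averaged over replicate runs.
#'
#' @param records Genet-record tibble of the observed quadrats.
#' @param params Per-species vital-rate parameter list (see [ibm_step()]);
#'   year tables must cover every historical transition year.
#' @param alphas An [alpha_matrix()].
#' @param climate Climate tibble covering the census span.
#' @param n_reps Replicate simulation runs to average.
#' @param mode `"full"` (climate and random year effects) or
#'   `"climate_only"` (year deviations at zero).
#' @param boundary Boundary behaviour, absorbing by default.
#' @return Tibble `site, quadrat, year, species, cover_pred, cover_obs`.
#' @export
simulate_historical <- function(records, params, alphas, climate, n_reps = 50,
                                mode = c("full", "climate_only"),
                                boundary = "absorbing") {
  mode <- match.arg(mode)
  sp <- names(params)
  out <- list()
  for (qd in split(records, interaction(records$site, records$quadrat, drop = TRUE))) {
    years <- sort(unique(qd$year))
    group <- qd$group[1]
    obs_cover <- quadrat_cover(qd)
    acc <- array(0, dim = c(length(years), length(sp)),
                 dimnames = list(years, sp))
    for (rep in seq_len(n_reps)) {
      state <- records_to_state(qd[qd$year == years[1], ])
      acc[1, ] <- cover_vec(state, sp)   # same every rep: the observation
      for (yi in seq_along(years)[-1]) {
        yr_from <- years[yi - 1]
        if (years[yi] - yr_from > 1L) {
          state <- records_to_state(qd[qd$year == years[yi], ])  # gap: re-init
        } else {
          Crow <- climate[climate$site == qd$site[1] & climate$year == yr_from, ]
          if (nrow(Crow) != 1) abort(paste("no climate row for year", yr_from))
          use_year <- if (mode == "full") yr_from else NULL
          if (mode == "full") {
            for (j in sp) {
              if (!yr_from %in% params[[j]]$survival$year$year) {
                abort(paste("missing year effects for historical year", yr_from))
              }
            }
          }
          state <- ibm_step(state, params, alphas,
                            unlist(Crow[climate_base_covariates]),
                            year = use_year, group = group,
                            boundary = boundary, marginal = FALSE)
        }
        acc[yi, ] <- acc[yi, ] + cover_vec(state, sp) / n_reps
      }
    }
    pred <- tibble::tibble(site = qd$site[1], quadrat = qd$quadrat[1],
                           year = rep(years, times = length(sp)),
                           species = rep(sp, each = length(years)),
                           cover_pred = as.vector(acc))
    out[[length(out) + 1]] <- pred |>
      left_join(obs_cover |> select("year", "species", cover_obs = "cover_cm2"),
                by = c("year", "species")) |>
      mutate(cover_obs = ifelse(is.na(.data$cover_obs), 0, .data$cover_obs))
  }
  list_rbind(out)
}

records_to_state <- function(rec) {
  ibm_state(tibble::tibble(species = rec$species, genet_id = rec$genet_id,
                           logsize = log(rec$area_cm2), x = rec$x, y = rec$y))
}

cover_vec <- function(state, sp) {
  cv <- cover_of(state, species = sp)
  setNames(cv$cover_cm2, cv$species)[sp]
}
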
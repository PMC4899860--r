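# Multispecies integral projection model: environmentally stochastic,
# demographically deterministic. Each species is a density n(u, t) over log
# size u on a shared midpoint-rule mesh; the kernel combines the fitted
# survival and growth models with a fecundity term derived from the
# quadrat-level recruitment model (per-capita fecundity proportional to
# arithmetic size, so total recruitment tracks total cover; recruit sizes
# enter as a point mass at the point-plant size). Crowding is spatially
# implicit: neighbours of other species are treated as randomly distributed
# (closed-form Gaussian-kernel expectation pi/alpha * cover density), while
# conspecific neighbours can respect a "no overlap" rule that excludes
# neighbour centres closer than the sum of the two circle radii — the
# Gaussian kernel then integrates to (pi/alpha) * exp(-alpha * r_excl^2).

#' Midpoint-rule size mesh
#'
#' @param n Number of nodes.
#' @param L,U Lower and upper log-size limits; must extend past the sizes the
#'   community can reach.
#' @return Object of class `size_mesh` with `nodes` (cell midpoints) and `h`
#'   (cell width); node weights are all `h` and sum to `U - L`.
#' @export
size_mesh <- function(n = 100L, L = log(0.2), U = log(400) + 1) {
  if (n < 2) abort("mesh needs at least 2 nodes")
  if (U <= L) abort("mesh upper limit must exceed the lower limit")
  h <- (U - L) / n
  structure(list(n = as.integer(n), L = L, U = U, h = h,
                 nodes = L + h * (seq_len(n) - 0.5)),
            class = "size_mesh")
}

recruit_node <- function(mesh, recruit_logsize = log(POINT_AREA_CM2)) {
  which.min(abs(mesh$nodes - recruit_logsize))
}

#' Construct an IPM community state
#'
#' @param mesh A [size_mesh()].
#' @param species Character vector of species codes.
#' @param n Optional species x nodes density matrix (genets per unit log size
#'   per quadrat); defaults to zero.
#' @return Object of class `ipm_state`.
#' @export
ipm_state <- function(mesh, species, n = NULL) {
  if (is.null(n)) n <- matrix(0, length(species), mesh$n)
  n <- matrix(n, length(species), mesh$n, dimnames = list(species, NULL))
  if (any(n < 0)) abort("densities must be non-negative")
  structure(list(mesh = mesh, species = species, n = n), class = "ipm_state")
}

#' Seed an IPM state with cover concentrated at the recruit size
#'
#' @inheritParams ipm_state
#' @param cover_cm2 Named (or recycled) per-species cover to seed.
#' @return An [ipm_state()].
#' @export
ipm_seed_state <- function(mesh, species, cover_cm2) {
  cover_cm2 <- rep(cover_cm2, length.out = length(species))
  st <- ipm_state(mesh, species)
  k <- recruit_node(mesh)
  st$n[, k] <- cover_cm2 / (exp(mesh$nodes[k]) * mesh$h)
  st
}

#' @export
cover_of.ipm_state <- function(state, species = NULL) {
  eu <- exp(state$mesh$nodes)
  cov <- as.vector(state$n %*% eu) * state$mesh$h
  out <- tibble::tibble(species = state$species, cover_cm2 = cov)
  if (!is.null(species)) {
    out <- tibble::tibble(species = species) |>
      left_join(out, by = "species") |>
      mutate(cover_cm2 = ifelse(is.na(.data$cover_cm2), 0, .data$cover_cm2))
  }
  out |> mutate(frac = .data$cover_cm2 / QUADRAT_AREA_CM2)
}

#' @export
print.ipm_state <- function(x, ...) {
  cv <- cover_of(x)
  cat(sprintf("<ipm_state: %d species on %d nodes; cover %s cm^2>\n",
              length(x$species), x$mesh$n,
              paste(sprintf("%s=%.1f", cv$species, cv$cover_cm2), collapse = ", ")))
  invisible(x)
}

# Gaussian-kernel expectation factors for conspecific neighbours under the
# no-overlap rule: entry [i, i'] = exp(-alpha * (r(u_i) + r(u_i'))^2) with
# r(u) the circle radius of area exp(u). Cached per species on a mesh.
no_overlap_cache <- function(mesh, alpha) {
  r <- sqrt(exp(mesh$nodes) / pi)
  re <- outer(r, r, "+")
  exp(-alpha * re^2)
}

ipm_caches <- function(mesh, species, alphas) {
  caches <- list(no_overlap = list(), eu = exp(mesh$nodes))
  for (j in species) caches$no_overlap[[j]] <- no_overlap_cache(mesh, alphas[j, j])
  caches
}

#' Spatially implicit mean crowding for a focal species
#'
#' Heterospecific components use the random-neighbour expectation
#' `pi / alpha_jm * (cover_m / A)`, independent of focal size; the
#' conspecific component additionally applies the no-overlap exclusion
#' factor, making it size-dependent and never larger than the random value.
#'
#' @param state An [ipm_state()].
#' @param alphas An [alpha_matrix()].
#' @param focal Focal species code.
#' @param no_overlap Apply the conspecific exclusion rule (default). With
#'   `FALSE` conspecifics are treated as randomly distributed too, matching
#'   an IBM whose recruits settle independently of the canopy.
#' @param caches Optional precomputed [ipm_caches] (internal).
#' @return Matrix nodes x species of expected crowding (cm^2).
#' @export
mean_crowding <- function(state, alphas, focal, no_overlap = TRUE,
                          caches = NULL) {
  mesh <- state$mesh
  eu <- exp(mesh$nodes)
  cv <- cover_of(state)
  covers <- setNames(cv$cover_cm2, cv$species)
  W <- matrix(0, mesh$n, length(state$species),
              dimnames = list(NULL, state$species))
  for (m in state$species) {
    a <- alpha_lookup(alphas, focal, m)
    if (m != focal || !no_overlap) {
      W[, m] <- (pi / a) * unname(covers[m]) / QUADRAT_AREA_CM2
    } else {
      E <- if (!is.null(caches)) caches$no_overlap[[focal]]
           else no_overlap_cache(mesh, a)
      W[, m] <- (pi / a) / QUADRAT_AREA_CM2 *
        as.vector(E %*% (eu * state$n[m, ] * mesh$h))
    }
  }
  W
}

#' Survival-growth transition kernel for one species
#'
#' Discretised kernel `K[v, u] = S(u) * G(v, u)` on the mesh (midpoint rule;
#' multiply by the cell width when projecting densities). Fecundity is
#' handled separately in [ipm_step()] because recruitment is a quadrat-level
#' function of total cover, not a per-capita kernel smooth in size.
#'
#' @param species Focal species code.
#' @param params Per-species parameter list (elements `survival`, `growth`).
#' @param C Named climate covariate vector.
#' @param W Mean-crowding matrix from [mean_crowding()].
#' @param mesh A [size_mesh()].
#' @param year Random-year level (`NULL` for marginal).
#' @return List with `K` (nodes x nodes matrix), `S` (survival by node).
#' @export
build_kernel <- function(species, params, C, W, mesh, year = NULL) {
  u <- mesh$nodes
  S <- survival_prob(u, C, W, params[[species]]$survival, year = year,
                     marginal = is.null(year))
  gm <- growth_moments(u, C, W, params[[species]]$growth, year = year,
                       marginal = is.null(year))
  sdv <- sqrt(gm$var)
  # columns: from-size u; rows: to-size v
  G <- vapply(seq_along(u), function(i) dnorm(u, gm$mean[i], sdv[i]),
              numeric(length(u)))
  list(K = sweep(G, 2, S, "*"), S = S, G = G)
}

#' Advance an IPM community one time step
#'
#' @inheritParams mean_crowding
#' @param params Named per-species list with `survival`, `growth`,
#'   `recruitment` parameter objects.
#' @param C Named climate vector, or a named list of such vectors (one per
#'   species) when species experience different climates.
#' @param year Random-year level applied to all species (`NULL` = marginal).
#' @param recruit_logsize Size at which recruits enter.
#' @return The next [ipm_state()].
#' @export
ipm_step <- function(state, params, alphas, C, year = NULL, no_overlap = TRUE,
                     caches = NULL, recruit_logsize = log(POINT_AREA_CM2)) {
  mesh <- state$mesh
  cv <- cover_of(state)
  covers <- setNames(cv$cover_cm2, cv$species)
  kr <- recruit_node(mesh, recruit_logsize)
  n_new <- state$n * 0
  for (j in state$species) {
    Cj <- if (is.list(C) && !is.null(names(C)) && j %in% names(C)) C[[j]] else C
    if (is.list(Cj)) abort("climate must be a named vector or per-species list")
    if (sum(state$n[j, ]) > 0) {
      W <- mean_crowding(state, alphas, j, no_overlap = no_overlap,
                         caches = caches)
      kern <- build_kernel(j, params, Cj, W, mesh, year = year)
      n_new[j, ] <- as.vector(kern$K %*% state$n[j, ]) * mesh$h
    }
    pj <- params[[j]]$recruitment
    Nprime <- effective_cover(covers, covers, pj$p_mix)  # single mean-field quadrat
    lambda <- recruit_intensity(Nprime, Cj, pj, year = year,
                                marginal = is.null(year))
    n_new[j, kr] <- n_new[j, kr] + lambda / (mesh$h * 1)
  }
  n_new[n_new < 0] <- 0
  ipm_state(mesh, state$species, n_new)
}

draw_climate_row <- function(climate, idx) {
  if (is.data.frame(climate)) {
    unlist(climate[idx, climate_base_covariates])
  } else {
    # named list of per-species tables sharing row indexing
    lapply(climate, function(tb) unlist(tb[idx, climate_base_covariates]))
  }
}

climate_rows <- function(climate) {
  if (is.data.frame(climate)) return(nrow(climate))
  ns <- unique(map_int(climate, nrow))
  if (length(ns) != 1) abort("per-species climate tables must have equal rows")
  ns
}

#' Run the stochastic IPM
#'
#' At each step one observed climate year and, independently, one set of
#' random year effects are drawn. With a fixed RNG seed the draw sequence —
#' and hence the whole trajectory — is reproducible, which is the
#' common-random-numbers contract the perturbation experiments rely on: the
#' drawn indices do not depend on the table contents, so paired runs with
#' perturbed climates see the same sequence of years.
#'
#' @inheritParams ipm_step
#' @param climate Climate tibble, or named list of per-species tibbles with
#'   identical year ordering (used for mixed perturbed/unperturbed runs).
#' @param n_steps Number of transitions.
#' @param year_library Year labels to draw random year effects from (`NULL`
#'   for marginal dynamics).
#' @param record `"cover"` returns the cover trajectory; `"state"` also
#'   returns the final state.
#' @return Tibble `step, species, cover_cm2, frac`; with
#'   `record = "state"`, a list `trajectory`, `state`.
#' @export
run_ipm <- function(state, params, alphas, climate, n_steps,
                    year_library = NULL, no_overlap = TRUE,
                    record = c("cover", "state")) {
  record <- match.arg(record)
  caches <- ipm_caches(state$mesh, state$species, alphas)
  nr <- climate_rows(climate)
  out <- list(cover_of(state) |> mutate(step = 0L))
  for (s in seq_len(n_steps)) {
    idx <- sample.int(nr, 1)
    yr <- if (is.null(year_library)) NULL else year_library[sample.int(length(year_library), 1)]
    state <- ipm_step(state, params, alphas, draw_climate_row(climate, idx),
                      year = yr, no_overlap = no_overlap, caches = caches)
    out[[s + 1]] <- cover_of(state) |> mutate(step = s)
  }
  traj <- list_rbind(out) |> select("step", "species", "cover_cm2", "frac")
  if (record == "cover") traj else list(trajectory = traj, state = state)
}

#' Per-species cover at stochastic equilibrium
#'
#' Initialises every species at very low abundance, discards a burn-in, and
#' averages cover over a post-burn-in window. A no-trend diagnostic (OLS
#' slope of cover on step; its 95% CI should cover zero) certifies the
#' window; species that fell below a trace cover are flagged extinct.
#'
#' @inheritParams run_ipm
#' @param mesh A [size_mesh()].
#' @param species Species codes (must name entries of `params`).
#' @param burn_in,window Steps to discard and to average.
#' @param init_cover Seed cover per species (cm^2).
#' @param extinct_cover Cover threshold below which a species is flagged
#'   extinct (reported as 0).
#' @return Tibble `species, cover_cm2, frac, se, trend_ok, extinct`, with the
#'   final state in attribute `state`.
#' @export
equilibrium_cover <- function(mesh, species, params, alphas, climate,
                              year_library = NULL, burn_in = 500,
                              window = 2000, init_cover = 1,
                              no_overlap = TRUE, extinct_cover = 1e-4) {
  st <- ipm_seed_state(mesh, species, init_cover)
  res <- run_ipm(st, params, alphas, climate, burn_in + window,
                 year_library = year_library, no_overlap = no_overlap,
                 record = "state")
  win <- res$trajectory |> filter(.data$step > burn_in)
  out <- win |>
    group_by(.data$species) |>
    summarise(
      cover_mean = mean(.data$cover_cm2),
      se = sd(.data$cover_cm2) / sqrt(dplyr::n()),
      trend_ok = {
        sl <- suppressWarnings(
          summary(lm(cover_cm2 ~ step, data = pick(everything())))$coefficients)
        abs(sl["step", 1]) <= 2 * sl["step", 2] |
          abs(sl["step", 1]) * dplyr::n() < 0.01 * mean(.data$cover_cm2)
      },
      .groups = "drop") |>
    mutate(extinct = .data$cover_mean < extinct_cover,
           cover_cm2 = ifelse(.data$extinct, 0, .data$cover_mean),
           frac = .data$cover_cm2 / QUADRAT_AREA_CM2) |>
    select("species", "cover_cm2", "frac", "se", "trend_ok", "extinct")
  attr(out, "state") <- res$state
  out
}
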
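# Invasion growth rates, equilibrium frequencies and the negative-frequency-
# dependence (NFD) slope. The NFD slope — the line through (frequency ~ 0,
# invasion growth rate) and (equilibrium frequency, 0) — is the community-
# level proxy for niche differences: the more negative the slope, the faster
# per-capita growth declines as the species' relative cover rises.

#' Invasion growth rate of a focal species
#'
#' Residents are first run to stochastic equilibrium without the focal
#' species. The focal is then introduced at negligible cover as a point mass
#' at the recruit size; at every subsequent step its cover is advanced one
#' transition, the log growth ratio is recorded, and its cover is reset to
#' the invader level, so it never influences the residents or itself. The
#' invasion growth rate is the mean of the step log ratios (the log of the
#' geometric mean growth factor).
#'
#' @param focal Focal species code.
#' @param mesh A [size_mesh()].
#' @param species All community species codes.
#' @param params Per-species vital-rate parameter list.
#' @param alphas An [alpha_matrix()].
#' @param climate Climate tibble.
#' @param year_library Year labels for random year effects (`NULL` =
#'   marginal).
#' @param n_steps One-step invasion experiments to average.
#' @param resident_burn_in Steps to equilibrate the residents.
#' @param invader_cover Cover at which the focal is held (cm^2).
#' @param no_overlap Conspecific crowding rule (see [mean_crowding()]).
#' @param resident_init Seed cover for the residents.
#' @return Tibble `species, igr, se, n_steps`; `se` is the Monte-Carlo
#'   standard error of the mean log ratio.
#' @export
invasion_growth_rate <- function(focal, mesh, species, params, alphas, climate,
                                 year_library = NULL, n_steps = 1000,
                                 resident_burn_in = 500, invader_cover = 1e-6,
                                 no_overlap = TRUE, resident_init = 1) {
  if (!focal %in% species) abort("focal species not in the community")
  residents <- setdiff(species, focal)
  st <- ipm_seed_state(mesh, species, 0)
  kr <- recruit_node(mesh)
  if (length(residents)) {
    st$n[residents, kr] <- resident_init / (exp(mesh$nodes[kr]) * mesh$h)
  }
  caches <- ipm_caches(mesh, species, alphas)
  nr <- climate_rows(climate)
  step_once <- function(state) {
    idx <- sample.int(nr, 1)
    yr <- if (is.null(year_library)) NULL else year_library[sample.int(length(year_library), 1)]
    ipm_step(state, params, alphas, draw_climate_row(climate, idx), year = yr,
             no_overlap = no_overlap, caches = caches)
  }
  for (s in seq_len(resident_burn_in)) st <- step_once(st)
  if (length(residents)) {
    res_cover <- cover_of(st, species = residents)$cover_cm2
    if (all(res_cover < 1e-4)) {
      abort("resident community collapsed before the invasion experiment")
    }
  }
  # introduce the focal as a recruit-sized point mass at negligible cover;
  # after every step its cover is returned to the invader level by rescaling,
  # so the size structure converges to the invasion structure while the focal
  # never influences residents or itself
  st$n[focal, ] <- 0
  st$n[focal, kr] <- invader_cover / (exp(mesh$nodes[kr]) * mesh$h)
  logr <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    st <- step_once(st)
    c1 <- cover_of(st, species = focal)$cover_cm2
    logr[s] <- log(c1 / invader_cover)
    if (c1 > 0) {
      st$n[focal, ] <- st$n[focal, ] * (invader_cover / c1)
    } else {
      st$n[focal, kr] <- invader_cover / (exp(mesh$nodes[kr]) * mesh$h)
    }
  }
  tibble::tibble(species = focal, igr = mean(logr),
                 se = sd(logr) / sqrt(n_steps), n_steps = n_steps)
}

#' Equilibrium frequency (relative cover) of each species
#'
#' @param covers Tibble `species, cover_cm2` (e.g. from
#'   [equilibrium_cover()]).
#' @return The tibble with a `frequency` column (`NA` if total cover is 0).
#' @export
equilibrium_frequency <- function(covers) {
  total <- sum(covers$cover_cm2)
  covers |>
    mutate(frequency = if (total > 0) .data$cover_cm2 / total else NA_real_)
}

#' Negative-frequency-dependence slope
#'
#' Slope of the line through (frequency ~ 0, `igr`) and (`f_eq`, 0):
#' `-igr / f_eq`. Negative exactly when the invasion growth rate is positive.
#'
#' @param f_eq Equilibrium frequency (relative cover, in (0, 1]).
#' @param igr Invasion growth rate (log scale per step).
#' @return The slope (log growth per unit frequency); `NA` when `f_eq` is 0.
#' @export
nfd_slope <- function(f_eq, igr) {
  ifelse(f_eq > 0, -igr / f_eq, NA_real_)
}

#' Full negative-frequency-dependence analysis of a community
#'
#' Estimates equilibrium cover (all species together), then the invasion
#' growth rate of each species against the remaining residents, and combines
#' them into the NFD slope.
#'
#' @inheritParams invasion_growth_rate
#' @param burn_in,window Equilibrium run lengths (see [equilibrium_cover()]).
#' @param seed Optional integer; when given, the equilibrium run and each
#'   species' invasion run start from reproducible RNG states.
#' @return Tibble of class `nfd_result`: `species, cover_cm2, frequency,
#'   igr, igr_se, slope`.
#' @export
nfd <- function(mesh, species, params, alphas, climate, year_library = NULL,
                n_steps = 1000, resident_burn_in = 500, burn_in = 500,
                window = 2000, invader_cover = 1e-6, no_overlap = TRUE,
                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eq <- equilibrium_cover(mesh, species, params, alphas, climate,
                          year_library = year_library, burn_in = burn_in,
                          window = window, no_overlap = no_overlap)
  freq <- equilibrium_frequency(eq)
  igrs <- list_rbind(map(species, function(j) {
    if (!is.null(seed)) set.seed(seed + match(j, species))
    invasion_growth_rate(j, mesh, species, params, alphas, climate,
                         year_library = year_library, n_steps = n_steps,
                         resident_burn_in = resident_burn_in,
                         invader_cover = invader_cover,
                         no_overlap = no_overlap)
  }))
  out <- freq |>
    left_join(igrs |> rename(igr_se = "se"), by = "species") |>
    mutate(slope = nfd_slope(.data$frequency, .data$igr)) |>
    select("species", "cover_cm2", "frequency", "igr", "igr_se", "slope")
  class(out) <- c("nfd_result", class(out))
  out
}
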
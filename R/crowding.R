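# Neighbourhood crowding indices. The crowding a focal genet of species j
# experiences from neighbours of species m is the size-weighted sum
#   w_jm = sum_k u_k * exp(-alpha_jm * d_k^2)
# over same-quadrat, same-year neighbours k of species m, with u_k the
# neighbour's arithmetic area (cm^2) and d_k the centroid distance (cm). The
# squared distance makes the kernel Gaussian; alpha_jm sets the spatial scale
# over which species m is felt by species j.

#' Construct an interaction-scale matrix
#'
#' @param species Character vector of species codes.
#' @param values Square numeric matrix (focal rows, neighbour columns) of
#'   positive spatial-scale parameters (cm^-2), or a single value recycled.
#' @return Named square matrix of class `alpha_matrix`.
#' @export
alpha_matrix <- function(species, values) {
  k <- length(species)
  if (length(values) == 1) values <- matrix(values, k, k)
  values <- as.matrix(values)
  stopifnot(nrow(values) == k, ncol(values) == k)
  if (any(values <= 0)) abort("alpha values must be positive")
  dimnames(values) <- list(focal = species, neighbour = species)
  class(values) <- c("alpha_matrix", class(values))
  values
}

alpha_lookup <- function(alphas, focal, neighbour) {
  if (!focal %in% rownames(alphas) || !neighbour %in% colnames(alphas)) {
    abort(sprintf("no alpha value for species pair (%s, %s)", focal, neighbour))
  }
  alphas[focal, neighbour]
}

#' Crowding experienced by one focal genet
#'
#' @param focal One-row tibble (or list) with `species`, `x`, `y`.
#' @param neighbours Tibble of same-quadrat, same-year genets with `species`,
#'   `area_cm2`, `x`, `y`; the focal itself must be excluded.
#' @param alphas An [alpha_matrix()] covering every species present.
#' @return Named numeric vector, one crowding value (cm^2) per neighbour
#'   species in `alphas`.
#' @export
compute_crowding <- function(focal, neighbours, alphas) {
  sp <- colnames(alphas)
  w <- setNames(numeric(length(sp)), sp)
  if (is.null(neighbours) || nrow(neighbours) == 0) return(w)
  d2 <- (neighbours$x - focal$x)^2 + (neighbours$y - focal$y)^2
  for (m in unique(neighbours$species)) {
    a <- alpha_lookup(alphas, focal$species, m)
    sel <- neighbours$species == m
    w[m] <- sum(neighbours$area_cm2[sel] * exp(-a * d2[sel]))
  }
  w
}

#' Crowding indices for every genet in a record table
#'
#' Vectorised batch version of [compute_crowding()]: within each
#' site-quadrat-year, every genet receives one crowding value per species in
#' `alphas`, appended as columns `w_<species>`. Neighbourhoods never cross
#' quadrat boundaries.
#'
#' @param records Genet-record tibble (`site, quadrat, year, species,
#'   area_cm2, x, y, ...`).
#' @param alphas An [alpha_matrix()].
#' @return `records` with the crowding columns appended.
#' @export
crowding_table <- function(records, alphas) {
  sp_all <- colnames(alphas)
  wcols <- matrix(0, nrow(records), length(sp_all),
                  dimnames = list(NULL, paste0("w_", sp_all)))
  groups <- split(seq_len(nrow(records)),
                  interaction(records$site, records$quadrat, records$year, drop = TRUE))
  for (idx in groups) {
    n <- length(idx)
    if (n < 2) next
    x <- records$x[idx]; y <- records$y[idx]
    u <- records$area_cm2[idx]; sp <- records$species[idx]
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    for (j in unique(sp)) {
      rows <- which(sp == j)
      for (m in unique(sp)) {
        a <- alpha_lookup(alphas, j, m)
        kern <- exp(-a * d2[rows, sp == m, drop = FALSE])
        w <- kern %*% u[sp == m]
        # exclude self-crowding for conspecifics (d = 0 diagonal terms)
        if (m == j) w <- w - u[rows]
        wcols[idx[rows], paste0("w_", m)] <- w
      }
    }
  }
  bind_cols(records, tibble::as_tibble(wcols))
}
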
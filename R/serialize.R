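# Text serialisation. Fitted vital-rate parameters are written as YAML (one
# file per species x vital rate) so the simulation engines are decoupled
# from the fitting session; result tables are delimited text accompanied by
# a YAML sidecar carrying the configuration and seed, which is what makes a
# run reproducible bit for bit.

params_to_list <- function(p) {
  out <- list(vital = p$vital, species = p$species, intercept = p$intercept)
  if (!is.null(p$size)) out$size <- p$size
  for (slot in c("crowding", "crowding_size", "climate", "climate_size", "dd")) {
    if (!is.null(p[[slot]]) && length(p[[slot]])) out[[slot]] <- as.list(p[[slot]])
  }
  for (slot in c("var_a", "var_b", "theta", "p_mix")) {
    if (!is.null(p[[slot]])) out[[slot]] <- p[[slot]]
  }
  out$year <- lapply(seq_len(nrow(p$year)), function(i) as.list(p$year[i, ]))
  out$group <- lapply(seq_len(nrow(p$group)), function(i) as.list(p$group[i, ]))
  out
}

#' Write and read vital-rate parameters as YAML
#'
#' One file per species and vital rate; everything the simulation engines
#' need (coefficients on raw covariate scales, per-year and per-group random
#' deviations, variance-function and dispersion parameters) round-trips
#' exactly.
#'
#' @param params A [survival_params()], [growth_params()] or
#'   [recruit_params()] object (or the `$params` of a fitted `vr_fit`).
#' @param path Output file path.
#' @return `path`, invisibly (`write_vital_params`); the reconstructed
#'   parameter object (`read_vital_params`).
#' @export
write_vital_params <- function(params, path) {
  stopifnot(inherits(params, "vital_params"))
  yaml::write_yaml(params_to_list(params), path)
  invisible(path)
}

#' @rdname write_vital_params
#' @export
read_vital_params <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  x <- yaml::read_yaml(path)
  named <- function(slot) {
    if (is.null(x[[slot]])) NULL else unlist(x[[slot]])
  }
  year <- if (length(x$year)) list_rbind(map(x$year, tibble::as_tibble)) else NULL
  group <- if (length(x$group)) list_rbind(map(x$group, tibble::as_tibble)) else NULL
  switch(x$vital,
    survival = survival_params(
      x$species, intercept = x$intercept, size = x$size,
      crowding = named("crowding"), crowding_size = named("crowding_size"),
      climate = named("climate"), climate_size = named("climate_size"),
      year = year, group = group),
    growth = growth_params(
      x$species, intercept = x$intercept, size = x$size,
      crowding = named("crowding"), crowding_size = named("crowding_size"),
      climate = named("climate"), climate_size = named("climate_size"),
      var_a = x$var_a, var_b = x$var_b, year = year, group = group),
    recruitment = recruit_params(
      x$species, intercept = x$intercept, dd = named("dd"),
      climate = named("climate"), theta = x$theta, p_mix = x$p_mix,
      year = year, group = group),
    abort(paste("unknown vital rate in parameter file:", x$vital)))
}

#' Write a results table with a run-metadata sidecar
#'
#' The table goes to `<path>` as CSV; `<path>.meta.yml` records the full
#' configuration, the seed and a timestamp, so any results file carries
#' enough provenance for a bit-identical re-run.
#'
#' @param results A data frame or tibble.
#' @param path Output CSV path.
#' @param config Configuration list (see [load_config()]).
#' @param seed Integer seed used for the run.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = default_config(), seed = NA) {
  readr::write_csv(tibble::as_tibble(results), path, progress = FALSE)
  yaml::write_yaml(list(seed = seed, written = format(Sys.time(), tz = "UTC"),
                        config = config),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_results
#' @return `read_results`: a list with `results` (tibble) and `meta`
#'   (list; `NULL` when no sidecar exists).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  meta_path <- paste0(path, ".meta.yml")
  list(results = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
       meta = if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL)
}
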
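# Fitting the vital-rate regressions. Survival is a binomial mixed model,
# growth a Gaussian mixed model (both with random year intercepts, random
# per-year size slopes and random group intercepts), recruitment a
# negative-binomial mixed count model at the quadrat level with an offset on
# log effective cover. Fitted objects are thin wrappers that expose the
# simulation-ready parameter containers of vital-params.R, with the per-year
# random deviations stored as empirical draws for later simulation.

#' Attach climate covariates (plus interactions) to a modelling frame
#'
#' @param data Frame with `site` and `year` columns (transition start year).
#' @param climate Climate tibble from [read_climate()] or
#'   [generate_climate()].
#' @return `data` with the covariate and interaction columns merged in; a
#'   transition year absent from the climate table is a hard error.
#' @export
attach_climate <- function(data, climate) {
  cl <- climate_interactions(climate)
  out <- left_join(data, cl, by = c("site", "year"))
  if (anyNA(out[, climate_base_covariates])) {
    abort("climate covariates missing for one or more transition years")
  }
  out
}

vr_formula <- function(response, base_terms, climate_terms, random_terms,
                       offset_term = NULL) {
  rhs <- c(base_terms, climate_terms, random_terms, offset_term)
  if (!length(rhs)) rhs <- "1"
  as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

new_vr_fit <- function(vital, species, model, params, formula, data,
                       converged, notes = character(), scaling = NULL) {
  structure(list(vital = vital, species = species, model = model,
                 params = params, formula = formula, data = data,
                 converged = converged, notes = notes, scaling = scaling),
            class = "vr_fit")
}

# Climate covariates are fitted on the standardised scale (mean 0, sd 1) for
# optimizer stability; coefficients are transformed back to the raw scale for
# the parameter containers and the tidy() table.
scale_climate_cols <- function(df, climate_covs) {
  scaling <- list()
  for (cc in climate_covs) {
    m <- mean(df[[cc]]); s <- sd(df[[cc]])
    if (!is.finite(s) || s == 0) s <- 1
    df[[cc]] <- (df[[cc]] - m) / s
    scaling[[cc]] <- c(mean = m, sd = s)
  }
  list(df = df, scaling = scaling)
}

unscale_climate <- function(coefs, scaling) {
  if (length(coefs) == 0 || is.null(scaling)) return(coefs)
  for (cc in intersect(names(coefs), names(scaling))) {
    coefs[cc] <- coefs[cc] / scaling[[cc]]["sd"]
  }
  coefs
}

intercept_shift <- function(fe, scaling) {
  if (is.null(scaling) || !length(scaling)) return(0)
  sum(vapply(names(scaling), function(cc) {
    if (cc %in% names(fe)) fe[[cc]] * scaling[[cc]]["mean"] / scaling[[cc]]["sd"]
    else 0
  }, numeric(1)))
}

#' @export
print.vr_fit <- function(x, ...) {
  cat(sprintf("<vr_fit: %s model for %s, %d obs%s>\n", x$vital, x$species,
              nrow(x$data), if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

lme4_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  is.null(msgs) || !any(grepl("failed to converge", msgs, ignore.case = TRUE))
}

extract_sg_params <- function(fit, vital, species, crowding_cols, climate_cols,
                              var_a = 1, var_b = 0, scaling = NULL) {
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)
  ytab <- tibble::tibble(year = numeric(0), intercept_dev = numeric(0),
                         size_dev = numeric(0))
  if (!is.null(re$year)) {
    ytab <- tibble::tibble(
      year = as.integer(rownames(re$year)),
      intercept_dev = re$year[["(Intercept)"]] %||% rep(0, nrow(re$year)),
      size_dev = re$year[["logarea0"]] %||% rep(0, nrow(re$year)))
  }
  gtab <- tibble::tibble(group = character(0), intercept_dev = numeric(0))
  if (!is.null(re$group)) {
    gtab <- tibble::tibble(group = rownames(re$group),
                           intercept_dev = re$group[["(Intercept)"]])
  }
  crowding <- setNames(unname(fe[crowding_cols]), sub("^w_", "", crowding_cols))
  climate <- unscale_climate(fe[intersect(climate_cols, names(fe))], scaling)
  args <- list(species = species,
               intercept = unname(fe["(Intercept)"]) - intercept_shift(fe, scaling),
               size = unname(fe["logarea0"]), crowding = crowding,
               climate = if (length(climate)) climate else NULL,
               year = ytab, group = gtab)
  if (vital == "survival") do.call(survival_params, args)
  else do.call(growth_params, c(args, list(var_a = var_a, var_b = var_b)))
}

#' Fit the survival model for one species
#'
#' Binomial GLMM: `survives ~ log size + crowding + climate`, with random
#' year intercepts, random per-year size slopes and random group intercepts.
#' Non-convergence never fails silently: the result carries a `converged`
#' flag and the optimizer messages.
#'
#' @param transitions Transition rows for the focal species with crowding
#'   columns `w_*` (see [crowding_table()], [build_transitions()]).
#' @param climate Climate tibble.
#' @param species Focal species code.
#' @param climate_covs Character vector of climate terms to include (possibly
#'   from [select_climate_covariates()]).
#' @param crowding_species Species whose crowding columns enter the model;
#'   defaults to every `w_*` column present.
#' @return A `vr_fit` whose `$params` is a simulation-ready
#'   [survival_params()].
#' @export
fit_survival <- function(transitions, climate, species,
                         climate_covs = character(),
                         crowding_species = NULL) {
  df <- prep_sg_frame(transitions, climate, species)
  sc <- scale_climate_cols(df, climate_covs)
  wcols <- crowding_cols(df, crowding_species)
  form <- vr_formula("survives", c("logarea0", wcols), climate_covs,
                     c("(logarea0 | year)", "(1 | group)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(form, data = sc$df, family = binomial(),
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             optCtrl = list(maxfun = 1e5)))))
  params <- extract_sg_params(fit, "survival", species, wcols, climate_covs,
                              scaling = sc$scaling)
  new_vr_fit("survival", species, fit, params, form, df, lme4_converged(fit),
             notes = unlist(fit@optinfo$conv$lme4$messages),
             scaling = sc$scaling)
}

#' Fit the growth model for one species
#'
#' Gaussian GLMM for next log size conditional on survival, same structure as
#' [fit_survival()]; the size-dependent residual variance
#' `var(v) = a exp(b v)` is then fitted to the squared conditional residuals
#' by a Gamma GLM with log link.
#'
#' @inheritParams fit_survival
#' @return A `vr_fit` whose `$params` is a [growth_params()].
#' @export
fit_growth <- function(transitions, climate, species,
                       climate_covs = character(), crowding_species = NULL) {
  df <- prep_sg_frame(transitions, climate, species) |>
    filter(.data$survives == 1, !is.na(.data$logarea1))
  sc <- scale_climate_cols(df, climate_covs)
  wcols <- crowding_cols(df, crowding_species)
  form <- vr_formula("logarea1", c("logarea0", wcols), climate_covs,
                     c("(logarea0 | year)", "(1 | group)"))
  fit <- suppressWarnings(suppressMessages(lme4::lmer(form, data = sc$df,
                                                      REML = FALSE)))
  res <- residuals(fit)
  vhat <- fitted(fit)
  vfit <- suppressWarnings(glm(I(res^2) ~ vhat, family = Gamma(link = "log")))
  var_a <- unname(exp(coef(vfit)[1])); var_b <- unname(coef(vfit)[2])
  if (var_a <= 0) abort("non-positive growth variance at fit time")
  params <- extract_sg_params(fit, "growth", species, wcols, climate_covs,
                              var_a = var_a, var_b = var_b,
                              scaling = sc$scaling)
  new_vr_fit("growth", species, fit, params, form, df, lme4_converged(fit),
             notes = unlist(fit@optinfo$conv$lme4$messages),
             scaling = sc$scaling)
}

prep_sg_frame <- function(transitions, climate, species) {
  if (inherits(transitions, "transition_table")) transitions <- transitions$transitions
  df <- transitions |> filter(.data$species == !!species)
  if (nrow(df) == 0) abort(paste("no transitions for species", species))
  if (length(unique(df$year)) < 2) abort("need at least 2 years of transitions")
  df <- attach_climate(df, climate)
  df$year <- as.integer(df$year)
  df$group <- as.character(df$group)
  df
}

crowding_cols <- function(df, crowding_species) {
  if (is.null(crowding_species)) {
    cols <- grep("^w_", names(df), value = TRUE)
  } else {
    cols <- paste0("w_", crowding_species)
  }
  miss <- setdiff(cols, names(df))
  if (length(miss)) abort(paste("missing crowding columns:", paste(miss, collapse = ", ")))
  cols
}

#' Build the quadrat-level recruitment modelling frame
#'
#' Joins recruit counts arriving in year t+1 to the per-species effective
#' cover in year t (mixing focal-quadrat and group-mean cover with fraction
#' `p_mix`) and to the climate covariates of the transition year t.
#'
#' @param transition_table A [build_transitions()] result.
#' @param records Genet records (for quadrat covers).
#' @param climate Climate tibble.
#' @param p_mix Effective-cover mixing fraction.
#' @return Tibble with `y` (recruit count), `Nprime_<sp>` columns, climate
#'   covariates, `year` (transition start) and `group`.
#' @export
recruitment_frame <- function(transition_table, records, climate, p_mix = 0.5) {
  covers <- quadrat_cover(records)
  sp_all <- sort(unique(covers$species))
  wide <- covers |>
    pivot_wider(names_from = "species", values_from = "cover_cm2",
                values_fill = 0)
  for (sp in sp_all) if (!sp %in% names(wide)) wide[[sp]] <- 0
  gm <- wide |>
    group_by(.data$site, .data$group, .data$year) |>
    summarise(across(all_of(sp_all), mean, .names = "gm_{.col}"), .groups = "drop")
  wide <- left_join(wide, gm, by = c("site", "group", "year"))
  for (sp in sp_all) {
    wide[[paste0("Nprime_", sp)]] <-
      effective_cover(wide[[sp]], wide[[paste0("gm_", sp)]], p_mix)
  }
  frame <- transition_table$recruits |>
    mutate(year = .data$year - 1L) |>          # key by transition start year
    rename(y = "n_recruits") |>
    inner_join(wide |> select("site", "quadrat", "year",
                              starts_with("Nprime_")),
               by = c("site", "quadrat", "year"))
  attach_climate(frame, climate)
}

#' Fit the recruitment model for one species
#'
#' Negative-binomial GLMM on quadrat-level recruit counts with mean
#' proportional to the focal species' effective cover (offset on its log) and
#' a Ricker exponent linear in the square roots of all species' effective
#' cover, plus climate covariates; random intercepts for year and group.
#' Quadrat-years with zero focal effective cover are dropped (the intensity
#' is structurally zero there). Optionally profiles the effective-cover
#' mixing fraction over a grid by maximum likelihood.
#'
#' @param frame Modelling frame from [recruitment_frame()], or pass
#'   `transition_table`, `records`, `climate` to build one.
#' @param species Focal species code.
#' @param climate_covs Climate terms (main effects only).
#' @param p_mix Mixing fraction used to build `frame` (recorded in params).
#' @return A `vr_fit` whose `$params` is a [recruit_params()].
#' @export
fit_recruitment <- function(frame, species, climate_covs = character(),
                            p_mix = 0.5) {
  focal_col <- paste0("Nprime_", species)
  if (!focal_col %in% names(frame)) abort(paste("no effective-cover column for", species))
  df <- frame |> filter(.data$species == !!species, .data[[focal_col]] > 0)
  sc <- scale_climate_cols(df, climate_covs)
  sp_all <- sub("^Nprime_", "", grep("^Nprime_", names(df), value = TRUE))
  dd_terms <- sprintf("sqrt(Nprime_%s)", sp_all)
  sc$df$year <- as.integer(sc$df$year)
  sc$df$group <- as.character(sc$df$group)
  form <- vr_formula("y", dd_terms, climate_covs,
                     c("(1 | year)", "(1 | group)"),
                     offset_term = sprintf("offset(log(%s))", focal_col))
  fit <- suppressWarnings(glmmTMB::glmmTMB(form, data = sc$df,
                                           family = glmmTMB::nbinom2()))
  fe <- glmmTMB::fixef(fit)$cond
  re <- glmmTMB::ranef(fit)$cond
  dd <- setNames(unname(fe[dd_terms]), sp_all)
  climate <- fe[intersect(climate_covs, names(fe))]
  ytab <- tibble::tibble(year = integer(0), intercept_dev = numeric(0))
  if (!is.null(re$year)) {
    ytab <- tibble::tibble(year = as.integer(rownames(re$year)),
                           intercept_dev = re$year[["(Intercept)"]])
  }
  gtab <- tibble::tibble(group = character(0), intercept_dev = numeric(0))
  if (!is.null(re$group)) {
    gtab <- tibble::tibble(group = rownames(re$group),
                           intercept_dev = re$group[["(Intercept)"]])
  }
  climate <- unscale_climate(climate, sc$scaling)
  params <- recruit_params(
    species,
    intercept = unname(fe["(Intercept)"]) - intercept_shift(fe, sc$scaling),
    dd = dd, climate = if (length(climate)) climate else NULL,
    theta = sigma(fit), p_mix = p_mix, year = ytab, group = gtab)
  conv <- isTRUE(fit$sdr$pdHess)
  new_vr_fit("recruitment", species, fit, params, form, df, conv,
             notes = if (conv) character() else "Hessian not positive definite",
             scaling = sc$scaling)
}

#' @rdname fit_recruitment
#' @param transition_table,records,climate Inputs for [recruitment_frame()]
#'   when profiling `p_mix`.
#' @param p_grid Candidate mixing fractions; the maximum-likelihood value is
#'   kept.
#' @export
fit_recruitment_profile_p <- function(transition_table, records, climate,
                                      species, climate_covs = character(),
                                      p_grid = c(0, 0.25, 0.5, 0.75, 1)) {
  fits <- map(p_grid, function(p) {
    frame <- recruitment_frame(transition_table, records, climate, p_mix = p)
    fit_recruitment(frame, species, climate_covs, p_mix = p)
  })
  ll <- map_dbl(fits, function(f) as.numeric(logLik(f$model)))
  fits[[which.max(ll)]]
}

#' Tidy coefficient table for a fitted vital-rate model
#'
#' Climate terms are reported on the raw covariate scale (estimates and
#' standard errors divided by the covariate's sample sd); the intercept row
#' is the value at mean climate.
#'
#' @param x A `vr_fit`.
#' @param ... Unused.
#' @return Tibble `term, estimate, std.error, statistic`.
#' @export
tidy.vr_fit <- function(x, ...) {
  if (inherits(x$model, "glmmTMB")) {
    s <- summary(x$model)$coefficients$cond
  } else {
    s <- summary(x$model)$coefficients
  }
  out <- tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                        std.error = unname(s[, 2]))
  for (cc in intersect(out$term, names(x$scaling))) {
    i <- match(cc, out$term)
    out$estimate[i] <- out$estimate[i] / x$scaling[[cc]]["sd"]
    out$std.error[i] <- out$std.error[i] / x$scaling[[cc]]["sd"]
  }
  out$statistic <- out$estimate / out$std.error
  out
}

#' One-line model summary for a fitted vital-rate model
#'
#' @inheritParams tidy.vr_fit
#' @return Tibble with `vital, species, nobs, logLik, AIC, converged`.
#' @export
glance.vr_fit <- function(x, ...) {
  tibble::tibble(vital = x$vital, species = x$species, nobs = nrow(x$data),
                 logLik = as.numeric(logLik(x$model)), AIC = AIC(x$model),
                 converged = x$converged)
}

#' Stepwise AIC selection of climate covariates
#'
#' Bidirectional stepwise search over the five climate covariates (and, for
#' survival and growth, the within-year precipitation x temperature
#' interactions, which only become eligible once both parent terms are in the
#' model). The search objective is the fixed-effects analogue of each vital
#' rate's model (binomial / Gaussian / negative-binomial regression with the
#' base structural terms always retained), which makes the selection
#' deterministic and fast; the chosen subset is then refitted with the full
#' random-effects structure.
#'
#' @param data Modelling frame (transitions with crowding for survival and
#'   growth; a [recruitment_frame()] for recruitment) with climate attached.
#' @param vital `"survival"`, `"growth"`, or `"recruitment"`.
#' @param species Focal species code.
#' @param interactions Consider precipitation x temperature interactions
#'   (ignored — never used — for recruitment).
#' @param objective `"mixed"` (default) scores candidate subsets with a
#'   random year intercept in the model, so that climate covariates compete
#'   against interannual noise at the year level rather than the transition
#'   level — without this, pseudo-replication across genets makes spurious
#'   covariates look significant. `"fixed"` scores plain fixed-effects
#'   regressions (faster, anticonservative).
#' @return Object of class `climate_selection`: `selected` (character) and
#'   `trace` (tibble of step, action, term, AIC).
#' @export
select_climate_covariates <- function(data, vital = c("survival", "growth",
                                                      "recruitment"),
                                      species, interactions = TRUE,
                                      objective = c("mixed", "fixed")) {
  vital <- match.arg(vital)
  objective <- match.arg(objective)
  if (vital == "recruitment") {
    focal_col <- paste0("Nprime_", species)
    df <- data |> filter(.data$species == !!species, .data[[focal_col]] > 0)
    sp_all <- sub("^Nprime_", "", grep("^Nprime_", names(df), value = TRUE))
    base <- sprintf("sqrt(Nprime_%s)", sp_all)
    off <- sprintf("offset(log(%s))", focal_col)
    candidates <- climate_base_covariates
    multi_group <- length(unique(df$group)) > 1
    if (objective == "mixed") {
      rterms <- c("(1 | year)", if (multi_group) "(1 | group)")
      fitter <- function(terms) {
        suppressWarnings(glmmTMB::glmmTMB(
          vr_formula("y", base, terms, rterms, off), data = df,
          family = glmmTMB::nbinom2()))
      }
    } else {
      if (multi_group) base <- c(base, "group")
      fitter <- function(terms) {
        suppressWarnings(MASS_glm_nb(vr_formula("y", base, terms, NULL, off), df))
      }
    }
  } else {
    df <- data |> filter(.data$species == !!species)
    if (vital == "growth") df <- df |> filter(.data$survives == 1, !is.na(.data$logarea1))
    wcols <- grep("^w_", names(df), value = TRUE)
    base <- c("logarea0", wcols)
    resp <- if (vital == "survival") "survives" else "logarea1"
    multi_group <- length(unique(df$group)) > 1
    if (objective == "mixed") {
      rterms <- c("(1 | year)", if (multi_group) "(1 | group)")
      if (vital == "survival") {
        fitter <- function(terms) {
          suppressWarnings(suppressMessages(lme4::glmer(
            vr_formula(resp, base, terms, rterms), data = df,
            family = binomial(), nAGQ = 0L)))
        }
      } else {
        fitter <- function(terms) {
          suppressWarnings(suppressMessages(lme4::lmer(
            vr_formula(resp, base, terms, rterms), data = df, REML = FALSE)))
        }
      }
    } else {
      if (multi_group) base <- c(base, "group")
      fam <- if (vital == "survival") binomial() else NULL
      fitter <- function(terms) {
        form <- vr_formula(resp, base, terms, NULL)
        if (is.null(fam)) lm(form, data = df) else glm(form, data = df, family = fam)
      }
    }
    candidates <- if (interactions) climate_covariate_names(TRUE)
                  else climate_base_covariates
  }
  stepwise_aic(fitter, candidates)
}

# glm.nb via MASS, isolated so MASS stays in Suggests.
MASS_glm_nb <- function(form, df) {
  if (!requireNamespace("MASS", quietly = TRUE)) {
    abort("MASS is required for recruitment covariate selection")
  }
  MASS::glm.nb(form, data = df)
}

interaction_parents <- list(ppt1_T1 = c("ppt1", "T1"), ppt2_T2 = c("ppt2", "T2"))

eligible_terms <- function(candidates, current) {
  ok <- map_lgl(candidates, function(tm) {
    parents <- interaction_parents[[tm]]
    is.null(parents) || all(parents %in% current)
  })
  candidates[ok]
}

stepwise_aic <- function(fitter, candidates) {
  current <- character()
  best_aic <- AIC(fitter(current))
  trace <- list(tibble::tibble(step = 0L, action = "start", term = NA_character_,
                               AIC = best_aic))
  step <- 0L
  repeat {
    step <- step + 1L
    addable <- eligible_terms(setdiff(candidates, current), current)
    adds <- if (length(addable)) setNames(as.list(addable), paste0("+", addable)) else list()
    drops <- if (length(current)) setNames(as.list(current), paste0("-", current)) else list()
    moves <- c(adds, drops)
    if (!length(moves)) break
    aics <- map_dbl(names(moves), function(mv) {
      term <- substring(mv, 2)
      trial <- if (startsWith(mv, "+")) c(current, term) else setdiff(current, term)
      # dropping a parent of an included interaction is not a legal move
      for (tm in trial) {
        parents <- interaction_parents[[tm]]
        if (!is.null(parents) && !all(parents %in% trial)) return(Inf)
      }
      AIC(fitter(trial))
    })
    if (min(aics) >= best_aic - 1e-8) break
    mv <- names(moves)[which.min(aics)]
    term <- substring(mv, 2)
    current <- if (startsWith(mv, "+")) c(current, term) else setdiff(current, term)
    best_aic <- min(aics)
    trace[[length(trace) + 1]] <-
      tibble::tibble(step = step, action = substring(mv, 1, 1), term = term,
                     AIC = best_aic)
  }
  structure(list(selected = current, trace = list_rbind(trace)),
            class = "climate_selection")
}

#' @export
print.climate_selection <- function(x, ...) {
  cat("<climate_selection:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      ">\n")
  invisible(x)
}

#' Proportion of interannual vital-rate variation explained by climate
#'
#' Compares a 'constant' model (no temporal terms), a 'climate' model
#' (climate covariates only) and a 'full' model (climate plus random year
#' effects) through their residual badness-of-fit X (sum of squared residuals
#' for growth; residual deviance for survival and recruitment):
#' `(X_constant - X_climate) / (X_constant - X_full)`.
#'
#' @param X_constant,X_climate,X_full Residual sums of squares or deviances.
#' @return Proportion in [0, 1]; values outside the unit interval (possible
#'   under sampling noise) are clipped with a warning, and an
#'   indistinguishable constant/full pair returns `NA`.
#' @export
variance_explained <- function(X_constant, X_climate, X_full) {
  denom <- X_constant - X_full
  if (abs(denom) < .Machine$double.eps * max(1, abs(X_constant))) {
    warn("constant and full models are indistinguishable; proportion undefined")
    return(NA_real_)
  }
  p <- (X_constant - X_climate) / denom
  if (p < 0 || p > 1) {
    warn(sprintf("variance-explained proportion %.3f outside [0, 1]; clipping", p))
    p <- min(1, max(0, p))
  }
  p
}

binomial_deviance <- function(y, p) {
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Climate share of interannual variation for one fitted vital rate
#'
#' Fits the constant / climate / full model triplet for one species and vital
#' rate and returns the [variance_explained()] proportion. Survival and
#' growth triplets use the fixed-effects structure (size, crowding, group)
#' with (i) nothing temporal, (ii) the selected climate covariates, (iii)
#' climate plus a fixed year factor soaking up the remaining interannual
#' variation; recruitment does the same on the negative-binomial count model.
#'
#' @inheritParams select_climate_covariates
#' @param climate_covs Climate covariates of the 'climate' and 'full' models.
#' @return One-row tibble `vital, species, X_constant, X_climate, X_full,
#'   prop_climate`.
#' @export
climate_variance_explained <- function(data, vital = c("survival", "growth",
                                                       "recruitment"),
                                       species, climate_covs) {
  vital <- match.arg(vital)
  if (vital == "recruitment") {
    focal_col <- paste0("Nprime_", species)
    df <- data |> filter(.data$species == !!species, .data[[focal_col]] > 0)
    sp_all <- sub("^Nprime_", "", grep("^Nprime_", names(df), value = TRUE))
    base <- sprintf("sqrt(Nprime_%s)", sp_all)
    if (length(unique(df$group)) > 1) base <- c(base, "group")
    off <- sprintf("offset(log(%s))", focal_col)
    X <- function(terms) {
      deviance(MASS_glm_nb(vr_formula("y", base, terms, NULL, off), df))
    }
    Xs <- c(X(character()), X(climate_covs),
            X(c(climate_covs, "factor(year)")))
  } else {
    df <- data |> filter(.data$species == !!species)
    if (vital == "growth") df <- df |> filter(.data$survives == 1, !is.na(.data$logarea1))
    wcols <- grep("^w_", names(df), value = TRUE)
    base <- c("logarea0", wcols)
    if (length(unique(df$group)) > 1) base <- c(base, "group")
    if (vital == "survival") {
      X <- function(terms) {
        fit <- glm(vr_formula("survives", base, terms, NULL), df,
                   family = binomial())
        binomial_deviance(df$survives, fitted(fit))
      }
    } else {
      X <- function(terms) {
        sum(residuals(lm(vr_formula("logarea1", base, terms, NULL), df))^2)
      }
    }
    Xs <- c(X(character()), X(climate_covs),
            X(c(climate_covs, "factor(year)")))
  }
  tibble::tibble(vital = vital, species = species, X_constant = Xs[1],
                 X_climate = Xs[2], X_full = Xs[3],
                 prop_climate = variance_explained(Xs[1], Xs[2], Xs[3]))
}

#' Grid search for the crowding spatial scale
#'
#' Utility for synthetic data: refits a fixed-effects survival (or growth)
#' regression at each candidate alpha (one shared intra/interspecific scale)
#' and returns the candidate maximising the likelihood.
#'
#' @param records Genet records.
#' @param transitions Transition table rows for the focal species.
#' @param species Focal species code.
#' @param candidates Candidate alpha values (cm^-2).
#' @param vital `"survival"` or `"growth"`.
#' @return Tibble `alpha, logLik` sorted by candidate, with attribute
#'   `best` (the maximising alpha).
#' @export
estimate_alpha <- function(records, transitions, species,
                           candidates = 10^seq(-3, -0.5, length.out = 8),
                           vital = c("survival", "growth")) {
  vital <- match.arg(vital)
  if (inherits(transitions, "transition_table")) transitions <- transitions$transitions
  ll <- map_dbl(candidates, function(a) {
    sp_all <- sort(unique(records$species))
    alphas <- alpha_matrix(sp_all, a)
    cw <- crowding_table(records, alphas) |>
      select("site", "quadrat", "species", "genet_id", "year",
             starts_with("w_"))
    df <- transitions |>
      filter(.data$species == !!species) |>
      inner_join(cw, by = c("site", "quadrat", "species", "genet_id", "year"))
    wcols <- grep("^w_", names(df), value = TRUE)
    if (vital == "survival") {
      fit <- glm(vr_formula("survives", c("logarea0", wcols), NULL, NULL),
                 data = df, family = binomial())
    } else {
      df <- df |> filter(.data$survives == 1)
      fit <- lm(vr_formula("logarea1", c("logarea0", wcols), NULL, NULL),
                data = df)
    }
    as.numeric(logLik(fit))
  })
  out <- tibble::tibble(alpha = candidates, logLik = ll)
  attr(out, "best") <- candidates[which.max(ll)]
  out
}
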
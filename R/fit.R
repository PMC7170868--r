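# Joint maximum-likelihood estimation of compartmental parameters across
# studies and routes, with study-specific log-scale error SDs, optional LOQ
# censoring, and AIC model selection.

SIGMA_FLOOR <- 1e-6

#' Fitting configuration
#'
#' @param seed integer seed recorded with the fit (the optimizer itself is
#'   deterministic: fixed multi-start schedule).
#' @param start_multipliers perturbation factors applied to the heuristic
#'   start to form the additional starts.
#' @param constrain_k21 constrain k21 = k12 in the two-compartment model.
#' @param group_by `"substance_species"` (joint IV+oral analysis, default) or
#'   `"route_substance"`.
#' @param media media treated as plasma-like when assembling datasets.
#' @param maxit_nm,maxit_bfgs iteration caps for the simplex search and the
#'   quasi-Newton polish.
#' @param reltol relative convergence tolerance.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(seed = 1, start_multipliers = c(0.3, 0.5, 2, 3),
                       constrain_k21 = FALSE,
                       group_by = c("substance_species", "route_substance"),
                       media = c("plasma", "blood", "serum"),
                       maxit_nm = 2000, maxit_bfgs = 200, reltol = 1e-8) {
  structure(list(seed = seed, start_multipliers = start_multipliers,
                 constrain_k21 = constrain_k21,
                 group_by = match.arg(group_by), media = media,
                 maxit_nm = maxit_nm, maxit_bfgs = maxit_bfgs,
                 reltol = reltol),
            class = "fit_config")
}

#' Construct a fitting dataset from bare observations
#'
#' For data that does not live in a [cvt_database()]: one row per mean
#' observation with `study_id`, `route` (intravenous/oral), `dose` (mg/kg),
#' `time_hr` and `conc` (ug/mL); optional `loq` and `below_loq` columns
#' enable censoring.
#'
#' @param observations data frame as described above.
#' @param substance,species labels carried through to fit results.
#' @return Object of class `fit_dataset`.
#' @export
fit_dataset <- function(observations, substance = "unknown",
                        species = NULL) {
  stopifnot(is.data.frame(observations), nrow(observations) >= 1,
            all(c("study_id", "route", "dose", "time_hr", "conc") %in%
                  names(observations)))
  if (!all(observations$route %in% c("intravenous", "oral")))
    cvt_error("cvt_input_error", "route must be intravenous or oral")
  if (any(observations$dose <= 0))
    cvt_error("cvt_input_error", "doses must be > 0")
  if (is.null(observations$loq)) observations$loq <- NA_real_
  if (is.null(observations$below_loq)) observations$below_loq <- FALSE
  structure(list(substance = substance, species = species,
                 observations = observations,
                 studies = unique(observations$study_id)),
            class = "fit_dataset")
}

#' Assemble a fitting dataset from a CvT database
#'
#' Selects the studies of a substance (optionally restricted to a species)
#' whose series are in a plasma-like medium, collapses each study to its mean
#' series via [study_mean_series()], and attaches the normalized dose and the
#' administration route (gavage is treated as oral). Multi-dose studies and
#' routes other than intravenous/oral are excluded. A mean observation is
#' treated as censored when every contributing value was below the LOQ; zero
#' concentrations with no recorded LOQ are dropped with a warning.
#'
#' @param db a [cvt_database()].
#' @param substance test substance (matched against `test_substance` and the
#'   series analyte).
#' @param species optional species filter.
#' @param media plasma-like media.
#' @return Object of class `fit_dataset` with `observations` (study_id, route,
#'   dose, time_hr, conc, loq, below_loq) and `studies`. Zero observations
#'   signal an empty dataset (not an error).
#' @export
build_fit_dataset <- function(db, substance, species = NULL,
                              media = c("plasma", "blood", "serum")) {
  stopifnot(inherits(db, "cvt_database"))
  st <- db$studies
  keep <- st$test_substance == substance
  if (!is.null(species)) keep <- keep & st$species == species
  keep <- keep & !is.na(st$study_id)
  st <- st[keep, , drop = FALSE]
  obs <- list()
  for (i in seq_len(nrow(st))) {
    route <- st$administration_route[i]
    route <- if (route %in% c("oral", "gavage")) "oral"
    else if (identical(route, "intravenous")) "intravenous" else NA
    if (is.na(route)) next
    if (!is.na(st$n_doses[i]) && st$n_doses[i] > 1) next
    dose <- st$dose_value_normalized[i]
    if (is.na(dose) || dose <= 0) next
    ms <- study_mean_series(db, st$study_id[i], media = media,
                            analyte = substance)
    if (nrow(ms) == 0) next
    sids <- db$series$series_id[db$series$study_id == st$study_id[i] &
                                  db$series$medium %in% media &
                                  db$series$analyte %in% substance]
    loqs <- db$series$loq[db$series$series_id %in% sids]
    loq <- if (all(is.na(loqs))) NA_real_ else max(loqs, na.rm = TRUE)
    obs[[length(obs) + 1L]] <- data.frame(
      study_id = st$study_id[i], route = route, dose = dose,
      time_hr = ms$time_hr, conc = ms$mean_conc, loq = loq,
      below_loq = ms$n_below_loq >= ms$n_series,
      stringsAsFactors = FALSE)
  }
  observations <- if (length(obs)) do.call(rbind, obs) else
    data.frame(study_id = character(0), route = character(0),
               dose = numeric(0), time_hr = numeric(0), conc = numeric(0),
               loq = numeric(0), below_loq = logical(0))
  drop <- observations$conc <= 0 & !observations$below_loq &
    is.na(observations$loq)
  if (any(drop)) {
    cvt_warning("cvt_zero_conc_warning",
                sprintf("dropping %d zero-concentration observation(s) with no LOQ",
                        sum(drop)))
    observations <- observations[!drop, , drop = FALSE]
  }
  structure(list(substance = substance, species = species,
                 observations = observations,
                 studies = unique(observations$study_id)),
            class = "fit_dataset")
}

#' @export
print.fit_dataset <- function(x, ...) {
  cat(sprintf("<fit_dataset> %s%s: %d observations, %d studies, routes: %s\n",
              x$substance,
              if (is.null(x$species)) "" else paste0(" / ", x$species),
              nrow(x$observations), length(x$studies),
              paste(unique(x$observations$route), collapse = "+")))
  invisible(x)
}

# Model predictions for every observation row.
predict_dataset <- function(params, dataset, model) {
  ob <- dataset$observations
  pred <- numeric(nrow(ob))
  key <- paste(ob$route, ob$dose)
  for (k in unique(key)) {
    ix <- which(key == k)
    pred[ix] <- concentration(model, ob$route[ix[1]], params,
                              ob$dose[ix[1]], ob$time_hr[ix])
  }
  pred
}

#' Negative log-likelihood of a compartmental model
#'
#' Gaussian likelihood on natural-log concentrations with a study-specific
#' error SD. Observations flagged below the LOQ contribute a censored term
#' `-log Phi((ln LOQ - ln Chat)/sigma_s)` when the LOQ is recorded. A
#' non-positive prediction at an uncensored observation returns `+Inf` (a
#' rejected point during optimization), never an error.
#'
#' @param params compartmental parameter object.
#' @param sigmas named numeric vector of per-study SDs (> 0), names = study
#'   ids.
#' @param dataset a [build_fit_dataset()] result.
#' @param model `"one_compartment"` or `"two_compartment"`.
#' @return The negative log-likelihood (finite or `+Inf`).
#' @export
negative_log_likelihood <- function(params, sigmas, dataset, model) {
  ob <- dataset$observations
  stopifnot(all(sigmas > 0), all(ob$study_id %in% names(sigmas)))
  pred <- predict_dataset(params, dataset, model)
  if (any(!is.finite(pred))) return(Inf)
  sg <- sigmas[ob$study_id]
  censored <- ob$below_loq & !is.na(ob$loq)
  nll <- 0
  if (any(!censored)) {
    p <- pred[!censored]
    if (any(p <= 0)) return(Inf)
    z <- (log(ob$conc[!censored]) - log(p)) / sg[!censored]
    nll <- nll + sum(log(sg[!censored]) + 0.5 * log(2 * pi) + 0.5 * z^2)
  }
  if (any(censored)) {
    p <- pred[censored]
    z <- ifelse(p <= 0, Inf, (log(ob$loq[censored]) - log(p)) / sg[censored])
    nll <- nll - sum(pnorm(z, log.p = TRUE))
  }
  nll
}

#' Akaike Information Criterion
#'
#' @param loglik maximized log-likelihood.
#' @param n_parameters number of estimated parameters (model parameters plus
#'   one error SD per study).
#' @return `2 * n_parameters - 2 * loglik`.
#' @export
aic_score <- function(loglik, n_parameters) {
  stopifnot(n_parameters >= 1)
  2 * n_parameters - 2 * loglik
}

# --- internal machinery -----------------------------------------------------

# Free structural parameters for a model/dataset, in optimization order.
free_structural <- function(model, routes, constrain_k21) {
  base <- if (model == "one_compartment") c("Vd", "kelim")
  else if (constrain_k21) c("V1", "kelim", "k12")
  else c("V1", "kelim", "k12", "k21")
  oral <- "oral" %in% routes
  both <- oral && "intravenous" %in% routes
  # Oral-only data cannot separate Fbio from the volume; Fbio is fixed at 1
  # and the volume absorbs it (apparent Vd/Fbio).
  list(names = c(base, if (oral) "kabsorb", if (both) "Fbio"),
       fbio_fixed = oral && !both)
}

theta_to_params <- function(theta, fs, model) {
  v <- setNames(numeric(length(fs$names)), fs$names)
  for (i in seq_along(fs$names)) {
    v[i] <- if (fs$names[i] == "Fbio") plogis(theta[i]) else exp(theta[i])
  }
  Fb <- if ("Fbio" %in% fs$names) unname(v["Fbio"]) else
    if (fs$fbio_fixed) 1 else NULL
  ka <- if ("kabsorb" %in% fs$names) unname(v["kabsorb"]) else NULL
  tryCatch({
    if (model == "one_compartment")
      one_comp_params(unname(v["Vd"]), unname(v["kelim"]), ka, Fb)
    else
      two_comp_params(unname(v["V1"]), unname(v["kelim"]), unname(v["k12"]),
                      if ("k21" %in% fs$names) unname(v["k21"]) else
                        unname(v["k12"]),
                      ka, Fb)
  }, cvt_error = function(e) NULL)
}

params_to_theta <- function(values, fs) {
  vapply(fs$names, function(nm) {
    if (nm == "Fbio") qlogis(min(max(values[[nm]], 0.02), 0.98))
    else log(values[[nm]])
  }, numeric(1))
}

# Heuristic start: terminal log-linear slope for kelim, back-extrapolated
# dose-normalized C0 for the volume; ka from the observed oral tmax.
heuristic_start <- function(dataset, model) {
  ob <- dataset$observations
  ok <- ob$conc > 0 & !ob$below_loq
  src <- if (any(ok & ob$route == "intravenous"))
    ob[ok & ob$route == "intravenous", ] else ob[ok, ]
  if (nrow(src) < 2) src <- ob[ob$conc > 0, ]
  src <- src[order(src$time_hr), ]
  tail_n <- max(3, ceiling(nrow(src) / 2))
  tl <- tail(src, tail_n)
  kelim0 <- 0.1; c0 <- max(src$conc / src$dose)
  if (nrow(tl) >= 2 && length(unique(tl$time_hr)) >= 2) {
    fit <- lm(log(conc / dose) ~ time_hr, data = tl)
    sl <- coef(fit)
    kelim0 <- max(-unname(sl[2]), 1e-3)
    c0 <- exp(unname(sl[1]))
  }
  V0 <- min(max(1 / c0, 1e-3), 1e4)
  ka0 <- 1
  oral <- ob[ob$route == "oral" & ob$conc > 0, ]
  if (nrow(oral)) {
    tmax_obs <- oral$time_hr[which.max(oral$conc / oral$dose)]
    if (tmax_obs > 0) ka0 <- max(1 / tmax_obs, 2 * kelim0)
  }
  list(Vd = V0, V1 = 0.6 * V0, kelim = kelim0, k12 = kelim0, k21 = kelim0,
       kabsorb = ka0, Fbio = 0.8)
}

profiled_sigmas <- function(params, dataset, model) {
  ob <- dataset$observations
  pred <- predict_dataset(params, dataset, model)
  if (any(pred <= 0) || any(!is.finite(pred))) return(NULL)
  r <- log(ob$conc) - log(pred)
  vapply(split(r, ob$study_id),
         function(x) max(sqrt(mean(x^2)), SIGMA_FLOOR), numeric(1))
}

#' Fit a compartmental model to a dataset by maximum likelihood
#'
#' Minimizes [negative_log_likelihood()] over log-transformed positive
#' parameters (logit for Fbio) using five deterministic starts: a heuristic
#' start (terminal log-linear slope and back-extrapolated C0) plus four
#' perturbations at fixed multipliers, each refined by a Nelder-Mead simplex
#' search and a quasi-Newton polish. When no observation is censored the
#' per-study error SDs are profiled out in closed form (floored at 1e-6);
#' with censoring they are estimated jointly. The AIC parameter count is the
#' number of free model parameters plus one SD per study.
#'
#' @param dataset a non-empty [build_fit_dataset()] result.
#' @param model `"one_compartment"` or `"two_compartment"`.
#' @param config a [fit_config()].
#' @return Object of class `cvt_fit`: `model`, `estimates`, `sigma_by_study`,
#'   `loglik`, `n_parameters`, `aic`, `convergence`, `n_observations`,
#'   `fbio_fixed`.
#' @export
fit_compartmental <- function(dataset, model = c("one_compartment",
                                                 "two_compartment"),
                              config = fit_config()) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "fit_dataset"))
  ob <- dataset$observations
  if (nrow(ob) == 0)
    cvt_error("cvt_empty_dataset_error", "dataset has no observations")
  fs <- free_structural(model, unique(ob$route), config$constrain_k21)
  n_studies <- length(dataset$studies)
  n_par <- length(fs$names) + n_studies
  if (nrow(ob) < n_par + 1)
    cvt_error("cvt_insufficient_data_error",
              sprintf("%d observations cannot support %d parameters",
                      nrow(ob), n_par))
  censored_any <- any(ob$below_loq & !is.na(ob$loq))

  objective <- function(theta) {
    params <- theta_to_params(theta[seq_along(fs$names)], fs, model)
    if (is.null(params)) return(1e10)
    if (censored_any) {
      sig <- SIGMA_FLOOR + exp(theta[-seq_along(fs$names)])
      names(sig) <- dataset$studies
    } else {
      sig <- profiled_sigmas(params, dataset, model)
      if (is.null(sig)) return(1e10)
    }
    val <- negative_log_likelihood(params, sig, dataset, model)
    if (!is.finite(val)) 1e10 else val
  }

  h <- heuristic_start(dataset, model)
  base_theta <- params_to_theta(h, fs)
  starts <- list(base_theta)
  for (m in config$start_multipliers) {
    th <- base_theta
    pos <- fs$names != "Fbio"
    th[pos] <- th[pos] + log(m)
    starts[[length(starts) + 1L]] <- th
  }
  if (censored_any) {
    sig0 <- rep(log(0.5), n_studies)
    starts <- lapply(starts, function(th) c(th, sig0))
  }

  best <- NULL
  for (th0 in starts) {
    res <- tryCatch({
      nm <- optim(th0, objective, method = "Nelder-Mead",
                  control = list(maxit = config$maxit_nm,
                                 reltol = config$reltol))
      bf <- tryCatch(optim(nm$par, objective, method = "BFGS",
                           control = list(maxit = config$maxit_bfgs,
                                          reltol = config$reltol)),
                     error = function(e) nm)
      if (bf$value <= nm$value) bf else nm
    }, error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best) || best$value >= 1e10)
    cvt_error("cvt_convergence_error",
              sprintf("no start converged for %s fit of '%s'",
                      model, dataset$substance))

  theta <- best$par
  estimates <- theta_to_params(theta[seq_along(fs$names)], fs, model)
  if (censored_any) {
    sigmas <- SIGMA_FLOOR + exp(theta[-seq_along(fs$names)])
    names(sigmas) <- dataset$studies
  } else {
    sigmas <- profiled_sigmas(estimates, dataset, model)
  }
  loglik <- -negative_log_likelihood(estimates, sigmas, dataset, model)
  structure(list(model = model, estimates = estimates,
                 sigma_by_study = sigmas, loglik = loglik,
                 n_parameters = n_par, aic = aic_score(loglik, n_par),
                 convergence = TRUE, n_observations = nrow(ob),
                 fbio_fixed = fs$fbio_fixed, substance = dataset$substance,
                 species = dataset$species),
            class = "cvt_fit")
}

#' @export
print.cvt_fit <- function(x, ...) {
  est <- x$estimates
  pn <- names(est)[!vapply(est, is.null, logical(1))]
  cat(sprintf("<cvt_fit> %s | logLik %.4f | AIC %.4f (%d parameters, %d obs)\n",
              x$model, x$loglik, x$aic, x$n_parameters, x$n_observations))
  for (p in pn) cat(sprintf("  %-8s %.6g\n", p, est[[p]]))
  cat(sprintf("  sigma:   %s\n",
              paste(sprintf("%s=%.4g", names(x$sigma_by_study),
                            x$sigma_by_study), collapse = ", ")))
  invisible(x)
}

#' Select between the one- and two-compartment fits by AIC
#'
#' Returns the fit with the lesser AIC; an exact tie goes to the
#' one-compartment model (parsimony). If only one fit converged it is
#' selected with a warning; if neither converged an error is raised.
#'
#' @param fit1c,fit2c [fit_compartmental()] results for the same dataset (or
#'   `NULL` for an unavailable/unconverged fit).
#' @return The selected `cvt_fit`.
#' @export
select_model <- function(fit1c, fit2c) {
  ok1 <- !is.null(fit1c) && isTRUE(fit1c$convergence)
  ok2 <- !is.null(fit2c) && isTRUE(fit2c$convergence)
  if (!ok1 && !ok2)
    cvt_error("cvt_convergence_error", "neither model fit converged")
  if (ok1 && !ok2) {
    cvt_warning("cvt_selection_warning",
                "two-compartment fit unavailable; selecting one-compartment")
    return(fit1c)
  }
  if (!ok1 && ok2) {
    cvt_warning("cvt_selection_warning",
                "one-compartment fit unavailable; selecting two-compartment")
    return(fit2c)
  }
  if (fit2c$aic < fit1c$aic) fit2c else fit1c
}

fit_record <- function(id_prefix, ref, model, name, value, units) {
  data.frame(record_id = paste(id_prefix, name, sep = "|"),
             study_or_group_reference = ref, model = model,
             parameter_name = name, value = value, units = units,
             calculated_with_invivopkfit = TRUE, stringsAsFactors = FALSE)
}

#' Fit every fittable substance group of a database
#'
#' Iterates over substance:species groups (or route:substance groups, per
#' `config$group_by`), fits both compartmental models where the data allow,
#' selects by AIC, and emits toxicokinetic parameter records (model
#' parameters plus derived half-life, total clearance and AUCinf normalized
#' to a 1 mg/kg dose) flagged as calculated by this fitter. Groups that lack
#' plasma data or fail to fit are reported, not fatal.
#'
#' @param db a [cvt_database()].
#' @param config a [fit_config()].
#' @return List with `tk_parameters` (data frame following the tk_parameters
#'   schema), `fits` (named list of selected `cvt_fit`s) and `report` (one
#'   row per group: counts, both AICs, chosen model, status).
#' @export
fit_all <- function(db, config = fit_config()) {
  stopifnot(inherits(db, "cvt_database"))
  st <- db$studies
  groups <- unique(st[!is.na(st$test_substance),
                      c("test_substance", "species")])
  groups <- groups[order(groups$test_substance, groups$species), ,
                   drop = FALSE]
  records <- list(); fits <- list(); report <- list()
  for (i in seq_len(nrow(groups))) {
    subst <- groups$test_substance[i]; spec <- groups$species[i]
    key <- paste(subst, spec, sep = "|")
    ds <- build_fit_dataset(db, subst, spec, media = config$media)
    row <- data.frame(group = key, substance = subst, species = spec,
                      n_obs = nrow(ds$observations),
                      n_studies = length(ds$studies),
                      aic_1c = NA_real_, aic_2c = NA_real_,
                      model_chosen = NA_character_, status = "ok",
                      stringsAsFactors = FALSE)
    if (nrow(ds$observations) == 0) {
      row$status <- "skipped: no plasma data"
      report[[i]] <- row
      next
    }
    f1 <- tryCatch(fit_compartmental(ds, "one_compartment", config),
                   cvt_error = function(e) NULL)
    f2 <- tryCatch(fit_compartmental(ds, "two_compartment", config),
                   cvt_error = function(e) NULL)
    sel <- tryCatch(suppressWarnings(select_model(f1, f2)),
                    cvt_error = function(e) NULL)
    if (is.null(sel)) {
      row$status <- "failed: no converged fit"
      report[[i]] <- row
      next
    }
    row$aic_1c <- if (!is.null(f1)) f1$aic else NA_real_
    row$aic_2c <- if (!is.null(f2)) f2$aic else NA_real_
    row$model_chosen <- sel$model
    report[[i]] <- row
    fits[[key]] <- sel

    est <- sel$estimates
    routes <- unique(ds$observations$route)
    vol_name <- if (sel$model == "one_compartment") "Vd" else "V1"
    pars <- list()
    add <- function(name, value, units)
      pars[[length(pars) + 1L]] <<- fit_record(paste("fit", key, sep = "|"),
                                               key, sel$model, name, value,
                                               units)
    add(vol_name, est[[vol_name]], "L/kg")
    add("kelim", est$kelim, "1/h")
    if (sel$model == "two_compartment") {
      add("k12", est$k12, "1/h")
      add("k21", est$k21, "1/h")
    }
    if (!is.null(est$kabsorb)) add("kabsorb", est$kabsorb, "1/h")
    if (!is.null(est$Fbio) && !sel$fbio_fixed)
      add("Fbio", est$Fbio, "fraction")
    dk <- derived_tk_parameters(sel$model, est, dose = 1,
                                route = if ("intravenous" %in% routes)
                                  "intravenous" else "oral")
    add("halflife", dk$halflife_h, "h")
    add("CLtot", dk$CLtot, "L/h/kg")
    add("AUCinf", dk$AUCinf, "ug*h/mL per mg/kg")
    records[[key]] <- do.call(rbind, pars)
  }
  list(tk_parameters = if (length(records)) do.call(rbind, c(records,
                                                             make.row.names = FALSE))
       else empty_cvt_table("tk_parameters"),
       fits = fits,
       report = do.call(rbind, c(report, make.row.names = FALSE)))
}
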
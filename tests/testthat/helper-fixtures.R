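# Shared fixtures and independent oracles, all built in code.

# Minimal clean database: 1 document, 1 study, 1 series, 3 values.
make_clean_db <- function() {
  cvt_database(
    documents = data.frame(
      document_id = "d1", citation_text = "Example citation",
      pmid = "123", extracted_flag = TRUE,
      candidate_chemical_names = "examplol",
      environmental_relevance_flag = TRUE, toxcast_flag = FALSE),
    studies = data.frame(
      study_id = "s1", document_id = "d1", test_substance = "examplol",
      species = "rat", sex = "M", administration_route = "intravenous",
      dose_value_original = 1, dose_units_original = "mg/kg",
      dose_value_normalized = 1, n_doses = 1, fasting_status = "unknown"),
    series = data.frame(
      series_id = "se1", study_id = "s1", analyte = "examplol",
      medium = "plasma", conc_units_original = "ng/mL",
      conc_units_normalized = "ug/mL", time_units_original = "h"),
    conc_time_values = data.frame(
      value_id = c("v1", "v2", "v3"), series_id = "se1",
      time_original = c(0, 1, 2), time_hr = c(0, 1, 2),
      conc_original = c(2000, 1000, 500),
      conc_normalized = c(2, 1, 0.5), below_loq_flag = FALSE))
}

# Two plasma series (on caller-supplied grids) plus one liver series in the
# same study, for study_mean_series checks. Each value list: list(t=, c=).
make_two_series_db <- function(values_a, values_b) {
  db <- make_clean_db()
  s1 <- db$series
  s2 <- s1; s2$series_id <- "se2"
  s3 <- s1; s3$series_id <- "se3"; s3$medium <- "liver"
  db$series <- rbind(s1, s2, s3)
  mk <- function(sid, vals) data.frame(
    value_id = paste0(sid, "-v", seq_along(vals$t)), series_id = sid,
    time_original = vals$t, time_hr = vals$t, conc_original = vals$c,
    conc_normalized = vals$c, conc_lower_bound = NA_real_,
    conc_upper_bound = NA_real_, below_loq_flag = FALSE,
    stringsAsFactors = FALSE)
  vt <- rbind(mk("se1", values_a), mk("se2", values_b),
              mk("se3", list(t = 0:1, c = c(9, 9))))
  db$conc_time_values <- cvt_database(conc_time_values = vt)$conc_time_values
  db
}

# Independent ODE oracle for the compartmental closed forms (deSolve).
ode_concentration <- function(model, route, params, dose, times) {
  p <- unclass(params)
  if (is.null(p$kabsorb)) p$kabsorb <- 0
  if (is.null(p$Fbio)) p$Fbio <- 1
  if (model == "one_compartment") {
    derivs <- function(t, y, q) list(c(
      -q$kabsorb * y[1],
      q$kabsorb * y[1] - q$kelim * y[2]))
    y0 <- if (route == "oral") c(p$Fbio * dose, 0) else c(0, dose)
    vol <- p$Vd
  } else {
    derivs <- function(t, y, q) list(c(
      -q$kabsorb * y[1],
      q$kabsorb * y[1] - (q$kelim + q$k12) * y[2] + q$k21 * y[3],
      q$k12 * y[2] - q$k21 * y[3]))
    y0 <- if (route == "oral") c(p$Fbio * dose, 0, 0) else c(0, dose, 0)
    vol <- p$V1
  }
  out <- deSolve::ode(y0, unique(c(0, times)), derivs, p,
                      rtol = 1e-10, atol = 1e-14)
  out[match(times, out[, 1]), 3] / vol   # column 3 = central amount
}

# Direct simulated fit dataset (no database round trip, no storage rounding).
make_sim_dataset <- function(model, params, route = "intravenous", dose = 1,
                             times = c(0.25, 0.5, 1, 2, 4, 8, 16, 24),
                             cv = 0, seed = 1, study_id = "sim1") {
  conc <- concentration(model, route, params, dose, times)
  if (cv > 0) {
    set.seed(seed)
    conc <- conc * exp(rnorm(length(conc), 0, sqrt(log(1 + cv^2))))
  }
  fit_dataset(data.frame(study_id = study_id, route = route, dose = dose,
                         time_hr = times, conc = conc,
                         stringsAsFactors = FALSE))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
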
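test_that("negative log-likelihood matches its closed form and is additive", {
  ds <- fit_dataset(data.frame(study_id = "a", route = "intravenous",
                               dose = 1, time_hr = 1, conc = 2 * exp(-0.3)))
  p <- one_comp_params(Vd = 0.5, kelim = 0.3)
  # observation equals the prediction, sigma = 1 -> 0.5 ln(2 pi)
  expect_equal(negative_log_likelihood(p, c(a = 1), ds, "one_compartment"),
               0.5 * log(2 * pi), tolerance = 1e-12)

  ds2 <- fit_dataset(data.frame(study_id = c("a", "b"),
                                route = "intravenous", dose = 1,
                                time_hr = 1, conc = 2 * exp(-0.3)))
  expect_equal(negative_log_likelihood(p, c(a = 1, b = 1), ds2,
                                       "one_compartment"),
               2 * 0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("censored observations contribute the LOQ term", {
  # prediction far below the LOQ: Phi -> 1, contribution -> 0
  ds <- fit_dataset(data.frame(study_id = "a", route = "intravenous",
                               dose = 1, time_hr = 40, conc = 0,
                               loq = 0.5, below_loq = TRUE))
  p <- one_comp_params(Vd = 0.5, kelim = 0.3)
  expect_equal(negative_log_likelihood(p, c(a = 0.5), ds,
                                       "one_compartment"), 0,
               tolerance = 1e-8)
  # prediction above the LOQ: contribution is -ln Phi((ln LOQ - ln C)/sigma)
  ds$observations$time_hr <- 0   # C(0) = D/Vd = 2
  expect_equal(negative_log_likelihood(p, c(a = 0.5), ds,
                                       "one_compartment"),
               -pnorm(log(0.5 / 2) / 0.5, log.p = TRUE), tolerance = 1e-10)
})

test_that("non-positive predictions are rejected with +Inf, not an error", {
  ds <- fit_dataset(data.frame(study_id = "a", route = "oral", dose = 1,
                               time_hr = 0, conc = 1))
  p <- one_comp_params(Vd = 0.5, kelim = 0.3, kabsorb = 1, Fbio = 1)
  expect_identical(negative_log_likelihood(p, c(a = 1), ds,
                                           "one_compartment"), Inf)
})

test_that("AIC arithmetic", {
  expect_equal(aic_score(0, 1), 2)
  expect_equal(aic_score(-10, 3), 26)
  expect_equal(aic_score(-5, 4) - aic_score(-5, 3), 2)
})

test_that("noiseless one-compartment IV data is recovered almost exactly", {
  truth <- one_comp_params(Vd = 0.5, kelim = 0.3)
  ds <- make_sim_dataset("one_compartment", truth,
                         times = c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 18, 24))
  fit <- fit_compartmental(ds, "one_compartment")
  expect_lt(rel_err(fit$estimates$Vd, 0.5), 1e-3)
  expect_lt(rel_err(fit$estimates$kelim, 0.3), 1e-3)
  expect_equal(fit$aic, aic_score(fit$loglik, fit$n_parameters),
               tolerance = 1e-9)
  expect_equal(fit$n_parameters, 3)   # Vd, kelim + one study SD
})

test_that("oral-only data identifies the apparent volume Vd/Fbio (Fbio fixed at 1)", {
  truth <- one_comp_params(Vd = 0.5, kelim = 0.3, kabsorb = 1, Fbio = 0.8)
  ds <- make_sim_dataset("one_compartment", truth, route = "oral",
                         times = c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 18, 24))
  fit <- fit_compartmental(ds, "one_compartment")
  expect_true(fit$fbio_fixed)
  expect_lt(rel_err(fit$estimates$Vd, 0.5 / 0.8), 1e-3)
  expect_lt(rel_err(fit$estimates$kelim, 0.3), 1e-3)
  expect_equal(fit$estimates$Fbio, 1)   # held at 1, not estimated
})

test_that("too few observations raise an insufficient-data error", {
  ds <- fit_dataset(data.frame(study_id = "a", route = "intravenous",
                               dose = 1, time_hr = c(1, 2), conc = c(1, 0.5)))
  expect_error(fit_compartmental(ds, "two_compartment"),
               class = "cvt_insufficient_data_error")
})

test_that("model selection prefers the lesser AIC with a parsimony tie-break", {
  mk <- function(model, aic) structure(list(model = model, aic = aic,
                                            convergence = TRUE),
                                       class = "cvt_fit")
  expect_equal(select_model(mk("one_compartment", 10),
                            mk("two_compartment", 8))$model,
               "two_compartment")
  expect_equal(select_model(mk("one_compartment", 10),
                            mk("two_compartment", 10))$model,
               "one_compartment")
  expect_warning(sel <- select_model(mk("one_compartment", 10), NULL),
                 class = "cvt_selection_warning")
  expect_equal(sel$model, "one_compartment")
  expect_error(suppressWarnings(select_model(NULL, NULL)),
               class = "cvt_convergence_error")
})

test_that("clearly bi-exponential data selects the two-compartment model", {
  truth <- two_comp_params(V1 = 0.4, kelim = 0.6, k12 = 1.2, k21 = 0.15)
  ds <- make_sim_dataset("two_compartment", truth,
                         times = c(0.1, 0.25, 0.5, 1, 2, 4, 8, 12, 24, 36),
                         cv = 0.05, seed = 77)
  f1 <- fit_compartmental(ds, "one_compartment")
  f2 <- fit_compartmental(ds, "two_compartment")
  expect_equal(select_model(f1, f2)$model, "two_compartment")
})

test_that("the MLE is invariant to observation order", {
  truth <- one_comp_params(Vd = 0.5, kelim = 0.3)
  ds <- make_sim_dataset("one_compartment", truth, cv = 0.2, seed = 5)
  set.seed(99)
  perm <- sample(nrow(ds$observations))
  ds_perm <- fit_dataset(ds$observations[perm, ])
  f <- fit_compartmental(ds, "one_compartment")
  fp <- fit_compartmental(ds_perm, "one_compartment")
  expect_equal(fp$estimates$Vd, f$estimates$Vd, tolerance = 1e-6)
  expect_equal(fp$estimates$kelim, f$estimates$kelim, tolerance = 1e-6)
  expect_equal(fp$loglik, f$loglik, tolerance = 1e-8)
})

test_that("build_fit_dataset selects plasma studies and routes correctly", {
  db <- make_clean_db()
  ds <- build_fit_dataset(db, "examplol", "rat")
  expect_equal(nrow(ds$observations), 3)
  expect_equal(length(ds$studies), 1)

  liver <- make_clean_db()
  liver$series$medium <- "liver"
  ds <- build_fit_dataset(liver, "examplol", "rat")
  expect_equal(nrow(ds$observations), 0)

  # add an oral study: two study slots, both routes
  db2 <- make_clean_db()
  st2 <- db2$studies; st2$study_id <- "s2"
  st2$administration_route <- "gavage"   # gavage is an oral subtype
  db2$studies <- rbind(db2$studies, st2)
  se2 <- db2$series; se2$series_id <- "se2"; se2$study_id <- "s2"
  db2$series <- rbind(db2$series, se2)
  cv2 <- db2$conc_time_values
  cv2$value_id <- paste0("b", 1:3); cv2$series_id <- "se2"
  cv2$time_hr <- c(1, 2, 4)
  db2$conc_time_values <- rbind(db2$conc_time_values, cv2)
  ds <- build_fit_dataset(db2, "examplol", "rat")
  expect_equal(length(ds$studies), 2)
  expect_setequal(unique(ds$observations$route), c("intravenous", "oral"))
})

test_that("fit_all is deterministic and reports skipped groups", {
  sim <- simulate_cvt_database(default_simulation_design(seed = 21,
                                                         noise_cv = 0.1))
  db <- sim$database
  # add a substance with only liver data: must be skipped, not fatal
  st <- db$studies[1, ]; st$study_id <- "st-liver"; st$test_substance <- "hepatol"
  db$studies <- rbind(db$studies, st)
  se <- db$series[1, ]; se$series_id <- "se-liver"; se$study_id <- "st-liver"
  se$medium <- "liver"; se$analyte <- "hepatol"
  db$series <- rbind(db$series, se)

  res1 <- fit_all(db, fit_config(seed = 1))
  res2 <- fit_all(db, fit_config(seed = 1))
  expect_identical(res1$tk_parameters, res2$tk_parameters)
  expect_true(all(res1$tk_parameters$calculated_with_invivopkfit))
  expect_true(any(grepl("skipped", res1$report$status[
    res1$report$substance == "hepatol"])))
  # both synthetic substances produced records
  expect_setequal(unique(res1$report$substance[res1$report$status == "ok"]),
                  c("synthex-a", "synthex-b"))
  expect_true(all(c("halflife", "CLtot", "AUCinf") %in%
                    res1$tk_parameters$parameter_name))
})
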
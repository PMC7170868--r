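# Seeded generators for CvT databases and abstract corpora with known ground
# truth, so fitting, normalization, validation statistics and triage can be
# exercised end-to-end without any external data.

#' Simulation design for a synthetic CvT database
#'
#' Describes the study conditions to emulate: multiple studies per substance,
#' IV-bolus and oral routes, per-study replicate series with multiplicative
#' lognormal measurement noise, per-study LOQ censoring, and heterogeneous
#' as-reported units (so normalization is exercised).
#'
#' @param substances named list: substance name -> list with `model`
#'   (`"one_compartment"`/`"two_compartment"`) and `params` (a matching
#'   parameter object).
#' @param studies list of study descriptors: `substance`, `route`
#'   (intravenous/oral), `dose_mg_kg`, `times_hr` (strictly increasing grid),
#'   `n_series` replicates, `noise_cv` (coefficient of variation of the
#'   multiplicative noise, >= 0), optional `loq` (normalized units), and the
#'   original units to emit (`conc_unit`, `time_unit`).
#' @param species species for all studies (default rat).
#' @param noise_model `"lognormal"` (matching the fitter's log-scale error
#'   model) or `"additive"` Gaussian (for misspecification stress tests).
#' @param seed mandatory integer seed.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(substances, studies, species = "rat",
                              noise_model = c("lognormal", "additive"),
                              seed) {
  noise_model <- match.arg(noise_model)
  if (missing(seed)) cvt_error("cvt_config_error", "seed is mandatory")
  for (s in studies) {
    if (!s$substance %in% names(substances))
      cvt_error("cvt_config_error",
                sprintf("study references unknown substance '%s'",
                        s$substance))
    if (!s$route %in% c("intravenous", "oral"))
      cvt_error("cvt_config_error", "route must be intravenous or oral")
    if (any(diff(s$times_hr) <= 0))
      cvt_error("cvt_config_error", "time grid must be strictly increasing")
    if (is.null(s$noise_cv) || s$noise_cv < 0)
      cvt_error("cvt_config_error", "noise_cv must be >= 0")
  }
  structure(list(substances = substances, studies = studies,
                 species = species, noise_model = noise_model, seed = seed),
            class = "simulation_design")
}

#' Default simulation design
#'
#' One one-compartment substance (Vd = 0.5 L/kg, kelim = 0.3/h, oral
#' kabsorb = 1/h, Fbio = 0.8) observed in two IV studies and one oral study,
#' and one clearly bi-exponential two-compartment substance, each with
#' replicate series, 20% CV lognormal noise and heterogeneous original units.
#'
#' @param seed integer seed.
#' @param noise_cv replicate noise CV (default 0.2).
#' @return A [simulation_design()].
#' @export
default_simulation_design <- function(seed, noise_cv = 0.2) {
  grid <- c(0.25, 0.5, 1, 2, 4, 8, 16, 24)
  simulation_design(
    substances = list(
      "synthex-a" = list(model = "one_compartment",
                         params = one_comp_params(Vd = 0.5, kelim = 0.3,
                                                  kabsorb = 1, Fbio = 0.8)),
      "synthex-b" = list(model = "two_compartment",
                         params = two_comp_params(V1 = 0.4, kelim = 0.6,
                                                  k12 = 1.2, k21 = 0.15))),
    studies = list(
      list(substance = "synthex-a", route = "intravenous", dose_mg_kg = 1,
           times_hr = grid, n_series = 2, noise_cv = noise_cv,
           conc_unit = "ng/mL", time_unit = "min"),
      list(substance = "synthex-a", route = "intravenous", dose_mg_kg = 5,
           times_hr = grid, n_series = 2, noise_cv = noise_cv,
           loq = 0.005, conc_unit = "ug/mL", time_unit = "h"),
      list(substance = "synthex-a", route = "oral", dose_mg_kg = 2,
           times_hr = grid, n_series = 2, noise_cv = noise_cv,
           conc_unit = "mg/L", time_unit = "h"),
      list(substance = "synthex-b", route = "intravenous", dose_mg_kg = 2,
           times_hr = c(0.1, 0.25, 0.5, 1, 2, 4, 8, 12, 24, 36),
           n_series = 2, noise_cv = noise_cv, conc_unit = "ng/mL",
           time_unit = "h")),
    species = "rat", seed = seed)
}

#' Phenytoin-style replicate design
#'
#' Three IV replicate series on an identical grid at a 25 mg/kg dose,
#' emulating a study repeated as its own control, to exercise the fractional
#' AUC variability and K-S concordance statistics.
#'
#' @param seed integer seed.
#' @param noise_cv replicate noise CV (default 0.1).
#' @return A [simulation_design()].
#' @export
design_replicate_scenario <- function(seed, noise_cv = 0.1) {
  simulation_design(
    substances = list(
      "phenytoin-like" = list(model = "one_compartment",
                              params = one_comp_params(Vd = 0.7,
                                                       kelim = 0.08))),
    studies = list(
      list(substance = "phenytoin-like", route = "intravenous",
           dose_mg_kg = 25, times_hr = c(0.5, 1, 2, 4, 8, 12, 24, 36, 48),
           n_series = 3, noise_cv = noise_cv, conc_unit = "ug/mL",
           time_unit = "h")),
    species = "rat", seed = seed)
}

#' Simulate a CvT database with known ground truth
#'
#' Evaluates each study's true compartmental model on its time grid,
#' multiplies by lognormal noise `exp(eps)`, `eps ~ N(0, sqrt(ln(1+CV^2)))`
#' (or adds Gaussian noise under the additive model), emits the values in the
#' requested original units, fills the normalized fields through the
#' normalization pipeline, and flags values below the study LOQ. The emitted
#' database passes [validate_database()] with zero issues.
#'
#' @param design a [simulation_design()].
#' @return List with `database` (a [cvt_database()]), `parameters` (true
#'   parameter table: substance, model, parameter, value) and `studies`
#'   (per-study truth: study_id, substance, route, dose, n_series, noise_cv,
#'   loq).
#' @export
simulate_cvt_database <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  registry <- default_unit_registry()
  docs <- list(); studies <- list(); series <- list(); values <- list()
  study_truth <- list()
  with_private_seed(design$seed, {
    for (i in seq_along(design$studies)) {
      sd_ <- design$studies[[i]]
      sub <- design$substances[[sd_$substance]]
      doc_id <- sprintf("doc-%03d", i)
      study_id <- sprintf("st-%03d", i)
      docs[[i]] <- data.frame(
        document_id = doc_id,
        citation_text = sprintf("Synthetic study %d of %s", i,
                                sd_$substance),
        pmid = NA_character_, extracted_flag = TRUE,
        candidate_chemical_names = sd_$substance,
        environmental_relevance_flag = TRUE, toxcast_flag = FALSE,
        stringsAsFactors = FALSE)
      studies[[i]] <- data.frame(
        study_id = study_id, document_id = doc_id,
        test_substance = sd_$substance, substance_identifier = NA_character_,
        species = design$species, strain_or_type = "synthetic",
        sex = "mixed", administration_route = sd_$route,
        dose_value_original = sd_$dose_mg_kg, dose_units_original = "mg/kg",
        dose_value_normalized = sd_$dose_mg_kg,
        dose_provenance = "per_kg_reported", dose_vehicle = "water",
        dose_volume = NA_real_, exposure_duration_h = NA_real_, n_doses = 1,
        dose_spacing_h = NA_real_, n_subjects_per_group = 5, n_groups = 1,
        fasting_status = "unknown", curation_notes = NA_character_,
        stringsAsFactors = FALSE)
      truth <- concentration(sub$model, sd_$route, sub$params,
                             sd_$dose_mg_kg, sd_$times_hr)
      cfac <- registry$factor_to_ug_per_ml[
        match(parse_conc_unit(sd_$conc_unit)$canonical, registry$unit)]
      tfac <- time_unit_factors[[tolower(sd_$time_unit)]]
      loq <- if (is.null(sd_$loq)) NA_real_ else sd_$loq
      for (r in seq_len(sd_$n_series)) {
        series_id <- sprintf("%s-se-%02d", study_id, r)
        series[[length(series) + 1L]] <- data.frame(
          series_id = series_id, study_id = study_id,
          analyte = sd_$substance, medium = "plasma",
          conc_units_original = sd_$conc_unit,
          conc_units_normalized = NA_character_,
          time_units_original = sd_$time_unit,
          subject_age_value = 10, subject_age_units = "week",
          subject_age_category = NA_character_,
          subject_height_cm = NA_real_, subject_weight_kg = 0.25,
          loq = loq, lod = NA_real_, analysis_method = "synthetic",
          figure_or_table_name = NA_character_, stringsAsFactors = FALSE)
        noisy <- if (sd_$noise_cv > 0) {
          if (design$noise_model == "lognormal")
            truth * exp(rnorm(length(truth), 0,
                              sqrt(log(1 + sd_$noise_cv^2))))
          else pmax(truth + rnorm(length(truth), 0,
                                  sd_$noise_cv * pmax(truth, 1e-12)), 0)
        } else truth
        values[[length(values) + 1L]] <- data.frame(
          value_id = sprintf("%s-v-%02d", series_id,
                             seq_along(sd_$times_hr)),
          series_id = series_id,
          time_original = sd_$times_hr / tfac,
          time_hr = NA_real_,
          conc_original = noisy / cfac,
          conc_normalized = NA_real_,
          conc_lower_bound = NA_real_, conc_upper_bound = NA_real_,
          below_loq_flag = FALSE, stringsAsFactors = FALSE)
      }
      study_truth[[i]] <- data.frame(
        study_id = study_id, substance = sd_$substance, route = sd_$route,
        dose_mg_kg = sd_$dose_mg_kg, n_series = sd_$n_series,
        noise_cv = sd_$noise_cv, loq = loq, stringsAsFactors = FALSE)
    }
  })
  db <- cvt_database(do.call(rbind, docs), do.call(rbind, studies),
                     do.call(rbind, series), do.call(rbind, values))
  db <- normalize_database(db)
  loq_of <- setNames(db$series$loq, db$series$series_id)
  lo <- loq_of[db$conc_time_values$series_id]
  db$conc_time_values$below_loq_flag <-
    !is.na(lo) & db$conc_time_values$conc_normalized < lo

  params <- do.call(rbind, lapply(names(design$substances), function(nm) {
    sub <- design$substances[[nm]]
    vals <- unlist(Filter(Negate(is.null), unclass(sub$params)))
    data.frame(substance = nm, model = sub$model, parameter = names(vals),
               value = unname(vals), stringsAsFactors = FALSE)
  }))
  list(database = db, parameters = params,
       studies = do.call(rbind, study_truth))
}

#' Corpus design for synthetic labelled abstracts
#'
#' Class-conditional bag-of-words corpora: a shared vocabulary plus
#' class-enriched vocabularies whose prominence is controlled by
#' `separation` (1 = class-exclusive enriched words, 0 = identical class
#' distributions), and per-class MeSH term pools with inclusion
#' probabilities.
#'
#' @param n_positive,n_negative class sizes.
#' @param n_shared_words,n_class_words vocabulary sizes.
#' @param separation frequency divergence between classes, in \[0, 1\].
#' @param abstract_length mean abstract length in words (Poisson).
#' @param mesh_pool_size MeSH terms per pool (own-class, other-class,
#'   shared).
#' @param seed mandatory integer seed.
#' @return List of class `corpus_design`.
#' @export
corpus_design <- function(n_positive = 40, n_negative = 40,
                          n_shared_words = 100, n_class_words = 30,
                          separation = 1, abstract_length = 60,
                          mesh_pool_size = 8, seed) {
  if (missing(seed)) cvt_error("cvt_config_error", "seed is mandatory")
  if (separation < 0 || separation > 1)
    cvt_error("cvt_config_error", "separation must lie in [0, 1]")
  structure(list(n_positive = n_positive, n_negative = n_negative,
                 n_shared_words = n_shared_words,
                 n_class_words = n_class_words, separation = separation,
                 abstract_length = abstract_length,
                 mesh_pool_size = mesh_pool_size, seed = seed),
            class = "corpus_design")
}

#' Simulate a labelled abstract corpus
#'
#' Draws each abstract as a multinomial bag of words over its class's word
#' distribution and attaches MeSH terms drawn from per-class pools with
#' class-dependent inclusion probabilities.
#'
#' @param design a [corpus_design()].
#' @return Data frame with columns `doc_id`, `label`, `abstract`,
#'   `mesh_terms` (pipe-separated).
#' @export
simulate_abstract_corpus <- function(design) {
  stopifnot(inherits(design, "corpus_design"))
  shared <- sprintf("shared%03d", seq_len(design$n_shared_words))
  posw <- sprintf("posw%03d", seq_len(design$n_class_words))
  negw <- sprintf("negw%03d", seq_len(design$n_class_words))
  mesh_pos <- sprintf("MeSH-pos-%02d", seq_len(design$mesh_pool_size))
  mesh_neg <- sprintf("MeSH-neg-%02d", seq_len(design$mesh_pool_size))
  mesh_shared <- sprintf("MeSH-shared-%02d", seq_len(design$mesh_pool_size))
  sep <- design$separation

  word_probs <- function(own, other) {
    w <- c(rep(0.6 / length(shared), length(shared)),
           rep(0.2 * (1 + sep) / length(own), length(own)),
           rep(0.2 * (1 - sep) / length(other), length(other)))
    setNames(w / sum(w), c(shared, own, other))
  }
  p_pos <- word_probs(posw, negw)
  p_neg <- word_probs(negw, posw)

  with_private_seed(design$seed, {
    n <- design$n_positive + design$n_negative
    label <- c(rep("positive", design$n_positive),
               rep("negative", design$n_negative))
    abstract <- character(n)
    mesh <- character(n)
    for (i in seq_len(n)) {
      p <- if (label[i] == "positive") p_pos else p_neg
      len <- max(20, rpois(1, design$abstract_length))
      abstract[i] <- paste(sample(names(p), len, replace = TRUE, prob = p),
                           collapse = " ")
      own <- if (label[i] == "positive") mesh_pos else mesh_neg
      other <- if (label[i] == "positive") mesh_neg else mesh_pos
      terms <- c(own[runif(length(own)) < 0.35 + 0.45 * sep],
                 other[runif(length(other)) < 0.35 * (1 - sep)],
                 mesh_shared[runif(length(mesh_shared)) < 0.5])
      mesh[i] <- paste(terms, collapse = "|")
    }
    data.frame(doc_id = sprintf("doc-%04d", seq_len(n)), label = label,
               abstract = abstract, mesh_terms = mesh,
               stringsAsFactors = FALSE)
  })
}
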
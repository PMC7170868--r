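# Unit normalization: as-reported concentrations/times/doses to the database's
# storage units (ug/mL or ug/m^3 for breath, hours, mg/kg bodyweight), plus
# species-specific age-category assignment.

#' Storage rounding
#'
#' Rounds to the database's storage precision (at most 5 digits after the
#' decimal point), half away from zero, applied once at storage.
#'
#' @param x numeric vector.
#' @param digits number of decimal places kept (default 5).
#' @return Rounded numeric vector.
#' @export
round5 <- function(x, digits = 5) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical lower-case ASCII unit spelling: micro signs to "u", whitespace
# stripped, molar shorthands expanded. Radiolabel units ("ugEq/mL" etc.) are
# detected and stripped of the "eq" marker; conversion arithmetic is shared
# with the plain mass unit.
parse_conc_unit <- function(unit) {
  u <- tolower(trimws(unit))
  u <- gsub("µ|μ", "u", u)
  u <- gsub("[[:space:]]", "", u)
  radiolabel <- grepl("eq", u, fixed = TRUE)
  u <- sub("eq", "", u, fixed = TRUE)
  u <- sub("^mcg", "ug", u)
  u <- gsub("m3$", "m^3", u)
  u <- switch(u, um = "umol/l", nm = "nmol/l", mm = "mmol/l", m = "mol/l",
              pm = "pmol/l", u)
  list(canonical = u, radiolabel = radiolabel)
}

#' Default concentration unit registry
#'
#' Loads the editable plain-text registry shipped with the package
#' (`extdata/unit_registry.csv`): one multiplicative rule per source unit with
#' the factor to ug/mL and a flag for molar units requiring a molecular
#' weight.
#'
#' @return Data frame with columns `unit`, `factor_to_ug_per_ml`, `needs_mw`.
#' @export
default_unit_registry <- function() {
  read.csv(system.file("extdata", "unit_registry.csv", package = "cvtkit"),
           stringsAsFactors = FALSE)
}

#' Normalized concentration unit implied by a medium
#'
#' Breath measurements are stored in ug/m^3; everything else (plasma, blood,
#' serum, tissues, excreta) in ug/mL, with radiolabel-derived measurements
#' labelled ugEq/mL.
#'
#' @param medium medium string.
#' @param radiolabel logical; radiolabel-derived measurement.
#' @return Unit string.
#' @export
normalized_unit_for <- function(medium, radiolabel = FALSE) {
  if (identical(tolower(medium), "breath")) return("ug/m^3")
  if (radiolabel) "ugEq/mL" else "ug/mL"
}

#' Normalize a concentration to storage units
#'
#' Converts a reported concentration to ug/mL (ug/m^3 for breath) via the unit
#' registry, applying the molecular weight for molar source units, and rounds
#' to the 5-decimal storage precision.
#'
#' @param value non-negative concentration value(s).
#' @param unit reported unit string.
#' @param medium medium the analyte was measured in (selects the target unit).
#' @param molecular_weight analyte molecular weight in g/mol; required for
#'   molar units.
#' @param registry unit registry (see [default_unit_registry()]).
#' @return Converted value(s), rounded to at most 5 decimals.
#' @export
normalize_concentration <- function(value, unit, medium = "plasma",
                                    molecular_weight = NULL,
                                    registry = default_unit_registry()) {
  stopifnot(all(is.na(value) | value >= 0))
  pu <- parse_conc_unit(unit)
  hit <- match(pu$canonical, registry$unit)
  if (is.na(hit))
    cvt_error("cvt_unit_error", sprintf("unrecognized unit '%s'", unit))
  fac <- registry$factor_to_ug_per_ml[hit]
  if (registry$needs_mw[hit]) {
    if (is.null(molecular_weight) || is.na(molecular_weight))
      cvt_error("cvt_missing_mw_error",
                sprintf("molar unit '%s' requires a molecular weight", unit))
    fac <- fac * molecular_weight
  }
  out <- value * fac  # value now in ug/mL
  if (identical(tolower(medium), "breath")) out <- out * 1e6  # 1 mL = 1e-6 m^3
  round5(out)
}

time_unit_factors <- c(s = 1 / 3600, sec = 1 / 3600, second = 1 / 3600,
                       seconds = 1 / 3600, min = 1 / 60, minute = 1 / 60,
                       minutes = 1 / 60, h = 1, hr = 1, hour = 1, hours = 1,
                       d = 24, day = 24, days = 24, wk = 168, week = 168,
                       weeks = 168)

#' Normalize a time to hours
#'
#' @param value non-negative time value(s).
#' @param unit one of s/min/h/day/week (common spellings accepted).
#' @return Time in hours, rounded to at most 5 decimals.
#' @export
normalize_time <- function(value, unit) {
  stopifnot(all(is.na(value) | value >= 0))
  u <- tolower(trimws(unit))
  if (!u %in% names(time_unit_factors))
    cvt_error("cvt_unit_error", sprintf("unrecognized time unit '%s'", unit))
  round5(value * time_unit_factors[[u]])
}

#' Normalize a dose to mg per kg bodyweight
#'
#' Doses already expressed per kg bodyweight pass through (rescaled to mg/kg).
#' Absolute-mass doses are divided by the subject's measured mass when
#' reported, otherwise by the average mass for all subjects of that type; the
#' provenance of the divisor is returned alongside.
#'
#' @param dose_value positive dose value.
#' @param dose_unit reported unit (mg/kg, ug/kg, g/kg, mg, ug, g).
#' @param subject_mass_kg measured subject mass, kg (optional).
#' @param cohort_average_mass_kg average mass for subjects of that type, kg
#'   (optional fallback).
#' @return List with `value` (mg/kg, at most 5 decimals) and `provenance`
#'   (`"per_kg_reported"`, `"subject_mass"` or `"cohort_average_mass"`).
#' @export
normalize_dose <- function(dose_value, dose_unit, subject_mass_kg = NULL,
                           cohort_average_mass_kg = NULL) {
  stopifnot(dose_value > 0)
  u <- gsub("[[:space:]]", "", tolower(dose_unit))
  u <- gsub("µ|μ", "u", u)
  u <- sub("/kgbw$|/kgbodyweight$", "/kg", u)
  per_kg <- c("mg/kg" = 1, "ug/kg" = 1e-3, "g/kg" = 1e3)
  absolute <- c(mg = 1, ug = 1e-3, g = 1e3)
  if (u %in% names(per_kg))
    return(list(value = round5(dose_value * per_kg[[u]]),
                provenance = "per_kg_reported"))
  if (!u %in% names(absolute))
    cvt_error("cvt_unit_error", sprintf("unrecognized dose unit '%s'",
                                        dose_unit))
  mg <- dose_value * absolute[[u]]
  if (!is.null(subject_mass_kg) && !is.na(subject_mass_kg))
    return(list(value = round5(mg / subject_mass_kg),
                provenance = "subject_mass"))
  if (!is.null(cohort_average_mass_kg) && !is.na(cohort_average_mass_kg))
    return(list(value = round5(mg / cohort_average_mass_kg),
                provenance = "cohort_average_mass"))
  cvt_error("cvt_missing_mass_error",
            "absolute-mass dose with no subject or cohort-average mass")
}

#' Default species age-category thresholds
#'
#' Loads the species-specific lower age thresholds for the categories infant,
#' child, adolescent, young_adult, adult and aged (per-species units: months
#' for dog and nonhuman primate, years for human, weeks for mouse and rat),
#' based on weaning age, reproductive potential and skeletal growth.
#'
#' @return Data frame with columns `species`, `unit` and the six thresholds.
#' @export
default_age_thresholds <- function() {
  read.csv(system.file("extdata", "age_thresholds.csv", package = "cvtkit"),
           stringsAsFactors = FALSE)
}

# Age/time-span conversion through days; calendar conventions documented in
# the vignette (month = 365.25/12 days).
age_unit_days <- c(day = 1, days = 1, week = 7, weeks = 7, wk = 7,
                   month = 365.25 / 12, months = 365.25 / 12,
                   year = 365.25, years = 365.25, yr = 365.25)

#' Assign a species-specific age category
#'
#' Converts the reported age to the species' threshold unit and returns the
#' highest category whose lower threshold is <= age (thresholds are inclusive
#' lower bounds); ages below the infant threshold are "neonate". Unknown
#' species yield "unknown" with a warning, never an error.
#'
#' @param species species name (matching the threshold table).
#' @param age_value non-negative age.
#' @param age_unit day/week/month/year.
#' @param table threshold table (see [default_age_thresholds()]).
#' @return One of neonate, infant, child, adolescent, young_adult, adult,
#'   aged, unknown.
#' @export
assign_age_category <- function(species, age_value, age_unit,
                                table = default_age_thresholds()) {
  stopifnot(age_value >= 0)
  row <- table[table$species == tolower(species), , drop = FALSE]
  if (nrow(row) == 0) {
    cvt_warning("cvt_unknown_species_warning",
                sprintf("no age thresholds for species '%s'", species))
    return("unknown")
  }
  au <- tolower(trimws(age_unit))
  if (!au %in% names(age_unit_days))
    cvt_error("cvt_unit_error", sprintf("unrecognized age unit '%s'",
                                        age_unit))
  age <- age_value * age_unit_days[[au]] / age_unit_days[[row$unit]]
  cats <- c("infant", "child", "adolescent", "young_adult", "adult", "aged")
  thr <- as.numeric(row[1, cats])
  hit <- which(age >= thr - 1e-9)
  if (length(hit) == 0) "neonate" else cats[max(hit)]
}

#' Normalize a series and its concentration-time values
#'
#' Fills the `*_normalized` fields of a series row and its values from the
#' `*_original` fields, leaving originals untouched: concentrations via
#' [normalize_concentration()] (target unit chosen by medium, radiolabel units
#' kept distinct as ugEq/mL), times via [normalize_time()], and the subject
#' age category via [assign_age_category()]. Idempotent; values whose
#' normalized fields are already filled and whose originals are absent are
#' left as they are.
#'
#' @param series one-row data frame following the series schema.
#' @param values data frame of this series' rows from `conc_time_values`.
#' @param species species of the parent study (for the age category).
#' @param molecular_weight analyte molecular weight (g/mol), for molar units.
#' @param registry unit registry.
#' @param age_table age threshold table.
#' @return List with elements `series` and `values`, normalized.
#' @export
normalize_series <- function(series, values, species = NULL,
                             molecular_weight = NULL,
                             registry = default_unit_registry(),
                             age_table = default_age_thresholds()) {
  stopifnot(nrow(series) == 1)
  sid <- series$series_id
  ctx <- function(e, what) cvt_error(
    "cvt_unit_error",
    sprintf("series '%s': cannot normalize %s: %s", sid, what,
            conditionMessage(e)))

  if (!is.na(series$conc_units_original)) {
    pu <- parse_conc_unit(series$conc_units_original)
    target <- normalized_unit_for(series$medium, pu$radiolabel)
    conc <- tryCatch(
      normalize_concentration(values$conc_original,
                              series$conc_units_original, series$medium,
                              molecular_weight, registry),
      cvt_error = function(e) ctx(e, sprintf(
        "concentrations (values %s)", paste(values$value_id, collapse = ","))))
    lower <- upper <- rep(NA_real_, nrow(values))
    if (any(!is.na(values$conc_lower_bound)))
      lower <- normalize_concentration(values$conc_lower_bound,
                                       series$conc_units_original,
                                       series$medium, molecular_weight,
                                       registry)
    if (any(!is.na(values$conc_upper_bound)))
      upper <- normalize_concentration(values$conc_upper_bound,
                                       series$conc_units_original,
                                       series$medium, molecular_weight,
                                       registry)
    values$conc_normalized <- conc
    if (any(!is.na(lower))) values$conc_lower_bound <- lower
    if (any(!is.na(upper))) values$conc_upper_bound <- upper
    series$conc_units_normalized <- target
  }
  if (!is.na(series$time_units_original)) {
    values$time_hr <- tryCatch(
      normalize_time(values$time_original, series$time_units_original),
      cvt_error = function(e) ctx(e, "times"))
  }
  if (!is.null(species) && !is.na(series$subject_age_value) &&
      !is.na(series$subject_age_units)) {
    series$subject_age_category <-
      assign_age_category(species, series$subject_age_value,
                          series$subject_age_units, age_table)
  }
  list(series = series, values = values)
}

#' Normalize every series of a database
#'
#' Applies [normalize_series()] across a whole [cvt_database()], looking up
#' each series' study for the species. Originals are left untouched.
#'
#' @param db a [cvt_database()].
#' @param molecular_weights optional named vector, analyte -> g/mol.
#' @param registry unit registry.
#' @param age_table age threshold table.
#' @return The normalized database.
#' @export
normalize_database <- function(db, molecular_weights = NULL,
                               registry = default_unit_registry(),
                               age_table = default_age_thresholds()) {
  stopifnot(inherits(db, "cvt_database"))
  for (i in seq_len(nrow(db$series))) {
    srow <- db$series[i, , drop = FALSE]
    vidx <- which(db$conc_time_values$series_id == srow$series_id)
    study <- db$studies[db$studies$study_id == srow$study_id, , drop = FALSE]
    species <- if (nrow(study)) study$species[1] else NULL
    mw <- if (!is.null(molecular_weights) &&
              srow$analyte %in% names(molecular_weights))
      molecular_weights[[srow$analyte]] else NULL
    res <- normalize_series(srow, db$conc_time_values[vidx, , drop = FALSE],
                            species, mw, registry, age_table)
    db$series[i, ] <- res$series
    db$conc_time_values[vidx, ] <- res$values
  }
  db
}
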
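# In-memory data model mirroring the CvT database schema: five linked tables
# (documents, studies, series, conc_time_values, tk_parameters) with a
# CSV-per-table interchange format and structural validation.

cvt_table_names <- c("documents", "studies", "series", "conc_time_values",
                     "tk_parameters")

# Canonical column order per table. Unknown columns are preserved after these.
cvt_table_columns <- list(
  documents = c("document_id", "citation_text", "pmid", "extracted_flag",
                "candidate_chemical_names", "environmental_relevance_flag",
                "toxcast_flag"),
  studies = c("study_id", "document_id", "test_substance",
              "substance_identifier", "species", "strain_or_type", "sex",
              "administration_route", "dose_value_original",
              "dose_units_original", "dose_value_normalized",
              "dose_provenance", "dose_vehicle", "dose_volume",
              "exposure_duration_h", "n_doses", "dose_spacing_h",
              "n_subjects_per_group", "n_groups", "fasting_status",
              "curation_notes"),
  series = c("series_id", "study_id", "analyte", "medium",
             "conc_units_original", "conc_units_normalized",
             "time_units_original", "subject_age_value", "subject_age_units",
             "subject_age_category", "subject_height_cm", "subject_weight_kg",
             "loq", "lod", "analysis_method", "figure_or_table_name"),
  conc_time_values = c("value_id", "series_id", "time_original", "time_hr",
                       "conc_original", "conc_normalized", "conc_lower_bound",
                       "conc_upper_bound", "below_loq_flag"),
  tk_parameters = c("record_id", "study_or_group_reference", "model",
                    "parameter_name", "value", "units",
                    "calculated_with_invivopkfit")
)

cvt_column_types <- c(
  document_id = "character", citation_text = "character", pmid = "character",
  extracted_flag = "logical", candidate_chemical_names = "character",
  environmental_relevance_flag = "logical", toxcast_flag = "logical",
  study_id = "character", test_substance = "character",
  substance_identifier = "character", species = "character",
  strain_or_type = "character", sex = "character",
  administration_route = "character", dose_value_original = "numeric",
  dose_units_original = "character", dose_value_normalized = "numeric",
  dose_provenance = "character", dose_vehicle = "character",
  dose_volume = "numeric", exposure_duration_h = "numeric",
  n_doses = "numeric", dose_spacing_h = "numeric",
  n_subjects_per_group = "numeric", n_groups = "numeric",
  fasting_status = "character", curation_notes = "character",
  series_id = "character", analyte = "character", medium = "character",
  conc_units_original = "character", conc_units_normalized = "character",
  time_units_original = "character", subject_age_value = "numeric",
  subject_age_units = "character", subject_age_category = "character",
  subject_height_cm = "numeric", subject_weight_kg = "numeric",
  loq = "numeric", lod = "numeric", analysis_method = "character",
  figure_or_table_name = "character",
  value_id = "character", time_original = "numeric", time_hr = "numeric",
  conc_original = "numeric", conc_normalized = "numeric",
  conc_lower_bound = "numeric", conc_upper_bound = "numeric",
  below_loq_flag = "logical",
  record_id = "character", study_or_group_reference = "character",
  model = "character", parameter_name = "character", value = "numeric",
  units = "character", calculated_with_invivopkfit = "logical"
)

cvt_id_column <- c(documents = "document_id", studies = "study_id",
                   series = "series_id", conc_time_values = "value_id",
                   tk_parameters = "record_id")

# Controlled vocabularies. "other:<text>" is accepted for species and route.
cvt_species_levels <- c("human", "rat", "mouse", "dog", "nonhuman primate")
cvt_sex_levels <- c("M", "F", "mixed", "unknown")
cvt_route_levels <- c("intravenous", "oral", "gavage", "inhalation", "dermal",
                      "subcutaneous", "intraperitoneal")
cvt_fasting_levels <- c("fasted", "fed", "unknown")
cvt_age_categories <- c("neonate", "infant", "child", "adolescent",
                        "young_adult", "adult", "aged", "unknown")
cvt_normalized_conc_units <- c("ug/mL", "ugEq/mL", "ug/m^3")
cvt_model_levels <- c("one_compartment", "two_compartment", "literature")
cvt_parameter_names <- c("Vd", "V1", "kelim", "k12", "k21", "kabsorb", "Fbio",
                         "halflife", "Cmax", "tmax", "CLtot", "AUCinf",
                         "Km", "Vmax")

empty_cvt_table <- function(table) {
  cols <- cvt_table_columns[[table]]
  out <- lapply(cols, function(cl) vector(cvt_column_types[[cl]], 0L))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

coerce_cvt_table <- function(df, table) {
  cols <- cvt_table_columns[[table]]
  if (is.null(df)) return(empty_cvt_table(table))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cl in cols) {
    if (!cl %in% names(df)) {
      df[[cl]] <- vector(cvt_column_types[[cl]], nrow(df))
      df[[cl]][] <- NA
    } else {
      df[[cl]] <- switch(cvt_column_types[[cl]],
                         character = as.character(df[[cl]]),
                         numeric = as.numeric(df[[cl]]),
                         logical = as.logical(df[[cl]]))
    }
  }
  extra <- sort(setdiff(names(df), cols))
  df[, c(cols, extra), drop = FALSE]
}

#' Construct a CvT database object
#'
#' Assembles the five linked tables of the CvT data model (documents, studies,
#' series, concentration-time values and toxicokinetic parameter records) into
#' a single object. Missing columns are added (filled with `NA`) and columns
#' are coerced to their schema types; columns not in the schema are preserved
#' as opaque annotations. No integrity checking is performed here; use
#' [validate_database()].
#'
#' @param documents,studies,series,conc_time_values,tk_parameters data frames
#'   (or `NULL` for an empty table) following the schema column names.
#' @return An object of class `cvt_database`: a list of the five tables.
#' @seealso [read_database()], [write_database()], [validate_database()]
#' @export
cvt_database <- function(documents = NULL, studies = NULL, series = NULL,
                         conc_time_values = NULL, tk_parameters = NULL) {
  db <- list(
    documents = coerce_cvt_table(documents, "documents"),
    studies = coerce_cvt_table(studies, "studies"),
    series = coerce_cvt_table(series, "series"),
    conc_time_values = coerce_cvt_table(conc_time_values, "conc_time_values"),
    tk_parameters = coerce_cvt_table(tk_parameters, "tk_parameters")
  )
  class(db) <- "cvt_database"
  db
}

#' @export
print.cvt_database <- function(x, ...) {
  cat("<cvt_database>\n")
  for (tb in cvt_table_names)
    cat(sprintf("  %-17s %d rows\n", tb, nrow(x[[tb]])))
  invisible(x)
}

check_referential_integrity <- function(db, stop_on_error = TRUE) {
  bad <- character(0)
  fk <- list(
    list(child = "studies", col = "document_id", parent = "documents"),
    list(child = "series", col = "study_id", parent = "studies"),
    list(child = "conc_time_values", col = "series_id", parent = "series")
  )
  for (f in fk) {
    child <- db[[f$child]]
    parent_ids <- db[[f$parent]][[cvt_id_column[[f$parent]]]]
    missing <- !is.na(child[[f$col]]) & !(child[[f$col]] %in% parent_ids)
    if (any(missing)) {
      rows <- child[[cvt_id_column[[f$child]]]][missing]
      bad <- c(bad, sprintf("%s row '%s': %s '%s' not found in %s",
                            f$child, rows, f$col, child[[f$col]][missing],
                            f$parent))
    }
  }
  if (length(bad) && stop_on_error)
    cvt_error("cvt_integrity_error",
              paste0("dangling foreign key(s):\n  ",
                     paste(bad, collapse = "\n  ")))
  bad
}

#' Read a CvT database from a directory of per-table CSV files
#'
#' Reads the CSV-per-table interchange layout (`documents.csv`, `studies.csv`,
#' `series.csv`, `conc_time_values.csv`, `tk_parameters.csv`; UTF-8, comma
#' separated, header row) written by [write_database()]. Empty cells are read
#' as `NA`. Unknown columns are kept.
#'
#' @param path directory containing the five files.
#' @return A validated [cvt_database()] passing referential integrity.
#' @export
read_database <- function(path) {
  if (!dir.exists(path))
    cvt_error("cvt_format_error", sprintf("directory '%s' does not exist", path))
  tables <- list()
  for (tb in cvt_table_names) {
    f <- file.path(path, paste0(tb, ".csv"))
    if (!file.exists(f))
      cvt_error("cvt_format_error", sprintf("required file '%s' is missing", f))
    df <- read.csv(f, stringsAsFactors = FALSE, na.strings = "",
                   colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8")
    tables[[tb]] <- df
  }
  db <- cvt_database(tables$documents, tables$studies, tables$series,
                     tables$conc_time_values, tables$tk_parameters)
  check_referential_integrity(db)
  db
}

#' Write a CvT database to a directory of per-table CSV files
#'
#' Emits the layout readable by [read_database()]. Output is deterministic:
#' fixed column order (schema columns first, then extras alphabetically) and
#' rows sorted by their id column, so two writes of the same database are
#' byte-identical.
#'
#' @param db a [cvt_database()].
#' @param path output directory (created if needed).
#' @return `db`, invisibly.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "cvt_database"))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    cvt_error("cvt_io_error", sprintf("cannot create directory '%s'", path))
  for (tb in cvt_table_names) {
    df <- db[[tb]]
    if (nrow(df) > 0)
      df <- df[order(df[[cvt_id_column[[tb]]]], method = "radix"), ,
               drop = FALSE]
    f <- file.path(path, paste0(tb, ".csv"))
    ok <- tryCatch({
      write.csv(df, f, row.names = FALSE, na = "", fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) cvt_error("cvt_io_error", sprintf("cannot write '%s'", f))
  }
  invisible(db)
}

issue_row <- function(severity, entity, id, field, message) {
  data.frame(severity = severity, entity = entity, id = as.character(id),
             field = field, message = message, stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(severity = character(0), entity = character(0),
             id = character(0), field = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

check_enum <- function(df, entity, field, levels, allow_other = FALSE,
                       allow_na = TRUE) {
  x <- df[[field]]
  ok <- x %in% levels
  if (allow_other) ok <- ok | grepl("^other:", x)
  if (allow_na) ok <- ok | is.na(x)
  if (!any(!ok)) return(no_issues())
  ids <- df[[cvt_id_column[[entity]]]][!ok]
  issue_row("error", entity, ids, field,
            sprintf("value '%s' not in permitted set", x[!ok]))
}

# TRUE where x carries more than `digits` decimal places (within float slop).
exceeds_decimals <- function(x, digits = 5) {
  !is.na(x) & abs(x - round(x, digits)) > 1e-9 * pmax(1, abs(x))
}

#' Validate a CvT database against the schema invariants
#'
#' Checks id uniqueness, referential integrity, controlled vocabularies,
#' positivity and range constraints, bound ordering, the normalized
#' concentration unit whitelist (`ug/mL`, `ugEq/mL`, `ug/m^3`) and the
#' 5-decimal storage precision of normalized values. Reports issues rather
#' than throwing.
#'
#' @param db a [cvt_database()].
#' @return A data frame of issues (`severity`, `entity`, `id`, `field`,
#'   `message`), ordered by entity then id; zero rows when the database is
#'   clean.
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "cvt_database"))
  iss <- list()
  add <- function(x) if (nrow(x)) iss[[length(iss) + 1L]] <<- x

  # id uniqueness + FK integrity
  for (tb in cvt_table_names) {
    idc <- cvt_id_column[[tb]]
    ids <- db[[tb]][[idc]]
    if (anyNA(ids))
      add(issue_row("error", tb, "<NA>", idc, "missing id"))
    dup <- unique(ids[duplicated(ids) & !is.na(ids)])
    if (length(dup))
      add(issue_row("error", tb, dup, idc, "duplicate id"))
  }
  for (msg in check_referential_integrity(db, stop_on_error = FALSE)) {
    id <- sub("^[a-z_]+ row '([^']*)'.*", "\\1", msg)
    entity <- sub("^([a-z_]+) row.*", "\\1", msg)
    add(issue_row("error", entity, id, "foreign_key", msg))
  }

  docs <- db$documents
  for (fl in c("extracted_flag", "environmental_relevance_flag",
               "toxcast_flag")) {
    bad <- is.na(docs[[fl]])
    if (any(bad))
      add(issue_row("error", "documents", docs$document_id[bad], fl,
                    "flag must be TRUE or FALSE"))
  }

  st <- db$studies
  add(check_enum(st, "studies", "species", cvt_species_levels,
                 allow_other = TRUE))
  add(check_enum(st, "studies", "sex", cvt_sex_levels))
  add(check_enum(st, "studies", "administration_route", cvt_route_levels,
                 allow_other = TRUE))
  add(check_enum(st, "studies", "fasting_status", cvt_fasting_levels))
  bad <- !is.na(st$dose_value_normalized) & st$dose_value_normalized <= 0
  if (any(bad))
    add(issue_row("error", "studies", st$study_id[bad],
                  "dose_value_normalized", "must be > 0 when present"))
  bad <- !is.na(st$n_doses) & st$n_doses < 1
  if (any(bad))
    add(issue_row("error", "studies", st$study_id[bad], "n_doses",
                  "must be >= 1"))

  se <- db$series
  bad <- !is.na(se$conc_units_normalized) &
    !(se$conc_units_normalized %in% cvt_normalized_conc_units)
  if (any(bad))
    add(issue_row("error", "series", se$series_id[bad],
                  "conc_units_normalized",
                  sprintf("'%s' is not a permitted normalized unit",
                          se$conc_units_normalized[bad])))
  add(check_enum(se, "series", "subject_age_category", cvt_age_categories))

  cv <- db$conc_time_values
  bad <- !is.na(cv$time_hr) & cv$time_hr < 0
  if (any(bad))
    add(issue_row("error", "conc_time_values", cv$value_id[bad], "time_hr",
                  "must be >= 0"))
  bad <- !is.na(cv$conc_normalized) & cv$conc_normalized < 0
  if (any(bad))
    add(issue_row("error", "conc_time_values", cv$value_id[bad],
                  "conc_normalized", "must be >= 0"))
  bad <- !is.na(cv$conc_lower_bound) & !is.na(cv$conc_normalized) &
    cv$conc_lower_bound > cv$conc_normalized
  if (any(bad))
    add(issue_row("error", "conc_time_values", cv$value_id[bad],
                  "conc_lower_bound", "exceeds conc_normalized"))
  bad <- !is.na(cv$conc_upper_bound) & !is.na(cv$conc_normalized) &
    cv$conc_upper_bound < cv$conc_normalized
  if (any(bad))
    add(issue_row("error", "conc_time_values", cv$value_id[bad],
                  "conc_upper_bound", "below conc_normalized"))
  bad <- is.na(cv$below_loq_flag) & nrow(cv) > 0
  if (any(bad))
    add(issue_row("error", "conc_time_values", cv$value_id[bad],
                  "below_loq_flag", "flag must be TRUE or FALSE"))
  for (fl in c("time_hr", "conc_normalized")) {
    bad <- exceeds_decimals(cv[[fl]])
    if (any(bad))
      add(issue_row("error", "conc_time_values", cv$value_id[bad], fl,
                    "stored with more than 5 decimal places"))
  }

  tk <- db$tk_parameters
  add(check_enum(tk, "tk_parameters", "model", cvt_model_levels,
                 allow_na = FALSE))
  add(check_enum(tk, "tk_parameters", "parameter_name", cvt_parameter_names,
                 allow_na = FALSE))
  positive_pars <- c("Vd", "V1", "kelim", "k12", "k21", "kabsorb", "halflife",
                     "CLtot", "Cmax", "AUCinf", "Vmax", "Km")
  bad <- tk$parameter_name %in% positive_pars & !is.na(tk$value) &
    tk$value <= 0
  if (any(bad))
    add(issue_row("error", "tk_parameters", tk$record_id[bad], "value",
                  "rate constants and volumes must be strictly positive"))
  bad <- tk$parameter_name == "Fbio" & !is.na(tk$value) &
    (tk$value < 0 | tk$value > 1)
  if (any(bad))
    add(issue_row("error", "tk_parameters", tk$record_id[bad], "value",
                  "Fbio must lie in [0, 1]"))
  bad <- is.na(tk$calculated_with_invivopkfit) & nrow(tk) > 0
  if (any(bad))
    add(issue_row("error", "tk_parameters", tk$record_id[bad],
                  "calculated_with_invivopkfit", "flag must be TRUE or FALSE"))

  out <- if (length(iss)) do.call(rbind, iss) else no_issues()
  out[order(out$entity, out$id, out$field, method = "radix"), ,
      drop = FALSE]
}

#' Mean concentration-time table of a study's plasma-like series
#'
#' Collapses all series of a study measured in a plasma-like medium to a
#' single mean curve: times are rounded to the 5-decimal storage precision and
#' matched by exact equality (union grid, no interpolation); at each time the
#' arithmetic mean of `conc_normalized` over the series observed at that time
#' is reported together with the number of contributing series.
#'
#' @param db a [cvt_database()].
#' @param study_id study to collapse.
#' @param media media treated as plasma-like (default plasma/blood/serum).
#' @param analyte optional analyte filter (e.g. the parent compound).
#' @return A data frame with columns `time_hr`, `mean_conc`, `n_series`,
#'   `n_below_loq`, sorted by time. Zero rows when the study has no
#'   qualifying series (an empty result, not an error).
#' @export
study_mean_series <- function(db, study_id,
                              media = c("plasma", "blood", "serum"),
                              analyte = NULL) {
  stopifnot(inherits(db, "cvt_database"))
  se <- db$series
  keep <- se$study_id == study_id & se$medium %in% media
  if (!is.null(analyte)) keep <- keep & se$analyte %in% analyte
  sids <- se$series_id[keep & !is.na(se$series_id)]
  cv <- db$conc_time_values
  cv <- cv[cv$series_id %in% sids & !is.na(cv$time_hr) &
             !is.na(cv$conc_normalized), , drop = FALSE]
  if (nrow(cv) == 0)
    return(data.frame(time_hr = numeric(0), mean_conc = numeric(0),
                      n_series = integer(0), n_below_loq = integer(0)))
  t5 <- round5(cv$time_hr)
  out <- do.call(rbind, lapply(split(seq_len(nrow(cv)), t5), function(ix) {
    data.frame(time_hr = t5[ix[1]],
               mean_conc = mean(cv$conc_normalized[ix]),
               n_series = length(unique(cv$series_id[ix])),
               n_below_loq = sum(cv$below_loq_flag[ix], na.rm = TRUE))
  }))
  out <- out[order(out$time_hr), , drop = FALSE]
  rownames(out) <- NULL
  out
}
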
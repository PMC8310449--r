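# Monitored objects: prescription items, patient profile, medical record.
# Records travel as JSON Lines, one record per line.

#' Construct a prescription item
#'
#' @param drug_ref Drug name or entity id.
#' @param single_dose Positive amount per administration (may be `NA` for
#'   items recovered from free text, where the dose is unknown).
#' @param times_per_day Positive integer administrations per day.
#' @param unit Unit string (default "g").
#' @return A list of class `cpm_item`; `daily_dose = single_dose *
#'   times_per_day`.
#' @export
prescription_item <- function(drug_ref, single_dose, times_per_day,
                              unit = "g") {
  if (!is.na(single_dose) && single_dose <= 0)
    stop("single_dose must be positive")
  if (!is.na(times_per_day) && (times_per_day <= 0 ||
                                times_per_day != round(times_per_day)))
    stop("times_per_day must be a positive integer")
  structure(list(drug_ref = as.character(drug_ref),
                 single_dose = as.numeric(single_dose),
                 times_per_day = as.integer(times_per_day),
                 unit = as.character(unit)),
            class = "cpm_item")
}

daily_dose <- function(item) item$single_dose * item$times_per_day

#' Construct a patient profile
#'
#' @param age_years Non-negative age in years.
#' @param pregnant,lactating,hepatic_impairment,renal_impairment Booleans.
#' @return A list of class `cpm_patient`.
#' @export
patient_profile <- function(age_years, pregnant = FALSE, lactating = FALSE,
                            hepatic_impairment = FALSE,
                            renal_impairment = FALSE) {
  if (is.na(age_years) || age_years < 0) stop("age_years must be non-negative")
  structure(list(age_years = as.numeric(age_years),
                 pregnant = isTRUE(pregnant), lactating = isTRUE(lactating),
                 hepatic_impairment = isTRUE(hepatic_impairment),
                 renal_impairment = isTRUE(renal_impairment)),
            class = "cpm_patient")
}

#' Population groups applicable to a patient
#'
#' Age thresholds follow the package convention (configurable): child is
#' age < 14 years, elderly is age >= 65 years.
#'
#' @param patient A `cpm_patient`.
#' @param child_max_age Exclusive upper age for `child` (default 14).
#' @param elderly_min_age Inclusive lower age for `elderly` (default 65).
#' @return Character vector of population-group ids.
#' @export
population_groups <- function(patient, child_max_age = 14,
                              elderly_min_age = 65) {
  g <- character()
  if (patient$age_years < child_max_age) g <- c(g, "child")
  if (patient$age_years >= elderly_min_age) g <- c(g, "elderly")
  if (patient$pregnant) g <- c(g, "pregnant")
  if (patient$lactating) g <- c(g, "lactating")
  if (patient$hepatic_impairment) g <- c(g, "hepatic_impairment")
  if (patient$renal_impairment) g <- c(g, "renal_impairment")
  g
}

#' Construct a medical record
#'
#' The monitored object: structured prescription items, diagnoses,
#' syndrome, symptoms and patient profile, and/or the two free-text
#' sections that hospital records carry (course record and discharge
#' summary). At least one of the structured item list and the text
#' sections must be present.
#'
#' @param record_id Identifier string.
#' @param items List of [prescription_item()]s.
#' @param diagnoses Character vector of disease names/ids (may be empty).
#' @param syndrome Syndrome name/id or `NULL`.
#' @param symptoms Character vector of symptom names/ids (may be empty).
#' @param patient A [patient_profile()].
#' @param course_record_text,discharge_summary_text Free-text sections.
#' @return A list of class `cpm_record`.
#' @export
medical_record <- function(record_id, items = list(),
                           diagnoses = character(), syndrome = NULL,
                           symptoms = character(),
                           patient = patient_profile(40),
                           course_record_text = "",
                           discharge_summary_text = "") {
  has_text <- nzchar(course_record_text) || nzchar(discharge_summary_text)
  if (!length(items) && !has_text)
    stop("record must carry prescription items or text sections")
  structure(list(record_id = as.character(record_id), items = items,
                 diagnoses = as.character(diagnoses),
                 syndrome = if (is.null(syndrome)) NULL else as.character(syndrome),
                 symptoms = as.character(symptoms), patient = patient,
                 course_record_text = course_record_text,
                 discharge_summary_text = discharge_summary_text),
            class = "cpm_record")
}

record_to_list <- function(r) {
  list(record_id = r$record_id,
       items = lapply(r$items, function(it)
         list(drug_ref = it$drug_ref, single_dose = it$single_dose,
              times_per_day = it$times_per_day, unit = it$unit)),
       diagnoses = as.list(r$diagnoses),
       syndrome = r$syndrome,
       symptoms = as.list(r$symptoms),
       patient = unclass(r$patient),
       course_record_text = r$course_record_text,
       discharge_summary_text = r$discharge_summary_text)
}

record_from_list <- function(x) {
  pt <- x$patient
  medical_record(
    record_id = x$record_id,
    items = lapply(x$items, function(it)
      prescription_item(it$drug_ref,
                        if (is.null(it$single_dose)) NA else it$single_dose,
                        if (is.null(it$times_per_day)) NA else it$times_per_day,
                        if (is.null(it$unit)) "g" else it$unit)),
    diagnoses = as.character(unlist(x$diagnoses)),
    syndrome = x$syndrome,
    symptoms = as.character(unlist(x$symptoms)),
    patient = patient_profile(pt$age_years, isTRUE(pt$pregnant),
                              isTRUE(pt$lactating),
                              isTRUE(pt$hepatic_impairment),
                              isTRUE(pt$renal_impairment)),
    course_record_text = if (is.null(x$course_record_text)) "" else x$course_record_text,
    discharge_summary_text = if (is.null(x$discharge_summary_text)) "" else x$discharge_summary_text)
}

#' Read / write medical records as JSON Lines
#'
#' One record object per line, UTF-8.
#'
#' @param path File path.
#' @return `read_records` returns a list of `cpm_record`.
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("malformed record at line %d: %s", i,
                                 conditionMessage(e)), call. = FALSE))
    record_from_list(x)
  })
}

#' @rdname read_records
#' @param records List of `cpm_record`.
#' @export
write_records <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records)
    writeLines(jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE,
                                null = "null", na = "null", digits = NA), con)
  invisible(path)
}

#' @export
print.cpm_record <- function(x, ...) {
  cat(sprintf("Medical record %s: %d items, %d diagnoses, %d symptoms%s\n",
              x$record_id, length(x$items), length(x$diagnoses),
              length(x$symptoms),
              if (is.null(x$syndrome)) "" else sprintf(", syndrome %s", x$syndrome)))
  invisible(x)
}
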
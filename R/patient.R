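#' Construct a patient record
#'
#' Bundles one pediatric intensive-care stay: the admission window,
#' timestamped laboratory observations (platelet count in count/mm3, INR
#' dimensionless), stay-level ICD-10-GM diagnoses, and procedure episodes
#' (currently ECMO). Stays shorter than 12 hours are rejected, mirroring the
#' study inclusion criterion, and all observation timestamps must fall
#' inside the stay.
#'
#' @param patient_id scalar identifier (coerced to character).
#' @param age_years age in years, in \[0, 18\].
#' @param admission,discharge stay boundaries; anything [parse_instant()]
#'   accepts.
#' @param observations data.frame with columns `analyte` (`"PLT"`/`"INR"`),
#'   `value` (PLT in count/mm3, INR dimensionless, both > 0), `timestamp`,
#'   and optionally `code` (LOINC; filled from `analyte` when absent).
#' @param diagnoses character vector of ICD-10-GM codes (uppercase
#'   alphanumeric with an optional dot, e.g. `"C91.0"`).
#' @param procedures data.frame with columns `procedure` (`"ECMO"`),
#'   `start`, `end`.
#' @return object of class `patient_record`.
#' @examples
#' p <- patient_record(
#'   "p1", 6, "2024-03-01 00:00", "2024-03-04 00:00",
#'   observations = data.frame(
#'     analyte = "PLT", value = 250000, timestamp = "2024-03-01 02:00"
#'   )
#' )
#' @export
patient_record <- function(patient_id, age_years, admission, discharge,
                           observations = NULL, diagnoses = character(0),
                           procedures = NULL) {
  patient_id <- as.character(patient_id)
  stopifnot(length(patient_id) == 1, nzchar(patient_id))
  age_years <- as.numeric(age_years)
  if (is.na(age_years) || age_years < 0 || age_years > 18) {
    stop("age_years must be in [0, 18], got ", age_years, call. = FALSE)
  }
  admission <- parse_instant(admission)
  discharge <- parse_instant(discharge)
  if (as.numeric(discharge) - as.numeric(admission) < hours_to_secs(12)) {
    stop("stay must last at least 12 hours (patient ", patient_id, ")", call. = FALSE)
  }

  observations <- normalize_observations(observations, patient_id)
  if (nrow(observations) > 0) {
    ts <- as.numeric(observations$timestamp)
    out <- ts < as.numeric(admission) | ts > as.numeric(discharge)
    if (any(out)) {
      stop(sum(out), " observation(s) outside [admission, discharge] for patient ",
           patient_id, call. = FALSE)
    }
    observations <- observations[order(observations$timestamp), , drop = FALSE]
    rownames(observations) <- NULL
  }

  diagnoses <- toupper(as.character(diagnoses))
  diagnoses <- diagnoses[nzchar(diagnoses)]
  bad <- !grepl("^[A-Z0-9][A-Z0-9.]*$", diagnoses)
  if (any(bad)) {
    stop("malformed ICD-10-GM code(s): ", paste(diagnoses[bad], collapse = ", "),
         call. = FALSE)
  }

  procedures <- normalize_procedures(procedures)

  structure(
    list(
      patient_id = patient_id,
      age_years = age_years,
      admission = admission,
      discharge = discharge,
      observations = observations,
      diagnoses = diagnoses,
      procedures = procedures
    ),
    class = "patient_record"
  )
}

loinc_for_analyte <- c(PLT = "777-3", INR = "6301-6")

normalize_observations <- function(observations, patient_id) {
  if (is.null(observations) || nrow(observations) == 0) {
    return(data.frame(
      analyte = character(0), value = numeric(0),
      timestamp = num_to_instant(numeric(0)), code = character(0)
    ))
  }
  stopifnot(all(c("analyte", "value", "timestamp") %in% names(observations)))
  analyte <- as.character(observations$analyte)
  if (!all(analyte %in% c("PLT", "INR"))) {
    stop("unknown analyte(s) for patient ", patient_id, ": ",
         paste(unique(setdiff(analyte, c("PLT", "INR"))), collapse = ", "),
         call. = FALSE)
  }
  value <- as.numeric(observations$value)
  if (any(is.na(value) | value <= 0)) {
    stop("lab values must be positive (patient ", patient_id, ")", call. = FALSE)
  }
  code <- if ("code" %in% names(observations)) {
    as.character(observations$code)
  } else {
    unname(loinc_for_analyte[analyte])
  }
  mismatch <- code != unname(loinc_for_analyte[analyte])
  if (any(mismatch)) {
    stop("LOINC code inconsistent with analyte (patient ", patient_id, ")",
         call. = FALSE)
  }
  data.frame(
    analyte = analyte, value = value,
    timestamp = parse_instant(observations$timestamp), code = code
  )
}

normalize_procedures <- function(procedures) {
  if (is.null(procedures) || nrow(procedures) == 0) {
    return(data.frame(
      procedure = character(0),
      start = num_to_instant(numeric(0)), end = num_to_instant(numeric(0))
    ))
  }
  stopifnot(all(c("procedure", "start", "end") %in% names(procedures)))
  procedure <- as.character(procedures$procedure)
  if (!all(procedure %in% "ECMO")) {
    stop("unsupported procedure(s): ",
         paste(unique(setdiff(procedure, "ECMO")), collapse = ", "), call. = FALSE)
  }
  start <- parse_instant(procedures$start)
  end <- parse_instant(procedures$end)
  if (any(as.numeric(end) < as.numeric(start))) {
    stop("procedure episodes must have start <= end", call. = FALSE)
  }
  data.frame(procedure = procedure, start = start, end = end)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(
    "Patient %s (%.1f y): %s to %s, %d lab obs, %d diagnoses, %d procedures\n",
    x$patient_id, x$age_years, format_instant(x$admission),
    format_instant(x$discharge), nrow(x$observations), length(x$diagnoses),
    nrow(x$procedures)
  ))
  invisible(x)
}
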
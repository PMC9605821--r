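# Flat-file canonical formats. All tables are UTF-8 CSV with a mandatory
# header row, comma separator, and ISO 8601 timestamps at minute
# resolution. They carry the same semantic payload as the clinical source
# systems: LOINC-coded laboratory observations, ICD-10-GM diagnoses, and
# procedure intervals.

analyte_for_loinc <- c("777-3" = "PLT", "6301-6" = "INR")

# count/mm3 is canonical for platelets; 10^9/L style units convert by x1000
plt_unit_factor <- c(
  "/mm3" = 1, "/ul" = 1, "1/mm3" = 1, "mm3" = 1,
  "10*9/l" = 1000, "10^9/l" = 1000, "g/l" = 1000, "gpt/l" = 1000,
  "10*3/ul" = 1000, "10^3/ul" = 1000, "1000/ul" = 1000
)
inr_units <- c("", "1", "{inr}", "inr", "ratio")

#' Read a laboratory observations table
#'
#' Expects columns `patient_id`, `loinc_code`, `value`, `unit`,
#' `timestamp`. Rows are filtered to the two supported LOINC codes
#' (`777-3` platelets, `6301-6` INR); rows with other codes are counted and
#' reported via a message and the `"n_skipped"` attribute, never silently
#' dropped. Platelet values are converted to count/mm3 (so `80` in
#' `10*9/L` becomes `80,000/mm3`); INR is dimensionless.
#'
#' @param path CSV file path.
#' @return data.frame with columns `patient_id`, `analyte`, `value`,
#'   `timestamp`, `code`; attribute `n_skipped` counts excluded rows.
#' @export
read_observations <- function(path) {
  df <- read_table_file(path, c("patient_id", "loinc_code", "value", "timestamp"))
  if (!"unit" %in% names(df)) df$unit <- ""
  known <- df$loinc_code %in% names(analyte_for_loinc)
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    message(n_skipped, " observation row(s) with unsupported LOINC code(s) skipped: ",
            paste(unique(df$loinc_code[!known]), collapse = ", "))
  }
  df <- df[known, , drop = FALSE]
  value <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(value))) {
    bad <- which(is.na(value))[1]
    stop("malformed value in ", path, " at data row ", which(known)[bad],
         call. = FALSE)
  }
  analyte <- unname(analyte_for_loinc[df$loinc_code])
  unit <- tolower(trimws(ifelse(is.na(df$unit), "", df$unit)))
  is_plt <- analyte == "PLT"
  bad_plt <- is_plt & !unit %in% names(plt_unit_factor)
  bad_inr <- !is_plt & !unit %in% inr_units
  if (any(bad_plt | bad_inr)) {
    stop("unknown unit(s) in ", path, ": ",
         paste(unique(df$unit[bad_plt | bad_inr]), collapse = ", "), call. = FALSE)
  }
  value[is_plt] <- value[is_plt] * unname(plt_unit_factor[unit[is_plt]])
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    analyte = analyte,
    value = value,
    timestamp = parse_instant(df$timestamp),
    code = df$loinc_code
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a patients table
#'
#' Columns: `patient_id`, `age_years`, `admission`, `discharge`.
#' @param path CSV file path.
#' @return data.frame with parsed instants.
#' @export
read_patients_table <- function(path) {
  df <- read_table_file(path, c("patient_id", "age_years", "admission", "discharge"))
  data.frame(
    patient_id = as.character(df$patient_id),
    age_years = as.numeric(df$age_years),
    admission = parse_instant(df$admission),
    discharge = parse_instant(df$discharge)
  )
}

#' Read a diagnoses table (`patient_id`, `icd10gm_code`)
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_diagnoses_table <- function(path) {
  df <- read_table_file(path, c("patient_id", "icd10gm_code"))
  data.frame(
    patient_id = as.character(df$patient_id),
    icd10gm_code = toupper(as.character(df$icd10gm_code))
  )
}

#' Read a procedures table (`patient_id`, `procedure`, `start`, `end`)
#' @param path CSV file path.
#' @return data.frame with parsed instants.
#' @export
read_procedures_table <- function(path) {
  df <- read_table_file(path, c("patient_id", "procedure", "start", "end"))
  data.frame(
    patient_id = as.character(df$patient_id),
    procedure = as.character(df$procedure),
    start = parse_instant(df$start),
    end = parse_instant(df$end)
  )
}

#' Read an episodes table (`patient_id`, `start`, `end`, optional `cause`)
#' @param path CSV file path.
#' @return data.frame with parsed instants.
#' @export
read_episodes <- function(path) {
  df <- read_table_file(path, c("patient_id", "start", "end"))
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    start = parse_instant(df$start),
    end = parse_instant(df$end)
  )
  if ("cause" %in% names(df)) out$cause <- as.character(df$cause)
  out
}

#' Write an episodes table
#' @param episodes data.frame with `patient_id`, `start`, `end` and
#'   optionally `cause`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  out <- episodes
  out$start <- format_instant(out$start)
  out$end <- format_instant(out$end)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_file <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Assemble patient records from a directory of canonical tables
#'
#' Reads `patients.csv` (required) plus `observations.csv`,
#' `diagnoses.csv` and `procedures.csv` (each optional) from `dir` and
#' builds one [patient_record()] per patient row. Observations outside a
#' patient's `[admission, discharge]` window are dropped with a warning,
#' never silently clamped.
#'
#' @param dir directory containing the tables.
#' @return named list of [patient_record()] objects.
#' @export
load_patient_records <- function(dir) {
  pts <- read_patients_table(file.path(dir, "patients.csv"))
  obs <- maybe_read(file.path(dir, "observations.csv"), read_observations)
  dia <- maybe_read(file.path(dir, "diagnoses.csv"), read_diagnoses_table)
  prc <- maybe_read(file.path(dir, "procedures.csv"), read_procedures_table)

  records <- vector("list", nrow(pts))
  names(records) <- pts$patient_id
  for (i in seq_len(nrow(pts))) {
    pid <- pts$patient_id[i]
    p_obs <- if (is.null(obs)) NULL else obs[obs$patient_id == pid, , drop = FALSE]
    if (!is.null(p_obs) && nrow(p_obs) > 0) {
      ts <- as.numeric(p_obs$timestamp)
      out_of_stay <- ts < as.numeric(pts$admission[i]) | ts > as.numeric(pts$discharge[i])
      if (any(out_of_stay)) {
        warning(sum(out_of_stay), " observation(s) outside the stay of patient ",
                pid, " dropped", call. = FALSE)
        p_obs <- p_obs[!out_of_stay, , drop = FALSE]
      }
    }
    p_dia <- if (is.null(dia)) character(0) else dia$icd10gm_code[dia$patient_id == pid]
    p_prc <- if (is.null(prc)) NULL else prc[prc$patient_id == pid, , drop = FALSE]
    records[[i]] <- patient_record(
      pid, pts$age_years[i], pts$admission[i], pts$discharge[i],
      observations = p_obs, diagnoses = p_dia, procedures = p_prc
    )
  }
  records
}

maybe_read <- function(path, reader) {
  if (file.exists(path)) reader(path) else NULL
}

#' Write a synthetic cohort as canonical flat files
#'
#' Writes `patients.csv`, `observations.csv`, `diagnoses.csv`,
#' `procedures.csv` and `truth_episodes.csv` into `dir` in the formats the
#' readers of this package consume.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pts <- do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(
      patient_id = p$patient_id, age_years = p$age_years,
      admission = format_instant(p$admission),
      discharge = format_instant(p$discharge)
    )
  }))
  utils::write.csv(pts, file.path(dir, "patients.csv"), row.names = FALSE, quote = FALSE)

  obs <- do.call(rbind, lapply(cohort$patients, function(p) {
    o <- p$observations
    if (nrow(o) == 0) return(NULL)
    data.frame(
      patient_id = p$patient_id,
      loinc_code = o$code,
      value = ifelse(o$analyte == "PLT", format(o$value, scientific = FALSE, trim = TRUE),
                     format(o$value, trim = TRUE)),
      unit = ifelse(o$analyte == "PLT", "/mm3", ""),
      timestamp = format_instant(o$timestamp)
    )
  }))
  if (is.null(obs)) {
    obs <- data.frame(patient_id = character(0), loinc_code = character(0),
                      value = character(0), unit = character(0), timestamp = character(0))
  }
  utils::write.csv(obs, file.path(dir, "observations.csv"), row.names = FALSE, quote = FALSE)

  dia <- do.call(rbind, lapply(cohort$patients, function(p) {
    if (length(p$diagnoses) == 0) return(NULL)
    data.frame(patient_id = p$patient_id, icd10gm_code = p$diagnoses)
  }))
  if (is.null(dia)) {
    dia <- data.frame(patient_id = character(0), icd10gm_code = character(0))
  }
  utils::write.csv(dia, file.path(dir, "diagnoses.csv"), row.names = FALSE, quote = FALSE)

  prc <- do.call(rbind, lapply(cohort$patients, function(p) {
    pr <- p$procedures
    if (nrow(pr) == 0) return(NULL)
    data.frame(
      patient_id = p$patient_id, procedure = pr$procedure,
      start = format_instant(pr$start), end = format_instant(pr$end)
    )
  }))
  if (is.null(prc)) {
    prc <- data.frame(patient_id = character(0), procedure = character(0),
                      start = character(0), end = character(0))
  }
  utils::write.csv(prc, file.path(dir, "procedures.csv"), row.names = FALSE, quote = FALSE)

  write_episodes(cohort$truth, file.path(dir, "truth_episodes.csv"))
  invisible(dir)
}

#' Load a pipeline configuration from YAML
#'
#' The file may contain any of the top-level sections `rule`, `eval` and
#' `sim`, whose keys mirror the arguments of [rule_config()],
#' [eval_config()] and [sim_config()]. Missing sections fall back to the
#' defaults; unknown keys are rejected.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return list with elements `rule`, `eval`, `sim`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  }
  build <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    unknown <- setdiff(names(args), names(formals(fn)))
    if (length(unknown) > 0) {
      stop("unknown ", section, " config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    do.call(fn, args)
  }
  list(
    rule = build("rule", rule_config),
    eval = build("eval", eval_config),
    sim = build("sim", sim_config)
  )
}

#' Write a run manifest into an output directory
#'
#' Every pipeline output directory carries exactly one `manifest.json`
#' recording the command, the fully resolved configuration, content digests
#' of the input files, the package version, and a wall-clock timestamp (the
#' timestamp is the only field that varies between identical re-runs; all
#' data outputs are bit-reproducible).
#'
#' @param dir output directory.
#' @param command subcommand name.
#' @param config named list echoed verbatim.
#' @param inputs character vector of input file paths to digest.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, config = list(), inputs = character(0)) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = command,
    config_echo = config,
    input_hashes = as.list(tools::md5sum(inputs)),
    versions = as.character(utils::packageVersion("hemod")),
    timestamp = format_instant(Sys.time())
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
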
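#' First platelet value after admission (the baseline)
#'
#' The relative-decline rule compares later platelet counts against the
#' first value recorded after admission rather than a rolling maximum, so
#' that platelet transfusions or surgical bleeding later in the stay do not
#' inflate the comparator.
#'
#' @param patient a [patient_record()].
#' @return one-row data.frame (the earliest PLT observation at or after
#'   admission) or `NULL` if the patient has no platelet observations.
#' @export
baseline_platelet <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  obs <- patient$observations
  plt <- obs[obs$analyte == "PLT" &
               as.numeric(obs$timestamp) >= as.numeric(patient$admission), , drop = FALSE]
  if (nrow(plt) == 0) return(NULL)
  plt[which.min(as.numeric(plt$timestamp)), , drop = FALSE]
}

#' Is the relative-decline rule applicable to this patient?
#'
#' `TRUE` iff any stay-level diagnosis matches the configured chronic
#' hematology/oncology code list. Diagnoses are not time-gated: the listed
#' conditions are chronic, so presence on the stay suffices.
#'
#' @param patient a [patient_record()].
#' @param config a [rule_config()].
#' @return logical scalar.
#' @export
applies_chronic_rule <- function(patient, config = rule_config()) {
  stopifnot(inherits(patient, "patient_record"), inherits(config, "rule_config"))
  codes_match(patient$diagnoses, config$chronic_hemonc_codes, config$prefix_match)
}

#' Should INR alarms be suppressed for this patient?
#'
#' `TRUE` iff any diagnosis matches the configured list of primary diseases
#' associated with a raised INR (e.g., hereditary factor deficiencies); for
#' such patients an elevated INR is attributed to the primary disease and
#' never contributes to an organ-dysfunction episode. Only the INR branch is
#' suppressed; platelet alarms are unaffected.
#'
#' @inheritParams applies_chronic_rule
#' @return logical scalar.
#' @export
inr_excluded <- function(patient, config = rule_config()) {
  stopifnot(inherits(patient, "patient_record"), inherits(config, "rule_config"))
  codes_match(patient$diagnoses, config$inr_exclusion_codes, config$prefix_match)
}

#' Extended ECMO suppression windows
#'
#' Each ECMO episode is widened by the configured pre- and post-ECMO margins
#' (defaults 2 h before, 12 h after), because circuit effects such as
#' heparin depress platelets beyond the cannulation interval itself.
#' Overlapping or touching extended windows are merged into maximal disjoint
#' intervals.
#'
#' @inheritParams applies_chronic_rule
#' @return data.frame with `start`, `end` (`POSIXct`), possibly empty.
#' @export
extended_ecmo_windows <- function(patient, config = rule_config()) {
  stopifnot(inherits(patient, "patient_record"), inherits(config, "rule_config"))
  pr <- patient$procedures
  pr <- pr[pr$procedure == "ECMO", , drop = FALSE]
  if (nrow(pr) == 0) return(empty_intervals())
  iv <- as_intervals(
    as.numeric(pr$start) - hours_to_secs(config$ecmo_pre_hours),
    as.numeric(pr$end) + hours_to_secs(config$ecmo_post_hours)
  )
  interval_union(iv)
}

#' Raw (unmerged) alarm events for one patient
#'
#' Classifies every observation against its analyte's normal range; for
#' chronic hematology/oncology patients a platelet value at or below
#' `(1 - decline_fraction)` times the admission baseline additionally
#' triggers a `TOO_LOW` alarm with criterion `RELATIVE_DECLINE` (the
#' baseline observation itself never triggers the relative rule). A point
#' measurement is given duration by event persistence: an abnormal value
#' holds from its specimen timestamp until the next observation of the same
#' analyte with a different category, or until discharge if none follows.
#'
#' @inheritParams applies_chronic_rule
#' @return data.frame with columns `patient_id`, `analyte`, `category`,
#'   `criterion`, `start`, `end`.
#' @export
raw_alarm_events <- function(patient, config = rule_config()) {
  stopifnot(inherits(patient, "patient_record"), inherits(config, "rule_config"))
  out <- empty_alarms()
  chronic <- applies_chronic_rule(patient, config)
  base <- if (chronic) baseline_platelet(patient) else NULL

  for (analyte in c("PLT", "INR")) {
    obs <- patient$observations
    obs <- obs[obs$analyte == analyte, , drop = FALSE]
    if (nrow(obs) == 0) next
    obs <- obs[order(obs$timestamp), , drop = FALSE]
    norm <- specify_norm(analyte, config)
    category <- categorize_values(obs$value, norm)
    criterion <- ifelse(category == "NORMAL", NA_character_, "ABSOLUTE")

    if (analyte == "PLT" && chronic && !is.null(base)) {
      rel <- obs$value <= (1 - config$decline_fraction) * base$value &
        as.numeric(obs$timestamp) != as.numeric(base$timestamp)
      promote <- rel & category == "NORMAL"
      category[promote] <- "TOO_LOW"
      criterion[promote] <- "RELATIVE_DECLINE"
    }

    ts <- as.numeric(obs$timestamp)
    n <- length(ts)
    abnormal <- which(category != "NORMAL")
    for (i in abnormal) {
      nxt <- which(category[seq_len(n) > i] != category[i])
      end <- if (length(nxt) > 0) ts[i + nxt[1]] else as.numeric(patient$discharge)
      if (end <= ts[i]) next # zero-length event (co-timed contradictory obs)
      out <- rbind(out, data.frame(
        patient_id = patient$patient_id, analyte = analyte,
        category = category[i], criterion = criterion[i],
        start = num_to_instant(ts[i]), end = num_to_instant(end)
      ))
    }
  }
  rownames(out) <- NULL
  out
}

empty_alarms <- function() {
  data.frame(
    patient_id = character(0), analyte = character(0), category = character(0),
    criterion = character(0),
    start = num_to_instant(numeric(0)), end = num_to_instant(numeric(0))
  )
}

#' Merge alarm events of the same parameter type and category
#'
#' Within each (patient, analyte, category) group, overlapping or touching
#' events are replaced by one united event running from the start of the
#' first to the end of the last overlapping event. Events of different
#' analytes or categories never merge. The united event's criterion is
#' `ABSOLUTE` if any contributing event was absolute, else
#' `RELATIVE_DECLINE`.
#'
#' @param events data.frame as returned by [raw_alarm_events()].
#' @return data.frame of the same shape, sorted, pairwise disjoint per
#'   group.
#' @export
merge_alarm_events <- function(events) {
  if (nrow(events) == 0) return(empty_alarms())
  key <- interaction(events$patient_id, events$analyte, events$category, drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(events)), key), function(idx) {
    grp <- events[idx, , drop = FALSE]
    merged <- interval_union(grp[, c("start", "end")])
    crit <- vapply(seq_len(nrow(merged)), function(i) {
      # every contributor lies within exactly one merged interval
      inside <- as.numeric(grp$start) >= as.numeric(merged$start[i]) &
        as.numeric(grp$end) <= as.numeric(merged$end[i])
      if (any(grp$criterion[inside] == "ABSOLUTE")) "ABSOLUTE" else "RELATIVE_DECLINE"
    }, character(1))
    data.frame(
      patient_id = grp$patient_id[1], analyte = grp$analyte[1],
      category = grp$category[1], criterion = crit,
      start = merged$start, end = merged$end
    )
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$patient_id, out$analyte, out$category, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect hematologic organ-dysfunction episodes for one patient
#'
#' Runs the full rule chain: platelet `TOO_LOW` alarms (absolute threshold
#' plus, for chronic hematology/oncology patients, the relative-decline
#' rule) are merged and then truncated by the extended ECMO windows;
#' INR `TOO_HIGH` alarms are merged unless the patient carries an
#' INR-raising primary diagnosis. Surviving platelet intervals become
#' `PLATELETS` episodes and INR intervals `INR` episodes; overlapping or
#' touching episodes of different cause are concatenated into a single
#' `BOTH` episode spanning their union. High platelets and low INR never
#' produce episodes.
#'
#' @inheritParams applies_chronic_rule
#' @param annotate_suppressed if `TRUE`, attach the ECMO-suppressed platelet
#'   alarm intervals as attribute `"suppressed"` on the result (a
#'   non-diagnostic annotation; they are never episodes).
#' @return data.frame with columns `patient_id`, `start`, `end`, `cause`
#'   (`"PLATELETS"`, `"INR"`, or `"BOTH"`), pairwise disjoint and sorted.
#' @export
detect_hematologic_od <- function(patient, config = rule_config(),
                                  annotate_suppressed = FALSE) {
  stopifnot(inherits(patient, "patient_record"), inherits(config, "rule_config"))
  merged <- merge_alarm_events(raw_alarm_events(patient, config))

  plt <- merged[merged$analyte == "PLT" & merged$category == "TOO_LOW",
                c("start", "end"), drop = FALSE]
  ecmo <- extended_ecmo_windows(patient, config)
  plt_surviving <- interval_subtract(plt, ecmo)

  inr <- if (inr_excluded(patient, config)) {
    empty_intervals()
  } else {
    merged[merged$analyte == "INR" & merged$category == "TOO_HIGH",
           c("start", "end"), drop = FALSE]
  }

  episodes <- concat_cause_intervals(patient$patient_id, plt_surviving, inr)

  if (annotate_suppressed) {
    suppressed <- if (nrow(plt) == 0) empty_intervals() else {
      removed <- interval_subtract(plt, plt_surviving)
      removed
    }
    attr(episodes, "suppressed") <- suppressed
  }
  episodes
}

# Label PLT and INR intervals, then concatenate overlapping/touching
# intervals of different cause into BOTH episodes spanning their union.
concat_cause_intervals <- function(patient_id, plt, inr) {
  parts <- rbind(
    if (nrow(plt) > 0) data.frame(cause = "PLATELETS", plt) else NULL,
    if (nrow(inr) > 0) data.frame(cause = "INR", inr) else NULL
  )
  out <- data.frame(
    patient_id = character(0),
    start = num_to_instant(numeric(0)), end = num_to_instant(numeric(0)),
    cause = character(0)
  )
  if (is.null(parts) || nrow(parts) == 0) return(out)
  parts <- parts[order(parts$start, parts$end), , drop = FALSE]
  s <- as.numeric(parts$start); e <- as.numeric(parts$end)
  cur_s <- s[1]; cur_e <- e[1]; cur_causes <- parts$cause[1]
  flush <- function() {
    cause <- if (length(unique(cur_causes)) > 1) "BOTH" else unique(cur_causes)
    out <<- rbind(out, data.frame(
      patient_id = patient_id,
      start = num_to_instant(cur_s), end = num_to_instant(cur_e), cause = cause
    ))
  }
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) { # overlap or touch
      cur_e <- max(cur_e, e[i])
      cur_causes <- c(cur_causes, parts$cause[i])
    } else {
      flush()
      cur_s <- s[i]; cur_e <- e[i]; cur_causes <- parts$cause[i]
    }
  }
  flush()
  rownames(out) <- NULL
  out
}

#' Detect episodes across a list of patients
#'
#' @param patients list of [patient_record()] objects.
#' @param config a [rule_config()].
#' @return one data.frame of episodes (see [detect_hematologic_od()]),
#'   stacked over patients.
#' @export
detect_cohort <- function(patients, config = rule_config()) {
  stopifnot(is.list(patients))
  out <- do.call(rbind, lapply(patients, detect_hematologic_od, config = config))
  if (is.null(out)) {
    out <- data.frame(
      patient_id = character(0),
      start = num_to_instant(numeric(0)), end = num_to_instant(numeric(0)),
      cause = character(0)
    )
  }
  rownames(out) <- NULL
  out
}
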
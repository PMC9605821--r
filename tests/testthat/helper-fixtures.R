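# Shared fixture builders: everything is constructed in code, no files.

t0 <- parse_instant("2024-03-01 00:00")

at_h <- function(h) t0 + 3600 * h

# Patient with labs given as data.frames of (t_h, value) hour offsets.
mk_patient <- function(id = "p1", stay_h = 96, plt = NULL, inr = NULL,
                       diagnoses = character(0), ecmo_h = NULL, age = 5) {
  obs <- rbind(
    if (!is.null(plt)) data.frame(analyte = "PLT", value = plt$value, timestamp = at_h(plt$t_h)),
    if (!is.null(inr)) data.frame(analyte = "INR", value = inr$value, timestamp = at_h(inr$t_h))
  )
  procedures <- if (!is.null(ecmo_h)) {
    data.frame(procedure = "ECMO", start = at_h(ecmo_h[1]), end = at_h(ecmo_h[2]))
  }
  patient_record(id, age, t0, at_h(stay_h),
                 observations = obs, diagnoses = diagnoses, procedures = procedures)
}

ep <- function(id, start_h, end_h) {
  data.frame(patient_id = id, start = at_h(start_h), end = at_h(end_h))
}

iv_h <- function(start_h, end_h) {
  data.frame(start = at_h(start_h), end = at_h(end_h))
}

hours_between <- function(a, b) (as.numeric(b) - as.numeric(a)) / 3600

# Independent brute-force detector: classifies every observation against the
# thresholds on its own, reconstructs maximal abnormal runs per analyte via
# rle, and sweeps the labeled intervals into episodes. Valid only for
# patients without chronic/exclusion diagnoses or ECMO.
oracle_detect <- function(patient, plt_min = 80000, inr_max = 2) {
  stopifnot(length(patient$diagnoses) == 0, nrow(patient$procedures) == 0)
  dis <- as.numeric(patient$discharge)
  branch_runs <- function(analyte, abnormal_fun) {
    o <- patient$observations
    o <- o[o$analyte == analyte, , drop = FALSE]
    o <- o[order(o$timestamp), , drop = FALSE]
    if (nrow(o) == 0) return(NULL)
    cat3 <- abnormal_fun(o$value)
    r <- rle(cat3)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    out <- NULL
    for (j in seq_along(r$values)) {
      if (!r$values[j] == "ALARM") next
      s <- as.numeric(o$timestamp[starts_idx[j]])
      e <- if (ends_idx[j] < nrow(o)) as.numeric(o$timestamp[ends_idx[j] + 1]) else dis
      out <- rbind(out, data.frame(s = s, e = e))
    }
    out
  }
  plt_runs <- branch_runs("PLT", function(v) ifelse(v < plt_min, "ALARM", ifelse(v > 1e6, "HI", "OK")))
  inr_runs <- branch_runs("INR", function(v) ifelse(v > inr_max, "ALARM", ifelse(v < 0.5, "LO", "OK")))
  segs <- rbind(
    if (!is.null(plt_runs)) cbind(plt_runs, cause = "PLATELETS"),
    if (!is.null(inr_runs)) cbind(inr_runs, cause = "INR")
  )
  if (is.null(segs) || nrow(segs) == 0) {
    return(data.frame(patient_id = character(0),
                      start = at_h(numeric(0)), end = at_h(numeric(0)),
                      cause = character(0)))
  }
  segs <- segs[order(segs$s, segs$e), , drop = FALSE]
  out <- NULL
  cs <- segs$s[1]; ce <- segs$e[1]; causes <- segs$cause[1]
  for (i in seq_len(nrow(segs))[-1]) {
    if (segs$s[i] <= ce) {
      ce <- max(ce, segs$e[i]); causes <- c(causes, segs$cause[i])
    } else {
      out <- rbind(out, data.frame(
        s = cs, e = ce,
        cause = if (length(unique(causes)) > 1) "BOTH" else causes[1]))
      cs <- segs$s[i]; ce <- segs$e[i]; causes <- segs$cause[i]
    }
  }
  out <- rbind(out, data.frame(
    s = cs, e = ce, cause = if (length(unique(causes)) > 1) "BOTH" else causes[1]))
  data.frame(
    patient_id = patient$patient_id,
    start = as.POSIXct(out$s, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(out$e, origin = "1970-01-01", tz = "UTC"),
    cause = out$cause
  )
}

# Clean-study generator settings: dense sampling, no noise, no confounders.
clean_sim <- function(n, seed, sampling = c(0.5, 1)) {
  sim_config(
    n_patients = n, seed = seed,
    plt_sampling_hours = sampling, inr_sampling_hours = sampling,
    noise_cv = 0, chronic_prevalence = 0, inr_exclusion_prevalence = 0,
    ecmo_prevalence = 0
  )
}

run_pipeline <- function(cohort, eval_cfg = eval_config(),
                         rules = rule_config()) {
  episodes <- detect_cohort(cohort$patients, rules)
  evaluate_episodes(cohort$patients, episodes, cohort$truth, eval_cfg)
}
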
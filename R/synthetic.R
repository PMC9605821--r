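#' Synthetic cohort configuration
#'
#' Parameters of the synthetic pediatric ICU cohort generator. Defaults
#' emulate the evaluation-study population: stays of a few days (minimum 12
#' hours), sparse irregular laboratory sampling, roughly a fifth of
#' patients with at least one injected dysfunction episode, and small
#' prevalences of chronic hematology/oncology diagnoses, INR-raising
#' primary diseases, and ECMO runs.
#'
#' @param n_patients number of patients to simulate.
#' @param seed master seed; all randomness flows from it through
#'   per-patient substreams, so adding patients does not perturb existing
#'   ones.
#' @param stay_median_days median stay length (lognormal; floored at 0.5
#'   days, the study inclusion minimum).
#' @param stay_sdlog lognormal sd of the stay length on the log scale.
#' @param plt_sampling_hours `(min, max)` of the uniform inter-sample gap
#'   for platelet counts.
#' @param inr_sampling_hours `(min, max)` inter-sample gap for INR.
#' @param baseline_plt_range `(min, max)` of the uniform platelet baseline,
#'   count/mm3.
#' @param inr_baseline_range `(min, max)` of the uniform INR baseline.
#' @param episode_prevalence probability a patient carries at least one
#'   injected dysfunction episode.
#' @param episodes_per_affected `(min, max)` integer range of episodes per
#'   affected patient.
#' @param episode_duration_hours `(min, max)` uniform episode duration.
#' @param plt_nadir_fraction platelet nadir as a fraction of baseline
#'   during an episode.
#' @param inr_peak_range `(min, max)` uniform INR peak during an episode.
#' @param episode_type_probs probabilities that an episode perturbs
#'   platelets only, INR only, or both (named `PLT`, `INR`, `BOTH`).
#' @param chronic_prevalence probability of a chronic hematology/oncology
#'   diagnosis.
#' @param inr_exclusion_prevalence probability of an INR-raising primary
#'   diagnosis.
#' @param ecmo_prevalence probability of one ECMO run during the stay.
#' @param noise_cv multiplicative lognormal coefficient of variation of the
#'   measured values around the latent curve.
#' @param error_spike_rate per-observation probability of a pre-analytic
#'   artifact (a spuriously low platelet count, as from a clotted
#'   specimen).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 168,
                       seed = 1L,
                       stay_median_days = 3,
                       stay_sdlog = 0.6,
                       plt_sampling_hours = c(6, 24),
                       inr_sampling_hours = c(12, 48),
                       baseline_plt_range = c(150000, 450000),
                       inr_baseline_range = c(0.9, 1.3),
                       episode_prevalence = 0.21,
                       episodes_per_affected = c(1, 3),
                       episode_duration_hours = c(12, 96),
                       plt_nadir_fraction = 0.2,
                       inr_peak_range = c(2.2, 4.0),
                       episode_type_probs = c(PLT = 0.5, INR = 0.2, BOTH = 0.3),
                       chronic_prevalence = 0.1,
                       inr_exclusion_prevalence = 0.05,
                       ecmo_prevalence = 0.05,
                       noise_cv = 0.05,
                       error_spike_rate = 0) {
  cfg <- as.list(environment())
  probs <- c(
    episode_prevalence, chronic_prevalence, inr_exclusion_prevalence,
    ecmo_prevalence, error_spike_rate
  )
  stopifnot(
    n_patients >= 1,
    all(probs >= 0 & probs <= 1),
    all(diff(plt_sampling_hours) >= 0), all(diff(inr_sampling_hours) >= 0),
    all(diff(baseline_plt_range) >= 0), all(diff(inr_baseline_range) >= 0),
    all(diff(episode_duration_hours) >= 0), all(diff(inr_peak_range) >= 0),
    episodes_per_affected[1] >= 1,
    episodes_per_affected[2] >= episodes_per_affected[1],
    plt_nadir_fraction > 0, plt_nadir_fraction < 1,
    noise_cv >= 0,
    abs(sum(episode_type_probs) - 1) < 1e-8
  )
  structure(cfg, class = "sim_config")
}

# Deterministic per-patient substream seed derived from the master seed.
patient_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 1299709) %% 2147483647)
}

sim_origin <- function() parse_instant("2024-01-01T00:00")

# Fraction of an episode spent ramping at each edge; the rest is a plateau
# at the nadir/peak, so most of the injected episode is beyond threshold.
EDGE_FRACTION <- 0.15

#' Generate a reproducible synthetic cohort with ground-truth episodes
#'
#' Each patient gets a stay, stay-level diagnoses and (possibly) an ECMO
#' run, latent platelet and INR trajectories (baseline plateaus with
#' trapezoidal excursions during injected episodes: a platelet fall to
#' `plt_nadir_fraction * baseline` and/or an INR rise into
#' `inr_peak_range`), and sparse irregular noisy samples from those
#' curves. Ground-truth dysfunction episodes are the threshold-crossing
#' intervals of the noise-free latent curves against `rule_config`
#' thresholds, with the chronic-patient relative-decline rule and the
#' INR-exclusion diagnoses applied, so they describe what an ideal
#' continuous observer applying the same rules would chart. ECMO timing is
#' drawn independently of the injected episodes; alarms the detector
#' suppresses around ECMO are therefore a genuine source of disagreement
#' with the truth.
#'
#' @param config a [sim_config()].
#' @param rules the [rule_config()] whose thresholds define the ground
#'   truth.
#' @return object of class `synthetic_cohort`: list with `patients` (list
#'   of [patient_record()]), `truth` (data.frame `patient_id`, `start`,
#'   `end`), `affected` (named logical: which patients drew at least one
#'   injected episode), and `config`.
#' @export
generate_cohort <- function(config = sim_config(), rules = rule_config()) {
  stopifnot(inherits(config, "sim_config"), inherits(rules, "rule_config"))
  patients <- vector("list", config$n_patients)
  truth_list <- vector("list", config$n_patients)
  affected <- logical(config$n_patients)
  n_undetectable <- 0

  for (k in seq_len(config$n_patients)) {
    sim <- simulate_patient(k, config, rules)
    patients[[k]] <- sim$patient
    truth_list[[k]] <- sim$truth
    affected[k] <- sim$affected
    n_undetectable <- n_undetectable + sim$n_undetectable
  }
  if (n_undetectable > 0) {
    warning(n_undetectable, " injected episode branch(es) never cross their ",
            "detection threshold under this configuration", call. = FALSE)
  }
  truth <- do.call(rbind, truth_list)
  if (is.null(truth)) {
    truth <- data.frame(
      patient_id = character(0),
      start = num_to_instant(numeric(0)), end = num_to_instant(numeric(0))
    )
  }
  rownames(truth) <- NULL
  names(affected) <- vapply(patients, `[[`, character(1), "patient_id")
  structure(
    list(patients = patients, truth = truth, affected = affected, config = config),
    class = "synthetic_cohort"
  )
}

simulate_patient <- function(k, config, rules) {
  set.seed(patient_seed(config$seed, k))
  pid <- sprintf("sim%04d", k)
  age <- round(stats::runif(1, 0, 18), 1)

  los_h <- max(12, stats::rlnorm(1, log(config$stay_median_days * 24), config$stay_sdlog))
  los_h <- round(los_h * 60) / 60
  admission <- num_to_instant(as.numeric(sim_origin()) + (k - 1) * 86400)
  discharge <- num_to_instant(as.numeric(admission) + hours_to_secs(los_h))

  diagnoses <- character(0)
  chronic <- stats::runif(1) < config$chronic_prevalence
  if (chronic) {
    diagnoses <- c(diagnoses, paste0(sample(rules$chronic_hemonc_codes, 1), ".0"))
  }
  excluded <- stats::runif(1) < config$inr_exclusion_prevalence
  if (excluded) {
    diagnoses <- c(diagnoses, paste0(sample(rules$inr_exclusion_codes, 1), ".0"))
  }

  procedures <- NULL
  if (stats::runif(1) < config$ecmo_prevalence && los_h > 36) {
    e_start <- stats::runif(1, 0, los_h - 30)
    e_dur <- stats::runif(1, 24, min(120, los_h - e_start - 2))
    procedures <- data.frame(
      procedure = "ECMO",
      start = num_to_instant(as.numeric(admission) + hours_to_secs(e_start)),
      end = num_to_instant(as.numeric(admission) + hours_to_secs(e_start + e_dur))
    )
  }

  baseline_plt <- stats::runif(1, config$baseline_plt_range[1], config$baseline_plt_range[2])
  baseline_inr <- stats::runif(1, config$inr_baseline_range[1], config$inr_baseline_range[2])

  episodes <- place_episodes(los_h, config)

  # latent excursions per analyte: rows (start_h, end_h, low/peak level)
  plt_exc <- episodes[episodes$type %in% c("PLT", "BOTH"), , drop = FALSE]
  inr_exc <- episodes[episodes$type %in% c("INR", "BOTH"), , drop = FALSE]
  nadir <- config$plt_nadir_fraction * baseline_plt
  inr_peaks <- if (nrow(inr_exc) > 0) {
    stats::runif(nrow(inr_exc), config$inr_peak_range[1], config$inr_peak_range[2])
  } else numeric(0)

  # ground truth: threshold crossings of the latent curves
  plt_threshold <- rules$plt_min
  if (chronic) {
    plt_threshold <- max(plt_threshold, (1 - rules$decline_fraction) * baseline_plt)
  }
  n_undetectable <- 0
  truth_h <- data.frame(start_h = numeric(0), end_h = numeric(0))
  for (i in seq_len(nrow(plt_exc))) {
    cr <- trapezoid_crossing(
      plt_exc$start_h[i], plt_exc$end_h[i],
      baseline_plt, nadir, plt_threshold, below = TRUE
    )
    if (is.null(cr)) n_undetectable <- n_undetectable + 1 else {
      truth_h <- rbind(truth_h, cr)
    }
  }
  if (!excluded) {
    # excluded patients' INR excursions are deliberately absent from truth
    for (i in seq_len(nrow(inr_exc))) {
      cr <- trapezoid_crossing(
        inr_exc$start_h[i], inr_exc$end_h[i],
        baseline_inr, inr_peaks[i], rules$inr_max, below = FALSE
      )
      if (is.null(cr)) n_undetectable <- n_undetectable + 1 else {
        truth_h <- rbind(truth_h, cr)
      }
    }
  }

  truth <- if (nrow(truth_h) == 0) NULL else {
    iv <- interval_union(as_intervals(
      as.numeric(admission) + hours_to_secs(truth_h$start_h),
      as.numeric(admission) + hours_to_secs(truth_h$end_h)
    ))
    iv$start <- round_minute(iv$start)
    iv$end <- round_minute(iv$end)
    data.frame(patient_id = pid, iv)
  }

  # sparse irregular sampling of the latent curves
  plt_times <- sample_times(0.25, 1.5, config$plt_sampling_hours, los_h)
  inr_times <- sample_times(0.5, 2, config$inr_sampling_hours, los_h)
  sdlog <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0

  plt_values <- latent_value(plt_times, plt_exc, baseline_plt, rep(nadir, nrow(plt_exc)))
  inr_values <- latent_value(inr_times, inr_exc, baseline_inr, inr_peaks)
  if (sdlog > 0) {
    plt_values <- plt_values * stats::rlnorm(length(plt_values), -sdlog^2 / 2, sdlog)
    inr_values <- inr_values * stats::rlnorm(length(inr_values), -sdlog^2 / 2, sdlog)
  }
  if (config$error_spike_rate > 0 && length(plt_values) > 0) {
    spike <- stats::runif(length(plt_values)) < config$error_spike_rate
    plt_values[spike] <- plt_values[spike] * stats::runif(sum(spike), 0.05, 0.3)
  }

  observations <- rbind(
    data.frame(
      analyte = rep("PLT", length(plt_times)),
      value = round(plt_values),
      timestamp = round_minute(num_to_instant(as.numeric(admission) + hours_to_secs(plt_times)))
    ),
    data.frame(
      analyte = rep("INR", length(inr_times)),
      value = round(inr_values, 2),
      timestamp = round_minute(num_to_instant(as.numeric(admission) + hours_to_secs(inr_times)))
    )
  )

  patient <- patient_record(
    pid, age, admission, discharge,
    observations = observations, diagnoses = diagnoses, procedures = procedures
  )
  list(patient = patient, truth = truth, affected = nrow(episodes) > 0,
       n_undetectable = n_undetectable)
}

# Draw non-overlapping episode windows (hours from admission), each kept at
# least 4 h from admission, 1 h from discharge, and 25 h apart so that the
# injected truth episodes stay distinct under the 24 h evaluation merge.
place_episodes <- function(los_h, config) {
  none <- data.frame(start_h = numeric(0), end_h = numeric(0), type = character(0))
  if (stats::runif(1) >= config$episode_prevalence) return(none)
  rng <- config$episodes_per_affected
  n_ep <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
  sep <- 25
  repeat {
    durs <- stats::runif(n_ep, config$episode_duration_hours[1], config$episode_duration_hours[2])
    durs <- pmin(durs, max(6, los_h - 6))
    slack <- los_h - 5 - sum(durs) - sep * (n_ep - 1)
    if (slack >= 0 || n_ep == 1) break
    n_ep <- n_ep - 1
  }
  if (slack < 0) { # stay too short even for one episode: shrink it
    durs <- max(6, los_h - 6)
    slack <- max(0, los_h - 5 - durs)
  }
  w <- stats::runif(n_ep + 1)
  w <- w / sum(w) * slack
  starts <- numeric(n_ep)
  t <- 4 + w[1]
  for (j in seq_len(n_ep)) {
    starts[j] <- t
    t <- t + durs[j] + sep + w[j + 1]
  }
  types <- sample(names(config$episode_type_probs), n_ep,
                  replace = TRUE, prob = config$episode_type_probs)
  data.frame(start_h = starts, end_h = starts + durs, type = types)
}

# Irregular sampling grid: first sample in [first_lo, first_hi] hours after
# admission, then uniform gaps, all within the stay.
sample_times <- function(first_lo, first_hi, gap_range, los_h) {
  t <- stats::runif(1, first_lo, min(first_hi, los_h / 2))
  times <- t
  repeat {
    t <- t + stats::runif(1, gap_range[1], max(gap_range[1], gap_range[2]))
    if (t > los_h) break
    times <- c(times, t)
  }
  times
}

# Trapezoidal excursion from `base` to `level` over [s, e] (hours): linear
# ramps over EDGE_FRACTION of the duration at each edge, plateau between.
# Returns the latent value at each time.
latent_value <- function(times_h, excursions, base, levels) {
  v <- rep(base, length(times_h))
  for (i in seq_len(nrow(excursions))) {
    s <- excursions$start_h[i]; e <- excursions$end_h[i]
    r <- EDGE_FRACTION * (e - s)
    lev <- levels[i]
    inside <- times_h >= s & times_h <= e
    tt <- times_h[inside]
    f <- pmin(1, pmin(tt - s, e - tt) / r)
    v[inside] <- base + (lev - base) * f
  }
  v
}

# Interval (hours from admission) over which the trapezoid is beyond
# `threshold` (below it when below = TRUE, above otherwise); NULL when the
# excursion never reaches the threshold.
trapezoid_crossing <- function(s, e, base, level, threshold, below) {
  reaches <- if (below) level < threshold && base > threshold else {
    level > threshold && base < threshold
  }
  if (!reaches) return(NULL)
  r <- EDGE_FRACTION * (e - s)
  frac <- (base - threshold) / (base - level) # in (0, 1)
  dt <- r * frac
  data.frame(start_h = s + dt, end_h = e - dt)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  affected <- length(unique(x$truth$patient_id))
  cat(sprintf(
    "Synthetic cohort: %d patients (seed %s), %d truth episodes in %d patients\n",
    length(x$patients), x$config$seed, nrow(x$truth), affected
  ))
  invisible(x)
}

#' Thin the laboratory sampling of a cohort
#'
#' Returns a copy of the cohort in which, per patient and analyte, only
#' every `factor`-th observation (by time order, always keeping the first)
#' is retained; ground-truth episodes are unchanged. Thinning is
#' deterministic, so the degraded cohort is reproducible from the original.
#'
#' @param cohort a [generate_cohort()] result.
#' @param factor sampling-interval multiplier, `>= 1`; `1` is the identity.
#' @return a `synthetic_cohort`.
#' @export
degrade_sampling <- function(cohort, factor) {
  stopifnot(inherits(cohort, "synthetic_cohort"), is.numeric(factor), factor >= 1)
  out <- cohort
  out$patients <- lapply(cohort$patients, function(p) {
    obs <- p$observations
    keep <- unlist(lapply(split(seq_len(nrow(obs)), obs$analyte), function(idx) {
      idx <- idx[order(obs$timestamp[idx])]
      idx[unique(round(seq(1, length(idx), by = factor)))]
    }), use.names = FALSE)
    p$observations <- obs[sort(keep), , drop = FALSE]
    rownames(p$observations) <- NULL
    p
  })
  out
}
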
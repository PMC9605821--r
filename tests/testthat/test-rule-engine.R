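test_that("specify_norm assigns the configured normal range per analyte", {
  cfg <- rule_config()
  plt <- specify_norm("PLT", cfg)
  expect_equal(c(plt$minimum, plt$maximum), c(80000, 1e6))
  inr <- specify_norm("INR", cfg)
  expect_equal(c(inr$minimum, inr$maximum), c(0.5, 2))
  custom <- specify_norm("PLT", rule_config(plt_min = 90000))
  expect_equal(custom$minimum, 90000)
  expect_equal(custom$maximum, 1e6)
  expect_error(specify_norm("NA+", cfg), "unknown analyte")
})

test_that("observation categories use strict threshold inequalities", {
  cfg <- rule_config()
  plt_norm <- specify_norm("PLT", cfg)
  inr_norm <- specify_norm("INR", cfg)
  expect_equal(evaluate_observation(list(analyte = "PLT", value = 70000), plt_norm), "TOO_LOW")
  expect_equal(evaluate_observation(list(analyte = "PLT", value = 80000), plt_norm), "NORMAL")
  expect_equal(evaluate_observation(list(analyte = "INR", value = 2.0), inr_norm), "NORMAL")
  expect_equal(evaluate_observation(list(analyte = "INR", value = 2.1), inr_norm), "TOO_HIGH")
  expect_equal(evaluate_observation(list(analyte = "INR", value = 0.4), inr_norm), "TOO_LOW")
  expect_error(evaluate_observation(list(analyte = "PLT", value = 1), inr_norm), "mismatch")
})

test_that("baseline platelet is the earliest value at or after admission", {
  p <- mk_patient(plt = data.frame(t_h = c(6, 1), value = c(150000, 200000)))
  b <- baseline_platelet(p)
  expect_equal(b$value, 200000)
  expect_null(baseline_platelet(mk_patient(inr = data.frame(t_h = 1, value = 1))))
  at_adm <- mk_patient(plt = data.frame(t_h = 0, value = 190000))
  expect_equal(baseline_platelet(at_adm)$value, 190000)
})

test_that("diagnosis gating matches configured code lists", {
  cfg <- rule_config(chronic_hemonc_codes = "C91.0", inr_exclusion_codes = "D66",
                     prefix_match = FALSE)
  expect_true(applies_chronic_rule(mk_patient(diagnoses = "C91.0"), cfg))
  expect_false(applies_chronic_rule(mk_patient(diagnoses = "J45.9"), cfg))
  expect_false(applies_chronic_rule(mk_patient(), cfg))
  # prefix matching widens the net; exact matching does not
  expect_false(applies_chronic_rule(mk_patient(diagnoses = "C91.00"), cfg))
  cfg_prefix <- rule_config(chronic_hemonc_codes = "C91", prefix_match = TRUE)
  expect_true(applies_chronic_rule(mk_patient(diagnoses = "C91.00"), cfg_prefix))
  expect_true(inr_excluded(mk_patient(diagnoses = c("J45.9", "D66.0")), rule_config()))
  expect_false(inr_excluded(mk_patient(diagnoses = "J45.9"), rule_config()))
  none <- rule_config(inr_exclusion_codes = character(0))
  expect_false(inr_excluded(mk_patient(diagnoses = "D66.0"), none))
})

test_that("ECMO windows extend 2 h before and 12 h after and merge", {
  p <- mk_patient(stay_h = 72, ecmo_h = c(10, 20))
  w <- extended_ecmo_windows(p)
  expect_equal(w$start, at_h(8))
  expect_equal(w$end, at_h(32))
  expect_equal(nrow(extended_ecmo_windows(mk_patient())), 0)
  two <- mk_patient(stay_h = 72)
  two$procedures <- data.frame(
    procedure = c("ECMO", "ECMO"),
    start = at_h(c(10, 13)), end = at_h(c(12, 15))
  )
  merged <- extended_ecmo_windows(two)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, at_h(8))
  expect_equal(merged$end, at_h(27))
})

test_that("relative-decline alarms require a chronic diagnosis", {
  labs <- data.frame(t_h = c(1, 24), value = c(200000, 90000))
  chronic <- mk_patient(diagnoses = "C91.0", plt = labs)
  ev <- raw_alarm_events(chronic)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$category, "TOO_LOW")
  expect_equal(ev$criterion, "RELATIVE_DECLINE")
  expect_equal(ev$start, at_h(24))
  expect_equal(ev$end, chronic$discharge)

  plain <- mk_patient(plt = labs)
  expect_equal(nrow(raw_alarm_events(plain)), 0)

  # the baseline observation itself never triggers the relative rule
  base_only <- mk_patient(diagnoses = "C91.0",
                          plt = data.frame(t_h = 1, value = 100000))
  expect_equal(nrow(raw_alarm_events(base_only)), 0)
})

test_that("alarm events persist until the next differing-category observation", {
  p <- mk_patient(plt = data.frame(t_h = c(2, 10, 20), value = c(70000, 75000, 120000)))
  ev <- raw_alarm_events(p)
  expect_equal(nrow(ev), 2)
  expect_equal(as.numeric(ev$end), rep(as.numeric(at_h(20)), 2))
  merged <- merge_alarm_events(ev)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, at_h(2))
  expect_equal(merged$end, at_h(20))
  expect_equal(merged$criterion, "ABSOLUTE")

  open_ended <- mk_patient(plt = data.frame(t_h = 2, value = 70000))
  ev2 <- raw_alarm_events(open_ended)
  expect_equal(ev2$end, open_ended$discharge)
})

test_that("merging respects parameter type and category and touching counts", {
  mk_ev <- function(analyte, category, s, e) {
    data.frame(patient_id = "p1", analyte = analyte, category = category,
               criterion = "ABSOLUTE", start = at_h(s), end = at_h(e))
  }
  expect_equal(nrow(merge_alarm_events(mk_ev("PLT", "TOO_LOW", 0, 1)[0, ])), 0)
  both <- rbind(mk_ev("PLT", "TOO_LOW", 0, 5), mk_ev("PLT", "TOO_LOW", 4, 8))
  m <- merge_alarm_events(both)
  expect_equal(nrow(m), 1)
  expect_equal(hours_between(m$start, m$end), 8)
  mixed <- rbind(mk_ev("PLT", "TOO_LOW", 0, 5), mk_ev("INR", "TOO_HIGH", 4, 8))
  expect_equal(nrow(merge_alarm_events(mixed)), 2)
  touching <- rbind(mk_ev("PLT", "TOO_LOW", 0, 5), mk_ev("PLT", "TOO_LOW", 5, 8))
  expect_equal(nrow(merge_alarm_events(touching)), 1)
})

test_that("episodes concatenate across causes and respect exclusions", {
  # overlapping platelet and INR intervals fuse into one BOTH episode
  p <- mk_patient(
    plt = data.frame(t_h = c(1, 2, 30), value = c(200000, 60000, 200000)),
    inr = data.frame(t_h = c(25, 40), value = c(2.5, 1.0))
  )
  od <- detect_hematologic_od(p)
  expect_equal(nrow(od), 1)
  expect_equal(od$cause, "BOTH")
  expect_equal(od$start, at_h(2))
  expect_equal(od$end, at_h(40))

  # an INR-raising primary diagnosis silences the INR branch only
  excl <- mk_patient(
    diagnoses = "D66.0",
    plt = data.frame(t_h = c(1, 2, 30), value = c(200000, 60000, 200000)),
    inr = data.frame(t_h = c(25, 40), value = c(2.5, 1.0))
  )
  od2 <- detect_hematologic_od(excl)
  expect_equal(od2$cause, "PLATELETS")
  expect_equal(od2$end, at_h(30))

  # high platelets / low INR are categories but never organ dysfunction
  weird <- mk_patient(
    plt = data.frame(t_h = c(1, 10), value = c(1.5e6, 300000)),
    inr = data.frame(t_h = c(2, 12), value = c(0.4, 1.0))
  )
  expect_equal(nrow(detect_hematologic_od(weird)), 0)
})

test_that("ECMO windows suppress platelet alarms, entirely or by truncation", {
  inside <- mk_patient(
    stay_h = 96,
    plt = data.frame(t_h = c(4, 10), value = c(70000, 200000)),
    ecmo_h = c(4, 20)
  )
  expect_equal(nrow(detect_hematologic_od(inside)), 0)
  sup <- detect_hematologic_od(inside, annotate_suppressed = TRUE)
  expect_equal(nrow(attr(sup, "suppressed")), 1)

  partial <- mk_patient(
    stay_h = 96,
    plt = data.frame(t_h = c(4, 60), value = c(70000, 200000)),
    ecmo_h = c(4, 20) # extended window ends at 32 h
  )
  od <- detect_hematologic_od(partial)
  expect_equal(nrow(od), 1)
  expect_equal(od$start, at_h(32))
  expect_equal(od$end, at_h(60))

  # INR alarms are untouched by ECMO
  inr_only <- mk_patient(
    stay_h = 96,
    inr = data.frame(t_h = c(4, 10), value = c(3, 1)),
    ecmo_h = c(2, 20)
  )
  expect_equal(detect_hematologic_od(inr_only)$cause, "INR")
})

test_that("detection is deterministic and matches the brute-force oracle", {
  cohort <- suppressWarnings(generate_cohort(clean_sim(15, seed = 11, sampling = c(2, 8))))
  a <- detect_cohort(cohort$patients)
  b <- detect_cohort(cohort$patients)
  expect_identical(a, b)
  oracle <- do.call(rbind, lapply(cohort$patients, oracle_detect))
  rownames(oracle) <- NULL
  expect_equal(a$patient_id, oracle$patient_id)
  expect_equal(as.numeric(a$start), as.numeric(oracle$start))
  expect_equal(as.numeric(a$end), as.numeric(oracle$end))
  expect_equal(a$cause, oracle$cause)
})

test_that("loosening a threshold never lengthens the alarmed time", {
  cohort <- suppressWarnings(generate_cohort(sim_config(
    n_patients = 25, seed = 5, episode_prevalence = 0.5,
    chronic_prevalence = 0, inr_exclusion_prevalence = 0, ecmo_prevalence = 0
  )))
  total_od_hours <- function(rules) {
    eps <- detect_cohort(cohort$patients, rules)
    sum(as.numeric(eps$end) - as.numeric(eps$start)) / 3600
  }
  base <- total_od_hours(rule_config())
  expect_lte(total_od_hours(rule_config(plt_min = 60000)), base)
  expect_lte(total_od_hours(rule_config(inr_max = 3)), base)
  expect_gte(total_od_hours(rule_config(plt_min = 100000)), base)
})

test_that("platelet episode time never intersects extended ECMO windows", {
  cohort <- suppressWarnings(generate_cohort(sim_config(
    n_patients = 30, seed = 13, episode_prevalence = 0.6, ecmo_prevalence = 0.6
  )))
  rules <- rule_config()
  for (p in cohort$patients) {
    od <- detect_hematologic_od(p, rules)
    plt_like <- od[od$cause %in% c("PLATELETS"), c("start", "end"), drop = FALSE]
    w <- extended_ecmo_windows(p, rules)
    expect_equal(hemod:::interval_intersect_secs(plt_like, w), 0)
  }
})
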
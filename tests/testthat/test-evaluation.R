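test_that("episodes merge only when the gap is strictly under the threshold", {
  two <- rbind(iv_h(0, 12), iv_h(32, 40)) # 20 h gap
  m <- merge_episodes(two, 24)
  expect_equal(nrow(m), 1)
  expect_equal(hours_between(m$start, m$end), 40)

  exact <- rbind(iv_h(0, 12), iv_h(36, 40)) # exactly 24 h gap
  expect_equal(nrow(merge_episodes(exact, 24)), 2)

  single <- iv_h(0, 12)
  expect_equal(merge_episodes(single, 24), single)

  # transitivity: chained short gaps collapse into one diagnostic episode
  chain <- rbind(iv_h(0, 10), iv_h(20, 30), iv_h(40, 50))
  expect_equal(nrow(merge_episodes(chain, 24)), 1)
  expect_equal(nrow(merge_episodes(NULL, 24)), 0)
})

test_that("boundaries snap onto reference boundaries within the tolerance", {
  ref <- iv_h(10, 40)
  late3 <- iv_h(13, 40)
  s <- snap_boundaries(late3, ref, 4)
  expect_equal(s$start, at_h(10))
  late5 <- iv_h(15, 40)
  expect_equal(snap_boundaries(late5, ref, 4)$start, at_h(15))
  # an episode collapsed by snapping is dropped
  tiny <- iv_h(39.5, 40.5)
  expect_equal(nrow(snap_boundaries(tiny, ref, 4)), 0)
  # no reference boundaries: identity
  expect_equal(snap_boundaries(late3, NULL, 4)$start, at_h(13))
})

test_that("blocks partition the stay and carry forced labels", {
  p <- mk_patient(stay_h = 96)

  only_tn <- build_blocks(p, NULL, NULL)
  expect_equal(nrow(only_tn), 1)
  expect_equal(only_tn$label, "TN")
  expect_equal(hours_between(only_tn$start, only_tn$end), 96)

  same <- iv_h(24, 48)
  agree <- build_blocks(p, same, same)
  expect_equal(agree$label, c("TN", "TP", "TN"))

  miss <- build_blocks(p, NULL, same)
  expect_equal(miss$label, c("TN", "FN", "TN"))

  expect_error(build_blocks(p, iv_h(-5, 10), NULL), "outside")

  # partition property on an arbitrary disagreement pattern
  blocks <- build_blocks(p, rbind(iv_h(10, 30), iv_h(50, 60)), rbind(iv_h(20, 55)))
  expect_equal(sum(hours_between(blocks$start, blocks$end)), 96)
  expect_equal(as.numeric(blocks$start[-1]), as.numeric(blocks$end[-nrow(blocks)]))
  expect_equal(blocks$label, c("TN", "FP", "TP", "FN", "TP", "FP", "TN"))
})

test_that("contingency counts blocks by label", {
  blocks <- data.frame(
    patient_id = "p1",
    label = rep(c("TP", "FP", "FN", "TN"), c(3, 1, 2, 7))
  )
  tab <- contingency(blocks)
  expect_equal(as.vector(tab), c(3, 2, 1, 7)) # column-major: TP, FN, FP, TN
  expect_equal(sum(tab), nrow(blocks))
  expect_equal(sum(contingency(blocks[0, ])), 0)
  one <- contingency(data.frame(patient_id = "p", label = "TP"))
  expect_equal(as.vector(one), c(1, 0, 0, 0))
})

test_that("pooled accuracy estimates are block-count ratios", {
  blocks <- data.frame(
    patient_id = rep(sprintf("p%02d", 1:20), length.out = 337),
    label = rep(c("TP", "FP", "FN", "TN"), c(55, 8, 12, 262))
  )
  acc <- diagnostic_accuracy(blocks)
  expect_equal(acc$sensitivity, 55 / 67)
  expect_equal(acc$specificity, 262 / 270)
  expect_equal(acc$n_blocks, 337)
  expect_true(acc$se_ci[1] < acc$sensitivity && acc$sensitivity < acc$se_ci[2])
  expect_true(all(acc$se_ci >= 0 & acc$se_ci <= 1))
  expect_true(all(acc$sp_ci >= 0 & acc$sp_ci <= 1))
})

test_that("a single error-free patient yields point estimates with zero-width CIs", {
  blocks <- data.frame(patient_id = "p1", label = c("TP", "TN", "TN"))
  acc <- diagnostic_accuracy(blocks)
  expect_equal(acc$sensitivity, 1)
  expect_equal(acc$specificity, 1)
  expect_equal(diff(acc$se_ci), 0)
  expect_equal(diff(acc$sp_ci), 0)
})

test_that("no reference-positive blocks leaves sensitivity undefined, not zero", {
  blocks <- data.frame(patient_id = c("p1", "p2"), label = c("TN", "FP"))
  acc <- diagnostic_accuracy(blocks)
  expect_true(is.na(acc$sensitivity))
  expect_match(acc$notes, "sensitivity undefined", all = FALSE)
  expect_equal(acc$specificity, 0.5)
})

test_that("cluster-robust intervals widen under between-patient heterogeneity", {
  # strongly clustered errors: patients are either all-hit or all-miss
  blocks <- rbind(
    data.frame(patient_id = rep(sprintf("h%d", 1:8), each = 4), label = "TP"),
    data.frame(patient_id = rep(sprintf("m%d", 1:2), each = 4), label = "FN")
  )
  cl <- diagnostic_accuracy(blocks, variance = "cluster")
  bin <- diagnostic_accuracy(blocks, variance = "binomial")
  expect_gt(diff(cl$se_ci), diff(bin$se_ci))
})

test_that("count conservation holds through the full evaluation", {
  cohort <- suppressWarnings(generate_cohort(sim_config(n_patients = 30, seed = 21)))
  res <- run_pipeline(cohort)
  tab <- contingency(res$blocks)
  expect_equal(sum(tab), nrow(res$blocks))
  expect_equal(tab["alarm", "positive"] + tab["no alarm", "positive"],
               sum(res$blocks$label %in% c("TP", "FN")))
  expect_equal(tab["alarm", "positive"] + tab["alarm", "negative"],
               sum(res$blocks$label %in% c("TP", "FP")))
  # every patient's blocks tile the stay exactly
  for (p in cohort$patients) {
    b <- res$blocks[res$blocks$patient_id == p$patient_id, , drop = FALSE]
    expect_equal(sum(hours_between(b$start, b$end)),
                 hours_between(p$admission, p$discharge))
  }
})

test_that("identical episode sets give perfect accuracy", {
  cohort <- suppressWarnings(generate_cohort(sim_config(n_patients = 20, seed = 31)))
  res <- evaluate_episodes(cohort$patients, cohort$truth, cohort$truth)
  expect_equal(res$accuracy$sensitivity, 1)
  expect_equal(res$accuracy$specificity, 1)
  tab <- res$accuracy$table
  expect_equal(tab["alarm", "negative"], 0)
  expect_equal(tab["no alarm", "positive"], 0)
})

test_that("widening the snap tolerance never loses true-positive blocks", {
  cohort <- suppressWarnings(generate_cohort(sim_config(n_patients = 40, seed = 41)))
  episodes <- detect_cohort(cohort$patients)
  tps <- vapply(c(0, 2, 4, 8), function(tol) {
    res <- evaluate_episodes(cohort$patients, episodes, cohort$truth,
                             eval_config(tolerance_hours = tol))
    contingency(res$blocks)["alarm", "positive"]
  }, numeric(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("zero tolerance and zero merge gap reduce to exact interval arithmetic", {
  p <- mk_patient(stay_h = 120)
  cdss <- rbind(iv_h(5, 20), iv_h(30, 44), iv_h(90, 100))
  ref <- rbind(iv_h(10, 35), iv_h(95, 118))
  res <- evaluate_episodes(list(p), data.frame(patient_id = "p1", cdss),
                           data.frame(patient_id = "p1", ref),
                           eval_config(tolerance_hours = 0, merge_gap_hours = 0))
  b <- res$blocks
  dur_by_label <- function(lbl) {
    sum(hours_between(b$start[b$label == lbl], b$end[b$label == lbl]))
  }
  # direct interval arithmetic on the hour line as the oracle
  grid <- seq(0, 120, by = 0.25) # midpoints of 15-min cells
  mids <- grid[-1] - 0.125
  in_cdss <- (mids >= 5 & mids < 20) | (mids >= 30 & mids < 44) | (mids >= 90 & mids < 100)
  in_ref <- (mids >= 10 & mids < 35) | (mids >= 95 & mids < 118)
  expect_equal(dur_by_label("TP"), 0.25 * sum(in_cdss & in_ref))
  expect_equal(dur_by_label("FP"), 0.25 * sum(in_cdss & !in_ref))
  expect_equal(dur_by_label("FN"), 0.25 * sum(!in_cdss & in_ref))
  expect_equal(dur_by_label("TN"), 0.25 * sum(!in_cdss & !in_ref))
})

test_that("clustered-count simulation hits its nominal accuracy on average", {
  set.seed(99)
  counts <- simulate_clustered_blocks(4000, sensitivity = 0.8, specificity = 0.95)
  acc <- accuracy_from_counts(counts)
  expect_lt(abs(acc$sensitivity - 0.8), 0.03)
  expect_lt(abs(acc$specificity - 0.95), 0.01)
})
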
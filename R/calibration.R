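#' Simulate clustered per-patient block counts with known accuracy
#'
#' Generates the per-patient (TP, FN, TN, FP) block counts of a hypothetical
#' evaluation study in which the detector's true sensitivity and specificity
#' are known by construction, with between-patient heterogeneity: each
#' patient's block-level detection probabilities are beta-distributed around
#' the target values, and block counts vary across patients. Because the
#' per-patient probabilities are drawn independently of the block counts,
#' the pooled ratio estimand equals the nominal `sensitivity` and
#' `specificity`, which makes this the oracle for checking confidence
#' interval calibration of [accuracy_from_counts()].
#'
#' @param n_patients number of simulated patients (clusters).
#' @param sensitivity,specificity true block-level detection probabilities.
#' @param pos_patient_prob probability that a patient has any
#'   reference-positive blocks.
#' @param mean_pos_blocks,mean_neg_blocks mean number of positive blocks per
#'   affected patient / negative blocks per patient (shifted Poisson,
#'   minimum 1).
#' @param concentration beta concentration of the per-patient
#'   probabilities; larger means less clustering.
#' @return data.frame with columns `patient_id`, `tp`, `fp`, `fn`, `tn`.
#' @export
simulate_clustered_blocks <- function(n_patients,
                                      sensitivity = 0.85,
                                      specificity = 0.95,
                                      pos_patient_prob = 0.35,
                                      mean_pos_blocks = 2,
                                      mean_neg_blocks = 3,
                                      concentration = 10) {
  stopifnot(
    n_patients >= 1,
    sensitivity > 0, sensitivity < 1, specificity > 0, specificity < 1,
    concentration > 0
  )
  has_pos <- stats::runif(n_patients) < pos_patient_prob
  n_pos <- ifelse(has_pos, 1 + stats::rpois(n_patients, mean_pos_blocks - 1), 0)
  n_neg <- 1 + stats::rpois(n_patients, mean_neg_blocks - 1)
  p <- stats::rbeta(n_patients, concentration * sensitivity,
                    concentration * (1 - sensitivity))
  q <- stats::rbeta(n_patients, concentration * specificity,
                    concentration * (1 - specificity))
  tp <- stats::rbinom(n_patients, n_pos, p)
  tn <- stats::rbinom(n_patients, n_neg, q)
  data.frame(
    patient_id = sprintf("c%04d", seq_len(n_patients)),
    tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn
  )
}

#' Monte-Carlo coverage of the clustered Wald confidence intervals
#'
#' Repeatedly simulates clustered block counts with known sensitivity and
#' specificity ([simulate_clustered_blocks()]), estimates both with
#' [accuracy_from_counts()], and reports how often the nominal confidence
#' intervals cover the truth.
#'
#' @param n_reps number of Monte-Carlo replicates.
#' @param n_patients patients per replicate.
#' @param sensitivity,specificity true values.
#' @param variance `"cluster"` or `"binomial"`, passed through.
#' @param ... further arguments for [simulate_clustered_blocks()].
#' @return list with elements `coverage_se`, `coverage_sp` (empirical
#'   coverage proportions) and `n_reps`.
#' @export
ci_coverage_study <- function(n_reps = 1000, n_patients = 200,
                              sensitivity = 0.85, specificity = 0.95,
                              variance = "cluster", ...) {
  hit_se <- logical(n_reps)
  hit_sp <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    counts <- simulate_clustered_blocks(
      n_patients, sensitivity = sensitivity, specificity = specificity, ...
    )
    acc <- accuracy_from_counts(counts, variance = variance)
    hit_se[r] <- !is.na(acc$sensitivity) &&
      acc$se_ci[1] <= sensitivity && sensitivity <= acc$se_ci[2]
    hit_sp[r] <- !is.na(acc$specificity) &&
      acc$sp_ci[1] <= specificity && specificity <= acc$sp_ci[2]
  }
  list(
    coverage_se = mean(hit_se),
    coverage_sp = mean(hit_sp),
    n_reps = n_reps
  )
}
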
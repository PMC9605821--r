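#' Evaluation configuration
#'
#' Parameters of the block-based comparison between detector output and the
#' clinician reference standard.
#'
#' @param tolerance_hours half-width of the window around each reference
#'   episode onset/end within which a detector boundary is snapped onto the
#'   reference boundary. Default 4.
#' @param merge_gap_hours episodes of one source separated by strictly less
#'   than this many hours are merged into one diagnostic episode before
#'   labeling. Default 24.
#' @param apply_merge_to `"both"` (default) merges detector and reference
#'   episode sets; `"reference_only"` merges only the reference.
#' @return object of class `eval_config`.
#' @export
eval_config <- function(tolerance_hours = 4, merge_gap_hours = 24,
                        apply_merge_to = c("both", "reference_only")) {
  apply_merge_to <- match.arg(apply_merge_to)
  stopifnot(
    is.numeric(tolerance_hours), tolerance_hours >= 0,
    is.numeric(merge_gap_hours), merge_gap_hours >= 0
  )
  structure(
    list(
      tolerance_hours = tolerance_hours,
      merge_gap_hours = merge_gap_hours,
      apply_merge_to = apply_merge_to
    ),
    class = "eval_config"
  )
}

#' Merge episodes separated by short gaps
#'
#' Consecutive episodes of one patient with strictly less than `gap_hours`
#' between them are replaced by a single episode spanning both, applied
#' transitively; a gap of exactly `gap_hours` is not merged. Overlapping or
#' touching episodes always merge.
#'
#' @param episodes data.frame with `start`, `end` (`POSIXct`), one patient.
#' @param gap_hours merge threshold in hours.
#' @return data.frame with `start`, `end`, disjoint, all gaps
#'   `>= gap_hours`.
#' @export
merge_episodes <- function(episodes, gap_hours = 24) {
  stopifnot(is.numeric(gap_hours), gap_hours >= 0)
  if (is.null(episodes) || nrow(episodes) == 0) return(empty_intervals())
  gap <- hours_to_secs(gap_hours)
  # strict "less than": a gap equal to the threshold stays; shrink the
  # closed comparison by one unit below minute resolution
  interval_gap_merge(episodes[, c("start", "end")], gap = max(gap - 1e-6, 0))
}

#' Snap detector boundaries onto nearby reference boundaries
#'
#' Every detector episode boundary lying within `tolerance_hours` of a
#' reference episode onset or end is moved to coincide with the nearest
#' such reference boundary (the earlier one wins on exact ties); boundaries
#' farther away are unchanged. Episodes that become degenerate (start >=
#' end) after snapping are dropped, and any overlaps introduced by snapping
#' are re-unioned.
#'
#' @param cdss_episodes data.frame with `start`, `end`, one patient,
#'   already merged per [merge_episodes()].
#' @param ref_episodes data.frame with `start`, `end`, same patient.
#' @param tolerance_hours snap radius in hours.
#' @return data.frame with `start`, `end`.
#' @export
snap_boundaries <- function(cdss_episodes, ref_episodes, tolerance_hours = 4) {
  if (is.null(cdss_episodes) || nrow(cdss_episodes) == 0) return(empty_intervals())
  if (is.null(ref_episodes) || nrow(ref_episodes) == 0 || tolerance_hours <= 0) {
    return(interval_union(cdss_episodes[, c("start", "end")]))
  }
  tol <- hours_to_secs(tolerance_hours)
  anchors <- sort(unique(c(as.numeric(ref_episodes$start), as.numeric(ref_episodes$end))))
  snap1 <- function(t) {
    d <- abs(anchors - t)
    i <- which.min(d) # ties resolve to the earlier anchor
    if (d[i] <= tol) anchors[i] else t
  }
  s <- vapply(as.numeric(cdss_episodes$start), snap1, numeric(1))
  e <- vapply(as.numeric(cdss_episodes$end), snap1, numeric(1))
  keep <- e > s
  interval_union(as_intervals(s[keep], e[keep]))
}

#' Partition a stay into labeled evaluation blocks
#'
#' Cuts `[admission, discharge]` at every status-change instant of either
#' the detector or the reference standard; each maximal sub-interval is one
#' block labeled from the (detector status, reference status) pair:
#' both positive = `TP`, reference only = `FN`, detector only = `FP`,
#' neither = `TN`. Episodes are assumed preprocessed ([merge_episodes()],
#' [snap_boundaries()]) and must lie within the stay. The blocks partition
#' the stay exactly; no block is unlabeled.
#'
#' @param patient a [patient_record()] (only admission/discharge and
#'   patient_id are used).
#' @param cdss_episodes,ref_episodes data.frames with `start`, `end` for
#'   this patient.
#' @return data.frame with columns `patient_id`, `start`, `end`, `label`.
#' @export
build_blocks <- function(patient, cdss_episodes, ref_episodes) {
  stopifnot(inherits(patient, "patient_record"))
  adm <- as.numeric(patient$admission)
  dis <- as.numeric(patient$discharge)
  cdss <- if (is.null(cdss_episodes) || nrow(cdss_episodes) == 0) {
    empty_intervals()
  } else interval_union(cdss_episodes[, c("start", "end")])
  ref <- if (is.null(ref_episodes) || nrow(ref_episodes) == 0) {
    empty_intervals()
  } else interval_union(ref_episodes[, c("start", "end")])

  for (iv in list(cdss, ref)) {
    if (nrow(iv) > 0 &&
        (min(as.numeric(iv$start)) < adm || max(as.numeric(iv$end)) > dis)) {
      stop("episode outside [admission, discharge] for patient ",
           patient$patient_id, call. = FALSE)
    }
  }

  cuts <- sort(unique(c(
    adm, dis,
    as.numeric(cdss$start), as.numeric(cdss$end),
    as.numeric(ref$start), as.numeric(ref$end)
  )))
  cuts <- cuts[cuts >= adm & cuts <= dis]
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]

  mids <- (starts + ends) / 2
  in_set <- function(iv, t) {
    if (nrow(iv) == 0) return(rep(FALSE, length(t)))
    vapply(t, function(ti) {
      any(ti >= as.numeric(iv$start) & ti < as.numeric(iv$end))
    }, logical(1))
  }
  cd <- in_set(cdss, mids)
  rf <- in_set(ref, mids)
  label <- ifelse(cd & rf, "TP", ifelse(!cd & rf, "FN", ifelse(cd & !rf, "FP", "TN")))

  data.frame(
    patient_id = patient$patient_id,
    start = num_to_instant(starts), end = num_to_instant(ends),
    label = label
  )
}

#' Cross-tabulate evaluation blocks
#'
#' @param blocks data.frame with a `label` column (`TP`/`FP`/`FN`/`TN`).
#' @return 2x2 integer matrix (rows: detector alarm yes/no; columns:
#'   reference positive/negative) with the block counts.
#' @export
contingency <- function(blocks) {
  lab <- factor(blocks$label, levels = c("TP", "FP", "FN", "TN"))
  cnt <- table(lab)
  matrix(
    c(cnt[["TP"]], cnt[["FP"]], cnt[["FN"]], cnt[["TN"]]),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      cdss = c("alarm", "no alarm"),
      reference = c("positive", "negative")
    )
  )
}

#' Clustered diagnostic accuracy from labeled blocks
#'
#' Pooled sensitivity `sum(TP) / sum(TP + FN)` and specificity
#' `sum(TN) / sum(TN + FP)` over all blocks, with Wald confidence intervals
#' whose variance treats patients as clusters: a ratio-of-cluster-totals
#' linearization over the per-patient sums, so several blocks from one
#' patient are not treated as independent. Patients contributing no
#' reference-positive blocks contribute nothing to the sensitivity variance
#' (and symmetrically for specificity). With `variance = "binomial"` the
#' naive pooled-binomial variance (clustering ignored) is used instead, for
#' comparison.
#'
#' @param blocks data.frame with columns `patient_id` and `label`.
#' @param conf_level confidence level (default 0.95, normal quantile).
#' @param variance `"cluster"` (default) or `"binomial"`.
#' @return object of class `accuracy_result`: the 2x2 block table, point
#'   estimates, standard errors, confidence intervals clipped to \[0, 1\],
#'   patient counts, and explanatory notes when an estimate is undefined.
#' @export
diagnostic_accuracy <- function(blocks, conf_level = 0.95,
                                variance = c("cluster", "binomial")) {
  variance <- match.arg(variance)
  stopifnot(all(c("patient_id", "label") %in% names(blocks)))
  counts <- blocks_to_counts(blocks)
  accuracy_from_counts(counts, conf_level = conf_level, variance = variance)
}

# Per-patient (TP, FP, FN, TN) block counts.
blocks_to_counts <- function(blocks) {
  lab <- factor(blocks$label, levels = c("TP", "FP", "FN", "TN"))
  tab <- table(patient_id = as.character(blocks$patient_id), lab)
  data.frame(
    patient_id = rownames(tab),
    tp = as.integer(tab[, "TP"]), fp = as.integer(tab[, "FP"]),
    fn = as.integer(tab[, "FN"]), tn = as.integer(tab[, "TN"])
  )
}

#' Diagnostic accuracy from per-patient block counts
#'
#' Same computation as [diagnostic_accuracy()] but starting from a
#' data.frame of per-patient counts (columns `patient_id`, `tp`, `fp`,
#' `fn`, `tn`), which is convenient for simulation studies.
#'
#' @inheritParams diagnostic_accuracy
#' @param counts per-patient count data.frame.
#' @return an `accuracy_result`.
#' @export
accuracy_from_counts <- function(counts, conf_level = 0.95,
                                 variance = c("cluster", "binomial")) {
  variance <- match.arg(variance)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- matrix(
    c(sum(counts$tp), sum(counts$fp), sum(counts$fn), sum(counts$tn)),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      cdss = c("alarm", "no alarm"),
      reference = c("positive", "negative")
    )
  )
  notes <- character(0)

  se_part <- ratio_estimate(counts$tp, counts$tp + counts$fn, variance)
  sp_part <- ratio_estimate(counts$tn, counts$tn + counts$fp, variance)
  if (is.na(se_part$estimate)) {
    notes <- c(notes, "sensitivity undefined: no reference-positive blocks")
  }
  if (is.na(sp_part$estimate)) {
    notes <- c(notes, "specificity undefined: no reference-negative blocks")
  }

  structure(
    list(
      table = tab,
      sensitivity = se_part$estimate,
      specificity = sp_part$estimate,
      se_se = se_part$se, sp_se = sp_part$se,
      se_ci = clip01(se_part$estimate + c(-1, 1) * z * se_part$se),
      sp_ci = clip01(sp_part$estimate + c(-1, 1) * z * sp_part$se),
      n_patients = nrow(counts),
      n_blocks = sum(tab),
      conf_level = conf_level,
      variance = variance,
      notes = notes
    ),
    class = "accuracy_result"
  )
}

# Ratio-of-cluster-totals R = sum(x) / sum(n) with linearized variance
# m/(m-1) * sum((x_i - R n_i)^2) / N^2 over the m clusters with n_i > 0.
ratio_estimate <- function(x, n, variance) {
  keep <- n > 0
  x <- x[keep]; n <- n[keep]
  N <- sum(n)
  if (N == 0) return(list(estimate = NA_real_, se = NA_real_))
  R <- sum(x) / N
  if (variance == "binomial") {
    return(list(estimate = R, se = sqrt(R * (1 - R) / N)))
  }
  m <- length(n)
  resid2 <- sum((x - R * n)^2)
  v <- if (resid2 == 0) 0 else m / (m - 1) * resid2 / N^2
  list(estimate = R, se = sqrt(v))
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' @export
print.accuracy_result <- function(x, ...) {
  cat("Block-based diagnostic accuracy (", x$n_blocks, " blocks, ",
      x$n_patients, " patients)\n", sep = "")
  print(x$table)
  fmt <- function(est, ci) {
    if (is.na(est)) return("undefined")
    sprintf("%.3f (%d%% CI: %.3f-%.3f)", est, round(100 * x$conf_level), ci[1], ci[2])
  }
  cat("  sensitivity:", fmt(x$sensitivity, x$se_ci), "\n")
  cat("  specificity:", fmt(x$specificity, x$sp_ci), "\n")
  cat("  variance:", x$variance, "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' End-to-end evaluation of detector episodes against a reference standard
#'
#' For each patient: merges both episode sets (per
#' `config$apply_merge_to`), snaps detector boundaries onto reference
#' boundaries within the tolerance, partitions the stay into labeled
#' blocks, and finally pools all blocks into a clustered accuracy estimate.
#'
#' @param patients list of [patient_record()] objects.
#' @param cdss_episodes data.frame with `patient_id`, `start`, `end` from
#'   the detector.
#' @param ref_episodes data.frame with `patient_id`, `start`, `end` from
#'   the clinician reference standard.
#' @param config an [eval_config()].
#' @param variance passed to [diagnostic_accuracy()].
#' @return list with `blocks` (all labeled blocks) and `accuracy` (an
#'   `accuracy_result`).
#' @export
evaluate_episodes <- function(patients, cdss_episodes, ref_episodes,
                              config = eval_config(), variance = "cluster") {
  stopifnot(inherits(config, "eval_config"))
  block_list <- lapply(patients, function(p) {
    cd <- subset_patient(cdss_episodes, p$patient_id)
    rf <- subset_patient(ref_episodes, p$patient_id)
    rf <- merge_episodes(rf, config$merge_gap_hours)
    if (config$apply_merge_to == "both") {
      cd <- merge_episodes(cd, config$merge_gap_hours)
    } else if (nrow(cd) > 0) {
      cd <- interval_union(cd[, c("start", "end")])
    }
    cd <- snap_boundaries(cd, rf, config$tolerance_hours)
    build_blocks(p, cd, rf)
  })
  blocks <- do.call(rbind, block_list)
  rownames(blocks) <- NULL
  list(blocks = blocks, accuracy = diagnostic_accuracy(blocks, variance = variance))
}

subset_patient <- function(episodes, patient_id) {
  if (is.null(episodes) || nrow(episodes) == 0) return(empty_intervals())
  out <- episodes[as.character(episodes$patient_id) == patient_id,
                  c("start", "end"), drop = FALSE]
  rownames(out) <- NULL
  out
}
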
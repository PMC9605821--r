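#' Detection rule configuration
#'
#' Thresholds, diagnosis code lists and suppression windows for the
#' hematologic organ-dysfunction rules. The diagnostic criteria fix one
#' boundary per analyte: platelets alarm below 80,000/mm3 and the
#' international normalized ratio (INR) alarms above 2. The respective other
#' boundary of each normal range is a clinical plausibility bound; values
#' beyond it are categorized (platelets "too high", INR "too low") but never
#' map to organ dysfunction.
#'
#' @param plt_min platelet lower bound, count/mm3. Values strictly below it
#'   are "too low". Default 80,000.
#' @param plt_max_plausible platelet upper plausibility bound, count/mm3.
#' @param inr_max INR upper bound; values strictly above it are "too high".
#'   Default 2.0.
#' @param inr_min_plausible INR lower plausibility bound.
#' @param decline_fraction relative platelet decline that triggers the
#'   chronic-patient rule: an observation with value
#'   `<= (1 - decline_fraction) * baseline` alarms. Default 0.5 (a drop of at
#'   least 50 percent from the first value after admission).
#' @param chronic_hemonc_codes ICD-10-GM codes identifying chronic
#'   hematologic/oncologic illness; only patients carrying one of these are
#'   eligible for the relative-decline rule. Defaults to the C81-C96
#'   malignant neoplasm prefixes, a placeholder list intended to be replaced
#'   by an institution's own curated set.
#' @param inr_exclusion_codes ICD-10-GM codes of primary diseases that raise
#'   INR (e.g., hereditary factor deficiencies); patients carrying one never
#'   contribute INR alarms. Defaults to the D66-D68 prefixes, likewise a
#'   placeholder.
#' @param prefix_match if `TRUE` (default) a patient diagnosis matches a
#'   configured code when it equals it or extends it (so `"C91.0"` matches
#'   configured `"C91"`); if `FALSE`, exact string equality is required.
#' @param ecmo_pre_hours hours added before each extracorporeal membrane
#'   oxygenation (ECMO) episode when building the platelet-alarm suppression
#'   window. Default 2.
#' @param ecmo_post_hours hours added after each ECMO episode. Default 12.
#' @return object of class `rule_config`.
#' @examples
#' cfg <- rule_config()
#' specify_norm("PLT", cfg)
#' @export
rule_config <- function(plt_min = 80000,
                        plt_max_plausible = 1e6,
                        inr_max = 2,
                        inr_min_plausible = 0.5,
                        decline_fraction = 0.5,
                        chronic_hemonc_codes = default_chronic_hemonc_codes(),
                        inr_exclusion_codes = default_inr_exclusion_codes(),
                        prefix_match = TRUE,
                        ecmo_pre_hours = 2,
                        ecmo_post_hours = 12) {
  stopifnot(
    is.numeric(plt_min), plt_min > 0,
    is.numeric(plt_max_plausible), plt_min < plt_max_plausible,
    is.numeric(inr_max), is.numeric(inr_min_plausible),
    inr_min_plausible < inr_max,
    is.numeric(decline_fraction), decline_fraction > 0, decline_fraction < 1,
    is.numeric(ecmo_pre_hours), ecmo_pre_hours >= 0,
    is.numeric(ecmo_post_hours), ecmo_post_hours >= 0,
    is.logical(prefix_match), length(prefix_match) == 1
  )
  structure(
    list(
      plt_min = plt_min,
      plt_max_plausible = plt_max_plausible,
      inr_max = inr_max,
      inr_min_plausible = inr_min_plausible,
      decline_fraction = decline_fraction,
      chronic_hemonc_codes = toupper(as.character(chronic_hemonc_codes)),
      inr_exclusion_codes = toupper(as.character(inr_exclusion_codes)),
      prefix_match = prefix_match,
      ecmo_pre_hours = ecmo_pre_hours,
      ecmo_post_hours = ecmo_post_hours
    ),
    class = "rule_config"
  )
}

#' Default chronic hematology/oncology diagnosis codes (placeholder list)
#'
#' The ICD-10-GM chapter II prefixes C81-C96 (malignant neoplasms of
#' lymphoid, hematopoietic and related tissue). A deployment should replace
#' this list with its own expert-curated set.
#' @return character vector of code prefixes.
#' @export
default_chronic_hemonc_codes <- function() sprintf("C%02d", 81:96)

#' Default INR-raising primary-disease codes (placeholder list)
#'
#' The ICD-10-GM prefixes D66-D68 (hereditary factor VIII/IX deficiency and
#' other coagulation defects). A deployment should replace this list with
#' its own expert-curated set.
#' @return character vector of code prefixes.
#' @export
default_inr_exclusion_codes <- function() c("D66", "D67", "D68")

#' @export
print.rule_config <- function(x, ...) {
  cat("Hematologic OD rule configuration\n")
  cat(sprintf("  platelets:  alarm < %s /mm3 (plausible <= %s)\n",
              format(x$plt_min, big.mark = ","), format(x$plt_max_plausible, big.mark = ",")))
  cat(sprintf("  INR:        alarm > %s (plausible >= %s)\n", x$inr_max, x$inr_min_plausible))
  cat(sprintf("  relative decline rule: value <= %.0f%% of admission baseline (chronic patients)\n",
              100 * (1 - x$decline_fraction)))
  cat(sprintf("  chronic codes: %d; INR exclusion codes: %d; prefix match: %s\n",
              length(x$chronic_hemonc_codes), length(x$inr_exclusion_codes), x$prefix_match))
  cat(sprintf("  ECMO suppression window: -%g h / +%g h\n", x$ecmo_pre_hours, x$ecmo_post_hours))
  invisible(x)
}

#' Assign the normal range for an analyte
#'
#' The "specify" inference step: picks the normal range a value will be
#' judged against from the rule configuration. For platelets the range is
#' `[plt_min, plt_max_plausible]`; for INR it is
#' `[inr_min_plausible, inr_max]`.
#'
#' @param analyte `"PLT"` or `"INR"`.
#' @param config a [rule_config()].
#' @return object of class `norm_range` with fields `analyte`, `minimum`,
#'   `maximum`.
#' @export
specify_norm <- function(analyte, config = rule_config()) {
  stopifnot(inherits(config, "rule_config"))
  if (!is.character(analyte) || length(analyte) != 1 || !analyte %in% c("PLT", "INR")) {
    stop("unknown analyte: ", deparse(analyte), " (expected \"PLT\" or \"INR\")",
         call. = FALSE)
  }
  rng <- if (analyte == "PLT") {
    c(config$plt_min, config$plt_max_plausible)
  } else {
    c(config$inr_min_plausible, config$inr_max)
  }
  structure(
    list(analyte = analyte, minimum = rng[1], maximum = rng[2]),
    class = "norm_range"
  )
}

#' Categorize an observation against its normal range
#'
#' The "evaluate" inference step: a value strictly below the minimum is
#' `"TOO_LOW"`, strictly above the maximum `"TOO_HIGH"`, otherwise
#' `"NORMAL"`. Boundary values are normal, matching the strict inequalities
#' of the diagnostic criteria (platelets < 80,000/mm3, INR > 2).
#'
#' @param obs a list or one-row data.frame with fields `analyte` and
#'   `value`.
#' @param norm a `norm_range` from [specify_norm()].
#' @return one of `"TOO_LOW"`, `"TOO_HIGH"`, `"NORMAL"`.
#' @export
evaluate_observation <- function(obs, norm) {
  stopifnot(inherits(norm, "norm_range"))
  analyte <- as.character(obs$analyte)
  if (!identical(analyte, norm$analyte)) {
    stop("analyte mismatch: observation is ", analyte, " but norm is for ",
         norm$analyte, call. = FALSE)
  }
  v <- as.numeric(obs$value)
  if (v < norm$minimum) "TOO_LOW" else if (v > norm$maximum) "TOO_HIGH" else "NORMAL"
}

# Vectorized categorization used by the alarm builder.
categorize_values <- function(values, norm) {
  ifelse(values < norm$minimum, "TOO_LOW",
         ifelse(values > norm$maximum, "TOO_HIGH", "NORMAL"))
}

# Does any patient diagnosis match any configured code (exact or prefix)?
codes_match <- function(diagnoses, codes, prefix_match) {
  if (length(diagnoses) == 0 || length(codes) == 0) return(FALSE)
  diagnoses <- toupper(diagnoses)
  if (!prefix_match) return(any(diagnoses %in% codes))
  any(vapply(diagnoses, function(d) any(startsWith(d, codes)), logical(1)))
}
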
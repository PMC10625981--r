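#' Area under the precision-recall curve (step integration)
#'
#' Traces the precision-recall curve over every unique score threshold
#' (descending) and integrates it as a step function (average-precision
#' style: sum of precision times recall increment), avoiding the optimistic
#' bias of trapezoidal interpolation. With constant scores the curve
#' collapses to a single point and the area equals the positive prevalence.
#'
#' @param probabilities numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return The area (numeric scalar in [0, 1]).
#' @export
auprc <- function(probabilities, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) {
    abort("AUPRC needs both classes present.", class = "cvdnotes_config_error")
  }
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; y <- y[ord]
  # group ties: cumulative counts at the end of each distinct-score block
  block_end <- cumsum(rle(p)$lengths)
  tp <- cumsum(y)[block_end]
  np <- sum(y)
  pred_pos <- block_end
  precision <- tp / pred_pos
  recall <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' Precision, recall and F1 after thresholding
#'
#' Uncertain decisions (-1) are excluded from the counted population before
#' the confusion matrix is formed. Metrics with a zero denominator are
#' reported as 0 and flagged as degenerate rather than dropped.
#'
#' @param decisions integer decisions in \{1, 0, -1\}.
#' @param labels 0/1 ground truth, same length.
#' @param exclude_uncertain drop -1 decisions before counting (the only
#'   supported evaluation convention; set to `FALSE` only for decision
#'   vectors that contain no -1).
#' @return One-row tibble: `precision`, `recall`, `f1`, `n_units` (counted),
#'   `n_uncertain_excluded`, `degenerate` (any zero-denominator metric).
#' @export
prf1 <- function(decisions, labels, exclude_uncertain = TRUE) {
  stopifnot(length(decisions) == length(labels),
            all(decisions %in% c(-1L, 0L, 1L)))
  y <- as.integer(labels)
  n_unc <- sum(decisions == -1L)
  if (exclude_uncertain) {
    keep <- decisions != -1L
    decisions <- decisions[keep]; y <- y[keep]
  } else if (n_unc > 0) {
    abort("Uncertain decisions present; use exclude_uncertain = TRUE.",
          class = "cvdnotes_config_error")
  }
  tp <- sum(decisions == 1L & y == 1L)
  fp <- sum(decisions == 1L & y == 0L)
  fn <- sum(decisions == 0L & y == 1L)
  degenerate <- (tp + fp) == 0 || (tp + fn) == 0
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n_units = length(decisions), n_uncertain_excluded = n_unc,
                 degenerate = degenerate)
}

#' Aggregate visit decisions to patient decisions (OR over certain visits)
#'
#' A patient is decided positive when any visit is certain-positive, negative
#' when no visit is certain-positive but at least one is certain-negative,
#' and excluded (NA) when every visit is uncertain.
#'
#' @param decisions visit-level decisions in \{1, 0, -1\}.
#' @param patient_id patient identifier per visit.
#' @return Tibble `patient_id`, `decision` (integer, NA when fully
#'   uncertain), with attribute `n_fully_uncertain`.
#' @export
by_patient_decisions <- function(decisions, patient_id) {
  stopifnot(length(decisions) == length(patient_id))
  out <- tibble::tibble(patient_id = as.character(patient_id),
                        d = as.integer(decisions)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(decision = if (any(.data$d == 1L)) 1L
                     else if (any(.data$d == 0L)) 0L
                     else NA_integer_) |>
    dplyr::ungroup()
  attr(out, "n_fully_uncertain") <- sum(is.na(out$decision))
  out
}

#' Evaluate a set of decision rules by visit and by patient
#'
#' Produces one report row per setting and uncertainty level: the single
#' threshold at level 0 and each calibrated double-threshold rule at its
#' target level. By-visit rows carry the (threshold-free) AUPRC; by-patient
#' rows aggregate thresholded visit decisions with an OR and count patients
#' excluded for having all visits uncertain.
#'
#' @param probabilities visit probabilities on the evaluation split.
#' @param labels visit 0/1 labels.
#' @param patient_id patient identifier per visit.
#' @param rules list of `threshold_search` objects (one single, any number of
#'   double rules).
#' @param patient_labels optional tibble (patient_id, patient_label); by
#'   default the OR of the visit labels in this split.
#' @param window window width (months; `Inf` allowed), echoed in the report.
#' @param setting "by_visit", "by_patient" or "both".
#' @return Tibble of class `cvd_evaluation`: `setting`, `window`,
#'   `uncertainty_level`, `auprc`, `precision`, `recall`, `f1`, `u_achieved`,
#'   `n_units`, `n_uncertain_excluded`, `n_patients_fully_uncertain`,
#'   `degenerate`.
#' @export
evaluate_rules <- function(probabilities, labels, patient_id, rules,
                           patient_labels = NULL, window = NA_real_,
                           setting = c("both", "by_visit", "by_patient")) {
  setting <- match.arg(setting)
  y <- as.integer(labels)
  if (is.null(patient_labels)) {
    patient_labels <- aggregate_by_patient(
      tibble::tibble(patient_id = as.character(patient_id), label = y))
  }
  ap <- auprc(probabilities, y)
  rows <- purrr::map(rules, function(rl) {
    level <- if (rl$rule$kind == "single") 0 else rl$rule$target_u
    dec <- apply_rule(probabilities, rl$rule)
    out <- list()
    if (setting != "by_patient") {
      m <- prf1(dec, y)
      out$by_visit <- dplyr::bind_cols(
        tibble::tibble(setting = "by_visit", window = window,
                       uncertainty_level = level, auprc = ap), m,
        tibble::tibble(u_achieved = mean(dec == -1L),
                       n_patients_fully_uncertain = NA_integer_))
    }
    if (setting != "by_visit") {
      pd <- by_patient_decisions(dec, patient_id)
      pd <- dplyr::inner_join(pd, patient_labels, by = "patient_id")
      counted <- !is.na(pd$decision)
      m <- prf1(pd$decision[counted], pd$patient_label[counted])
      m$n_uncertain_excluded <- attr(pd, "n_fully_uncertain", exact = TRUE) %||%
        sum(is.na(pd$decision))
      out$by_patient <- dplyr::bind_cols(
        tibble::tibble(setting = "by_patient", window = window,
                       uncertainty_level = level, auprc = NA_real_), m,
        tibble::tibble(u_achieved = mean(dec == -1L),
                       n_patients_fully_uncertain = sum(is.na(pd$decision))))
    }
    dplyr::bind_rows(out)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$setting, .data$uncertainty_level)
  class(out) <- c("cvd_evaluation", class(out))
  out
}

#' Evaluate a fitted model end to end on an encoded test split
#'
#' Predicts probabilities for the retained visits and delegates to
#' [evaluate_rules()].
#'
#' @param model a fitted `blstm`.
#' @param rules list of `threshold_search` objects.
#' @param enc encoded test sequences.
#' @param labels 0/1 test labels.
#' @param patient_id patient identifier per test visit.
#' @inheritParams evaluate_rules
#' @return A `cvd_evaluation` tibble.
#' @export
evaluate_pipeline <- function(model, rules, enc, labels, patient_id,
                              patient_labels = NULL, window = NA_real_,
                              setting = c("both", "by_visit", "by_patient")) {
  probs <- predict(model, enc)
  evaluate_rules(probs, labels, patient_id, rules, patient_labels, window,
                 setting)
}

#' Bar-chart view of an evaluation report
#'
#' Precision, recall and F1 per uncertainty level, faceted by setting (and
#' window when several are present), mirroring the usual presentation of
#' reject-option results.
#'
#' @param object a `cvd_evaluation` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cvd_evaluation <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("precision", "recall", "f1"), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric,
                                  levels = c("f1", "precision", "recall")),
                  level = factor(sprintf("%g%%", 100 * .data$uncertainty_level)))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                          fill = .data$level)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Target uncertainty") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(object$window) > 1) {
    p + ggplot2::facet_grid(window ~ setting)
  } else {
    p + ggplot2::facet_wrap(~setting)
  }
}
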
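#' Decision rules over predicted probabilities
#'
#' The single-threshold rule classifies a visit positive when its predicted
#' probability is at least `th`. The double-threshold (reject-option) rule
#' classifies positive at or above `th_high`, negative at or below `th_low`,
#' and abstains (decision -1, "uncertain") strictly in between; the width of
#' the band is calibrated against a target uncertainty level.
#'
#' @param kind "single" or "double".
#' @param th single threshold (single rule).
#' @param th_low,th_high band bounds, `th_low < th_high` (double rule).
#' @param target_u target uncertain fraction the double rule was calibrated
#'   for (conventionally 0.05, 0.10, 0.15 or 0.20).
#' @return A list of class `threshold_rule`.
#' @export
threshold_rule <- function(kind = c("single", "double"), th = NULL,
                           th_low = NULL, th_high = NULL, target_u = NULL) {
  kind <- match.arg(kind)
  if (kind == "single") {
    if (is.null(th) || !is.numeric(th) || is.na(th) || th < 0 || th > 1) {
      abort("Single rule needs a threshold `th` in [0, 1].",
            class = "cvdnotes_config_error")
    }
    rule <- list(kind = "single", th = th)
  } else {
    ok <- is.numeric(th_low) && is.numeric(th_high) && !is.na(th_low) &&
      !is.na(th_high) && th_low >= 0 && th_high <= 1 && th_low < th_high
    if (!ok) {
      abort("Double rule needs 0 <= th_low < th_high <= 1.",
            class = "cvdnotes_config_error")
    }
    rule <- list(kind = "double", th_low = th_low, th_high = th_high,
                 target_u = target_u)
  }
  structure(rule, class = "threshold_rule")
}

#' Apply a decision rule to probabilities
#'
#' @param probabilities numeric vector in [0, 1].
#' @param rule a [threshold_rule()].
#' @return Integer decisions: 1 (positive), 0 (negative), and -1 (uncertain,
#'   double rule only; a single rule never abstains).
#' @export
apply_rule <- function(probabilities, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  p <- probabilities
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("Probabilities must lie in [0, 1].", class = "cvdnotes_config_error")
  }
  if (rule$kind == "single") {
    as.integer(p >= rule$th)
  } else {
    dplyr::case_when(p >= rule$th_high ~ 1L, p <= rule$th_low ~ 0L,
                     .default = -1L)
  }
}

#' Threshold-calibration cost
#'
#' `J = |F1 - 1| + |U_achieved - U_target|`: perfect classification at
#' exactly the target uncertainty gives zero cost.
#'
#' @param f1 achieved F1-score on certain decisions.
#' @param u_achieved achieved uncertain fraction.
#' @param u_target target uncertain fraction.
#' @return The cost (numeric).
#' @export
threshold_cost <- function(f1, u_achieved, u_target) {
  stopifnot(all(f1 >= 0 & f1 <= 1), all(u_achieved >= 0 & u_achieved <= 1),
            all(u_target >= 0 & u_target <= 1))
  abs(f1 - 1) + abs(u_achieved - u_target)
}

.f1_from_counts <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  ifelse(den == 0, 0, 2 * tp / den)
}

#' Optimise the single threshold on a validation set
#'
#' Scans every unique predicted probability as a cut-off and returns the one
#' maximising F1; ties resolve to the lowest threshold (maximising recall).
#'
#' @param probabilities validation probabilities.
#' @param labels 0/1 validation labels (both classes required).
#' @return List of class `threshold_search`: `rule` (a single
#'   [threshold_rule()]), `f1`, `u_achieved` (always 0), `cost`.
#' @export
optimise_single <- function(probabilities, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) {
    abort("Validation labels must contain both classes.",
          class = "cvdnotes_config_error")
  }
  np <- sum(y == 1)
  cand <- sort(unique(probabilities))
  f1 <- vapply(cand, function(th) {
    pred <- probabilities >= th
    tp <- sum(pred & y == 1)
    .f1_from_counts(tp, sum(pred) - tp, np - tp)
  }, numeric(1))
  best <- which(f1 >= max(f1) - 1e-12)[1]  # candidates ascending: lowest th wins
  structure(list(rule = threshold_rule("single", th = cand[best]),
                 f1 = f1[best], u_achieved = 0,
                 cost = threshold_cost(f1[best], 0, 0)),
            class = "threshold_search")
}

# map linear pair indices (enumerated i<j by increasing i) back to (i, j)
.pair_from_index <- function(idx, m) {
  csum <- cumsum((m - 1):1)
  i <- findInterval(idx - 1, c(0, csum), rightmost.closed = FALSE)
  j <- idx - c(0, csum)[i] + i
  cbind(i, j)
}

#' Optimise the double-threshold (reject-option) rule
#'
#' Evaluates candidate (th_low, th_high) pairs drawn from the unique
#' validation probabilities: all ordered pairs when there are at most
#' `n_candidates` of them, otherwise a uniform random subsample of
#' `n_candidates` pairs (seeded). F1 is computed on certain decisions only;
#' the pair minimising `J = |F1 - 1| + |U_achieved - U|` wins, with ties
#' resolved to smaller achieved uncertainty and then smaller `th_low`.
#'
#' @param probabilities validation probabilities.
#' @param labels 0/1 validation labels (both classes required).
#' @param u_target target uncertain fraction (the calibration levels used
#'   downstream are 5%, 10%, 15% and 20%).
#' @param n_candidates candidate-pair budget (default 500000).
#' @param seed seed for subsampling when the budget binds.
#' @return List of class `threshold_search`: `rule`, `f1`, `u_achieved`,
#'   `cost`.
#' @export
optimise_double <- function(probabilities, labels, u_target,
                            n_candidates = 500000L, seed = 1L) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) {
    abort("Validation labels must contain both classes.",
          class = "cvdnotes_config_error")
  }
  stopifnot(u_target >= 0, u_target < 1)
  n <- length(probabilities)
  u <- sort(unique(probabilities))
  m <- length(u)
  if (m < 2) {
    abort("Need at least two distinct probabilities to place a band.",
          class = "cvdnotes_config_error")
  }
  # cumulative counts over sorted unique values
  n_at <- tabulate(match(probabilities, u), m)
  p_at <- tabulate(match(probabilities[y == 1], u), m)
  n_le <- cumsum(n_at);  p_le <- cumsum(p_at)       # p <= u_k
  n_ge <- n - c(0, n_le[-m]); p_ge <- sum(y) - c(0, p_le[-m])  # p >= u_k

  total_pairs <- m * (m - 1) / 2
  if (total_pairs <= n_candidates) {
    i <- rep(seq_len(m - 1), times = (m - 1):1)
    j <- sequence((m - 1):1, from = 2:m)
  } else {
    idx <- withr::with_seed(seed, sort(sample(total_pairs, n_candidates)))
    ij <- .pair_from_index(idx, m)
    i <- ij[, 1]; j <- ij[, 2]
  }
  tp <- p_ge[j]
  fp <- n_ge[j] - tp
  fn <- p_le[i]
  certain <- n_ge[j] + n_le[i]
  if (all(tp + fp == 0)) {
    abort("No candidate pair yields any certain positive prediction.",
          class = "cvdnotes_config_error")
  }
  u_th <- 1 - certain / n
  f1 <- .f1_from_counts(tp, fp, fn)
  cost <- threshold_cost(f1, u_th, u_target)
  # ties (within float noise) resolve to smaller U_th, then smaller th_low
  tied <- which(cost <= min(cost) + 1e-10)
  best <- tied[order(u_th[tied], u[i[tied]])[1]]
  structure(list(rule = threshold_rule("double", th_low = u[i[best]],
                                       th_high = u[j[best]],
                                       target_u = u_target),
                 f1 = f1[best], u_achieved = u_th[best], cost = cost[best]),
            class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  if (x$rule$kind == "single") {
    cat(sprintf("<threshold_search> single th = %.4f | F1 = %.3f\n",
                x$rule$th, x$f1))
  } else {
    cat(sprintf("<threshold_search> double (%.4f, %.4f) | target U = %.2f | F1 = %.3f | U = %.3f | J = %.3f\n",
                x$rule$th_low, x$rule$th_high, x$rule$target_u, x$f1,
                x$u_achieved, x$cost))
  }
  invisible(x)
}

#' @export
tidy.threshold_search <- function(x, ...) {
  tibble::tibble(kind = x$rule$kind,
                 th = if (x$rule$kind == "single") x$rule$th else NA_real_,
                 th_low = if (x$rule$kind == "double") x$rule$th_low else NA_real_,
                 th_high = if (x$rule$kind == "double") x$rule$th_high else NA_real_,
                 target_u = if (x$rule$kind == "double") x$rule$target_u else 0,
                 f1 = x$f1, u_achieved = x$u_achieved, cost = x$cost)
}

#' Serialise threshold rules to JSON
#'
#' @param rules named list of `threshold_search` results.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_threshold_rules <- function(rules, path) {
  out <- purrr::map(rules, function(x) {
    c(x$rule[setdiff(names(x$rule), "kind")],
      list(kind = x$rule$kind, f1 = x$f1, u_achieved = x$u_achieved,
           cost = x$cost))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
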
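#' Shift calendar dates by whole months, clamping day-of-month overflow
#'
#' The look-back windows are defined in calendar months: the window of width
#' `w` before a visit on date `t` starts at `t` shifted back `w` months, with
#' day-of-month overflow clamped to the last day of the target month
#' (2015-03-31 minus one month is 2015-02-28). Both endpoints are inclusive.
#'
#' @param dates a `Date` vector.
#' @param months integer number of months to add (negative to go back).
#' @return A `Date` vector.
#' @export
add_months <- function(dates, months) {
  dates %m+% lubridate::period(months, units = "month")
}

#' @importFrom lubridate %m+%
NULL

#' ICD-9-CM policy defining a CVD hospitalisation
#'
#' A discharge counts as a CVD hospitalisation if any diagnosis code falls in
#' the circulatory-system category range (390-459 on the leading three digits
#' of the dot-free code) or any procedure code matches a revascularisation
#' code. The default procedure set expands the conventional ranges
#' 00.61-00.66, 36.03, 36.06-36.07, 36.10-36.19, plus 00.55, 39.50, 39.52,
#' 38.48, 39.71 and 39.90, written dot-free ("36.06" is "3606"). Procedure
#' matching is by prefix at the full precision of the set entry, so "36061"
#' matches "3606".
#'
#' @param diagnosis_range inclusive integer interval of 3-digit diagnosis
#'   categories.
#' @param intervention_codes character vector of dot-free procedure codes.
#' @return A list of class `code_policy`.
#' @export
code_policy <- function(diagnosis_range = c(390L, 459L),
                        intervention_codes = default_intervention_codes()) {
  stopifnot(length(diagnosis_range) == 2, diagnosis_range[1] <= diagnosis_range[2])
  structure(list(diagnosis_range = as.integer(diagnosis_range),
                 intervention_codes = as.character(intervention_codes)),
            class = "code_policy")
}

#' @rdname code_policy
#' @export
default_intervention_codes <- function() {
  c(sprintf("00%02d", 61:66),          # 00.61-00.66
    "3603", "3606", "3607",            # 36.03, 36.06-36.07
    sprintf("36%02d", 10:19),          # 36.10-36.19
    "0055", "3950", "3952", "3848", "3971", "3990")
}

.split_codes <- function(x) {
  if (is.list(x)) return(lapply(x, as.character))
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

#' Identify CVD hospitalisations by ICD-9-CM code
#'
#' @param hospitalisations tibble with `diagnosis_codes` and
#'   `intervention_codes` columns (semicolon-joined dot-free code strings, or
#'   list columns of code vectors).
#' @param policy a [code_policy()].
#' @return Logical vector, one element per discharge record. Records whose
#'   codes are all empty are skipped (`FALSE`) with a warning.
#' @export
is_cvd_hospitalisation <- function(hospitalisations, policy = code_policy()) {
  dx <- .split_codes(hospitalisations$diagnosis_codes)
  pr <- .split_codes(hospitalisations$intervention_codes)
  rng <- policy$diagnosis_range
  iset <- policy$intervention_codes
  dx_hit <- vapply(dx, function(codes) {
    codes <- codes[nzchar(codes)]
    if (length(codes) == 0) return(FALSE)
    cat3 <- suppressWarnings(as.integer(substr(codes, 1, 3)))
    any(!is.na(cat3) & cat3 >= rng[1] & cat3 <= rng[2] & nchar(codes) >= 3)
  }, logical(1))
  pr_hit <- vapply(pr, function(codes) {
    codes <- codes[nzchar(codes)]
    if (length(codes) == 0) return(FALSE)
    any(vapply(codes, function(cd) any(startsWith(cd, iset)), logical(1)))
  }, logical(1))
  n_codes <- lengths(lapply(dx, function(z) z[nzchar(z)])) +
    lengths(lapply(pr, function(z) z[nzchar(z)]))
  if (any(n_codes == 0)) {
    warn(sprintf("%d discharge record(s) carry no non-empty code and were skipped.",
                 sum(n_codes == 0)))
  }
  dx_hit | pr_hit
}

#' Harmonise a visit table against eligibility and sporadic-entry filters
#'
#' Applies, in order: (1) keep visits inside the observation interval;
#' (2) keep visits inside the patient's eligibility period; (3) drop all
#' visits of patients who do not have at least one visit per calendar year in
#' at least three distinct years (non-consecutive years qualify).
#'
#' @param visits visit tibble (patient_id, visit_date, ...).
#' @param eligibility eligibility tibble (patient_id, start_date, end_date).
#' @param observation_start,observation_end observation interval bounds.
#' @param min_years minimum number of distinct visit years per patient.
#' @return The filtered visit tibble.
#' @export
harmonise_visits <- function(visits, eligibility,
                             observation_start, observation_end,
                             min_years = 3L) {
  observation_start <- as.Date(observation_start)
  observation_end <- as.Date(observation_end)
  out <- visits |>
    dplyr::filter(.data$visit_date >= observation_start,
                  .data$visit_date <= observation_end) |>
    dplyr::inner_join(eligibility, by = "patient_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$visit_date >= .data$start_date,
                  .data$visit_date <= .data$end_date) |>
    dplyr::select(-"start_date", -"end_date")
  keep <- out |>
    dplyr::mutate(.year = as.integer(format(.data$visit_date, "%Y"))) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(.n_years = dplyr::n_distinct(.data$.year)) |>
    dplyr::filter(.data$.n_years >= min_years)
  dplyr::semi_join(out, keep, by = "patient_id")
}

#' Label visits by prior CVD hospitalisation under a look-back window
#'
#' For a finite window of `window_months`, a visit is labelled 1 when a
#' qualifying discharge lies in the inclusive interval from the visit date
#' shifted back `window_months` calendar months up to the visit date itself
#' (a discharge on the visit date counts as prior). With `window_months =
#' Inf` any earlier discharge qualifies, regardless of time distance. Visits
#' whose look-back window is incomplete -- the patient's eligibility period
#' started less than `window_months` before the visit -- are removed for
#' finite windows.
#'
#' @param visits visit tibble.
#' @param hospitalisations discharge registry tibble.
#' @param eligibility eligibility tibble (anchors window completeness).
#' @param policy a [code_policy()].
#' @param window_months positive number of months, or `Inf`.
#' @param observation_end optional; if supplied, a discharge after this date
#'   raises a configuration error.
#' @return The retained visits with `label` (integer 0/1) and `window`
#'   (numeric, `Inf` allowed) columns appended.
#' @export
label_visits <- function(visits, hospitalisations, eligibility,
                         policy = code_policy(), window_months = Inf,
                         observation_end = NULL) {
  stopifnot(is.numeric(window_months), length(window_months) == 1,
            window_months > 0)
  if (!is.null(observation_end) &&
      nrow(hospitalisations) > 0 &&
      any(hospitalisations$discharge_date > as.Date(observation_end))) {
    abort("Discharge dates after `observation_end` found; registry and observation interval disagree.",
          class = "cvdnotes_config_error")
  }
  qualifying <- hospitalisations[is_cvd_hospitalisation(hospitalisations, policy),
                                 c("patient_id", "discharge_date")]
  out <- visits
  if (is.finite(window_months)) {
    w <- as.integer(window_months)
    elig_start <- eligibility[, c("patient_id", "start_date")]
    out <- out |>
      dplyr::inner_join(elig_start, by = "patient_id",
                        relationship = "many-to-many") |>
      dplyr::filter(.data$start_date <= add_months(.data$visit_date, -w)) |>
      dplyr::select(-"start_date")
    win_start <- add_months(out$visit_date, -w)
  } else {
    win_start <- structure(rep(-Inf, nrow(out)), class = "Date")
  }
  out$.row <- seq_len(nrow(out))
  out$.win_start <- win_start
  label <- integer(nrow(out))
  if (nrow(qualifying) > 0 && nrow(out) > 0) {
    hits <- dplyr::inner_join(out[, c(".row", "patient_id", "visit_date", ".win_start")],
                              qualifying, by = "patient_id",
                              relationship = "many-to-many")
    hits <- hits[hits$discharge_date <= hits$visit_date &
                   hits$discharge_date >= hits$.win_start, ]
    label[unique(hits$.row)] <- 1L
  }
  out$label <- label
  out$window <- window_months
  out$.row <- NULL
  out$.win_start <- NULL
  out
}

#' Aggregate visit labels to patient labels (logical OR)
#'
#' A patient is positive if at least one of their visits is positive.
#'
#' @param labelled tibble with `patient_id` and `label` columns.
#' @return Tibble with one row per patient: `patient_id`, `patient_label`.
#' @export
aggregate_by_patient <- function(labelled) {
  labelled |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(patient_label = as.integer(any(.data$label == 1L))) |>
    dplyr::ungroup()
}

#' Patient-grouped train/validation/test split
#'
#' Partitions patients (never visits) into subsets so that all visits of one
#' patient share a split. Subset sizes follow largest-remainder apportionment
#' of the patient count, so 1000 patients at (0.8, 0.1, 0.1) give exactly
#' 800/100/100. Deterministic given `seed`.
#'
#' @param patient_ids character vector (repeats allowed; unique patients are
#'   split).
#' @param fractions named numeric vector summing to 1 (train, validation,
#'   test).
#' @param seed integer seed for the patient permutation.
#' @return Tibble `patient_id`, `split` (factor train/validation/test).
#' @export
split_by_patient <- function(patient_ids,
                             fractions = c(train = 0.8, validation = 0.1, test = 0.1),
                             seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  if (is.null(names(fractions))) {
    names(fractions) <- c("train", "validation", "test")[seq_along(fractions)]
  }
  patients <- sort(unique(as.character(patient_ids)))
  n <- length(patients)
  if (n < sum(fractions > 0)) {
    abort("Fewer patients than non-empty splits.", class = "cvdnotes_config_error")
  }
  quota <- n * fractions
  counts <- floor(quota)
  remainder <- n - sum(counts)
  if (remainder > 0) {
    ord <- order(quota - counts, decreasing = TRUE)  # ties: earlier split wins
    counts[ord[seq_len(remainder)]] <- counts[ord[seq_len(remainder)]] + 1
  }
  shuffled <- withr::with_seed(seed, sample(patients))
  split <- rep(factor(names(fractions), levels = names(fractions)),
               times = counts)
  tibble::tibble(patient_id = shuffled, split = split) |>
    dplyr::arrange(.data$patient_id)
}

#' Build a window-specific labelled dataset with split assignment
#'
#' Runs [harmonise_visits()], [label_visits()] and [split_by_patient()] and
#' returns the per-visit table the classifier consumes, with the by-patient
#' ground truth attached as an attribute.
#'
#' @inheritParams label_visits
#' @inheritParams split_by_patient
#' @param observation_start,observation_end observation interval.
#' @return Tibble `patient_id, visit_date, text, label, window, split`, with
#'   attributes `patient_labels` (tibble) and `window`.
#' @export
build_labelled_dataset <- function(visits, hospitalisations, eligibility,
                                   policy = code_policy(), window_months = Inf,
                                   observation_start, observation_end,
                                   fractions = c(train = 0.8, validation = 0.1,
                                                 test = 0.1),
                                   seed = 1L) {
  harmonised <- harmonise_visits(visits, eligibility, observation_start,
                                 observation_end)
  labelled <- label_visits(harmonised, hospitalisations, eligibility, policy,
                           window_months, observation_end)
  assignment <- split_by_patient(labelled$patient_id, fractions, seed)
  out <- dplyr::inner_join(labelled, assignment, by = "patient_id")
  attr(out, "patient_labels") <- aggregate_by_patient(labelled)
  attr(out, "window") <- window_months
  out
}
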
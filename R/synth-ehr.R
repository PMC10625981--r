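#' Configuration for the synthetic EHR generator
#'
#' Describes a synthetic cohort of diabetes outpatients: how many patients,
#' how often they visit, how often they are hospitalised for cardiovascular
#' disease (CVD), and how reliably a recent hospitalisation leaves a lexical
#' trace in the free-form visit note. The defaults emulate the regime the
#' analysis assumes: roughly 3% of visits positive under a 24-month look-back
#' window, notes that sometimes mention CVD without any recent hospitalisation
#' (risk-factor or family-history phrasing), and hospitalised patients whose
#' notes sometimes omit the event entirely.
#'
#' @param n_patients number of patients.
#' @param visits_per_patient_range integer interval (low, high) for the number
#'   of visits per patient; low must be >= 1.
#' @param observation_start,observation_end calendar dates bounding the
#'   observation period (ISO strings or `Date`s).
#' @param hosp_rate expected hospital discharges per patient-year (all causes
#'   generated here; a fraction carries only non-CVD codes, see
#'   `noncvd_code_rate`). See [calibrate_hosp_rate()] to target a given
#'   positive-visit prevalence.
#' @param mention_given_recent_hosp probability that a note written within
#'   `mention_horizon_months` after a CVD discharge contains hospitalisation
#'   vocabulary.
#' @param spurious_mention_rate probability that a note with no recent CVD
#'   discharge contains CVD vocabulary (risk-factor/history phrasing).
#' @param mention_horizon_months months after a discharge during which the
#'   note may still mention it; beyond this the mention probability drops to
#'   zero (stale mentions are what make narrow windows hard).
#' @param noncvd_code_rate probability that a generated discharge carries only
#'   non-CVD codes.
#' @param seed integer seed; generation is a pure function of the full config.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 2000,
                             visits_per_patient_range = c(3L, 7L),
                             observation_start = "2011-01-01",
                             observation_end = "2018-09-30",
                             hosp_rate = calibrate_hosp_rate(),
                             mention_given_recent_hosp = 0.9,
                             spurious_mention_rate = 0.02,
                             mention_horizon_months = 24L,
                             noncvd_code_rate = 0.15,
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    visits_per_patient_range = as.integer(visits_per_patient_range),
    observation_start = as.Date(observation_start),
    observation_end = as.Date(observation_end),
    hosp_rate = hosp_rate,
    mention_given_recent_hosp = mention_given_recent_hosp,
    spurious_mention_rate = spurious_mention_rate,
    mention_horizon_months = as.integer(mention_horizon_months),
    noncvd_code_rate = noncvd_code_rate,
    seed = as.integer(seed)
  )
  probs <- c(mention_given_recent_hosp = cfg$mention_given_recent_hosp,
             spurious_mention_rate = cfg$spurious_mention_rate,
             noncvd_code_rate = cfg$noncvd_code_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("All probabilities must lie in [0, 1].", class = "cvdnotes_config_error")
  }
  if (cfg$n_patients < 1) {
    abort("`n_patients` must be a positive integer.", class = "cvdnotes_config_error")
  }
  if (length(cfg$visits_per_patient_range) != 2 ||
      cfg$visits_per_patient_range[1] < 1 ||
      diff(cfg$visits_per_patient_range) < 0) {
    abort("`visits_per_patient_range` must be an increasing interval with lower bound >= 1.",
          class = "cvdnotes_config_error")
  }
  if (is.na(cfg$observation_start) || is.na(cfg$observation_end) ||
      cfg$observation_start >= cfg$observation_end) {
    abort("`observation_start` must precede `observation_end`.",
          class = "cvdnotes_config_error")
  }
  if (!is.finite(cfg$hosp_rate) || cfg$hosp_rate < 0) {
    abort("`hosp_rate` must be a non-negative rate.", class = "cvdnotes_config_error")
  }
  if (cfg$mention_horizon_months < 1) {
    abort("`mention_horizon_months` must be positive.", class = "cvdnotes_config_error")
  }
  structure(cfg, class = "generator_config")
}

#' Hospitalisation rate that targets a given positive-visit prevalence
#'
#' CVD discharges arrive as a Poisson process with rate
#' `hosp_rate * (1 - noncvd_code_rate)` per patient-year, so a visit with a
#' complete `window_months` look-back window is positive with probability
#' `1 - exp(-rate * window_months / 12)`. Inverting that relation gives the
#' all-cause discharge rate needed to hit a target prevalence.
#'
#' @param target_prevalence desired fraction of positive visits at the window.
#' @param window_months look-back window the prevalence refers to.
#' @param noncvd_code_rate fraction of discharges carrying only non-CVD codes.
#' @return Discharges per patient-year (numeric scalar).
#' @export
calibrate_hosp_rate <- function(target_prevalence = 0.03, window_months = 24,
                                noncvd_code_rate = 0.15) {
  stopifnot(target_prevalence > 0, target_prevalence < 1, window_months > 0,
            noncvd_code_rate >= 0, noncvd_code_rate < 1)
  -log(1 - target_prevalence) / (window_months / 12) / (1 - noncvd_code_rate)
}

# token pools for templated pseudo-Italian notes -------------------------------

.note_theme_phrases <- c(
  "controllo della glicemia a digiuno",
  "emoglobina glicata in lieve aumento",
  "buon compenso glicemico complessivo",
  "valori glicemici nella norma",
  "prosegue terapia con metformina",
  "terapia insulinica invariata",
  "modificato il dosaggio della terapia",
  "consigliata dieta ipocalorica",
  "calo ponderale da monitorare",
  "si raccomanda attivita fisica regolare",
  "esame del fundus oculare programmato",
  "microalbuminuria nella norma",
  "pressione arteriosa ben controllata",
  "prossimo controllo tra sei mesi",
  "esami ematochimici di routine richiesti",
  "paziente in buone condizioni generali",
  "riferita buona aderenza alla dieta",
  "peso corporeo stabile alla visita"
)

# phrasing a clinician uses when a recent hospital stay is discussed
.note_hosp_phrases <- c(
  "recente ricovero per infarto miocardico acuto",
  "ricovero ospedaliero per scompenso cardiaco",
  "dimesso dopo angioplastica coronarica con stent",
  "ricovero per cardiopatia ischemica instabile",
  "recente ricovero per ictus cerebrale",
  "eseguito bypass aortocoronarico durante il ricovero"
)

# CVD vocabulary with no hospitalisation narrative (risk factors, history)
.note_risk_phrases <- c(
  "familiarita per cardiopatia ischemica",
  "rischio cardiovascolare da monitorare",
  "riferita pregressa angina da sforzo",
  "ipertensione arteriosa in trattamento"
)

.cvd_dx_pool <- c("41071", "41401", "4280", "43491", "4139", "42731", "44024")
.noncvd_dx_pool <- c("25000", "5849", "4869", "5990", "71590", "53081")
.cvd_proc_pool <- c("3606", "3607", "3603", "3612", "0061", "0066", "3950",
                    "3952", "3848", "3971", "3990", "0055")
.noncvd_proc_pool <- c("8154", "5123", "8051")

#' Generate a synthetic visit table, discharge registry and eligibility table
#'
#' Simulates, per patient, an eligibility period (the full observation window
#' for 90% of patients, a random sub-interval for the rest), visit dates inside
#' that period, and hospital discharges from a Poisson process. Discharges
#' carry ICD-9-CM codes (dot-free digit strings); a configurable fraction is
#' non-CVD only. Visit notes are assembled from templated clinical phrases;
#' a note written within `mention_horizon_months` after a CVD discharge
#' contains hospitalisation vocabulary with probability
#' `mention_given_recent_hosp`, while other notes contain spurious CVD
#' vocabulary (risk-factor phrasing) with probability `spurious_mention_rate`.
#'
#' @param config a [generator_config()].
#' @return A list with tibbles `visits` (patient_id, visit_date, text),
#'   `hospitalisations` (patient_id, discharge_date, diagnosis_codes,
#'   intervention_codes; codes semicolon-joined), and `eligibility`
#'   (patient_id, start_date, end_date).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  span <- as.integer(cfg$observation_end - cfg$observation_start)

  # eligibility: most patients observed throughout; 10% a random sub-interval
  partial <- runif(n) < 0.10
  third <- span %/% 3
  start_off <- ifelse(partial, floor(runif(n, 0, third + 1)), 0)
  end_off <- ifelse(partial, floor(runif(n, 0, third + 1)), 0)
  eligibility <- tibble::tibble(
    patient_id = ids,
    start_date = cfg$observation_start + start_off,
    end_date = cfg$observation_end - end_off
  )

  elig_days <- as.integer(eligibility$end_date - eligibility$start_date)
  n_visits <- sample(seq(cfg$visits_per_patient_range[1],
                         cfg$visits_per_patient_range[2]), n, replace = TRUE)
  visits <- tibble::tibble(
    patient_id = rep(ids, n_visits),
    .start = rep(eligibility$start_date, n_visits),
    .days = rep(elig_days, n_visits)
  )
  visits$visit_date <- visits$.start + floor(runif(nrow(visits), 0, visits$.days + 1))
  visits <- dplyr::arrange(visits[, c("patient_id", "visit_date")],
                           .data$patient_id, .data$visit_date)

  # discharges: Poisson process over each eligibility period
  n_hosp <- rpois(n, cfg$hosp_rate * elig_days / 365.25)
  hosp <- tibble::tibble(
    patient_id = rep(ids, n_hosp),
    .start = rep(eligibility$start_date, n_hosp),
    .days = rep(elig_days, n_hosp)
  )
  m <- nrow(hosp)
  hosp$discharge_date <- hosp$.start + floor(runif(m, 0, hosp$.days + 1))
  is_cvd <- runif(m) >= cfg$noncvd_code_rate
  proc_only <- is_cvd & runif(m) < 0.25  # revascularisation without a 390-459 code
  dx <- character(m); proc <- character(m)
  if (m > 0) {
    dx[is_cvd] <- sample(.cvd_dx_pool, sum(is_cvd), replace = TRUE)
    dx[proc_only] <- "25000"
    dx[!is_cvd] <- sample(.noncvd_dx_pool, sum(!is_cvd), replace = TRUE)
    proc[proc_only] <- sample(.cvd_proc_pool, sum(proc_only), replace = TRUE)
    idx_np <- !is_cvd & runif(m) < 0.3
    proc[idx_np] <- sample(.noncvd_proc_pool, sum(idx_np), replace = TRUE)
  }
  hospitalisations <- tibble::tibble(
    patient_id = hosp$patient_id,
    discharge_date = hosp$discharge_date,
    diagnosis_codes = dx,
    intervention_codes = proc
  )
  hospitalisations <- dplyr::arrange(hospitalisations, .data$patient_id,
                                     .data$discharge_date)

  # notes: does a CVD discharge precede the visit within the mention horizon?
  cvd_hosp <- hospitalisations[is_cvd_hospitalisation(hospitalisations), ]
  horizon_start <- add_months(visits$visit_date, -cfg$mention_horizon_months)
  recent <- logical(nrow(visits))
  if (nrow(cvd_hosp) > 0) {
    hits <- dplyr::inner_join(
      dplyr::mutate(visits, .row = dplyr::row_number(), .h = horizon_start),
      cvd_hosp[, c("patient_id", "discharge_date")],
      by = "patient_id", relationship = "many-to-many"
    )
    hits <- hits[hits$discharge_date <= hits$visit_date &
                   hits$discharge_date >= hits$.h, ]
    recent[unique(hits$.row)] <- TRUE
  }
  nv <- nrow(visits)
  mention <- ifelse(recent, runif(nv) < cfg$mention_given_recent_hosp, FALSE)
  spurious <- !recent & runif(nv) < cfg$spurious_mention_rate
  n_phrase <- sample(2:4, nv, replace = TRUE)
  base_text <- vapply(n_phrase, function(k) {
    paste(sample(.note_theme_phrases, k, replace = FALSE), collapse = " ")
  }, character(1))
  extra <- character(nv)
  extra[mention] <- sample(.note_hosp_phrases, sum(mention), replace = TRUE)
  extra[spurious] <- sample(.note_risk_phrases, sum(spurious), replace = TRUE)
  text <- ifelse(extra == "", base_text,
                 ifelse(runif(nv) < 0.5, paste(extra, base_text),
                        paste(base_text, extra)))
  visits <- tibble::tibble(patient_id = visits$patient_id,
                           visit_date = visits$visit_date, text = text)
  list(visits = visits, hospitalisations = hospitalisations,
       eligibility = eligibility)
}

#' Write / read a synthetic cohort as CSV files
#'
#' `write_cohort()` writes `visits.csv`, `hospitalisations.csv` and
#' `eligibility.csv` (UTF-8, header row, ISO-8601 dates, ICD-9-CM codes
#' semicolon-joined) into `dir`; `read_cohort()` reads them back and validates
#' dates and columns, naming the offending line on failure. The round trip is
#' the identity.
#'
#' @param cohort list with `visits`, `hospitalisations`, `eligibility` tibbles.
#' @param dir directory to write to / read from (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns a
#'   cohort list like [generate_cohort()]'s.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$visits, file.path(dir, "visits.csv"))
  readr::write_csv(cohort$hospitalisations, file.path(dir, "hospitalisations.csv"))
  readr::write_csv(cohort$eligibility, file.path(dir, "eligibility.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(
    visits = .read_table(file.path(dir, "visits.csv"),
                         c("patient_id", "visit_date", "text"), "visit_date"),
    hospitalisations = .read_table(
      file.path(dir, "hospitalisations.csv"),
      c("patient_id", "discharge_date", "diagnosis_codes", "intervention_codes"),
      "discharge_date"),
    eligibility = .read_table(file.path(dir, "eligibility.csv"),
                              c("patient_id", "start_date", "end_date"),
                              c("start_date", "end_date"))
  )
}

.read_table <- function(path, columns, date_cols) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "cvdnotes_parse_error")
  }
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  missing <- setdiff(columns, names(x))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing column(s) ", paste(missing, collapse = ", ")),
          class = "cvdnotes_parse_error")
  }
  x <- x[columns]
  for (col in date_cols) {
    parsed <- as.Date(x[[col]], format = "%Y-%m-%d", optional = TRUE)
    bad <- which(is.na(parsed) & !is.na(x[[col]]))
    bad <- c(bad, which(is.na(x[[col]])))
    if (length(bad) > 0) {
      abort(sprintf("%s: cannot parse %s as ISO-8601 date at line %d",
                    path, col, min(bad) + 1L),  # +1 for the header row
            class = "cvdnotes_parse_error")
    }
    x[[col]] <- parsed
  }
  replace_na_chr <- function(v) ifelse(is.na(v), "", v)
  for (col in setdiff(columns, c(date_cols, "patient_id"))) {
    if (is.character(x[[col]])) x[[col]] <- replace_na_chr(x[[col]])
  }
  x
}
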
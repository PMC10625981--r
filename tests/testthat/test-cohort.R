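test_that("diagnosis codes are matched on their 3-digit category", {
  h <- tibble::tibble(
    diagnosis_codes = c("41071", "25000", "390", "4599", "38900", "46000"),
    intervention_codes = "")
  expect_equal(is_cvd_hospitalisation(h),
               c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("intervention codes match by prefix at the set entry's precision", {
  h <- tibble::tibble(
    diagnosis_codes = "25000",
    intervention_codes = c("3606", "36061", "3615", "3620", "0061", "8154",
                           "3950;8154"))
  expect_equal(is_cvd_hospitalisation(h),
               c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("records without any code are skipped with a warning", {
  h <- tibble::tibble(diagnosis_codes = c("", "41071"),
                      intervention_codes = c("", ""))
  expect_warning(res <- is_cvd_hospitalisation(h), "skipped")
  expect_equal(res, c(FALSE, TRUE))
})

test_that("window labelling follows inclusive month arithmetic", {
  co <- tiny_cohort()
  # A: discharge 2014-12-01; visit 2015-06-01 is 6 months later
  lab12 <- label_visits(co$visits, co$hospitalisations, co$eligibility,
                        window_months = 12)
  expect_equal(lab12$label[lab12$patient_id == "A" &
                             lab12$visit_date == as.Date("2015-06-01")], 1L)
  # a discharge preceding the visit by *at most* the window width counts:
  # 2014-12-01 is exactly 6 months before, so the 6-month window keeps it
  lab6 <- label_visits(co$visits, co$hospitalisations, co$eligibility,
                       window_months = 6)
  expect_equal(lab6$label[lab6$patient_id == "A" &
                            lab6$visit_date == as.Date("2015-06-01")], 1L)
  # one day further back falls outside the window
  hosp2 <- dplyr::mutate(co$hospitalisations,
                         discharge_date = discharge_date - 1)
  lab6b <- label_visits(co$visits, hosp2, co$eligibility, window_months = 6)
  expect_equal(lab6b$label[lab6b$patient_id == "A" &
                             lab6b$visit_date == as.Date("2015-06-01")], 0L)
  # infinite window: any prior discharge counts, regardless of distance
  labinf <- label_visits(co$visits, co$hospitalisations, co$eligibility,
                         window_months = Inf)
  expect_true(all(labinf$label[labinf$patient_id == "B"] == 1L))
})

test_that("day-of-month overflow clamps to month end", {
  expect_equal(add_months(as.Date("2015-03-31"), -1), as.Date("2015-02-28"))
  expect_equal(add_months(as.Date("2016-03-31"), -1), as.Date("2016-02-29"))
  v <- tibble::tibble(patient_id = "Z", visit_date = as.Date("2015-03-31"),
                      text = "x")
  e <- tibble::tibble(patient_id = "Z", start_date = as.Date("2010-01-01"),
                      end_date = as.Date("2018-01-01"))
  h <- tibble::tibble(patient_id = "Z",
                      discharge_date = as.Date(c("2015-02-28", "2015-02-27")),
                      diagnosis_codes = "4280", intervention_codes = "")
  lab <- label_visits(v, h[1, ], e, window_months = 1)
  expect_equal(lab$label, 1L)
  lab <- label_visits(v, h[2, ], e, window_months = 1)
  expect_equal(lab$label, 0L)
})

test_that("visits with incomplete look-back windows are removed", {
  co <- tiny_cohort()  # C's eligibility starts 2015-10-01
  lab6 <- label_visits(co$visits, co$hospitalisations, co$eligibility,
                       window_months = 6)
  expect_false("C" %in% lab6$patient_id)  # 2016-01-01 is < 6 months after start
  labinf <- label_visits(co$visits, co$hospitalisations, co$eligibility,
                         window_months = Inf)
  expect_true("C" %in% labinf$patient_id)  # no removal for the infinite window
})

test_that("a discharge after the observation end is a configuration error", {
  co <- tiny_cohort()
  expect_error(label_visits(co$visits, co$hospitalisations, co$eligibility,
                            window_months = 24,
                            observation_end = "2015-01-01"),
               class = "cvdnotes_config_error")
})

test_that("labelling matches the all-pairs oracle and windows are monotone", {
  co <- generate_cohort(generator_config(n_patients = 120, seed = 14,
                                         hosp_rate = 0.08))
  qual <- co$hospitalisations[is_cvd_hospitalisation(co$hospitalisations), ]
  labs <- lapply(c(6, 12, 24, Inf), function(w) {
    lab <- label_visits(co$visits, co$hospitalisations, co$eligibility,
                        window_months = w)
    expect_equal(lab$label, oracle_label(lab, qual, w))
    lab
  })
  common <- Reduce(function(a, b) {
    dplyr::inner_join(a, b, by = c("patient_id", "visit_date"))
  }, lapply(labs, function(l) l[, c("patient_id", "visit_date", "label")] |>
              dplyr::distinct()))
  # label_6 <= label_12 <= label_24 <= label_inf for every common visit
  m <- as.matrix(common[, grep("label", names(common))])
  expect_true(all(diff(t(m)) >= 0))
})

test_that("harmonisation keeps patients with visits in three distinct years", {
  elig <- tibble::tibble(patient_id = c("A", "B", "C"),
                         start_date = as.Date("2011-01-01"),
                         end_date = as.Date("2018-09-30"))
  visits <- tibble::tibble(
    patient_id = c(rep("A", 3), rep("B", 5), rep("C", 3)),
    visit_date = as.Date(c("2012-03-01", "2013-07-01", "2014-11-01",      # A: 3 years
                           rep("2012-05-02", 5),                          # B: 1 year
                           "2012-03-01", "2013-07-01", "2019-01-01")),    # C: 3rd outside obs
    text = "x")
  out <- harmonise_visits(visits, elig, "2011-01-01", "2018-09-30")
  expect_setequal(unique(out$patient_id), "A")
  expect_equal(nrow(out), 3)
})

test_that("visits outside eligibility are dropped before the year count", {
  elig <- tibble::tibble(patient_id = "D", start_date = as.Date("2013-01-01"),
                         end_date = as.Date("2018-09-30"))
  visits <- tibble::tibble(
    patient_id = "D",
    visit_date = as.Date(c("2012-06-01", "2013-06-01", "2014-06-01", "2015-06-01")),
    text = "x")
  out <- harmonise_visits(visits, elig, "2011-01-01", "2018-09-30")
  # 2012 visit is outside eligibility; D still has 2013/2014/2015
  expect_equal(nrow(out), 3)
  visits2 <- visits[1:3, ]
  out2 <- harmonise_visits(visits2, elig, "2011-01-01", "2018-09-30")
  expect_equal(nrow(out2), 0)  # only 2 eligible years remain
})

test_that("patient aggregation is an OR over visit labels", {
  lab <- tibble::tibble(patient_id = c("A", "A", "A", "B", "B", "C"),
                        label = c(0L, 0L, 1L, 0L, 0L, 1L))
  agg <- aggregate_by_patient(lab)
  expect_equal(agg$patient_label[match(c("A", "B", "C"), agg$patient_id)],
               c(1L, 0L, 1L))
  # brute-force per-patient max oracle on random data
  set.seed(4)
  lab <- tibble::tibble(patient_id = sample(letters[1:15], 80, replace = TRUE),
                        label = sample(0:1, 80, replace = TRUE, prob = c(.9, .1)))
  agg <- aggregate_by_patient(lab)
  brute <- tapply(lab$label, lab$patient_id, max)
  expect_equal(agg$patient_label, as.integer(brute[agg$patient_id]),
               ignore_attr = TRUE)
})

test_that("patient-grouped splits are deterministic and exactly apportioned", {
  ids <- sprintf("P%03d", 1:1000)
  a <- split_by_patient(ids, seed = 7)
  b <- split_by_patient(ids, seed = 7)
  expect_identical(a, b)
  expect_equal(as.integer(table(a$split)), c(800L, 100L, 100L))
  # all visits of one patient share a split by construction
  many <- rep(ids, times = sample(1:4, 1000, replace = TRUE))
  s <- split_by_patient(many, seed = 1)
  expect_equal(nrow(s), 1000)
  # degenerate fractions
  all_train <- split_by_patient(ids[1:10], fractions = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))
  expect_error(split_by_patient(c("A", "B"), seed = 1),
               class = "cvdnotes_config_error")
})
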
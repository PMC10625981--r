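# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as naive loops over first-principles
# definitions, sharing no code path with the package internals.

# all-pairs date-comparison labelling oracle (plain vectors for speed)
oracle_label <- function(visits, cvd_discharges, window_months) {
  vp <- visits$patient_id; vd <- visits$visit_date
  hp <- cvd_discharges$patient_id; hd <- cvd_discharges$discharge_date
  win_start <- if (is.finite(window_months)) {
    add_months(vd, -window_months)
  } else {
    structure(rep(-Inf, length(vd)), class = "Date")
  }
  out <- integer(length(vp))
  for (i in seq_along(vp)) {
    hit <- FALSE
    for (j in seq_along(hp)) {
      if (hp[j] != vp[i]) next
      if (hd[j] > vd[i]) next
      if (hd[j] < win_start[i]) next
      hit <- TRUE
      break
    }
    out[i] <- as.integer(hit)
  }
  out
}

# step-curve AUPRC by explicit threshold enumeration
oracle_auprc <- function(probs, y) {
  ths <- sort(unique(probs), decreasing = TRUE)
  np <- sum(y == 1)
  prev_recall <- 0
  area <- 0
  for (th in ths) {
    pred <- probs >= th
    tp <- sum(pred & y == 1)
    precision <- tp / sum(pred)
    recall <- tp / np
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

oracle_prf1 <- function(decisions, y) {
  keep <- decisions != -1L
  d <- decisions[keep]; yy <- y[keep]
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(d)) {
    if (d[i] == 1 && yy[i] == 1) tp <- tp + 1
    if (d[i] == 1 && yy[i] == 0) fp <- fp + 1
    if (d[i] == 0 && yy[i] == 1) fn <- fn + 1
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

# exhaustive single-threshold scan
oracle_single <- function(probs, y) {
  best_f1 <- -1; best_th <- NA
  for (th in sort(unique(probs))) {
    dec <- as.integer(probs >= th)
    f1 <- oracle_prf1(dec, y)[["f1"]]
    if (f1 > best_f1 + 1e-12) {
      best_f1 <- f1; best_th <- th
    }
  }
  list(th = best_th, f1 = best_f1)
}

# exhaustive double-threshold scan over ordered pairs of unique probabilities
oracle_double <- function(probs, y, u_target) {
  u <- sort(unique(probs))
  n <- length(probs)
  best <- NULL
  for (i in seq_len(length(u) - 1)) {
    for (j in (i + 1):length(u)) {
      dec <- ifelse(probs >= u[j], 1L, ifelse(probs <= u[i], 0L, -1L))
      u_th <- mean(dec == -1L)
      f1 <- oracle_prf1(dec, y)[["f1"]]
      cost <- abs(f1 - 1) + abs(u_th - u_target)
      cand <- list(lo = u[i], hi = u[j], f1 = f1, u = u_th, cost = cost)
      if (is.null(best) || cost < best$cost - 1e-12 ||
          (abs(cost - best$cost) <= 1e-12 &&
           (u_th < best$u - 1e-12 ||
            (abs(u_th - best$u) <= 1e-12 && u[i] < best$lo)))) {
        best <- cand
      }
    }
  }
  best
}

# plug-in mutual information between two binary vectors (nats)
mutual_info <- function(x, y) {
  mi <- 0
  for (a in c(FALSE, TRUE)) {
    for (b in c(0L, 1L)) {
      pxy <- mean(x == a & y == b)
      if (pxy == 0) next
      mi <- mi + pxy * log(pxy / (mean(x == a) * mean(y == b)))
    }
  }
  mi
}

cvd_lexicon <- function() {
  c("ricovero", "dimesso", "infarto", "miocardico", "scompenso", "cardiaco",
    "angioplastica", "coronarica", "stent", "bypass", "aortocoronarico",
    "ictus", "cerebrale", "cardiopatia", "ischemica", "familiarita",
    "cardiovascolare", "angina", "ipertensione")
}

note_has_cvd_vocab <- function(texts) {
  vapply(strsplit(tolower(texts), "\\s+"),
         function(tk) any(tk %in% cvd_lexicon()), logical(1))
}

# small hand-written fixture used across cohort tests
tiny_cohort <- function() {
  visits <- tibble::tibble(
    patient_id = c("A", "A", "A", "B", "B", "C"),
    visit_date = as.Date(c("2013-05-10", "2014-06-01", "2015-06-01",
                           "2014-03-03", "2015-03-31", "2016-01-01")),
    text = paste("nota visita numero", 1:6)
  )
  hosp <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    discharge_date = as.Date(c("2014-12-01", "2001-01-01", "2015-12-31")),
    diagnosis_codes = c("41071", "4280", "25000"),
    intervention_codes = c("", "", "")
  )
  elig <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    start_date = as.Date(c("2011-01-01", "2011-01-01", "2015-10-01")),
    end_date = as.Date(rep("2018-09-30", 3))
  )
  list(visits = visits, hospitalisations = hosp, eligibility = elig)
}
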
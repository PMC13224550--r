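# Shared in-code fixtures for the unit tests.

sofa1_tab <- read_score_table("sofa1")
sofa2_tab <- read_score_table("sofa2")

# one admission, two days, hand-checkable values
tiny_observations <- function(id = "a1") {
  data.frame(
    admission_id = id,
    variable = c("platelets", "map", "pao2", "fio2", "gcs_total",
                 "bilirubin", "creatinine", "urine_output"),
    time_h = c(2, 3, 5, 4, 6, 7, 8, 20),
    value = c(45, 65, 80, 0.5, 6, 30, 120, 900),
    unit = c("10^9/L", "mmHg", "mmHg", "fraction", "score",
             "umol/L", "umol/L", "mL"))
}

tiny_therapies <- function(id = "a1") {
  data.frame(admission_id = id, therapy = "mechanical_ventilation",
             drug = NA_character_, rate = NA_real_, start_h = 20, end_h = 30)
}

# independent straight-line re-scorer: filters events per day by explicit
# comparison and applies the band logic domain by domain (SOFA-1 bands,
# no imputation) — the brute-force oracle for the vectorised engine
oracle_sofa1_day <- function(obs, ther, id, day) {
  inwin <- function(v) {
    e <- obs[obs$admission_id == id & obs$variable == v &
               obs$time_h >= 24 * (day - 1) & obs$time_h < 24 * day, ]
    e$value
  }
  flag <- function(tp) {
    t <- ther[ther$admission_id == id & ther$therapy == tp, ]
    any(t$start_h < 24 * day & t$end_h > 24 * (day - 1))
  }
  score <- c(respiration = 0, coagulation = 0, liver = 0,
             cardiovascular = 0, brain = 0, renal = 0)
  plt <- inwin("platelets")
  if (length(plt)) {
    p <- min(plt)
    score["coagulation"] <-
      if (p < 20) 4 else if (p < 50) 3 else if (p < 100) 2 else if (p < 150) 1 else 0
  }
  bil <- inwin("bilirubin")
  if (length(bil)) {
    b <- max(bil)
    score["liver"] <-
      if (b > 204) 4 else if (b >= 102) 3 else if (b >= 33) 2 else if (b >= 20) 1 else 0
  }
  cre <- inwin("creatinine"); uo <- inwin("urine_output")
  cr <- if (length(cre)) max(cre) else NA
  u <- if (length(uo)) sum(uo) else NA
  r <- 0
  if (!is.na(cr)) r <- max(r, if (cr > 440) 4 else if (cr >= 300) 3
                           else if (cr >= 171) 2 else if (cr >= 110) 1 else 0)
  if (!is.na(u)) r <- max(r, if (u < 200) 4 else if (u < 500) 3 else 0)
  score["renal"] <- r
  g <- inwin("gcs_total")
  if (length(g)) {
    gm <- min(g)
    score["brain"] <-
      if (gm < 6) 4 else if (gm < 10) 3 else if (gm < 13) 2 else if (gm < 15) 1 else 0
  }
  mp <- inwin("map")
  vas <- ther[ther$admission_id == id & ther$therapy == "vasopressor" &
                ther$start_h < 24 * day & ther$end_h > 24 * (day - 1), ]
  nee <- if (nrow(vas)) sum(tapply(vas$rate, vas$drug, max)) else 0
  score["cardiovascular"] <-
    if (nee > 0.1) 4 else if (nee > 0) 3 else if (length(mp) && min(mp) < 70) 1 else 0
  # respiration: pair each pao2 with most recent fio2 (whole stay)
  pa <- obs[obs$admission_id == id & obs$variable == "pao2" &
              obs$time_h >= 24 * (day - 1) & obs$time_h < 24 * day, ]
  fi <- obs[obs$admission_id == id & obs$variable == "fio2", ]
  if (nrow(pa)) {
    ratios <- sapply(seq_len(nrow(pa)), function(i) {
      prev <- fi[fi$time_h <= pa$time_h[i], ]
      f <- if (nrow(prev)) prev$value[which.max(prev$time_h)] else
        if (nrow(fi)) fi$value[which.min(fi$time_h)] else 0.21
      pa$value[i] / f
    })
    pf <- min(ratios)
    supp <- flag("mechanical_ventilation") || flag("ecmo")
    score["respiration"] <-
      if (pf < 100 && supp) 4 else if (pf < 200 && supp) 3 else
        if (pf < 300) 2 else if (pf < 400) 1 else 0
  }
  score
}

# random event streams for property tests (all noradrenaline vasopressors)
random_admission_events <- function(id, n_days = 3, n_events = 30) {
  vars <- c("platelets", "bilirubin", "creatinine", "map", "gcs_total",
            "urine_output", "pao2", "fio2")
  v <- sample(vars, n_events, replace = TRUE)
  val <- vapply(v, function(x) switch(x,
    platelets = runif(1, 5, 400), bilirubin = runif(1, 2, 400),
    creatinine = runif(1, 40, 600), map = runif(1, 40, 110),
    gcs_total = sample(3:15, 1), urine_output = runif(1, 50, 900),
    pao2 = runif(1, 40, 140), fio2 = runif(1, 0.21, 1)), numeric(1))
  obs <- data.frame(admission_id = id, variable = v,
                    time_h = runif(n_events, 0, 24 * n_days), value = val,
                    unit = NA_character_)
  k <- sample(0:3, 1)
  ther <- if (k > 0) {
    tp <- sample(c("mechanical_ventilation", "vasopressor"), k, replace = TRUE)
    s <- runif(k, 0, 24 * n_days - 1)
    data.frame(admission_id = id, therapy = tp,
               drug = ifelse(tp == "vasopressor", "noradrenaline", NA),
               rate = ifelse(tp == "vasopressor", runif(k, 0.01, 0.5), NA),
               start_h = s, end_h = s + runif(k, 1, 30))
  } else {
    data.frame(admission_id = character(0), therapy = character(0),
               drug = character(0), rate = numeric(0), start_h = numeric(0),
               end_h = numeric(0))
  }
  list(observations = obs, therapies = ther)
}

# all-pairs concordance oracle for the AUROC
auroc_bruteforce <- function(scores, labels) {
  ev <- scores[labels == 1]; ne <- scores[labels == 0]
  tot <- 0
  for (x in ev) tot <- tot + sum(x > ne) + 0.5 * sum(x == ne)
  tot / (length(ev) * length(ne))
}
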
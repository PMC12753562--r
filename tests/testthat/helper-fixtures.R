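# Hand-built claims fixtures and independent oracles used across the suite.

library(data.table)

D0 <- as.Date("2017-01-01")  # fixture origin; "day k" means D0 + k

dayd <- function(k) D0 + k

fx_patients <- function(ids, birth = "1960-06-15",
                        start = 0L, end = 2200L, sex = "M") {
  data.table(patient_id = ids, sex = rep_len(sex, length(ids)),
             birth_date = as.Date(rep_len(birth, length(ids))),
             observable_start = dayd(rep_len(start, length(ids))),
             observable_end = dayd(rep_len(end, length(ids))))
}

fx_dx <- function(id, day, code, facility = "F1", setting = "outpatient",
                  hosp = NA_character_) {
  data.table(patient_id = id, date = dayd(day), code = code,
             facility_id = facility, setting = setting,
             hospitalization_id = hosp)
}

fx_rx <- function(id, day, code, supply = 30L, facility = "F1",
                  setting = "outpatient", hosp = NA_character_) {
  data.table(patient_id = id, date = dayd(day), code = code,
             days_supply = as.integer(supply), daily_dose = 1,
             facility_id = facility, setting = setting,
             hospitalization_id = hosp)
}

fx_hosp <- function(hid, id, adm, dis) {
  data.table(hospitalization_id = hid, patient_id = id,
             admission_date = dayd(adm), discharge_date = dayd(dis))
}

fx_meas <- function(id, day, kind, value) {
  data.table(patient_id = id, date = dayd(day), kind = kind, value = value)
}

claims_fixture <- function(patients, diagnoses = NULL, prescriptions = NULL,
                           hospitalizations = NULL, measurements = NULL) {
  empty_dx <- fx_dx(character(), integer(), character())[0]
  empty_rx <- fx_rx(character(), integer(), character())[0]
  empty_h <- fx_hosp(character(), character(), integer(), integer())[0]
  empty_m <- fx_meas(character(), integer(), character(), numeric())[0]
  structure(list(
    patients = patients,
    diagnoses = if (is.null(diagnoses)) empty_dx else rbindlist(diagnoses),
    prescriptions = if (is.null(prescriptions)) empty_rx
                    else rbindlist(prescriptions),
    hospitalizations = if (is.null(hospitalizations)) empty_h
                       else rbindlist(hospitalizations),
    measurements = if (is.null(measurements)) empty_m
                   else rbindlist(measurements)),
    class = "claims_dataset")
}

# study config matching the fixture origin: cutoff at day 365
fx_config <- function(...) {
  study_config(cutoff_date = dayd(365), ...)
}

# a simulation config with all confounding switched off
null_sim_config <- function(n, seed, ...) {
  spec <- default_covariate_spec()
  spec$beta_treat <- 0
  spec$beta_outcome <- 0
  sim_config(n_patients = n, covariate_spec = spec,
             beta_age_treat = 0, beta_age_outcome = 0,
             beta_female_treat = 0, beta_female_outcome = 0,
             beta_smoking_treat = 0, beta_smoking_outcome = 0,
             beta_bmi_treat = 0, beta_bmi_outcome = 0,
             missing_spec = list(target = 0, beta_age = 0, beta_female = 0,
                                 beta_diabetes = 0),
             seed = seed, ...)
}

# confounded config without missingness (complete-covariate scenarios)
confounded_sim_config <- function(n, seed, ...) {
  sim_config(n_patients = n,
             missing_spec = list(target = 0, beta_age = 0, beta_female = 0,
                                 beta_diabetes = 0),
             seed = seed, ...)
}

## -- independent oracles ---------------------------------------------------

# day-by-day boolean coverage brute force for exposure episode merging
episodes_brute_force <- function(dates, supply, gap_days) {
  if (!length(dates)) return(data.table(start = integer(), end = integer()))
  covered <- sort(unique(unlist(mapply(
    function(d, s) seq.int(d, d + s - 1L), dates, supply,
    SIMPLIFY = FALSE))))
  starts <- covered[1]; ends <- integer()
  if (length(covered) > 1) {
    gaps <- diff(covered) - 1L
    brk <- which(gaps > gap_days)
    starts <- covered[c(1L, brk + 1L)]
    ends <- covered[brk]
  }
  data.table(start = starts, end = c(ends, covered[length(covered)]))
}

# Breslow partial log-likelihood for a single binary covariate, written
# independently of the survival package
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# inverse-transform sampler for a piecewise-exponential time from 0 with
# change points `breaks` (starts of pieces) and per-piece rates
rpexp_inverse <- function(n, breaks, rates) {
  u <- runif(n)
  target <- -log(1 - u)
  ends <- c(breaks[-1], Inf)
  cumh <- c(0, cumsum(rates * (ends - breaks))[-length(breaks)])
  out <- numeric(n)
  for (j in seq_len(n)) {
    k <- max(which(cumh <= target[j]))
    out[j] <- breaks[k] + (target[j] - cumh[k]) / rates[k]
  }
  out
}

# naive ever-user/never-user comparator anchored at first diagnosis; this
# design exhibits immortal time bias and exists only in the test suite
naive_comparator_fit <- function(ds, cfg) {
  idx <- tmcohort:::claims_index(ds, cfg)
  elig <- which(!is.na(idx$first_elig))
  fe <- idx$first_elig[elig]
  ever <- vapply(elig, function(p) length(idx$pema[[p]]) > 0, logical(1))
  ev <- tmcohort:::cohort_event_days(
    data.table(patient_id = idx$pid[elig], index_date = tmcohort:::day_to_date(fe)),
    ds, cfg)
  end <- pmin(ifelse(is.na(ev), idx$en[elig], ev), idx$en[elig])
  fu <- data.table(group = ifelse(ever, "exposed", "control"),
                   time_days = as.integer(end - fe),
                   event = !is.na(ev) & ev <= end)
  weighted_cox(fu)
}
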
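#' Generate a synthetic longitudinal claims dataset
#'
#' Simulates a claims extract with known ground truth: dyslipidemia patients
#' whose pemafibrate initiation depends on baseline covariates (confounding
#' by indication), refill prescription sequences, and VTE outcomes generated
#' from a proportional-hazards model with the exposure as a time-varying
#' binary covariate at log hazard ratio `true_log_hr`. Events are drawn as a
#' piecewise-inhomogeneous Poisson process, so the time to first event is
#' exactly piecewise-exponential. Each event emits a VTE diagnosis record
#' plus a qualifying anticoagulant/thrombolytic prescription satisfying the
#' setting-specific co-occurrence rule (same facility and date for
#' outpatient events, same hospitalization for inpatient events), so the
#' downstream ascertainment algorithm can detect it. BMI and smoking
#' measurements are then deleted under a MAR mechanism conditioned only on
#' fully observed covariates (age, sex, diabetes).
#'
#' Initiation is suppressed for patients whose first event precedes their
#' latent initiation date: a patient who has just had a VTE does not become
#' a new fibrate user. This is what gives a naive ever-user/never-user
#' comparison its immortal-time bias while leaving the time-matched design
#' unbiased.
#'
#' @param config A [sim_config()] object.
#' @return A `claims_dataset`: list of `data.table`s `patients`,
#'   `diagnoses`, `prescriptions`, `hospitalizations`, `measurements`, plus
#'   a `truth` table of the latent per-patient state (covariates, linear
#'   predictors, initiation date, exposure end, event dates) for testing.
#' @examples
#' ds <- generate_claims(sim_config(n_patients = 200, seed = 42))
#' nrow(ds$patients)
#' @export
generate_claims <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object")
  withr::with_seed(config$seed, generate_claims_impl(config))
}

generate_claims_impl <- function(cfg) {
  n <- cfg$n_patients
  span_start <- cfg$study_start
  span_end <- cfg$study_end
  span <- span_end - span_start

  ## -- patients ------------------------------------------------------------
  age0 <- pmin(pmax(rnorm(n, 66, 14), 20), 95)
  female <- rbinom(n, 1, 0.47)
  birth <- span_start - as.integer(round(age0 * 365.25 + runif(n, 0, 365)))
  obs_start <- span_start + as.integer(floor(runif(n, 0, 0.25 * span)))
  obs_end <- span_end - as.integer(floor(runif(n, 0, 0.25 * span)))
  obs_end <- pmin(pmax(obs_end, obs_start + 365L), span_end)
  fac_pool <- sprintf("F%03d", seq_len(max(20L, n %/% 500L)))
  facility <- sample(fac_pool, n, replace = TRUE)
  pid <- sprintf("P%06d", seq_len(n))

  spec <- cfg$covariate_spec
  k <- nrow(spec)
  flags <- matrix(0L, n, k, dimnames = list(NULL, spec$name))
  for (j in seq_len(k)) flags[, j] <- rbinom(n, 1, spec$prevalence[j])
  bmi <- pmin(pmax(rnorm(n, 24, 4.3), 14), 55)
  smoking <- rbinom(n, 1, 0.40)

  lp_treat <- as.vector(flags %*% spec$beta_treat) +
    cfg$beta_age_treat * (age0 - 65) + cfg$beta_female_treat * female +
    cfg$beta_smoking_treat * smoking + cfg$beta_bmi_treat * (bmi - 24)
  lp_out <- as.vector(flags %*% spec$beta_outcome) +
    cfg$beta_age_outcome * (age0 - 65) + cfg$beta_female_outcome * female +
    cfg$beta_smoking_outcome * smoking + cfg$beta_bmi_outcome * (bmi - 24)

  ## -- first dyslipidemia diagnosis ---------------------------------------
  first_dx <- obs_start + 30L +
    as.integer(floor(runif(n) * pmax(obs_end - obs_start - 30L, 1L)))
  first_dx <- pmin(first_dx, obs_end)

  ## -- latent initiation ---------------------------------------------------
  t0 <- pmax(first_dx, cfg$drug_launch_date)
  delay <- pmin(rexp(n, rate = cfg$init_rate * exp(lp_treat)), 5e7)
  init <- t0 + as.integer(ceiling(delay))
  init[t0 > obs_end | init > obs_end] <- NA_integer_

  ## -- outcome events: base-rate Poisson process over the whole window ----
  rate <- cfg$baseline_hazard * exp(lp_out)
  len_all <- obs_end - obs_start + 1L
  nev <- rpois(n, rate * len_all)
  base_ev <- data.table::data.table(i = rep(seq_len(n), nev))
  base_ev[, day := obs_start[i] + as.integer(floor(runif(.N) * len_all[i]))]

  first_base <- rep(NA_integer_, n)
  if (nrow(base_ev))
    first_base[base_ev[, min(day), by = i]$i] <- base_ev[, min(day), by = i]$V1
  # suppression: an event before the latent initiation date cancels initiation
  suppressed <- !is.na(init) & !is.na(first_base) & first_base < init
  init[suppressed] <- NA_integer_
  initiator <- !is.na(init)

  ## -- refill sequences for initiators ------------------------------------
  rs <- cfg$refill_spec
  rx_parts <- list()
  ii <- which(initiator)
  if (length(ii)) {
    cur <- init[ii]
    active <- rep(TRUE, length(ii))
    round <- 0L
    while (any(active) && round < 200L) {
      round <- round + 1L
      a <- which(active)
      supply <- rs$supply_days[sample.int(length(rs$supply_days), length(a),
                                          TRUE, prob = rs$probs)]
      rx_parts[[round]] <- data.table::data.table(
        i = ii[a], date = cur[a], days_supply = as.integer(supply))
      cur_end <- cur[a] + supply - 1L
      stop_now <- runif(length(a)) < rs$p_stop
      long <- runif(length(a)) < rs$p_long_gap
      gap <- ifelse(long,
        rs$long_gap_range[1] +
          floor(runif(length(a)) * diff(rs$long_gap_range + c(0, 1))),
        floor(runif(length(a)) * (rs$short_gap_max + 1)))
      nxt <- cur_end + 1L + as.integer(gap)
      keep <- !stop_now & nxt <= obs_end[ii[a]]
      cur[a] <- nxt
      active[a] <- keep
    }
  }
  pema_rx <- if (length(rx_parts)) data.table::rbindlist(rx_parts)
             else data.table::data.table(i = integer(), date = integer(),
                                         days_supply = integer())
  cov_end <- rep(NA_integer_, n)
  if (nrow(pema_rx)) {
    ce <- pema_rx[, max(date + days_supply - 1L), by = i]
    cov_end[ce$i] <- ce$V1
  }

  ## -- resample events for initiators (piecewise rates after initiation) --
  keep_ev <- base_ev[!initiator[i] | day < init[i]]
  init_ev <- list()
  if (length(ii)) {
    a_end <- pmin(cov_end[ii], obs_end[ii])
    lenA <- a_end - init[ii] + 1L
    nA <- rpois(length(ii), rate[ii] * exp(cfg$true_log_hr) * pmax(lenA, 0))
    evA <- data.table::data.table(i = rep(ii, nA))
    if (nrow(evA))
      evA[, day := init[i] + as.integer(floor(runif(.N) * lenA[match(i, ii)]))]
    lenB <- obs_end[ii] - a_end
    nB <- rpois(length(ii), rate[ii] * pmax(lenB, 0))
    evB <- data.table::data.table(i = rep(ii, nB))
    if (nrow(evB))
      evB[, day := a_end[match(i, ii)] + 1L +
            as.integer(floor(runif(.N) * lenB[match(i, ii)]))]
    init_ev <- list(evA, evB)
  }
  events <- data.table::rbindlist(c(list(keep_ev), init_ev), fill = TRUE)
  events <- unique(events[, .(i, day)])[order(i, day)]

  ## -- routine dyslipidemia and covariate records --------------------------
  scatter_regular <- function(i_idx, from, to, spacing, offset_max,
                              jitter_first = TRUE) {
    # regularly spaced records (spacing <= baseline window) with jitter, so
    # an active chronic covariate is visible in any 180-day baseline window
    offset <- as.integer(floor(runif(length(i_idx)) * offset_max))
    counts <- pmax((to - from - offset) %/% spacing + 1L, 1L)
    out <- data.table::data.table(i = rep(i_idx, counts),
                                  k = unlist(lapply(counts, seq_len)) - 1L)
    jit <- as.integer(floor(runif(nrow(out)) * 11)) - 5L
    if (!jitter_first) jit[out$k == 0L] <- 0L
    out[, date := from[match(i, i_idx)] + offset[match(i, i_idx)] +
          k * spacing + jit]
    out[, date := pmin(pmax(date, from[match(i, i_idx)]), to[match(i, i_idx)])]
    out[, k := NULL]
    out
  }

  dys <- scatter_regular(seq_len(n), first_dx, obs_end, 180L, 1L,
                         jitter_first = FALSE)
  dys[, code := sample(c("E780", "E784", "E785"), .N, TRUE)]

  cov_dx_parts <- list(); cov_rx_parts <- list()
  for (j in seq_len(k)) {
    act <- which(flags[, j] == 1L)
    if (!length(act)) next
    recs <- scatter_regular(act, obs_start[act], obs_end[act], 90L, 61L)
    recs[, code := paste0(spec$code[j], "1")]
    if (spec$record[j] == "diagnosis") cov_dx_parts[[j]] <- recs
    else cov_rx_parts[[j]] <- recs
  }

  ## -- noise records -------------------------------------------------------
  lone_vte <- which(rbinom(n, 1, cfg$vte_noise_rate) == 1L)
  lone_dx <- data.table::data.table(
    i = lone_vte,
    date = obs_start[lone_vte] + as.integer(floor(
      runif(length(lone_vte)) * len_all[lone_vte])),
    code = sample(c("I260", "I802", "I829"), length(lone_vte), TRUE))

  other_fib <- which(rbinom(n, 1, 0.03) == 1L)
  fib_rx <- data.table::data.table(
    i = other_fib,
    date = obs_start[other_fib] + as.integer(floor(
      runif(length(other_fib)) * len_all[other_fib])),
    code = "C10A2B1", days_supply = 30L)

  # stray pre-diagnosis pemafibrate (feeds exclusion criterion 4)
  can_prior <- which(first_dx - obs_start > 30L)
  prior_pema <- can_prior[rbinom(length(can_prior), 1, 0.005) == 1L]
  prior_rx <- data.table::data.table(
    i = prior_pema,
    date = obs_start[prior_pema] + as.integer(floor(
      runif(length(prior_pema)) * (first_dx[prior_pema] - obs_start[prior_pema]))),
    code = "C10A2P1", days_supply = 30L)

  # post-exposure switch to another fibrate for some initiators
  sw <- ii[rbinom(length(ii), 1, 0.02) == 1L]
  sw_date <- cov_end[sw] + 10L + as.integer(floor(runif(length(sw)) * 51))
  okse <- sw_date <= obs_end[sw]
  switch_rx <- data.table::data.table(
    i = sw[okse], date = sw_date[okse], code = "C10A2F1", days_supply = 30L)

  ## -- event emission (diagnosis + qualifying prescription) ----------------
  hosp_parts <- list(); ev_dx <- NULL; ev_rx <- NULL
  if (nrow(events)) {
    ne <- nrow(events)
    inpat <- runif(ne) < cfg$inpatient_fraction
    dx_code <- sample(c("I260", "I801", "I829"), ne, TRUE)
    rx_code <- sample(c("B01AF01", "B01AB01", "B01AD01"), ne, TRUE,
                      prob = c(0.6, 0.3, 0.1))
    ev_dx <- data.table::data.table(
      i = events$i, date = events$day, code = dx_code,
      setting = ifelse(inpat, "inpatient", "outpatient"),
      hospitalization_id = NA_character_)
    ev_rx <- data.table::data.table(
      i = events$i, date = events$day, code = rx_code,
      days_supply = sample(c(14L, 30L), ne, TRUE),
      setting = ev_dx$setting, hospitalization_id = NA_character_)
    hi <- which(inpat)
    if (length(hi)) {
      hid <- sprintf("H%06d", seq_along(hi))
      adm <- pmax(obs_start[events$i[hi]],
                  events$day[hi] - as.integer(floor(runif(length(hi)) * 4)))
      dis <- pmin(obs_end[events$i[hi]],
                  events$day[hi] + 3L + as.integer(floor(runif(length(hi)) * 8)))
      hosp_parts[["ev"]] <- data.table::data.table(
        hospitalization_id = hid, i = events$i[hi],
        admission_date = adm, discharge_date = dis)
      ev_dx$hospitalization_id[hi] <- hid
      ev_rx$hospitalization_id[hi] <- hid
      # half the inpatient diagnoses land the day before the prescription,
      # exercising the earliest-on-or-after outcome-date rule
      back <- hi[runif(length(hi)) < 0.5]
      ev_dx$date[back] <- pmax(ev_dx$date[back] - 1L,
                               adm[match(back, hi)])
    }
  }

  # random unrelated hospitalizations
  rh <- which(rbinom(n, 1, 0.08) == 1L)
  if (length(rh)) {
    adm <- obs_start[rh] + as.integer(floor(runif(length(rh)) *
                                            pmax(len_all[rh] - 20L, 1L)))
    dis <- pmin(adm + 4L + as.integer(floor(runif(length(rh)) * 11)), obs_end[rh])
    hosp_parts[["rand"]] <- data.table::data.table(
      hospitalization_id = sprintf("HR%05d", seq_along(rh)), i = rh,
      admission_date = adm, discharge_date = dis)
  }

  ## -- measurements with MAR deletion --------------------------------------
  meas <- data.table::rbindlist(list(
    data.table::data.table(i = seq_len(n), date = first_dx, kind = "bmi",
                           value = round(bmi, 1)),
    data.table::data.table(i = seq_len(n), date = first_dx, kind = "smoking",
                           value = as.numeric(smoking))))
  second <- which(rbinom(n, 1, 0.3) == 1L)
  d2 <- first_dx[second] + 150L + as.integer(floor(runif(length(second)) * 101))
  oks <- d2 <= obs_end[second]
  if (any(oks)) {
    meas <- data.table::rbindlist(list(meas,
      data.table::data.table(i = second[oks], date = d2[oks], kind = "bmi",
                             value = round(bmi[second[oks]] +
                                           rnorm(sum(oks), 0, 0.5), 1)),
      data.table::data.table(i = second[oks], date = d2[oks],
                             kind = "smoking",
                             value = as.numeric(smoking[second[oks]]))))
  }
  ms <- cfg$missing_spec
  if (ms$target > 0) {
    lp_miss <- ms$beta_age * (age0 - 65) / 10 + ms$beta_female * female +
      ms$beta_diabetes * flags[, "diabetes"]
    cal <- stats::uniroot(function(c0) mean(plogis(c0 + lp_miss)) - ms$target,
                          c(-25, 25))$root
    p_miss <- plogis(cal + lp_miss)
    drop_bmi <- rbinom(n, 1, p_miss) == 1L
    drop_smk <- rbinom(n, 1, p_miss) == 1L
    meas <- meas[!(kind == "bmi" & drop_bmi[i]) &
                 !(kind == "smoking" & drop_smk[i])]
  }

  ## -- assemble tables ------------------------------------------------------
  finalize_dx <- function(dt) {
    dt[, .(patient_id = pid[i], date = day_to_date(date), code,
           facility_id = facility[i],
           setting = if ("setting" %in% names(dt)) setting else "outpatient",
           hospitalization_id = if ("hospitalization_id" %in% names(dt))
             hospitalization_id else NA_character_)]
  }
  finalize_rx <- function(dt) {
    dt[, .(patient_id = pid[i], date = day_to_date(date), code,
           days_supply = if ("days_supply" %in% names(dt)) days_supply else 30L,
           daily_dose = if (any(startsWith(dt$code, "C10A2P"))) 0.2 else 1,
           facility_id = facility[i],
           setting = if ("setting" %in% names(dt)) setting else "outpatient",
           hospitalization_id = if ("hospitalization_id" %in% names(dt))
             hospitalization_id else NA_character_)]
  }

  dys[, setting := "outpatient"]
  lone_dx[, setting := "outpatient"]
  dx_all <- data.table::rbindlist(c(
    list(finalize_dx(dys), finalize_dx(lone_dx)),
    lapply(Filter(Negate(is.null), cov_dx_parts), finalize_dx),
    if (!is.null(ev_dx)) list(finalize_dx(ev_dx))), use.names = TRUE)

  pema_rx2 <- data.table::copy(pema_rx)[, code := "C10A2P1"]
  rx_all <- data.table::rbindlist(c(
    list(finalize_rx(pema_rx2), finalize_rx(fib_rx), finalize_rx(prior_rx),
         finalize_rx(switch_rx)),
    lapply(Filter(Negate(is.null), cov_rx_parts), finalize_rx),
    if (!is.null(ev_rx)) list(finalize_rx(ev_rx))), use.names = TRUE)

  hosp <- if (length(hosp_parts)) {
    h <- data.table::rbindlist(hosp_parts)
    h[, .(hospitalization_id, patient_id = pid[i],
          admission_date = day_to_date(admission_date),
          discharge_date = day_to_date(discharge_date))]
  } else data.table::data.table(hospitalization_id = character(),
                                patient_id = character(),
                                admission_date = as.Date(character()),
                                discharge_date = as.Date(character()))

  patients <- data.table::data.table(
    patient_id = pid, sex = ifelse(female == 1, "F", "M"),
    birth_date = day_to_date(birth),
    observable_start = day_to_date(obs_start),
    observable_end = day_to_date(obs_end))

  measurements <- meas[, .(patient_id = pid[i], date = day_to_date(date),
                           kind, value)]

  first_event <- rep(NA_integer_, n)
  if (nrow(events)) {
    fe <- events[, min(day), by = i]
    first_event[fe$i] <- fe$V1
  }
  truth <- data.table::data.table(
    patient_id = pid, age = age0, female = female, bmi = bmi,
    smoking = smoking, first_dx = day_to_date(first_dx),
    init_date = day_to_date(init),
    exposure_end = day_to_date(cov_end),
    first_event = day_to_date(first_event),
    lp_treat = lp_treat, lp_out = lp_out)
  truth <- cbind(truth, data.table::as.data.table(flags))

  ds <- list(
    patients = patients[order(patient_id)],
    diagnoses = dx_all[order(patient_id, date, code)],
    prescriptions = rx_all[order(patient_id, date, code)],
    hospitalizations = hosp[order(patient_id, admission_date)],
    measurements = measurements[order(patient_id, date, kind)],
    truth = truth)
  structure(ds, class = "claims_dataset")
}

#' Validate the internal consistency of a claims dataset
#'
#' Checks the structural invariants: every record date lies within the
#' owning patient's observable window; every non-missing hospitalization id
#' resolves to a hospitalization of the same patient whose stay contains the
#' record date; `days_supply >= 1` for every prescription.
#'
#' @param dataset A `claims_dataset`.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_claims <- function(dataset) {
  p <- dataset$patients
  win <- p[, .(patient_id, s = as_day(observable_start),
               e = as_day(observable_end))]
  chk_window <- function(tab, nm, datecol = "date") {
    if (!nrow(tab)) return(invisible(TRUE))
    m <- merge(tab[, .(patient_id, d = as_day(get(datecol)))], win,
               by = "patient_id", all.x = TRUE)
    bad <- m[is.na(s) | d < s | d > e]
    if (nrow(bad))
      stop("table '", nm, "': ", nrow(bad),
           " record(s) outside the patient observable window (first: ",
           bad$patient_id[1], ")")
  }
  chk_window(dataset$diagnoses, "diagnoses")
  chk_window(dataset$prescriptions, "prescriptions")
  chk_window(dataset$measurements, "measurements")
  if (nrow(dataset$prescriptions) &&
      any(dataset$prescriptions$days_supply < 1))
    stop("prescriptions: days_supply must be >= 1")
  h <- dataset$hospitalizations
  for (nm in c("diagnoses", "prescriptions")) {
    tab <- dataset[[nm]]
    if (!nrow(tab)) next
    withid <- tab[!is.na(hospitalization_id)]
    if (!nrow(withid)) next
    m <- merge(withid, h, by = "hospitalization_id", all.x = TRUE,
               suffixes = c("", ".h"))
    bad <- m[is.na(patient_id.h) | patient_id != patient_id.h |
             as_day(date) < as_day(admission_date) |
             as_day(date) > as_day(discharge_date)]
    if (nrow(bad))
      stop("table '", nm, "': ", nrow(bad),
           " record(s) with unresolvable or mismatched hospitalization_id")
  }
  invisible(TRUE)
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  for (nm in c("patients", "diagnoses", "prescriptions",
               "hospitalizations", "measurements"))
    cat(sprintf("  %-16s %8d rows\n", nm, nrow(x[[nm]])))
  if (!is.null(x$truth))
    cat("  (includes simulation truth table)\n")
  invisible(x)
}
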
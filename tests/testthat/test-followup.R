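test_that("exposure episodes merge according to the uncovered-span rule", {
  ep <- build_exposure_episodes(c(0, 35), c(30, 30), gap_days = 30)
  expect_equal(as.data.frame(ep), data.frame(start = 0L, end = 64L))
  ep0 <- build_exposure_episodes(c(0, 35), c(30, 30), gap_days = 0)
  expect_equal(as.data.frame(ep0),
               data.frame(start = c(0L, 35L), end = c(29L, 64L)))
  # back-to-back refill is continuous even at gap 0
  bb <- build_exposure_episodes(c(0, 30), c(30, 30), gap_days = 0)
  expect_equal(as.data.frame(bb), data.frame(start = 0L, end = 59L))
  # minimal one-day supply
  expect_equal(as.data.frame(build_exposure_episodes(10, 1, 0)),
               data.frame(start = 10L, end = 10L))
  # overlapping supplies merge unconditionally and unsorted input is fine
  ov <- build_exposure_episodes(c(20, 0), c(30, 30), gap_days = 0)
  expect_equal(as.data.frame(ov), data.frame(start = 0L, end = 49L))
  expect_error(build_exposure_episodes(0, 0, 0), "days_supply")
})

test_that("episode merging matches the day-coverage brute force", {
  withr::with_seed(77, {
    for (case in seq_len(250)) {
      k <- sample(1:6, 1)
      dates <- sort(sample(0:300, k))
      supply <- sample(c(1, 7, 30, 60, 90), k, replace = TRUE)
      for (g in c(0L, 30L, 90L, 180L)) {
        expect_equal(
          as.data.frame(build_exposure_episodes(dates, supply, g)),
          as.data.frame(episodes_brute_force(dates, supply, g)),
          info = sprintf("case %d gap %d", case, g))
      }
    }
  })
})

test_that("exposure end adds the grace period to the last episode", {
  ep <- data.table(start = c(0L, 100L), end = c(64L, 120L))
  expect_equal(exposure_end(ep, 90), 210L)
  expect_equal(exposure_end(ep, 0), 120L)
  expect_error(exposure_end(ep[0], 30), "empty")
})

test_that("outpatient VTE ascertainment requires same facility and date", {
  cfg <- fx_config()
  base <- function(rx_fac) claims_fixture(
    fx_patients("A"),
    diagnoses = list(fx_dx("A", 50, "I260", facility = "F1")),
    prescriptions = list(fx_rx("A", 50, "B01AF01", facility = rx_fac)))
  ev <- ascertain_vte("A", base("F1"), c(dayd(0), dayd(100)), cfg)
  expect_equal(ev$day, dayd(50))
  expect_equal(ev$setting, "outpatient")
  expect_null(ascertain_vte("A", base("F2"), c(dayd(0), dayd(100)), cfg))
  # lone diagnosis or lone prescription is not an event
  lone <- claims_fixture(fx_patients("A"),
                         diagnoses = list(fx_dx("A", 50, "I260")))
  expect_null(ascertain_vte("A", lone, c(dayd(0), dayd(100)), cfg))
  # window filtering
  expect_null(ascertain_vte("A", base("F1"), c(dayd(60), dayd(100)), cfg))
})

test_that("inpatient ascertainment uses the same stay and earliest on/after rule", {
  mk <- function(rx_days, strict = FALSE) {
    ds <- claims_fixture(
      fx_patients("A"),
      diagnoses = list(fx_dx("A", 60, "I801", setting = "inpatient",
                             hosp = "H1")),
      prescriptions = lapply(rx_days, function(d)
        fx_rx("A", d, "B01AB01", setting = "inpatient", hosp = "H1")),
      hospitalizations = list(fx_hosp("H1", "A", 55, 70)))
    list(ds = ds, cfg = fx_config(rx_after_dx_strict = strict))
  }
  w <- c(dayd(0), dayd(100))
  f <- mk(c(59, 62))
  expect_equal(ascertain_vte("A", f$ds, w, f$cfg)$day, dayd(62))
  f2 <- mk(c(60, 62))
  expect_equal(ascertain_vte("A", f2$ds, w, f2$cfg)$day, dayd(60))
  f3 <- mk(c(60, 62), strict = TRUE)
  expect_equal(ascertain_vte("A", f3$ds, w, f3$cfg)$day, dayd(62))
  # only a pre-diagnosis prescription in the stay: co-occurrence stands
  f4 <- mk(59)
  expect_equal(ascertain_vte("A", f4$ds, w, f4$cfg)$day, dayd(59))
  # unknown hospitalization id is an error
  bad <- f$ds
  bad$hospitalizations <- bad$hospitalizations[0]
  expect_error(ascertain_vte("A", bad, w, f$cfg), "unknown hospitalization")
})

pp_fixture <- function(event_day = NULL, rx_days = 0, supplies = 30,
                       extra_rx = NULL) {
  # exposed member E indexed at day 700 (dx 600, pema at 700 + rx_days)
  presc <- c(lapply(rx_days, function(d) fx_rx("E", 700 + d, "C10A2P1",
                                               supply = supplies)),
             extra_rx)
  dxs <- list(fx_dx("E", 600, "E780"))
  if (!is.null(event_day)) {
    dxs <- c(dxs, list(fx_dx("E", event_day, "I260")))
    presc <- c(presc, list(fx_rx("E", event_day, "B01AF01")))
  }
  claims_fixture(fx_patients("E"), diagnoses = dxs, prescriptions = presc)
}

exposed_member <- function() {
  data.table(patient_id = "E", group = "exposed", index_date = dayd(700),
             first_dyslipidemia_date = dayd(600), offset_days_X = 100L,
             matched_set_id = "S1")
}

test_that("per-protocol follow-up censors at exposure end per gap/grace", {
  cfg <- fx_config()
  m <- exposed_member()
  # single 30-day fill, grace 0, event at index+45: censored at index+29
  ds <- pp_fixture(event_day = 745)
  r0 <- pp_followup(m, ds, cfg, 0)
  expect_false(r0$event)
  expect_equal(r0$end, dayd(729))
  expect_equal(r0$censor_reason, "exposure_end")
  # grace 90: the event at +45 falls inside the residual-effect window
  r90 <- pp_followup(m, ds, cfg, 90)
  expect_true(r90$event)
  expect_equal(r90$end, dayd(745))
  expect_equal(r90$censor_reason, "event")
  # other fibrate during follow-up censors the exposed member
  ds2 <- pp_fixture(rx_days = c(0, 30, 60), extra_rx = list(
    fx_rx("E", 760, "C10A2F1")))
  r2 <- pp_followup(m, ds2, cfg, 180)
  expect_equal(r2$censor_reason, "other_fibrate")
  expect_equal(r2$end, dayd(760))
})

test_that("control follow-up censors at fibrate initiation; ITT does not", {
  cfg <- fx_config()
  ctl <- data.table(patient_id = "C", group = "control",
                    index_date = dayd(700),
                    first_dyslipidemia_date = dayd(600),
                    offset_days_X = 100L, matched_set_id = "S1")
  ds <- claims_fixture(
    fx_patients("C"),
    diagnoses = list(fx_dx("C", 600, "E780")),
    prescriptions = list(fx_rx("C", 710, "C10A2B1")))
  r <- pp_followup(ctl, ds, cfg, 30)
  expect_equal(r$censor_reason, "other_fibrate")
  expect_equal(r$end, dayd(710))
  ds_p <- claims_fixture(
    fx_patients("C"),
    diagnoses = list(fx_dx("C", 600, "E780")),
    prescriptions = list(fx_rx("C", 720, "C10A2P1")))
  rp <- pp_followup(ctl, ds_p, cfg, 30)
  expect_equal(rp$censor_reason, "pemafibrate_start")
  expect_equal(rp$end, dayd(720))
  # ITT ignores mid-follow-up initiation entirely
  ri <- itt_followup(ctl, ds_p, cfg)
  expect_equal(ri$censor_reason, "end_observable")
  expect_equal(ri$end, dayd(2200))
})

test_that("ITT records end at the event or the observable end", {
  cfg <- fx_config()
  m <- exposed_member()
  ds <- pp_fixture(event_day = 745)
  r <- itt_followup(m, ds, cfg)
  expect_true(r$event)
  expect_equal(r$end, dayd(745))
  expect_equal(r$time_days, 45L)
  r2 <- itt_followup(m, pp_fixture(), cfg)
  expect_false(r2$event)
  expect_equal(r2$censor_reason, "end_observable")
  # index after the observable end is a construction error
  broken <- exposed_member()
  broken$index_date <- dayd(3000)
  expect_error(itt_followup(broken, pp_fixture(), cfg), "observable")
})

test_that("person-time arithmetic and incidence rates", {
  fu <- data.table(event = c(TRUE, FALSE), time_days = c(365.25 * 20,
                                                         365.25 * 30))
  r <- person_time_and_events(fu)
  expect_equal(r$person_years, 50)
  expect_equal(r$rate_per_100py, 2)
  none <- data.table(event = FALSE, time_days = 100)
  expect_equal(person_time_and_events(none)$rate_per_100py, 0)
  expect_error(person_time_and_events(none[0]), "no follow-up")
  expect_error(person_time_and_events(data.table(event = TRUE,
                                                 time_days = 0)),
               "zero person-time")
})

test_that("PP person-time is monotone in gap/grace and bounded by ITT", {
  ds <- generate_claims(sim_config(n_patients = 1500, seed = 41))
  cfg <- study_config()
  co <- assemble_cohort(ds, cfg)
  itt <- itt_followup(co, ds, cfg)
  prev <- NULL
  for (g in cfg$gap_grace_days) {
    pp <- pp_followup(co, ds, cfg, g)
    expect_true(all(pp$time_days <= itt$time_days), info = paste("gap", g))
    if (!is.null(prev))
      expect_true(all(prev$time_days <= pp$time_days),
                  info = paste("gap", g))
    prev <- pp
  }
  # every ascertained event has its defining records inside the window
  evs <- itt[event == TRUE]
  for (j in seq_len(min(nrow(evs), 25))) {
    ev <- ascertain_vte(evs$patient_id[j], ds,
                        c(evs$start[j], evs$end[j]), cfg)
    expect_equal(ev$day, evs$event_date[j])
  }
})
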
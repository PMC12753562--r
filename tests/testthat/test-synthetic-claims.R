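test_that("generation is deterministic under a fixed seed and varies across seeds", {
  a <- generate_claims(sim_config(n_patients = 300, seed = 5))
  b <- generate_claims(sim_config(n_patients = 300, seed = 5))
  c <- generate_claims(sim_config(n_patients = 300, seed = 6))
  for (nm in c("patients", "diagnoses", "prescriptions",
               "hospitalizations", "measurements"))
    expect_equal(a[[nm]], b[[nm]])
  expect_false(isTRUE(all.equal(a$diagnoses, c$diagnoses)))
})

test_that("generated datasets satisfy the structural invariants", {
  ds <- generate_claims(sim_config(n_patients = 1000, seed = 3))
  expect_true(validate_claims(ds))
  expect_true(all(ds$prescriptions$days_supply >= 1))
  # every inpatient event record resolves to a same-patient hospitalization
  withid <- ds$diagnoses[!is.na(hospitalization_id)]
  expect_gt(nrow(withid), 0)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_patients = 0), "positive")
  expect_error(sim_config(missing_spec = list(target = 1.2, beta_age = 0,
                                              beta_female = 0,
                                              beta_diabetes = 0)),
               "missing_spec")
  expect_error(sim_config(study_start = "2020-01-01",
                          study_end = "2019-01-01"), "dates")
})

test_that("BMI missingness hits the 80% target within 0.05 at n = 20,000", {
  ds <- generate_claims(sim_config(n_patients = 20000, seed = 17))
  observed <- length(unique(ds$measurements[kind == "bmi", patient_id]))
  realized <- 1 - observed / 20000
  expect_lt(abs(realized - 0.8), 0.05)
  observed_s <- length(unique(ds$measurements[kind == "smoking", patient_id]))
  expect_lt(abs(1 - observed_s / 20000 - 0.8), 0.05)
})

test_that("with constant hazard and no treatment the mean event time is ~1/h", {
  h <- 0.005
  cfg <- null_sim_config(20000, seed = 21, baseline_hazard = h,
                         init_rate = 1e-9, vte_noise_rate = 0)
  ds <- generate_claims(cfg)
  tr <- ds$truth
  waits <- as.numeric(tr$first_event) -
    as.numeric(ds$patients$observable_start[match(tr$patient_id,
                                                  ds$patients$patient_id)])
  waits <- waits[!is.na(waits)]
  se <- (1 / h) / sqrt(length(waits))
  # day-granular floor shifts the mean by at most one day
  expect_lt(abs(mean(waits) - 1 / h), 3 * se + 1)
})

test_that("post-initiation event times match piecewise-exponential inverse-transform sampling", {
  # single 90-day fill at 3x hazard, then baseline hazard: exact two-piece
  # exponential; compare the simulated first-event waits with an
  # independent inverse-transform sample by a two-sample KS distance
  h <- 0.002
  cfg <- null_sim_config(
    12000, seed = 31, baseline_hazard = h, init_rate = 0.5,
    true_log_hr = log(3), vte_noise_rate = 0,
    study_start = "2018-06-02", study_end = "2020-12-31",
    drug_launch_date = "2018-06-02",
    refill_spec = list(supply_days = 90, probs = 1, p_stop = 1,
                       short_gap_max = 0, long_gap_range = c(1, 2),
                       p_long_gap = 0))
  ds <- generate_claims(cfg)
  tr <- merge(ds$truth, ds$patients[, .(patient_id, observable_end)],
              by = "patient_id")
  tr <- tr[!is.na(init_date)]
  tr[, room := as.integer(observable_end - init_date)]
  tr[, wait := as.numeric(first_event - init_date)]
  horizon <- 400
  sim <- tr[room >= horizon & !is.na(wait) & wait >= 0 & wait <= horizon,
            wait]
  expect_gt(length(sim), 1000)
  withr::with_seed(99, {
    ref <- rpexp_inverse(50000, breaks = c(0, 90), rates = c(3 * h, h))
    ref <- floor(ref[ref <= horizon])[seq_len(min(50000, 20000))]
  })
  ref <- ref[!is.na(ref)]
  D <- suppressWarnings(stats::ks.test(sim, ref)$statistic)
  crit <- 1.628 * sqrt((length(sim) + length(ref)) /
                       (length(sim) * length(ref)))  # alpha = 0.01
  expect_lt(D, crit)
})

test_that("null-effect, no-confounding configs give equal exposed/unexposed event rates", {
  # pooled over replicates: person-day event rate while exposed vs the
  # baseline rate among never-initiators
  reps <- 10
  on_ev <- 0; on_days <- 0; off_ev <- 0; off_days <- 0
  for (r in seq_len(reps)) {
    ds <- generate_claims(null_sim_config(2000, seed = 100 + r,
                                          baseline_hazard = 2e-4,
                                          vte_noise_rate = 0))
    tr <- merge(ds$truth, ds$patients[, .(patient_id, observable_start,
                                          observable_end)],
                by = "patient_id")
    ini <- tr[!is.na(init_date)]
    ini[, span := as.numeric(pmin(exposure_end, observable_end) - init_date) + 1]
    ini[, ev := !is.na(first_event) & first_event >= init_date &
          first_event <= pmin(exposure_end, observable_end)]
    on_ev <- on_ev + sum(ini$ev); on_days <- on_days + sum(ini$span)
    nev <- tr[is.na(init_date)]
    nev[, span := as.numeric(observable_end - observable_start) + 1]
    off_ev <- off_ev + sum(!is.na(nev$first_event))
    off_days <- off_days + sum(nev$span)
  }
  r_on <- on_ev / on_days
  r_off <- off_ev / off_days
  se <- sqrt(r_on / on_days + r_off / off_days)
  expect_lt(abs(r_on - r_off), 3 * se)
})

test_that("claims round-trip through CSV losslessly", {
  ds <- generate_claims(sim_config(n_patients = 150, seed = 9))
  dir <- withr::local_tempdir()
  write_claims(ds, dir)
  back <- read_claims(dir)
  for (nm in c("patients", "diagnoses", "prescriptions",
               "hospitalizations", "measurements"))
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(ds[[nm]]))
})

test_that("schema violations are reported with table and column context", {
  ds <- generate_claims(sim_config(n_patients = 50, seed = 2))
  dir <- withr::local_tempdir()
  write_claims(ds, dir)
  tab <- data.table::fread(file.path(dir, "diagnoses.csv"))
  tab[, patient_id := NULL]
  data.table::fwrite(tab, file.path(dir, "diagnoses.csv"))
  expect_error(read_claims(dir), "diagnoses.*patient_id")

  write_claims(ds, dir)
  tab <- data.table::fread(file.path(dir, "measurements.csv"),
                           colClasses = list(character = "date"))
  tab$date[2] <- "not-a-date"
  data.table::fwrite(tab, file.path(dir, "measurements.csv"))
  expect_error(read_claims(dir), "measurements.*date.*row 2")
})

test_that("empty tables survive the round trip without error", {
  ds <- claims_fixture(fx_patients(character(0)))
  dir <- withr::local_tempdir()
  write_claims(ds, dir)
  back <- read_claims(dir)
  expect_equal(nrow(back$diagnoses), 0)
  expect_equal(nrow(back$patients), 0)
})
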
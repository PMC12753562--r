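# Fixture geometry: cutoff at day 365 (fx_config), observable window
# [0, 2200] unless stated, baseline window 180 days.

test_that("first eligible diagnosis honors the cutoff and first-ever rule", {
  ds <- claims_fixture(
    fx_patients(c("A", "B", "C")),
    diagnoses = list(
      fx_dx("A", 400, "E780"), fx_dx("A", 500, "E780"),
      fx_dx("B", 100, "E780"), fx_dx("B", 400, "E785"),
      fx_dx("C", 400, "I100")))
  cfg <- fx_config()
  expect_equal(first_eligible_diagnosis("A", ds, cfg), dayd(400))
  # B's overall first diagnosis precedes the cutoff: never eligible
  expect_true(is.na(first_eligible_diagnosis("B", ds, cfg)))
  # C has no dyslipidemia code at all
  expect_true(is.na(first_eligible_diagnosis("C", ds, cfg)))
  expect_error(first_eligible_diagnosis("Z", ds, cfg), "unknown patient")
})

test_that("exclusion criteria fire at their window boundaries", {
  cfg <- fx_config()
  mk <- function(start) claims_fixture(
    fx_patients("A", start = start),
    diagnoses = list(fx_dx("A", 600, "E780")),
    prescriptions = list(fx_rx("A", 700, "C10A2P1")))
  # 180-day history: observable_start must be <= index - 180
  r <- check_exclusions("A", dayd(700), "exposed", mk(521), cfg)
  expect_false(r$eligible)
  expect_true("insufficient_history" %in% r$violations)
  r <- check_exclusions("A", dayd(700), "exposed", mk(520), cfg)
  expect_true(r$eligible)
  expect_length(r$violations, 0)

  # baseline fibrate / VTE / contraindications, window [index-180, index-1]
  ds <- claims_fixture(
    fx_patients("A", start = 0),
    diagnoses = list(fx_dx("A", 600, "E780"), fx_dx("A", 650, "I260"),
                     fx_dx("A", 690, "K831")),
    prescriptions = list(fx_rx("A", 700, "C10A2P1"),
                         fx_rx("A", 640, "C10A2B1"),
                         fx_rx("A", 660, "L04X01")))
  r <- check_exclusions("A", dayd(700), "exposed", ds, cfg)
  expect_setequal(r$violations,
                  c("baseline_fibrate", "baseline_vte",
                    "baseline_biliary_gallstone",
                    "baseline_contraindicated_rx"))

  # age: under 20 at index violates, 20 passes
  young <- claims_fixture(
    fx_patients("A", birth = "1999-11-01", start = 0),
    diagnoses = list(fx_dx("A", 600, "E780")),
    prescriptions = list(fx_rx("A", 700, "C10A2P1")))
  r <- check_exclusions("A", dayd(700), "exposed", young, cfg)  # age 19
  expect_true("age_under_minimum" %in% r$violations)
  old <- claims_fixture(
    fx_patients("A", birth = "1998-11-01", start = 0),
    diagnoses = list(fx_dx("A", 600, "E780")),
    prescriptions = list(fx_rx("A", 700, "C10A2P1")))
  r <- check_exclusions("A", dayd(700), "exposed", old, cfg)  # age 20
  expect_false("age_under_minimum" %in% r$violations)

  # control role: observable end before index
  short <- claims_fixture(
    fx_patients("A", start = 0, end = 650),
    diagnoses = list(fx_dx("A", 600, "E780")))
  r <- check_exclusions("A", dayd(700), "control", short, cfg)
  expect_true("observable_end_before_index" %in% r$violations)
})

test_that("exposed cohort is built with correct X offsets and exclusions", {
  # six patients: P1, P2 eligible; P3 pema before first diagnosis; P4 first
  # diagnosis before cutoff; P5 no pemafibrate; P6 baseline fibrate
  ds <- claims_fixture(
    fx_patients(paste0("P", 1:6)),
    diagnoses = list(
      fx_dx("P1", 400, "E780"), fx_dx("P2", 500, "E780"),
      fx_dx("P3", 600, "E780"), fx_dx("P4", 200, "E780"),
      fx_dx("P4", 600, "E780"), fx_dx("P5", 600, "E780"),
      fx_dx("P6", 600, "E780")),
    prescriptions = list(
      fx_rx("P1", 430, "C10A2P1"), fx_rx("P2", 720, "C10A2P1"),
      fx_rx("P3", 300, "C10A2P1"), fx_rx("P3", 650, "C10A2P1"),
      fx_rx("P4", 700, "C10A2P1"), fx_rx("P6", 700, "C10A2P1"),
      fx_rx("P6", 650, "C10A2B1")))
  res <- build_exposed_cohort(ds, fx_config())
  expect_equal(sort(res$members$patient_id), c("P1", "P2"))
  expect_equal(res$members[patient_id == "P1", offset_days_X], 30L)
  expect_equal(res$members[patient_id == "P2", offset_days_X], 220L)
  expect_true(all(diff(res$attrition$remaining[-(1:2)]) <= 0))

  empty <- claims_fixture(fx_patients(character(0)))
  expect_equal(nrow(build_exposed_cohort(empty, fx_config())$members), 0)
})

test_that("control matching applies the time-matched pemafibrate lookback", {
  # exposed E: first dx day 500, pema day 560 -> X = 60
  # candidates all first dx day 600 -> candidate index day 660
  mk_cand <- function(id, rxs = NULL)
    list(dx = fx_dx(id, 600, "E780"), rxs = rxs)
  ds <- claims_fixture(
    fx_patients(c("E", "C1", "C2", "C3", "C4", "C5", "X1", "X2")),
    diagnoses = list(
      fx_dx("E", 500, "E780"),
      fx_dx("C1", 600, "E780"), fx_dx("C2", 600, "E780"),
      fx_dx("C3", 600, "E780"), fx_dx("C4", 600, "E780"),
      fx_dx("C5", 600, "E780"), fx_dx("X1", 600, "E780"),
      fx_dx("X2", 600, "E780")),
    prescriptions = list(
      fx_rx("E", 560, "C10A2P1"),
      fx_rx("X1", 660, "C10A2P1"),    # pemafibrate at candidate index
      fx_rx("X2", 480, "C10A2P1")))   # inside [index-180, index] lookback
  cfg <- fx_config()
  ex <- build_exposed_cohort(ds, cfg)$members
  expect_true("E" %in% ex$patient_id)  # X1 qualifies as exposed in its own right
  ex <- ex[patient_id == "E"]
  withr::with_seed(1, ctl <- match_controls(ex[1], ds, cfg))
  expect_setequal(ctl$patient_id, paste0("C", 1:5))
  expect_true(all(ctl$index_date == dayd(660)))
  expect_true(all(ctl$offset_days_X == 60))
  # X2's prescription at day 480 = index - 180 is inside the inclusive
  # lookback; a prescription one day earlier would be admissible
  ds2 <- ds
  ds2$prescriptions[patient_id == "X2" & code == "C10A2P1",
                    date := dayd(479)]
  expect_warning(
    pool2 <- withr::with_seed(1, match_controls(
      ex[1], ds2, study_config(cutoff_date = dayd(365), match_ratio = 7))),
    "pool smaller")
  expect_setequal(pool2$patient_id, c(paste0("C", 1:5), "X2"))
})

test_that("a short pool returns all members with a warning", {
  ds <- claims_fixture(
    fx_patients(c("E", "C1")),
    diagnoses = list(fx_dx("E", 500, "E780"), fx_dx("C1", 600, "E780")),
    prescriptions = list(fx_rx("E", 560, "C10A2P1")))
  cfg <- fx_config()
  ex <- build_exposed_cohort(ds, cfg)$members
  expect_warning(
    ctl <- withr::with_seed(1, match_controls(ex[1], ds, cfg)),
    "pool smaller")
  expect_equal(ctl$patient_id, "C1")
})

test_that("cohort assembly is deterministic and permits dual membership", {
  ds <- generate_claims(sim_config(n_patients = 1200, seed = 13))
  cfg <- study_config(seed = 4)
  a <- assemble_cohort(ds, cfg)
  b <- assemble_cohort(ds, cfg)
  expect_equal(a$members, b$members)
  expect_gt(length(a$dual_membership), 0)
  dual <- a$dual_membership[1]
  rows <- a$members[patient_id == dual]
  expect_gt(data.table::uniqueN(rows$index_date), 1)

  none <- claims_fixture(fx_patients("A"),
                         diagnoses = list(fx_dx("A", 600, "E780")))
  expect_equal(nrow(assemble_cohort(none, fx_config())$members), 0)
})

test_that("every selected control has a pemafibrate-free lookback (direct scan)", {
  ds <- generate_claims(sim_config(n_patients = 1500, seed = 19))
  cfg <- study_config(seed = 2)
  co <- assemble_cohort(ds, cfg)
  ctl <- co$members[group == "control"]
  rx <- ds$prescriptions[startsWith(code, "C10A2P"),
                         .(patient_id, d = as.integer(date))]
  m <- rx[ctl[, .(patient_id, i0 = as.integer(index_date) - 180L,
                  i1 = as.integer(index_date))],
          on = .(patient_id, d >= i0, d <= i1), nomatch = NULL]
  expect_equal(nrow(m), 0)
  # matched-set sizes respect 1 + match_ratio
  sizes <- co$members[, .N, by = matched_set_id]
  expect_true(all(sizes$N <= 1 + cfg$match_ratio))
  expect_equal(sum(co$members$group == "control"),
               cfg$match_ratio * sum(co$members$group == "exposed"))
})
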
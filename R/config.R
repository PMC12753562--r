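#' Default covariate specification for the claims simulator
#'
#' One row per baseline covariate: prevalence among patients, the code
#' emitted in claims records, the table it is recorded in, its log-odds
#' effect on treatment initiation (`beta_treat`, confounding channel into
#' exposure) and its log-hazard effect on the outcome (`beta_outcome`,
#' confounding channel into VTE risk). Age, sex, BMI and smoking are handled
#' separately (see [sim_config()]); this table covers the code-defined
#' binary covariates.
#'
#' The default effect pattern mirrors the qualitative structure reported for
#' real-world pemafibrate users: initiators are younger, more often male,
#' heavier, more often diabetic and on other lipid-modifying drugs, while
#' VTE risk rises with age, cancer, heart failure and kidney disease. With
#' these defaults the crude (unweighted) hazard ratio under a null exposure
#' effect is biased below 1.
#'
#' @return A `data.table` with columns `name`, `prevalence`, `code`,
#'   `record` (`"diagnosis"` or `"prescription"`), `beta_treat`,
#'   `beta_outcome`.
#' @export
default_covariate_spec <- function() {
  data.table::data.table(
    name = c("hypertension", "diabetes", "liver_disease", "cancer",
             "heart_failure", "pneumonia", "chronic_kidney_disease",
             "statin", "ezetimibe", "ipe", "omega3_fatty_acid",
             "oral_anticoagulant"),
    prevalence = c(0.14, 0.25, 0.08, 0.20, 0.12, 0.15, 0.05,
                   0.25, 0.03, 0.017, 0.009, 0.05),
    code = c("I10", "E11", "K76", "C18", "I50", "J18", "N18",
             "C10A1", "C10AX", "C10X1", "C10X2", "B01AF"),
    record = c(rep("diagnosis", 7), rep("prescription", 5)),
    beta_treat = c(0.20, 0.55, 0.60, -0.30, 0.00, 0.15, 0.30,
                   0.10, 0.90, 0.90, 1.10, -0.10),
    beta_outcome = c(0.20, 0.30, 0.20, 0.80, 0.50, 0.30, 0.40,
                     -0.10, 0.00, 0.10, 0.10, 0.30)
  )
}

#' Simulation configuration for synthetic claims generation
#'
#' Defines the generative model for [generate_claims()]: study window, drug
#' launch date, covariate structure (confounding), the true exposure effect
#' on the outcome hazard, refill behaviour, and the MAR missingness
#' mechanism for BMI and smoking measurements.
#'
#' @param n_patients Number of patients (positive integer).
#' @param study_start,study_end Calendar bounds of the claims extract.
#' @param drug_launch_date Date the study drug becomes prescribable; only
#'   first-diagnosis dates on/after this date make a patient cohort-eligible
#'   downstream.
#' @param covariate_spec Data frame as returned by
#'   [default_covariate_spec()].
#' @param beta_age_treat,beta_age_outcome Per-year effects of (age - 65) on
#'   the initiation log-rate and outcome log-hazard.
#' @param beta_female_treat,beta_female_outcome Effects of female sex.
#' @param beta_smoking_treat,beta_smoking_outcome Effects of smoking.
#' @param beta_bmi_treat,beta_bmi_outcome Per-unit effects of (BMI - 24).
#' @param true_log_hr True log hazard ratio of the exposure on the outcome
#'   (time-varying: applies while drug supply is active).
#' @param baseline_hazard Outcome events per person-day at covariate
#'   reference values (age 65, male, BMI 24, non-smoker, no comorbidity).
#'   The default corresponds to about 1.3 events per 100 person-years.
#' @param init_rate Treatment-initiation events per person-day at reference
#'   covariate values, acting from the later of first diagnosis and drug
#'   launch.
#' @param refill_spec List with `supply_days` (values, `probs`), per-refill
#'   discontinuation probability `p_stop`, and the inter-refill gap mixture:
#'   `short_gap_max`, `long_gap_range`, `p_long_gap`. Defaults produce both
#'   continuous and clearly discontinued exposure histories.
#' @param missing_spec List with `target` (proportion of BMI/smoking
#'   measurements deleted, in `[0, 1)`) and MAR log-odds coefficients on the
#'   fully observed covariates `age` (per decade from 65), `female`,
#'   `diabetes`. The intercept is calibrated so the realized deletion
#'   probability averages `target`. `target = 0` disables missingness.
#' @param inpatient_fraction Probability that an outcome's diagnosis and
#'   treatment records occur during a hospitalization (inpatient setting).
#' @param vte_noise_rate Fraction of patients given a lone VTE diagnosis
#'   (no qualifying prescription) that must not be ascertained as an event.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output tables.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_patients = 5000,
                       study_start = "2017-12-01",
                       study_end = "2023-07-31",
                       drug_launch_date = "2018-06-01",
                       covariate_spec = default_covariate_spec(),
                       beta_age_treat = -0.045, beta_age_outcome = 0.035,
                       beta_female_treat = -0.65, beta_female_outcome = 0.05,
                       beta_smoking_treat = 0.60, beta_smoking_outcome = 0.25,
                       beta_bmi_treat = 0.09, beta_bmi_outcome = 0.02,
                       true_log_hr = 0,
                       baseline_hazard = 3.6e-5,
                       init_rate = 2.5e-4,
                       refill_spec = list(
                         supply_days = c(30, 60, 90),
                         probs = c(0.5, 0.3, 0.2),
                         p_stop = 0.15,
                         short_gap_max = 14,
                         long_gap_range = c(20, 120),
                         p_long_gap = 0.2),
                       missing_spec = list(
                         target = 0.8,
                         beta_age = 0.3, beta_female = -0.2,
                         beta_diabetes = 0.4),
                       inpatient_fraction = 0.2,
                       vte_noise_rate = 0.01,
                       seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1)
    stop("n_patients must be a positive integer")
  cfg <- list(
    n_patients = as.integer(n_patients),
    study_start = as_day(study_start),
    study_end = as_day(study_end),
    drug_launch_date = as_day(drug_launch_date),
    covariate_spec = data.table::as.data.table(covariate_spec),
    beta_age_treat = beta_age_treat, beta_age_outcome = beta_age_outcome,
    beta_female_treat = beta_female_treat,
    beta_female_outcome = beta_female_outcome,
    beta_smoking_treat = beta_smoking_treat,
    beta_smoking_outcome = beta_smoking_outcome,
    beta_bmi_treat = beta_bmi_treat, beta_bmi_outcome = beta_bmi_outcome,
    true_log_hr = true_log_hr,
    baseline_hazard = baseline_hazard,
    init_rate = init_rate,
    refill_spec = refill_spec,
    missing_spec = missing_spec,
    inpatient_fraction = inpatient_fraction,
    vte_noise_rate = vte_noise_rate,
    seed = as.integer(seed)
  )
  if (!(cfg$study_start <= cfg$drug_launch_date &&
        cfg$drug_launch_date < cfg$study_end))
    stop("dates must satisfy study_start <= drug_launch_date < study_end")
  ms <- cfg$missing_spec$target
  if (is.null(ms) || ms < 0 || ms >= 1)
    stop("missing_spec target must lie in [0, 1)")
  probs <- c(cfg$covariate_spec$prevalence, cfg$inpatient_fraction,
             cfg$refill_spec$p_stop, cfg$refill_spec$p_long_gap,
             cfg$vte_noise_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Study-design configuration (code lists and design constants)
#'
#' Holds the code dictionary and the design constants of the cohort study:
#' the inclusion cutoff date, the 180-day baseline window, the 1:5 matching
#' ratio, minimum age 20, the per-protocol gap/grace scenarios
#' {0, 30, 90, 180} days, and the number of imputations (20).
#'
#' The default code lists are the synthetic dictionary matching
#' [generate_claims()]; real-data users supply their own prefixes.
#'
#' @param dyslipidemia_codes,pemafibrate_codes,fibrate_codes,vte_codes
#'   Character vectors of code prefixes. `fibrate_codes` must cover every
#'   fibrate including pemafibrate (baseline fibrate exclusion).
#' @param contraindication_dx_codes,contraindication_rx_codes Baseline
#'   exclusion code prefixes (biliary atresia/gallstone diagnoses;
#'   cyclosporine/rifampicin prescriptions).
#' @param thrombolytic_anticoagulant_codes Prescription prefixes that
#'   qualify a VTE diagnosis as an outcome event.
#' @param cutoff_date First-diagnosis inclusion cutoff.
#' @param baseline_days Length of the baseline window before the index date.
#' @param match_ratio Controls selected per exposed patient.
#' @param min_age Minimum age (completed years) at the index date.
#' @param gap_grace_days Per-protocol gap/grace scenario durations (days).
#' @param n_imputations Imputations for the missing-data model.
#' @param rx_after_dx_strict If `TRUE`, the inpatient outcome date must be
#'   strictly after the VTE diagnosis record; default is on-or-after.
#' @param seed Integer seed for control sampling.
#' @return An object of class `study_config`.
#' @export
study_config <- function(dyslipidemia_codes = "E78",
                         pemafibrate_codes = "C10A2P",
                         fibrate_codes = "C10A2",
                         vte_codes = c("I26", "I80", "I82"),
                         contraindication_dx_codes = c("K831", "K80"),
                         contraindication_rx_codes = c("L04X0", "J04A1"),
                         thrombolytic_anticoagulant_codes =
                           c("B01AA", "B01AB", "B01AD", "B01AF"),
                         cutoff_date = "2018-06-01",
                         baseline_days = 180L,
                         match_ratio = 5L,
                         min_age = 20L,
                         gap_grace_days = c(0L, 30L, 90L, 180L),
                         n_imputations = 20L,
                         rx_after_dx_strict = FALSE,
                         seed = 1L) {
  lists <- list(dyslipidemia_codes = dyslipidemia_codes,
                pemafibrate_codes = pemafibrate_codes,
                fibrate_codes = fibrate_codes, vte_codes = vte_codes,
                contraindication_dx_codes = contraindication_dx_codes,
                contraindication_rx_codes = contraindication_rx_codes,
                thrombolytic_anticoagulant_codes =
                  thrombolytic_anticoagulant_codes)
  empty <- names(lists)[vapply(lists, length, 1L) == 0]
  if (length(empty))
    stop("code list(s) must be non-empty: ", paste(empty, collapse = ", "))
  if (baseline_days <= 0) stop("baseline_days must be positive")
  if (match_ratio < 1) stop("match_ratio must be >= 1")
  if (any(gap_grace_days < 0)) stop("gap_grace_days must be non-negative")
  structure(list(
    dyslipidemia_codes = dyslipidemia_codes,
    pemafibrate_codes = pemafibrate_codes,
    fibrate_codes = fibrate_codes,
    vte_codes = vte_codes,
    contraindication_dx_codes = contraindication_dx_codes,
    contraindication_rx_codes = contraindication_rx_codes,
    thrombolytic_anticoagulant_codes = thrombolytic_anticoagulant_codes,
    cutoff_date = as_day(cutoff_date),
    baseline_days = as.integer(baseline_days),
    match_ratio = as.integer(match_ratio),
    min_age = as.integer(min_age),
    gap_grace_days = as.integer(gap_grace_days),
    n_imputations = as.integer(n_imputations),
    rx_after_dx_strict = isTRUE(rx_after_dx_strict),
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Default covariate code dictionary
#'
#' Maps covariate names to code prefixes for baseline covariate extraction.
#' Each entry has `prefixes` (matched by string prefix against diagnosis or
#' prescription codes), `record` (`"diagnosis"` or `"prescription"`), and
#' `kind` (`"binary-from-codes"`; BMI and smoking are
#' `"continuous-measurement"` / `"categorical-measurement"` handled from the
#' measurements table). The default is the synthetic-compatible dictionary;
#' real-data dictionaries can be loaded from YAML with
#' [read_code_dictionary()].
#'
#' @return A named list of class `code_dictionary`.
#' @export
default_code_dictionary <- function() {
  spec <- default_covariate_spec()
  dict <- lapply(seq_len(nrow(spec)), function(i) {
    list(prefixes = spec$code[i], record = spec$record[i],
         kind = "binary-from-codes")
  })
  names(dict) <- spec$name
  structure(dict, class = "code_dictionary")
}

#' Read a covariate code dictionary from YAML
#'
#' @param path YAML file: `covariate_name: {prefixes: [..], record: ..,
#'   kind: ..}`.
#' @return A `code_dictionary`.
#' @export
read_code_dictionary <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in names(raw)) {
    entry <- raw[[nm]]
    if (is.null(entry$prefixes) || length(entry$prefixes) == 0)
      stop("dictionary entry '", nm, "' has no prefixes")
    raw[[nm]]$record <- entry$record %||% "diagnosis"
    raw[[nm]]$kind <- entry$kind %||% "binary-from-codes"
  }
  structure(raw, class = "code_dictionary")
}
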
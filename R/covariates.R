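# Baseline covariate extraction: code-defined binary flags from the
# baseline window [index - baseline_days, index - 1], BMI category and
# smoking from the latest in-window measurement, age and sex from the
# patients table.

bmi_breaks <- c(-Inf, 18.5, 25, 30, 35, 40, Inf)
bmi_levels <- c("<18.5", "18.5-25", "25-30", "30-35", "35-40", ">=40")

#' Cut numeric BMI into the six study categories
#'
#' Left-closed categories `<18.5, [18.5,25), [25,30), [30,35), [35,40),
#' >=40`, returned as an ordered factor.
#'
#' @param bmi Numeric vector.
#' @return Ordered factor with six levels.
#' @export
bmi_category <- function(bmi) {
  cut(bmi, breaks = bmi_breaks, labels = bmi_levels,
      right = FALSE, ordered_result = TRUE)
}

#' Extract baseline covariate vectors for cohort members
#'
#' For each member: each code-defined flag is 1 iff any record with a
#' matching code prefix exists in the member's baseline window; BMI and
#' smoking come from the latest measurement in the window (missing if
#' none, ties on the same date broken by record order, latest wins); age
#' (completed years at index) and sex come from the patients table.
#'
#' @param members Cohort member table (or a `tm_cohort`).
#' @param dataset A `claims_dataset`.
#' @param dictionary A `code_dictionary`; default
#'   [default_code_dictionary()].
#' @param config A [study_config()].
#' @return A `data.table`: one row per member with `patient_id`, `group`,
#'   `index_date`, `matched_set_id`, `age`, `female`, `bmi_category`
#'   (ordered factor, NA if unmeasured), `smoking` (0/1/NA), and one 0/1
#'   column per dictionary covariate.
#' @export
extract_covariates <- function(members, dataset,
                               dictionary = default_code_dictionary(),
                               config = study_config()) {
  if (inherits(members, "tm_cohort")) members <- members$members
  members <- data.table::as.data.table(members)
  out <- members[, .(patient_id, group, index_date, matched_set_id)]
  out[, row_id := .I]
  b <- config$baseline_days
  win <- out[, .(row_id, patient_id, w0 = as_day(index_date) - b,
                 w1 = as_day(index_date) - 1L)]

  p <- dataset$patients[, .(patient_id, sex, birth_date)]
  out <- merge(out, p, by = "patient_id", all.x = TRUE, sort = FALSE)
  out[, age := completed_years(birth_date, index_date)]
  out[, female := as.integer(sex == "F")]
  out[, c("sex", "birth_date") := NULL]

  dx <- dataset$diagnoses[, .(patient_id, d = as_day(date), code)]
  rx <- dataset$prescriptions[, .(patient_id, d = as_day(date), code)]
  for (nm in names(dictionary)) {
    entry <- dictionary[[nm]]
    if (!entry$kind %in% c("binary-from-codes"))
      stop("unknown covariate kind '", entry$kind, "' for '", nm, "'")
    tab <- if (identical(entry$record, "prescription")) rx else dx
    recs <- tab[code_matches(code, entry$prefixes)]
    hit <- recs[win, on = .(patient_id, d >= w0, d <= w1), nomatch = NULL,
                .(row_id = i.row_id)]
    data.table::set(out, j = nm, value = 0L)
    if (nrow(hit)) data.table::set(out, i = unique(hit$row_id), j = nm,
                                   value = 1L)
  }

  meas <- dataset$measurements[, .(patient_id, d = as_day(date), kind, value,
                                   rec = .I)]
  for (mk in c("bmi", "smoking")) {
    mm <- meas[kind == mk]
    hit <- mm[win, on = .(patient_id, d >= w0, d <= w1), nomatch = NULL,
              .(row_id = i.row_id, d = x.d, value = x.value, rec = x.rec)]
    # latest measurement in window wins; same-date ties by record order
    latest <- hit[order(row_id, d, rec)][, .SD[.N], by = row_id]
    col <- if (mk == "bmi") "bmi_value" else "smoking"
    data.table::set(out, j = col,
                    value = if (mk == "bmi") NA_real_ else NA_integer_)
    if (nrow(latest))
      data.table::set(out, i = latest$row_id, j = col,
                      value = if (mk == "bmi") latest$value
                              else as.integer(latest$value))
  }
  out[, bmi_category := bmi_category(bmi_value)]
  out[, bmi_value := NULL]
  out[, row_id := NULL]
  out[]
}

# names of the code-defined + measured covariates in a covariate table
covariate_columns <- function(covariates) {
  setdiff(names(covariates),
          c("patient_id", "group", "index_date", "matched_set_id"))
}
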
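# Cohort construction: inclusion, the eight exclusion criteria, and the
# time-matched (X-day offset) selection of controls at a fixed ratio.
#
# Window conventions (day-granular, closed intervals):
#   baseline window for criteria 2, 3, 7, 8 and covariates:
#       [index - baseline_days, index - 1]  (the index day is follow-up)
#   control pemafibrate lookback: [index - baseline_days, index] inclusive,
#       since a control on pemafibrate at index would be exposed.

exclusion_labels <- c(
  "1" = "insufficient_history",
  "2" = "baseline_fibrate",
  "3" = "baseline_vte",
  "4" = "pemafibrate_before_first_diagnosis",
  "5" = "observable_end_before_index",
  "6" = "age_under_minimum",
  "7" = "baseline_biliary_gallstone",
  "8" = "baseline_contraindicated_rx")

has_in <- function(v, a, b) {
  length(v) > 0L && (findInterval(b, v) - findInterval(a - 1L, v)) > 0L
}

#' Precompute a per-patient lookup index over a claims dataset
#'
#' Internal accelerator for cohort construction: per-patient observable
#' bounds, the day the patient reaches the minimum age, the first
#' dyslipidemia diagnosis, and sorted date vectors of the code classes used
#' by the exclusion criteria.
#'
#' @param dataset A `claims_dataset`.
#' @param config A [study_config()].
#' @return An opaque list consumed by the cohort functions.
#' @keywords internal
claims_index <- function(dataset, config) {
  p <- dataset$patients
  pidv <- p$patient_id
  st <- as_day(p$observable_start)
  en <- as_day(p$observable_end)
  birth <- as_day(p$birth_date)
  bl <- as.POSIXlt(day_to_date(birth))
  bl$year <- bl$year + config$min_age
  minday <- as_day(as.Date(bl))

  dx <- dataset$diagnoses[, .(patient_id, d = as_day(date), code)]
  rx <- dataset$prescriptions[, .(patient_id, d = as_day(date), code)]
  split_dates <- function(tab) {
    s <- split(tab$d, factor(tab$patient_id, levels = pidv))
    lapply(s, sort)
  }
  dys <- split_dates(dx[code_matches(code, config$dyslipidemia_codes)])
  first_dys <- vapply(dys, function(v) if (length(v)) v[1] else NA_integer_,
                      integer(1))
  first_elig <- ifelse(!is.na(first_dys) & first_dys >= config$cutoff_date,
                       first_dys, NA_integer_)

  list(pid = pidv, pos = stats::setNames(seq_along(pidv), pidv),
       st = st, en = en, birth = birth, minday = minday,
       first_dys = first_dys, first_elig = as.integer(first_elig),
       pema = split_dates(rx[code_matches(code, config$pemafibrate_codes)]),
       fib = split_dates(rx[code_matches(code, config$fibrate_codes)]),
       vte = split_dates(dx[code_matches(code, config$vte_codes)]),
       cdx = split_dates(dx[code_matches(code, config$contraindication_dx_codes)]),
       crx = split_dates(rx[code_matches(code, config$contraindication_rx_codes)]),
       config = config)
}

# scalar evaluation of the eight Table-1 criteria for one patient position
violations_at <- function(idx, pos, index_day, role) {
  cfg <- idx$config
  b <- cfg$baseline_days
  a0 <- index_day - b
  a1 <- index_day - 1L
  v <- character()
  if (!(idx$st[pos] <= a0)) v <- c(v, exclusion_labels["1"])
  if (has_in(idx$fib[[pos]], a0, a1)) v <- c(v, exclusion_labels["2"])
  if (has_in(idx$vte[[pos]], a0, a1)) v <- c(v, exclusion_labels["3"])
  if (role == "exposed") {
    fe <- idx$first_elig[pos]
    pm <- idx$pema[[pos]]
    if (!is.na(fe) && length(pm) && pm[1] < fe)
      v <- c(v, exclusion_labels["4"])
  } else {
    if (idx$en[pos] < index_day) v <- c(v, exclusion_labels["5"])
  }
  if (index_day < idx$minday[pos]) v <- c(v, exclusion_labels["6"])
  if (has_in(idx$cdx[[pos]], a0, a1)) v <- c(v, exclusion_labels["7"])
  if (has_in(idx$crx[[pos]], a0, a1)) v <- c(v, exclusion_labels["8"])
  unname(v)
}

#' First cohort-eligible dyslipidemia diagnosis for one patient
#'
#' The earliest dyslipidemia diagnosis on/after the cutoff date, provided
#' the patient's overall first dyslipidemia diagnosis itself falls on/after
#' the cutoff (a patient first diagnosed earlier is never eligible).
#'
#' @param patient_id Patient identifier.
#' @param dataset A `claims_dataset`.
#' @param config A [study_config()].
#' @param index Optional prebuilt [claims_index()].
#' @return A `Date`, or `NA` if the patient has no eligible first diagnosis.
#' @export
first_eligible_diagnosis <- function(patient_id, dataset, config,
                                     index = NULL) {
  idx <- index %||% claims_index(dataset, config)
  pos <- unname(idx$pos[patient_id])
  if (is.na(pos)) stop("unknown patient: ", patient_id)
  day_to_date(idx$first_elig[pos])
}

#' Evaluate the exclusion criteria for a patient at an index date
#'
#' Applies all eight exclusion criteria in their role-specific form and
#' returns every violated criterion, not just the first.
#'
#' @param patient_id Patient identifier.
#' @param index_date Candidate index date.
#' @param role `"exposed"` or `"control"`.
#' @inheritParams first_eligible_diagnosis
#' @return A list with `eligible` (logical) and `violations` (character
#'   vector of criterion labels).
#' @export
check_exclusions <- function(patient_id, index_date, role, dataset, config,
                             index = NULL) {
  role <- match.arg(role, c("exposed", "control"))
  idx <- index %||% claims_index(dataset, config)
  pos <- unname(idx$pos[patient_id])
  if (is.na(pos)) stop("unknown patient: ", patient_id)
  d <- as_day(index_date)
  if (role == "exposed" && !has_in(idx$pema[[pos]], d, d))
    stop("exposed role requires a pemafibrate prescription at the index ",
         "date (cohort construction bug)")
  v <- violations_at(idx, pos, d, role)
  list(eligible = length(v) == 0L, violations = v)
}

#' Build the exposed cohort with an attrition report
#'
#' One member per patient whose first pemafibrate prescription on/after
#' their first eligible dyslipidemia diagnosis passes all exclusion
#' criteria; the index date is that prescription date and `offset_days_X`
#' is the number of days from first diagnosis to index.
#'
#' @inheritParams first_eligible_diagnosis
#' @return A list with `members` (a `data.table`) and `attrition` (ordered
#'   step/label/remaining counts).
#' @export
build_exposed_cohort <- function(dataset, config, index = NULL) {
  idx <- index %||% claims_index(dataset, config)
  n <- length(idx$pid)
  att <- data.table::data.table(step = "all_patients", remaining = n)
  elig <- which(!is.na(idx$first_elig))
  att <- rbind(att, data.table::data.table(
    step = "first_diagnosis_on_or_after_cutoff", remaining = length(elig)))

  # first pemafibrate on/after the first eligible diagnosis
  fe <- idx$first_elig[elig]
  index_day <- rep(NA_integer_, length(elig))
  for (j in seq_along(elig)) {
    pm <- idx$pema[[elig[j]]]
    k <- findInterval(fe[j] - 1L, pm) + 1L
    if (k <= length(pm)) index_day[j] <- pm[k]
  }
  have_rx <- !is.na(index_day)
  elig <- elig[have_rx]; fe <- fe[have_rx]; index_day <- index_day[have_rx]
  att <- rbind(att, data.table::data.table(
    step = "pemafibrate_on_or_after_first_diagnosis",
    remaining = length(elig)))

  viol <- lapply(seq_along(elig), function(j)
    violations_at(idx, elig[j], index_day[j], "exposed"))
  for (cr in names(exclusion_labels)) {
    if (cr == "5") next  # control-only criterion
    lb <- exclusion_labels[[cr]]
    hit <- vapply(viol, function(v) lb %in% v, logical(1))
    keep <- !vapply(viol, function(v)
      any(v %in% exclusion_labels[seq_len(match(cr, names(exclusion_labels)))]),
      logical(1))
    att <- rbind(att, data.table::data.table(
      step = paste0("excl_", cr, "_", lb), remaining = sum(keep)))
  }
  ok <- vapply(viol, length, 1L) == 0L
  members <- data.table::data.table(
    patient_id = idx$pid[elig[ok]],
    group = "exposed",
    index_date = day_to_date(index_day[ok]),
    first_dyslipidemia_date = day_to_date(fe[ok]),
    offset_days_X = index_day[ok] - fe[ok],
    matched_set_id = NA_character_)
  list(members = members[order(index_date, patient_id)], attrition = att)
}

# core matching walk: uniform sample without replacement from the valid pool
match_controls_core <- function(idx, exposed_pos, X, set_id) {
  cfg <- idx$config
  b <- cfg$baseline_days
  candidates <- which(!is.na(idx$first_elig))
  candidates <- candidates[candidates != exposed_pos]
  if (!length(candidates)) return(integer(0))
  perm <- candidates[sample.int(length(candidates))]
  found <- integer(0); found_idx <- integer(0)
  for (p in perm) {
    ci <- idx$first_elig[p] + X
    if (idx$en[p] < ci) next
    if (!(idx$st[p] <= ci - b)) next
    if (ci < idx$minday[p]) next
    if (has_in(idx$pema[[p]], ci - b, ci)) next       # time-matched lookback
    if (has_in(idx$fib[[p]], ci - b, ci - 1L)) next
    if (has_in(idx$vte[[p]], ci - b, ci - 1L)) next
    if (has_in(idx$cdx[[p]], ci - b, ci - 1L)) next
    if (has_in(idx$crx[[p]], ci - b, ci - 1L)) next
    found <- c(found, p); found_idx <- c(found_idx, ci)
    if (length(found) == cfg$match_ratio) break
  }
  if (length(found) < cfg$match_ratio)
    warning("matched set ", set_id, ": control pool smaller than ",
            cfg$match_ratio, " (found ", length(found), ")", call. = FALSE)
  data.table::data.table(
    patient_id = idx$pid[found], group = "control",
    index_date = day_to_date(found_idx),
    first_dyslipidemia_date = day_to_date(idx$first_elig[found]),
    offset_days_X = X, matched_set_id = set_id)
}

#' Select time-matched controls for one exposed member
#'
#' The candidate pool consists of every other patient with a first eligible
#' dyslipidemia diagnosis whose candidate index date (their own first
#' diagnosis plus the exposed member's X-day offset) has a pemafibrate-free
#' lookback window and passes the control-role exclusion criteria. Controls
#' are drawn uniformly at random without replacement; if the pool is
#' smaller than the matching ratio all pool members are returned with a
#' warning.
#'
#' @param exposed_member One-row exposed member (as from
#'   [build_exposed_cohort()]).
#' @inheritParams first_eligible_diagnosis
#' @return A `data.table` of control members sharing the exposed member's
#'   `matched_set_id`.
#' @export
match_controls <- function(exposed_member, dataset, config, index = NULL) {
  idx <- index %||% claims_index(dataset, config)
  pos <- unname(idx$pos[exposed_member$patient_id])
  set_id <- exposed_member$matched_set_id
  if (is.na(set_id)) set_id <- paste0("S_", exposed_member$patient_id)
  match_controls_core(idx, pos, exposed_member$offset_days_X, set_id)
}

#' Assemble the full time-matched cohort
#'
#' Builds the exposed cohort, then selects controls per exposed member in
#' ascending index-date order (ties broken by patient id) so results are
#' reproducible under the config seed. Dual group membership is permitted:
#' the same patient may appear as a control for one matched set and as the
#' exposed member of another, at distinct index dates.
#'
#' @inheritParams first_eligible_diagnosis
#' @return A `tm_cohort` object: list with `members`, `attrition`,
#'   `realized_ratio`, and `dual_membership` (patient ids in both groups).
#' @export
assemble_cohort <- function(dataset, config, index = NULL) {
  idx <- index %||% claims_index(dataset, config)
  ex <- build_exposed_cohort(dataset, config, index = idx)
  members <- ex$members
  controls <- list()
  if (nrow(members)) {
    members[, matched_set_id := sprintf("S%06d", seq_len(.N))]
    withr::with_seed(config$seed, {
      for (j in seq_len(nrow(members))) {
        controls[[j]] <- match_controls_core(
          idx, idx$pos[[members$patient_id[j]]],
          members$offset_days_X[j], members$matched_set_id[j])
      }
    })
  }
  all_members <- data.table::rbindlist(c(list(members), controls))
  n_exp <- sum(all_members$group == "exposed")
  n_ctl <- sum(all_members$group == "control")
  dual <- intersect(all_members[group == "exposed", patient_id],
                    all_members[group == "control", patient_id])
  att <- rbind(ex$attrition, data.table::data.table(
    step = "matched_controls", remaining = n_ctl))
  structure(list(members = all_members, attrition = att,
                 realized_ratio = if (n_exp) n_ctl / n_exp else NA_real_,
                 dual_membership = dual),
            class = "tm_cohort")
}

#' @export
print.tm_cohort <- function(x, ...) {
  cat("<tm_cohort> ", sum(x$members$group == "exposed"), " exposed, ",
      sum(x$members$group == "control"), " controls (ratio ",
      format(x$realized_ratio, digits = 3), ")\n", sep = "")
  if (length(x$dual_membership))
    cat("  ", length(x$dual_membership),
        " patient(s) appear in both groups\n", sep = "")
  invisible(x)
}
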
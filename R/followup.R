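# Follow-up construction: drug exposure episodes with gap merging, grace
# extension, VTE ascertainment (diagnosis + treatment co-occurrence), and
# ITT / per-protocol analysis intervals.

#' Build drug exposure episodes from prescription records
#'
#' Each prescription covers the closed interval
#' `[date, date + days_supply - 1]`. Consecutive supply intervals merge
#' into one episode when the uncovered span between them
#' (`next_start - current_end - 1`) is at most `gap_days`; overlapping
#' supplies always merge. With `gap_days = 0`, back-to-back refills are
#' continuous but any uncovered day splits the episode.
#'
#' @param dates Prescription dates (Date or integer days), study drug only.
#' @param days_supply Supplied days per prescription (all `>= 1`).
#' @param gap_days Maximum uncovered span treated as continuous exposure.
#' @return A `data.table` with `start`, `end` (integer days), ordered and
#'   disjoint.
#' @examples
#' build_exposure_episodes(c(0, 35), c(30, 30), gap_days = 30) # one episode
#' build_exposure_episodes(c(0, 35), c(30, 30), gap_days = 0)  # two
#' @export
build_exposure_episodes <- function(dates, days_supply, gap_days) {
  if (length(dates) == 0)
    return(data.table::data.table(start = integer(), end = integer()))
  if (any(days_supply < 1)) stop("days_supply must be >= 1")
  d <- as_day(dates)
  o <- order(d)
  d <- d[o]; s <- as.integer(days_supply)[o]
  start <- d[1]; end <- d[1] + s[1] - 1L
  starts <- integer(); ends <- integer()
  for (j in seq_along(d)[-1]) {
    uncovered <- d[j] - end - 1L
    if (uncovered <= gap_days) {
      end <- max(end, d[j] + s[j] - 1L)
    } else {
      starts <- c(starts, start); ends <- c(ends, end)
      start <- d[j]; end <- d[j] + s[j] - 1L
    }
  }
  data.table::data.table(start = c(starts, start), end = c(ends, end))
}

#' End of drug exposure after the grace extension
#'
#' The last episode's end plus `grace_days` residual-effect days.
#'
#' @param episodes Episode table from [build_exposure_episodes()].
#' @param grace_days Non-negative integer.
#' @return Integer day.
#' @export
exposure_end <- function(episodes, grace_days) {
  if (!nrow(episodes)) stop("empty episode list")
  episodes$end[nrow(episodes)] + as.integer(grace_days)
}

#' Ascertain the earliest VTE event for one patient in a window
#'
#' Outpatient rule: a VTE diagnosis and a qualifying
#' thrombolytic/anticoagulant prescription for the same patient at the same
#' facility on the same date. Inpatient rule: both recorded within the same
#' hospitalization; the event date is the prescription date, taking the
#' earliest prescription on/after the diagnosis record (strictly after if
#' `config$rx_after_dx_strict`; if no prescription follows the diagnosis
#' within the stay, the stay's earliest qualifying prescription is used).
#'
#' @param patient_id Patient identifier.
#' @param dataset A `claims_dataset`.
#' @param window Length-2 vector of days/Dates `[a, b]` (closed).
#' @param config A [study_config()].
#' @return A list with `day` (Date), `setting`, `dx_date`, `rx_date`, or
#'   `NULL` if no event occurs in the window.
#' @export
ascertain_vte <- function(patient_id, dataset, window, config) {
  a <- as_day(window[1]); b <- as_day(window[2])
  if (a > b) stop("invalid window")
  pid <- patient_id
  dx <- dataset$diagnoses[patient_id == pid &
                          code_matches(code, config$vte_codes)]
  rx <- dataset$prescriptions[
    patient_id == pid &
    code_matches(code, config$thrombolytic_anticoagulant_codes)]
  if (!nrow(dx) || !nrow(rx)) return(NULL)
  dx[, d := as_day(date)]
  rx[, d := as_day(date)]
  cand <- list()

  # outpatient: same facility, same date
  op <- merge(dx[setting == "outpatient", .(d, facility_id)],
              rx[setting == "outpatient", .(d, facility_id)],
              by = c("d", "facility_id"))
  if (nrow(op))
    cand[["op"]] <- data.table::data.table(day = op$d, setting = "outpatient",
                                           dx_date = op$d, rx_date = op$d)

  # inpatient: same hospitalization
  dxh <- dx[!is.na(hospitalization_id)]
  rxh <- rx[!is.na(hospitalization_id)]
  if (nrow(dxh) && nrow(rxh)) {
    unknown <- setdiff(c(dxh$hospitalization_id, rxh$hospitalization_id),
                       dataset$hospitalizations$hospitalization_id)
    if (length(unknown))
      stop("records reference unknown hospitalization id(s): ",
           paste(head(unknown, 3), collapse = ", "))
    both <- intersect(dxh$hospitalization_id, rxh$hospitalization_id)
    for (hid in both) {
      ddx <- min(dxh[hospitalization_id == hid, d])
      rr <- sort(rxh[hospitalization_id == hid, d])
      after <- if (config$rx_after_dx_strict) rr[rr > ddx] else rr[rr >= ddx]
      ev <- if (length(after)) after[1] else rr[1]
      cand[[paste0("ip_", hid)]] <- data.table::data.table(
        day = ev, setting = "inpatient", dx_date = ddx, rx_date = ev)
    }
  }
  if (!length(cand)) return(NULL)
  all_ev <- data.table::rbindlist(cand)[day >= a & day <= b][order(day)]
  if (!nrow(all_ev)) return(NULL)
  list(day = day_to_date(all_ev$day[1]), setting = all_ev$setting[1],
       dx_date = day_to_date(all_ev$dx_date[1]),
       rx_date = day_to_date(all_ev$rx_date[1]))
}

# vectorized event lookup for a whole cohort: returns, per member row, the
# earliest qualifying event day on/after the member's index date (NA if none)
cohort_event_days <- function(members, dataset, config) {
  dx <- dataset$diagnoses[code_matches(code, config$vte_codes),
                          .(patient_id, d = as_day(date), setting,
                            facility_id, hospitalization_id)]
  rx <- dataset$prescriptions[
    code_matches(code, config$thrombolytic_anticoagulant_codes),
    .(patient_id, d = as_day(date), setting, facility_id,
      hospitalization_id)]
  ev <- data.table::data.table(patient_id = character(), day = integer())
  if (nrow(dx) && nrow(rx)) {
    op <- merge(dx[setting == "outpatient",
                   .(patient_id, d, facility_id)],
                rx[setting == "outpatient",
                   .(patient_id, d, facility_id)],
                by = c("patient_id", "d", "facility_id"))
    ev <- rbind(ev, unique(op[, .(patient_id, day = d)]))
    dxh_src <- dx[!is.na(hospitalization_id)]
    dxh <- if (nrow(dxh_src))
      dxh_src[, .(first_dx = min(d)), by = .(patient_id, hospitalization_id)]
    else data.table::data.table(patient_id = character(),
                                hospitalization_id = character(),
                                first_dx = integer())
    rxh <- rx[!is.na(hospitalization_id),
              .(patient_id, hospitalization_id, d)]
    ip <- merge(dxh, rxh, by = c("patient_id", "hospitalization_id"))
    if (nrow(ip)) {
      strict <- config$rx_after_dx_strict
      ip[, ok := if (strict) d > first_dx else d >= first_dx]
      ip_ev <- ip[, {
        after <- d[ok]
        .(day = if (length(after)) min(after) else min(d))
      }, by = .(patient_id, hospitalization_id)]
      ev <- rbind(ev, ip_ev[, .(patient_id, day)])
    }
  }
  members <- data.table::as.data.table(members)
  mem <- members[, .(row_id = .I, patient_id, idx = as_day(index_date))]
  hit <- ev[mem, on = .(patient_id, day >= idx), nomatch = NULL,
            .(row_id = i.row_id, day = x.day)]
  first_hit <- if (nrow(hit)) hit[, .(event_day = min(day)), by = row_id]
               else data.table::data.table(row_id = integer(),
                                           event_day = integer())
  out <- rep(NA_integer_, nrow(members))
  out[first_hit$row_id] <- first_hit$event_day
  out
}

finish_followup <- function(members, start, end, event_day, reasons,
                            analysis) {
  data.table::data.table(
    patient_id = members$patient_id, group = members$group,
    matched_set_id = members$matched_set_id, analysis = analysis,
    start = day_to_date(start), end = day_to_date(end),
    event = !is.na(event_day) & event_day <= end,
    event_date = day_to_date(ifelse(!is.na(event_day) & event_day <= end,
                                    event_day, NA_integer_)),
    censor_reason = reasons, time_days = as.integer(end - start))
}

#' Intention-to-treat follow-up records
#'
#' Follow-up runs from the index date to the earlier of the first VTE event
#' and the end of the observable period; treatment changes during follow-up
#' are ignored.
#'
#' @param members Cohort member table (or `tm_cohort`).
#' @param dataset A `claims_dataset`.
#' @param config A [study_config()].
#' @return A `data.table` of follow-up records (`analysis = "ITT"`).
#' @export
itt_followup <- function(members, dataset, config = study_config()) {
  if (inherits(members, "tm_cohort")) members <- members$members
  members <- data.table::as.data.table(members)
  obs <- dataset$patients[, .(patient_id, oe = as_day(observable_end))]
  m <- merge(members, obs, by = "patient_id", all.x = TRUE, sort = FALSE)
  start <- as_day(m$index_date)
  if (any(m$oe < start))
    stop("observable period ends before index for ",
         sum(m$oe < start), " member(s); they should have been excluded")
  event_day <- cohort_event_days(m, dataset, config)
  end <- pmin(ifelse(is.na(event_day), m$oe, event_day), m$oe)
  reasons <- ifelse(!is.na(event_day) & event_day <= end, "event",
                    "end_observable")
  finish_followup(m, start, end, event_day, reasons, "ITT")
}

#' Per-protocol follow-up records under one gap/grace scenario
#'
#' Exposed members are followed until the earliest of: event, end of the
#' observable period, first prescription of another fibrate, or the end of
#' pemafibrate exposure (last episode end under gap merging, plus the grace
#' period). Controls are followed until the earliest of: event, end of the
#' observable period, or first prescription of pemafibrate or any other
#' fibrate on/after the index date.
#'
#' @inheritParams itt_followup
#' @param gap_grace_days Single non-negative integer: the scenario's shared
#'   gap and grace duration.
#' @return A `data.table` of follow-up records (`analysis = "PP-<days>"`).
#' @export
pp_followup <- function(members, dataset, config = study_config(),
                        gap_grace_days = 0L) {
  if (inherits(members, "tm_cohort")) members <- members$members
  members <- data.table::as.data.table(members)
  g <- as.integer(gap_grace_days)
  obs <- dataset$patients[, .(patient_id, oe = as_day(observable_end))]
  m <- merge(members, obs, by = "patient_id", all.x = TRUE, sort = FALSE)
  start <- as_day(m$index_date)
  event_day <- cohort_event_days(m, dataset, config)

  rx <- dataset$prescriptions[, .(patient_id, d = as_day(date), code,
                                  days_supply)]
  is_pema <- code_matches(rx$code, config$pemafibrate_codes)
  is_fib <- code_matches(rx$code, config$fibrate_codes)
  pema_rx <- rx[is_pema]
  other_fib <- rx[is_fib & !is_pema]

  mem <- data.table::data.table(row_id = seq_len(nrow(m)),
                                patient_id = m$patient_id, idx = start)

  first_on_after <- function(tab) {
    hit <- tab[mem, on = .(patient_id, d >= idx), nomatch = NULL,
               .(row_id = i.row_id, d = x.d)]
    res <- if (nrow(hit)) hit[, .(d = min(d)), by = row_id]
           else data.table::data.table(row_id = integer(), d = integer())
    out <- rep(NA_integer_, nrow(m))
    out[res$row_id] <- res$d
    out
  }
  other_fib_day <- first_on_after(other_fib)
  pema_day_after <- first_on_after(pema_rx)

  exp_end <- rep(NA_integer_, nrow(m))
  is_exp <- m$group == "exposed"
  if (any(is_exp)) {
    per <- pema_rx[mem[is_exp], on = .(patient_id, d >= idx), nomatch = NULL,
                   .(row_id = i.row_id, d = x.d, days_supply = x.days_supply)]
    ee <- per[, {
      ep <- build_exposure_episodes(d, days_supply, g)
      .(exp_end = exposure_end(ep, g))
    }, by = row_id]
    exp_end[ee$row_id] <- ee$exp_end
  }

  if (any(m$oe < start))
    stop("observable period ends before index for ",
         sum(m$oe < start), " member(s); they should have been excluded")
  end <- m$oe
  reason <- rep("end_observable", nrow(m))
  # candidates applied in increasing priority: on a tied day the later
  # label wins (treatment-change censoring preferred over end of data)
  take <- function(cand, label, current_end, current_reason) {
    better <- !is.na(cand) & cand <= current_end
    current_reason[better] <- label
    list(pmin(current_end, cand, na.rm = TRUE), current_reason)
  }
  for (spec in list(
    list(ifelse(is_exp, other_fib_day, NA_integer_), "other_fibrate"),
    list(ifelse(is_exp, exp_end, NA_integer_), "exposure_end"),
    list(ifelse(!is_exp, pema_day_after, NA_integer_), "pemafibrate_start"),
    list(ifelse(!is_exp, other_fib_day, NA_integer_), "other_fibrate"))) {
    res <- take(spec[[1]], spec[[2]], end, reason)
    end <- res[[1]]; reason <- res[[2]]
  }
  end <- pmax(end, start)  # censoring bound never precedes the index day
  has_event <- !is.na(event_day) & event_day <= end
  end[has_event] <- event_day[has_event]
  reason[has_event] <- "event"
  finish_followup(m, start, end, event_day, reason,
                  paste0("PP-", g))
}

#' Events, person-years and incidence per 100 person-years
#'
#' Person-years are `sum(end - start) / 365.25` (optionally weighted); the
#' rate is `events / person-years * 100`.
#'
#' @param followups Follow-up table from [itt_followup()]/[pp_followup()],
#'   or any table with `time_days` and `event`.
#' @param weights Optional per-record weights (default 1).
#' @return A list with `events`, `person_years`, `rate_per_100py`.
#' @export
person_time_and_events <- function(followups, weights = NULL) {
  if (!nrow(followups)) stop("no follow-up records")
  w <- weights %||% rep(1, nrow(followups))
  py <- sum(w * followups$time_days) / 365.25
  if (py <= 0) stop("zero person-time")
  ev <- sum(w * followups$event)
  list(events = ev, person_years = py, rate_per_100py = 100 * ev / py)
}
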
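# Weighted Cox proportional hazards (exposure as the sole covariate;
# confounding adjustment is carried entirely by the SMRW weights), weighted
# Kaplan-Meier curves, Rubin pooling across imputations, subgroup analyses
# and the forest-style results table.

#' Weighted Cox model of exposure on time to first event
#'
#' Maximizes the weighted partial likelihood with the exposure indicator as
#' the only covariate. The robust (sandwich) variance is reported alongside
#' the model-based variance and is used for confidence intervals, since
#' weighting invalidates the naive information-based variance. Ties use the
#' Breslow approximation by default. Zero-length follow-up (event on the
#' index day) is shifted to half a day so the risk set is well defined.
#' With all events in one group (monotone likelihood) the fit is
#' ridge-stabilized and a warning is issued.
#'
#' @param followups Follow-up table with `group`, `time_days`, `event`.
#' @param weights Optional positive weights (default 1).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level Confidence level.
#' @return A `cox_fit` list: `log_hr`, `var_model`, `var_robust`, `hr`,
#'   `ci`, `ties`, `n_events`, `n`.
#' @export
weighted_cox <- function(followups, weights = NULL,
                         ties = c("breslow", "efron"), conf_level = 0.95) {
  ties <- match.arg(ties)
  w <- weights %||% rep(1, nrow(followups))
  if (any(w <= 0)) stop("weights must be positive")
  d <- data.frame(
    time = pmax(followups$time_days, 0.5),
    event = as.integer(followups$event),
    exposed = as.integer(followups$group == "exposed"),
    w = w)
  if (sum(d$event) == 0) stop("no events: hazard ratio inestimable")
  ev_by_group <- tapply(d$event, d$exposed, sum)
  monotone <- length(ev_by_group) < 2 || any(ev_by_group == 0)
  if (monotone) {
    warning("all events in one group; reporting ridge-stabilized estimate",
            call. = FALSE)
    fit <- survival::coxph(
      survival::Surv(time, event) ~ survival::ridge(exposed, theta = 1),
      data = d, weights = w, ties = ties, robust = TRUE)
  } else {
    fit <- survival::coxph(survival::Surv(time, event) ~ exposed,
                           data = d, weights = w, ties = ties,
                           robust = TRUE)
  }
  b <- unname(coef(fit)[1])
  vr <- unname(fit$var[1, 1])
  vm <- unname((fit$naive.var %||% fit$var)[1, 1])
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    log_hr = b, var_model = vm, var_robust = vr,
    hr = exp(b), ci = exp(c(b - z * sqrt(vr), b + z * sqrt(vr))),
    ties = ties, n_events = sum(d$event), n = nrow(d)),
    class = "cox_fit")
}

#' Weighted Kaplan-Meier survival curves by group
#'
#' Weighted product-limit estimator per exposure group.
#'
#' @inheritParams weighted_cox
#' @return A `data.table` with `group`, `time` (days), `survival`.
#' @export
weighted_km <- function(followups, weights = NULL) {
  if (!nrow(followups)) stop("no follow-up records")
  w <- weights %||% rep(1, nrow(followups))
  d <- data.frame(time = pmax(followups$time_days, 0.5),
                  event = as.integer(followups$event),
                  group = followups$group, w = w)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d,
                           weights = w)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  data.table::data.table(group = sub("^group=", "", strata),
                         time = fit$time, survival = fit$surv)
}

# largest vertical gap between per-imputation KM curves of the same group,
# used as the cross-imputation consistency diagnostic
km_max_discrepancy <- function(km_list) {
  if (length(km_list) < 2) return(0)
  grid <- sort(unique(unlist(lapply(km_list, function(k) k$time))))
  gap <- 0
  for (g in unique(km_list[[1]]$group)) {
    curves <- vapply(km_list, function(k) {
      kk <- k[k$group == g]
      stats::stepfun(kk$time, c(1, kk$survival), right = FALSE)(grid)
    }, numeric(length(grid)))
    gap <- max(gap, max(apply(curves, 1, max) - apply(curves, 1, min)))
  }
  gap
}

#' Pool Cox fits across imputed datasets by Rubin's rules
#'
#' Applies [rubin_pool()] to the log hazard ratios and robust variances of
#' per-imputation fits, then exponentiates onto the hazard-ratio scale.
#'
#' @param fits List of `cox_fit` objects on the same follow-up data,
#'   differing only by imputed covariates.
#' @param conf_level Confidence level.
#' @return A `pooled_hazard_result`: `log_hr`, `total_variance`, `hr`,
#'   `ci`, `df`, `m`.
#' @export
pool_across_imputations <- function(fits, conf_level = 0.95) {
  if (length(fits) < 1) stop("no fits to pool")
  ties <- unique(vapply(fits, function(f) f$ties, character(1)))
  if (length(ties) != 1)
    stop("inconsistent ties methods across fits: ",
         paste(ties, collapse = ", "))
  est <- vapply(fits, function(f) f$log_hr, numeric(1))
  va <- vapply(fits, function(f) f$var_robust, numeric(1))
  if (length(fits) == 1) {
    z <- qnorm(1 - (1 - conf_level) / 2)
    return(structure(list(
      log_hr = est, total_variance = va, hr = exp(est),
      ci = exp(c(est - z * sqrt(va), est + z * sqrt(va))),
      df = Inf, m = 1L), class = "pooled_hazard_result"))
  }
  pl <- rubin_pool(est, va, conf_level = conf_level)
  structure(list(log_hr = pl$estimate, total_variance = pl$total_variance,
                 hr = exp(pl$estimate), ci = exp(pl$ci), df = pl$df,
                 m = pl$m), class = "pooled_hazard_result")
}

#' @export
print.pooled_hazard_result <- function(x, ...) {
  cat(sprintf("HR %.3f (95%% CI %.3f-%.3f), m = %d\n",
              x$hr, x$ci[1], x$ci[2], x$m))
  invisible(x)
}

#' Subgroup analyses on the primary endpoint
#'
#' For each level of a baseline covariate, refits the weighted Cox model
#' within the subgroup per imputation (membership taken from each imputed
#' table, weights reused from the full-cohort propensity model) and pools
#' by Rubin's rules. Levels with no events are flagged inestimable rather
#' than dropped.
#'
#' @param followups Follow-up table for the chosen analysis.
#' @param stack An `imputed_stack` aligned row-for-row with `followups`.
#' @param weights_list Full-cohort SMRW weights per imputation.
#' @param covariate Covariate name in the imputed tables.
#' @param levels Optional level set; default all observed values.
#' @param ties Ties method for [weighted_cox()].
#' @return A `data.table`: one row per level with pooled HR, CI, events,
#'   and an `estimable` flag.
#' @export
subgroup_analysis <- function(followups, stack, weights_list, covariate,
                              levels = NULL, ties = "breslow") {
  vals <- stack$tables[[1]][[covariate]]
  if (is.null(vals)) stop("unknown covariate: ", covariate)
  lvls <- levels %||% sort(unique(stats::na.omit(
    unlist(lapply(stack$tables, function(t) as.character(t[[covariate]]))))))
  rows <- list()
  for (lv in lvls) {
    fits <- list()
    n_events <- 0L
    ok <- TRUE
    for (im in seq_len(stack$m)) {
      sel <- as.character(stack$tables[[im]][[covariate]]) == lv
      if (!any(sel)) { ok <- FALSE; break }
      sub_f <- followups[sel]
      n_events <- max(n_events, sum(sub_f$event))
      if (sum(sub_f$event) == 0 ||
          length(unique(sub_f$group[sub_f$event])) < 1 ||
          length(unique(sub_f$group)) < 2) { ok <- FALSE; break }
      fits[[im]] <- tryCatch(
        suppressWarnings(weighted_cox(sub_f, weights_list[[im]][sel],
                                      ties = ties)),
        error = function(e) NULL)
      if (is.null(fits[[im]])) { ok <- FALSE; break }
    }
    rows[[lv]] <- if (ok) {
      pl <- pool_across_imputations(fits)
      data.table::data.table(covariate = covariate, level = lv,
                             estimable = TRUE, events = n_events,
                             hr = pl$hr, ci_lower = pl$ci[1],
                             ci_upper = pl$ci[2])
    } else {
      data.table::data.table(covariate = covariate, level = lv,
                             estimable = FALSE, events = n_events,
                             hr = NA_real_, ci_lower = NA_real_,
                             ci_upper = NA_real_)
    }
  }
  data.table::rbindlist(rows)
}

#' Forest-style results table across analysis scenarios
#'
#' @param results Non-empty named list of scenario results, each a list
#'   with `label`, `events`, `person_years`, `rate_per_100py`, and a
#'   `pooled` `pooled_hazard_result`.
#' @return A `data.table`: one row per scenario with events, person-years,
#'   rate, HR and CI.
#' @export
forest_table <- function(results) {
  if (!length(results)) stop("no results to tabulate")
  data.table::rbindlist(lapply(results, function(r) {
    data.table::data.table(
      analysis = r$label, events = r$events,
      person_years = r$person_years, rate_per_100py = r$rate_per_100py,
      hr = r$pooled$hr, ci_lower = r$pooled$ci[1],
      ci_upper = r$pooled$ci[2])
  }))
}
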
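# Propensity scores, standardized mortality ratio weights (SMRW, the ATT
# estimand: exposed weight 1, control weight e/(1-e)), and covariate
# balance via standardized differences.

# main-effects design matrix for the propensity model; BMI category enters
# as integer scores (consistent with its ordinal imputation model)
propensity_design <- function(covariates) {
  cols <- covariate_columns(covariates)
  X <- data.frame(row.names = seq_len(nrow(covariates)))
  for (cn in cols) {
    x <- covariates[[cn]]
    if (cn == "bmi_category") X[[cn]] <- as.numeric(x)
    else X[[cn]] <- as.numeric(x)
  }
  X
}

#' Fit a main-effects propensity model for exposure
#'
#' Logistic regression of exposure-group membership on all covariates
#' (age, sex, BMI category as integer scores, smoking, and every binary
#' flag). Requires a complete (post-imputation) covariate table. On
#' separation or non-convergence the model is refit with a small ridge
#' penalty and a warning is issued. Zero-variance covariates are dropped.
#'
#' @param covariates Completed covariate table with a `group` column.
#' @return Numeric vector of propensity scores strictly inside (0, 1).
#' @export
fit_propensity <- function(covariates) {
  y <- as.integer(covariates$group == "exposed")
  X <- propensity_design(covariates)
  keep <- vapply(X, function(x) var(x) > 0, logical(1))
  X <- X[keep]
  if (anyNA(X)) stop("propensity model requires complete covariates")
  if (!ncol(X)) return(rep(mean(y), length(y)))
  df <- data.frame(.y = y, X)
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  eps <- 1e-8
  p <- fit$fitted.values
  if (!fit$converged || any(is.na(coef(fit))) ||
      any(p < eps | p > 1 - eps)) {
    warning("propensity model separation; refitting with ridge penalty",
            call. = FALSE)
    xm <- as.matrix(X)
    if (ncol(xm) == 1) xm <- cbind(xm, xm)  # glmnet needs >= 2 columns
    rf <- glmnet::glmnet(xm, y, family = "binomial",
                         alpha = 0, lambda = 1e-4)
    p <- as.vector(predict(rf, xm, type = "response"))
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Standardized mortality ratio weights from propensity scores
#'
#' Exposed members receive weight 1; controls receive the propensity odds
#' `e / (1 - e)`, reweighting the control group to the exposed covariate
#' population (the ATT estimand). Optional percentile truncation caps
#' extreme control weights.
#'
#' @param scores Propensity scores in (0, 1).
#' @param group Character vector, `"exposed"`/`"control"`.
#' @param truncate_at Optional upper percentile (e.g. 0.99) at which
#'   control weights are capped; default no truncation.
#' @return Positive numeric weights.
#' @export
compute_smrw <- function(scores, group, truncate_at = NULL) {
  if (any(scores <= 0 | scores >= 1))
    stop("propensity scores must lie strictly inside (0, 1)")
  w <- ifelse(group == "exposed", 1, scores / (1 - scores))
  if (!is.null(truncate_at)) {
    cap <- quantile(w[group == "control"], truncate_at)
    w[group == "control"] <- pmin(w[group == "control"], cap)
  }
  w
}

#' Standardized difference between exposed and control distributions
#'
#' Binary covariates: `(p1 - p0) / sqrt((p1(1-p1) + p0(1-p0)) / 2)`;
#' continuous: `(m1 - m0) / sqrt((s1^2 + s0^2) / 2)`, with weighted
#' means/proportions/variances when weights are supplied. The sign
#' convention is control minus exposed; balance work reads `|StdDiff|`.
#'
#' @param values Numeric vector (0/1 values are treated as binary).
#' @param group `"exposed"`/`"control"` labels.
#' @param weights Optional weights.
#' @return A single standardized difference.
#' @export
standardized_difference <- function(values, group, weights = NULL) {
  w <- weights %||% rep(1, length(values))
  g1 <- group == "control"; g0 <- group == "exposed"
  if (!any(g1) || !any(g0)) stop("need two non-empty groups")
  x <- as.numeric(values)
  binary <- all(x %in% c(0, 1))
  m1 <- wtd_mean(x[g1], w[g1]); m0 <- wtd_mean(x[g0], w[g0])
  if (binary) {
    v1 <- m1 * (1 - m1); v0 <- m0 * (1 - m0)
  } else {
    v1 <- wtd_var(x[g1], w[g1]); v0 <- wtd_var(x[g0], w[g0])
  }
  pooled <- (v1 + v0) / 2
  if (pooled == 0) {
    if (isTRUE(all.equal(m1, m0))) return(0)
    stop("degenerate covariate: zero pooled variance with unequal means")
  }
  (m1 - m0) / sqrt(pooled)
}

# expand a covariate table into balance rows: age and binaries as-is, BMI
# category as one indicator per level
balance_variables <- function(covariates) {
  cols <- covariate_columns(covariates)
  out <- list()
  for (cn in setdiff(cols, "bmi_category"))
    out[[cn]] <- as.numeric(covariates[[cn]])
  if ("bmi_category" %in% cols) {
    bc <- covariates$bmi_category
    for (lv in levels(bc))
      out[[paste0("bmi_", lv)]] <- as.numeric(bc == lv)
  }
  out
}

#' Covariate balance before weighting and across imputations after SMRW
#'
#' For each covariate: the unweighted standardized difference on the raw
#' (pre-imputation) data, computed on complete cases for the measured
#' covariates, plus the minimum and maximum SMRW-weighted standardized
#' difference across the imputed datasets.
#'
#' @param covariates Raw covariate table (may contain missing BMI/smoking).
#' @param stack An `imputed_stack` from [fcs_impute()].
#' @param weights_list List of SMRW weight vectors, one per imputation.
#' @return A `data.table` with `covariate`, `unweighted`, `weighted_min`,
#'   `weighted_max`.
#' @export
balance_table <- function(covariates, stack, weights_list) {
  if (length(weights_list) != stack$m)
    stop("need one weight vector per imputation")
  group <- covariates$group
  raw_vars <- balance_variables(covariates)
  rows <- list()
  for (vn in names(raw_vars)) {
    x <- raw_vars[[vn]]
    ok <- !is.na(x)
    unw <- standardized_difference(x[ok], group[ok])
    wts <- vapply(seq_len(stack$m), function(im) {
      v <- balance_variables(stack$tables[[im]])[[vn]]
      standardized_difference(v, group, weights_list[[im]])
    }, numeric(1))
    rows[[vn]] <- data.table::data.table(
      covariate = vn, unweighted = unw,
      weighted_min = min(wts), weighted_max = max(wts))
  }
  data.table::rbindlist(rows)
}
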
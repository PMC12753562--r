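# Fully conditional specification (chained equations) imputation of
# missing BMI category (proportional-odds model) and smoking (logistic
# model), plus Rubin's rules for pooling downstream estimates.

#' Imputation model specification
#'
#' @param m Number of imputations (>= 2).
#' @param n_cycles FCS sweeps per imputation.
#' @param seed Integer seed.
#' @return An `imputation_spec` list.
#' @export
imputation_spec <- function(m = 20L, n_cycles = 10L, seed = 1L) {
  if (m < 2) stop("m must be >= 2")
  structure(list(m = as.integer(m), n_cycles = as.integer(n_cycles),
                 seed = as.integer(seed)), class = "imputation_spec")
}

# multivariate-normal draw around a fitted model's coefficients
# glmnet requires at least two columns; a duplicated column under ridge
# shrinkage is equivalent to splitting the coefficient
ridge_matrix <- function(X) {
  xm <- as.matrix(X)
  if (ncol(xm) == 1) xm <- cbind(xm, xm)
  xm
}

draw_mvn <- function(mean, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(mean)
  as.vector(mean + drop(crossprod(ch, rnorm(length(mean)))))
}

# keep only predictors that vary within the rows the model is fit on
drop_constant <- function(X, rows = NULL) {
  sub <- if (is.null(rows)) X else X[rows, , drop = FALSE]
  keep <- vapply(sub, function(x) var(as.numeric(x)) > 0, logical(1))
  X[keep]
}

impute_binary <- function(y, X, miss) {
  obs <- !miss
  py <- y[obs]
  if (length(unique(py)) < 2) {
    # degenerate: draw from the (constant) observed margin
    return(rep(py[1], sum(miss)))
  }
  X <- drop_constant(X, obs)
  if (!ncol(X)) {
    # intercept-only model: fitted probability is the observed proportion
    return(rbinom(sum(miss), 1, mean(py)))
  }
  df <- data.frame(.y = py, X[obs, , drop = FALSE])
  fit <- tryCatch(
    suppressWarnings(glm(.y ~ ., data = df, family = binomial())),
    error = function(e) NULL)
  sep <- !is.null(fit) &&
    (!fit$converged || any(!is.finite(coef(fit))) || any(is.na(coef(fit))))
  if (is.null(fit) || sep) {
    warning("binary imputation model unstable; using ridge fallback",
            call. = FALSE)
    xm <- ridge_matrix(X)
    rf <- glmnet::glmnet(xm[obs, , drop = FALSE], py, family = "binomial",
                         alpha = 0, lambda = 1e-3)
    p <- as.vector(predict(rf, xm[miss, , drop = FALSE], type = "response"))
    return(rbinom(sum(miss), 1, p))
  }
  beta <- draw_mvn(coef(fit), vcov(fit))
  mm <- cbind(1, as.matrix(X[miss, , drop = FALSE]))
  p <- plogis(drop(mm %*% beta))
  rbinom(sum(miss), 1, p)
}

impute_ordinal <- function(y, X, miss) {
  # y: ordered factor; returns imputed levels (character) for missing rows
  obs <- !miss
  oy <- droplevels(y[obs])
  if (nlevels(oy) < 2)
    return(sample(as.character(oy), sum(miss), replace = TRUE))
  X <- drop_constant(X, obs)
  if (!ncol(X))
    return(sample(as.character(oy), sum(miss), replace = TRUE))
  df <- data.frame(.y = oy, X[obs, , drop = FALSE])
  fit <- tryCatch(
    suppressWarnings(MASS::polr(.y ~ ., data = df, Hess = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("ordinal imputation model unstable; using ridge fallback",
            call. = FALSE)
    xm <- ridge_matrix(X)
    rf <- glmnet::glmnet(xm[obs, , drop = FALSE], oy, family = "multinomial",
                         alpha = 0, lambda = 1e-3)
    p <- drop(predict(rf, xm[miss, , drop = FALSE], type = "response"))
    p <- matrix(p, nrow = sum(miss))
    lv <- levels(oy)
    return(lv[apply(p, 1, function(pr) sample.int(length(lv), 1, prob = pr))])
  }
  # collinear predictors may still be dropped by the fit; align by name
  X <- X[intersect(names(coef(fit)), colnames(X))]
  if (!ncol(X))
    return(sample(as.character(oy), sum(miss), replace = TRUE))
  theta_hat <- c(coef(fit)[colnames(X)], fit$zeta)
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  theta <- theta_hat
  if (!is.null(V)) {
    for (try in 1:5) {
      cand <- draw_mvn(theta_hat, V)
      z <- cand[seq_along(fit$zeta) + length(coef(fit))]
      if (!is.unsorted(z)) { theta <- cand; break }
    }
  }
  k <- length(coef(fit))
  beta <- theta[seq_len(k)]
  zeta <- theta[-seq_len(k)]
  eta <- drop(as.matrix(X[miss, , drop = FALSE]) %*% beta)
  cum <- plogis(outer(zeta, eta, "-"))     # P(Y <= j | x), rows = cutpoints
  pr <- rbind(cum, 1)
  pr <- pr - rbind(0, cum)
  lv <- levels(oy)
  lv[apply(pr, 2, function(p) sample.int(length(lv), 1,
                                         prob = pmax(p, 0)))]
}

#' Impute missing BMI category and smoking by chained equations
#'
#' Missingness is restricted to `bmi_category` and `smoking`. Each
#' imputation initializes missing cells by draws from the observed margins
#' and then cycles variable-by-variable: smoking by Bayesian logistic
#' regression (posterior draw of the coefficients, then a Bernoulli draw),
#' BMI category by a proportional-odds model (posterior draw, then a
#' categorical draw). Predictors are all other covariates, the event
#' indicator, and log follow-up time; zero-variance predictors are dropped
#' and recorded.
#'
#' @param covariates Covariate table from [extract_covariates()].
#' @param followups Follow-up table aligned row-for-row with `covariates`
#'   (same members, same order), e.g. from [itt_followup()].
#' @param spec An [imputation_spec()].
#' @return An `imputed_stack`: list with `tables` (m completed covariate
#'   tables), `dropped_predictors`, `m`, `seeds`.
#' @export
fcs_impute <- function(covariates, followups, spec = imputation_spec()) {
  covariates <- data.table::as.data.table(covariates)
  if (nrow(covariates) != nrow(followups))
    stop("covariates and followups must align row-for-row")
  imp_vars <- c("smoking", "bmi_category")
  other <- setdiff(covariate_columns(covariates), imp_vars)
  if (any(vapply(other, function(cn) anyNA(covariates[[cn]]), logical(1))))
    stop("missingness is restricted to BMI category and smoking")

  pred <- as.data.frame(covariates[, ..other])
  pred$.event <- as.numeric(followups$event)
  pred$.log_time <- log(pmax(followups$time_days, 1))
  zero_var <- names(pred)[vapply(pred, function(x) var(as.numeric(x)) == 0,
                                 logical(1))]
  if (length(zero_var)) pred <- pred[setdiff(names(pred), zero_var)]

  smoking0 <- covariates$smoking
  bmi0 <- covariates$bmi_category
  miss_smk <- is.na(smoking0)
  miss_bmi <- is.na(bmi0)
  seeds <- derive_seed(spec$seed, "impute") + seq_len(spec$m)

  tables <- vector("list", spec$m)
  for (im in seq_len(spec$m)) {
    tables[[im]] <- withr::with_seed(seeds[im], {
      smk <- smoking0
      bmi <- bmi0
      if (!any(miss_smk) && !any(miss_bmi)) {
        # nothing to do: completed table equals the input
      } else {
        if (any(miss_smk))
          smk[miss_smk] <- sample(smoking0[!miss_smk], sum(miss_smk), TRUE)
        if (any(miss_bmi))
          bmi[miss_bmi] <- sample(bmi0[!miss_bmi], sum(miss_bmi), TRUE)
        for (cy in seq_len(spec$n_cycles)) {
          if (any(miss_smk)) {
            Xs <- cbind(pred, .bmi = as.numeric(bmi))
            smk[miss_smk] <- impute_binary(smk, Xs, miss_smk)
          }
          if (any(miss_bmi)) {
            Xb <- cbind(pred, .smoking = as.numeric(smk))
            lev <- impute_ordinal(bmi, Xb, miss_bmi)
            bmi[miss_bmi] <- factor(lev, levels = levels(bmi0),
                                    ordered = TRUE)
          }
        }
      }
      done <- data.table::copy(covariates)
      done[, smoking := smk]
      done[, bmi_category := bmi]
      done[]
    })
  }
  structure(list(tables = tables, dropped_predictors = zero_var,
                 m = spec$m, seeds = seeds),
            class = "imputed_stack")
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean; total variance is the within-imputation
#' mean variance plus `(1 + 1/m)` times the between-imputation variance;
#' the confidence interval uses a t reference with Barnard-Rubin degrees of
#' freedom (reducing to the classical Rubin df when `df_complete = Inf`).
#'
#' @param estimates,variances Equal-length numeric vectors (length m >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @param df_complete Complete-data degrees of freedom (default `Inf`).
#' @return List with `estimate`, `within`, `between`, `total_variance`,
#'   `df`, `ci` (length-2), `m`.
#' @examples
#' rubin_pool(c(0, 1), c(1, 1))  # pooled 0.5, total variance 1.75
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95,
                       df_complete = Inf) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m)
    stop("need equal-length estimate/variance vectors with m >= 2")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (B > 0 && Tv > 0) {
    lambda <- (1 + 1 / m) * B / Tv
    nu_old <- (m - 1) / lambda^2
    if (is.finite(df_complete)) {
      nu_obs <- (df_complete + 1) / (df_complete + 3) * df_complete *
        (1 - lambda)
      nu <- 1 / (1 / nu_old + 1 / nu_obs)
    } else nu <- nu_old
  } else nu <- Inf
  half <- qt(1 - (1 - conf_level) / 2, df = nu) * sqrt(Tv)
  list(estimate = qbar, within = W, between = B, total_variance = Tv,
       df = nu, ci = c(qbar - half, qbar + half), m = m)
}
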
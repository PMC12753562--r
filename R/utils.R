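#' @import data.table
#' @importFrom stats glm binomial coef vcov rnorm runif rbinom rpois rexp
#'   plogis qlogis sd var quantile pnorm qnorm qt ks.test as.formula
#'   predict sd setNames
#' @importFrom utils head tail
NULL

# Claims records are day-granular; dates are handled internally as integer
# day offsets (the Date epoch, 1970-01-01) and exposed as Date in all tables.

as_day <- function(x) {
  if (inherits(x, "Date")) return(as.integer(x))
  if (is.character(x)) return(as.integer(as.Date(x)))
  as.integer(x)
}

day_to_date <- function(d) as.Date(d, origin = "1970-01-01")

#' Completed years between two dates
#'
#' Age in completed years (birthday counting), not `floor(days/365.25)`.
#'
#' @param birth,at `Date` vectors (or integer day offsets).
#' @return Integer vector of completed years.
#' @keywords internal
completed_years <- function(birth, at) {
  b <- as.POSIXlt(day_to_date(as_day(birth)))
  a <- as.POSIXlt(day_to_date(as_day(at)))
  age <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(age - before_birthday)
}

# Stage seeds are derived from one master seed by fixed small offsets so a
# whole run is reproducible from a single integer (kept below 2^31).
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, cohort = 23L, extract = 37L, impute = 41L,
               weight = 53L, analyze = 67L, report = 79L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 101 + offsets[[stage]]) %% .Machine$integer.max)
}

# Weighted mean / variance (reliability weights) used by balance diagnostics.
wtd_mean <- function(x, w) sum(w * x) / sum(w)

wtd_var <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  denom <- sw - sum(w^2) / sw
  if (denom <= 0) return(NA_real_)
  sum(w * (x - m)^2) / denom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Match codes against a character vector of prefixes ("I26" matches "I26x").
code_matches <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}
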
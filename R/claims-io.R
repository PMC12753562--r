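# Five delimited text files (CSV, UTF-8, header row, ISO-8601 dates):
# patients.csv, diagnoses.csv, prescriptions.csv, hospitalizations.csv,
# measurements.csv. The truth table, when present, is written alongside as
# truth.csv so a simulated run can be archived losslessly.

claims_schema <- list(
  patients = list(
    cols = c("patient_id", "sex", "birth_date", "observable_start",
             "observable_end"),
    dates = c("birth_date", "observable_start", "observable_end")),
  diagnoses = list(
    cols = c("patient_id", "date", "code", "facility_id", "setting",
             "hospitalization_id"),
    dates = "date"),
  prescriptions = list(
    cols = c("patient_id", "date", "code", "days_supply", "daily_dose",
             "facility_id", "setting", "hospitalization_id"),
    dates = "date"),
  hospitalizations = list(
    cols = c("hospitalization_id", "patient_id", "admission_date",
             "discharge_date"),
    dates = c("admission_date", "discharge_date")),
  measurements = list(
    cols = c("patient_id", "date", "kind", "value"),
    dates = "date"))

#' Write a claims dataset to a directory of CSV files
#'
#' @param dataset A `claims_dataset`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_claims <- function(dataset, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- character()
  for (nm in names(claims_schema)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    data.table::fwrite(dataset[[nm]], path, dateTimeAs = "ISO")
    paths <- c(paths, path)
  }
  if (!is.null(dataset$truth)) {
    path <- file.path(directory, "truth.csv")
    data.table::fwrite(dataset$truth, path, dateTimeAs = "ISO")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a claims dataset from a directory of CSV files
#'
#' Malformed tables (missing column, unparseable date) are reported with the
#' table name and the first offending row number.
#'
#' @param directory Directory containing the five claims CSV files.
#' @return A `claims_dataset`.
#' @export
read_claims <- function(directory) {
  ds <- list()
  for (nm in names(claims_schema)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing table file: ", path)
    hdr <- names(data.table::fread(path, nrows = 0))
    want_chr <- intersect(c("patient_id", "hospitalization_id", "code",
                            "facility_id", "setting", "sex", "kind"),
                          intersect(claims_schema[[nm]]$cols, hdr))
    tab <- data.table::fread(path, colClasses =
      if (length(want_chr)) list(character = want_chr) else NULL)
    sch <- claims_schema[[nm]]
    missing_cols <- setdiff(sch$cols, names(tab))
    if (length(missing_cols))
      stop("table '", nm, "': missing column(s) ",
           paste(missing_cols, collapse = ", "))
    for (dc in sch$dates) {
      if (!inherits(tab[[dc]], "Date")) {
        parsed <- as.Date(as.character(tab[[dc]]), format = "%Y-%m-%d")
        bad <- which(!is.na(tab[[dc]]) & tab[[dc]] != "" & is.na(parsed))
        if (length(bad))
          stop("table '", nm, "': unparseable date in column '", dc,
               "' at row ", bad[1])
        data.table::set(tab, j = dc, value = parsed)
      }
    }
    if ("hospitalization_id" %in% names(tab))
      tab[hospitalization_id == "", hospitalization_id := NA_character_]
    ds[[nm]] <- tab
  }
  tp <- file.path(directory, "truth.csv")
  if (file.exists(tp)) {
    tr <- data.table::fread(tp, colClasses = list(character = "patient_id"))
    for (dc in intersect(c("first_dx", "init_date", "exposure_end",
                           "first_event"), names(tr)))
      data.table::set(tr, j = dc, value = as.Date(as.character(tr[[dc]])))
    ds$truth <- tr
  }
  structure(ds, class = "claims_dataset")
}
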
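#' Fold error between observed and predicted values
#'
#' `fold_error = observed/predicted` when the observed value is larger,
#' `predicted/observed` otherwise, i.e.
#' `max(observed, predicted) / min(observed, predicted)`; always >= 1,
#' symmetric in its arguments and invariant to a common scale factor. A
#' prediction is conventionally considered successful when the fold error
#' is below 2.
#'
#' @param observed,predicted positive values (vectorised).
#' @return fold error, dimensionless, >= 1.
#' @examples
#' fold_error(708.86, 580)     # 1.22
#' fold_error(1403.9, 1737.3)  # 1.24 (predicted exceeds observed)
#' @export
fold_error <- function(observed, predicted) {
  if (any(observed <= 0) || any(predicted <= 0)) {
    stop("observed and predicted must be positive", call. = FALSE)
  }
  pmax(observed, predicted) / pmin(observed, predicted)
}

#' Validate a table of observed/predicted pairs
#'
#' Applies [fold_error()] to every record, flags each against the 2-fold
#' acceptance criterion, and reports the arithmetic mean fold error across
#' all records (AUC and Cmax entries averaged jointly). Row order is
#' preserved; fold errors are kept at full precision and only rounded when
#' printed.
#'
#' @param records a data.frame with columns `observed` and `predicted`
#'   (optionally `label` and `metric`), or a numeric vector of observed
#'   values if `predicted` is given separately.
#' @param predicted optional numeric vector of predicted values.
#' @param threshold acceptance threshold on the fold error (default 2).
#' @return an object of class `validation_report`: the records data.frame
#'   with `fold_error` and `passed` columns, and attributes
#'   `mean_fold_error`, `all_passed` and `threshold`.
#' @examples
#' validate_table(data.frame(observed = c(708.86, 897.06),
#'                           predicted = c(580, 772.99)))
#' @export
validate_table <- function(records, predicted = NULL, threshold = 2) {
  if (!is.null(predicted)) {
    records <- data.frame(observed = records, predicted = predicted)
  }
  stopifnot(is.data.frame(records),
            all(c("observed", "predicted") %in% names(records)))
  if (nrow(records) == 0L) {
    stop("validation requires at least one observed/predicted pair",
         call. = FALSE)
  }
  fe <- fold_error(records$observed, records$predicted)
  records$fold_error <- fe
  records$passed <- fe < threshold
  structure(records,
            class = c("validation_report", "data.frame"),
            mean_fold_error = mean(fe),
            all_passed = all(records$passed),
            threshold = threshold)
}

#' @export
print.validation_report <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df$fold_error <- round(df$fold_error, digits)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("mean fold error: %.2f; %s (threshold %g)\n",
              attr(x, "mean_fold_error"),
              if (attr(x, "all_passed")) "all records passed"
              else "SOME RECORDS FAILED",
              attr(x, "threshold")))
  invisible(x)
}

#' Mean fold error of a validation report
#' @param report a [validate_table()] report.
#' @return the arithmetic mean fold error (full precision).
#' @export
mean_fold_error <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  attr(report, "mean_fold_error")
}

#' Read observed/predicted validation records from CSV
#'
#' Expects columns `label`, `metric` (`AUC` or `CMAX`), `observed`,
#' `predicted`. The package ships the published adult and pediatric
#' observed/predicted tables:
#' `daptosim_extdata("adult_pk_validation.csv")` and
#' `daptosim_extdata("child_pk_validation.csv")`.
#'
#' @param path CSV file path.
#' @return a data.frame suitable for [validate_table()].
#' @export
read_validation_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observed", "predicted")
  if (!all(need %in% names(df))) {
    stop("validation CSV must contain columns 'observed' and 'predicted'",
         call. = FALSE)
  }
  df
}

#' Write a validation report
#' @param report a [validate_table()] report.
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(records = as.data.frame(report),
           mean_fold_error = mean_fold_error(report),
           all_passed = attr(report, "all_passed"),
           threshold = attr(report, "threshold")),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}

#' Path to a packaged data file
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a vector of file names).
#' @export
daptosim_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "daptosim")))
  }
  path <- system.file("extdata", file, package = "daptosim")
  if (path == "") stop("no packaged file called ", file, call. = FALSE)
  path
}
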
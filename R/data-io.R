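#' Read long-format measurement data from CSV
#'
#' Expects a comma-separated file with header columns `id`, `time`,
#' `value` ('.' decimal, no index column).  Rows are sorted by subject and
#' time on reading; duplicated (id, time) pairs raise an error.
#'
#' @param path path to the CSV file.
#' @return A [longitudinal_data()] object.
#' @export
read_long_csv <- function(path) {
  df <- read_checked_csv(path, c("id", "time", "value"), c("time", "value"))
  validate_longitudinal(df, where = path)
}

#' Read per-subject survival data from CSV
#'
#' Columns `id`, `time`, `status` (status 0/1).
#'
#' @param path path to the CSV file.
#' @return A [survival_data()] object.
#' @export
read_surv_csv <- function(path) {
  df <- read_checked_csv(path, c("id", "time", "status"), c("time", "status"))
  validate_survival(df, where = path)
}

#' Read a baseline covariate table from CSV
#'
#' An `id` column plus numeric covariate columns.
#'
#' @param path path to the CSV file.
#' @return A [covariate_table()] object.
#' @export
read_covar_csv <- function(path) {
  df <- read_checked_csv(path, "id", character())
  covariate_table(df)
}

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop(path, ": no data rows", call. = FALSE)
  if (identical(numeric_cols, character()))
    numeric_cols <- setdiff(names(df), "id")
  for (v in numeric_cols) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    bad <- which(is.na(x) & !is.na(df[[v]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric '%s' in row %d: '%s'",
                   path, v, bad[1L], df[[v]][bad[1L]]), call. = FALSE)
    df[[v]] <- x
  }
  df
}

# Full-precision numeric formatting so write/read round-trips exactly.
fmt_full <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

write_plain_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_full), stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write long-format measurement data to CSV
#'
#' Numeric columns are written with enough digits that
#' `read_long_csv(write_long_csv(x))` reproduces `x` exactly.
#'
#' @param data a [longitudinal_data()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  write_plain_csv(as.data.frame(data)[c("id", "time", "value")], path)
}

#' Write survival data to CSV
#' @param data a [survival_data()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surv_csv <- function(data, path) {
  write_plain_csv(as.data.frame(data)[c("id", "time", "status")], path)
}

#' Write a covariate table to CSV
#' @param data a [covariate_table()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covar_csv <- function(data, path) {
  write_plain_csv(as.data.frame(data), path)
}
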
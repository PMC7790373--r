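#' Read and validate a daily environmental health series
#'
#' Reads a CSV of daily observations -- calendar date, death count, mean
#' temperature, and pollutant concentrations -- and validates it into a
#' `daily_series` data frame.  Rows with a missing required field are
#' dropped (daily pollutant records are occasionally missing in monitoring
#' data and the customary remedy at low missing rates is omission) and the
#' number of dropped rows is reported; set `on_missing = "error"` to refuse
#' incomplete files instead.
#'
#' Required columns (after `column_map` renaming): `date` (ISO-8601),
#' `death` (non-negative integer count), `temperature` (degrees C), `o3`
#' (ppb daily mean), `pm25` (ug/m3 daily mean).  Optional: `co`, `pm10`,
#' `so2`.  Dates must be strictly increasing; duplicated or out-of-order
#' dates are an error naming the first offending row.
#'
#' @param path path to a CSV file with a header row.
#' @param column_map optional named character vector mapping canonical names
#'   to file column names, e.g. `c(death = "Death", temperature = "Temp")`.
#' @param on_missing `"drop"` (default) or `"error"`.
#' @return A `daily_series` data frame with attribute `n_dropped`, the
#'   number of incomplete rows omitted.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(date = as.Date("2012-01-01") + 0:4, death = 60:64,
#'                      temperature = 20, o3 = 28, pm25 = 20),
#'           f, row.names = FALSE)
#' s <- read_daily_csv(f)
#' nrow(s); attr(s, "n_dropped")
#' @export
read_daily_csv <- function(path, column_map = NULL,
                           on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      from <- column_map[[canonical]]
      if (!from %in% names(raw)) {
        stopf("mapped column '%s' (for '%s') not present in %s",
              from, canonical, path)
      }
      names(raw)[names(raw) == from] <- canonical
    }
  }
  as_daily_series(raw, on_missing = on_missing)
}

#' Validate a data frame as a daily series
#'
#' Core validator behind [read_daily_csv()]; useful when the series was
#' built in memory (e.g. by [simulate_mortality()] + editing).
#'
#' @param x data frame with at least `date`, `death`, `temperature`, `o3`,
#'   `pm25`.
#' @param on_missing `"drop"` incomplete rows (default) or `"error"`.
#' @return a `daily_series` data frame (attribute `n_dropped`).
#' @export
as_daily_series <- function(x, on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  required <- c("date", "death", "temperature", "o3", "pm25")
  optional <- c("co", "pm10", "so2")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stopf("unparseable date at row %d", which(is.na(x$date))[1])

  keep <- c(required, intersect(optional, names(x)))
  x <- x[keep]
  incomplete <- !stats::complete.cases(x[required])
  n_dropped <- sum(incomplete)
  if (n_dropped > 0) {
    if (on_missing == "error") {
      stopf("%d row(s) have missing required fields (first at row %d)",
            n_dropped, which(incomplete)[1])
    }
    message(sprintf("daily_series: omitted %d incomplete row(s)", n_dropped))
    x <- x[!incomplete, , drop = FALSE]
  }
  if (nrow(x) == 0) stopf("no complete rows")

  d <- diff(as.integer(x$date))
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1
    stopf("dates must be strictly increasing; row %d (%s) %s row %d",
          bad, format(x$date[bad]),
          if (d[bad - 1] == 0) "duplicates" else "precedes", bad - 1)
  }
  if (!all(x$death >= 0) || any(x$death != round(x$death))) {
    stopf("death must be a non-negative integer count")
  }
  if (any(!is.finite(x$temperature))) stopf("temperature must be finite")
  for (p in intersect(c("o3", "pm25", optional), names(x))) {
    if (any(x[[p]] < 0, na.rm = TRUE)) stopf("%s must be non-negative", p)
  }
  rownames(x) <- NULL
  structure(x, n_dropped = n_dropped,
            class = c("daily_series", "data.frame"))
}

#' Write a grid or permutation-ratio report to CSV
#'
#' One row per hyperparameter cell; numeric columns are written at full
#' precision so that a written report re-read with [read_report()] equals
#' the original.
#'
#' @param results a grid data frame (e.g. from [run_grid()], [pr_table()],
#'   or [ref_grid()]); must be non-empty.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.null(results) || nrow(as.data.frame(results)) == 0) {
    stopf("empty results; nothing to write")
  }
  df <- as.data.frame(results)
  status <- try(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
                silent = TRUE)
  if (inherits(status, "try-error")) stopf("cannot write report to %s", path)
  invisible(path)
}

#' Read a grid report written by [write_report()]
#'
#' @param path CSV path.
#' @return a `lagcv_grid` data frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  as_grid(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run configuration for grid experiments
#'
#' Bundles the knobs shared by the CV schemes, the network trainer and the
#' permutation machinery, with the defaults used throughout: a 70/30
#' chronological split, five folds, a 30-day maximum lag, and a 50,000
#' iteration training budget.
#'
#' @param train_fraction proportion of days in the training region.
#' @param n_folds folds per CV scheme.
#' @param max_lag maximum exposure lag in days.
#' @param max_iterations full-batch training iterations per network fit.
#' @param seed base integer seed; all derived seeds are deterministic in it.
#' @param hidden_layout integer vector of hidden-layer widths (1-3 layers).
#' @param scheme `"five_fold"`, `"lobo"`, or `"tb"`.
#' @param n_permutations outcome permutations per permuted CV error.
#' @return a validated `run_config` list.
#' @export
run_config <- function(train_fraction = 0.70, n_folds = 5L, max_lag = 30L,
                       max_iterations = 50000L, seed = 1L,
                       hidden_layout = c(12L, 12L),
                       scheme = c("five_fold", "lobo", "tb"),
                       n_permutations = 1L) {
  scheme <- match.arg(scheme)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("train_fraction must be in (0, 1)")
  }
  if (n_folds < 2) stopf("n_folds must be >= 2")
  if (max_lag < 0) stopf("max_lag must be >= 0")
  if (max_iterations < 1) stopf("max_iterations must be >= 1")
  if (length(hidden_layout) < 1 || length(hidden_layout) > 3 ||
      any(hidden_layout < 1)) {
    stopf("hidden_layout must be 1-3 positive widths")
  }
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  structure(list(train_fraction = train_fraction, n_folds = as.integer(n_folds),
                 max_lag = as.integer(max_lag),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 hidden_layout = as.integer(hidden_layout), scheme = scheme,
                 n_permutations = as.integer(n_permutations)),
            class = "run_config")
}
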
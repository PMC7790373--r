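#' Build the network input matrix from a daily series
#'
#' Expands a [daily series][read_daily_csv] into the predictor matrix whose
#' columns are the input neurons: calendar indicators (one per year present,
#' 12 months, weekday/weekend/holiday), distributed temperature lags 0..`max_lag`,
#' lagged mortality 1..`max_lag` (the same-day outcome never enters the
#' predictors), and same-day ozone and PM2.5.  For a five-year series with
#' `max_lag = 30` the default set is 5 + 12 + 3 + 31 + 30 + 2 = 83 columns.
#'
#' The first `max_lag` days lack a full lag history and are dropped rather
#' than zero-padded: fabricated exposure would bias the lag structure the
#' models are meant to learn.  The `"paper54"` profile is the leaner
#' 54-column variant sometimes quoted for this design: 24 independent
#' variables (5 year + 12 month + 3 day-type indicators and the four
#' pollutants O3, PM2.5, CO, PM10 when present) plus temperature lags
#' 1..`max_lag` -- no mortality lags and no same-day temperature.
#'
#' @param series a `daily_series`.
#' @param max_lag maximum lag in days (default 30); must be < series length.
#' @param include character vector of feature groups to build; any subset of
#'   `c("year", "month", "daytype", "temperature", "mortality", "pollutants")`.
#' @param holidays optional `Date` vector of holidays (the weekday/weekend
#'   flags are derived from the date; holidays need a user-supplied list).
#' @param profile `"full"` (default, all requested groups) or `"paper54"`.
#' @return a `feature_matrix`: list with `X` (numeric matrix, named
#'   columns), `y` (death count per row), `row_dates`, `feature_names`.
#' @export
build_feature_matrix <- function(series, max_lag = 30L,
                                 include = c("year", "month", "daytype",
                                             "temperature", "mortality",
                                             "pollutants"),
                                 holidays = NULL,
                                 profile = c("full", "paper54")) {
  profile <- match.arg(profile)
  known <- c("year", "month", "daytype", "temperature", "mortality",
             "pollutants")
  unknown <- setdiff(include, known)
  if (length(unknown) > 0) {
    stopf("unknown feature group(s): %s", paste(unknown, collapse = ", "))
  }
  n <- nrow(series)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) stopf("max_lag (%d) must be < series length (%d)", max_lag, n)
  if (profile == "paper54") include <- setdiff(include, "mortality")

  rows <- (max_lag + 1L):n           # days with a complete lag history
  dates <- series$date[rows]
  blocks <- list()

  one_hot <- function(values, levels, prefix) {
    m <- vapply(levels, function(l) as.numeric(values == l),
                numeric(length(values)))
    colnames(m) <- paste0(prefix, levels)
    m
  }
  if ("year" %in% include) {
    yr <- format(dates, "%Y")
    blocks$year <- one_hot(yr, sort(unique(yr)), "year_")
  }
  if ("month" %in% include) {
    blocks$month <- one_hot(format(dates, "%m"), sprintf("%02d", 1:12),
                            "month_")
  }
  if ("daytype" %in% include) {
    wd <- as.POSIXlt(dates)$wday      # 0 = Sunday
    holiday <- if (is.null(holidays)) rep(FALSE, length(dates)) else
      dates %in% as.Date(holidays)
    weekend <- (wd == 0 | wd == 6) & !holiday
    weekday <- !weekend & !holiday
    blocks$daytype <- cbind(weekday = as.numeric(weekday),
                            weekend = as.numeric(weekend),
                            holiday = as.numeric(holiday))
  }
  if ("temperature" %in% include) {
    lags <- if (profile == "paper54") seq_len(max_lag) else 0:max_lag
    m <- vapply(lags, function(k) series$temperature[rows - k],
                numeric(length(rows)))
    colnames(m) <- paste0("temp_lag", lags)
    blocks$temperature <- m
  }
  if ("mortality" %in% include && max_lag >= 1) {
    m <- vapply(seq_len(max_lag), function(k) as.numeric(series$death[rows - k]),
                numeric(length(rows)))
    colnames(m) <- paste0("death_lag", seq_len(max_lag))
    blocks$mortality <- m
  }
  if ("pollutants" %in% include) {
    m <- cbind(o3 = series$o3[rows], pm25 = series$pm25[rows])
    if (profile == "paper54") {
      for (p in intersect(c("co", "pm10"), names(series))) {
        m <- cbind(m, series[[p]][rows])
        colnames(m)[ncol(m)] <- p
      }
    }
    blocks$pollutants <- m
  }
  if (length(blocks) == 0) stopf("no feature groups selected")
  X <- do.call(cbind, unname(blocks))
  if (anyNA(X)) stopf("feature matrix contains missing values (incomplete series?)")
  structure(list(X = X, y = as.numeric(series$death[rows]), row_dates = dates,
                 feature_names = colnames(X)),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d rows x %d input neurons (%s .. %s)\n",
              nrow(x$X), ncol(x$X), format(min(x$row_dates)),
              format(max(x$row_dates))))
  invisible(x)
}

is_indicator <- function(col) all(col %in% c(0, 1))

#' Center and scale continuous feature columns
#'
#' Scaling statistics (mean, standard deviation) are computed ONLY on
#' `stats_from` rows -- in cross-validation those are the fold's training
#' rows, so no validation information leaks into the inputs.  Indicator
#' (0/1) columns pass through untouched, as does any continuous column with
#' zero spread in `stats_from` (with a warning).
#'
#' @param x a `feature_matrix` or plain numeric matrix.
#' @param stats_from row indices to compute statistics from (default: all).
#' @return the object with scaled `X` and a `scaling` record (data frame of
#'   per-column center/scale) attached; apply it elsewhere with
#'   [apply_scaling()].
#' @export
standardize <- function(x, stats_from = NULL) {
  X <- if (inherits(x, "feature_matrix")) x$X else as.matrix(x)
  if (is.null(stats_from)) stats_from <- seq_len(nrow(X))
  if (length(stats_from) == 0) stopf("stats_from must be non-empty")
  ref <- X[stats_from, , drop = FALSE]
  center <- numeric(ncol(X))
  scale_ <- rep(1, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (is_indicator(X[, j])) next
    s <- stats::sd(ref[, j])
    if (!is.finite(s) || s == 0) {
      warnf("column '%s' has zero spread in stats_from; left unscaled",
            colnames(X)[j])
      next
    }
    center[j] <- mean(ref[, j])
    scale_[j] <- s
  }
  scaling <- data.frame(column = colnames(X), center = center, scale = scale_,
                        stringsAsFactors = FALSE)
  Xs <- apply_scaling(scaling, X)
  if (inherits(x, "feature_matrix")) {
    x$X <- Xs
    x$scaling <- scaling
    x
  } else {
    attr(Xs, "scaling") <- scaling
    Xs
  }
}

#' Apply a stored scaling record to new rows
#'
#' @param scaling a scaling record from [standardize()].
#' @param X numeric matrix with the same columns the record was built from.
#' @return scaled matrix.
#' @export
apply_scaling <- function(scaling, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(scaling)) {
    stopf("X has %d columns but the scaling record covers %d",
          ncol(X), nrow(scaling))
  }
  sweep(sweep(X, 2, scaling$center, "-"), 2, scaling$scale, "/")
}
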
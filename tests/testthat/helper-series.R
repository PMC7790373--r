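# deterministic toy series builders shared across test files

# consecutive daily series with analytically known columns; spans
# 2012-01-01 onward so a 5-year series carries 5 year indicators
toy_series <- function(n = 120, start = "2012-01-01",
                       temperature = NULL, death = NULL) {
  dates <- as.Date(start) + seq_len(n) - 1L
  if (is.null(temperature)) {
    temperature <- 23 + 6 * cos(2 * pi * (seq_len(n) - 200) / 365.25) +
      sin(seq_len(n) / 3)
  }
  if (is.null(death)) death <- 55L + (seq_len(n) %% 11L)
  as_daily_series(data.frame(date = dates, death = death,
                             temperature = temperature,
                             o3 = 28 + (seq_len(n) %% 7),
                             pm25 = 20 + (seq_len(n) %% 5)))
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# tiny feature matrix + plan + spec for fast end-to-end runs
tiny_setup <- function(n = 160, max_lag = 5, hidden = c(4L, 4L),
                       iters = 150, seed = 3L) {
  fm <- build_feature_matrix(toy_series(n), max_lag = max_lag)
  split <- chronological_split(nrow(fm$X), 0.7)
  plan <- lobo_folds(split$train, 4)
  spec <- network_spec(ncol(fm$X), hidden, max_iterations = iters,
                       seed = seed)
  list(fm = fm, split = split, plan = plan, spec = spec)
}
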
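#' Configuration for the DLNM simulator
#'
#' Defaults emulate five years of Taipei-like daily data: ~60 all-cause
#' deaths/day, mean temperature ~23.6 degC with an annual cycle and
#' autocorrelated day-to-day noise, ozone ~28 ppb coupled positively and
#' PM2.5 ~20 ug/m3 coupled negatively to temperature anomalies.  Daily
#' death counts are Poisson with log-mean
#' `alpha + cross-basis(temperature, lag) %*% beta + b_o3*O3 + b_pm25*PM2.5
#' + seasonal-spline %*% theta`.
#'
#' The default lag-temperature coefficient vector `beta` encodes a U-shaped
#' cumulative temperature-mortality response: excess risk at both the cold
#' and hot ends of the temperature distribution, with the heat effect
#' concentrated at short lags and the cold effect spread over longer lags.
#' The default seasonal coefficients `theta` are the least-squares
#' projection of a winter-peaking annual cosine (amplitude `seasonal_amp`
#' on the log scale) onto the seasonal spline basis, so the generative
#' model is exactly the spline model that an analyst would fit.
#'
#' @param n_days series length (default 1818, ~5 years).
#' @param start_date first calendar day.
#' @param alpha log baseline daily deaths (default `log(60)`).
#' @param beta cross-basis coefficients (length `v_x * v_l` = 25), or
#'   `NULL` for the default U-shaped pattern built by [default_beta()].
#' @param beta_o3 log-rate per ppb ozone.
#' @param beta_pm25 log-rate per ug/m3 PM2.5.
#' @param seasonal_amp amplitude of the seasonal log-mortality cycle.
#' @param max_lag maximum temperature lag in days.
#' @param df_per_year seasonal spline degrees of freedom per year.
#' @param temp_mean,temp_amp,temp_phase annual temperature cycle: mean,
#'   amplitude (degC) and day-of-year of the peak.
#' @param temp_ar1,temp_noise_sd day-to-day anomaly autocorrelation and
#'   innovation standard deviation.
#' @param o3_base,o3_coupling,o3_noise_sd ozone level, coupling to the
#'   temperature anomaly, and noise.
#' @param pm25_base,pm25_coupling,pm25_noise_sd likewise for PM2.5.
#' @param log_mu_cap error guard: simulation aborts if `|log mu|` exceeds it.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_days = 1818L, start_date = as.Date("2012-01-01"),
                       alpha = log(60), beta = NULL,
                       beta_o3 = 0.0020, beta_pm25 = 0.0015,
                       seasonal_amp = 0.06, max_lag = 30L, df_per_year = 8L,
                       temp_mean = 23.6, temp_amp = 6.5, temp_phase = 205,
                       temp_ar1 = 0.8, temp_noise_sd = 1.6,
                       o3_base = 28, o3_coupling = 0.6, o3_noise_sd = 8,
                       pm25_base = 20.5, pm25_coupling = -0.9,
                       pm25_noise_sd = 8.5,
                       log_mu_cap = 8, seed = 1L) {
  max_lag <- as.integer(max_lag)
  n_days <- as.integer(n_days)
  if (n_days <= max_lag) stopf("n_days must exceed max_lag")
  if (is.null(beta)) beta <- default_beta()
  if (length(beta) != 25) stopf("beta must have length 25 (v_x * v_l = 5 * 5)")
  if (!is.finite(alpha) || exp(alpha) <= 0 || exp(alpha) > 1e4) {
    stopf("exp(alpha) outside a plausible daily count range")
  }
  structure(list(n_days = n_days, start_date = as.Date(start_date),
                 alpha = alpha, beta = beta, beta_o3 = beta_o3,
                 beta_pm25 = beta_pm25, seasonal_amp = seasonal_amp,
                 max_lag = max_lag, df_per_year = as.integer(df_per_year),
                 temp_mean = temp_mean, temp_amp = temp_amp,
                 temp_phase = temp_phase, temp_ar1 = temp_ar1,
                 temp_noise_sd = temp_noise_sd, o3_base = o3_base,
                 o3_coupling = o3_coupling, o3_noise_sd = o3_noise_sd,
                 pm25_base = pm25_base, pm25_coupling = pm25_coupling,
                 pm25_noise_sd = pm25_noise_sd, log_mu_cap = log_mu_cap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default U-shaped lag-temperature coefficient pattern
#'
#' Outer product of a temperature profile over the 5 temperature-basis
#' columns (elevated at both ends of the temperature range) and a lag
#' profile over the 5 lag-basis columns (front-loaded), flattened
#' column-major to match the cross-basis column order.
#'
#' @param scale overall effect magnitude on the log-mortality scale.
#' @return numeric vector of length 25.
#' @export
default_beta <- function(scale = 0.04) {
  temp_profile <- c(1.0, 0.25, -0.15, 0.35, 0.9)   # cold end .. hot end
  lag_profile <- c(0.9, 0.5, 0.25, 0.1, 0.05)
  as.vector(outer(temp_profile, lag_profile)) * scale
}

#' Simulate the environmental covariates
#'
#' Temperature is an annual sinusoid plus a first-order autoregressive
#' anomaly; ozone and PM2.5 are a base level plus a linear coupling to the
#' temperature anomaly from the annual mean plus independent noise,
#' truncated at zero.  Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return a data frame with `date`, `temperature`, `o3`, `pm25` (no
#'   deaths yet; see [simulate_mortality()]).
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_days
  dates <- config$start_date + seq_len(n) - 1L
  doy <- as.integer(format(dates, "%j"))
  cycle <- config$temp_amp * cos(2 * pi * (doy - config$temp_phase) / 365.25)
  with_seed(config$seed, {
    innov <- stats::rnorm(n, 0, config$temp_noise_sd)
    anomaly <- as.numeric(stats::filter(innov, config$temp_ar1,
                                        method = "recursive"))
    temperature <- config$temp_mean + cycle + anomaly
    dev <- temperature - config$temp_mean
    o3 <- pmax(0, config$o3_base + config$o3_coupling * dev +
                 stats::rnorm(n, 0, config$o3_noise_sd))
    pm25 <- pmax(0, config$pm25_base + config$pm25_coupling * dev +
                   stats::rnorm(n, 0, config$pm25_noise_sd))
    data.frame(date = dates, temperature = temperature, o3 = o3, pm25 = pm25)
  })
}

log_lag_knots <- function(max_lag, n_knots = 3) {
  exp(seq(log(1), log(max_lag), length.out = n_knots + 2))[2:(n_knots + 1)]
}

#' Cross-basis for a distributed-lag nonlinear temperature effect
#'
#' Tensor-product basis combining a quadratic B-spline in temperature
#' (internal knots at the 10th/75th/90th percentiles, no intercept; 5
#' columns) with a natural cubic spline in lag 0..`max_lag` (5 df: three
#' internal knots equally spaced on the log-lag scale, intercept included).
#' Row `t`, column `(i, j)` holds
#' `sum_k B_temp(x[t-k], i) * B_lag(k, j)`, so a single coefficient vector
#' of length 25 encodes the whole lag-temperature surface.  Rows whose lag
#' history is incomplete (the first `max_lag` days) are `NA` and flagged.
#'
#' @param x daily mean temperature series.
#' @param max_lag maximum lag in days (default 30).
#' @param temp_knot_probs percentile positions of the temperature knots.
#' @param lag_knots internal lag knots; default log-spaced via the rule
#'   above.
#' @return a `cross_basis`: the `n x 25` basis matrix with attributes
#'   `valid` (logical row flag), `temp_basis` (knots/boundary), `lag_basis`
#'   (the `(max_lag+1) x 5` lag basis), `max_lag`.
#' @export
cross_basis <- function(x, max_lag = 30L,
                        temp_knot_probs = c(0.10, 0.75, 0.90),
                        lag_knots = NULL) {
  max_lag <- as.integer(max_lag)
  n <- length(x)
  if (n <= max_lag) stopf("series length must exceed max_lag")
  knots <- stats::quantile(x, probs = temp_knot_probs, names = FALSE)
  if (length(unique(x)) <= length(knots) + 2) {
    stopf("too few distinct temperatures to place %d knots", length(knots))
  }
  bound <- range(x)
  Bt <- splines::bs(x, degree = 2, knots = knots, Boundary.knots = bound)
  v_x <- ncol(Bt)                                   # 2 + 3 knots = 5
  if (is.null(lag_knots)) lag_knots <- log_lag_knots(max_lag)
  Bl <- splines::ns(0:max_lag, knots = lag_knots,
                    Boundary.knots = c(0, max_lag), intercept = TRUE)
  v_l <- ncol(Bl)                                   # 1 + 3 knots + 1 = 5

  cb <- matrix(NA_real_, n, v_x * v_l)
  for (i in seq_len(v_x)) {
    for (j in seq_len(v_l)) {
      # one-sided moving sum over lags: sum_k Bl[k+1, j] * Bt[t - k, i]
      cb[, (j - 1L) * v_x + i] <-
        as.numeric(stats::filter(Bt[, i], Bl[, j], sides = 1))
    }
  }
  colnames(cb) <- paste0("cb_t", rep(seq_len(v_x), v_l),
                         "_l", rep(seq_len(v_l), each = v_x))
  valid <- seq_len(n) > max_lag
  structure(cb, valid = valid,
            temp_basis = list(degree = 2, knots = knots,
                              boundary = bound),
            lag_basis = Bl, max_lag = max_lag, class = "cross_basis")
}

#' Seasonal natural cubic spline basis
#'
#' Natural cubic spline over the sequential day index with `df_per_year`
#' degrees of freedom per year of span (default 8), boundary knots at the
#' series ends.  One spline spans the whole period; the years of span are
#' `max(1, round(n / 365.25))`, so a five-year series gets 40 columns.
#'
#' @param dates `Date` vector, one entry per day.
#' @param df_per_year degrees of freedom per year (default 8).
#' @return basis matrix with `n_years * df_per_year` columns.
#' @export
seasonal_spline <- function(dates, df_per_year = 8L) {
  n <- length(dates)
  if (n < 2) stopf("degenerate date span")
  n_years <- max(1L, as.integer(round(n / 365.25)))
  df <- n_years * as.integer(df_per_year)
  if (df >= n) stopf("seasonal df (%d) must be < number of days (%d)", df, n)
  B <- splines::ns(seq_len(n), df = df)
  colnames(B) <- paste0("seas", seq_len(df))
  B
}

# full generative design for the log-mean: centered cross-basis columns,
# pollutants, centered seasonal basis.  Centering (over valid rows) makes
# alpha the marginal log baseline and is shared by simulation and recovery.
dlnm_design <- function(env, config) {
  cb <- cross_basis(env$temperature, max_lag = config$max_lag)
  valid <- attr(cb, "valid")
  seas <- seasonal_spline(env$date, config$df_per_year)
  cb_c <- scale(unclass(cb), center = colMeans(cb[valid, , drop = FALSE]),
                scale = FALSE)
  seas_c <- scale(seas, center = colMeans(seas[valid, , drop = FALSE]),
                  scale = FALSE)
  list(cb = cb_c, seas = seas_c, valid = valid)
}

# theta: least-squares projection of the annual cosine onto the seasonal basis
seasonal_theta <- function(env, seas_c, valid, config) {
  doy <- as.integer(format(env$date, "%j"))
  target <- config$seasonal_amp * cos(2 * pi * doy / 365.25)  # winter peak
  theta <- stats::lm.fit(seas_c[valid, , drop = FALSE],
                         target[valid])$coefficients
  theta[is.na(theta)] <- 0   # pivoted-out redundant columns
  theta
}

#' Simulate Poisson daily deaths from the distributed-lag model
#'
#' Computes `log(mu_t) = alpha + s(x_t, l; beta) + beta_o3 O3_t +
#' beta_pm25 PM2.5_t + f(t; theta)` for every day with a complete lag
#' history and draws `death_t ~ Poisson(mu_t)` under the config seed.  The
#' first `max_lag` days carry covariates but no simulated deaths (`NA`);
#' pass `burn_in = TRUE` to simulate `max_lag` extra lead-in days
#' internally and return `n_days` fully observed days instead.
#'
#' @param environment covariate frame from [simulate_environment()], or
#'   `NULL` to simulate one from `config`.
#' @param config a [sim_config()].
#' @param burn_in discard an internally simulated lag-history lead-in so
#'   every returned day has a death count (default `FALSE`).
#' @return a data frame `date, death, temperature, o3, pm25` with
#'   attributes `mu` (true means) and `theta` (seasonal coefficients);
#'   with `burn_in = TRUE` it is also a validated `daily_series`.
#' @export
simulate_mortality <- function(environment = NULL, config = sim_config(),
                               burn_in = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (burn_in) {
    cfg_ext <- config
    cfg_ext$n_days <- config$n_days + config$max_lag
    cfg_ext$start_date <- config$start_date - config$max_lag
    sim <- simulate_mortality(NULL, cfg_ext, burn_in = FALSE)
    out <- as_daily_series(sim[-seq_len(config$max_lag), , drop = FALSE])
    attr(out, "mu") <- attr(sim, "mu")[-seq_len(config$max_lag)]
    attr(out, "theta") <- attr(sim, "theta")
    return(out)
  }
  if (is.null(environment)) environment <- simulate_environment(config)
  if (nrow(environment) <= config$max_lag) {
    stopf("environment must be longer than max_lag")
  }
  d <- dlnm_design(environment, config)
  theta <- seasonal_theta(environment, d$seas, d$valid, config)
  log_mu <- config$alpha +
    drop(d$cb %*% config$beta) +
    config$beta_o3 * environment$o3 +
    config$beta_pm25 * environment$pm25 +
    drop(d$seas %*% theta)
  log_mu[!d$valid] <- NA_real_
  extreme <- abs(log_mu) > config$log_mu_cap
  if (any(extreme, na.rm = TRUE)) {
    stopf(paste0("log(mu) exceeds %g in magnitude on day %d; ",
                 "check the scales of alpha/beta/beta_o3/beta_pm25"),
          config$log_mu_cap, which(extreme)[1])
  }
  mu <- exp(log_mu)
  death <- rep(NA_integer_, nrow(environment))
  death[d$valid] <- with_seed(derive_seed(config$seed, 104729),
                              stats::rpois(sum(d$valid), mu[d$valid]))
  out <- data.frame(date = environment$date, death = death,
                    temperature = environment$temperature,
                    o3 = environment$o3, pm25 = environment$pm25)
  attr(out, "mu") <- mu
  attr(out, "theta") <- theta
  out
}

#' Refit the generative model to one simulated series
#'
#' Fits the correctly specified log-linear Poisson regression -- intercept,
#' centered cross-basis, ozone, PM2.5, centered seasonal spline -- to the
#' valid days of a simulated series and reports Wald 95% confidence
#' intervals for the scalar parameters alpha, beta_o3 and beta_pm25
#' together with coverage flags against the generating config.
#'
#' @param sim output of [simulate_mortality()] (with its environment
#'   columns), using the same `config`.
#' @param config the generating [sim_config()].
#' @return data frame with one row per parameter: estimate, standard
#'   error, 95% CI, true value, `covered`.
#' @export
recover_parameters <- function(sim, config) {
  env <- data.frame(date = sim$date, temperature = sim$temperature,
                    o3 = sim$o3, pm25 = sim$pm25)
  d <- dlnm_design(env, config)
  ok <- d$valid & !is.na(sim$death)
  X <- cbind(d$cb, o3 = env$o3, pm25 = env$pm25, d$seas)[ok, , drop = FALSE]
  fit <- stats::glm.fit(cbind(1, X), sim$death[ok],
                        family = stats::poisson())
  cf <- fit$coefficients
  # Wald SEs from the Fisher information at the fit
  XtWX <- crossprod(cbind(1, X) * sqrt(fit$weights))
  se <- sqrt(diag(chol2inv(chol(XtWX))))
  pick <- c(1, which(colnames(X) == "o3") + 1, which(colnames(X) == "pm25") + 1)
  truth <- c(alpha = config$alpha, beta_o3 = config$beta_o3,
             beta_pm25 = config$beta_pm25)
  est <- cf[pick]
  s <- se[pick]
  lower <- est - stats::qnorm(0.975) * s
  upper <- est + stats::qnorm(0.975) * s
  data.frame(parameter = names(truth), estimate = unname(est),
             se = unname(s), lower = unname(lower), upper = unname(upper),
             truth = unname(truth),
             covered = unname(truth >= lower & truth <= upper))
}

#' Parameter-recovery study for the simulator
#'
#' Simulates `n_rep` independent series from the config (seeds derived
#' from `seed`), refits the generative model to each with
#' [recover_parameters()], and counts how often the 95% intervals cover
#' the true alpha, beta_o3 and beta_pm25.  Nominal behaviour is ~95
#' coverages per 100 replicates for each parameter.
#'
#' @param n_rep replicates (default 100).
#' @param config a [sim_config()].
#' @param seed base seed.
#' @return list with `coverage` (named counts), `n_rep`, and the
#'   per-replicate coverage matrix.
#' @export
recovery_study <- function(n_rep = 100L, config = sim_config(), seed = 1L) {
  hits <- matrix(NA, n_rep, 3,
                 dimnames = list(NULL, c("alpha", "beta_o3", "beta_pm25")))
  for (r in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    sim <- simulate_mortality(NULL, cfg)
    hits[r, ] <- recover_parameters(sim, cfg)$covered
  }
  list(coverage = colSums(hits), n_rep = as.integer(n_rep), hits = hits)
}
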
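# brute-force double-sum oracle for the cross-basis: evaluates the tensor
# product day by day and lag by lag with no matrix machinery
naive_cross_basis <- function(x, max_lag, Bt, Bl) {
  n <- length(x)
  v_x <- ncol(Bt); v_l <- ncol(Bl)
  out <- matrix(NA_real_, n, v_x * v_l)
  for (t in seq_len(n)) {
    if (t <= max_lag) next
    for (i in seq_len(v_x)) {
      for (j in seq_len(v_l)) {
        acc <- 0
        for (k in 0:max_lag) acc <- acc + Bt[t - k, i] * Bl[k + 1, j]
        out[t, (j - 1) * v_x + i] <- acc
      }
    }
  }
  out
}

test_that("a noiseless environment is an exact sinusoid with flat pollutants", {
  cfg <- sim_config(n_days = 400, temp_noise_sd = 0, temp_ar1 = 0,
                    o3_coupling = 0, o3_noise_sd = 0,
                    pm25_coupling = 0, pm25_noise_sd = 0, seed = 1)
  env <- simulate_environment(cfg)
  doy <- as.integer(format(env$date, "%j"))
  expect_equal(env$temperature,
               cfg$temp_mean + cfg$temp_amp *
                 cos(2 * pi * (doy - cfg$temp_phase) / 365.25))
  expect_equal(env$o3, rep(cfg$o3_base, 400))
  expect_equal(env$pm25, rep(cfg$pm25_base, 400))
})

test_that("the environment is seed-reproducible with realistic persistence", {
  cfg <- sim_config(n_days = 1818, seed = 8)
  env <- simulate_environment(cfg)
  expect_identical(env, simulate_environment(cfg))
  r1 <- cor(env$temperature[-1], env$temperature[-1818])
  expect_gt(r1, 0.5)                     # day-to-day persistence
  expect_gt(cor(env$o3, env$temperature), 0)
  expect_lt(cor(env$pm25, env$temperature), 0)
})

test_that("the cross-basis has the contracted dimensions and validity flags", {
  set.seed(10)
  x <- rnorm(120, 23, 5)
  cb <- cross_basis(x, max_lag = 30)
  expect_equal(ncol(cb), 25)             # v_x * v_l = 5 * 5
  expect_equal(nrow(cb), 120)
  valid <- attr(cb, "valid")
  expect_equal(sum(!valid), 30)
  expect_true(all(is.na(cb[!valid, ])))
  expect_true(all(is.finite(cb[valid, ])))
  expect_equal(ncol(attr(cb, "lag_basis")), 5)
  expect_error(cross_basis(rep(20, 50), 5), "distinct")
})

test_that("cross-basis rows equal the brute-force double sum at small lags", {
  set.seed(11)
  for (max_lag in 1:3) {
    x <- round(runif(10, 10, 33), 1)
    cb <- cross_basis(x, max_lag = max_lag, lag_knots = max_lag / 2)
    oracle <- naive_cross_basis(x, max_lag,
                                splines::bs(x, degree = 2,
                                            knots = quantile(x, c(.1, .75, .9),
                                                             names = FALSE),
                                            Boundary.knots = range(x)),
                                attr(cb, "lag_basis"))
    expect_equal(unclass(cb), oracle, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("a constant exposure collapses every valid row to the same tensor", {
  x <- rep(c(21), 40) + rep(0, 40)
  cb <- suppressWarnings(try(cross_basis(x, 5), silent = TRUE))
  expect_s3_class(cb, "try-error")       # knots cannot be placed
  # nearly-constant exposure: all valid rows identical by translation
  x2 <- c(seq(15, 30, length.out = 10), rep(22, 30))
  cb2 <- cross_basis(x2, 5)
  tail_rows <- unclass(cb2)[36:40, ]
  expect_equal(tail_rows, tail_rows[rep(1, 5), ], tolerance = 1e-12)
})

test_that("the cross-basis is linear in its coefficients", {
  set.seed(12)
  x <- rnorm(80, 23, 5)
  cb <- cross_basis(x, 10)
  valid <- attr(cb, "valid")
  b1 <- rnorm(25); b2 <- rnorm(25)
  expect_equal(unclass(cb)[valid, ] %*% (b1 + b2),
               unclass(cb)[valid, ] %*% b1 + unclass(cb)[valid, ] %*% b2,
               tolerance = 1e-12)
})

test_that("the seasonal spline has 8 df per year and absorbs cubic trends", {
  dates <- seq(as.Date("2012-01-01"), by = "day", length.out = 1827)
  B <- seasonal_spline(dates)
  expect_equal(ncol(B), 40)              # 5 years x 8 df
  expect_equal(nrow(B), 1827)
  # continuity: adjacent-day basis values change smoothly
  expect_lt(max(abs(diff(B[, 3]))), 0.05)
  # a cubic in the day index is absorbed almost exactly (the natural
  # boundary constraint leaves only a tiny edge discrepancy)
  t <- seq_len(1827)
  target <- 2 + 0.001 * t - 1e-6 * t^2 + 1e-10 * t^3
  fit <- lm.fit(cbind(1, B), target)
  expect_lt(max(abs(fit$residuals)), 1e-3 * diff(range(target)))
  interior <- 200:1600
  expect_lt(max(abs(fit$residuals[interior])), 1e-4 * diff(range(target)))
  expect_error(seasonal_spline(dates[1]), "degenerate")
})

test_that("the null simulation is i.i.d. Poisson at the baseline rate", {
  cfg <- sim_config(n_days = 2030, beta = rep(0, 25), beta_o3 = 0,
                    beta_pm25 = 0, seasonal_amp = 0, alpha = log(60),
                    seed = 5)
  sim <- simulate_mortality(NULL, cfg, burn_in = TRUE)
  n <- nrow(sim)
  expect_equal(n, 2030)
  expect_false(anyNA(sim$death))
  expect_lt(abs(mean(sim$death) - 60), 3 * sqrt(60 / n))
  # Poisson mean-variance: dispersion index near 1
  expect_lt(abs(var(sim$death) / mean(sim$death) - 1), 0.15)
  expect_equal(unname(range(attr(sim, "mu"))), c(60, 60))
})

test_that("the pollutant effect acts monotonically through the link", {
  cfg1 <- sim_config(n_days = 200, seed = 6)
  cfg2 <- cfg1; cfg2$beta_o3 <- 2 * cfg1$beta_o3
  env <- simulate_environment(cfg1)
  mu1 <- attr(simulate_mortality(env, cfg1), "mu")
  mu2 <- attr(simulate_mortality(env, cfg2), "mu")
  ratio <- log(mu2 / mu1)                # = beta_o3 * o3 per day
  expect_equal(ratio[!is.na(ratio)], cfg1$beta_o3 * env$o3[!is.na(ratio)],
               tolerance = 1e-12)
  expect_true(all(ratio[!is.na(ratio)] >= 0))     # o3 is truncated at zero
  expect_gt(mean(ratio[!is.na(ratio)] > 0), 0.95)
})

test_that("runaway coefficient scales abort with a named guard", {
  cfg <- sim_config(n_days = 120, alpha = log(900), beta_o3 = 0.3)
  expect_error(simulate_mortality(NULL, cfg), "log\\(mu\\)")
})

test_that("the first max_lag days carry covariates but no deaths", {
  cfg <- sim_config(n_days = 100, max_lag = 20, seed = 2)
  sim <- simulate_mortality(NULL, cfg)
  expect_true(all(is.na(sim$death[1:20])))
  expect_false(anyNA(sim$death[21:100]))
  expect_false(anyNA(sim$temperature))
  expect_true(all(sim$death[21:100] >= 0))
})

test_that("refitting the generative model recovers its parameters", {
  cfg <- sim_config(n_days = 1000, seed = 31)
  sim <- simulate_mortality(NULL, cfg)
  rp <- recover_parameters(sim, cfg)
  expect_equal(rp$parameter, c("alpha", "beta_o3", "beta_pm25"))
  expect_true(all(rp$upper > rp$lower))
  # a small replicate study covers the truth most of the time
  rs <- recovery_study(n_rep = 10, config = sim_config(n_days = 800),
                       seed = 13)
  expect_true(all(rs$coverage >= 7))
})
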
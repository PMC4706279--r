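test_that("trapezoid AUC matches closed forms", {
  expect_equal(auc_trapezoid(c(0, 2, 7), c(3, 3, 3)), 21)
  expect_equal(auc_trapezoid(c(0, 1), c(0, 2), "linear"), 1)

  tt <- seq(0, 10, length.out = 1000)
  expect_equal(auc_trapezoid(tt, exp(-tt)), 1 - exp(-10), tolerance = 1e-3)
  # linear trapezoid overestimates a convex decay; log-down is closer
  expect_lt(abs(auc_trapezoid(tt, exp(-tt)) - (1 - exp(-10))),
            abs(auc_trapezoid(tt, exp(-tt), "linear") - (1 - exp(-10))))

  expect_error(auc_trapezoid(c(1, 0), c(1, 1)), "increasing")
  expect_error(auc_trapezoid(c(0, 1), c(-1, 1)), ">= 0")
  expect_error(auc_trapezoid(1, 1), "2 points")
})

test_that("terminal slope selection maximizes adjusted R-squared", {
  tt <- c(1, 2, 4, 8, 24, 48, 96, 168, 240, 336)
  cc <- 10 * exp(-0.01 * tt)
  fit <- fit_lambda_z(tt, cc)
  expect_equal(fit$lambda_z, 0.01, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(fit$t_half, log(2) / 0.01, tolerance = 1e-9)
  # ties on perfect fit resolve to the longest window (all post-Tmax points)
  expect_identical(fit$n_points, 9L)

  # selection agrees with the exhaustive oracle on random bi-exponentials
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, 1, 10); b <- runif(1, 0.05, 0.5)
    l1 <- runif(1, 0.05, 0.2); l2 <- runif(1, 0.001, 0.02)
    cc <- a * exp(-l1 * tt) + b * exp(-l2 * tt)
    cc <- cc * exp(rnorm(length(tt), 0, 0.05))
    got <- fit_lambda_z(tt, cc)
    orc <- brute_lambda_z(tt, cc)
    expect_equal(got$lambda_z, orc$lambda_z, tolerance = 1e-9)
    expect_identical(got$n_points, as.integer(orc$n))
  }

  # rising profile: no negative slope available
  flagged <- fit_lambda_z(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_true(is.na(flagged$lambda_z))
})

test_that("extrapolated AUC behaves as defined", {
  tt <- c(0, seq(0.5, 12, by = 0.5), seq(14, 300, by = 2))
  cc <- 8 * exp(-0.05 * tt)                 # mono-exponential, D/CL = 160
  r <- nca_profile(tt, cc, window = 336)
  expect_equal(r$auc_inf, 8 / 0.05, tolerance = 5e-3)
  expect_equal(r$extrap_frac, 100 * (r$auc_inf - r$auc_last) / r$auc_inf)

  # long-half-life profile: lambda_z is overestimated so AUC_inf still
  # underestimates the true total exposure
  p <- fixture_params()
  grid <- make_design("sequential")$sample_rel[-1]
  pr <- pk_predict(p, dose_events(0, 400), grid)
  rp <- nca_profile(grid, pr$conc_parent)
  expect_lt(rp$auc_inf, auc_model(p, dose_events(0, 400), 0, Inf)[["parent"]])
  # apparent terminal half-life: a few hundred hours, far below the truth
  expect_gt(rp$t_half, 50)
  expect_lt(rp$t_half, 1000)
  expect_lt(rp$t_half, terminal_halflife(p) / 5)
})

test_that("trial GMR matches identities and a hand-computed toy", {
  p <- fixture_params()
  ds <- simulate_trial(make_design("sequential"), p, seed = 8)
  nca <- nca_dataset(ds)

  # identical periods: force period 2 equal to period 1
  n2 <- nca
  for (id in unique(n2$ID)) for (an in c("parent", "metab")) {
    i1 <- n2$ID == id & n2$PERIOD == 1 & n2$analyte == an
    i2 <- n2$ID == id & n2$PERIOD == 2 & n2$analyte == an
    n2$auc_window[i2] <- n2$auc_window[i1]
  }
  expect_equal(as.numeric(trial_gmr(n2, "auc_window", "parent")), 1)

  # doubling period-2 metrics doubles the GMR; scale invariance
  n3 <- n2
  n3$auc_window[n3$PERIOD == 2] <- 2 * n3$auc_window[n3$PERIOD == 2]
  expect_equal(as.numeric(trial_gmr(n3, "auc_window", "parent")), 2)
  g0 <- as.numeric(trial_gmr(nca, "auc_window", "metab"))
  n4 <- nca; n4$auc_window <- 7.3 * n4$auc_window
  expect_equal(as.numeric(trial_gmr(n4, "auc_window", "metab")), g0)

  # 3-subject spreadsheet oracle
  toy <- data.frame(ID = rep(1:3, 2), PERIOD = rep(1:2, each = 3),
                    ARM = "seq", analyte = "parent",
                    auc_window = c(10, 20, 40, 15, 18, 80))
  expect_equal(as.numeric(trial_gmr(toy, "auc_window", "parent")),
               prod(c(15 / 10, 18 / 20, 80 / 40))^(1 / 3))

  # parallel arms
  toyp <- data.frame(ID = 1:4, PERIOD = 1,
                     ARM = rep(c("control", "treated"), each = 2),
                     analyte = "parent", auc_window = c(10, 40, 30, 120))
  expect_equal(as.numeric(trial_gmr(toyp, "auc_window", "parent")), 3)

  # non-positive values excluded with a count
  toy$auc_window[4] <- 0
  g <- trial_gmr(toy, "auc_window", "parent")
  expect_identical(attr(g, "n_excluded"), 1L)
  expect_error(trial_gmr(nca, "nonsense", "parent"), "unknown metric")
})

test_that("trial summaries use the documented percentile convention", {
  expect_equal(summarize_trials(2)$median, 2)
  expect_equal(summarize_trials(2)$lo90, 2)
  set.seed(9)
  g <- exp(rnorm(4000, log(1.3), 0.1))
  s <- summarize_trials(g)
  expect_equal(s$median, 1.3, tolerance = 0.01)
  expect_equal(s$lo90, quantile(g, 0.05, names = FALSE))
  expect_error(summarize_trials(numeric(0)), "at least one")
})
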
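test_that("the shipped fixture satisfies its calibration constraints", {
  p <- fixture_params()
  fr <- fraction_observed(p, 1, 336)
  expect_equal(fr[["parent"]], 48, tolerance = 0.5 / 48)
  expect_equal(fr[["metab"]], 29, tolerance = 0.5 / 29)
  th <- terminal_halflife(p)
  expect_gte(th, 3600)
  expect_lte(th, 4800)
  tmax <- ddilong:::profile_tmax(p)
  expect_gte(tmax, 3)
  expect_lte(tmax, 8)
})

test_that("calibration is deterministic and reproduces the fixture", {
  p <- calibrate_bdq_like()
  expect_equal(p, fixture_params(), tolerance = 0)
})

test_that("subject sampling reproduces the stated variability", {
  # all-zero CVs give exactly zero etas
  s0 <- sample_subjects(20, iiv_params(0, 0, 0, 0, 0), seed = 1)
  expect_true(all(s0[, c("eta_cl_p", "eta_cl_m", "eta_ie_p", "eta_ie_m")] == 0))

  s <- sample_subjects(1e5, iiv_params(), seed = 7)
  cv_emp <- 100 * sd(exp(s$eta_cl_p)) / mean(exp(s$eta_cl_p))
  expect_equal(cv_emp, 24, tolerance = 0.01)          # lognormal moments
  expect_equal(cor(s$eta_ie_p, s$eta_ie_m), 0.75, tolerance = 0.02 / 0.75)

  # lognormal IE: median of individual factors equals the population value
  ie_ind <- 0.5 * exp(s$eta_ie_m)
  expect_equal(median(ie_ind), 0.5, tolerance = 5e-3)

  # weight distribution
  expect_equal(median(s$weight), 70, tolerance = 0.01)

  expect_error(iiv_params(corr_ie = 1.2), "corr")
  expect_error(iiv_params(cv_cl_p = -5), "CV")
  expect_error(sample_subjects(0), "n >= 1")
})

test_that("simulated trials honour the generative model exactly", {
  p <- fixture_params()
  d <- make_design("sequential")
  no_iiv <- iiv_params(0, 0, 0, 0, 0)
  no_err <- residual_model(0, 0)
  scen <- interaction_scenario(0.5)
  ds <- simulate_trial(d, p, no_iiv, scen, no_err, seed = 3)

  # zero IIV + zero residual: observations equal the model prediction
  id <- 5L
  sub <- ds[ds$ID == id & ds$EVID == 0 & ds$CMT == 2, ]
  pi <- scale_allometric(p, sub$WT[1])
  tl <- clearance_timeline(672 - 168, c(1, 0.5), c(1, 0.5))
  pr <- pk_predict(pi, dose_events(c(0, 672), 400), sub$TIME, tl)
  expect_equal(sub$DV, pr$conc_parent, tolerance = 1e-12)

  # carry-over: period-2 pre-dose concentration is positive under the null
  ds0 <- simulate_trial(d, p, scen = interaction_scenario(1), seed = 5)
  pre2 <- ds0[ds0$EVID == 0 & ds0$PERIOD == 2 & ds0$TIME == 672 &
                ds0$CMT == 2, "DV"]
  expect_true(all(pre2 > 0))

  # RNG contract
  expect_identical(simulate_trial(d, p, seed = 11),
                   simulate_trial(d, p, seed = 11))
  expect_false(identical(simulate_trial(d, p, seed = 11),
                         simulate_trial(d, p, seed = 12)))

  # parallel arms are weight-matched
  dp <- simulate_trial(make_design("parallel1"), p, seed = 2)
  wc <- unique(dp[dp$ARM == "control", c("ID", "WT")])$WT
  wt <- unique(dp[dp$ARM == "treated", c("ID", "WT")])$WT
  expect_equal(sort(wc), sort(wt))
})

test_that("datasets round-trip losslessly and invariants are enforced", {
  p <- fixture_params()
  ds <- simulate_trial(make_design("sequential"), p, seed = 21)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(ds, f)
  back <- read_pk_dataset(f)
  a <- ds; attr(a, "design") <- NULL
  expect_equal(back, a, tolerance = 0)

  bad <- ds
  bad$MDV[bad$EVID == 0 & bad$TIME == 0][1] <- 0L
  bad$DV[bad$EVID == 0 & bad$TIME == 0][1] <- 1
  expect_error(validate_dataset(bad), "pre-first-dose")
  expect_error(validate_dataset(ds[, -3]), "lacks columns")
})
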
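test_that("allometric scaling follows the power law", {
  p <- fixture_params()

  expect_equal(scale_allometric(p, p$WT_ref), p)

  p1 <- p; p1$exp_V <- 1
  class(p1) <- "pk_params"
  s <- scale_allometric(p1, 2 * p1$WT_ref)
  for (nm in c("V1_P", "V2_P", "V3_P", "V1_M", "V2_M"))
    expect_equal(s[[nm]], 2 * p1[[nm]])

  # direct power-computation oracle
  s2 <- scale_allometric(p, 140)
  expect_equal(s2$CL_P, p$CL_P * (140 / 70)^0.75)
  expect_equal(s2$Q_M, p$Q_M * 2^0.75)
  expect_equal(s2$MTT, p$MTT)

  expect_error(scale_allometric(p, 0), "positive")
  expect_error(scale_allometric(p, -10), "positive")
})

test_that("rate matrix reduces correctly and conserves transfer mass", {
  # uncoupled 1-compartment limit
  p <- toy_params(CL_P = 2, V1_P = 10, CL_M = 3, V1_M = 15, KA = 0.4)
  A <- build_system(p)
  ev <- sort(eigen(A, only.values = TRUE)$values)
  # depot/parent/metabolite rates plus one zero per disconnected peripheral
  expect_equal(sort(c(-0.4, -2 / 10, -3 / 15, 0, 0, 0)), ev,
               tolerance = 1e-12)

  # with fm = 1 every column sum equals minus the elimination leaving the
  # system from that compartment (metabolite central only)
  p2 <- fixture_params()
  A2 <- build_system(p2)
  elim <- numeric(ncol(A2))
  elim[p2$NTR + 5] <- p2$CL_M / p2$V1_M
  expect_equal(colSums(A2), -elim, ignore_attr = TRUE, tolerance = 1e-12)

  # eigenvalues never in the right half plane (random valid systems)
  set.seed(11)
  for (i in 1:20) {
    Ar <- build_system(random_params())
    expect_true(all(Re(eigen(Ar, only.values = TRUE)$values) <= 1e-10))
  }
})

test_that("predict matches closed forms and an RK4 oracle", {
  p <- fixture_params()
  tt <- c(1, 4, 12, 48, 168, 336)

  # zero dose / empty dose list
  z <- pk_predict(p, dose_events(numeric(0)), tt)
  expect_equal(z$conc_parent, rep(0, 6))
  expect_equal(z$conc_metab, rep(0, 6))

  # 1-compartment bolus limit: conc ~ e^(-t)
  pb <- toy_params(CL_P = 1, V1_P = 1, KA = 1e4)
  out <- pk_predict(pb, dose_events(0, 1), c(0.5, 1, 2))
  expect_equal(out$conc_parent, exp(-c(0.5, 1, 2)), tolerance = 2e-4)

  # full model vs independent RK4 integration
  pr <- pk_predict(p, dose_events(0, 400), tt)
  orc <- oracle_conc(p, 400, tt)
  expect_equal(pr$conc_parent, unname(orc[, "parent"]), tolerance = 1e-6)
  expect_equal(pr$conc_metab, unname(orc[, "metab"]), tolerance = 1e-6)

  expect_error(pk_predict(p, dose_events(0, 400), c(5, 1)), "sorted")
})

test_that("model AUC obeys exact identities and dense quadrature", {
  p <- fixture_params()
  d <- dose_events(0, 400)

  expect_equal(auc_model(p, d, 0, Inf)[["parent"]], 400 / p$CL_P)
  expect_equal(auc_model(p, d, 0, Inf)[["metab"]], 400 / p$CL_M)

  # scaling both clearances by k divides infinite AUCs by k
  tl <- clearance_timeline(numeric(0), 2.5, 2.5)
  expect_equal(auc_model(p, d, 0, Inf, tl),
               auc_model(p, d, 0, Inf) / 2.5, tolerance = 1e-10)

  # dose proportionality
  expect_equal(auc_model(p, dose_events(0, 800), 0, 336),
               2 * auc_model(p, d, 0, 336), tolerance = 1e-12)

  # dense trapezoid of predict() converges to the exact window AUC
  tt <- seq(0, 336, length.out = 50001)
  pr <- pk_predict(p, d, tt)
  a_exact <- auc_model(p, d, 0, 336)
  expect_equal(sum(diff(tt) * (head(pr$conc_parent, -1) + pr$conc_parent[-1]) / 2),
               a_exact[["parent"]], tolerance = 1e-4)
  expect_equal(sum(diff(tt) * (head(pr$conc_metab, -1) + pr$conc_metab[-1]) / 2),
               a_exact[["metab"]], tolerance = 1e-4)

  expect_error(auc_model(p, d, 10, 10), "t1 < t2")
})

test_that("mass balance holds through the metabolite with fm = 1", {
  p <- fixture_params()
  # all parent mass eventually leaves via metabolite elimination:
  # CL_M * AUC_M(0, inf) = F * Dose (parent-mass equivalents)
  am <- auc_model(p, dose_events(0, 400), 0, Inf)[["metab"]]
  expect_equal(p$CL_M * am, p$F * 400, tolerance = 1e-6)
})

test_that("terminal half-life matches closed form, scaling and tail slope", {
  p1 <- toy_params(CL_P = 1, V1_P = 10, CL_M = 20, V1_M = 10)
  expect_equal(terminal_halflife(p1), log(2) / 0.1, tolerance = 1e-9)

  p <- fixture_params()
  expect_gt(terminal_halflife(p), 3600)   # more than five months

  # exp_CL = exp_V = 1: CL/V ratios unchanged, half-life invariant
  p2 <- p; p2$exp_CL <- 1; p2$exp_V <- 1
  class(p2) <- "pk_params"
  expect_equal(terminal_halflife(scale_allometric(p2, 120)),
               terminal_halflife(p2), tolerance = 1e-10)

  # equals the noise-free log-concentration tail slope within 0.1%
  A <- build_system(p)
  idx <- (p$NTR + 2):(p$NTR + 6)
  mags <- sort(abs(Re(eigen(A[idx, idx], only.values = TRUE)$values)))
  t_start <- 10 * log(2) / mags[2]        # past the second-slowest phase
  tt <- seq(t_start, t_start + 20000, length.out = 40)
  pr <- pk_predict(p, dose_events(0, 400), tt)
  slope <- -coef(lm(log(pr$conc_parent) ~ tt))[[2]]
  expect_equal(log(2) / slope, terminal_halflife(p), tolerance = 1e-3)
})

test_that("fraction observed is monotone in the interaction factor", {
  p <- fixture_params()
  expect_equal(fraction_observed(p, 1, 1e7), c(parent = 100, metab = 100),
               tolerance = 1e-3)
  grid <- t(vapply(c(0.2, 0.5, 1, 2, 5),
                   function(ie) fraction_observed(p, ie, 336), numeric(2)))
  expect_true(all(diff(grid[, 1]) > 0))
  expect_true(all(diff(grid[, 2]) > 0))
  expect_error(fraction_observed(p, 0, 336), "ie_factor")
  expect_error(fraction_observed(p, 1, -5), "window")
})

test_that("parameter config files round-trip", {
  p <- fixture_params()
  f <- withr::local_tempfile(fileext = ".txt")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(q, p)
  f2 <- withr::local_tempfile()
  writeLines("CL_P: 1", f2)
  expect_error(read_params(f2), "missing parameters")
})

test_that("timeline and dose validation reject bad input", {
  expect_error(clearance_timeline(c(5, 1), c(1, 1, 1), c(1, 1, 1)), "increasing")
  expect_error(clearance_timeline(5, c(1, -1), c(1, 1)), "> 0")
  expect_error(clearance_timeline(5, 1, c(1, 1, 1)), "per interval")
  expect_error(dose_events(c(5, 1)), "non-decreasing")
  expect_error(dose_events(0, -1), "non-negative")
  expect_error(structural_params(CL_P = -1, V1_P = 1, V2_P = 1, V3_P = 1,
                                 Q2_P = 0, Q3_P = 0, CL_M = 1, V1_M = 1,
                                 V2_M = 1, Q_M = 0), "positive")
})
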
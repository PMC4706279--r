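test_that("interaction-effect arithmetic is exact", {
  expect_equal(ie_specific(0.7, 1), 0.7)
  expect_equal(ie_specific(1, 0.3), 1)
  expect_equal(ie_specific(2, 0.5), 3)
  expect_error(ie_specific(2, 0), "fm")
  expect_warning(ie_specific(0.1, 0.5), "inconsistent")

  mock <- list(ie_p = 0.2, ie_m = 5, spec = list(analytes = "both"))
  expect_equal(rel_cavg_ss(mock), c(parent = 5, metab = 0.2))
  mock$ie_p <- -1
  expect_error(rel_cavg_ss(mock), "nonpositive")
})

test_that("relCavg,ss equals the steady-state weekly AUC ratio", {
  # superposition oracle: many weekly doses, weekly AUC in the last interval
  p <- toy_params(CL_P = 4, V1_P = 80, CL_M = 6, V1_M = 90, KA = 0.5)
  n_dose <- 30
  d <- dose_events(seq(0, by = 168, length.out = n_dose), 400)
  t1 <- 168 * (n_dose - 1); t2 <- 168 * n_dose
  ie <- 0.4
  a0 <- auc_model(p, d, t1, t2)
  a1 <- auc_model(p, d, t1, t2, clearance_timeline(numeric(0), ie, ie))
  expect_equal(unname(a1 / a0), c(1 / ie, 1 / ie), tolerance = 1e-3)
})

test_that("Laplace matches a 64-node Gauss-Hermite quadrature oracle", {
  # 1-compartment toy, one random effect (on CL_P), five subjects
  p <- toy_params()
  d <- make_design("parallel1",
                   overrides = list(
                     n_subjects = 10L,
                     sample_rel = c(0, 0.5, 1, 2, 3, 4, 6, 8, 12, 18, 24, 36)))
  iiv <- iiv_params(cv_cl_p = 30, cv_cl_m = 0, cv_ie_p = 0, cv_ie_m = 0,
                    corr_ie = 0)
  res <- residual_model(10, 10)
  ds <- simulate_trial(d, p, iiv, interaction_scenario(1), res, seed = 31)
  ds <- ds[ds$ID <= 5 & (ds$EVID == 1 | ds$CMT == 2), ]   # 5 subjects, parent
  spec <- model_spec("parent", estimate_omega = FALSE, estimate_sigma = FALSE)

  lap <- marginal_nll(ds, d, p, iiv = iiv, res = res, spec = spec)

  # oracle: adaptive Gauss-Hermite (nodes centred at the joint-density mode,
  # scaled by the curvature), located independently with stats::optimize
  gh <- gauss_hermite(64)
  om <- sqrt(log(1 + 0.3^2))
  sig <- 0.10
  subjects <- ddilong:::prep_subjects(ds, d, spec)
  oracle <- 0
  for (s in subjects) {
    th <- ddilong:::as_theta(scale_allometric(p, s$weight))
    jfun <- function(eta) {
      f <- ddilong:::cond_pred_cpp(s$dat, th, 1, 1, c(eta, 0, 0, 0))
      -sum(dnorm(s$dat$y, f, sig * f, log = TRUE)) +
        0.5 * eta^2 / om^2 + 0.5 * log(2 * pi * om^2)
    }
    o <- optimize(jfun, c(-1.5, 1.5), tol = 1e-10)
    h <- 1e-4
    curv <- (jfun(o$minimum + h) - 2 * o$objective + jfun(o$minimum - h)) / h^2
    sd_post <- 1 / sqrt(curv)
    etak <- o$minimum + sqrt(2) * sd_post * gh$nodes
    lik <- sum(gh$weights * exp(gh$nodes^2) *
                 exp(-vapply(etak, jfun, numeric(1))) * sqrt(2) * sd_post)
    oracle <- oracle - 2 * log(lik)
  }
  expect_lt(abs(lap - oracle), 0.1)
})

test_that("the marginal likelihood is exchangeable over subjects", {
  p <- fixture_params()
  d <- make_design("sequential")
  ds <- simulate_trial(d, p, scen = interaction_scenario(0.5), seed = 13)
  v1 <- marginal_nll(ds, d, p, 0.5, 0.5)
  ids <- unique(ds$ID)
  perm <- rev(ids)
  ds2 <- do.call(rbind, lapply(perm, function(id) ds[ds$ID == id, ]))
  v2 <- marginal_nll(ds2, d, p, 0.5, 0.5)
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("Omega -> 0 reduces to the fixed-effects deviance", {
  p <- toy_params()
  d <- make_design("parallel1",
                   overrides = list(n_subjects = 6L,
                                    sample_rel = c(0, 2, 6, 12, 24)))
  iiv0 <- iiv_params(0, 0, 0, 0, 0)
  res <- residual_model(10, 10)
  ds <- simulate_trial(d, p, iiv0, interaction_scenario(1), res, seed = 17)
  spec <- model_spec("both", estimate_omega = FALSE, estimate_sigma = FALSE)
  got <- marginal_nll(ds, d, p, iiv = iiv0, res = res, spec = spec)

  # direct least-squares deviance oracle
  dev <- 0
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id & ds$EVID == 0 & ds$MDV == 0, ]
    psub <- scale_allometric(p, sub$WT[1])
    pr <- pk_predict(psub, dose_events(0, 400), unique(sub$TIME))
    f <- ifelse(sub$CMT == 2,
                pr$conc_parent[match(sub$TIME, pr$time)],
                pr$conc_metab[match(sub$TIME, pr$time)])
    v <- (0.1 * f)^2
    dev <- dev + sum(log(2 * pi * v) + (sub$DV - f)^2 / v)
  }
  expect_equal(got, dev, tolerance = 1e-10)
})

test_that("zero-noise data are recovered exactly from a perturbed start", {
  p <- fixture_params()
  d <- make_design("sequential", overrides = list(n_subjects = 6L))
  iiv0 <- iiv_params(0, 0, 0, 0, 0)
  res0 <- residual_model(0, 0)
  ds <- simulate_trial(d, p, iiv0, interaction_scenario(0.5), res0, seed = 23)
  spec <- model_spec("both", estimate = c("CL_P", "CL_M"),
                     estimate_omega = FALSE, estimate_sigma = FALSE)
  init <- ddilong:::perturb_params(p, 1.15, spec$estimate)
  fit <- fit_nlme(ds, d, init_p = init, init_ie_p = 0.6, init_ie_m = 0.6,
                  init_iiv = iiv0, init_res = residual_model(1, 1),
                  spec = spec)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["CL_P"]], p$CL_P, tolerance = 1e-3)
  expect_equal(fit$estimates[["CL_M"]], p$CL_M, tolerance = 1e-3)
  expect_equal(fit$estimates[["IE_P"]], 0.5, tolerance = 1e-3)
  expect_equal(fit$estimates[["IE_M"]], 0.5, tolerance = 1e-3)
  expect_equal(unname(rel_cavg_ss(fit)), c(2, 2), tolerance = 1e-3)
})

test_that("standard errors follow the sqrt-n law on a fixed-effects toy", {
  p <- toy_params()
  iiv0 <- iiv_params(0, 0, 0, 0, 0)
  res <- residual_model(10, 10)
  spec <- model_spec("parent", estimate = c("CL_P", "V1_P"),
                     estimate_omega = FALSE, estimate_sigma = FALSE)
  rse_for <- function(n) {
    d <- make_design("parallel1",
                     overrides = list(n_subjects = n,
                                      sample_rel = c(0, 1, 3, 6, 12, 24, 48)))
    ds <- simulate_trial(d, p, iiv0, interaction_scenario(0.7), res, seed = 29)
    fit <- fit_nlme(ds, d, init_p = p, init_ie_p = 0.7, init_iiv = iiv0,
                    init_res = res, spec = spec)
    se <- standard_errors(fit)
    expect_true(attr(se, "ok"))
    # fixed parameters carry no standard error rows
    expect_false("V2_P" %in% se$parameter)
    se$rse[se$parameter == "IE_P"]
  }
  r8 <- rse_for(8L)
  r32 <- rse_for(32L)
  expect_equal(r8 / r32, 2, tolerance = 0.3)
})
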
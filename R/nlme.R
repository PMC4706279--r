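ALL_ESTIMABLE <- c("MTT", "KA", "CL_P", "V1_P", "V2_P", "V3_P", "Q2_P",
                   "Q3_P", "CL_M", "V1_M", "V2_M", "Q_M")
METAB_PARAMS <- c("CL_M", "V1_M", "V2_M", "Q_M")

#' Mixed-effects model specification
#'
#' Defines which data enter the likelihood and which parameters are
#' estimated. Fixed effects are estimated on the log scale (positivity);
#' interaction effects are log-scale parameters reported as factors.
#' Random effects (lognormal) sit on CL_P, CL_M and the two interaction
#' effects; the parent-only variant drops the metabolite data, parameters
#' and random effects.
#'
#' The default estimated set (clearances, central volumes and both
#' interaction effects, plus the omega diagonal and proportional sigma)
#' identifies the DDI quantities; `estimate = "all"` re-estimates every
#' structural fixed effect.
#'
#' @param analytes `"both"` (parent + metabolite, the default) or
#'   `"parent"`.
#' @param estimate character vector of structural parameters to estimate,
#'   or `"all"`. `IE_P`/`IE_M` are always estimated.
#' @param estimate_omega estimate random-effect SDs (log scale)?
#' @param estimate_corr estimate the IE correlation (Fisher-z scale)?
#'   Only meaningful with both analytes.
#' @param estimate_sigma estimate the proportional residual CVs?
#' @return An object of class `ddi_model_spec`.
#' @export
model_spec <- function(analytes = c("both", "parent"), estimate = NULL,
                       estimate_omega = TRUE, estimate_corr = FALSE,
                       estimate_sigma = TRUE) {
  analytes <- match.arg(analytes)
  if (is.null(estimate))
    estimate <- if (analytes == "both")
      c("CL_P", "V1_P", "CL_M", "V1_M") else c("CL_P", "V1_P")
  if (identical(estimate, "all")) estimate <- ALL_ESTIMABLE
  bad <- setdiff(estimate, ALL_ESTIMABLE)
  if (length(bad)) stop("cannot estimate: ", paste(bad, collapse = ", "))
  if (analytes == "parent") {
    if (any(estimate %in% METAB_PARAMS))
      stop("parent-only spec cannot contain metabolite parameters")
    estimate_corr <- FALSE
  }
  structure(list(analytes = analytes, estimate = estimate,
                 estimate_omega = estimate_omega,
                 estimate_corr = estimate_corr,
                 estimate_sigma = estimate_sigma),
            class = "ddi_model_spec")
}

# eta slots (0-based, fixed meaning in the C++ engine)
eta_slots <- function(spec) {
  if (spec$analytes == "both") c(0L, 1L, 2L, 3L) else c(0L, 2L)
}

# slots that actually carry variability: a zero-CV eta with a fixed omega is
# dropped from the marginal integral (its contribution is exactly a point
# mass at zero)
eta_active_slots <- function(spec, iiv) {
  slots <- eta_slots(spec)
  cvs <- c(iiv$cv_cl_p, iiv$cv_cl_m, iiv$cv_ie_p, iiv$cv_ie_m)[slots + 1L]
  if (spec$estimate_omega) slots else slots[cvs > 0]
}

# per-subject structures the C++ likelihood consumes
prep_subjects <- function(ds, design, spec) {
  validate_dataset(ds)
  covered <- covered_dose_time(design) + design$ie_onset
  lapply(unique(ds$ID), function(id) {
    d <- ds[ds$ID == id, ]
    obs <- d[d$EVID == 0 & d$MDV == 0, ]
    if (spec$analytes == "parent") obs <- obs[obs$CMT == 2L, ]
    arm <- d$ARM[1]
    active <- design$type == "sequential" || arm == "treated"
    first_dose <- min(d$TIME[d$EVID == 1])
    if (!active) {
      sw <- numeric(0); flag <- 0L
    } else if (covered <= first_dose) {
      sw <- numeric(0); flag <- 1L
    } else {
      sw <- covered; flag <- c(0L, 1L)
    }
    list(id = id, weight = d$WT[1],
         dat = list(dose_time = d$TIME[d$EVID == 1],
                    dose_amt = d$AMT[d$EVID == 1],
                    switch_time = sw, ie_active = as.integer(flag),
                    obs_time = obs$TIME, analyte = obs$CMT - 1L,
                    y = obs$DV))
  })
}

# parameter vector packing -------------------------------------------------

pack_init <- function(spec, p, ie_p, ie_m, iiv, res) {
  v <- c()
  for (nm in spec$estimate) v[paste0("log_", nm)] <- log(p[[nm]])
  v["log_IE_P"] <- log(ie_p)
  if (spec$analytes == "both") v["log_IE_M"] <- log(ie_m)
  if (spec$estimate_omega) {
    v["log_om_CL_P"] <- log(sqrt(cv_to_omega2(max(iiv$cv_cl_p, 1e-3))))
    if (spec$analytes == "both")
      v["log_om_CL_M"] <- log(sqrt(cv_to_omega2(max(iiv$cv_cl_m, 1e-3))))
    v["log_om_IE_P"] <- log(sqrt(cv_to_omega2(max(iiv$cv_ie_p, 1e-3))))
    if (spec$analytes == "both")
      v["log_om_IE_M"] <- log(sqrt(cv_to_omega2(max(iiv$cv_ie_m, 1e-3))))
  }
  if (spec$estimate_corr) v["z_corr_IE"] <- atanh(iiv$corr_ie)
  if (spec$estimate_sigma) {
    v["log_sig_P"] <- log(res$cv_p / 100)
    if (spec$analytes == "both") v["log_sig_M"] <- log(res$cv_m / 100)
  }
  v
}

unpack_par <- function(vec, spec, p0, ie0_p, ie0_m, iiv0, res0,
                       slots = eta_active_slots(spec, iiv0)) {
  p <- p0
  for (nm in spec$estimate) p[[nm]] <- exp(vec[[paste0("log_", nm)]])
  ie_p <- exp(vec[["log_IE_P"]])
  ie_m <- if (spec$analytes == "both") exp(vec[["log_IE_M"]]) else ie0_m
  om <- c(CL_P = sqrt(cv_to_omega2(iiv0$cv_cl_p)),
          CL_M = sqrt(cv_to_omega2(iiv0$cv_cl_m)),
          IE_P = sqrt(cv_to_omega2(iiv0$cv_ie_p)),
          IE_M = sqrt(cv_to_omega2(iiv0$cv_ie_m)))
  if (spec$estimate_omega) {
    om["CL_P"] <- exp(vec[["log_om_CL_P"]])
    om["IE_P"] <- exp(vec[["log_om_IE_P"]])
    if (spec$analytes == "both") {
      om["CL_M"] <- exp(vec[["log_om_CL_M"]])
      om["IE_M"] <- exp(vec[["log_om_IE_M"]])
    }
  }
  corr <- if (spec$estimate_corr) tanh(vec[["z_corr_IE"]]) else iiv0$corr_ie
  Of <- diag(pmax(om, 1e-6)^2)
  Of[3, 4] <- Of[4, 3] <- corr * om[3] * om[4]
  Omega <- Of[slots + 1L, slots + 1L, drop = FALSE]
  sig_p <- if (spec$estimate_sigma) exp(vec[["log_sig_P"]]) else res0$cv_p / 100
  sig_m <- if (spec$estimate_sigma && spec$analytes == "both")
    exp(vec[["log_sig_M"]]) else res0$cv_m / 100
  list(p = p, ie_p = ie_p, ie_m = ie_m, Omega = Omega,
       sig_p = max(sig_p, 1e-6), sig_m = max(sig_m, 1e-6))
}

# objective factory: returns f(vec) = -2 log marginal likelihood, with
# per-subject warm-started inner modes kept in `env`
make_nll <- function(subjects, spec, p0, ie0_p, ie0_m, iiv0, res0, settings) {
  slots <- eta_active_slots(spec, iiv0)
  q <- length(slots)
  env <- new.env()
  env$warm <- lapply(subjects, function(s) numeric(q))
  hess_code <- switch(settings$inner_hessian,
                      auto = if (q <= 2) 2L else 1L, gn = 1L, fd = 2L)
  force(subjects)
  function(vec) {
    u <- tryCatch(unpack_par(vec, spec, p0, ie0_p, ie0_m, iiv0, res0, slots),
                  error = function(e) NULL)
    if (is.null(u)) return(1e10)
    tot <- 0
    for (i in seq_along(subjects)) {
      s <- subjects[[i]]
      th <- as_theta(scale_allometric(u$p, s$weight))
      if (q == 0L) {
        # no random effects: plain fixed-effects deviance
        f <- cond_pred_cpp(s$dat, th, u$ie_p, u$ie_m, numeric(4))
        sig <- ifelse(s$dat$analyte == 1, u$sig_p, u$sig_m)
        ok <- f > 0
        v <- (sig[ok] * f[ok])^2
        tot <- tot + sum(log(2 * pi * v) + (s$dat$y[ok] - f[ok])^2 / v)
        next
      }
      r <- tryCatch(
        laplace_subject_cpp(s$dat, th, u$ie_p, u$ie_m, u$sig_p, u$sig_m,
                            u$Omega, slots, env$warm[[i]],
                            settings$inner_maxit, settings$inner_tol,
                            hess_code),
        error = function(e) NULL)
      if (is.null(r) || !is.finite(r$m2ll)) {
        if (settings$fail_hard)
          stop("inner optimization failed for subject ", s$id)
        return(1e10)
      }
      env$warm[[i]] <- r$eta
      tot <- tot + r$m2ll
    }
    tot
  }
}

#' Estimation settings
#'
#' @param inner_maxit,inner_tol inner (random-effect mode) Newton controls.
#' @param inner_hessian `"auto"` (exact finite-difference log-det Hessian
#'   for up to 2 random effects, Gauss-Newton beyond), `"gn"` or `"fd"`.
#' @param outer_maxit,outer_reltol outer optimizer (nlminb) controls.
#' @param grad_step central-difference step (log-parameter scale) for the
#'   outer gradient.
#' @param restarts number of automatic optimizer restarts from the stopping
#'   point after a non-converged outer run.
#' @param fail_hard error (TRUE) or return a penalty value (FALSE) when a
#'   subject's inner optimization fails.
#' @return A named list of settings.
#' @export
estimation_settings <- function(inner_maxit = 50L, inner_tol = 1e-5,
                                inner_hessian = "auto", outer_maxit = 150L,
                                outer_reltol = 1e-6, grad_step = 1e-4,
                                restarts = 2L, fail_hard = FALSE) {
  list(inner_maxit = as.integer(inner_maxit), inner_tol = inner_tol,
       inner_hessian = match.arg(inner_hessian, c("auto", "gn", "fd")),
       outer_maxit = as.integer(outer_maxit), outer_reltol = outer_reltol,
       grad_step = grad_step, restarts = as.integer(restarts),
       fail_hard = fail_hard)
}

#' Marginal -2 log-likelihood (Laplace)
#'
#' Evaluates the Laplace-approximated marginal -2 log-likelihood of a
#' dataset at given parameter values: per subject the random-effect
#' posterior mode is located by a damped Gauss-Newton search and the
#' marginal contribution is
#' `cond(-2LL) + eta' Omega^-1 eta + log|Omega| + log|H|` at the mode.
#'
#' @param ds dataset (see [simulate_trial()]).
#' @param design the [make_design()] the data came from.
#' @param p structural parameters at which to evaluate.
#' @param ie_p,ie_m interaction-effect factors.
#' @param iiv,res [iiv_params()] and [residual_model()] values.
#' @param spec a [model_spec()].
#' @param settings see [estimation_settings()].
#' @return The scalar -2 log marginal likelihood.
#' @export
marginal_nll <- function(ds, design, p, ie_p = 1, ie_m = 1,
                         iiv = iiv_params(), res = residual_model(),
                         spec = model_spec(),
                         settings = estimation_settings()) {
  subjects <- prep_subjects(ds, design, spec)
  vec <- pack_init(spec, p, ie_p, ie_m, iiv, res)
  # evaluate at the packed point with everything else fixed at the inputs
  f <- make_nll(subjects, spec, p, ie_p, ie_m, iiv, res, settings)
  f(vec)
}

#' Fit the mixed-effects model to one trial
#'
#' Maximum (Laplace-approximated marginal) likelihood estimation from the
#' supplied initial values, by `nlminb` on the packed log-scale parameter
#' vector. Non-convergence is reported in the result, never silently
#' accepted.
#'
#' @inheritParams marginal_nll
#' @param init_p,init_ie_p,init_ie_m,init_iiv,init_res initial values
#'   (simulation studies conventionally perturb the truth, e.g. x 1.2).
#' @return An object of class `ddi_fit`: estimates table, objective value,
#'   convergence flag/message, the packed optimum, and a likelihood closure
#'   used by [standard_errors()].
#' @export
fit_nlme <- function(ds, design, init_p, init_ie_p = 1, init_ie_m = 1,
                     init_iiv = iiv_params(), init_res = residual_model(),
                     spec = model_spec(),
                     settings = estimation_settings()) {
  subjects <- prep_subjects(ds, design, spec)
  v0 <- pack_init(spec, init_p, init_ie_p, init_ie_m, init_iiv, init_res)
  f <- make_nll(subjects, spec, init_p, init_ie_p, init_ie_m, init_iiv,
                init_res, settings)
  # central-difference gradient with a step large enough to dominate the
  # inner-optimization noise floor (nlminb's internal steps are too small)
  gr <- function(x) {
    h <- settings$grad_step
    g <- numeric(length(x))
    for (i in seq_along(x)) {
      e <- replace(numeric(length(x)), i, h)
      g[i] <- (f(x + e) - f(x - e)) / (2 * h)
    }
    g
  }
  ctrl <- list(iter.max = settings$outer_maxit,
               rel.tol = settings$outer_reltol)
  opt <- nlminb(v0, f, gradient = gr, control = ctrl)
  tries <- 0L
  while (opt$convergence != 0 && tries < settings$restarts) {
    # "false convergence" is usually the quasi-Newton model tripping on the
    # inner-search noise floor; restarting from the stopping point with a
    # fresh Hessian model typically clears it
    tries <- tries + 1L
    opt <- nlminb(opt$par, f, gradient = gr, control = ctrl)
  }
  par <- setNames(opt$par, names(v0))
  u <- unpack_par(par, spec, init_p, init_ie_p, init_ie_m, init_iiv, init_res)
  est <- exp(par)
  names(est) <- sub("^log_", "", names(par))
  if (spec$estimate_corr)
    est[["z_corr_IE"]] <- tanh(par[["z_corr_IE"]])
  structure(list(par = par, estimates = est, params = u$p,
                 ie_p = u$ie_p, ie_m = u$ie_m, Omega = u$Omega,
                 sig_p = u$sig_p, sig_m = u$sig_m,
                 objective = opt$objective,
                 converged = opt$convergence == 0,
                 message = opt$message, nll = f, spec = spec,
                 settings = settings, n_subjects = length(subjects)),
            class = "ddi_fit")
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat(sprintf("Laplace mixed-effects fit (%s analytes, %d subjects)\n",
              x$spec$analytes, x$n_subjects))
  cat(sprintf("  -2LL = %.3f, converged: %s (%s)\n", x$objective,
              x$converged, x$message))
  print(round(x$estimates, 4))
  invisible(x)
}

# central-difference Hessian of a scalar function
fd_hessian <- function(f, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(p), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Standard errors and RSEs of a fit
#'
#' From the observed information: the finite-difference Hessian of the
#' -2 log marginal likelihood at the optimum. Parameters are estimated on
#' the log scale, so `RSE(%) = 100 * SE(log parameter)` by the delta
#' method. A non-invertible Hessian is flagged with `ok = FALSE` and `NA`
#' standard errors.
#'
#' @param fit a [fit_nlme()] result.
#' @param h finite-difference step on the log-parameter scale.
#' @return A `data.frame` with `parameter`, `estimate`, `se`, `rse`
#'   (percent), and attribute `ok`.
#' @export
standard_errors <- function(fit, h = 1e-3) {
  stopifnot(inherits(fit, "ddi_fit"))
  if (!fit$converged)
    warning("standard errors from a non-converged fit")
  H <- fd_hessian(fit$nll, fit$par, h)
  cov <- tryCatch(2 * solve(H), error = function(e) NULL)
  ok <- !is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) > 0)
  se_log <- if (ok) sqrt(diag(cov)) else rep(NA_real_, length(fit$par))
  est <- fit$estimates
  out <- data.frame(parameter = names(est), estimate = unname(est),
                    se = unname(est * se_log), rse = unname(100 * se_log))
  attr(out, "ok") <- ok
  attr(out, "cov_log") <- if (ok) cov else NULL
  out
}

#' Expected parameter precision at given parameter values
#'
#' RSEs from the observed information of the Laplace marginal likelihood
#' evaluated at supplied (for simulated data: true) parameter values --
#' no fitting involved. This is the standard design-evaluation measure of
#' how much information a dataset carries about each parameter under a
#' model variant, and is the stable way to compare the joint
#' (parent + metabolite) against the parent-only model when a full
#' maximum-likelihood fit of every parameter is too expensive or fragile.
#'
#' @inheritParams marginal_nll
#' @param h finite-difference step for the outer Hessian.
#' @return A `data.frame` with `parameter` and `rse` (%); entries are `NA`
#'   where the information matrix is not positive definite.
#' @export
expected_rse <- function(ds, design, p, ie_p = 1, ie_m = 1,
                         iiv = iiv_params(), res = residual_model(),
                         spec = model_spec(),
                         settings = estimation_settings(inner_hessian = "gn"),
                         h = 1e-3) {
  subjects <- prep_subjects(ds, design, spec)
  v <- pack_init(spec, p, ie_p, ie_m, iiv, res)
  f <- make_nll(subjects, spec, p, ie_p, ie_m, iiv, res, settings)
  H <- fd_hessian(f, v, h)
  cov <- tryCatch(2 * solve(H), error = function(e) NULL)
  rse <- if (is.null(cov)) rep(NA_real_, length(v)) else {
    dg <- diag(cov)
    ifelse(dg > 0, 100 * sqrt(pmax(dg, 0)), NA_real_)
  }
  data.frame(parameter = sub("^log_", "", names(v)), rse = unname(rse))
}

#' Model-based DDI prediction: relative average steady-state concentration
#'
#' The ratio of average steady-state concentrations with and without the
#' interaction equals the inverse clearance fold-change,
#' `relCavg,ss = CL_apparent / CL_apparent^IE = 1 / IE_apparent`, per
#' analyte (identical to the ratio of weekly AUC at steady state).
#'
#' @param fit a [fit_nlme()] result (or a list with `ie_p`/`ie_m`).
#' @return Named vector `c(parent =, metab =)`; metabolite entry `NA` for
#'   parent-only fits.
#' @export
rel_cavg_ss <- function(fit) {
  ie_p <- fit$ie_p
  ie_m <- if (!is.null(fit$spec) && fit$spec$analytes == "parent") NA_real_
          else fit$ie_m
  if (!is.finite(ie_p) || ie_p <= 0) stop("nonpositive IE estimate")
  c(parent = 1 / ie_p, metab = if (is.na(ie_m)) NA_real_ else 1 / ie_m)
}

#' Pathway-specific interaction effect
#'
#' Converts the apparent clearance fold-change into the fold-change of the
#' affected pathway when only a fraction `fm` of the parent is eliminated
#' through it: `IE_specific = (IE_apparent + fm - 1) / fm`.
#'
#' @param ie_apparent apparent clearance fold-change (> 0).
#' @param fm fraction eliminated via the affected pathway, in (0, 1].
#' @return `IE_specific`; values <= 0 are flagged as an inconsistent `fm`.
#' @export
ie_specific <- function(ie_apparent, fm) {
  if (any(fm <= 0) || any(fm > 1)) stop("fm must be in (0, 1]")
  out <- (ie_apparent + fm - 1) / fm
  if (any(out <= 0))
    warning("IE_specific <= 0: fm inconsistent with the apparent effect")
  out
}
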
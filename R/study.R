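#' True relative steady-state exposure under a scenario
#'
#' The interaction changes the apparent clearances by factors
#' (`ie_p`, `ie_m`); the true relative average steady-state concentration is
#' their inverse for each analyte (with `F = fm = 1`).
#'
#' @param scen an [interaction_scenario()].
#' @return Named vector `c(parent =, metab =)`.
#' @export
true_rel_cavg_ss <- function(scen) {
  stopifnot(inherits(scen, "ddi_scenario"))
  c(parent = 1 / scen$ie_p, metab = 1 / scen$ie_m)
}

#' Named PK variability scenarios
#'
#' `"original"`: the originally estimated IIV magnitudes (24/19% CV on
#' clearances, 21/28% on interaction effects, 75% IE correlation);
#' `"high_cl_iiv"`: 50% CV on both clearances; `"high_ie_iiv"`: 50% CV on
#' both interaction effects.
#'
#' @param name scenario name.
#' @return An [iiv_params()] object.
#' @export
pk_scenario <- function(name = c("original", "high_cl_iiv", "high_ie_iiv")) {
  name <- match.arg(name)
  switch(name,
         original = iiv_params(),
         high_cl_iiv = iiv_params(cv_cl_p = 50, cv_cl_m = 50),
         high_ie_iiv = iiv_params(cv_ie_p = 50, cv_ie_m = 50))
}

#' Scenario grid for a bias/precision study
#'
#' @param designs design names (see [make_design()]).
#' @param pk_scenarios PK variability scenario names (see [pk_scenario()]).
#' @param ie_factors population clearance fold-changes to simulate.
#' @param n_trials replicate trials per cell (the reference analysis used
#'   100; the desk-scale default is 20).
#' @param base_seed integer; trial t of cell c uses seed
#'   `base_seed + 1000 * (c - 1) + t`, so any cell/trial is replayable.
#' @return An object of class `ddi_grid`.
#' @export
scenario_grid <- function(designs = "sequential",
                          pk_scenarios = "original",
                          ie_factors = c(0.2, 0.5, 1, 2, 5),
                          n_trials = 20, base_seed = 20150L) {
  cells <- expand.grid(design = designs, pk_scenario = pk_scenarios,
                       ie = ie_factors, stringsAsFactors = FALSE)
  structure(list(cells = cells, n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed)), class = "ddi_grid")
}

#' Run the bias/precision study
#'
#' For every grid cell and replicate trial: simulate the trial, analyse it
#' with NCA (GMR of windowed AUC and of extrapolated AUC(0, inf)) and
#' optionally with model-based re-estimation (joint parent+metabolite and
#' parent-only variants), then aggregate per cell into bias and spread of
#' the DDI prediction against the true relative steady-state exposure.
#' Bias is `100 * (predicted - true) / true` of the cell's central value
#' (median across trials; the mean is also reported).
#'
#' @param grid a [scenario_grid()].
#' @param p structural parameters (the calibrated fixture, typically).
#' @param methods subset of `c("nca", "model")`. Model-based analysis costs
#'   roughly a minute per trial and variant; NCA is near-instant.
#' @param res residual model.
#' @param spec,settings model-based analysis controls (see [model_spec()],
#'   [estimation_settings()]); initial values are the truth perturbed by
#'   `init_factor`.
#' @param init_factor multiplicative perturbation of the true values used
#'   as initial estimates.
#' @param window NCA AUC window (h).
#' @param keep_trials return the per-trial table as attribute `trials`?
#' @return A `data.frame` with one row per cell x method x analyte:
#'   central predictions, true value, bias (%), interquartile and 90%
#'   ranges, failure counts. Attribute `trials` (optional) has the
#'   trial-level results.
#' @export
run_study <- function(grid, p, methods = c("nca", "model"),
                      res = residual_model(), spec = model_spec(),
                      settings = estimation_settings(), init_factor = 1.2,
                      window = 336, keep_trials = TRUE) {
  stopifnot(inherits(grid, "ddi_grid"))
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list(); kk <- 0L
  for (ci in seq_len(nrow(grid$cells))) {
    cell <- grid$cells[ci, ]
    design <- make_design(cell$design)
    iiv <- pk_scenario(cell$pk_scenario)
    scen <- interaction_scenario(cell$ie)
    for (tr in seq_len(grid$n_trials)) {
      seed <- grid$base_seed + 1000L * (ci - 1L) + tr
      ds <- simulate_trial(design, p, iiv, scen, res, seed = seed)
      rec <- data.frame(cell = ci, design = cell$design,
                        pk_scenario = cell$pk_scenario, ie = cell$ie,
                        trial = tr, seed = seed)
      if ("nca" %in% methods) {
        nca <- nca_dataset(ds, window = window)
        for (an in c("parent", "metab")) {
          rec[[paste0("nca_auc_window_", an)]] <-
            tryCatch(as.numeric(trial_gmr(nca, "auc_window", an)),
                     error = function(e) NA_real_)
          rec[[paste0("nca_auc_inf_", an)]] <-
            tryCatch(as.numeric(trial_gmr(nca, "auc_inf", an)),
                     error = function(e) NA_real_)
        }
      }
      if ("model" %in% methods) {
        fit <- tryCatch(
          fit_nlme(ds, design,
                   init_p = perturb_params(p, init_factor, spec$estimate),
                   init_ie_p = cell$ie * init_factor,
                   init_ie_m = cell$ie * init_factor,
                   init_iiv = iiv, init_res = res, spec = spec,
                   settings = settings),
          error = function(e) NULL)
        if (!is.null(fit) && fit$converged) {
          rel <- rel_cavg_ss(fit)
          rec$model_rel_parent <- rel[["parent"]]
          rec$model_rel_metab <- rel[["metab"]]
        } else {
          rec$model_rel_parent <- NA_real_
          rec$model_rel_metab <- NA_real_
        }
      }
      kk <- kk + 1L
      rows[[kk]] <- rec
    }
  }
  trials <- do.call(rbind, rows)
  summ <- summarize_study(trials, window_label = window)
  if (keep_trials) attr(summ, "trials") <- trials
  summ
}

# perturb only the parameters the spec estimates: the rest stay at the truth
# (perturbing a fixed parameter would misspecify, not initialize, the model)
perturb_params <- function(p, factor = 1.2, which = ALL_ESTIMABLE) {
  q <- p
  for (nm in which) q[[nm]] <- p[[nm]] * factor
  q
}

# cell-level bias/spread table from the trial-level table
summarize_study <- function(trials, window_label = 336) {
  method_cols <- list(
    `NCA-AUCwindow` = c(parent = "nca_auc_window_parent",
                        metab = "nca_auc_window_metab"),
    `NCA-AUCinf` = c(parent = "nca_auc_inf_parent",
                     metab = "nca_auc_inf_metab"),
    `model-based` = c(parent = "model_rel_parent", metab = "model_rel_metab"))
  out <- list(); kk <- 0L
  for (ci in unique(trials$cell)) {
    d <- trials[trials$cell == ci, ]
    truth <- true_rel_cavg_ss(interaction_scenario(d$ie[1]))
    for (m in names(method_cols)) {
      for (an in c("parent", "metab")) {
        col <- method_cols[[m]][[an]]
        if (!col %in% names(d)) next
        v <- d[[col]]
        nfail <- sum(!is.finite(v))
        v <- v[is.finite(v)]
        if (!length(v)) next
        tv <- truth[[an]]
        kk <- kk + 1L
        out[[kk]] <- data.frame(
          design = d$design[1], pk_scenario = d$pk_scenario[1], ie = d$ie[1],
          method = m, analyte = an, n_trials = length(v), n_failed = nfail,
          true_rel = tv, pred_median = median(v), pred_mean = mean(v),
          bias_median = 100 * (median(v) - tv) / tv,
          bias_mean = 100 * (mean(v) - tv) / tv,
          iqr_lo = quantile(v, 0.25, names = FALSE),
          iqr_hi = quantile(v, 0.75, names = FALSE),
          lo90 = quantile(v, 0.05, names = FALSE),
          hi90 = quantile(v, 0.95, names = FALSE))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Precision gain from metabolite data
#'
#' Fits the joint (parent + metabolite) and the parent-only model to the
#' same simulated trials and compares the RSE of the interaction-effect
#' parameter on the parent clearance. Paired per trial; trials where either
#' variant fails are excluded with a count.
#'
#' @param p structural parameters.
#' @param design a [make_design()] object.
#' @param scen interaction scenario.
#' @param iiv,res variability models.
#' @param n_trials number of replicate trials.
#' @param base_seed seed policy as in [scenario_grid()].
#' @param settings estimation settings.
#' @param init_factor initial-value perturbation of the truth.
#' @param joint_spec,parent_spec the two [model_spec()] variants compared.
#' @return A `data.frame` per trial with `rse_joint`, `rse_parent_only`,
#'   `ratio`, plus attribute `n_excluded`.
#' @export
rse_comparison <- function(p, design, scen = interaction_scenario(0.5),
                           iiv = iiv_params(), res = residual_model(),
                           n_trials = 3, base_seed = 400L,
                           settings = estimation_settings(),
                           init_factor = 1.2,
                           joint_spec = model_spec("both"),
                           parent_spec = model_spec("parent")) {
  rows <- list(); excl <- 0L
  for (tr in seq_len(n_trials)) {
    ds <- simulate_trial(design, p, iiv, scen, res, seed = base_seed + tr)
    one <- function(sp) {
      fit <- fit_nlme(ds, design,
                      init_p = perturb_params(p, init_factor, sp$estimate),
                      init_ie_p = scen$ie_p * init_factor,
                      init_ie_m = scen$ie_m * init_factor,
                      init_iiv = iiv, init_res = res, spec = sp,
                      settings = settings)
      se <- standard_errors(fit)
      se$rse[se$parameter == "IE_P"]
    }
    rj <- tryCatch(one(joint_spec), error = function(e) NA_real_)
    rp <- tryCatch(one(parent_spec), error = function(e) NA_real_)
    if (!is.finite(rj) || !is.finite(rp)) { excl <- excl + 1L; next }
    rows[[length(rows) + 1L]] <-
      data.frame(trial = tr, rse_joint = rj, rse_parent_only = rp,
                 ratio = rp / rj)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all trials failed in rse_comparison")
  attr(out, "n_excluded") <- excl
  out
}
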
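# clearance timeline seen by one arm of a design under a scenario; the
# individual eta multipliers enter through mult when IE is active
arm_timeline <- function(design, scen, arm, ie_p_i, ie_m_i) {
  covered <- covered_dose_time(design) + scen$onset
  if (design$type == "sequential" || arm == "treated") {
    first_dose <- design$dose_times[1]
    if (covered <= first_dose) {
      # active over the whole profile
      clearance_timeline(numeric(0), ie_p_i, ie_m_i)
    } else {
      clearance_timeline(covered, c(1, ie_p_i), c(1, ie_m_i))
    }
  } else {
    clearance_timeline()                       # control arm: never active
  }
}

subject_params <- function(p, weight, eta_cl_p, eta_cl_m) {
  pi <- scale_allometric(p, weight)
  pi$CL_P <- pi$CL_P * exp(eta_cl_p)
  pi$CL_M <- pi$CL_M * exp(eta_cl_m)
  pi
}

#' Simulate one DDI trial
#'
#' Draws subjects (weights, correlated random effects), computes each
#' subject's exact concentration profile under the design's dosing/sampling
#' schedule and the scenario's clearance timeline, and applies proportional
#' residual error. Individual clearances are
#' `CL_pop * (WT/WT_ref)^0.75 * exp(eta_CL)`, multiplied while the
#' interaction is active by `ie * exp(eta_IE)`.
#'
#' In a sequential design the perpetrator covers period 2 (carry-over from
#' dose 1 is present in the period-2 samples); in a parallel design the
#' treated arm is covered throughout and the parallel arms are matched on
#' body weight (one weight vector assigned to both arms). True
#' pre-first-dose samples are recorded as noise-free zeros with `MDV = 1`.
#'
#' @param design a [make_design()] object.
#' @param p population [structural_params()].
#' @param iiv an [iiv_params()] object.
#' @param scen an [interaction_scenario()].
#' @param res a [residual_model()].
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return A long-format `data.frame` (NONMEM layout) with columns
#'   `ID, TIME, DV, AMT, EVID, CMT, MDV, WT, PERIOD, ARM`; `CMT` is 1 for
#'   dose records (first transit/depot), 2 for parent and 3 for metabolite
#'   observations. Units: h, mg, mg/L.
#' @export
simulate_trial <- function(design, p, iiv = iiv_params(),
                           scen = interaction_scenario(1),
                           res = residual_model(), seed = 1L) {
  stopifnot(inherits(design, "ddi_design"), inherits(p, "pk_params"),
            inherits(scen, "ddi_scenario"), inherits(res, "ddi_resid"))
  set.seed(as.integer(seed))
  n <- design$n_subjects
  subj <- sample_subjects(n, iiv)
  arms <- design_arms(design)
  if (design$type == "parallel") {
    # weight matching: both arms get the same weight vector
    half <- n / 2
    subj$weight[seq_len(half) + half] <- subj$weight[seq_len(half)]
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- subject_params(p, subj$weight[i], subj$eta_cl_p[i], subj$eta_cl_m[i])
    tl <- arm_timeline(design, scen, arms[i],
                       scen$ie_p * exp(subj$eta_ie_p[i]),
                       scen$ie_m * exp(subj$eta_ie_m[i]))
    doses <- dose_events(design$dose_times, design$dose_amt)
    obs_t <- as.vector(outer(design$sample_rel, design$dose_times, `+`))
    period <- rep(seq_along(design$dose_times), each = length(design$sample_rel))
    ord <- order(obs_t)
    obs_t <- obs_t[ord]; period <- period[ord]
    pr <- pk_predict(pi, doses, obs_t, tl)

    f <- c(pr$conc_parent, pr$conc_metab)
    analyte <- rep(1:2, each = length(obs_t))
    cv <- ifelse(analyte == 1, res$cv_p, res$cv_m) / 100
    add <- ifelse(analyte == 1, res$add_p, res$add_m)
    eps <- rnorm(length(f))
    dv <- f * (1 + cv * eps) + add * rnorm(length(f))
    predose <- f == 0                       # true pre-first-dose samples
    dv[predose] <- 0

    obs <- data.frame(ID = subj$id[i], TIME = rep(obs_t, 2), DV = dv,
                      AMT = 0, EVID = 0L, CMT = analyte + 1L,
                      MDV = as.integer(predose), WT = subj$weight[i],
                      PERIOD = rep(period, 2), ARM = arms[i])
    dose_period <- seq_along(design$dose_times)
    dos <- data.frame(ID = subj$id[i], TIME = design$dose_times, DV = NA_real_,
                      AMT = design$dose_amt, EVID = 1L, CMT = 1L, MDV = 1L,
                      WT = subj$weight[i], PERIOD = dose_period, ARM = arms[i])
    rec <- rbind(dos, obs)
    # dose records precede observations at the same timestamp only for the
    # record ordering; the engine treats same-time observations as pre-dose
    rec <- rec[order(rec$TIME, rec$EVID, rec$CMT), ]
    out[[i]] <- rec
  }
  ds <- do.call(rbind, out)
  rownames(ds) <- NULL
  attr(ds, "design") <- design$name
  validate_dataset(ds)
  ds
}

#' Validate a long-format PK dataset
#'
#' Checks the dataset invariants: required columns, non-decreasing times
#' within subject, and that every observation is preceded by a dose for its
#' subject unless it is a true pre-first-dose sample (then `DV = 0`,
#' `MDV = 1`).
#'
#' @param ds a dataset as returned by [simulate_trial()].
#' @return `ds` invisibly; errors on violation.
#' @export
validate_dataset <- function(ds) {
  need <- c("ID", "TIME", "DV", "AMT", "EVID", "CMT", "MDV", "WT", "PERIOD",
            "ARM")
  miss <- setdiff(need, names(ds))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  for (id in unique(ds$ID)) {
    d <- ds[ds$ID == id, ]
    if (is.unsorted(d$TIME)) stop("times not non-decreasing for subject ", id)
    first_dose <- suppressWarnings(min(d$TIME[d$EVID == 1]))
    pre <- d$EVID == 0 & d$TIME <= first_dose
    bad <- pre & (d$MDV != 1 | (!is.na(d$DV) & d$DV != 0))
    if (any(bad)) stop("pre-first-dose sample not a noise-free zero, subject ",
                       id)
  }
  invisible(ds)
}

#' Read / write a PK dataset as NONMEM-compatible CSV
#'
#' Missing `DV` on dose records is written as `.`; numeric columns keep full
#' double precision so a write/read cycle is lossless.
#'
#' @param ds a dataset (see [simulate_trial()]).
#' @param path file path.
#' @return `read_pk_dataset()` returns the dataset `data.frame`;
#'   `write_pk_dataset()` returns `path` invisibly.
#' @export
write_pk_dataset <- function(ds, path) {
  out <- ds
  num <- c("TIME", "DV", "AMT", "WT")
  for (nm in num)
    out[[nm]] <- ifelse(is.na(out[[nm]]), ".",
                        formatC(out[[nm]], format = "g", digits = 17))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pk_dataset
#' @export
read_pk_dataset <- function(path) {
  ds <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("TIME", "DV", "AMT", "WT"))
    ds[[nm]] <- suppressWarnings(as.numeric(ifelse(ds[[nm]] == ".", NA,
                                                   ds[[nm]])))
  for (nm in c("ID", "EVID", "CMT", "MDV", "PERIOD"))
    ds[[nm]] <- as.integer(ds[[nm]])
  validate_dataset(ds)
  ds
}
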
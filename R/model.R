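#' Piecewise-constant clearance timeline
#'
#' Describes when and how strongly an interaction perturbs the parent and
#' metabolite clearances. Interval i covers `[switch_times[i-1],
#' switch_times[i])`; the first interval starts at minus infinity. A
#' multiplier of 1 is the no-interaction state.
#'
#' @param switch_times sorted vector of switch times (h); may be empty.
#' @param mult_p,mult_m strictly positive multipliers on CL_P and CL_M, one
#'   per interval (`length(switch_times) + 1`).
#' @return An object of class `ddi_timeline`.
#' @export
clearance_timeline <- function(switch_times = numeric(0), mult_p = 1,
                               mult_m = 1) {
  k <- length(switch_times)
  if (k && is.unsorted(switch_times, strictly = TRUE))
    stop("switch_times must be strictly increasing")
  if (length(mult_p) == 1) mult_p <- rep(mult_p, k + 1)
  if (length(mult_m) == 1) mult_m <- rep(mult_m, k + 1)
  if (length(mult_p) != k + 1 || length(mult_m) != k + 1)
    stop("need one multiplier per interval (length(switch_times) + 1)")
  if (any(mult_p <= 0) || any(mult_m <= 0)) stop("multipliers must be > 0")
  structure(list(switch_times = as.numeric(switch_times),
                 mult_p = as.numeric(mult_p), mult_m = as.numeric(mult_m)),
            class = "ddi_timeline")
}

#' Dose events
#'
#' @param time dose times (h), non-decreasing.
#' @param amt dose amounts (mg), non-negative; recycled against `time`.
#' @return A `data.frame` with columns `time` and `amt`.
#' @export
dose_events <- function(time, amt = 400) {
  if (length(time) && is.unsorted(time)) stop("dose times must be non-decreasing")
  amt <- rep_len(amt, length(time))
  if (any(amt < 0)) stop("dose amounts must be non-negative")
  data.frame(time = as.numeric(time), amt = as.numeric(amt))
}

#' Rate matrix of the linear system
#'
#' Returns the ODE system matrix \eqn{dx/dt = A x} of dimension
#' `NTR + 1 + 3 + 2` with named rows/columns: the transit chain, the depot,
#' parent central/peripheral and metabolite central/peripheral compartments.
#' Column sums of the transfer part vanish; only elimination terms remove
#' mass, so all eigenvalues have non-positive real part.
#'
#' @param p a [structural_params()] object.
#' @param mult_p,mult_m clearance multipliers applied to CL_P and CL_M.
#' @return A square numeric matrix (1/h).
#' @export
build_system <- function(p, mult_p = 1, mult_m = 1) {
  stopifnot(inherits(p, "pk_params"))
  A <- rate_matrix_cpp(as_theta(p), mult_p, mult_m)
  nm <- c(if (p$NTR > 0) paste0("transit", seq_len(p$NTR)), "depot",
          "parent_c", "parent_p2", "parent_p3", "metab_c", "metab_p")
  dimnames(A) <- list(nm, nm)
  A
}

state_names <- function(p) colnames(build_system(p))

#' Predict concentration-time profiles
#'
#' Exact solution of the linear system: the state is propagated with matrix
#' exponentials over every interval on which the clearance timeline is
#' constant, dose events add `amt * F` to the first transit (or depot)
#' compartment, and concentrations are amounts over central volumes.
#' An observation coinciding with a dose time is a pre-dose sample.
#'
#' @param p a [structural_params()] object.
#' @param doses a [dose_events()] data frame (possibly empty).
#' @param times observation times (h), sorted non-decreasing.
#' @param timeline a [clearance_timeline()]; default: no interaction.
#' @return A `data.frame` with columns `time`, `conc_parent`, `conc_metab`
#'   (mg/L).
#' @export
pk_predict <- function(p, doses, times, timeline = clearance_timeline()) {
  stopifnot(inherits(p, "pk_params"), inherits(timeline, "ddi_timeline"))
  if (is.unsorted(times)) stop("observation times must be sorted")
  r <- pk_profile_cpp(as_theta(p), doses$time, doses$amt,
                      timeline$switch_times, timeline$mult_p,
                      timeline$mult_m, as.numeric(times), 0, 0, FALSE)
  data.frame(time = as.numeric(times), conc_parent = r$conc_parent,
             conc_metab = r$conc_metab)
}

#' Exact model AUC over a window
#'
#' Integrates the model concentrations over `[t1, t2]` through the
#' integrated matrix-exponential system (no quadrature error). With constant
#' clearances the infinite integrals reduce to `F*Dose/CL_P` for the parent
#' and `F*fm*Dose/CL_M` for the metabolite.
#'
#' @inheritParams pk_predict
#' @param t1,t2 window bounds (h); `t2` may be `Inf`.
#' @return Named numeric vector `c(parent =, metab =)` in mg*h/L.
#' @export
auc_model <- function(p, doses, t1 = 0, t2 = Inf,
                      timeline = clearance_timeline()) {
  stopifnot(inherits(p, "pk_params"), inherits(timeline, "ddi_timeline"))
  if (!(t1 < t2)) stop("need t1 < t2")
  r <- pk_profile_cpp(as_theta(p), doses$time, doses$amt,
                      timeline$switch_times, timeline$mult_p,
                      timeline$mult_m, numeric(0), t1, t2, TRUE)
  c(parent = r$auc_parent, metab = r$auc_metab)
}

#' True terminal half-life of the disposition system
#'
#' `ln(2)/|lambda_min|` where `lambda_min` is the smallest-magnitude nonzero
#' eigenvalue of the post-absorption (disposition) system, i.e. the parent
#' and metabolite compartments only.
#'
#' @param p a [structural_params()] object.
#' @param tol relative tolerance used to flag (error on) nearly repeated
#'   slow eigenvalues, for which a single terminal slope is ill-defined.
#' @return Terminal half-life in hours.
#' @export
terminal_halflife <- function(p, tol = 1e-8) {
  stopifnot(inherits(p, "pk_params"))
  A <- build_system(p)
  idx <- (p$NTR + 2):(p$NTR + 6)
  ev <- eigen(A[idx, idx], only.values = TRUE)$values
  mag <- abs(Re(ev))
  mag <- sort(mag[mag > 1e-300])
  if (!length(mag)) stop("no elimination: terminal half-life undefined")
  if (length(mag) > 1 && (mag[2] - mag[1]) < tol * mag[1])
    stop("degenerate disposition system: repeated terminal eigenvalue")
  log(2) / mag[1]
}

#' Fraction of total AUC captured by a finite sampling window
#'
#' For a single dose with a constant interaction factor applied to both
#' clearances, returns `100 * AUC(0, window) / AUC(0, Inf)` per analyte.
#' Because a stronger interaction (larger clearance factor) speeds the
#' washout, this fraction increases with `ie_factor`.
#'
#' @param p a [structural_params()] object.
#' @param ie_factor constant multiplier on both clearances (> 0); 1 is the
#'   no-interaction baseline.
#' @param window window length (h), > 0.
#' @param dose dose amount (mg).
#' @return Named numeric vector `c(parent =, metab =)` in percent.
#' @export
fraction_observed <- function(p, ie_factor = 1, window = 336, dose = 400) {
  if (!is.finite(ie_factor) || ie_factor <= 0) stop("ie_factor must be > 0")
  if (!is.finite(window) || window <= 0) stop("window must be > 0")
  tl <- clearance_timeline(numeric(0), ie_factor, ie_factor)
  d <- dose_events(0, dose)
  100 * auc_model(p, d, 0, window, tl) / auc_model(p, d, 0, Inf, tl)
}
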
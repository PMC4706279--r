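#' Inter-individual variability parameters
#'
#' Lognormal IIV magnitudes, given as percent coefficients of variation, on
#' the parent and metabolite clearances and on the two interaction effects,
#' plus the correlation between the interaction-effect random effects. The
#' variance mapping is \eqn{\omega^2 = \ln(1 + (CV/100)^2)}.
#'
#' Defaults are the originally estimated magnitudes: 24/19% CV on the
#' clearances, 21/28% CV on the interaction effects, 75% IE correlation.
#'
#' @param cv_cl_p,cv_cl_m CV (%) of IIV on CL_P and CL_M.
#' @param cv_ie_p,cv_ie_m CV (%) of IIV on the interaction effects.
#' @param corr_ie correlation of the two IE random effects, in `[-1, 1]`.
#' @return An object of class `ddi_iiv`.
#' @export
iiv_params <- function(cv_cl_p = 24, cv_cl_m = 19, cv_ie_p = 21,
                       cv_ie_m = 28, corr_ie = 0.75) {
  cvs <- c(cv_cl_p, cv_cl_m, cv_ie_p, cv_ie_m)
  if (any(!is.finite(cvs)) || any(cvs < 0)) stop("CVs must be >= 0")
  if (!is.finite(corr_ie) || abs(corr_ie) > 1) stop("|corr_ie| must be <= 1")
  structure(list(cv_cl_p = cv_cl_p, cv_cl_m = cv_cl_m, cv_ie_p = cv_ie_p,
                 cv_ie_m = cv_ie_m, corr_ie = corr_ie), class = "ddi_iiv")
}

cv_to_omega2 <- function(cv) log(1 + (cv / 100)^2)

#' Random-effect covariance matrix from IIV parameters
#'
#' @param iiv an [iiv_params()] object.
#' @return 4x4 covariance matrix for the random effects on
#'   (CL_P, CL_M, IE_P, IE_M); the only off-diagonal element is the IE
#'   covariance. Errors if the matrix is not positive semi-definite.
#' @export
omega_matrix <- function(iiv) {
  stopifnot(inherits(iiv, "ddi_iiv"))
  w2 <- cv_to_omega2(c(iiv$cv_cl_p, iiv$cv_cl_m, iiv$cv_ie_p, iiv$cv_ie_m))
  O <- diag(w2)
  O[3, 4] <- O[4, 3] <- iiv$corr_ie * sqrt(w2[3] * w2[4])
  dimnames(O) <- list(c("CL_P", "CL_M", "IE_P", "IE_M"),
                      c("CL_P", "CL_M", "IE_P", "IE_M"))
  if (any(eigen(O, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop("invalid Omega: not positive semi-definite")
  O
}

#' Sample trial subjects
#'
#' Draws body weights (lognormal; `median_wt` median, `cv_wt`% CV) and
#' random-effect vectors from `N(0, Omega)` built by [omega_matrix()].
#' Degenerate zero-variance components yield exactly zero etas.
#'
#' @param n number of subjects (>= 1).
#' @param iiv an [iiv_params()] object.
#' @param median_wt,cv_wt weight distribution parameters (kg, %).
#' @param seed optional integer seed for reproducibility.
#' @return A `data.frame` with columns `id`, `weight`, `eta_cl_p`,
#'   `eta_cl_m`, `eta_ie_p`, `eta_ie_m`.
#' @export
sample_subjects <- function(n, iiv = iiv_params(), median_wt = 70, cv_wt = 15,
                            seed = NULL) {
  if (n < 1) stop("need n >= 1")
  if (!is.null(seed)) set.seed(seed)
  O <- omega_matrix(iiv)
  wt <- exp(rnorm(n, log(median_wt), sqrt(cv_to_omega2(cv_wt))))
  eta <- mvn_chol(n, O)
  data.frame(id = seq_len(n), weight = wt,
             eta_cl_p = eta[, 1], eta_cl_m = eta[, 2],
             eta_ie_p = eta[, 3], eta_ie_m = eta[, 4])
}

# MVN draws via pivoted Cholesky, tolerant of zero-variance components
mvn_chol <- function(n, O) {
  q <- ncol(O)
  z <- matrix(rnorm(n * q), n, q)
  sd0 <- sqrt(diag(O))
  act <- which(sd0 > 0)
  out <- matrix(0, n, q)
  if (length(act)) {
    L <- t(chol(O[act, act, drop = FALSE] +
                  diag(1e-12 * max(sd0)^2, length(act))))
    out[, act] <- z[, act, drop = FALSE] %*% t(L)
  }
  out
}

#' Interaction scenario
#'
#' Population fold-change of the parent and metabolite clearances caused by
#' the perpetrator (e.g. 0.2 and 0.5 for inhibition, 2 and 5 for induction,
#' 1 for no interaction), with the onset time relative to the
#' perpetrator-covered dose. The default onset of -168 h means the effect is
#' fully established one week before that dose.
#'
#' @param ie_p,ie_m clearance fold-changes (> 0). `ie_m` defaults to `ie_p`
#'   (same magnitude on both analytes).
#' @param onset onset time (h) relative to the covered dose.
#' @return An object of class `ddi_scenario`.
#' @export
interaction_scenario <- function(ie_p, ie_m = ie_p, onset = -168) {
  if (!is.finite(ie_p) || ie_p <= 0 || !is.finite(ie_m) || ie_m <= 0)
    stop("interaction factors must be > 0")
  structure(list(ie_p = ie_p, ie_m = ie_m, onset = onset),
            class = "ddi_scenario")
}

#' Residual error model
#'
#' Proportional (and optionally additive) residual unexplained variability
#' per analyte. The main source does not state the original residual model;
#' the 15% CV default reflects typical LC-MS/MS assay performance.
#'
#' @param cv_p,cv_m proportional CV (%) for parent and metabolite.
#' @param add_p,add_m additive SD (mg/L), default 0.
#' @return An object of class `ddi_resid`.
#' @export
residual_model <- function(cv_p = 15, cv_m = 15, add_p = 0, add_m = 0) {
  v <- c(cv_p, cv_m, add_p, add_m)
  if (any(!is.finite(v)) || any(v < 0)) stop("residual magnitudes must be >= 0")
  structure(list(cv_p = cv_p, cv_m = cv_m, add_p = add_p, add_m = add_m),
            class = "ddi_resid")
}
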
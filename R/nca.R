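#' Trapezoidal AUC
#'
#' Default `"linuplogdown"`: linear trapezoid on rising or flat segments,
#' log trapezoid on strictly falling segments with positive endpoints;
#' `"linear"` uses linear trapezoids everywhere.
#'
#' @param times sorted sampling times (h).
#' @param conc non-negative concentrations (mg/L).
#' @param method `"linuplogdown"` (default) or `"linear"`.
#' @return AUC in mg*h/L.
#' @export
auc_trapezoid <- function(times, conc, method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  if (length(times) < 2) stop("need at least 2 points")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(conc < 0) || any(is.na(conc))) stop("concentrations must be >= 0")
  dt <- diff(times)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linuplogdown") {
    dn <- c2 < c1 & c2 > 0
    seg[dn] <- (c1[dn] - c2[dn]) / log(c1[dn] / c2[dn]) * dt[dn]
  }
  sum(seg)
}

#' Terminal slope selection by adjusted R-squared
#'
#' Fits ordinary least squares of `log(conc)` against time on every
#' candidate set of the last `n` observations after Tmax (the Tmax point
#' excluded, `n >= 3`, non-positive concentrations dropped) and selects the
#' candidate maximizing adjusted R-squared among those with a negative
#' slope; ties go to the larger `n`.
#'
#' @param times sorted sampling times (h).
#' @param conc concentrations (mg/L).
#' @return A list with `lambda_z` (1/h), `n_points`, `adj_r2`, `t_half` (h);
#'   `lambda_z` is `NA` (flagged) when no candidate has a negative slope.
#' @export
fit_lambda_z <- function(times, conc) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  imax <- which.max(conc)
  keep <- seq_along(times) > imax & conc > 0
  tt <- times[keep]; cc <- log(conc[keep])
  m <- length(tt)
  failed <- list(lambda_z = NA_real_, n_points = NA_integer_,
                 adj_r2 = NA_real_, t_half = NA_real_)
  if (m < 3) return(failed)
  best <- NULL
  for (n in 3:m) {
    i <- (m - n + 1):m
    x <- tt[i]; y <- cc[i]
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) next
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 1
    ar2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
    if (is.null(best) || ar2 > best$adj_r2 + 1e-12 ||
        (abs(ar2 - best$adj_r2) <= 1e-12 && n > best$n_points)) {
      best <- list(lambda_z = -as.numeric(slope), n_points = n,
                   adj_r2 = ar2, t_half = log(2) / -as.numeric(slope))
    }
  }
  if (is.null(best)) failed else best
}

#' Non-compartmental summary of one profile
#'
#' @param times sorted sampling times (h), relative to the period's dose.
#' @param conc concentrations (mg/L).
#' @param window AUC window (h), default 336.
#' @param method trapezoid method, see [auc_trapezoid()].
#' @return One-row `data.frame`: `cmax`, `tmax`, `auc_window`, `auc_last`,
#'   `lambda_z`, `n_points`, `adj_r2`, `t_half`, `auc_inf`,
#'   `extrap_frac` (%). `auc_inf = auc_last + C_last_observed / lambda_z`;
#'   it is `NA` when the terminal slope is undefined.
#' @export
nca_profile <- function(times, conc, window = 336,
                        method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  in_win <- times <= window + 1e-9
  auc_w <- auc_trapezoid(times[in_win], conc[in_win], method)
  auc_last <- auc_trapezoid(times, conc, method)
  lz <- fit_lambda_z(times, conc)
  clast <- conc[length(conc)]
  auc_inf <- if (is.na(lz$lambda_z)) NA_real_ else auc_last + clast / lz$lambda_z
  data.frame(cmax = max(conc), tmax = times[which.max(conc)],
             auc_window = auc_w, auc_last = auc_last,
             lambda_z = lz$lambda_z, n_points = lz$n_points,
             adj_r2 = lz$adj_r2, t_half = lz$t_half, auc_inf = auc_inf,
             extrap_frac = if (is.na(auc_inf)) NA_real_ else
               100 * (auc_inf - auc_last) / auc_inf)
}

#' NCA over a simulated dataset
#'
#' Runs [nca_profile()] for every subject/period/analyte, with times taken
#' relative to the period's dose. The period-2 pre-dose sample enters as the
#' `t = 0` point (no carry-over subtraction; set `subtract_carryover = TRUE`
#' to subtract the extrapolated period-1 tail, a correction that is
#' unreliable exactly because the terminal slope is poorly estimated).
#'
#' @param ds a dataset from [simulate_trial()] or [read_pk_dataset()].
#' @param window,method see [nca_profile()].
#' @param subtract_carryover subtract the lambda-z-extrapolated previous-dose
#'   tail from later-period concentrations before analysis (off by default).
#' @return Tidy `data.frame`, one row per subject/period/analyte, with the
#'   [nca_profile()] metrics plus `ID`, `PERIOD`, `ARM`, `analyte`.
#' @export
nca_dataset <- function(ds, window = 336, method = "linuplogdown",
                        subtract_carryover = FALSE) {
  validate_dataset(ds)
  out <- list()
  k <- 0L
  for (id in unique(ds$ID)) {
    d <- ds[ds$ID == id, ]
    for (per in sort(unique(d$PERIOD[d$EVID == 0]))) {
      dose_t <- d$TIME[d$EVID == 1 & d$PERIOD == per]
      if (!length(dose_t)) stop("no dose record for subject ", id,
                                " period ", per)
      for (an in c(1L, 2L)) {
        o <- d[d$EVID == 0 & d$PERIOD == per & d$CMT == an + 1L, ]
        if (!nrow(o)) next
        tt <- o$TIME - dose_t[1]
        cc <- o$DV
        if (subtract_carryover && per > 1) {
          prev <- d[d$EVID == 0 & d$PERIOD == per - 1L & d$CMT == an + 1L, ]
          pd <- d$TIME[d$EVID == 1 & d$PERIOD == per - 1L][1]
          lz <- fit_lambda_z(prev$TIME - pd, prev$DV)
          if (!is.na(lz$lambda_z)) {
            clast <- prev$DV[nrow(prev)]
            tlast <- prev$TIME[nrow(prev)]
            cc <- pmax(0, cc - clast * exp(-lz$lambda_z * (o$TIME - tlast)))
          }
        }
        cc[cc < 0] <- 0
        k <- k + 1L
        out[[k]] <- cbind(data.frame(ID = id, PERIOD = per, ARM = o$ARM[1],
                                     analyte = c("parent", "metab")[an]),
                          nca_profile(tt, cc, window = window, method = method))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

geomean <- function(x) exp(mean(log(x)))

#' Geometric mean ratio of an exposure metric for one trial
#'
#' Sequential designs: geometric mean over subjects of the period-2 over
#' period-1 metric ratio. Parallel designs: geometric mean of the treated
#' arm over the geometric mean of the control arm. Non-positive or missing
#' metric values are excluded; the number excluded is attached as attribute
#' `n_excluded`.
#'
#' @param nca a table from [nca_dataset()].
#' @param metric column name, e.g. `"auc_window"` or `"auc_inf"`.
#' @param analyte `"parent"` or `"metab"`.
#' @return The GMR (scalar) with attribute `n_excluded`.
#' @export
trial_gmr <- function(nca, metric = "auc_window", analyte = "parent") {
  x <- nca[nca$analyte == analyte, ]
  if (!metric %in% names(x)) stop("unknown metric: ", metric)
  sequentialp <- any(x$PERIOD > 1)
  nexc <- 0L
  if (sequentialp) {
    p1 <- x[x$PERIOD == 1, c("ID", metric)]
    p2 <- x[x$PERIOD == 2, c("ID", metric)]
    m <- merge(p1, p2, by = "ID", suffixes = c("_1", "_2"))
    v1 <- m[[paste0(metric, "_1")]]
    v2 <- m[[paste0(metric, "_2")]]
    ok <- is.finite(v1) & is.finite(v2) & v1 > 0 & v2 > 0
    nexc <- sum(!ok)
    if (!any(ok)) stop("no usable subject ratios")
    g <- geomean(v2[ok] / v1[ok])
  } else {
    if (!all(c("control", "treated") %in% x$ARM))
      stop("parallel GMR needs both a control and a treated arm")
    vt <- x[[metric]][x$ARM == "treated"]
    vc <- x[[metric]][x$ARM == "control"]
    okt <- is.finite(vt) & vt > 0
    okc <- is.finite(vc) & vc > 0
    nexc <- sum(!okt) + sum(!okc)
    if (!any(okt) || !any(okc)) stop("no usable arm values")
    g <- geomean(vt[okt]) / geomean(vc[okc])
  }
  structure(g, n_excluded = nexc)
}

#' Summarize GMRs across replicate trials
#'
#' Median and nonparametric 90% interval (empirical 5th/95th percentiles,
#' `quantile()` type 7) across trials.
#'
#' @param gmrs numeric vector of per-trial GMRs.
#' @param metric label carried through to the output.
#' @return One-row `data.frame`: `metric`, `n_trials`, `median`, `lo90`,
#'   `hi90`.
#' @export
summarize_trials <- function(gmrs, metric = "auc_window") {
  if (!length(gmrs)) stop("need at least one trial")
  q <- quantile(gmrs, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  data.frame(metric = metric, n_trials = length(gmrs),
             median = q[2], lo90 = q[1], hi90 = q[3])
}
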
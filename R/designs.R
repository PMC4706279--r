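# default rich sampling grid: 1 pre-dose + 16 post-dose samples per period,
# denser early (h post-dose)
DEFAULT_GRID <- c(1, 2, 3, 4, 5, 6, 8, 12, 24, 48, 72, 96, 120, 168, 240, 336)

#' DDI trial designs
#'
#' Encodes the evaluated single-dose DDI study designs:
#' \describe{
#'   \item{`sequential`}{16 subjects, two 400-mg doses 4 weeks (672 h)
#'     apart; period 1 without and period 2 with the perpetrator, whose
#'     effect on clearance is fully active from 1 week before dose 2.
#'     1 pre-dose + 16 samples over 336 h in each period.}
#'   \item{`parallel1`}{32 subjects, 16 per arm (control/treated), one dose,
#'     same 17-sample schedule, perpetrator active throughout the treated
#'     arm's profile.}
#'   \item{`parallel2`}{16 subjects, 8 per arm, one dose, the 17-sample
#'     schedule extended by 17 log-spaced samples out to 1008 h (6 weeks).}
#'   \item{`original_sequential`}{the sequential layout with 35 subjects,
#'     mirroring the source study.}
#' }
#' The three comparison designs plan an identical number of samples
#' (16*2*17 = 32*17 = 16*34 = 544), enforced at construction.
#'
#' @param name one of `"sequential"`, `"parallel1"`, `"parallel2"`,
#'   `"original_sequential"`.
#' @param overrides named list of fields to override (`n_subjects`,
#'   `dose_amt`, `dose_times`, `sample_rel`, `ie_onset`).
#' @return An object of class `ddi_design`.
#' @export
make_design <- function(name = c("sequential", "parallel1", "parallel2",
                                 "original_sequential"),
                        overrides = list()) {
  name <- match.arg(name)
  long_grid <- c(DEFAULT_GRID,
                 round(exp(seq(log(336), log(1008), length.out = 18))[-1]))
  d <- switch(name,
    sequential = list(type = "sequential", n_subjects = 16L,
                      dose_times = c(0, 672), sample_rel = c(0, DEFAULT_GRID)),
    original_sequential = list(type = "sequential", n_subjects = 35L,
                               dose_times = c(0, 672),
                               sample_rel = c(0, DEFAULT_GRID)),
    parallel1 = list(type = "parallel", n_subjects = 32L, dose_times = 0,
                     sample_rel = c(0, DEFAULT_GRID)),
    parallel2 = list(type = "parallel", n_subjects = 16L, dose_times = 0,
                     sample_rel = c(0, long_grid)))
  d$name <- name
  d$dose_amt <- 400
  d$ie_onset <- -168           # h relative to the perpetrator-covered dose
  d <- modifyList(d, overrides)
  d$n_subjects <- as.integer(d$n_subjects)
  if (d$type == "sequential" && length(d$dose_times) != 2)
    stop("sequential designs have exactly 2 periods/doses")
  if (d$type == "parallel") {
    if (length(d$dose_times) != 1) stop("parallel designs have 1 period")
    if (d$n_subjects %% 2 != 0) stop("parallel designs need 2 equal arms")
  }
  if (is.unsorted(d$sample_rel, strictly = TRUE))
    stop("sampling times must be strictly increasing")
  class(d) <- "ddi_design"
  if (name %in% c("sequential", "parallel1", "parallel2") &&
      !length(overrides) && planned_samples(d) != 544L)
    stop("internal error: comparison designs must plan 544 samples")
  d
}

#' Number of planned samples of a design
#' @param d a `ddi_design`.
#' @return Integer count of planned observation times across all subjects
#'   and periods (per analyte).
#' @export
planned_samples <- function(d) {
  stopifnot(inherits(d, "ddi_design"))
  n_periods <- length(d$dose_times)
  as.integer(d$n_subjects * n_periods * length(d$sample_rel))
}

#' @export
print.ddi_design <- function(x, ...) {
  cat(sprintf("DDI trial design '%s' (%s): %d subjects, %d period(s), %d samples/period/subject\n",
              x$name, x$type, x$n_subjects, length(x$dose_times),
              length(x$sample_rel)))
  invisible(x)
}

# arm labels per subject; parallel arms are weight-matched by construction
design_arms <- function(d) {
  if (d$type == "sequential") rep("seq", d$n_subjects)
  else rep(c("control", "treated"), each = d$n_subjects / 2)
}

# perpetrator-covered dose: last dose of a sequential design, the only dose
# of a parallel treated arm
covered_dose_time <- function(d) d$dose_times[length(d$dose_times)]
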
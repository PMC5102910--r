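#' Pipeline configuration
#'
#' Collects every tunable knob of the characterization pipeline in one list.
#' Defaults reproduce the standard operating conditions: 2 Hz fura-2 ratio
#' recordings of roughly two minutes with a stimulus after a short baseline.
#'
#' @param seed Integer seed used for every stochastic step (mixture-model
#'   restarts, gap-statistic reference draws). Logged per run.
#' @param tv_alpha_scale Dimensionless scale `c` of the total-variation
#'   regularization weight `alpha = c * sigma_plus * N * mean(dt)`; the
#'   default was calibrated once on the synthetic recovery suite.
#' @param tv_max_iter Maximum number of total-variation iterations.
#' @param drift_multistart Number of multistart values for the exponential
#'   drift time constant.
#' @param hill_n_max Upper bound for Hill coefficients (activation and
#'   deactivation).
#' @param min_tail_points Minimum number of usable points after the
#'   deactivation inflection required to fit the mono-exponential decay.
#' @param mpr_min_height_sigma Minimum deviation height, in units of the
#'   lower noise bound `sigma_minus`, for an event to count as a peak/trough.
#' @param mpr_min_spacing_s Minimum spacing between events, seconds.
#' @param gmm_kmax Maximum number of mixture components considered.
#' @param gap_B Number of uniform reference data sets for the gap statistic.
#' @param detection_sigma Detection threshold, in units of `sigma_minus`, by
#'   which the data estimate must exceed the drift.
#' @param detection_points Minimum number of points exceeding the detection
#'   threshold.
#' @param time_scale Multiplier applied to the input time column to convert
#'   it to seconds.
#' @param trim_before Optional time (s); samples before it are dropped at
#'   ingestion (for recordings with large pre-stimulus artifacts).
#'
#' @return A named list of class `catrace_config`.
#' @export
#' @examples
#' cfg <- catrace_config(seed = 42)
#' cfg$tv_max_iter
catrace_config <- function(seed = 1L,
                           tv_alpha_scale = 0.03,
                           tv_max_iter = 50L,
                           drift_multistart = 3L,
                           hill_n_max = 50,
                           min_tail_points = 10L,
                           mpr_min_height_sigma = 6,
                           mpr_min_spacing_s = 5,
                           gmm_kmax = 5L,
                           gap_B = 20L,
                           detection_sigma = 4,
                           detection_points = 6L,
                           time_scale = 1,
                           trim_before = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    tv_alpha_scale = tv_alpha_scale,
    tv_max_iter = as.integer(tv_max_iter),
    drift_multistart = as.integer(drift_multistart),
    hill_n_max = hill_n_max,
    min_tail_points = as.integer(min_tail_points),
    mpr_min_height_sigma = mpr_min_height_sigma,
    mpr_min_spacing_s = mpr_min_spacing_s,
    gmm_kmax = as.integer(gmm_kmax),
    gap_B = as.integer(gap_B),
    detection_sigma = detection_sigma,
    detection_points = as.integer(detection_points),
    time_scale = time_scale,
    trim_before = trim_before
  )
  structure(cfg, class = "catrace_config")
}

as_catrace_config <- function(config) {
  if (is.null(config)) return(catrace_config())
  if (inherits(config, "catrace_config")) return(config)
  do.call(catrace_config, config)
}
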
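#' Characterize one trace
#'
#' Runs the full pipeline on a single recording: TV derivative estimation
#' with spike rejection, drift delimitation and fitting, transient
#' detection and model fitting, transient metrics, and (when more than two
#' deviations remain) oscillation analysis with a reliability-weighted
#' refit and coherent-subset clustering.
#'
#' @param data Tibble with columns `time`, `value` (optionally `trace_id`).
#' @param config Optional [catrace_config()].
#' @return Object of class `trace_fit` holding every intermediate result:
#'   `trace`, `tv`, `delim`, `drift0`, `drift`, `activation`, `detection`,
#'   `response`, `tr_metrics`, `deviations`, `mpr_all`, `mpr_coherent`,
#'   `flags`. Use [glance()] for the one-row report, [tidy()] for the
#'   parameter table and [ggplot2::autoplot()] for a diagnostic figure.
#' @export
#' @examples
#' sim <- generate_trace(fixture_spec(seed = 7))
#' fit <- characterize_trace(sim$trace)
#' glance(fit)
characterize_trace <- function(data, config = NULL) {
  cfg <- as_catrace_config(config)
  stopifnot(all(c("time", "value") %in% names(data)))
  if (nrow(data) == 0L) stop("empty trace")
  trace <- tibble::tibble(
    trace_id = if ("trace_id" %in% names(data)) data$trace_id[1L] else "trace",
    time = as.numeric(data$time),
    value = as.numeric(data$value)
  )
  flags <- character(0)

  tv <- tv_iterate(trace$time, trace$value, cfg)
  flags <- c(flags, tv$flags)
  dl <- delimit(trace, tv)

  drift0 <- fit_drift_initial(trace, dl, tv$clean_idx, cfg)
  drift_w <- fit_drift_weighted(trace, tv, drift0, cfg)
  flags <- c(flags, drift_w$flags)

  act <- NULL
  det <- list(detected = FALSE, criteria = c(FALSE, FALSE, FALSE))
  resp <- NULL
  tr_metrics <- NULL

  if (length(dl$i_local) > 0L) {
    act <- tryCatch(fit_activation(trace, tv, dl, drift_w, cfg),
                    error = function(e) NULL)
    if (!is.null(act)) flags <- c(flags, act$flags)
    det <- detect_transient(trace, tv, dl, drift_w, act, cfg)
  }

  if (det$detected && !is.null(act)) {
    resp <- tryCatch(fit_response(trace, tv, dl, act, cfg),
                     error = function(e) NULL)
    if (is.null(resp)) {
      flags <- c(flags, "response_fit_error")
    } else {
      flags <- c(flags, resp$flags)
    }
  }

  # deviations from the fitted transient (or from the drift alone when no
  # transient was detected)
  base_fit <- resp %||% list(params = NULL, drift = drift_w$params,
                             t_end = trace$time[nrow(trace)])
  dev <- tryCatch(find_deviations(trace, tv, base_fit, cfg),
                  error = function(e) NULL)
  mpr_all <- NULL
  mpr_coh <- NULL
  if (!is.null(dev) && nrow(dev) > 2L) {
    if (!is.null(resp)) {
      o <- bias_weights(dev)
      Om <- reliability_weights(trace, tv, resp, dev, o)
      resp2 <- refit_response_weighted(trace, tv, dl, act, resp, Om, cfg)
      if (is.finite(resp2$value %||% NA) &&
          is.finite(resp$value %||% NA) && resp2$value <= resp$value * 10) {
        resp <- resp2
      }
      dev <- tryCatch(find_deviations(trace, tv, resp, cfg),
                      error = function(e) dev)
    }
    dev <- cluster_coherent(dev, cfg)
    mpr_all <- mpr_metrics(dev, "all")
    mpr_coh <- mpr_metrics(dev, "coherent")
  } else if (!is.null(dev)) {
    dev$coherent <- rep(TRUE, nrow(dev))
  }

  if (det$detected && !is.null(resp)) {
    tr_metrics <- extract_tr_metrics(resp, trace, tv, cfg)
    flags <- c(flags, unlist(tr_metrics$flags))
  }

  structure(list(trace = trace, tv = tv, delim = dl, drift0 = drift0,
                 drift = drift_w, activation = act, detection = det,
                 response = resp, tr_metrics = tr_metrics,
                 deviations = dev, mpr_all = mpr_all, mpr_coherent = mpr_coh,
                 config = cfg, flags = unique(flags), error = NULL),
            class = "trace_fit")
}

#' @export
print.trace_fit <- function(x, ...) {
  cat("<trace_fit>", x$trace_id %||% x$trace$trace_id[1L], "\n")
  if (!is.null(x$error)) {
    cat("  error:", x$error, "\n")
    return(invisible(x))
  }
  cat("  detected:", x$detection$detected,
      " criteria:", paste(as.integer(x$detection$criteria), collapse = ""),
      "\n")
  if (!is.null(x$tr_metrics)) {
    m <- x$tr_metrics
    cat(sprintf("  t_onset %.2f s | rise 10-90%% %.2f s | amplitude %.3f | AUC %.2f | FWHM %.2f s | tau %.2f s\n",
                m$t_onset, m$t_10_90, m$amplitude, m$auc, m$fwhm,
                m$tau_decay))
  }
  if (!is.null(x$mpr_all)) {
    cat(sprintf("  oscillations: %d peaks (T = %.1f s), %d coherent\n",
                x$mpr_all$n_osc, x$mpr_all$period_T,
                x$mpr_coherent$n_osc))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

empty_report_row <- function(trace_id, flags, detected = NA) {
  tibble::tibble(
    trace_id = trace_id, detected = detected,
    t_onset = NA_real_, t_10_90 = NA_real_, amplitude = NA_real_,
    auc = NA_real_, fwhm = NA_real_, rho = NA_real_, tau_decay = NA_real_,
    mpr_all_n_osc = NA_integer_, mpr_all_magnitude = NA_real_,
    mpr_all_period = NA_real_, mpr_all_sigma_T = NA_real_,
    mpr_all_persistence = NA_real_, mpr_all_duty = NA_real_,
    mpr_coh_n_osc = NA_integer_, mpr_coh_magnitude = NA_real_,
    mpr_coh_period = NA_real_, mpr_coh_sigma_T = NA_real_,
    mpr_coh_persistence = NA_real_, mpr_coh_duty = NA_real_,
    flags = flags
  )
}

#' One-row report of a characterized trace
#'
#' @param x A `trace_fit`.
#' @param ... Unused.
#' @return Tibble with the detection verdict, the six transient parameters
#'   (`NA` when no transient was detected), the two oscillation blocks and
#'   the collapsed flag string.
#' @export
glance.trace_fit <- function(x, ...) {
  id <- if (!is.null(x[["trace"]])) x[["trace"]]$trace_id[1L] else x$trace_id
  if (!is.null(x$error)) {
    return(empty_report_row(id, x$flags %||% paste0("error: ", x$error)))
  }
  out <- empty_report_row(id, paste(x$flags, collapse = ";"),
                          detected = x$detection$detected)
  if (!is.null(x$tr_metrics)) {
    m <- x$tr_metrics
    out$t_onset <- m$t_onset
    out$t_10_90 <- m$t_10_90
    out$amplitude <- m$amplitude
    out$auc <- m$auc
    out$fwhm <- m$fwhm
    out$rho <- m$rho
    out$tau_decay <- m$tau_decay
  }
  if (!is.null(x$mpr_all)) {
    out$mpr_all_n_osc <- x$mpr_all$n_osc
    out$mpr_all_magnitude <- x$mpr_all$magnitude_E
    out$mpr_all_period <- x$mpr_all$period_T
    out$mpr_all_sigma_T <- x$mpr_all$sigma_T
    out$mpr_all_persistence <- x$mpr_all$persistence
    out$mpr_all_duty <- x$mpr_all$duty_cycle
    out$mpr_coh_n_osc <- x$mpr_coherent$n_osc
    out$mpr_coh_magnitude <- x$mpr_coherent$magnitude_E
    out$mpr_coh_period <- x$mpr_coherent$period_T
    out$mpr_coh_sigma_T <- x$mpr_coherent$sigma_T
    out$mpr_coh_persistence <- x$mpr_coherent$persistence
    out$mpr_coh_duty <- x$mpr_coherent$duty_cycle
  }
  out
}

#' Parameter table of a characterized trace
#'
#' @param x A `trace_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `block` (transient /
#'   oscillation / drift / noise).
#' @export
tidy.trace_fit <- function(x, ...) {
  rows <- list()
  if (!is.null(x$tr_metrics)) {
    m <- x$tr_metrics
    rows$tr <- tibble::tibble(
      term = c("t_onset", "t_10_90", "amplitude", "auc", "fwhm", "rho",
               "tau_decay"),
      estimate = c(m$t_onset, m$t_10_90, m$amplitude, m$auc, m$fwhm, m$rho,
                   m$tau_decay),
      block = "transient")
  }
  for (blk in c("all", "coherent")) {
    mm <- if (blk == "all") x$mpr_all else x$mpr_coherent
    if (!is.null(mm)) {
      rows[[blk]] <- tibble::tibble(
        term = paste0("mpr_", blk, "_",
                      c("n_osc", "magnitude", "period", "sigma_T",
                        "persistence", "duty_cycle")),
        estimate = as.numeric(c(mm$n_osc, mm$magnitude_E, mm$period_T,
                                mm$sigma_T, mm$persistence, mm$duty_cycle)),
        block = "oscillation")
    }
  }
  dpar <- (x$response$drift %||% x$drift$params)
  rows$drift <- tibble::tibble(term = names(dpar),
                               estimate = as.numeric(unlist(dpar)),
                               block = "drift")
  rows$noise <- tibble::tibble(
    term = c("sigma_plus", "sigma_minus", "phi", "n_spikes"),
    estimate = c(x$tv$sigma_plus, x$tv$sigma_minus, x$tv$phi,
                 length(x$tv$spike_idx)),
    block = "noise")
  dplyr::bind_rows(rows)
}

#' Diagnostic plot of a characterized trace
#'
#' Raw data, TV data estimate, fitted drift and (when detected) the full
#' fitted model, with rejected noise spikes and oscillation events marked.
#'
#' @param object A `trace_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trace_fit
#' @export
autoplot.trace_fit <- function(object, ...) {
  tr <- object$trace
  layers <- tibble::tibble(time = tr$time, value = tr$value,
                           Au = object$tv$Au)
  dpar <- object$response$drift %||% object$drift$params
  layers$drift <- global_drift(tr$time, dpar)
  if (!is.null(object$response)) {
    layers$model <- global_response(tr$time, object$response$params,
                                    object$response$drift,
                                    object$response$t_end)
  }
  p <- ggplot2::ggplot(layers, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.6,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$Au, colour = "TV estimate")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$drift, colour = "drift"),
                       linetype = "dashed")
  if (!is.null(layers$model)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$model,
                                             colour = "fitted model"))
  }
  if (length(object$tv$spike_idx)) {
    p <- p + ggplot2::geom_point(
      data = layers[object$tv$spike_idx, ],
      ggplot2::aes(y = .data$value), colour = "red", shape = 4)
  }
  if (!is.null(object$deviations) && nrow(object$deviations)) {
    ev <- object$deviations
    p <- p + ggplot2::geom_vline(xintercept = ev$time[ev$type == "peak"],
                                 alpha = 0.15)
  }
  p + ggplot2::labs(x = "time (s)", y = "signal (a.u.)", colour = NULL,
                    title = tr$trace_id[1L]) +
    ggplot2::theme_minimal()
}
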
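# Synthetic fura-2-like recordings with known ground truth: drift +
# transient + oscillatory events + Gaussian noise + intermittent spikes.

#' Specification of a synthetic recording
#'
#' Defaults emulate the standard acquisition: ~120 s at 2 samples/s with a
#' stimulus after 10 s of baseline, a fura-2 ratio baseline near 1 a.u.,
#' a transient of 0.5 a.u. (signal-to-noise 20 at the default noise), and a
#' gently saturating downward drift.
#'
#' @param duration Recording length (s).
#' @param dt Sampling interval (s).
#' @param stimulus_time Stimulus application time (s).
#' @param drift Named list `a1, tau1, m1, a2, tau2, m2, t2, z`.
#' @param tr Named list of response parameters (`t_on`, `A_act`, `beta`,
#'   `n_act`, `m_act`, `t_de`, `sigma_act`, `sigma_de`, `A_de`, `gamma`,
#'   `n_de`) or `NULL` for no transient.
#' @param osc Named list `period` (s), `amplitude` (a.u.), `n_cycles`,
#'   `jitter_sd` (s), `fwhm` (s), `start` (s) or `NULL` for none.
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param spike Named list `count`, `amplitude_sigma` (multiples of
#'   `noise_sd`), `sign` (+1/-1) or `NULL`.
#' @param seed Integer seed; the generated trace is bit-reproducible.
#' @return Named list of class `fixture_spec`.
#' @export
fixture_spec <- function(duration = 120, dt = 0.5, stimulus_time = 10,
                         drift = list(a1 = -0.05, tau1 = 40, m1 = -2e-4,
                                      a2 = 0, tau2 = 40, m2 = 0, t2 = 60,
                                      z = 1),
                         tr = list(t_on = 11, A_act = 0.5, beta = 2.5,
                                   n_act = 2.5, m_act = 0, t_de = 18,
                                   sigma_act = 2, sigma_de = 4, A_de = 0.5,
                                   gamma = 15, n_de = 2),
                         osc = NULL,
                         noise_sd = 0.025,
                         spike = NULL,
                         seed = 1L) {
  stopifnot(dt > 0, duration / dt >= 20)
  structure(list(duration = duration, dt = dt, stimulus_time = stimulus_time,
                 drift = drift, tr = tr, osc = osc, noise_sd = noise_sd,
                 spike = spike, seed = as.integer(seed)),
            class = "fixture_spec")
}

# gaussian bump with height E and full width at half maximum fw
gauss_bump <- function(t, center, E, fw) {
  s <- fw / (2 * sqrt(2 * log(2)))
  E * exp(-(t - center)^2 / (2 * s^2))
}

#' Generate a synthetic trace and its ground truth
#'
#' The noiseless signal is drift + transient (the package's own response
#' model) + a train of Gaussian bumps at jittered times; i.i.d. Gaussian
#' noise and optional high-amplitude spikes are added on top. Ground-truth
#' transient metrics are computed from the generating formulas on a 1 ms
#' grid, never through the estimation pipeline.
#'
#' @param spec A [fixture_spec()].
#' @return List with `trace` (tibble `trace_id`, `time`, `value`) and
#'   `truth` (generating parameters, true noiseless signal, true transient
#'   and oscillation metrics, spike indices).
#' @export
generate_trace <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  tvec <- seq(0, by = spec$dt, length.out = round(spec$duration / spec$dt))
  t_end <- tvec[length(tvec)]
  n <- length(tvec)

  f_drift <- global_drift(tvec, spec$drift)
  f_tr <- if (!is.null(spec$tr)) response_model(tvec, spec$tr, t_end) else 0

  osc_truth <- NULL
  f_osc <- 0
  if (!is.null(spec$osc)) {
    o <- spec$osc
    centers <- o$start + (seq_len(o$n_cycles) - 1L) * o$period +
      rnorm(o$n_cycles, sd = o$jitter_sd %||% 0)
    keep <- centers <= t_end
    truncated <- any(!keep)
    centers <- centers[keep]
    f_osc <- rowSums(vapply(centers, function(ct)
      gauss_bump(tvec, ct, o$amplitude, o$fwhm), numeric(n)))
    periods <- diff(centers)
    osc_truth <- list(centers = centers, amplitude = o$amplitude,
                      fwhm = o$fwhm, truncated = truncated,
                      n_osc = length(centers),
                      period_T = if (length(periods)) mean(periods) else NA,
                      sigma_T = sd0(periods),
                      persistence = if (length(centers) > 1)
                        max(centers) - min(centers) else 0,
                      duty_cycle = if (length(periods))
                        o$fwhm / mean(periods) else NA)
  }

  f_true <- f_drift + f_tr + f_osc
  value <- f_true + rnorm(n, sd = spec$noise_sd)

  spike_idx <- integer(0)
  if (!is.null(spec$spike) && spec$spike$count > 0) {
    margin <- which(tvec > 2 & tvec < t_end - 2)
    spike_idx <- sort(sample(margin, spec$spike$count))
    sgn <- spec$spike$sign %||% 1
    value[spike_idx] <- value[spike_idx] +
      sgn * spec$spike$amplitude_sigma * spec$noise_sd
  }

  tr_truth <- NULL
  if (!is.null(spec$tr)) {
    tr_truth <- true_tr_metrics(spec$tr, t_end)
  }

  list(trace = as_trace(tvec, value, sprintf("sim_seed%d", spec$seed)),
       truth = list(spec = spec, f_true = f_true, drift = f_drift,
                    tr = tr_truth, osc = osc_truth, spike_idx = spike_idx,
                    noise_sd = spec$noise_sd))
}

# ground-truth transient metrics by fine-grid brute force on the
# generating response model
true_tr_metrics <- function(tr, t_end, dt_fine = 1e-3) {
  tg <- seq(tr$t_on, t_end, by = dt_fine)
  g <- response_model(tg, tr, t_end)
  amp <- max(g)
  i_pk <- which.max(g)
  up <- function(level) tg[min(which(g[seq_len(i_pk)] >= level))]
  dn <- function(level) {
    seg <- g[i_pk:length(g)]
    ix <- which(seg <= level)
    if (!length(ix)) tg[length(tg)] else tg[i_pk + min(ix) - 1L]
  }
  p <- response_pars(tr, t_end)
  rho <- if (p$n_de > 1) {
    p$t_de + p$gamma * ((p$n_de - 1) / (p$n_de + 1))^(1 / p$n_de)
  } else p$t_de
  # decay constant of the model tail: least squares on the noiseless curve
  tt <- tg[tg > rho]
  yy <- response_model(tt, tr, t_end)
  tau <- NA_real_
  if (length(tt) > 10 && all(is.finite(yy))) {
    ft <- try(minpack.lm::nls.lm(c(max(yy[1], 1e-8), log(max(p$gamma, 1))),
                                 fn = function(par)
                                   par[1] * exp(-(tt - rho) / exp(par[2])) - yy,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 200)),
              silent = TRUE)
    if (!inherits(ft, "try-error")) tau <- exp(ft$par[2])
  }
  tibble::tibble(t_onset = tr$t_on, t_10_90 = up(0.9 * amp) - up(0.1 * amp),
                 amplitude = amp, auc = pracma::trapz(tg, g),
                 fwhm = dn(amp / 2) - up(amp / 2), rho = rho, tau_decay = tau)
}
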
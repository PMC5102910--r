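# Transient response: Hill-type activation, decreasing-Hill deactivation,
# C1 cubic Hermite junction, detection criteria and kinetic parameters.

# cached 64-node Gauss-Legendre rule on [-1, 1]
.gl64 <- local({
  g <- pracma::gaussLegendre(64, -1, 1)
  list(x = g$x, w = g$w)
})

# int_0^t b^n / (x^n + b^n) dx, vectorized over t >= 0
hill_integral <- function(t, b, n) {
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (length(pos)) {
    tp <- t[pos]
    # map nodes onto [0, t]
    X <- outer(tp / 2, .gl64$x + 1)          # length(tp) x 64
    fx <- b^n / (X^n + b^n)
    out[pos] <- (tp / 2) * as.numeric(fx %*% .gl64$w)
  }
  out
}

#' Activation-phase model
#'
#' `g_act(t) = A_act * t^n / (t^n + beta^n) + m_act * int_0^t x^n / (x^n + beta^n) dx`:
#' a Hill rise (amplitude `A_act`, half-rise time `beta`, coefficient
#' `n_act`) plus a quasi-linear term of asymptotic slope `m_act` for the
#' gradual recruitment that dominates late activation. Time is measured
#' from onset; the model is 0 for `t <= 0`.
#'
#' @param t Time since onset (s), vectorized.
#' @param params Named list/vector with `A_act`, `beta`, `n_act`, `m_act`.
#' @return Model values (a.u.).
#' @export
activation_model <- function(t, params) {
  p <- as.list(params)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  hill <- tp^p$n_act / (tp^p$n_act + p$beta^p$n_act)
  out[pos] <- p$A_act * hill +
    p$m_act * (tp - hill_integral(tp, p$beta, p$n_act))
  out
}

activation_model_deriv <- function(t, params) {
  p <- as.list(params)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  bn <- p$beta^p$n_act
  tn <- tp^p$n_act
  out[pos] <- p$A_act * p$n_act * bn * tp^(p$n_act - 1) / (tn + bn)^2 +
    p$m_act * tn / (tn + bn)
  out
}

# deactivation branch, time measured from t_de; m_de supplied
deactivation_model <- function(t, A_de, gam, n_de, m_de) {
  gn <- gam^n_de
  A_de * gn / (t^n_de + gn) + m_de * hill_integral(t, gam, n_de)
}

deactivation_model_deriv <- function(t, A_de, gam, n_de, m_de) {
  gn <- gam^n_de
  -A_de * gn * n_de * t^(n_de - 1) / (t^n_de + gn)^2 + m_de * gn / (t^n_de + gn)
}

# slope of the quasi-linear deactivation term forcing the response to
# return to zero at the end of the recording
m_de_closed_form <- function(A_de, gam, n_de, t_end_rel) {
  den <- hill_integral(t_end_rel, gam, n_de)
  if (den <= 0) return(0)
  -A_de * gam^n_de / (t_end_rel^n_de + gam^n_de) / den
}

# two-point cubic Hermite on [x0, x1]
hermite_eval <- function(t, x0, x1, v0, d0, v1, d1) {
  hlen <- x1 - x0
  s <- (t - x0) / hlen
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * v0 + h10 * hlen * d0 + h01 * v1 + h11 * hlen * d1
}

hermite_eval_deriv <- function(t, x0, x1, v0, d0, v1, d1) {
  hlen <- x1 - x0
  s <- (t - x0) / hlen
  dh00 <- (6 * s^2 - 6 * s) / hlen
  dh10 <- (3 * s^2 - 4 * s + 1)
  dh01 <- (6 * s - 6 * s^2) / hlen
  dh11 <- (3 * s^2 - 2 * s)
  dh00 * v0 + dh10 * d0 + dh01 * v1 + dh11 * d1
}

response_pars <- function(params, t_end) {
  p <- as.list(params)
  p$ell_act <- p$t_de - p$t_on
  p$sigma_act <- min(p$sigma_act, 0.95 * p$ell_act)
  p$sigma_de <- min(p$sigma_de, 0.95 * 2 * p$gamma)
  p$m_de <- m_de_closed_form(p$A_de, p$gamma, p$n_de, t_end - p$t_de)
  p
}

#' Drift-free transient response model
#'
#' Piecewise model: Hill activation on `[t_on, t_de - sigma_act)`, cubic
#' Hermite junction on `[t_de - sigma_act, t_de + sigma_de)` matching value
#' and slope of both neighbours, decreasing-Hill deactivation afterwards;
#' continuously differentiable by construction. The deactivation slope
#' `m_de` is not free: its closed form makes the response return to zero at
#' `t_end`.
#'
#' @param t Absolute time (s), vectorized.
#' @param params Named list with `t_on`, `A_act`, `beta`, `n_act`, `m_act`,
#'   `t_de`, `sigma_act`, `sigma_de`, `A_de`, `gamma`, `n_de`.
#' @param t_end End of the recording (s), used by the `m_de` closed form.
#' @param deriv Return the time derivative instead of the value.
#' @return Model values (a.u.), 0 before `t_on`.
#' @export
response_model <- function(t, params, t_end, deriv = FALSE) {
  p <- response_pars(params, t_end)
  x0 <- p$t_de - p$sigma_act
  x1 <- p$t_de + p$sigma_de
  act_par <- list(A_act = p$A_act, beta = p$beta, n_act = p$n_act,
                  m_act = p$m_act)
  v0 <- activation_model(x0 - p$t_on, act_par)
  d0 <- activation_model_deriv(x0 - p$t_on, act_par)
  v1 <- deactivation_model(p$sigma_de, p$A_de, p$gamma, p$n_de, p$m_de)
  d1 <- deactivation_model_deriv(p$sigma_de, p$A_de, p$gamma, p$n_de, p$m_de)

  out <- numeric(length(t))
  reg_act <- t >= p$t_on & t < x0
  reg_h <- t >= x0 & t < x1
  reg_de <- t >= x1
  if (deriv) {
    out[reg_act] <- activation_model_deriv(t[reg_act] - p$t_on, act_par)
    if (any(reg_h)) {
      out[reg_h] <- hermite_eval_deriv(t[reg_h], x0, x1, v0, d0, v1, d1)
    }
    out[reg_de] <- deactivation_model_deriv(t[reg_de] - p$t_de, p$A_de,
                                            p$gamma, p$n_de, p$m_de)
  } else {
    out[reg_act] <- activation_model(t[reg_act] - p$t_on, act_par)
    if (any(reg_h)) {
      out[reg_h] <- hermite_eval(t[reg_h], x0, x1, v0, d0, v1, d1)
    }
    out[reg_de] <- deactivation_model(t[reg_de] - p$t_de, p$A_de, p$gamma,
                                      p$n_de, p$m_de)
  }
  out
}

# global data model: drift + response (response zero before onset)
global_response <- function(t, params, drift_params, t_end, deriv = FALSE) {
  if (deriv) {
    global_drift_deriv(t, drift_params) + response_model(t, params, t_end, TRUE)
  } else {
    global_drift(t, drift_params) + response_model(t, params, t_end, FALSE)
  }
}

unpack_act <- function(par, t2_fix) {
  list(t_on = par[1L], A_act = par[2L], beta = exp(par[3L]),
       n_act = exp(par[4L]), m_act = par[5L],
       drift = list(a1 = par[6L], tau1 = exp(par[7L]), m1 = par[8L],
                    a2 = par[9L], tau2 = exp(par[10L]), m2 = par[11L],
                    t2 = t2_fix, z = par[12L]))
}

#' Fit the activation phase jointly with the drift
#'
#' Minimizes `phi^2 * sum (F - G_act)^2 + phi * sum (u_hat - dG_act/dt)^2 +
#' S_drift` over the activation parameters and the drift parameters, where
#' `G_act` applies the activation model between onset and the response peak
#' and the pure drift elsewhere. Onset is confined to
#' `[t[i_act0], t[i_max]]`.
#'
#' @param trace Tibble with `time`, `value`.
#' @param tvstate A [tv_iterate()] state.
#' @param delim A [delimit()] result with a nonempty `i_local`.
#' @param theta_drift A `drift_fit` (weighted refit) used as start and for
#'   the drift penalty weights.
#' @param config Optional [catrace_config()].
#' @return List of class `activation_fit`: `params` (`t_on, A_act, beta,
#'   n_act, m_act`), `drift` (refined drift parameters), `value`, `flags`.
#' @export
fit_activation <- function(trace, tvstate, delim, theta_drift, config = NULL) {
  cfg <- as_catrace_config(config)
  times <- trace$time
  F <- trace$value
  j <- tvstate$clean_idx
  phi <- max(tvstate$phi, 1e-6)
  p0 <- theta_drift$params
  k <- theta_drift$k
  w <- theta_drift$w %||% rep(1, length(k))
  t_lo <- times[delim$i_act0]
  t_hi <- times[delim$i_max]
  if (t_hi <= t_lo) t_hi <- t_lo + min(diff(times))
  t_max <- times[delim$i_max]
  dt_min <- min(diff(times))
  span <- diff(range(times))

  model_fun <- function(ap, dp, deriv = FALSE) {
    base <- if (deriv) global_drift_deriv(times, dp) else global_drift(times, dp)
    reg <- times >= ap$t_on & times < t_max
    if (any(reg)) {
      add <- if (deriv) {
        activation_model_deriv(times[reg] - ap$t_on, ap)
      } else {
        activation_model(times[reg] - ap$t_on, ap)
      }
      base[reg] <- base[reg] + add
    }
    base
  }

  # the model is drift-only beyond the peak, so the deactivation segment
  # (i_max..i_end0) would force the drift to absorb the transient; the
  # activation stage is therefore evaluated on the activation epoch and the
  # drift-dominated epochs only
  jj <- intersect(j, c(seq_len(delim$i_max), delim$i_end0:length(F)))
  resid_fun <- function(par) {
    u <- unpack_act(par, p0$t2)
    Gv <- model_fun(u, u$drift, FALSE)
    Gd <- model_fun(u, u$drift, TRUE)
    c(phi * (F[jj] - Gv[jj]),
      sqrt(phi) * (tvstate$u[jj] - Gd[jj]),
      drift_resid(u$drift, times[k], F[k], tvstate$u[k], w))
  }

  # the activation model only acts below t_max, so amplitude and half-rise
  # time are unidentifiable beyond the observed excursion; bound them to
  # the scale of the data
  rng <- diff(range(tvstate$Au))
  A0 <- max(tvstate$Au[delim$i_max] - global_drift(t_max, p0), 4 * tvstate$sigma_minus)
  beta0 <- max((t_hi - t_lo) / 2, dt_min)
  win <- max(t_max - t_lo, 2 * dt_min)
  par0 <- c(t_lo, A0, log(beta0), log(2), 0,
            p0$a1, log(p0$tau1), p0$m1, p0$a2, log(p0$tau2), p0$m2, p0$z)
  lo <- c(t_lo, 0, log(dt_min / 2), log(1), -Inf,
          -Inf, log(dt_min), -Inf, -Inf, log(dt_min), -Inf, -Inf)
  hi <- c(t_hi, 3 * rng, log(2 * win), log(cfg$hill_n_max), Inf,
          Inf, log(10 * span), Inf, Inf, log(10 * span), Inf, Inf)
  fit <- try(minpack.lm::nls.lm(par0, lower = lo, upper = hi, fn = resid_fun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 300)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    u <- unpack_act(par0, p0$t2)
    return(structure(list(params = u[c("t_on", "A_act", "beta", "n_act",
                                       "m_act")],
                          drift = p0, value = NA_real_, t_max = t_max,
                          flags = "activation_solver_failed"),
                     class = "activation_fit"))
  }
  u <- unpack_act(fit$par, p0$t2)
  structure(list(params = u[c("t_on", "A_act", "beta", "n_act", "m_act")],
                 drift = u$drift, value = fit$deviance, t_max = t_max,
                 flags = character(0)),
            class = "activation_fit")
}

#' Transient detection criteria
#'
#' A transient is declared present when (i) at least one derivative maximum
#' is significant, (ii) the better of the two drift estimates lies below
#' the TV data estimate by at least `detection_sigma * sigma_minus` for at
#' least `detection_points` samples, and (iii) the data-minus-drift
#' residual is not strictly increasing after the activation maximum.
#'
#' @param trace Tibble with `time`, `value`.
#' @param tvstate A [tv_iterate()] state.
#' @param delim A [delimit()] result.
#' @param drift_fit Weighted `drift_fit`.
#' @param act_fit Optional `activation_fit` (its refined drift competes with
#'   `drift_fit` on the drift objective).
#' @param config Optional [catrace_config()].
#' @return List: `detected` and the logical vector `criteria` (length 3).
#' @export
detect_transient <- function(trace, tvstate, delim, drift_fit,
                             act_fit = NULL, config = NULL) {
  cfg <- as_catrace_config(config)
  c1 <- length(delim$i_local) > 0L

  c2 <- FALSE
  c3_bad <- FALSE
  if (c1) {
    k <- drift_fit$k
    w <- drift_fit$w %||% rep(1, length(k))
    cand <- list(drift_fit$params)
    if (!is.null(act_fit)) cand <- c(cand, list(act_fit$drift))
    obj <- vapply(cand, drift_objective, numeric(1), trace = trace,
                  tvstate = tvstate, k = k, w = w)
    best <- cand[[which.min(obj)]]
    D <- global_drift(trace$time, best)
    excess <- tvstate$Au - D
    c2 <- sum(excess > cfg$detection_sigma * tvstate$sigma_minus) >=
      cfg$detection_points
    tail_r <- excess[delim$i_max0:length(excess)]
    c3_bad <- length(tail_r) > 1L && all(diff(tail_r) > 0)
  }
  detected <- c1 && c2 && !c3_bad
  list(detected = detected, criteria = c(c1, c2, !c3_bad))
}

unpack_resp <- function(par, t_on_bounds, t2_fix, t_end) {
  dp <- list(a1 = par[12L], tau1 = exp(par[13L]), m1 = par[14L],
             a2 = par[15L], tau2 = exp(par[16L]), m2 = par[17L],
             t2 = t2_fix, z = par[18L])
  rp <- list(t_on = par[1L], A_act = par[2L], beta = exp(par[3L]),
             n_act = exp(par[4L]), m_act = par[5L],
             t_de = NA, sigma_act = NA, sigma_de = NA,
             A_de = par[9L], gamma = exp(par[10L]), n_de = exp(par[11L]))
  # t_de parametrized as onset + activation duration so it cannot cross t_on
  rp$t_de <- min(par[1L] + exp(par[6L]), t_end - 1e-3)
  # junction widths through bounded fractions of their admissible ranges;
  # the junction is a local smoothing device, so it may not extend past
  # the end of the recording
  q_act <- stats::plogis(par[7L])
  q_de <- stats::plogis(par[8L])
  ell <- rp$t_de - rp$t_on
  rp$sigma_act <- 0.05 + 0.9 * q_act * ell
  rp$sigma_de <- (0.05 + 0.9 * q_de) * 2 * rp$gamma
  rp$sigma_de <- min(rp$sigma_de, 0.95 * 2 * rp$gamma,
                     0.9 * max(t_end - rp$t_de, 1e-3),
                     4 * max(ell, 0.5))
  list(resp = rp, drift = dp)
}

#' Fit the full transient response jointly with the drift
#'
#' Starts from the activation fit (feed-forward), adds the deactivation
#' parameters, and minimizes the value+derivative misfit plus a
#' secondary-drift area penalty weighted by the drift/response coherence
#' `kappa` and the drift objective weighted by `lambda` (ratio of post-
#' transient to activation derivative maxima).
#'
#' @param trace Tibble with `time`, `value`.
#' @param tvstate A [tv_iterate()] state.
#' @param delim A [delimit()] result.
#' @param act_fit An `activation_fit`.
#' @param config Optional [catrace_config()].
#' @param weights Optional per-sample reliability weights (used by the
#'   oscillation-aware refit); default all one.
#' @return List of class `response_fit`: `params` (response parameters incl.
#'   realised `sigma_act`, `sigma_de`, `m_de`), `drift`, `kappa`, `lambda`,
#'   `value`, `flags`.
#' @export
fit_response <- function(trace, tvstate, delim, act_fit, config = NULL,
                         weights = NULL) {
  cfg <- as_catrace_config(config)
  times <- trace$time
  F <- trace$value
  n <- length(F)
  t_end <- times[n]
  j <- tvstate$clean_idx
  phi <- max(tvstate$phi, 1e-6)
  Om <- weights %||% rep(1, n)
  ap <- act_fit$params
  dp <- act_fit$drift
  dt_min <- min(diff(times))
  span <- diff(range(times))

  # guard against a degenerate activation fit (amplitude or half-rise far
  # beyond the data scale) before feeding it forward
  rng <- diff(range(tvstate$Au))
  excess0 <- tvstate$Au - global_drift(times, dp)
  pk <- excess0[delim$i_max]
  if (!is.finite(ap$A_act) || ap$A_act > 3 * rng ||
      ap$beta > 2 * (times[delim$i_max] - ap$t_on + 1)) {
    ap <- list(t_on = ap$t_on, A_act = max(pk, 4 * tvstate$sigma_minus),
               beta = max((times[delim$i_max] - ap$t_on) / 2, dt_min),
               n_act = 2, m_act = 0)
  }

  # coherence between drift and response scales the secondary-drift penalty
  AuN <- tvstate$Au[n]
  g_peak <- activation_model(act_fit$t_max - ap$t_on, ap)
  base_win <- delim$i_act0:delim$i_max
  denom <- AuN - min(tvstate$Au[base_win])
  kappa <- if (abs(denom) > 1e-12) abs((AuN - g_peak) / denom) else 0
  post <- tvstate$u[seq_len(n) > delim$i_end0]
  act_win_max <- max(tvstate$u[base_win])
  lambda <- if (length(post) && act_win_max > 0) {
    max(abs(post)) / act_win_max
  } else 0

  k <- act_fit$k %||% NULL
  # drift penalty reuses the weighted pre/post index set
  kset <- if (!is.null(k)) k else {
    intersect(c(seq_len(delim$i_act0), delim$i_end0:n), tvstate$clean_idx)
  }
  wk <- rep(1, length(kset))

  # data-driven initialisation of the deactivation: start at the response
  # peak; half-decay time of the drift-corrected TV estimate seeds gamma
  t_de0 <- times[delim$i_max]
  post_ix <- delim$i_max:n
  half_ix <- post_ix[excess0[post_ix] <= pk / 2]
  gamma0 <- if (length(half_ix)) {
    max(times[min(half_ix)] - t_de0, 2 * dt_min)
  } else max((t_end - t_de0) / 3, 2 * dt_min)
  A_de0 <- max(pk, 4 * tvstate$sigma_minus)
  resid_fun <- function(par) {
    up <- unpack_resp(par, NULL, dp$t2, t_end)
    rp <- up$resp
    Gv <- global_response(times, rp, up$drift, t_end, FALSE)
    Gd <- global_response(times, rp, up$drift, t_end, TRUE)
    d2 <- drift_component(pmax(times - up$drift$t2, 0), up$drift$a2,
                          up$drift$tau2, up$drift$m2)
    c(phi * Om[j] * (F[j] - Gv[j]),
      sqrt(phi) * Om[j] * (tvstate$u[j] - Gd[j]),
      sqrt(kappa) * phi * d2[j],
      sqrt(lambda) * phi *
        drift_resid(up$drift, times[kset], F[kset], tvstate$u[kset], wk))
  }

  act_win <- max(times[delim$i_max] - ap$t_on, 2 * dt_min)
  ell0 <- max(t_de0 - ap$t_on, 2 * dt_min)
  lo <- c(times[delim$i_act0], 0, log(dt_min / 2), log(1), -Inf,
          log(dt_min), -4, -4, 0, log(dt_min), log(1),
          -Inf, log(dt_min), -Inf, -Inf, log(dt_min), -Inf, -Inf)
  hi <- c(times[delim$i_max], 3 * rng, log(2 * act_win), log(cfg$hill_n_max),
          Inf, log(span), 4, 4, 3 * rng, log(span),
          log(cfg$hill_n_max),
          Inf, log(10 * span), Inf, Inf, log(10 * span), Inf, Inf)
  gamma_starts <- unique(pmin(pmax(c(gamma0, (t_end - t_de0) / 3), dt_min),
                              span * 0.95))
  make_par0 <- function(g0, t_on0 = ap$t_on) {
    c(t_on0, min(ap$A_act, 3 * rng),
      min(log(ap$beta), log(2 * act_win) - 0.1), log(ap$n_act),
      ap$m_act, log(max(t_de0 - t_on0, 2 * dt_min)), 0, 0,
      min(A_de0, 3 * rng), log(g0), log(2),
      dp$a1, log(dp$tau1), dp$m1, dp$a2, log(dp$tau2), dp$m2, dp$z)
  }
  # amplitude of a candidate's drift-free response, for degeneracy screening
  cand_amp <- function(ft) {
    up <- unpack_resp(ft$par, NULL, dp$t2, t_end)
    max(response_model(seq(up$resp$t_on, t_end, length.out = 200),
                       up$resp, t_end))
  }
  # a second onset start only when the activation fit ran into its late
  # bound (its own optimum is then suspect)
  t_on_starts <- ap$t_on
  if (ap$t_on > times[delim$i_max] - 2 * dt_min) {
    t_on_starts <- unique(c(t_on_starts,
                            min(times[delim$i_act0] + dt_min,
                                times[delim$i_max] - dt_min)))
  }
  fits <- list()
  for (g0 in gamma_starts) {
    for (t0 in t_on_starts) {
      ft <- try(minpack.lm::nls.lm(make_par0(g0, t0), lower = lo, upper = hi,
                                   fn = resid_fun,
                                   control = minpack.lm::nls.lm.control(
                                     maxiter = 400)),
                silent = TRUE)
      if (!inherits(ft, "try-error")) fits <- c(fits, list(ft))
    }
  }
  fit <- NULL
  if (length(fits)) {
    dev <- vapply(fits, function(f) f$deviance, numeric(1))
    amps <- vapply(fits, cand_amp, numeric(1))
    # a transient was detected, so candidates that fit essentially no
    # response are degenerate local optima; prefer the others
    sane <- amps >= 4 * tvstate$sigma_minus
    pick <- if (any(sane)) which(sane)[which.min(dev[sane])] else
      which.min(dev)
    fit <- fits[[pick]]
  }
  if (is.null(fit)) {
    par0 <- make_par0(gamma_starts[1L])
    up <- unpack_resp(par0, NULL, dp$t2, t_end)
    rp <- response_pars(up$resp, t_end)
    return(structure(list(params = rp, drift = dp, kappa = kappa,
                          lambda = lambda, value = NA_real_, t_end = t_end,
                          kset = kset, flags = "response_solver_failed"),
                     class = "response_fit"))
  }
  up <- unpack_resp(fit$par, NULL, dp$t2, t_end)
  rp <- response_pars(up$resp, t_end)
  structure(list(params = rp, drift = up$drift, kappa = kappa,
                 lambda = lambda, value = fit$deviance, t_end = t_end,
                 kset = kset, flags = character(0)),
            class = "response_fit")
}

#' Kinetic and magnitude parameters of a fitted transient
#'
#' Evaluated on a time grid ten times finer than the samples: amplitude
#' (max of the drift-free response), 10-90% rise time, full width at half
#' maximum, area under the response by the trapezoidal rule, the
#' deactivation inflection time `rho = t_de + gamma * ((n_de - 1) /
#' (n_de + 1))^(1/n_de)`, and the decay constant of a mono-exponential
#' least-squares fit to the drift-corrected data after `rho`.
#'
#' @param response_fit A `response_fit`.
#' @param trace Tibble with `time`, `value`.
#' @param tvstate A [tv_iterate()] state (spike indices are excluded from
#'   the decay fit).
#' @param config Optional [catrace_config()].
#' @return Tibble with one row: `t_onset`, `t_10_90`, `amplitude`, `auc`,
#'   `fwhm`, `rho`, `tau_decay`, `flags`.
#' @export
extract_tr_metrics <- function(response_fit, trace, tvstate = NULL,
                               config = NULL) {
  cfg <- as_catrace_config(config)
  p <- response_fit$params
  times <- trace$time
  t_end <- times[length(times)]
  flags <- character(0)

  dt_fine <- min(diff(times)) / 10
  tg <- seq(p$t_on, t_end, by = dt_fine)
  g <- response_model(tg, p, t_end)
  amp <- max(g)
  i_pk <- which.max(g)

  cross_up <- function(level) {
    ix <- which(g[seq_len(i_pk)] >= level)
    if (!length(ix)) return(tg[1L])
    i1 <- min(ix)
    if (i1 == 1L) return(tg[1L])
    approx(g[(i1 - 1L):i1], tg[(i1 - 1L):i1], xout = level)$y
  }
  cross_down <- function(level) {
    seg <- g[i_pk:length(g)]
    ix <- which(seg <= level)
    if (!length(ix)) return(tg[length(tg)])
    i1 <- min(ix)
    if (i1 == 1L) return(tg[i_pk])
    approx(seg[(i1 - 1L):i1], tg[i_pk + (i1 - 2L):(i1 - 1L)], xout = level)$y
  }

  t10 <- cross_up(0.1 * amp)
  t90 <- cross_up(0.9 * amp)
  t_10_90 <- t90 - t10
  fwhm <- cross_down(amp / 2) - cross_up(amp / 2)
  auc <- pracma::trapz(tg, g)

  n_de <- p$n_de
  if (n_de > 1) {
    rho <- p$t_de + p$gamma * ((n_de - 1) / (n_de + 1))^(1 / n_de)
  } else {
    rho <- p$t_de
    flags <- c(flags, "rho_undefined")
  }

  tau_decay <- NA_real_
  tail_ix <- which(times > rho)
  if (!is.null(tvstate)) {
    tail_ix <- setdiff(tail_ix, tvstate$spike_idx)
    # once the fitted response has decayed below the noise floor the
    # drift-corrected data carry no decay information, only drift error
    resp_tail <- response_model(times[tail_ix], p, t_end)
    if (sum(resp_tail > 0.5 * tvstate$sigma_minus) >= cfg$min_tail_points) {
      tail_ix <- tail_ix[resp_tail > 0.5 * tvstate$sigma_minus]
    }
  }
  if (length(tail_ix) >= cfg$min_tail_points) {
    yt <- trace$value[tail_ix] - global_drift(times[tail_ix], response_fit$drift)
    tt <- times[tail_ix] - rho
    y0 <- max(yt[1L], 1e-8)
    rfun <- function(par) par[1L] * exp(-tt / exp(par[2L])) - yt
    ft <- try(minpack.lm::nls.lm(c(y0, log(max(p$gamma, 1))), fn = rfun,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 200)),
              silent = TRUE)
    if (!inherits(ft, "try-error")) {
      tau_decay <- exp(ft$par[2L])
    } else {
      flags <- c(flags, "tau_decay_failed")
    }
  } else {
    flags <- c(flags, "tau_decay_too_few_points")
  }

  tibble::tibble(t_onset = p$t_on, t_10_90 = t_10_90, amplitude = amp,
                 auc = auc, fwhm = fwhm, rho = rho, tau_decay = tau_decay,
                 flags = list(flags))
}
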
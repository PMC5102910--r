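# Baseline drift: saturating-exponential + linear components in up to two
# epochs, delimited from the transient using the TV derivative estimate and
# fitted by successive (then derivative-weighted) least squares.

#' Single drift component
#'
#' `d(t) = a * (1 - exp(-t / tau)) + m * t`: a saturating exponential of
#' amplitude `a` (a.u.) and time constant `tau` (s) plus a linear trend of
#' slope `m` (a.u./s).
#'
#' @param t Time (s), vectorized.
#' @param a,tau,m Component parameters; `tau > 0`.
#' @return Drift values (a.u.).
#' @export
drift_component <- function(t, a, tau, m) {
  if (tau <= 0) stop("tau must be > 0")
  a * (1 - exp(-t / tau)) + m * t
}

drift_component_deriv <- function(t, a, tau, m) {
  a / tau * exp(-t / tau) + m
}

#' Global (two-epoch) drift model
#'
#' The initial drift `d1` acts throughout; a secondary drift `d2` starts at
#' `t2` and adds to it, with `z` the offset at `t = 0`:
#' `D(t) = d1(t) + z` for `t < t2`, `d1(t) + d2(t - t2) + z` for `t >= t2`.
#' Continuous at `t2` since `d2(0) = 0`.
#'
#' @param t Time (s), vectorized.
#' @param params Named list/vector with `a1, tau1, m1, a2, tau2, m2, t2, z`.
#' @return Drift values (a.u.).
#' @export
global_drift <- function(t, params) {
  p <- as.list(params)
  d <- drift_component(t, p$a1, p$tau1, p$m1) + p$z
  late <- t >= p$t2
  if (any(late)) {
    d[late] <- d[late] + drift_component(t[late] - p$t2, p$a2, p$tau2, p$m2)
  }
  d
}

#' @rdname global_drift
#' @export
global_drift_deriv <- function(t, params) {
  p <- as.list(params)
  dd <- drift_component_deriv(t, p$a1, p$tau1, p$m1)
  late <- t >= p$t2
  if (any(late)) {
    dd[late] <- dd[late] + drift_component_deriv(t[late] - p$t2, p$a2, p$tau2, p$m2)
  }
  dd
}

# local maxima of a sequence (plateau-tolerant: >= both neighbours)
local_maxima <- function(u) {
  n <- length(u)
  if (n < 3L) return(integer(0))
  which(u >= c(-Inf, u[-n]) & u >= c(u[-1L], -Inf))
}

#' Delimit the transient epoch from the drift-dominated epochs
#'
#' Statistical analysis of the TV derivative estimate locates the indices
#' bracketing the transient: the earliest likely activation `i_act0`, the
#' derivative maxima considered significant (`i_local`), the response peak
#' `i_max`, and the end of deactivation `i_end0` after which the signal is
#' drift-dominated again.
#'
#' @param trace Tibble with `time`, `value` (one trace).
#' @param tvstate Converged [tv_iterate()] state.
#' @return A list of class `delimitation`: `i_local`, `i_act0`, `i_max0`,
#'   `i_max_end`, `i_max`, `i_end0`, `nu_minus`, `mu`, `n_end`, `i_plus0`.
#'   `i_local` is empty (and the other indices `NA`) when no derivative
#'   maximum is significant, in which case no transient is detectable.
#' @export
delimit <- function(trace, tvstate) {
  u <- tvstate$u
  Au <- tvstate$Au
  times <- tvstate$times
  n <- length(u)
  empty <- structure(list(i_local = integer(0), i_act0 = NA_integer_,
                          i_max0 = NA_integer_, i_max_end = NA_integer_,
                          i_max = NA_integer_, i_end0 = NA_integer_,
                          nu_minus = numeric(0), mu = numeric(0),
                          n_end = NA_integer_, i_plus0 = NA_integer_),
                     class = "delimitation")
  s_all <- sd(u)
  if (!is.finite(s_all) || s_all == 0) return(empty)

  cand <- local_maxima(u)
  i_local <- cand[u[cand] > s_all]
  if (length(i_local) == 0L) return(empty)
  i_local0 <- min(i_local)

  # window of non-negative derivative running up to the first significant max
  i_plus0 <- i_local0
  while (i_plus0 > 1L && u[i_plus0 - 1L] >= 0) i_plus0 <- i_plus0 - 1L

  win <- u[i_plus0:i_local0]
  s_win <- sd(win)
  if (!is.finite(s_win) || s_win == 0) {
    i_act0 <- i_plus0
  } else {
    below <- which(win < s_win)
    i_act0 <- if (length(below)) i_plus0 + max(below) - 1L else i_plus0
  }

  # baseline value and activation rate around every significant maximum
  n_local <- length(i_local)
  q_idx <- r_idx <- integer(n_local)
  for (s in seq_len(n_local)) {
    r0 <- i_local[s]
    qs <- which(u[seq_len(r0 - 1L)] <= 0)
    q_idx[s] <- if (length(qs)) max(qs) else 1L
    rs <- which(u <= 0 & seq_len(n) > r0)
    r_idx[s] <- if (length(rs)) min(rs) else n
  }
  nu_minus <- Au[q_idx] +
    (times[r_idx] - times[q_idx]) * (u[pmax(r_idx - 1L, 1L)] + u[r_idx]) / 2
  mu <- (Au[r_idx] - nu_minus) /
    pmax(times[r_idx] - times[q_idx], .Machine$double.eps)

  ok <- mu >= mean(mu) - 3 * sd0(mu) & nu_minus > mean(nu_minus) - sd0(nu_minus)
  i_max0 <- if (any(ok)) i_local[min(which(ok))] else i_local0

  # first point past i_max0 where the per-sample change drops below noise
  h <- c(times[2L] - times[1L], diff(times))
  tail_ix <- i_max0:n
  drop_ix <- tail_ix[u[tail_ix] * h[tail_ix] < tvstate$sigma_minus]
  i_max_end <- if (length(drop_ix)) min(drop_ix) else n

  span <- i_max0:i_max_end
  i_max <- span[which.max(Au[span])][1L]

  # staircase test on |u| over the decay for the end of the transient;
  # a band level only counts if at least three samples exceed it (a single
  # exceedance is satisfied by one noisy derivative sample and would end
  # the transient immediately after its peak)
  i_decay <- i_max:n
  au <- abs(u[i_decay])
  m_au <- mean(au)
  s_au <- sd0(au)
  n_end <- 0L
  for (nn in 3:0) {
    if (sum(au - m_au > nn * s_au) >= 3L) { n_end <- nn; break }
  }
  exceed <- which(au - m_au > n_end * s_au)
  i_end0 <- if (length(exceed)) min(i_decay[max(exceed)] + 1L, n) else i_max

  # a slowly decaying response has a small derivative long before its value
  # becomes negligible; extend the end of deactivation until the data
  # estimate stays within noise of the end-of-record baseline, so the
  # post-transient drift window is not contaminated by the tail
  cap <- max(i_max + 1L, floor(0.9 * n))
  base <- median(Au[cap:n])
  runmax <- rev(cummax(rev(Au - base)))
  ok_val <- which(runmax < 2 * tvstate$sigma_minus)
  i_end0_val <- if (length(ok_val)) min(ok_val) else cap
  i_end0 <- min(max(i_end0, i_end0_val), cap)
  structure(list(i_local = i_local, i_act0 = as.integer(i_act0),
                 i_max0 = as.integer(i_max0), i_max_end = as.integer(i_max_end),
                 i_max = as.integer(i_max), i_end0 = as.integer(i_end0),
                 nu_minus = nu_minus, mu = mu, n_end = n_end,
                 i_plus0 = as.integer(i_plus0)),
            class = "delimitation")
}

# sample sd that returns 0 (not NA) for length-1 input
sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)

drift_par_vec <- function(p) {
  c(a1 = p$a1, tau1 = p$tau1, m1 = p$m1, a2 = p$a2, tau2 = p$tau2,
    m2 = p$m2, t2 = p$t2, z = p$z)
}

#' Initial drift fit
#'
#' Nonlinear least squares of the global drift model over the
#' pre-activation and post-deactivation samples only (intersected with the
#' spike-free index set). Multistart over decades of the exponential time
#' constant; bounded trust-region Levenberg-Marquardt.
#'
#' @param trace Tibble with `time`, `value`.
#' @param delim A [delimit()] result.
#' @param clean_idx Spike-free indices (from the TV state).
#' @param config Optional [catrace_config()].
#' @return Named list of class `drift_fit`: parameters (`a1 ... z`), fitted
#'   index set `k`, objective value, and `flags`.
#' @export
fit_drift_initial <- function(trace, delim, clean_idx, config = NULL) {
  cfg <- as_catrace_config(config)
  times <- trace$time
  F <- trace$value
  n <- length(F)
  flags <- character(0)

  if (length(delim$i_local) == 0L || is.na(delim$i_act0)) {
    k <- clean_idx
  } else {
    k <- intersect(c(seq_len(delim$i_act0), delim$i_end0:n), clean_idx)
  }
  t2_fix <- if (!is.na(delim$i_end0)) times[delim$i_end0] else times[n]

  if (length(k) < 8L) {
    pre <- if (!is.na(delim$i_act0)) F[seq_len(delim$i_act0)] else F
    p <- list(a1 = 0, tau1 = diff(range(times)) / 3, m1 = 0, a2 = 0,
              tau2 = diff(range(times)) / 3, m2 = 0, t2 = t2_fix,
              z = median(pre))
    return(structure(list(params = p, k = k, value = NA_real_,
                          flags = c(flags, "too_few_drift_points")),
                     class = "drift_fit"))
  }

  tk <- times[k]
  Fk <- F[k]
  span <- diff(range(times))
  slope0 <- if (length(k) > 2) coef(lm(Fk ~ tk))[[2L]] else 0
  z0 <- Fk[which.min(tk)]

  resid_fun <- function(par) {
    p <- list(a1 = par[1L], tau1 = exp(par[2L]), m1 = par[3L],
              a2 = par[4L], tau2 = exp(par[5L]), m2 = par[6L],
              t2 = t2_fix, z = par[7L])
    global_drift(tk, p) - Fk
  }
  dt_min <- min(diff(times))
  lo <- c(-Inf, log(dt_min), -Inf, -Inf, log(dt_min), -Inf, -Inf)
  hi <- c(Inf, log(10 * span), Inf, Inf, log(10 * span), Inf, Inf)

  starts <- exp(seq(log(span / 10), log(span),
                    length.out = max(cfg$drift_multistart, 1L)))
  best <- NULL
  for (tau0 in starts) {
    par0 <- c(0, log(tau0), slope0, 0, log(tau0), 0, z0)
    fit <- try(minpack.lm::nls.lm(par0, lower = lo, upper = hi,
                                  fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    p <- list(a1 = 0, tau1 = span / 3, m1 = 0, a2 = 0, tau2 = span / 3,
              m2 = 0, t2 = t2_fix, z = median(Fk))
    return(structure(list(params = p, k = k, value = NA_real_,
                          flags = c(flags, "drift_solver_failed")),
                     class = "drift_fit"))
  }
  par <- best$par
  p <- list(a1 = par[1L], tau1 = exp(par[2L]), m1 = par[3L], a2 = par[4L],
            tau2 = exp(par[5L]), m2 = par[6L], t2 = t2_fix, z = par[7L])
  structure(list(params = p, k = k, value = best$deviance, flags = flags),
            class = "drift_fit")
}

# weighted drift objective residuals used in later joint fits
drift_resid <- function(par_list, tk, Fk, uk, w) {
  r1 <- sqrt(w) * (global_drift(tk, par_list) - Fk)
  r2 <- sqrt(w) * (global_drift_deriv(tk, par_list) - uk)
  c(r1, r2)
}

#' Derivative-weighted drift refit
#'
#' Reweights the drift objective with `w_k = exp(-y^2 / mean(y^2))`,
#' `y = |u_hat - dD/dt(theta0)|`, so samples whose observed derivative
#' disagrees with the current drift trend (e.g. an unrelated early baseline
#' shift) lose influence, then refits values and derivatives jointly.
#'
#' @param trace Tibble with `time`, `value`.
#' @param tvstate A [tv_iterate()] state.
#' @param theta0 A `drift_fit` from [fit_drift_initial()].
#' @param config Optional [catrace_config()].
#' @return A `drift_fit` with refined parameters and the weight vector `w`
#'   (on the fitted index set).
#' @export
fit_drift_weighted <- function(trace, tvstate, theta0, config = NULL) {
  times <- trace$time
  F <- trace$value
  k <- theta0$k
  if (length(k) < 8L) {
    theta0$w <- rep(1, length(k))
    theta0$flags <- c(theta0$flags, "weighted_refit_skipped")
    return(theta0)
  }
  tk <- times[k]
  Fk <- F[k]
  uk <- tvstate$u[k]

  y <- abs(uk - global_drift_deriv(tk, theta0$params))
  msq <- mean(y^2)
  w <- if (msq > 0) exp(-y^2 / msq) else rep(1, length(y))

  p0 <- theta0$params
  span <- diff(range(times))
  dt_min <- min(diff(times))
  resid_fun <- function(par) {
    p <- list(a1 = par[1L], tau1 = exp(par[2L]), m1 = par[3L],
              a2 = par[4L], tau2 = exp(par[5L]), m2 = par[6L],
              t2 = p0$t2, z = par[7L])
    drift_resid(p, tk, Fk, uk, w)
  }
  par0 <- c(p0$a1, log(p0$tau1), p0$m1, p0$a2, log(p0$tau2), p0$m2, p0$z)
  lo <- c(-Inf, log(dt_min), -Inf, -Inf, log(dt_min), -Inf, -Inf)
  hi <- c(Inf, log(10 * span), Inf, Inf, log(10 * span), Inf, Inf)
  fit <- try(minpack.lm::nls.lm(par0, lower = lo, upper = hi, fn = resid_fun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    theta0$w <- w
    theta0$flags <- c(theta0$flags, "weighted_drift_solver_failed")
    return(theta0)
  }
  par <- fit$par
  p <- list(a1 = par[1L], tau1 = exp(par[2L]), m1 = par[3L], a2 = par[4L],
            tau2 = exp(par[5L]), m2 = par[6L], t2 = p0$t2, z = par[7L])
  structure(list(params = p, k = k, value = fit$deviance, w = w,
                 flags = theta0$flags),
            class = "drift_fit")
}

# weighted drift sum of squares at arbitrary parameters (used by detection
# and by the joint activation/response objectives)
drift_objective <- function(params, trace, tvstate, k, w) {
  tk <- trace$time[k]
  sum(drift_resid(params, tk, trace$value[k], tvstate$u[k], w)^2)
}
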
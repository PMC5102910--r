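# Multi-peaked responses: deviations of the data estimate from the fitted
# transient baseline, reliability-weighted refit of the transient, coherent
# oscillation identification by Gaussian-mixture clustering with a gap
# statistic, and the oscillatory summary parameters.

# linear-interpolated full width at half maximum of one event in signal r
event_fwhm <- function(tt, r, idx, dt) {
  half <- r[idx] / 2
  n <- length(r)
  # walk left until below half or a rising valley
  left <- idx
  while (left > 1L && r[left - 1L] > half && r[left - 1L] <= r[left]) {
    left <- left - 1L
  }
  tL <- if (left > 1L && r[left - 1L] <= half) {
    approx(r[(left - 1L):left], tt[(left - 1L):left], xout = half)$y
  } else tt[left] - dt / 2
  right <- idx
  while (right < n && r[right + 1L] > half && r[right + 1L] <= r[right]) {
    right <- right + 1L
  }
  tR <- if (right < n && r[right + 1L] <= half) {
    approx(r[right:(right + 1L)], tt[right:(right + 1L)], xout = half)$y
  } else tt[right] + dt / 2
  max(tR - tL, dt / 2)
}

find_events <- function(tt, r, min_height, min_dist_s) {
  dt <- median(diff(tt))
  min_dist <- max(1L, round(min_dist_s / dt))
  pk <- pracma::findpeaks(r, minpeakheight = min_height,
                          minpeakdistance = min_dist)
  if (is.null(pk)) {
    return(tibble::tibble(time = numeric(0), height = numeric(0),
                          fwhm = numeric(0)))
  }
  pk <- pk[order(pk[, 2L]), , drop = FALSE]
  tibble::tibble(
    time = tt[pk[, 2L]],
    height = pk[, 1L],
    fwhm = vapply(pk[, 2L], function(i) event_fwhm(tt, r, i, dt), numeric(1))
  )
}

# fitted transient baseline truncated at half maximum, allowing a first
# oscillation peak to coincide with the transient onset
truncated_baseline <- function(trace, response_fit) {
  times <- trace$time
  D <- global_drift(times, response_fit$drift)
  if (is.null(response_fit$params)) return(D)
  g <- response_model(times, response_fit$params, response_fit$t_end)
  D + pmin(g, max(g) / 2)
}

#' Find oscillatory deviations from the fitted transient
#'
#' Peaks and troughs of the residual between the TV data estimate and the
#' fitted transient baseline truncated at its half maximum. Events must be
#' at least `mpr_min_height_sigma * sigma_minus` high and
#' `mpr_min_spacing_s` seconds apart.
#'
#' @param trace Tibble with `time`, `value`.
#' @param tvstate A [tv_iterate()] state.
#' @param response_fit A `response_fit`, or a bare list with `drift` (and
#'   `params = NULL`) when no transient was detected.
#' @param config Optional [catrace_config()].
#' @return A tibble of class `deviation_set`: one row per event with
#'   `time`, `height`, `fwhm`, `type` (peak/trough), `period` (interval to
#'   the previous same-type event, the first event inheriting the next
#'   interval), and `coherent` (filled by [cluster_coherent()]).
#' @export
find_deviations <- function(trace, tvstate, response_fit, config = NULL) {
  cfg <- as_catrace_config(config)
  base <- truncated_baseline(trace, response_fit)
  r <- tvstate$Au - base
  min_h <- cfg$mpr_min_height_sigma * tvstate$sigma_minus
  pks <- find_events(trace$time, r, min_h, cfg$mpr_min_spacing_s)
  trs <- find_events(trace$time, -r, min_h, cfg$mpr_min_spacing_s)
  ev <- dplyr::bind_rows(
    dplyr::mutate(pks, type = "peak"),
    dplyr::mutate(trs, type = "trough")
  )
  ev <- dplyr::arrange(ev, .data$time)
  ev$period <- NA_real_
  for (ty in c("peak", "trough")) {
    ix <- which(ev$type == ty)
    if (length(ix) >= 2L) {
      gaps <- diff(ev$time[ix])
      ev$period[ix] <- c(gaps[1L], gaps)
    }
  }
  ev$coherent <- NA
  class(ev) <- c("deviation_set", class(ev))
  ev
}

#' Peak/trough bias weights
#'
#' `o_peak = exp(-(E1_peak / E1_trough)^4)` and symmetrically for troughs:
#' when the first peak is much taller than the first trough the deviations
#' are treated as one-sided (above baseline), and vice versa. With no
#' trough the bias is fully toward peaks (`o_peak = 1`, `o_trough = 0`),
#' and symmetrically.
#'
#' @param deviations A `deviation_set`.
#' @return Named list `o_peak`, `o_trough`, both in `[0, 1]`.
#' @export
bias_weights <- function(deviations) {
  e1p <- deviations$height[deviations$type == "peak"][1L]
  e1t <- deviations$height[deviations$type == "trough"][1L]
  if (is.na(e1p) && is.na(e1t)) return(list(o_peak = 1, o_trough = 1))
  if (is.na(e1t)) return(list(o_peak = 1, o_trough = 0))
  if (is.na(e1p)) return(list(o_peak = 0, o_trough = 1))
  list(o_peak = exp(-(e1p / e1t)^4), o_trough = exp(-(e1t / e1p)^4))
}

#' Per-sample reliability weights around oscillatory deviations
#'
#' Combines Gaussian windows around each peak/trough (scaled by the bias
#' weights and the noise-to-signal ratio) with a derivative-agreement
#' factor `Gamma = exp(-((u - dG/dt) / (2 sd))^2)`:
#' `Omega_i = Gamma_i * (pi_peak + pi_trough - min pi_peak - min pi_trough)`.
#' Samples inside oscillation support get small weights, so a refit with
#' `Omega^2` recovers the underlying transient baseline.
#'
#' @param trace Tibble with `time`, `value`.
#' @param tvstate A [tv_iterate()] state.
#' @param response_fit A `response_fit`.
#' @param deviations A `deviation_set`.
#' @param o Optional [bias_weights()] result (computed if missing).
#' @return Numeric vector `Omega`, length `nrow(trace)`, non-negative.
#' @export
reliability_weights <- function(trace, tvstate, response_fit, deviations,
                                o = NULL) {
  o <- o %||% bias_weights(deviations)
  times <- trace$time
  n <- length(times)
  phi <- max(tvstate$phi, 1e-6)

  # Each summand o*e + (1-o)*(1-e) down-weights the window around the
  # deviation only for o < 1/2 (above that it inverts; at o ~ 0 the term
  # collapses), so the bias values are clamped into [0.05, exp(-1)] before
  # building the windows. The window width is the event's own FWHM: scaling
  # it by the noise-to-signal ratio or the bias widens it past the
  # oscillation period and the weights lose all locality.
  pi_of <- function(type, o_this) {
    ev <- deviations[deviations$type == type, ]
    if (nrow(ev) == 0L) return(rep(0, n))
    o_this <- min(max(o_this, 0.05), exp(-1))
    acc <- numeric(n)
    for (r in seq_len(nrow(ev))) {
      e <- exp(-((times - ev$time[r]) / ev$fwhm[r])^2)
      acc <- acc + o_this * e + (1 - o_this) * (1 - e)
    }
    acc
  }
  pi_peak <- pi_of("peak", o$o_peak)
  pi_trough <- pi_of("trough", o$o_trough)

  Gd <- global_response(times, response_fit$params, response_fit$drift,
                        response_fit$t_end, deriv = TRUE)
  resid_d <- tvstate$u - Gd
  s <- sd(resid_d)
  Gamma <- if (s > 0) exp(-(resid_d / (2 * s))^2) else rep(1, n)
  Omega <- Gamma * (pi_peak + pi_trough - min(pi_peak) - min(pi_trough))
  pmax(Omega, 0)
}

#' Oscillation-aware refit of the transient
#'
#' Reruns the response fit with the squared reliability weights so the
#' transient baseline is estimated from the samples not dominated by
#' oscillatory deviations. Skipped when there are two deviations or fewer
#' (the transient itself is then the only deviation).
#'
#' @param trace,tvstate,delim,act_fit As in [fit_response()].
#' @param response_fit The unweighted `response_fit`.
#' @param Omega Weights from [reliability_weights()].
#' @param config Optional [catrace_config()].
#' @return A `response_fit`.
#' @export
refit_response_weighted <- function(trace, tvstate, delim, act_fit,
                                    response_fit, Omega, config = NULL) {
  fit <- try(fit_response(trace, tvstate, delim, act_fit, config = config,
                          weights = Omega),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    response_fit$flags <- c(response_fit$flags, "weighted_refit_failed")
    return(response_fit)
  }
  fit
}

# within-cluster dispersion (total within-cluster sum of squares)
wss_of <- function(X, cl) {
  sum(vapply(split(seq_len(nrow(X)), cl), function(ix) {
    Xi <- X[ix, , drop = FALSE]
    sum(scale(Xi, scale = FALSE)^2)
  }, numeric(1)))
}

# EM mixture clustering for a fixed k with mclust; kmeans fallback for
# degenerate covariances
gmm_classify <- function(X, k) {
  if (k == 1L) return(rep(1L, nrow(X)))
  cl <- tryCatch({
    fit <- mclust::Mclust(X, G = k, verbose = FALSE)
    if (is.null(fit)) NULL else fit$classification
  }, error = function(e) NULL)
  if (is.null(cl) || length(unique(cl)) < k) {
    cl <- tryCatch(stats::kmeans(X, centers = k, nstart = 5)$cluster,
                   error = function(e) rep(1L, nrow(X)))
  }
  cl
}

# gap statistic over k = 1..kmax with B uniform reference draws
gap_statistic <- function(X, kmax, B) {
  n <- nrow(X)
  rng <- apply(X, 2L, range)
  logW <- numeric(kmax)
  cls <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    cls[[k]] <- gmm_classify(X, k)
    logW[k] <- log(max(wss_of(X, cls[[k]]), 1e-12))
  }
  logWref <- matrix(0, B, kmax)
  for (b in seq_len(B)) {
    Xb <- apply(rng, 2L, function(r) runif(n, r[1L], r[2L]))
    for (k in seq_len(kmax)) {
      logWref[b, k] <- log(max(wss_of(Xb, gmm_classify(Xb, k)), 1e-12))
    }
  }
  gap <- colMeans(logWref) - logW
  sk <- apply(logWref, 2L, sd) * sqrt(1 + 1 / B)
  k_opt <- kmax
  for (k in seq_len(kmax - 1L)) {
    if (gap[k] >= gap[k + 1L] - sk[k + 1L]) { k_opt <- k; break }
  }
  list(k = k_opt, classification = cls[[k_opt]], gap = gap, sk = sk)
}

#' Identify the coherent subset of oscillatory deviations
#'
#' Standardized (period, width) pairs of the deviations are clustered with
#' a Gaussian mixture model (EM), the number of clusters chosen by the gap
#' statistic against uniform reference draws. The largest cluster seeds the
#' coherent set; temporally adjacent clusters are merged when a linear
#' trend of period and width over the current coherent events predicts the
#' adjacent cluster's first event within twice the residual spread. All
#' stochastic steps are driven by `config$seed`.
#'
#' @param deviations A `deviation_set`.
#' @param config Optional [catrace_config()] (uses `gmm_kmax`, `gap_B`,
#'   `seed`).
#' @return The `deviation_set` with the logical `coherent` column filled.
#' @export
cluster_coherent <- function(deviations, config = NULL) {
  cfg <- as_catrace_config(config)
  ev <- deviations
  n <- nrow(ev)
  if (n <= 2L) {
    ev$coherent <- rep(TRUE, n)
    return(ev)
  }
  feat_ok <- is.finite(ev$period) & is.finite(ev$fwhm)
  X <- cbind(T = ev$period[feat_ok], xi = ev$fwhm[feat_ok])
  if (nrow(X) < 3L) {
    ev$coherent <- rep(TRUE, n)
    return(ev)
  }
  Xs <- scale(X)
  Xs[, !is.finite(colSums(Xs))] <- 0

  kmax <- max(1L, min(cfg$gmm_kmax, floor(n / 2)))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(cfg$seed)
  gs <- gap_statistic(Xs, kmax, cfg$gap_B)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  cl <- gs$classification
  idx <- which(feat_ok)
  times <- ev$time[idx]

  # order clusters by first event time; seed with the largest
  cl_ids <- unique(cl[order(times)])
  sizes <- vapply(cl_ids, function(g) sum(cl == g), integer(1))
  core <- cl_ids[which.max(sizes)]
  accepted <- core
  pos_core <- which(cl_ids == core)

  predict_ok <- function(acc_ids, cand_id) {
    acc <- which(cl %in% acc_ids)
    cand <- which(cl == cand_id)
    if (length(acc) < 2L || !length(cand)) return(FALSE)
    first <- cand[which.min(times[cand])]
    tol <- function(col) {
      y <- X[acc, col]
      if (length(unique(times[acc])) < 2L) {
        pred <- mean(y)
        res_sd <- sd0(y)
      } else {
        fit <- lm(y ~ times[acc])
        pred <- unname(coef(fit)[1L] + coef(fit)[2L] * times[first])
        res_sd <- sd0(stats::residuals(fit))
      }
      band <- 2 * max(res_sd, 0.1 * abs(mean(y)), 1e-8)
      abs(X[first, col] - pred) <= band
    }
    tol(1L) && tol(2L)
  }

  # grow outwards over temporally adjacent clusters
  repeat {
    grown <- FALSE
    for (dpos in c(-1L, 1L)) {
      pos <- if (dpos < 0) min(match(accepted, cl_ids)) - 1L else
        max(match(accepted, cl_ids)) + 1L
      if (pos >= 1L && pos <= length(cl_ids) &&
          !(cl_ids[pos] %in% accepted) &&
          predict_ok(accepted, cl_ids[pos])) {
        accepted <- c(accepted, cl_ids[pos])
        grown <- TRUE
      }
    }
    if (!grown) break
  }

  coh <- rep(FALSE, n)
  coh[idx[cl %in% accepted]] <- TRUE
  # events without a defined period join the coherent set if their nearest
  # same-type neighbour is coherent
  for (i in which(!feat_ok)) {
    same <- which(ev$type == ev$type[i] & feat_ok)
    if (length(same)) {
      nb <- same[which.min(abs(ev$time[same] - ev$time[i]))]
      coh[i] <- coh[nb]
    }
  }
  ev$coherent <- coh
  # the coherent subset must be at least as regular as the full set; if the
  # clustering produced a subset with larger period spread it has failed
  # (e.g. dropped a train member, merging two gaps) and all deviations are
  # treated as one coherent set
  s_all <- mpr_metrics(ev, "all")$sigma_T
  s_coh <- mpr_metrics(ev, "coherent")$sigma_T
  if (is.finite(s_all) && is.finite(s_coh) && s_coh > s_all) {
    ev$coherent <- rep(TRUE, n)
  }
  ev
}

#' Oscillatory summary parameters
#'
#' The six oscillation parameters over all events or over the coherent
#' subset: number of peaks, mean magnitude (mean peak height plus mean
#' trough height), mean and standard deviation of the inter-peak period,
#' persistence (first to last peak), and mean duty cycle (mean peak width
#' over mean period).
#'
#' @param deviations A `deviation_set` (after [cluster_coherent()] when
#'   `which = "coherent"`).
#' @param which `"all"` or `"coherent"`.
#' @return One-row tibble: `n_osc`, `magnitude_E`, `period_T`, `sigma_T`,
#'   `persistence`, `duty_cycle`.
#' @export
mpr_metrics <- function(deviations, which = c("all", "coherent")) {
  which <- match.arg(which)
  ev <- deviations
  if (which == "coherent") ev <- ev[!is.na(ev$coherent) & ev$coherent, ]
  pk <- ev[ev$type == "peak", ]
  tr <- ev[ev$type == "trough", ]
  n_osc <- nrow(pk)
  mag <- mean(pk$height)
  if (nrow(tr)) mag <- mag + mean(tr$height)
  if (n_osc >= 2L) {
    gaps <- diff(sort(pk$time))
    period_T <- mean(gaps)
    sigma_T <- sd0(gaps)
    persistence <- max(pk$time) - min(pk$time)
    duty <- mean(pk$fwhm) / period_T
  } else {
    period_T <- sigma_T <- persistence <- duty <- NA_real_
  }
  tibble::tibble(n_osc = n_osc, magnitude_E = mag, period_T = period_T,
                 sigma_T = sigma_T, persistence = persistence,
                 duty_cycle = duty)
}
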
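flat_drift <- list(a1 = 0, tau1 = 40, m1 = 0, a2 = 0, tau2 = 40, m2 = 0,
                   t2 = 60, z = 1)

osc_spec <- function(seed, amplitude_sigma = 10, period = 12, n_cycles = 8,
                     noise_sd = 0.01, fwhm = 3, jitter = 0) {
  fixture_spec(seed = seed, drift = flat_drift, tr = NULL,
               osc = list(period = period,
                          amplitude = amplitude_sigma * noise_sd * 0.8,
                          n_cycles = n_cycles, jitter_sd = jitter,
                          fwhm = fwhm, start = 15),
               noise_sd = noise_sd)
}

drift_only_fit <- function(trace, st) {
  list(params = NULL,
       drift = flat_drift,
       t_end = trace$time[nrow(trace)])
}

test_that("deviations of a sinusoid are found; sub-threshold ones are not", {
  # 8 full cycles of a 12 s sinusoid on a flat baseline
  set.seed(1)
  t <- seq(0, 119.5, by = 0.5)
  osc_win <- t >= 10 & t < 10 + 8 * 12
  sino <- ifelse(osc_win, 0.1 * sin(2 * pi * (t - 10) / 12 - pi / 2), 0)
  trace <- tibble::tibble(time = t, value = 1 + sino + rnorm(240, sd = 0.01))
  st <- tv_iterate(trace$time, trace$value)
  base <- drift_only_fit(trace, st)
  expect_gt(0.1, 6 * st$sigma_minus)   # amplitude is ~10 sigma_minus
  dev <- find_deviations(trace, st, base)
  pk <- dev[dev$type == "peak", ]
  expect_equal(nrow(pk), 8)
  expect_true(nrow(dev[dev$type == "trough", ]) %in% c(7, 8, 9))
  centers <- 10 + 6 + 12 * (0:7)
  expect_lt(max(abs(sort(pk$time) - centers)), 1.5)

  # amplitude below the 6 sigma_minus threshold: nothing is reported
  trace2 <- tibble::tibble(time = t,
                           value = 1 + 0.3 * sino + rnorm(240, sd = 0.01))
  st2 <- tv_iterate(trace2$time, trace2$value)
  expect_lt(0.03, 6 * st2$sigma_minus)
  dev2 <- find_deviations(trace2, st2, drift_only_fit(trace2, st2))
  expect_equal(nrow(dev2[dev2$type == "peak", ]), 0)

  # identically zero residual
  tr0 <- tibble::tibble(time = t, value = rep(1, 240))
  st0 <- tv_iterate(tr0$time, tr0$value)
  dev0 <- find_deviations(tr0, st0, list(params = NULL,
                                         drift = modifyList(flat_drift,
                                                            list(z = 1)),
                                         t_end = 119.5))
  expect_equal(nrow(dev0), 0)
})

test_that("bias weights follow the first-peak/first-trough ratio formula", {
  ev <- make_deviation_set(time = c(10, 16), fwhm = c(3, 3),
                           period = c(12, 12), type = c("peak", "trough"),
                           height = c(1, 1))
  o <- bias_weights(ev)
  expect_equal(o$o_peak, exp(-1))
  expect_equal(o$o_trough, exp(-1))

  ev2 <- make_deviation_set(time = c(10, 16), fwhm = c(3, 3),
                            period = c(12, 12), type = c("peak", "trough"),
                            height = c(3, 1))
  o2 <- bias_weights(ev2)
  expect_equal(o2$o_peak, exp(-81))
  expect_equal(o2$o_trough, exp(-1 / 81))

  # swapping labels (keeping each event's height) swaps the weights
  ev3 <- ev2
  ev3$type <- rev(ev3$type)
  o3 <- bias_weights(ev3)
  expect_equal(o3$o_peak, o2$o_trough)
  expect_equal(o3$o_trough, o2$o_peak)

  # missing troughs: all-peak bias
  ev4 <- make_deviation_set(time = c(10, 22), fwhm = 3, period = 12,
                            type = "peak")
  expect_equal(bias_weights(ev4), list(o_peak = 1, o_trough = 0))
})

test_that("reliability weights down-weight oscillation epochs", {
  tr_par <- fixture_spec()$tr
  spec <- fixture_spec(seed = 5, drift = flat_drift, tr = tr_par,
                       osc = list(period = 12, amplitude = 0.25,
                                  n_cycles = 6, jitter_sd = 0.2, fwhm = 3,
                                  start = 30), noise_sd = 0.02)
  sim <- generate_trace(spec)
  st <- tv_iterate(sim$trace$time, sim$trace$value)
  dl <- delimit(sim$trace, st)
  d0 <- fit_drift_initial(sim$trace, dl, st$clean_idx)
  dw <- fit_drift_weighted(sim$trace, st, d0)
  af <- fit_activation(sim$trace, st, dl, dw)
  rf <- fit_response(sim$trace, st, dl, af)
  dev <- find_deviations(sim$trace, st, rf)
  Om <- reliability_weights(sim$trace, st, rf, dev)
  expect_true(all(Om >= 0))
  centers <- sim$truth$osc$centers
  on_osc <- sapply(sim$trace$time, function(x) any(abs(x - centers) < 2))
  quiet <- sim$trace$time < 9
  expect_lt(mean(Om[on_osc]), mean(Om[quiet]))
})

test_that("the weighted refit improves the transient estimate under oscillations", {
  # oscillations overlapping the transient peak bias the unweighted fit
  wins <- logical(20)
  for (s in 1:20) {
    tr_par <- fixture_spec()$tr
    spec <- fixture_spec(seed = s, drift = flat_drift, tr = tr_par,
                         osc = list(period = 11, amplitude = 0.35,
                                    n_cycles = 8, jitter_sd = 0.2, fwhm = 4,
                                    start = 20), noise_sd = 0.02)
    sim <- generate_trace(spec)
    st <- tv_iterate(sim$trace$time, sim$trace$value)
    dl <- delimit(sim$trace, st)
    d0 <- fit_drift_initial(sim$trace, dl, st$clean_idx)
    dw <- fit_drift_weighted(sim$trace, st, d0)
    af <- fit_activation(sim$trace, st, dl, dw)
    rf <- fit_response(sim$trace, st, dl, af)
    dev <- find_deviations(sim$trace, st, rf)
    if (nrow(dev) <= 2) { wins[s] <- NA; next }
    Om <- reliability_weights(sim$trace, st, rf, dev)
    rf2 <- refit_response_weighted(sim$trace, st, dl, af, rf, Om)
    tg <- seq(11, 119.5, by = 0.05)
    amp_true <- sim$truth$tr$amplitude
    e1 <- abs(max(response_model(tg, rf$params, 119.5)) - amp_true)
    e2 <- abs(max(response_model(tg, rf2$params, 119.5)) - amp_true)
    wins[s] <- e2 <= e1 + 0.02 * amp_true
  }
  expect_gte(mean(wins, na.rm = TRUE), 0.8)
})

test_that("uniform weights reproduce the unweighted response optimum", {
  sim <- sim_trace(3)
  st <- tv_iterate(sim$trace$time, sim$trace$value)
  dl <- delimit(sim$trace, st)
  d0 <- fit_drift_initial(sim$trace, dl, st$clean_idx)
  dw <- fit_drift_weighted(sim$trace, st, d0)
  af <- fit_activation(sim$trace, st, dl, dw)
  rf <- fit_response(sim$trace, st, dl, af)
  rf1 <- fit_response(sim$trace, st, dl, af,
                      weights = rep(1, nrow(sim$trace)))
  tg <- seq(0, 119.5, by = 0.5)
  expect_equal(response_model(tg, rf1$params, 119.5),
               response_model(tg, rf$params, 119.5), tolerance = 1e-6)
})

test_that("clustering keeps a strictly periodic train and rejects far outliers", {
  # strictly periodic: one tight cluster, all coherent
  ev <- make_deviation_set(time = seq(10, 94, by = 12), fwhm = 3, period = 12)
  ev1 <- cluster_coherent(ev, catrace_config(seed = 1))
  expect_true(all(ev1$coherent))
  expect_equal(mpr_metrics(ev1, "coherent")$sigma_T, 0)

  # periodic train + 3 interspersed events far away in (T, xi)
  acc <- rep(NA_real_, 50)
  for (s in 1:50) {
    set.seed(s)
    n_tr <- 8
    ev <- make_deviation_set(
      time = c(seq(10, 10 + 12 * (n_tr - 1), by = 12), sort(runif(3, 12, 95))),
      fwhm = c(rnorm(n_tr, 3, 0.1), runif(3, 0.3, 0.6)),
      period = c(rnorm(n_tr, 12, 0.3), runif(3, 55, 70)))
    truth <- c(rep(TRUE, n_tr), rep(FALSE, 3))[order(c(seq(10, 94, 12),
                                                       numeric(0)))]
    truth <- ev$fwhm > 1  # train events have fwhm ~ 3, outliers < 0.6
    ev2 <- cluster_coherent(ev, catrace_config(seed = s))
    acc[s] <- mean(ev2$coherent == truth)
  }
  expect_gte(mean(acc), 0.9)
})

test_that("trend merging reunites a chirped train split by the mixture model", {
  per <- 8
  times <- 10
  for (i in 1:9) {
    per <- per * 1.1
    times <- c(times, times[length(times)] + per)
  }
  gaps <- diff(times)
  ev <- make_deviation_set(time = times, fwhm = 3,
                           period = c(gaps[1L], gaps))
  ev2 <- cluster_coherent(ev, catrace_config(seed = 1))
  expect_true(all(ev2$coherent))
})

test_that("identical seeds give identical coherent masks", {
  set.seed(99)
  ev <- make_deviation_set(time = sort(runif(12, 5, 110)),
                           fwhm = runif(12, 1, 4),
                           period = runif(12, 8, 40))
  m1 <- cluster_coherent(ev, catrace_config(seed = 7))$coherent
  m2 <- cluster_coherent(ev, catrace_config(seed = 7))$coherent
  expect_identical(m1, m2)
})

test_that("oscillation metrics are exact on hand-constructed event sets", {
  ev <- make_deviation_set(time = seq(10, 94, by = 12), fwhm = 3, period = 12)
  m <- mpr_metrics(ev, "all")
  expect_equal(m$n_osc, 8L)
  expect_equal(m$period_T, 12)
  expect_equal(m$sigma_T, 0)
  expect_equal(m$persistence, 84)
  expect_equal(m$duty_cycle, 0.25)

  # jittered periods: sample mean and sd of the actual inter-peak gaps
  ev2 <- make_deviation_set(time = c(0, 10, 22, 36), fwhm = 3,
                            period = c(10, 10, 12, 14))
  m2 <- mpr_metrics(ev2, "all")
  expect_equal(m2$period_T, 12)
  expect_equal(m2$sigma_T, 2)

  # single peak: period undefined
  ev3 <- make_deviation_set(time = 10, fwhm = 3, period = NA_real_)
  expect_true(is.na(mpr_metrics(ev3, "all")$period_T))
})

test_that("the coherent subset never has larger period spread than the full set", {
  for (s in 1:20) {
    set.seed(s + 300)
    train <- seq(10, 10 + 12 * 6, by = 12) + rnorm(7, sd = 0.3)
    extra <- runif(2, 15, 100)
    tt <- sort(c(train, extra))
    gaps <- diff(tt)
    ev <- make_deviation_set(time = tt, fwhm = rnorm(9, 3, 0.2),
                             period = c(gaps[1L], gaps))
    ev <- cluster_coherent(ev, catrace_config(seed = s))
    m_all <- mpr_metrics(ev, "all")
    m_coh <- mpr_metrics(ev, "coherent")
    expect_true(all(which(ev$coherent) %in% seq_len(nrow(ev))))
    expect_lte(m_coh$n_osc, m_all$n_osc)
    if (is.finite(m_coh$sigma_T) && is.finite(m_all$sigma_T)) {
      expect_lte(m_coh$sigma_T, m_all$sigma_T + 1e-8)
    }
  }
})

test_that("the reported period of a near-noiseless periodic train is exact", {
  sim <- generate_trace(fixture_spec(
    seed = 17, drift = flat_drift, tr = NULL, noise_sd = 0.01,
    osc = list(period = 12, amplitude = 0.3, n_cycles = 7,
               jitter_sd = 0, fwhm = 3, start = 25)))
  fit <- run_pipeline(sim$trace)
  expect_equal(fit$mpr_all$n_osc, 7L)
  # within one sample interval of the generating period
  expect_lt(abs(fit$mpr_all$period_T - 12), 0.5)
})

test_that("the full pipeline resolves oscillations superimposed on a transient", {
  sim <- generate_trace(fixture_spec(
    seed = 17, osc = list(period = 12, amplitude = 0.3, n_cycles = 7,
                          jitter_sd = 0, fwhm = 3, start = 25)))
  fit <- run_pipeline(sim$trace)
  expect_true(fit$detection$detected)
  expect_gte(fit$mpr_all$n_osc, 5)
  expect_equal(fit$mpr_all$period_T, 12, tolerance = 0.25)
})
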
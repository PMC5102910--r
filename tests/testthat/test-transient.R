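test_that("activation model reproduces Hill landmarks", {
  p <- list(A_act = 2, beta = 4, n_act = 3, m_act = 0)
  expect_equal(activation_model(4, p), 1)       # half-max at t = beta
  expect_equal(activation_model(0, p), 0)
  # steep-Hill limit of the quasi-linear term: slope -> 1, value ~ t - beta
  p2 <- list(A_act = 0, beta = 4, n_act = 50, m_act = 1)
  tt <- 40
  expect_equal(activation_model(tt, p2), tt - 4, tolerance = 0.01 * (tt - 4))
})

test_that("activation model derivative matches numerical differentiation", {
  p <- list(A_act = 1.5, beta = 3, n_act = 2.5, m_act = 0.02)
  tt <- seq(0.5, 30, by = 0.7)
  h <- 1e-6
  num <- (activation_model(tt + h, p) - activation_model(tt - h, p)) / (2 * h)
  expect_equal(activation_model_deriv(tt, p), num, tolerance = 1e-5)
})

test_that("response model is C1 at both Hermite knots and returns to zero", {
  set.seed(31)
  t_end <- 119.5
  for (i in 1:50) {
    p <- list(t_on = runif(1, 8, 15), A_act = runif(1, 0.2, 1),
              beta = runif(1, 1, 5), n_act = runif(1, 1, 6),
              m_act = runif(1, -0.01, 0.02), t_de = runif(1, 18, 40),
              sigma_act = NA, sigma_de = NA, A_de = runif(1, 0.2, 1),
              gamma = runif(1, 5, 30), n_de = runif(1, 1.1, 6))
    p$sigma_act <- runif(1, 0.1, 0.9) * (p$t_de - p$t_on)
    p$sigma_de <- runif(1, 0.1, 0.9) * min(2 * p$gamma, t_end - p$t_de)
    pr <- catrace:::response_pars(p, t_end)
    knots <- c(pr$t_de - pr$sigma_act, pr$t_de + pr$sigma_de)
    h <- 1e-5
    for (k in knots) {
      gl <- response_model(k - h, p, t_end)
      gr <- response_model(k + h, p, t_end)
      dl <- response_model(k - h, p, t_end, deriv = TRUE)
      dr <- response_model(k + h, p, t_end, deriv = TRUE)
      scale_v <- max(abs(c(gl, gr, p$A_act)))
      scale_d <- max(abs(c(dl, dr)), 1e-3)
      expect_lt(abs(gr - gl), 1e-4 * scale_v + 1e-8)
      expect_lt(abs(dr - dl) / scale_d, 1e-3)
    }
    # m_de closed form: response returns to zero at the end of the record
    expect_lt(abs(response_model(t_end, p, t_end)), 1e-6 * p$A_act + 1e-10)
  }
})

test_that("degenerate junction widths recover the unsmoothed piecewise model", {
  t_end <- 119.5
  p <- list(t_on = 11, A_act = 0.5, beta = 2.5, n_act = 2.5, m_act = 0,
            t_de = 18, sigma_act = 1e-4, sigma_de = 1e-4, A_de = 0.5,
            gamma = 15, n_de = 2)
  tt <- c(seq(11.5, 17, by = 0.5), seq(19, 110, by = 1))  # away from t_de
  g <- response_model(tt, p, t_end)
  act <- activation_model(tt - 11, p)
  pr <- catrace:::response_pars(p, t_end)
  de <- catrace:::deactivation_model(tt - 18, 0.5, 15, 2, pr$m_de)
  expect_equal(g[tt < 17.5], act[tt < 17.5], tolerance = 1e-8)
  expect_equal(g[tt > 18.5], de[tt > 18.5], tolerance = 1e-8)
})

test_that("activation fit recovers onset within the delimited window", {
  t_on_err <- A_err <- rep(NA_real_, 25)
  for (s in 1:25) {
    sim <- sim_trace(s)
    st <- tv_iterate(sim$trace$time, sim$trace$value)
    dl <- delimit(sim$trace, st)
    d0 <- fit_drift_initial(sim$trace, dl, st$clean_idx)
    dw <- fit_drift_weighted(sim$trace, st, d0)
    af <- fit_activation(sim$trace, st, dl, dw)
    expect_gte(af$params$t_on, sim$trace$time[dl$i_act0])
    expect_lte(af$params$t_on, sim$trace$time[dl$i_max])
    t_on_err[s] <- abs(af$params$t_on - 11)
  }
  expect_lte(median(t_on_err), 1)
})

test_that("transient detection has high sensitivity and a low false-positive rate", {
  det_noise <- det_tr <- logical(40)
  for (s in 1:40) {
    # pure noise around a constant baseline
    set.seed(s + 900)
    t <- seq(0, 119.5, by = 0.5)
    noise_fit <- run_pipeline(tibble::tibble(time = t,
                                             value = 1 + rnorm(240, sd = 0.025)))
    det_noise[s] <- isTRUE(noise_fit$detection$detected)
    # 8 sigma transient
    sim <- sim_trace(s, tr = modifyList(fixture_spec()$tr,
                                        list(A_act = 8 * 0.025,
                                             A_de = 8 * 0.025)))
    fit <- run_pipeline(sim$trace)
    det_tr[s] <- isTRUE(fit$detection$detected)
  }
  expect_lte(mean(det_noise), 0.05)
  expect_gte(mean(det_tr), 0.95)
})

test_that("a monotone ramp with no return is rejected by criterion (iii)", {
  set.seed(55)
  t <- seq(0, 119.5, by = 0.5)
  ramp <- pmax(0, t - 30) * 0.01
  fit <- run_pipeline(tibble::tibble(time = t,
                                     value = 1 + ramp + rnorm(240, sd = 0.005)))
  expect_false(fit$detection$detected)
})

test_that("rho formula matches the brute-force inflection of the deactivation", {
  set.seed(13)
  for (i in 1:20) {
    gam <- runif(1, 3, 30)
    nde <- runif(1, 1.2, 8)
    # second derivative of the pure Hill decay on a 1e-3 s grid
    tt <- seq(1e-3, 4 * gam, by = 1e-3)
    g <- gam^nde / (tt^nde + gam^nde)
    d2 <- diff(g, differences = 2)
    # concave before the inflection, convex after: interpolate the zero
    # up-crossing of the second difference
    i0 <- min(which(d2 > 1e-6 * max(abs(d2)))) - 1L
    frac <- -d2[i0] / (d2[i0 + 1L] - d2[i0])
    t_inf <- tt[i0 + 1L] + frac * 1e-3
    rho_rel <- gam * ((nde - 1) / (nde + 1))^(1 / nde)
    expect_lt(abs(rho_rel - t_inf), 1e-3)
  }
  # analytic limits
  expect_equal(0 * ((1 - 1) / 2)^1, 0)  # n_de = 1: rho collapses onto t_de
})

test_that("transient metrics are exact on analytically known cases", {
  # triangle pulse sampled exactly: trapezoid AUC is exact
  tt <- seq(0, 10, by = 0.5)
  tri <- pmax(0, 1 - abs(tt - 5) / 5)
  expect_equal(pracma::trapz(tt, tri), 5)

  # metrics of a fitted-form response against its fine-grid ground truth
  tr_par <- fixture_spec()$tr
  truth <- catrace:::true_tr_metrics(tr_par, 119.5)
  rf <- structure(list(params = tr_par,
                       drift = list(a1 = 0, tau1 = 40, m1 = 0, a2 = 0,
                                    tau2 = 40, m2 = 0, t2 = 60, z = 0),
                       t_end = 119.5),
                  class = "response_fit")
  trace <- tibble::tibble(time = seq(0, 119.5, by = 0.5),
                          value = response_model(seq(0, 119.5, by = 0.5),
                                                 tr_par, 119.5))
  m <- extract_tr_metrics(rf, trace)
  expect_equal(m$amplitude, truth$amplitude, tolerance = 1e-3)
  expect_equal(m$t_10_90, truth$t_10_90, tolerance = 0.05)
  expect_equal(m$fwhm, truth$fwhm, tolerance = 0.05)
  expect_equal(m$auc, truth$auc, tolerance = 1e-3 * truth$auc)
  expect_equal(m$rho, truth$rho)
})

test_that("tau_decay is recovered from a mono-exponential tail", {
  errs <- rep(NA_real_, 25)
  for (s in 1:25) {
    sim <- sim_trace(s)
    fit <- run_pipeline(sim$trace)
    if (!is.null(fit$tr_metrics)) {
      errs[s] <- abs(fit$tr_metrics$tau_decay - sim$truth$tr$tau_decay) /
        sim$truth$tr$tau_decay
    }
  }
  expect_lte(median(errs, na.rm = TRUE), 0.15)
})

test_that("full-pipeline parameter recovery at SNR 20", {
  res <- matrix(NA_real_, 30, 4,
                dimnames = list(NULL, c("amp", "t_on", "auc", "fwhm")))
  for (s in 1:30) {
    sim <- sim_trace(s)
    fit <- run_pipeline(sim$trace)
    if (is.null(fit$tr_metrics)) next
    m <- fit$tr_metrics
    tt <- sim$truth$tr
    res[s, ] <- c(abs(m$amplitude - tt$amplitude) / tt$amplitude,
                  abs(m$t_onset - tt$t_onset),
                  abs(m$auc - tt$auc) / tt$auc,
                  abs(m$fwhm - tt$fwhm) / tt$fwhm)
  }
  med <- apply(res, 2, median, na.rm = TRUE)
  expect_lte(med["amp"], 0.10)
  expect_lte(med["t_on"], 1)
  expect_lte(med["auc"], 0.15)
  expect_lte(med["fwhm"], 0.15)
})

test_that("kappa vanishes when the activation plateau matches the end level", {
  # direct evaluation of the coherence ratio at a constructed state
  sim <- sim_trace(3)
  st <- tv_iterate(sim$trace$time, sim$trace$value)
  dl <- delimit(sim$trace, st)
  d0 <- fit_drift_initial(sim$trace, dl, st$clean_idx)
  dw <- fit_drift_weighted(sim$trace, st, d0)
  af <- fit_activation(sim$trace, st, dl, dw)
  g_peak <- activation_model(af$t_max - af$params$t_on, af$params)
  AuN <- st$Au[length(st$Au)]
  denom <- AuN - min(st$Au[dl$i_act0:dl$i_max])
  kappa <- abs((AuN - g_peak) / denom)
  # forcing the plateau to the end level zeroes the numerator
  ap0 <- af$params
  ap0$A_act <- 0
  tq <- af$t_max - ap0$t_on
  ap0$m_act <- AuN /
    (tq - catrace:::hill_integral(tq, ap0$beta, ap0$n_act))
  g_peak0 <- activation_model(af$t_max - ap0$t_on, ap0)
  expect_equal(abs((AuN - g_peak0) / denom), 0, tolerance = 1e-8)
  expect_gt(kappa, 0)
})

test_that("lambda is small for a clean transient that returns to baseline", {
  sim <- sim_trace(3)
  fit <- run_pipeline(sim$trace)
  expect_lte(fit$response$lambda, 0.3)
})
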
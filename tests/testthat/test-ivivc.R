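test_that("phase segmentation returns explicit breakpoints verbatim", {
  prof <- release_profile(c(12, 24, 48, 96), cbind(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(segment_phases(prof, breakpoints = c(24, 312)), c(24, 312))
})

test_that("segmentation auto-detects an accelerated-phase onset", {
  tt <- c(48, 72, 120, 168, 240, 312, 408, 504, 600, 672, 720)
  # piecewise truth: slow power law to 312 h, then erosion-driven phase
  f <- ifelse(tt <= 312, 0.012 * tt^0.6,
              0.012 * 312^0.6 + 2e-4 * (tt - 312)^1.3)
  prof <- release_profile(tt, cbind(f))
  expect_equal(segment_phases(prof), c(24, 312))
  # a biphasic profile yields no third window
  f2 <- 0.012 * tt^0.6
  expect_equal(segment_phases(release_profile(tt, cbind(f2))), 24)
})

test_that("modeled F_abs follows the scaled frozen-phase convention", {
  m1 <- fix$celecoxib$F1$model
  s1 <- fix$celecoxib$F1$scaling
  expect_equal(modeled_fabs(m1, s1, 0), 0)
  # default convention: second phase accrues from the burst end
  expect_equal(modeled_fabs(m1, s1, 24), 2.0 * 0.0485 * 24^0.471,
               tolerance = 1e-12)
  # legacy zero-anchor convention reproduces the co-growing evaluation
  s1z <- scaling_fit(s1$table, phase2_anchor = "zero")
  expect_equal(modeled_fabs(m1, s1z, 24),
               2.0 * 0.0485 * 24^0.471 + 0.72 * 0.0125 * 24^0.616,
               tolerance = 1e-12)
  expect_equal(modeled_fabs(m1, s1z, 24), 0.497, tolerance = 0.002)
  # complete absorption: the cap is reached before 672 h
  expect_equal(modeled_fabs(m1, s1, 672), 1)
  expect_equal(modeled_fabs(m1, s1z, 672), 1)
  # monotone and bounded across all formulations
  tt <- seq(0, 2016, by = 8)
  for (f in c("F1", "F2", "F3", "F4")) {
    v <- modeled_fabs(fix$celecoxib[[f]]$model, fix$celecoxib[[f]]$scaling, tt)
    expect_true(all(diff(v) >= -1e-12) && all(v >= 0 & v <= 1))
  }
})

test_that("scaling factors are recovered from constructed absorption data", {
  m1 <- fix$celecoxib$F1$model
  tt <- c(1, 2, 4, 7, 12, 18, 24)
  # F_abs exactly twice the in vitro burst
  burst <- power_law_phase(0.0485, 0.471, t_end = 24)
  dv <- structure(list(times = tt, F_abs = 2 * eval_power_law(burst, tt),
                       rate_per_h = NA, dose_ug = DOSE_UG,
                       n_negative_rates = 0, residual = rep(0, length(tt)),
                       clamped = FALSE), class = "deconv_result")
  sc <- fit_scaling(list(F1 = m1), list(F1 = dv),
                    windows = list(F1 = c(burst = 24)))
  expect_equal(sc$table$A, 2, tolerance = 1e-9)
})

test_that("tied scaling factors are shared and recovered from simulation", {
  des <- pk_design(4, sched$sc_h, 10, residual_cv = 0.1, route = "SC")
  ties <- list(burst = list(c("F1", "burst")),
               second = list(c("F1", "phase2"), c("F1", "phase3")))
  win <- list(F1 = c(burst = 24, phase2 = 312, phase3 = 1656))
  truth <- fix$celecoxib$F1$model
  err <- sapply(1:20, function(s) {
    study <- simulate_sc_pk(truth, fix$celecoxib$F1$scaling, ref_uir,
                            des, seed = s)
    dv <- suppressMessages(deconvolve_staircase(mean_profile(study),
                                                ref_uir, clamp = TRUE))
    sc <- fit_scaling(list(F1 = truth), list(F1 = dv), windows = win,
                      ties = ties)
    A <- sc$table$A[match(c("burst", "phase2", "phase3"), sc$table$phase)]
    expect_equal(A[2], A[3])   # tie contract
    abs(A[1:2] - c(2.0, 0.72)) / c(2.0, 0.72)
  })
  expect_lt(median(err[1, ]), 0.15)
  expect_lt(median(err[2, ]), 0.15)
})

test_that("convolution obeys its degenerate-input identities", {
  zero <- composite_release_model(list(
    power_law_phase(1e-300, 0.5, t_end = 24, label = "burst")))
  szero <- scaling_fit(data.frame(formulation = "Z", phase = "burst",
                                  A = 1, t_end = 24))
  p0 <- convolve_model(zero, szero, ref_uir, DOSE_UG, horizon_h = 200)
  expect_true(all(p0$conc < 1e-250))
  # near-instantaneous complete absorption approaches the UIR itself
  step <- composite_release_model(list(
    power_law_phase(1.2, 0.02, t_end = 1e-3, label = "burst")))
  sstep <- scaling_fit(data.frame(formulation = "S", phase = "burst",
                                  A = 1, t_end = 1e-3))
  pd <- convolve_model(step, sstep, ref_uir, DOSE_UG, horizon_h = 96,
                       first_obs_h = 1e-3)
  late <- pd$times > 1
  expect_equal(pd$conc[late], eval_uir(ref_uir, pd$times[late], DOSE_UG),
               tolerance = 0.01)
})

test_that("convolution conserves mass on every study fixture", {
  for (f in c("F1", "F2", "F3", "F4")) {
    prof <- convolve_model(fix$celecoxib[[f]]$model,
                           fix$celecoxib[[f]]$scaling,
                           ref_uir, DOSE_UG)
    expect_lt(attr(prof, "mass_balance_rel_err"), 0.005)
  }
})

test_that("prediction errors follow the internal %PE definition", {
  obs <- data.frame(formulation = c("F1", "F1"),
                    parameter = c("Cmax", "AUC_48h"), value = c(670, 1000))
  mod <- data.frame(formulation = c("F1", "F1"),
                    parameter = c("Cmax", "AUC_48h"), value = c(635, 1100))
  pe <- prediction_errors(obs, mod)
  expect_equal(pe$table$pe_pct[pe$table$parameter == "Cmax"],
               (670 - 635) / 670 * 100)
  expect_equal(round(pe$table$pe_pct[pe$table$parameter == "Cmax"]), 5)
  # modeled above observed gives a negative error
  expect_lt(pe$table$pe_pct[pe$table$parameter == "AUC_48h"], 0)
  # exact agreement gives zero
  pe0 <- prediction_errors(obs, obs)
  expect_equal(pe0$table$pe_pct, c(0, 0))
})

test_that("Levy pairing aligns absorption and dissolution series", {
  tt <- c(4, 8, 24, 48)
  dv <- structure(list(times = tt, F_abs = c(0.1, 0.2, 0.4, 0.6),
                       rate_per_h = NA, dose_ug = 1, n_negative_rates = 0,
                       residual = rep(0, 4), clamped = FALSE),
                  class = "deconv_result")
  fp <- release_profile(tt, cbind(c(0.1, 0.2, 0.4, 0.6)))
  pairs <- levy_pairs(dv, fp)
  expect_equal(pairs$F_abs, pairs$F_diss)
  # burst regime: absorption running at twice dissolution
  fp2 <- release_profile(tt, cbind(c(0.05, 0.1, 0.2, 0.3)))
  pairs2 <- levy_pairs(dv, fp2)
  expect_equal(pairs2$F_abs, 2 * pairs2$F_diss)
  # disjoint ranges fail loudly
  fp3 <- release_profile(c(100, 200), cbind(c(0.7, 0.8)))
  expect_error(levy_pairs(dv, fp3), "overlap")
})

test_that("simulated depot studies show the burst-then-crossover pattern", {
  # early: absorption ahead of dissolution (burst scaling > 1);
  # late: absorption lags dissolution (second-phase scaling < 1)
  f <- "F2"
  des <- pk_design(4, sched$sc_h, 10, residual_cv = 0, route = "SC")
  study <- simulate_sc_pk(fix$celecoxib[[f]]$model,
                          fix$celecoxib[[f]]$scaling, ref_uir, des,
                          seed = 5)
  dv <- deconvolve_staircase(mean_profile(study), ref_uir)
  ivr <- release_profile(sched$ivr_h,
                         cbind(eval_composite(fix$celecoxib[[f]]$model,
                                              sched$ivr_h)))
  pairs <- levy_pairs(dv, ivr)
  early <- pairs$time_h <= 24
  late <- pairs$time_h >= 336
  expect_true(all(pairs$F_abs[early] > pairs$F_diss[early]))
  expect_true(all(pairs$F_abs[late] < pairs$F_diss[late]))
})
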
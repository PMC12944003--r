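test_that("NCA matches closed forms on densely sampled profiles", {
  # mono-exponential: AUC_inf = C0/k, t_half = ln2/k
  tt <- seq(0.25, 120, by = 0.25)
  p <- conc_profile("s1", tt, 100 * exp(-0.1 * tt), route = "IV",
                    dose_mg_per_kg = 1, body_weight_g = 250)
  res <- nca(p)
  expect_equal(res$auc_inf, 1000, tolerance = 0.005)
  expect_equal(res$t_half, log(2) / 0.1, tolerance = 0.01)
  # biexponential at the study's UIR, 269 ug dose
  tt2 <- seq(0.1, 96, by = 0.1)
  p2 <- conc_profile("s2", tt2, eval_uir(ref_uir, tt2, 269), route = "IV",
                     dose_mg_per_kg = 1, body_weight_g = 269)
  res2 <- nca(p2)
  auc_closed <- 269 * (1.78 / 0.201 + 0.563 / 3.10)   # = 2431.04
  expect_equal(res2$auc_inf, auc_closed, tolerance = 0.005)
  expect_equal(res2$t_half, log(2) / 0.201, tolerance = 0.01)
})

test_that("constant concentrations integrate exactly", {
  p <- conc_profile("s", c(0, 12, 24, 48), rep(8, 4), route = "SC",
                    dose_mg_per_kg = 1, body_weight_g = 250)
  res <- suppressWarnings(nca(p, partial_h = 48))
  expect_equal(unname(res$auc_partial["AUC_48h"]), 8 * 48)
})

test_that("partial AUCs are ordered and flagged beyond tlast", {
  des <- pk_design(2, sched$sc_h, 10, residual_cv = 0.1, route = "SC")
  study <- simulate_sc_pk(fix$celecoxib$F1$model, fix$celecoxib$F1$scaling,
                          ref_uir, des, seed = 3)
  for (p in study) {
    res <- nca(p)
    a <- res$auc_partial
    expect_true(all(diff(c(a[c("AUC_48h", "AUC_168h", "AUC_672h")],
                           res$auc_last)) >= -1e-9))
    expect_true(res$Cmax >= max(p$conc))
  }
  # cut beyond tlast is not computed
  short <- conc_profile("s", c(1, 2, 4, 8), c(5, 9, 7, 4), route = "SC",
                        dose_mg_per_kg = 1, body_weight_g = 250)
  res2 <- nca(short, partial_h = c(4, 48))
  expect_true(is.na(res2$auc_partial["AUC_48h"]))
  expect_match(paste(res2$flags, collapse = " "), "beyond tlast")
})

test_that("IV C0 back-extrapolates log-linearly from the first samples", {
  tt <- c(1, 2, 4, 8, 16, 32)
  p <- conc_profile("s", tt, 200 * exp(-0.15 * tt), route = "IV",
                    dose_mg_per_kg = 1, body_weight_g = 250)
  expect_equal(nca(p)$C0, 200, tolerance = 1e-9)
})

test_that("UIR evaluation honours the per-microgram dose basis", {
  expect_equal(eval_uir(ref_uir, 0, 269), (1.78 + 0.563) * 269)
  expect_equal((1.78 + 0.563) * 269, 630.3, tolerance = 1e-3)
  # consistent with the observed IV C0 of the study (626 ng/mL) within 1%
  expect_equal(eval_uir(ref_uir, 0, 269),
               fix$observed_pk$C0[fix$observed_pk$formulation == "F5"],
               tolerance = 0.01)
  expect_equal(eval_uir(ref_uir, 5, 0), 0)
  # half-life identity of the slow term once the fast term has decayed
  u_slow <- uir(A = 2, B = 0, alpha = 0.2, beta = 3)
  expect_equal(eval_uir(u_slow, log(2) / 0.2, 100),
               eval_uir(u_slow, 0, 100) / 2)
})

test_that("UIR fitting recovers noise-free macro-constants exactly", {
  tt <- sched$iv_h
  p <- conc_profile("mean", tt, eval_uir(ref_uir, tt, 269), route = "IV",
                    dose_mg_per_kg = 1, body_weight_g = 269)
  u2 <- fit_uir(p)
  expect_equal(u2$A, 1.78, tolerance = 1e-6)
  expect_equal(u2$alpha, 0.201, tolerance = 1e-6)
  expect_equal(u2$B, 0.563, tolerance = 1e-6)
  expect_equal(u2$beta, 3.10, tolerance = 1e-6)
  # alpha stored as the slow constant regardless of term ordering
  expect_lt(u2$alpha, u2$beta)
})

test_that("mono-exponential IV data give a degenerate fast term", {
  tt <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
  p <- conc_profile("m", tt, 500 * exp(-0.2 * tt), route = "IV",
                    dose_mg_per_kg = 1, body_weight_g = 250)
  expect_warning(u2 <- fit_uir(p), "degenerate|mono")
  expect_true(isTRUE(attr(u2, "degenerate")))
})

test_that("UIR alpha is recovered from noisy group means", {
  des <- pk_design(4, sched$iv_h, 1, residual_cv = 0.1, route = "IV")
  err <- vapply(1:20, function(s) {
    u2 <- suppressWarnings(fit_uir(mean_profile(simulate_iv_pk(
      ref_uir, des, seed = s))))
    abs(u2$alpha - 0.201) / 0.201
  }, 0)
  expect_lt(median(err), 0.15)
})
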
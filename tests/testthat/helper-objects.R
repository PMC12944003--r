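# shared objects for the test suite; everything is built in code

fix <- reference_fixtures()
sched <- default_schedules()
ref_uir <- fix$uir

# dose used throughout the SC depot application: 10 mg/kg in a 269 g rat
DOSE_UG <- 10 * 269

# quick single-phase truth (the combined burst+diffusion main law)
main_law <- function(K = 0.0652, n = 0.406)
  composite_release_model(list(power_law_phase(K, n, label = "burst")))

# noise-free release profile from a truth model on a given grid
profile_from_model <- function(model, times)
  data.frame(time_h = times, F = eval_composite(model, times))

# build a conc_profile by staircase-convolving a known rate vector
stair_profile <- function(times, rates, u, dose_ug, route = "SC") {
  dt <- diff(c(0, times))
  sA <- 0; sB <- 0
  conc <- numeric(length(times))
  for (k in seq_along(times)) {
    ea <- exp(-u$alpha * dt[k]); eb <- exp(-u$beta * dt[k])
    sA <- sA * ea + rates[k] * u$A / u$alpha * (1 - ea)
    sB <- sB * eb + rates[k] * u$B / u$beta * (1 - eb)
    conc[k] <- dose_ug * (sA + sB)
  }
  conc_profile("oracle", times, conc, route = route,
               dose_mg_per_kg = 1, body_weight_g = dose_ug)
}
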
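## Simulators for dissolution vessels and small-animal PK studies.
## Noise is multiplicative lognormal by default (assay SDs in this field
## scale roughly with the mean); an additive-gaussian alternative is
## provided. All simulators are deterministic given a seed.

# run code with a temporary RNG state; restores the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# noise multipliers / additive perturbation, mean-one for lognormal
.apply_noise <- function(x, cv, error_model) {
  if (cv == 0) return(x)
  if (error_model == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
  } else {
    out <- x + stats::rnorm(length(x), 0, cv * x)
    n_neg <- sum(out < 0)
    if (n_neg) message(n_neg, " negative value(s) after additive noise clamped to 0")
    pmax(out, 0)
  }
}

#' Simulate an in vitro release study with withdrawal/replacement
#'
#' Generates the raw concentration table an analyst would measure from
#' replicate dissolution vessels sampled with withdrawal and drug-free
#' medium replacement. For each vessel, the true medium concentration obeys
#' the physical bookkeeping
#' \deqn{C_i = (m_i - V_s \sum_{j<i} C_j) / V}
#' where \eqn{m_i} is the cumulative released mass (truth model times
#' vessel dose), \eqn{V} the medium volume and \eqn{V_s} the withdrawal
#' volume; assay noise perturbs the measured concentration, not the
#' underlying mass (assay error acts on the analytical measurement).
#'
#' @param truth a [composite_release_model()] (fraction released vs time).
#' @param design an [ivr_design()].
#' @param seed integer seed; identical seed and design give identical
#'   output.
#' @param error_model `"lognormal"` (multiplicative, CV-parameterised,
#'   mean 1; the default) or `"additive"` (gaussian with SD = CV times the
#'   true value, negatives clamped to 0).
#' @return long data.frame `vessel_id`, `time_h`, `conc_mg_per_ml`.
#' @export
simulate_ivr_study <- function(truth, design, seed,
                               error_model = c("lognormal", "additive")) {
  stopifnot(inherits(truth, "composite_release_model"),
            inherits(design, "ivr_design"))
  error_model <- match.arg(error_model)
  tt <- design$schedule_h
  F_true <- eval_composite(truth, tt)
  mass <- F_true * design$dose_mg
  V <- design$medium_volume_ml; Vs <- design$withdrawal_volume_ml
  C_true <- numeric(length(tt))
  removed <- 0
  for (i in seq_along(tt)) {
    C_true[i] <- (mass[i] - removed) / V
    removed <- removed + C_true[i] * Vs
  }
  .with_seed(seed, {
    do.call(rbind, lapply(seq_len(design$n_vessels), function(v) {
      data.frame(vessel_id = paste0("V", v), time_h = tt,
                 conc_mg_per_ml = .apply_noise(C_true, design$noise_cv,
                                               error_model))
    }))
  })
}

#' PK study design
#'
#' @param n_subjects subjects per group.
#' @param schedule_h strictly increasing sampling times (h).
#' @param dose_mg_per_kg dose (mg/kg), adjusted to each subject's body
#'   weight.
#' @param body_weight_range_g body-weight range (g); weights are drawn
#'   uniformly on this range.
#' @param residual_cv residual (assay + biological) coefficient of
#'   variation, >= 0.
#' @param route `"IV"` or `"SC"`.
#' @return An object of class `pk_design`.
#' @export
pk_design <- function(n_subjects = 4, schedule_h, dose_mg_per_kg,
                      body_weight_range_g = c(250, 350), residual_cv = 0.1,
                      route = c("SC", "IV")) {
  route <- match.arg(route)
  stopifnot(n_subjects >= 1, !is.unsorted(schedule_h, strictly = TRUE),
            all(schedule_h > 0), dose_mg_per_kg > 0,
            all(body_weight_range_g > 0), residual_cv >= 0)
  structure(list(n_subjects = n_subjects, schedule_h = schedule_h,
                 dose_mg_per_kg = dose_mg_per_kg,
                 body_weight_range_g = body_weight_range_g,
                 residual_cv = residual_cv, route = route),
            class = "pk_design")
}

.draw_weights <- function(design)
  stats::runif(design$n_subjects, design$body_weight_range_g[1],
               design$body_weight_range_g[2])

#' Simulate an IV bolus PK group
#'
#' Per-subject plasma profiles under biexponential disposition:
#' \eqn{C(t) = D_{\mu g} (A e^{-\alpha t} + B e^{-\beta t})} times
#' multiplicative residual error, with \eqn{D_{\mu g}} the absolute dose in
#' micrograms (dose in mg/kg times body weight in g).
#'
#' @param uir_truth a [uir()] (per-microgram basis).
#' @param design a [pk_design()] with `route = "IV"`.
#' @param seed integer seed.
#' @param error_model see [simulate_ivr_study()].
#' @return list of [conc_profile()] objects (class `pk_study`).
#' @export
simulate_iv_pk <- function(uir_truth, design, seed,
                           error_model = c("lognormal", "additive")) {
  stopifnot(inherits(uir_truth, "uir"), inherits(design, "pk_design"))
  if (design$route != "IV") stop("design route must be IV")
  error_model <- match.arg(error_model)
  .with_seed(seed, {
    bw <- .draw_weights(design)
    out <- lapply(seq_len(design$n_subjects), function(s) {
      dose_ug <- design$dose_mg_per_kg * bw[s]
      cc <- .apply_noise(eval_uir(uir_truth, design$schedule_h, dose_ug),
                         design$residual_cv, error_model)
      conc_profile(paste0("S", s), design$schedule_h, cc, route = "IV",
                   dose_mg_per_kg = design$dose_mg_per_kg,
                   body_weight_g = bw[s])
    })
    structure(out, class = c("pk_study", "list"))
  })
}

#' Simulate an SC depot PK group
#'
#' Per-subject plasma profiles from a depot whose in vivo absorption is the
#' scaled in vitro release model: the modeled fraction absorbed is
#' evaluated at the sampling schedule, represented as a staircase input and
#' convolved with the UIR (closed-form interval integrals), then perturbed
#' by multiplicative residual error.
#'
#' @param release_truth the in vitro [composite_release_model()].
#' @param scaling_truth a [scaling_fit()] (the true in vivo scaling).
#' @param u a [uir()].
#' @param design a [pk_design()] with `route = "SC"`.
#' @inheritParams simulate_iv_pk
#' @return list of [conc_profile()] objects (class `pk_study`).
#' @export
simulate_sc_pk <- function(release_truth, scaling_truth, u, design, seed,
                           error_model = c("lognormal", "additive")) {
  stopifnot(inherits(u, "uir"), inherits(design, "pk_design"))
  if (design$route != "SC") stop("design route must be SC")
  error_model <- match.arg(error_model)
  tt <- design$schedule_h
  Fk <- modeled_fabs(release_truth, scaling_truth, tt)
  if (any(diff(Fk) < -1e-12)) stop("modeled F_abs must be non-decreasing")
  rate <- diff(c(0, Fk)) / diff(c(0, tt))
  .with_seed(seed, {
    bw <- .draw_weights(design)
    out <- lapply(seq_len(design$n_subjects), function(s) {
      dose_ug <- design$dose_mg_per_kg * bw[s]
      cc <- dose_ug * .stair_forward(tt, rate, u)
      cc <- .apply_noise(cc, design$residual_cv, error_model)
      conc_profile(paste0("S", s), tt, cc, route = "SC",
                   dose_mg_per_kg = design$dose_mg_per_kg,
                   body_weight_g = bw[s])
    })
    structure(out, class = c("pk_study", "list"))
  })
}

#' Flatten a simulated PK study to a long data.frame
#' @param study a `pk_study` (list of [conc_profile()]).
#' @return data.frame `subject_id`, `time_h`, `conc_ng_per_ml`.
#' @export
pk_study_table <- function(study) {
  do.call(rbind, lapply(study, function(p)
    data.frame(subject_id = p$subject_id, time_h = p$times,
               conc_ng_per_ml = p$conc)))
}

#' Default sampling schedules
#'
#' Study-realistic sampling grids used as simulator defaults: a
#' three-month dissolution schedule for slowly releasing depots (early
#' points in the first days, then roughly weekly), an SC plasma sampling
#' schedule spanning 1 to 2016 h, and a 72 h IV schedule.
#'
#' @return named list with elements `ivr_h`, `sc_h`, `iv_h`.
#' @export
default_schedules <- function() {
  list(ivr_h = c(1, 3, 7, 24, 48, 72, 168, 336, 504, 672, 840, 1008, 1176,
                 1344, 1512, 1680, 1848, 2016, 2568),
       sc_h = c(1, 2, 4, 7, 24, 48, 72, 168, 336, 504, 672, 840, 1008,
                1176, 1344, 1512, 1680, 1848, 2016),
       iv_h = c(1, 2, 4, 7, 24, 48, 72))
}
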
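## Orchestration of the two-part analysis:
##   Part 1 -- in vitro release characterisation (withdrawal-corrected
##             profiles, summary statistics, power-law fits, mechanism
##             labels, K-vs-solubility regression).
##   Part 2 -- IVIVC (UIR, NCA, deconvolution, phase-specific scaling,
##             convolution to predicted PK, internal prediction errors).
## Both parts are plain functions over the package's building blocks; all
## tabular output is data.frames ready for write.csv().

# provenance stamp: md5 of the serialized configuration
.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run Part 1: in vitro release characterisation
#'
#' For each study (one drug-formulation combination) converts the raw
#' vessel concentrations to withdrawal-corrected release profiles and
#' produces the observed summary (%IVR at 48 h, t50, t80 by linear
#' interpolation, per-vessel mean and SD), power-law fits with mechanism
#' classification, and (when solubilities are supplied) the regression of
#' the rate constant on solubility per formulation group.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{studies}{named list; each element a list with `raw` (long
#'       data.frame `vessel_id`, `time_h`, `conc_mg_per_ml`), `design` (an
#'       [ivr_design()]), optional `breakpoints` (triphasic fitting),
#'       optional `fixed_n`, and optional `drug`/`formulation` tags.}
#'     \item{solubility}{optional data.frame `drug`,
#'       `ivr_medium_mg_per_ml` for the K-vs-solubility regression.}
#'     \item{f_cutoff}{fraction cutoff for biphasic fits (default 0.85).}
#'   }
#' @return list with `profiles`, `summary` (one row per study), `fits`
#'   (one row per fitted phase), `regression` (per formulation group, or
#'   NULL) and `provenance`.
#' @export
run_part1 <- function(config) {
  stopifnot(is.list(config), !is.null(config$studies))
  f_cutoff <- if (is.null(config$f_cutoff)) 0.85 else config$f_cutoff
  profiles <- list()
  summary_rows <- list()
  fit_rows <- list()
  for (nm in names(config$studies)) {
    st <- config$studies[[nm]]
    prof <- cumulative_release(st$raw, st$design)
    profiles[[nm]] <- prof
    t50 <- time_to_fraction(prof, 0.5)
    t80 <- time_to_fraction(prof, 0.8)
    i48 <- which.min(abs(prof$times - 48))
    summary_rows[[nm]] <- data.frame(
      study = nm,
      drug = if (is.null(st$drug)) NA_character_ else st$drug,
      formulation = if (is.null(st$formulation)) NA_character_
                    else st$formulation,
      n_vessels = ncol(prof$F),
      pct_ivr_48h = prof$mean[i48] * 100,
      t50_h = t50$mean, t50_h_sd = t50$sd,
      t80_h = t80$mean, t80_h_sd = t80$sd,
      t80_censored = all(t80$censored))
    if (is.null(st$breakpoints)) {
      ft <- fit_power_law(prof, fixed_n = st$fixed_n, f_cutoff = f_cutoff)
      r <- goodness_of_fit_pearson(ft, prof)
      fit_rows[[nm]] <- data.frame(
        study = nm, phase = "main", K = ft$model$K, n = ft$model$n,
        anchor = ft$model$anchor, t_start = ft$window_used[1],
        t_end = ft$window_used[2], sse = ft$sse, pearson_r = r,
        mechanism = classify_mechanism(ft$model$n))
    } else {
      ft <- fit_composite(prof, st$breakpoints, fixed_n = st$fixed_n)
      r <- goodness_of_fit_pearson(ft, prof)
      fit_rows[[nm]] <- do.call(rbind, lapply(ft$model$phases, function(p)
        data.frame(study = nm, phase = p$label, K = p$K, n = p$n,
                   anchor = p$anchor, t_start = p$anchor, t_end = p$t_end,
                   sse = ft$sse, pearson_r = r,
                   mechanism = classify_mechanism(p$n))))
    }
  }
  fits <- do.call(rbind, fit_rows)
  rownames(fits) <- NULL
  regression <- NULL
  if (!is.null(config$solubility)) {
    main <- fits[fits$phase %in% c("main", "burst"), ]
    main <- merge(main, do.call(rbind, summary_rows)[, c("study", "drug",
                                                         "formulation")],
                  by = "study")
    main <- merge(main, config$solubility, by = "drug")
    regression <- do.call(rbind, lapply(split(main, main$formulation),
      function(g) {
        if (nrow(g) < 2L) return(NULL)
        r <- regress_K_on_solubility(g$K, g$ivr_medium_mg_per_ml)
        data.frame(formulation = g$formulation[1], slope = r$slope,
                   intercept = r$intercept, r_squared = r$r_squared,
                   n_drugs = nrow(g))
      }))
    rownames(regression) <- NULL
  }
  list(profiles = profiles,
       summary = do.call(rbind, summary_rows),
       fits = fits,
       regression = regression,
       provenance = list(config_hash = .config_hash(
         list(studies = names(config$studies), f_cutoff = f_cutoff))))
}

#' Predict depot PK from reference release fits and scaling factors
#'
#' Desk-scale Part 2 computation: builds the modeled in vivo absorption for
#' each formulation from the in vitro phase fits and scaling factors,
#' convolves with the UIR at the study dose, runs NCA on the dense
#' predicted profile, and tabulates internal prediction errors against the
#' observed PK parameters.
#'
#' @param fix a fixture bundle from [reference_fixtures()] (or a list with
#'   the same structure carrying other parameter sets).
#' @param formulations formulations to predict.
#' @return list with `modeled` (data.frame formulation x parameter),
#'   `profiles` (predicted [conc_profile()]s), `pe` (a
#'   [prediction_errors()] object).
#' @export
predict_reference_pk <- function(fix = reference_fixtures(),
                                 formulations = c("F1", "F2", "F3", "F4")) {
  dose_ug <- fix$doses$sc_mg_per_kg * fix$doses$body_weight_g
  cuts <- c(48, 168, 672, 2016)
  profiles <- list()
  modeled <- list()
  for (f in formulations) {
    cf <- fix$celecoxib[[f]]
    prof <- convolve_model(cf$model, cf$scaling, fix$uir, dose_ug,
                           formulation = f,
                           horizon_h = fix$doses$horizon_h,
                           first_obs_h = fix$doses$first_obs_h)
    res <- nca(prof, partial_h = cuts)
    profiles[[f]] <- prof
    modeled[[f]] <- data.frame(
      formulation = f,
      parameter = c("Cmax", paste0("AUC_", cuts, "h")),
      value = c(res$Cmax, unname(res$auc_partial)))
  }
  modeled <- do.call(rbind, modeled)
  rownames(modeled) <- NULL
  obs <- fix$observed_pk[fix$observed_pk$formulation %in% formulations, ]
  observed <- do.call(rbind, lapply(seq_len(nrow(obs)), function(i)
    data.frame(formulation = obs$formulation[i],
               parameter = c("Cmax", paste0("AUC_", cuts, "h")),
               value = unlist(obs[i, c("Cmax", "AUC_48h", "AUC_168h",
                                       "AUC_672h", "AUC_2016h")],
                              use.names = FALSE))))
  list(modeled = modeled, profiles = profiles,
       pe = prediction_errors(observed, modeled))
}

#' Run Part 2: IVIVC from plasma data or reference fixtures
#'
#' In `"fixture"` mode, reproduces the modeled PK table from the
#' transcribed phase fits, scaling factors and UIR alone (no raw data; see
#' [predict_reference_pk()]). In `"data"` mode, runs the full chain: UIR
#' estimation from the IV group (unless a UIR is supplied), NCA per SC
#' group, deconvolution of the mean SC profiles, phase-specific scaling
#' estimation with tie constraints, convolution to predicted profiles, and
#' prediction errors.
#'
#' @param config list with `mode = "fixture"` (optionally `fix`,
#'   `formulations`) or `mode = "data"` with:
#'   \describe{
#'     \item{iv_profiles}{list of IV [conc_profile()]s (used when `uir` is
#'       not supplied).}
#'     \item{uir}{optional [uir()]; required if `iv_profiles` is absent.}
#'     \item{sc_groups}{named list (per formulation) of lists of SC
#'       [conc_profile()]s.}
#'     \item{models}{named list of in vitro [composite_release_model()]s.}
#'     \item{windows, ties}{see [fit_scaling()].}
#'     \item{horizon_h, first_obs_h}{convolution controls (defaults 2016
#'       and the first SC sampling time).}
#'   }
#' @return list with `uir`, `nca_observed`, `fabs`, `scaling`, `modeled`,
#'   `pe`, `provenance`. In fixture mode, the [predict_reference_pk()]
#'   result plus provenance.
#' @export
run_part2 <- function(config) {
  stopifnot(is.list(config))
  mode <- if (is.null(config$mode)) "fixture" else config$mode
  if (mode == "fixture") {
    fix <- if (is.null(config$fix)) reference_fixtures() else config$fix
    forms <- if (is.null(config$formulations)) c("F1", "F2", "F3", "F4")
             else config$formulations
    out <- predict_reference_pk(fix, forms)
    out$provenance <- list(mode = "fixture",
                           config_hash = .config_hash(list(mode = "fixture",
                                                           forms = forms)))
    return(out)
  }
  if (mode != "data") stop("mode must be 'fixture' or 'data'")
  if (is.null(config$uir) && is.null(config$iv_profiles))
    stop("configuration error: supply either a UIR or IV profiles")
  u <- if (!is.null(config$uir)) config$uir
       else fit_uir(mean_profile(config$iv_profiles))
  stopifnot(!is.null(config$sc_groups), !is.null(config$models))
  cuts <- c(48, 168, 672, 2016)
  nca_observed <- do.call(rbind, lapply(names(config$sc_groups), function(f) {
    rows <- lapply(config$sc_groups[[f]], function(p)
      cbind(formulation = f, as.data.frame(nca(p, partial_h = cuts))))
    do.call(rbind, rows)
  }))
  fabs <- lapply(config$sc_groups, function(g)
    deconvolve_staircase(mean_profile(g), u))
  scaling <- fit_scaling(config$models, fabs, windows = config$windows,
                         ties = config$ties)
  horizon <- if (is.null(config$horizon_h)) 2016 else config$horizon_h
  modeled <- list(); profiles <- list()
  for (f in names(config$sc_groups)) {
    g <- config$sc_groups[[f]]
    dose_ug <- mean(vapply(g, `[[`, 0, "dose_ug"))
    first_obs <- if (is.null(config$first_obs_h)) min(g[[1]]$times)
                 else config$first_obs_h
    # staircase knots mirror the observation schedule (the grid on which
    # the deconvolution resolved the absorption input)
    prof <- convolve_model(config$models[[f]], scaling, u, dose_ug,
                           formulation = f, horizon_h = horizon,
                           first_obs_h = first_obs,
                           knots = g[[1]]$times[g[[1]]$times <= horizon])
    # NCA of the modeled profile: on the dense prediction grid (default,
    # mirroring a convolution-toolkit workflow) or on the observation grid
    # (apples-to-apples with the observed NCA)
    nca_input <- if (identical(config$nca_grid, "observation")) {
      obs_t <- g[[1]]$times[g[[1]]$times <= horizon]
      conc_profile("model", obs_t,
                   stats::approx(prof$times, prof$conc, xout = obs_t)$y,
                   route = "SC", dose_mg_per_kg = 1,
                   body_weight_g = dose_ug)
    } else prof
    res <- nca(nca_input, partial_h = cuts)
    profiles[[f]] <- prof
    modeled[[f]] <- data.frame(
      formulation = f, parameter = c("Cmax", paste0("AUC_", cuts, "h")),
      value = c(res$Cmax, unname(res$auc_partial)))
  }
  modeled <- do.call(rbind, modeled)
  rownames(modeled) <- NULL
  observed <- do.call(rbind, lapply(split(nca_observed,
                                          nca_observed$formulation),
    function(d) data.frame(
      formulation = d$formulation[1],
      parameter = c("Cmax", paste0("AUC_", cuts, "h")),
      value = c(mean(d$Cmax), colMeans(d[, paste0("AUC_", cuts, "h"),
                                         drop = FALSE], na.rm = TRUE)))))
  pe <- prediction_errors(observed, modeled)
  list(uir = u, nca_observed = nca_observed, fabs = fabs, scaling = scaling,
       modeled = modeled, profiles = profiles, pe = pe,
       provenance = list(mode = "data",
                         config_hash = .config_hash(
                           list(mode = "data",
                                forms = names(config$sc_groups)))))
}
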
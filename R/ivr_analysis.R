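#' Dissolution vessel design
#'
#' Describes an in vitro release (IVR) vessel experiment with
#' withdrawal/replacement sampling: at each scheduled time a fixed volume of
#' medium is withdrawn for assay and replaced with fresh, drug-free medium.
#'
#' @param medium_volume_ml medium volume in the vessel (mL).
#' @param withdrawal_volume_ml volume withdrawn (and replaced) at each
#'   sampling time (mL); must be smaller than the medium volume.
#' @param injected_mass_g mass of formulation injected into the vessel (g).
#' @param drug_load_mg_per_g drug content of the formulation (mg drug per g
#'   formulation).
#' @param schedule_h strictly increasing sampling times (h), all positive.
#' @param n_vessels number of replicate vessels (>= 1).
#' @param noise_cv assay coefficient of variation applied to measured
#'   concentrations in simulation (dimensionless, >= 0).
#' @return An object of class `ivr_design`; `$dose_mg` is the drug dose per
#'   vessel.
#' @export
ivr_design <- function(medium_volume_ml = 50, withdrawal_volume_ml = 4,
                       injected_mass_g = 0.3, drug_load_mg_per_g = 10,
                       schedule_h, n_vessels = 4, noise_cv = 0.05) {
  stopifnot(withdrawal_volume_ml < medium_volume_ml,
            withdrawal_volume_ml >= 0, medium_volume_ml > 0,
            all(schedule_h > 0), !is.unsorted(schedule_h, strictly = TRUE),
            n_vessels >= 1, noise_cv >= 0,
            injected_mass_g * drug_load_mg_per_g > 0)
  structure(list(medium_volume_ml = medium_volume_ml,
                 withdrawal_volume_ml = withdrawal_volume_ml,
                 injected_mass_g = injected_mass_g,
                 drug_load_mg_per_g = drug_load_mg_per_g,
                 schedule_h = schedule_h, n_vessels = n_vessels,
                 noise_cv = noise_cv,
                 dose_mg = injected_mass_g * drug_load_mg_per_g),
            class = "ivr_design")
}

#' Release profile container
#'
#' Time versus cumulative fraction dissolved, per vessel, with mean/SD
#' aggregation across vessels. Small overshoots above 1 from assay noise are
#' tolerated up to 1.05 and flagged beyond.
#'
#' @param times strictly increasing times (h).
#' @param F matrix of fractions dissolved, one column per vessel.
#' @param dose_mg drug dose per vessel (mg).
#' @return An object of class `release_profile` with elements `times`, `F`,
#'   `mean`, `sd`, `dose_mg`.
#' @export
release_profile <- function(times, F, dose_mg = NA_real_) {
  F <- as.matrix(F)
  stopifnot(!is.unsorted(times, strictly = TRUE), nrow(F) == length(times))
  if (any(F < 0, na.rm = TRUE))
    stop("fractions dissolved must be non-negative")
  if (any(F > 1.05, na.rm = TRUE))
    warning("fraction dissolved exceeds 1.05 in at least one vessel")
  structure(list(times = times, F = F,
                 mean = rowMeans(F, na.rm = TRUE),
                 sd = apply(F, 1, stats::sd, na.rm = TRUE),
                 dose_mg = dose_mg),
            class = "release_profile")
}

#' @export
print.release_profile <- function(x, ...) {
  cat("Release profile:", length(x$times), "time points,",
      ncol(x$F), "vessel(s), dose", x$dose_mg, "mg\n")
  cat("  t range:", min(x$times), "-", max(x$times), "h; mean F range:",
      sprintf("%.3f - %.3f", min(x$mean), max(x$mean)), "\n")
  invisible(x)
}

#' Cumulative release with withdrawal correction
#'
#' Converts raw vessel concentrations to cumulative fraction dissolved.
#' Because each withdrawal removes drug that is replaced by drug-free
#' medium, the cumulative dissolved mass at time \eqn{t_i} is
#' \deqn{m_i = C_i V + \sum_{j<i} C_j V_s}
#' where \eqn{V} is the medium volume and \eqn{V_s} the withdrawal volume.
#'
#' @param raw long-format data.frame with columns `vessel_id`, `time_h`,
#'   `conc_mg_per_ml` (sorted or not; sorted internally).
#' @param design an [ivr_design()].
#' @return A [release_profile()]; vessels missing any scheduled time are
#'   excluded with a warning.
#' @export
cumulative_release <- function(raw, design) {
  stopifnot(is.data.frame(raw),
            all(c("vessel_id", "time_h", "conc_mg_per_ml") %in% names(raw)),
            inherits(design, "ivr_design"))
  if (any(raw$conc_mg_per_ml < 0)) stop("concentrations must be >= 0")
  times <- sort(unique(raw$time_h))
  vessels <- unique(raw$vessel_id)
  V <- design$medium_volume_ml; Vs <- design$withdrawal_volume_ml
  cols <- lapply(vessels, function(v) {
    d <- raw[raw$vessel_id == v, ]
    d <- d[order(d$time_h), ]
    if (!identical(d$time_h, times)) return(NULL)
    C <- d$conc_mg_per_ml
    removed <- cumsum(c(0, C[-length(C)])) * Vs
    (C * V + removed) / design$dose_mg
  })
  keep <- !vapply(cols, is.null, TRUE)
  if (!all(keep))
    warning(sum(!keep), " vessel(s) excluded: missing time points")
  if (!any(keep)) stop("no complete vessel profiles")
  F <- do.call(cbind, cols[keep])
  colnames(F) <- as.character(vessels[keep])
  release_profile(times, F, dose_mg = design$dose_mg)
}

#' Time to reach a target fraction dissolved
#'
#' Linear interpolation between the bracketing observed points of each
#' vessel profile (first crossing), plus mean/SD across vessels. Vessels
#' that never reach the target are censored (`NA` with the last observed
#' time recorded).
#'
#' @param profile a [release_profile()].
#' @param q target fraction in (0, 1), e.g. 0.5 or 0.8.
#' @param on `"vessels"` (default) interpolates each vessel and summarises
#'   mean (SD); `"mean"` interpolates the mean profile.
#' @return list with `per_vessel` (numeric, `NA` if censored), `mean`, `sd`,
#'   `censored` (logical vector), `censor_time` (last observed time).
#' @export
time_to_fraction <- function(profile, q, on = c("vessels", "mean")) {
  stopifnot(inherits(profile, "release_profile"), q > 0, q < 1)
  on <- match.arg(on)
  cross <- function(tt, ff) {
    i <- which(ff >= q)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    if (i == 1L) return(tt[1] * q / ff[1])  # interpolate from (0, 0)
    if (ff[i] == q) return(tt[i])
    t0 <- tt[i - 1]; f0 <- ff[i - 1]
    t0 + (q - f0) / (ff[i] - f0) * (tt[i] - t0)
  }
  if (on == "mean") {
    tq <- cross(profile$times, profile$mean)
    return(list(per_vessel = NULL, mean = tq, sd = NA_real_,
                censored = is.na(tq), censor_time = max(profile$times)))
  }
  tq <- apply(profile$F, 2, cross, tt = profile$times)
  list(per_vessel = tq, mean = mean(tq, na.rm = TRUE),
       sd = stats::sd(tq, na.rm = TRUE), censored = is.na(tq),
       censor_time = max(profile$times))
}

#' f1 difference factor between dissolution profiles
#'
#' \deqn{f_1 = 100 \sum_t |R_t - T_t| / \sum_t R_t}
#' where \eqn{R_t}, \eqn{T_t} are mean percent dissolved of the reference
#' and test product on a common time grid. Identical profiles give 0.
#'
#' @param reference,test mean percent dissolved, aligned on the same time
#'   grid (no silent resampling: lengths must match).
#' @return f1 (dimensionless).
#' @export
f1_difference <- function(reference, test) {
  if (length(reference) != length(test))
    stop("profiles must share the same time grid")
  if (sum(reference) == 0) stop("reference profile sums to zero; f1 undefined")
  sum(abs(reference - test)) / sum(reference) * 100
}

#' f2 similarity factor between dissolution profiles
#'
#' \deqn{f_2 = 50 \log_{10}\left\{\left[1 + \frac{1}{n}\sum_t (R_t-T_t)^2
#' \right]^{-0.5} \times 100\right\}}
#' Identical profiles give 100; an average 10-point gap gives about 50.
#'
#' @inheritParams f1_difference
#' @return f2 (dimensionless).
#' @export
f2_similarity <- function(reference, test) {
  if (length(reference) != length(test))
    stop("profiles must share the same time grid")
  n <- length(reference)
  50 * log10((1 + sum((reference - test)^2) / n)^-0.5 * 100)
}

#' Welch's two-sample t-test
#'
#' Two-tailed heteroscedastic t-test (unequal variances,
#' Welch–Satterthwaite degrees of freedom), the standard comparison for
#' small dissolution / PK groups.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2,
                  p_value = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2, p_value = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
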
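#' Plasma concentration-time profile
#'
#' @param subject_id subject identifier.
#' @param times strictly increasing sampling times (h).
#' @param conc plasma concentrations (ng/mL), `NA` for missing /
#'   below-quantification samples.
#' @param route dosing route, `"IV"` or `"SC"`.
#' @param dose_mg_per_kg dose in mg per kg body weight.
#' @param body_weight_g body weight at dosing (g). With the dose in mg/kg
#'   and the weight in g, the absolute dose in micrograms is simply
#'   `dose_mg_per_kg * body_weight_g`.
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(subject_id, times, conc, route = c("SC", "IV"),
                         dose_mg_per_kg, body_weight_g) {
  route <- match.arg(route)
  stopifnot(!is.unsorted(times, strictly = TRUE),
            length(conc) == length(times),
            all(conc >= 0 | is.na(conc)),
            dose_mg_per_kg > 0, body_weight_g > 0)
  structure(list(subject_id = subject_id, times = times, conc = conc,
                 route = route, dose_mg_per_kg = dose_mg_per_kg,
                 body_weight_g = body_weight_g,
                 dose_ug = dose_mg_per_kg * body_weight_g),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("Plasma profile %s (%s, %.3g mg/kg, %.4g g): %d samples, %g-%g h\n",
              x$subject_id, x$route, x$dose_mg_per_kg, x$body_weight_g,
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Mean plasma profile across subjects
#'
#' Averages concentrations over subjects sharing a common sampling schedule
#' (the deconvolution and UIR estimation in this package operate on mean
#' profiles of the dose group).
#'
#' @param profiles list of [conc_profile()] objects with identical times,
#'   route and dose.
#' @return A [conc_profile()] with `subject_id = "mean"` and the mean body
#'   weight.
#' @export
mean_profile <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "conc_profile")))
  t0 <- profiles[[1]]$times
  for (p in profiles)
    if (!isTRUE(all.equal(p$times, t0)))
      stop("profiles must share the sampling schedule")
  conc <- rowMeans(vapply(profiles, `[[`, numeric(length(t0)), "conc"))
  conc_profile("mean", t0, conc, route = profiles[[1]]$route,
               dose_mg_per_kg = profiles[[1]]$dose_mg_per_kg,
               body_weight_g = mean(vapply(profiles, `[[`, 0, "body_weight_g")))
}

#' Biexponential unit impulse response (UIR)
#'
#' Disposition function per unit dose,
#' \eqn{C_\delta(t) = A e^{-\alpha t} + B e^{-\beta t}}, from a
#' two-compartment IV-bolus, first-order elimination model. The
#' macro-constants are stored with `alpha` as the slow (terminal)
#' disposition constant and `beta` as the fast one, matching the roles in
#' the depot application this package targets. The dose basis is explicit:
#' `A` and `B` are concentrations per microgram of dose.
#'
#' @param A,B macro-constant coefficients (ng/mL per microgram of dose),
#'   non-negative.
#' @param alpha,beta disposition rate constants (1/h), positive.
#' @param dose_basis character tag for the dose unit of the coefficients
#'   (only `"ug"` is used).
#' @return An object of class `uir`.
#' @export
uir <- function(A, B, alpha, beta, dose_basis = "ug") {
  stopifnot(A >= 0, B >= 0, alpha > 0, beta > 0)
  structure(list(A = A, B = B, alpha = alpha, beta = beta,
                 dose_basis = dose_basis),
            class = "uir")
}

#' @export
print.uir <- function(x, ...) {
  cat(sprintf("Biexponential UIR (per %s dose):\n", x$dose_basis))
  cat(sprintf("  C_delta(t) = %.4g exp(-%.4g t) + %.4g exp(-%.4g t) ng/mL\n",
              x$A, x$alpha, x$B, x$beta))
  cat(sprintf("  AUC per unit dose: %.4g ng.h/mL\n",
              x$A / x$alpha + x$B / x$beta))
  invisible(x)
}

#' Evaluate the UIR for a given dose
#'
#' @param u a [uir()].
#' @param t times (h), non-negative.
#' @param dose_ug dose in micrograms (default 1: unit impulse).
#' @return concentrations (ng/mL).
#' @export
eval_uir <- function(u, t, dose_ug = 1) {
  stopifnot(inherits(u, "uir"), all(t >= 0), dose_ug >= 0)
  dose_ug * (u$A * exp(-u$alpha * t) + u$B * exp(-u$beta * t))
}

## ------------------------------------------------------------------------
## non-compartmental analysis

# linear interpolation of concentration at a cut time (within tlast)
.interp_conc <- function(times, conc, at) {
  stats::approx(times, conc, xout = at, rule = 1)$y
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# lin-up/log-down trapezoid
.trapz_linlog <- function(x, y) {
  s <- 0
  for (k in 2:length(x)) {
    dx <- x[k] - x[k - 1]
    if (y[k] < y[k - 1] && y[k] > 0 && y[k - 1] > 0)
      s <- s + dx * (y[k - 1] - y[k]) / log(y[k - 1] / y[k])
    else s <- s + dx * (y[k - 1] + y[k]) / 2
  }
  s
}

#' Non-compartmental analysis of a plasma profile
#'
#' Computes Cmax/tmax from the observed maxima, partial AUCs by the
#' trapezoidal rule with linear interpolation at the cut times, AUC to the
#' last quantifiable sample, the terminal log-linear slope
#' \eqn{\lambda_z} (regression window chosen by best adjusted R-squared
#' over candidate terminal windows of at least 3 points, excluding Cmax;
#' ties resolved toward more points), the terminal half-life
#' \eqn{t_{1/2} = \ln 2/\lambda_z}, and, for IV profiles, the
#' back-extrapolated `C0` (log-linear through the first two samples) and
#' \eqn{AUC_\infty = AUC_{last} + C_{last}/\lambda_z}.
#'
#' Missing (below-quantification) concentrations are excluded, not set to
#' zero. The concentration at time zero is taken as `C0` for IV profiles
#' and 0 for extravascular ones.
#'
#' @param profile a [conc_profile()].
#' @param partial_h cut times (h) for partial AUCs.
#' @param auc_method `"linear"` trapezoid (default) or `"linup-logdown"`.
#' @return An object of class `nca_result`: list with `C0`, `Cmax`, `tmax`,
#'   `tlast`, `auc_partial` (named vector; `NA` and flagged when a cut time
#'   exceeds `tlast`), `auc_last`, `auc_inf`, `lambda_z`, `t_half`,
#'   `lambda_z_points`, `flags`.
#' @export
nca <- function(profile, partial_h = c(48, 168, 672, 2016),
                auc_method = c("linear", "linup-logdown")) {
  stopifnot(inherits(profile, "conc_profile"))
  auc_method <- match.arg(auc_method)
  ok <- !is.na(profile$conc)
  tt <- profile$times[ok]; cc <- profile$conc[ok]
  if (sum(cc > 0) < 3L) stop("need at least 3 positive concentrations")
  flags <- character(0)

  imax <- which.max(cc)
  Cmax <- cc[imax]; tmax <- tt[imax]
  tlast <- max(tt[cc > 0])

  ## C(0): observed if sampled, else back-extrapolated for IV, 0 for SC
  C0 <- NA_real_
  if (profile$route == "IV") {
    if (tt[1] == 0) C0 <- cc[1]
    else {
      i12 <- which(cc > 0)[1:2]
      sl <- (log(cc[i12[2]]) - log(cc[i12[1]])) / (tt[i12[2]] - tt[i12[1]])
      C0 <- exp(log(cc[i12[1]]) - sl * tt[i12[1]])
    }
  }
  if (tt[1] == 0) {
    t_grid <- tt
    c_grid <- cc
  } else {
    t_grid <- c(0, tt)
    c_grid <- c(if (profile$route == "IV") C0 else 0, cc)
  }

  auc_fun <- if (auc_method == "linear") .trapz else .trapz_linlog
  ilast <- max(which(c_grid > 0))
  auc_last <- auc_fun(t_grid[1:ilast], c_grid[1:ilast])

  auc_partial <- vapply(partial_h, function(cut) {
    if (cut > tlast) return(NA_real_)
    keep <- t_grid <= cut
    xs <- t_grid[keep]; ys <- c_grid[keep]
    if (max(xs) < cut) {
      xs <- c(xs, cut)
      ys <- c(ys, .interp_conc(t_grid, c_grid, cut))
    }
    auc_fun(xs, ys)
  }, 0)
  names(auc_partial) <- paste0("AUC_", partial_h, "h")
  if (anyNA(auc_partial))
    flags <- c(flags, "partial AUC cut beyond tlast: not computed")

  ## terminal slope; candidate windows: the last 3..12 points after Cmax
  pos <- which(cc > 0 & tt > tmax)  # strictly after Cmax
  lambda_z <- NA_real_; t_half <- NA_real_; lz_pts <- NA_integer_
  if (length(pos) >= 3L) {
    best <- NULL
    for (k in seq(3L, min(length(pos), 12L))) {
      idx <- utils::tail(pos, k)
      x <- tt[idx]; y <- log(cc[idx])
      sxx <- sum((x - mean(x))^2)
      slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
      if (slope >= 0) next
      sst <- sum((y - mean(y))^2)
      sse <- sst - slope^2 * sxx
      r2 <- if (sst <= 0) 1 else 1 - sse / sst
      ar2 <- 1 - (1 - r2) * (k - 1) / (k - 2)
      if (is.null(best) || ar2 > best$ar2 + 1e-12 ||
          abs(ar2 - best$ar2) <= 1e-12 && k > best$k)
        best <- list(ar2 = ar2, k = k, slope = slope)
    }
    if (!is.null(best)) {
      lambda_z <- -best$slope
      t_half <- log(2) / lambda_z
      lz_pts <- best$k
    }
  }
  if (is.na(lambda_z)) flags <- c(flags, "lambda_z not estimable")
  auc_inf <- if (!is.na(lambda_z))
    auc_last + c_grid[ilast] / lambda_z else NA_real_

  structure(list(C0 = C0, Cmax = Cmax, tmax = tmax, tlast = tlast,
                 auc_partial = auc_partial, auc_last = auc_last,
                 auc_inf = auc_inf, lambda_z = lambda_z, t_half = t_half,
                 lambda_z_points = lz_pts, flags = flags,
                 subject_id = profile$subject_id, route = profile$route),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA (%s, %s): Cmax %.4g ng/mL at %g h; AUC_last %.5g ng.h/mL\n",
              x$subject_id, x$route, x$Cmax, x$tmax, x$auc_last))
  if (!is.na(x$lambda_z))
    cat(sprintf("  lambda_z %.4g /h (%d pts), t1/2 %.4g h, AUC_inf %.5g\n",
                x$lambda_z, x$lambda_z_points, x$t_half, x$auc_inf))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  out <- data.frame(subject_id = x$subject_id, route = x$route, C0 = x$C0,
                    Cmax = x$Cmax, tmax = x$tmax, tlast = x$tlast,
                    auc_last = x$auc_last, auc_inf = x$auc_inf,
                    lambda_z = x$lambda_z, t_half = x$t_half)
  for (nm in names(x$auc_partial)) out[[nm]] <- x$auc_partial[[nm]]
  out
}

## ------------------------------------------------------------------------
## UIR estimation

# curve stripping: terminal log-linear fit, then residual fit
.strip_biexp <- function(tt, yy, n_terminal = 3L) {
  n <- length(tt)
  idx_t <- seq(max(1L, n - max(n_terminal, floor(n / 2)) + 1L), n)
  ft <- stats::lm(log(yy[idx_t]) ~ tt[idx_t])
  alpha0 <- max(-unname(stats::coef(ft)[2]), 1e-6)
  A0 <- exp(unname(stats::coef(ft)[1]))
  res <- yy - A0 * exp(-alpha0 * tt)
  idx_e <- which(res > 0 & seq_len(n) <= ceiling(n / 2))
  if (length(idx_e) >= 2L) {
    fe <- stats::lm(log(res[idx_e]) ~ tt[idx_e])
    beta0 <- max(-unname(stats::coef(fe)[2]), alpha0 * 2)
    B0 <- exp(unname(stats::coef(fe)[1]))
  } else {
    beta0 <- alpha0 * 10
    B0 <- max(yy[1] - A0, A0 * 0.1)
  }
  c(A = A0, alpha = alpha0, B = B0, beta = beta0)
}

#' Fit a biexponential UIR to an IV profile
#'
#' Dose-normalises the concentrations (per microgram) and fits
#' \eqn{C_\delta(t) = A e^{-\alpha t} + B e^{-\beta t}} by nonlinear least
#' squares, initialised by curve stripping (terminal log-linear fit, then a
#' log-linear fit of the early residuals). The slower constant is reported
#' as `alpha`.
#'
#' @param profile an IV [conc_profile()] (typically the [mean_profile()] of
#'   the IV group) with at least 4 positive concentrations.
#' @return A [uir()] with per-microgram dose basis. If the fast term is
#'   degenerate (`B` negligible) the result is flagged with attribute
#'   `degenerate = TRUE` and a warning.
#' @export
fit_uir <- function(profile) {
  stopifnot(inherits(profile, "conc_profile"))
  if (profile$route != "IV") stop("UIR estimation requires an IV profile")
  ok <- !is.na(profile$conc) & profile$conc > 0
  tt <- profile$times[ok]
  yy <- profile$conc[ok] / profile$dose_ug
  if (length(tt) < 4L) stop("need at least 4 positive concentrations")
  st <- .strip_biexp(tt, yy)
  resid_fun <- function(p)
    p[1] * exp(-p[2] * tt) + p[3] * exp(-p[4] * tt) - yy
  starts <- list(unname(st),
                 c(yy[1] * 0.75, st[["alpha"]], yy[1] * 0.25,
                   st[["alpha"]] * 15))
  best <- NULL
  for (s0 in starts) {
    opt <- try(suppressWarnings(minpack.lm::nls.lm(
      s0, lower = rep(1e-10, 4), upper = rep(Inf, 4), fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15))), silent = TRUE)
    if (inherits(opt, "try-error")) next
    sse <- sum(resid_fun(opt$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(par = opt$par, sse = sse)
  }
  if (is.null(best))
    stop("UIR fit did not converge; stripped starts: ",
         paste(sprintf("%s=%.3g", names(st), st), collapse = ", "))
  cf <- best$par
  names(cf) <- c("A", "alpha", "B", "beta")
  # order so that alpha is the slow constant
  if (cf[["alpha"]] > cf[["beta"]])
    cf <- c(A = cf[["B"]], alpha = cf[["beta"]],
            B = cf[["A"]], beta = cf[["alpha"]])
  out <- uir(cf[["A"]], cf[["B"]], cf[["alpha"]], cf[["beta"]])
  if (cf[["B"]] < 1e-6 * max(cf[["A"]], 1e-12)) {
    warning("fast term degenerate: data are effectively mono-exponential")
    attr(out, "degenerate") <- TRUE
  }
  out
}
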
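#' Power-law (Korsmeyer-Peppas) release phase
#'
#' A single empirical power-law release segment \eqn{F(t) = K (t - a)^n},
#' active for \eqn{t > a} and frozen at its value at `t_end` for later times.
#' These segments are the building blocks of multiphasic depot release
#' profiles: an initial burst, a slower diffusion-controlled phase, and
#' (for erodible polymers) a late accelerated phase.
#'
#' @param K release rate constant (units 1/h^n), `K >= 0`.
#' @param n release exponent (dimensionless), `n > 0`. Diagnoses the release
#'   mechanism; see [classify_mechanism()].
#' @param anchor time origin of the power law in hours. The burst and the
#'   second phase of a depot profile are conventionally anchored at 0; a late
#'   accelerated phase is anchored at its own onset time.
#' @param t_end end of active growth (h). The phase contribution is frozen at
#'   its `t_end` value for `t > t_end`. `Inf` means never frozen.
#' @param scale multiplier applied to `K` (used for in vivo scaling factors;
#'   default 1).
#' @param label optional phase name ("burst", "phase2", "phase3").
#' @return An object of class `power_law_phase`.
#' @seealso [composite_release_model()], [eval_power_law()]
#' @export
power_law_phase <- function(K, n, anchor = 0, t_end = Inf, scale = 1,
                            label = NULL) {
  stopifnot(is.numeric(K), length(K) == 1L, K >= 0,
            is.numeric(n), length(n) == 1L, n > 0,
            is.numeric(anchor), anchor >= 0,
            is.numeric(t_end), t_end > anchor,
            is.numeric(scale), scale > 0)
  structure(list(K = K, n = n, anchor = anchor, t_end = t_end,
                 scale = scale, label = label),
            class = "power_law_phase")
}

#' Higuchi release model
#'
#' Fickian square-root-of-time release, a power law with the exponent fixed
#' at 0.5.
#'
#' @inheritParams power_law_phase
#' @return A `power_law_phase` with `n = 0.5`.
#' @export
higuchi_phase <- function(K, anchor = 0, t_end = Inf) {
  power_law_phase(K, 0.5, anchor = anchor, t_end = t_end, label = "higuchi")
}

#' Peppas-Sahlin release model
#'
#' Two-term release model \eqn{F(t) = K_1 t^{n_1} + K_2 t^{n_2}} separating a
#' diffusional and a relaxational contribution. Provided as an alternative
#' empirical form; the composite piecewise power law is the primary model.
#'
#' @param K1,K2 rate constants (1/h^n), non-negative.
#' @param n1,n2 exponents (dimensionless), positive.
#' @return An object of class `peppas_sahlin`.
#' @export
peppas_sahlin <- function(K1, K2, n1, n2) {
  stopifnot(K1 >= 0, K2 >= 0, n1 > 0, n2 > 0)
  structure(list(K1 = K1, K2 = K2, n1 = n1, n2 = n2),
            class = "peppas_sahlin")
}

#' Evaluate a Peppas-Sahlin model
#' @param model a [peppas_sahlin()] object.
#' @param t times (h), non-negative.
#' @return fraction released at `t`.
#' @export
eval_peppas_sahlin <- function(model, t) {
  stopifnot(inherits(model, "peppas_sahlin"), all(t >= 0))
  model$K1 * t^model$n1 + model$K2 * t^model$n2
}

#' Evaluate a power-law phase contribution
#'
#' Returns \eqn{K (\min(t, t_{end}) - a)^n} for `t > a` and 0 otherwise;
#' the contribution is frozen at its `t_end` value for `t > t_end`.
#'
#' @param phase a [power_law_phase()].
#' @param t times (h), non-negative.
#' @return fraction contribution of this phase at each `t`.
#' @export
eval_power_law <- function(phase, t) {
  stopifnot(inherits(phase, "power_law_phase"), all(t >= 0))
  te <- pmin(t, phase$t_end)
  out <- ifelse(t > phase$anchor,
                phase$scale * phase$K * pmax(te - phase$anchor, 0)^phase$n,
                0)
  out
}

#' Composite multiphasic release model
#'
#' An ordered set of power-law phases combined additively, with each phase's
#' contribution frozen beyond its own growth window and the total capped at
#' `cap` (complete release). The default convention for triphasic depot
#' profiles is: burst anchored at 0 and frozen at the burst end; second phase
#' anchored at 0 (co-growing with the burst) and frozen at its window end;
#' accelerated third phase anchored at its onset.
#'
#' @param phases list of [power_law_phase()] objects, ordered by onset.
#' @param cap maximum total fraction (default 1).
#' @return An object of class `composite_release_model`.
#' @export
composite_release_model <- function(phases, cap = 1) {
  stopifnot(is.list(phases), length(phases) >= 1L,
            all(vapply(phases, inherits, TRUE, "power_law_phase")),
            is.numeric(cap), cap > 0)
  anchors <- vapply(phases, `[[`, 0, "anchor")
  if (is.unsorted(anchors)) stop("phases must be ordered by anchor time")
  structure(list(phases = phases, cap = cap),
            class = "composite_release_model")
}

#' @export
print.composite_release_model <- function(x, ...) {
  cat("Composite power-law release model (", length(x$phases),
      " phase(s), cap ", x$cap, ")\n", sep = "")
  for (p in x$phases) {
    cat(sprintf("  %-7s K = %-9.4g n = %-6.4g anchor = %-5g t_end = %g%s\n",
                if (is.null(p$label)) "" else p$label,
                p$K, p$n, p$anchor, p$t_end,
                if (p$scale != 1) sprintf("  (scale %.3g)", p$scale) else ""))
  }
  invisible(x)
}

#' Evaluate a composite release model
#'
#' Sum of the frozen-phase contributions, capped at the model cap. The
#' result is non-decreasing in `t` and bounded in `[0, cap]`.
#'
#' @param model a [composite_release_model()].
#' @param t times (h), non-negative.
#' @return fraction released/absorbed at each `t`.
#' @export
eval_composite <- function(model, t) {
  stopifnot(inherits(model, "composite_release_model"), all(t >= 0))
  total <- 0
  for (p in model$phases) total <- total + eval_power_law(p, t)
  pmin(total, model$cap)
}

## ------------------------------------------------------------------------
## fitting

# extract (time, F) pairs from a release_profile / data.frame for fitting
.fit_data <- function(profile) {
  if (inherits(profile, "release_profile")) {
    data.frame(time_h = profile$times, F = profile$mean)
  } else if (is.data.frame(profile)) {
    nm <- names(profile)
    tcol <- intersect(c("time_h", "time", "t"), nm)[1]
    fcol <- intersect(c("F", "F_diss", "fdiss", "f"), nm)[1]
    if (is.na(tcol) || is.na(fcol))
      stop("data.frame profile needs a time and an F column")
    data.frame(time_h = profile[[tcol]], F = profile[[fcol]])
  } else stop("profile must be a release_profile or data.frame")
}

# closed-form least-squares K for fixed exponent (no intercept)
.kp_K_for_n <- function(tt, ff, n, anchor) {
  x <- pmax(tt - anchor, 0)^n
  s2 <- sum(x^2)
  if (s2 == 0) return(0)
  max(sum(ff * x) / s2, 0)
}

.kp_sse <- function(tt, ff, K, n, anchor) {
  sum((K * pmax(tt - anchor, 0)^n - ff)^2)
}

#' Fit a single power-law release model
#'
#' Least-squares fit of \eqn{F = K (t - a)^n} on the fraction scale. For a
#' given exponent the optimal `K` has a closed form, so the free-exponent
#' problem reduces to a one-dimensional search over `n`, run from three
#' starting subintervals to guard against local minima.
#'
#' @param profile a [release_profile][cumulative_release] or a data.frame
#'   with `time_h` and `F` columns (mean fraction released).
#' @param window fitting window in hours, `c(lo, hi)`; only observed points
#'   with `lo <= t <= hi` enter the fit.
#' @param fixed_n if supplied, the exponent is held at this value and only
#'   `K` is estimated.
#' @param anchor time origin of the power law (h).
#' @param f_cutoff upper fraction cutoff: observed points with mean F above
#'   this are excluded (release models are fitted only up to approximately
#'   85% release by convention). `NULL` disables the cutoff.
#' @param n_bounds search bounds for the free exponent.
#' @return A `fit_result` list: `model` (the fitted [power_law_phase()]),
#'   `sse`, `n_points`, `window_used`.
#' @export
fit_power_law <- function(profile, window = c(0, Inf), fixed_n = NULL,
                          anchor = 0, f_cutoff = 0.85,
                          n_bounds = c(0.05, 3)) {
  d <- .fit_data(profile)
  keep <- d$time_h >= window[1] & d$time_h <= window[2] & d$time_h > anchor
  if (!is.null(f_cutoff)) keep <- keep & d$F <= f_cutoff
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 points in the fitting window")
  if (any(d$F < 0 | d$F > 1.05)) stop("F values must lie in [0, 1]")
  tt <- d$time_h; ff <- d$F
  if (max(ff) - min(ff) < .Machine$double.eps^0.5 && all(ff == ff[1])) {
    warning("degenerate window: all F equal; returning K = 0")
    phase <- power_law_phase(0 + .Machine$double.xmin, 1, anchor = anchor)
    phase$K <- 0
    return(structure(list(model = phase, sse = .kp_sse(tt, ff, 0, 1, anchor),
                          n_points = length(tt), window_used = range(tt)),
                     class = "fit_result"))
  }
  if (!is.null(fixed_n)) {
    n_hat <- fixed_n
    K_hat <- .kp_K_for_n(tt, ff, n_hat, anchor)
  } else {
    obj <- function(n) .kp_sse(tt, ff, .kp_K_for_n(tt, ff, n, anchor), n, anchor)
    # multi-start: three subintervals of the exponent range
    brk <- exp(seq(log(n_bounds[1]), log(n_bounds[2]), length.out = 4))
    cands <- lapply(1:3, function(i)
      stats::optimize(obj, lower = brk[i], upper = brk[i + 1], tol = 1e-12))
    best <- cands[[which.min(vapply(cands, `[[`, 0, "objective"))]]
    n_hat <- best$minimum
    K_hat <- .kp_K_for_n(tt, ff, n_hat, anchor)
  }
  phase <- power_law_phase(max(K_hat, .Machine$double.xmin), n_hat,
                           anchor = anchor)
  phase$K <- K_hat
  structure(list(model = phase, sse = .kp_sse(tt, ff, K_hat, n_hat, anchor),
                 n_points = length(tt), window_used = range(tt)),
            class = "fit_result")
}

#' Joint power-law fit with a shared exponent across profiles
#'
#' Fits one power law per profile under the constraint that all profiles
#' share a single exponent `n` (exponents of depot release profiles are often
#' similar across drugs and formulations, and refitting with a common
#' average exponent eases trend comparison). The shared exponent is found by
#' one-dimensional least squares over the pooled SSE; each profile's `K` is
#' the closed-form conditional optimum.
#'
#' @param profiles a list of profiles (see [fit_power_law()]).
#' @inheritParams fit_power_law
#' @return list with `n` (shared exponent), `fits` (list of `fit_result`),
#'   `sse` (pooled).
#' @export
fit_power_law_tied <- function(profiles, window = c(0, Inf), anchor = 0,
                               f_cutoff = 0.85, n_bounds = c(0.05, 3)) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  dat <- lapply(profiles, function(p) {
    d <- .fit_data(p)
    keep <- d$time_h >= window[1] & d$time_h <= window[2] & d$time_h > anchor
    if (!is.null(f_cutoff)) keep <- keep & d$F <= f_cutoff
    d[keep, , drop = FALSE]
  })
  pooled_sse <- function(n) sum(vapply(dat, function(d) {
    .kp_sse(d$time_h, d$F, .kp_K_for_n(d$time_h, d$F, n, anchor), n, anchor)
  }, 0))
  brk <- exp(seq(log(n_bounds[1]), log(n_bounds[2]), length.out = 4))
  cands <- lapply(1:3, function(i)
    stats::optimize(pooled_sse, lower = brk[i], upper = brk[i + 1], tol = 1e-12))
  best <- cands[[which.min(vapply(cands, `[[`, 0, "objective"))]]
  n_hat <- best$minimum
  fits <- lapply(seq_along(profiles), function(i)
    fit_power_law(profiles[[i]], window = window, fixed_n = n_hat,
                  anchor = anchor, f_cutoff = f_cutoff))
  list(n = n_hat, fits = fits, sse = best$objective)
}

#' Fit a composite (multiphasic) release model
#'
#' Fits a burst phase, a second phase and optionally an accelerated third
#' phase to a release profile under the additive frozen-phase convention:
#' burst anchored at 0 and frozen at the first breakpoint, second phase
#' anchored at `phase2_anchor` and frozen at the second breakpoint (or the
#' last observation), third phase anchored at the second breakpoint.
#' Initial estimates come from sequential residual stripping; all phase
#' parameters are then refined jointly by bounded least squares.
#'
#' @inheritParams fit_power_law
#' @param breakpoints numeric vector of 1 or 2 phase boundaries (h):
#'   `c(burst_end)` for a biphasic profile or `c(burst_end, onset3)` for a
#'   triphasic one. Must lie inside the observed time range.
#' @param fixed_n optional numeric vector of exponents (one per phase, `NA`
#'   for free).
#' @param phase2_anchor anchor of the second phase: 0 (co-growing with the
#'   burst, the in vitro convention) or the burst end.
#' @return A `fit_result` with `model` a [composite_release_model()].
#' @export
fit_composite <- function(profile, breakpoints, fixed_n = NULL,
                          phase2_anchor = 0, f_cutoff = NULL, cap = 1) {
  d <- .fit_data(profile)
  if (!is.null(f_cutoff)) d <- d[d$F <= f_cutoff, , drop = FALSE]
  tt <- d$time_h; ff <- d$F
  if (length(breakpoints) < 1L || length(breakpoints) > 2L)
    stop("breakpoints must have length 1 or 2")
  if (any(breakpoints <= min(tt)) || any(breakpoints >= max(tt)))
    stop("breakpoints must lie inside the observed time range")
  bp1 <- breakpoints[1]
  bp2 <- if (length(breakpoints) == 2L) breakpoints[2] else NA_real_
  n_phases <- if (is.na(bp2)) 2L else 3L
  if (is.null(fixed_n)) fixed_n <- rep(NA_real_, n_phases)
  stopifnot(length(fixed_n) == n_phases)

  t_end2 <- if (is.na(bp2)) max(tt) else bp2

  ## -- sequential initial estimates -------------------------------------
  f1 <- fit_power_law(d[tt <= bp1, , drop = FALSE], anchor = 0,
                      fixed_n = if (is.na(fixed_n[1])) NULL else fixed_n[1],
                      f_cutoff = NULL)
  burst0 <- f1$model; burst0$t_end <- bp1
  res2 <- ff - eval_power_law(burst0, tt)
  in2 <- tt > bp1 & (is.na(bp2) | tt <= bp2)
  d2 <- data.frame(time_h = tt[in2], F = pmax(res2[in2], 0))
  f2 <- if (nrow(d2) >= 3L)
    fit_power_law(d2, anchor = phase2_anchor,
                  fixed_n = if (is.na(fixed_n[2])) NULL else fixed_n[2],
                  f_cutoff = NULL)
  else list(model = power_law_phase(1e-3, 0.5, anchor = phase2_anchor))
  ph2_0 <- f2$model; ph2_0$t_end <- t_end2
  init <- list(burst0, ph2_0)
  if (n_phases == 3L) {
    frozen <- eval_power_law(burst0, tt) + eval_power_law(ph2_0, tt)
    in3 <- tt > bp2
    d3 <- data.frame(time_h = tt[in3], F = pmax(ff[in3] - frozen[in3], 0))
    f3 <- if (nrow(d3) >= 3L)
      fit_power_law(d3, anchor = bp2,
                    fixed_n = if (is.na(fixed_n[3])) NULL else fixed_n[3],
                    f_cutoff = NULL)
    else list(model = power_law_phase(1e-4, 1.2, anchor = bp2))
    ph3_0 <- f3$model
    init <- c(init, list(ph3_0))
  }

  ## -- joint refinement --------------------------------------------------
  anchors <- c(0, phase2_anchor, if (n_phases == 3L) bp2)
  t_ends <- c(bp1, t_end2, if (n_phases == 3L) max(tt))
  free_n <- is.na(fixed_n)
  par0 <- unlist(lapply(seq_len(n_phases), function(i)
    c(log(max(init[[i]]$K, 1e-12)), if (free_n[i]) init[[i]]$n)))
  unpack <- function(par) {
    out <- vector("list", n_phases); j <- 1L
    for (i in seq_len(n_phases)) {
      K <- exp(par[j]); j <- j + 1L
      n <- if (free_n[i]) { v <- par[j]; j <- j + 1L; v } else fixed_n[i]
      out[[i]] <- power_law_phase(K, n, anchor = anchors[i], t_end = t_ends[i])
    }
    out
  }
  resid_fun <- function(par) {
    m <- composite_release_model(unpack(par), cap = cap)
    eval_composite(m, tt) - ff
  }
  lower <- unlist(lapply(seq_len(n_phases), function(i)
    c(-30, if (free_n[i]) 0.05)))
  upper <- unlist(lapply(seq_len(n_phases), function(i)
    c(5, if (free_n[i]) 3)))
  opt <- minpack.lm::nls.lm(par0, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
  phases <- unpack(opt$par)
  labs <- c("burst", "phase2", "phase3")
  for (i in seq_len(n_phases)) phases[[i]]$label <- labs[i]
  model <- composite_release_model(phases, cap = cap)
  structure(list(model = model, sse = sum(resid_fun(opt$par)^2),
                 n_points = length(tt), window_used = range(tt),
                 convergence = opt$info),
            class = "fit_result")
}

#' Joint composite fit with exponents tied across profiles
#'
#' Fits composite (multiphasic) release models to several profiles
#' simultaneously under the constraint that corresponding phases share
#' their exponents across profiles (release exponents of depot
#' formulations of one drug are typically similar, and tying them is the
#' standard guard against overfitting). Given the exponents, every rate
#' constant enters the model linearly (each phase contribution is `K`
#' times a known frozen-power-law basis), so the inner problem is solved
#' exactly by linear least squares per profile and only the tied exponents
#' are optimised nonlinearly. Observed points beyond the release plateau
#' (`F > f_max`, first crossing) are excluded, as the cap makes the model
#' nonlinear there.
#'
#' @param profiles named list of profiles (see [fit_power_law()]).
#' @param breakpoints named list of breakpoint vectors per profile (see
#'   [fit_composite()]).
#' @param tie_groups named list mapping each profile to an integer vector,
#'   one entry per phase, giving the index of the shared-exponent group
#'   that phase belongs to (e.g. `list(F1 = c(1, 2, 3), F2 = c(1, 2))`:
#'   bursts tied, second phases tied, F1's third phase its own group).
#' @param K_tie_groups optional named list of the same shape tying rate
#'   constants across profiles (e.g. formulations with equal polymer
#'   concentration sharing one burst `K`); by default every
#'   (profile, phase) has its own `K`.
#' @param n_start numeric vector of starting exponents, one per group.
#' @param f_max plateau exclusion threshold.
#' @return list with `n` (fitted exponents per group), `models` (named
#'   list of [composite_release_model()]s), `sse` (pooled).
#' @export
fit_composite_tied <- function(profiles, breakpoints, tie_groups,
                               K_tie_groups = NULL, n_start = NULL,
                               f_max = 0.95) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            setequal(names(profiles), names(breakpoints)),
            setequal(names(profiles), names(tie_groups)))
  nms <- names(profiles)
  n_groups <- max(unlist(tie_groups))
  if (is.null(n_start)) n_start <- rep(0.5, n_groups)
  if (is.null(K_tie_groups)) {
    counter <- 0L
    K_tie_groups <- lapply(nms, function(f) {
      idx <- counter + seq_along(tie_groups[[f]])
      counter <<- counter + length(tie_groups[[f]])
      idx
    })
    names(K_tie_groups) <- nms
  }
  stopifnot(setequal(names(K_tie_groups), nms))
  nK <- max(unlist(K_tie_groups))
  dat <- lapply(nms, function(f) {
    d <- .fit_data(profiles[[f]])
    over <- which(d$F > f_max)
    if (length(over)) d <- d[seq_len(over[1] - 1L), , drop = FALSE]
    d
  })
  names(dat) <- nms
  geom <- lapply(nms, function(f) {
    bp <- breakpoints[[f]]
    np <- length(tie_groups[[f]])
    stopifnot(np == length(bp) + 1L)
    tmax <- max(dat[[f]]$time_h)
    list(anchor = c(0, 0, if (np == 3L) bp[2]),
         t_end = c(bp[1],
                   if (np >= 2L) (if (length(bp) == 2L) bp[2] else tmax),
                   if (np == 3L) tmax))
  })
  names(geom) <- nms
  basis <- function(f, nvec, tt) {
    g <- geom[[f]]; gi <- tie_groups[[f]]
    vapply(seq_along(gi), function(i)
      pmax(pmin(tt, g$t_end[i]) - g$anchor[i], 0)^nvec[gi[i]] *
        (tt > g$anchor[i]),
      numeric(length(tt)))
  }
  # one global linear solve over all profiles: columns are K tie groups
  design_all <- function(nvec) {
    X <- NULL; y <- NULL
    for (f in nms) {
      B <- basis(f, nvec, dat[[f]]$time_h)
      Xf <- matrix(0, nrow(B), nK)
      for (i in seq_along(K_tie_groups[[f]]))
        Xf[, K_tie_groups[[f]][i]] <- Xf[, K_tie_groups[[f]][i]] + B[, i]
      X <- rbind(X, Xf); y <- c(y, dat[[f]]$F)
    }
    list(X = X, y = y)
  }
  solve_K <- function(nvec) {
    d <- design_all(nvec)
    used <- colSums(abs(d$X)) > 0
    K <- numeric(nK)
    K[used] <- stats::coef(stats::lm.fit(d$X[, used, drop = FALSE], d$y))
    unname(pmax(K, 0))
  }
  resid_all <- function(nvec) {
    d <- design_all(nvec)
    drop(d$X %*% solve_K(nvec)) - d$y
  }
  opt <- suppressWarnings(minpack.lm::nls.lm(
    n_start, lower = rep(0.05, n_groups), upper = rep(3, n_groups),
    fn = resid_all,
    control = minpack.lm::nls.lm.control(maxiter = 500)))
  n_hat <- opt$par
  K_hat <- solve_K(n_hat)
  models <- lapply(nms, function(f) {
    g <- geom[[f]]; gi <- tie_groups[[f]]
    labs <- c("burst", "phase2", "phase3")
    composite_release_model(lapply(seq_along(gi), function(i) {
      K <- K_hat[K_tie_groups[[f]][i]]
      p <- power_law_phase(max(K, .Machine$double.xmin), n_hat[gi[i]],
                           anchor = g$anchor[i], t_end = g$t_end[i],
                           label = labs[i])
      p$K <- K
      p
    }))
  })
  names(models) <- nms
  list(n = n_hat, models = models, sse = sum(resid_all(n_hat)^2))
}

#' Pearson goodness of fit for a release model
#'
#' Pearson correlation between fitted and observed fractions, computed over
#' the observed profile truncated at the first time point where the fitted
#' fraction exceeds `plateau` (or the last point if no plateau is reached).
#'
#' @param fit a `fit_result` (or any object with an evaluable model:
#'   `power_law_phase` or `composite_release_model`).
#' @param profile observed profile (see [fit_power_law()]).
#' @param plateau truncation threshold on the fitted fraction (default 0.95).
#' @return Pearson correlation coefficient; `NA` (with a warning) if fewer
#'   than 2 points remain or a series is constant.
#' @export
goodness_of_fit_pearson <- function(fit, profile, plateau = 0.95) {
  model <- if (inherits(fit, "fit_result")) fit$model else fit
  d <- .fit_data(profile)
  pred <- if (inherits(model, "composite_release_model"))
    eval_composite(model, d$time_h) else eval_power_law(model, d$time_h)
  over <- which(pred > plateau)
  if (length(over)) {
    cut <- over[1]  # include the first point past the plateau
    d <- d[seq_len(cut), , drop = FALSE]
    pred <- pred[seq_len(cut)]
  }
  if (nrow(d) < 2L) {
    warning("fewer than 2 points after plateau truncation; r undefined")
    return(NA_real_)
  }
  if (stats::sd(pred) == 0 || stats::sd(d$F) == 0) {
    warning("zero variance in fitted or observed values; r undefined")
    return(NA_real_)
  }
  stats::cor(pred, d$F)
}

#' Classify the release mechanism from the power-law exponent
#'
#' `n <= 0.5`: (pseudo-)Fickian diffusion; `0.5 < n < 1`: anomalous
#' (non-Fickian) transport; `n = 1`: case II (zero-order); `n > 1`:
#' super-case II transport driven by polymer erosion/swelling/dissolution.
#'
#' @param n release exponent(s), positive.
#' @return character vector of mechanism labels.
#' @export
classify_mechanism <- function(n) {
  stopifnot(all(n > 0))
  out <- character(length(n))
  out[n <= 0.5] <- "pseudo-Fickian"
  out[n > 0.5 & n < 1] <- "anomalous"
  out[n == 1] <- "case II"
  out[n > 1] <- "super-case II"
  out
}

#' Regress release rate constants on drug solubility
#'
#' Ordinary least-squares line `K = a * solubility + b` within a formulation
#' group, summarising how the release rate constant scales with drug
#' solubility in the release medium.
#'
#' @param K power-law rate constants.
#' @param solubility drug solubilities in the release medium (mg/mL).
#' @return list with `slope`, `intercept`, `r_squared` and the `lm` fit.
#' @export
regress_K_on_solubility <- function(K, solubility) {
  stopifnot(length(K) == length(solubility), length(K) >= 2L)
  if (stats::sd(solubility) == 0) stop("singular design: constant solubility")
  fit <- stats::lm(K ~ solubility)
  r2 <- if (stats::sd(K) == 0) 0 else summary(fit)$r.squared
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, fit = fit)
}
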
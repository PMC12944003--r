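# depotr

Release kinetics and point-to-point in vitro–in vivo correlation (IVIVC)
for long-acting injectable depots.

`depotr` is an R toolkit for formulation scientists and pharmacometricians
working on polymer depot systems such as PLGA in situ gels: formulations
that solidify after subcutaneous injection and release drug over weeks to
months. It covers the two halves of a depot development study and the
bridge between them:

**Part 1 — in vitro release (IVR) characterisation**

- withdrawal-corrected cumulative release: with medium volume *V*,
  withdrawal volume *V*ₛ and measured concentrations *Cᵢ*, the dissolved
  mass at the *i*-th sampling time is
  *mᵢ = Cᵢ·V + Σ<sub>j&lt;i</sub> Cⱼ·V*ₛ (drug removed at earlier
  withdrawals is added back);
- Korsmeyer–Peppas power-law fitting, *F(t) = K·tⁿ*, single-phase or as an
  additive piecewise composite (burst, slower diffusion phase, late
  accelerated erosion phase, each frozen at its window end and the total
  capped at 1), with exponents optionally tied across formulations;
- release-mechanism classification from *n* (pseudo-Fickian, anomalous,
  case II, super-case II), t50/t80 by linear interpolation, f1/f2
  difference/similarity factors, Welch's t-test, and regression of *K* on
  drug solubility;
- Higuchi and Peppas–Sahlin forms as alternative models.

**Part 2 — pharmacokinetics and IVIVC**

- non-compartmental analysis (Cmax, tmax, partial AUCs by trapezoid,
  λ<sub>z</sub> with adjusted-R² terminal-window selection, back-extrapolated C0,
  AUC<sub>∞</sub>);
- biexponential unit impulse response (UIR)
  *C*<sub>δ</sub>(t) = A·e<sup>−αt</sup> + B·e<sup>−βt</sup> per microgram of
  dose, estimated from mean IV profiles by curve stripping plus
  Levenberg–Marquardt refinement;
- exact staircase deconvolution of plasma profiles to the fraction
  absorbed *F*<sub>abs</sub>(t) (closed-form biexponential interval
  integrals, no quadrature), with `reconvolve()` as its exact inverse;
- phase-specific IVIVC: in vivo release modeled as
  *F*<sub>abs</sub> = A·K·tⁿ per phase, with the scaling factors *A*
  estimated by linear least squares under tie constraints across
  formulations and phases, convolution back to predicted plasma profiles,
  and internal prediction errors
  %PE = (observed − modeled)/observed × 100.

A synthetic-data module simulates dissolution vessels (with the physical
withdrawal/replacement bookkeeping) and IV/SC rat PK groups with
multiplicative residual error, so the entire pipeline is testable without
any external data. `reference_fixtures()` carries the transcribed
parameter tables of a published celecoxib ISG study (five model drugs ×
four PLGA/NMP formulations) used for desk-scale reproduction.

## Worked example

```r
library(depotr)

fix <- reference_fixtures()

## Part 1 -- simulate a quadruplicate vessel study for the slowest
## formulation and characterise its release from the raw concentrations
design <- ivr_design(schedule_h = default_schedules()$ivr_h,
                     n_vessels = 4, noise_cv = 0.05)
raw <- simulate_ivr_study(fix$celecoxib$F1$model, design, seed = 42)
profile <- suppressWarnings(cumulative_release(raw, design))
fit <- fit_power_law(profile)           # F = K t^n up to ~85% release
cat(sprintf("K = %.4f /h^n, n = %.3f (%s)\n", fit$model$K, fit$model$n,
            classify_mechanism(fit$model$n)))
t80 <- time_to_fraction(profile, 0.8)
cat(sprintf("t80 = %.0f (%.0f) h\n", t80$mean, t80$sd))

## Part 2 -- predict the depot pharmacokinetics from the published
## phase fits, scaling factors and unit impulse response
pred <- predict_reference_pk(fix)
subset(pred$modeled, parameter == "Cmax")
round(pred$pe$mean_abs, 1)
```

```
K = 0.0817 /h^n, n = 0.368 (pseudo-Fickian)
t80 = 477 (42) h
 formulation parameter    value
          F1      Cmax 640.2452
          F2      Cmax 640.2452
          F3      Cmax 345.6004
          F4      Cmax 246.8574
 AUC_168h AUC_2016h   AUC_48h  AUC_672h      Cmax 
      8.4       6.8       8.8       8.7       4.3
```

The simulated vessel study releases 80% of its dose after about 477 h
(~20 days) with a sub-0.5 exponent, i.e. diffusion-controlled release.
The predicted plasma peaks (640, 640, 346, 247 ng/mL for formulations
1–4 at 10 mg/kg SC in a 269 g rat) come from convolving the scaled
release models with the IV-derived unit impulse response; mean absolute
internal prediction errors against the observed PK parameters are below
10% for every parameter, which is the usual benchmark for an internally
valid point-to-point IVIVC.

Full-pipeline drivers are `run_part1()` (raw vessel CSV → summary, fits,
mechanism labels, K-vs-solubility regression) and `run_part2()` (plasma
data or fixtures → UIR, NCA, deconvolution, scaling, predicted PK, %PE).

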
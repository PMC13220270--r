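## Proteoliposome proton-transport kinetics ---------------------------------

#' Liposome specification
#'
#' Geometry and electrical properties of the proteoliposomes used to
#' convert membrane-potential slopes into per-liposome proton fluxes.
#'
#' @param diameter vesicle diameter, nm. Default 100 (extrusion pore size).
#' @param specific_capacitance membrane capacitance per area, uF/cm^2.
#'   Default 0.9 (typical lipid bilayer).
#' @param orientation_fraction_n_inside fraction of transporters with the
#'   N-side channel facing the liposome interior, in \[0, 1\]. Default 0.75.
#' @return list of class `LiposomeSpec`.
#' @export
liposome_spec <- function(diameter = 100, specific_capacitance = 0.9,
                          orientation_fraction_n_inside = 0.75) {
  if (diameter <= 0) stop("diameter must be > 0")
  if (specific_capacitance <= 0) stop("specific_capacitance must be > 0")
  if (orientation_fraction_n_inside < 0 || orientation_fraction_n_inside > 1)
    stop("orientation_fraction_n_inside must lie in [0, 1]")
  structure(list(diameter = diameter,
                 specific_capacitance = specific_capacitance,
                 orientation_fraction_n_inside =
                   orientation_fraction_n_inside),
            class = "LiposomeSpec")
}

## Pyranine (HPTS) ----------------------------------------------------------

#' Fit the pyranine pH calibration
#'
#' Least-squares fit of `pH = a * log10(R) + b` to (ratio, pH) calibration
#' pairs, where R is the 460/405 nm excitation-ratio of pyranine emission.
#'
#' @param ratio fluorescence ratios I460/I405, all > 0.
#' @param pH matching buffer pH values.
#' @return list of class `PyranineCalibration`: `a`, `b`, `fit_residual`
#'   (RMS pH).
#' @export
fit_ph_calibration <- function(ratio, pH) {
  if (length(ratio) != length(pH)) stop("ratio and pH lengths differ")
  if (length(ratio) < 2L) stop("need at least 2 calibration points")
  if (any(ratio <= 0)) stop("ratios must be > 0")
  if (length(unique(ratio)) < 2L)
    stop("calibration is rank deficient: all ratios equal")
  fit <- lm(pH ~ log10(ratio))
  structure(list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
                 fit_residual = sqrt(mean(fit$residuals^2))),
            class = "PyranineCalibration")
}

#' Fixed pyranine calibration
#'
#' Wraps known calibration parameters (e.g. a published a = 1.931,
#' b = 7.926) into a `PyranineCalibration` without fitting.
#'
#' @param a slope (pH per decade of ratio), nonzero.
#' @param b pH intercept (pH at ratio 1).
#' @return `PyranineCalibration`.
#' @export
pyranine_calibration <- function(a, b) {
  if (a == 0) stop("calibration slope a must be nonzero")
  structure(list(a = a, b = b, fit_residual = 0),
            class = "PyranineCalibration")
}

#' Convert a pyranine trace to a pH time series
#'
#' `pH(t) = a * log10(I460 / I405) + b` pointwise.
#'
#' @param trace `AssayTrace` with channels `I405` and `I460`.
#' @param calib a `PyranineCalibration`.
#' @return data.frame with columns `time` (s) and `pH`.
#' @export
ph_trace <- function(trace, calib) {
  ch <- trace$channels
  if (!all(c("I405", "I460") %in% names(ch)))
    stop("trace must carry channels I405 and I460")
  bad <- which(ch$I405 <= 0 | ch$I460 <= 0)
  if (length(bad) > 0L)
    stop(sprintf("nonpositive intensity at t = %g s", trace$time[bad[1]]))
  data.frame(time = trace$time,
             pH = calib$a * log10(ch$I460 / ch$I405) + calib$b)
}

#' Extract delta-pH from a pH time series
#'
#' The initial pH is the baseline average over `baseline_window` seconds
#' before the triggering addition at `event_time`; the final pH is the
#' plateau of a single-exponential fit
#' `pH(t) = pH_inf + (pH_0 - pH_inf) * exp(-k (t - event))` over
#' \[event_time, end_time\]; delta_pH = initial - final. Initialisation:
#' plateau from the last decile of the fit window, amplitude from the first
#' post-event point, rate from a log-linearised early decay.
#'
#' @param ph data.frame with `time`, `pH` (from [ph_trace()]).
#' @param event_time time of the triggering addition (e.g. ATP), s; taken
#'   from trace metadata by the pipeline, not auto-detected.
#' @param baseline_window baseline length before the event, s. Default 60.
#' @param end_time end of the fit window, s. Default: last sample.
#' @return list of class `KineticsResult`: `initial_pH`, `final_pH`,
#'   `delta_pH`, `exp_rate_constant` (1/s), standard errors `se_delta_pH`,
#'   `se_k`, the fit covariance matrix and a `flag` (`"ok"`,
#'   `"flat"` when the amplitude is indistinguishable from zero and k is
#'   unidentifiable, or `"negative_rate"`).
#' @export
extract_delta_ph <- function(ph, event_time, baseline_window = 60,
                             end_time = max(ph$time)) {
  t <- ph$time
  y <- ph$pH
  base <- t >= event_time - baseline_window & t < event_time
  if (!any(base)) stop("no samples in the baseline window")
  fitw <- t >= event_time & t <= end_time
  if (sum(fitw) < 10L) stop("need at least 10 post-event samples")
  initial_pH <- mean(y[base])
  se_initial <- sd(y[base]) / sqrt(sum(base))
  tf <- t[fitw] - event_time
  yf <- y[fitw]
  ## initialisation
  n10 <- max(3L, ceiling(length(yf) / 10))
  p_inf0 <- mean(tail(yf, n10))
  p00 <- yf[1]
  amp0 <- p00 - p_inf0
  noise <- sd(tail(yf, n10))
  ## flatness check on averaged early/late levels, not single noisy points
  nhead <- min(10L, length(yf))
  amp_est <- mean(head(yf, nhead)) - p_inf0
  if (abs(amp_est) <= 3 * noise * sqrt(1 / nhead + 1 / n10) + 1e-12) {
    ## flat trace: no resolvable amplitude, k unidentifiable
    return(structure(list(
      initial_pH = initial_pH, final_pH = mean(yf),
      delta_pH = initial_pH - mean(yf), exp_rate_constant = NA_real_,
      se_delta_pH = sqrt(se_initial^2 + (sd(yf) / sqrt(length(yf)))^2),
      se_k = NA_real_, covariance = NULL, flag = "flat"),
      class = "KineticsResult"))
  }
  early <- which(tf <= max(tf) / 3 &
                   (yf - p_inf0) / amp0 > 0.05)
  k0 <- if (length(early) >= 3L) {
    z <- log(pmax((yf[early] - p_inf0) / amp0, 1e-8))
    -unname(coef(lm(z ~ tf[early]))[2])
  } else 1 / max(tf)
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / max(tf)
  fit <- tryCatch(
    minpack.lm::nlsLM(yf ~ p_inf + (p0 - p_inf) * exp(-k * tf),
                      start = list(p_inf = p_inf0, p0 = p00, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("exponential fit did not converge (starts: p_inf=",
           signif(p_inf0, 4), ", p0=", signif(p00, 4), ", k=",
           signif(k0, 4), "): ", conditionMessage(e)))
  cf <- coef(fit)
  vc <- vcov(fit)
  final_pH <- unname(cf["p_inf"])
  k <- unname(cf["k"])
  flag <- if (k < 0) "negative_rate" else "ok"
  structure(list(
    initial_pH = initial_pH, final_pH = final_pH,
    delta_pH = initial_pH - final_pH, exp_rate_constant = k,
    se_delta_pH = sqrt(se_initial^2 + vc["p_inf", "p_inf"]),
    se_k = sqrt(vc["k", "k"]), covariance = vc, flag = flag),
    class = "KineticsResult")
}

## Oxonol VI ----------------------------------------------------------------

#' Nernst potential from a potassium gradient
#'
#' Valinomycin-mediated K+ diffusion potential:
#' `delta_psi = (R T / F) ln(K_out / K_in)`, in mV.
#'
#' @param K_out,K_in potassium concentrations (same units), > 0.
#' @param temperature K. Default 310.
#' @return potential, mV.
#' @export
nernst_potential <- function(K_out, K_in, temperature = 310) {
  if (any(K_out <= 0) || any(K_in <= 0)) stop("concentrations must be > 0")
  ## log difference, not log of the ratio: exactly antisymmetric under
  ## swapping K_out and K_in
  1000 * (.const$R_gas * temperature / .const$faraday) *
    (log(K_out) - log(K_in))
}

#' Fit the oxonol VI membrane-potential calibration
#'
#' Known potentials are set by potassium gradients across the liposome
#' membrane in the presence of valinomycin ([nernst_potential()]); the
#' calibration is a linear fit `delta_psi = slope * dA + intercept` of those
#' potentials against the 588-625 nm differential absorbance.
#'
#' @param dA differential absorbance values (A588 - A625).
#' @param K_out,K_in potassium concentrations per point, mM.
#' @param temperature K. Default 310.
#' @return list of class `PsiCalibration`: `slope` (mV per absorbance
#'   unit), `intercept` (mV), `fit_residual` (RMS mV).
#' @export
fit_psi_calibration <- function(dA, K_out, K_in, temperature = 310) {
  if (length(dA) < 2L) stop("need at least 2 calibration points")
  psi <- nernst_potential(K_out, K_in, temperature)
  if (length(unique(round(psi, 9))) < 2L)
    stop("calibration is rank deficient: all potentials equal")
  fit <- lm(psi ~ dA)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 fit_residual = sqrt(mean(fit$residuals^2))),
            class = "PsiCalibration")
}

#' Fixed oxonol VI calibration
#'
#' @param slope mV per absorbance unit, nonzero and finite.
#' @param intercept mV.
#' @return `PsiCalibration`.
#' @export
psi_calibration <- function(slope, intercept = 0) {
  if (!is.finite(slope) || slope == 0)
    stop("calibration slope must be finite and nonzero")
  structure(list(slope = slope, intercept = intercept, fit_residual = 0),
            class = "PsiCalibration")
}

#' Convert an oxonol VI trace to a membrane-potential series
#'
#' `delta_psi(t) = slope * (A588(t) - A625(t)) + intercept`.
#'
#' @param trace `AssayTrace` with channels `A588` and `A625`.
#' @param calib a `PsiCalibration`.
#' @return data.frame with `time` (s) and `psi` (mV).
#' @export
psi_trace <- function(trace, calib) {
  ch <- trace$channels
  if (!all(c("A588", "A625") %in% names(ch)))
    stop("trace must carry channels A588 and A625")
  data.frame(time = trace$time,
             psi = calib$slope * (ch$A588 - ch$A625) + calib$intercept)
}

#' Initial rate of membrane-potential formation
#'
#' Least-squares slope of psi(t) over the first `window` seconds of the
#' reaction (stopped-flow convention: a linear fit over the first second).
#'
#' @param psi data.frame with `time`, `psi` (from [psi_trace()]).
#' @param start reaction start time, s. Default 0.
#' @param window fit window length, s. Default 1.
#' @return list: `rate` (mV/s), `se` (mV/s), `n` points used.
#' @export
initial_rate <- function(psi, start = 0, window = 1) {
  w <- psi$time >= start & psi$time <= start + window
  if (sum(w) < 5L) stop("need at least 5 points in the rate window")
  fit <- .ls_slope(psi$time[w], psi$psi[w])
  list(rate = fit$slope, se = fit$se, n = sum(w))
}

#' Per-liposome proton flux from a membrane-potential slope
#'
#' Charging a vesicle of diameter d (membrane area pi d^2) and specific
#' capacitance C_m at a rate dPsi/dt moves charge
#' `I = C_m * pi * d^2 * dPsi/dt`; dividing by the elementary charge gives
#' the proton flux per liposome. Unit bookkeeping: C_m in uF/cm^2 is
#' 1e-6 F/cm^2; d in nm is 1e-7 cm; rate in mV/s is 1e-3 V/s.
#'
#' @param rate dPsi/dt, mV/s. Signed rates are allowed; a negative flux is
#'   flagged via `attr(, "negative")`.
#' @param lip a [liposome_spec()].
#' @param orientation_corrected divide by the fraction of transporters
#'   oriented N-side-in. Default FALSE (raw flux).
#' @return proton flux, H+/s per liposome.
#' @export
proton_flux <- function(rate, lip = liposome_spec(),
                        orientation_corrected = FALSE) {
  area_cm2 <- pi * (lip$diameter * 1e-7)^2
  cap_F <- lip$specific_capacitance * 1e-6 * area_cm2
  flux <- cap_F * (rate * 1e-3) / .const$e_charge
  if (orientation_corrected)
    flux <- flux / lip$orientation_fraction_n_inside
  if (any(flux < 0)) attr(flux, "negative") <- TRUE
  flux
}
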
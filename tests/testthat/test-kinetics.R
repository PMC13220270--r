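test_that("pyranine calibration recovers generating parameters", {
  ratios <- c(0.5, 1, 2, 4)
  cal <- fit_ph_calibration(ratios, 1.931 * log10(ratios) + 7.926)
  expect_equal(cal$a, 1.931, tolerance = 1e-12)
  expect_equal(cal$b, 7.926, tolerance = 1e-12)
  expect_equal(cal$fit_residual, 0, tolerance = 1e-12)
  ## rank deficiency and domain errors
  expect_error(fit_ph_calibration(c(2, 2), c(7, 8)), "rank deficient")
  expect_error(fit_ph_calibration(c(-1, 2), c(7, 8)), "> 0")
  expect_error(fit_ph_calibration(2, 7), "at least 2")
})

test_that("noisy calibration recovers the slope within Monte-Carlo bounds", {
  set.seed(101)
  ratios <- exp(runif(50, log(0.3), log(5)))
  pH <- 1.931 * log10(ratios) + 7.926 + rnorm(50, sd = 0.02)
  cal <- fit_ph_calibration(ratios, pH)
  expect_lt(abs(cal$a - 1.931), 0.05)
  expect_lt(abs(cal$b - 7.926), 0.05)
})

test_that("pH conversion follows the ratiometric model", {
  cal <- pyranine_calibration(1.931, 7.926)
  tr <- assay_trace(c(0, 1, 2), list(I405 = c(100, 100, 100),
                                     I460 = c(100, 1000, 50)))
  ph <- ph_trace(tr, cal)
  expect_equal(ph$pH[1], 7.926)             # ratio 1 -> pH = b
  expect_equal(ph$pH[2], 9.857)             # ratio 10 -> a + b
  bad <- assay_trace(c(0, 1), list(I405 = c(100, 0), I460 = c(90, 90)))
  expect_error(ph_trace(bad, cal), "t = 1")
})

test_that("delta-pH extraction recovers noiseless and noisy truths", {
  cal <- pyranine_calibration(1.931, 7.926)
  ## noiseless: exact recovery up to fit tolerance
  tr0 <- make_pyranine_trace(0.081, noise_sd = 0, seed = 1)
  r0 <- extract_delta_ph(ph_trace(tr0, cal), event_time = 60)
  expect_equal(r0$delta_pH, 0.081, tolerance = 1e-6)
  expect_equal(r0$exp_rate_constant, 0.01, tolerance = 1e-4)
  expect_equal(r0$flag, "ok")
  ## noisy: within stated tolerance of the generating value
  tr1 <- make_pyranine_trace(0.081, noise_sd = 0.002, seed = 42)
  r1 <- extract_delta_ph(ph_trace(tr1, cal), event_time = 60)
  expect_lt(abs(r1$delta_pH - 0.081), 0.005)
  ## flat trace: delta-pH ~ 0, rate unidentifiable, flagged
  trf <- make_pyranine_trace(0, noise_sd = 0.002, seed = 5)
  rf <- extract_delta_ph(ph_trace(trf, cal), event_time = 60)
  expect_equal(rf$flag, "flat")
  expect_lt(abs(rf$delta_pH), 0.002)
  expect_true(is.na(rf$exp_rate_constant))
})

test_that("delta-pH recovery holds across the assayed range", {
  ## generating values spanning the magnitudes seen across channel variants
  cal <- pyranine_calibration(1.931, 7.926)
  for (dpH in c(0.01, 0.05, 0.1)) {
    for (seed in 1:3) {
      tr <- make_pyranine_trace(dpH, noise_sd = 0.002, seed = 400 + seed)
      r <- extract_delta_ph(ph_trace(tr, cal), event_time = 60)
      expect_lt(abs(r$delta_pH - dpH), 3 * r$se_delta_pH + 1e-4)
    }
  }
})

test_that("Nernst potentials are correct and antisymmetric", {
  expect_equal(nernst_potential(10, 10, 310), 0)
  expect_equal(nernst_potential(10, 1, 310), 61.5, tolerance = 1e-3)
  expect_equal(nernst_potential(150, 15, 310),
               -nernst_potential(15, 150, 310))
  expect_error(nernst_potential(-1, 10), "> 0")
})

test_that("oxonol calibration fits potentials against absorbance", {
  ## noiseless line: slope/intercept recovered exactly
  dA <- c(0.00, 0.01, 0.02, 0.03)
  K_in <- rep(15, 4)
  ## choose K_out so that psi = 2000 * dA + 5
  psi <- 2000 * dA + 5
  K_out <- K_in * exp(psi / 1000 * 96485.33212 / (8.314462618 * 310))
  cal <- fit_psi_calibration(dA, K_out, K_in, temperature = 310)
  expect_equal(cal$slope, 2000, tolerance = 1e-6)
  expect_equal(cal$intercept, 5, tolerance = 1e-6)
  expect_error(fit_psi_calibration(dA, rep(15, 4), K_in), "rank deficient")
})

test_that("psi conversion and initial rates follow the linear model", {
  cal <- psi_calibration(2000, 0)
  tr <- assay_trace(c(0, 1), list(A588 = c(0.5, 0.51), A625 = c(0.5, 0.5)))
  psi <- psi_trace(tr, cal)
  expect_equal(psi$psi, c(0, 20))  # dA step of 0.01 at 2000 mV/AU
  ## exact line of slope 53.5 mV/s
  t <- seq(0, 2, by = 0.002)
  lin <- data.frame(time = t, psi = 53.5 * t)
  expect_equal(initial_rate(lin)$rate, 53.5, tolerance = 1e-9)
  expect_equal(initial_rate(data.frame(time = t, psi = rep(7, length(t))))$rate,
               0, tolerance = 1e-12)
  ## noisy line at 2 ms sampling: slope within 1 mV/s
  set.seed(9)
  noisy <- data.frame(time = t, psi = 30 * t + rnorm(length(t), sd = 1))
  expect_lt(abs(initial_rate(noisy)$rate - 30), 1)
  expect_error(initial_rate(lin[1:3, ]), "5 points")
})

test_that("oxonol rate recovery through the full trace pipeline", {
  cal <- psi_calibration(2000, 0)
  tr0 <- make_oxonol_trace(53.5, noise_sd = 0, seed = 1, calib = cal)
  expect_equal(initial_rate(psi_trace(tr0, cal))$rate, 53.5,
               tolerance = 1e-9)
  r <- initial_rate(psi_trace(make_oxonol_trace(26.7, noise_sd = 1,
                                                seed = 8, calib = cal),
                              cal))
  expect_lt(abs(r$rate - 26.7), 3 * r$se + 0.5)
})

test_that("proton flux follows the capacitance model", {
  lip <- liposome_spec(diameter = 100, specific_capacitance = 0.9)
  f <- as.numeric(proton_flux(120, lip))
  expect_gt(f, 210); expect_lt(f, 212)
  expect_equal(as.numeric(proton_flux(0, lip)), 0)
  ## linear in rate, linear in capacitance, quadratic in diameter
  expect_equal(as.numeric(proton_flux(240, lip)), 2 * f)
  lip2 <- liposome_spec(diameter = 200, specific_capacitance = 0.9)
  expect_equal(as.numeric(proton_flux(120, lip2)), 4 * f)
  lip3 <- liposome_spec(diameter = 100, specific_capacitance = 1.8)
  expect_equal(as.numeric(proton_flux(120, lip3)), 2 * f)
  ## orientation correction scales by the inside fraction
  expect_equal(as.numeric(proton_flux(120, lip,
                                      orientation_corrected = TRUE)),
               f / 0.75)
  expect_error(liposome_spec(diameter = -1), "> 0")
  expect_error(liposome_spec(specific_capacitance = 0), "> 0")
})
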
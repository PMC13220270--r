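test_that("profile reports round-trip to machine precision", {
  p <- channel_profile(coordinate = 0:4,
                       occupancy = c(0.1, 0.25, 1 / 3, 0.99, 0),
                       occupancy_sd = c(0, 0.01, 0.02, 0.03, 0),
                       field_vector = matrix(rnorm(15), 5, 3),
                       n_frames = 100L, replicas = 1:3)
  prefix <- file.path(tempdir(), "prof")
  files <- write_profile_report(p, prefix)
  lines <- readLines(files["csv"])
  expect_length(lines, 6L)  # header + 5 data rows
  got <- read_profile_report(prefix)[[1]]
  expect_identical(got$occupancy, p$occupancy)
  expect_identical(got$field_vector[, 1], p$field_vector[, 1])
  expect_identical(got$field_magnitude, p$field_magnitude)
  expect_error(write_profile_report(list(), prefix), "empty profile")
})

test_that("the channel pipeline recovers generated occupancy end to end", {
  cfg_path <- file.path(tempdir(), "cfg_channel.json")
  out_dir <- file.path(tempdir(), "chan_out")
  jsonlite::write_json(list(
    seed = 5, output_dir = out_dir,
    channel = list(fixture = list(length = 20, lumen_radius = 3,
                                  occupancy_targets = c(0.2, 0.9, 0.6),
                                  n_frames = 300, n_replicas = 3))),
    cfg_path, auto_unbox = TRUE)
  res <- run_channel_pipeline(cfg_path)
  expect_lt(abs(res$path$bottleneck_radius - 3), 0.8)
  ## aggregate occupancy near the generating targets (binomial error over
  ## 3 x 300 frames)
  tgt <- rep(c(0.2, 0.9, 0.6), length.out = length(res$aggregate$occupancy))
  expect_true(all(abs(res$aggregate$occupancy - tgt) < 0.1))
  expect_true(file.exists(file.path(out_dir, "profile_aggregate.csv")))
  ## determinism: identical config + seed -> byte-identical reports
  csv1 <- readLines(file.path(out_dir, "profile_aggregate.csv"))
  run_channel_pipeline(cfg_path)
  expect_identical(readLines(file.path(out_dir, "profile_aggregate.csv")),
                   csv1)
})

test_that("config validation catches missing inputs", {
  cfg_path <- file.path(tempdir(), "cfg_bad.json")
  jsonlite::write_json(list(
    seed = 1,
    channel = list(structure_path = "/nonexistent/str.pdb")),
    cfg_path, auto_unbox = TRUE)
  expect_error(read_run_config(cfg_path), "missing file")
})

test_that("the kinetics pipeline handles batches and corrupt traces", {
  out_dir <- file.path(tempdir(), "kin_out")
  dir.create(out_dir, showWarnings = FALSE)
  ## synthetic batch with fixed calibration
  cfg1 <- file.path(tempdir(), "cfg_kin1.json")
  jsonlite::write_json(list(
    seed = 2, output_dir = out_dir,
    kinetics = list(pyranine_a = 1.931, pyranine_b = 7.926,
                    psi_slope = 2000,
                    synthetic = list(delta_pH = c(0.046, 0.081, 0.09),
                                     rates = c(26.7, 53.5)))),
    cfg1, auto_unbox = TRUE)
  res <- run_kinetics_pipeline(cfg1)
  expect_equal(nrow(res$delta_ph), 3L)
  expect_true(all(abs(res$delta_ph$delta_pH - c(0.046, 0.081, 0.09)) <
                    0.005))
  expect_equal(nrow(res$rates), 2L)
  expect_true(all(abs(res$rates$rate_mV_s - c(26.7, 53.5)) < 1))
  expect_true(all(res$rates$proton_flux > 0))
  ## file batch with one corrupt member: skipped with a warning
  good <- file.path(tempdir(), "good.csv")
  write_trace(make_pyranine_trace(0.05, seed = 3), good)
  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("time,I405,I460", "0,100,90", "0,100,91"), bad)
  cfg2 <- file.path(tempdir(), "cfg_kin2.json")
  jsonlite::write_json(list(
    seed = 2, output_dir = out_dir,
    kinetics = list(pyranine_path = c(good, bad))),
    cfg2, auto_unbox = TRUE)
  expect_warning(res2 <- run_kinetics_pipeline(cfg2), "skipping")
  expect_equal(nrow(res2$delta_ph), 1L)
  expect_lt(abs(res2$delta_ph$delta_pH - 0.05), 0.005)
})

test_that("the assay pipeline normalizes against the reference construct", {
  out_dir <- file.path(tempdir(), "resp_out")
  dir.create(out_dir, showWarnings = FALSE)
  mk <- function(rate, f) {
    o2 <- file.path(tempdir(), paste0("o2_", f, ".csv"))
    write_trace(make_o2_trace(rate, noise_sd = 0.2, seed = 11), o2)
    fecn <- file.path(tempdir(), paste0("fecn_", f, ".csv"))
    t <- seq(0, 120, 1)
    write_trace(assay_trace(t, list(A410 = 1.2 - 0.004 * t)), fecn)
    c(o2 = o2, fecn = fecn)
  }
  wt <- mk(0.8, "wt"); mut <- mk(0.8 * 0.73, "mut")
  cfg <- file.path(tempdir(), "cfg_resp.json")
  jsonlite::write_json(list(
    seed = 1, output_dir = out_dir,
    assays = list(reference = "WT", constructs = list(
      list(name = "WT", o2_path = wt[["o2"]], fecn_path = wt[["fecn"]],
           protein = 1.5),
      list(name = "L226A", o2_path = mut[["o2"]],
           fecn_path = mut[["fecn"]], protein = 1.5)))),
    cfg, auto_unbox = TRUE)
  res <- run_assay_pipeline(cfg)
  expect_equal(res$normalized_pct[res$construct == "WT"], 100)
  expect_lt(abs(res$normalized_pct[res$construct == "L226A"] - 73), 3)
  ## missing FeCN file names the construct
  cfg_bad <- file.path(tempdir(), "cfg_resp_bad.json")
  jsonlite::write_json(list(
    seed = 1, output_dir = out_dir,
    assays = list(reference = "WT", constructs = list(
      list(name = "WT", o2_path = wt[["o2"]], protein = 1.5)))),
    cfg_bad, auto_unbox = TRUE)
  expect_error(run_assay_pipeline(cfg_bad), "WT.*FeCN")
})
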
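## End-to-end pipelines -----------------------------------------------------

#' Read and validate a run configuration
#'
#' A single JSON file drives the pipelines. Recognised blocks: `channel`
#' (structure/trajectory inputs or a `fixture` spec, search parameters,
#' capture/exclusion radii), `kinetics` (pyranine/oxonol trace paths or a
#' synthetic batch spec, calibration constants or calibration-data paths,
#' liposome spec), `assays` (per-construct trace paths, protein
#' concentrations, reference construct), plus `output_dir` and `seed`. All
#' referenced files must exist at validation time.
#'
#' @param path JSON config file.
#' @return list of class `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  ## every entry named *_path or *file must exist
  check_paths <- function(x) {
    if (is.list(x)) {
      for (k in names(x)) {
        if (grepl("(path|file)$", k) && is.character(x[[k]])) {
          for (p in x[[k]])
            if (!file.exists(p))
              stop("config references a missing file: ", p)
        } else check_paths(x[[k]])
      }
    }
  }
  check_paths(cfg)
  structure(cfg, class = c("RunConfig", "list"))
}

.provenance <- function(config, seed) {
  list(seed = seed,
       config = unclass(config),
       package_version = as.character(utils::packageVersion("protonpath")))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the structure-to-profiles pipeline
#'
#' Builds (or loads) a channel-bearing structure, detects the channel,
#' profiles water occupancy and electric field per replica trajectory, and
#' aggregates replicas. One report is written per replica plus the
#' aggregate, with the resolved config and seed embedded in a provenance
#' JSON.
#'
#' For a synthetic run the `channel.fixture` block gives
#' `length`, `lumen_radius`, `geometry`, `occupancy_targets`, `n_frames`
#' and `n_replicas`; replica trajectories are generated with seeds
#' `seed + replica`.
#'
#' @param config a `RunConfig` (or path to one).
#' @return list: `path` (TunnelPath), per-replica profiles, `aggregate`,
#'   and output file paths.
#' @export
run_channel_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cc <- config$channel
  if (is.null(cc)) stop("config has no 'channel' block")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  if (!is.null(cc$fixture)) {
    fx <- .stage("synthesize", do.call(make_channel_structure, c(
      list(), cc$fixture[intersect(names(cc$fixture),
                                   c("length", "lumen_radius", "geometry",
                                     "lining"))])))
    struct <- fx$structure
    spec <- search_spec(start = fx$seed_selector,
                        probe_radius = cc$probe_radius %||% 0.9,
                        bulk = fx$bulk)
  } else {
    struct <- .stage("read_structure",
                     read_structure(cc$structure_path, cc$charge_table_path))
    spec <- search_spec(start = cc$start,
                        probe_radius = cc$probe_radius %||% 0.9,
                        excluded_residues = cc$excluded_residues %||%
                          character())
  }
  grid <- .stage("build_grid",
                 build_grid(struct, spec, spacing = cc$spacing %||% 0.8))
  path <- .stage("find_channel", find_channel(grid, spec))
  capture <- cc$capture_radius %||% 2
  excl <- cc$exclusion_radius %||% 2
  ## synthetic water slots must sit farther apart than the capture radius
  ## so per-point occupancy targets are recovered exactly in expectation
  step <- cc$step %||% (if (!is.null(cc$fixture)) 5 else 1)
  profiles <- list()
  if (!is.null(cc$fixture)) {
    nrep <- cc$fixture$n_replicas %||% 3
    nfr <- cc$fixture$n_frames %||% 200
    targets <- cc$fixture$occupancy_targets %||% 0.5
    for (r in seq_len(nrep)) {
      wt <- .stage("synthesize_trajectory",
                   make_water_trajectory(list(structure = struct,
                                              path = path),
                                         targets, nfr,
                                         seed = seed + r, step = step))
      occ <- .stage("water_occupancy",
                    water_occupancy(wt$trajectory, wt$structure, path,
                                    capture_radius = capture, step = step))
      occ$replicas <- r
      profiles[[r]] <- occ
    }
  } else {
    for (r in seq_along(cc$trajectory_path)) {
      traj <- .stage("read_trajectory",
                     read_trajectory(cc$trajectory_path[r], struct,
                                     replica_id = r))
      occ <- .stage("water_occupancy",
                    water_occupancy(traj, struct, path,
                                    capture_radius = capture, step = step))
      fld <- .stage("electric_field",
                    electric_field(traj, struct, path,
                                   exclusion_radius = excl, step = step))
      occ$field_vector <- fld$field_vector
      occ$field_magnitude <- fld$field_magnitude
      profiles[[r]] <- occ
    }
  }
  agg <- .stage("aggregate_replicas",
                aggregate_replicas(profiles,
                                   normalize = isTRUE(cc$normalize)))
  outs <- character(0)
  for (r in seq_along(profiles))
    outs <- c(outs, write_profile_report(
      profiles[[r]], file.path(config$output_dir,
                               sprintf("profile_replica%d", r))))
  outs <- c(outs, write_profile_report(
    agg, file.path(config$output_dir, "profile_aggregate")))
  prov_path <- file.path(config$output_dir, "channel_provenance.json")
  jsonlite::write_json(c(.provenance(config, seed),
                         list(bottleneck_radius = path$bottleneck_radius,
                              arc_length = max(path$arclength))),
                       prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(path = path, profiles = profiles, aggregate = agg,
       files = c(outs, prov_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the traces-to-kinetics pipeline
#'
#' Converts a batch of pyranine traces to delta-pH values (baseline +
#' single-exponential fit) and a batch of oxonol VI traces to initial
#' rates and per-liposome proton fluxes. Calibrations are either fixed
#' constants from the config (`kinetics.pyranine_a/b`,
#' `kinetics.psi_slope/intercept`) or fitted from calibration-pair CSVs.
#' Corrupt traces are skipped with a warning; the rest are processed.
#'
#' With `kinetics.synthetic`, traces are generated instead:
#' `delta_pH` (vector) and `rates` (vector) give the generating values,
#' one trace per entry, seeded from the config seed.
#'
#' @param config a `RunConfig` (or path to one).
#' @return list with data.frames `delta_ph` and `rates` plus output paths.
#' @export
run_kinetics_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  kc <- config$kinetics
  if (is.null(kc)) stop("config has no 'kinetics' block")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  ph_cal <- if (!is.null(kc$pyranine_a))
    pyranine_calibration(kc$pyranine_a, kc$pyranine_b)
  else if (!is.null(kc$ph_calibration_path)) {
    tab <- read.csv(kc$ph_calibration_path)
    fit_ph_calibration(tab$ratio, tab$pH)
  } else pyranine_calibration(1.931, 7.926)
  psi_cal <- if (!is.null(kc$psi_slope))
    psi_calibration(kc$psi_slope, kc$psi_intercept %||% 0)
  else if (!is.null(kc$psi_calibration_path)) {
    tab <- read.csv(kc$psi_calibration_path)
    fit_psi_calibration(tab$dA, tab$K_out, tab$K_in)
  } else psi_calibration(2000, 0)
  lip <- do.call(liposome_spec, kc$liposome %||% list())
  ## pyranine traces
  traces <- list()
  if (!is.null(kc$synthetic$delta_pH)) {
    for (i in seq_along(kc$synthetic$delta_pH))
      traces[[sprintf("synthetic_dpH_%d", i)]] <-
        make_pyranine_trace(kc$synthetic$delta_pH[i], calib = ph_cal,
                            seed = seed + i)
  } else if (!is.null(kc$pyranine_path)) {
    for (p in kc$pyranine_path)
      traces[[basename(p)]] <- tryCatch(
        read_trace(p, c("I405", "I460")),
        error = function(e) {
          warning("skipping corrupt trace ", p, ": ",
                  conditionMessage(e))
          NULL
        })
    traces <- Filter(Negate(is.null), traces)
  }
  dp_rows <- lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    ev <- tr$metadata$event_time %||% 60
    res <- tryCatch(
      extract_delta_ph(ph_trace(tr, ph_cal), event_time = ev),
      error = function(e) {
        warning("skipping trace ", nm, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) return(NULL)
    data.frame(trace = nm, delta_pH = res$delta_pH,
               se_delta_pH = res$se_delta_pH,
               initial_pH = res$initial_pH, final_pH = res$final_pH,
               k = res$exp_rate_constant, flag = res$flag,
               stringsAsFactors = FALSE)
  })
  delta_ph <- do.call(rbind, dp_rows)
  ## oxonol traces
  otraces <- list()
  if (!is.null(kc$synthetic$rates)) {
    for (i in seq_along(kc$synthetic$rates))
      otraces[[sprintf("synthetic_rate_%d", i)]] <-
        make_oxonol_trace(kc$synthetic$rates[i], calib = psi_cal,
                          seed = seed + 1000L + i)
  } else if (!is.null(kc$oxonol_path)) {
    for (p in kc$oxonol_path)
      otraces[[basename(p)]] <- tryCatch(
        read_trace(p, c("A588", "A625")),
        error = function(e) {
          warning("skipping corrupt trace ", p, ": ",
                  conditionMessage(e))
          NULL
        })
    otraces <- Filter(Negate(is.null), otraces)
  }
  rate_rows <- lapply(names(otraces), function(nm) {
    tr <- otraces[[nm]]
    r <- initial_rate(psi_trace(tr, psi_cal))
    data.frame(trace = nm, rate_mV_s = r$rate, se = r$se,
               proton_flux = as.numeric(proton_flux(r$rate, lip)),
               stringsAsFactors = FALSE)
  })
  rates <- do.call(rbind, rate_rows)
  paths <- character(0)
  if (!is.null(delta_ph)) {
    p <- file.path(config$output_dir, "delta_ph.csv")
    write.csv(delta_ph, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(rates)) {
    p <- file.path(config$output_dir, "initial_rates.csv")
    write.csv(rates, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  summ <- c(.provenance(config, seed), list(
    n_pyranine = length(traces), n_oxonol = length(otraces)))
  if (!is.null(delta_ph)) {
    summ$mean_delta_pH <- mean(delta_ph$delta_pH)
    summ$sd_delta_pH <- sd(delta_ph$delta_pH)
  }
  jp <- file.path(config$output_dir, "kinetics_summary.json")
  jsonlite::write_json(summ, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(delta_ph = delta_ph, rates = rates, files = c(paths, jp))
}

#' Run the respiration-assay pipeline
#'
#' For each construct block (`name`, `o2_path`, `fecn_path`, `protein`),
#' computes the oxygen-consumption and FeCN rates and normalizes against
#' the designated reference construct. Missing inputs raise an error naming
#' the construct.
#'
#' @param config a `RunConfig` (or path to one).
#' @return data.frame of per-construct normalized rates (also written to
#'   `normalized_respiration.csv`).
#' @export
run_assay_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  ac <- config$assays
  if (is.null(ac)) stop("config has no 'assays' block")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  constructs <- ac$constructs
  if (is.data.frame(constructs))
    constructs <- split(constructs, seq_len(nrow(constructs)))
  get_rates <- function(co) {
    if (is.null(co$o2_path) || !file.exists(co$o2_path %||% ""))
      stop("construct ", co$name, ": missing oxygraph trace file")
    if (is.null(co$fecn_path) || !file.exists(co$fecn_path %||% ""))
      stop("construct ", co$name, ": missing FeCN trace file")
    o2 <- read_trace(co$o2_path, "O2")
    fe <- read_trace(co$fecn_path, "A410")
    list(raw = -linear_rate(o2, "O2")$rate, fecn = fecn_activity(fe)$rate,
         protein = co$protein)
  }
  names(constructs) <- vapply(constructs, function(co) co$name,
                              character(1))
  ref_name <- ac$reference
  if (is.null(ref_name) || !ref_name %in% names(constructs))
    stop("reference construct not found among constructs")
  rates <- lapply(constructs, get_rates)
  ref <- rates[[ref_name]]
  rows <- lapply(names(rates), function(nm) {
    r <- rates[[nm]]
    nr <- normalize_respiration(r$raw, r$protein, r$fecn,
                                ref$raw, ref$protein, ref$fecn)
    data.frame(construct = nm, raw_rate = r$raw, protein = r$protein,
               fecn_rate = r$fecn, normalized_pct = nr$normalized,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p <- file.path(config$output_dir, "normalized_respiration.csv")
  write.csv(out, p, row.names = FALSE)
  out
}
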
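## Profile reports ----------------------------------------------------------

#' Write channel profiles to a report
#'
#' Emits `<prefix>.csv` — one row per coordinate with the mean and SD of
#' each quantity present — and `<prefix>.json` with the scalar summary
#' (frame counts, replicas, extrema). Multiple profiles must share a
#' coordinate grid; they are aggregated columnwise (`occupancy.1`,
#' `occupancy.2`, ...). Numbers are written with 17 significant digits so
#' [read_profile_report()] round-trips to machine precision.
#'
#' @param profiles a `ChannelProfile` or list of them (shared grid).
#' @param prefix output path prefix (without extension).
#' @return invisibly, the two file paths.
#' @export
write_profile_report <- function(profiles, prefix) {
  if (inherits(profiles, "ChannelProfile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("empty profile")
  R <- profiles[[1]]$coordinate
  if (length(R) == 0L) stop("empty profile")
  df <- data.frame(coordinate = R)
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (length(p$coordinate) != length(R) ||
        any(abs(p$coordinate - R) > 1e-9))
      stop("profiles share no common coordinate grid; resample first")
    sfx <- if (length(profiles) > 1L) paste0(".", i) else ""
    if (!is.null(p$occupancy))
      df[[paste0("occupancy", sfx)]] <- p$occupancy
    if (!is.null(p$occupancy_sd))
      df[[paste0("occupancy_sd", sfx)]] <- p$occupancy_sd
    if (!is.null(p$field_magnitude))
      df[[paste0("field_magnitude", sfx)]] <- p$field_magnitude
    if (!is.null(p$field_vector)) {
      df[[paste0("field_x", sfx)]] <- p$field_vector[, 1]
      df[[paste0("field_y", sfx)]] <- p$field_vector[, 2]
      df[[paste0("field_z", sfx)]] <- p$field_vector[, 3]
    }
  }
  csv_path <- paste0(prefix, ".csv")
  con <- file(csv_path, "w")
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, function(col)
    sprintf("%.17g", col)), sep = ",")), con)
  close(con)
  summ <- list(
    n_profiles = length(profiles),
    n_points = length(R),
    coordinate_range = range(R),
    n_frames = vapply(profiles, function(p) p$n_frames, integer(1)),
    replicas = lapply(profiles, function(p) p$replicas))
  if (!is.null(profiles[[1]]$occupancy))
    summ$max_occupancy <- vapply(profiles,
                                 function(p) max(p$occupancy), numeric(1))
  if (!is.null(profiles[[1]]$field_magnitude))
    summ$max_field_magnitude <- vapply(
      profiles, function(p) max(p$field_magnitude), numeric(1))
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a profile report written by [write_profile_report()]
#'
#' @param prefix the path prefix used when writing.
#' @return list of `ChannelProfile`s (length 1 for a single profile).
#' @export
read_profile_report <- function(prefix) {
  csv_path <- paste0(prefix, ".csv")
  json_path <- paste0(prefix, ".json")
  if (!file.exists(csv_path)) stop("no such report: ", csv_path)
  df <- read.csv(csv_path)
  summ <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  n <- summ$n_profiles
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sfx <- if (n > 1L) paste0(".", i) else ""
    pick <- function(what) {
      col <- paste0(what, sfx)
      if (col %in% names(df)) df[[col]] else NULL
    }
    fx <- pick("field_x")
    fvec <- if (!is.null(fx))
      cbind(fx, pick("field_y"), pick("field_z")) else NULL
    out[[i]] <- channel_profile(
      coordinate = df$coordinate, occupancy = pick("occupancy"),
      occupancy_sd = pick("occupancy_sd"), field_vector = fvec,
      field_magnitude = pick("field_magnitude"),
      n_frames = summ$n_frames[i],
      replicas = if (is.list(summ$replicas)) summ$replicas[[i]]
      else summ$replicas[i])
  }
  out
}
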
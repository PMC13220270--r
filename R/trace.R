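## Assay traces -------------------------------------------------------------

#' Construct an AssayTrace
#'
#' Timestamped spectroscopy series: pyranine fluorescence (`I405`, `I460`),
#' oxonol VI absorbance (`A588`, `A625`), oxygraph oxygen concentration
#' (`O2`), FeCN absorbance (`A410`) or an emission spectrum. Time must be
#' strictly increasing and every channel the same length as time.
#'
#' @param time numeric vector, seconds (or nm for spectra).
#' @param channels named list or data.frame of numeric series.
#' @param sample_interval nominal sampling interval, seconds (pyranine
#'   instruments resolve 0.6 s; stopped-flow 2 ms).
#' @param metadata named list of free-form labels (construct name, addition
#'   events with timestamps, generating parameters of synthetic traces).
#' @return Object of class `AssayTrace`.
#' @export
assay_trace <- function(time, channels, sample_interval = NULL,
                        metadata = list()) {
  time <- as.numeric(time)
  if (length(time) == 0L) stop("empty trace")
  if (any(diff(time) <= 0))
    stop("time axis must be strictly increasing")
  channels <- as.data.frame(channels)
  if (nrow(channels) != length(time))
    stop("all channels must have the same length as time")
  if (is.null(sample_interval))
    sample_interval <- if (length(time) > 1) median(diff(time)) else NA_real_
  structure(list(time = time, channels = channels,
                 sample_interval = sample_interval, metadata = metadata),
            class = "AssayTrace")
}

#' @export
print.AssayTrace <- function(x, ...) {
  cat(sprintf("AssayTrace: %d samples, dt = %g s, channels: %s\n",
              length(x$time), x$sample_interval,
              paste(names(x$channels), collapse = ", ")))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Read a delimited assay trace
#'
#' Expects a CSV whose header contains `time` plus the channels named in
#' `schema`. Lines starting with `#` are treated as metadata annotations:
#' `# key=value` pairs are parsed into named metadata; other comment lines
#' are collected under `notes`.
#'
#' @param path CSV file.
#' @param schema character vector of required channel names.
#' @return An [assay_trace()].
#' @export
read_trace <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  cm <- grepl("^\\s*#", raw)
  meta <- list()
  notes <- character()
  for (line in sub("^\\s*#\\s*", "", raw[cm])) {
    if (grepl("^[A-Za-z0-9_.-]+=", line)) {
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(kv[1])]] <- if (is.na(num)) val else num
    } else notes <- c(notes, line)
  }
  if (length(notes)) meta$notes <- notes
  df <- read.csv(textConnection(raw[!cm]), stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stop("trace file lacks a 'time' column")
  missing_ch <- setdiff(schema, names(df))
  if (length(missing_ch) > 0L)
    stop("trace file lacks channel(s): ", paste(missing_ch, collapse = ", "))
  if (any(diff(df$time) <= 0))
    stop("time axis must be strictly increasing (duplicate or decreasing ",
         "timestamp in ", path, ")")
  assay_trace(df$time, df[, schema, drop = FALSE], metadata = meta)
}

#' Write an assay trace to CSV
#'
#' Metadata is emitted as `# key=value` comment lines before the header so
#' [read_trace()] round-trips it. Numeric values are written with 17
#' significant digits so the round trip is exact to machine precision.
#'
#' @param trace an `AssayTrace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(trace$metadata)) {
    v <- trace$metadata[[k]]
    if (k == "notes") {
      for (n in v) writeLines(paste("#", n), con)
    } else {
      if (is.numeric(v)) v <- sprintf("%.17g", v)
      writeLines(sprintf("# %s=%s", k, v), con)
    }
  }
  df <- cbind(time = trace$time, trace$channels)
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)),
    sep = ","))
  writeLines(body, con)
  invisible(path)
}
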
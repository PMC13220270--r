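## Membrane respiration assays ----------------------------------------------

## closed-form least-squares slope and its SE (avoids summary.lm noise on
## zero-residual fits)
.ls_slope <- function(t, y) {
  n <- length(t)
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- sum(tc * y) / sxx
  res <- y - mean(y) - slope * tc
  se <- if (n > 2) sqrt(sum(res^2) / (n - 2) / sxx) else NA_real_
  list(slope = slope, se = se)
}

#' Linear rate of an assay trace
#'
#' Least-squares slope of a channel against time. With
#' `range_selection = "auto"` the fit window is the longest contiguous run
#' of samples whose running local slope (over `local_window` points) stays
#' within `tolerance` of the median local slope — the operational definition
#' of the "linear range" of an oxygraph or FeCN trace. An explicit window
#' `c(t0, t1)` bypasses the detection.
#'
#' @param trace an `AssayTrace`.
#' @param channel channel name to fit. Default: the first channel.
#' @param range_selection `"auto"` or a numeric window `c(t0, t1)`, s.
#' @param tolerance relative deviation of the local slope from its median
#'   tolerated inside the linear range. Default 0.1.
#' @param local_window points per running local-slope estimate. Default 10.
#' @return list: `rate` (channel units/s), `se`, `window` (t0, t1), `n`.
#' @export
linear_rate <- function(trace, channel = names(trace$channels)[1],
                        range_selection = "auto", tolerance = 0.1,
                        local_window = 10L) {
  if (!channel %in% names(trace$channels))
    stop("no channel '", channel, "' in trace")
  t <- trace$time
  y <- trace$channels[[channel]]
  if (is.numeric(range_selection)) {
    keep <- t >= range_selection[1] & t <= range_selection[2]
    if (sum(keep) < 5L) stop("fewer than 5 points in the explicit window")
  } else {
    n <- length(t)
    if (n < local_window + 4L)
      stop("trace too short for automatic linear-range detection; ",
           "supply an explicit window")
    nw <- n - local_window + 1L
    loc <- vapply(seq_len(nw), function(i) {
      ii <- i:(i + local_window - 1L)
      .ls_slope(t[ii], y[ii])$slope
    }, numeric(1))
    med <- median(loc)
    scale_ref <- max(abs(med), 1e-12)
    ok <- abs(loc - med) <= tolerance * scale_ref
    ## longest contiguous TRUE run
    r <- rle(ok)
    if (!any(r$values))
      stop("no window of >= 5 points satisfies the linearity tolerance; ",
           "supply an explicit window")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    i0 <- starts[best]
    i1 <- ends[best] + local_window - 1L
    keep <- seq(i0, min(i1, n))
    if (length(keep) < 5L)
      stop("no window of >= 5 points satisfies the linearity tolerance; ",
           "supply an explicit window")
    keep <- seq_len(n) %in% keep
  }
  fit <- .ls_slope(t[keep], y[keep])
  list(rate = fit$slope, se = fit$se,
       window = range(t[keep]), n = sum(keep))
}

#' FeCN (NADH dehydrogenase) activity
#'
#' Rate of ferricyanide absorbance decay at 410 nm, by linear fit — the
#' same contract as [linear_rate()] on the `A410` channel. Returned as a
#' positive decay rate.
#'
#' @inheritParams linear_rate
#' @return list as [linear_rate()], with `rate` the positive decay rate
#'   (A410 units/s).
#' @export
fecn_activity <- function(trace, range_selection = "auto",
                          tolerance = 0.1, local_window = 10L) {
  r <- linear_rate(trace, channel = "A410",
                   range_selection = range_selection,
                   tolerance = tolerance, local_window = local_window)
  r$rate <- -r$rate
  r
}

#' Normalize a respiration rate against a reference construct
#'
#' The specific activity of a construct is its raw oxygen-consumption rate
#' divided by total protein concentration and by its FeCN (NADH
#' dehydrogenase) rate; the normalized value is that specific activity as a
#' percentage of the reference construct's. SDs of replicate means are
#' propagated to the percentage by first-order error propagation (relative
#' variances add).
#'
#' @param raw_rate,protein,fecn_rate construct raw O2 rate (signal/s,
#'   positive for consumption), protein concentration (mg/mL) and FeCN rate.
#' @param ref_raw_rate,ref_protein,ref_fecn_rate the same for the reference
#'   construct.
#' @param sds optional named list of SDs (`raw_rate`, `protein`,
#'   `fecn_rate`, `ref_raw_rate`, `ref_protein`, `ref_fecn_rate`); missing
#'   entries are treated as 0.
#' @return list of class `NormalizedRate`: `normalized` (%), `sd` (%),
#'   `specific_activity`, `ref_specific_activity`.
#' @export
normalize_respiration <- function(raw_rate, protein, fecn_rate,
                                  ref_raw_rate, ref_protein, ref_fecn_rate,
                                  sds = list()) {
  vals <- c(raw_rate = raw_rate, protein = protein, fecn_rate = fecn_rate,
            ref_raw_rate = ref_raw_rate, ref_protein = ref_protein,
            ref_fecn_rate = ref_fecn_rate)
  if (any(vals[c("protein", "ref_protein")] <= 0))
    stop("protein concentrations must be > 0")
  if (any(vals[c("fecn_rate", "ref_fecn_rate")] == 0))
    stop("FeCN rates must be nonzero")
  spec <- raw_rate / protein / fecn_rate
  ref_spec <- ref_raw_rate / ref_protein / ref_fecn_rate
  ## ratio first: the reference construct is exactly 100 by definition
  pct <- 100 * (spec / ref_spec)
  relvar <- 0
  for (k in names(vals)) {
    s <- sds[[k]]
    if (!is.null(s)) relvar <- relvar + (s / vals[[k]])^2
  }
  structure(list(normalized = pct, sd = abs(pct) * sqrt(relvar),
                 specific_activity = spec,
                 ref_specific_activity = ref_spec),
            class = "NormalizedRate")
}

#' sfGFP expression level from an emission spectrum
#'
#' Peak emission at 510 nm, corrected by the total protein concentration.
#' `mode = "nearest"` reads the sample closest to 510 nm;
#' `mode = "quadratic"` refines the peak by a local quadratic (three-point
#' parabola) around the spectrum maximum near 510 nm.
#'
#' @param spectrum `AssayTrace` whose time axis is wavelength (nm) and
#'   whose first channel is emission intensity; must cover 500-600 nm.
#' @param protein total protein concentration, mg/mL, > 0.
#' @param mode `"nearest"` or `"quadratic"`.
#' @return normalized fluorescence (intensity per mg/mL protein).
#' @export
gfp_level <- function(spectrum, protein, mode = c("nearest", "quadratic")) {
  mode <- match.arg(mode)
  if (protein <= 0) stop("protein concentration must be > 0")
  wl <- spectrum$time
  em <- spectrum$channels[[1]]
  if (min(wl) > 510 || max(wl) < 510)
    stop("spectrum does not cover 510 nm")
  if (mode == "nearest") {
    val <- em[which.min(abs(wl - 510))]
  } else {
    ## local quadratic around the maximum within 505-515 nm
    nearw <- which(wl >= 505 & wl <= 515)
    if (length(nearw) < 3L) stop("too few samples near 510 nm for ",
                                 "quadratic peak interpolation")
    i <- nearw[which.max(em[nearw])]
    i <- min(max(i, 2L), length(wl) - 1L)
    x <- wl[(i - 1):(i + 1)]
    yv <- em[(i - 1):(i + 1)]
    cf <- coef(lm(yv ~ x + I(x^2)))
    val <- if (cf[3] >= 0) yv[2] else
      unname(cf[1] - cf[2]^2 / (4 * cf[3]))
  }
  val / protein
}
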
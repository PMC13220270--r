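## Hydration profiling along the channel coordinate -------------------------

#' Construct a ChannelProfile
#'
#' Per-channel-coordinate quantities: water occupancy (fraction of frames
#' with a water at the coordinate), its across-replica SD, and the electric
#' field (vector and magnitude, V/Angstrom).
#'
#' @param coordinate channel coordinate grid R, Angstrom.
#' @param occupancy occupancy fraction per point, in \[0, 1\] (or NA for
#'   field-only profiles).
#' @param occupancy_sd per-point SD (population convention across replicas).
#' @param field_vector m x 3 matrix, V/Angstrom, or NULL.
#' @param field_magnitude per-point field magnitude, V/Angstrom.
#' @param n_frames number of frames analysed.
#' @param replicas contributing replica ids.
#' @return Object of class `ChannelProfile`.
#' @export
channel_profile <- function(coordinate, occupancy = NULL, occupancy_sd = NULL,
                            field_vector = NULL, field_magnitude = NULL,
                            n_frames = 0L, replicas = integer(0)) {
  m <- length(coordinate)
  if (m == 0L) stop("empty profile")
  if (!is.null(occupancy)) {
    if (length(occupancy) != m) stop("occupancy length mismatch")
    if (any(occupancy < -1e-12 | occupancy > 1 + 1e-12, na.rm = TRUE))
      stop("occupancy must lie in [0, 1]")
  }
  if (!is.null(occupancy_sd) && any(occupancy_sd < 0, na.rm = TRUE))
    stop("occupancy_sd must be >= 0")
  if (!is.null(field_vector)) {
    field_vector <- as.matrix(field_vector)
    if (nrow(field_vector) != m) stop("field_vector row mismatch")
    if (is.null(field_magnitude))
      field_magnitude <- sqrt(rowSums(field_vector^2))
  }
  structure(list(coordinate = coordinate, occupancy = occupancy,
                 occupancy_sd = occupancy_sd, field_vector = field_vector,
                 field_magnitude = field_magnitude,
                 n_frames = as.integer(n_frames),
                 replicas = as.integer(replicas)),
            class = "ChannelProfile")
}

#' @export
print.ChannelProfile <- function(x, ...) {
  cat(sprintf("ChannelProfile: %d points, R in [%.1f, %.1f] A, %d frames, replicas: %s\n",
              length(x$coordinate), min(x$coordinate), max(x$coordinate),
              x$n_frames,
              if (length(x$replicas)) paste(x$replicas, collapse = ",")
              else "-"))
  invisible(x)
}

#' Resample a tunnel path onto a regular channel-coordinate grid
#'
#' Linear interpolation of the centreline against arc length; the grid runs
#' from 0 to the total arc length in steps of `step`.
#'
#' @param path a `TunnelPath`.
#' @param step grid step along R, Angstrom. Default 1.
#' @return list with `R` (grid) and `points` (m x 3 interpolated centreline).
#' @export
resample_path <- function(path, step = 1) {
  if (step <= 0) stop("step must be > 0")
  R <- seq(0, max(path$arclength), by = step)
  pts <- cbind(approx(path$arclength, path$points[, 1], xout = R)$y,
               approx(path$arclength, path$points[, 2], xout = R)$y,
               approx(path$arclength, path$points[, 3], xout = R)$y)
  list(R = R, points = pts)
}

## indices of water oxygen atoms
.water_oxygens <- function(structure) {
  a <- structure$atoms
  el <- .element_from_name(a$name, a$resname, a$is_solvent)
  which(a$is_solvent & el == "O")
}

#' Water occupancy along a channel
#'
#' The occupancy at a channel coordinate is the ratio of frames with at
#' least one water molecule (identified by its oxygen) within
#' `capture_radius` of that coordinate to the total number of analysed
#' frames. Distances use the minimum-image convention when the structure
#' carries a periodic box. The trajectory must already be superposed onto
#' the frame in which the path was computed (see [superpose()]).
#'
#' @param traj a `Trajectory`.
#' @param structure the matching `StructureModel` (solvent flags).
#' @param path the `TunnelPath` defining the channel coordinate.
#' @param capture_radius capture radius around each coordinate, Angstrom.
#'   Default 2.
#' @param step channel-coordinate grid step, Angstrom. Default 1.
#' @return A [channel_profile()] with occupancy filled.
#' @export
water_occupancy <- function(traj, structure, path, capture_radius = 2,
                            step = 1) {
  if (n_frames(traj) == 0L) stop("trajectory has zero frames")
  widx <- .water_oxygens(structure)
  if (length(widx) == 0L) stop("no waters in system")
  rs <- resample_path(path, step)
  pts <- rs$points
  m <- nrow(pts)
  counts <- integer(m)
  r2 <- capture_radius^2
  box <- structure$box
  for (f in seq_len(n_frames(traj))) {
    w <- traj$frames[[f]][widx, , drop = FALSE]
    for (k in seq_len(m)) {
      disp <- cbind(w[, 1] - pts[k, 1], w[, 2] - pts[k, 2],
                    w[, 3] - pts[k, 3])
      disp <- .min_image(disp, box)
      if (any(rowSums(disp^2) <= r2)) counts[k] <- counts[k] + 1L
    }
  }
  channel_profile(coordinate = rs$R, occupancy = counts / n_frames(traj),
                  n_frames = n_frames(traj), replicas = traj$replica_id)
}

#' Aggregate channel profiles across replicas
#'
#' Mean and SD (population convention: divisor n, not n - 1) across
#' replicas per coordinate, for occupancy and field magnitude. With
#' `normalize = TRUE` the mean occupancy is rescaled by its maximum so the
#' peak equals 1 (SD rescaled by the same factor); normalisation against a
#' bulk-water expectation is not applied.
#'
#' @param profiles list of `ChannelProfile`s on identical coordinate grids.
#' @param normalize rescale occupancy so its maximum is 1. Default FALSE.
#' @return A [channel_profile()] with `occupancy_sd` filled.
#' @export
aggregate_replicas <- function(profiles, normalize = FALSE) {
  if (inherits(profiles, "ChannelProfile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("no profiles to aggregate")
  R <- profiles[[1]]$coordinate
  for (p in profiles)
    if (length(p$coordinate) != length(R) ||
        any(abs(p$coordinate - R) > 1e-9))
      stop("profiles are on different coordinate grids; resample first")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  occ <- occ_sd <- fmag <- NULL
  fvec <- NULL
  if (!is.null(profiles[[1]]$occupancy)) {
    occ_mat <- vapply(profiles, function(p) p$occupancy,
                      numeric(length(R)))
    occ_mat <- matrix(occ_mat, nrow = length(R))
    occ <- rowMeans(occ_mat)
    occ_sd <- apply(occ_mat, 1, pop_sd)
    if (normalize) {
      mx <- max(occ)
      if (mx > 0) {
        occ <- occ / mx
        occ_sd <- occ_sd / mx
      }
    }
  }
  if (!is.null(profiles[[1]]$field_magnitude)) {
    f_mat <- vapply(profiles, function(p) p$field_magnitude,
                    numeric(length(R)))
    f_mat <- matrix(f_mat, nrow = length(R))
    fmag <- rowMeans(f_mat)
  }
  if (!is.null(profiles[[1]]$field_vector)) {
    fvec <- Reduce(`+`, lapply(profiles, function(p) p$field_vector)) /
      length(profiles)
  }
  channel_profile(coordinate = R, occupancy = occ, occupancy_sd = occ_sd,
                  field_vector = fvec, field_magnitude = fmag,
                  n_frames = sum(vapply(profiles, function(p) p$n_frames,
                                        integer(1))),
                  replicas = unlist(lapply(profiles,
                                           function(p) p$replicas)))
}

#' Superpose a trajectory onto its reference structure
#'
#' Least-squares rigid-body superposition (Kabsch) of every frame onto the
#' reference coordinates, fitting on the selected residues; the transform
#' is applied to all atoms. Required before profiling so that the fixed
#' channel coordinate axis is meaningful across frames.
#'
#' @param traj a `Trajectory`.
#' @param structure the reference `StructureModel`.
#' @param selection residue selectors ([resolve_residues()]) defining the
#'   fit atoms; must resolve to at least 3 atoms.
#' @return A `Trajectory` of superposed frames, with per-frame RMSD (over
#'   the fit selection, Angstrom) in `attr(, "rmsd")`.
#' @export
superpose <- function(traj, structure, selection) {
  sel <- resolve_residues(structure, selection)
  sel <- which(sel & structure$atoms$is_heavy)
  if (length(sel) < 3L)
    stop("superposition selection must resolve to at least 3 heavy atoms")
  ref <- coords(structure)[sel, , drop = FALSE]
  ref_c <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_c)
  rmsd <- numeric(n_frames(traj))
  frames <- vector("list", n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    mob_all <- traj$frames[[f]]
    mob <- mob_all[sel, , drop = FALSE]
    mob_c <- colMeans(mob)
    mob0 <- sweep(mob, 2, mob_c)
    s <- svd(crossprod(mob0, ref0))
    d <- sign(det(s$v %*% t(s$u)))
    rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    new_all <- sweep(mob_all, 2, mob_c) %*% t(rot)
    new_all <- sweep(new_all, 2, ref_c, `+`)
    frames[[f]] <- new_all
    fit <- sweep(mob0 %*% t(rot), 2, ref_c, `+`)
    rmsd[f] <- sqrt(mean(rowSums((fit - ref)^2)))
  }
  out <- trajectory(frames, frame_interval = traj$frame_interval,
                    replica_id = traj$replica_id)
  attr(out, "rmsd") <- rmsd
  out
}
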
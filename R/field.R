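## Intra-protein electric field along the channel ---------------------------

#' Electric field along a channel
#'
#' Direct (vacuum) Coulomb field at each channel coordinate from the
#' partial charges of non-solvent atoms: for each frame and grid point,
#' \deqn{E = k_e \sum_i q_i \hat{r}_i / r_i^2}
#' with \eqn{k_e = 1/(4\pi\epsilon_0) = 14.3996} V Angstrom / e, summing
#' over source atoms farther than `exclusion_radius` from the measurement
#' point (solvent molecules are always excluded). Sources inside the cutoff
#' are omitted to avoid near-singular contributions; the alternative
#' reading — keeping only sources within the cutoff — is available via
#' `exclusion_mode = "include_within"`. The reported magnitude is, by
#' default, the magnitude of the frame-averaged field vector;
#' `average = "magnitude"` averages per-frame magnitudes instead.
#'
#' Units: V/Angstrom; multiply by 100 for MV/cm.
#'
#' @param traj a `Trajectory`.
#' @param structure the matching `StructureModel` (charges, solvent flags).
#' @param path the `TunnelPath`.
#' @param exclusion_radius source cutoff around the measurement point,
#'   Angstrom. Default 2.
#' @param step channel-coordinate grid step, Angstrom. Default 1.
#' @param exclusion_mode `"exclude_within"` (default: sources closer than
#'   the cutoff are omitted) or `"include_within"` (only sources within the
#'   cutoff are kept).
#' @param average `"vector"` (default) or `"magnitude"`.
#' @return A [channel_profile()] with `field_vector` and `field_magnitude`.
#' @export
electric_field <- function(traj, structure, path, exclusion_radius = 2,
                           step = 1,
                           exclusion_mode = c("exclude_within",
                                              "include_within"),
                           average = c("vector", "magnitude")) {
  exclusion_mode <- match.arg(exclusion_mode)
  average <- match.arg(average)
  if (n_frames(traj) == 0L) stop("trajectory has zero frames")
  a <- structure$atoms
  src <- which(!a$is_solvent)
  q <- a$charge[src]
  if (all(q == 0)) {
    warning("all source charges are zero; field is zero everywhere")
  }
  rs <- resample_path(path, step)
  pts <- rs$points
  m <- nrow(pts)
  box <- structure$box
  ke <- .const$ke_VA_e
  acc_vec <- matrix(0, m, 3)
  acc_mag <- numeric(m)
  for (f in seq_len(n_frames(traj))) {
    sc <- traj$frames[[f]][src, , drop = FALSE]
    Ef <- matrix(0, m, 3)
    for (k in seq_len(m)) {
      disp <- cbind(pts[k, 1] - sc[, 1], pts[k, 2] - sc[, 2],
                    pts[k, 3] - sc[, 3])
      disp <- .min_image(disp, box)
      r2 <- rowSums(disp^2)
      keep <- if (exclusion_mode == "exclude_within")
        r2 > exclusion_radius^2 else r2 <= exclusion_radius^2 & r2 > 0
      if (!any(keep)) next
      r <- sqrt(r2[keep])
      Ef[k, ] <- ke * colSums(disp[keep, , drop = FALSE] *
                                (q[keep] / r^3))
    }
    acc_vec <- acc_vec + Ef
    acc_mag <- acc_mag + sqrt(rowSums(Ef^2))
  }
  nf <- n_frames(traj)
  fvec <- acc_vec / nf
  fmag <- if (average == "vector") sqrt(rowSums(fvec^2)) else acc_mag / nf
  channel_profile(coordinate = rs$R, field_vector = fvec,
                  field_magnitude = fmag, n_frames = nf,
                  replicas = traj$replica_id)
}

#' Convert a field from V/Angstrom to MV/cm
#'
#' 1 V/Angstrom = 100 MV/cm.
#'
#' @param x field values in V/Angstrom.
#' @return values in MV/cm.
#' @export
field_to_mv_cm <- function(x) x * 100
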